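# Adaptive MCMC engine for the mixed-effects location-scale model.
#
# Parameterization (centered):
#   y_n ~ Normal(mu_n, sigma_n^2)
#   mu_n    = x_n' beta + zl_n' b_{i(n)}
#   log sigma_n = w_n' eta + zs_n' v_{i(n)}
#   (b_i, v_i) ~ MVN(0, Sigma),  Sigma = diag(tau) Omega diag(tau)
#
# Updates: conjugate Gibbs for beta and b; adaptive random-walk Metropolis
# for eta, v, log tau and the correlation angles; plus an interweaved
# (ancillary) rescaling move for tau that steps through the non-centered
# parameterization and removes the usual funnel in the random-effect SDs.
# Adaptation runs during warmup only.

# spherical Cholesky parameterization of a correlation matrix:
# phi (unconstrained, length q(q-1)/2) -> angles in (0, pi) -> lower L
angles_to_chol <- function(phi, q) {
  L <- diag(q)
  if (q == 1L) return(L)
  th <- pi * stats::plogis(phi)
  k <- 0L
  for (i in 2:q) {
    prodsin <- 1
    for (j in 1:(i - 1)) {
      k <- k + 1L
      L[i, j] <- cos(th[k]) * prodsin
      prodsin <- prodsin * sin(th[k])
    }
    L[i, i] <- prodsin
  }
  L
}

phi_to_corr <- function(phi, q) {
  if (length(phi) == 0L) return(diag(q))  # correlations fixed at zero
  L <- angles_to_chol(phi, q)
  tcrossprod(L)
}

offdiag_lower <- function(M) M[lower.tri(M)]

# log |d vech(Omega) / d phi| by central differences; makes the implied
# correlation matrix uniform (LKJ eta = 1) when used as the log prior on phi
log_phi_jacobian <- function(phi, q, eps = 1e-6) {
  m <- length(phi)
  if (m == 0L) return(0)
  f0 <- offdiag_lower(phi_to_corr(phi, q))
  Jm <- matrix(0, m, m)
  for (k in seq_len(m)) {
    up <- phi; up[k] <- up[k] + eps
    Jm[, k] <- (offdiag_lower(phi_to_corr(up, q)) - f0) / eps
  }
  d <- determinant(Jm, logarithm = TRUE)
  if (d$sign == 0) -Inf else as.numeric(d$modulus)
}

log_prior_phi <- function(phi, q, lkj_eta = 1) {
  if (length(phi) == 0L) return(0)
  lj <- log_phi_jacobian(phi, q)
  if (!is.finite(lj)) return(-Inf)
  extra <- 0
  if (lkj_eta != 1) {
    d <- determinant(phi_to_corr(phi, q), logarithm = TRUE)
    if (d$sign <= 0) return(-Inf)
    extra <- (lkj_eta - 1) * as.numeric(d$modulus)
  }
  lj + extra
}

# half-Student-t log prior on tau, expressed in log tau (includes Jacobian)
log_prior_ltau <- function(ltau, df, scale) {
  tau <- exp(ltau)
  sum(stats::dt(tau / scale, df = df, log = TRUE) - log(scale) + log(2) + ltau)
}

# Find (fixed column j, RE column k, participant-level g) triples with
# M[, j] == g[pidx] * Z[, k]: along such directions the linear predictor is
# invariant under (coef_j += delta, re[, k] -= delta * g), and delta has a
# Gaussian full conditional (exact "translation" Gibbs update). These moves
# break the strong posterior correlation between intercept-like fixed
# effects and the corresponding random-effect means.
find_translation_pairs <- function(M, Z, pidx, J) {
  if (is.null(Z)) return(list())
  out <- list()
  for (j in seq_len(ncol(M))) {
    for (k in seq_len(ncol(Z))) {
      nz <- Z[, k] != 0
      if (any(M[!nz, j] != 0)) next
      ratio <- M[nz, j] / Z[nz, k]
      g <- rep(0, J)
      ok <- TRUE
      for (i in unique(pidx[nz])) {
        ri <- ratio[pidx[nz] == i]
        if (max(ri) - min(ri) > 1e-12) { ok <- FALSE; break }
        g[i] <- ri[1]
      }
      if (ok && any(g != 0)) out[[length(out) + 1L]] <- list(j = j, k = k, g = g)
    }
  }
  out
}

# covariance structure for the MVN level; `full = TRUE` adds the
# cross-block conditionals used by the b and v updates
sigma_struct <- function(ltau, phi, ql, qs, lkj_eta, full = TRUE) {
  q <- ql + qs
  tau <- exp(ltau)
  Omega <- phi_to_corr(phi, q)
  Sigma <- outer(tau, tau) * Omega
  U <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(U)) return(NULL)
  Sinv <- chol2inv(U)
  out <- list(Sigma = Sigma, Omega = Omega, U = U, Sinv = Sinv,
              logdet = 2 * sum(log(diag(U))))
  if (!full) return(out)
  bi <- seq_len(ql)
  si <- if (qs > 0) ql + seq_len(qs) else integer(0)
  if (ql > 0) {
    if (qs > 0) {
      Sww_inv <- solve(Sigma[si, si, drop = FALSE])
      out$Abw <- Sigma[bi, si, drop = FALSE] %*% Sww_inv
      Cb <- Sigma[bi, bi, drop = FALSE] - out$Abw %*% Sigma[si, bi, drop = FALSE]
    } else Cb <- Sigma[bi, bi, drop = FALSE]
    out$Cb <- Cb
    out$Cbinv <- solve(Cb)
  }
  if (qs > 0) {
    if (ql > 0) {
      Sbb_inv <- solve(Sigma[bi, bi, drop = FALSE])
      out$Awb <- Sigma[si, bi, drop = FALSE] %*% Sbb_inv
      Cw <- Sigma[si, si, drop = FALSE] - out$Awb %*% Sigma[bi, si, drop = FALSE]
    } else Cw <- Sigma[si, si, drop = FALSE]
    out$Cw <- Cw
    out$Cwinv <- solve(Cw)
  }
  out
}

# sum_i log MVN(r_i; 0, Sigma) given a sigma_struct
mvn_loglik_rows <- function(r, ss) {
  J <- nrow(r)
  quad <- sum((r %*% ss$Sinv) * r)
  -0.5 * (J * ss$logdet + quad) - 0.5 * J * ncol(r) * log(2 * pi)
}

# Gaussian data log-likelihood up to the constant
data_loglik <- function(y, mu, lsig) {
  -sum(lsig) - 0.5 * sum((y - mu)^2 * exp(-2 * lsig))
}

# One MCMC chain. Returns kept draws for reported parameters, running means
# of mu / log sigma / random effects, and thinned log-likelihood draws.
melsm_chain <- function(y, X, W, Zl, Zs, pidx, J, priors, control, chain_seed,
                        loglik_keep, re_keep) {
  with_seed(chain_seed, {
    n <- length(y)
    p <- ncol(X); ps <- ncol(W)
    ql <- if (is.null(Zl)) 0L else ncol(Zl)
    qs <- if (is.null(Zs)) 0L else ncol(Zs)
    q <- ql + qs
    est_cor <- control$cor_re && q > 1L
    m_ang <- if (est_cor) q * (q - 1L) / 2L else 0L
    iter <- control$iter; warmup <- control$warmup
    kept <- iter - warmup

    beta_prec <- 1 / priors$beta_sd^2
    eta_sd <- rep_len(priors$eta_sd, ps)

    # --- initial values (data-informed, chain-jittered) ---
    fit0 <- stats::lm.fit(X, y)
    beta <- fit0$coefficients + stats::rnorm(p, 0, 0.1)
    beta[is.na(beta)] <- 0
    res0 <- y - X %*% beta
    eta <- c(log(stats::sd(res0)), rep(0, ps - 1L)) + stats::rnorm(ps, 0, 0.05)
    b <- if (ql > 0) matrix(stats::rnorm(J * ql, 0, 0.1), J, ql) else NULL
    v <- if (qs > 0) matrix(stats::rnorm(J * qs, 0, 0.02), J, qs) else NULL
    ltau <- if (q > 0) {
      init <- c(rep(log(max(stats::sd(res0) / 2, 0.1)), ql), rep(log(0.2), qs))
      init + stats::rnorm(q, 0, 0.1)
    } else numeric(0)
    phi <- rep(0, m_ang)

    ss <- if (q > 0) sigma_struct(ltau, phi, ql, qs, priors$lkj_eta) else NULL
    lp_phi_cur <- if (est_cor) log_prior_phi(phi, q, priors$lkj_eta) else 0

    b_lin <- if (ql > 0) rowSums(Zl * b[pidx, , drop = FALSE]) else 0
    v_lin <- if (qs > 0) rowSums(Zs * v[pidx, , drop = FALSE]) else 0
    xb <- drop(X %*% beta)
    eta_lin <- drop(W %*% eta)
    mu <- xb + b_lin
    lsig <- eta_lin + v_lin

    # --- adaptation state ---
    step_eta <- 0.5 / sqrt(ps)
    eta_cov_chol <- diag(ps)
    eta_hist <- matrix(0, 0, ps)
    step_v <- rep(0.3, J)
    step_tau <- rep(0.3, q)
    step_phi <- 0.2
    step_iw <- rep(0.2, q)
    acc <- c(eta = 0, v = 0, tau = 0, phi = 0, iw = 0)

    # --- storage ---
    par_names <- c(paste0("loc_", colnames(X)), paste0("scl_", colnames(W)))
    if (ql > 0) par_names <- c(par_names, paste0("tau_loc_", colnames(Zl)))
    if (qs > 0) par_names <- c(par_names, paste0("tau_scl_", colnames(Zs)))
    if (est_cor) {
      re_names <- c(if (ql > 0) paste0("loc_", colnames(Zl)),
                    if (qs > 0) paste0("scl_", colnames(Zs)))
      cmb <- which(lower.tri(diag(q)), arr.ind = TRUE)
      par_names <- c(par_names,
                     paste0("cor_", re_names[cmb[, 2]], "__", re_names[cmb[, 1]]))
    }
    draws <- matrix(NA_real_, kept, length(par_names),
                    dimnames = list(NULL, par_names))
    mu_sum <- numeric(n); lsig_sum <- numeric(n)
    re_sum <- if (q > 0) matrix(0, J, q) else NULL
    loglik <- matrix(NA_real_, length(loglik_keep), n)
    ll_row <- 0L
    re_draws <- if (q > 0) array(NA_real_, c(length(re_keep), J, q)) else NULL
    re_row <- 0L

    lower_pairs <- if (ql > 0) {
      kk <- which(lower.tri(diag(ql), diag = TRUE), arr.ind = TRUE)
      kk[order(kk[, 1], kk[, 2]), , drop = FALSE]
    } else NULL

    for (t in seq_len(iter)) {
      adapting <- t <= warmup
      gam <- if (adapting) min(0.25, 2 / sqrt(t)) else 0
      siginv2 <- exp(-2 * lsig)

      ## beta | . (conjugate)
      Xw <- X * siginv2
      P <- crossprod(Xw, X)
      diag(P) <- diag(P) + beta_prec
      rhs <- crossprod(Xw, y - b_lin)
      U <- chol(P)
      mb <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
      beta <- drop(mb + backsolve(U, stats::rnorm(p)))
      xb <- drop(X %*% beta)
      mu <- xb + b_lin

      ## b_i | . (conjugate, vectorized for ql <= 2)
      if (ql > 0) {
        resf <- y - xb
        pm <- if (qs > 0) v %*% t(ss$Abw) else matrix(0, J, ql)
        Ci <- ss$Cbinv
        if (ql == 1L) {
          s11 <- rowsum(siginv2 * Zl[, 1]^2, pidx)[, 1] + Ci[1, 1]
          r1 <- rowsum(siginv2 * resf * Zl[, 1], pidx)[, 1] + Ci[1, 1] * pm[, 1]
          mpost <- r1 / s11
          b[, 1] <- mpost + stats::rnorm(J) / sqrt(s11)
        } else if (ql == 2L) {
          z1 <- Zl[, 1]; z2 <- Zl[, 2]
          s11 <- rowsum(siginv2 * z1 * z1, pidx)[, 1] + Ci[1, 1]
          s12 <- rowsum(siginv2 * z1 * z2, pidx)[, 1] + Ci[1, 2]
          s22 <- rowsum(siginv2 * z2 * z2, pidx)[, 1] + Ci[2, 2]
          r1 <- rowsum(siginv2 * resf * z1, pidx)[, 1] +
            Ci[1, 1] * pm[, 1] + Ci[1, 2] * pm[, 2]
          r2 <- rowsum(siginv2 * resf * z2, pidx)[, 1] +
            Ci[2, 1] * pm[, 1] + Ci[2, 2] * pm[, 2]
          l11 <- sqrt(s11); l21 <- s12 / l11; l22 <- sqrt(pmax(s22 - l21^2, 1e-12))
          a1 <- r1 / l11; a2 <- (r2 - l21 * a1) / l22
          m2 <- a2 / l22; m1 <- (a1 - l21 * m2) / l11
          zr1 <- stats::rnorm(J); zr2 <- stats::rnorm(J)
          d2 <- zr2 / l22; d1 <- (zr1 - l21 * d2) / l11
          b[, 1] <- m1 + d1; b[, 2] <- m2 + d2
        } else {
          rs_quad <- sapply(seq_len(nrow(lower_pairs)), function(k)
            rowsum(siginv2 * Zl[, lower_pairs[k, 1]] * Zl[, lower_pairs[k, 2]],
                   pidx)[, 1])
          rs_rhs <- sapply(seq_len(ql), function(k)
            rowsum(siginv2 * resf * Zl[, k], pidx)[, 1])
          for (i in seq_len(J)) {
            Pi <- matrix(0, ql, ql)
            for (k in seq_len(nrow(lower_pairs))) {
              Pi[lower_pairs[k, 1], lower_pairs[k, 2]] <- rs_quad[i, k]
              Pi[lower_pairs[k, 2], lower_pairs[k, 1]] <- rs_quad[i, k]
            }
            Pi <- Pi + Ci
            ri <- rs_rhs[i, ] + Ci %*% pm[i, ]
            Ui <- chol(Pi)
            mi <- backsolve(Ui, backsolve(Ui, ri, transpose = TRUE))
            b[i, ] <- mi + backsolve(Ui, stats::rnorm(ql))
          }
        }
        b_lin <- rowSums(Zl * b[pidx, , drop = FALSE])
        mu <- xb + b_lin
      }

      ## eta | . (joint adaptive RW Metropolis)
      res <- y - mu
      prop <- eta + step_eta * drop(eta_cov_chol %*% stats::rnorm(ps))
      lsig_prop <- drop(W %*% prop) + v_lin
      ll_cur <- -sum(lsig) - 0.5 * sum(res^2 * exp(-2 * lsig))
      ll_prop <- -sum(lsig_prop) - 0.5 * sum(res^2 * exp(-2 * lsig_prop))
      lr <- ll_prop - ll_cur - 0.5 * sum((prop / eta_sd)^2) +
        0.5 * sum((eta / eta_sd)^2)
      a_eta <- is.finite(lr) && log(stats::runif(1)) < lr
      if (a_eta) {
        eta <- prop; eta_lin <- drop(W %*% eta); lsig <- lsig_prop
      }
      if (adapting) {
        step_eta <- exp(log(step_eta) + gam * ((a_eta) - 0.234))
        eta_hist <- rbind(eta_hist, eta)
        if (t >= 100 && t %% 50 == 0 && ps > 1) {
          cv <- stats::cov(eta_hist[max(1, nrow(eta_hist) - 500):nrow(eta_hist), ,
                                    drop = FALSE])
          ch <- tryCatch(chol(cv + diag(1e-8, ps)), error = function(e) NULL)
          if (!is.null(ch)) eta_cov_chol <- t(ch)
        }
      } else acc["eta"] <- acc["eta"] + a_eta

      ## v_i | . (per-participant RW Metropolis, vectorized)
      if (qs > 0) {
        res <- y - mu
        # proposal scaled per column by the current prior SD so that small
        # variance components (e.g. scale event slopes) still move
        col_sc <- pmax(exp(ltau[ql + seq_len(qs)]), 1e-3)
        prop_v <- v + step_v * sweep(matrix(stats::rnorm(J * qs), J, qs),
                                     2, col_sc, `*`)
        v_lin_prop <- rowSums(Zs * prop_v[pidx, , drop = FALSE])
        lsig_prop <- eta_lin + v_lin_prop
        llo_cur <- -lsig - 0.5 * res^2 * exp(-2 * lsig)
        llo_prop <- -lsig_prop - 0.5 * res^2 * exp(-2 * lsig_prop)
        dll <- rowsum(llo_prop - llo_cur, pidx)[, 1]
        pmv <- if (ql > 0) b %*% t(ss$Awb) else matrix(0, J, qs)
        dcur <- v - pmv; dprop <- prop_v - pmv
        qcur <- rowSums((dcur %*% ss$Cwinv) * dcur)
        qprop <- rowSums((dprop %*% ss$Cwinv) * dprop)
        lr_v <- dll - 0.5 * (qprop - qcur)
        a_v <- log(stats::runif(J)) < lr_v
        a_v[!is.finite(lr_v)] <- FALSE
        if (any(a_v)) {
          v[a_v, ] <- prop_v[a_v, , drop = FALSE]
          v_lin <- ifelse(a_v[pidx], v_lin_prop, v_lin)
          lsig <- eta_lin + v_lin
        }
        if (adapting) {
          step_v <- exp(log(step_v) + gam * (as.numeric(a_v) - 0.35))
          step_v <- pmin(pmax(step_v, 1e-3), 5)
        } else acc["v"] <- acc["v"] + mean(a_v)
      }

      ## tau, Omega | random effects (elementwise Metropolis on the MVN level,
      ## repeated a few times per iteration: these moves are O(J q^2))
      if (q > 0) {
        r_all <- cbind(b, v)
        ssc <- ss  # core fields are valid for the MVN evaluations
        for (rep_i in seq_len(control$n_vc_reps)) {
          lp_cur <- mvn_loglik_rows(r_all, ssc) +
            log_prior_ltau(ltau, priors$tau_df, priors$tau_scale)
          for (k in seq_len(q)) {
            prop_lt <- ltau
            prop_lt[k] <- prop_lt[k] + step_tau[k] * stats::rnorm(1)
            ss_prop <- sigma_struct(prop_lt, phi, ql, qs, priors$lkj_eta,
                                    full = FALSE)
            a_tau <- FALSE
            if (!is.null(ss_prop)) {
              lp_prop <- mvn_loglik_rows(r_all, ss_prop) +
                log_prior_ltau(prop_lt, priors$tau_df, priors$tau_scale)
              lr <- lp_prop - lp_cur
              a_tau <- is.finite(lr) && log(stats::runif(1)) < lr
            }
            if (a_tau) {
              ltau <- prop_lt; ssc <- ss_prop; lp_cur <- lp_prop
            }
            if (adapting)
              step_tau[k] <- exp(log(step_tau[k]) + gam * (a_tau - 0.44))
            else acc["tau"] <- acc["tau"] + a_tau / (q * control$n_vc_reps)
          }
          if (est_cor) {
            prop_phi <- phi + step_phi * stats::rnorm(m_ang)
            ss_prop <- sigma_struct(ltau, prop_phi, ql, qs, priors$lkj_eta,
                                    full = FALSE)
            a_phi <- FALSE
            if (!is.null(ss_prop)) {
              lpp_prior_prop <- log_prior_phi(prop_phi, q, priors$lkj_eta)
              lr <- mvn_loglik_rows(r_all, ss_prop) + lpp_prior_prop -
                (mvn_loglik_rows(r_all, ssc) + lp_phi_cur)
              a_phi <- is.finite(lr) && log(stats::runif(1)) < lr
            }
            if (a_phi) { phi <- prop_phi; ssc <- ss_prop; lp_phi_cur <- lpp_prior_prop }
            if (adapting) step_phi <- exp(log(step_phi) + gam * (a_phi - 0.234))
            else acc["phi"] <- acc["phi"] + a_phi / control$n_vc_reps
          }
        }

        ## interweaved rescaling moves (non-centered tau steps, one SD at a
        ## time); the MVN and proposal-Jacobian terms cancel, leaving the
        ## data likelihood and the tau prior
        for (k in seq_len(q)) {
          d_lt <- step_iw[k] * stats::rnorm(1)
          prop_lt <- ltau
          prop_lt[k] <- prop_lt[k] + d_lt
          sc <- exp(d_lt)
          is_loc <- k <= ql
          if (is_loc) {
            contrib <- Zl[, k] * b[pidx, k]
            mu_new <- mu + (sc - 1) * contrib
            dll <- -0.5 * sum(((y - mu_new)^2 - (y - mu)^2) * exp(-2 * lsig))
          } else {
            ks <- k - ql
            contrib <- Zs[, ks] * v[pidx, ks]
            lsig_new <- lsig + (sc - 1) * contrib
            dll <- -sum(lsig_new - lsig) -
              0.5 * sum((y - mu)^2 * (exp(-2 * lsig_new) - exp(-2 * lsig)))
          }
          lr <- dll +
            log_prior_ltau(prop_lt, priors$tau_df, priors$tau_scale) -
            log_prior_ltau(ltau, priors$tau_df, priors$tau_scale)
          a_iw <- is.finite(lr) && log(stats::runif(1)) < lr
          if (a_iw) {
            ltau <- prop_lt
            if (is_loc) {
              b[, k] <- sc * b[, k]
              b_lin <- b_lin + (sc - 1) * contrib
              mu <- mu_new
            } else {
              v[, ks] <- sc * v[, ks]
              v_lin <- v_lin + (sc - 1) * contrib
              lsig <- lsig_new
            }
          }
          if (adapting) step_iw[k] <- exp(log(step_iw[k]) + gam * (a_iw - 0.44))
          else acc["iw"] <- acc["iw"] + a_iw / q
        }
        # refresh the full covariance caches once for the next iteration
        ss <- sigma_struct(ltau, phi, ql, qs, priors$lkj_eta)

        ## exact translation updates (likelihood-invariant Gibbs moves)
        for (tp in control$trans_loc) {
          K <- tp$j; Kr <- tp$k
          sg2 <- sum(tp$g^2)
          r_all <- cbind(b, v)
          A <- beta_prec + ss$Sinv[Kr, Kr] * sg2
          B <- -beta[K] * beta_prec + sum(tp$g * (r_all %*% ss$Sinv[, Kr]))
          delta <- stats::rnorm(1, B / A, 1 / sqrt(A))
          beta[K] <- beta[K] + delta
          b[, Kr] <- b[, Kr] - delta * tp$g
          xb <- xb + delta * X[, K]
          b_lin <- b_lin - delta * tp$g[pidx] * Zl[, Kr]
        }
        for (tp in control$trans_scl) {
          K <- tp$j; Kr <- ql + tp$k
          sg2 <- sum(tp$g^2)
          r_all <- cbind(b, v)
          A <- 1 / eta_sd[K]^2 + ss$Sinv[Kr, Kr] * sg2
          B <- -eta[K] / eta_sd[K]^2 + sum(tp$g * (r_all %*% ss$Sinv[, Kr]))
          delta <- stats::rnorm(1, B / A, 1 / sqrt(A))
          eta[K] <- eta[K] + delta
          v[, tp$k] <- v[, tp$k] - delta * tp$g
          eta_lin <- eta_lin + delta * W[, K]
          v_lin <- v_lin - delta * tp$g[pidx] * Zs[, tp$k]
        }
        if (length(control$trans_loc)) mu <- xb + b_lin
        if (length(control$trans_scl)) lsig <- eta_lin + v_lin
      }

      ## record
      if (t > warmup) {
        k <- t - warmup
        row <- c(beta, eta)
        if (q > 0) row <- c(row, exp(ltau))
        if (est_cor) row <- c(row, offdiag_lower(ss$Omega))
        draws[k, ] <- row
        mu_sum <- mu_sum + mu
        lsig_sum <- lsig_sum + lsig
        if (q > 0) re_sum <- re_sum + cbind(b, v)
        if (ll_row < length(loglik_keep) && k == loglik_keep[ll_row + 1L]) {
          ll_row <- ll_row + 1L
          loglik[ll_row, ] <- stats::dnorm(y, mu, exp(lsig), log = TRUE)
        }
        if (q > 0 && re_row < length(re_keep) && k == re_keep[re_row + 1L]) {
          re_row <- re_row + 1L
          re_draws[re_row, , ] <- cbind(b, v)
        }
      }
    }

    list(draws = draws,
         mu_mean = mu_sum / kept,
         lsig_mean = lsig_sum / kept,
         re_mean = if (q > 0) re_sum / kept else NULL,
         loglik = loglik,
         re_draws = re_draws,
         accept = acc / max(kept, 1))
  })
}
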