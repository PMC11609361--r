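# Convergence diagnostics: rank-normalized split R-hat and bulk effective
# sample size, computed per parameter over an iterations x chains matrix.

rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

split_chains <- function(mat) {
  n <- nrow(mat)
  h <- floor(n / 2)
  cbind(mat[seq_len(h), , drop = FALSE],
        mat[seq.int(n - h + 1, n), , drop = FALSE])
}

#' Split R-hat for one parameter
#' @param mat iterations x chains matrix of draws.
#' @return Rank-normalized split R-hat (scalar; `NA` for constant draws).
#' @export
rhat <- function(mat) {
  mat <- as.matrix(mat)
  if (stats::sd(mat) == 0 || nrow(mat) < 4) return(NA_real_)
  z <- matrix(rank_normalize(as.vector(mat)), nrow(mat), ncol(mat))
  z <- split_chains(z)
  n <- nrow(z); m <- ncol(z)
  means <- colMeans(z)
  vars <- apply(z, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bulk effective sample size for one parameter
#' @inheritParams rhat
#' @return Bulk ESS (scalar; `NA` for constant draws).
#' @export
ess_bulk <- function(mat) {
  mat <- as.matrix(mat)
  if (stats::sd(mat) == 0 || nrow(mat) < 4) return(NA_real_)
  z <- matrix(rank_normalize(as.vector(mat)), nrow(mat), ncol(mat))
  z <- split_chains(z)
  n <- nrow(z); m <- ncol(z)
  # per-chain autocovariances
  acov <- apply(z, 2, function(x)
    stats::acf(x, lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1])
  chain_var <- acov[1, ] * n / (n - 1)
  mean_var <- mean(chain_var)
  var_plus <- mean_var * (n - 1) / n + stats::var(colMeans(z))
  if (var_plus == 0) return(NA_real_)
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # Geyer initial positive monotone sequence over lag pairs
  max_t <- 1
  tsum <- 0
  prev <- Inf
  t <- 1
  while (t + 1 < length(rho)) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair <= 0) break
    pair <- min(pair, prev)
    prev <- pair
    tsum <- tsum + pair
    t <- t + 2
  }
  tau <- 1 + 2 * rho[1] + 2 * tsum - 2  # rho[1] is lag 0 == 1
  tau <- max(tau, 1 / log10(n * m + 1))
  min(n * m / tau, n * m * log10(n * m))
}

# diagnostics for an iterations x chains x params array
melsm_diagnostics <- function(arr) {
  pn <- dimnames(arr)[[3]]
  r <- vapply(seq_along(pn), function(k) rhat(arr[, , k]), numeric(1))
  e <- vapply(seq_along(pn), function(k) ess_bulk(arr[, , k]), numeric(1))
  data.frame(parameter = pn, rhat = r, ess_bulk = e, row.names = NULL)
}
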