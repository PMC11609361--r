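# Time-window mean-amplitude scoring windows and channels per component.
mmn_d:
  window_start_ms: 265
  window_end_ms: 315
  channel: Fz
mmn_f:
  window_start_ms: 175
  window_end_ms: 225
  channel: Fz
p3a:
  window_start_ms: 250
  window_end_ms: 450
  channel: Cz
p3b:
  window_start_ms: 300
  window_end_ms: 500
  channel: Pz
ern:
  window_start_ms: 0
  window_end_ms: 100
  channel: FCz
rewp:
  window_start_ms: 250
  window_end_ms: 350
  channel: FCz
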