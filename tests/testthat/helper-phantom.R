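# Small phantom configuration for fast tests: same structure as the default
# study conditions, reduced grid. Noise, jitter and drift are inherited from
# the defaults unless a test overrides them.

small_spec <- function(...) {
  args <- utils::modifyList(
    list(dim = c(32, 32, 6), spacing = c(1, 1, 3),
         wg_semiaxes = c(11, 9, 7), tumor_offset = c(0, 4, 0),
         tumor_radius = 3),
    list(...))
  do.call(phantom_spec, args)
}

# Build an acquisition series from a closed-form signal function of the axis
# value (constant over the volume), on a small grid.
signal_series <- function(fun, axis_values, kind, d = c(4, 4, 2), tr = NULL) {
  vols <- lapply(axis_values, function(a) {
    image_volume(array(fun(a), d))
  })
  acquisition_series(vols, kind, axis_values, repetition_time = tr)
}

spgr_signal <- function(alpha_deg, m0, t1, tr, kappa = 1) {
  a <- kappa * alpha_deg * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}
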