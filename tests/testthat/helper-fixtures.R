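# Shared fixtures: small regular-grid setups keep the unit tests fast;
# the staggered full layout is exercised where the staggering matters.

small_geometry <- function(n = 9L) build_grid_geometry(n, n, 1)

small_grid <- function(n = 9L) {
  h <- n %/% 2L
  grid_spec(1, 1, c(-h, h), c(-h, h))
}

# a locked-plan session on a small regular grid, anchors at +/- 3 and
# Greer scans over the full extent
small_session <- function(plan = "2dbp_locked", n = 9L,
                          model = profile_model("bowl"),
                          spread = 0.03, noise = 0,
                          overrides = list(), seed = 1L) {
  h <- n %/% 2L
  geometry <- small_geometry(n)
  grid <- small_grid(n)
  truth <- sample_sensitivities(geometry, spread, seed = seed)
  ses <- generate_session(plan, model, truth, geometry, grid,
                          noise_sd_rel = noise,
                          perturb_overrides = overrides, seed = seed,
                          anchors_lat = c(-3L, 3L), anchors_lng = c(-3L, 3L),
                          scan_lat = c(-h, h), scan_lng = c(-h, h))
  ses
}

# ground-truth normalized profile evaluated on the session's grid
truth_on_grid <- function(session) {
  grid <- session$grid
  xs <- grid$x_range[1L]:grid$x_range[2L]
  ys <- grid$y_range[1L]:grid$y_range[2L]
  model <- session$truth$model
  vals <- outer(ys * grid$step_y_cm, xs * grid$step_x_cm,
                function(y, x) evaluate_profile(model, x, y))
  vals / vals[match(0L, ys), match(0L, xs)]
}

# ground-truth sensitivities normalized at the origin detector
truth_sens_normalized <- function(session) {
  o <- session$geometry$origin_index
  v <- session$truth$sensitivities$values
  v / v[o[1L], o[2L]]
}
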