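test_that("ratio chains recover a hand-built row profile independent of sensitivities", {
  # truth on indices -3..2 so the shifted row is defined on -2..2
  r_true <- c(1.2, 1.10, 1.03, 1.00, 1.03, 1.10)
  idx_true <- -3:2
  idx <- -2:2
  set.seed(42)
  for (trial in 1:5) {
    s <- exp(rnorm(5, 0, 0.05))
    mc <- r_true[match(idx, idx_true)] * s
    mlat <- r_true[match(idx - 1L, idx_true)] * s
    prof <- lateral_row_profile(mc, mlat, idx)
    expect_equal(prof$values, c(1.10, 1.03, 1.00, 1.03, 1.10),
                 tolerance = 1e-12)
  }
  # identical rows (flat truth) give all ones
  flat <- lateral_row_profile(rep(2, 5), rep(2, 5), idx)
  expect_identical(flat$values[3], 1)
  expect_equal(flat$values, rep(1, 5), tolerance = 1e-15)
})

test_that("chains satisfy the general two-point telescoping relation", {
  # oracle: direct product between two arbitrary indices, written
  # independently of the chain implementation
  oracle_ratio <- function(mlat, mc, idx, x1, x2) {
    stopifnot(x1 < x2)
    prod(vapply(seq_len(x2 - x1), function(i)
      mlat[match(x1 + i, idx)] / mc[match(x1 + i, idx)], 0))
  }
  set.seed(1)
  for (trial in 1:200) {
    n <- sample(5:9, 1)
    half <- n %/% 2
    idx <- (-half):(n - half - 1L)
    mc <- exp(rnorm(n, 0, 0.2))
    mlat <- exp(rnorm(n, 0, 0.2))
    prof <- lateral_row_profile(mc, mlat, idx)
    pairs <- utils::combn(idx, 2)
    for (k in seq_len(ncol(pairs))) {
      x1 <- pairs[1, k]; x2 <- pairs[2, k]
      expect_equal(prof$values[match(x1, idx)] / prof$values[match(x2, idx)],
                   oracle_ratio(mlat, mc, idx, x1, x2), tolerance = 1e-10)
    }
  }
})

test_that("masked readings truncate a chain; nonpositive readings are errors", {
  idx <- -3:3
  mc <- rep(1, 7); mlat <- rep(1, 7)
  mc[match(2L, idx)] <- NA
  prof <- lateral_row_profile(mc, mlat, idx)
  expect_true(all(is.na(prof$values[idx >= 2])))
  expect_true(all(!is.na(prof$values[idx < 2])))
  mc2 <- rep(1, 7); mc2[match(1L, idx)] <- 0
  expect_error(lateral_row_profile(mc2, mlat, idx), "grid index 1")
})

test_that("reconstruction is exact on noiseless sessions and blind to sensitivities", {
  ses <- small_session("2dbp_unlocked", spread = 0.05, seed = 2)
  recon <- reconstruct_2dbp(ses)
  truth <- truth_on_grid(ses)
  expect_lt(max(abs(recon$values / truth - 1), na.rm = TRUE), 1e-12)
  expect_identical(recon$values[recon$y_index == 0, recon$x_index == 0], 1)
  # a different sensitivity map leaves the reconstruction unchanged
  ses2 <- small_session("2dbp_unlocked", spread = 0.05, seed = 77)
  recon2 <- reconstruct_2dbp(ses2)
  expect_equal(recon2$values, recon$values, tolerance = 1e-12)
  # flat truth reconstructs to all ones
  ses_flat <- small_session("2dbp_unlocked", model = profile_model("flat"),
                            seed = 3)
  rf <- reconstruct_2dbp(ses_flat)
  expect_equal(rf$values, matrix(1, nrow(rf$values), ncol(rf$values)),
               tolerance = 1e-12)
})

test_that("2D composition reweighs rows by the central longitudinal profile", {
  # separable truth f(x) g(y): closed form by substitution
  f <- function(x) 1 + 0.002 * x^2
  g <- function(y) 1 + 0.001 * y^2 + 0.01 * y
  model <- profile_model("custom", fun = function(x, y) f(x) * g(y))
  ses <- small_session("2dbp_unlocked", model = model, seed = 5)
  recon <- reconstruct_2dbp(ses)
  xs <- recon$x_index; ys <- recon$y_index
  expected <- outer(ys, xs, function(Y, X) f(X) / f(0) * g(Y) / g(0))
  expect_equal(recon$values, expected, tolerance = 1e-12)
  # all-ones inputs compose to all ones
  rows <- lapply(-2:2, function(y)
    normalized_profile_1d("lateral", -2:2, rep(1, 5), at = y))
  centre <- normalized_profile_1d("longitudinal", -2:2, rep(1, 5))
  comp <- compose_2d(rows, centre)
  expect_equal(comp$values, matrix(1, 5, 5))
  # a missing longitudinal value is an error naming the row
  centre_short <- normalized_profile_1d("longitudinal", -1:1, rep(1, 3))
  expect_error(compose_2d(rows, centre_short), "Y = -2")
})

test_that("session role bookkeeping is strict", {
  ses <- small_session("2dbp_unlocked", seed = 1)
  ses$measurements$mlat <- NULL
  expect_error(reconstruct_2dbp(ses), "missing the 'mlat'")
  ses2 <- small_session("2dbp_unlocked", seed = 1)
  ses2$measurements$extra <- ses2$measurements$mc
  expect_error(reconstruct_2dbp(ses2), "expected one")
  ses3 <- small_session("2dbp_unlocked", seed = 1)
  ses3$measurements$mlat$shift_steps <- c(-2L, 0L)
  expect_error(reconstruct_2dbp(ses3), "shifted \\(-1, 0\\)")
})

test_that("the noniterative scan method agrees with the iterative one when nothing is wrong", {
  ses_g <- small_session("greer", spread = 0.04, seed = 6)
  ses_i <- small_session("2dbp_unlocked", spread = 0.04, seed = 6)
  rg <- reconstruct_greer(ses_g)
  ri <- reconstruct_2dbp(ses_i)
  ix <- match(rg$x_index, ri$x_index); iy <- match(rg$y_index, ri$y_index)
  expect_lt(max(abs(rg$values / ri$values[iy, ix] - 1), na.rm = TRUE), 1e-12)
  # and both equal the simulator's ground truth
  truth <- truth_on_grid(ses_g)
  expect_lt(max(abs(rg$values / truth - 1), na.rm = TRUE), 1e-12)
})

test_that("local errors stay local in the scan method instead of propagating", {
  k <- 1.004
  ses <- small_session("greer", seed = 8,
                       overrides = list(
                         `scan_lat_+2` = perturbation_spec(output_scale = 1.004)))
  clean <- small_session("greer", seed = 8)
  rp <- reconstruct_greer(ses)
  rc <- reconstruct_greer(clean)
  ratio <- rp$values / rc$values
  hit <- rp$x_index == 2L
  expect_equal(unique(round(ratio[, hit], 12)), round(1 / k, 12))
  expect_lt(max(abs(ratio[, !hit] - 1)), 1e-12)
  # by contrast the iterative chain spreads the same error over a side
  ses_i <- small_session("2dbp_unlocked", seed = 8,
                         overrides = list(
                           mlat = perturbation_spec(output_scale = 1.004)))
  clean_i <- small_session("2dbp_unlocked", seed = 8)
  rpi <- reconstruct_2dbp(ses_i)
  rci <- reconstruct_2dbp(clean_i)
  ratio_i <- rpi$values / rci$values
  expect_gt(sum(abs(ratio_i - 1) > 1e-6), sum(hit) * length(rp$y_index))
})

test_that("the scan method validates its scan set", {
  ses <- small_session("2dbp_unlocked", seed = 1)
  expect_error(reconstruct_greer(ses), "no 'scan_lat'")
  ses_g <- small_session("greer", seed = 1)
  ses_g$measurements$`scan_lat_+1` <- NULL
  expect_error(reconstruct_greer(ses_g), "regular sequence")
})
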