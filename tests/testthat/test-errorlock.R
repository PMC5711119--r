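test_that("propagation factors compound geometrically and grow with chain length", {
  expect_identical(propagation_factor(0.02, 0), 1)
  expect_equal(propagation_factor(0.001, 3), 1.001^3)
  expect_error(propagation_factor(-1.5, 4), "positive")
  for (e in c(-0.01, -1e-4, 1e-4, 0.01)) {
    f <- abs(propagation_factor(e, 0:20) - 1)
    expect_true(all(diff(f) >= 0))
  }
})

test_that("the two-sided error model has the documented sign semantics", {
  idx <- -5:5
  unit <- normalized_profile_1d("lateral", idx, rep(1, 11))
  expect_equal(apply_propagation_error(unit, 0, 0)$values, rep(1, 11))
  # output error alone tilts: negative side up, positive side down
  tilt <- apply_propagation_error(unit, 1e-3, 0)
  expect_true(all(tilt$values[idx < 0] > 1))
  expect_true(all(tilt$values[idx > 0] < 1))
  # positioning error alone flattens both sides the same way
  flat <- apply_propagation_error(unit, 0, 1e-3)
  expect_true(all(flat$values[idx != 0] < 1))
  # the flattening is symmetric to first order in e2
  expect_equal(flat$values[idx == -3], flat$values[idx == 3],
               tolerance = 1e-5)
  # e1 = e2 cancels on the negative side only
  canc <- apply_propagation_error(unit, 5e-4, 5e-4)
  expect_equal(canc$values[idx < 0], rep(1, 5), tolerance = 1e-15)
  expect_true(all(canc$values[idx > 0] < 1))
  # the centre is never touched
  expect_identical(canc$values[idx == 0], 1)
})

test_that("apply -> solve recovers any injected error pair exactly", {
  idx <- -16:16
  bowl <- profile_model("bowl")
  base <- evaluate_profile(bowl, idx, 0)
  prof <- normalized_profile_1d("lateral", idx, base / base[idx == 0])
  a <- -11L; c <- 11L
  anchors <- c(prof$values[idx == a], prof$values[idx == c])
  set.seed(3)
  for (trial in 1:50) {
    e1 <- runif(1, -2e-3, 2e-3)
    e2 <- runif(1, -2e-3, 2e-3)
    distorted <- apply_propagation_error(prof, e1, e2)
    est <- solve_errors(distorted, anchors, a, c)
    expect_lt(abs(est$e1 - e1), 1e-10)
    expect_lt(abs(est$e2 - e2), 1e-10)
    # correction is the exact inverse
    fixed <- correct_profile(distorted, est)
    expect_equal(fixed$values, prof$values, tolerance = 1e-12)
  }
  # identical profile and anchors solve to (0, 0)
  est0 <- solve_errors(prof, anchors, a, c)
  expect_equal(est0$e1, 0, tolerance = 1e-15)
  expect_equal(est0$e2, 0, tolerance = 1e-15)
})

test_that("the solve splits reference edge deviations into the expected components", {
  # reconstructed profile 0.30% low at 16 steps on one side and 1.45%
  # low (anchor/reconstructed = 1.0145) at 16 steps on the other
  idx <- c(-16L, 0L, 16L)
  recon <- normalized_profile_1d("lateral", idx, c(0.9970, 1, 1 / 1.0145))
  est <- solve_errors(recon, c(1, 1), -16L, 16L)
  expect_equal(round(est$e1_pct, 3), 0.036)
  expect_equal(round(est$e2_pct, 3), 0.054)
})

test_that("triad measurements yield exact relative sensitivities and anchors", {
  ses <- small_session("2dbp_locked", spread = 0.05, seed = 13)
  g <- ses$geometry; grid <- ses$grid
  triad <- beamcal:::session_triad(ses, "lateral")
  rel <- triad_relative_sensitivities(triad, g, grid)
  s <- ses$truth$sensitivities$values
  map <- beamcal:::grid_detector_index(g, grid)
  xs <- grid$x_range[1]:grid$x_range[2]
  pick <- function(x_pos) {
    ix <- match(x_pos, xs)
    s[cbind(map$row[, ix], map$col[, ix])]
  }
  expect_equal(rel$s_a, pick(-3L) / pick(0L), tolerance = 1e-12)
  expect_equal(rel$s_c, pick(3L) / pick(0L), tolerance = 1e-12)
  # anchors equal the true normalized profile at A and C
  anch <- anchor_points(ses$measurements$mc, rel, triad, g, grid)
  truth <- truth_on_grid(ses)
  ys <- grid$y_range[1]:grid$y_range[2]
  expect_equal(anch$r_a, truth[, match(-3L, xs)] / truth[, match(0L, xs)],
               tolerance = 1e-12)
  expect_equal(anch$r_c, truth[, match(3L, xs)] / truth[, match(0L, xs)],
               tolerance = 1e-12)
  # with unit relative sensitivities the anchors are the raw ratios
  rel1 <- rel; rel1$s_a[] <- 1; rel1$s_c[] <- 1
  anch1 <- anchor_points(ses$measurements$mc, rel1, triad, g, grid)
  gmc <- measurement_grid(ses$measurements$mc, g, grid)$values
  expect_equal(anch1$r_a, gmc[, match(-3L, xs)] / gmc[, match(0L, xs)],
               tolerance = 1e-15)
})

test_that("output drift on one triad exposure scales that anchor's ratios (documented bias mode)", {
  k <- 1.003
  ses <- small_session("2dbp_locked", spread = 0.05, seed = 13,
                       overrides = list(
                         lock_lat_A = perturbation_spec(output_scale = k)))
  clean <- small_session("2dbp_locked", spread = 0.05, seed = 13)
  g <- ses$geometry; grid <- ses$grid
  rel_p <- triad_relative_sensitivities(beamcal:::session_triad(ses, "lateral"),
                                        g, grid)
  rel_c <- triad_relative_sensitivities(beamcal:::session_triad(clean, "lateral"),
                                        g, grid)
  expect_equal(rel_p$s_a, rel_c$s_a * k, tolerance = 1e-12)
  expect_equal(rel_p$s_c, rel_c$s_c, tolerance = 1e-15)
})

test_that("a session-wide lock removes a model-conforming output drift exactly", {
  # drift on the shifted lateral measurement is exactly the E1 model, so
  # the locked reconstruction must recover the truth to machine precision
  e <- 8e-4
  ses <- small_session("2dbp_locked", spread = 0.04, seed = 17,
                       overrides = list(
                         mlat = perturbation_spec(output_scale = 1 + e)))
  recon <- reconstruct_2dbp(ses)
  est <- estimate_session_errors(ses, recon)
  expect_lt(abs(est$lateral$e1 - e), 1e-10)
  expect_lt(abs(est$lateral$e2 - 0), 1e-10)
  expect_lt(abs(est$longitudinal$e1), 1e-10)
  locked <- correct_reconstruction(recon, est)
  truth <- truth_on_grid(ses)
  expect_lt(max(abs(locked$values / truth - 1), na.rm = TRUE), 1e-10)
})

test_that("a full-span ratio product is blind to pure positioning error", {
  # the rotation-based commercial scheme estimates errors from products
  # over the whole detector span; a pure positioning error cancels out
  # of that product while still distorting the chain ends
  ses_err <- small_session("2dbp_unlocked", n = 17L, seed = 21,
                           overrides = list(
                             mlat = perturbation_spec(position_error_cm = c(0.5, 0))))
  ses_ok <- small_session("2dbp_unlocked", n = 17L, seed = 21)
  grid <- ses_ok$grid
  row0 <- function(ses, role) {
    gm <- measurement_grid(ses$measurements[[role]], ses$geometry, grid)
    gm$values[gm$y_index == 0, ]
  }
  span_log_product <- function(ses) {
    sum(log(row0(ses, "mlat")[-1] / row0(ses, "mc")[-1]))
  }
  full_span_change <- abs(span_log_product(ses_err) - span_log_product(ses_ok))
  edge_distortion <- max(abs(log(
    reconstruct_2dbp(ses_err)$values / reconstruct_2dbp(ses_ok)$values)),
    na.rm = TRUE)
  expect_lt(full_span_change, 0.15 * edge_distortion)
  expect_gt(edge_distortion, 5e-3)
})

test_that("locking reduces the worst-case distortion from a 5 mm positioning error at least fivefold", {
  st <- run_robustness_study(seed = 5, noise_sd_rel = 0)
  tb <- st$table
  p <- tb[tb$condition != "normal", ]
  mx <- function(m) p$max_abs_pct[p$method == m]
  expect_gte(mx("2dbp_unlocked") / mx("2dbp"), 5)
  # and the locked estimate flags the positioning error, not the output
  e <- st$errors$perturbed$longitudinal
  expect_gt(e$e2_pct, 5 * abs(e$e1_pct))
})

test_that("error-estimate invariants reject impossible values", {
  expect_error(error_estimate("lateral", -0.6, 0.5), "positive")
  idx <- c(-4L, 0L, 4L)
  p <- normalized_profile_1d("lateral", idx, c(1.01, 1, 0.99))
  expect_error(solve_errors(p, c(1, 1), 2L, 4L), "A < 0 < C")
  expect_error(solve_errors(p, c(-1, 1), -4L, 4L), "positive")
})
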