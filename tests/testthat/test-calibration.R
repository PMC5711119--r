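test_that("bilinear interpolation is exact at nodes and for bilinear surfaces", {
  g <- build_mapcheck2_geometry()
  grid <- default_grid(g)
  xs <- grid$x_range[1]:grid$x_range[2]
  ys <- grid$y_range[1]:grid$y_range[2]
  # bilinear truth is reproduced exactly everywhere, including the
  # staggered (off-grid) detectors
  f <- function(x, y) 1 + 0.003 * x + 0.002 * y + 1e-4 * x * y
  prof <- structure(list(x_index = xs, y_index = ys,
                         values = outer(ys, xs, function(Y, X) f(X, Y))),
                    class = "normalized_profile_2d")
  res <- interpolate_to_detectors(prof, g, grid)
  pos <- detector_positions(g)
  got <- res$rnor[cbind(pos$row, pos$col)]
  want <- f(pos$x, pos$y)
  keep <- !is.na(got)
  expect_equal(got[keep], want[keep], tolerance = 1e-12)
  # a constant surface stays constant
  prof_c <- prof; prof_c$values[] <- 2.5
  res_c <- interpolate_to_detectors(prof_c, g, grid)
  expect_equal(unique(round(res_c$rnor[!is.na(res_c$rnor)], 12)), 2.5)
  # a fully defined surface covers every detector
  expect_equal(nrow(res$excluded), 0)
  # with the corner grid nodes undefined (as after a real reconstruction
  # on the corner-masked layout), staggered detectors adjacent to the
  # masked region are excluded with a reason rather than extrapolated
  prof_na <- prof
  prof_na$values[outer(ys, xs, function(Y, X) abs(X) + abs(Y) > 22)] <- NA
  res_na <- interpolate_to_detectors(prof_na, g, grid)
  expect_gt(nrow(res_na$excluded), 0)
  expect_true(all(res_na$excluded$reason == "undefined grid node"))
})

test_that("detectors outside the grid hull are flagged, not extrapolated", {
  g <- build_grid_geometry(9, 9, 1)
  prof <- structure(list(x_index = -2:2, y_index = -2:2,
                         values = matrix(1, 5, 5)),
                    class = "normalized_profile_2d")
  res <- interpolate_to_detectors(prof, g, grid_spec(1, 1, c(-2, 2), c(-2, 2)))
  expect_equal(nrow(res$excluded), 81 - 25)
  expect_true(all(res$excluded$reason == "outside grid hull"))
  expect_equal(sum(!is.na(res$rnor)), 25)
})

test_that("sensitivities are the normalized reading over the profile, unity at the origin", {
  g <- small_geometry()
  m <- matrix(runif(81, 0.9, 1.1), 9, 9)
  s_id <- compute_sensitivities(m, m, g)
  expect_equal(s_id$values, matrix(1, 9, 9))
  expect_error(compute_sensitivities(m, -m, g), "positive")
  expect_identical(s_id$values[g$origin_index[1], g$origin_index[2]], 1)
})

test_that("the noiseless pipeline recovers the simulated sensitivities", {
  g <- build_mapcheck2_geometry()
  grid <- default_grid(g)
  model <- profile_model("bowl")
  truth <- sample_sensitivities(g, 0.03, seed = 31)
  ses <- generate_session("2dbp_locked", model, truth, g, grid, seed = 31)
  cal <- calibrate_session(ses, "2dbp")
  o <- g$origin_index
  truth_nor <- truth$values / truth$values[o[1], o[2]]
  err <- abs(cal$sensitivities$values / truth_nor - 1)
  # exact on the reconstruction-grid detectors
  map <- beamcal:::grid_detector_index(g, grid)
  on_grid <- cbind(map$row[!is.na(map$row)], map$col[!is.na(map$col)])
  expect_lt(max(err[on_grid]), 1e-10)
  # bounded by bilinear interpolation error of the bowl elsewhere
  expect_lt(max(err, na.rm = TRUE), 1e-3)
})

test_that("calibration correction inverts the sensitivity factor", {
  ses <- small_session("2dbp_unlocked", spread = 0.05, seed = 41)
  cal <- calibrate_session(ses, "2dbp_unlocked")
  mc <- ses$measurements$mc
  corrected <- apply_calibration(mc, cal$sensitivities)
  # corrected readings are proportional to the true beam profile
  pos <- detector_positions(ses$geometry)
  truth <- evaluate_profile(ses$truth$model, pos$x, pos$y,
                            field = mc$field)
  ratio <- corrected$readings[cbind(pos$row, pos$col)] / truth
  expect_lt(max(abs(ratio / ratio[1] - 1)), 1e-10)
  # a unit map is the identity; applying twice is not
  unit <- cal$sensitivities; unit$values[] <- 1
  expect_equal(apply_calibration(mc, unit)$readings, mc$readings)
  twice <- apply_calibration(corrected, cal$sensitivities)
  expect_false(isTRUE(all.equal(twice$readings, corrected$readings)))
})

test_that("deviation statistics match a direct computation", {
  a <- matrix(c(1, 1.01, NA, 0.98), 2, 2)
  b <- matrix(1, 2, 2)
  st <- profile_deviation_stats(a, b)
  expect_equal(st$n, 3L)
  expect_equal(st$mean_abs_pct, mean(c(0, 1, 2)))
  expect_equal(st$max_abs_pct, 2)
  st0 <- profile_deviation_stats(b, b)
  expect_equal(st0$mean_abs_pct, 0)
  expect_equal(st0$sd_abs_pct, 0)
  # random field cross-check against the defining formula
  set.seed(9)
  a2 <- matrix(runif(100, 0.9, 1.1), 10, 10)
  b2 <- matrix(runif(100, 0.9, 1.1), 10, 10)
  st2 <- profile_deviation_stats(a2, b2)
  dev <- 100 * abs(a2 - b2) / b2
  expect_equal(st2$mean_abs_pct, mean(dev))
  expect_equal(st2$sd_abs_pct, sd(dev))
  expect_equal(sum(st2$histogram$count), 100L)
  expect_error(profile_deviation_stats(a, b, mask = matrix(FALSE, 2, 2)),
               "empty")
})

test_that("noise accumulates along chains: edge sensitivities vary more across repeats", {
  sd_rel <- 0.002
  n_rep <- 30L
  maps <- lapply(seq_len(n_rep), function(k) {
    ses <- small_session("2dbp_unlocked", n = 9L, spread = 0.02,
                         noise = sd_rel, seed = 100 + k)
    calibrate_session(ses, "2dbp_unlocked")$sensitivities$values
  })
  # the truth differs per seed, so compare each recovery to its own truth
  devs <- lapply(seq_len(n_rep), function(k) {
    ses <- small_session("2dbp_unlocked", n = 9L, spread = 0.02,
                         noise = sd_rel, seed = 100 + k)
    maps[[k]] / truth_sens_normalized(ses) - 1
  })
  arr <- simplify2array(devs)
  per_det_sd <- apply(arr, c(1, 2), sd)
  g <- small_geometry(9L)
  pos <- detector_positions(g)
  d <- abs(pos$x) + abs(pos$y)
  sds <- per_det_sd[cbind(pos$row, pos$col)]
  centre <- mean(sds[d <= 2 & d > 0])
  edge <- mean(sds[d >= 6])
  expect_gt(edge, centre)
  # magnitudes consistent with the noise level propagated through a
  # handful of readings per chain
  expect_gt(mean(sds[d > 0]), sd_rel)
  expect_lt(mean(sds[d > 0]), 8 * sd_rel)
})

test_that("under a 5 mm positioning error the methods order as designed", {
  st <- run_robustness_study(seed = 1)
  tb <- st$table
  pick <- function(cond, m, col) tb[[col]][tb$condition == cond &
                                             tb$method == m]
  pert <- unique(tb$condition[tb$condition != "normal"])
  # locking strictly improves on the unlocked chain, and the
  # noniterative reference is the accuracy floor
  expect_lt(pick(pert, "2dbp", "mean_abs_pct"),
            pick(pert, "2dbp_unlocked", "mean_abs_pct"))
  expect_lt(pick(pert, "2dbp", "max_abs_pct"),
            pick(pert, "2dbp_unlocked", "max_abs_pct"))
  expect_lt(pick(pert, "greer", "mean_abs_pct"),
            pick(pert, "2dbp", "mean_abs_pct"))
  # locked stays sub-percent on average; the unlocked chain does not
  expect_lt(pick(pert, "2dbp", "mean_abs_pct"), 1)
  expect_gt(pick(pert, "2dbp_unlocked", "mean_abs_pct"), 1)
  # under normal conditions all three agree at the few-tenths level
  for (m in c("2dbp", "2dbp_unlocked", "greer"))
    expect_lt(pick("normal", m, "mean_abs_pct"), 0.5)
})
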