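geom <- test_geom()
mats <- test_materials()
w100 <- mats$W100

test_that("traced rays classify as open, face-clipping or full-thickness", {
  s <- leaf_setting(6)
  pos <- seq(4.5, 6.6, by = 0.01)
  prof <- trace_profile(s, w100, geom, pos)
  expect_s3_class(prof, "dose_profile")
  # open field well inside the light edge
  expect_equal(prof$doses[pos <= 5], rep(1, sum(pos <= 5)))
  # monotone non-increasing across the edge
  expect_true(all(diff(prof$doses) <= 1e-12))
  # far beyond the planning position the full slant thickness attenuates
  x_far <- 9.3
  prof9 <- quiet_field(trace_profile(leaf_setting(9), w100, geom,
                                     seq(9.29, 9.37, by = 0.01)))
  t_far <- atan(x_far / geom$sad)
  expect_equal(prof9$doses[which.min(abs(prof9$positions - x_far))],
               exp(-w100$thickness / (w100$lambda * cos(t_far))),
               tolerance = 1e-12)
})

test_that("traced 50% crossing matches the analytic chord solve", {
  s <- quiet_setting(9)
  pos <- seq(8.95, 9.29, by = 0.001)
  m <- quiet_field(extract_edge_metrics(trace_profile(s, w100, geom, pos)))
  expect_lt(abs(m$x50 - quiet_field(solve_x_p(s, w100, geom, 0.5))), 1e-4)
})

test_that("grid refinement converges the extracted edge to the analytic value", {
  s <- leaf_setting(4)
  truth <- solve_x_p(s, w100, geom, 0.5)
  err <- vapply(c(0.01, 0.001), function(gr) {
    pos <- seq(3.9, 4.25, by = gr)
    abs(extract_edge_metrics(trace_profile(s, w100, geom, pos))$x50 - truth)
  }, numeric(1))
  expect_lt(err[2], err[1] + 1e-12)
  expect_lt(err[2], 1e-4)
})

test_that("edge metrics on an analytic ramp are exact", {
  a <- 2; w <- 0.4
  pos <- seq(1, 3.4, by = 0.01)
  dose <- pmin(1, pmax(0, 1 - (pos - a) / w))
  prof <- dose_profile(pos, dose)
  m <- extract_edge_metrics(prof)
  expect_equal(m$x50, a + w / 2, tolerance = 1e-9)
  expect_equal(m$x20, a + 0.8 * w, tolerance = 1e-9)
  expect_equal(m$x80, a + 0.2 * w, tolerance = 1e-9)
  expect_equal(m$penumbra_mm, 0.6 * w * 10, tolerance = 1e-9)
})

test_that("traced penumbra agrees with the closed-form model penumbra", {
  s <- leaf_setting(6)
  pos <- seq(5.9, 6.22, by = 0.001)
  m <- extract_edge_metrics(trace_profile(s, w100, geom, pos))
  expect_equal(m$penumbra_mm, model_penumbra(s, w100, geom), tolerance = 1e-3)
})

test_that("degenerate and ambiguous profiles are reported", {
  pos <- seq(0, 1, length.out = 20)
  expect_error(extract_edge_metrics(dose_profile(pos, rep(1, 20))),
               "edge not found")
  # a non-monotone wiggle crossing 50% three times: outermost edge + warning
  dose <- c(rep(1, 5), 0.4, 0.7, rep(c(0.3, 0.1), length.out = 13))
  expect_warning(m <- extract_edge_metrics(dose_profile(pos, dose)),
                 "outermost")
  expect_gt(m$x50, pos[6])
  expect_error(dose_profile(1:5, rep(1, 5)), "at least 8")
  expect_error(dose_profile(c(1:7, 7), rep(1, 8)), "strictly increasing")
})

test_that("H-D calibration interpolates knots exactly and stays monotone", {
  cal <- fit_calibration(c(5, 100, 200), c(0.1, 0.8, 1.2))
  expect_equal(apply_calibration(cal, 0.8), 100)
  expect_equal(apply_calibration(cal, c(0.1, 1.2)), c(5, 200))
  r <- seq(0.1, 1.2, by = 0.01)
  d <- apply_calibration(cal, r)
  expect_true(all(diff(d) >= 0))
  expect_true(all(d >= 5 & d <= 200))
  expect_error(apply_calibration(cal, 1.3), "outside")
  expect_error(fit_calibration(c(5, 100, 200), c(0.1, 0.8, 0.8)),
               "strictly increasing")
  expect_error(fit_calibration(c(5, 100), c(0.1, 0.8)), ">= 3")
})

test_that("calibration recovers a saturating generator curve within 2%", {
  doses <- c(5, 10, 15, 40, 60, 80, 100, 150, 200)
  resp <- -log(1 - doses / 250)  # dose = 250 (1 - e^{-r})
  cal <- fit_calibration(doses, resp)
  mid <- (resp[-1] + resp[-length(resp)]) / 2
  truth <- 250 * (1 - exp(-mid))
  expect_true(all(abs(apply_calibration(cal, mid) - truth) / truth < 0.02))
})

test_that("calibration is invariant under a redundant collinear knot", {
  doses <- c(10, 60, 110, 160)
  resp <- 0.2 + 0.004 * doses
  cal <- fit_calibration(doses, resp)
  cal2 <- fit_calibration(sort(c(doses, 135)), sort(c(resp, 0.2 + 0.004 * 135)))
  r <- seq(min(resp), max(resp), length.out = 41)
  expect_equal(apply_calibration(cal, r), apply_calibration(cal2, r),
               tolerance = 1e-10)
})

test_that("seeded fixtures are byte-reproducible and carry a faithful manifest", {
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  m1 <- generate_fixture_profiles(d1, seed = 1, n_cases = 3)
  m2 <- generate_fixture_profiles(d2, seed = 1, n_cases = 3)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # noiseless fixtures recover the generator truth
  for (cs in m1$cases) {
    prof <- read_dose_profile(file.path(d1, cs$file))
    m <- extract_edge_metrics(prof)
    expect_lt(abs(m$x50 - cs$truth$x50), 1e-4)
    expect_lt(abs(m$x20 - cs$truth$x20), 1e-4)
    expect_lt(abs(m$x80 - cs$truth$x80), 1e-4)
  }
  # a different seed yields different cases
  m3 <- generate_fixture_profiles(file.path(withr::local_tempdir(), "c"),
                                  seed = 2, n_cases = 3)
  expect_false(identical(
    vapply(m1$cases, `[[`, 0, "half_field"),
    vapply(m3$cases, `[[`, 0, "half_field")))
})
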