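# Ground-truth generator: block covariances, session simulation, cohorts.

test_that("block covariance reproduces planted structure exactly", {
  part <- partition(c("a", "a", "b", "b"))
  B <- make_block_covariance(4, part, within_r = 0.6, between_r = 0)
  expect_equal(B[1, 2], 0.6)
  expect_equal(B[1, 3], 0)
  expect_equal(diag(B), setNames(rep(1, 4), rownames(B)))
  expect_equal(make_block_covariance(4, part, 0, 0), diag(4),
               ignore_attr = TRUE)
  # equicorrelated determinant, checked against base det()
  E <- make_block_covariance(4, partition(rep("a", 4)), within_r = 0.3)
  expect_equal(det(E), (1 - 0.3)^3 * (1 + 3 * 0.3), tolerance = 1e-12)
})

test_that("non-positive-definite parameters are rejected naming the block", {
  part <- partition(rep(c("a", "b"), each = 4))
  expect_error(make_block_covariance(8, part, within_r = c(a = -0.5, b = 0.3)),
               "block 'a'")
  expect_error(make_block_covariance(8, part, within_r = 1.2), "in \\(-1, 1\\)")
})

test_that("sessions are reproducible and match the target covariance", {
  S <- diag(6)
  a <- simulate_session(S, 5000, tr = 2, seed = 5)
  b <- simulate_session(S, 5000, tr = 2, seed = 5)
  expect_identical(a$data, b$data)
  r <- cor(a$data)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
  expect_error(simulate_session(S, 1, tr = 2, seed = 1), "at least 2")
})

test_that("sample covariance converges to the generating covariance in T", {
  part <- partition(rep(c("a", "b"), each = 3))
  S <- make_block_covariance(6, part, within_r = 0.5, between_r = 0.1)
  fro <- vapply(c(1000, 10000, 100000), function(T) {
    ts <- simulate_session(S, T, tr = 2, seed = 31)
    norm(cov(ts$data) - S, "F")
  }, numeric(1))
  expect_true(all(diff(fro) < 0))
})

test_that("the global-signal component raises parcel-to-GS coupling", {
  S <- diag(8)
  quiet <- simulate_session(S, 2000, gs_amplitude = 0, tr = 2, seed = 21)
  loud <- simulate_session(S, 2000, gs_amplitude = 5, tr = 2, seed = 21)
  m0 <- amplitude_metrics(quiet)
  m5 <- amplitude_metrics(loud)
  expect_gt(mean(m5$parcel_gs_cor), mean(m0$parcel_gs_cor))
  expect_gt(m5$global_signal_sd, m0$global_signal_sd)
})

test_that("the AR(1) switch induces temporal autocorrelation at unit variance", {
  S <- diag(4)
  ts <- simulate_session(S, 5000, tr = 2, seed = 8, ar1 = 0.6)
  ac <- mean(apply(ts$data, 2, function(x) cor(x[-1], x[-length(x)])))
  expect_gt(ac, 0.5)
  expect_lt(abs(sd(ts$data[, 1]) - 1), 0.1)
})

test_that("task-evoked responses are injected and removable by regression", {
  ev <- data.frame(onset = c(10, 60, 110), duration = 4, trial_type = "stim")
  S <- diag(5)
  ts <- suppressWarnings(
    simulate_session(S, 100, events = ev, tr = 2, seed = 13,
                     task_amplitude = 8))
  truth <- attr(ts, "truth")
  expect_false(is.null(truth$task_component))
  X <- build_task_regressors(ev, 100, 2)
  clean <- regress_task(ts, X)
  # residuals orthogonal to every regressor
  expect_lt(max(abs(crossprod(X, clean$data))), 1e-7)
})

test_that("zero behavioral coupling leaves behavior unrelated to true FCR change", {
  hp <- toy_hp(K7 = 2, K17 = 2, m = 2)
  spec <- suppressWarnings(ground_truth_spec(
    8, hp, within_r = list(w = 0.3, d = 0.3), between_r = list(w = 0, d = 0),
    n_timepoints = 30, behavior_coupling = 0, behavior_noise_sd = 1,
    seed = 61))
  coh <- suppressWarnings(simulate_cohort(spec, 100))
  acc <- coh$truth$accuracy_change[, 1]
  expect_lt(abs(cor(coh$truth$delta_fcr, acc)), 0.25)
})

test_that("noise-free coupling makes behavior an exact affine function of dFCR", {
  hp <- toy_hp(K7 = 2, K17 = 2, m = 2)
  spec <- suppressWarnings(ground_truth_spec(
    8, hp, within_r = list(w = 0.3, d = 0.45), between_r = list(w = 0.05, d = 0.05),
    n_timepoints = 30, behavior_coupling = -3, behavior_noise_sd = 0,
    seed = 62))
  coh <- suppressWarnings(simulate_cohort(spec, 10))
  expect_equal(unname(coh$truth$accuracy_change[, 2]),
               unname(-3 * coh$truth$delta_fcr), tolerance = 1e-12)
})

test_that("cohorts are bitwise reproducible from spec and seed", {
  hp <- toy_hp(K7 = 2, K17 = 2, m = 2)
  spec <- suppressWarnings(ground_truth_spec(
    8, hp, within_r = list(w = 0.3, d = 0.5), between_r = list(w = 0.1, d = 0.1),
    n_timepoints = 30, seed = 77))
  a <- suppressWarnings(simulate_cohort(spec, 3))
  b <- suppressWarnings(simulate_cohort(spec, 3))
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$behavior, b$behavior)
})

test_that("true FCR from the generating covariance matches the closed equicorrelation form", {
  # one system of equicorrelated pairs: analytic within/between terms
  part <- partition(rep(c("a", "b"), each = 2))
  S <- make_block_covariance(4, part, within_r = 0.3, between_r = 0)
  expect_equal(decompose_integration(S, part)$I_ws, -log(1 - 0.09),
               tolerance = 1e-12)
})

test_that("a condition shift in within-block correlation yields positive group dFCR", {
  hp <- toy_hp(K7 = 2, K17 = 2, m = 5)
  spec <- ground_truth_spec(
    20, hp, within_r = list(rested = 0.3, deprived = 0.5),
    between_r = list(rested = 0.1, deprived = 0.1),
    n_timepoints = 300, seed = 90)
  coh <- simulate_cohort(spec, 10)
  part7 <- partition(hp$level7, hp$parcel_ids)
  dfcr <- vapply(coh$subjects, function(s) {
    fcr(cor(coh$sessions[[s]]$deprived$data), part7) -
      fcr(cor(coh$sessions[[s]]$rested$data), part7)
  }, numeric(1))
  expect_gt(mean(dfcr), 0)
  expect_gt(mean(coh$truth$delta_fcr), 0)
})

test_that("write_cohort emits readable text plus a manifest", {
  hp <- toy_hp(K7 = 2, K17 = 2, m = 2)
  spec <- suppressWarnings(ground_truth_spec(
    8, hp, within_r = list(w = 0.3, d = 0.4), between_r = list(w = 0, d = 0),
    n_timepoints = 30, seed = 5))
  coh <- suppressWarnings(simulate_cohort(spec, 2))
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  expect_true(file.exists(file.path(d, "sub01_w_bold.tsv")))
  back <- read_parcel_ts(file.path(d, "sub01_w_bold.tsv"), tr = 2)
  expect_equal(unname(back$data), unname(coh$sessions$sub01$w$data),
               tolerance = 1e-10)
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$seed, 5)
  beh <- read_behavior(file.path(d, "behavior.tsv"))
  expect_equal(nrow(beh), nrow(coh$behavior))
})
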