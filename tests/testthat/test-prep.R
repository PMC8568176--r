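# Task regressors, regression, concatenation, amplitude and motion metrics.

test_that("an impulse event reproduces the HRF at volume times", {
  ev <- data.frame(onset = 0, duration = 0, trial_type = "x")
  X <- build_task_regressors(ev, 50, tr = 2, fir_span = 2)
  expect_equal(ncol(X), 1L)
  h <- canonical_hrf((0:49) * 2)
  # proportional: both are the double-gamma sampled at volume times, each
  # normalized on its own grid; the regressor kernel is truncated at 32 s,
  # where the analytic curve is already below 1e-3 of peak
  expect_lt(max(abs(X[, 1] / max(X[, 1]) - h / max(h))), 1e-3)
  expect_equal((X[, 1] / max(X[, 1]))[1:16], (h / max(h))[1:16],
               tolerance = 1e-10)
})

test_that("regressors are linear in events and counted per type x bin", {
  single <- function(onset) build_task_regressors(
    data.frame(onset = onset, duration = 0, trial_type = "x"), 120, tr = 2,
    fir_span = 2)
  both <- build_task_regressors(
    data.frame(onset = c(0, 100), duration = 0, trial_type = "x"), 120,
    tr = 2, fir_span = 2)
  expect_equal(both[, 1], single(0)[, 1] + single(100)[, 1],
               tolerance = 1e-10)
  ev2 <- data.frame(onset = c(4, 40), duration = 2,
                    trial_type = c("go", "stop"))
  X2 <- build_task_regressors(ev2, 60, tr = 2, fir_span = 16)
  expect_equal(ncol(X2), 2 * 8)
  expect_setequal(colnames(X2), c(paste0("go.b", 1:8), paste0("stop.b", 1:8)))
})

test_that("events are validated: empty errors, out-of-run truncates", {
  expect_error(build_task_regressors(
    data.frame(onset = numeric(), duration = numeric(),
               trial_type = character()), 50, 2), "empty")
  expect_warning(X <- build_task_regressors(
    data.frame(onset = c(2, 900), duration = 0, trial_type = "x"), 50, 2),
    "truncated")
  expect_equal(ncol(X), 8L)
})

test_that("task regression returns residuals orthogonal to the design", {
  ev <- data.frame(onset = c(8, 48), duration = 4, trial_type = "stim")
  X <- build_task_regressors(ev, 80, tr = 2)
  set.seed(3)
  noise <- matrix(rnorm(80 * 4), 80, 4)
  Y <- noise + 5 * rowSums(X)
  ts <- parcel_ts(Y, tr = 2)
  clean <- regress_task(ts, X)
  expect_lt(max(abs(crossprod(cbind(1, X), clean$data))), 1e-8)
  # a series equal to a design column leaves a (numerically) zero residual
  ts2 <- parcel_ts(cbind(X[, 1], X[, 2]), tr = 2)
  clean2 <- regress_task(ts2, X)
  expect_lt(max(abs(clean2$data)), 1e-10)
  # residual sd never exceeds input sd
  expect_true(all(apply(clean$data, 2, sd) <= apply(Y, 2, sd) + 1e-12))
})

test_that("intercept-plus-trend regression demeans and detrends", {
  set.seed(4)
  Y <- matrix(rnorm(60 * 3), 60, 3) + 2
  out <- regress_task(parcel_ts(Y, tr = 2), design = NULL)
  expect_equal(colMeans(out$data), c(p1 = 0, p2 = 0, p3 = 0),
               tolerance = 1e-12)
  trend <- seq_len(60) - mean(seq_len(60))
  expect_lt(max(abs(crossprod(trend, out$data))), 1e-8)
})

test_that("a rank-deficient design errors naming the collinear column", {
  X <- cbind(a = rnorm(30), b = rnorm(30))
  X <- cbind(X, dup = X[, "a"])
  expect_error(regress_task(parcel_ts(matrix(rnorm(60), 30, 2), tr = 2), X),
               "rank deficient")
})

test_that("run concatenation stacks, demeans, and is associative", {
  mk <- function(seed, shift = 0) {
    set.seed(seed)
    parcel_ts(matrix(rnorm(100 * 3), 100, 3) + shift, tr = 2,
              parcel_ids = c("a", "b", "c"))
  }
  runs <- list(mk(1, 0), mk(2, 5), mk(3, -2))
  cc <- concatenate_runs(runs)
  expect_equal(nrow(cc$data), 300)
  expect_equal(unname(colMeans(cc$data)), rep(0, 3), tolerance = 1e-12)
  # associativity: concatenating pre-concatenated demeaned pieces agrees
  left <- concatenate_runs(list(concatenate_runs(runs[1:2]), runs[[3]]))
  right <- concatenate_runs(list(runs[[1]], concatenate_runs(runs[2:3])))
  expect_equal(left$data, right$data, tolerance = 1e-12)
  # single run: just the demeaned input
  one <- concatenate_runs(runs[1])
  expect_equal(unname(one$data), unname(scale(runs[[1]]$data, scale = FALSE)),
               ignore_attr = TRUE)
  bad <- parcel_ts(matrix(rnorm(300), 100, 3), tr = 2,
                   parcel_ids = c("a", "b", "zzz"))
  expect_error(concatenate_runs(list(runs[[1]], bad)), "zzz")
})

test_that("amplitude metrics: degenerate, scaling, and GS variance behavior", {
  x <- rnorm(50)
  same <- parcel_ts(cbind(x, x, x), tr = 2, parcel_ids = c("a", "b", "c"))
  m <- amplitude_metrics(same)
  expect_equal(unname(m$parcel_gs_cor), rep(1, 3))
  # doubling values doubles sds, leaves correlations unchanged
  set.seed(9)
  Y <- matrix(rnorm(200 * 4), 200, 4)
  m1 <- amplitude_metrics(parcel_ts(Y, tr = 2))
  m2 <- amplitude_metrics(parcel_ts(2 * Y, tr = 2))
  expect_equal(m2$parcel_sd, 2 * m1$parcel_sd)
  expect_equal(m2$parcel_gs_cor, m1$parcel_gs_cor)
  # i.i.d. parcels: GS sd ~ 1/sqrt(N)
  set.seed(10)
  big <- parcel_ts(matrix(rnorm(4000 * 100), 4000, 100), tr = 2)
  expect_equal(amplitude_metrics(big)$global_signal_sd, 1 / sqrt(100),
               tolerance = 0.15)
  # constant parcel: missing correlation with a warning
  const <- parcel_ts(cbind(a = rnorm(50), b = rep(1, 50)), tr = 2)
  expect_warning(mc <- amplitude_metrics(const), "constant")
  expect_true(is.na(mc$parcel_gs_cor[2]))
})

test_that("amplitude metrics follow parcel permutations", {
  set.seed(11)
  Y <- matrix(rnorm(100 * 5), 100, 5)
  ids <- paste0("p", 1:5)
  perm <- c(3, 1, 5, 2, 4)
  m <- amplitude_metrics(parcel_ts(Y, tr = 2, parcel_ids = ids))
  mp <- amplitude_metrics(parcel_ts(Y[, perm], tr = 2, parcel_ids = ids[perm]))
  expect_equal(mp$parcel_sd, m$parcel_sd[perm])
  expect_equal(mp$parcel_gs_cor, m$parcel_gs_cor[perm])
  expect_equal(mp$global_signal, m$global_signal)
})

test_that("framewise displacement follows the rigid-body formula", {
  zero <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(zero)$fd, rep(0, 10))
  step <- zero; step[5:10, 1] <- 0.1
  expect_equal(framewise_displacement(step)$fd[5], 0.1)
  rot <- zero; rot[5:10, 4] <- 0.002
  expect_equal(framewise_displacement(rot)$fd[5], 0.1)   # 50 mm x 0.002 rad
  expect_equal(framewise_displacement(rot, head_radius = 100)$fd[5], 0.2)
  expect_error(framewise_displacement(zero[, 1:5]), "6 columns")
})
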