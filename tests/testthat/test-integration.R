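# Closed-form Gaussian integration, the within/between decomposition, FCR,
# and the hierarchical walk.

test_that("entropy matches the eigenvalue oracle and closed forms", {
  expect_equal(gaussian_entropy(diag(3)), 0)
  expect_equal(gaussian_entropy(matrix(4, 1, 1)), log(2))
  S <- rand_pd(50, seed = 11)
  expect_equal(gaussian_entropy(S), entropy_oracle(S), tolerance = 1e-10)
})

test_that("non-PD covariance errors report the smallest eigenvalue; ridge repairs", {
  bad <- matrix(c(1, 2, 2, 1), 2)   # indefinite
  expect_error(gaussian_entropy(bad), "smallest eigenvalue")
  expect_message(h <- gaussian_entropy(.Machine$double.eps * diag(2) +
                                         matrix(c(1, 1, 1, 1), 2),
                                       ridge = TRUE), "ridge repair")
  expect_true(is.finite(h))
})

test_that("total integration reproduces the bivariate and equicorrelation closed forms", {
  S <- matrix(c(1, .5, .5, 1), 2)
  expect_equal(total_integration(S), -0.5 * log(1 - 0.5^2), tolerance = 1e-12)
  R <- matrix(0.3, 4, 4); diag(R) <- 1
  # det of an equicorrelated matrix: (1-r)^(N-1) (1+(N-1)r)
  expect_equal(total_integration(R), -0.5 * log((1 - 0.3)^3 * (1 + 3 * 0.3)),
               tolerance = 1e-12)
  expect_equal(total_integration(diag(5)), 0)
  # block units: against the oracle
  lab <- c("a", "a", "b", "b")
  expect_equal(total_integration(R, partition(lab)),
               integration_oracle(R, lab), tolerance = 1e-12)
})

test_that("decomposition is exact on the worked equicorrelated example", {
  R <- matrix(0.3, 4, 4); diag(R) <- 1
  res <- decompose_integration(R, partition(c("a", "a", "b", "b")))
  expect_equal(res$I_ws, 2 * (-0.5 * log(1 - 0.09)), tolerance = 1e-12)
  expect_equal(res$I_tot, -0.5 * log(0.343 * 1.9), tolerance = 1e-12)
  expect_equal(res$I_bs, res$I_tot - res$I_ws, tolerance = 1e-12)
  expect_equal(fcr(res), res$I_ws / res$I_bs)
  expect_equal(unname(res$per_system), rep(-0.5 * log(0.91), 2))
})

test_that("block-diagonal structure gives zero between-system integration and an FCR guard", {
  part <- partition(c("a", "a", "b", "b"))
  B <- make_block_covariance(4, part, within_r = 0.6, between_r = 0)
  res <- decompose_integration(B, part)
  expect_equal(res$I_bs, 0, tolerance = 1e-12)
  expect_equal(res$I_ws, 2 * (-0.5 * log(1 - 0.36)), tolerance = 1e-12)
  expect_error(fcr(B, part), "undefined")
  # I_ws = 0 with diagonal blocks but coupled systems -> FCR 0
  C <- make_block_covariance(4, part, within_r = 0, between_r = 0.3)
  expect_equal(fcr(C, part), 0, tolerance = 1e-10)
})

test_that("identity covariance yields zero everywhere; singletons contribute nothing", {
  part <- partition(c("a", "a", "b", "b"))
  res <- decompose_integration(diag(4), part)
  expect_equal(c(res$I_tot, res$I_ws, res$I_bs), c(0, 0, 0))
  # singleton system: zero within-integration, decomposition still exact
  S <- rand_pd(5, seed = 3)
  res <- decompose_integration(S, partition(c("a", "a", "b", "b", "c")))
  expect_equal(unname(res$per_system["c"]), 0)
  expect_equal(res$I_tot, res$I_ws + res$I_bs, tolerance = 1e-10)
})

test_that("additivity and non-negativity hold on random covariances and partitions", {
  for (i in 1:30) {
    n <- sample(4:30, 1)
    S <- rand_pd(n, seed = 100 + i)
    lab <- rand_labels(n, sample(2:4, 1), seed = 200 + i)
    res <- decompose_integration(S, partition(lab))
    expect_equal(res$I_tot, res$I_ws + res$I_bs,
                 tolerance = 1e-10 * max(1, abs(res$I_tot)))
    expect_gte(res$I_tot, -1e-10)
    expect_gte(res$I_ws, -1e-10)
    expect_gte(res$I_bs, -1e-10)
    expect_equal(res$I_tot, integration_oracle(S), tolerance = 1e-8)
  }
})

test_that("all integration quantities are invariant to marginal rescaling", {
  S <- rand_pd(12, seed = 42)
  lab <- rand_labels(12, 3, seed = 43)
  base <- decompose_integration(S, partition(lab))
  set.seed(44)
  for (i in 1:10) {
    d <- exp(rnorm(12))
    res <- decompose_integration(diag(d) %*% S %*% diag(d), partition(lab))
    expect_equal(res$I_tot, base$I_tot, tolerance = 1e-10)
    expect_equal(res$I_ws, base$I_ws, tolerance = 1e-10)
    expect_equal(res$I_bs, base$I_bs, tolerance = 1e-10)
    expect_equal(res$FCR, base$FCR, tolerance = 1e-10)
  }
})

test_that("omitting the entropy constant does not change integration values", {
  # full differential entropy adds (N/2)(1 + log 2 pi); block sizes sum to N,
  # so the constants cancel in sum_k H(block) - H(full)
  full_entropy <- function(cov) entropy_oracle(cov) +
    nrow(cov) / 2 * (1 + log(2 * pi))
  S <- rand_pd(9, seed = 7)
  lab <- c("a", "a", "a", "b", "b", "b", "c", "c", "c")
  blocks <- split(seq_len(9), lab)
  with_const <- sum(vapply(blocks, function(idx)
    full_entropy(S[idx, idx]), numeric(1))) - full_entropy(S)
  expect_equal(total_integration(S, partition(lab)), with_const,
               tolerance = 1e-10)
})

test_that("raising within-block correlation never decreases within-system integration", {
  part <- partition(rep(c("a", "b"), each = 5))
  prev <- -Inf
  for (r in seq(0.05, 0.6, by = 0.05)) {
    S <- make_block_covariance(10, part, within_r = r, between_r = 0.02)
    iws <- decompose_integration(S, part)$I_ws
    expect_gte(iws, prev)
    prev <- iws
  }
})

test_that("hierarchical walk telescopes to the singleton integration", {
  hp <- toy_hp(K7 = 3, K17 = 2, m = 4)   # 24 parcels
  part7 <- partition(hp$level7, hp$parcel_ids)
  S <- make_block_covariance(24, partition(hp$level17, hp$parcel_ids),
                             within_r = 0.5, between_r = 0.1)
  tree <- hierarchical_integration(S, hp)
  # cortex-level I_tot equals the telescoped sum: cortex I_bs plus each
  # level-7 node's I_tot computed over its level-17 systems plus the
  # singleton integration inside every level-17 system
  leaves <- sum(vapply(unique(hp$level17), function(s17) {
    idx <- which(hp$level17 == s17)
    total_integration(S[idx, idx, drop = FALSE])
  }, numeric(1)))
  mids <- sum(vapply(tree$level7, function(nd) nd$I_bs, numeric(1)))
  expect_equal(tree$cortex$I_bs + mids + leaves,
               total_integration(S), tolerance = 1e-8)
  expect_equal(tree$cortex$I_tot, total_integration(S, part7) +
                 sum(vapply(names(tree$level7), function(nw) {
                   idx <- which(hp$level7 == nw)
                   total_integration(S[idx, idx, drop = FALSE])
                 }, numeric(1))), tolerance = 1e-8)
  # identity: all nodes zero
  tree0 <- hierarchical_integration(diag(24), hp)
  expect_equal(tree0$cortex$I_tot, 0)
  expect_true(all(vapply(tree0$level7, function(nd) abs(nd$I_tot) < 1e-12,
                         logical(1))))
})

test_that("hierarchy nodes with fewer than 2 children are skipped with a warning", {
  hp <- suppressWarnings(hierarchical_partition(
    paste0("p", 1:6), c("A", "A", "A", "A", "B", "B"),
    c("A1", "A1", "A2", "A2", "B1", "B1")))
  S <- rand_pd(6, seed = 9)
  expect_warning(tree <- hierarchical_integration(S, hp),
                 "fewer than 2 level-17")
  expect_null(tree$level7$B)
  expect_s3_class(tree$level7$A, "integration_result")
})
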