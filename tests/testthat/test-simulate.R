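test_that("planted designs validate and translate into the right couplings", {
  cat6 <- small_catalog(6)
  des <- planted_design(
    blocks = list(A = c("D1", "D2", "D3"), B = c("D4", "D5", "D6")),
    w_in = 1.0,
    prevalence = stats::setNames(rep(0.3, 6), cat6$code),
    catalog = cat6)
  W <- build_planted_ising(des, calibrate = "mean_field")$W
  # two blocks of 3 -> 6 nonzero unordered pairs
  expect_equal(sum(W[upper.tri(W)] != 0), 6)
  expect_true(isSymmetric(W))
  expect_equal(unname(diag(W)), rep(0, 6))

  # isolate rows are all zero
  des2 <- planted_design(
    blocks = list(A = c("D1", "D2", "D3"), B = c("D4", "D5")),
    isolates = "D6", w_in = 1.0,
    prevalence = stats::setNames(rep(0.3, 6), cat6$code), catalog = cat6)
  W2 <- build_planted_ising(des2, calibrate = "mean_field")$W
  expect_equal(unname(W2["D6", ]), rep(0, 6))

  # overlapping blocks rejected; partition must cover the catalog
  expect_error(planted_design(
    blocks = list(A = c("D1", "D2"), B = c("D2", "D3")),
    prevalence = stats::setNames(rep(0.3, 6), cat6$code), catalog = cat6),
    "disjoint")
  expect_error(planted_design(
    blocks = list(A = c("D1", "D2")),
    prevalence = stats::setNames(rep(0.3, 6), cat6$code), catalog = cat6),
    "partition")

  # W = 0, targets 0.5 -> h = 0 by logistic symmetry
  des3 <- planted_design(
    blocks = list(), isolates = cat6$code, w_in = 1,
    prevalence = stats::setNames(rep(0.5, 6), cat6$code), catalog = cat6)
  h <- build_planted_ising(des3, calibrate = "mean_field")$h
  expect_equal(unname(h), rep(0, 6), tolerance = 1e-9)
})

test_that("Gibbs sampling reproduces independent Bernoulli margins when W = 0", {
  p <- 6
  codes <- paste0("D", 1:p)
  params <- structure(list(
    W = matrix(0, p, p, dimnames = list(codes, codes)),
    h = stats::setNames(rep(0, p), codes)), class = "ising_parameters")
  X <- sample_ising(params, n = 10000, burn_in = 20, seed = 1)
  expect_true(all(colMeans(X) > 0.48 & colMeans(X) < 0.52))

  params$h[] <- stats::qlogis(0.2)
  X2 <- sample_ising(params, n = 10000, burn_in = 20, seed = 2)
  expect_true(all(abs(colMeans(X2) - 0.2) < 0.015))

  # pairwise independence: max |correlation| bounded by ~3/sqrt(n)
  cors <- stats::cor(X)
  expect_lt(max(abs(cors[upper.tri(cors)])), 3 / sqrt(10000))
})

test_that("a coupled pair reproduces the exact 4-state log odds ratio", {
  # for p = 2 the joint is exactly p(x) propto exp(h.x + W12 x1 x2), so the
  # (x1, x2) table log-odds-ratio equals W12 = 2
  codes <- c("D1", "D2")
  W <- matrix(c(0, 2, 2, 0), 2, dimnames = list(codes, codes))
  params <- structure(list(W = W, h = stats::setNames(c(0, 0), codes)),
                      class = "ising_parameters")
  X <- sample_ising(params, n = 20000, burn_in = 100, seed = 3)
  tb <- table(factor(X[, 1], 0:1), factor(X[, 2], 0:1))
  lor <- log(tb[1, 1] * tb[2, 2] / (tb[1, 2] * tb[2, 1]))
  expect_equal(lor, 2, tolerance = 0.1 / 2)

  # and the marginals match exact enumeration of the 4 states
  states <- expand.grid(x1 = 0:1, x2 = 0:1)
  pr <- exp(2 * states$x1 * states$x2)
  pr <- pr / sum(pr)
  expect_equal(mean(X[, 1]), sum(pr[states$x1 == 1]), tolerance = 0.015)
})

test_that("sampling is seed-deterministic and label-equivariant", {
  params <- chain_params(5, 1)
  X1 <- sample_ising(params, n = 200, burn_in = 50, seed = 9)
  X2 <- sample_ising(params, n = 200, burn_in = 50, seed = 9)
  expect_identical(X1, X2)

  expect_error(sample_ising(structure(list(
    W = matrix(c(0, 1, 0, 0), 2), h = c(0, 0)),
    class = "ising_parameters"), n = 10), "symmetric")

  # permuting node labels permutes the sampled distribution identically:
  # marginals and pairwise associations must agree under the relabeling
  perm <- c(3, 1, 4, 5, 2)
  Wp <- params$W[perm, perm]
  hp <- params$h[perm]
  Xbig <- sample_ising(params, n = 6000, burn_in = 80, seed = 10)
  Xp <- sample_ising(structure(list(W = Wp, h = hp),
                               class = "ising_parameters"),
                     n = 6000, burn_in = 80, seed = 77)
  expect_identical(colnames(Xp), colnames(Xbig)[perm])
  expect_lt(max(abs(colMeans(Xp) - colMeans(Xbig)[perm])), 0.04)
  expect_lt(max(abs(stats::cor(Xp) - stats::cor(Xbig)[perm, perm])), 0.08)
})

test_that("single-chain mode with thinning yields the requested sample size", {
  X <- sample_ising(chain_params(4, 0.5), n = 50, burn_in = 20, thin = 3,
                    seed = 4, chains = "single")
  expect_equal(dim(X), c(50, 4))
  expect_true(all(X %in% 0:1))
})

test_that("calibrated default design hits its target marginals by simulation", {
  des <- default_design()
  params <- build_planted_ising(des)
  X <- sample_ising(params, n = 5000, burn_in = 200, seed = 11)
  expect_lt(max(abs(colMeans(X) - des$prevalence[colnames(X)])), 0.03)
  # the planted 0.30 marginal specifically, within Monte-Carlo error
  expect_lt(abs(mean(X[, "D15"]) - 0.30), 0.02)
})

test_that("demographics attach reproducibly with the requested frequencies", {
  X <- matrix(rbinom(10000 * 2, 1, 0.1), 10000, 2,
              dimnames = list(NULL, c("D1", "D2")))
  spec <- demographic_spec(age_group = c(`50-64` = 1, `65-74` = 0,
                                         `75plus` = 0))
  coh <- attach_demographics(X, spec, seed = 5, catalog = small_catalog(2))
  expect_true(all(coh$age_group == "50-64"))
  expect_true(all(abs(table(coh$income_q) / 10000 - 0.25) < 0.015))
  coh2 <- attach_demographics(X, spec, seed = 5, catalog = small_catalog(2))
  expect_identical(coh, coh2)
  expect_error(demographic_spec(gender = c(M = 0.7, F = 0.7)), "probability")
})

test_that("regression cohorts carry the planted odds ratio", {
  spec <- demographic_spec(outcome_link = list(intercept = 0, beta = c()))
  coh0 <- generate_regression_cohort(spec, n = 4000,
                                     prevalence = c(Z = 0.5), seed = 6)
  expect_equal(mean(coh0$outcome), 0.5, tolerance = 0.03)

  spec4 <- demographic_spec(outcome_link = list(
    intercept = -0.5, beta = c(Z = log(4))))
  coh <- generate_regression_cohort(spec4, n = 20000,
                                    prevalence = c(Z = 0.4), seed = 7)
  tb <- table(coh$Z, coh$outcome)
  or <- (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1])
  expect_equal(or, 4, tolerance = 0.1)
  coh2 <- generate_regression_cohort(spec4, n = 20000,
                                     prevalence = c(Z = 0.4), seed = 7)
  expect_identical(coh$outcome, coh2$outcome)
})
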