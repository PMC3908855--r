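test_that("positivity shift follows the minimum-gap rule", {
  expect_equal(shift_to_positive(c(1, 2, 3)),
               list(x = c(1, 2, 3), shift = 0))
  got <- shift_to_positive(c(-1, 0, 2))
  expect_equal(got$shift, 2)           # -(-1) + smallest gap 1
  expect_equal(got$x, c(1, 2, 4))
  expect_error(shift_to_positive(c(5, 5, 5)), "constant")
})

test_that("FP basis covers identity, log and the repeated-power limit", {
  x <- c(0.5, 1, 2, 4)
  expect_equal(unname(fp_basis(x, 1)[, 1]), x)        # p = 1 is identity
  expect_equal(unname(fp_basis(x, 0)[, 1]), log(x))   # p = 0 is ln
  expect_equal(unname(fp_basis(4, c(0.5, -1))), cbind(2, 0.25),
               ignore_attr = TRUE)
  expect_equal(unname(fp_basis(1, c(2, 2))), cbind(1, 0),
               ignore_attr = TRUE)
  b <- fp_basis(x, c(3, 3))
  expect_equal(unname(b[, 2]), x^3 * log(x))
  expect_error(fp_basis(c(-1, 2), 1), "strictly positive")
  expect_error(fp_basis(x, 1.5), "powers")
  expect_error(fp_basis(x, c(1, 2, 3)), "powers")
})

test_that("the FP2 candidate grid has 36 power pairs", {
  pairs <- betaturn:::fp2_power_pairs()
  expect_identical(nrow(pairs), 36L)
  expect_true(all(pairs$p <= pairs$q))
})

test_that("IRLS reproduces closed-form logistic fits", {
  # intercept-only, half successes: coef 0, deviance 2 n ln 2
  y <- rep(c(0, 1), 50)
  fit <- fit_logistic_irls(cbind(rep(1, 100)), y)
  expect_equal(fit$coefficients, 0, tolerance = 1e-8)
  expect_equal(fit$deviance, 2 * 100 * log(2), tolerance = 1e-8)

  # two-group saturated fit: logit of the group rates, exactly
  x <- rep(c(0, 1), each = 10)
  y <- c(rep(1, 2), rep(0, 8), rep(1, 7), rep(0, 3))
  fit <- fit_logistic_irls(cbind(1, x), y)
  expect_equal(fit$coefficients[1], qlogis(0.2), tolerance = 1e-8)
  expect_equal(fit$coefficients[2], qlogis(0.7) - qlogis(0.2),
               tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("IRLS matches glm across random problems", {
  set.seed(21)
  for (r in 1:10) {
    n <- sample(40:150, 1)
    p <- sample(1:4, 1)
    X <- cbind(1, matrix(rnorm(n * p), n))
    y <- rbinom(n, 1, plogis(drop(X %*% rnorm(p + 1, 0, 0.8))))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic_irls(X, y)
    ref <- glm.fit(X, y, family = binomial())
    expect_equal(fit$deviance, ref$deviance, tolerance = 1e-8)
    expect_equal(fit$coefficients, unname(ref$coefficients),
                 tolerance = 1e-6)
  }
})

test_that("IRLS flags rank deficiency and nested-model monotonicity holds", {
  X <- cbind(1, 1:20, 2 * (1:20))
  colnames(X) <- c("int", "a", "b")
  expect_error(fit_logistic_irls(X, rep(c(0, 1), 10)), "collinear.*b")
  set.seed(2)
  x <- rnorm(80)
  y <- rbinom(80, 1, plogis(x))
  d_null <- fit_logistic_irls(cbind(rep(1, 80)), y)$deviance
  d_full <- fit_logistic_irls(cbind(1, x), y)$deviance
  expect_lte(d_full, d_null)
})

test_that("deviance_test is the upper-tail chi-square of the difference", {
  expect_equal(deviance_test(10, 10, 1), 1)
  expect_equal(deviance_test(13.841, 10, 1), 0.05, tolerance = 1e-3)
  expect_lt(deviance_test(110, 10, 2), 1e-10)
  expect_error(deviance_test(10, 20, 1), "nested")
})

test_that("closed test recovers log and linear truths from simulation", {
  sim <- simulate_fp_data(5000, 0, c(1, 2), seed = 31)
  m <- suppressWarnings(run_mfp_cycles(cbind(d1 = sim$x), sim$y))
  expect_identical(m$transforms[[1]]$form, "FP1")
  expect_identical(m$transforms[[1]]$powers, 0)

  sim <- simulate_fp_data(5000, 1, c(-1, 0.8), seed = 32)
  m <- suppressWarnings(run_mfp_cycles(cbind(d1 = sim$x), sim$y))
  expect_identical(m$transforms[[1]]$form, "linear")
})

test_that("each variable's scan is deviance-monotone: null >= linear >= FP1 >= FP2", {
  sim <- simulate_fp_data(3000, c(1, 2), c(-2, 1.5, -0.5), seed = 33)
  m <- suppressWarnings(run_mfp_cycles(cbind(d1 = sim$x), sim$y))
  tr <- fp_trace_table(m)
  for (cyc in unique(tr$cycle)) {
    s <- tr[tr$cycle == cyc, ]
    dv <- setNames(s$deviance, s$form)
    expect_gte(dv["omitted"], dv["linear"] - 1e-6)
    expect_gte(dv["linear"], dv["FP1"] - 1e-6)
    expect_gte(dv["FP1"], dv["FP2"] - 1e-6)
  }
})

test_that("linear-truth covariates settle to all-linear within two cycles", {
  set.seed(41)
  d <- matrix(rnorm(3 * 4000), ncol = 3)
  eta <- -1 + 0.9 * d[, 1] + 0.6 * d[, 2] - 0.7 * d[, 3]
  y <- rbinom(4000, 1, plogis(eta))
  m <- suppressWarnings(run_mfp_cycles(d, y))
  expect_lte(m$cycles_run, 2L)
  expect_true(all(vapply(m$transforms, `[[`, "", "form") == "linear"))
  # refitting on the same inputs reproduces the model exactly
  m2 <- suppressWarnings(run_mfp_cycles(d, y))
  expect_identical(m$coefficients, m2$coefficients)
  expect_identical(m$deviance, m2$deviance)
})

test_that("full-model deviance never increases across cycles", {
  sim1 <- simulate_fp_data(3000, 0, c(0.5, 1.5), seed = 51)
  sim2 <- simulate_fp_data(3000, c(1, 2), c(-1, 1, -0.4), seed = 52)
  d <- cbind(sim1$x, sim2$x)
  y <- rbinom(3000, 1, plogis(-1 + 2 * log(sim1$x) + sim2$x - 0.4 * sim2$x^2))
  m <- suppressWarnings(run_mfp_cycles(d, y, max_cycles = 4))
  expect_true(all(diff(m$cycle_deviance) <= 1e-6))
  expect_equal(m$deviance, m$cycle_deviance[length(m$cycle_deviance)],
               tolerance = 1e-8)
})

test_that("interaction screening keeps a planted product and counts pairs", {
  set.seed(61)
  d <- matrix(rnorm(3 * 4000), ncol = 3)
  y <- rbinom(4000, 1, plogis(0.5 * d[, 1] + 0.5 * d[, 2] +
                              1.2 * d[, 1] * d[, 2]))
  m <- suppressWarnings(run_mfp_cycles(d, y))
  m_int <- suppressWarnings(screen_interactions(m, d, y))
  got <- vapply(m_int$interactions, function(p) paste(p, collapse = ","), "")
  expect_true("1,2" %in% got)

  # null data: no interaction retained at this fixed seed
  set.seed(62)
  d0 <- matrix(rnorm(3 * 4000), ncol = 3)
  y0 <- rbinom(4000, 1, plogis(0.8 * d0[, 1] - 0.5 * d0[, 2] + 0.4 * d0[, 3]))
  m0 <- suppressWarnings(run_mfp_cycles(d0, y0))
  m0_int <- suppressWarnings(screen_interactions(m0, d0, y0))
  expect_length(m0_int$interactions, 0)
  expect_length(utils::combn(3, 2, simplify = FALSE), 3)
})

test_that("prediction applies stored shifts, clamps and stays in (0,1)", {
  sim <- simulate_fp_data(3000, 0, c(1, 2), seed = 71)
  d <- cbind(d1 = sim$x - 1)   # force a positivity shift
  m <- suppressWarnings(run_mfp_cycles(d, sim$y))
  p <- predict(m, d)
  expect_true(all(p > 0 & p < 1))
  # monotone when the fitted transform is increasing (log truth)
  ord <- order(d[, 1])
  expect_true(all(diff(p[ord]) >= -1e-12))
  # refitting reproduces fitted probabilities bit-identically
  m2 <- suppressWarnings(run_mfp_cycles(d, sim$y))
  expect_identical(predict(m2, d), p)
  # values below the training support are clamped with a warning
  expect_warning(predict(m, cbind(min(d) - 10)), "clamped")
})

test_that("zero coefficients give probability one half", {
  sim <- simulate_fp_data(500, 1, c(0.3, 0.5), seed = 81)
  m <- suppressWarnings(run_mfp_cycles(cbind(sim$x), sim$y))
  m$coefficients <- rep(0, length(m$coefficients))
  expect_equal(unname(predict(m, cbind(sim$x))), rep(0.5, 500))
})
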