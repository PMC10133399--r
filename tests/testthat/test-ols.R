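test_that("planted slope difference is recovered", {
  pd <- make_pair(20, beta3 = 2, slope = 1, intercept = 1, noise_sd = 0.1,
                  seed = 11)
  fit <- fit_ols_interaction(pd)
  expect_lt(abs(unname(fit$beta3) - 2), 0.1)
  expect_equal(unname(fit$per_group_slope["B"] - fit$per_group_slope["A"]),
               unname(fit$beta3))
  # the oracle fit on the same data agrees
  orc <- oracle_interaction_fit(pd$x, pd$y, pd$group)
  expect_equal(unname(coef(fit)), unname(orc$beta), tolerance = 1e-12)
})

test_that("OLS fit matches the normal-equations oracle on random datasets", {
  for (s in 1:25) {
    pd <- make_pair(15, beta3 = runif(1, -2, 2), slope = rnorm(1),
                    noise_sd = runif(1, 0.1, 1), seed = 1000 + s)
    fit <- fit_ols_interaction(pd)
    orc <- oracle_interaction_fit(pd$x, pd$y, pd$group)
    expect_lt(max(abs(coef(fit) - orc$beta)), 1e-10)
    expect_lt(abs(fit$f_statistic - orc$f), 1e-10)
    expect_lt(abs(fit$p_interaction - orc$p), 1e-10)
    expect_identical(c(fit$df_num, fit$df_den), c(orc$df_num, orc$df_den))
  }
})

test_that("group relabeling negates beta3 but leaves the p-value unchanged", {
  pd <- make_pair(20, beta3 = 1.2, seed = 3)
  fit <- fit_ols_interaction(pd)
  pd_swap <- pd
  pd_swap$group <- factor(ifelse(pd$group == "A", "B", "A"),
                          levels = c("A", "B"))
  fit_swap <- fit_ols_interaction(pd_swap)
  expect_equal(unname(fit_swap$beta3), -unname(fit$beta3), tolerance = 1e-9)
  expect_equal(fit_swap$p_interaction, fit$p_interaction, tolerance = 1e-12)
})

test_that("for two groups the F-test equals the squared Wald t on the interaction", {
  pd <- make_pair(25, beta3 = 0.8, seed = 5)
  fit <- fit_ols_interaction(pd)
  sfit <- summary(stats::lm(y ~ x * group,
                            data.frame(y = pd$y, x = pd$x,
                                       group = pd$group)))
  tval <- sfit$coefficients["x:groupB", "t value"]
  tp <- sfit$coefficients["x:groupB", "Pr(>|t|)"]
  expect_lt(abs(fit$f_statistic - tval^2), 1e-10)
  expect_lt(abs(fit$p_interaction - tp), 1e-10)
  expect_equal(fit$df_num, 1L)
})

test_that("p-value is invariant to affine rescaling of x and y", {
  pd <- make_pair(30, beta3 = 0.5, seed = 9)
  p0 <- fit_ols_interaction(pd)$p_interaction
  for (ab in list(c(2, 3, -1.5, 10), c(-0.4, 0, 5, -2))) {
    pd2 <- pd
    pd2$x <- ab[1] * pd$x + ab[2]
    pd2$y <- ab[3] * pd$y + ab[4]
    expect_equal(fit_ols_interaction(pd2)$p_interaction, p0,
                 tolerance = 1e-9)
  }
})

test_that("changing the reference group changes coefficients, never the p-value", {
  set.seed(21)
  n <- 60
  group <- factor(rep(c("A", "B", "C"), each = 20), levels = c("A", "B", "C"))
  x <- rnorm(n)
  y <- 1 + x * c(A = 1, B = 2, C = 0.5)[group] + rnorm(n, sd = 0.3)
  pd <- structure(list(x = x, y = y, group = group, n = n, predictor = "GX",
                       response = "GY", degenerate = FALSE,
                       reason = NA_character_), class = "pair_data")
  fit1 <- fit_ols_interaction(pd)
  expect_equal(fit1$df_num, 2L)  # k = 3 joint (one-way-ANOVA-style) test
  pd2 <- pd
  pd2$group <- factor(group, levels = c("C", "A", "B"))
  fit2 <- fit_ols_interaction(pd2)
  expect_false(isTRUE(all.equal(unname(fit1$beta1), unname(fit2$beta1))))
  expect_equal(fit1$p_interaction, fit2$p_interaction, tolerance = 1e-10)
})

test_that("empirical power is monotone in the planted effect size", {
  power_at <- function(beta3) {
    rej <- vapply(1:60, function(s) {
      pd <- make_pair(15, beta3 = beta3, noise_sd = 1, seed = 7000 + s)
      fit_ols_interaction(pd)$p_interaction < 0.05
    }, logical(1))
    mean(rej)
  }
  pw <- vapply(c(0, 0.5, 1, 2), power_at, numeric(1))
  expect_true(all(diff(pw) >= 0))
  expect_gt(pw[4], 0.9)
})

test_that("degenerate designs yield missing p with machine-readable reasons", {
  pd <- make_pair(10, seed = 2)
  pd$x[pd$group == "B"] <- 3  # zero predictor variance in one group
  fit <- fit_ols_interaction(pd)
  expect_true(is.na(fit$p_interaction))
  expect_identical(fit$reason, "zero_variance")
  expect_identical(fit_robust_interaction(pd)$reason, "zero_variance")
})

test_that("BH adjustment follows the step-up formula and missing policy", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  # m counts non-missing entries only: the lone real p is unchanged
  expect_equal(adjust_pvalues(c(0.04, NA)), c(0.04, NA))
  v <- c(0.5, NA, 0.001, 0.2)
  expect_identical(adjust_pvalues(v, method = "none"), v)
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  # agrees with a hand-coded step-up on a larger vector
  set.seed(4)
  p <- runif(40)
  m <- length(p)
  o <- order(p)
  stepped <- p[o] * m / seq_len(m)
  expected <- pmin(rev(cummin(rev(stepped))), 1)[order(o)]
  expect_equal(adjust_pvalues(p), expected)
})
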