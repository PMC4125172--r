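# Statistics chain: ANOVA/post hoc, Spearman, ICC, VIF, stepwise logistic,
# ROC and the threshold rule.

test_that("one-way ANOVA handles identical groups and strong separation", {
  g <- factor(rep(c("AIS", "MIA", "INV"), each = 10))
  y_same <- rep(stats::rnorm(10, 0, 1), 3)
  res <- anova_with_posthoc(y_same, g)
  expect_equal(res$f, 0, tolerance = 1e-12)
  expect_equal(res$p_raw, 1, tolerance = 1e-12)

  set.seed(1)
  g30 <- factor(rep(c("A", "B", "C"), each = 30))
  y_sep <- stats::rnorm(90, rep(c(0, 10, 20), each = 30), 1)
  expect_lt(anova_with_posthoc(y_sep, g30)$p_raw, 1e-6)

  g3 <- factor(rep(c("A", "B", "C"), each = 5))
  expect_error(anova_with_posthoc(rep(c(1, 2, 3), each = 5), g3),
               "zero within-group variance")
})

test_that("family Bonferroni correction multiplies and caps at 1", {
  set.seed(2)
  g <- factor(rep(c("A", "B", "C"), each = 20))
  y <- stats::rnorm(60, rep(c(0, 0.5, 1), each = 20), 1)
  r1 <- anova_with_posthoc(y, g, family_size = 1)
  r7 <- anova_with_posthoc(y, g, family_size = 7)
  expect_equal(r7$p_family, min(1, r1$p_raw * 7))
  expect_gte(r7$p_family, r7$p_raw)
})

test_that("Spearman correlation equals the rank-then-Pearson oracle", {
  expect_equal(spearman_vs_invasion(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_vs_invasion(1:10, -(1:10)^3)$rho, -1)
  expect_error(spearman_vs_invasion(rep(1, 10), 1:10), "constant")

  set.seed(3)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    x <- stats::rnorm(n); y <- 0.4 * x + stats::rnorm(n)
    got <- spearman_vs_invasion(x, y)
    orc <- stats::cor.test(rank(x), rank(y), method = "pearson")
    expect_equal(got$rho, unname(orc$estimate), tolerance = 1e-12)
    expect_equal(got$p, orc$p.value, tolerance = 1e-12)
  }
})

test_that("ICC is 1 for identical observers, symmetric, and matches aov oracle", {
  set.seed(4)
  x <- stats::rnorm(30, 10, 3)
  same <- icc_two_observers(x, x)
  expect_equal(same$icc, 1)
  expect_equal(same$ci, c(1, 1))

  y <- x + stats::rnorm(30, 0.5, 1)
  ab <- icc_two_observers(x, y)
  ba <- icc_two_observers(y, x)
  expect_equal(ab$icc, ba$icc, tolerance = 1e-12)
  expect_true(ab$ci[1] <= ab$icc && ab$icc <= ab$ci[2])

  for (i in 1:20) {
    n <- sample(5:40, 1)
    a <- stats::rnorm(n, 5, 2)
    b <- 0.8 * a + stats::rnorm(n, 0, 1.5)
    expect_equal(icc_two_observers(a, b)$icc, oracle_icc(a, b),
                 tolerance = 1e-9)
  }

  # independent observers at large n agree only by chance
  a <- stats::rnorm(2000); b <- stats::rnorm(2000)
  expect_lt(abs(icc_two_observers(a, b)$icc), 0.08)
  expect_error(icc_two_observers(1:4, 1:4), "at least 5")
})

test_that("VIF screen matches the R-squared definition and removes collinear features", {
  set.seed(5)
  n <- 300
  d <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n), c = stats::rnorm(n))
  res <- vif_screen(d, c("a", "b", "c"))
  expect_setequal(res$retained, c("a", "b", "c"))
  expect_true(all(res$steps$vif < 1.1))
  # VIF values equal 1/(1-R^2) computed independently
  for (f in c("a", "b", "c")) {
    r2 <- summary(stats::lm(stats::reformulate(setdiff(c("a", "b", "c"), f), f),
                            data = d))$r.squared
    expect_equal(res$steps$vif[res$steps$feature == f], 1 / (1 - r2),
                 tolerance = 1e-9)
  }

  d$dup <- d$a
  res2 <- vif_screen(d, c("a", "b", "c", "dup"))
  expect_length(intersect(c("a", "dup"), res2$removed), 1)

  d$s <- d$a + d$b + stats::rnorm(n, 0, 0.05)
  res3 <- vif_screen(d[, c("a", "b", "c", "s")], c("a", "b", "c", "s"))
  expect_true("s" %in% res3$removed || all(c("a", "b") %in% res3$removed))
})

test_that("stepwise logistic keeps a strong predictor and flags separation", {
  set.seed(6)
  n <- 200
  d <- data.frame(x1 = stats::rnorm(n), x2 = stats::rnorm(n), x3 = stats::rnorm(n))
  p <- stats::plogis(-0.3 + 1.5 * d$x1)
  d$y <- stats::runif(n) < p
  m <- stepwise_logistic(d, "y", c("x1", "x2", "x3"))
  expect_true("x1" %in% m$retained)
  expect_true(all(m$coefficients$ci_low <= m$coefficients$odds_ratio &
                    m$coefficients$odds_ratio <= m$coefficients$ci_high))
  expect_true(all(m$coefficients$odds_ratio > 0))

  # the removal rule never drops a variable whose LR test P is <= 0.10
  removed <- m$trace[m$trace$action == "removed", ]
  if (nrow(removed)) expect_true(all(removed$lrt_p > 0.10))

  sep <- data.frame(x = c(-3, -2, -1, 1, 2, 3), y = c(0, 0, 0, 1, 1, 1))
  expect_error(stepwise_logistic(sep, "y", "x"), "separation")

  one_class <- data.frame(x = stats::rnorm(10), y = rep(TRUE, 10))
  expect_error(stepwise_logistic(one_class, "y", "x"), "single-class")
})

test_that("ROC AUC equals pairwise concordance and respects monotone transforms", {
  perfect <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1), ci = FALSE)
  expect_equal(perfect$auc, 1)

  set.seed(7)
  for (i in 1:30) {
    n <- sample(6:50, 1)
    s <- sample(round(stats::rnorm(n, 0, 2), 1))  # ties likely
    l <- stats::runif(n) < 0.5
    if (!any(l)) l[1] <- TRUE
    if (all(l)) l[1] <- FALSE
    r <- roc_auc(s, l, ci = FALSE)
    expect_equal(r$auc, oracle_auc(s, l))
    # strictly monotone transform leaves AUC unchanged
    r2 <- roc_auc(exp(s / 2), l, ci = FALSE)
    expect_equal(r2$auc, r$auc)
  }

  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")

  # bootstrap CI is reproducible and brackets the point estimate
  set.seed(8)
  s <- stats::rnorm(100); l <- stats::runif(100) < stats::plogis(s)
  if (!any(l)) l[1] <- TRUE
  if (all(l)) l[1] <- FALSE
  r1 <- roc_auc(s, l, n_boot = 200, seed = 9L)
  r2 <- roc_auc(s, l, n_boot = 200, seed = 9L)
  expect_identical(r1$ci, r2$ci)
  expect_true(r1$ci[1] <= r1$auc && r1$auc <= r1$ci[2])
})

test_that("threshold rule is an inclusive AND and PPV matches counting", {
  rule <- threshold_rule()
  f <- data.frame(
    p75_hu = c(-400, -500, -470, -470, -460),
    entropy_bits = c(8.0, 8.5, 7.90, 7.89, 8.1)
  )
  expect_equal(apply_rule(f, rule), c(TRUE, FALSE, TRUE, FALSE, TRUE))

  truth <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  ev <- evaluate_rule(f, truth, rule, seed = 1L)
  pred <- apply_rule(f, rule)
  expect_equal(ev$n_positive, sum(pred))
  expect_equal(ev$ppv, sum(pred & truth) / sum(pred))
  expect_equal(ev$sensitivity, sum(pred & truth) / sum(truth))
  expect_equal(ev$specificity, sum(!pred & !truth) / sum(!truth))

  expect_error(apply_rule(data.frame(p75_hu = 1), rule), "entropy_bits")
})
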