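# Inference chain for a nodule feature table: group comparison with
# Bonferroni correction, correlation with invasion extent, interobserver
# agreement, multicollinearity screening, backward-stepwise logistic
# selection, ROC analysis and the two-threshold invasiveness rule.

#' One-way ANOVA with Bonferroni post hoc comparisons
#'
#' Classic one-way ANOVA across the pathologic classes, pooled-variance
#' pairwise t tests with Bonferroni multiplication by the number of pairs,
#' and a family-level Bonferroni correction of the overall P by
#' `family_size` (the number of variables tested in the same family, e.g.
#' 2 for size variables, 7 for histogram variables).
#'
#' @param values numeric response.
#' @param groups factor (or coercible) of group labels, >= 2 levels with
#'   n >= 2 each.
#' @param family_size Bonferroni family factor for the overall P.
#' @return list with `f`, `df`, `p_raw`, `p_family` and `posthoc`, a data
#'   frame of pairwise comparisons (`group1`, `group2`, `p`).
#' @export
anova_with_posthoc <- function(values, groups, family_size = 1) {
  groups <- factor(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs n >= 2")
  wvar <- tapply(values, groups, stats::var)
  if (all(wvar == 0)) stop("zero within-group variance in all groups")
  fit <- stats::lm(values ~ groups)
  an <- stats::anova(fit)
  f <- an$`F value`[1]
  p_raw <- an$`Pr(>F)`[1]
  pt <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  pm <- pt$p.value
  pairs <- which(!is.na(pm), arr.ind = TRUE)
  posthoc <- data.frame(
    group1 = colnames(pm)[pairs[, 2]],
    group2 = rownames(pm)[pairs[, 1]],
    p = pm[pairs],
    stringsAsFactors = FALSE
  )
  list(f = f, df = an$Df[1:2], p_raw = p_raw,
       p_family = min(1, p_raw * family_size), posthoc = posthoc)
}

#' Spearman correlation with the extent of invasion
#'
#' Spearman rho between a feature and the pathologic invasion extent, with
#' a two-sided P from the t approximation on ranks (equivalent to a Pearson
#' test on rank-transformed data).
#'
#' @param x,y numeric vectors of equal length >= 4, neither constant.
#' @return list with `rho` and `p`.
#' @export
spearman_vs_invasion <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(rho = rho, p = p)
}

#' Two-observer intraclass correlation coefficient
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC (ICC(A,1)
#' in the McGraw-Wong taxonomy), computed from the repeated-measures ANOVA
#' mean squares, with the F-based 95% confidence interval.
#'
#' @param obs1,obs2 paired measurements from the two observers, n >= 5.
#' @param conf_level confidence level for the interval.
#' @return list with `icc`, `ci` (length 2) and the mean squares
#'   (`ms_rows`, `ms_cols`, `ms_error`).
#' @export
icc_two_observers <- function(obs1, obs2, conf_level = 0.95) {
  ok <- is.finite(obs1) & is.finite(obs2)
  x <- cbind(obs1[ok], obs2[ok])
  n <- nrow(x); k <- 2
  if (n < 5) stop("need at least 5 paired measurements for the ICC")
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ss_rows <- k * sum((rm_ - grand)^2)
  ss_cols <- n * sum((cm - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    ci <- c(1, 1)
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lo, hi)
  }
  list(icc = icc, ci = ci, ms_rows = msr, ms_cols = msc, ms_error = mse)
}

#' Variance-inflation-factor multicollinearity screen
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing candidate j on the remaining
#' candidates. Candidates are removed one at a time, largest VIF first,
#' until all remaining VIFs are at or below the threshold. A perfectly
#' collinear candidate has infinite VIF and is removed first.
#'
#' @param table data frame containing the candidate columns.
#' @param candidates character vector of >= 2 column names.
#' @param threshold VIF threshold (default 10).
#' @return list with `retained`, `removed` (in removal order) and `steps`,
#'   a data frame of the VIFs at each round.
#' @export
vif_screen <- function(table, candidates, threshold = 10) {
  stopifnot(length(candidates) >= 2, all(candidates %in% names(table)))
  dat <- table[, candidates, drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) <= length(candidates) + 1) {
    stop("need n > number of candidates + 1")
  }
  vif_one <- function(j, cols) {
    fit <- stats::lm(stats::reformulate(cols[cols != j], response = j),
                     data = dat)
    # a perfectly collinear candidate triggers a "perfect fit" warning on
    # purpose; its VIF is reported as +Inf below
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  retained <- candidates
  removed <- character(0)
  steps <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    vifs <- vapply(retained, vif_one, numeric(1), cols = retained)
    steps[[round]] <- data.frame(round = round, feature = retained,
                                 vif = unname(vifs), stringsAsFactors = FALSE)
    if (all(vifs <= threshold) || length(retained) == 2) break
    worst <- retained[which.max(vifs)]
    removed <- c(removed, worst)
    retained <- setdiff(retained, worst)
  }
  list(retained = retained, removed = removed, steps = do.call(rbind, steps))
}

# Perfect-separation diagnostic for a fitted binomial glm.
.check_separation <- function(fit, y) {
  p <- stats::fitted(fit)
  eps <- 1e-7
  if (length(unique(y)) == 2 &&
      all(p[y == 1] > 1 - eps) && all(p[y == 0] < eps)) {
    stop("perfect separation detected: logistic estimates diverge; ",
         "odds ratios are not identifiable for this candidate set")
  }
  invisible(fit)
}

#' Backward-stepwise logistic regression
#'
#' Fits the full binomial logistic model of a binary outcome (invasive vs.
#' pre-/minimally invasive) on the candidate features, then eliminates
#' backward: at each step the variable whose likelihood-ratio removal test
#' has the largest P is dropped if that P exceeds `remove_level` (default
#' 0.10); selection stops when every remaining variable has removal-test
#' P <= `remove_level`. Candidates are expected to be pre-screened (ANOVA
#' P < 0.10 and a VIF screen).
#'
#' @param table data frame with outcome and candidate columns.
#' @param outcome name of a logical/0-1 column (TRUE = invasive) .
#' @param candidates character vector of candidate feature columns.
#' @param remove_level likelihood-ratio removal level (default 0.10).
#' @return object of class `logistic_model`: list with `fit` (the final
#'   `glm`), `retained`, `coefficients` (data frame: variable, odds_ratio,
#'   ci_low, ci_high, p_wald), and `trace`, one row per elimination step.
#' @export
stepwise_logistic <- function(table, outcome, candidates, remove_level = 0.10) {
  stopifnot(outcome %in% names(table), all(candidates %in% names(table)))
  dat <- table[, c(outcome, candidates), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  y <- as.integer(as.logical(dat[[outcome]]))
  if (length(unique(y)) < 2) stop("single-class outcome: both classes required")
  dat[[outcome]] <- y
  current <- candidates
  trace <- list()
  step_i <- 0L
  fit_model <- function(vars) {
    form <- if (length(vars) == 0) {
      stats::reformulate("1", response = outcome)
    } else {
      stats::reformulate(vars, response = outcome)
    }
    fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = dat))
    .check_separation(fit, y)
    fit
  }
  fit <- fit_model(current)
  repeat {
    if (length(current) == 0) break
    d1 <- suppressWarnings(stats::drop1(fit, test = "LRT"))
    pvals <- d1$`Pr(>Chi)`[-1]
    names(pvals) <- rownames(d1)[-1]
    worst <- names(pvals)[which.max(pvals)]
    step_i <- step_i + 1L
    trace[[step_i]] <- data.frame(
      step = step_i, candidate = worst, lrt_p = max(pvals),
      action = if (max(pvals) > remove_level) "removed" else "stop",
      stringsAsFactors = FALSE
    )
    if (max(pvals) <= remove_level) break
    current <- setdiff(current, worst)
    fit <- fit_model(current)
  }
  sm <- summary(fit)$coefficients
  rows <- setdiff(rownames(sm), "(Intercept)")
  z <- stats::qnorm(0.975)
  coef_tab <- data.frame(
    variable = rows,
    odds_ratio = exp(sm[rows, "Estimate"]),
    ci_low = exp(sm[rows, "Estimate"] - z * sm[rows, "Std. Error"]),
    ci_high = exp(sm[rows, "Estimate"] + z * sm[rows, "Std. Error"]),
    p_wald = sm[rows, "Pr(>|z|)"],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(list(
    fit = fit, retained = current, coefficients = coef_tab,
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(step = integer(0), candidate = character(0),
                 lrt_p = numeric(0), action = character(0)),
    remove_level = remove_level
  ), class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Backward-stepwise logistic model\n")
  cat("Retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(intercept only)", "\n")
  if (nrow(x$coefficients)) print(x$coefficients, digits = 3)
  invisible(x)
}

#' ROC curve and AUC with bootstrap confidence interval
#'
#' AUC by the trapezoidal rule over all score thresholds with half credit
#' for ties (equivalently the Mann-Whitney concordance probability). The
#' confidence interval is a seeded stratified bootstrap (resampling within
#' each class).
#'
#' @param scores numeric predictor (higher = more likely positive).
#' @param labels logical/0-1 truth; both classes must be present.
#' @param n_boot bootstrap resamples for the CI (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param conf_level confidence level.
#' @param ci compute the bootstrap CI (disable for speed in simulations).
#' @return object of class `roc_result`: list with `auc`, `ci`,
#'   `n_pos`, `n_neg` and `points`, a data frame of operating points
#'   (threshold, sensitivity, specificity).
#' @export
roc_auc <- function(scores, labels, n_boot = 2000, seed = 1L,
                    conf_level = 0.95, ci = TRUE) {
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels)) stop("both classes must be present")
  auc_of <- function(s, l) {
    r <- rank(s)
    n1 <- sum(l); n0 <- sum(!l)
    (sum(r[l]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_of(scores, labels)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1))
  points <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  ci_est <- c(NA_real_, NA_real_)
  if (ci) {
    pos <- which(labels); neg <- which(!labels)
    ci_est <- with_seed(seed, {
      boots <- vapply(seq_len(n_boot), function(b) {
        i <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
        auc_of(scores[i], labels[i])
      }, numeric(1))
      alpha <- 1 - conf_level
      unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), type = 7))
    })
  }
  structure(list(auc = auc, ci = ci_est, n_pos = sum(labels),
                 n_neg = sum(!labels), points = points),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC AUC = %.3f", x$auc))
  if (!any(is.na(x$ci))) cat(sprintf(" (95%% CI: %.3f-%.3f)", x$ci[1], x$ci[2]))
  cat(sprintf("  [%d positive / %d negative]\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' Two-threshold invasiveness rule
#'
#' A nodule is called invasive when BOTH conditions hold: 75th-percentile
#' attenuation >= `p75_cutoff_hu` and entropy >= `entropy_cutoff_bits`.
#' Both comparisons are inclusive. Defaults are the published operating
#' point (-470 HU, 7.90 bits).
#'
#' @param p75_cutoff_hu 75th-percentile HU cutoff.
#' @param entropy_cutoff_bits entropy cutoff in bits.
#' @return object of class `threshold_rule`.
#' @export
threshold_rule <- function(p75_cutoff_hu = -470, entropy_cutoff_bits = 7.90) {
  structure(list(p75_cutoff_hu = p75_cutoff_hu,
                 entropy_cutoff_bits = entropy_cutoff_bits,
                 combination = "AND"),
            class = "threshold_rule")
}

#' Apply the invasiveness rule to feature rows
#'
#' @param features data frame with `p75_hu` and `entropy_bits` columns.
#' @param rule a [threshold_rule()].
#' @return logical vector, TRUE = predicted invasive.
#' @export
apply_rule <- function(features, rule = threshold_rule()) {
  stopifnot(inherits(rule, "threshold_rule"))
  need <- c("p75_hu", "entropy_bits")
  if (!all(need %in% names(features))) {
    stop("features must contain p75_hu and entropy_bits")
  }
  p75 <- features$p75_hu; ent <- features$entropy_bits
  if (any(is.na(p75)) || any(is.na(ent))) stop("missing p75_hu or entropy_bits")
  p75 >= rule$p75_cutoff_hu & ent >= rule$entropy_cutoff_bits
}

#' Cohort-level evaluation of the invasiveness rule
#'
#' @param features feature data frame (see [apply_rule()]).
#' @param truth_invasive logical/0-1 truth per row.
#' @param rule a [threshold_rule()].
#' @param seed seed for the binary-rule ROC bootstrap CI.
#' @return list with counts (`n_positive`, `n_true_positive`), `ppv`,
#'   `sensitivity`, `specificity` and `roc` (the binary rule treated as a
#'   0/1 score).
#' @export
evaluate_rule <- function(features, truth_invasive, rule = threshold_rule(),
                          seed = 1L) {
  pred <- apply_rule(features, rule)
  truth <- as.logical(truth_invasive)
  stopifnot(length(pred) == length(truth))
  n_pos <- sum(pred)
  n_tp <- sum(pred & truth)
  list(
    n_positive = n_pos,
    n_true_positive = n_tp,
    ppv = if (n_pos > 0) n_tp / n_pos else NA_real_,
    sensitivity = sum(pred & truth) / sum(truth),
    specificity = sum(!pred & !truth) / sum(!truth),
    roc = roc_auc(as.numeric(pred), truth, seed = seed)
  )
}
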