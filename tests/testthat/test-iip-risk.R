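# logistic risk classifier, operating thresholds, prevalence, rank tests

make_features <- function(n0, n1, sep = 2, seed = 1L, p = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n0 * p, 0), n0, p),
             matrix(rnorm(n1 * p, -sep), n1, p))
  colnames(x) <- paste0("adj_density_f", seq_len(p))
  list(x = x, y = rep(c(0, 1), c(n0, n1)))
}

test_that("the IRLS fit matches glm on an 8-point toy set", {
  x <- matrix(c(0.1, 0.5, 0.9, 1.3, 1.8, 2.2, 2.6, 3.0,
                1.0, -0.5, 0.3, 0.8, -1.2, 0.1, 0.6, -0.3), 8, 2)
  y <- c(0, 0, 1, 0, 1, 1, 0, 1)
  ours <- logistic_ridge_fit(x, y, lambda = 0)
  ref <- coef(glm(y ~ x, family = binomial()))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("separable features give cross-validated AUC above 0.99", {
  f <- make_features(60, 40, sep = 6)
  model <- fit_iip_classifier(f$x, f$y)
  expect_gt(rank_auc(model$cv_scores, f$y), 0.99)
  expect_equal(model$yi_threshold >= 0 && model$yi_threshold <= 1, TRUE)
})

test_that("permuted labels give chance-level AUC", {
  f <- make_features(60, 40, sep = 2)
  aucs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    yperm <- sample(f$y)
    model <- fit_iip_classifier(f$x, yperm, seed = s)
    rank_auc(model$cv_scores, yperm)
  }, numeric(1))
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("classifier preconditions are enforced", {
  f <- make_features(30, 30)
  expect_error(fit_iip_classifier(f$x, rep(0, 60)), "both classes")
  expect_error(fit_iip_classifier(f$x[1:10, ], f$y[c(1:5, 56:60)]),
               "at least 20")
})

test_that("thresholds match an exhaustive search oracle", {
  set.seed(8)
  scores <- runif(40)
  labels <- rbinom(40, 1, plogis(4 * (scores - 0.5)))
  labels[1:2] <- c(0, 1)  # both classes guaranteed
  thr <- select_thresholds(scores, labels, spec_target = 0.8)
  s <- sort(unique(scores))
  cand <- (s[-1] + s[-length(s)]) / 2
  sens <- vapply(cand, function(t) mean(scores[labels == 1] >= t), 1)
  spec <- vapply(cand, function(t) mean(scores[labels == 0] < t), 1)
  yi_brute <- cand[which.max(sens + spec - 1)]
  spec_brute <- cand[which(spec >= 0.8)[1]]
  expect_equal(thr$yi_threshold, yi_brute)
  expect_equal(thr$spec95_threshold, spec_brute)
  # contract: specificity at the screening threshold reaches the target
  at <- thr$roc[thr$roc$threshold == thr$spec95_threshold, ]
  expect_gte(at$specificity, 0.8)
})

test_that("perfectly separated scores reach sensitivity = specificity = 1", {
  scores <- c(runif(10, 0, 0.3), runif(10, 0.7, 1))
  labels <- rep(c(0, 1), each = 10)
  thr <- select_thresholds(scores, labels)
  for (t in c(thr$yi_threshold, thr$spec95_threshold)) {
    expect_equal(mean(scores[labels == 1] >= t), 1)
    expect_equal(mean(scores[labels == 0] < t), 1)
  }
})

test_that("an unreachable specificity target is an error", {
  scores <- c(0.9, 0.9, 0.1, 0.2, 0.3)
  labels <- c(0, 0, 1, 1, 1)  # negatives sit at the top: spec always 0
  expect_error(select_thresholds(scores, labels), "specificity")
})

test_that("scores are probabilities and behave monotonically", {
  f <- make_features(50, 50, sep = 2, seed = 5L)
  model <- fit_iip_classifier(f$x, f$y)
  sc <- score_subjects(model, f$x, group = rep(c("normative", "IIP"),
                                               each = 50))
  expect_true(all(sc$risk >= 0 & sc$risk <= 1))
  # balanced training data: score at the feature mean is near 0.5
  at_mean <- score_subjects(model, rbind(colMeans(f$x)))
  expect_lt(abs(at_mean$risk - 0.5), 0.15)
  # the density coefficients are negative: lowering density raises risk
  expect_true(all(model$coefficients[-1] < 0))
  lower <- rbind(colMeans(f$x) - c(1, 0))
  colnames(lower) <- colnames(f$x)
  expect_gt(score_subjects(model, lower)$risk, at_mean$risk)
})

test_that("missing features are scored as missing, with a warning", {
  f <- make_features(30, 30)
  model <- fit_iip_classifier(f$x, f$y)
  xm <- f$x
  xm[3, 1] <- NA
  expect_warning(sc <- score_subjects(model, xm), "missing")
  expect_true(is.na(sc$risk[3]))
  expect_false(anyNA(sc$risk[-3]))
  expect_error(score_subjects(model, f$x[, 1, drop = FALSE]),
               "missing feature column")
})

test_that("prevalence equals a direct count and hits both extremes", {
  sc <- data.frame(risk = c(0.1, 0.6, 0.9, 0.2, 0.8, 0.85),
                   group = rep(c("A", "B"), each = 3))
  prev <- estimate_prevalence(sc, 0.7)
  expect_equal(prev$percent[prev$group == "A"], 100 * 1 / 3)
  expect_equal(prev$percent[prev$group == "B"], 100 * 2 / 3)
  expect_equal(estimate_prevalence(sc, 0.95)$percent, c(0, 0))
  expect_equal(estimate_prevalence(sc, 0)$percent, c(100, 100))
})

test_that("prevalence is monotone non-increasing in the threshold", {
  set.seed(10)
  sc <- data.frame(risk = runif(200),
                   group = sample(c("A", "B", "C"), 200, replace = TRUE))
  thresholds <- seq(0, 1, by = 0.05)
  prev <- sapply(thresholds, function(t) estimate_prevalence(sc, t)$percent)
  expect_true(all(apply(prev, 1, function(p) all(diff(p) <= 0))))
})

test_that("the U statistic matches exhaustive pair counting on 4 vs 3", {
  x <- c(0.9, 0.4, 0.7, 0.55)
  y <- c(0.3, 0.6, 0.2)
  sc <- data.frame(risk = c(x, y),
                   group = rep(c("A", "B"), c(4, 3)))
  cmp <- compare_risk_distributions(sc, pairs = list(c("A", "B")))
  u_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(cmp$U, u_brute)
})

test_that("copied distributions are not significant after Bonferroni", {
  v <- c(0.1, 0.35, 0.5, 0.62, 0.8)
  sc <- data.frame(risk = c(v, v, v + 0.3),
                   group = rep(c("A", "B", "C"), each = 5))
  cmp <- compare_risk_distributions(sc, pairs = list(c("A", "B"),
                                                     c("C", "B")))
  expect_equal(cmp$p_bonferroni[1], 1)
  expect_true(all(cmp$p_bonferroni >= cmp$p))
  expect_equal(unique(cmp$m_comparisons), 2)
})

test_that("undersized risk groups are rejected", {
  sc <- data.frame(risk = c(0.5, 0.1, 0.2), group = c("A", "B", "B"))
  expect_error(compare_risk_distributions(sc, pairs = list(c("A", "B"))),
               "at least 2")
})

test_that("Spearman correlation matches the rank formula and is symmetric", {
  risk <- c(0.12, 0.5, 0.31, 0.78, 0.44, 0.91)
  age <- c(0.4, 2.2, 1.1, 5.6, 3.3, 4.8)
  out <- correlate_risk_age(risk, age)
  d <- rank(risk) - rank(age)
  rho_hand <- 1 - 6 * sum(d^2) / (6 * (36 - 1))
  expect_equal(out$rho, rho_hand, tolerance = 1e-12)
  expect_equal(out$rho, correlate_risk_age(age, risk)$rho)
  # strictly monotone association
  expect_equal(correlate_risk_age(sort(risk), sort(age))$rho, 1)
})

test_that("degenerate correlation inputs are handled explicitly", {
  expect_error(correlate_risk_age(c(0.1, 0.2), c(1, 2)), "at least 3")
  expect_warning(out <- correlate_risk_age(rep(0.5, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
})

test_that("the feature builder produces one adjusted column per region", {
  cohort <- simulate_cohort(small_cohort_design(rng_seed = 9L))
  fb <- adjusted_density_features(cohort)
  expect_equal(colnames(fb$features),
               paste0("adj_density_", study_regions()))
  expect_equal(nrow(fb$features), nrow(cohort))
  expect_named(fb$fits, study_regions())
  # adjusted feature equals manual adjustment for a spot-checked region
  manual <- adjust_measurements(cohort, fb$fits$global)
  expect_equal(unname(fb$features[, "adj_density_global"]), manual)
})
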