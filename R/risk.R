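#' Ridge-penalised logistic regression by IRLS
#'
#' Maximum-likelihood logistic fit via iteratively reweighted least squares,
#' with an optional L2 penalty on the non-intercept coefficients to keep
#' separable inputs finite. With `lambda = 0` this is the plain ML fit.
#'
#' @param x Numeric feature matrix (no intercept column).
#' @param y Binary response (0/1).
#' @param lambda Ridge penalty (0 = none).
#' @param max_iter,tol IRLS controls.
#' @return Named coefficient vector (`(Intercept)` first).
#' @export
logistic_ridge_fit <- function(x, y, lambda = 0, max_iter = 100L,
                               tol = 1e-10) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  X <- cbind(`(Intercept)` = 1, x)
  y <- as.numeric(y)
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  setNames(as.vector(beta), colnames(X))
}

# Deterministic stratified k-fold assignment.
#' @keywords internal
stratified_folds <- function(y, nfolds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

#' Fit the IIP risk classifier on adjusted bone densities
#'
#' Logistic classifier separating the chronic-IIP reference group from
#' normative subjects on covariate-adjusted bone density features (global
#' plus per-bone). Out-of-fold cross-validated probabilities are retained
#' and used to choose the operating thresholds (Youden index and
#' 95%-specificity); the returned coefficients come from a final fit on all
#' data.
#'
#' @param x Feature matrix or data.frame (adjusted densities).
#' @param y Binary labels (1 = IIP, 0 = normative).
#' @param lambda Light ridge penalty; keeps separable data finite.
#' @param nfolds Stratified cross-validation folds.
#' @param seed Seed for fold assignment.
#' @param spec_target Specificity for the screening threshold.
#' @return A `risk_model` list: `coefficients`, `feature_names`, `lambda`,
#'   `cv` (scheme), `cv_scores`, `labels`, `roc`, `yi_threshold`,
#'   `spec95_threshold`.
#' @export
fit_iip_classifier <- function(x, y, lambda = 1e-4, nfolds = 10L, seed = 1L,
                               spec_target = 0.95) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  if (length(y) < 20)
    stop("need at least 20 subjects to fit the classifier", call. = FALSE)
  nfolds <- min(nfolds, min(table(y)))
  fold <- stratified_folds(y, nfolds, seed)
  cv_scores <- rep(NA_real_, length(y))
  for (k in seq_len(nfolds)) {
    tr <- fold != k
    b <- logistic_ridge_fit(x[tr, , drop = FALSE], y[tr], lambda = lambda)
    cv_scores[!tr] <- plogis(b[1] +
                               as.vector(x[!tr, , drop = FALSE] %*% b[-1]))
  }
  beta <- logistic_ridge_fit(x, y, lambda = lambda)
  thr <- select_thresholds(cv_scores, y, spec_target = spec_target)
  structure(
    list(coefficients = beta, feature_names = colnames(x), lambda = lambda,
         cv = list(scheme = "stratified k-fold", nfolds = nfolds,
                   seed = seed),
         cv_scores = cv_scores, labels = y, roc = thr$roc,
         yi_threshold = thr$yi_threshold,
         spec95_threshold = thr$spec95_threshold),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> ", length(x$feature_names), " features, ",
      x$cv$nfolds, "-fold CV, YI threshold ", round(x$yi_threshold, 3),
      ", ", "95%-specificity threshold ", round(x$spec95_threshold, 3),
      "\n", sep = "")
  invisible(x)
}

#' Operating thresholds from cross-validated scores
#'
#' Candidate thresholds are the midpoints of consecutive sorted unique
#' scores; a score at or above the threshold counts as positive. The Youden
#' threshold maximises sensitivity + specificity - 1 (smallest maximiser on
#' ties); the screening threshold is the smallest candidate with
#' specificity at least `spec_target`.
#'
#' @param scores Classifier probabilities.
#' @param labels Binary labels aligned with `scores`.
#' @param spec_target Required specificity.
#' @return List: `yi_threshold`, `spec95_threshold`, `roc` (data.frame of
#'   threshold, sensitivity, specificity, youden).
#' @export
select_thresholds <- function(scores, labels, spec_target = 0.95) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  s <- sort(unique(scores))
  if (length(s) < 2) stop("need at least two distinct scores", call. = FALSE)
  cand <- (s[-1] + s[-length(s)]) / 2
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
  roc <- data.frame(threshold = cand, sensitivity = sens, specificity = spec,
                    youden = sens + spec - 1)
  yi <- cand[which.max(roc$youden)]
  ok <- which(spec >= spec_target)
  if (!length(ok))
    stop("no threshold reaches specificity ", spec_target, call. = FALSE)
  list(yi_threshold = yi, spec95_threshold = cand[min(ok)], roc = roc)
}

#' Probabilistic IIP risk of subjects
#'
#' Applies the logistic model to per-subject features. Subjects with any
#' missing feature get `NA` risk with a warning.
#'
#' @param model A `risk_model`.
#' @param x Feature matrix/data.frame with the model's feature columns.
#' @param group Optional group label per subject.
#' @return Data frame with `risk` (probability in `[0, 1]`) and `group`.
#' @export
score_subjects <- function(model, x, group = NULL) {
  stopifnot(inherits(model, "risk_model"))
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && !is.null(model$feature_names)) {
    miss <- setdiff(model$feature_names, colnames(x))
    if (length(miss))
      stop("missing feature column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    x <- x[, model$feature_names, drop = FALSE]
  }
  bad <- rowSums(is.na(x)) > 0
  if (any(bad))
    warning(sum(bad), " subject(s) with missing features scored as NA")
  b <- model$coefficients
  risk <- rep(NA_real_, nrow(x))
  risk[!bad] <- plogis(b[1] + as.vector(x[!bad, , drop = FALSE] %*% b[-1]))
  data.frame(risk = risk,
             group = if (is.null(group)) NA_character_ else as.character(group))
}

#' Estimated prevalence of IIP signs per group
#'
#' Percentage of each group whose risk probability is at or above the
#' operating threshold.
#'
#' @param scores Data frame from [score_subjects()] (`risk`, `group`).
#' @param threshold Probability threshold.
#' @return Data frame: `group`, `n`, `percent`.
#' @export
estimate_prevalence <- function(scores, threshold) {
  sp <- split(scores$risk, scores$group)
  out <- data.frame(
    group = names(sp),
    n = vapply(sp, function(r) sum(!is.na(r)), integer(1)),
    percent = vapply(sp, function(r) {
      r <- r[!is.na(r)]
      if (!length(r)) NA_real_ else 100 * mean(r >= threshold)
    }, numeric(1))
  )
  rownames(out) <- NULL
  out
}

#' Nonparametric comparison of risk distributions between groups
#'
#' Two-sided Mann-Whitney U test per group pair with Bonferroni adjustment
#' over the pairs actually compared.
#'
#' @param scores Data frame from [score_subjects()].
#' @param pairs List of length-2 character vectors; `NULL` compares every
#'   non-reference group against the first group present.
#' @return Data frame: `pair`, `U`, `p`, `p_bonferroni`, `m_comparisons`.
#' @export
compare_risk_distributions <- function(scores, pairs = NULL) {
  groups <- unique(scores$group[!is.na(scores$risk)])
  if (is.null(pairs)) {
    ref <- groups[1]
    pairs <- lapply(setdiff(groups, ref), function(g) c(g, ref))
  }
  m <- length(pairs)
  out <- lapply(pairs, function(pr) {
    x <- scores$risk[scores$group == pr[1] & !is.na(scores$risk)]
    y <- scores$risk[scores$group == pr[2] & !is.na(scores$risk)]
    if (length(x) < 2 || length(y) < 2)
      stop("each group needs at least 2 observations (",
           pr[1], ", ", pr[2], ")", call. = FALSE)
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    data.frame(pair = paste(pr[1], "versus", pr[2]),
               U = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, out)
  out$p_bonferroni <- pmin(1, m * out$p)
  out$m_comparisons <- m
  out
}

#' Spearman correlation between IIP risk and age
#'
#' Tie-corrected Spearman rank correlation with a two-sided p-value. A
#' constant input leaves the correlation undefined (`NA`, with warning).
#'
#' @param risk Risk probabilities.
#' @param age Ages (years).
#' @return List: `rho`, `p`, `n`.
#' @export
correlate_risk_age <- function(risk, age) {
  keep <- !is.na(risk) & !is.na(age)
  risk <- risk[keep]; age <- age[keep]
  n <- length(risk)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (sd(risk) == 0 || sd(age) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  ct <- suppressWarnings(cor.test(risk, age, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Adjusted-density feature matrix for the risk classifier
#'
#' Builds the classifier features (covariate-adjusted density, global and
#' per region) for every subject of a cohort, using per-region fits of the
#' normative model.
#'
#' @param cohort Data frame from [simulate_cohort()].
#' @param regions Density regions to use as features.
#' @param fits Optional named list of `normative_fit` objects per region
#'   (fitted on `cohort` when omitted).
#' @param groups Indicator set passed to [fit_normative_regression()].
#' @return List: `features` (matrix, columns `adj_density_<region>`),
#'   `fits`.
#' @export
adjusted_density_features <- function(cohort, regions = study_regions(),
                                      fits = NULL,
                                      groups = study_groups()[-1]) {
  if (is.null(fits)) {
    fits <- lapply(regions, function(r)
      fit_normative_regression(cohort, r, "density", groups = groups))
    names(fits) <- regions
  }
  feats <- vapply(regions, function(r) adjust_measurements(cohort, fits[[r]]),
                  numeric(nrow(cohort)))
  colnames(feats) <- paste0("adj_density_", regions)
  list(features = feats, fits = fits)
}
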