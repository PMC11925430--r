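#' Fit the 10-term normative covariate regression
#'
#' Ordinary least squares of a per-region measurement on intercept, age
#' (years), sex (1 male / 0 female), original voxel volume (mm^3) and the
#' six mutually exclusive diagnostic-group indicators. The fitted group
#' coefficients are the group-vs-normative local differences; the age, sex
#' and voxel-volume coefficients drive covariate adjustment.
#'
#' @param cohort Data frame from [simulate_cohort()] (or the same schema).
#' @param region One of [study_regions()].
#' @param measure `"thickness"` or `"density"`.
#' @param groups Indicator columns to include; the default is the full
#'   six-indicator model. A cohort missing one of the requested groups makes
#'   the design rank deficient, which is reported as an error naming the
#'   collinear column.
#' @return A `normative_fit` list: `coefficients` (named, length 10 for the
#'   full model), `se`, `sigma` (residual SD), `n`, `region`, `measure`.
#' @export
fit_normative_regression <- function(cohort, region = "global",
                                     measure = c("density", "thickness"),
                                     groups = study_groups()[-1]) {
  measure <- match.arg(measure)
  ycol <- paste(measure, region, sep = "_")
  if (!ycol %in% names(cohort))
    stop("cohort has no column ", ycol, call. = FALSE)
  n <- nrow(cohort)
  if (n <= 10) stop("need more than 10 subjects to fit the 10-term model",
                    call. = FALSE)
  X <- design_matrix(cohort, groups = groups)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "),
         " (is a diagnostic group absent?)", call. = FALSE)
  }
  y <- cohort[[ycol]]
  fit <- lm(y ~ X - 1)
  beta <- setNames(coef(fit), colnames(X))
  # residual SD computed directly (summary.lm warns on noiseless fits)
  sigma <- sqrt(sum(residuals(fit)^2) / fit$df.residual)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- setNames(sigma * sqrt(diag(XtXinv)), colnames(X))
  structure(
    list(coefficients = beta, se = se, sigma = sigma,
         n = n, region = region, measure = measure),
    class = "normative_fit"
  )
}

#' @export
print.normative_fit <- function(x, ...) {
  cat("<normative_fit> ", x$measure, " / ", x$region, ", n = ", x$n,
      ", residual SD = ", signif(x$sigma, 4), "\n", sep = "")
  print(round(rbind(beta = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Covariate-adjusted measurements
#'
#' Removes the fitted age, sex and voxel-volume effects from the observed
#' measurement: `adjusted = observed - (b_age * age + b_sex * sex +
#' b_vox * voxel_vol)`. Diagnostic-group effects are deliberately retained —
#' they are the signal of interest.
#'
#' @param cohort Data frame with `age`, `sex`, `voxel_vol` and the
#'   measurement column of `fit`.
#' @param fit A `normative_fit`.
#' @return Numeric vector of adjusted values (`NA` where the measurement is
#'   missing).
#' @export
adjust_measurements <- function(cohort, fit) {
  stopifnot(inherits(fit, "normative_fit"))
  ycol <- paste(fit$measure, fit$region, sep = "_")
  if (!ycol %in% names(cohort))
    stop("cohort has no column ", ycol, call. = FALSE)
  b <- fit$coefficients
  cohort[[ycol]] - (b[["age"]] * cohort$age + b[["sex"]] * cohort$sex +
                      b[["voxel_vol"]] * cohort$voxel_vol)
}

#' Two-group contrast of adjusted measurements
#'
#' Mean difference of adjusted values between two diagnostic groups, its
#' standard error, and a two-sided Welch t-test p-value. If both groups are
#' numerically identical (zero variance, zero difference) the degenerate
#' answer (difference 0, p = 1) is returned directly.
#'
#' @param adjusted Numeric vector of adjusted values.
#' @param groups Group label per value.
#' @param pair Length-2 character vector, e.g. `c("MC", "normative")`; the
#'   contrast is `pair[1] - pair[2]`.
#' @return Data frame: `pair`, `mean_diff`, `sd` (standard error of the
#'   difference), `p`, `n1`, `n2`.
#' @export
contrast_groups <- function(adjusted, groups, pair) {
  stopifnot(length(pair) == 2)
  x <- adjusted[groups == pair[1]]
  y <- adjusted[groups == pair[2]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations (",
         pair[1], ": ", length(x), ", ", pair[2], ": ", length(y), ")",
         call. = FALSE)
  md <- mean(x) - mean(y)
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  if (se == 0) {
    p <- if (md == 0) 1 else 0
  } else {
    p <- t.test(x, y, var.equal = FALSE)$p.value
  }
  data.frame(pair = paste(pair[1], "versus", pair[2]), mean_diff = md,
             sd = se, p = p, n1 = length(x), n2 = length(y))
}

#' Full contrast table across regions, measures and group pairs
#'
#' Builds the study-style report: for every region and measure, each
#' patient group versus normative and each craniosynostosis group versus
#' the IIP reference, on covariate-adjusted values from per-region fits of
#' the 10-term model.
#'
#' @param cohort Data frame from [simulate_cohort()].
#' @param regions Regions to report.
#' @param measures Measures to report.
#' @param pairs List of length-2 character vectors; `NULL` for the default
#'   layout (groups vs normative, then CS groups vs IIP).
#' @return Data frame of contrasts with `region` and `measure` columns.
#' @export
contrast_table <- function(cohort, regions = study_regions(),
                           measures = c("thickness", "density"),
                           pairs = NULL) {
  present <- levels(droplevels(factor(cohort$group)))
  if (is.null(pairs)) {
    vs_norm <- lapply(intersect(c("IIP", "MC", "SC", "UCC", "BCC", "AS"),
                                present),
                      function(g) c(g, "normative"))
    vs_iip <- lapply(intersect(c("MC", "SC", "UCC", "BCC", "AS"), present),
                     function(g) c(g, "IIP"))
    pairs <- c(vs_norm, if ("IIP" %in% present) vs_iip)
  }
  out <- list()
  for (measure in measures) {
    for (region in regions) {
      fit <- fit_normative_regression(
        cohort, region, measure,
        groups = intersect(study_groups()[-1], present))
      adj <- adjust_measurements(cohort, fit)
      for (pr in pairs) {
        ct <- contrast_groups(adj, cohort$group, pr)
        out[[length(out) + 1L]] <- cbind(region = region, measure = measure,
                                         ct)
      }
    }
  }
  do.call(rbind, out)
}
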