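#' Study groups and measurement regions
#'
#' The seven diagnostic groups handled by the cohort simulator and the
#' regression model: `normative`, `IIP` (chronic increased intracranial
#' pressure unrelated to craniosynostosis), the nonsyndromic
#' craniosynostosis phenotypes `MC` (metopic), `SC` (sagittal), `UCC`
#' (unicoronal), `BCC` (bicoronal), and `AS` (Apert syndrome). The group
#' indicators of the regression are mutually exclusive; all-zero means
#' normative.
#'
#' @return Character vector of group names.
#' @export
study_groups <- function() {
  c("normative", "IIP", "MC", "SC", "UCC", "BCC", "AS")
}

#' @rdname study_groups
#' @export
study_regions <- function() c("frontal", "parietal", "occipital", "global")

#' @keywords internal
beta_names <- function() {
  c("intercept", "age", "sex", "voxel_vol", "IIP", "MC", "SC", "UCC",
    "BCC", "AS")
}

#' Per-region regression coefficients used by the default simulator
#'
#' Coefficient vectors (intercept, age, sex, voxel volume, six group
#' effects) for thickness (mm) and density (HU) per region. Group effects
#' are the published group-vs-normative local differences for each bone and
#' the whole calvaria; baseline terms (intercept, age, sex, voxel volume)
#' are plausible pediatric values chosen once for simulation (see the
#' methods vignette).
#'
#' @return Named list with elements `thickness` and `density`, each a named
#'   list of length-10 coefficient vectors per region.
#' @export
default_true_betas <- function() {
  nm <- beta_names()
  mk <- function(b0, age, sex, vox, iip, mc, sc, ucc, bcc, as_) {
    setNames(c(b0, age, sex, vox, iip, mc, sc, ucc, bcc, as_), nm)
  }
  list(
    thickness = list(
      frontal   = mk(2.5, 0.40, 0.05, -0.5, 0.06, 0.51, 0.47, 0.43, 0.61, 0.39),
      parietal  = mk(2.3, 0.40, 0.05, -0.5, -0.04, 0.37, 0.37, 0.33, 0.40, 0.24),
      occipital = mk(2.7, 0.40, 0.05, -0.5, 0.18, 0.35, 0.35, 0.31, 0.51, 0.33),
      global    = mk(2.5, 0.40, 0.05, -0.5, 0.04, 0.41, 0.40, 0.37, 0.50, 0.31)
    ),
    density = list(
      frontal   = mk(870, 40, 10, -300, -174.65, -155.80, -140.24, -141.24,
                     -161.63, -255.63),
      parietal  = mk(840, 40, 10, -300, -175.35, -134.10, -165.51, -138.77,
                     -125.55, -197.99),
      occipital = mk(880, 40, 10, -300, -120.31, -94.44, -122.30, -90.68,
                     -95.02, -109.07),
      global    = mk(850, 40, 10, -300, -163.73, -132.92, -149.60, -130.96,
                     -131.84, -196.47)
    )
  )
}

#' Cohort simulation design
#'
#' Describes a multi-group cohort whose per-region thickness and density
#' follow the 10-term linear model (intercept + age + sex + voxel volume +
#' six mutually exclusive group indicators) plus Gaussian residual noise.
#' Defaults mirror the study composition: 1018 normative subjects, 48 with
#' chronic IIP, 79 MC / 242 SC / 63 UCC / 19 BCC nonsyndromic scans and 19
#' Apert-syndrome scans, with the published per-group age, sex-ratio and
#' original-voxel-volume distributions.
#'
#' @param n_per_group Named counts for the [study_groups()].
#' @param age_mean,age_sd Named per-group age distributions (years).
#' @param sex_male_frac Named per-group fraction of male subjects.
#' @param voxel_mean,voxel_sd Named per-group original voxel volume (mm^3).
#' @param true_betas Coefficients as in [default_true_betas()].
#' @param noise_sd Residual SDs, named `thickness` (mm) and `density` (HU).
#' @param rng_seed Integer seed.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(
    n_per_group = c(normative = 1018, IIP = 48, MC = 79, SC = 242, UCC = 63,
                    BCC = 19, AS = 19),
    age_mean = c(normative = 3.08, IIP = 4.23, MC = 0.39, SC = 0.39,
                 UCC = 0.39, BCC = 0.39, AS = 0.25),
    age_sd = c(normative = 3.02, IIP = 3.13, MC = 0.33, SC = 0.33,
               UCC = 0.33, BCC = 0.33, AS = 0.26),
    sex_male_frac = c(normative = 0.5295, IIP = 0.4792, MC = 0.66, SC = 0.66,
                      UCC = 0.66, BCC = 0.66, AS = 0.50),
    voxel_mean = c(normative = 0.105, IIP = 0.095, MC = 0.087, SC = 0.087,
                   UCC = 0.087, BCC = 0.087, AS = 0.056),
    voxel_sd = c(normative = 0.057, IIP = 0.030, MC = 0.045, SC = 0.045,
                 UCC = 0.045, BCC = 0.045, AS = 0.017),
    true_betas = default_true_betas(),
    noise_sd = c(thickness = 0.3, density = 80),
    rng_seed = 1L) {
  groups <- study_groups()
  n_per_group <- n_per_group[groups]
  names(n_per_group) <- groups
  n_per_group[is.na(n_per_group)] <- 0
  if (any(n_per_group < 0)) stop("group counts must be >= 0", call. = FALSE)
  if (sum(n_per_group) == 0) stop("empty cohort design", call. = FALSE)
  pick <- function(x, default) {
    out <- x[groups]; names(out) <- groups
    out[is.na(out)] <- default
    out
  }
  structure(
    list(n_per_group = n_per_group,
         age_mean = pick(age_mean, 1), age_sd = pick(age_sd, 0.5),
         sex_male_frac = pick(sex_male_frac, 0.5),
         voxel_mean = pick(voxel_mean, 0.09),
         voxel_sd = pick(voxel_sd, 0.03),
         true_betas = true_betas, noise_sd = noise_sd,
         rng_seed = as.integer(rng_seed)),
    class = "cohort_design"
  )
}

#' Simulate a multi-group cohort of per-region bone measurements
#'
#' Each subject receives covariates (age in years, truncated positive; sex
#' coded 1 male / 0 female; original voxel volume in mm^3, truncated
#' positive), a one-hot diagnostic group, and per-region thickness and
#' density drawn as linear predictor + Gaussian noise under the design's
#' true coefficients. Fully reproducible under `rng_seed`.
#'
#' @param design A [cohort_design()].
#' @return Data frame with one row per subject: `subject_id`, `group`,
#'   `age`, `sex`, `voxel_vol`, and `thickness_<region>` /
#'   `density_<region>` columns.
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$rng_seed)
  groups <- study_groups()
  rows <- list()
  for (g in groups) {
    n <- design$n_per_group[[g]]
    if (n == 0) next
    age <- pmax(1 / 365, rnorm(n, design$age_mean[[g]], design$age_sd[[g]]))
    sex <- rbinom(n, 1, design$sex_male_frac[[g]])
    vv <- pmax(0.005, rnorm(n, design$voxel_mean[[g]], design$voxel_sd[[g]]))
    rows[[g]] <- data.frame(group = g, age = age, sex = sex, voxel_vol = vv)
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  cohort$group <- factor(cohort$group, levels = groups)
  n <- nrow(cohort)
  cohort <- cbind(subject_id = sprintf("S%04d", seq_len(n)), cohort)
  X <- design_matrix(cohort)
  for (measure in c("thickness", "density")) {
    for (region in names(design$true_betas[[measure]])) {
      beta <- design$true_betas[[measure]][[region]]
      mu <- as.vector(X %*% beta[beta_names()])
      eps <- rnorm(n, sd = design$noise_sd[[measure]])
      cohort[[paste(measure, region, sep = "_")]] <- mu + eps
    }
  }
  cohort
}

# Regression design matrix (intercept, age, sex, voxel volume, one-hot
# group indicators; all-zero indicators = normative). The full model has
# 10 columns; `groups` can restrict the indicator set.
#' @keywords internal
design_matrix <- function(cohort, groups = study_groups()[-1]) {
  ind <- vapply(groups,
                function(g) as.numeric(cohort$group == g),
                numeric(nrow(cohort)))
  X <- cbind(1, cohort$age, cohort$sex, cohort$voxel_vol, ind)
  colnames(X) <- c("intercept", "age", "sex", "voxel_vol", groups)
  X
}

#' Phenotype composition of a cohort
#'
#' Counts and percentages per diagnostic group, plus the composition of the
#' nonsyndromic craniosynostosis subset (MC/SC/UCC/BCC) expressed as a
#' percentage of that subset — the fused-suture breakdown of the study's
#' dataset table.
#'
#' @param cohort Data frame from [simulate_cohort()].
#' @return List with data.frames `overall` and `nonsyndromic`
#'   (columns `group`, `n`, `percent`).
#' @export
cohort_composition <- function(cohort) {
  tab <- table(factor(cohort$group, levels = study_groups()))
  overall <- data.frame(group = names(tab), n = as.integer(tab),
                        percent = round(100 * as.integer(tab) / nrow(cohort), 2))
  ns_groups <- c("MC", "SC", "UCC", "BCC")
  ns <- tab[ns_groups]
  nonsyndromic <- data.frame(group = ns_groups, n = as.integer(ns),
                             percent = round(100 * as.integer(ns) / sum(ns), 2))
  list(overall = overall, nonsyndromic = nonsyndromic)
}
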