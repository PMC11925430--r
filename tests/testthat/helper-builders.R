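# Shared small-scale builders for fast tests. Sizes here are test
# conveniences; study-scale defaults live in the package functions.

# A small spherical shell (outer 38 mm) that exercises the full metric
# stack in a few seconds.
small_shell_spec <- function(outer = 38, thickness = 3, density = 800,
                             spacing = c(1, 1, 1), suture_gaps = NULL,
                             blur_fwhm = 0, noise_sd = 0, rng_seed = 1L,
                             ...) {
  phantom_spec(outer_radii = rep(outer, 3), thickness_field = thickness,
               density_field = density, suture_gaps = suture_gaps,
               blur_fwhm = blur_fwhm, noise_sd = noise_sd,
               spacing = spacing, rng_seed = rng_seed, ...)
}

# A compact cohort design covering all seven groups.
small_cohort_design <- function(n_norm = 60, n_other = 20, noise_sd =
                                  c(thickness = 0.3, density = 80),
                                rng_seed = 1L, ...) {
  cohort_design(
    n_per_group = c(normative = n_norm, IIP = n_other, MC = n_other,
                    SC = n_other, UCC = n_other, BCC = n_other,
                    AS = n_other),
    noise_sd = noise_sd, rng_seed = rng_seed, ...)
}

# Rank-based AUC (independent of the package's classifier internals).
rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Minimal 12-subject cohort with a full-rank 10-column design.
tiny_full_rank_cohort <- function(seed = 42L) {
  set.seed(seed)
  groups <- c(rep("normative", 6), "IIP", "MC", "SC", "UCC", "BCC", "AS")
  data.frame(
    subject_id = sprintf("T%02d", 1:12),
    group = factor(groups, levels = study_groups()),
    age = round(runif(12, 0.1, 6), 3),
    sex = rep(c(0, 1), 6),
    voxel_vol = round(runif(12, 0.05, 0.15), 4),
    density_global = round(rnorm(12, 800, 50), 2),
    thickness_global = round(rnorm(12, 3, 0.5), 2)
  )
}
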