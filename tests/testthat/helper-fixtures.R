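# Fixtures built in code: hand-made curve sets and cohorts small enough to
# reason about exactly.

# A curve set with constant (age-independent) bounds.
make_flat_curveset <- function(lower, mid, upper, ages = 0:100,
                               structure = "left_hippocampus") {
  values <- cbind(
    `tau_0.05` = rep(lower, length(ages)),
    `tau_0.5` = rep(mid, length(ages)),
    `tau_0.95` = rep(upper, length(ages))
  )
  structure(
    list(
      structure = structure, smoothing = "none",
      tau_levels = c(0.05, 0.5, 0.95), age_grid = ages, values = values,
      fit_meta = list(n_subjects = 0L, basis_size = 0L, lambda = 0,
                      subset_label = "combined", converged = TRUE,
                      iterations = 0L, crossings_repaired = 0L)
    ),
    class = "expectile_curveset"
  )
}

# A curve set whose three bounds are arbitrary functions of age.
make_curveset <- function(ages, lower, mid, upper,
                          structure = "left_hippocampus") {
  values <- cbind(`tau_0.05` = lower, `tau_0.5` = mid, `tau_0.95` = upper)
  structure(
    list(
      structure = structure, smoothing = "none",
      tau_levels = c(0.05, 0.5, 0.95), age_grid = ages, values = values,
      fit_meta = list(n_subjects = 0L, basis_size = 0L, lambda = 0,
                      subset_label = "combined", converged = TRUE,
                      iterations = 0L, crossings_repaired = 0L)
    ),
    class = "expectile_curveset"
  )
}

# A cohort whose %ICV-normalized values are exactly `normalized` (data frame
# of structure columns), via a constant ICV of 1000 cm^3.
cohort_from_normalized <- function(normalized, age,
                                   group = rep("CN", nrow(normalized)),
                                   field = rep(1.5, nrow(normalized)),
                                   session = rep(0L, nrow(normalized)),
                                   site = rep("", nrow(normalized))) {
  df <- data.frame(
    subject_id = sprintf("X%04d", seq_len(nrow(normalized))),
    age = age, sex = "F", group = group, field_strength = field,
    scanner_model = "", site = site, session = session, icv = 1000,
    stringsAsFactors = FALSE
  )
  for (s in names(normalized)) df[[s]] <- normalized[[s]] / 100 * 1000
  as_brain_cohort(df, names(normalized))
}

# Manufacture atrophy-call frames directly (for classification tests).
make_calls <- function(atrophied, deviation_score = -as.numeric(atrophied)) {
  data.frame(atrophied = atrophied, deviation_score = deviation_score)
}

# Brute-force AUC: proportion of (positive, negative) marker pairs won, ties
# counted one half.
auc_pairwise <- function(marker_pos, marker_neg) {
  wins <- 0
  for (p in marker_pos) {
    for (q in marker_neg) {
      wins <- wins + (p > q) + 0.5 * (p == q)
    }
  }
  wins / (length(marker_pos) * length(marker_neg))
}
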