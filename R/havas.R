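#' @title HAVAs composite atrophy score
#' @description The hippocampal-amygdalo-ventricular atrophy score: regional
#'   volumes are first normalized by ICV, then z-scored against a cognitively
#'   normal lifespan reference; the raw composite is
#'   `z(hippocampus) + z(amygdala) - z(inferior lateral ventricle)` (AD shows
#'   medial-temporal atrophy with ventricular enlargement), and the composite
#'   itself is z-normalized against the same reference population.  The
#'   double normalization absorbs inter-individual and inter-structural
#'   variability.  Left and right scores are computed independently.
#' @name havas
NULL

.havas_structures <- function(side) {
  c(hippocampus = paste0(side, "_hippocampus"),
    amygdala = paste0(side, "_amygdala"),
    ventricle = paste0(side, "_inferior_lateral_ventricle"))
}

#' Reference statistics for the HAVAs score
#'
#' From a CN-only cohort, computes the lifespan mean and standard deviation
#' (n-1 convention) of the ICV-normalized hippocampal, amygdalar and inferior
#' lateral ventricle volumes per side, then the mean and sd of the raw
#' composite per side.  Statistics are global over the whole lifespan; the
#' age dependence of the score is handled later by its own reference curve.
#'
#' @param cn_cohort CN-only `normalized_cohort` (or `brain_cohort`) with the
#'   three structures present bilaterally and at least 30 records.
#' @param sides which sides to prepare (default both).
#' @return A `havas_reference_stats`: `structure_stats` (structure, mean,
#'   sd), `composite_stats` (side, mean, sd), `n_reference`.
#' @export
compute_reference_stats <- function(cn_cohort, sides = c("left", "right")) {
  nc <- as_normalized(cn_cohort)
  if (any(nc$records$group != "CN")) {
    stop("HAVAs reference statistics are computed from CN records only")
  }
  if (nrow(nc$records) < 30) stop("need at least 30 CN reference records")
  needed <- unlist(lapply(sides, .havas_structures))
  missing <- setdiff(needed, names(nc$normalized))
  if (length(missing)) {
    stop("missing structure(s): ", paste(missing, collapse = ", "))
  }
  structure_stats <- data.frame(
    structure = needed,
    mean = vapply(needed, function(s) mean(nc$normalized[[s]]), numeric(1)),
    sd = vapply(needed, function(s) stats::sd(nc$normalized[[s]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (any(structure_stats$sd <= 0)) {
    stop("zero standard deviation in reference cohort for: ",
         paste(structure_stats$structure[structure_stats$sd <= 0], collapse = ", "))
  }
  composite <- lapply(sides, function(side) {
    st <- .havas_structures(side)
    z <- vapply(st, function(s) {
      row <- structure_stats[structure_stats$structure == s, ]
      (nc$normalized[[s]] - row$mean) / row$sd
    }, numeric(nrow(nc$records)))
    raw <- z[, "hippocampus"] + z[, "amygdala"] - z[, "ventricle"]
    data.frame(side = side, mean = mean(raw), sd = stats::sd(raw),
               stringsAsFactors = FALSE)
  })
  composite_stats <- do.call(rbind, composite)
  if (any(composite_stats$sd <= 0)) stop("zero composite sd in reference cohort")
  structure(
    list(structure_stats = structure_stats, composite_stats = composite_stats,
         n_reference = nrow(nc$records)),
    class = "havas_reference_stats"
  )
}

#' @export
print.havas_reference_stats <- function(x, ...) {
  cat(sprintf("<havas_reference_stats> n_reference=%d\n", x$n_reference))
  print(x$structure_stats)
  print(x$composite_stats)
  invisible(x)
}

#' HAVAs scores for a cohort
#'
#' Computes per-record z-scores of the three ICV-normalized volumes against
#' the reference statistics, the raw composite
#' `z_hippocampus + z_amygdala - z_ventricle`, and the normalized composite
#' `(raw - mean_raw_CN) / sd_raw_CN`.
#'
#' @param cohort a `brain_cohort` or `normalized_cohort` (any groups).
#' @param stats a `havas_reference_stats`.
#' @param side `"left"` or `"right"`.
#' @return A `havas_scores` data frame: `subject_id`, `session`, `group`,
#'   `age`, `side`, `z_hippocampus`, `z_amygdala`, `z_ventricle`, `raw`,
#'   `normalized`.
#' @export
havas_score <- function(cohort, stats, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(stats, "havas_reference_stats"))
  nc <- as_normalized(cohort)
  st <- .havas_structures(side)
  missing <- setdiff(st, names(nc$normalized))
  if (length(missing)) {
    stop("missing structure(s): ", paste(missing, collapse = ", "))
  }
  z <- vapply(st, function(s) {
    row <- stats$structure_stats[stats$structure_stats$structure == s, ]
    if (!nrow(row)) stop("reference statistics missing for ", s)
    (nc$normalized[[s]] - row$mean) / row$sd
  }, numeric(nrow(nc$records)))
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L, dimnames = list(NULL, names(st)))
  raw <- z[, "hippocampus"] + z[, "amygdala"] - z[, "ventricle"]
  comp <- stats$composite_stats[stats$composite_stats$side == side, ]
  if (!nrow(comp)) stop("reference composite statistics missing for side ", side)
  out <- data.frame(
    subject_id = nc$records$subject_id,
    session = nc$records$session,
    group = nc$records$group,
    age = nc$records$age,
    side = side,
    z_hippocampus = z[, "hippocampus"],
    z_amygdala = z[, "amygdala"],
    z_ventricle = z[, "ventricle"],
    raw = raw,
    normalized = (raw - comp$mean) / comp$sd,
    stringsAsFactors = FALSE
  )
  class(out) <- c("havas_scores", "data.frame")
  out
}

#' Reference curves for the normalized HAVAs score
#'
#' Fits tau = 0.05 / 0.50 / 0.95 expectile curves of the normalized HAVAs
#' score against age on CN records, in score units.
#'
#' @inheritParams havas_score
#' @param cn_cohort CN-only cohort providing the curve-fitting data.
#' @param smoothing,grid_step,basis_size,lambda,quiet as in
#'   [fit_reference_curves()].
#' @return An `expectile_curveset` with structure `"havas_<side>"`.
#' @export
havas_reference_curves <- function(cn_cohort, stats,
                                   side = c("left", "right"),
                                   smoothing = c("concave", "none", "convex"),
                                   grid_step = 1, basis_size = 20L,
                                   lambda = 1, quiet = FALSE) {
  side <- match.arg(side)
  smoothing <- match.arg(smoothing)
  nc <- as_normalized(cn_cohort)
  if (any(nc$records$group != "CN")) {
    stop("HAVAs reference curves are built from CN records only")
  }
  scores <- havas_score(nc, stats, side)
  .fit_curveset(
    age = scores$age, y = scores$normalized,
    structure = paste0("havas_", side), smoothing = smoothing,
    tau_levels = c(0.05, 0.5, 0.95), grid_step = grid_step,
    basis_size = basis_size, lambda = lambda,
    subset_label = "combined", quiet = quiet
  )
}

#' Pathology calls from HAVAs scores
#'
#' A score is pathological when the normalized composite falls strictly below
#' the lower (tau = 0.05) curve at the subject's age.  Reuses the atrophy
#' deviation-score convention for the ROC marker.  When both CN and AD
#' records are present, a [classification_report()] is included.
#'
#' @param scores a `havas_scores` data frame.
#' @param curves the matching `expectile_curveset` from
#'   [havas_reference_curves()].
#' @return list with `calls` (an `atrophy_calls`-style data frame),
#'   `rate_cn`, `rate_ad` (percent, `NA` when the group is absent) and
#'   `report` (a `classification_report` or `NULL`).
#' @export
havas_pathology <- function(scores, curves) {
  stopifnot(inherits(scores, "havas_scores"),
            inherits(curves, "expectile_curveset"))
  taus <- sort(curves$tau_levels)
  lower <- evaluate_curve(curves, scores$age, taus[1])
  mid <- evaluate_curve(curves, scores$age, taus[ceiling(length(taus) / 2)])
  calls <- data.frame(
    subject_id = scores$subject_id,
    session = scores$session,
    group = scores$group,
    site = "",
    structure = curves$structure,
    age = scores$age,
    value = scores$normalized,
    lower_bound = lower,
    mid = mid,
    atrophied = scores$normalized < lower,
    deviation_score = (scores$normalized - mid) / pmax(mid - lower, 1e-9),
    stringsAsFactors = FALSE
  )
  class(calls) <- c("atrophy_calls", "data.frame")
  cn <- calls[calls$group == "CN", , drop = FALSE]
  ad <- calls[calls$group == "AD", , drop = FALSE]
  list(
    calls = calls,
    rate_cn = if (nrow(cn)) atrophy_rate(cn) else NA_real_,
    rate_ad = if (nrow(ad)) atrophy_rate(ad) else NA_real_,
    report = if (nrow(cn) && nrow(ad)) classification_report(ad, cn) else NULL
  )
}
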