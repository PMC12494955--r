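#' @title Atrophy calls and classification metrics
#' @description Atrophy is called when an ICV-normalized volume falls strictly
#'   below the lower (tau = 0.05) expectile bound of the reference curve at
#'   the subject's age.  Group rates, sensitivity/specificity/balanced
#'   accuracy/AUC, McNemar comparisons between methods and repeated-scan
#'   consistency summaries complete the assessment.
#' @name atrophy_classification
NULL

#' Call atrophy against a reference curve set
#'
#' For every record, evaluates the lower (smallest tau) and mid (middle tau)
#' curves at the record's age and calls atrophy when the normalized value is
#' strictly below the lower bound.  The scale-free deviation score
#' `(value - mid) / max(mid - lower, 1e-9)` (negative = below the mid curve,
#' -1 at the lower bound) is the continuous marker used for ROC analysis.
#'
#' @param cohort a `brain_cohort` or `normalized_cohort`; ages must lie
#'   within the curve grid.
#' @param curveset an `expectile_curveset` for `structure`.
#' @param structure structure name (defaults to the curve set's).
#' @return An `atrophy_calls` data frame: `subject_id`, `session`, `group`,
#'   `site`, `structure`, `age`, `value`, `lower_bound`, `mid`, `atrophied`,
#'   `deviation_score`.
#' @export
call_atrophy <- function(cohort, curveset, structure = curveset$structure) {
  nc <- as_normalized(cohort)
  if (!structure %in% names(nc$normalized)) {
    stop("unknown structure: ", structure)
  }
  taus <- sort(curveset$tau_levels)
  age <- nc$records$age
  value <- nc$normalized[[structure]]
  lower <- evaluate_curve(curveset, age, taus[1])
  mid <- evaluate_curve(curveset, age, taus[ceiling(length(taus) / 2)])
  out <- data.frame(
    subject_id = nc$records$subject_id,
    session = nc$records$session,
    group = nc$records$group,
    site = nc$records$site,
    structure = structure,
    age = age,
    value = value,
    lower_bound = lower,
    mid = mid,
    atrophied = value < lower,
    deviation_score = (value - mid) / pmax(mid - lower, 1e-9),
    stringsAsFactors = FALSE
  )
  class(out) <- c("atrophy_calls", "data.frame")
  out
}

#' Percentage of atrophied calls
#'
#' @param calls an `atrophy_calls` data frame (or logical vector).
#' @return Percent of calls flagged atrophied.
#' @export
atrophy_rate <- function(calls) {
  flags <- if (is.data.frame(calls)) calls$atrophied else calls
  if (!length(flags)) stop("no calls: atrophy rate undefined")
  100 * mean(flags)
}

#' Classification metrics from AD and CN atrophy calls
#'
#' AD is the positive class.  Sensitivity is the AD atrophy rate, specificity
#' the CN non-atrophy rate, balanced accuracy their exact average, and AUC
#' the Mann-Whitney probability (ties counted 1/2) that an AD record has a
#' higher risk marker (`-deviation_score`) than a CN record.
#'
#' @param calls_ad,calls_cn `atrophy_calls` for the AD and CN groups.
#' @return A `classification_report`: `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `auc` and `counts` (TP/FN/TN/FP).
#' @export
classification_report <- function(calls_ad, calls_cn) {
  if (!nrow(calls_ad) || !nrow(calls_cn)) stop("empty group")
  tp <- sum(calls_ad$atrophied)
  fn <- nrow(calls_ad) - tp
  fp <- sum(calls_cn$atrophied)
  tn <- nrow(calls_cn) - fp
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  marker <- c(-calls_ad$deviation_score, -calls_cn$deviation_score)
  n_ad <- nrow(calls_ad)
  n_cn <- nrow(calls_cn)
  r <- rank(marker)
  auc <- (sum(r[seq_len(n_ad)]) - n_ad * (n_ad + 1) / 2) / (n_ad * n_cn)
  structure(
    list(
      sensitivity = sens, specificity = spec,
      balanced_accuracy = (sens + spec) / 2, auc = auc,
      counts = list(TP = tp, FN = fn, TN = tn, FP = fp)
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> sens=%.3f spec=%.3f bacc=%.3f auc=%.3f (TP=%d FN=%d TN=%d FP=%d)\n",
    x$sensitivity, x$specificity, x$balanced_accuracy, x$auc,
    x$counts$TP, x$counts$FN, x$counts$TN, x$counts$FP
  ))
  invisible(x)
}

#' McNemar test between two paired call vectors
#'
#' Compares two atrophy-calling methods applied to the same subjects in the
#' same order.  With discordant counts `b` (method 1 only) and `c` (method 2
#' only), the continuity-corrected statistic is
#' `(|b - c| - 1)^2 / (b + c)`, with a chi-squared (1 df) p-value; when
#' `b + c < 25` the p-value comes from the exact two-sided binomial test
#' instead (the statistic is still reported).  When `b + c = 0`, the
#' statistic is 0 and p = 1 by convention.
#'
#' @param calls_method1,calls_method2 logical vectors of equal length.
#' @return list with `statistic`, `p_value`, `b`, `c`, `method`.
#' @export
#' @examples
#' mcnemar_test(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
mcnemar_test <- function(calls_method1, calls_method2) {
  stopifnot(is.logical(calls_method1), is.logical(calls_method2))
  if (length(calls_method1) != length(calls_method2)) {
    stop("call vectors must be paired (equal length, same subjects)")
  }
  b <- sum(calls_method1 & !calls_method2)
  cc <- sum(!calls_method1 & calls_method2)
  n <- b + cc
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, b = b, c = cc,
                method = "degenerate (no discordant pairs)"))
  }
  stat <- (abs(b - cc) - 1)^2 / n
  if (n < 25) {
    k <- min(b, cc)
    p <- min(1, 2 * stats::pbinom(k, n, 0.5))
    return(list(statistic = stat, p_value = p, b = b, c = cc,
                method = "exact binomial (two-sided)"))
  }
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       b = b, c = cc,
       method = "chi-squared with continuity correction")
}

#' Per-subject consistency of repeated atrophy calls
#'
#' For subjects scanned at several sites or sessions, summarizes how stable
#' the atrophy call is: consistency is the fraction of sessions agreeing with
#' the majority call.  Subjects with a single session are skipped with a
#' message.
#'
#' @param calls an `atrophy_calls` data frame with repeated `subject_id`s.
#' @return data.frame with `subject_id`, `n_sessions`, `n_atrophied`,
#'   `modal_call`, `consistency`.
#' @export
stability_report <- function(calls) {
  stopifnot(is.data.frame(calls))
  counts <- table(calls$subject_id)
  singles <- names(counts)[counts < 2]
  if (length(singles)) {
    message(length(singles), " subject(s) with a single session skipped")
  }
  keep <- calls$subject_id %in% names(counts)[counts >= 2]
  calls <- calls[keep, , drop = FALSE]
  ids <- unique(calls$subject_id)
  rows <- lapply(ids, function(id) {
    flags <- calls$atrophied[calls$subject_id == id]
    n <- length(flags)
    na <- sum(flags)
    data.frame(
      subject_id = id, n_sessions = n, n_atrophied = na,
      modal_call = na > n - na, # ties resolve to the non-atrophied call
      consistency = max(na, n - na) / n,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
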