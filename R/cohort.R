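#' @title Subject-level cohort data model
#' @description Readers, writers and validators for per-scan volumetry tables.
#'   A cohort is a data frame with one row per scan and the columns
#'   `subject_id`, `age`, `sex` (`"F"`/`"M"`), `group` (`"CN"`/`"AD"`),
#'   `field_strength` (1.5 or 3.0 tesla), `scanner_model`, `site`, `session`,
#'   `icv` (intracranial volume, cm^3) and one numeric column per named brain
#'   structure (cm^3).  The structure columns are recorded in the
#'   `"structures"` attribute.
#' @name cohort
NULL

.cohort_meta_cols <- c(
  "subject_id", "age", "sex", "group", "field_strength",
  "scanner_model", "site", "session", "icv"
)

.required_cols <- c("subject_id", "age", "sex", "group", "field_strength", "icv")

#' Construct a cohort data frame from validated columns
#'
#' Low-level constructor used by [read_cohort()] and the synthetic generator.
#' Fills in optional columns (`scanner_model`, `site` as empty strings,
#' `session` as 0) and stamps the `"structures"` attribute.
#'
#' @param df data frame containing at least the required demographic columns
#'   and one numeric column per structure.
#' @param structures character vector naming the structure columns; defaults
#'   to every non-metadata column of `df`.
#' @return A `brain_cohort` data frame.
#' @export
as_brain_cohort <- function(df, structures = NULL) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.required_cols, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$scanner_model)) df$scanner_model <- rep("", nrow(df))
  if (is.null(df$site)) df$site <- rep("", nrow(df))
  if (is.null(df$session)) df$session <- rep(0L, nrow(df))
  if (is.null(structures)) {
    structures <- setdiff(names(df), .cohort_meta_cols)
  }
  if (!length(structures)) stop("cohort has no structure columns")
  df <- df[, c(.cohort_meta_cols, structures)]
  df$subject_id <- as.character(df$subject_id)
  df$session <- as.integer(df$session)
  structure(df,
    structures = structures,
    class = c("brain_cohort", "data.frame")
  )
}

#' Structure names of a cohort
#' @param cohort a `brain_cohort` or `normalized_cohort`.
#' @return Character vector of structure column names.
#' @export
cohort_structures <- function(cohort) {
  if (inherits(cohort, "normalized_cohort")) {
    return(attr(cohort$records, "structures"))
  }
  attr(cohort, "structures")
}

# Row-level invariant checks; returns character vector of problems (possibly
# empty) for one row.
.row_problems <- function(row, structures) {
  probs <- character(0)
  if (is.na(row$age) || row$age < 0 || row$age > 120) {
    probs <- c(probs, "age must be in [0, 120]")
  }
  if (!row$sex %in% c("F", "M")) probs <- c(probs, "sex must be F or M")
  if (!row$group %in% c("CN", "AD")) probs <- c(probs, "group must be CN or AD")
  if (!isTRUE(row$field_strength %in% c(1.5, 3.0))) {
    probs <- c(probs, "field_strength must be 1.5 or 3.0")
  }
  if (is.na(row$icv) || row$icv <= 0) probs <- c(probs, "icv must be positive")
  for (s in structures) {
    v <- row[[s]]
    if (is.na(v)) next # explicit absent marker, handled downstream
    if (v <= 0) probs <- c(probs, sprintf("%s must be positive", s))
    else if (!is.na(row$icv) && row$icv > 0 && v >= row$icv) {
      probs <- c(probs, sprintf("%s must be smaller than icv", s))
    }
  }
  probs
}

#' Read a cohort CSV
#'
#' Reads a comma-separated, `.`-decimal, UTF-8 table with one row per scan.
#' Rows violating the record invariants (age outside \[0, 120\], non-positive
#' ICV or volume, volume at or above ICV, bad factor levels, duplicated
#' `(subject_id, session)`) are rejected; the indices and reasons are kept in
#' the load report.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping canonical column
#'   names (e.g. `age`) to the file's column names (e.g. `c(age = "Age")`).
#' @return A `brain_cohort` data frame of the accepted rows, with a
#'   `"load_report"` attribute: `list(n_read, n_accepted, n_rejected, errors)`
#'   where `errors` is a data frame of row index and message.
#' @export
#' @examples
#' cf <- synthetic_config(n_cn = 5, seed = 1)
#' path <- tempfile(fileext = ".csv")
#' write_cohort(generate_cohort(cf), path)
#' co <- read_cohort(path)
#' attr(co, "load_report")$n_accepted
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  # read as character: type guessing would turn an all-"F" sex column into
  # logical FALSE; numeric columns are converted (and checked) explicitly
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      idx <- match(schema[[canonical]], names(raw))
      if (!is.na(idx)) names(raw)[idx] <- canonical
    }
  }
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(raw$group)) {
    warning("no group column; defaulting all records to CN")
    raw$group <- "CN"
  }
  numeric_cols <- c("age", "field_strength", "icv",
                    intersect("session", names(raw)),
                    setdiff(names(raw), c(.cohort_meta_cols)))
  errors <- list()
  for (cn in numeric_cols) {
    suppressWarnings(conv <- as.numeric(raw[[cn]]))
    bad <- which(!is.na(raw[[cn]]) & raw[[cn]] != "" & is.na(conv))
    for (i in bad) {
      errors[[length(errors) + 1L]] <-
        data.frame(row = i, message = sprintf("non-numeric %s", cn))
    }
    raw[[cn]] <- conv
  }
  structures <- setdiff(names(raw), .cohort_meta_cols)
  if (is.null(raw$session)) raw$session <- 0L
  dup <- duplicated(raw[, c("subject_id", "session")])
  for (i in which(dup)) {
    errors[[length(errors) + 1L]] <- data.frame(
      row = i,
      message = sprintf("duplicate (subject_id, session): (%s, %s)",
                        raw$subject_id[i], raw$session[i])
    )
  }
  for (i in seq_len(nrow(raw))) {
    probs <- .row_problems(raw[i, , drop = FALSE], structures)
    for (p in probs) {
      errors[[length(errors) + 1L]] <- data.frame(row = i, message = p)
    }
  }
  errors <- if (length(errors)) do.call(rbind, errors) else
    data.frame(row = integer(0), message = character(0))
  keep <- setdiff(seq_len(nrow(raw)), unique(errors$row))
  cohort <- as_brain_cohort(raw[keep, , drop = FALSE], structures)
  rownames(cohort) <- NULL
  attr(cohort, "load_report") <- list(
    n_read = nrow(raw),
    n_accepted = length(keep),
    n_rejected = nrow(raw) - length(keep),
    errors = errors
  )
  cohort
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: comma-separated, `.`-decimal, one row per scan.
#'
#' @param cohort a `brain_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "brain_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize regional volumes by intracranial volume
#'
#' Converts each structure volume to a percentage of the subject's ICV
#' (`100 * volume / icv`), the scale on which all reference curves are fitted.
#' Raw volumes are preserved alongside.
#'
#' @param records a `brain_cohort`.
#' @return A `normalized_cohort`: `list(records, normalized, mode)` where
#'   `normalized` is a data frame of structure columns in %ICV.
#' @export
#' @examples
#' co <- generate_cohort(synthetic_config(n_cn = 5, seed = 1))
#' nc <- normalize_by_icv(co)
#' head(nc$normalized)
normalize_by_icv <- function(records) {
  stopifnot(inherits(records, "brain_cohort"))
  if (any(records$icv <= 0)) {
    bad <- records$subject_id[records$icv <= 0][1]
    stop("icv must be positive (subject ", bad, ")")
  }
  structures <- cohort_structures(records)
  normalized <- as.data.frame(
    lapply(records[structures], function(v) 100 * v / records$icv)
  )
  structure(
    list(records = records, normalized = normalized, mode = "icv_percent"),
    class = "normalized_cohort"
  )
}

#' @export
print.normalized_cohort <- function(x, ...) {
  cat(sprintf(
    "<normalized_cohort> %d records, %d structures (%s), mode=%s\n",
    nrow(x$records), ncol(x$normalized),
    paste(utils::head(names(x$normalized), 3), collapse = ", "), x$mode
  ))
  invisible(x)
}

# Coerce raw cohort to normalized form where a normalized_cohort is expected.
as_normalized <- function(cohort) {
  if (inherits(cohort, "normalized_cohort")) return(cohort)
  if (inherits(cohort, "brain_cohort")) return(normalize_by_icv(cohort))
  stop("expected a brain_cohort or normalized_cohort")
}

#' Percent difference between two field-strength medians
#'
#' The elementary worked-example computation behind
#' [median_field_difference()]: `100 * |m3 - m15| / m3`, the higher field
#' (3T) median serving as the reference denominator.
#'
#' @param median_15t,median_3t group medians (same units).
#' @return Percent difference (>= 0).
#' @export
#' @examples
#' field_difference_percent(3.63, 3.70) # 1.89
field_difference_percent <- function(median_15t, median_3t) {
  if (median_3t == 0) stop("3T median is zero; percent difference undefined")
  100 * abs(median_3t - median_15t) / abs(median_3t)
}

#' Median percentage volume difference between field strengths
#'
#' For one structure, computes the medians of the (normalized or raw) volume
#' in the 1.5T and 3T groups and returns their percent difference relative to
#' the 3T median.  With `structure = NULL`, computes the per-structure values
#' and aggregates them by their median.
#'
#' @param cohort a `brain_cohort` or `normalized_cohort`.
#' @param structure structure name, or `NULL` for the cohort-level median
#'   across structures.
#' @param normalized logical; use %ICV values (default) or raw cm^3.
#' @return Percent difference (scalar).
#' @export
median_field_difference <- function(cohort, structure = NULL, normalized = TRUE) {
  nc <- as_normalized(cohort)
  values <- if (normalized) nc$normalized else
    as.data.frame(nc$records)[cohort_structures(nc)]
  fs <- nc$records$field_strength
  one <- function(s) {
    v <- values[[s]]
    g15 <- v[fs == 1.5]
    g3 <- v[fs == 3.0]
    if (!length(g15) || !length(g3)) {
      stop("field group empty for structure ", s)
    }
    field_difference_percent(stats::median(g15), stats::median(g3))
  }
  if (!is.null(structure)) {
    if (!structure %in% names(values)) stop("unknown structure: ", structure)
    return(one(structure))
  }
  stats::median(vapply(names(values), one, numeric(1)))
}
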