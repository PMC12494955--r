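#' @title Curve-pair error metrics
#' @description Five scale-invariant, sign-agnostic error metrics for
#'   comparing a reference series `A` with a compared series `F` on a common
#'   grid: sMAPE, sMSPE, wMAPE, sMdAPE and MASE.  The ideal value of each is
#'   0 (identical curves).
#' @name curve_metrics
NULL

.check_pair <- function(A, F) {
  if (length(A) != length(F)) stop("length mismatch between A and F")
  if (!length(A)) stop("empty vectors")
  if (any(abs(A) + abs(F) == 0)) {
    stop("undefined symmetric percentage: |A| + |F| = 0 at some point")
  }
}

#' Symmetric mean absolute percentage error
#'
#' `100 * mean(2 |F - A| / (|A| + |F|))`; symmetric in its arguments,
#' invariant under joint positive rescaling, bounded by 200.
#'
#' @param A reference values; @param F compared values (equal length).
#' @return Percent in \[0, 200\].
#' @export
#' @examples
#' smape(c(100, 100), c(50, 150)) # 53.33
smape <- function(A, F) {
  .check_pair(A, F)
  100 * mean(2 * abs(F - A) / (abs(A) + abs(F)))
}

#' Symmetric mean squared percentage error
#'
#' `100 * mean((2 |F - A| / (|A| + |F|))^2)`: squaring the symmetric ratios
#' amplifies large deviations.
#'
#' @inheritParams smape
#' @return Percent (>= 0).
#' @export
smspe <- function(A, F) {
  .check_pair(A, F)
  100 * mean((2 * abs(F - A) / (abs(A) + abs(F)))^2)
}

#' Weighted mean absolute percentage error
#'
#' `100 * sum(|F - A|) / sum(|A|)`: absolute errors weighted by the magnitude
#' of the reference values, so large-volume regions dominate.
#'
#' @inheritParams smape
#' @return Percent (>= 0).
#' @export
wmape <- function(A, F) {
  if (length(A) != length(F)) stop("length mismatch between A and F")
  if (sum(abs(A)) == 0) stop("all-zero reference: wMAPE undefined")
  100 * sum(abs(F - A)) / sum(abs(A))
}

#' Symmetric median absolute percentage error
#'
#' `100 * median(2 |F - A| / (|A| + |F|))`; the median (mean of the central
#' pair for even lengths) makes it robust to isolated outliers.
#'
#' @inheritParams smape
#' @return Percent in \[0, 200\].
#' @export
smdape <- function(A, F) {
  .check_pair(A, F)
  100 * stats::median(2 * abs(F - A) / (abs(A) + abs(F)))
}

#' Mean absolute scaled error
#'
#' `mean(|F - A|) / mean(|diff(A)|)` after keeping every
#' `subsample_step`-th point: the mean absolute error scaled by the in-sample
#' naive (one-step) forecast error of the reference.  On very regular, nearly
#' flat reference curves the naive scale is tiny and MASE becomes unstable;
#' `subsample_step` exposes that sensitivity.
#'
#' @inheritParams smape
#' @param subsample_step keep every k-th grid point (default 1 = all).
#' @return Ratio (>= 0).
#' @export
mase <- function(A, F, subsample_step = 1L) {
  if (length(A) != length(F)) stop("length mismatch between A and F")
  if (subsample_step < 1) stop("subsample_step must be >= 1")
  idx <- seq(1L, length(A), by = subsample_step)
  if (length(idx) < 2L) stop("fewer than 2 points after subsampling")
  A <- A[idx]
  F <- F[idx]
  naive <- mean(abs(diff(A)))
  if (naive == 0) stop("MASE undefined on flat reference")
  mean(abs(F - A)) / naive
}

.metric_funs <- list(
  smape = smape, smspe = smspe, wmape = wmape, smdape = smdape,
  mase = function(A, F) mase(A, F)
)

#' Compare two expectile curve sets bound by bound
#'
#' Restricts both curve sets to the intersection of their age grids and
#' computes each requested metric for the matched bound pairs (lower vs
#' lower, mean vs mean, upper vs upper).
#'
#' @param ref reference `expectile_curveset` (the `A` series).
#' @param other compared `expectile_curveset` (the `F` series); must describe
#'   the same structure and overlap in age.
#' @param metrics subset of `c("smape", "smspe", "wmape", "smdape", "mase")`.
#' @return A `curve_error_report`: `structure`, `values` (bound x metric
#'   matrix with rows `lower`, `mean`, `upper`), `n_grid_points`,
#'   `grid_range`.  Use [as.data.frame()] for the long format.
#' @export
compare_curvesets <- function(ref, other,
                              metrics = c("smape", "smspe", "wmape", "smdape", "mase")) {
  stopifnot(inherits(ref, "expectile_curveset"),
            inherits(other, "expectile_curveset"))
  if (!identical(ref$structure, other$structure)) {
    stop("curve sets describe different structures: ",
         ref$structure, " vs ", other$structure)
  }
  metrics <- match.arg(metrics, several.ok = TRUE)
  ga <- round(ref$age_grid, 6)
  gb <- round(other$age_grid, 6)
  common <- intersect(ga, gb)
  if (!length(common)) stop("disjoint age ranges: no common grid")
  ia <- match(common, ga)
  ib <- match(common, gb)
  ntau <- length(ref$tau_levels)
  bounds <- if (ntau == 3L) c("lower", "mean", "upper") else
    sprintf("tau_%g", ref$tau_levels)
  values <- matrix(NA_real_, nrow = ntau, ncol = length(metrics),
                   dimnames = list(bounds, metrics))
  for (j in seq_len(ntau)) {
    A <- ref$values[ia, j]
    F <- other$values[ib, j]
    for (m in metrics) values[j, m] <- .metric_funs[[m]](A, F)
  }
  structure(
    list(structure = ref$structure, values = values,
         n_grid_points = length(common), grid_range = range(common)),
    class = "curve_error_report"
  )
}

#' @export
as.data.frame.curve_error_report <- function(x, ...) {
  v <- x$values
  data.frame(
    structure = x$structure,
    bound = rep(rownames(v), times = ncol(v)),
    metric = rep(colnames(v), each = nrow(v)),
    value = as.vector(v),
    stringsAsFactors = FALSE
  )
}

#' @export
print.curve_error_report <- function(x, ...) {
  cat(sprintf("<curve_error_report> %s (%d grid points, ages %g-%g)\n",
              x$structure, x$n_grid_points, x$grid_range[1], x$grid_range[2]))
  print(round(x$values, 4))
  invisible(x)
}
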