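#' @title Field-strength bias detection by label shuffling
#' @description The observed 1.5T-vs-3T curve discrepancy is compared with a
#'   null distribution obtained by permuting the field-strength labels across
#'   subjects (group sizes preserved), refitting both per-field curve sets and
#'   recomputing the metrics.  A bias is flagged when the true-label metric
#'   falls outside the empirical 5th-95th percentile range of the null.
#' @name bootstrap_bias
NULL

# Precompute everything that does not change under label permutation: design
# matrix on a shared basis spanning the full CN age range, grid design, and
# penalty.  Labels permute; ages do not.
.field_engine <- function(cohort, structure, smoothing, basis_size, lambda,
                          grid_step = 1, tau_levels = c(0.05, 0.5, 0.95)) {
  nc <- as_normalized(cohort)
  if (any(nc$records$group != "CN")) {
    stop("field-bias analysis uses CN records only: remove non-CN records")
  }
  if (!structure %in% names(nc$normalized)) {
    stop("unknown structure: ", structure)
  }
  age <- nc$records$age
  y <- nc$normalized[[structure]]
  fs <- nc$records$field_strength
  if (!any(fs == 1.5) || !any(fs == 3.0)) stop("field group empty")
  knots <- .pspline_knots(min(age), max(age), basis_size)
  B <- .pspline_design(knots, age)
  grid <- .make_age_grid(min(age), max(age), grid_step)
  Bgrid <- .pspline_design(knots, grid)
  D2 <- diff(diag(ncol(B)), differences = 2L)
  mu <- mean(y)
  s <- stats::sd(y)
  if (!is.finite(s) || s < 1e-12) s <- 1
  list(
    age = age, ys = (y - mu) / s, fs = fs, B = B, grid = grid,
    Bgrid = Bgrid, D2 = D2, mu = mu, s = s, smoothing = smoothing,
    lambda = lambda, tau_levels = sort(tau_levels), grid_step = grid_step
  )
}

# Fit both field groups for given labels and return the bound x metric matrix
# on the common grid.  Grid restricted to each subset's own age range (no
# extrapolation); degenerate permutations (a group spanning < 1 grid step)
# raise an error, which the bootstrap loop treats as a retry.
.field_metrics_for_labels <- function(eng, labels, metrics) {
  one_group <- function(idx) {
    r <- range(eng$age[idx])
    mask <- eng$grid >= r[1] & eng$grid <= r[2]
    if (sum(mask) < 2L) stop("degenerate group age range")
    vals <- vapply(eng$tau_levels, function(tau) {
      fit <- .asls_fit(eng$B[idx, , drop = FALSE], eng$ys[idx], tau,
                       eng$lambda, eng$D2, eng$smoothing)
      drop(eng$Bgrid[mask, , drop = FALSE] %*% fit$beta) * eng$s + eng$mu
    }, numeric(sum(mask)))
    vals <- t(apply(vals, 1L, sort)) # non-crossing repair
    list(mask = mask, values = vals)
  }
  g3 <- one_group(which(labels == 3.0))
  g15 <- one_group(which(labels == 1.5))
  common <- g3$mask & g15$mask
  if (sum(common) < 2L) stop("disjoint group age ranges")
  bounds <- c("lower", "mean", "upper")
  out <- matrix(NA_real_, nrow = 3L, ncol = length(metrics),
                dimnames = list(bounds, metrics))
  for (j in 1:3) {
    A <- g15$values[common[g15$mask], j] # 1.5T curves are the reference series
    F <- g3$values[common[g3$mask], j]
    for (m in metrics) out[j, m] <- .metric_funs[[m]](A, F)
  }
  out
}

#' Observed (true-label) field-strength metrics
#'
#' Fits 1.5T-only and 3T-only expectile curve sets for one structure on a
#' shared basis spanning the full CN age range and returns the curve-pair
#' metrics for each bound, with the 1.5T curves as the reference series
#' against which the 3T curves are compared.
#'
#' @param cohort CN-only `normalized_cohort` (or `brain_cohort`).
#' @param structure structure name.
#' @param smoothing `"concave"`, `"none"` or `"convex"`.
#' @param metrics metric names (see [compare_curvesets()]).
#' @param basis_size,lambda spline settings shared by both fits.
#' @return Bound x metric matrix (rows `lower`, `mean`, `upper`).
#' @export
observed_field_metrics <- function(cohort, structure,
                                   smoothing = c("concave", "none", "convex"),
                                   metrics = c("smape", "smspe", "wmape", "smdape"),
                                   basis_size = 20L, lambda = 1) {
  smoothing <- match.arg(smoothing)
  metrics <- match.arg(metrics,
    c("smape", "smspe", "wmape", "smdape", "mase"), several.ok = TRUE)
  eng <- .field_engine(cohort, structure, smoothing, basis_size, lambda)
  .field_metrics_for_labels(eng, eng$fs, metrics)
}

#' Label-shuffling null for field-strength bias
#'
#' Computes the observed per-bound metrics between the 1.5T-only and 3T-only
#' reference curves, then builds a null distribution by `B` iterations of
#' permuting the field-strength labels across subjects (the label multiset is
#' fixed, so group sizes are preserved exactly), refitting both curve sets
#' and recomputing the metrics.  Empirical 5th and 95th percentiles of each
#' null distribution (linear-interpolation quantiles, type 7) bracket the
#' chance variability; a bias is flagged when the observed value falls
#' outside them.  Permutations that make a fit degenerate are retried with a
#' fresh permutation; more than 5% failures aborts.
#'
#' @inheritParams observed_field_metrics
#' @param B number of permutations (default 10000; >= 100 recommended).
#' @param seed integer seed for the permutation stream (recorded in the
#'   result).
#' @return A `bootstrap_bias_result`: list with `structure`, `B`, `seed`,
#'   `n_retries`, `observed` (bound x metric matrix), `null_values`
#'   (B x bound x metric array), `p5`, `p95` and `bias_flag` matrices.
#' @export
bootstrap_field_bias <- function(cohort, structure,
                                 smoothing = c("concave", "none", "convex"),
                                 metrics = c("smape", "smspe", "wmape", "smdape"),
                                 B = 10000L, seed = NULL,
                                 basis_size = 20L, lambda = 1) {
  smoothing <- match.arg(smoothing)
  metrics <- match.arg(metrics,
    c("smape", "smspe", "wmape", "smdape", "mase"), several.ok = TRUE)
  if (B < 1) stop("B must be positive")
  if (!is.null(seed)) set.seed(seed)
  eng <- .field_engine(cohort, structure, smoothing, basis_size, lambda)
  observed <- .field_metrics_for_labels(eng, eng$fs, metrics)
  null_values <- array(
    NA_real_, dim = c(B, 3L, length(metrics)),
    dimnames = list(NULL, rownames(observed), metrics)
  )
  n_retries <- 0L
  max_failures <- max(1L, ceiling(0.05 * B))
  for (b in seq_len(B)) {
    repeat {
      res <- tryCatch(
        .field_metrics_for_labels(eng, sample(eng$fs), metrics),
        error = function(e) NULL
      )
      if (!is.null(res)) break
      n_retries <- n_retries + 1L
      if (n_retries > max_failures) {
        stop("more than 5% of permutations failed to fit; aborting")
      }
    }
    null_values[b, , ] <- res
  }
  p5 <- apply(null_values, c(2, 3), stats::quantile, probs = 0.05,
              type = 7, names = FALSE)
  p95 <- apply(null_values, c(2, 3), stats::quantile, probs = 0.95,
               type = 7, names = FALSE)
  dimnames(p5) <- dimnames(p95) <- dimnames(observed)
  structure(
    list(
      structure = structure, smoothing = smoothing, metrics = metrics,
      B = B, seed = seed, n_retries = n_retries,
      observed = observed, null_values = null_values,
      p5 = p5, p95 = p95,
      bias_flag = observed < p5 | observed > p95
    ),
    class = "bootstrap_bias_result"
  )
}

#' @export
print.bootstrap_bias_result <- function(x, ...) {
  cat(sprintf("<bootstrap_bias_result> %s, B=%d, seed=%s, retries=%d\n",
              x$structure, x$B,
              if (is.null(x$seed)) "none" else x$seed, x$n_retries))
  print(bias_report(x))
  invisible(x)
}

#' Long-format table of bootstrap bias results
#'
#' One row per (bound, metric) with the observed value, null percentiles and
#' the bias flag; the raw null distributions for histogram plotting are kept
#' in the `"null_values"` attribute.
#'
#' @param results a `bootstrap_bias_result` or a list of them.
#' @return data.frame with columns `structure`, `bound`, `metric`,
#'   `observed`, `p5`, `p95`, `bias_flag`.
#' @export
bias_report <- function(results) {
  if (inherits(results, "bootstrap_bias_result")) results <- list(results)
  if (!length(results)) stop("no results to report")
  rows <- lapply(results, function(r) {
    data.frame(
      structure = r$structure,
      bound = rep(rownames(r$observed), times = ncol(r$observed)),
      metric = rep(colnames(r$observed), each = nrow(r$observed)),
      observed = as.vector(r$observed),
      p5 = as.vector(r$p5),
      p95 = as.vector(r$p95),
      bias_flag = as.vector(r$bias_flag),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "null_values") <- lapply(results, `[[`, "null_values")
  out
}
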