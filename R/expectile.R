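#' @title Shape-constrained expectile reference curves
#' @description Penalized B-spline (P-spline) expectile regression of
#'   ICV-normalized volume on age.  The tau-expectile minimizes an
#'   asymmetrically weighted squared loss; tau = 0.05 / 0.50 / 0.95 give the
#'   lower, mid and upper bounds of a normative band.  Optional concave or
#'   convex shape constraints keep lifespan trajectories physiologically
#'   plausible.
#' @name expectile_curves
NULL

#' Scalar expectile of a sample
#'
#' Solves the balance equation
#' `(1 - tau) * sum_(x < e) (e - x) = tau * sum_(x > e) (x - e)`
#' by the damped fixed-point iteration `e <- sum(w * x) / sum(w)` with
#' `w = tau` above `e` and `1 - tau` below.  The 0.5-expectile is the mean.
#' Serves as the independent oracle for the curve fitter on degenerate
#' (single-age) designs.
#'
#' @param x numeric vector (NAs dropped).
#' @param tau asymmetry level in (0, 1).
#' @return The tau-expectile (scalar).
#' @export
#' @examples
#' scalar_expectile(c(0, 10), 0.9) # 9
scalar_expectile <- function(x, tau) {
  if (!is.numeric(x)) stop("x must be numeric")
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty sample: expectile undefined")
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  scale <- max(abs(x), 1)
  e <- mean(x)
  for (i in seq_len(500)) {
    w <- ifelse(x > e, tau, 1 - tau)
    e_new <- sum(w * x) / sum(w)
    if (abs(e_new - e) < 1e-12 * scale) {
      return(e_new)
    }
    e <- e_new
  }
  e
}

# Uniform cubic B-spline knot vector giving exactly `basis_size` basis
# functions over [lo, hi] (P-spline construction: ndx = basis_size - 3
# interior segments, knots extended 3 steps beyond each boundary).  Knot
# spacing never drops below `min_spacing`: age structure finer than the grid
# resolution is not modeled, so a narrow age cluster degenerates cleanly to a
# single-location (scalar expectile) fit instead of a full-rank local fit.
.pspline_knots <- function(lo, hi, basis_size, min_spacing = 1) {
  if (hi <= lo) stop("age spread must be positive")
  ndx <- basis_size - 3L
  if (ndx < 1L) stop("basis_size must be at least 4")
  h <- (hi - lo) / ndx
  if (h < min_spacing) {
    h <- min_spacing
    mid <- (lo + hi) / 2
    lo <- mid - ndx * h / 2
    hi <- mid + ndx * h / 2
  }
  seq(lo - 3 * h, hi + 3 * h, by = h)
}

.pspline_design <- function(knots, x) {
  # clamp into the representable span to absorb float error in the knot seq
  lo <- knots[4L]
  hi <- knots[length(knots) - 3L]
  x <- pmin(pmax(x, lo), hi)
  splines::splineDesign(knots, x, ord = 4L, outer.ok = FALSE)
}

# Asymmetric penalized least squares on a fixed design matrix.  y is assumed
# standardized by the caller.  Shape constraints are enforced through an
# iterated quadratic penalty on sign-violating second differences of the
# coefficients (sufficient for concavity/convexity on uniform knots).
.asls_fit <- function(B, y, tau, lambda, D2, shape = "none",
                      kappa = 1e9, max_iter = 100L, tol = 1e-6) {
  K <- ncol(B)
  P <- lambda * crossprod(D2)
  ridge <- diag(1e-10, K)
  BtB <- crossprod(B)
  beta <- solve(BtB + P + ridge, crossprod(B, y))
  fitted <- drop(B %*% beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- ifelse(y > fitted, tau, 1 - tau)
    Pshape <- 0
    if (shape != "none") {
      d2b <- drop(D2 %*% beta)
      viol <- if (shape == "concave") d2b > 0 else d2b < 0
      if (any(viol)) {
        Pshape <- kappa * crossprod(D2[viol, , drop = FALSE])
      }
    }
    beta_new <- solve(crossprod(B * w, B) + P + Pshape + ridge,
                      crossprod(B, w * y))
    fitted_new <- drop(B %*% beta_new)
    # convergence judged on fitted values: coefficients can be arbitrarily
    # large on ill-conditioned (e.g. single-age-cluster) designs
    delta <- max(abs(fitted_new - fitted)) / max(1, max(abs(fitted)))
    beta <- beta_new
    fitted <- fitted_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = drop(beta), converged = converged, iterations = iter)
}

# GCV score for the tau = 0.5 (constant-weight) smoother; used for optional
# lambda selection, then the chosen lambda is shared across tau levels.
.gcv_lambda <- function(B, y, D2, grid = 10^seq(-3, 3, length.out = 13)) {
  n <- length(y)
  BtB <- crossprod(B)
  Bty <- crossprod(B, y)
  DtD <- crossprod(D2)
  scores <- vapply(grid, function(lam) {
    M <- solve(0.5 * BtB + lam * DtD + diag(1e-10, ncol(B)))
    beta <- M %*% (0.5 * Bty)
    rss <- sum((y - drop(B %*% beta))^2)
    edf <- sum(diag(M %*% (0.5 * BtB)))
    n * rss / (n - edf)^2
  }, numeric(1))
  grid[which.min(scores)]
}

#' Fit one penalized-spline expectile curve
#'
#' Minimizes the asymmetric least-squares objective
#' `sum(w_i(tau) * (y_i - f(age_i))^2) + lambda * ||D2 beta||^2`, with
#' `w_i = tau` for positive residuals and `1 - tau` otherwise, over a cubic
#' B-spline expansion `f` on uniform knots spanning the observed age range
#' (`basis_size` coefficients, second-order difference penalty), by
#' iteratively reweighted penalized least squares.  The response is centered
#' and scaled internally, so `lambda` acts on standardized data and fits are
#' exactly translation- and scale-equivariant.  Concavity (or convexity) is
#' imposed through an iterated large quadratic penalty on coefficient second
#' differences of the wrong sign.
#'
#' @param age,value numeric vectors of equal length (>= max(basis_size, 30)
#'   points, positive age spread).
#' @param tau expectile level in (0, 1).
#' @param basis_size number of B-spline coefficients (default 20).
#' @param lambda smoothness penalty (>= 0, default 1 on standardized data),
#'   or `"gcv"` to select it on a 13-point log grid by generalized
#'   cross-validation at tau = 0.5.
#' @param shape `"none"`, `"concave"` or `"convex"`.
#' @param max_iter,tol IRLS iteration cap and relative-change tolerance.
#' @return An `expectile_fit`: coefficients, knots, data range, response
#'   transform, `converged` flag and iteration count.  Non-convergence is
#'   flagged, not raised.
#' @export
fit_expectile_curve <- function(age, value, tau, basis_size = 20L,
                                lambda = 1, shape = c("none", "concave", "convex"),
                                max_iter = 100L, tol = 1e-6) {
  shape <- match.arg(shape)
  stopifnot(length(age) == length(value))
  ok <- !is.na(age) & !is.na(value)
  age <- age[ok]
  value <- value[ok]
  n <- length(age)
  if (n < max(basis_size, 30L)) {
    stop(sprintf("too few points (%d) to fit %d basis functions", n, basis_size))
  }
  if (diff(range(age)) <= 0) stop("age spread must be positive")
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  knots <- .pspline_knots(min(age), max(age), basis_size)
  B <- .pspline_design(knots, age)
  D2 <- diff(diag(ncol(B)), differences = 2L)
  mu <- mean(value)
  s <- stats::sd(value)
  if (!is.finite(s) || s < 1e-12) s <- 1
  ys <- (value - mu) / s
  if (identical(lambda, "gcv")) lambda <- .gcv_lambda(B, ys, D2)
  fit <- .asls_fit(B, ys, tau, lambda, D2, shape,
                   max_iter = max_iter, tol = tol)
  structure(
    list(
      coef = fit$beta, knots = knots, tau = tau, shape = shape,
      lambda = lambda, basis_size = ncol(B),
      age_range = range(age), center = mu, scale = s,
      n = n, converged = fit$converged, iterations = fit$iterations
    ),
    class = "expectile_fit"
  )
}

#' @export
predict.expectile_fit <- function(object, newages, ...) {
  r <- object$age_range
  if (any(newages < r[1] - 1e-9 | newages > r[2] + 1e-9)) {
    stop("extrapolation not supported: age outside fitted range")
  }
  newages <- pmin(pmax(newages, r[1]), r[2])
  B <- .pspline_design(object$knots, newages)
  drop(B %*% object$coef) * object$scale + object$center
}

# Align grid to multiples of the step so that grids from different subsets of
# the same cohort share their overlapping points exactly.
.make_age_grid <- function(lo, hi, step) {
  g <- seq(ceiling(lo / step) * step, floor(hi / step) * step, by = step)
  if (!length(g)) stop("age range narrower than one grid step")
  g
}

# Internal: fit the three tau levels on given (age, y), evaluate on a grid and
# assemble an expectile_curveset.  Used by fit_reference_curves and the HAVAs
# score curves.
.fit_curveset <- function(age, y, structure, smoothing, tau_levels, grid_step,
                          basis_size, lambda, subset_label, quiet = FALSE) {
  tau_levels <- sort(tau_levels)
  first <- fit_expectile_curve(age, y, tau_levels[1], basis_size, lambda,
                               shape = smoothing)
  lambda_used <- first$lambda # resolves "gcv" once, then shared
  fits <- c(list(first), lapply(tau_levels[-1], function(tau) {
    fit_expectile_curve(age, y, tau, basis_size, lambda_used, shape = smoothing)
  }))
  grid <- .make_age_grid(min(age), max(age), grid_step)
  values <- vapply(fits, function(f) predict(f, grid), numeric(length(grid)))
  colnames(values) <- sprintf("tau_%g", tau_levels)
  crossings <- sum(values != t(apply(values, 1L, sort)))
  if (crossings > 0) {
    values <- t(apply(values, 1L, sort))
    colnames(values) <- sprintf("tau_%g", tau_levels)
    if (!quiet) {
      warning(sprintf(
        "expectile curves crossed at %d grid value(s); repaired by pointwise sorting",
        crossings
      ))
    }
  }
  structure(
    list(
      structure = structure, smoothing = smoothing, tau_levels = tau_levels,
      age_grid = grid, values = values,
      fit_meta = list(
        n_subjects = length(age), basis_size = basis_size,
        lambda = lambda_used, subset_label = subset_label,
        converged = all(vapply(fits, `[[`, logical(1), "converged")),
        iterations = max(vapply(fits, `[[`, integer(1), "iterations")),
        crossings_repaired = crossings
      )
    ),
    class = "expectile_curveset"
  )
}

#' Fit the reference curve set for one structure
#'
#' Fits tau = 0.05, 0.50 and 0.95 expectile curves of the ICV-normalized
#' volume of `structure` against age on cognitively normal records, sharing
#' the basis and penalty across the three levels, and evaluates them on a
#' uniform age grid (no extrapolation beyond the observed age range).  Any
#' pointwise crossing of the three curves is repaired by sorting, with a
#' warning.
#'
#' @param cohort a `normalized_cohort` (or `brain_cohort`, normalized on the
#'   fly) containing only CN records; AD records raise an error because
#'   reference curves are built from controls.
#' @param structure structure name.
#' @param smoothing `"concave"` (default), `"none"` or `"convex"`.
#' @param subset `"combined"`, `"1.5T"` or `"3T"` field-strength filter.
#' @param grid_step age grid step in years (default 1).
#' @param tau_levels expectile levels (default `c(0.05, 0.5, 0.95)`).
#' @param basis_size,lambda passed to [fit_expectile_curve()]; `lambda` may be
#'   `"gcv"` (selected at tau = 0.5, then shared).
#' @param quiet suppress the crossing-repair warning.
#' @return An `expectile_curveset`: `structure`, `smoothing`, `tau_levels`,
#'   `age_grid`, `values` (grid x tau matrix) and `fit_meta`.
#' @export
#' @examples
#' co <- generate_cohort(synthetic_config(n_cn = 200, seed = 1))
#' cs <- fit_reference_curves(normalize_by_icv(co), "left_hippocampus")
#' head(cs$values)
fit_reference_curves <- function(cohort, structure,
                                 smoothing = c("concave", "none", "convex"),
                                 subset = c("combined", "1.5T", "3T"),
                                 grid_step = 1, tau_levels = c(0.05, 0.5, 0.95),
                                 basis_size = 20L, lambda = 1, quiet = FALSE) {
  smoothing <- match.arg(smoothing)
  subset <- match.arg(subset)
  nc <- as_normalized(cohort)
  if (any(nc$records$group != "CN")) {
    stop("reference curves are built from controls: remove non-CN records")
  }
  if (!structure %in% names(nc$normalized)) {
    stop("unknown structure: ", structure)
  }
  keep <- switch(subset,
    combined = rep(TRUE, nrow(nc$records)),
    `1.5T` = nc$records$field_strength == 1.5,
    `3T` = nc$records$field_strength == 3.0
  )
  if (!any(keep)) stop("empty subset: no records at ", subset)
  .fit_curveset(
    age = nc$records$age[keep], y = nc$normalized[[structure]][keep],
    structure = structure, smoothing = smoothing, tau_levels = tau_levels,
    grid_step = grid_step, basis_size = basis_size, lambda = lambda,
    subset_label = subset, quiet = quiet
  )
}

#' Evaluate a curve set at arbitrary ages
#'
#' Linear interpolation between grid values; ages outside the grid raise an
#' extrapolation error.
#'
#' @param curveset an `expectile_curveset`.
#' @param ages numeric vector within the curve's age grid range.
#' @param tau one of the set's `tau_levels`.
#' @return Numeric vector of curve values at `ages`.
#' @export
evaluate_curve <- function(curveset, ages, tau) {
  stopifnot(inherits(curveset, "expectile_curveset"))
  j <- which(abs(curveset$tau_levels - tau) < 1e-9)
  if (!length(j)) {
    stop("tau ", tau, " not in curve set (levels: ",
         paste(curveset$tau_levels, collapse = ", "), ")")
  }
  g <- curveset$age_grid
  if (any(ages < g[1] - 1e-9 | ages > g[length(g)] + 1e-9)) {
    stop("extrapolation not supported: age outside curve grid")
  }
  stats::approx(g, curveset$values[, j], xout = ages, rule = 1)$y
}

#' @export
print.expectile_curveset <- function(x, ...) {
  cat(sprintf(
    "<expectile_curveset> %s [%s, %s smoothing], ages %g-%g, taus %s, n=%d\n",
    x$structure, x$fit_meta$subset_label, x$smoothing,
    min(x$age_grid), max(x$age_grid),
    paste(x$tau_levels, collapse = "/"), x$fit_meta$n_subjects
  ))
  invisible(x)
}

#' Export a curve set to CSV (and optionally JSON metadata)
#'
#' Writes one row per grid age with columns `age`, `p05`, `p50`, `p95` (or
#' `tau_*` names for non-default levels); fit metadata goes to a JSON sidecar
#' when `json_path` is given.
#'
#' @param curveset an `expectile_curveset`.
#' @param path CSV output path.
#' @param json_path optional JSON path for the full object.
#' @return `path`, invisibly.
#' @export
write_curveset <- function(curveset, path, json_path = NULL) {
  df <- data.frame(age = curveset$age_grid, curveset$values)
  std <- all(abs(curveset$tau_levels - c(0.05, 0.5, 0.95)) < 1e-9)
  if (std) names(df) <- c("age", "p05", "p50", "p95")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    out <- curveset
    out$values <- as.data.frame(out$values)
    jsonlite::write_json(unclass(out), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
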