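#' @title Synthetic cohort generator
#' @description Generates per-scan volumetry tables with the statistical
#'   structure the analysis assumes: concave lifespan trajectories of
#'   ICV-normalized volume, sex-dependent ICV, multiplicative per-field
#'   measurement bias on 3T scans, additive Gaussian measurement noise,
#'   multiplicative AD effects (medial-temporal atrophy, ventricular
#'   enlargement) and traveling-subject designs with additive site noise.
#'   Every draw is deterministic given the config seed, and the latent
#'   (noise- and bias-free) normalized values are returned alongside for
#'   oracle tests.
#' @name synthetic_data
NULL

#' Default lifespan trajectory specs
#'
#' Trajectory parameters on the %ICV scale for the six structures the
#' composite score needs.  `decline_rate` is the quadratic coefficient per
#' decade from the peak (`concave_quadratic`) or the linear %ICV-per-decade
#' slope after the peak (`flat_then_linear`); negative rates grow (the
#' ventricle enlarges with age).  `noise_sd` overrides the config-level
#' default per structure, since the structures span an order of magnitude in
#' size.
#'
#' @return Named list of trajectory specs.
#' @export
default_structure_specs <- function() {
  hip <- list(peak_value = 0.25, peak_age = 35, decline_rate = 0.004,
              shape = "concave_quadratic", noise_sd = 0.020)
  amy <- list(peak_value = 0.090, peak_age = 40, decline_rate = 0.0012,
              shape = "concave_quadratic", noise_sd = 0.008)
  ven <- list(peak_value = 0.030, peak_age = 40, decline_rate = -0.010,
              shape = "flat_then_linear", noise_sd = 0.006)
  list(
    left_hippocampus = hip, right_hippocampus = hip,
    left_amygdala = amy, right_amygdala = amy,
    left_inferior_lateral_ventricle = ven,
    right_inferior_lateral_ventricle = ven
  )
}

.trajectory_value <- function(spec, age) {
  d <- (age - spec$peak_age) / 10
  v <- if (spec$shape == "concave_quadratic") {
    spec$peak_value - spec$decline_rate * d^2
  } else { # flat_then_linear
    ifelse(age <= spec$peak_age, spec$peak_value,
           spec$peak_value - spec$decline_rate * d)
  }
  pmax(v, 1e-4)
}

#' Build and validate a synthetic cohort configuration
#'
#' Defaults mirror the pooled lifespan cohort the reference curves target:
#' ages uniform on 7-94 years, 51.2% female, 68% of scans at 3T, sex-specific
#' ICV (F: 1380 +/- 100 cm^3, M: 1550 +/- 110 cm^3), bilateral hippocampus /
#' amygdala / inferior lateral ventricle trajectories, and AD effects of 0.8
#' (hippocampus), 0.85 (amygdala) and 1.4 (ventricle).
#'
#' @param n_cn,n_ad numbers of cognitively normal and AD subjects.
#' @param age_range two-element years interval.
#' @param sex_ratio fraction female.
#' @param icv_model list with `F` and `M`, each `c(mean, sd)` in cm^3.
#' @param structures named list of trajectory specs (see
#'   [default_structure_specs()]).
#' @param noise_sd default measurement noise sd in %ICV for structures whose
#'   spec has none.
#' @param field_bias named multiplicative factors applied to 3T measurements
#'   (default 1 for every structure: no field effect).
#' @param fraction_3T probability a scan is acquired at 3T.
#' @param ad_effects named multiplicative factors applied to AD subjects'
#'   latent values.
#' @param n_sites,n_sessions,site_noise_sd traveling-subject design: sites
#'   per subject, sessions per site, additive site perturbation sd (%ICV).
#' @param seed integer RNG seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_cn = 500L, n_ad = 0L,
                             age_range = c(7, 94), sex_ratio = 0.512,
                             icv_model = list(F = c(mean = 1380, sd = 100),
                                              M = c(mean = 1550, sd = 110)),
                             structures = default_structure_specs(),
                             noise_sd = 0.02,
                             field_bias = NULL,
                             fraction_3T = 0.684,
                             ad_effects = c(
                               left_hippocampus = 0.8, right_hippocampus = 0.8,
                               left_amygdala = 0.85, right_amygdala = 0.85,
                               left_inferior_lateral_ventricle = 1.4,
                               right_inferior_lateral_ventricle = 1.4
                             ),
                             n_sites = 1L, n_sessions = 1L,
                             site_noise_sd = 0,
                             seed = 42L) {
  cfg <- list(
    n_cn = as.integer(n_cn), n_ad = as.integer(n_ad),
    age_range = age_range, sex_ratio = sex_ratio, icv_model = icv_model,
    structures = structures, noise_sd = noise_sd,
    field_bias = field_bias, fraction_3T = fraction_3T,
    ad_effects = ad_effects, n_sites = as.integer(n_sites),
    n_sessions = as.integer(n_sessions), site_noise_sd = site_noise_sd,
    seed = as.integer(seed)
  )
  if (is.null(cfg$field_bias)) {
    cfg$field_bias <- stats::setNames(
      rep(1, length(structures)), names(structures))
  }
  errs <- character(0)
  if (cfg$n_cn < 0 || cfg$n_ad < 0) errs <- c(errs, "n_cn/n_ad must be >= 0")
  if (cfg$n_cn + cfg$n_ad < 1) errs <- c(errs, "cohort must have at least one subject")
  if (length(age_range) != 2 || age_range[1] >= age_range[2] ||
      age_range[1] < 0 || age_range[2] > 120) {
    errs <- c(errs, "age_range must be an increasing interval within [0, 120]")
  }
  if (sex_ratio < 0 || sex_ratio > 1) errs <- c(errs, "sex_ratio must be in [0, 1]")
  if (fraction_3T < 0 || fraction_3T > 1) errs <- c(errs, "fraction_3T must be in [0, 1]")
  if (noise_sd < 0) errs <- c(errs, "noise_sd must be >= 0")
  if (site_noise_sd < 0) errs <- c(errs, "site_noise_sd must be >= 0")
  if (!length(structures) || is.null(names(structures))) {
    errs <- c(errs, "structures must be a named list")
  }
  if (any(cfg$field_bias <= 0)) errs <- c(errs, "field_bias factors must be > 0")
  if (any(cfg$ad_effects <= 0)) errs <- c(errs, "ad_effects factors must be > 0")
  if (cfg$n_sites < 1 || cfg$n_sessions < 1) {
    errs <- c(errs, "n_sites and n_sessions must be >= 1")
  }
  for (s in names(structures)) {
    sp <- structures[[s]]
    if (is.null(sp$peak_value) || sp$peak_value <= 0) {
      errs <- c(errs, sprintf("structures$%s: peak_value must be > 0", s))
    }
    if (!isTRUE(sp$shape %in% c("concave_quadratic", "flat_then_linear"))) {
      errs <- c(errs, sprintf("structures$%s: unknown shape", s))
    }
  }
  if (length(errs)) {
    stop("invalid synthetic config:\n  - ", paste(errs, collapse = "\n  - "))
  }
  structure(cfg, class = "synthetic_config")
}

.structure_noise_sd <- function(cfg, s) {
  sp <- cfg$structures[[s]]
  if (!is.null(sp$noise_sd)) sp$noise_sd else cfg$noise_sd
}

#' Generate a synthetic cross-sectional cohort
#'
#' Draws ages uniformly on the configured range, sex and field strength by
#' Bernoulli sampling, ICV from the sex-specific normals, evaluates the true
#' normalized trajectory of every structure at each age, applies the AD
#' multiplier to AD subjects and the field-bias multiplier to 3T scans, adds
#' Gaussian measurement noise and back-converts to cm^3 through the ICV.
#' Fully deterministic given `config$seed`.
#'
#' @param config a `synthetic_config`.
#' @return A `brain_cohort` with attributes `"latent"` (data frame of
#'   noise-free, bias-free normalized values per structure, AD effect
#'   included) and `"config"`.
#' @export
#' @examples
#' co <- generate_cohort(synthetic_config(n_cn = 50, n_ad = 10, seed = 7))
#' table(co$group, co$field_strength)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_cn + config$n_ad
  group <- rep(c("CN", "AD"), c(config$n_cn, config$n_ad))
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")
  icv <- ifelse(
    sex == "F",
    stats::rnorm(n, config$icv_model$F["mean"], config$icv_model$F["sd"]),
    stats::rnorm(n, config$icv_model$M["mean"], config$icv_model$M["sd"])
  )
  icv <- pmax(icv, 800) # physiological floor
  field <- ifelse(stats::runif(n) < config$fraction_3T, 3.0, 1.5)
  structures <- names(config$structures)
  latent <- list()
  observed <- list()
  for (s in structures) {
    tv <- .trajectory_value(config$structures[[s]], age)
    ad_mult <- ifelse(group == "AD",
                      if (s %in% names(config$ad_effects)) config$ad_effects[[s]] else 1,
                      1)
    lat <- tv * ad_mult
    bias <- if (s %in% names(config$field_bias)) config$field_bias[[s]] else 1
    obs <- lat * ifelse(field == 3.0, bias, 1) +
      stats::rnorm(n, 0, .structure_noise_sd(config, s))
    latent[[s]] <- lat
    observed[[s]] <- pmax(obs, 1e-6)
  }
  df <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = age, sex = sex, group = group, field_strength = field,
    scanner_model = "", site = "", session = 0L, icv = icv,
    stringsAsFactors = FALSE
  )
  for (s in structures) df[[s]] <- observed[[s]] / 100 * icv
  cohort <- as_brain_cohort(df, structures)
  attr(cohort, "latent") <- as.data.frame(latent)
  attr(cohort, "config") <- config
  cohort
}

#' Generate a traveling-subjects cohort
#'
#' Each subject carries one fixed latent value per structure (age is constant
#' across sessions: the design emulates repeat scanning within a short
#' window); each (site, session) adds an independent N(0, `site_noise_sd`)
#' perturbation on the %ICV scale.  Produces `n_sites * n_sessions` rows per
#' subject, all at 3T.
#'
#' @param config a `synthetic_config` with `n_sites >= 2`; `n_cn` is the
#'   number of traveling subjects.
#' @return A `brain_cohort` with a `"latent"` attribute (one row per subject).
#' @export
generate_traveling_subjects <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_sites < 2) stop("traveling design needs n_sites >= 2")
  set.seed(config$seed)
  n <- config$n_cn
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")
  icv <- pmax(ifelse(
    sex == "F",
    stats::rnorm(n, config$icv_model$F["mean"], config$icv_model$F["sd"]),
    stats::rnorm(n, config$icv_model$M["mean"], config$icv_model$M["sd"])
  ), 800)
  structures <- names(config$structures)
  latent <- vapply(structures, function(s) {
    .trajectory_value(config$structures[[s]], age)
  }, numeric(n))
  reps <- config$n_sites * config$n_sessions
  idx <- rep(seq_len(n), each = reps)
  site_no <- rep(rep(seq_len(config$n_sites), each = config$n_sessions), times = n)
  sess_no <- rep(seq_len(reps), times = n)
  df <- data.frame(
    subject_id = sprintf("T%03d", idx),
    age = age[idx], sex = sex[idx], group = "CN", field_strength = 3.0,
    scanner_model = "", site = sprintf("site%02d", site_no),
    session = as.integer(sess_no), icv = icv[idx],
    stringsAsFactors = FALSE
  )
  for (s in structures) {
    obs <- latent[idx, s] + stats::rnorm(nrow(df), 0, config$site_noise_sd)
    df[[s]] <- pmax(obs, 1e-6) / 100 * icv[idx]
  }
  cohort <- as_brain_cohort(df, structures)
  attr(cohort, "latent") <- as.data.frame(latent)
  attr(cohort, "config") <- config
  cohort
}

#' Catalog of preset synthetic scenarios
#'
#' Frozen configurations exercised by the test and acceptance suites:
#' \describe{
#'   \item{null_field}{600 CN, balanced fields, no field bias, left
#'     hippocampus only - the exchangeable null for permutation calibration.}
#'   \item{biased_field_5pct}{1000 CN, balanced fields, 5% multiplicative 3T
#'     bias on the hippocampus.}
#'   \item{ad_contrast}{1000 CN + 1000 AD, full structure set with the
#'     default AD effects (hippocampus 0.8, amygdala 0.85, ventricle 1.4).}
#'   \item{traveling}{9 subjects x 12 sites, additive site noise.}
#' }
#'
#' @param name preset name; `NULL` returns the whole named list.
#' @return A `synthetic_config`, or a named list of them.
#' @export
preset_scenarios <- function(name = NULL) {
  hip_only <- default_structure_specs()["left_hippocampus"]
  presets <- list(
    null_field = synthetic_config(
      n_cn = 600L, fraction_3T = 0.5, structures = hip_only, seed = 101L
    ),
    biased_field_5pct = synthetic_config(
      n_cn = 1000L, fraction_3T = 0.5, structures = hip_only,
      field_bias = c(left_hippocampus = 1.05), seed = 202L
    ),
    ad_contrast = synthetic_config(
      n_cn = 1000L, n_ad = 1000L, seed = 303L
    ),
    traveling = synthetic_config(
      n_cn = 9L, n_sites = 12L, n_sessions = 1L, site_noise_sd = 0.01,
      seed = 404L
    )
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]]
}
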