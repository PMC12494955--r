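#' @title End-to-end pipeline
#' @description Orchestrates simulate/load -> normalize -> fit reference
#'   curves (combined, 1.5T-only, 3T-only) -> curve comparison -> permutation
#'   bias test -> atrophy and HAVAs reports, writing CSV/JSON artifacts and a
#'   run manifest.  Reruns with the same config produce identical artifacts.
#' @name pipeline_cli
NULL

#' Validate a pipeline configuration file
#'
#' Reads a YAML (or JSON) run configuration, fills defaults and reports all
#' problems at once.  Recognized fields: `preset` or `input` (cohort CSV
#' path), `structures` (default: all structures in the data), `smoothing`
#' (default `"concave"`), `subsets` (default combined/1.5T/3T), `metrics`
#' (default the four percentage metrics), `B` (default 10000), `grid_step`
#' (default 1), `seed` (default 1), `out_dir` (default `"brainref_run"`),
#' and logical stage switches `bootstrap`, `atrophy`, `havas`.
#'
#' @param path configuration file path, or a named list already in memory.
#' @return A validated `run_config` list; invalid configs raise one error
#'   listing every problem.
#' @export
validate_config <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else {
    if (!file.exists(path)) stop("config file not found: ", path)
    if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  defaults <- list(
    preset = NULL, input = NULL, structures = NULL,
    smoothing = "concave", subsets = c("combined", "1.5T", "3T"),
    metrics = c("smape", "smspe", "wmape", "smdape"),
    B = 10000L, grid_step = 1, seed = 1L, out_dir = "brainref_run",
    bootstrap = TRUE, atrophy = TRUE, havas = TRUE
  )
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  errs <- character(0)
  if (is.null(cfg$preset) && is.null(cfg$input)) {
    errs <- c(errs, "one of 'preset' or 'input' is required")
  }
  if (!is.null(cfg$preset) && !is.null(cfg$input)) {
    errs <- c(errs, "'preset' and 'input' are mutually exclusive")
  }
  if (!is.null(cfg$preset) && !cfg$preset %in% names(preset_scenarios())) {
    errs <- c(errs, paste0("unknown preset '", cfg$preset, "'"))
  }
  if (!is.null(cfg$input) && !file.exists(cfg$input)) {
    errs <- c(errs, paste0("input file not found: ", cfg$input))
  }
  if (!cfg$smoothing %in% c("concave", "none", "convex")) {
    errs <- c(errs, "smoothing must be one of concave, none, convex")
  }
  bad_sub <- setdiff(cfg$subsets, c("combined", "1.5T", "3T"))
  if (length(bad_sub)) {
    errs <- c(errs, paste0("unknown subset(s): ", paste(bad_sub, collapse = ", ")))
  }
  bad_met <- setdiff(cfg$metrics, c("smape", "smspe", "wmape", "smdape", "mase"))
  if (length(bad_met)) {
    errs <- c(errs, paste0("unknown metric(s): ", paste(bad_met, collapse = ", ")))
  }
  if (!is.numeric(cfg$B) || cfg$B < 1) errs <- c(errs, "B must be positive")
  if (!is.numeric(cfg$grid_step) || cfg$grid_step <= 0) {
    errs <- c(errs, "grid_step must be positive")
  }
  if (length(errs)) {
    stop("invalid run config:\n  - ", paste(errs, collapse = "\n  - "))
  }
  cfg$B <- as.integer(cfg$B)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

.stage <- function(manifest, name, expr) {
  if (!is.null(manifest$failed) && manifest$failed) {
    manifest$stages[[name]] <- "skipped"
    return(manifest)
  }
  res <- tryCatch(
    {
      force(expr)
      "ok"
    },
    error = function(e) paste0("failed: ", conditionMessage(e))
  )
  manifest$stages[[name]] <- res
  if (res != "ok") manifest$failed <- TRUE
  manifest
}

#' Run the full pipeline
#'
#' Executes the configured stages in order, writing per-structure curve CSVs
#' and JSON, a long-format curve comparison table, the permutation bias
#' report, atrophy and HAVAs reports, and a `manifest.json` recording the
#' config, seed and per-stage status.  A stage failure marks downstream
#' stages as skipped and the manifest as failed.
#'
#' @param config a `run_config` from [validate_config()] (or a config list /
#'   file path, validated on the fly).
#' @return The manifest list, invisibly; artifacts go to `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("brainref")),
    seed = config$seed,
    config = unclass(config),
    stages = list(),
    failed = FALSE
  )
  env <- new.env(parent = emptyenv())

  manifest <- .stage(manifest, "data", {
    env$cohort <- if (!is.null(config$preset)) {
      cfg <- preset_scenarios(config$preset)
      cfg$seed <- config$seed + cfg$seed # run seed shifts the preset stream
      generate_cohort(synthetic_config_update(cfg))
    } else {
      read_cohort(config$input)
    }
    write_cohort(env$cohort, file.path(out, "cohort.csv"))
    env$structures <- config$structures
    if (is.null(env$structures)) env$structures <- cohort_structures(env$cohort)
    unknown <- setdiff(env$structures, cohort_structures(env$cohort))
    if (length(unknown)) {
      stop("unknown structure(s) in config: ", paste(unknown, collapse = ", "))
    }
  })

  manifest <- .stage(manifest, "normalize", {
    env$cn <- normalize_by_icv(
      subset_cohort(env$cohort, env$cohort$group == "CN"))
    env$all <- normalize_by_icv(env$cohort)
  })

  manifest <- .stage(manifest, "curves", {
    env$curves <- list()
    for (s in env$structures) {
      for (sub in config$subsets) {
        cs <- fit_reference_curves(
          env$cn, s, smoothing = config$smoothing, subset = sub,
          grid_step = config$grid_step, quiet = TRUE
        )
        env$curves[[s]][[sub]] <- cs
        tag <- gsub("[^A-Za-z0-9]+", "", sub)
        write_curveset(
          cs,
          file.path(out, sprintf("curves_%s_%s.csv", s, tag)),
          file.path(out, sprintf("curves_%s_%s.json", s, tag))
        )
      }
    }
  })

  manifest <- .stage(manifest, "compare", {
    needed <- all(c("1.5T", "3T") %in% config$subsets)
    if (needed) {
      rows <- lapply(env$structures, function(s) {
        as.data.frame(compare_curvesets(
          env$curves[[s]][["1.5T"]], env$curves[[s]][["3T"]],
          metrics = config$metrics
        ))
      })
      utils::write.csv(do.call(rbind, rows),
                       file.path(out, "curve_comparison.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  })

  manifest <- .stage(manifest, "bootstrap", {
    if (isTRUE(config$bootstrap)) {
      results <- lapply(env$structures, function(s) {
        bootstrap_field_bias(
          env$cn, s, smoothing = config$smoothing, metrics = config$metrics,
          B = config$B, seed = config$seed
        )
      })
      rep <- bias_report(results)
      attr(rep, "null_values") <- NULL
      utils::write.csv(rep, file.path(out, "bootstrap_bias.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  })

  manifest <- .stage(manifest, "atrophy", {
    has_ad <- any(env$cohort$group == "AD")
    if (isTRUE(config$atrophy) && has_ad) {
      reports <- list()
      for (s in env$structures) {
        cs <- env$curves[[s]][["combined"]]
        if (is.null(cs)) cs <- env$curves[[s]][[1]]
        ok <- env$cohort$age >= min(cs$age_grid) &
          env$cohort$age <= max(cs$age_grid)
        calls <- call_atrophy(
          normalize_by_icv(subset_cohort(env$cohort, ok)), cs, s)
        ad <- calls[calls$group == "AD", , drop = FALSE]
        cn <- calls[calls$group == "CN", , drop = FALSE]
        rep <- classification_report(ad, cn)
        reports[[s]] <- list(
          atrophy_rate_cn = atrophy_rate(cn), atrophy_rate_ad = atrophy_rate(ad),
          sensitivity = rep$sensitivity, specificity = rep$specificity,
          balanced_accuracy = rep$balanced_accuracy, auc = rep$auc
        )
      }
      jsonlite::write_json(reports, file.path(out, "atrophy_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  })

  manifest <- .stage(manifest, "havas", {
    have_all <- all(unlist(lapply(c("left", "right"), function(sd) {
      all(.havas_structures(sd) %in% cohort_structures(env$cohort))
    })))
    if (isTRUE(config$havas) && have_all) {
      stats <- compute_reference_stats(env$cn)
      hav <- lapply(c("left", "right"), function(sd) {
        curves <- havas_reference_curves(env$cn, stats, side = sd,
                                         smoothing = config$smoothing,
                                         quiet = TRUE)
        scores <- havas_score(env$all, stats, sd)
        ok <- scores$age >= min(curves$age_grid) &
          scores$age <= max(curves$age_grid)
        path <- havas_pathology(scores[ok, , drop = FALSE], curves)
        out_item <- list(side = sd, rate_cn = path$rate_cn,
                         rate_ad = path$rate_ad)
        if (!is.null(path$report)) {
          out_item <- c(out_item, list(
            sensitivity = path$report$sensitivity,
            specificity = path$report$specificity,
            balanced_accuracy = path$report$balanced_accuracy,
            auc = path$report$auc
          ))
        }
        out_item
      })
      jsonlite::write_json(hav, file.path(out, "havas_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  })

  manifest$failed <- isTRUE(manifest$failed)
  jsonlite::write_json(
    manifest[c("package_version", "seed", "stages", "failed")],
    file.path(out, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (manifest$failed) {
    warning("pipeline finished with a failed stage; see manifest.json")
  }
  invisible(manifest)
}

#' Subset a cohort keeping its attributes
#'
#' @param cohort a `brain_cohort`.
#' @param keep logical or integer row index.
#' @return The subsetted `brain_cohort`.
#' @export
subset_cohort <- function(cohort, keep) {
  stopifnot(inherits(cohort, "brain_cohort"))
  out <- as.data.frame(cohort)[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_brain_cohort(out, cohort_structures(cohort))
}

# Rebuild (and so re-validate) a synthetic_config after field edits.
synthetic_config_update <- function(cfg) {
  do.call(synthetic_config, unclass(cfg))
}
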