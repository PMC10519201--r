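# End-to-end orchestration: validate or simulate the two inputs, fit the
# hierarchical isotope model, compute niches and overlaps, run the diet
# classifiers, and collect machine-readable result tables. All randomness
# fans out from one root seed through fixed per-stage streams, so a bundle
# is reproducible from its config and seed alone.

#' Default pipeline configuration
#'
#' Returns the full configuration list understood by
#' [run_full_analysis()], with synthetic inputs at the calibrated study
#' conditions and every stage enabled. Any element can be overridden by
#' supplying a partial list (or YAML file) to `run_full_analysis()`; the
#' values here fill the gaps.
#'
#' @return Nested list: `isotope`/`diet` input blocks (`simulate = TRUE` or
#'   `file`/`column_map`), `stages`, and per-stage settings (`hier` passed
#'   to [hier_config()], `niche`, `overlap`, `classify`).
#' @export
default_pipeline_config <- function() {
  list(
    isotope = list(simulate = TRUE),
    diet = list(simulate = TRUE),
    stages = c("hier", "niche", "overlap", "classify"),
    hier = list(),
    niche = list(ndraw = 4000L, group_by = "species"),
    overlap = list(conf = 0.95, nmc = 1e4L),
    classify = list(
      tasks = list(
        list(label = "species", target = "species", species = NULL),
        list(label = "N_entemedor stages", target = "stage",
             species = "N_entemedor")
      ),
      grid = NULL
    )
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full resource-partitioning analysis
#'
#' Executes the configured stages in dependency order on the configured
#' inputs: `hier` (hierarchical bivariate Student-t model with species
#' means, pairwise contrasts and factor effects), `niche` (per-group
#' Bayesian standard ellipses), `overlap` (directional overlap matrix) and
#' `classify` (tuned random-forest diet classifiers with Shapley prey
#' rankings). A failing stage halts with an error naming the stage; if
#' `out_dir` is set, partial outputs plus a `FAILED` marker are retained.
#'
#' @param config Partial configuration list or path to a YAML file;
#'   defaults are taken from [default_pipeline_config()].
#' @param seed Root integer seed; each stage derives its own stream.
#' @param out_dir Optional output directory for CSV tables, the JSON
#'   bundle and a run log.
#' @param quiet Suppress progress messages.
#' @return Object of class `report_bundle`: result tables per stage plus
#'   diagnostics and provenance (config hash, seed, package version).
#' @export
#' @examples
#' \donttest{
#' cfg <- list(stages = "classify",
#'             classify = list(tasks = list(list(label = "species",
#'                                               target = "species",
#'                                               species = NULL)),
#'                             grid = default_rf_grid()[c(2, 30), ]))
#' bundle <- run_full_analysis(cfg, seed = 1)
#' bundle$classifiers
#' }
run_full_analysis <- function(config = list(), seed = 1L, out_dir = NULL,
                              quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_pipeline_config(), config)
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_lines <- character()
  log_it <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
    say("%s", line)
  }
  fail_marker <- function(stage, e) {
    if (!is.null(out_dir)) {
      writeLines(c(log_lines, sprintf("FAILED at stage %s: %s", stage,
                                      conditionMessage(e))),
                 file.path(out_dir, "FAILED"))
    }
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) fail_marker(stage, e))
  }

  bundle <- list()
  # -- inputs ----------------------------------------------------------
  iso <- run_stage("data", {
    if (isTRUE(cfg$isotope$simulate)) {
      log_it("simulating isotope data (study-calibrated spec)")
      simulate_isotopes(cfg$isotope$spec %||% default_isotope_spec(),
                        seed = .stage_seed(seed, 1L))
    } else if (!is.null(cfg$isotope$file)) {
      log_it("reading isotope data from %s", cfg$isotope$file)
      read_isotope_table(cfg$isotope$file, column_map = cfg$isotope$column_map)
    } else NULL
  })
  diet <- run_stage("data", {
    if (isTRUE(cfg$diet$simulate)) {
      log_it("simulating diet data (study-calibrated spec)")
      simulate_diet(cfg$diet$spec %||% default_diet_spec(),
                    seed = .stage_seed(seed, 2L))
    } else if (!is.null(cfg$diet$file)) {
      log_it("reading diet data from %s", cfg$diet$file)
      read_diet_table(cfg$diet$file, column_map = cfg$diet$column_map)
    } else NULL
  })
  bundle$counts <- list(
    isotope = if (!is.null(iso)) table(iso$species),
    diet = if (!is.null(diet)) table(diet$species)
  )

  # -- hierarchical model ----------------------------------------------
  if ("hier" %in% cfg$stages && !is.null(iso)) {
    run_stage("hier", {
      log_it("fitting hierarchical bivariate Student-t model")
      hc <- do.call(hier_config, cfg$hier)
      fit <- fit_isotope_hier(iso, config = hc, seed = .stage_seed(seed, 3L))
      bundle$hier_fit <- fit
      bundle$species_means <- species_means(fit, force = TRUE)
      bundle$contrasts <- species_contrasts(fit, force = TRUE)
      bundle$effects <- factor_effects(fit, force = TRUE)
      bundle$diagnostics <- list(
        max_rhat = max(fit$diagnostics$rhat),
        min_ess = min(fit$diagnostics$ess),
        divergences = fit$divergences,
        converged = fit$converged
      )
      log_it("hier: converged = %s (max R-hat %.4f, min ESS %.0f)",
             fit$converged, max(fit$diagnostics$rhat), min(fit$diagnostics$ess))
    })
  }

  # -- ellipses ---------------------------------------------------------
  if ("niche" %in% cfg$stages && !is.null(iso)) {
    run_stage("niche", {
      log_it("fitting Bayesian standard ellipses per %s",
             paste(cfg$niche$group_by, collapse = " x "))
      nps <- fit_niche_by_group(iso, group_by = cfg$niche$group_by,
                                ndraw = cfg$niche$ndraw,
                                seed = .stage_seed(seed, 4L))
      bundle$niche_posteriors <- nps
      areas <- lapply(nps, sea_b)
      bundle$niche_areas <- data.frame(
        group = names(areas),
        n = vapply(nps, function(p) p$n, numeric(1L)),
        sea_b_mean = vapply(areas, function(a) a$mean, numeric(1L)),
        hdi_lower = vapply(areas, function(a) a$hdi[1L], numeric(1L)),
        hdi_upper = vapply(areas, function(a) a$hdi[2L], numeric(1L)),
        row.names = NULL
      )
      pairs <- utils::combn(names(areas), 2L)
      bundle$area_comparisons <- do.call(rbind, lapply(
        seq_len(ncol(pairs)), function(q) {
          cmp <- compare_areas(areas[[pairs[1L, q]]], areas[[pairs[2L, q]]])
          data.frame(pair = paste(pairs[1L, q], "-", pairs[2L, q]),
                     mean_diff = cmp$mean_diff, hdi_lower = cmp$hdi[1L],
                     hdi_upper = cmp$hdi[2L], p_greater = cmp$p_greater)
        }))
    })
  }

  # -- overlaps ---------------------------------------------------------
  if ("overlap" %in% cfg$stages && !is.null(bundle$niche_posteriors)) {
    run_stage("overlap", {
      log_it("computing directional overlap matrix (conf %.2f, nmc %d)",
             cfg$overlap$conf, cfg$overlap$nmc)
      bundle$overlap <- overlap_matrix(bundle$niche_posteriors,
                                       conf = cfg$overlap$conf,
                                       nmc = cfg$overlap$nmc,
                                       seed = .stage_seed(seed, 5L))
    })
  }

  # -- classifiers ------------------------------------------------------
  if ("classify" %in% cfg$stages && !is.null(diet)) {
    run_stage("classify", {
      grid <- cfg$classify$grid %||% default_rf_grid()
      fits <- list()
      for (ti in seq_along(cfg$classify$tasks)) {
        task <- cfg$classify$tasks[[ti]]
        dd <- diet
        if (!is.null(task$species)) dd <- dd[dd$species == task$species, ]
        log_it("classifier task '%s' (%d rows)", task$label, nrow(dd))
        fits[[task$label]] <- rf_classify(dd, task$target, grid = grid,
                                          seed = .stage_seed(seed, 10L + ti),
                                          label = task$label)
      }
      bundle$classifier_fits <- fits
      bundle$classifiers <- do.call(rbind, lapply(fits, function(f) {
        data.frame(task = f$label, trees = f$best$num_trees,
                   max_depth = f$best$max_depth, max_features = f$best$mtry,
                   cv_auc = f$cv_auc, test_auc = f$test_auc,
                   balanced = f$balanced, row.names = NULL)
      }))
      bundle$importance <- lapply(fits, function(f) {
        sh <- shapley_importance(f, d = f$train_data, n_samples = 50L,
                                 seed = .stage_seed(seed, 20L))
        data.frame(prey = names(sh$importance),
                   mean_abs_shap = unname(sh$importance),
                   row.names = NULL)[order(-sh$importance), ]
      })
    })
  }

  # -- provenance -------------------------------------------------------
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tf)
  bundle$provenance <- list(
    config_hash = unname(tools::md5sum(tf)),
    seed = seed,
    package_version = as.character(utils::packageVersion("isopart")),
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  )
  unlink(tf)
  class(bundle) <- "report_bundle"

  if (!is.null(out_dir)) {
    .write_bundle(bundle, out_dir, log_lines, iso, diet)
  }
  bundle
}

.write_bundle <- function(bundle, out_dir, log_lines, iso, diet) {
  wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)
  if (!is.null(iso)) write_isotope_table(iso, file.path(out_dir, "isotope_data.csv"))
  if (!is.null(diet)) write_diet_table(diet, file.path(out_dir, "diet_data.csv"))
  if (!is.null(bundle$species_means)) wcsv(bundle$species_means, "species_means.csv")
  if (!is.null(bundle$contrasts)) wcsv(bundle$contrasts, "species_contrasts.csv")
  if (!is.null(bundle$effects)) wcsv(bundle$effects, "factor_effects.csv")
  if (!is.null(bundle$niche_areas)) wcsv(bundle$niche_areas, "niche_areas.csv")
  if (!is.null(bundle$area_comparisons)) wcsv(bundle$area_comparisons,
                                              "area_comparisons.csv")
  if (!is.null(bundle$overlap)) {
    ov <- as.data.frame(unclass(bundle$overlap)[seq_len(nrow(bundle$overlap)), ,
                                                drop = FALSE])
    ov <- cbind(group = rownames(bundle$overlap), ov)
    wcsv(ov, "overlap_matrix.csv")
  }
  if (!is.null(bundle$classifiers)) wcsv(bundle$classifiers, "classifiers.csv")
  json <- list(
    counts = lapply(bundle$counts, function(t) if (!is.null(t)) as.list(t)),
    species_means = bundle$species_means,
    contrasts = bundle$contrasts,
    effects = bundle$effects,
    niche_areas = bundle$niche_areas,
    area_comparisons = bundle$area_comparisons,
    overlap_pct = if (!is.null(bundle$overlap)) {
      m <- unclass(bundle$overlap)
      attributes(m)[c("draws", "conf")] <- NULL
      m
    },
    classifiers = bundle$classifiers,
    importance = bundle$importance,
    diagnostics = bundle$diagnostics,
    provenance = bundle$provenance
  )
  jsonlite::write_json(json, file.path(out_dir, "report_bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Resource-partitioning report bundle\n")
  if (!is.null(x$counts$isotope)) {
    cat("  isotope rows:", paste(sprintf("%s=%d", names(x$counts$isotope),
                                         x$counts$isotope), collapse = ", "), "\n")
  }
  if (!is.null(x$species_means)) {
    cat("\nSpecies-level posterior means:\n")
    print(x$species_means, digits = 4L, row.names = FALSE)
  }
  if (!is.null(x$niche_areas)) {
    cat("\nSEA_B niche areas:\n")
    print(x$niche_areas, digits = 3L, row.names = FALSE)
  }
  if (!is.null(x$overlap)) {
    cat("\nDirectional overlaps (%, row within column region):\n")
    print(round(unclass(x$overlap)[, , drop = FALSE], 1L))
  }
  if (!is.null(x$classifiers)) {
    cat("\nDiet classifiers:\n")
    print(x$classifiers, digits = 3L, row.names = FALSE)
  }
  invisible(x)
}
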