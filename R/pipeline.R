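#' Default configuration of the salmon calibration study
#'
#' The study conditions used throughout the package's examples and
#' acceptance checks: 300 samples with the salmon-muscle composition
#' statistics and correlation structure, triplicate Raman-like and
#' NIR-reflectance-like spectra with multiplicative scatter, random
#' polynomial baselines (order 4 Raman, order 2 NIR) and additive noise,
#' 7-fold venetian-blind cross-validation with up to 20 components, and
#' minimum-RMSECV component selection.
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param n_samples samples to simulate (default 300).
#' @param output_dir where run artifacts are written.
#' @return a named list usable as `config` in [run_pipeline()].
#' @export
salmon_study_config <- function(seed = 1, n_samples = 300,
                                output_dir = tempfile("specfat_run_")) {
  list(
    seed = seed,
    n_samples = n_samples,
    modalities = c("raman", "nir"),
    n_replicates = 3,
    raman = list(noise_sd = 0.001, scatter_sd = 0.05, baseline_order = 4,
                 baseline_amp = 0.01, trim = c(500, 1800), emsc_order = 6,
                 reference_baseline_order = 4),
    nir = list(noise_sd = 0.0012, scatter_sd = 0.10, baseline_order = 2,
               baseline_amp = 0.03, trim = c(1150, 2500)),
    targets = list(fa = salmon_reference_stats()$name,
                   features = c("EPA_DHA", "SFA", "MUFA", "PUFA", "IV"),
                   content = "proportional"),
    folds = 7,
    A_max = 20,
    rule = "min",
    selection = NULL,
    write_spectra = FALSE,
    output_dir = output_dir)
}

# fixed fan-out of the global seed to per-stage seeds (32-bit safe)
derive_seed <- function(seed, stage) {
  offs <- c(composition = 10007, raman = 20011, nir = 30011)
  as.integer((as.numeric(seed) + offs[[stage]]) %% 2147483647)
}

# resolve the response vector for a named target
target_vector <- function(target, comps, content = "proportional") {
  V <- comps$V
  y <- if (target %in% colnames(V)) {
    V[, target]
  } else if (target %in% c("EPA_DHA", "SFA", "MUFA", "PUFA")) {
    fa_features(V, fatty_acid_definitions(colnames(V)))[, target]
  } else if (target == "IV") {
    iodine_value(V, fatty_acid_definitions(colnames(V)))
  } else if (target == "fat") {
    return(comps$fat)
  } else {
    stop("unknown target: ", target)
  }
  if (identical(content, "absolute") && target != "fat")
    y <- y * comps$fat / 100
  y
}

#' Run the full simulation-to-diagnostics pipeline
#'
#' Executes the stages in order — simulate compositions, synthesize spectra
#' per modality, preprocess (modality-specific chain), calibrate every
#' target with cross-validated PLS, optionally run variable selection, and
#' assemble diagnostics — writing all artifacts and a manifest (seed, config
#' hash, package version) under `config$output_dir`. A failing stage aborts
#' with the stage named; artifacts of completed stages remain on disk.
#'
#' @param config configuration list as from [salmon_study_config()], or a
#'   path to a YAML file with the same structure.
#' @return (invisibly) a list with `compositions`, `spectra` (preprocessed,
#'   per modality), `models`, `cv` results, `selection` results,
#'   `diagnostics`, and `manifest`.
#' @export
run_pipeline <- function(config = salmon_study_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$seed))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$output_dir, "config.yaml")
  yaml::write_yaml(rapply(config, as.vector, how = "replace"), cfg_path)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_msg <- function(...) message("[specfat] ", sprintf(...))

  # -- simulate ------------------------------------------------------------
  comps <- stage("simulate", {
    spec <- composition_spec(n_samples = config$n_samples,
                             seed = derive_seed(config$seed, "composition"))
    cc <- draw_compositions(spec)
    write_composition_csv(cc, file.path(config$output_dir, "compositions.csv"))
    cc
  })
  log_msg("simulated %d compositions", nrow(comps$V))

  raw <- list()
  pre <- list()
  for (mod in config$modalities) {
    mc <- config[[mod]]
    raw[[mod]] <- stage(paste0("synthesize_", mod), {
      synthesize_spectra(
        comps,
        modality = if (mod == "nir") "nir_reflectance" else "raman",
        noise_sd = mc$noise_sd, scatter_sd = mc$scatter_sd,
        baseline_order = mc$baseline_order, baseline_amp = mc$baseline_amp,
        n_replicates = config$n_replicates,
        seed = derive_seed(config$seed, mod))
    })
    pre[[mod]] <- stage(paste0("preprocess_", mod), {
      if (mod == "nir") {
        preprocess_nir(raw[[mod]], range = mc$trim)
      } else {
        preprocess_raman(raw[[mod]], range = mc$trim,
                         emsc_order = mc$emsc_order,
                         baseline_order = mc$reference_baseline_order)$spectra
      }
    })
    if (isTRUE(config$write_spectra))
      write_spectra_csv(pre[[mod]],
                        file.path(config$output_dir,
                                  paste0("spectra_", mod, ".csv")))
    log_msg("%s: %d spectra x %d channels after preprocessing", mod,
            nrow(pre[[mod]]$intensities), length(pre[[mod]]$axis))
  }

  # -- calibrate -----------------------------------------------------------
  targets <- c(config$targets$fa, config$targets$features)
  folds <- venetian_blinds(config$n_samples, config$folds)
  models <- list(); cvs <- list()
  for (mod in config$modalities) {
    X <- pre[[mod]]$intensities
    models[[mod]] <- list(); cvs[[mod]] <- list()
    rows <- list()
    for (tg in targets) {
      res <- stage(paste0("calibrate_", mod), {
        y <- target_vector(tg, comps, config$targets$content)
        cv <- cross_validate(X, y, A_max = config$A_max, folds = folds)
        A <- select_components(cv, config$rule)
        list(cv = cv, A = A, model = pls_fit(X, y, A_max = config$A_max))
      })
      models[[mod]][[tg]] <- res$model
      cvs[[mod]][[tg]] <- res$cv
      rows[[tg]] <- data.frame(modality = mod, target = tg,
                               n_components = res$A,
                               rmsecv = min(res$cv$rmsecv),
                               r2cv = res$cv$r2cv[res$A])
    }
    perf <- do.call(rbind, rows)
    utils::write.csv(perf,
                     file.path(config$output_dir,
                               paste0("cv_summary_", mod, ".csv")),
                     row.names = FALSE)
    log_msg("%s: calibrated %d targets (mean R2cv %.2f)", mod, nrow(perf),
            mean(perf$r2cv))
  }

  # -- select (optional) ---------------------------------------------------
  selection <- NULL
  if (!is.null(config$selection)) {
    selection <- stage("select", {
      sc <- config$selection
      mod <- sc$modality %||% "raman"
      X <- pre[[mod]]$intensities
      out <- lapply(sc$targets %||% targets[1], function(tg) {
        y <- target_vector(tg, comps, config$targets$content)
        if (identical(sc$method, "regions")) {
          region_retrain(X, y, pre[[mod]]$axis, sc$regions,
                         A_max = config$A_max, folds = folds)
        } else {
          bottom_up_select(X, y, block_size = sc$block_size %||% 100,
                           A_max = config$A_max, tol = sc$tol %||% 0,
                           folds = folds)
        }
      })
      names(out) <- sc$targets %||% targets[1]
      for (tg in names(out))
        write_selection_yaml(out[[tg]],
                             file.path(config$output_dir,
                                       sprintf("selection_%s_%s.yaml", mod,
                                               gsub("[^A-Za-z0-9]+", "_", tg))),
                             axis = pre[[mod]]$axis)
      out
    })
  }

  # -- diagnose ------------------------------------------------------------
  diagnostics <- stage("diagnose", {
    blocks <- c(list(references = comps$V),
                lapply(pre, function(s) s$intensities))
    fa <- config$targets$fa
    mod1 <- config$modalities[1]
    pred <- vapply(fa, function(tg) {
      cv <- cvs[[mod1]][[tg]]
      cv$predictions[, select_components(cv, config$rule)]
    }, numeric(config$n_samples))
    rep <- diagnostics_report(blocks, comps$V[, fa, drop = FALSE], pred)
    write_diagnostics(rep, file.path(config$output_dir, "diagnostics"))
    rep
  })

  manifest <- list(
    package = "specfat",
    version = as.character(utils::packageVersion("specfat")),
    seed = config$seed,
    stage_seeds = list(composition = derive_seed(config$seed, "composition"),
                       raman = derive_seed(config$seed, "raman"),
                       nir = derive_seed(config$seed, "nir")),
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(cfg_path)),
    artifacts = list.files(config$output_dir, recursive = TRUE))
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))

  invisible(list(compositions = comps, spectra = pre, models = models,
                 cv = cvs, selection = selection, diagnostics = diagnostics,
                 manifest = manifest, config = config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
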