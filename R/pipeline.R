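#' Pipeline configuration
#'
#' One object drives the end-to-end analysis: simulate (or load) spectra per
#' instrument window, duplex-split with cow blocking, run the preprocessing
#' grid with parsimonious chain/latent selection per component, select
#' wavelengths, evaluate on the held-out validation set and, with several
#' windows, compare instruments.
#'
#' @param synthetic a [synthetic_config()], or `NULL` to load CSVs.
#' @param spectra_path,composition_path CSV paths (load mode; the spectra
#'   file is restricted to each requested window).
#' @param components character subset of the composition columns to model.
#' @param windows named list of [instrument_window()]s to emulate; default
#'   the single 1550-1950 nm transmittance module.
#' @param selection a [selection_config()]; defaults to
#'   `selection_config(max_latent = 8, n_intervals = 8)` in fast grid mode
#'   and the full defaults otherwise.
#' @param grid `"fast"` ([fast_chains()]) or `"full"` (all 420 chains).
#' @param cv_k number of cross-validation folds (default 10).
#' @param out_dir output directory for report CSVs, serialized models and the
#'   manifest; `NULL` keeps everything in memory.
#' @param seed integer seed for fold assignment (and the synthetic generator
#'   if `synthetic` carries no seed of its own).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL,
                            spectra_path = NULL, composition_path = NULL,
                            components = c("fat_pct", "protein_pct", "lactose_pct"),
                            windows = instrument_windows()["nirone_2.0_T"],
                            selection = NULL,
                            grid = c("fast", "full"),
                            cv_k = 10,
                            out_dir = NULL,
                            seed = 1L) {
  grid <- match.arg(grid)
  if (length(components) == 0) {
    stopf("at least one component must be modelled", class = "nirmilk_config_error")
  }
  if (is.null(synthetic) &&
      (is.null(spectra_path) || is.null(composition_path))) {
    stopf("either a synthetic config or both CSV paths are required",
          class = "nirmilk_config_error")
  }
  if (!is.null(spectra_path) && !file.exists(spectra_path)) {
    stopf("spectra_path does not exist: %s", spectra_path,
          class = "nirmilk_config_error")
  }
  if (is.null(selection)) {
    selection <- if (grid == "fast") {
      selection_config(max_latent = 8, n_intervals = 8)
    } else {
      selection_config()
    }
  }
  structure(list(synthetic = synthetic, spectra_path = spectra_path,
                 composition_path = composition_path,
                 components = components, windows = windows,
                 selection = selection, grid = grid,
                 cv_k = as.integer(cv_k), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end calibration pipeline
#'
#' Stages, in order, per instrument window and component: acquire data
#' (synthetic generation or CSV load + window restriction), cow-blocked
#' duplex split, cow-blocked CV folds, preprocessing-grid cross-validation
#' with parsimonious chain and latent selection, wavelength selection (FULL,
#' VIP, JK, RiPLS, FiPLS), final fit on the whole calibration set and
#' evaluation on the untouched validation set; finally a Tukey comparison of
#' windows when more than one is emulated.  Validation spectra are never
#' read before the evaluation stage.
#'
#' @param cfg a [pipeline_config()].
#' @return object of class `pipeline_result`: list with `split`, `models`
#'   (tibble: window, component, chain, latent count, retained wavelengths,
#'   RMSECV/RMSEP/R2, ICAR flags), `selection_reports`, `grid_rankings`,
#'   `comparisons` (per component, when several windows ran), `artifacts`
#'   (named list of per-model detail), and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  # --- acquire -------------------------------------------------------------
  datasets <- list()
  if (!is.null(cfg$synthetic)) {
    base <- cfg$synthetic
    cs <- sample_compositions(base)
    composition <- cs$composition
    for (wname in names(cfg$windows)) {
      wcfg <- base
      wcfg$window <- cfg$windows[[wname]]
      datasets[[wname]] <- generate_spectra(wcfg, composition, cs$truth)$dataset
    }
  } else {
    loaded <- read_dataset(cfg$spectra_path, cfg$composition_path)
    composition <- loaded$composition
    composition$cow_id <- loaded$dataset$meta$cow_id
    for (wname in names(cfg$windows)) {
      datasets[[wname]] <- restrict_wavelengths(loaded$dataset,
                                                cfg$windows[[wname]])
    }
  }
  comps_avail <- composition_components(composition)
  bad <- setdiff(cfg$components, comps_avail)
  if (length(bad)) {
    stopf("component(s) not in the composition table: %s",
          paste(bad, collapse = ", "), class = "nirmilk_config_error")
  }

  # --- split (composition only; spectra untouched) -------------------------
  split <- duplex_split(composition)
  cal <- split$assignment$set == "cal"
  folds <- make_cv_folds(split$assignment$cow_id[cal], k = cfg$cv_k,
                         seed = cfg$seed)
  chains <- if (cfg$grid == "fast") fast_chains() else enumerate_chains()$label
  scfg <- cfg$selection

  models <- list(); grids <- list(); sel_reports <- list(); artifacts <- list()
  for (wname in names(datasets)) {
    ds <- datasets[[wname]]
    wl <- ds$wavelengths_nm
    X_cal <- ds$intensities[cal, , drop = FALSE]
    X_val <- ds$intensities[!cal, , drop = FALSE]
    for (comp in cfg$components) {
      y_cal <- composition[[comp]][cal]
      y_val <- composition[[comp]][!cal]
      key <- paste(wname, comp, sep = ".")

      grid_res <- run_chain_grid(chains, X_cal, y_cal, folds,
                                 max_latent = scfg$max_latent,
                                 alpha = scfg$alpha, wavelengths = wl)
      chain_sel <- select_chain(grid_res, scfg$alpha)
      grids[[key]] <- dplyr::mutate(chain_sel$ranking, window = wname,
                                    component = comp, .before = 1)

      ws <- select_wavelengths(X_cal, y_cal, folds, scfg,
                               chain = chain_sel$label, wavelengths = wl)
      sel_reports[[key]] <- dplyr::mutate(ws$report, window = wname,
                                          component = comp, .before = 1)
      chosen <- ws$chosen

      proc <- apply_chain(chain_sel$label, X_cal, y_cal, X_val, wavelengths = wl)
      model <- fit_plsr(proc$X_cal[, chosen$indices, drop = FALSE], y_cal,
                        chosen$n_latent,
                        wavelengths = wl[chosen$indices],
                        chain_label = chain_sel$label,
                        wavelength_mask = chosen$indices)
      y_hat <- predict(model, proc$X_new[, chosen$indices, drop = FALSE])
      ev <- evaluate_predictions(y_val, y_hat, component = comp,
                                 rmsecv = chosen$rmsecv, r2cv = chosen$r2cv,
                                 spectrometer = wname)
      models[[key]] <- dplyr::mutate(
        glance(ev),
        chain = chain_sel$label, selection = chosen$method,
        n_latent = chosen$n_latent,
        effective_latent = chosen$n_latent +
          as.integer(parse_chain(chain_sel$label)$step4 == "OSC"),
        n_retained = chosen$n_retained, .after = "spectrometer"
      )
      artifacts[[key]] <- list(model = model, eval = ev, subset = chosen,
                               chain = chain_sel$label)
      if (!is.null(out_dir)) {
        write_plsr(model, file.path(out_dir, paste0("model_", key, ".json")))
        readr::write_csv(
          tibble::tibble(sample_id = split$assignment$sample_id[!cal],
                         reference = y_val, predicted = y_hat),
          file.path(out_dir, paste0("predictions_", key, ".csv"))
        )
      }
    }
  }

  models_tbl <- dplyr::bind_rows(models)
  grid_tbl <- dplyr::bind_rows(grids)
  sel_tbl <- dplyr::bind_rows(sel_reports)

  # --- cross-window comparison --------------------------------------------
  comparisons <- list()
  if (length(datasets) >= 2) {
    for (comp in cfg$components) {
      keys <- paste(names(datasets), comp, sep = ".")
      sq <- sapply(keys, function(k) artifacts[[k]]$eval$predictions$residual^2)
      colnames(sq) <- names(datasets)
      comparisons[[comp]] <- compare_spectrometers(sq, alpha = scfg$alpha)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("nirmilk")),
    seed = cfg$seed,
    grid = cfg$grid,
    n_chains = length(chains),
    components = cfg$components,
    windows = names(cfg$windows),
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  )
  if (!is.null(out_dir)) {
    write_split(split, file.path(out_dir, "split.csv"))
    readr::write_csv(grid_tbl, file.path(out_dir, "grid_ranking.csv"))
    readr::write_csv(sel_tbl, file.path(out_dir, "wavelength_selection.csv"))
    readr::write_csv(models_tbl, file.path(out_dir, "evaluation.csv"))
    for (comp in names(comparisons)) {
      readr::write_csv(comparisons[[comp]]$letters,
                       file.path(out_dir, paste0("comparison_", comp, ".csv")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(split = split, models = models_tbl, grid_rankings = grid_tbl,
                 selection_reports = sel_tbl, comparisons = comparisons,
                 artifacts = artifacts, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d model(s)\n", nrow(x$models)))
  print(dplyr::select(x$models, dplyr::any_of(c(
    "spectrometer", "component", "chain", "selection", "n_latent",
    "n_retained", "rmsecv", "rmsep", "r2p"
  ))))
  invisible(x)
}
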