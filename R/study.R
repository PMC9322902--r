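#' Full-study configuration
#'
#' @param input a fixture name from [make_fixture()] ("easy", "hard",
#'   "prescription") or a path to a spectra CSV
#' @param recipes preset recipe names screened in the model grid
#' @param model_kinds classifiers screened in the model grid
#' @param fraction Kennard-Stone calibration fraction (default 0.8)
#' @param rf,svm,plsda model configurations
#' @param regions named [region_set()] list for the region experiment
#' @param vip_cutoffs importance cutoffs for the selection experiment
#' @param positive_class label treated as class 1 (default first sorted)
#' @param seed master RNG seed for every stochastic stage
#' @param out_dir output directory (`NULL`: a fresh temporary directory)
#' @return a `study_config` list
#' @export
study_config <- function(input = "easy", recipes = preset_names(),
                         model_kinds = c("rf", "svm", "plsda"),
                         fraction = 0.8, rf = rf_config(),
                         svm = svm_config(), plsda = plsda_config(),
                         regions = default_regions(),
                         vip_cutoffs = c(0.05, 0.01, 0.015, 0.020),
                         positive_class = NULL, seed = 20220720,
                         out_dir = NULL) {
  known <- preset_names()
  bad <- setdiff(recipes, known)
  if (length(bad)) stop("unknown recipe name(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(model_kinds, c("rf", "svm", "plsda"))
  if (length(bad)) stop("unknown model kind(s): ", paste(bad, collapse = ", "))
  structure(list(input = input, recipes = recipes,
                 model_kinds = model_kinds, fraction = fraction, rf = rf,
                 svm = svm, plsda = plsda, regions = regions,
                 vip_cutoffs = vip_cutoffs, positive_class = positive_class,
                 seed = seed, out_dir = out_dir),
            class = "study_config")
}

load_study_input <- function(cfg) {
  if (cfg$input %in% c("easy", "hard", "prescription"))
    make_fixture(cfg$input, seed = cfg$seed)$training
  else read_spectra_csv(cfg$input)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                           force = TRUE, digits = NA)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full discrimination study
#'
#' Executes, in order: (1) load or generate the labeled spectra;
#' (2) the pretreatment x classifier [comparison_grid()]; (3) selection of
#' the best (recipe, model) cell by validation accuracy (ties toward higher
#' MCC); (4) deep tuning of the random forest under the best recipe —
#' [tune_ntree()], [tune_mtry()], [region_experiment()],
#' [vip_experiment()] — and a final refit on the variables surviving the
#' best importance cutoff; (5) final validation metrics, a class-mean band
#' report, and serialization of every table, the trained model, a log and a
#' run manifest into the output directory. Rerunning with the same config
#' and seed reproduces all tables bit-identically.
#'
#' @param cfg a [study_config()]
#' @return (invisibly) a list with all tables, the final `ftir_model` and
#'   the output directory
#' @export
run_study <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "study_config"))
  out_dir <- cfg$out_dir %||% tempfile("ftir_study_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " INFO ",
                   sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  note("loading input '%s'", cfg$input)
  s <- load_study_input(cfg)
  positive_class <- cfg$positive_class %||% sort(unique(s$labels))[1]
  note("loaded %d samples x %d points; positive class %s",
       n_samples(s), n_points(s), positive_class)

  note("running %d-recipe x %d-model comparison grid",
       length(cfg$recipes), length(cfg$model_kinds))
  grid <- comparison_grid(s, recipes = cfg$recipes,
                          model_kinds = cfg$model_kinds,
                          fraction = cfg$fraction, seed = cfg$seed,
                          positive_class = positive_class, rf = cfg$rf,
                          svm = cfg$svm, plsda = cfg$plsda)
  val <- grid[grid$set == "validation" & is.na(grid$error), ]
  best_cell <- val[order(-val$acc, -val$mcc), ][1, ]
  note("best cell: recipe=%s model=%s (validation ACC %.4f)",
       best_cell$recipe, best_cell$model, best_cell$acc)

  best_recipe <- best_cell$recipe
  prep <- prepare_split_data(s, best_recipe, cfg$fraction, NULL, cfg$seed)

  note("tuning RF ensemble size over {%s}",
       paste(cfg$rf$n_tree_grid, collapse = ", "))
  rf_cfg <- cfg$rf; rf_cfg$seed <- cfg$seed
  nt <- tune_ntree(prep$Xcal, prep$ycal, rf_cfg,
                   positive_class = positive_class)
  note("best n_tree = %d", nt$best_n_tree)
  mt <- tune_mtry(prep$Xcal, prep$ycal, n_tree = nt$best_n_tree,
                  grid = rf_cfg$m_try_grid, seed = cfg$seed,
                  positive_class = positive_class)
  note("best m_try = %d", mt$best_m_try)

  region_tab <- region_experiment(
    s, regions = cfg$regions, recipe_name = best_recipe,
    n_tree = nt$best_n_tree, m_try = NULL, fraction = cfg$fraction,
    seed = cfg$seed, positive_class = positive_class)
  note("region experiment: best region %s (ACC %.4f)",
       region_tab$region[which.max(region_tab$acc)], max(region_tab$acc,
                                                         na.rm = TRUE))

  vip_tab <- vip_experiment(
    s, cutoffs = cfg$vip_cutoffs, recipe_name = best_recipe,
    n_tree = nt$best_n_tree, m_try = mt$best_m_try,
    fraction = cfg$fraction, seed = cfg$seed,
    positive_class = positive_class)
  best_cut <- vip_tab[order(-vip_tab$acc, -vip_tab$mcc), ][1, ]
  note("VIP experiment: best cutoff %.3f keeps %d variables (ACC %.4f)",
       best_cut$cutoff, best_cut$n_selected, best_cut$acc)

  # final refit: tuned (n_tree, m_try), variables surviving the best cutoff
  full_rf <- fit_rf(prep$Xcal, prep$ycal, n_tree = nt$best_n_tree,
                    m_try = mt$best_m_try, seed = cfg$seed,
                    positive_class = positive_class)
  sel <- suppressWarnings(select_by_vip(rf_importance(full_rf),
                                        best_cut$cutoff))
  final <- fit_rf(prep$Xcal[, sel, drop = FALSE], prep$ycal,
                  n_tree = nt$best_n_tree,
                  m_try = min(mt$best_m_try, length(sel)), seed = cfg$seed,
                  positive_class = positive_class)
  final$var_names <- colnames(prep$Xcal)
  final$selected_idx <- sel
  final$fitted_recipe <- prep$fitted_recipe
  final$training_wavenumbers <- s$wavenumbers
  final$metadata <- list(recipe = best_recipe, seed = cfg$seed,
                         split_hash = config_hash(prep$split),
                         n_tree = nt$best_n_tree, m_try = mt$best_m_try,
                         vip_cutoff = best_cut$cutoff)
  pv <- stats::predict(final, prep$Xval)
  final_metrics <- evaluate_predictions(prep$yval, pv$labels, pv$scores,
                                        positive_class)
  note("final RF validation: ACC %.4f, MCC %.4f",
       final_metrics$acc, final_metrics$mcc)

  band_report <- discriminating_report(s)

  # --- write everything ---
  wr <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE)
  wr(grid, "comparison_grid.csv")
  wr(nt$table, "ntree_table.csv")
  wr(mt$table, "mtry_table.csv")
  wr(region_tab, "region_table.csv")
  wr(vip_tab, "vip_table.csv")
  wr(final_metrics, "final_metrics.csv")
  wr(band_report, "band_report.csv")
  jsonlite::write_json(
    list(final_metrics = as.list(final_metrics),
         best_recipe = best_recipe, best_model = best_cell$model,
         n_tree = nt$best_n_tree, m_try = mt$best_m_try,
         vip_cutoff = best_cut$cutoff, n_selected = length(sel)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  save_model(final, file.path(out_dir, "model"))
  write_split_csv(prep$split, s, file.path(out_dir, "split.csv"))
  # hash the substantive configuration, not the ephemeral paths
  manifest <- list(config_hash = config_hash(
    cfg[setdiff(names(cfg), c("input", "out_dir"))]), seed = cfg$seed,
                   input = cfg$input,
                   package_version =
                     as.character(utils::packageVersion("ftirdisc")),
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))

  invisible(list(out_dir = out_dir, grid = grid, best_recipe = best_recipe,
                 best_model = best_cell$model, ntree = nt, mtry = mt,
                 region_table = region_tab, vip_table = vip_tab,
                 final_model = final, final_metrics = final_metrics,
                 band_report = band_report, split = prep$split,
                 manifest = manifest))
}

#' Score external spectra with a frozen trained model
#'
#' Applies the model's frozen pretreatment recipe (calibration-set MSC
#' reference and all) and the trained classifier to new spectra. Spectra on
#' a different grid are linearly interpolated onto the training grid when
#' they cover the training range (flagged in the result); otherwise an
#' error is raised. When the external file carries labels, the four
#' confusion-matrix parameters plus AUC are appended.
#'
#' @param model an `ftir_model` carrying a fitted recipe (as produced by
#'   [run_study()]), or the path of a [save_model()] directory
#' @param spectra a `spectrum_set` in transmittance mode, or a CSV path
#' @return list(predictions = data.frame, metrics = data.frame or NULL,
#'   interpolated = logical)
#' @export
predict_external <- function(model, spectra) {
  if (is.character(model)) model <- load_model(model)
  stopifnot(inherits(model, "ftir_model"))
  if (is.null(model$fitted_recipe))
    stop("model carries no fitted recipe; retrain via run_study()")
  if (is.character(spectra)) spectra <- read_spectra_csv(spectra)

  grid <- model$training_wavenumbers
  interpolated <- FALSE
  if (!isTRUE(all.equal(spectra$wavenumbers, grid))) {
    rng_new <- range(spectra$wavenumbers)
    if (min(grid) < rng_new[1] || max(grid) > rng_new[2])
      stop("external grid does not cover the training range ",
           sprintf("[%g, %g]", min(grid), max(grid)))
    vals <- t(apply(spectra$values, 1, function(row)
      stats::approx(spectra$wavenumbers, row, xout = grid)$y))
    spectra <- spectrum_set(grid, vals, spectra$mode, spectra$sample_ids,
                            spectra$labels)
    interpolated <- TRUE
    warning("external spectra linearly interpolated onto the training grid")
  }
  pre <- suppressWarnings(apply_recipe(model$fitted_recipe, spectra))
  pr <- stats::predict(model, pre$values)
  predictions <- data.frame(sample_id = spectra$sample_ids,
                            predicted = pr$labels, score = pr$scores,
                            stringsAsFactors = FALSE)
  metr <- NULL
  if (!is.null(spectra$labels)) {
    predictions$label <- spectra$labels
    metr <- evaluate_predictions(spectra$labels, pr$labels, pr$scores,
                                 model$positive_class)
  }
  list(predictions = predictions, metrics = metr,
       interpolated = interpolated)
}
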