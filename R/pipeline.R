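#' Configuration of a full experiment run
#'
#' Bundles the per-stage configurations. `scale` expresses the per-class
#' fruit counts as a fraction of the study scale (1105/1205/962); an
#' explicit `n_fruits_per_class` overrides it. The desk-scale default is
#' 60 fruits per class. The CNN batch size defaults to a quarter of the
#' calibration set, mirroring the full-scale ratio (batch 400 of ~1600
#' calibration samples), and desk-scale epochs default to 100.
#'
#' @param n_fruits_per_class integer (scalar or length 3); overrides
#'   `scale`.
#' @param scale fraction in (0, 1] of the study-scale class counts.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param scene overrides for [scene_config()] fields (list).
#' @param selection overrides for [select_effective()] parameters.
#' @param svm_grid overrides for [svm_grid_search()] (cost/gamma grids).
#' @param cnn overrides for [cnn_spec()] fields.
#' @param max_lv PLS-DA latent-variable search cap.
#' @param out output directory for reports and the manifest (`NULL` for
#'   none).
#' @return a `run_config` list.
#' @export
run_config <- function(n_fruits_per_class = 60L, scale = NULL, seed = 1L,
                       scene = list(), selection = list(),
                       svm_grid = list(), cnn = list(), max_lv = 15L,
                       out = NULL) {
  if (!is.null(scale)) {
    if (scale <= 0 || scale > 1)
      hsi_abort("scale must be in (0, 1]", "hsi_invalid_argument")
    n_fruits_per_class <- pmax(1L, as.integer(round(scale * c(1105, 1205, 962))))
  }
  structure(list(n_fruits_per_class = rep(as.integer(n_fruits_per_class),
                                          length.out = 3L),
                 seed = as.integer(seed), scene = scene,
                 selection = selection, svm_grid = svm_grid, cnn = cnn,
                 max_lv = as.integer(max_lv), out = out),
            class = "run_config")
}

#' Run the full experiment
#'
#' simulate -> correct -> segment -> preprocess -> split -> select
#' effective wavelengths -> train PLS-DA, SVM and CNN on full spectra and
#' on effective wavelengths -> confusion matrices for the calibration,
#' validation and prediction splits -> report. Fully deterministic under
#' the config seed.
#'
#' @param cfg a [run_config()].
#' @param verbose print stage progress.
#' @return list with `table` (the split-assigned `spectrum_table`),
#'   `effective` (selected wavelengths), `results` (confusion matrices by
#'   feature set and model), `accuracy` (data.frame of all 18 cells),
#'   `models`, `manifest`.
#' @export
run_experiment <- function(cfg = run_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- cfg$seed

  say("stage 1/6: simulating scenes")
  scene_cfg <- do.call(scene_config, c(
    list(n_fruits_per_class = max(cfg$n_fruits_per_class),
         seed = derive_seed(seed, 1L)), cfg$scene))
  scene_cfg$n_fruits_per_class <- max(cfg$n_fruits_per_class) # unused by plan
  ds_cfg <- scene_cfg
  ds_cfg$n_fruits_per_class <- cfg$n_fruits_per_class
  dataset <- generate_dataset(ds_cfg, seed = derive_seed(seed, 2L))

  say("stage 2/6: correction, segmentation, preprocessing")
  table <- dataset_to_table(dataset)

  say("stage 3/6: splitting samples")
  totals <- vapply(0:2, function(cl) sum(table$label == cl), integer(1))
  counts <- proportional_counts(totals)
  table$split <- split_samples(table$label, counts, seed = derive_seed(seed, 3L))

  say("stage 4/6: effective wavelength selection")
  cal <- table_split(table, "calibration")
  cm <- class_mean_spectra(cal)
  deriv <- second_derivative(cm)
  ew <- do.call(select_effective, c(list(deriv = deriv,
                                         wavelength = table$wavelength),
                                    cfg$selection))
  if (length(ew$index) < 11L) {
    # the Conv/Pool stack needs >= 11 inputs; relax candidate pruning so
    # the effective-wavelength models stay buildable
    sel2 <- cfg$selection
    sel2$spread_quantile <- 0
    ew <- do.call(select_effective, c(list(deriv = deriv,
                                           wavelength = table$wavelength),
                                      sel2))
  }
  feature_sets <- list(full_spectra = table,
                       effective_wavelengths = subset_table(table, ew))

  results <- list(); models <- list()
  for (fs in names(feature_sets)) {
    tb <- feature_sets[[fs]]
    tb_cal <- table_split(tb, "calibration")
    tb_val <- table_split(tb, "validation")

    say("stage 5/6: PLS-DA (%s)", fs)
    sel <- plsda_select_lv(tb_cal, max_lv = cfg$max_lv)
    pls <- plsda_fit(tb_cal, n_lv = sel$n_lv)
    models[[fs]]$plsda <- pls
    results[[fs]]$plsda <- evaluate_splits(
      function(t) plsda_predict(pls, t), tb)

    say("stage 5/6: SVM grid search (%s)", fs)
    gs <- do.call(svm_grid_search, c(
      list(x = tb_cal, seed = derive_seed(seed, 4L)), cfg$svm_grid))
    svm <- svm_fit(tb_cal, C = gs$C, gamma = gs$gamma)
    models[[fs]]$svm <- svm
    models[[fs]]$svm_search <- gs[c("C", "gamma", "cv_accuracy")]
    results[[fs]]$svm <- evaluate_splits(
      function(t) svm_predict(svm, t), tb)

    say("stage 5/6: CNN (%s)", fs)
    cnn_args <- c(list(seed = derive_seed(seed, 5L)), cfg$cnn)
    if (is.null(cnn_args$batch_size))
      cnn_args$batch_size <- max(8L, as.integer(round(0.25 * nrow(tb_cal$spectra))))
    if (is.null(cnn_args$epochs)) cnn_args$epochs <- 100L
    spec <- do.call(cnn_spec, cnn_args)
    net <- cnn_build(spec, ncol(tb_cal$spectra))
    net <- cnn_train(net, tb_cal, x_val = tb_val)
    models[[fs]]$cnn <- net
    results[[fs]]$cnn <- evaluate_splits(
      function(t) cnn_predict(net, t), tb)
  }

  say("stage 6/6: reporting")
  acc <- do.call(rbind, lapply(names(results), function(fs)
    do.call(rbind, lapply(names(results[[fs]]), function(mod)
      do.call(rbind, lapply(split_names(), function(sp) data.frame(
        feature_set = fs, model = mod, split = sp,
        accuracy = accuracy(results[[fs]][[mod]][[sp]]))))))))

  manifest <- list(
    seed = seed, n_fruits_per_class = cfg$n_fruits_per_class,
    scene = scene_cfg[setdiff(names(scene_cfg), "n_fruits_per_class")],
    selection = ew$params, n_effective = length(ew$index),
    svm = lapply(models, function(m) m$svm_search),
    plsda_n_lv = lapply(models, function(m) m$plsda$n_lv),
    cnn = list(epochs = cnn_args$epochs, batch_size = cnn_args$batch_size,
               learning_rate = 5e-4),
    package_version = as.character(utils::packageVersion("oleasterHSI")))

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    report(results, cfg$out)
    write_spectrum_table(table, file.path(cfg$out, "spectrum_table.csv"))
    write_effective_wavelengths(ew, file.path(cfg$out, "effective_wavelengths.json"))
    jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(table = table, effective = ew, results = results, accuracy = acc,
       models = models, manifest = manifest)
}
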