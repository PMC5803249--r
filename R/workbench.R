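#' Benchmark configuration
#'
#' Assembles the knobs of the end-to-end comparison: the synthetic surface
#' (dimension, coupling graph and strength), the dataset size, the torsion
#' scan resolution, and the ensemble training settings. The defaults define
#' the package's standard benchmark: a 5-dihedral surface with a branched
#' coupling graph at 2 kcal/mol coupling strength — emulating the strongly
#' correlated regime of branched aromatics, where an additive force field
#' must fail — with 20,000 random conformations split 72/13/15.
#'
#' @param n_d number of dihedrals.
#' @param n_samples dataset size.
#' @param coupling_strength kcal/mol; 0 gives the separable control regime.
#' @param amplitude_scale global multiplier on the surface's amplitudes. The
#'   default of 4 puts random-conformer energies on the tens-of-kcal/mol
#'   scale of semi-empirical conformer energies for branched aromatics, so
#'   the 46 kcal/mol low/high class boundary falls inside the energy
#'   distribution with both classes well populated.
#' @param coupling_pairs dihedral pairs to couple (`NULL` = branched default).
#' @param n_s scan samples per dihedral for the uncorrelated models.
#' @param seed master seed (dataset, splits, member initialization).
#' @param specs regressor architectures ([network_specs()]).
#' @param classifier train the classification ensemble too.
#' @param classifier_threshold low/high class boundary, kcal/mol.
#' @param control a [training_control()].
#' @param fractions a [split_fractions()].
#' @param encoding a [feature_encoding()].
#' @return a list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_d = 5L, n_samples = 20000L,
                             coupling_strength = 2, amplitude_scale = 4,
                             coupling_pairs = NULL,
                             n_s = 72L, seed = 1L,
                             specs = network_specs(),
                             classifier = TRUE,
                             classifier_threshold = 46,
                             control = training_control(),
                             fractions = split_fractions(),
                             encoding = feature_encoding()) {
  structure(list(n_d = as.integer(n_d), n_samples = as.integer(n_samples),
                 coupling_strength = coupling_strength,
                 amplitude_scale = amplitude_scale,
                 coupling_pairs = coupling_pairs, n_s = as.integer(n_s),
                 seed = as.integer(seed), specs = specs,
                 classifier = classifier,
                 classifier_threshold = classifier_threshold,
                 control = control, fractions = fractions,
                 encoding = encoding),
            class = "benchmark_config")
}

#' Read a benchmark configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [benchmark_config()] (scalar
#' fields plus `specs` as a list of hidden-size lists and `control` as a
#' mapping of [training_control()] arguments); missing keys keep defaults.
#'
#' @param path YAML file.
#' @return a `benchmark_config`.
#' @export
read_benchmark_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("n_d", "n_samples", "coupling_strength", "amplitude_scale",
                "n_s", "seed", "classifier", "classifier_threshold"))
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  if (!is.null(y$coupling_pairs))
    args$coupling_pairs <- lapply(y$coupling_pairs, as.integer)
  if (!is.null(y$specs)) args$specs <- lapply(y$specs, as.integer)
  if (!is.null(y$control)) args$control <- do.call(training_control, y$control)
  if (!is.null(y$fractions))
    args$fractions <- do.call(split_fractions, y$fractions)
  do.call(benchmark_config, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("benchmark stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full model-comparison benchmark
#'
#' End to end: generate a random-conformer dataset from a synthetic
#' correlated surface, scan-parameterize the uncorrelated force field in
#' both Fourier and tabulated modes, train the five-network energy ensemble
#' and (optionally) the classification ensemble, and evaluate every model on
#' the identical held-out test split.
#'
#' @param config a [benchmark_config()], or the path of a YAML file for
#'   [read_benchmark_config()].
#' @return an object of class `benchmark_report`: per-model [pes_metrics]
#'   (`metrics$ann`, `metrics$fourier`, `metrics$tabulated`), classifier
#'   results (confusion matrix, metrics, lattice check, low-energy
#'   coverage), the dataset descriptor, and the fitted objects themselves
#'   (`pes`, `ensemble`, `ff_fourier`, `ff_tabulated`, `classifier`).
#' @export
run_benchmark <- function(config = benchmark_config()) {
  if (is.character(config)) config <- read_benchmark_config(config)
  stopifnot(inherits(config, "benchmark_config"))

  pes <- .stage("make_pes",
                make_pes(config$n_d, config$coupling_pairs,
                         config$coupling_strength, seed = config$seed,
                         amplitude_scale = config$amplitude_scale))
  dataset <- .stage("generate_dataset",
                    generate_dataset(pes, config$n_samples,
                                     seed = config$seed + 1L))
  ensemble <- .stage("train_ensemble",
                     train_energy_ensemble(dataset, config$specs,
                                           config$encoding, config$fractions,
                                           config$control, config$seed))
  oracle <- pes_oracle(pes)
  ff_fourier <- .stage("scan_fourier",
                       scan_parameterize(oracle, config$n_d, config$n_s,
                                         "fourier"))
  ff_tabulated <- .stage("scan_tabulated",
                         scan_parameterize(oracle, config$n_d, config$n_s,
                                           "tabulated"))

  parts <- .dataset_parts(dataset)
  test <- ensemble$split$test
  ref <- parts$energy[test]
  a_test <- parts$angles[test, , drop = FALSE]
  metrics <- .stage("evaluate", list(
    ann = evaluate_predictions(predict_energy(ensemble, a_test), ref,
                               config$n_d),
    fourier = evaluate_predictions(eval_ff(ff_fourier, a_test), ref,
                                   config$n_d),
    tabulated = evaluate_predictions(eval_ff(ff_tabulated, a_test), ref,
                                     config$n_d)))

  classifier <- NULL
  classifier_report <- NULL
  if (isTRUE(config$classifier) &&
      any(parts$energy >= config$classifier_threshold) &&
      any(parts$energy < config$classifier_threshold)) {
    classifier <- .stage("train_classifier",
                         train_classifier_ensemble(
                           dataset, config$classifier_threshold,
                           encoding = config$encoding,
                           fractions = config$fractions,
                           control = config$control, seed = config$seed))
    cls <- classify(classifier, a_test)
    actual_low <- ref < config$classifier_threshold
    deep <- ref < config$classifier_threshold / 2
    classifier_report <- list(
      confusion = confusion_matrix(cls$is_low, actual_low),
      metrics = confusion_metrics(confusion_matrix(cls$is_low, actual_low)),
      probability_lattice = sort(unique(cls$probability)),
      low_coverage_below_half_threshold =
        if (any(deep)) mean(cls$is_low[deep]) else NA_real_,
      n_below_half_threshold = sum(deep))
  }

  structure(list(
    dataset_descriptor = list(
      n_d = config$n_d, n_samples = config$n_samples,
      coupling_strength = config$coupling_strength,
      amplitude_scale = config$amplitude_scale,
      coupling_pairs = pes$couplings$pairs,
      separable_regime = config$coupling_strength == 0 ||
        nrow(pes$couplings$pairs) == 0L,
      split_sizes = lengths(ensemble$split), seed = config$seed,
      n_s = config$n_s),
    metrics = metrics,
    classifier_report = classifier_report,
    config = config, pes = pes, ensemble = ensemble,
    ff_fourier = ff_fourier, ff_tabulated = ff_tabulated,
    classifier = classifier), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  d <- x$dataset_descriptor
  cat(sprintf("<benchmark_report> n_d = %d, n = %d, coupling %.3g kcal/mol (%s)\n",
              d$n_d, d$n_samples, d$coupling_strength,
              if (d$separable_regime) "separable regime" else "coupled regime"))
  cat(sprintf("  split train/val/test: %s\n",
              paste(d$split_sizes, collapse = " / ")))
  for (m in names(x$metrics)) {
    mm <- x$metrics[[m]]
    cat(sprintf("  %-10s MAE %.4f kcal/mol (%.2f meV) per dihedral, Pearson r %s\n",
                m, mm$mae_kcal, mm$mae_mev,
                ifelse(is.na(mm$pearson_r), "undefined",
                       sprintf("%.4f", mm$pearson_r))))
  }
  if (!is.null(x$classifier_report)) {
    met <- x$classifier_report$metrics
    cat(sprintf("  classifier: sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%, F1 %.1f%%\n",
                100 * met["sensitivity"], 100 * met["specificity"],
                100 * met["accuracy"], 100 * met["f1"]))
  }
  invisible(x)
}

#' Diagnostic plots for a benchmark report
#'
#' `plot_correlation` draws predicted-versus-reference energy scatter for
#' one model; `plot_energy_histogram` overlays the reference and predicted
#' energy distributions. Plots are optional artifacts; no metric depends on
#' them.
#'
#' @param report a [run_benchmark()] report.
#' @param model `"ann"`, `"fourier"` or `"tabulated"`.
#' @export
plot_correlation <- function(report, model = "ann") {
  stopifnot(model %in% names(report$metrics))
  parts <- .dataset_parts(.stage("regenerate dataset", generate_dataset(
    report$pes, report$config$n_samples, seed = report$config$seed + 1L)))
  test <- report$ensemble$split$test
  a <- parts$angles[test, , drop = FALSE]
  ref <- parts$energy[test]
  pred <- switch(model,
                 ann = predict_energy(report$ensemble, a),
                 fourier = eval_ff(report$ff_fourier, a),
                 tabulated = eval_ff(report$ff_tabulated, a))
  graphics::plot(ref, pred, pch = ".", col = "#00000040",
                 xlab = "reference energy (kcal/mol)",
                 ylab = sprintf("%s energy (kcal/mol)", model),
                 main = sprintf("%s vs reference (r = %.3f)", model,
                                report$metrics[[model]]$pearson_r))
  graphics::abline(0, 1, col = 2)
  invisible(report)
}

#' @rdname plot_correlation
#' @export
plot_energy_histogram <- function(report, model = "ann") {
  h <- report$metrics[[model]]$histogram
  mids <- h$breaks[-length(h$breaks)] + diff(h$breaks) / 2
  graphics::plot(mids, h$reference, type = "s", lwd = 2,
                 xlab = "energy (kcal/mol)", ylab = "count",
                 main = sprintf("energy distribution: reference vs %s", model))
  graphics::lines(mids, h$predicted, type = "s", col = 2, lwd = 2)
  graphics::legend("topright", c("reference", model), col = c(1, 2), lwd = 2)
  invisible(report)
}
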