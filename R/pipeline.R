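#' Pipeline configuration
#'
#' Assembles the full analysis configuration with defaults reproducing the
#' study's stated settings: 0-9 ppm binned at 0.001 ppm (9000 bins), water
#' exclusion 4.6-5.1 ppm, total-intensity normalization, unit-variance
#' scaling, one orthogonal component, 7-fold cross-validation, 200
#' permutations, VIP > 1 with alpha 0.05/0.01 thresholds, 5-feature
#' multivariate ROC over 100 splits, and the acetate/glycerol and
#' lactate/citrate ratio diagnostics. The configuration round-trips through
#' YAML losslessly ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param cohort A [cohort_config()], or a list with element `manifest`
#'   naming a spectra manifest to load instead of simulating.
#' @param preprocess List: `lo`, `hi`, `width`, `water` (length-2 window).
#' @param model List: `scaling`, `n_orth`, `cv_folds`, `n_perm`.
#' @param significance List: `alpha` (two levels), `window` half-width.
#' @param biomarker List: `n_features`, `n_splits`, `ratios` (list of
#'   `c(numerator, denominator)` pairs).
#' @param seed Integer master seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(
    cohort = cohort_config(),
    preprocess = list(lo = 0, hi = 9, width = 0.001, water = c(4.6, 5.1)),
    model = list(scaling = "uv", n_orth = 1, cv_folds = 7, n_perm = 200),
    significance = list(alpha = c(0.05, 0.01), window = 0.01),
    biomarker = list(n_features = 5, n_splits = 100,
                     ratios = list(c("Acetate", "Glycerol"),
                                   c("Lactate", "Citrate"))),
    seed = 1) {
  defaults <- list(
    preprocess = list(lo = 0, hi = 9, width = 0.001, water = c(4.6, 5.1)),
    model = list(scaling = "uv", n_orth = 1, cv_folds = 7, n_perm = 200),
    significance = list(alpha = c(0.05, 0.01), window = 0.01),
    biomarker = list(n_features = 5, n_splits = 100,
                     ratios = list(c("Acetate", "Glycerol"),
                                   c("Lactate", "Citrate")))
  )
  preprocess <- utils::modifyList(defaults$preprocess, preprocess)
  model <- utils::modifyList(defaults$model, model)
  significance <- utils::modifyList(defaults$significance, significance)
  biomarker <- utils::modifyList(defaults$biomarker, biomarker)
  if (preprocess$hi <= preprocess$lo || preprocess$width <= 0 ||
      length(preprocess$water) != 2) {
    abort("invalid preprocess settings", class = "nmrmet_config_error")
  }
  if (length(significance$alpha) != 2) {
    abort("significance$alpha needs two levels", class = "nmrmet_config_error")
  }
  structure(list(cohort = cohort, preprocess = preprocess, model = model,
                 significance = significance, biomarker = biomarker,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (inherits(x$cohort, "cohort_config")) {
    x$cohort <- c(unclass(x$cohort), list(.type = "cohort_config"))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  cohort <- x$cohort
  if (identical(cohort$.type, "cohort_config")) {
    cohort$.type <- NULL
    cohort <- do.call(cohort_config, cohort)
  }
  x$biomarker$ratios <- lapply(x$biomarker$ratios, unlist)
  pipeline_config(cohort = cohort, preprocess = x$preprocess,
                  model = x$model, significance = x$significance,
                  biomarker = x$biomarker, seed = x$seed)
}

stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "nmrmet_pipeline_error", parent = e)
  })
}

#' Run the full serum NMR analysis pipeline
#'
#' Executes simulate/load, lactate referencing, binning, water exclusion,
#' total-intensity normalization, the three pairwise OPLS-DA models (polyp
#' vs control, CRC vs control, CRC vs polyp) with permutation testing and
#' CV-ANOVA, an overview PCA, the differential-metabolite table, the
#' multivariate ROC analyses (polyp vs control and CRC vs control), and the
#' ratio-biomarker ROC curves for every configured ratio and comparison.
#' All randomness derives from `config$seed`; the same configuration and
#' seed reproduce every number exactly.
#'
#' @param config A [pipeline_config()].
#' @param reference Reference tibble (default the packaged table).
#' @param out_dir Optional directory; when given, model summaries, scores,
#'   the significance table, ROC tables and a run manifest are written as
#'   CSV/TSV/JSON.
#' @return An `nmr_pipeline` list: `spectra`, `binned`, `pca`, `models`,
#'   `validation`, `significance`, `mroc`, `ratio_roc`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         reference = metabolite_reference(),
                         out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort("config must come from pipeline_config()",
          class = "nmrmet_config_error")
  }
  spectra <- stage("cohort", {
    if (inherits(config$cohort, "cohort_config")) {
      cfg <- config$cohort
      cfg$seed <- cfg$seed %||% config$seed
      simulate_cohort(reference, cfg)
    } else if (!is.null(config$cohort$manifest)) {
      read_spectra(config$cohort$manifest)
    } else {
      abort("cohort must be a cohort_config or name a manifest",
            class = "nmrmet_config_error")
    }
  })
  binned <- stage("preprocess", {
    spectra |>
      reference_to_lactate() |>
      bin_spectra(lo = config$preprocess$lo, hi = config$preprocess$hi,
                  width = config$preprocess$width) |>
      exclude_water(config$preprocess$water[1], config$preprocess$water[2]) |>
      normalize_total()
  })
  pca <- stage("pca", fit_pca(binned, n_components = 3,
                              scaling = config$model$scaling))
  comparisons <- .comparisons
  models <- stage("fit", {
    setNames(lapply(comparisons, function(cmp) {
      gr <- split_comparison(cmp)
      sub <- filter_groups(binned, gr)
      fit_oplsda(sub, n_orth = config$model$n_orth,
                 scaling = config$model$scaling,
                 cv_folds = config$model$cv_folds, cv_seed = config$seed)
    }), comparisons)
  })
  validation <- stage("validate", {
    setNames(lapply(comparisons, function(cmp) {
      gr <- split_comparison(cmp)
      sub <- filter_groups(binned, gr)
      list(
        permutation = permutation_test(
          sub, n_perm = config$model$n_perm, seed = config$seed,
          n_orth = config$model$n_orth, k = config$model$cv_folds,
          scaling = config$model$scaling),
        cv_anova = cv_anova(
          sub, n_orth = config$model$n_orth, k = config$model$cv_folds,
          seed = config$seed, scaling = config$model$scaling)
      )
    }), comparisons)
  })
  quant <- stage("quantify",
                 quantify_metabolites(binned, reference,
                                      window = config$significance$window))
  sig <- stage("diff-table", {
    differential_table(quant, models, reference,
                       alpha = config$significance$alpha,
                       window = config$significance$window)
  })
  mroc <- stage("multivariate-roc", {
    setNames(lapply(c("polyp_vs_control", "crc_vs_control"), function(cmp) {
      gr <- split_comparison(cmp)
      multivariate_roc(quant[quant$group %in% gr, , drop = FALSE] |>
                         dplyr::mutate(group = droplevels(.data$group)),
                       n_features = config$biomarker$n_features,
                       n_splits = config$biomarker$n_splits,
                       seed = config$seed, positive = gr[1])
    }), c("polyp_vs_control", "crc_vs_control"))
  })
  ratio_roc <- stage("ratio-roc", {
    lapply(config$biomarker$ratios, function(rt) {
      feat <- ratio_feature(quant, rt[1], rt[2])
      rocs <- setNames(lapply(comparisons, function(cmp) {
        gr <- split_comparison(cmp)
        sub <- feat[feat$group %in% gr, , drop = FALSE]
        roc_curve(sub$ratio, droplevels(sub$group), positive = gr[1])
      }), comparisons)
      list(numerator = rt[1], denominator = rt[2], roc = rocs)
    })
  })
  manifest <- list(
    package = "nmrmet",
    version = as.character(utils::packageVersion("nmrmet")),
    seed = config$seed,
    n_samples = nrow(spectra$samples),
    n_bins = length(binned$excluded),
    n_masked = sum(binned$excluded),
    settings = list(preprocess = config$preprocess, model = config$model,
                    significance = config$significance,
                    biomarker = lapply(config$biomarker$ratios, paste,
                                       collapse = "/"))
  )
  res <- structure(
    list(spectra = spectra, binned = binned, pca = pca, models = models,
         validation = validation, quant = quant, significance = sig,
         mroc = mroc, ratio_roc = ratio_roc, manifest = manifest,
         config = config),
    class = "nmr_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.nmr_pipeline <- function(x, ...) {
  cat("<nmr_pipeline> ", x$manifest$n_samples, " samples, ",
      x$manifest$n_bins, " bins (", x$manifest$n_masked, " masked)\n",
      sep = "")
  for (cmp in names(x$models)) {
    g <- glance(x$models[[cmp]])
    cat("  ", cmp, ": R2X=", round(g$r2x, 3), " R2Y=", round(g$r2y, 3),
        " Q2=", round(g$q2, 3),
        " CV-ANOVA p=", signif(x$validation[[cmp]]$cv_anova$p, 3), "\n",
        sep = "")
  }
  cat("  differential metabolites reported: ",
      length(unique(x$significance$metabolite)), "\n", sep = "")
  invisible(x)
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  summaries <- dplyr::bind_rows(
    lapply(res$models, glance), .id = "comparison")
  utils::write.csv(summaries, file.path(out_dir, "model_summaries.csv"),
                   row.names = FALSE)
  for (cmp in names(res$models)) {
    utils::write.csv(tidy(res$models[[cmp]]),
                     file.path(out_dir, paste0("scores_", cmp, ".csv")),
                     row.names = FALSE)
    val <- res$validation[[cmp]]
    jsonlite::write_json(
      list(permutation = glance(val$permutation), cv_anova = val$cv_anova),
      file.path(out_dir, paste0("validation_", cmp, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  write_differential_table(res$significance,
                           file.path(out_dir, "differential_metabolites.tsv"),
                           alpha = res$config$significance$alpha)
  for (cmp in names(res$mroc)) {
    utils::write.csv(res$mroc[[cmp]]$ranking,
                     file.path(out_dir, paste0("mroc_ranking_", cmp, ".csv")),
                     row.names = FALSE)
  }
  ratio_rows <- purrr::map_dfr(res$ratio_roc, function(rt) {
    purrr::imap_dfr(rt$roc, function(rc, cmp) {
      dplyr::mutate(glance(rc),
                    ratio = paste0(rt$numerator, "/", rt$denominator),
                    comparison = cmp)
    })
  })
  utils::write.csv(ratio_rows, file.path(out_dir, "ratio_roc.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
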