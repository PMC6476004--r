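#' Critical correlation threshold for OPLS-DA loading significance
#'
#' Two-tailed critical value of the Pearson correlation coefficient at level
#' `alpha` with degrees of freedom `min(n1, n2) - 1` (the smaller group of
#' the pairwise comparison, minus one): `r_c = t_c / sqrt(t_c^2 + df)` where
#' `t_c` is the two-tailed Student-t critical value. For the study's group
#' sizes this gives 0.344 / 0.442 (38 vs 32, alpha 0.05 / 0.01) and
#' 0.316 / 0.408 (38 vs 40) after rounding to three decimals.
#'
#' @param n1,n2 Group sizes (the smaller must be >= 3).
#' @param alpha Significance level(s) in (0, 1).
#' @return Numeric threshold(s), unrounded (report to 3 decimals).
#' @examples
#' round(critical_r(38, 32, 0.05), 3) # 0.344
#' @export
critical_r <- function(n1, n2, alpha = 0.05) {
  df <- min(n1, n2) - 1
  if (df < 2) abort("min(n1, n2) must be >= 3", class = "nmrmet_domain_error")
  if (any(alpha <= 0 | alpha >= 1)) {
    abort("alpha must be in (0, 1)", class = "nmrmet_domain_error")
  }
  tc <- qt(1 - alpha / 2, df)
  tc / sqrt(tc^2 + df)
}

#' Classify variables by the VIP rule and correlation thresholds
#'
#' A variable is `very_significant` when `VIP > 1` and
#' `|r| > critical_r(alpha[2])`; `significant` when `VIP > 1` and
#' `critical_r(alpha[1]) < |r| <= critical_r(alpha[2])`; otherwise `NS`.
#' The VIP rule dominates: a variable with `VIP <= 1` is `NS` regardless of
#' `|r|`.
#'
#' @param vip Per-variable VIP scores.
#' @param r Per-variable correlation loadings, aligned with `vip`.
#' @param n1,n2 Group sizes of the comparison.
#' @param alpha Two significance levels, default `c(0.05, 0.01)`.
#' @return Factor with levels `very_significant`, `significant`, `NS`.
#' @export
classify_variables <- function(vip, r, n1, n2, alpha = c(0.05, 0.01)) {
  if (length(vip) != length(r)) {
    abort("vip and r must align to the same variables",
          class = "nmrmet_alignment_error")
  }
  thr <- critical_r(n1, n2, sort(alpha, decreasing = TRUE))
  cls <- dplyr::case_when(
    vip > 1 & abs(r) > thr[2] ~ "very_significant",
    vip > 1 & abs(r) > thr[1] ~ "significant",
    TRUE ~ "NS"
  )
  factor(cls, levels = c("very_significant", "significant", "NS"))
}

# bins covered by a metabolite's quantification windows (quantify-flagged
# peaks only, centre +/- window, masked bins dropped)
metabolite_bins <- function(binned, peaks, window) {
  pk <- peaks[peaks$quantify, , drop = FALSE]
  idx <- integer(0)
  for (cc in pk$center_ppm) {
    idx <- c(idx, which(binned$bin_centers >= cc - window &
                          binned$bin_centers < cc + window))
  }
  sort(unique(idx))
}

#' Relative metabolite concentrations from a normalized binned matrix
#'
#' The relative concentration of each metabolite is the sum of normalized
#' bin values over its signature windows (centre plus/minus `window` for each
#' quantification-flagged peak; peaks overlapping other metabolites' windows
#' are pre-flagged out in the packaged reference table). Requires a
#' normalized matrix.
#'
#' @param binned A normalized `nmr_binned` object.
#' @param reference Reference tibble from [metabolite_reference()].
#' @param window Window half-width in ppm (default 0.01).
#' @return A wide tibble: `sample_id`, `group`, one column per metabolite.
#' @export
quantify_metabolites <- function(binned, reference, window = 0.01) {
  if (!isTRUE(binned$provenance$normalized)) {
    abort("binned matrix must be normalized (see normalize_total())",
          class = "nmrmet_quantify_error")
  }
  act <- active_matrix(binned)
  if (all(act == 0)) {
    abort("all active bins are zero", class = "nmrmet_quantify_error")
  }
  out <- tibble::tibble(sample_id = binned$sample_id, group = binned$groups)
  for (i in seq_len(nrow(reference))) {
    idx <- metabolite_bins(binned, reference$peaks[[i]], window)
    idx <- idx[!binned$excluded[idx]]
    if (length(idx) == 0) {
      abort(paste0("metabolite '", reference$metabolite[i],
                   "': quantification windows fall entirely inside the ",
                   "excluded region"),
            class = "nmrmet_quantify_error")
    }
    out[[reference$metabolite[i]]] <-
      unname(rowSums(binned$values[, idx, drop = FALSE]))
  }
  out
}

star_code <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' Differential-metabolite table across pairwise OPLS-DA comparisons
#'
#' Aggregates bin-level model statistics to the metabolite level: within each
#' metabolite's quantification windows the bin with maximum `|r|` supplies
#' the reported correlation and its VIP; significance classes follow
#' [classify_variables()] with thresholds from the comparison's group sizes.
#' Fold changes are ratios of group mean relative concentrations expressed
#' `>= 1` with a direction flag, and a two-sided Mann-Whitney test provides
#' the univariate p-value with star coding (`*` p < 0.05, `**` p < 0.01).
#'
#' @param quant Metabolite table from [quantify_metabolites()].
#' @param models Named list of fitted OPLS-DA `nmr_latent` models, one per
#'   comparison, names like `"polyp_vs_control"`.
#' @param reference Reference tibble (supplies the windows).
#' @param alpha Two significance levels for the thresholds.
#' @param window Window half-width (ppm), matching the quantification.
#' @param all Keep all metabolite-comparison rows (default `FALSE`: only
#'   metabolites significant in at least one comparison are reported).
#' @return A tibble: `metabolite`, `comparison`, `vip`, `r`, `class`,
#'   `fold_change`, `direction`, `p`, `stars`, `n1`, `n2`.
#' @export
differential_table <- function(quant, models, reference,
                               alpha = c(0.05, 0.01), window = 0.01,
                               all = FALSE) {
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    abort("models must be a named list keyed by comparison",
          class = "nmrmet_config_error")
  }
  rows <- purrr::imap(models, function(model, comparison) {
    if (!inherits(model, "nmr_latent") || model$kind != "oplsda") {
      abort(paste0("comparison '", comparison,
                   "': a fitted OPLS-DA model is required"),
            class = "nmrmet_config_error")
    }
    if (is.null(model$variable_ppm)) {
      abort(paste0("comparison '", comparison,
                   "': model lacks bin ppm positions (fit from nmr_binned)"),
            class = "nmrmet_config_error")
    }
    gr <- split_comparison(comparison)
    sizes <- table(model$group)
    n1 <- unname(sizes[gr[1]])
    n2 <- unname(sizes[gr[2]])
    vv <- vip(model)
    rr <- correlation_loadings(model)
    qa <- quant[quant$group == gr[1], , drop = FALSE]
    qb <- quant[quant$group == gr[2], , drop = FALSE]
    purrr::map_dfr(seq_len(nrow(reference)), function(i) {
      met <- reference$metabolite[i]
      pk <- reference$peaks[[i]][reference$peaks[[i]]$quantify, ]
      in_win <- rep(FALSE, length(model$variable_ppm))
      for (cc in pk$center_ppm) {
        in_win <- in_win | (model$variable_ppm >= cc - window &
                              model$variable_ppm < cc + window)
      }
      if (!any(in_win)) {
        abort(paste0("metabolite '", met, "' has no bins in model variables"),
              class = "nmrmet_config_error")
      }
      j <- which(in_win)[which.max(abs(rr$r[in_win]))]
      ma <- mean(qa[[met]])
      mb <- mean(qb[[met]])
      pval <- suppressWarnings(
        wilcox.test(qa[[met]], qb[[met]], exact = FALSE)$p.value)
      tibble::tibble(
        metabolite = met,
        comparison = comparison,
        vip = vv$vip[j],
        r = rr$r[j],
        class = classify_variables(vv$vip[j], rr$r[j], n1, n2, alpha),
        fold_change = max(ma / mb, mb / ma),
        direction = dplyr::case_when(ma > mb ~ "up", ma < mb ~ "down",
                                     TRUE ~ "none"),
        p = pval,
        stars = star_code(pval),
        n1 = n1, n2 = n2
      )
    })
  })
  tab <- dplyr::bind_rows(rows)
  if (!all) {
    keep <- tab |>
      dplyr::filter(.data$class != "NS") |>
      dplyr::distinct(.data$metabolite)
    tab <- dplyr::semi_join(tab, keep, by = "metabolite")
  }
  tab
}

#' Write a differential-metabolite table as TSV with a threshold header
#'
#' @param tab Table from [differential_table()].
#' @param path Output path.
#' @param alpha The significance levels used (recorded in the header).
#' @return Invisibly, `path`.
#' @export
write_differential_table <- function(tab, path, alpha = c(0.05, 0.01)) {
  con <- file(path, "w")
  on.exit(close(con))
  pairs <- dplyr::distinct(tab, .data$comparison, .data$n1, .data$n2)
  for (i in seq_len(nrow(pairs))) {
    thr <- critical_r(pairs$n1[i], pairs$n2[i], sort(alpha, decreasing = TRUE))
    writeLines(sprintf(
      "# %s: n1=%d n2=%d df=%d r(%.2g)=%.3f r(%.2g)=%.3f",
      pairs$comparison[i], pairs$n1[i], pairs$n2[i],
      min(pairs$n1[i], pairs$n2[i]) - 1,
      sort(alpha, decreasing = TRUE)[1], thr[1],
      sort(alpha, decreasing = TRUE)[2], thr[2]), con)
  }
  write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
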