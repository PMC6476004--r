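# Fixture builders shared across the suite. Everything is generated in code;
# no stored data beyond the packaged reference table.

# construct an nmr_spectra directly (toy spectra with known shapes)
make_spectra <- function(ppm, intensity, groups = NULL, ids = NULL) {
  n <- nrow(intensity)
  nmrmet:::new_nmr_spectra(
    ppm, intensity,
    tibble::tibble(
      sample_id = ids %||% paste0("s", seq_len(n)),
      group = factor(groups %||% rep("control", n))
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_axis <- function() seq(-0.05, 9.05, by = 5e-4)

# one-metabolite reference table (defaults to the lactate doublet/quartet)
mini_ref <- function(name = "Lactate",
                     peaks = tibble::tibble(
                       center_ppm = c(1.33, 4.12),
                       multiplicity = c("d", "q"),
                       weight = c(0.6, 0.4),
                       quantify = c(TRUE, FALSE)),
                     base_conc = 1, direction = "none", fold = 1) {
  tibble::tibble(
    metabolite = name,
    peaks = list(peaks),
    base_conc = base_conc,
    effects = list(tibble::tibble(
      comparison = c("polyp_vs_control", "crc_vs_control", "crc_vs_polyp"),
      direction = direction, fold = fold))
  )
}

# strip all group effects from a reference table
null_effects <- function(ref) {
  ref$effects <- lapply(ref$effects, function(e) {
    e$direction <- "none"
    e$fold <- 1
    e
  })
  ref
}

# plant a single metabolite's effect, everything else null
plant_effect <- function(ref, metabolite, direction, fold,
                         comparisons = c("polyp_vs_control",
                                         "crc_vs_control")) {
  ref <- null_effects(ref)
  i <- which(ref$metabolite == metabolite)
  e <- ref$effects[[i]]
  sel <- e$comparison %in% comparisons
  e$direction[sel] <- direction
  e$fold[sel] <- fold
  ref$effects[[i]] <- e
  ref
}

# two-class binned matrix built directly from a value matrix
toy_binned <- function(values, lo = 0, width = 0.001, groups = NULL,
                       normalized = FALSE) {
  n_bins <- ncol(values)
  centers <- lo + width * (seq_len(n_bins) - 0.5)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  }
  colnames(values) <- sprintf("%.4f", centers)
  nmrmet:::new_nmr_binned(
    values = values, bin_centers = centers,
    bin_edges = lo + width * (0:n_bins),
    groups = factor(groups %||% rep("control", nrow(values))),
    sample_id = rownames(values),
    excluded = rep(FALSE, n_bins),
    provenance = list(lo = lo, hi = lo + width * n_bins, width = width,
                      referenced = NULL, water_excluded = NULL,
                      normalized = normalized)
  )
}

# restrict an nmr_binned to a subset of groups
sub_binned <- function(b, gr) filter_groups(b, gr)

# exhaustive concordant-pair AUC (Mann-Whitney oracle, ties count 1/2)
pair_count_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}
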