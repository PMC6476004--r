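#' Load the serum metabolite reference table
#'
#' Reads the packaged 23-metabolite serum reference table (or a user-supplied
#' file in the same format). Each metabolite carries its \eqn{^1}H multiplet
#' assignments (chemical shift in ppm, multiplicity code, relative weight and
#' a flag marking peaks clean enough for window quantification), a relative
#' base concentration used by the cohort simulator, and per-comparison effect
#' records (direction and fold change) for the three pairwise group contrasts
#' (polyp vs control, CRC vs control, CRC vs polyp).
#'
#' Two shifts in the source assignments are transcribed as 0.92 ppm
#' (isoleucine CH3 triplet) and 0.98 ppm (valine CH3 doublet), the canonical
#' serum positions for these methyl resonances.
#'
#' @param path Path to a tab-separated reference table. `NULL` (default)
#'   loads the packaged table. Columns: `metabolite`, `peaks` (semicolon
#'   separated `center:multiplicity:weight[:quantify]` tokens), `base_conc`,
#'   and one `direction:fold` column per comparison.
#' @return A tibble with one row per metabolite: `metabolite`, `peaks`
#'   (list-column of tibbles with `center_ppm`, `multiplicity`, `weight`,
#'   `quantify`), `base_conc`, and `effects` (list-column of tibbles with
#'   `comparison`, `direction`, `fold`).
#' @examples
#' ref <- metabolite_reference()
#' nrow(ref) # 23
#' ref$peaks[[which(ref$metabolite == "Lactate")]]
#' @export
metabolite_reference <- function(path = NULL) {
  path <- path %||% system.file("extdata", "metabolite_reference.tsv",
                                package = "nmrmet", mustWork = TRUE)
  raw <- tryCatch(
    read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) abort(paste0("cannot read reference table: ",
                                     conditionMessage(e)),
                              class = "nmrmet_parse_error")
  )
  needed <- c("metabolite", "peaks", "base_conc", .comparisons)
  if (nrow(raw) == 0 || !all(needed %in% names(raw))) {
    abort("reference table is empty or lacks required columns",
          class = "nmrmet_parse_error")
  }
  peaks <- purrr::map2(raw$peaks, raw$metabolite, parse_peaks)
  effects <- purrr::pmap(
    c(raw[.comparisons], list(metabolite = raw$metabolite)),
    function(..., metabolite) {
      recs <- purrr::map2(list(...), .comparisons, parse_effect,
                          metabolite = metabolite)
      dplyr::bind_rows(recs)
    }
  )
  ref <- tibble::tibble(
    metabolite = raw$metabolite,
    peaks = peaks,
    base_conc = as.numeric(raw$base_conc),
    effects = effects
  )
  if (anyNA(ref$base_conc) || any(ref$base_conc <= 0)) {
    abort("base_conc must be positive for every metabolite",
          class = "nmrmet_parse_error")
  }
  if (anyDuplicated(ref$metabolite)) {
    abort("duplicate metabolite names in reference table",
          class = "nmrmet_parse_error")
  }
  ref
}

.multiplicities <- c("s", "d", "t", "q", "m", "bra")

parse_peaks <- function(txt, metabolite) {
  tokens <- strsplit(trimws(txt), ";", fixed = TRUE)[[1]]
  if (length(tokens) == 0 || !nzchar(txt)) {
    abort(paste0("metabolite '", metabolite, "': no peaks listed"),
          class = "nmrmet_parse_error")
  }
  rows <- purrr::map(tokens, function(tok) {
    f <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (length(f) < 3 || !nzchar(f[1]) || is.na(suppressWarnings(as.numeric(f[1])))) {
      abort(paste0("metabolite '", metabolite, "': malformed peak token '",
                   tok, "' (expect center:multiplicity:weight[:quantify])"),
            class = "nmrmet_parse_error")
    }
    if (!f[2] %in% .multiplicities) {
      abort(paste0("metabolite '", metabolite, "': unknown multiplicity code '",
                   f[2], "'"), class = "nmrmet_parse_error")
    }
    tibble::tibble(
      center_ppm = as.numeric(f[1]),
      multiplicity = f[2],
      weight = as.numeric(f[3]),
      quantify = if (length(f) >= 4) f[4] == "1" else TRUE
    )
  })
  pk <- dplyr::bind_rows(rows)
  if (any(pk$center_ppm < 0 | pk$center_ppm > 9)) {
    abort(paste0("metabolite '", metabolite,
                 "': peak center outside 0-9 ppm"),
          class = "nmrmet_parse_error")
  }
  if (abs(sum(pk$weight) - 1) > 1e-6) {
    abort(paste0("metabolite '", metabolite,
                 "': peak weights must sum to 1"),
          class = "nmrmet_parse_error")
  }
  pk
}

parse_effect <- function(txt, comparison, metabolite) {
  f <- strsplit(trimws(txt), ":", fixed = TRUE)[[1]]
  fold <- suppressWarnings(as.numeric(f[2]))
  if (length(f) != 2 || !f[1] %in% c("up", "down", "none") ||
      is.na(fold) || fold <= 0) {
    abort(paste0("metabolite '", metabolite, "', comparison '", comparison,
                 "': malformed effect '", txt, "' (expect direction:fold)"),
          class = "nmrmet_parse_error")
  }
  tibble::tibble(comparison = comparison, direction = f[1], fold = fold)
}

#' Per-comparison effect records in long form
#'
#' @param reference A reference tibble from [metabolite_reference()].
#' @return A tibble with columns `metabolite`, `comparison`, `direction`,
#'   `fold`.
#' @export
reference_effects <- function(reference) {
  reference |>
    dplyr::select("metabolite", "effects") |>
    tidyr::unnest("effects")
}

#' Group-specific concentration multipliers implied by the reference table
#'
#' Control samples sit at the base concentration; polyp and CRC multipliers
#' are derived from the two vs-control effect records (fold for "up",
#' 1/fold for "down", 1 for "none"). The CRC-vs-polyp column is not used to
#' build group means; it is retained as the planted-direction reference for
#' that comparison.
#'
#' @inheritParams reference_effects
#' @return A tibble `metabolite`, `control`, `polyp`, `crc`.
#' @export
reference_multipliers <- function(reference) {
  eff <- reference_effects(reference) |>
    dplyr::filter(.data$comparison %in% c("polyp_vs_control", "crc_vs_control")) |>
    dplyr::mutate(
      mult = dplyr::case_when(
        .data$direction == "up" ~ .data$fold,
        .data$direction == "down" ~ 1 / .data$fold,
        TRUE ~ 1
      ),
      group = dplyr::if_else(.data$comparison == "polyp_vs_control",
                             "polyp", "crc")
    ) |>
    dplyr::select("metabolite", "group", "mult") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mult")
  tibble::tibble(
    metabolite = reference$metabolite,
    control = 1
  ) |>
    dplyr::left_join(eff, by = "metabolite")
}
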