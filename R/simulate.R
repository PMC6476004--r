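#' Cohort simulation settings
#'
#' Defaults reproduce the study design: 38 healthy controls, 32 colorectal
#' polyp patients and 40 CRC patients (110 serum spectra). Noise, jitter,
#' baseline and residual-water amplitudes are in the arbitrary intensity
#' units of the simulator (a metabolite of base concentration 1 contributes
#' unit integrated area across its multiplets).
#'
#' @param n_control,n_polyp,n_crc Group sizes (each at least 2).
#' @param noise_sd Standard deviation of additive Gaussian point noise.
#' @param jitter_sd Standard deviation (ppm) of the per-sample global
#'   chemical-shift miscalibration applied to every resonance.
#' @param baseline_amp Amplitude of the gently sloping per-sample baseline.
#' @param water_amp Integrated area of the residual-water hump centred at
#'   4.85 ppm.
#' @param conc_sdlog Log-normal sdlog of per-sample metabolite concentrations,
#'   so group fold changes act multiplicatively.
#' @param seed Integer seed fixing the cohort exactly; `NULL` leaves the RNG
#'   stream untouched.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_control = 38, n_polyp = 32, n_crc = 40,
                          noise_sd = 0.2, jitter_sd = 0.002,
                          baseline_amp = 0.5, water_amp = 5,
                          conc_sdlog = 0.15, seed = NULL) {
  counts <- c(n_control = n_control, n_polyp = n_polyp, n_crc = n_crc)
  if (any(!is.finite(counts)) || any(counts < 2) || any(counts != round(counts))) {
    abort("group counts must be integers >= 2", class = "nmrmet_config_error")
  }
  sds <- c(noise_sd = noise_sd, jitter_sd = jitter_sd,
           baseline_amp = baseline_amp, water_amp = water_amp,
           conc_sdlog = conc_sdlog)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    abort("noise/jitter/baseline/water/conc parameters must be >= 0",
          class = "nmrmet_config_error")
  }
  structure(
    list(n_control = as.integer(n_control), n_polyp = as.integer(n_polyp),
         n_crc = as.integer(n_crc), noise_sd = noise_sd,
         jitter_sd = jitter_sd, baseline_amp = baseline_amp,
         water_amp = water_amp, conc_sdlog = conc_sdlog, seed = seed),
    class = "cohort_config"
  )
}

# line-shape constants: sharp multiplet lines vs broad m/bra envelopes,
# fixed J-spacing with binomial intensity ratios
.fwhm_sharp <- 0.002
.fwhm_broad <- 0.02
.j_ppm <- 0.012
.line_truncation <- 0.3 # render each Lorentzian only within +/- this (ppm)

multiplet_lines <- function(multiplicity) {
  switch(multiplicity,
    s = list(offset = 0, frac = 1, fwhm = .fwhm_sharp),
    d = list(offset = c(-1, 1) * .j_ppm / 2, frac = c(1, 1) / 2,
             fwhm = .fwhm_sharp),
    t = list(offset = c(-1, 0, 1) * .j_ppm, frac = c(1, 2, 1) / 4,
             fwhm = .fwhm_sharp),
    q = list(offset = c(-1.5, -0.5, 0.5, 1.5) * .j_ppm,
             frac = c(1, 3, 3, 1) / 8, fwhm = .fwhm_sharp),
    m = ,
    bra = list(offset = 0, frac = 1, fwhm = .fwhm_broad),
    abort(paste0("unknown multiplicity '", multiplicity, "'"),
          class = "nmrmet_parse_error")
  )
}

# unit-area Lorentzian
lorentz <- function(x, center, hwhm) {
  (hwhm / pi) / ((x - center)^2 + hwhm^2)
}

#' Simulate a serum NMR cohort
#'
#' Renders one CPMG-style frequency-domain spectrum per sample on a uniform
#' ppm grid. Each metabolite contributes Lorentzian multiplets at its
#' reference shifts (doublets/triplets/quartets as 2/3/4 lines with binomial
#' ratios at a fixed 0.012 ppm spacing; `m`/`bra` as one broadened line).
#' Per-sample concentrations are drawn log-normally around the base
#' concentration times the group multiplier implied by the reference effect
#' records, so pairwise fold changes follow the planted directions. A broad
#' residual-water hump (4.6-5.1 ppm), a gently sloping baseline, a global
#' per-sample ppm jitter and additive Gaussian noise complete the spectrum;
#' intensities are clipped at zero.
#'
#' @param reference Reference tibble from [metabolite_reference()].
#' @param config A [cohort_config()].
#' @return An `nmr_spectra` object: `ppm` (shared axis), `intensity`
#'   (samples x points matrix) and `samples` (tibble `sample_id`, `group`).
#' @examples
#' ref <- metabolite_reference()
#' cohort <- simulate_cohort(ref, cohort_config(seed = 1))
#' nrow(cohort$samples) # 110
#' @export
simulate_cohort <- function(reference, config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    abort("config must be created by cohort_config()",
          class = "nmrmet_config_error")
  }
  with_seed_(config$seed, {
    ppm <- seq(-0.05, 9.05, by = 5e-4)
    groups <- rep(.groups, times = c(config$n_control, config$n_polyp,
                                     config$n_crc))
    n <- length(groups)
    sample_id <- sprintf("%s_%02d", groups,
                         unlist(lapply(c(config$n_control, config$n_polyp,
                                         config$n_crc), seq_len)))
    mult <- reference_multipliers(reference)
    mult_mat <- as.matrix(mult[, .groups])
    rownames(mult_mat) <- mult$metabolite

    # per-sample metabolite concentrations (log-normal around group mean)
    base <- setNames(reference$base_conc, reference$metabolite)
    conc <- sapply(reference$metabolite, function(m) {
      mu <- base[[m]] * mult_mat[m, groups]
      rlnorm(n, meanlog = log(mu), sdlog = config$conc_sdlog)
    }) # n x metabolites
    jitter <- rnorm(n, 0, config$jitter_sd)

    intensity <- matrix(0, nrow = n, ncol = length(ppm))
    for (i in seq_len(nrow(reference))) {
      pk <- reference$peaks[[i]]
      ci <- conc[, reference$metabolite[i]]
      for (j in seq_len(nrow(pk))) {
        lines <- multiplet_lines(pk$multiplicity[j])
        for (l in seq_along(lines$offset)) {
          centers <- pk$center_ppm[j] + lines$offset[l] + jitter
          area <- ci * pk$weight[j] * lines$frac[l]
          lo <- pk$center_ppm[j] + lines$offset[l] - .line_truncation
          hi <- pk$center_ppm[j] + lines$offset[l] + .line_truncation
          cols <- which(ppm >= lo & ppm <= hi)
          # points x samples profile, scaled per-sample by drawn area
          prof <- lorentz(matrix(ppm[cols], nrow = length(cols), ncol = n),
                          matrix(centers, nrow = length(cols), ncol = n,
                                 byrow = TRUE),
                          lines$fwhm[1] / 2)
          intensity[, cols] <- intensity[, cols] +
            t(prof * rep(area, each = length(cols)))
        }
      }
    }

    if (config$water_amp > 0) {
      wcols <- which(ppm >= 4.85 - 1 & ppm <= 4.85 + 1)
      wprof <- lorentz(matrix(ppm[wcols], nrow = length(wcols), ncol = n),
                       matrix(4.85 + jitter, nrow = length(wcols), ncol = n,
                              byrow = TRUE), 0.15 / 2)
      intensity[, wcols] <- intensity[, wcols] + t(wprof) * config$water_amp
    }
    if (config$baseline_amp > 0) {
      b0 <- runif(n, 0.5, 1)
      b1 <- runif(n, -0.3, 0.3)
      intensity <- intensity + config$baseline_amp *
        (b0 + outer(b1, ppm / 9))
    }
    if (config$noise_sd > 0) {
      intensity <- intensity + matrix(rnorm(n * length(ppm), 0, config$noise_sd),
                                      nrow = n)
    }
    intensity <- pmax(intensity, 0)
    new_nmr_spectra(ppm, intensity,
                    tibble::tibble(sample_id = sample_id,
                                   group = factor(groups, levels = .groups)))
  })
}

new_nmr_spectra <- function(ppm, intensity, samples) {
  stopifnot(ncol(intensity) == length(ppm), nrow(intensity) == nrow(samples))
  structure(list(ppm = ppm, intensity = intensity, samples = samples),
            class = "nmr_spectra")
}

#' @export
print.nmr_spectra <- function(x, ...) {
  cat("<nmr_spectra> ", nrow(x$samples), " spectra, ",
      length(x$ppm), " points over [",
      round(min(x$ppm), 3), ", ", round(max(x$ppm), 3), "] ppm\n", sep = "")
  print(dplyr::count(x$samples, .data$group))
  invisible(x)
}

#' Long-format view of a spectra set
#'
#' @param x An `nmr_spectra` object.
#' @param ... Unused.
#' @return Tibble `sample_id`, `group`, `ppm`, `intensity`.
#' @method tidy nmr_spectra
#' @export
tidy.nmr_spectra <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$samples$sample_id, each = length(x$ppm)),
    group = rep(x$samples$group, each = length(x$ppm)),
    ppm = rep(x$ppm, times = nrow(x$samples)),
    intensity = as.vector(t(x$intensity))
  )
}

#' Write a spectra set as per-sample two-column text plus a manifest
#'
#' @param x An `nmr_spectra` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path (`manifest.tsv`: `sample_id`,
#'   `group`, `file`).
#' @export
write_spectra <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, paste0(x$samples$sample_id, ".tsv"))
  for (i in seq_along(files)) {
    write.table(data.frame(ppm = x$ppm, intensity = x$intensity[i, ]),
                files[i], sep = "\t", row.names = FALSE, quote = FALSE)
  }
  manifest <- file.path(dir, "manifest.tsv")
  write.table(data.frame(sample_id = x$samples$sample_id,
                         group = as.character(x$samples$group),
                         file = basename(files)),
              manifest, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a spectra set written by [write_spectra()]
#'
#' All samples must share the same ppm axis.
#'
#' @param manifest Path to the cohort manifest TSV.
#' @return An `nmr_spectra` object.
#' @export
read_spectra <- function(manifest) {
  man <- read.delim(manifest, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group", "file") %in% names(man)) || nrow(man) == 0) {
    abort("manifest must have columns sample_id, group, file",
          class = "nmrmet_parse_error")
  }
  dir <- dirname(manifest)
  ppm <- NULL
  rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    d <- read.delim(file.path(dir, man$file[i]), sep = "\t")
    if (is.null(ppm)) {
      ppm <- d$ppm
    } else if (length(d$ppm) != length(ppm) || any(abs(d$ppm - ppm) > 1e-9)) {
      abort(paste0("sample '", man$sample_id[i],
                   "' has a mismatched ppm axis"),
            class = "nmrmet_parse_error")
    }
    rows[[i]] <- d$intensity
  }
  new_nmr_spectra(ppm, do.call(rbind, rows),
                  tibble::tibble(sample_id = man$sample_id,
                                 group = factor(man$group,
                                                levels = unique(man$group))))
}
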