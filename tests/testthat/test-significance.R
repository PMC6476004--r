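test_that("critical correlation thresholds match the published values", {
  expect_equal(round(critical_r(38, 32, 0.05), 3), 0.344)
  expect_equal(round(critical_r(38, 32, 0.01), 3), 0.442)
  expect_equal(round(critical_r(38, 40, 0.05), 3), 0.316)
  expect_equal(round(critical_r(38, 40, 0.01), 3), 0.408)
  # tabulated Pearson critical value at df = 30, alpha = 0.05
  expect_equal(round(critical_r(31, 40, 0.05), 3), 0.349)
})

test_that("critical_r is monotone and vanishes in the large-sample limit", {
  df_grid <- c(5, 10, 30, 100, 1000, 1e6)
  thr <- vapply(df_grid, function(d) critical_r(d + 1, d + 5, 0.05),
                numeric(1))
  expect_true(all(diff(thr) < 0))
  expect_lt(thr[length(thr)], 0.002)
  expect_gt(critical_r(38, 32, 0.01), critical_r(38, 32, 0.05))
  expect_error(critical_r(3, 2, 0.05), class = "nmrmet_domain_error")
  expect_error(critical_r(38, 32, 0), class = "nmrmet_domain_error")
})

test_that("variable classification combines the VIP rule with |r| thresholds", {
  expect_equal(as.character(classify_variables(2.0, 0.50, 38, 32)),
               "very_significant")
  expect_equal(as.character(classify_variables(0.9, 0.99, 38, 32)), "NS")
  expect_equal(as.character(classify_variables(1.5, 0.40, 38, 32)),
               "significant")
  expect_equal(as.character(classify_variables(1.5, -0.45, 38, 32)),
               "very_significant")
  expect_error(classify_variables(c(1, 2), 0.5, 38, 32),
               class = "nmrmet_alignment_error")
})

test_that("classification is a pure, permutation-invariant function", {
  set.seed(41)
  v <- runif(50, 0, 3)
  r <- runif(50, -1, 1)
  cls <- classify_variables(v, r, 38, 32)
  perm <- sample(50)
  expect_identical(classify_variables(v[perm], r[perm], 38, 32), cls[perm])
  expect_identical(classify_variables(v, r, 38, 32), cls)
})

test_that("quantification integrates signature windows of a single species", {
  ref <- metabolite_reference()
  sp <- simulate_cohort(mini_ref(), cohort_config(2, 2, 2, noise_sd = 0,
                                                  jitter_sd = 0,
                                                  baseline_amp = 0,
                                                  water_amp = 0,
                                                  conc_sdlog = 0, seed = 6))
  b <- sp |> bin_spectra() |> exclude_water() |> normalize_total()
  q <- quantify_metabolites(b, ref)
  # lactate value equals the total signal inside its quantification window
  sel <- b$bin_centers >= 1.32 & b$bin_centers < 1.34
  expect_equal(q$Lactate[1], sum(b$values[1, sel]), tolerance = 1e-12)
  expect_gt(q$Lactate[1], 0.5) # bulk of the rendered area (d peak weight 0.6)
  others <- unlist(q[1, setdiff(ref$metabolite, "Lactate")])
  expect_true(all(others < 0.01))
})

test_that("quantification guards normalization, masking and empty signals", {
  ref <- metabolite_reference()
  b_raw <- toy_binned(matrix(runif(30, 0.1, 1), nrow = 3))
  expect_error(quantify_metabolites(b_raw, ref),
               class = "nmrmet_quantify_error")
  # a metabolite whose only window sits inside the water mask
  wref <- mini_ref(name = "WaterBound",
                   peaks = tibble::tibble(center_ppm = 4.8,
                                          multiplicity = "s",
                                          weight = 1, quantify = TRUE))
  sp <- simulate_cohort(mini_ref(), cohort_config(2, 2, 2, seed = 7))
  b <- sp |> bin_spectra() |> exclude_water() |> normalize_total()
  expect_error(quantify_metabolites(b, wref), "WaterBound",
               class = "nmrmet_quantify_error")
})

test_that("the differential table reports folds >= 1 with coherent directions", {
  ref <- metabolite_reference()
  sp <- simulate_cohort(ref, cohort_config(10, 10, 10, seed = 9))
  b <- sp |> reference_to_lactate() |> bin_spectra(width = 0.01) |>
    exclude_water() |> normalize_total()
  q <- quantify_metabolites(b, ref)
  models <- list(
    polyp_vs_control = fit_oplsda(sub_binned(b, c("polyp", "control")),
                                  cv = FALSE),
    crc_vs_control = fit_oplsda(sub_binned(b, c("crc", "control")),
                                cv = FALSE),
    crc_vs_polyp = fit_oplsda(sub_binned(b, c("crc", "polyp")), cv = FALSE)
  )
  tab <- differential_table(q, models, ref, all = TRUE)
  expect_equal(nrow(tab), 3 * 23)
  expect_true(all(tab$fold_change >= 1))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$stars[tab$p < 0.01] == "**"))
  expect_true(all(tab$stars[tab$p >= 0.05] == ""))
  # direction agrees with the quantified group means
  for (k in sample(nrow(tab), 10)) {
    gr <- strsplit(tab$comparison[k], "_vs_")[[1]]
    ma <- mean(q[[tab$metabolite[k]]][q$group == gr[1]])
    mb <- mean(q[[tab$metabolite[k]]][q$group == gr[2]])
    expect_equal(tab$direction[k], if (ma > mb) "up" else "down")
  }
  # the union filter keeps only metabolites significant somewhere
  tab_u <- differential_table(q, models, ref)
  expect_true(all(tab_u$metabolite %in%
                    tab$metabolite[tab$class != "NS"]))
  expect_error(differential_table(q, list(fit = models[[1]]), ref),
               class = "nmrmet_config_error")
})

test_that("label-permuted cohorts yield almost no significant calls", {
  ref <- null_effects(metabolite_reference())
  ns_rate <- vapply(1:5, function(s) {
    sp <- simulate_cohort(ref, cohort_config(12, 12, 12, seed = 100 + s))
    b <- sp |> reference_to_lactate() |> bin_spectra(width = 0.01) |>
      exclude_water() |> normalize_total()
    q <- quantify_metabolites(b, ref)
    models <- list(
      polyp_vs_control = fit_oplsda(sub_binned(b, c("polyp", "control")),
                                    cv = FALSE),
      crc_vs_control = fit_oplsda(sub_binned(b, c("crc", "control")),
                                  cv = FALSE)
    )
    tab <- differential_table(q, models, ref, all = TRUE)
    mean(tab$class == "NS")
  }, numeric(1))
  expect_gte(mean(ns_rate), 0.9)
})

test_that("the significance table serializes with a threshold header", {
  tab <- tibble::tibble(
    metabolite = "Lactate", comparison = "polyp_vs_control", vip = 2,
    r = 0.5, class = factor("very_significant"), fold_change = 1.5,
    direction = "up", p = 0.001, stars = "**", n1 = 32, n2 = 38
  )
  path <- tempfile(fileext = ".tsv")
  write_differential_table(tab, path)
  lines <- readLines(path)
  expect_true(grepl("df=31", lines[1]))
  expect_true(grepl("0.344", lines[1]))
})
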