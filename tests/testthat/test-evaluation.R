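test_that("PPV/NPV outcomes partition transcripts and honour the contracts", {
  sim <- small_sim(n_samples = 30, n_genes = 25, seed = 5, expr_meanlog = log(0.08))
  tab <- compute_mrsd_table(sim$reference, sim$models)
  test_sample <- extract_sample(sim$reference, "S010")
  res <- evaluate_ppv_npv(
    tab, test_sample$counts, test_sample$depth_millions, sim$models
  )
  out <- res$outcomes
  expect_equal(nrow(out), nrow(tab))
  # unfeasible transcripts always predict insufficient
  expect_true(all(!out$predicted_sufficient[!is.finite(out$mrsd_millions)]))
  # PPV + false discovery proportion = 1 within the positive stratum
  if (any(out$predicted_sufficient)) {
    fdp <- mean(!out$achieved[out$predicted_sufficient])
    expect_equal(res$ppv + fdp, 1)
  }
  # empty test sample at zero depth: every prediction negative, PPV undefined
  res0 <- evaluate_ppv_npv(tab, jt("chr1", integer(), integer(),
    unique_reads = integer()
  ), 0, sim$models)
  expect_true(all(!res0$outcomes$predicted_sufficient))
  expect_true(is.na(res0$ppv))
  # a covered-anyway unfeasible transcript counts against NPV
  expect_equal(
    res0$npv, mean(!res0$outcomes$achieved)
  )
})

test_that("held-out calibration concentrates near m", {
  cfg <- generator_config(n_samples = 60, n_genes = 40, seed = 21)
  sim <- generate_reference_set(cfg)
  tab <- compute_mrsd_table(sim$reference, sim$models)
  held <- generate_reference_set(cfg, sample_seed = 999, n_samples = 150)$reference
  cal <- calibration_experiment(tab, held, sim$models)
  expect_gt(cal$coverage, 0.85)
  expect_lt(cal$coverage, 1)
  expect_equal(nrow(cal$per_transcript), sum(is.finite(tab$mrsd_millions)))
})

test_that("binomial thinning is exact in distribution and deterministic under seed", {
  x <- jt("chr1", 1:3 * 100L, 1:3 * 100L + 50L, unique_reads = c(1000L, 10L, 0L))
  expect_equal(downsample_gene(x, 0), x) # fraction 0 is the identity
  t1 <- downsample_gene(x, 0.5, seed = 7)
  t2 <- downsample_gene(x, 0.5, seed = 7)
  expect_identical(t1, t2)
  expect_equal(t1$unique_reads[3], 0L)

  # mean and variance match Binomial(n, 1 - f) over replicates
  set.seed(123)
  reps <- replicate(2000, downsample_gene(1000L, 0.3))
  expect_equal(mean(reps), 700, tolerance = 0.01)
  expect_equal(var(reps), 1000 * 0.7 * 0.3, tolerance = 0.1)
})

test_that("rank stability experiment tracks an injected event across thinning", {
  sim <- small_sim(n_samples = 25, n_genes = 15, seed = 13)
  case <- extract_sample(sim$reference, "S001")
  ref <- drop_samples(sim$reference, "S001")
  inj <- inject_aberrant_event(case, ref, sim$models, "G0004",
    target_nrc = 1, reads = 100, singleton = TRUE
  )
  res <- rank_stability_experiment(
    inj$case$counts, inj$reference, sim$models, inj$truth$key,
    fractions = c(0, 0.5, 0.95), seed = 4, min_reads = 2, min_nrc = 0
  )
  base <- res[res$fraction_removed == 0, ]
  expect_true(base$detected)
  expect_equal(base$read_count, 100L)
  half <- res[res$fraction_removed == 0.5, ]
  expect_true(half$detected)
  expect_true(abs(half$read_count - 50) < 30) # binomial spread
  # at 95% removal the event is usually lost or heavily depleted
  deep <- res[res$fraction_removed == 0.95, ]
  expect_true(!deep$detected || deep$read_count < 20)
})

test_that("bootstrap background is reproducible and summarises medians", {
  sim <- small_sim(n_samples = 45, n_genes = 12, seed = 17)
  case <- extract_sample(sim$reference, "S001")
  ref <- drop_samples(sim$reference, "S001")
  b1 <- bootstrap_background(case$counts, ref, sim$models,
    control_sizes = c(10, 30), n_bootstraps = 50, seed = 99
  )
  b2 <- bootstrap_background(case$counts, ref, sim$models,
    control_sizes = c(10, 30), n_bootstraps = 50, seed = 99
  )
  expect_identical(
    attr(b1, "replicates")$n_singletons, attr(b2, "replicates")$n_singletons
  )
  expect_identical(b1$median_singletons, b2$median_singletons)
  expect_equal(b1$n_bootstraps, c(50L, 50L))
  # a case identical to its whole control pool retains ~no events
  dup <- extract_sample(sim$reference, "S002")
  b3 <- bootstrap_background(dup$counts, sim$reference, sim$models,
    control_sizes = nrow(sim$reference$samples), n_bootstraps = 5, seed = 1
  )
  expect_equal(b3$median_singletons, 0)
})

test_that("TPM comparison recovers the inverse law and rejects tiny overlaps", {
  # deterministic limit: high-mean Poisson counts, so coverage tracks TPM
  sim <- generate_reference_set(generator_config(
    n_samples = 40, n_genes = 60, seed = 31, nb_size = Inf,
    expr_meanlog = log(20), expr_sdlog = 1
  ))
  tab <- compute_mrsd_table(sim$reference, sim$models)
  fit <- compare_tpm(tab, sim$tpm)
  expect_gt(fit$r_squared, 0.99)
  expect_equal(fit$slope, -1, tolerance = 0.05)
  expect_error(compare_tpm(tab, sim$tpm[1:2, ]), "fewer than 3")
  expect_error(
    compare_tpm(tab, tibble::tibble(gene_id = "nope", tpm = 1)),
    "fewer than 3"
  )
})

test_that("panel report counts low-MRSD proportions and flags joint-best tissues", {
  mk_tab <- function(classes) {
    structure(
      tibble::tibble(
        gene_id = paste0("G", seq_along(classes)),
        transcript_id = paste0("T", seq_along(classes)),
        mrsd_millions = ifelse(classes == "low_mrsd", 10, 500),
        class = classes
      ),
      class = c("mrsd_table", class(tibble::tibble()))
    )
  }
  tabs <- list(
    blood = mk_tab(c("high_mrsd", "high_mrsd", "high_mrsd", "low_mrsd")),
    lcl = mk_tab(c("low_mrsd", "low_mrsd", "high_mrsd", "low_mrsd")),
    fib = mk_tab(c("low_mrsd", "low_mrsd", "high_mrsd", "low_mrsd"))
  )
  panels <- tibble::tibble(
    panel_name = c("P1", "P1", "P1", "P2", "P2", "P3"),
    gene_id = c("G1", "G2", "G3", "G1", "G4", "G999"),
    rating = c("green", "green", "green", "green", "green", "green")
  )
  report <- NULL
  expect_warning(report <- panel_report(tabs, panels), "P3")
  p1 <- report[report$panel_name == "P1", ]
  expect_equal(p1$prop_low[p1$tissue == "blood"], 0)
  expect_equal(p1$prop_low[p1$tissue == "lcl"], 2 / 3)
  expect_equal(sort(p1$tissue[p1$is_best]), c("fib", "lcl")) # joint best
  p2 <- report[report$panel_name == "P2", ]
  expect_equal(p2$prop_low[p2$tissue == "blood"], 1 / 2)
  expect_equal(sort(p2$tissue[p2$is_best]), c("fib", "lcl"))
  # non-green rows are excluded
  panels2 <- panels
  panels2$rating[2] <- "amber"
  report2 <- NULL
  expect_warning(report2 <- panel_report(tabs, panels2), "P3")
  expect_equal(report2$n_genes[report2$panel_name == "P1"][1], 2L)
})

test_that("VUS feasibility filters by significance and inclusive score threshold", {
  tabs <- list(
    blood = structure(
      tibble::tibble(
        gene_id = paste0("G", 1:5), transcript_id = paste0("T", 1:5),
        mrsd_millions = c(10, 500, Inf, 20, 30),
        class = c("low_mrsd", "high_mrsd", "unfeasible", "low_mrsd", "low_mrsd")
      ),
      class = c("mrsd_table", class(tibble::tibble()))
    )
  )
  variants <- tibble::tibble(
    variant_id = paste0("v", 1:10),
    gene_id = c("G1", "G1", "G2", "G3", "G4", "G4", "G5", "G9", "G2", "G1"),
    clinical_significance = c(
      rep("Uncertain significance", 7), "Uncertain significance",
      "Conflicting interpretations of pathogenicity", "Pathogenic"
    ),
    spliceai_max = c(0.9, 0.5, 0.8, 0.7, 0.6, 0.49, 0.9, 0.8, 0.55, 0.95)
  )
  res <- vus_feasibility(variants, tabs)
  # retained: v1 v2 (G1), v3 (G2), v4 (G3), v5 (G4), v7 (G5), v8 (G9), v9 (G2)
  expect_equal(res$n_retained, 8)
  expect_true("v2" %in% res$variants$variant_id) # score 0.5 exactly retained
  expect_false("v6" %in% res$variants$variant_id) # 0.49 dropped
  expect_false("v10" %in% res$variants$variant_id) # pathogenic excluded
  expect_equal(
    res$variants$class_blood[res$variants$variant_id == "v8"], "unscored"
  )
  # low in >= 1 tissue: v1, v2 (G1), v5 (G4), v7 (G5) -> 4 of 8
  expect_equal(res$fraction_low_any, 0.5)
})
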