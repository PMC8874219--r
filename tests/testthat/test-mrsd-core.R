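test_that("critical_count matches its definition on worked examples", {
  expect_equal(critical_count(c(4, 0, 10, 2), 0.75), 2) # 3 of 4 counts >= 2
  expect_equal(critical_count(7, 0.5), 7)
  expect_equal(critical_count(c(0, 0, 0), 0.75), 0)
  expect_equal(order_counts(c(4, 0, 10, 2)), c(0, 2, 4, 10))
})

test_that("critical_count and aggregate_mrsd match brute force on random vectors", {
  set.seed(42)
  for (i in 1:400) {
    n <- sample(1:12, 1)
    counts <- sample(0:20, n, replace = TRUE)
    p <- runif(1, 0.05, 1)
    expect_equal(critical_count(counts, p), oracle_critical_count(counts, p))
    vals <- ifelse(runif(n) < 0.2, Inf, sample(1:50, n, replace = TRUE))
    m <- runif(1, 0.05, 1)
    expect_equal(aggregate_mrsd(vals, m), oracle_aggregate(vals, m))
  }
})

test_that("per-sample MRSD scales coverage to the target and flags zero R_p", {
  expect_equal(per_sample_mrsd(8, 4, 50), 100)
  expect_equal(per_sample_mrsd(8, 0, 50), Inf) # unfeasible
  expect_equal(per_sample_mrsd(8, 8, 30), 30) # self-consistency fixed point
  expect_equal(per_sample_mrsd(8, c(4, 0), c(50, 50)), c(100, Inf))
})

test_that("aggregate_mrsd picks the ceil(m*n)-th order statistic with Inf sentinel", {
  expect_equal(aggregate_mrsd(1:5, 0.95), 5)
  expect_equal(aggregate_mrsd(c(Inf, Inf), 0.95), Inf)
  expect_equal(aggregate_mrsd(c(10, 20, Inf), 0.5), 20)
})

test_that("feasibility classes split at the 100 M boundary", {
  expect_equal(classify_mrsd(99.99), "low_mrsd")
  expect_equal(classify_mrsd(100), "high_mrsd")
  expect_equal(classify_mrsd(Inf), "unfeasible")
  expect_equal(classify_mrsd(c(5, 250), threshold = 200), c("low_mrsd", "high_mrsd"))
})

test_that("parameter ranges are validated", {
  expect_error(mrsd_params(r = 0), "r must")
  expect_error(mrsd_params(p = 1.2), "p must")
  expect_error(mrsd_params(m = 0), "m must")
})

test_that("a sample meeting the target at its own depth gets MRSD <= its depth", {
  ref <- tiny_reference(
    counts_list = list(c(10, 9, 8, 20, 15)), # all junctions >= r = 8
    depths = 40
  )
  tab <- compute_mrsd_table(ref, tiny_models(), mrsd_params(r = 8, p = 0.75, m = 0.95))
  expect_true(all(tab$mrsd_millions <= 40))
})

test_that("MRSD is linear in r and monotone in p and m", {
  sim <- small_sim()
  t8 <- compute_mrsd_table(sim$reference, sim$models, mrsd_params(r = 8))
  t16 <- compute_mrsd_table(sim$reference, sim$models, mrsd_params(r = 16))
  fin <- is.finite(t8$mrsd_millions)
  expect_equal(t16$mrsd_millions[fin], 2 * t8$mrsd_millions[fin])

  t99 <- compute_mrsd_table(sim$reference, sim$models, mrsd_params(m = 0.99))
  both <- is.finite(t8$mrsd_millions) & is.finite(t99$mrsd_millions)
  expect_true(all(t99$mrsd_millions[both] >= t8$mrsd_millions[both]))

  tp <- compute_mrsd_table(sim$reference, sim$models, mrsd_params(p = 0.95))
  both <- is.finite(t8$mrsd_millions) & is.finite(tp$mrsd_millions)
  expect_true(all(tp$mrsd_millions[both] >= t8$mrsd_millions[both]))
})

test_that("results are independent of sample order", {
  sim <- small_sim(n_samples = 15, n_genes = 10)
  ref <- sim$reference
  perm <- rev(seq_len(nrow(ref$samples)))
  ref_perm <- ref
  ref_perm$counts <- ref$counts[perm, , drop = FALSE]
  ref_perm$samples <- ref$samples[perm, , drop = FALSE]
  t1 <- compute_mrsd_table(ref, sim$models)
  t2 <- compute_mrsd_table(ref_perm, sim$models)
  expect_equal(t1$mrsd_millions, t2$mrsd_millions)
})

test_that("feasibility is determined by the count of zero-R_p samples", {
  sim <- small_sim(n_samples = 25, n_genes = 30, expr_meanlog = log(0.03))
  params <- mrsd_params()
  tab <- compute_mrsd_table(sim$reference, sim$models, params, keep_per_sample = TRUE)
  need <- ceiling(params$m * nrow(sim$reference$samples))
  for (k in seq_len(nrow(tab))) {
    n_pos <- sum(tab$per_sample[[k]]$R_p > 0)
    expect_equal(is.finite(tab$mrsd_millions[k]), n_pos >= need)
  }
  expect_gt(sum(!is.finite(tab$mrsd_millions)), 0) # fixture exercises both arms
  expect_gt(sum(is.finite(tab$mrsd_millions)), 0)
})

test_that("a zero-junction model yields an error record, not a global failure", {
  ref <- tiny_reference()
  models <- dplyr::bind_rows(
    tiny_models(),
    tibble::tibble(
      gene_id = "G0", transcript_id = "G0.1", tier = "MANE", n_junctions = 0L,
      junctions = list(jt("chr9", integer(), integer()))
    )
  )
  tab <- compute_mrsd_table(ref, models)
  expect_equal(tab$class[tab$gene_id == "G0"], "error")
  expect_true(all(tab$class[tab$gene_id != "G0"] != "error"))
})

test_that("MRSD tables round-trip through TSV with 'unfeasible' literals", {
  sim <- small_sim(n_samples = 20, n_genes = 15, expr_meanlog = log(0.04))
  tab <- compute_mrsd_table(sim$reference, sim$models)
  path <- tempfile(fileext = ".tsv")
  write_mrsd_table(tab, path)
  raw <- readLines(path)
  expect_true(any(grepl("\tunfeasible\t", raw)))
  expect_false(any(grepl("\tInf\t", raw)))
  back <- read_mrsd_table(path)
  expect_equal(back$mrsd_millions, tab$mrsd_millions, tolerance = 1e-8)
  expect_equal(back$class, tab$class)
})
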