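# Events are evaluated against the tiny two-gene fixture; gene GA has model
# junctions (1001-1500), (2001-2500), (3001-3500) on chr1:+.

ga_model <- function() tiny_models()[1, ]

test_that("NRC is the ratio to the highest adjoining canonical junction", {
  sample_counts <- dplyr::bind_rows(
    jt("chr1", c(1001, 2001, 3001), c(1500, 2500, 3500), unique_reads = c(40, 25, 5)),
    jt("chr1", 1001, 2500, unique_reads = 10) # exon-skip sharing both sites
  )
  ev <- jt("chr1", 1001, 2500)
  expect_equal(compute_nrc(ev, sample_counts, ga_model()), 0.25) # 10 / max(40, 25)

  # event reads equal to the adjoining max give NRC 1; NRC > 1 is legal
  sample_counts$unique_reads[4] <- 40L
  expect_equal(compute_nrc(ev, sample_counts, ga_model()), 1)
  sample_counts$unique_reads[4] <- 90L
  expect_equal(compute_nrc(ev, sample_counts, ga_model()), 2.25)
})

test_that("NRC falls back to flanking junctions, then the gene-wide maximum", {
  # novel junction in the intron between model junctions 2 and 3 shares no
  # splice site: its flanks are (2001-2500) and (3001-3500), not the
  # gene-wide maximum at (1001-1500)
  sample_counts <- dplyr::bind_rows(
    jt("chr1", c(1001, 2001, 3001), c(1500, 2500, 3500), unique_reads = c(80, 12, 6)),
    jt("chr1", 2600, 2900, unique_reads = 3)
  )
  ev <- jt("chr1", 2600, 2900)
  expect_equal(compute_nrc(ev, sample_counts, ga_model()), 3 / 12) # flanking max, not 80

  # zero-read flanks fall back to the gene-wide canonical maximum
  sample_counts$unique_reads <- c(80L, 0L, 0L, 3L)
  expect_equal(compute_nrc(ev, sample_counts, ga_model()), 3 / 80)

  # no canonical junction with reads anywhere in the gene: NRC undefined
  sample_counts$unique_reads <- c(0L, 0L, 0L, 3L)
  expect_true(is.na(compute_nrc(ev, sample_counts, ga_model())))
})

test_that("fold change compares against the best control, singletons are NA", {
  expect_equal(compute_fold_change(0.5, c(0.1, 0.05)), 5)
  expect_true(is.na(compute_fold_change(0.5, numeric())))
  expect_equal(compute_fold_change(0.5, 0.5), 1)
  # control NRC of exactly 0 treated as junction absent in that control
  expect_true(is.na(compute_fold_change(0.5, 0)))
})

test_that("the uniqueness/NRC-dominance filter applies a strict inequality", {
  ev <- tibble::tibble(
    key = c("a", "b", "c", "d"),
    read_count = c(1L, 5L, 5L, 5L),
    nrc = c(0.1, 0.3, 0.25, NA),
    control_max_nrc = c(NA, 0.25, 0.25, 0.2),
    singleton = c(TRUE, FALSE, FALSE, FALSE),
    n_samples = c(1L, 3L, 3L, 3L),
    nrc_fold_change = c(NA, 1.2, 1.0, NA)
  )
  kept <- filter_events(ev)
  expect_equal(kept$key, c("a", "b")) # equal NRC dropped; undefined NRC dropped
})

test_that("read and NRC thresholds match the documented boundaries", {
  ev <- tibble::tibble(
    key = c("s1", "n1", "n2"),
    read_count = c(1L, 5L, 5L),
    nrc = c(0.9, 0.26, 0.25),
    control_max_nrc = c(NA, 0.1, 0.1),
    singleton = c(TRUE, FALSE, FALSE),
    n_samples = c(1L, 2L, 2L),
    nrc_fold_change = c(NA, 2.6, 2.5)
  )
  kept <- apply_thresholds(ev, min_reads = 2, min_nrc = 0.25)
  expect_equal(kept$key, "n1") # 1-read singleton dropped; NRC == 0.25 dropped (strict)

  # filtering is monotone in both thresholds
  for (mr in c(1, 2, 6)) {
    for (mn in c(0, 0.25, 0.5)) {
      sub <- apply_thresholds(ev, min_reads = mr, min_nrc = mn)
      tighter <- apply_thresholds(ev, min_reads = mr + 1, min_nrc = mn + 0.1)
      expect_true(all(tighter$key %in% sub$key))
    }
  }
})

test_that("ranking places singletons first and breaks ties as documented", {
  ev <- tibble::tibble(
    key = c("ns_fc400", "s_3reads", "s_10reads", "ns_fc8", "ns_fc5a", "ns_fc5b"),
    read_count = c(50L, 3L, 10L, 4L, 7L, 3L),
    nrc = c(2, 0.5, 0.5, 0.4, 0.4, 0.4),
    control_max_nrc = c(0.005, NA, NA, 0.05, 0.08, 0.08),
    singleton = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    n_samples = c(5L, 1L, 1L, 3L, 3L, 3L),
    nrc_fold_change = c(400, NA, NA, 8.2, 5, 5)
  )
  ranked <- rank_events(ev)
  expect_equal(
    ranked$key,
    c("s_10reads", "s_3reads", "ns_fc400", "ns_fc8", "ns_fc5a", "ns_fc5b")
  )
  expect_equal(ranked$rank, 1:6)
  # permutation invariance
  set.seed(9)
  ranked2 <- rank_events(ev[sample(nrow(ev)), ])
  expect_equal(ranked2$key, ranked$key)
})

test_that("score_events computes metrics per gene against each sample's own canon", {
  ref <- tiny_reference()
  case <- dplyr::bind_rows(
    jt("chr1", c(1001, 2001, 3001), c(1500, 2500, 3500), unique_reads = c(40, 30, 20)),
    jt("chr1", 1001, 2500, unique_reads = 10), # novel in case only
    jt("chr2", 501, 900, strand = "-", unique_reads = 50) # canonical junction of GB
  )
  ev <- score_events(case, ref, tiny_models(), case_id = "P1")
  novel <- ev[ev$key == junction_key("chr1", 1001, 2500, "+"), ]
  expect_equal(novel$read_count, 10L)
  expect_equal(novel$nrc, 0.25)
  expect_true(novel$singleton)
  expect_equal(novel$n_samples, 1L)
  expect_equal(novel$gene_id, "GA")
  # canonical GB junction is present in all 3 controls
  gb <- ev[ev$key == junction_key("chr2", 501, 900, "-"), ]
  expect_equal(gb$n_samples, 4L)
  expect_false(gb$singleton)
  # intergenic junctions are dropped
  stray <- jt("chr9", 5, 10, unique_reads = 3)
  ev2 <- score_events(dplyr::bind_rows(case, stray), ref, tiny_models())
  expect_false(junction_key("chr9", 5, 10, "+") %in% ev2$key)
})

test_that("injected events are recovered end to end with their target metrics", {
  sim <- small_sim(n_samples = 30, n_genes = 20, seed = 3)
  case <- extract_sample(sim$reference, "S001")
  ref <- drop_samples(sim$reference, "S001")

  inj1 <- inject_aberrant_event(case, ref, sim$models, "G0001",
    target_nrc = 0.25, reads = 10, singleton = TRUE
  )
  expect_equal(inj1$truth$attained_nrc, 0.25) # denominator 40 by arithmetic inversion
  inj2 <- inject_aberrant_event(inj1$case, inj1$reference, sim$models, "G0002",
    target_nrc = 0.8, reads = 8, singleton = FALSE, n_carriers = 2
  )
  ranked <- detect_events(inj2$case$counts, inj2$reference, sim$models,
    min_reads = 2, min_nrc = 0.19
  )
  r1 <- ranked[ranked$key == inj1$truth$key, ]
  r2 <- ranked[ranked$key == inj2$truth$key, ]
  expect_equal(nrow(r1), 1)
  expect_equal(nrow(r2), 1)
  expect_true(r1$singleton)
  expect_false(r2$singleton)
  expect_equal(r2$n_samples, 3L) # case + 2 carriers
  expect_equal(r1$nrc, inj1$truth$attained_nrc)
  expect_lt(r1$rank, r2$rank) # singleton outranks non-singleton
})

test_that("event TSVs render singleton fold changes as a literal", {
  ev <- tibble::tibble(
    chrom = "chr1", start = 1001L, end = 2500L, strand = "+",
    key = "chr1:1001-2500:+", sample_id = "P1", gene_id = "GA",
    read_count = 10L, nrc = 0.25, control_max_nrc = NA_real_,
    n_samples = 1L, singleton = TRUE, nrc_fold_change = NA_real_, rank = 1L
  )
  path <- tempfile(fileext = ".tsv")
  write_events_tsv(ev, path)
  expect_true(any(grepl("\tsingleton", readLines(path))))
})
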