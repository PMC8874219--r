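# Synthetic reference cohorts with known ground truth. Junction counts are
# negative binomial,
#
#   count[g, j, s] ~ NegBin(mean = expr_g * d_s * bias_gj, size),
#
# where expr_g is the gene's junction coverage rate in reads per million
# (log-normal across genes), d_s the sample depth in millions of reads
# (gamma across samples), and bias_gj an optional monotone multiplicative
# ramp along the transcript emulating 3' coverage bias of poly-A selected
# libraries: the 3'-most junction is unbiased and the 5'-most is depressed
# by exp(-strength). size = Inf gives the Poisson limit. Identical config
# and seed give bit-identical output.

#' Configuration for the synthetic reference-set generator
#'
#' Defaults emulate a realistically sized control cohort: 150 samples (the
#' size of typical whole-blood/fibroblast reference cohorts), gamma depths
#' with mean 80 M uniquely mapping reads, log-normal per-gene junction
#' coverage rates spanning unfeasible to deeply covered genes, and moderate
#' negative-binomial overdispersion.
#'
#' @param n_samples Number of control samples.
#' @param n_genes Number of genes.
#' @param junctions_per_gene Integer range (length 2) of junctions per gene.
#' @param depth_mean,depth_sd Mean / sd of sample depth, millions of reads.
#' @param expr_meanlog,expr_sdlog Log-normal parameters of the per-gene
#'   junction coverage rate (reads per million per junction).
#' @param nb_size Negative-binomial size (dispersion = 1/size); `Inf` for
#'   the Poisson limit.
#' @param three_prime_bias Maximum 3'-bias ramp strength; each gene draws
#'   its strength uniformly from \[0, `three_prime_bias`\]. 0 disables bias.
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_samples = 150, n_genes = 200,
                             junctions_per_gene = c(4, 12),
                             depth_mean = 80, depth_sd = 20,
                             expr_meanlog = log(0.2), expr_sdlog = 1.5,
                             nb_size = 20, three_prime_bias = 0, seed = 1) {
  stopifnot(
    n_samples >= 1, n_genes >= 1, length(junctions_per_gene) == 2,
    junctions_per_gene[1] >= 1, junctions_per_gene[2] >= junctions_per_gene[1],
    depth_mean > 0, depth_sd > 0, nb_size > 0, three_prime_bias >= 0
  )
  structure(
    list(
      n_samples = n_samples, n_genes = n_genes,
      junctions_per_gene = as.integer(junctions_per_gene),
      depth_mean = depth_mean, depth_sd = depth_sd,
      expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
      nb_size = nb_size, three_prime_bias = three_prime_bias,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# Deterministic synthetic gene structure: gene g sits on chr((g-1) %% 22 + 1)
# at base offset 2e6 * g; exon k spans [base + 2000(k-1), base + 2000(k-1) + 499],
# so junction j = (base + 2000(j-1) + 500, base + 2000j - 1).
synthetic_gene_layout <- function(config) {
  withr::with_seed(config$seed, {
    n_j <- sample(
      seq(config$junctions_per_gene[1], config$junctions_per_gene[2]),
      config$n_genes,
      replace = TRUE
    )
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    bias_strength <- if (config$three_prime_bias > 0) {
      runif(config$n_genes, 0, config$three_prime_bias)
    } else {
      rep(0, config$n_genes)
    }
    expr <- rlnorm(config$n_genes, config$expr_meanlog, config$expr_sdlog)
    tibble::tibble(
      gene_id = sprintf("G%04d", seq_len(config$n_genes)),
      chrom = paste0("chr", (seq_len(config$n_genes) - 1L) %% 22L + 1L),
      base = 2e6 * seq_len(config$n_genes),
      strand = strand, n_junctions = n_j, bias_strength = bias_strength,
      expr_per_million = expr
    )
  })
}

gene_junctions <- function(layout_row) {
  j <- seq_len(layout_row$n_junctions)
  tibble::tibble(
    chrom = layout_row$chrom,
    start = as.integer(layout_row$base + 2000 * (j - 1) + 500),
    end = as.integer(layout_row$base + 2000 * j - 1),
    strand = layout_row$strand
  )
}

# 3' ramp over junction order j = 1..J (5' -> 3'): factor exp(-s (J-j)/(J-1)).
bias_ramp <- function(n, strength) {
  if (n == 1 || strength == 0) return(rep(1, n))
  exp(-strength * (n - seq_len(n)) / (n - 1))
}

rcount <- function(n, mu, size) {
  if (is.infinite(size)) rpois(n, mu) else rnbinom(n, mu = mu, size = size)
}

#' Generate a synthetic reference set with ground truth
#'
#' The gene-level model (gene structure, per-gene coverage rates, bias
#' strengths) is seeded by `config$seed`; sample-level noise (depths and
#' counts) by `sample_seed`. Two calls with the same config but different
#' `sample_seed` therefore yield independent cohorts from the same
#' generative model, e.g. a reference cohort and held-out samples.
#'
#' @param config A [generator_config()].
#' @param tissue_label Label for the cohort.
#' @param sample_seed Seed for depths and counts; defaults to
#'   `config$seed + 1`.
#' @param n_samples Number of samples to draw; defaults to
#'   `config$n_samples`.
#' @return List: `reference` (`mrsd_reference`), `truth` (per-gene tibble:
#'   coverage rate `expr_per_million`, `bias_strength`, `n_junctions`),
#'   `tpm` (tibble `gene_id`, `tpm`: relative expression proportional to
#'   the gene's mean junction coverage including bias, scaled to sum to
#'   1e6), `models` (transcript-model tibble for the synthetic genes, tier
#'   `"gencode_union"`), and `config`.
#' @export
generate_reference_set <- function(config, tissue_label = "synthetic",
                                   sample_seed = NULL, n_samples = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(sample_seed)) sample_seed <- config$seed + 1L
  if (is.null(n_samples)) n_samples <- config$n_samples
  layout <- synthetic_gene_layout(config)
  junctions <- purrr::map_dfr(seq_len(config$n_genes), function(g) {
    jt <- gene_junctions(layout[g, ])
    jt$gene_id <- layout$gene_id[g]
    jt$bias <- bias_ramp(nrow(jt), layout$bias_strength[g])
    jt$mu_per_million <- layout$expr_per_million[g] * jt$bias
    jt
  })
  out <- withr::with_seed(as.integer(sample_seed), {
    shape <- (config$depth_mean / config$depth_sd)^2
    depths <- rgamma(n_samples, shape = shape, rate = shape / config$depth_mean)
    mu <- outer(depths, junctions$mu_per_million) # samples x junctions
    counts <- matrix(
      rcount(length(mu), as.vector(mu), config$nb_size),
      nrow = n_samples
    )
    list(depths = depths, counts = counts)
  })
  samples <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    depth_millions = out$depths
  )
  juniv <- junctions[, c("chrom", "start", "end", "strand")]
  juniv$key <- junction_key(juniv$chrom, juniv$start, juniv$end, juniv$strand)
  dimnames(out$counts) <- list(samples$sample_id, juniv$key)
  # Reorder into canonical coordinate-sorted universe.
  ord <- order(juniv$chrom, juniv$start, juniv$end, juniv$strand)
  reference <- new_reference_set(
    out$counts[, ord, drop = FALSE], samples, juniv[ord, , drop = FALSE],
    tissue_label
  )
  truth <- layout[, c(
    "gene_id", "chrom", "strand", "n_junctions", "bias_strength",
    "expr_per_million"
  )]
  mean_cov <- tapply(junctions$mu_per_million, junctions$gene_id, mean)
  tpm_raw <- as.numeric(mean_cov[truth$gene_id])
  tpm <- tibble::tibble(
    gene_id = truth$gene_id,
    tpm = tpm_raw / sum(tpm_raw) * 1e6
  )
  models <- dplyr::bind_rows(lapply(seq_len(config$n_genes), function(g) {
    model_row(
      layout$gene_id[g], paste0(layout$gene_id[g], "|gencode_union"),
      "gencode_union", gene_junctions(layout[g, ])
    )
  }))
  list(
    reference = reference, truth = truth, tpm = tpm, models = models,
    config = config
  )
}

#' Inject a synthetic aberrant splice event into a case sample
#'
#' Adds a novel exon-skipping junction (donor of model junction `skip_from`,
#' acceptor of the next model junction) to the case with a chosen read count,
#' and pins the case's adjoining canonical maximum so the event's NRC equals
#' `target_nrc` as nearly as integer counts allow. For non-singleton events,
#' carrier controls receive the junction at a lower NRC computed against
#' their own canonical counts.
#'
#' @param case List with `counts` (junction tibble) and `depth_millions`,
#'   e.g. from [extract_sample()].
#' @param ref Control `mrsd_reference` (modified when `singleton = FALSE`).
#' @param models Transcript-model tibble containing `gene_id`.
#' @param gene_id Gene to disrupt.
#' @param target_nrc Desired NRC of the event (> 0).
#' @param reads Supporting read count of the event (>= 1).
#' @param singleton Should the junction be absent from all controls?
#' @param n_carriers Number of carrier controls for non-singleton events.
#' @param carrier_nrc_frac Carrier NRC as a fraction of the attained case
#'   NRC (must be < 1 so the case exceeds every control).
#' @param skip_from Index of the model junction whose donor the novel
#'   junction reuses.
#' @return List: `case` (modified), `reference` (modified), `truth`
#'   (one-row tibble: junction coordinates/key, `reads`, `target_nrc`,
#'   `attained_nrc`, `singleton`, `carriers`).
#' @export
inject_aberrant_event <- function(case, ref, models, gene_id, target_nrc,
                                  reads, singleton = TRUE, n_carriers = 3,
                                  carrier_nrc_frac = 0.5, skip_from = 1) {
  stopifnot(target_nrc > 0, reads >= 1, carrier_nrc_frac > 0, carrier_nrc_frac < 1)
  k <- match(gene_id, models$gene_id)
  if (is.na(k)) stop("gene not found: ", gene_id, call. = FALSE)
  jt <- models$junctions[[k]]
  if (nrow(jt) < 2) stop("need >= 2 model junctions to skip an exon", call. = FALSE)
  stopifnot(skip_from >= 1, skip_from < nrow(jt))
  j1 <- jt[skip_from, ]
  j2 <- jt[skip_from + 1, ]
  novel <- tibble::tibble(
    chrom = j1$chrom, start = j1$start, end = j2$end, strand = j1$strand
  )
  key <- junction_key(novel$chrom, novel$start, novel$end, novel$strand)
  mkeys <- junction_key(jt$chrom, jt$start, jt$end, jt$strand)
  if (key %in% mkeys) stop("novel junction collides with a model junction", call. = FALSE)

  # Denominator that makes NRC = reads / denom come closest to target.
  denom <- max(1L, as.integer(round(reads / target_nrc)))
  attained <- reads / denom

  cc <- case$counts
  ckey <- junction_key(cc$chrom, cc$start, cc$end, cc$strand)
  # Pin adjoining canonical counts: sharing junctions get <= denom, with the
  # max exactly denom (set on j1).
  adj <- adjoining_indices(novel, jt)
  for (a in adj) {
    i <- match(mkeys[a], ckey)
    val <- if (a == skip_from) denom else min(denom, if (is.na(i)) 0L else cc$unique_reads[i])
    if (is.na(i)) {
      if (val > 0) {
        cc <- dplyr::bind_rows(cc, dplyr::mutate(jt[a, ], unique_reads = as.integer(val)))
      }
    } else {
      cc$unique_reads[i] <- as.integer(val)
    }
    ckey <- junction_key(cc$chrom, cc$start, cc$end, cc$strand)
  }
  i <- match(key, ckey)
  if (is.na(i)) {
    cc <- dplyr::bind_rows(cc, dplyr::mutate(novel, unique_reads = as.integer(reads)))
  } else {
    cc$unique_reads[i] <- as.integer(reads)
  }
  case$counts <- cc

  carriers <- character()
  if (!singleton) {
    canon_ctrl <- junction_count_matrix(ref, mkeys)
    denom_ctrl <- nrc_denominator(canon_ctrl, adj)
    # a carrier needs >= 1 read while staying strictly below the case NRC,
    # so its canonical denominator must exceed 1 / attained
    eligible <- which(denom_ctrl * attained > 1 + 1e-9)
    if (length(eligible) == 0) {
      stop("no control expresses the gene deeply enough to host a carrier", call. = FALSE)
    }
    pick <- eligible[seq_len(min(n_carriers, length(eligible)))]
    carriers <- ref$samples$sample_id[pick]
    for (s in pick) {
      creads <- max(1L, floor(carrier_nrc_frac * attained * denom_ctrl[s]))
      # Keep the carrier NRC strictly below the case NRC.
      while (creads / denom_ctrl[s] >= attained && creads > 1L) creads <- creads - 1L
      if (creads / denom_ctrl[s] >= attained) {
        stop("cannot place a carrier NRC below the case NRC with integer counts", call. = FALSE)
      }
      ref <- set_junction_count(
        ref, ref$samples$sample_id[s], novel$chrom, novel$start, novel$end,
        novel$strand, creads
      )
    }
  }
  list(
    case = case, reference = ref,
    truth = tibble::tibble(
      gene_id = gene_id, chrom = novel$chrom, start = novel$start,
      end = novel$end, strand = novel$strand, key = key,
      reads = as.integer(reads), target_nrc = target_nrc,
      attained_nrc = attained, singleton = singleton,
      carriers = list(carriers)
    )
  )
}

#' Generate an annotation fixture exercising the selection hierarchy
#'
#' Writes a small GENCODE-style GTF, a RefSeq-style GTF, and a MANE
#' transcript list containing genes for every selection tier: MANE-supported,
#' MANE with an unsupported junction (falls through to the RefSeq
#' composite), RefSeq-only, annotation-union-only, and a single-exon gene
#' for error paths.
#'
#' @param dir Output directory (created if needed).
#' @return List: `gencode_gtf`, `refseq_gtf`, `mane_tsv` (paths) and
#'   `expected` (tibble `gene_id`, `expected_tier`).
#' @export
generate_annotation_fixture <- function(dir = tempfile("annot")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  exon <- function(gene, tx, chrom, starts, ends, strand = "+") {
    sprintf(
      "%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
      chrom, starts, ends, strand, gene, tx
    )
  }
  # GENE_A: MANE transcript A.1 with exons matching GENCODE transcript.
  gencode <- c(
    exon("GENE_A", "GENE_A.gc1", "chr1", c(1000, 2000, 3000), c(1500, 2500, 3500)),
    exon("GENE_A", "GENE_A.gc2", "chr1", c(1000, 3000), c(1500, 3500)),
    # GENE_B: MANE transcript has a junction absent from GENCODE -> falls to
    # the RefSeq composite.
    exon("GENE_B", "GENE_B.gc1", "chr2", c(1000, 2000), c(1500, 2500)),
    # GENE_C: no MANE, no RefSeq -> union of two GENCODE transcripts.
    exon("GENE_C", "GENE_C.gc1", "chr3", c(1000, 2000), c(1500, 2500)),
    exon("GENE_C", "GENE_C.gc2", "chr3", c(1000, 3000), c(1500, 3500)),
    # GENE_D: single exon everywhere (error path).
    exon("GENE_D", "GENE_D.gc1", "chr4", 1000, 2000)
  )
  refseq <- c(
    exon("GENE_A", "NM_A1", "chr1", c(1000, 2000, 3000), c(1500, 2500, 3500)),
    exon("GENE_B", "NM_B1", "chr2", c(900, 2000, 4000), c(1500, 2500, 4500)),
    exon("GENE_B", "NM_B2", "chr2", c(1000, 2000), c(1500, 2500))
  )
  mane <- c(
    "gene_id\ttranscript_id",
    "GENE_A\tNM_A1",
    "GENE_B\tNM_B1" # junction (2501, 3999) unsupported in GENCODE
  )
  paths <- list(
    gencode_gtf = file.path(dir, "gencode.gtf"),
    refseq_gtf = file.path(dir, "refseq.gtf"),
    mane_tsv = file.path(dir, "mane.tsv")
  )
  writeLines(gencode, paths$gencode_gtf)
  writeLines(refseq, paths$refseq_gtf)
  writeLines(mane, paths$mane_tsv)
  c(paths, list(expected = tibble::tibble(
    gene_id = c("GENE_A", "GENE_B", "GENE_C", "GENE_D"),
    expected_tier = c("MANE", "refseq_composite", "gencode_union", "error")
  )))
}
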