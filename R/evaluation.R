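# Evaluation of MRSD predictions and the event pipeline: predictive values
# on independent samples, calibration against held-out samples from the same
# generative model, binomial read thinning, rank stability under reduced
# expression, bootstrap background event counts, TPM comparison, gene-panel
# tissue recommendation, and feasibility annotation of candidate variants.

achieved_coverage <- function(counts, r, p) {
  n <- length(counts)
  sum(counts >= r) >= ceiling(p * n - 1e-9)
}

#' Positive and negative predictive value of an MRSD table
#'
#' For an independent test sample: the prediction for a transcript is
#' positive when the sample's depth meets or exceeds the transcript's MRSD
#' (unfeasible transcripts always predict insufficient); coverage is
#' achieved when at least proportion `p` of the model's junctions carry at
#' least `r` reads -- the same rule MRSD itself uses, so self-evaluation is
#' exactly consistent. PPV is the proportion of positive predictions that
#' achieved coverage; NPV the proportion of negative predictions that did
#' not.
#'
#' @param mrsd_table An `mrsd_table` (scored with the same parameters).
#' @param test_counts Junction tibble with `unique_reads` for the test
#'   sample.
#' @param depth_millions Test sample depth in millions of uniquely mapping
#'   reads (0 is allowed and makes every prediction negative).
#' @param models Transcript-model tibble matching the table.
#' @param params [mrsd_params()]; defaults to the table's parameters.
#' @return List: `ppv`, `npv` (`NA` when the corresponding denominator is
#'   zero), and `outcomes`, a tibble with one row per scoreable transcript.
#' @export
evaluate_ppv_npv <- function(mrsd_table, test_counts, depth_millions, models,
                             params = attr(mrsd_table, "params")) {
  stopifnot(depth_millions >= 0)
  if (is.null(params)) {
    params <- mrsd_params(mrsd_table$r[1], mrsd_table$p[1], mrsd_table$m[1])
  }
  skey <- junction_key(
    test_counts$chrom, test_counts$start, test_counts$end, test_counts$strand
  )
  tab <- mrsd_table[!is.na(mrsd_table$mrsd_millions), , drop = FALSE]
  outcomes <- purrr::map_dfr(seq_len(nrow(tab)), function(k) {
    jt <- models$junctions[[match(tab$transcript_id[k], models$transcript_id)]]
    cnt <- test_counts$unique_reads[match(
      junction_key(jt$chrom, jt$start, jt$end, jt$strand), skey
    )]
    cnt[is.na(cnt)] <- 0L
    tibble::tibble(
      gene_id = tab$gene_id[k],
      transcript_id = tab$transcript_id[k],
      mrsd_millions = tab$mrsd_millions[k],
      predicted_sufficient = is.finite(tab$mrsd_millions[k]) &&
        depth_millions >= tab$mrsd_millions[k],
      achieved = achieved_coverage(cnt, params$r, params$p)
    )
  })
  pos <- outcomes$predicted_sufficient
  list(
    ppv = if (any(pos)) mean(outcomes$achieved[pos]) else NA_real_,
    npv = if (any(!pos)) mean(!outcomes$achieved[!pos]) else NA_real_,
    outcomes = outcomes
  )
}

#' Calibration of MRSD against held-out samples
#'
#' For every transcript with a finite MRSD, each held-out sample is scaled
#' to exactly the predicted depth (counts multiplied by MRSD / d, the
#' deterministic count-marginal of sequencing the same library at the
#' predicted depth) and checked for achieving `r`-read coverage of
#' proportion `p` of junctions. When the held-out samples come from the
#' same generative model as the reference cohort, the achieved proportion
#' concentrates near `m`.
#'
#' @param mrsd_table An `mrsd_table` computed from the reference cohort.
#' @param heldout An `mrsd_reference` of held-out samples from the same
#'   generative model.
#' @param models Transcript-model tibble.
#' @param params [mrsd_params()]; defaults to the table's.
#' @return List of class `mrsd_calibration`: `per_transcript` (tibble with
#'   `prop_achieved` over held-out samples), `coverage` (mean of the
#'   per-transcript proportions), `mc_se` (Monte-Carlo standard error of
#'   `coverage`: sd of per-transcript proportions / sqrt(T)), `m`,
#'   `n_heldout`.
#' @export
calibration_experiment <- function(mrsd_table, heldout, models,
                                   params = attr(mrsd_table, "params")) {
  if (is.null(params)) {
    params <- mrsd_params(mrsd_table$r[1], mrsd_table$p[1], mrsd_table$m[1])
  }
  tab <- mrsd_table[is.finite(mrsd_table$mrsd_millions), , drop = FALSE]
  stopifnot(nrow(tab) >= 1)
  d <- heldout$samples$depth_millions
  per <- purrr::map_dfr(seq_len(nrow(tab)), function(k) {
    jt <- models$junctions[[match(tab$transcript_id[k], models$transcript_id)]]
    keys <- junction_key(jt$chrom, jt$start, jt$end, jt$strand)
    counts <- junction_count_matrix(heldout, keys)
    scale <- tab$mrsd_millions[k] / d
    hit <- vapply(seq_along(d), function(s) {
      achieved_coverage(counts[s, ] * scale[s], params$r, params$p)
    }, logical(1))
    tibble::tibble(
      gene_id = tab$gene_id[k], transcript_id = tab$transcript_id[k],
      mrsd_millions = tab$mrsd_millions[k], prop_achieved = mean(hit)
    )
  })
  structure(
    list(
      per_transcript = per,
      coverage = mean(per$prop_achieved),
      mc_se = sd(per$prop_achieved) / sqrt(nrow(per)),
      m = params$m,
      n_heldout = length(d)
    ),
    class = "mrsd_calibration"
  )
}

#' @export
print.mrsd_calibration <- function(x, ...) {
  cat(
    "<mrsd_calibration> coverage ", signif(x$coverage, 4), " (target m = ", x$m,
    "), MC se ", signif(x$mc_se, 3), ", ", nrow(x$per_transcript),
    " transcripts x ", x$n_heldout, " held-out samples\n",
    sep = ""
  )
  invisible(x)
}

#' Binomially thin junction read counts
#'
#' Removes a random fraction of reads from each junction by independent
#' binomial sampling with retention probability `1 - fraction_removed`:
#' the exact count-marginal of removing reads uniformly at random, used to
#' mimic reduced expression of a gene.
#'
#' @param counts Junction tibble with `unique_reads` (or an integer
#'   vector).
#' @param fraction_removed Fraction of reads to remove, in \[0, 1).
#' @param seed Optional integer; when given the thinning is reproducible
#'   and the caller's RNG state is untouched.
#' @return Same shape as `counts` with thinned `unique_reads`.
#' @export
downsample_gene <- function(counts, fraction_removed, seed = NULL) {
  stopifnot(fraction_removed >= 0, fraction_removed < 1)
  thin <- function(x) {
    as.integer(rbinom(length(x), size = as.integer(x), prob = 1 - fraction_removed))
  }
  run <- function() {
    if (is.data.frame(counts)) {
      counts$unique_reads <- thin(counts$unique_reads)
      counts
    } else {
      thin(counts)
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Event rank stability under reduced gene expression
#'
#' Re-runs event detection after thinning the counts of the genes harbouring
#' the events of interest at each removal fraction, recording each event's
#' read count, rank, and whether it is still detected.
#'
#' @param case_counts Case junction tibble with `unique_reads`.
#' @param ref Control `mrsd_reference`.
#' @param models Transcript-model tibble.
#' @param event_keys Junction keys (see [junction_key()]) of the events of
#'   interest, detected at full depth.
#' @param fractions Removal fractions, e.g. `seq(0, 0.9, by = 0.1)`.
#' @param seed Integer seed controlling the thinning.
#' @param min_reads,min_nrc Detection thresholds; set `min_reads = 1`,
#'   `min_nrc = 0` to rank without threshold filtering.
#' @param case_id Case identifier.
#' @return Tibble: `fraction_removed`, `key`, `read_count`, `rank`,
#'   `detected`.
#' @export
rank_stability_experiment <- function(case_counts, ref, models, event_keys,
                                      fractions = seq(0, 0.9, by = 0.1),
                                      seed = 1, min_reads = 2, min_nrc = 0.25,
                                      case_id = "case") {
  base_events <- score_events(case_counts, ref, models, case_id)
  genes <- unique(base_events$gene_id[base_events$key %in% event_keys])
  if (length(genes) == 0) stop("no event of interest maps to a modelled gene", call. = FALSE)
  gene_keys <- base_events$key[base_events$gene_id %in% genes]
  ckey <- junction_key(
    case_counts$chrom, case_counts$start, case_counts$end, case_counts$strand
  )
  in_gene <- ckey %in% gene_keys
  purrr::map_dfr(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    thinned <- case_counts
    thinned$unique_reads[in_gene] <- downsample_gene(
      case_counts$unique_reads[in_gene], f,
      seed = seed + fi
    )
    thinned <- thinned[thinned$unique_reads > 0, , drop = FALSE]
    ranked <- detect_events(thinned, ref, models,
      case_id = case_id,
      min_reads = min_reads, min_nrc = min_nrc
    )
    idx <- match(event_keys, ranked$key)
    tibble::tibble(
      fraction_removed = f,
      key = event_keys,
      read_count = ranked$read_count[idx],
      rank = ranked$rank[idx],
      detected = !is.na(idx)
    )
  })
}

#' Bootstrap background of retained splice events
#'
#' Estimates how many events the uniqueness/NRC-dominance filter retains
#' for a case when compared against resampled control cohorts: for each
#' bootstrap replicate, `control_size` controls are drawn with replacement
#' from the pool, the filter is applied, and singleton / non-singleton
#' retained events are counted. Medians over replicates are reported.
#'
#' @param case_counts Case junction tibble with `unique_reads`.
#' @param ref Control pool (`mrsd_reference`), at least `control_size`
#'   samples.
#' @param models Transcript-model tibble.
#' @param control_sizes Cohort sizes to bootstrap (default `c(30, 60, 90)`).
#' @param n_bootstraps Replicates per size (default 2000).
#' @param seed Integer seed; results are bit-reproducible for a fixed seed.
#' @param min_reads Read-count threshold applied to events (default 1 =
#'   no filtering).
#' @param case_id Case identifier.
#' @return Tibble of class `bootstrap_summary`: one row per control size
#'   with `n_bootstraps`, `median_singletons`, `median_non_singletons`;
#'   per-replicate counts in `attr(, "replicates")`.
#' @export
bootstrap_background <- function(case_counts, ref, models,
                                 control_sizes = c(30, 60, 90),
                                 n_bootstraps = 2000, seed = 1,
                                 min_reads = 1, case_id = "case") {
  n_pool <- nrow(ref$samples)
  stopifnot(all(control_sizes <= n_pool), n_bootstraps >= 1)
  profile <- event_nrc_profile(case_counts, ref, models, case_id)
  ev <- profile$events
  ok <- !is.na(ev$nrc) & ev$read_count >= min_reads
  pres <- profile$ctrl_present[ok, , drop = FALSE]
  nrcs <- profile$ctrl_nrc[ok, , drop = FALSE]
  nrcs[is.na(nrcs)] <- 0 # undefined control NRC = junction treated absent
  case_nrc <- ev$nrc[ok]
  reps <- withr::with_seed(seed, {
    purrr::map_dfr(control_sizes, function(size) {
      purrr::map_dfr(seq_len(n_bootstraps), function(b) {
        idx <- sample.int(n_pool, size, replace = TRUE)
        cols <- unique(idx)
        n_present <- rowSums(pres[, cols, drop = FALSE])
        cmax <- Reduce(pmax, lapply(cols, function(j) nrcs[, j]))
        singleton <- n_present == 0
        retained <- singleton | case_nrc > cmax
        tibble::tibble(
          control_size = size, bootstrap = b,
          n_singletons = sum(retained & singleton),
          n_non_singletons = sum(retained & !singleton)
        )
      })
    })
  })
  out <- reps |>
    dplyr::group_by(.data$control_size) |>
    dplyr::summarise(
      n_bootstraps = dplyr::n(),
      median_singletons = median(.data$n_singletons),
      median_non_singletons = median(.data$n_non_singletons),
      .groups = "drop"
    )
  class(out) <- c("bootstrap_summary", class(out))
  attr(out, "replicates") <- reps
  out
}

#' Compare MRSD with relative expression (TPM)
#'
#' Fits log10(MRSD) against log10(TPM) over genes with finite MRSD and
#' TPM > 0 (zero-TPM and unfeasible genes are excluded from the fit), and
#' summarises the TPM distribution within each MRSD feasibility bracket to
#' expose high-expression genes that nonetheless require deep sequencing.
#'
#' @param mrsd_table An `mrsd_table`.
#' @param tpm_table Tibble `gene_id`, `tpm`.
#' @return List of class `mrsd_tpm_fit`: `r_squared`, `slope`, `n`, `data`
#'   (the fitted pairs), `brackets` (per-bracket TPM quantiles).
#' @export
compare_tpm <- function(mrsd_table, tpm_table) {
  joined <- dplyr::inner_join(
    tibble::as_tibble(mrsd_table)[, c("gene_id", "mrsd_millions", "class")],
    tpm_table[, c("gene_id", "tpm")],
    by = "gene_id"
  )
  if (nrow(joined) < 3) stop("fewer than 3 genes shared between tables", call. = FALSE)
  fitdat <- joined[is.finite(joined$mrsd_millions) & joined$tpm > 0, , drop = FALSE]
  if (nrow(fitdat) < 3) stop("fewer than 3 genes with finite MRSD and TPM > 0", call. = FALSE)
  fit <- lm(log10(mrsd_millions) ~ log10(tpm), data = fitdat)
  brackets <- joined[joined$tpm > 0, , drop = FALSE] |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_tpm = median(.data$tpm),
      q25_tpm = stats::quantile(.data$tpm, 0.25),
      q75_tpm = stats::quantile(.data$tpm, 0.75),
      .groups = "drop"
    )
  structure(
    list(
      r_squared = summary(fit)$r.squared,
      slope = unname(coef(fit)[2]),
      n = nrow(fitdat),
      data = fitdat,
      brackets = brackets
    ),
    class = "mrsd_tpm_fit"
  )
}

#' @export
print.mrsd_tpm_fit <- function(x, ...) {
  cat(
    "<mrsd_tpm_fit> log-log r^2 = ", signif(x$r_squared, 4), ", slope = ",
    signif(x$slope, 4), ", n = ", x$n, "\n",
    sep = ""
  )
  invisible(x)
}

#' @method glance mrsd_tpm_fit
#' @export
glance.mrsd_tpm_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, slope = x$slope, n = x$n)
}

#' @method tidy mrsd_tpm_fit
#' @export
tidy.mrsd_tpm_fit <- function(x, ...) tibble::as_tibble(x$data)

#' Per-panel, per-tissue low-MRSD proportions and best tissue
#'
#' For each gene panel and tissue, reports the proportion of the panel's
#' mappable genes classed low-MRSD, and flags the tissue(s) with the highest
#' proportion (ties are joint-best). Panels should already be restricted to
#' multi-exon genes with a confident ("green") disease association; if a
#' `rating` column is present, only `"green"` rows are used.
#'
#' @param mrsd_tables Named list of `mrsd_table`s, one per tissue.
#' @param panels Tibble `panel_name`, `gene_id` (optional `rating`).
#' @return Tibble: `panel_name`, `tissue`, `n_genes` (mappable), `n_low`,
#'   `prop_low`, `is_best`. Panels with zero mappable genes in every tissue
#'   are dropped with a warning.
#' @export
panel_report <- function(mrsd_tables, panels) {
  stopifnot(length(mrsd_tables) >= 1, !is.null(names(mrsd_tables)))
  if ("rating" %in% names(panels)) {
    panels <- panels[tolower(panels$rating) == "green", , drop = FALSE]
  }
  rows <- purrr::map_dfr(names(mrsd_tables), function(tissue) {
    tab <- mrsd_tables[[tissue]]
    cls <- tab$class[match(panels$gene_id, tab$gene_id)]
    tibble::tibble(
      panel_name = panels$panel_name, gene_id = panels$gene_id,
      tissue = tissue, class = cls
    )
  })
  out <- rows |>
    dplyr::filter(!is.na(.data$class), .data$class != "error") |>
    dplyr::group_by(.data$panel_name, .data$tissue) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_low = sum(.data$class == "low_mrsd"),
      prop_low = .data$n_low / .data$n_genes,
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$panel_name) |>
    dplyr::mutate(is_best = .data$prop_low == max(.data$prop_low)) |>
    dplyr::ungroup()
  dropped <- setdiff(unique(panels$panel_name), unique(out$panel_name))
  if (length(dropped)) {
    warning(
      "panel(s) with no mappable genes skipped: ", paste(dropped, collapse = ", ")
    )
  }
  out
}

#' Feasibility of assaying candidate splice-impacting variants
#'
#' Filters a variant table to those annotated as uncertain significance or
#' conflicting interpretations with a splice-impact score at or above
#' `spliceai_min` (inclusive), then annotates each retained variant with its
#' gene's MRSD feasibility class in every tissue.
#'
#' @param variants Tibble with `variant_id`, `gene_id`,
#'   `clinical_significance`, `spliceai_max`.
#' @param mrsd_tables Named list of `mrsd_table`s per tissue.
#' @param spliceai_min Score threshold, inclusive (default 0.5).
#' @return List of class `vus_feasibility`: `variants` (retained variants
#'   with one `class_<tissue>` column per tissue, `"unscored"` when the
#'   gene is absent from a table), `fraction_low_any` (fraction of retained
#'   variants low-MRSD in at least one tissue), `n_input`, `n_retained`.
#' @export
vus_feasibility <- function(variants, mrsd_tables, spliceai_min = 0.5) {
  stopifnot(length(mrsd_tables) >= 1, !is.null(names(mrsd_tables)))
  sig <- tolower(trimws(variants$clinical_significance))
  keep <- sig %in% c(
    "uncertain significance", "conflicting interpretations of pathogenicity"
  ) & !is.na(variants$spliceai_max) & variants$spliceai_max >= spliceai_min
  retained <- variants[keep, , drop = FALSE]
  for (tissue in names(mrsd_tables)) {
    tab <- mrsd_tables[[tissue]]
    cls <- tab$class[match(retained$gene_id, tab$gene_id)]
    cls[is.na(cls)] <- "unscored"
    retained[[paste0("class_", tissue)]] <- cls
  }
  cls_cols <- paste0("class_", names(mrsd_tables))
  low_any <- if (nrow(retained)) {
    apply(as.matrix(retained[, cls_cols]) == "low_mrsd", 1, any)
  } else {
    logical()
  }
  retained$low_mrsd_any <- low_any
  structure(
    list(
      variants = retained,
      fraction_low_any = if (nrow(retained)) mean(low_any) else NA_real_,
      n_input = nrow(variants),
      n_retained = nrow(retained)
    ),
    class = "vus_feasibility"
  )
}

#' @export
print.vus_feasibility <- function(x, ...) {
  cat(
    "<vus_feasibility> ", x$n_retained, "/", x$n_input,
    " variants retained; fraction low-MRSD in >=1 tissue: ",
    signif(x$fraction_low_any, 4), "\n",
    sep = ""
  )
  invisible(x)
}
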