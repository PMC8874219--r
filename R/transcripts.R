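# One junction-set "transcript model" per gene, selected hierarchically:
# (1) the gene's MANE transcript, provided every one of its junctions is
#     present in the gene's annotation-wide junction union;
# (2) otherwise a RefSeq composite: the union of junctions over all RefSeq
#     transcripts of the gene;
# (3) otherwise the union over all annotation (GENCODE-style) transcripts.
# Junctions are derived from GTF exons: junction = (exon_i end + 1,
# exon_{i+1} start - 1), 1-based closed intron coordinates.

#' Derive per-transcript splice junctions from a GTF annotation
#'
#' Reads exon features and converts consecutive exon pairs of each transcript
#' into intron (junction) intervals. Single-exon transcripts contribute no
#' junctions.
#'
#' @param gtf Path to a GTF file (GENCODE dialect: attributes `gene_id`,
#'   `transcript_id`), or a data frame of exons with columns
#'   `chrom`/`seqnames`, `start`, `end`, `strand`, `type`, `gene_id`,
#'   `transcript_id`.
#' @param genes Optional character vector restricting output to these genes.
#' @return Tibble with one row per junction: `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand`.
#' @export
gtf_to_junctions <- function(gtf, genes = NULL) {
  if (is.character(gtf)) {
    gr <- as.data.frame(rtracklayer::import(gtf, format = "gtf"))
    exons <- tibble::tibble(
      chrom = as.character(gr$seqnames),
      start = gr$start,
      end = gr$end,
      strand = as.character(gr$strand),
      type = as.character(gr$type),
      gene_id = gr$gene_id,
      transcript_id = gr$transcript_id
    )
  } else {
    exons <- tibble::as_tibble(gtf)
    if ("seqnames" %in% names(exons) && !"chrom" %in% names(exons)) {
      exons$chrom <- as.character(exons$seqnames)
    }
  }
  exons <- exons[exons$type == "exon", , drop = FALSE]
  if (!is.null(genes)) exons <- exons[exons$gene_id %in% genes, , drop = FALSE]
  if (nrow(exons) == 0) {
    return(tibble::tibble(
      gene_id = character(), transcript_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    ))
  }
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  parts <- split(exons, exons$transcript_id)
  out <- purrr::map(parts, function(tx) {
    n <- nrow(tx)
    if (n < 2) return(NULL)
    if (any(tx$start[-1] <= tx$end[-n])) {
      stop("overlapping exons within transcript ", tx$transcript_id[1], call. = FALSE)
    }
    tibble::tibble(
      gene_id = tx$gene_id[1],
      transcript_id = tx$transcript_id[1],
      chrom = tx$chrom[1],
      start = as.integer(tx$end[-n] + 1L),
      end = as.integer(tx$start[-1] - 1L),
      strand = tx$strand[1]
    )
  })
  dplyr::bind_rows(out)
}

#' Union of junction sets across transcripts
#'
#' @param transcripts List of junction tibbles (columns `chrom`, `start`,
#'   `end`, `strand`), or a single long tibble covering several transcripts.
#' @return Deduplicated junction tibble sorted by (chrom, start, end).
#' @export
build_union <- function(transcripts) {
  if (is.data.frame(transcripts)) transcripts <- list(transcripts)
  stopifnot(length(transcripts) >= 1)
  all <- dplyr::bind_rows(lapply(transcripts, function(j) {
    j[, c("chrom", "start", "end", "strand")]
  }))
  sort_junction_tbl(dplyr::distinct(all))
}

junctions_for_transcript <- function(long, transcript_id) {
  long[long$transcript_id %in% transcript_id, , drop = FALSE]
}

#' Select one transcript model for a gene
#'
#' Applies the three-tier hierarchy. A MANE transcript is used only if every
#' one of its junctions coordinate-matches a junction derivable from some
#' annotation transcript of the gene ("supported"); otherwise selection falls
#' through to the RefSeq composite, then to the annotation-wide union.
#'
#' @param gene_id Gene to model.
#' @param gencode_junctions Long junction tibble for the base annotation
#'   (from [gtf_to_junctions()]); must contain the gene.
#' @param mane Optional tibble `gene_id`, `transcript_id` naming MANE
#'   transcripts. MANE junctions are looked up by transcript id in
#'   `refseq_junctions`, then in `gencode_junctions`.
#' @param refseq_junctions Optional long junction tibble for RefSeq
#'   transcripts.
#' @return One-row tibble: `gene_id`, `transcript_id`, `tier` (one of
#'   `"MANE"`, `"refseq_composite"`, `"gencode_union"`), `n_junctions`, and
#'   list-column `junctions`.
#' @export
select_transcript <- function(gene_id, gencode_junctions, mane = NULL,
                              refseq_junctions = NULL) {
  gc <- gencode_junctions[gencode_junctions$gene_id == gene_id, , drop = FALSE]
  if (nrow(gc) == 0) {
    stop("gene ", gene_id, " absent from annotation or single-exon in all transcripts",
      call. = FALSE
    )
  }
  gc_union <- build_union(gc)
  gc_keys <- junction_key(gc_union$chrom, gc_union$start, gc_union$end, gc_union$strand)

  # Tier 1: MANE, if all its junctions are supported in the annotation union.
  if (!is.null(mane)) {
    mane_tx <- mane$transcript_id[mane$gene_id == gene_id]
    for (tx in mane_tx) {
      jt <- NULL
      if (!is.null(refseq_junctions)) {
        jt <- junctions_for_transcript(refseq_junctions, tx)
      }
      if (is.null(jt) || nrow(jt) == 0) {
        jt <- junctions_for_transcript(gencode_junctions, tx)
      }
      if (nrow(jt) == 0) next
      keys <- junction_key(jt$chrom, jt$start, jt$end, jt$strand)
      if (all(keys %in% gc_keys)) {
        jt <- sort_junction_tbl(jt[, c("chrom", "start", "end", "strand")])
        return(model_row(gene_id, tx, "MANE", jt))
      }
    }
  }

  # Tier 2: composite of all RefSeq transcripts of the gene.
  if (!is.null(refseq_junctions)) {
    rs <- refseq_junctions[refseq_junctions$gene_id == gene_id, , drop = FALSE]
    if (nrow(rs) > 0) {
      return(model_row(
        gene_id, paste0(gene_id, "|refseq_composite"),
        "refseq_composite", build_union(rs)
      ))
    }
  }

  # Tier 3: annotation-wide union.
  model_row(gene_id, paste0(gene_id, "|gencode_union"), "gencode_union", gc_union)
}

model_row <- function(gene_id, transcript_id, tier, junctions) {
  tibble::tibble(
    gene_id = gene_id, transcript_id = transcript_id, tier = tier,
    n_junctions = nrow(junctions), junctions = list(tibble::as_tibble(junctions))
  )
}

#' Build transcript models for many genes
#'
#' Vectorised driver for [select_transcript()]. Genes with no junctions in
#' the base annotation (absent or single-exon everywhere) are skipped with a
#' warning.
#'
#' @inheritParams select_transcript
#' @param genes Genes to model; defaults to all genes present in
#'   `gencode_junctions`.
#' @return Tibble of transcript models, one row per gene.
#' @export
build_transcript_models <- function(gencode_junctions, mane = NULL,
                                    refseq_junctions = NULL, genes = NULL) {
  if (is.null(genes)) genes <- unique(gencode_junctions$gene_id)
  ok <- genes %in% gencode_junctions$gene_id
  if (any(!ok)) {
    warning(
      sum(!ok), " gene(s) without multi-exon transcripts in the annotation were skipped"
    )
  }
  dplyr::bind_rows(lapply(genes[ok], function(g) {
    select_transcript(g, gencode_junctions, mane, refseq_junctions)
  }))
}

#' Inter-transcript MRSD variability per gene
#'
#' Summarises how stable MRSD is across a gene's alternative transcripts.
#' The coefficient of variation (CV) is the population (n-denominator)
#' standard deviation over the mean of the finite per-transcript MRSDs;
#' unfeasible transcripts (MRSD `Inf`) are excluded from the CV but counted,
#' so feasibility discordance stays visible.
#'
#' @param per_transcript Tibble with columns `gene_id` and `mrsd_millions`
#'   (numeric, `Inf` for unfeasible), one row per transcript.
#' @param selected Optional tibble `gene_id`, `mrsd_millions` giving the
#'   MRSD of each gene's selected model, joined into the report.
#' @return Tibble per gene: `n_transcripts`, `n_feasible`, `cv_mrsd` (NA
#'   when fewer than two finite values), `min_mrsd` (`Inf` when none
#'   finite), `selected_mrsd` (if supplied).
#' @export
cv_mrsd_report <- function(per_transcript, selected = NULL) {
  out <- per_transcript |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_transcripts = dplyr::n(),
      n_feasible = sum(is.finite(.data$mrsd_millions)),
      cv_mrsd = {
        x <- .data$mrsd_millions[is.finite(.data$mrsd_millions)]
        if (length(x) >= 2 && mean(x) > 0) {
          sqrt(mean((x - mean(x))^2)) / mean(x)
        } else {
          NA_real_
        }
      },
      min_mrsd = {
        x <- .data$mrsd_millions[is.finite(.data$mrsd_millions)]
        if (length(x)) min(x) else Inf
      },
      .groups = "drop"
    )
  if (!is.null(selected)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(selected, "gene_id", selected_mrsd = "mrsd_millions"),
      by = "gene_id"
    )
  }
  out
}
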