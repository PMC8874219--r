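# Splice-event metrics for a case sample against a control reference set:
#   read count       split reads supporting the junction in the case
#   NRC              read count / highest-count adjoining canonical junction
#                    (canonical = the gene's selected transcript model)
#   NRC fold change  case NRC / highest control NRC for the same junction
#   n samples        case + controls in which the junction is present
#   rank             singletons first by decreasing read count, then
#                    non-singletons by decreasing NRC fold change
# Control NRCs are computed against each control's own canonical counts.
# "Adjoining" canonical junctions are those sharing the event's donor or
# acceptor coordinate; if none exist the nearest flanking canonical junction
# on each side is used, and if those carry no reads the gene-wide canonical
# maximum stands in before the NRC is declared undefined.

adjoining_indices <- function(junction, model_jt) {
  same_site <- which(
    model_jt$start == junction$start | model_jt$end == junction$end
  )
  self <- which(
    model_jt$start == junction$start & model_jt$end == junction$end &
      model_jt$strand == junction$strand
  )
  same_site <- setdiff(same_site, self)
  if (length(same_site) > 0) return(same_site)
  left <- which(model_jt$end < junction$start)
  right <- which(model_jt$start > junction$end)
  flank <- c(
    if (length(left)) left[which.max(model_jt$end[left])],
    if (length(right)) right[which.min(model_jt$start[right])]
  )
  setdiff(flank, self)
}

# Per-sample NRC denominator given canonical count rows (samples x model
# junctions): adjoining max, falling back to the gene-wide canonical max.
nrc_denominator <- function(canon_counts, adj_idx) {
  if (is.null(dim(canon_counts))) canon_counts <- matrix(canon_counts, nrow = 1)
  gene_max <- apply(canon_counts, 1, max)
  if (length(adj_idx) == 0) return(gene_max)
  adj_max <- apply(canon_counts[, adj_idx, drop = FALSE], 1, max)
  ifelse(adj_max > 0, adj_max, gene_max)
}

#' Normalized read count (NRC) of one junction in one sample
#'
#' Ratio of the junction's read count to the highest-count adjoining
#' canonical junction of the gene's transcript model, in the same sample.
#' NRC may exceed 1.
#'
#' @param junction One-row junction tibble (`chrom`, `start`, `end`,
#'   `strand`) identifying the event.
#' @param sample_counts Junction tibble with `unique_reads`: all junctions
#'   observed in the sample.
#' @param model Transcript model (one-row model tibble or junction tibble)
#'   supplying the canonical junctions.
#' @return NRC as a scalar; `NA` if no canonical junction of the gene
#'   carries reads in the sample (event flagged undefined).
#' @export
compute_nrc <- function(junction, sample_counts, model) {
  model_jt <- model_junction_tbl(model)
  stopifnot(nrow(model_jt) >= 1)
  skey <- junction_key(
    sample_counts$chrom, sample_counts$start, sample_counts$end,
    sample_counts$strand
  )
  canon <- sample_counts$unique_reads[match(
    junction_key(model_jt$chrom, model_jt$start, model_jt$end, model_jt$strand),
    skey
  )]
  canon[is.na(canon)] <- 0L
  ev <- sample_counts$unique_reads[match(
    junction_key(junction$chrom, junction$start, junction$end, junction$strand),
    skey
  )]
  if (is.na(ev) || ev < 1) stop("event junction has no reads in the sample", call. = FALSE)
  denom <- nrc_denominator(matrix(canon, nrow = 1), adjoining_indices(junction, model_jt))
  if (denom == 0) return(NA_real_)
  ev / denom
}

#' NRC fold change of a case event over controls
#'
#' Fold difference between the case NRC and the highest control NRC for the
#' same junction. Controls in which the junction is absent (zero reads, or
#' NRC undefined) do not contribute.
#'
#' @param event_nrc Case NRC (> 0).
#' @param control_nrcs NRCs of the controls carrying the junction.
#' @return `event_nrc / max(control_nrcs)`, or `NA` when no control carries
#'   the junction (a singleton event).
#' @export
compute_fold_change <- function(event_nrc, control_nrcs) {
  stopifnot(event_nrc > 0)
  control_nrcs <- control_nrcs[!is.na(control_nrcs) & control_nrcs > 0]
  if (length(control_nrcs) == 0) return(NA_real_)
  event_nrc / max(control_nrcs)
}

# Assign case junctions to genes: same chrom and strand, overlapping the
# model's genomic span; a gene sharing a splice site wins ties.
assign_events_to_genes <- function(case_jt, models) {
  gene_spans <- tibble::tibble(
    gene_id = models$gene_id,
    chrom = purrr::map_chr(models$junctions, ~ .x$chrom[1]),
    strand = purrr::map_chr(models$junctions, ~ .x$strand[1]),
    span_start = purrr::map_int(models$junctions, ~ min(.x$start)),
    span_end = purrr::map_int(models$junctions, ~ max(.x$end))
  )
  sites <- lapply(models$junctions, function(j) c(j$start, j$end))
  names(sites) <- models$gene_id
  cand <- dplyr::inner_join(case_jt, gene_spans,
    by = c("chrom", "strand"), relationship = "many-to-many"
  )
  cand <- cand[cand$start <= cand$span_end & cand$end >= cand$span_start, , drop = FALSE]
  if (nrow(cand) == 0) return(cand[, c(names(case_jt), "gene_id")])
  cand$shared_site <- purrr::map2_lgl(
    seq_len(nrow(cand)), cand$gene_id,
    function(i, g) cand$start[i] %in% sites[[g]] || cand$end[i] %in% sites[[g]]
  )
  cand |>
    dplyr::group_by(.data$chrom, .data$start, .data$end, .data$strand) |>
    dplyr::arrange(dplyr::desc(.data$shared_site), .data$gene_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(names(case_jt)), "gene_id")
}

# Case NRCs plus per-control count/NRC matrices for the case's junctions;
# the reusable core of scoring and of the bootstrap background.
event_nrc_profile <- function(case_counts, ref, models, case_id = "case") {
  validate_junction_tbl(case_counts, what = "case sample")
  case_jt <- case_counts[case_counts$unique_reads >= 1, , drop = FALSE]
  assigned <- assign_events_to_genes(case_jt, models)
  if (nrow(assigned) == 0) {
    return(list(events = empty_events_tbl(case_id), ctrl_present = NULL, ctrl_nrc = NULL))
  }
  events <- list()
  ctrl_present <- list()
  ctrl_nrc <- list()
  skey <- junction_key(case_jt$chrom, case_jt$start, case_jt$end, case_jt$strand)
  for (g in unique(assigned$gene_id)) {
    model_jt <- models$junctions[[match(g, models$gene_id)]]
    mkeys <- junction_key(model_jt$chrom, model_jt$start, model_jt$end, model_jt$strand)
    canon_case <- case_jt$unique_reads[match(mkeys, skey)]
    canon_case[is.na(canon_case)] <- 0L
    canon_ctrl <- junction_count_matrix(ref, mkeys)
    ev <- assigned[assigned$gene_id == g, , drop = FALSE]
    ekeys <- junction_key(ev$chrom, ev$start, ev$end, ev$strand)
    ecounts_ctrl <- junction_count_matrix(ref, ekeys)
    for (i in seq_len(nrow(ev))) {
      adj <- adjoining_indices(ev[i, ], model_jt)
      denom_case <- nrc_denominator(matrix(canon_case, nrow = 1), adj)
      nrc <- if (denom_case > 0) ev$unique_reads[i] / denom_case else NA_real_
      denom_ctrl <- nrc_denominator(canon_ctrl, adj)
      cc <- ecounts_ctrl[, i]
      cnrc <- ifelse(cc > 0 & denom_ctrl > 0, cc / denom_ctrl, NA_real_)
      events[[length(events) + 1]] <- tibble::tibble(
        chrom = ev$chrom[i], start = ev$start[i], end = ev$end[i],
        strand = ev$strand[i], key = ekeys[i], sample_id = case_id,
        gene_id = g, read_count = as.integer(ev$unique_reads[i]), nrc = nrc
      )
      ctrl_present[[length(ctrl_present) + 1]] <- cc > 0
      ctrl_nrc[[length(ctrl_nrc) + 1]] <- cnrc
    }
  }
  list(
    events = dplyr::bind_rows(events),
    ctrl_present = do.call(rbind, ctrl_present),
    ctrl_nrc = do.call(rbind, ctrl_nrc)
  )
}

empty_events_tbl <- function(case_id = character()) {
  tibble::tibble(
    chrom = character(), start = integer(), end = integer(), strand = character(),
    key = character(), sample_id = character(), gene_id = character(),
    read_count = integer(), nrc = double(), control_max_nrc = double(),
    n_samples = integer(), singleton = logical(), nrc_fold_change = double()
  )
}

# Finalise an event table from a profile and a control-column subset.
profile_to_events <- function(profile, ctrl_cols = NULL) {
  ev <- profile$events
  if (nrow(ev) == 0) return(empty_events_tbl())
  pres <- profile$ctrl_present
  nrcs <- profile$ctrl_nrc
  if (!is.null(ctrl_cols)) {
    pres <- pres[, ctrl_cols, drop = FALSE]
    nrcs <- nrcs[, ctrl_cols, drop = FALSE]
  }
  ev$n_samples <- 1L + as.integer(rowSums(pres))
  ev$singleton <- ev$n_samples == 1L
  cmax <- apply(nrcs, 1, function(x) {
    x <- x[!is.na(x) & x > 0]
    if (length(x)) max(x) else NA_real_
  })
  ev$control_max_nrc <- cmax
  ev$nrc_fold_change <- ifelse(
    ev$singleton | is.na(ev$nrc) | is.na(cmax), NA_real_, ev$nrc / cmax
  )
  ev
}

#' Score a case sample's splice junctions against a reference set
#'
#' Computes the event metrics (read count, NRC, NRC fold change, number of
#' samples, singleton status) for every case junction assignable to a gene
#' in `models`. Junctions outside all modelled genes are out of scope and
#' dropped.
#'
#' @param case_counts Junction tibble with `unique_reads` for the case
#'   sample.
#' @param ref An `mrsd_reference` of control samples.
#' @param models Transcript-model tibble.
#' @param case_id Identifier recorded in the output.
#' @return Event tibble; `nrc` is `NA` (flagged) when no canonical junction
#'   of the gene carries reads in the case, `nrc_fold_change` is `NA` for
#'   singletons.
#' @export
score_events <- function(case_counts, ref, models, case_id = "case") {
  profile_to_events(event_nrc_profile(case_counts, ref, models, case_id))
}

#' Retain singleton or control-exceeding events
#'
#' Keeps events unique to the case sample (singletons) or present in
#' multiple samples but with increased usage in the case: NRC strictly
#' higher than every control's NRC for that junction. Events with undefined
#' NRC are dropped (they remain flagged in the [score_events()] output).
#'
#' @param events Event tibble from [score_events()].
#' @return Filtered event tibble.
#' @export
filter_events <- function(events) {
  # Controls carrying the junction with an undefined NRC contribute nothing
  # (treated as absent), so they cannot block retention.
  keep <- !is.na(events$nrc) & (
    events$singleton |
      is.na(events$control_max_nrc) |
      events$nrc > events$control_max_nrc
  )
  events[keep, , drop = FALSE]
}

#' Apply read-count and NRC thresholds
#'
#' Retains events supported by at least `min_reads` reads that are either
#' singletons or have NRC strictly above `min_nrc`.
#'
#' @param events Event tibble.
#' @param min_reads Minimum supporting reads (default 2).
#' @param min_nrc NRC threshold for non-singletons (default 0.25, strict
#'   `>`).
#' @return Filtered event tibble.
#' @export
apply_thresholds <- function(events, min_reads = 2, min_nrc = 0.25) {
  keep <- events$read_count >= min_reads &
    (events$singleton | (!is.na(events$nrc) & events$nrc > min_nrc))
  events[keep, , drop = FALSE]
}

#' Rank filtered events
#'
#' Singletons come first, ordered by decreasing read count; non-singletons
#' follow, ordered by decreasing NRC fold change. Ties break by decreasing
#' read count, then lexicographic junction key. Ranks are 1-based and
#' invariant to input order.
#'
#' @param events Event tibble.
#' @return The events sorted with a `rank` column.
#' @export
rank_events <- function(events) {
  if (nrow(events) == 0) {
    events$rank <- integer()
    return(events)
  }
  fc <- ifelse(is.na(events$nrc_fold_change), -Inf, events$nrc_fold_change)
  ord <- order(
    !events$singleton, # singletons first
    ifelse(events$singleton, -events$read_count, -fc),
    -events$read_count,
    events$key
  )
  out <- events[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' End-to-end event detection for a case sample
#'
#' Runs [score_events()], [filter_events()], [apply_thresholds()] and
#' [rank_events()] in sequence.
#'
#' @inheritParams score_events
#' @inheritParams apply_thresholds
#' @return Ranked event tibble.
#' @export
detect_events <- function(case_counts, ref, models, case_id = "case",
                          min_reads = 2, min_nrc = 0.25) {
  score_events(case_counts, ref, models, case_id) |>
    filter_events() |>
    apply_thresholds(min_reads = min_reads, min_nrc = min_nrc) |>
    rank_events()
}

#' Write an event table as TSV
#'
#' Singleton events carry the literal string `"singleton"` in the
#' `nrc_fold_change` column.
#'
#' @param events Event tibble.
#' @param path Output path.
#' @export
write_events_tsv <- function(events, path) {
  out <- tibble::as_tibble(events)
  out$nrc_fold_change <- ifelse(
    out$singleton, "singleton",
    format(out$nrc_fold_change, digits = 6, trim = TRUE)
  )
  readr::write_tsv(out, path)
  invisible(path)
}
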