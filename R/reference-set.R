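# A reference set is the control cohort for one tissue: a samples x junctions
# matrix of uniquely-mapping read counts plus each sample's total depth in
# millions of reads. The junction universe is the union over samples, sorted
# by (chrom, start, end, strand) so assembly is invariant to sample order.

new_reference_set <- function(counts, samples, junctions, tissue_label) {
  stopifnot(
    nrow(counts) == nrow(samples), ncol(counts) == nrow(junctions),
    !anyDuplicated(samples$sample_id)
  )
  structure(
    list(
      counts = counts, samples = samples, junctions = junctions,
      tissue_label = tissue_label
    ),
    class = "mrsd_reference"
  )
}

sort_junction_tbl <- function(j) {
  j[order(j$chrom, j$start, j$end, j$strand), , drop = FALSE]
}

#' Assemble a reference set from per-sample junction counts
#'
#' Collates per-sample splice-junction read counts into a samples-by-junctions
#' matrix. The junction universe is the union of all junctions observed in any
#' sample; a junction absent from a sample gets count 0. Sample order is
#' preserved; junctions are sorted by coordinate so the assembled universe
#' does not depend on sample input order.
#'
#' @param samples Tibble with columns `sample_id`, `depth_millions` (total
#'   uniquely-mapping reads, in millions, > 0) and list-column `junctions`
#'   (junction tibbles with `unique_reads`), e.g. from
#'   [read_sample_manifest()].
#' @param tissue_label Free-text label for the cohort's tissue.
#' @return An object of class `mrsd_reference`.
#' @export
assemble_reference_set <- function(samples, tissue_label = "") {
  stopifnot(nrow(samples) >= 1)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids in reference set", call. = FALSE)
  }
  if (any(samples$depth_millions <= 0)) {
    stop("all sample depths must be positive", call. = FALSE)
  }
  purrr::walk2(
    samples$junctions, samples$sample_id,
    function(j, id) validate_junction_tbl(j, what = paste0("sample ", id))
  )
  universe <- dplyr::distinct(
    dplyr::bind_rows(lapply(samples$junctions, function(j) {
      j[, c("chrom", "start", "end", "strand")]
    }))
  )
  universe <- sort_junction_tbl(universe)
  universe$key <- junction_key(universe$chrom, universe$start, universe$end, universe$strand)
  counts <- matrix(0L,
    nrow = nrow(samples), ncol = nrow(universe),
    dimnames = list(samples$sample_id, universe$key)
  )
  for (i in seq_len(nrow(samples))) {
    j <- samples$junctions[[i]]
    if (nrow(j) == 0) next
    idx <- match(junction_key(j$chrom, j$start, j$end, j$strand), universe$key)
    counts[i, idx] <- as.integer(j$unique_reads)
  }
  new_reference_set(
    counts,
    tibble::tibble(
      sample_id = samples$sample_id,
      depth_millions = samples$depth_millions
    ),
    universe, tissue_label
  )
}

#' Read a reference set from a manifest file
#'
#' @param manifest_path Path to a sample manifest (see
#'   [read_sample_manifest()]).
#' @inheritParams assemble_reference_set
#' @return An `mrsd_reference`.
#' @export
read_reference_set <- function(manifest_path, tissue_label = "") {
  assemble_reference_set(read_sample_manifest(manifest_path), tissue_label)
}

model_junction_tbl <- function(model) {
  if (is.data.frame(model) && "junctions" %in% names(model) &&
    is.list(model$junctions)) {
    stopifnot(nrow(model) == 1)
    model <- model$junctions[[1]]
  }
  stopifnot(is.data.frame(model))
  model
}

#' Restrict a reference set to a transcript model's junctions
#'
#' Returns a reference set whose junction list is exactly the model's
#' junctions, in model order. Model junctions never observed in any control
#' sample appear with all-zero counts; matching is by full junction identity
#' (chromosome, start, end, strand), so a strand-mismatched junction is
#' unobserved.
#'
#' @param ref An `mrsd_reference`.
#' @param model A one-row transcript-model tibble (from
#'   [build_transcript_models()]) or a plain junction tibble.
#' @return An `mrsd_reference` over the model's junctions.
#' @export
subset_by_transcript <- function(ref, model) {
  stopifnot(inherits(ref, "mrsd_reference"))
  jt <- model_junction_tbl(model)
  if (nrow(jt) == 0) {
    stop("transcript model has no junctions (single-exon transcript?)", call. = FALSE)
  }
  keys <- junction_key(jt$chrom, jt$start, jt$end, jt$strand)
  counts <- junction_count_matrix(ref, keys)
  junctions <- tibble::tibble(
    chrom = jt$chrom, start = jt$start, end = jt$end, strand = jt$strand,
    key = keys
  )
  new_reference_set(counts, ref$samples, junctions, ref$tissue_label)
}

# Counts for an arbitrary key vector; unobserved keys give zero columns.
junction_count_matrix <- function(ref, keys) {
  idx <- match(keys, ref$junctions$key)
  counts <- matrix(0L,
    nrow = nrow(ref$samples), ncol = length(keys),
    dimnames = list(ref$samples$sample_id, keys)
  )
  hit <- !is.na(idx)
  if (any(hit)) counts[, hit] <- ref$counts[, idx[hit], drop = FALSE]
  counts
}

#' Extract one sample from a reference set
#'
#' @param ref An `mrsd_reference`.
#' @param sample_id Sample to extract.
#' @return List with `sample_id`, `depth_millions`, and `counts` (a junction
#'   tibble restricted to junctions with at least one read in the sample).
#' @export
extract_sample <- function(ref, sample_id) {
  i <- match(sample_id, ref$samples$sample_id)
  if (is.na(i)) stop("sample not found: ", sample_id, call. = FALSE)
  cnt <- ref$counts[i, ]
  keep <- cnt > 0
  counts <- ref$junctions[keep, c("chrom", "start", "end", "strand")]
  counts$unique_reads <- as.integer(cnt[keep])
  list(
    sample_id = sample_id,
    depth_millions = ref$samples$depth_millions[i],
    counts = tibble::as_tibble(counts)
  )
}

#' Drop samples from a reference set
#'
#' @param ref An `mrsd_reference`.
#' @param sample_ids Samples to remove.
#' @return An `mrsd_reference` without the given samples.
#' @export
drop_samples <- function(ref, sample_ids) {
  keep <- !(ref$samples$sample_id %in% sample_ids)
  stopifnot(any(keep))
  new_reference_set(
    ref$counts[keep, , drop = FALSE],
    ref$samples[keep, , drop = FALSE],
    ref$junctions, ref$tissue_label
  )
}

# In-place count edit used by the event injector.
set_junction_count <- function(ref, sample_id, chrom, start, end, strand, value) {
  key <- junction_key(chrom, start, end, strand)
  i <- match(sample_id, ref$samples$sample_id)
  stopifnot(!is.na(i))
  if (!key %in% ref$junctions$key) {
    add <- tibble::tibble(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      strand = strand, key = key
    )
    ref$junctions <- dplyr::bind_rows(ref$junctions, add)
    newcol <- matrix(0L, nrow = nrow(ref$counts), ncol = 1, dimnames = list(NULL, key))
    ref$counts <- cbind(ref$counts, newcol)
  }
  ref$counts[i, key] <- as.integer(value)
  ref
}

#' @export
print.mrsd_reference <- function(x, ...) {
  cat(
    "<mrsd_reference> ", nrow(x$samples), " samples x ", nrow(x$junctions),
    " junctions", if (nzchar(x$tissue_label)) paste0(" [", x$tissue_label, "]"), "\n",
    "  depth (millions): median ", signif(median(x$samples$depth_millions), 4),
    ", range ", signif(min(x$samples$depth_millions), 4), "-",
    signif(max(x$samples$depth_millions), 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a reference set into long format
#'
#' @param x An `mrsd_reference`.
#' @param ... Unused.
#' @return Long tibble: one row per (sample, junction) with `unique_reads`
#'   and `depth_millions`; zero counts included.
#' @method tidy mrsd_reference
#' @export
tidy.mrsd_reference <- function(x, ...) {
  long <- tibble::tibble(
    sample_id = rep(x$samples$sample_id, times = nrow(x$junctions)),
    depth_millions = rep(x$samples$depth_millions, times = nrow(x$junctions)),
    chrom = rep(x$junctions$chrom, each = nrow(x$samples)),
    start = rep(x$junctions$start, each = nrow(x$samples)),
    end = rep(x$junctions$end, each = nrow(x$samples)),
    strand = rep(x$junctions$strand, each = nrow(x$samples)),
    unique_reads = as.integer(x$counts)
  )
  long
}
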