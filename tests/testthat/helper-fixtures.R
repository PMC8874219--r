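# Shared fixtures built in code at test time.

jt <- function(chrom, start, end, strand = "+", unique_reads = NULL) {
  out <- tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand
  )
  if (!is.null(unique_reads)) out$unique_reads <- as.integer(unique_reads)
  out
}

# Tiny deterministic two-gene reference: gene GA on chr1:+ with 3 junctions,
# gene GB on chr2:- with 2 junctions.
tiny_models <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      gene_id = "GA", transcript_id = "GA.1", tier = "MANE", n_junctions = 3L,
      junctions = list(jt("chr1", c(1001, 2001, 3001), c(1500, 2500, 3500)))
    ),
    tibble::tibble(
      gene_id = "GB", transcript_id = "GB.1", tier = "gencode_union",
      n_junctions = 2L,
      junctions = list(jt("chr2", c(501, 1501), c(900, 1900), strand = "-"))
    )
  )
}

# Reference set over the tiny models with hand-set counts.
tiny_reference <- function(counts_list = NULL, depths = c(50, 80, 100)) {
  ga <- tiny_models()$junctions[[1]]
  gb <- tiny_models()$junctions[[2]]
  if (is.null(counts_list)) {
    counts_list <- list(
      c(40, 30, 20, 10, 8),
      c(60, 45, 30, 16, 12),
      c(80, 60, 40, 20, 16)
    )
  }
  samples <- tibble::tibble(
    sample_id = paste0("C", seq_along(counts_list)),
    depth_millions = depths[seq_along(counts_list)],
    junctions = lapply(counts_list, function(cnt) {
      all <- dplyr::bind_rows(ga, gb)
      all$unique_reads <- as.integer(cnt)
      all[all$unique_reads > 0, , drop = FALSE]
    })
  )
  assemble_reference_set(samples, tissue_label = "tiny")
}

small_sim <- function(n_samples = 40, n_genes = 30, seed = 11, ...) {
  generate_reference_set(
    generator_config(n_samples = n_samples, n_genes = n_genes, seed = seed, ...)
  )
}

write_star_file <- function(rows, path = tempfile(fileext = ".tab")) {
  writeLines(rows, path)
  path
}
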