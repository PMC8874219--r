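# The MRSD score. For one transcript in one control sample with junction
# read counts R (ascending) and total depth d million uniquely mapping
# reads, the critical count R_p is the count at the largest order-statistic
# position whose suffix holds at least proportion p of the counts. The
# per-sample minimum required sequencing depth for r-read coverage is then
#
#   MRSD = r * d / R_p   (millions of reads; unfeasible when R_p = 0),
#
# i.e. the sample's observed per-million coverage R_p / d scaled up to r.
# Across the n control samples the reported score is the ceil(m*n)-th order
# statistic of per-sample MRSDs (unfeasible = +Inf): the depth that holds
# for at least proportion m of controls. Pure order statistics are used
# throughout -- no interpolation, so every reported value is one actually
# implied by an observed count. Unfeasible values are carried as Inf in R
# and rendered as the string "unfeasible" in files.

#' MRSD model parameters
#'
#' @param r Desired reads per junction (positive; default 8).
#' @param p Proportion of a transcript's junctions that must reach `r`
#'   reads (0 < p <= 1; default 0.75).
#' @param m Proportion of control samples for which the returned depth must
#'   hold (0 < m <= 1; default 0.95, 0.99 for a stricter model).
#' @return An `mrsd_params` object.
#' @export
mrsd_params <- function(r = 8, p = 0.75, m = 0.95) {
  if (!is.numeric(r) || length(r) != 1 || r < 1) {
    stop("r must be a positive number >= 1", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1) {
    stop("p must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1 || m <= 0 || m > 1) {
    stop("m must lie in (0, 1]", call. = FALSE)
  }
  structure(list(r = r, p = p, m = m), class = "mrsd_params")
}

#' @export
print.mrsd_params <- function(x, ...) {
  cat("<mrsd_params> r =", x$r, " p =", x$p, " m =", x$m, "\n")
  invisible(x)
}

#' Order junction read counts ascending
#'
#' @param counts Numeric vector of junction read counts.
#' @return Stable ascending sort.
#' @export
order_counts <- function(counts) {
  stopifnot(length(counts) >= 1)
  sort(counts, method = "radix")
}

#' Critical junction count R_p
#'
#' The read count at the position in the ascending-ordered counts at which
#' proportion `p` of the counts are greater than or equal to it: the largest
#' 1-based index i with suffix proportion (n - i + 1)/n >= p.
#'
#' @param counts Junction read counts (any order).
#' @param p Junction proportion in (0, 1].
#' @return The critical count (scalar).
#' @export
critical_count <- function(counts, p) {
  n <- length(counts)
  stopifnot(n >= 1, p > 0, p <= 1)
  xs <- order_counts(counts)
  i <- n - ceiling(n * p - 1e-9) + 1L
  xs[[i]]
}

#' Per-sample MRSD
#'
#' @param r Desired reads per junction.
#' @param R_p Critical junction count(s); vectorised.
#' @param d Sample depth(s) in millions of uniquely mapping reads.
#' @return Required depth in millions of reads; `Inf` (unfeasible) where
#'   `R_p` is zero.
#' @export
per_sample_mrsd <- function(r, R_p, d) {
  stopifnot(r > 0, all(d > 0), all(R_p >= 0))
  ifelse(R_p == 0, Inf, r * d / R_p)
}

#' Aggregate per-sample MRSDs across the control cohort
#'
#' Returns the ceil(m*n)-th smallest per-sample MRSD, treating unfeasible
#' samples as +Inf, so the returned depth holds for at least proportion `m`
#' of controls.
#'
#' @param values Per-sample MRSDs (finite or `Inf`).
#' @param m Control-sample proportion in (0, 1].
#' @return Aggregated MRSD in millions of reads, `Inf` if unfeasible.
#' @export
aggregate_mrsd <- function(values, m) {
  n <- length(values)
  stopifnot(n >= 1, m > 0, m <= 1)
  xs <- sort(values) # Inf sorts last
  xs[[ceiling(m * n - 1e-9)]]
}

#' Classify an MRSD value into feasibility brackets
#'
#' @param mrsd_millions Numeric vector of MRSDs (`Inf` for unfeasible).
#' @param threshold Bracket boundary in millions of reads (default 100);
#'   values at the boundary are high-MRSD.
#' @return Character vector: `"low_mrsd"` (< threshold), `"high_mrsd"`
#'   (>= threshold, finite), or `"unfeasible"`.
#' @export
classify_mrsd <- function(mrsd_millions, threshold = 100) {
  dplyr::case_when(
    !is.finite(mrsd_millions) ~ "unfeasible",
    mrsd_millions < threshold ~ "low_mrsd",
    .default = "high_mrsd"
  )
}

#' Compute an MRSD table for a set of transcript models
#'
#' The main scoring entry point: for every transcript model, extracts the
#' model's junction counts from the reference set (zero for junctions never
#' observed), computes each control sample's critical count and per-sample
#' MRSD, and aggregates across samples. Results do not depend on sample
#' order.
#'
#' @param ref An `mrsd_reference` control cohort.
#' @param models Transcript-model tibble from [build_transcript_models()]
#'   (or any tibble with `gene_id`, `transcript_id`, `tier`, list-column
#'   `junctions`).
#' @param params [mrsd_params()].
#' @param threshold Feasibility-bracket boundary in millions of reads.
#' @param keep_per_sample Keep a list-column of per-sample detail (sample
#'   id, critical count, depth, per-sample MRSD)?
#' @return A tibble of class `mrsd_table`: one row per model with
#'   `gene_id`, `transcript_id`, `tier`, `n_junctions`, `mrsd_millions`
#'   (`Inf` = unfeasible), `class`, `r`, `p`, `m`, `n_samples`,
#'   `tissue_label`. Models with zero junctions yield a row with `NA`
#'   score and class `"error"` rather than failing the run.
#' @export
compute_mrsd_table <- function(ref, models, params = mrsd_params(),
                               threshold = 100, keep_per_sample = FALSE) {
  stopifnot(inherits(ref, "mrsd_reference"), nrow(ref$samples) >= 1)
  if (!inherits(params, "mrsd_params")) params <- do.call(mrsd_params, params)
  d <- ref$samples$depth_millions
  n <- length(d)
  rows <- vector("list", nrow(models))
  for (k in seq_len(nrow(models))) {
    jt <- models$junctions[[k]]
    if (is.null(jt) || nrow(jt) == 0) {
      rows[[k]] <- tibble::tibble(
        gene_id = models$gene_id[k], transcript_id = models$transcript_id[k],
        tier = models$tier[k], n_junctions = 0L, mrsd_millions = NA_real_,
        class = "error"
      )
      next
    }
    keys <- junction_key(jt$chrom, jt$start, jt$end, jt$strand)
    counts <- junction_count_matrix(ref, keys)
    rp <- apply(counts, 1, critical_count, p = params$p)
    ps <- per_sample_mrsd(params$r, rp, d)
    mrsd <- aggregate_mrsd(ps, params$m)
    row <- tibble::tibble(
      gene_id = models$gene_id[k], transcript_id = models$transcript_id[k],
      tier = models$tier[k], n_junctions = nrow(jt), mrsd_millions = mrsd,
      class = classify_mrsd(mrsd, threshold)
    )
    if (keep_per_sample) {
      row$per_sample <- list(tibble::tibble(
        sample_id = ref$samples$sample_id, R_p = as.integer(rp),
        depth_millions = d, mrsd_millions = ps
      ))
    }
    rows[[k]] <- row
  }
  out <- dplyr::bind_rows(rows)
  out$r <- params$r
  out$p <- params$p
  out$m <- params$m
  out$n_samples <- n
  out$tissue_label <- ref$tissue_label
  class(out) <- c("mrsd_table", class(out))
  attr(out, "params") <- params
  attr(out, "threshold") <- threshold
  out
}

#' Write / read an MRSD table as TSV
#'
#' Unfeasible scores are written as the literal string `"unfeasible"` (never
#' a numeric sentinel) and restored to `Inf` on reading.
#'
#' @param x An `mrsd_table`.
#' @param path Output path.
#' @export
write_mrsd_table <- function(x, path) {
  out <- dplyr::select(
    tibble::as_tibble(x), "gene_id", "transcript_id", "tier", "n_junctions",
    "mrsd_millions", "class", "r", "p", "m", "n_samples", "tissue_label"
  )
  out$mrsd_millions <- ifelse(
    is.finite(out$mrsd_millions), format(out$mrsd_millions, digits = 10, trim = TRUE),
    ifelse(is.na(out$mrsd_millions), "NA", "unfeasible")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_mrsd_table
#' @export
read_mrsd_table <- function(path) {
  out <- readr::read_tsv(path,
    col_types = readr::cols(
      mrsd_millions = readr::col_character(), tissue_label = readr::col_character(),
      .default = readr::col_guess()
    ), progress = FALSE
  )
  out$mrsd_millions <- ifelse(
    out$mrsd_millions == "unfeasible", Inf,
    suppressWarnings(as.numeric(out$mrsd_millions))
  )
  out$tissue_label[is.na(out$tissue_label)] <- ""
  class(out) <- c("mrsd_table", class(out))
  out
}

#' Summarise an MRSD table
#'
#' @param x An `mrsd_table`.
#' @param ... Unused.
#' @return One-row tibble: transcript counts by feasibility, median feasible
#'   MRSD, and the parameters used.
#' @method glance mrsd_table
#' @export
glance.mrsd_table <- function(x, ...) {
  fin <- x$mrsd_millions[is.finite(x$mrsd_millions)]
  tibble::tibble(
    n_transcripts = nrow(x),
    n_feasible = length(fin),
    n_unfeasible = sum(!is.finite(x$mrsd_millions) & !is.na(x$mrsd_millions)),
    median_mrsd = if (length(fin)) median(fin) else NA_real_,
    r = x$r[1], p = x$p[1], m = x$m[1],
    n_samples = x$n_samples[1], tissue_label = x$tissue_label[1]
  )
}
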