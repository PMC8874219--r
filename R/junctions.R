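# Splice junctions are 1-based, fully-closed intron intervals: `start` is the
# first intronic base and `end` the last, matching STAR's SJ.out.tab so that
# file is the zero-conversion input path. Identity is (chrom, start, end,
# strand); strand "*" (unmapped strand, STAR code 0) matches only "*".

star_strand_map <- c("0" = "*", "1" = "+", "2" = "-")

#' Build the canonical junction identity key
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based first/last intronic base.
#' @param strand One of `"+"`, `"-"`, `"*"` (unknown).
#' @return Character vector `chrom:start-end:strand`.
#' @export
junction_key <- function(chrom, start, end, strand) {
  paste0(chrom, ":", start, "-", end, ":", strand)
}

empty_junction_tbl <- function() {
  tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), unique_reads = integer()
  )
}

validate_junction_tbl <- function(x, what = "junction table") {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(x)))
  if (any(x$start > x$end)) {
    stop(what, ": junction start greater than end", call. = FALSE)
  }
  if (any(!nzchar(x$chrom))) stop(what, ": empty chromosome name", call. = FALSE)
  if (!all(x$strand %in% c("+", "-", "*"))) {
    stop(what, ": strand must be one of '+', '-', '*'", call. = FALSE)
  }
  if ("unique_reads" %in% names(x)) {
    if (any(is.na(x$unique_reads)) || any(x$unique_reads < 0)) {
      stop(what, ": negative or missing read counts", call. = FALSE)
    }
  }
  key <- junction_key(x$chrom, x$start, x$end, x$strand)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(what, ": duplicate junction ", dup, call. = FALSE)
  }
  invisible(x)
}

#' Read a STAR SJ.out.tab splice-junction file
#'
#' Parses the 9-column, headerless tab-separated format emitted by STAR:
#' chromosome, intron start (1-based), intron end (1-based), strand code
#' (0 = unknown, 1 = +, 2 = -), intron motif, annotation flag, number of
#' uniquely mapping reads, number of multi-mapping reads, maximum overhang.
#' Only the uniquely-mapping read count is retained; multimappers are
#' discarded.
#'
#' @param path Path to an `SJ.out.tab` file.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `unique_reads`; zero rows for an empty file.
#' @export
read_star_sj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_junction_tbl())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    bad <- which(nf < 9)[1]
    stop("malformed SJ.out.tab row at line ", bad, ": expected >= 9 fields, found ",
      nf[bad],
      call. = FALSE
    )
  }
  mat <- t(vapply(fields, function(f) f[1:9], character(9)))
  strand <- star_strand_map[mat[, 4]]
  if (any(is.na(strand))) {
    bad <- which(is.na(strand))[1]
    stop("invalid strand code at line ", bad, ": ", mat[bad, 4], call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = mat[, 1],
    start = as.integer(mat[, 2]),
    end = as.integer(mat[, 3]),
    strand = unname(strand),
    unique_reads = as.integer(mat[, 7])
  )
  if (any(is.na(out$start)) || any(is.na(out$end)) || any(is.na(out$unique_reads))) {
    bad <- which(is.na(out$start) | is.na(out$end) | is.na(out$unique_reads))[1]
    stop("non-numeric coordinate or count at line ", bad, call. = FALSE)
  }
  validate_junction_tbl(out, what = path)
  out
}

#' Read or write a generic junction TSV
#'
#' The generic interchange format is a header line
#' `chrom start end strand unique_reads` (tab-separated) followed by one row
#' per junction, with 1-based closed intron coordinates.
#'
#' @param path File path.
#' @return `read_junction_tsv()` returns a junction tibble.
#' @export
read_junction_tsv <- function(path) {
  out <- readr::read_tsv(path,
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), strand = readr::col_character(),
      unique_reads = readr::col_integer()
    ),
    progress = FALSE
  )
  validate_junction_tbl(out, what = path)
  out
}

#' @rdname read_junction_tsv
#' @param junctions A junction tibble (`chrom`, `start`, `end`, `strand`,
#'   `unique_reads`).
#' @export
write_junction_tsv <- function(junctions, path) {
  validate_junction_tbl(junctions)
  readr::write_tsv(junctions[, c("chrom", "start", "end", "strand", "unique_reads")], path)
  invisible(path)
}

#' Read a sample manifest
#'
#' A manifest is a TSV with header `sample_id path depth_millions`, one row
#' per control sample: the junction file (STAR `SJ.out.tab` or generic
#' junction TSV, auto-detected) and the sample's total uniquely-mapping read
#' count in millions. Depth is supplied, not inferred, because junction
#' counts alone cannot recover a run's total depth.
#'
#' @param path Manifest path.
#' @param base_dir Directory against which relative junction paths are
#'   resolved; defaults to the manifest's directory.
#' @return Tibble `sample_id`, `depth_millions`, and list-column `junctions`
#'   of junction tibbles, ready for [assemble_reference_set()].
#' @export
read_sample_manifest <- function(path, base_dir = dirname(path)) {
  man <- readr::read_tsv(path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      path = readr::col_character(),
      depth_millions = readr::col_double()
    ),
    progress = FALSE
  )
  if (any(is.na(man$depth_millions)) || any(man$depth_millions <= 0)) {
    stop("manifest: depth_millions must be positive", call. = FALSE)
  }
  files <- ifelse(file.exists(man$path), man$path, file.path(base_dir, man$path))
  man$junctions <- purrr::map(files, read_junction_file)
  man[, c("sample_id", "depth_millions", "junctions")]
}

# Auto-detect STAR vs generic format from the first line.
read_junction_file <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) return(empty_junction_tbl())
  if (grepl("^chrom\t", first)) read_junction_tsv(path) else read_star_sj(path)
}
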