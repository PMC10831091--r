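## Insert-length QC. FFPE-derived sequencing templates are
## characteristically shorter than fresh-frozen ones (formaldehyde
## fragments the DNA), so the insert-size distribution of an alignment is
## a cheap fixation fingerprint.

## SAM flag bits used by the read filter.
FLAG_PROPER_PAIR <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_SECONDARY <- 0x100L
FLAG_DUPLICATE <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

#' Insert-length summary of an alignment
#'
#' Computes the insert (template) length distribution from aligned reads,
#' keeping only reads that are properly mapped in a pair, not duplicates,
#' not secondary, not supplementary, and have mapping quality strictly
#' greater than 20. Each template is counted once, via the mate with
#' positive template length (TLEN), so a pair contributes a single insert.
#'
#' @param alignments either a path to a BAM or SAM file, or a data.frame
#'   with integer columns `flag`, `mapq`, `isize` (one row per read).
#' @param mapq_min reads must have mapping quality strictly greater than
#'   this value (default 20).
#' @return A list of class `insert_length_summary` with elements
#'   `lengths` (integer vector of insert sizes), `median` (`NA` when no
#'   read qualifies), `n_reads_used`, and `n_reads_excluded`.
#' @export
compute_insert_lengths <- function(alignments, mapq_min = 20) {
  if (is.character(alignments)) {
    reads <- read_alignment_fields(alignments)
  } else if (is.data.frame(alignments)) {
    stopifnot(all(c("flag", "mapq", "isize") %in% names(alignments)))
    reads <- alignments
  } else {
    stop("alignments must be a BAM/SAM path or a data.frame")
  }
  flag <- as.integer(reads$flag)
  mapq <- as.integer(reads$mapq)
  isize <- as.integer(reads$isize)
  ok <- bitwAnd(flag, FLAG_PROPER_PAIR) != 0L &
    bitwAnd(flag, FLAG_UNMAPPED) == 0L &
    bitwAnd(flag, FLAG_DUPLICATE) == 0L &
    bitwAnd(flag, FLAG_SECONDARY) == 0L &
    bitwAnd(flag, FLAG_SUPPLEMENTARY) == 0L &
    !is.na(mapq) & mapq > mapq_min
  ## one insert per template: the mate reporting the positive TLEN
  use <- ok & !is.na(isize) & isize > 0L
  lengths <- isize[use]
  structure(
    list(
      lengths = lengths,
      median = if (length(lengths) > 0) stats::median(lengths) else NA_real_,
      n_reads_used = length(lengths),
      n_reads_excluded = length(flag) - length(lengths)
    ),
    class = "insert_length_summary"
  )
}

#' @export
print.insert_length_summary <- function(x, ...) {
  cat("Insert-length summary:", x$n_reads_used, "templates used,",
      x$n_reads_excluded, "reads excluded; median =",
      ifelse(is.na(x$median), "undefined", x$median), "bp\n")
  invisible(x)
}

## Internal: pull flag/mapq/isize for every read via Rsamtools. SAM input
## is converted to BAM on the fly.
read_alignment_fields <- function(path) {
  if (!file.exists(path)) stop("cannot read alignment file: ", path)
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    bam <- Rsamtools::asBam(path, destination = tempfile(), indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(what = c("flag", "mapq", "isize"))
  )[[1]]
  data.frame(flag = res$flag, mapq = res$mapq, isize = res$isize)
}
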