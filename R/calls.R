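#' ffpesieve: classify FFPE-induced artifacts in somatic variant calls
#'
#' Formalin fixation fragments DNA and deaminates cytosine, so variant
#' calling on FFPE tumour material yields large numbers of artifactual
#' low-frequency C:G>T:A calls on top of the real somatic mutations.
#' This package labels FFPE calls against a matched fresh-frozen (FF)
#' call set, derives 41 numeric predictors per called allele from
#' MuTect2 annotations, and trains a small feed-forward network to
#' score each call with a probability of being a true variant.
#'
#' @keywords internal
"_PACKAGE"

## Canonical column layout of a variant-call table. One row per called
## alternate allele; multi-allelic VCF records are split upstream.
CALL_COLUMNS <- c(
  "chrom", "pos", "ref", "alt",
  "depth", "ad_ref", "ad_alt",
  "f1r2_ref", "f1r2_alt", "f2r1_ref", "f2r1_alt",
  "mbq_ref", "mbq_alt", "mmq_ref", "mmq_alt",
  "mfrl_ref", "mfrl_alt", "mpos", "tlod", "ecnt",
  "popaf", "germq", "seqq", "strandq", "roq",
  "filter_status"
)

LABEL_TRUE <- "TRUE_VARIANT"
LABEL_ARTIFACT <- "FFPE_ARTIFACT"

#' Variant-call label constants
#'
#' The two-class vocabulary used throughout the package: calls present in
#' both the FFPE and matched FF call sets are `"TRUE_VARIANT"` (positive
#' class); calls private to the FFPE sample are `"FFPE_ARTIFACT"`.
#'
#' @return A character vector of length 2, `c(TRUE_VARIANT, FFPE_ARTIFACT)`.
#' @export
variant_labels <- function() c(LABEL_TRUE, LABEL_ARTIFACT)

#' Construct a variant-call table
#'
#' Builds the canonical per-allele call table used by every other module.
#' Annotation arguments that MuTect2 did not emit are left `NA` (an
#' explicit missing sentinel -- never silently zero); imputation is the
#' feature module's job.
#'
#' @param chrom,pos,ref,alt variant key components; `pos` is 1-based.
#' @param depth total read depth (`DP`).
#' @param ad_ref,ad_alt allele depths for the reference and this alternate
#'   allele.
#' @param f1r2_ref,f1r2_alt,f2r1_ref,f2r1_alt read-orientation counts.
#' @param mbq_ref,mbq_alt median base qualities.
#' @param mmq_ref,mmq_alt median mapping qualities.
#' @param mfrl_ref,mfrl_alt median fragment lengths.
#' @param mpos median position of the alternate allele within reads.
#' @param tlod tumour log-odds.
#' @param ecnt number of events in the haplotype.
#' @param popaf population allele-frequency annotation (negative log10).
#' @param germq,seqq,strandq,roq site-level Phred-scaled qualities.
#' @param filter_status VCF FILTER string; `"PASS"` or `"."` mean pass.
#' @return A `data.frame` with one row per call and the columns listed in
#'   [call_columns()].
#' @export
variant_calls <- function(chrom, pos, ref, alt,
                          depth = NA_integer_,
                          ad_ref = NA_integer_, ad_alt = NA_integer_,
                          f1r2_ref = NA_integer_, f1r2_alt = NA_integer_,
                          f2r1_ref = NA_integer_, f2r1_alt = NA_integer_,
                          mbq_ref = NA_real_, mbq_alt = NA_real_,
                          mmq_ref = NA_real_, mmq_alt = NA_real_,
                          mfrl_ref = NA_real_, mfrl_alt = NA_real_,
                          mpos = NA_real_, tlod = NA_real_,
                          ecnt = NA_real_, popaf = NA_real_,
                          germq = NA_real_, seqq = NA_real_,
                          strandq = NA_real_, roq = NA_real_,
                          filter_status = "PASS") {
  n <- length(chrom)
  rl <- function(x) if (length(x) == 1L && n != 1L) rep(x, n) else x
  for (nm in setdiff(names(formals()), c("chrom", "pos", "ref", "alt"))) {
    assign(nm, rl(get(nm)))
  }
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    depth = as.integer(depth),
    ad_ref = as.integer(ad_ref), ad_alt = as.integer(ad_alt),
    f1r2_ref = as.integer(f1r2_ref), f1r2_alt = as.integer(f1r2_alt),
    f2r1_ref = as.integer(f2r1_ref), f2r1_alt = as.integer(f2r1_alt),
    mbq_ref = as.numeric(mbq_ref), mbq_alt = as.numeric(mbq_alt),
    mmq_ref = as.numeric(mmq_ref), mmq_alt = as.numeric(mmq_alt),
    mfrl_ref = as.numeric(mfrl_ref), mfrl_alt = as.numeric(mfrl_alt),
    mpos = as.numeric(mpos), tlod = as.numeric(tlod),
    ecnt = as.numeric(ecnt), popaf = as.numeric(popaf),
    germq = as.numeric(germq), seqq = as.numeric(seqq),
    strandq = as.numeric(strandq), roq = as.numeric(roq),
    filter_status = as.character(filter_status),
    stringsAsFactors = FALSE
  )
  validate_calls(df)
  df
}

#' Column names of a variant-call table
#' @return Character vector of the canonical call-table columns.
#' @export
call_columns <- function() CALL_COLUMNS

#' Variant keys
#'
#' The identity of a call is the full tuple (chrom, pos, ref, alt): a
#' different alternate allele at a shared site is a different variant.
#' Keys are plain strings so they can be used for set operations.
#'
#' @param calls a variant-call table (or any data.frame with `chrom`,
#'   `pos`, `ref`, `alt` columns).
#' @return Character vector `"chrom:pos:ref:alt"`, one per row.
#' @export
variant_key <- function(calls) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(calls)))
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Validate a variant-call table
#'
#' Checks the structural invariants of the call table: required columns,
#' positive 1-based positions, non-empty ACGT alleles with ref != alt, and
#' non-negative counts. Allele-depth sums exceeding `DP` are reported with
#' a warning (some caller edge cases emit them) but recorded verbatim.
#'
#' @param calls candidate call table.
#' @return `calls`, invisibly; stops on violation.
#' @export
validate_calls <- function(calls) {
  if (!is.data.frame(calls)) stop("calls must be a data.frame")
  missing_cols <- setdiff(CALL_COLUMNS, names(calls))
  if (length(missing_cols) > 0) {
    stop("call table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(calls) == 0) return(invisible(calls))
  if (any(is.na(calls$pos)) || any(calls$pos < 1)) {
    stop("pos must be >= 1 (1-based coordinates)")
  }
  alleles_ok <- grepl("^[ACGT]+$", calls$ref) & grepl("^[ACGT]+$", calls$alt)
  if (!all(alleles_ok)) {
    stop("ref and alt must be non-empty uppercase A/C/G/T strings")
  }
  if (any(calls$ref == calls$alt)) stop("ref must differ from alt")
  count_cols <- c("depth", "ad_ref", "ad_alt",
                  "f1r2_ref", "f1r2_alt", "f2r1_ref", "f2r1_alt")
  for (cc in count_cols) {
    v <- calls[[cc]]
    if (any(!is.na(v) & v < 0)) stop(cc, " contains negative counts")
  }
  ad_sum <- calls$ad_ref + calls$ad_alt
  bad <- !is.na(ad_sum) & !is.na(calls$depth) & ad_sum > calls$depth
  if (any(bad)) {
    warning(sum(bad), " call(s) with ad_ref + ad_alt > DP; recorded verbatim")
  }
  invisible(calls)
}

## Internal: error on duplicate variant keys within one call set.
check_unique_keys <- function(calls, what = "call set") {
  k <- variant_key(calls)
  if (anyDuplicated(k)) {
    dup <- unique(k[duplicated(k)])
    stop("duplicate variant keys in ", what, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  invisible(k)
}

## Internal: TRUE when a FILTER string means pass (PASS literal, ".", or
## the empty set of filter labels).
is_pass_filter <- function(filter_status) {
  fs <- trimws(ifelse(is.na(filter_status), ".", filter_status))
  fs == "PASS" | fs == "." | fs == ""
}
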