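## MuTect2-dialect VCF input/output.
##
## Reading goes through vcfR; per-allele slot assignment (VCF Number=A/R
## conventions) and multi-allelic splitting are done here because the
## classifier operates per alternate allele. Coordinates are VCF-native
## 1-based; no normalisation or left-alignment is applied -- matched FF
## and FFPE samples are assumed to come from the identical calling
## pipeline, so allele representations agree.

## INFO keys carried by the dialect, with their VCF Number class.
MUTECT_INFO_SCALAR <- c("DP", "ECNT", "GERMQ", "ROQ", "SEQQ", "STRANDQ")
MUTECT_INFO_R <- c("MBQ", "MMQ", "MFRL")     # ref slot + one per alt
MUTECT_INFO_A <- c("MPOS", "POPAF", "TLOD")  # one per alt

## INFO key used to carry the classifier probability on output.
PROB_INFO_KEY <- "TVP"
ARTIFACT_FILTER_LABEL <- "ffpe_artifact"

## Internal: numeric conversion that treats "." as missing and flags
## genuinely non-numeric annotation text instead of coercing silently.
parse_numeric <- function(x, what) {
  x <- ifelse(is.na(x) | x == "." | x == "", NA_character_, x)
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("non-numeric ", what, " annotation: '", x[which(bad)[1]], "'")
  }
  out
}

## Internal: split comma lists into a list of numeric vectors.
split_numeric <- function(x, what) {
  lapply(strsplit(ifelse(is.na(x), ".", x), ",", fixed = TRUE),
         parse_numeric, what = what)
}

nth_or_na <- function(lst, i, j) {
  v <- lst[[i]]
  if (length(v) >= j) v[j] else NA_real_
}

#' Read a MuTect2-dialect VCF into a variant-call table
#'
#' Parses a VCF 4.2 file produced by MuTect2 (or emitted by this package)
#' and returns one row per (record, alternate allele) pair. Per-allele
#' INFO and FORMAT annotations follow VCF `Number=A`/`Number=R`
#' conventions: the allele's own slot is taken when a record is
#' multi-allelic. Missing annotations become `NA`, never 0.
#'
#' @param path path to an existing VCF file (plain or gzipped).
#' @param pass_only if `TRUE`, keep only records whose FILTER field is
#'   `PASS` or `.` (unfiltered pass per the VCF specification).
#' @param sample name of the sample column to read FORMAT fields from;
#'   `NULL` (default) takes the first sample column.
#' @param strict if `TRUE`, a record missing any of `DP`, `AD`, `F1R2`,
#'   `F2R1` raises a parse error naming the record instead of yielding
#'   `NA` annotations.
#' @return A variant-call table (see [variant_calls()]). When the file
#'   carries the classifier probability annotation (`TVP`), an extra
#'   `tvp` column is returned.
#' @export
read_mutect_vcf <- function(path, pass_only = TRUE, sample = NULL,
                            strict = FALSE) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n <- nrow(fix)
  if (is.null(n) || n == 0) {
    return(variant_calls(character(0), integer(0), character(0), character(0)))
  }

  filt <- as.character(fix[, "FILTER"])
  keep <- if (pass_only) is_pass_filter(filt) else rep(TRUE, n)

  info_get <- function(key) as.character(vcfR::extract.info(vcf, element = key))
  gt_get <- function(key) {
    if (ncol(vcf@gt) < 2) return(rep(NA_character_, n))
    m <- vcfR::extract.gt(vcf, element = key)
    samples <- colnames(m)
    col <- if (is.null(sample)) 1L else match(sample, samples)
    if (is.na(col)) stop("sample '", sample, "' not found in VCF (have: ",
                         paste(samples, collapse = ", "), ")")
    as.character(m[, col])
  }

  info <- list()
  for (key in MUTECT_INFO_SCALAR) info[[key]] <- parse_numeric(info_get(key), key)
  for (key in c(MUTECT_INFO_R, MUTECT_INFO_A)) {
    info[[key]] <- split_numeric(info_get(key), key)
  }
  ad <- split_numeric(gt_get("AD"), "AD")
  f1r2 <- split_numeric(gt_get("F1R2"), "F1R2")
  f2r1 <- split_numeric(gt_get("F2R1"), "F2R1")
  fmt_dp <- parse_numeric(gt_get("DP"), "DP")
  has_tvp <- any(grepl(paste0("##INFO=<ID=", PROB_INFO_KEY, ","), vcf@meta,
                       fixed = TRUE))
  tvp <- if (has_tvp) parse_numeric(info_get(PROB_INFO_KEY), PROB_INFO_KEY)
         else NULL

  if (strict) {
    miss_scalar <- is.na(info$DP) & is.na(fmt_dp)
    miss_list <- vapply(seq_len(n), function(i) {
      all(is.na(ad[[i]])) || all(is.na(f1r2[[i]])) || all(is.na(f2r1[[i]]))
    }, logical(1))
    bad <- which(keep & (miss_scalar | miss_list))
    if (length(bad) > 0) {
      i <- bad[1]
      stop("record ", fix[i, "CHROM"], ":", fix[i, "POS"],
           " is missing a required key (DP/AD/F1R2/F2R1)")
    }
  }

  rows <- vector("list", n)
  for (i in which(keep)) {
    alts <- strsplit(as.character(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    dp_i <- if (!is.na(fmt_dp[i])) fmt_dp[i] else info$DP[i]
    per_alt <- lapply(seq_along(alts), function(j) {
      data.frame(
        chrom = as.character(fix[i, "CHROM"]),
        pos = as.integer(as.numeric(fix[i, "POS"])),
        ref = as.character(fix[i, "REF"]),
        alt = alts[j],
        depth = as.integer(dp_i),
        ad_ref = as.integer(nth_or_na(ad, i, 1)),
        ad_alt = as.integer(nth_or_na(ad, i, 1 + j)),
        f1r2_ref = as.integer(nth_or_na(f1r2, i, 1)),
        f1r2_alt = as.integer(nth_or_na(f1r2, i, 1 + j)),
        f2r1_ref = as.integer(nth_or_na(f2r1, i, 1)),
        f2r1_alt = as.integer(nth_or_na(f2r1, i, 1 + j)),
        mbq_ref = nth_or_na(info$MBQ, i, 1),
        mbq_alt = nth_or_na(info$MBQ, i, 1 + j),
        mmq_ref = nth_or_na(info$MMQ, i, 1),
        mmq_alt = nth_or_na(info$MMQ, i, 1 + j),
        mfrl_ref = nth_or_na(info$MFRL, i, 1),
        mfrl_alt = nth_or_na(info$MFRL, i, 1 + j),
        mpos = nth_or_na(info$MPOS, i, j),
        tlod = nth_or_na(info$TLOD, i, j),
        ecnt = info$ECNT[i],
        popaf = nth_or_na(info$POPAF, i, j),
        germq = info$GERMQ[i],
        seqq = info$SEQQ[i],
        strandq = info$STRANDQ[i],
        roq = info$ROQ[i],
        filter_status = filt[i],
        stringsAsFactors = FALSE
      )
    })
    block <- do.call(rbind, per_alt)
    if (!is.null(tvp)) block$tvp <- tvp[i]
    rows[[i]] <- block
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- variant_calls(character(0), integer(0), character(0), character(0))
    if (!is.null(tvp)) out$tvp <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_calls(out)
  out
}

## Internal: render one numeric annotation value for VCF text output.
fmt_vcf_num <- function(x) {
  ifelse(is.na(x), ".",
         ifelse(abs(x - round(x)) < 1e-9, sprintf("%d", as.integer(round(x))),
                sub("0+$", "", sprintf("%.4f", x))))
}

## Internal: build MuTect2-dialect VCF lines for a call table (one VCF
## record per row; multi-allelic records are not re-merged on output).
## `extra_info` is an optional character vector of per-row INFO fragments,
## `filter_override` an optional per-row FILTER column.
format_mutect_vcf <- function(calls, sample_id = "TUMOR",
                              extra_info = NULL, filter_override = NULL,
                              extra_header = character(0)) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ffpesieve",
    "##FILTER=<ID=PASS,Description=\"Site passes all filters\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Approximate read depth\">",
    "##INFO=<ID=ECNT,Number=1,Type=Integer,Description=\"Number of events in this haplotype\">",
    "##INFO=<ID=GERMQ,Number=1,Type=Integer,Description=\"Phred-scaled quality that alt alleles are not germline variants\">",
    "##INFO=<ID=MBQ,Number=R,Type=Integer,Description=\"median base quality by allele\">",
    "##INFO=<ID=MFRL,Number=R,Type=Integer,Description=\"median fragment length by allele\">",
    "##INFO=<ID=MMQ,Number=R,Type=Integer,Description=\"median mapping quality by allele\">",
    "##INFO=<ID=MPOS,Number=A,Type=Integer,Description=\"median distance from end of read\">",
    "##INFO=<ID=POPAF,Number=A,Type=Float,Description=\"negative log 10 population allele frequencies of alt alleles\">",
    "##INFO=<ID=ROQ,Number=1,Type=Float,Description=\"Phred-scaled qualities that alt allele are not due to read orientation artifact\">",
    "##INFO=<ID=SEQQ,Number=1,Type=Integer,Description=\"Phred-scaled quality that alt alleles are not sequencing errors\">",
    "##INFO=<ID=STRANDQ,Number=1,Type=Integer,Description=\"Phred-scaled quality of strand bias artifact\">",
    "##INFO=<ID=TLOD,Number=A,Type=Float,Description=\"Log 10 likelihood ratio score of variant existing versus not existing\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fractions of alternate alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Approximate read depth\">",
    "##FORMAT=<ID=F1R2,Number=R,Type=Integer,Description=\"Count of reads in F1R2 pair orientation supporting each allele\">",
    "##FORMAT=<ID=F2R1,Number=R,Type=Integer,Description=\"Count of reads in F2R1 pair orientation supporting each allele\">",
    extra_header,
    paste0("##tumor_sample=", sample_id),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  if (nrow(calls) == 0) return(header)

  info_field <- function(key, value) {
    v <- fmt_vcf_num(value)
    ifelse(v == ".", NA_character_, paste0(key, "=", v))
  }
  pair_field <- function(key, ref_v, alt_v) {
    ifelse(is.na(ref_v) | is.na(alt_v), NA_character_,
           paste0(key, "=", fmt_vcf_num(ref_v), ",", fmt_vcf_num(alt_v)))
  }
  parts <- cbind(
    info_field("DP", calls$depth),
    info_field("ECNT", calls$ecnt),
    info_field("GERMQ", calls$germq),
    pair_field("MBQ", calls$mbq_ref, calls$mbq_alt),
    pair_field("MFRL", calls$mfrl_ref, calls$mfrl_alt),
    pair_field("MMQ", calls$mmq_ref, calls$mmq_alt),
    info_field("MPOS", calls$mpos),
    info_field("POPAF", calls$popaf),
    info_field("ROQ", calls$roq),
    info_field("SEQQ", calls$seqq),
    info_field("STRANDQ", calls$strandq),
    info_field("TLOD", calls$tlod)
  )
  if (!is.null(extra_info)) parts <- cbind(parts, extra_info)
  info <- apply(parts, 1, function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0) "." else paste(p, collapse = ";")
  })

  af <- calls$ad_alt / pmax(calls$ad_ref + calls$ad_alt, 1L)
  fmt <- paste(
    "0/1",
    paste0(calls$ad_ref, ",", calls$ad_alt),
    sprintf("%.4f", af),
    calls$depth,
    paste0(calls$f1r2_ref, ",", calls$f1r2_alt),
    paste0(calls$f2r1_ref, ",", calls$f2r1_alt),
    sep = ":"
  )
  filt <- if (is.null(filter_override)) {
    ifelse(is_pass_filter(calls$filter_status), "PASS", calls$filter_status)
  } else filter_override
  body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                filt, info, "GT:AD:AF:DP:F1R2:F2R1", fmt, sep = "\t")
  c(header, body)
}

#' Write classifier-annotated calls to a VCF
#'
#' Emits a MuTect2-dialect VCF preserving the input calls, with the
#' classifier's true-variant probability in the `TVP` INFO field (three
#' decimals) and the filter label `ffpe_artifact` applied to calls whose
#' probability falls below the decision threshold.
#'
#' @param calls variant-call table.
#' @param probabilities numeric vector in `[0, 1]`, one per call.
#' @param threshold decision threshold in `(0, 1)`; calls with
#'   `probability >= threshold` keep their original filter status.
#' @param path output file path (written atomically).
#' @param sample_id sample column name for the output.
#' @return `path`, invisibly.
#' @export
write_classified_vcf <- function(calls, probabilities, threshold = 0.5,
                                 path, sample_id = "TUMOR") {
  validate_calls(calls)
  if (length(probabilities) != nrow(calls)) {
    stop("length(probabilities) must equal nrow(calls)")
  }
  if (any(is.na(probabilities)) ||
      any(probabilities < 0) || any(probabilities > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  keep <- probabilities >= threshold
  orig <- ifelse(is_pass_filter(calls$filter_status), "PASS",
                 calls$filter_status)
  filt <- ifelse(keep, orig,
                 ifelse(orig == "PASS", ARTIFACT_FILTER_LABEL,
                        paste(orig, ARTIFACT_FILTER_LABEL, sep = ";")))
  lines <- format_mutect_vcf(
    calls, sample_id = sample_id,
    extra_info = sprintf("%s=%.3f", PROB_INFO_KEY, probabilities),
    filter_override = filt,
    extra_header = c(
      paste0("##FILTER=<ID=", ARTIFACT_FILTER_LABEL,
             ",Description=\"Classified as an FFPE-induced artifact\">"),
      paste0("##INFO=<ID=", PROB_INFO_KEY, ",Number=1,Type=Float,",
             "Description=\"Classifier probability of being a true variant\">")
    )
  )
  write_lines_atomic(lines, path)
  invisible(path)
}

## Internal: atomic text write (write-then-rename in the target directory).
write_lines_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  con <- file(tmp, open = "wb")  # fixed '\n' endings => reproducible bytes
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, sep = "\n")
  close(con)
  on.exit(NULL)
  if (!file.rename(tmp, path)) stop("cannot move output into place: ", path)
  invisible(path)
}
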