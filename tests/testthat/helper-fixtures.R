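# Fixtures shared across test files. Everything is built in code at test
# time; nothing binary is stored.

# One fully-annotated call row with overridable fields.
make_call <- function(...) {
  defaults <- list(chrom = "chr1", pos = 100L, ref = "C", alt = "T",
                   depth = 100L, ad_ref = 90L, ad_alt = 10L,
                   f1r2_ref = 45L, f1r2_alt = 5L,
                   f2r1_ref = 45L, f2r1_alt = 5L,
                   mbq_ref = 32, mbq_alt = 30, mmq_ref = 60, mmq_alt = 60,
                   mfrl_ref = 180, mfrl_alt = 170, mpos = 35, tlod = 20.5,
                   ecnt = 1, popaf = 4.6, germq = 93, seqq = 93,
                   strandq = 93, roq = 80)
  do.call(variant_calls, utils::modifyList(defaults, list(...)))
}

# Calls with distinct keys at consecutive positions.
make_calls <- function(n, chrom = "chr1", start = 1000L, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_call(chrom = chrom, pos = start + i, ...)
  }))
}

vcf_header_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##FILTER=<ID=weak_evidence,Description=\"weak\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##INFO=<ID=ECNT,Number=1,Type=Integer,Description=\"events\">",
    "##INFO=<ID=GERMQ,Number=1,Type=Integer,Description=\"germq\">",
    "##INFO=<ID=MBQ,Number=R,Type=Integer,Description=\"mbq\">",
    "##INFO=<ID=MFRL,Number=R,Type=Integer,Description=\"mfrl\">",
    "##INFO=<ID=MMQ,Number=R,Type=Integer,Description=\"mmq\">",
    "##INFO=<ID=MPOS,Number=A,Type=Integer,Description=\"mpos\">",
    "##INFO=<ID=POPAF,Number=A,Type=Float,Description=\"popaf\">",
    "##INFO=<ID=ROQ,Number=1,Type=Float,Description=\"roq\">",
    "##INFO=<ID=SEQQ,Number=1,Type=Integer,Description=\"seqq\">",
    "##INFO=<ID=STRANDQ,Number=1,Type=Integer,Description=\"strandq\">",
    "##INFO=<ID=TLOD,Number=A,Type=Float,Description=\"tlod\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"af\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=F1R2,Number=R,Type=Integer,Description=\"f1r2\">",
    "##FORMAT=<ID=F2R1,Number=R,Type=Integer,Description=\"f2r1\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", sep = "\t"))
}

# Three single-allele records, the second filtered as weak_evidence.
write_fixture_vcf <- function(path = tempfile(fileext = ".vcf")) {
  body <- c(
    paste("chr1", 1001, ".", "C", "T", ".", "PASS",
          "DP=100;ECNT=1;GERMQ=93;MBQ=32,30;MFRL=180,165;MMQ=60,60;MPOS=33;POPAF=4.61;ROQ=80;SEQQ=93;STRANDQ=93;TLOD=21.5",
          "GT:AD:AF:DP:F1R2:F2R1", "0/1:90,10:0.1000:100:45,8:45,2",
          sep = "\t"),
    paste("chr1", 2002, ".", "G", "A", ".", "weak_evidence",
          "DP=80;ECNT=1;GERMQ=93;MBQ=31,28;MFRL=175,150;MMQ=60,60;MPOS=12;POPAF=5.2;ROQ=40;SEQQ=93;STRANDQ=93;TLOD=6.1",
          "GT:AD:AF:DP:F1R2:F2R1", "0/1:76,4:0.0500:80:38,4:38,0",
          sep = "\t"),
    paste("chr2", 3003, ".", "A", "AT", ".", "PASS",
          "DP=60;ECNT=2;GERMQ=93;MBQ=30,29;MFRL=182,170;MMQ=60,58;MPOS=41;POPAF=3.9;ROQ=75;SEQQ=93;STRANDQ=93;TLOD=15.2",
          "GT:AD:AF:DP:F1R2:F2R1", "0/1:42,18:0.3000:60:20,9:22,9",
          sep = "\t"))
  writeLines(c(vcf_header_lines(), body), path)
  path
}

# One bi-allelic record (ALT=A,T) with per-allele annotation slots.
write_multiallelic_vcf <- function(path = tempfile(fileext = ".vcf")) {
  body <- paste(
    "chr3", 500, ".", "C", "A,T", ".", "PASS",
    "DP=120;ECNT=1;GERMQ=93;MBQ=33,30,28;MFRL=181,170,160;MMQ=60,60,55;MPOS=30,22;POPAF=4.0,5.1;ROQ=70;SEQQ=93;STRANDQ=93;TLOD=12.5,8.25",
    "GT:AD:AF:DP:F1R2:F2R1", "0/1/2:100,12,8:0.1000,0.0667:120:52,7,1:48,5,7",
    sep = "\t")
  writeLines(c(vcf_header_lines(), body), path)
  path
}

# Header-only VCF.
write_empty_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(vcf_header_lines(), path)
  path
}

# Minimal coordinate-sorted SAM exercising every read-filter clause.
write_fixture_sam <- function(path = tempfile(fileext = ".sam")) {
  seq10 <- "ACGTACGTAC"
  q10 <- "IIIIIIIIII"
  rows <- c(
    paste("@HD", "VN:1.6", "SO:coordinate", sep = "\t"),
    paste("@SQ", "SN:chr1", "LN:10000", sep = "\t"),
    # proper pair, MQ 60, insert 147 (counted once via the positive TLEN)
    paste("r1", 99, "chr1", 100, 60, "10M", "=", 237, 147, seq10, q10, sep = "\t"),
    paste("r1", 147, "chr1", 237, 60, "10M", "=", 100, -147, seq10, q10, sep = "\t"),
    # proper pair but MQ exactly 20: excluded (strict inequality)
    paste("r2", 99, "chr1", 300, 20, "10M", "=", 500, 210, seq10, q10, sep = "\t"),
    # duplicate: excluded regardless of MQ
    paste("r3", 1123, "chr1", 400, 60, "10M", "=", 700, 310, seq10, q10, sep = "\t"),
    # supplementary: excluded
    paste("r4", 2147, "chr1", 600, 60, "10M", "=", 1000, 410, seq10, q10, sep = "\t")
  )
  writeLines(rows, path)
  path
}

# External benchmark fixture: published confusion counts and reported
# three-decimal metrics for four FFPE artifact filters (a MuTect
# orientation-bias filter, FFPolish, SOBDetector, and a neural
# classifier) across evaluation strata. Used to test the metric
# formulas; none of these tools is re-implemented here.
benchmark_table <- function() {
  rows <- list(
    # tool, stratum, tp, tn, fp, fn, spec, sens, prec, f1, acc
    list("mutect_filter", "All", 401, 11204, 16306, 13, 0.407, 0.969, 0.024, 0.047, 0.416),
    list("mutect_filter", "Fibrosarcoma", 43, 0, 41, 0, 0.000, 1.000, 0.512, 0.677, 0.512),
    list("mutect_filter", "Lung cancer", 138, 124, 917, 2, 0.119, 0.986, 0.131, 0.231, 0.222),
    list("mutect_filter", "Liver cancer", 7, 0, 97, 0, 0.000, 1.000, 0.067, 0.126, 0.067),
    list("mutect_filter", "Colon cancer", 17, 0, 53, 0, 0.000, 1.000, 0.243, 0.391, 0.243),
    list("mutect_filter", "Breast cancer", 196, 11080, 15198, 11, 0.422, 0.947, 0.013, 0.025, 0.426),
    list("mutect_filter", "G:C>T:A", 47, 0, 1062, 0, 0.000, 1.000, 0.042, 0.081, 0.042),
    list("mutect_filter", "C:G>T:A", 142, 11204, 11603, 13, 0.491, 0.916, 0.012, 0.024, 0.494),
    list("mutect_filter", "Low MAF variants", 4, 110, 1360, 0, 0.075, 1.000, 0.003, 0.006, 0.077),
    list("mutect_filter", "A549 WES", 739, 0, 51, 0, 0.000, 1.000, 0.935, 0.967, 0.935),
    list("mutect_filter", "A549 panel", 15, 0, 6, 0, 0.000, 1.000, 0.714, 0.833, 0.714),
    list("ffpolish", "All", 282, 25607, 1903, 132, 0.931, 0.681, 0.129, 0.217, 0.927),
    list("ffpolish", "Fibrosarcoma", 32, 33, 8, 11, 0.805, 0.744, 0.800, 0.771, 0.774),
    list("ffpolish", "Lung cancer", 104, 949, 92, 36, 0.912, 0.743, 0.531, 0.619, 0.892),
    list("ffpolish", "Liver cancer", 0, 87, 10, 7, 0.897, 0.000, 0.000, 0.000, 0.837),
    list("ffpolish", "Colon cancer", 13, 42, 11, 4, 0.792, 0.765, 0.542, 0.634, 0.786),
    list("ffpolish", "Breast cancer", 133, 24496, 1782, 74, 0.932, 0.643, 0.069, 0.125, 0.930),
    list("ffpolish", "G:C>T:A", 41, 1028, 34, 6, 0.968, 0.872, 0.547, 0.672, 0.964),
    list("ffpolish", "C:G>T:A", 120, 21012, 1795, 35, 0.921, 0.774, 0.063, 0.116, 0.920),
    list("ffpolish", "Low MAF variants", 0, 1453, 17, 4, 0.988, 0.000, 0.000, 0.000, 0.986),
    list("ffpolish", "A549 WES", 648, 47, 4, 91, 0.922, 0.877, 0.994, 0.932, 0.880),
    list("ffpolish", "A549 panel", 13, 6, 0, 2, 1.000, 0.867, 1.000, 0.929, 0.905),
    list("sobdetector", "All", 352, 19852, 7658, 62, 0.722, 0.850, 0.044, 0.084, 0.724),
    list("sobdetector", "Fibrosarcoma", 38, 16, 25, 5, 0.390, 0.884, 0.603, 0.717, 0.643),
    list("sobdetector", "Lung cancer", 125, 585, 456, 15, 0.562, 0.893, 0.215, 0.347, 0.601),
    list("sobdetector", "Liver cancer", 2, 62, 35, 5, 0.639, 0.286, 0.054, 0.091, 0.615),
    list("sobdetector", "Colon cancer", 15, 30, 23, 2, 0.566, 0.882, 0.395, 0.545, 0.643),
    list("sobdetector", "Breast cancer", 172, 19159, 7119, 35, 0.729, 0.831, 0.024, 0.046, 0.730),
    list("sobdetector", "G:C>T:A", 47, 848, 214, 0, 0.798, 1.000, 0.180, 0.305, 0.807),
    list("sobdetector", "C:G>T:A", 143, 15745, 7062, 12, 0.690, 0.923, 0.020, 0.039, 0.692),
    list("sobdetector", "Low MAF variants", 3, 768, 702, 1, 0.522, 0.750, 0.004, 0.008, 0.523),
    list("sobdetector", "A549 WES", 698, 24, 27, 41, 0.471, 0.945, 0.963, 0.954, 0.914),
    list("sobdetector", "A549 panel", 13, 5, 1, 2, 0.833, 0.867, 0.929, 0.897, 0.857),
    list("neural_classifier", "All", 293, 27408, 102, 121, 0.996, 0.708, 0.742, 0.724, 0.992),
    list("neural_classifier", "Fibrosarcoma", 37, 35, 6, 6, 0.854, 0.860, 0.860, 0.860, 0.857),
    list("neural_classifier", "Lung cancer", 110, 996, 45, 30, 0.957, 0.786, 0.710, 0.746, 0.936),
    list("neural_classifier", "Liver cancer", 5, 91, 6, 2, 0.938, 0.714, 0.455, 0.556, 0.923),
    list("neural_classifier", "Colon cancer", 16, 49, 4, 1, 0.925, 0.941, 0.800, 0.865, 0.929),
    list("neural_classifier", "Breast cancer", 125, 26237, 41, 82, 0.998, 0.604, 0.753, 0.670, 0.995),
    list("neural_classifier", "G:C>T:A", 38, 1047, 15, 9, 0.986, 0.809, 0.717, 0.760, 0.978),
    list("neural_classifier", "C:G>T:A", 89, 22786, 21, 66, 0.999, 0.574, 0.809, 0.672, 0.996),
    list("neural_classifier", "Low MAF variants", 1, 1462, 8, 3, 0.995, 0.250, 0.111, 0.154, 0.993),
    list("neural_classifier", "A549 WES", 711, 33, 18, 28, 0.647, 0.962, 0.975, 0.969, 0.942),
    list("neural_classifier", "A549 panel", 15, 6, 0, 0, 1.000, 1.000, 1.000, 1.000, 1.000)
  )
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(tool = r[[1]], stratum = r[[2]], tp = r[[3]], tn = r[[4]],
               fp = r[[5]], fn = r[[6]], specificity = r[[7]],
               sensitivity = r[[8]], precision = r[[9]], f1 = r[[10]],
               accuracy = r[[11]], stringsAsFactors = FALSE)
  }))
  df
}

# Exhaustive F1 maximisation oracle: sorts calls by score and evaluates
# every achievable decision set (ties grouped), independent of
# sweep_threshold's candidate construction.
brute_force_best_f1 <- function(probabilities, truth) {
  u <- sort(unique(c(probabilities, 0, 1, 2)))  # 2 => empty positive set
  best <- 0
  for (th in u) {
    pos <- probabilities >= th
    tp <- sum(pos & truth == "TRUE_VARIANT")
    fp <- sum(pos & truth == "FFPE_ARTIFACT")
    fn <- sum(!pos & truth == "TRUE_VARIANT")
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f1 > best) best <- f1
  }
  best
}

# A 41-wide toy design whose first column carries all the signal.
toy_separable <- function(n = 500, seed = 7) {
  set.seed(seed)
  y <- rep(c(1, 0), length.out = n)
  x <- matrix(stats::rnorm(n * 41, 0, 0.05), n, 41)
  x[, 1] <- ifelse(y == 1, 1, -1) + stats::rnorm(n, 0, 0.1)
  list(x = x, y = y)
}
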