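test_that("PASS filtering keeps only passing records and is a subset", {
  path <- write_fixture_vcf()
  passed <- read_mutect_vcf(path, pass_only = TRUE)
  all_calls <- read_mutect_vcf(path, pass_only = FALSE)
  expect_equal(nrow(passed), 2)
  expect_equal(nrow(all_calls), 3)
  expect_true(all(variant_key(passed) %in% variant_key(all_calls)))
  expect_false("chr1:2002:G:A" %in% variant_key(passed))
  expect_true("chr1:2002:G:A" %in% variant_key(all_calls))
})

test_that("a header-only VCF yields an empty call table", {
  calls <- read_mutect_vcf(write_empty_vcf())
  expect_equal(nrow(calls), 0)
  expect_true(all(call_columns() %in% names(calls)))
})

test_that("per-allele annotations land in the right slots", {
  calls <- read_mutect_vcf(write_fixture_vcf(), pass_only = TRUE)
  first <- calls[calls$pos == 1001, ]
  expect_equal(first$ad_ref, 90)
  expect_equal(first$ad_alt, 10)
  expect_equal(first$f1r2_alt, 8)
  expect_equal(first$f2r1_alt, 2)
  expect_equal(first$mbq_ref, 32)
  expect_equal(first$mbq_alt, 30)
  expect_equal(first$mfrl_alt, 165)
  expect_equal(first$mpos, 33)
  expect_equal(first$tlod, 21.5)
  expect_equal(first$depth, 100)
})

test_that("multi-allelic records split into per-allele calls", {
  calls <- read_mutect_vcf(write_multiallelic_vcf())
  expect_equal(nrow(calls), 2)
  expect_equal(calls$chrom, c("chr3", "chr3"))
  expect_equal(calls$pos, c(500L, 500L))
  expect_equal(calls$ref, c("C", "C"))
  expect_equal(calls$alt, c("A", "T"))
  # shared ref slot, allele-specific alt slots (Number=R)
  expect_equal(calls$ad_ref, c(100L, 100L))
  expect_equal(calls$ad_alt, c(12L, 8L))
  expect_equal(calls$f1r2_alt, c(7L, 1L))
  expect_equal(calls$f2r1_alt, c(5L, 7L))
  expect_equal(calls$mbq_alt, c(30, 28))
  # Number=A slots
  expect_equal(calls$mpos, c(30, 22))
  expect_equal(calls$tlod, c(12.5, 8.25))
  expect_equal(calls$popaf, c(4.0, 5.1))
})

test_that("strict mode names the record missing a required key", {
  path <- tempfile(fileext = ".vcf")
  body <- paste("chr1", 42, ".", "C", "T", ".", "PASS", "ECNT=1",
                "GT", "0/1", sep = "\t")
  writeLines(c(vcf_header_lines(), body), path)
  expect_error(read_mutect_vcf(path, strict = TRUE), "chr1:42")
  expect_silent(calls <- read_mutect_vcf(path, strict = FALSE))
  expect_true(is.na(calls$ad_alt))
})

test_that("non-numeric annotations raise a parse error", {
  path <- tempfile(fileext = ".vcf")
  body <- paste("chr1", 7, ".", "C", "T", ".", "PASS",
                "DP=abc;MBQ=30,30", "GT:AD:F1R2:F2R1",
                "0/1:5,5:3,2:2,3", sep = "\t")
  writeLines(c(vcf_header_lines(), body), path)
  expect_error(read_mutect_vcf(path), "non-numeric")
})

test_that("classified VCF output applies the artifact filter and round-trips", {
  calls <- rbind(make_call(pos = 10L), make_call(pos = 20L, ref = "G", alt = "A"))
  out <- tempfile(fileext = ".vcf")
  write_classified_vcf(calls, c(0.9, 0.1), threshold = 0.5, path = out)
  back_all <- read_mutect_vcf(out, pass_only = FALSE)
  expect_equal(variant_key(back_all), variant_key(calls))
  expect_equal(back_all$filter_status, c("PASS", "ffpe_artifact"))
  expect_equal(back_all$tvp, c(0.9, 0.1))
  # only the above-threshold call survives PASS filtering
  expect_equal(nrow(read_mutect_vcf(out, pass_only = TRUE)), 1)
})

test_that("classified VCF output rejects bad probabilities", {
  calls <- make_call()
  expect_error(write_classified_vcf(calls, c(0.5, 0.5), path = tempfile()),
               "length")
  expect_error(write_classified_vcf(calls, 1.2, path = tempfile(fileext = ".vcf")),
               "\\[0, 1\\]")
})

test_that("read -> write -> read is the identity on keys, counts, filters", {
  orig <- read_mutect_vcf(write_fixture_vcf(), pass_only = FALSE)
  out <- tempfile(fileext = ".vcf")
  writeLines(ffpesieve:::format_mutect_vcf(orig), out)
  back <- read_mutect_vcf(out, pass_only = FALSE)
  for (col in c("chrom", "pos", "ref", "alt", "depth", "ad_ref", "ad_alt",
                "f1r2_ref", "f1r2_alt", "f2r1_ref", "f2r1_alt",
                "filter_status")) {
    expect_equal(back[[col]], orig[[col]], info = col)
  }
})

test_that("insert-length filter honours all five read criteria", {
  reads <- data.frame(
    flag = c(99L, 147L, 99L, 1123L, 2147L, 355L, 0L),
    mapq = c(60L, 60L, 20L, 60L, 60L, 60L, 60L),
    isize = c(147L, -147L, 210L, 310L, 410L, 510L, 0L)
  )
  # row 3: MQ == 20 excluded (strictly greater than 20 required)
  # row 4: duplicate; row 5: supplementary; row 6: secondary
  # row 7: unpaired (no proper-pair bit); row 2: mate of row 1 (TLEN < 0)
  s <- compute_insert_lengths(reads)
  expect_equal(s$lengths, 147L)
  expect_equal(s$median, 147)
  expect_equal(s$n_reads_used, 1)
  expect_equal(s$n_reads_excluded, 6)
})

test_that("insert-length median is permutation invariant and NA when empty", {
  set.seed(1)
  n <- 50
  reads <- data.frame(flag = rep(99L, n), mapq = rep(60L, n),
                      isize = sample(100:400, n, replace = TRUE))
  ref <- compute_insert_lengths(reads)
  shuf <- compute_insert_lengths(reads[sample.int(n), ])
  expect_equal(shuf$median, ref$median)
  empty <- compute_insert_lengths(reads[0, ])
  expect_true(is.na(empty$median))
  expect_equal(empty$n_reads_used, 0)
})

test_that("insert lengths can be computed from a SAM file", {
  s <- compute_insert_lengths(write_fixture_sam())
  expect_equal(s$lengths, 147L)
  expect_equal(s$median, 147)
  expect_equal(s$n_reads_excluded, 4)
})
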