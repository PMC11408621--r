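test_that("VCF ingest converts coordinates, filters and recovers dosages", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "D1", "D2"), collapse = "\t"),
    "chr1\t1001\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "chr1\t2001\trs2\tA\tG,T\t.\tPASS\t.\tGT\t0|0\t0|1",   # multi-allelic
    "chrX\t3001\trs3\tC\tT\t.\tPASS\t.\tGT\t0|0\t0|1",     # non-autosomal
    "chr2\t4001\trs4\tG\tC\t.\tPASS\t.\tGT\t.\t1|1"        # missing call
  ), vcf)
  panel <- read_genotype_vcf(vcf)
  expect_equal(panel$snps$snp_id, c("rs1", "rs4"))
  expect_equal(panel$snps$pos, c(1000L, 4000L))  # 1-based -> 0-based
  expect_equal(unname(panel$dosage["rs1", ]), c(1L, 2L))
  expect_equal(unname(panel$dosage["rs4", ]), c(NA_integer_, 2L))
  skip_log <- attr(panel, "skip_log")
  expect_equal(unname(skip_log[["multi_allelic"]]), 1)
  expect_equal(unname(skip_log[["non_autosomal"]]), 1)
  expect_error(read_genotype_vcf(vcf, donor_subset = c("D1", "NOPE")),
               "absent")
})

test_that("panel VCF write/read round trip recovers the dosage matrix", {
  ds <- tiny_dataset(seed = 5)
  path <- tempfile(fileext = ".vcf")
  write_genotype_vcf(ds$panel, path)
  back <- read_genotype_vcf(path, covariates = ds$panel$covariates)
  expect_setequal(back$snps$snp_id, ds$panel$snps$snp_id)
  expect_equal(back$dosage[rownames(ds$panel$dosage), colnames(ds$panel$dosage)],
               ds$panel$dosage)
  expect_equal(
    back$snps[match(ds$panel$snps$snp_id, back$snps$snp_id), ],
    ds$panel$snps, ignore_attr = TRUE)
})

test_that("loop-table union, anchor swapping and distance filters", {
  d1 <- tempfile(fileext = ".tsv")
  d2 <- tempfile(fileext = ".tsv")
  hdr <- "chr1\ts1\te1\tchr2\ts2\te2\tobs\texp\tsig"
  writeLines(c(hdr,
    "chr1\t10000\t15000\tchr1\t50000\t55000\t8\t4\tTRUE",
    "chr1\t90000\t95000\tchr1\t40000\t45000\t6\t3\tTRUE",  # unsorted anchors
    "chr1\t10000\t15000\tchr1\t15000\t20000\t5\t1\tTRUE"   # distance 5 kb
  ), d1)
  writeLines(c(hdr,
    "chr1\t10000\t15000\tchr1\t50000\t55000\t2\t4\tFALSE"
  ), d2)
  expect_warning(
    profs <- read_loop_table(c(A = d1, B = d2)),
    "unsorted")
  # union: shared loop appears once with both donors' counts; the 5 kb row
  # is excluded; the swapped row is canonicalized
  expect_equal(nrow(profs$loops), 2L)
  expect_equal(unname(profs$observed["chr1:10000-50000", ]), c(8, 2))
  expect_true("chr1:40000-90000" %in% profs$loops$loop_id)
  # donor lacking a union loop: observed 0, significant FALSE
  expect_equal(unname(profs$observed["chr1:40000-90000", "B"]), 0)
  expect_false(profs$significant["chr1:40000-90000", "B"])
})

test_that("loop-table dialect round trip preserves counts and flags", {
  ds <- tiny_dataset(seed = 6)
  path <- tempfile(fileext = ".tsv")
  write_loop_table(ds$profiles, path)
  back <- read_loop_table(path)
  ord <- match(ds$profiles$loops$loop_id, back$loops$loop_id)
  expect_false(anyNA(ord))
  expect_equal(back$observed[ds$profiles$loops$loop_id, ds$profiles$donors],
               ds$profiles$observed, ignore_attr = TRUE)
  expect_equal(back$expected[ds$profiles$loops$loop_id, ds$profiles$donors],
               ds$profiles$expected, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$significant[ds$profiles$loops$loop_id, ds$profiles$donors],
               ds$profiles$significant, ignore_attr = TRUE)
})

test_that("inter-chromosomal and malformed loop rows are rejected", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\ts1\te1\tchr2\ts2\te2\tobs",
               "chr1\t10000\t15000\tchr2\t50000\t55000\t3"), bad)
  expect_error(read_loop_table(c(A = bad)), "inter-chromosomal")
  bad2 <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\ts1\te1\tchr2\ts2\te2\tobs",
               "chr1\t10000\t16000\tchr1\t50000\t55000\t3"), bad2)
  expect_error(read_loop_table(c(A = bad2)), "resolution")
})

test_that("BED intervals follow the 0-based half-open convention", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t150\t250", "chr2\t0\t50"), bed)
  iv <- read_bed_intervals(bed)
  expect_equal(nrow(iv), 3L)          # overlapping intervals kept un-merged
  expect_equal(iv$start[1], 100L)
  expect_equal(iv$end[1], 200L)
  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(nrow(read_bed_intervals(empty)), 0L)
})

test_that("results tables round-trip with stable ordering", {
  recs <- tibble::tibble(
    snp_id = c("rs2", "rs1"), chrom = "chr1",
    b1_start = c(20000L, 10000L), b2_start = c(60000L, 50000L),
    p_geno = c(0.2, 0.01), fdr_def = c(0.3, 0.02),
    accepted = c(FALSE, TRUE), reason = c("fdr_def", NA)
  )
  path <- tempfile(fileext = ".tsv")
  write_results_table(recs, path, kind = "association")
  back <- read_results_table(path)
  expect_equal(back$snp_id, c("rs1", "rs2"))  # sorted by loop then SNP
  expect_equal(back$p_geno, c(0.01, 0.2))
  expect_equal(back$accepted, c(TRUE, FALSE))
  expect_equal(back$reason, c(NA, "fdr_def"))
  # empty input -> header-only file
  write_results_table(recs[0, ], path, kind = "association")
  expect_equal(nrow(read_results_table(path)), 0L)
  expect_equal(length(readLines(path)), 1L)
})
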