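test_that("GT values map to dosage codes and dots code missing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  rec <- data.frame(chrom = "Gm01", pos = c(100, 200, 300, 400),
                    ref = "A", alt = "G")
  write_tiny_vcf(path, rec, gts = matrix(c("0/0", "0/1", "1/1", "./."),
                                         ncol = 1))
  panel <- read_vcf(path)
  expect_equal(unname(panel$geno[1, ]), c(0L, 1L, 2L, -1L))
  # phased separators are equivalent
  write_tiny_vcf(path, rec, gts = matrix(c("0|0", "0|1", "1|1", ".|."),
                                         ncol = 1))
  expect_equal(unname(read_vcf(path)$geno[1, ]), c(0L, 1L, 2L, -1L))
})

test_that("multi-allelic and symbolic records are skipped and tallied", {
  path <- withr::local_tempfile(fileext = ".vcf")
  rec <- data.frame(chrom = "Gm01", pos = c(100, 200, 300, 400, 500),
                    ref = c("A", "C", "G", "T", "A"),
                    alt = c("G", "T,A", "C", "<DEL>", "T"))
  write_tiny_vcf(path, rec, gts = matrix("0/0", 5, 1))
  panel <- read_vcf(path)
  expect_equal(n_sites(panel), 3)
  expect_equal(attr(panel, "n_skipped"), 2L)
})

test_that("region filtering is 1-based inclusive on both ends", {
  path <- withr::local_tempfile(fileext = ".vcf")
  rec <- data.frame(chrom = "Gm05", pos = c(99, 100, 200, 201),
                    ref = "A", alt = "G")
  write_tiny_vcf(path, rec, gts = matrix("0/1", 4, 1))
  panel <- read_vcf(path, region = "Gm05:100-200")
  expect_equal(panel$sites$pos, c(100L, 200L))
  expect_equal(n_sites(read_vcf(path, region = "Gm05")), 4)
  expect_equal(n_sites(read_vcf(path, region = "Gm09")), 0)
})

test_that("VCF without GT format and unreadable files are fatal", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S01"), collapse = "\t"),
               paste(c("Gm01", "100", ".", "A", "G", ".", ".", ".", "DP",
                       "10"), collapse = "\t")), path)
  expect_error(read_vcf(path), "GT")
  expect_error(read_vcf(file.path(tempdir(), "nope.vcf")), "cannot read")
})

test_that("write_vcf round-trips samples, sites, codes and INFO scalars", {
  set.seed(42)
  panel <- random_panel(6, 30)
  panel$sites$qd <- round(runif(30, 10, 40), 2)
  panel$sites$mq <- round(runif(30, 20, 60), 2)
  panel <- assign_snp_ids(panel)
  path <- withr::local_tempfile(fileext = ".vcf.gz")
  write_vcf(panel, path)
  back <- read_vcf(path)
  expect_identical(back$samples, panel$samples)
  expect_identical(back$sites$pos, panel$sites$pos)
  expect_identical(back$sites$id, panel$sites$id)
  expect_identical(unname(back$geno), unname(panel$geno))
  expect_equal(back$sites$qd, panel$sites$qd)
  expect_equal(back$sites$mq, panel$sites$mq)
})

test_that("hard filter applies the printed expressions with strict bounds", {
  sites <- data.frame(
    vtype = c("SNP", "SNP", "SNP", "SNP", "INDEL", "SNP"),
    qd = c(26.0, 25.9, 30, 30, 30, 30),
    fs = c(60.0, 10, 60.1, 10, 150, 150),
    mq = c(40.0, 50, 50, 39.9, 45, 45))
  flags <- hard_filter(sites)
  # boundary values pass (all comparisons strict); each clause fails alone;
  # FS 150 fails a SNP (> 60) but passes an indel (<= 200)
  expect_equal(as.character(flags),
               c("PASS", "FAIL", "FAIL", "FAIL", "PASS", "FAIL"))
})

test_that("missing INFO never fails a site and is tallied; order equivariant", {
  sites <- data.frame(vtype = rep("SNP", 3),
                      qd = c(NA, 30, 20), fs = c(10, NA, 10),
                      mq = c(50, 50, NA))
  flags <- hard_filter(sites)
  expect_equal(as.character(flags), c("PASS", "PASS", "FAIL"))
  expect_equal(attr(flags, "n_missing_info"), 3L)
  set.seed(1)
  big <- data.frame(vtype = sample(c("SNP", "INDEL"), 50, TRUE),
                    qd = runif(50, 20, 30), fs = runif(50, 0, 250),
                    mq = runif(50, 30, 50))
  perm <- sample(50)
  expect_equal(as.character(hard_filter(big))[perm],
               as.character(hard_filter(big[perm, ])))
})

test_that("SNP id assignment is positional, unique and idempotent", {
  panel <- make_panel(matrix(0L, 1, 3),
                      chrom = c("Gm01", "Gm01", "Gm02"),
                      pos = c(12345L, 99L, 12345L),
                      ref = c("A", "C", "A"), alt = c("G", "T", "G"))
  named <- assign_snp_ids(panel)
  expect_equal(named$sites$id,
               c("Gm01_99_C_T", "Gm01_12345_A_G", "Gm02_12345_A_G"))
  expect_identical(assign_snp_ids(named)$sites$id, named$sites$id)
  expect_false(anyDuplicated(named$sites$id) > 0)
})

test_that("missing/het fractions match hand counts and partition to one", {
  panel <- make_panel(rbind(c(0L, 1L), c(-1L, 2L)))
  st <- missing_het_stats(panel)
  expect_equal(st$missing_fraction, 0.25)
  expect_equal(st$het_fraction, 0.25)
  expect_equal(missing_het_stats(make_panel(rbind(c(0L, 2L))))$het_fraction, 0)
  expect_equal(missing_het_stats(make_panel(rbind(c(-1L, -1L))))$missing_fraction, 1)
  set.seed(7)
  p <- random_panel(8, 40)
  st <- missing_het_stats(p)
  hom <- sum(p$geno %in% c(0L, 2L)) / length(p$geno)
  expect_equal(st$missing_fraction + st$het_fraction + hom, 1)
  expect_error(missing_het_stats(make_panel(matrix(integer(), 0, 0))), "empty")
})

test_that("panel invariants are enforced", {
  expect_error(make_panel(matrix(3L, 1, 1)), "codes")
  expect_error(genotype_panel(c("A", "A"), data.frame(chrom = "c", pos = 1,
                                                      ref = "A", alt = "G"),
                              matrix(0L, 2, 1)), "duplicate sample")
  expect_error(make_panel(matrix(0L, 1, 2), pos = c(5L, 5L)), "duplicate")
  # unsorted input is sorted on construction
  p <- make_panel(matrix(c(0L, 2L), 1, 2), pos = c(200L, 100L))
  expect_equal(p$sites$pos, c(100L, 200L))
  expect_equal(unname(p$geno[1, ]), c(2L, 0L))
})
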