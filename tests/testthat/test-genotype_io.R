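test_that("GT fields decode to dosages; phasing and half-calls handled", {
  p <- write_vcf_fixture(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0|1\t1|1",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t./1\t./."))
  m <- read_vcf(p)
  expect_equal(n_sites(m), 3L)
  expect_equal(unname(m$geno[1, ]), c(1L, 2L))
  # phased decodes identically to unphased
  expect_equal(unname(m$geno[2, ]), c(1L, 2L))
  # half-call and missing both NA
  expect_true(all(is.na(m$geno[3, ])))
})

test_that("multi-allelic, indel and symbolic records are dropped and counted", {
  p <- write_vcf_fixture(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
    "chr1\t200\t.\tA\tA,T\t.\tPASS\t.\tGT\t0/1\t1/2",
    "chr1\t300\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t400\t.\tG\t<DEL>\t.\tPASS\t.\tGT\t0/1\t0/0"))
  m <- read_vcf(p)
  expect_equal(n_sites(m), 1L)
  expect_equal(attr(m, "n_dropped"), 3L)
})

test_that("malformed header and unknown subset samples are errors", {
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("not a vcf", "chr1\t1\t.\tA\tG"), bad)
  expect_error(read_vcf(bad), "fileformat")
  p <- write_vcf_fixture("chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1")
  expect_error(read_vcf(p, sample_subset = c("s1", "nope")), "nope")
  m <- read_vcf(p, sample_subset = "s2")
  expect_equal(m$samples, "s2")
  expect_equal(unname(m$geno[1, ]), 2L)
})

test_that("write_vcf / read_vcf round-trip is exact for biallelic SNPs", {
  toy <- toy_matrix(n_sites = 15, seed = 9, miss_prob = 0.1)
  f <- tempfile(fileext = ".vcf")
  write_vcf(toy$matrix, f)
  back <- read_vcf(f)
  expect_identical(back$chrom, toy$matrix$chrom)
  expect_identical(back$pos, toy$matrix$pos)
  expect_identical(back$ref, toy$matrix$ref)
  expect_identical(back$alt, toy$matrix$alt)
  expect_identical(unname(back$geno), unname(toy$matrix$geno))
})

test_that("genotype-quality masking precedes site filters, and MAF/missingness filters drop sites", {
  gq <- matrix(c(9, 30, 30, 30,
                 30, 30, 30, 30,
                 30, 30, 30, 30), 3, 4, byrow = TRUE)
  geno <- matrix(c(1L, 0L, 0L, 0L,
                   1L, 0L, 0L, 0L,
                   0L, 0L, 0L, 0L), 3, 4, byrow = TRUE)
  m <- geno_matrix(rep("c", 3), 1:3, rep("A", 3), rep("T", 3), geno,
                   paste0("s", 1:4), gq = gq)
  # GQ 9 < 10 becomes missing, killing the only alt allele at site 1
  f <- filter_sites(m, min_gq = 10, min_maf = 0.05)
  expect_equal(n_sites(f), 1L)
  expect_equal(f$pos, 2L)
  # site with MAF 0.04 removed at min_maf 0.05
  geno2 <- matrix(c(rep(0L, 24), 1L), 1, 25)
  m2 <- geno_matrix("c", 1L, "A", "T", geno2, paste0("s", 1:25))
  expect_warning(f2 <- filter_sites(m2, min_maf = 0.05), "removed")
  expect_equal(n_sites(f2), 0L)
  # no thresholds: identity
  toy <- toy_matrix()$matrix
  expect_identical(filter_sites(toy)$geno, toy$geno)
})

test_that("filter_sites is idempotent", {
  toy <- toy_matrix(n_sites = 30, seed = 5, miss_prob = 0.3)$matrix
  once <- filter_sites(toy, max_missing_fraction = 0.2, min_maf = 0.1)
  twice <- filter_sites(once, max_missing_fraction = 0.2, min_maf = 0.1)
  expect_identical(once$pos, twice$pos)
  expect_identical(once$geno, twice$geno)
})

test_that("allele counts sum dosages over called genotypes", {
  m <- geno_matrix("c", 1L, "A", "T",
                   matrix(c(1L, 2L, NA), 1, 3), paste0("s", 1:3))
  pm <- pop_map(paste0("s", 1:3), rep("p", 3))
  expect_equal(unname(allele_counts(m, 1, "p", pm)), c(4L, 3L))
  m2 <- geno_matrix("c", 1L, "A", "T",
                    matrix(NA_integer_, 1, 3), paste0("s", 1:3))
  expect_equal(unname(allele_counts(m2, 1, "p", pm)), c(0L, 0L))
  m3 <- geno_matrix("c", 1L, "A", "T",
                    matrix(c(0L, 0L), 1, 2), c("s1", "s2"))
  pm3 <- pop_map(c("s1", "s2"), c("p", "p"))
  expect_equal(unname(allele_counts(m3, 1, "p", pm3)), c(4L, 0L))
  expect_error(allele_counts(m3, 1, "nope", pm3), "population")
})

test_that("windows tile from position 1 with inclusive boundaries", {
  m <- geno_matrix(c("c", "c"), c(10000L, 10001L), c("A", "A"),
                   c("T", "T"), matrix(0L, 2, 1), "s1")
  w <- iter_windows(m, 10000)
  expect_equal(w[[1]]$start, 1L)
  expect_equal(w[[1]]$end, 10000L)
  expect_equal(w[[1]]$idx, 1L)
  expect_equal(w[[2]]$start, 10001L)
  expect_equal(w[[2]]$idx, 2L)
  expect_error(iter_windows(m, 10000, step = 0), "step")
})

test_that("sliding-window membership matches enumeration of covering spans", {
  m <- geno_matrix("c", 5200L, "A", "T", matrix(0L, 1, 1), "s1")
  w <- iter_windows(m, 5000, step = 500)
  hit <- Filter(function(x) length(x$idx) > 0, w)
  # oracle: all starts 1, 501, ... whose span covers position 5200
  starts <- seq(1L, 5200L, by = 500L)
  covering <- starts[starts <= 5200 & starts + 4999 >= 5200]
  expect_equal(vapply(hit, `[[`, 0L, "start"), covering)
  expect_length(hit, 10L)
})

test_that("non-overlapping windows emit every site exactly once", {
  toy <- toy_matrix(n_sites = 40, seed = 3)$matrix
  w <- iter_windows(toy, 350)
  emitted <- sort(unlist(lapply(w, `[[`, "idx")))
  expect_equal(emitted, seq_len(n_sites(toy)))
})

test_that("population maps validate coordinates and reject duplicates", {
  f <- tempfile()
  writeLines(c("sample\tpopulation", "s1\tA", "s2\tB"), f)
  pm <- read_popmap(f)
  expect_equal(pop_samples(pm, "A"), "s1")
  writeLines(c("sample\tpopulation", "s1\tA", "s1\tB"), f)
  expect_error(read_popmap(f), "duplicate")
  writeLines(c("sample\tpopulation\tlat\tlon", "s1\tA\t95.0\t10"), f)
  expect_error(read_popmap(f), "latitude")
})
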