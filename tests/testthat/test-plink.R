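# independent 2-bit packing oracle following the published .bed layout:
# SNP-major, 4 samples per byte, least-significant pair first;
# 00 = hom A1, 01 = missing, 10 = het, 11 = hom A2 (A1 = allele B here)
pack_bed_oracle <- function(calls) {
  two_bit <- function(d) {
    if (is.na(d)) return(c(1L, 0L))
    switch(as.character(d),
           "2" = c(0L, 0L),   # hom A1 (= B)
           "1" = c(0L, 1L),   # het
           "0" = c(1L, 1L))   # hom A2 (= A)
  }
  bytes <- raw(0)
  for (i in seq_len(nrow(calls))) {
    bits <- unlist(lapply(calls[i, ], two_bit))
    pad <- 8 * ceiling(length(bits) / 8) - length(bits)
    bits <- c(bits, rep(0L, pad))
    for (b in seq_len(length(bits) / 8)) {
      byte <- sum(bits[(b - 1) * 8 + 1:8] * 2^(0:7))
      bytes <- c(bytes, as.raw(byte))
    }
  }
  c(as.raw(c(0x6C, 0x1B, 0x01)), bytes)
}

test_that("bed bytes match the 2-bit packing oracle on elementary cases", {
  pre <- withr::local_tempfile()
  # single B-homozygote -> [magic, magic, mode, 0x00]
  write_plink(tiny_gset(matrix(2L, 1, 1)), pre)
  expect_identical(readBin(paste0(pre, ".bed"), "raw", 10),
                   as.raw(c(0x6C, 0x1B, 0x01, 0x00)))
  # single missing call -> last byte 0x01
  write_plink(tiny_gset(matrix(NA_integer_, 1, 1)), pre)
  expect_identical(readBin(paste0(pre, ".bed"), "raw", 10),
                   as.raw(c(0x6C, 0x1B, 0x01, 0x01)))
  # random fixtures against the oracle
  set.seed(51)
  for (rep in 1:5) {
    nm <- sample(1:6, 1); ns <- sample(1:9, 1)
    calls <- matrix(sample(c(0:2, NA), nm * ns, replace = TRUE), nm, ns)
    g <- tiny_gset(calls)
    write_plink(g, pre)
    expect_identical(readBin(paste0(pre, ".bed"), "raw",
                             file.size(paste0(pre, ".bed"))),
                     pack_bed_oracle(g$calls))
  }
})

test_that("bed payload size is 3 + n_markers * ceil(n_samples/4) bytes", {
  pre <- withr::local_tempfile()
  set.seed(52)
  for (ns in c(1, 3, 4, 5, 8, 9)) {
    g <- tiny_gset(matrix(sample(0:2, 7 * ns, replace = TRUE), 7, ns))
    write_plink(g, pre)
    expect_equal(file.size(paste0(pre, ".bed")), 3 + 7 * ceiling(ns / 4))
  }
})

test_that("PLINK round trip is exact on calls, map and pedigree", {
  set.seed(53)
  calls <- matrix(sample(c(0:2, NA), 15, replace = TRUE), 5, 3)
  mk <- tiny_map(5)
  mk$chrom <- c("1", "1", "2", "X", "X")
  mk$cM <- c(NA, 2.5, NA, NA, 7.25)
  sm <- data.frame(id = c("a", "b", "c"), family = "f1",
                   father = c(NA, NA, "a"), mother = c(NA, NA, "b"),
                   sex = c("male", "female", "unknown"),
                   phenotype = c(1, 2, NA))
  g <- genotypes(calls, mk, sm)
  pre <- withr::local_tempfile()
  write_plink(g, pre)
  g2 <- read_plink(pre)
  expect_identical(g2$calls, g$calls)
  expect_equal(g2$markers$pos, g$markers$pos)
  expect_equal(g2$markers$cM, g$markers$cM)
  expect_equal(g2$markers$allele_A, g$markers$allele_A)
  expect_identical(g2$samples$sex, g$samples$sex)
  expect_identical(g2$samples$father, g$samples$father)
  expect_equal(g2$samples$phenotype, g$samples$phenotype)
})

test_that("corrupt bed files are rejected", {
  pre <- withr::local_tempfile()
  g <- tiny_gset(matrix(0L, 2, 2))
  write_plink(g, pre)
  bed <- paste0(pre, ".bed")
  raw <- readBin(bed, "raw", file.size(bed))
  writeBin(c(as.raw(c(0x00, 0x00)), raw[-(1:2)]), bed)
  expect_error(read_plink(pre), "magic")
  writeBin(raw[-length(raw)], bed)
  expect_error(read_plink(pre), "length")
})

test_that("unknown alleles export as 0 0 with a warning", {
  g <- tiny_gset(matrix(1L, 1, 1))
  g$markers$allele_A <- NA_character_
  pre <- withr::local_tempfile()
  expect_warning(write_plink(g, pre), "unknown alleles")
  bim <- read.table(paste0(pre, ".bim"))
  expect_equal(as.character(bim[1, 5:6]), c("0", "0"))
})

test_that("R/qtl export lays out the single-file cross format", {
  calls <- matrix(c(0L, 2L, 1L, NA), 2, 2)
  g <- tiny_gset(calls)
  f <- withr::local_tempfile(fileext = ".csv")
  expect_warning(write_rqtl_csv(g, f), "cM")
  lines <- readLines(f)
  expect_equal(lines[1], "pheno,rs1,rs2")
  expect_equal(lines[2], ",1,1")
  expect_equal(lines[3], ",1,2")          # Mbp fallback for missing cM
  expect_equal(strsplit(lines[4], ",")[[1]][2:3], c("A", "B"))
  expect_equal(strsplit(lines[5], ",")[[1]][2:3], c("H", "-"))
  # empty sample set: header-only file
  g0 <- subset_genotypes(g, samples = character(0))
  expect_warning(write_rqtl_csv(g0, f), "cM")
  expect_length(readLines(f), 3L)
})

test_that("HGDP export writes two-letter genotypes and skips unknown alleles", {
  calls <- matrix(c(0L, 1L, 2L, NA), 2, 2)
  g <- tiny_gset(calls)                    # alleles A/G
  f <- withr::local_tempfile(fileext = ".txt")
  write_hgdp(g, f)
  lines <- readLines(f)
  expect_equal(lines[2], "rs1\tAA\tGG")
  expect_equal(lines[3], "rs2\tAG\t--")
  g$markers$allele_B[2] <- NA_character_
  expect_warning(write_hgdp(g, f), "skipped")
  expect_length(readLines(f), 2L)
})
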