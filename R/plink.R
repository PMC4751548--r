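#' Write a PLINK binary fileset
#'
#' Writes `prefix.bed`, `prefix.bim` and `prefix.fam` in PLINK 1 binary
#' format.  The .bed file starts with the magic bytes `0x6C 0x1B` and the
#' SNP-major mode byte `0x01`; for each marker, samples are packed four per
#' byte, two bits each, least-significant pair first, with `00` = homozygous
#' A1, `01` = missing, `10` = heterozygous, `11` = homozygous A2.
#'
#' Note the allele orientation: A1 is set to the manifest's B allele and A2
#' to the A allele, so that PLINK's count-of-A1 dosage equals this package's
#' internal B-allele dosage.  PLINK users used to A1-is-minor should keep
#' this in mind.  Markers with unknown alleles are exported as "0 0" with a
#' warning.
#'
#' @param gset a `genotypes` object with calls.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gset, prefix) {
  mk <- gset$markers
  sm <- gset$samples
  n_mk <- nrow(mk); n_sm <- nrow(sm)

  a1 <- mk$allele_B; a2 <- mk$allele_A
  unknown <- is.na(a1) | is.na(a2)
  if (any(unknown)) {
    warning(sum(unknown), " marker(s) with unknown alleles exported as '0 0'")
    a1[unknown] <- "0"; a2[unknown] <- "0"
  }
  bim <- data.table::data.table(
    chrom = mk$chrom, name = mk$name,
    cM = ifelse(is.na(mk$cM), 0, mk$cM), pos = mk$pos, A1 = a1, A2 = a2)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE)

  sex_code <- c(unknown = 0L, male = 1L, female = 2L)[sm$sex]
  fam <- data.table::data.table(
    family = ifelse(is.na(sm$family), sm$id, sm$family), id = sm$id,
    father = ifelse(is.na(sm$father), "0", sm$father),
    mother = ifelse(is.na(sm$mother), "0", sm$mother),
    sex = unname(sex_code),
    phenotype = ifelse(is.na(sm$phenotype), -9, sm$phenotype))
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE)

  # 2-bit codes indexed by dosage 0,1,2; NA handled separately
  # dosage of A1(=B): 2 -> 00 (hom A1), 1 -> 10 (het), 0 -> 11 (hom A2)
  code <- c(3L, 2L, 0L)
  per_byte <- 4L
  n_bytes <- ceiling(n_sm / per_byte)
  bed <- raw(3 + n_mk * n_bytes)
  bed[1:3] <- as.raw(c(0x6C, 0x1B, 0x01))
  shift <- c(1L, 4L, 16L, 64L)  # left-shifts by 0,2,4,6 bits
  for (i in seq_len(n_mk)) {
    d <- gset$calls[i, ]
    cc <- ifelse(is.na(d), 1L, code[d + 1L])
    cc <- c(cc, integer(n_bytes * per_byte - n_sm))
    m <- matrix(cc * shift, nrow = per_byte)
    bed[3 + (i - 1) * n_bytes + seq_len(n_bytes)] <- as.raw(colSums(m))
  }
  writeBin(bed, paste0(prefix, ".bed"))
  invisible(prefix)
}

#' Read a PLINK binary fileset
#'
#' Inverse of [write_plink()] on calls and metadata (intensities are not
#' part of the PLINK format).  Validates the magic and mode bytes and the
#' .bed payload length.
#'
#' @param prefix path prefix of `prefix.bed`/`.bim`/`.fam`.
#' @return a `genotypes` object.
#' @export
read_plink <- function(prefix) {
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE,
    col.names = c("chrom", "name", "cM", "pos", "A1", "A2"),
    colClasses = list(character = c(1, 2, 5, 6)))
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE,
    col.names = c("family", "id", "father", "mother", "sex", "phenotype"),
    colClasses = list(character = 1:4))
  n_mk <- nrow(bim); n_sm <- nrow(fam)

  bedfile <- paste0(prefix, ".bed")
  bed <- readBin(bedfile, "raw", n = file.size(bedfile))
  if (length(bed) < 3 || bed[1] != as.raw(0x6C) || bed[2] != as.raw(0x1B))
    stop("not a PLINK .bed file (bad magic bytes)")
  if (bed[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  n_bytes <- ceiling(n_sm / 4)
  if (length(bed) != 3 + n_mk * n_bytes)
    stop(".bed length ", length(bed), " does not match ",
         3 + n_mk * n_bytes, " expected for ", n_mk, " markers x ",
         n_sm, " samples")

  payload <- as.integer(bed[-(1:3)])
  # unpack 4 two-bit fields per byte, least-significant first
  two_bits <- sapply(0:3, function(k) (payload %/% 4L^k) %% 4L)
  cc <- as.vector(t(two_bits))                    # sample-within-marker order
  cc <- matrix(cc, nrow = 4 * n_bytes)[seq_len(n_sm), , drop = FALSE]
  dosage <- c(2L, NA_integer_, 1L, 0L)[cc + 1L]   # invert the write coding
  calls <- matrix(dosage, n_mk, n_sm, byrow = TRUE)

  markers <- data.frame(name = bim$name, chrom = bim$chrom, pos = bim$pos,
                        cM = ifelse(bim$cM == 0, NA_real_, bim$cM),
                        allele_A = bim$A2, allele_B = bim$A1)
  samples <- data.frame(
    id = fam$id, family = fam$family,
    father = ifelse(fam$father == "0", NA_character_, fam$father),
    mother = ifelse(fam$mother == "0", NA_character_, fam$mother),
    sex = c("unknown", "male", "female")[fam$sex + 1L],
    phenotype = ifelse(fam$phenotype == -9, NA_real_, fam$phenotype))
  genotypes(calls, markers, samples)
}

#' Export genotypes in R/qtl single-file cross format
#'
#' One CSV: a header row of marker names (first column reserved for the
#' phenotype), a chromosome row, a genetic-map position row, then one
#' genotype row per sample with tokens `A` (dosage 0), `H` (1), `B` (2) and
#' `-` (missing).  Markers lacking a cM position fall back to physical
#' position in Mbp, with a warning.
#'
#' @param gset a `genotypes` object; typically recoded against parental
#'   lines first (see [recode_by_parents()]).
#' @param path output CSV path.
#' @param phenotype_col name of the sample-table column used as the
#'   phenotype (default `"phenotype"`).
#' @return `path`, invisibly.
#' @export
write_rqtl_csv <- function(gset, path, phenotype_col = "phenotype") {
  mk <- gset$markers
  cm <- mk$cM
  if (anyNA(cm)) {
    warning("markers without cM position: using pos/1e6 (Mbp) as map position")
    cm[is.na(cm)] <- mk$pos[is.na(cm)] / 1e6
  }
  tok <- c("A", "H", "B")
  lines <- c(paste(c("pheno", mk$name), collapse = ","),
             paste(c("", mk$chrom), collapse = ","),
             paste(c("", format(cm, trim = TRUE, digits = 10)),
                   collapse = ","))
  if (ncol(gset$calls) > 0) {
    ph <- gset$samples[[phenotype_col]]
    if (is.null(ph)) ph <- rep(NA, ncol(gset$calls))
    for (j in seq_len(ncol(gset$calls))) {
      d <- gset$calls[, j]
      g <- ifelse(is.na(d), "-", tok[d + 1L])
      lines <- c(lines, paste(c(ifelse(is.na(ph[j]), "", ph[j]), g),
                              collapse = ","))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export genotypes in Stanford HGDP format
#'
#' Tab-delimited genotype matrix: a header of sample ids, then one row per
#' marker with the marker name followed by two-letter nucleotide genotypes
#' (e.g. `"AG"`), `"--"` for missing.  Markers with unknown alleles are
#' skipped with a warning.
#'
#' @param gset a `genotypes` object with known marker alleles.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hgdp <- function(gset, path) {
  mk <- gset$markers
  known <- !is.na(mk$allele_A) & !is.na(mk$allele_B)
  if (!all(known))
    warning(sum(!known), " marker(s) with unknown alleles skipped")
  lines <- paste(c("marker", gset$samples$id), collapse = "\t")
  for (i in which(known)) {
    d <- gset$calls[i, ]
    g <- ifelse(is.na(d), "--",
                paste0(ifelse(d == 2, mk$allele_B[i], mk$allele_A[i]),
                       ifelse(d >= 1, mk$allele_B[i], mk$allele_A[i])))
    lines <- c(lines, paste(c(mk$name[i], g), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
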