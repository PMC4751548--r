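#' FinalReport dialect description
#'
#' BeadStudio/GenomeStudio FinalReport exports vary with export settings;
#' this object pins down the variants the reader and writer understand.
#'
#' @param allele_coding `"AB"` (calls are the letters A/B) or `"nucleotide"`
#'   (calls are forward-strand nucleotides, matched against the manifest's
#'   A/B alleles with reverse-complement fallback).
#' @param missing_token token used for a missing allele call (default `"-"`).
#' @param delimiter field delimiter, tab or comma.
#' @param has_header_block whether a `[Header]` block precedes the `[Data]`
#'   section.
#' @return a list of class `finalreport_dialect`.
#' @export
finalreport_dialect <- function(allele_coding = c("AB", "nucleotide"),
                                missing_token = "-",
                                delimiter = "\t",
                                has_header_block = TRUE) {
  allele_coding <- match.arg(allele_coding)
  if (!nzchar(missing_token)) stop("missing_token must be non-empty")
  structure(list(allele_coding = allele_coding,
                 missing_token = missing_token, delimiter = delimiter,
                 has_header_block = has_header_block),
            class = "finalreport_dialect")
}

NUC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# dosage of the B allele for one nucleotide call against (allele_A, allele_B);
# tries the manifest strand first, then its reverse complement
nucleotide_dosage <- function(a1, a2, allele_A, allele_B, missing_token) {
  n <- length(a1)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (a1[i] == missing_token || a2[i] == missing_token) next
    if (is.na(allele_A[i]) || is.na(allele_B[i])) next
    pair <- c(a1[i], a2[i])
    for (strand in 1:2) {
      if (strand == 2) pair <- unname(NUC_COMPLEMENT[pair])
      if (all(pair %in% c(allele_A[i], allele_B[i]))) {
        out[i] <- sum(pair == allele_B[i])
        break
      }
    }
  }
  out
}

#' Read a BeadStudio/GenomeStudio FinalReport
#'
#' Parses a long-format FinalReport text file (optionally ZIP- or
#' gzip-compressed): one row per (sample, SNP) carrying the SNP name, sample
#' id, two allele-call columns, and x/y intensities.  An optional `[Header]`
#' block is skipped up to the `[Data]` line.  Column names are matched
#' case-insensitively: `SNP Name`, `Sample ID`, columns starting with
#' `Allele1` / `Allele2`, and `X` / `Y` (`X Raw` / `Y Raw` accepted when
#' `raw_intensities = TRUE`).
#'
#' Calls are translated to B-allele dosage via the manifest: AB coding
#' directly, nucleotide coding by matching against the manifest alleles with
#' reverse-complement (strand-flip) fallback.  SNPs absent from the manifest
#' are dropped with a message reporting the count.
#'
#' @param path FinalReport file (`.txt`, `.csv`, `.zip` or `.gz`).
#' @param manifest marker map data frame (see [genotypes()]); defines the
#'   marker universe and A/B alleles.
#' @param dialect a [finalreport_dialect()].
#' @param allow_ragged if `FALSE` (default), a sample missing part of the
#'   marker set is an error; if `TRUE`, absent (sample, SNP) pairs are
#'   filled with missing calls.
#' @param raw_intensities accept `X Raw`/`Y Raw` intensity columns.
#' @param zip_member for multi-entry ZIP archives, the member to read.
#' @return a `genotypes` object with calls and x/y intensities.
#' @export
read_beadstudio <- function(path, manifest,
                            dialect = finalreport_dialect(),
                            allow_ragged = FALSE, raw_intensities = FALSE,
                            zip_member = NULL) {
  lines <- read_report_lines(path, zip_member)
  start <- 1L
  if (dialect$has_header_block) {
    dl <- grep("^\\[Data\\]", lines)
    if (length(dl) == 0)
      stop("no [Data] section found in FinalReport")
    start <- dl[1] + 1L
  }
  tab <- data.table::fread(text = lines[start:length(lines)],
                           sep = dialect$delimiter, header = TRUE,
                           colClasses = "character", data.table = TRUE)
  cols <- resolve_report_columns(names(tab), raw_intensities)
  manifest <- complete_marker_map(manifest)

  snp <- tab[[cols$snp]]
  keep <- snp %in% manifest$name
  if (!all(keep)) {
    message("dropping ", length(unique(snp[!keep])),
            " SNPs absent from the manifest")
    tab <- tab[keep, ]
    snp <- snp[keep]
  }
  sample_ids <- unique(tab[[cols$sample]])
  mi <- match(snp, manifest$name)
  si <- match(tab[[cols$sample]], sample_ids)

  a1 <- toupper(tab[[cols$a1]]); a2 <- toupper(tab[[cols$a2]])
  miss <- toupper(dialect$missing_token)
  if (dialect$allele_coding == "AB") {
    dos <- ifelse(a1 == miss | a2 == miss, NA_integer_,
                  (a1 == "B") + (a2 == "B"))
  } else {
    dos <- nucleotide_dosage(a1, a2, manifest$allele_A[mi],
                             manifest$allele_B[mi], miss)
  }

  n_mk <- nrow(manifest); n_sm <- length(sample_ids)
  calls <- matrix(NA_integer_, n_mk, n_sm)
  x <- matrix(NA_real_, n_mk, n_sm)
  y <- matrix(NA_real_, n_mk, n_sm)
  idx <- cbind(mi, si)
  seen <- matrix(FALSE, n_mk, n_sm)
  seen[idx] <- TRUE
  if (!all(seen) && !allow_ragged)
    stop("incomplete marker set for ", sum(colSums(!seen) > 0),
         " sample(s); use allow_ragged = TRUE to missing-fill")
  calls[idx] <- as.integer(dos)
  x[idx] <- as.numeric(tab[[cols$x]])
  y[idx] <- as.numeric(tab[[cols$y]])
  genotypes(calls, manifest, data.frame(id = sample_ids), x = x, y = y)
}

read_report_lines <- function(path, zip_member = NULL) {
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    entries <- utils::unzip(path, list = TRUE)$Name
    member <- if (!is.null(zip_member)) zip_member else {
      if (length(entries) > 1)
        stop("multi-entry ZIP archive: name the member via 'zip_member'")
      entries[1]
    }
    con <- unz(path, member)
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  if (grepl("\\.gz$", path, ignore.case = TRUE)) {
    con <- gzfile(path)
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  readLines(path, warn = FALSE)
}

resolve_report_columns <- function(nms, raw_intensities) {
  lower <- tolower(nms)
  pick <- function(pattern, what) {
    hit <- grep(pattern, lower)
    if (length(hit) == 0) stop("FinalReport lacks a '", what, "' column")
    nms[hit[1]]
  }
  xcol <- if (raw_intensities) "^x raw$|^x$" else "^x$"
  ycol <- if (raw_intensities) "^y raw$|^y$" else "^y$"
  list(snp = pick("^snp name$", "SNP Name"),
       sample = pick("^sample id$", "Sample ID"),
       a1 = pick("^allele1", "Allele1"),
       a2 = pick("^allele2", "Allele2"),
       x = pick(xcol, "X"), y = pick(ycol, "Y"))
}

#' Write a FinalReport file
#'
#' Emits a syntactically valid BeadStudio-style FinalReport (a `[Header]`
#' block with SNP/sample counts, then a `[Data]` section, one row per
#' (sample, SNP)) that [read_beadstudio()] round-trips exactly on calls and
#' to 6 decimals on intensities.  Mainly a fixture generator for testing
#' the import path against simulated data.
#'
#' @param gset a `genotypes` object with calls and x/y intensities.
#' @param path output file; a `.gz` suffix gzip-compresses.
#' @param dialect a [finalreport_dialect()].
#' @return `path`, invisibly.
#' @export
write_finalreport <- function(gset, path, dialect = finalreport_dialect()) {
  if (is.null(gset$x) || is.null(gset$y))
    stop("intensities required to write a FinalReport")
  n_mk <- nrow(gset$calls); n_sm <- ncol(gset$calls)
  mk <- gset$markers
  rows <- vector("list", n_sm)
  for (j in seq_len(n_sm)) {
    d <- gset$calls[, j]
    if (dialect$allele_coding == "AB") {
      a1 <- ifelse(is.na(d), dialect$missing_token, ifelse(d >= 1, "B", "A"))
      a2 <- ifelse(is.na(d), dialect$missing_token, ifelse(d == 2, "B", "A"))
    } else {
      a1 <- ifelse(is.na(d), dialect$missing_token,
                   ifelse(d >= 1, mk$allele_B, mk$allele_A))
      a2 <- ifelse(is.na(d), dialect$missing_token,
                   ifelse(d == 2, mk$allele_B, mk$allele_A))
    }
    rows[[j]] <- data.table::data.table(
      snp = mk$name, sample = gset$samples$id[j], a1 = a1, a2 = a2,
      X = sprintf("%.6f", gset$x[, j]), Y = sprintf("%.6f", gset$y[, j]))
  }
  dat <- data.table::rbindlist(rows)
  allele_tag <- if (dialect$allele_coding == "AB") "AB" else "Forward"
  col_names <- c("SNP Name", "Sample ID",
                 paste("Allele1 -", allele_tag),
                 paste("Allele2 -", allele_tag), "X", "Y")
  header <- c("[Header]",
              "GSGT Version\tsnparray simulated",
              paste0("Num SNPs\t", n_mk),
              paste0("Total SNPs\t", n_mk),
              paste0("Num Samples\t", n_sm),
              paste0("Total Samples\t", n_sm),
              "[Data]")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (dialect$has_header_block) writeLines(header, con)
  writeLines(paste(col_names, collapse = dialect$delimiter), con)
  writeLines(do.call(paste, c(as.list(dat), sep = dialect$delimiter)), con)
  invisible(path)
}
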