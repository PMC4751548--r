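#' Genotype dataset container
#'
#' A `genotypes` object is a self-contained representation of a SNP-array
#' dataset, modelled on a PLINK fileset: a markers-by-samples matrix of
#' genotype calls stored in parallel with a marker map, sample metadata and
#' (optionally) two-channel hybridization intensities and the normalized
#' BAF/LRR tracks derived from them.
#'
#' Calls are coded as the count of "B" (alternate) alleles: 0, 1, 2 or `NA`
#' for missing.  All matrices present in the object have identical dimensions
#' and identical marker/sample ordering; markers are kept sorted by
#' (chromosome, position).
#'
#' @param calls integer matrix, markers x samples, entries in `{0,1,2,NA}`.
#'   Rownames/colnames, when present, must agree with `markers$name` and
#'   `samples$id`.
#' @param markers data frame with columns `name`, `chrom`, `pos` and
#'   optionally `cM`, `allele_A`, `allele_B`.  Positions are 1-based.
#' @param samples data frame with column `id` and optionally `family`,
#'   `father`, `mother`, `sex` (`"male"`, `"female"` or `"unknown"`),
#'   `phenotype`, `batch`, `qc_flag`.
#' @param x,y optional non-negative intensity matrices, same shape as `calls`.
#' @param baf,lrr optional normalized-track matrices, same shape as `calls`.
#' @param normalized logical flag recording whether tQN has been applied.
#'
#' @return an object of class `genotypes`.
#' @export
genotypes <- function(calls, markers, samples, x = NULL, y = NULL,
                      baf = NULL, lrr = NULL, normalized = FALSE) {
  if (!is.matrix(calls))
    stop("'calls' must be a matrix (markers x samples)")
  markers <- complete_marker_map(markers)
  samples <- complete_sample_table(samples)
  if (nrow(calls) != nrow(markers))
    stop("dimension mismatch: ", nrow(calls), " call rows vs ",
         nrow(markers), " markers")
  if (ncol(calls) != nrow(samples))
    stop("dimension mismatch: ", ncol(calls), " call columns vs ",
         nrow(samples), " samples")
  if (anyDuplicated(markers$name))
    stop("duplicate marker names: ",
         paste(unique(markers$name[duplicated(markers$name)]), collapse = ", "))
  if (anyDuplicated(samples$id))
    stop("duplicate sample ids: ",
         paste(unique(samples$id[duplicated(samples$id)]), collapse = ", "))
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad))
    stop("illegal call codes (must be 0, 1, 2 or NA): found ",
         paste(unique(calls[bad]), collapse = ", "))

  obj <- structure(list(calls = calls, x = x, y = y, baf = baf, lrr = lrr,
                        markers = markers, samples = samples,
                        normalized = isTRUE(normalized)),
                   class = "genotypes")
  obj <- set_dimnames(obj)
  ord <- order(chrom_rank(markers$chrom), markers$pos)
  if (any(ord != seq_along(ord)))
    obj <- permute_markers(obj, ord)
  validate_genotypes(obj)
}

#' @rdname genotypes
#' @param object a `genotypes` object.
#' @export
validate_genotypes <- function(object) {
  stopifnot(inherits(object, "genotypes"))
  d <- dim(object$calls)
  for (nm in c("x", "y", "baf", "lrr")) {
    m <- object[[nm]]
    if (!is.null(m) && !identical(dim(m), d))
      stop("matrix '", nm, "' does not match the dimensions of 'calls'")
  }
  if (!is.null(object$baf)) {
    b <- object$baf
    if (any(b < 0 | b > 1, na.rm = TRUE))
      stop("BAF values outside [0,1]")
  }
  mk <- object$markers
  both <- !is.na(mk$allele_A) & !is.na(mk$allele_B)
  if (any(both & mk$allele_A == mk$allele_B))
    stop("markers with identical A and B alleles: ",
         paste(mk$name[both & mk$allele_A == mk$allele_B], collapse = ", "))
  invisible(object)
}

# fill optional columns of the marker map with defaults and type-check
complete_marker_map <- function(markers) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "pos")
  if (!all(need %in% names(markers)))
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  markers$name <- as.character(markers$name)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  if (is.null(markers$cM)) markers$cM <- NA_real_
  if (is.null(markers$allele_A)) markers$allele_A <- NA_character_
  if (is.null(markers$allele_B)) markers$allele_B <- NA_character_
  markers$cM <- as.numeric(markers$cM)
  for (al in c("allele_A", "allele_B")) {
    v <- toupper(as.character(markers[[al]]))
    v[!(v %in% c("A", "C", "G", "T"))] <- NA_character_
    markers[[al]] <- v
  }
  rownames(markers) <- NULL
  markers[, c("name", "chrom", "pos", "cM", "allele_A", "allele_B")]
}

complete_sample_table <- function(samples) {
  if (is.character(samples)) samples <- data.frame(id = samples)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(samples$id))
    stop("sample table must have a column 'id'")
  samples$id <- as.character(samples$id)
  defaults <- list(family = samples$id, father = NA_character_,
                   mother = NA_character_, sex = "unknown",
                   phenotype = NA_real_, batch = NA_character_,
                   qc_flag = "unset")
  for (nm in names(defaults))
    if (is.null(samples[[nm]])) samples[[nm]] <- defaults[[nm]]
  sex <- as.character(samples$sex)
  sex[is.na(sex)] <- "unknown"
  if (!all(sex %in% c("unknown", "male", "female")))
    stop("sample sex must be 'male', 'female' or 'unknown'")
  samples$sex <- sex
  rownames(samples) <- NULL
  samples[, c("id", "family", "father", "mother", "sex", "phenotype",
              "batch", "qc_flag")]
}

# sort key for chromosome labels: numeric chromosomes first (numerically),
# then X, XY, Y, M/MT, then anything else alphabetically
chrom_rank <- function(chrom) {
  chrom <- toupper(as.character(chrom))
  n <- suppressWarnings(as.numeric(chrom))
  r <- ifelse(!is.na(n), n,
              match(chrom, c("X", "XY", "Y", "M", "MT"), nomatch = 0L) + 1000)
  r[r == 1000] <- 2000 + as.numeric(factor(chrom[r == 1000]))
  r
}

is_autosome <- function(chrom) {
  !(toupper(as.character(chrom)) %in% c("X", "Y", "XY", "M", "MT"))
}

set_dimnames <- function(obj) {
  for (nm in c("calls", "x", "y", "baf", "lrr"))
    if (!is.null(obj[[nm]]))
      dimnames(obj[[nm]]) <- list(obj$markers$name, obj$samples$id)
  obj
}

permute_markers <- function(obj, ord) {
  for (nm in c("calls", "x", "y", "baf", "lrr"))
    if (!is.null(obj[[nm]])) obj[[nm]] <- obj[[nm]][ord, , drop = FALSE]
  obj$markers <- obj$markers[ord, , drop = FALSE]
  rownames(obj$markers) <- NULL
  obj
}

permute_samples <- function(obj, ord) {
  for (nm in c("calls", "x", "y", "baf", "lrr"))
    if (!is.null(obj[[nm]])) obj[[nm]] <- obj[[nm]][, ord, drop = FALSE]
  obj$samples <- obj$samples[ord, , drop = FALSE]
  rownames(obj$samples) <- NULL
  obj
}

#' @export
dim.genotypes <- function(x) dim(x$calls)

#' @export
print.genotypes <- function(x, ...) {
  cat("A genotypes object: ", nrow(x$calls), " markers x ",
      ncol(x$calls), " samples\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$markers$chrom), collapse = ", "),
      "\n", sep = "")
  cat("  intensities: ", if (is.null(x$x)) "absent" else "present",
      "; normalized (tQN): ", x$normalized, "\n", sep = "")
  invisible(x)
}

#' Subset a genotypes object
#'
#' Subsets markers and/or samples, keeping every matrix and the metadata
#' consistent.  Selectors may be character vectors of ids, logical masks,
#' integer indices, or (for markers) a genomic region
#' `list(chrom =, start =, end =)` interpreted as a 1-based closed interval.
#' An empty selection is valid and yields an empty (but well-formed) object.
#'
#' @param gset a `genotypes` object.
#' @param markers,samples selector for markers resp. samples; `NULL` keeps all.
#' @return a `genotypes` object.
#' @export
subset_genotypes <- function(gset, markers = NULL, samples = NULL) {
  stopifnot(inherits(gset, "genotypes"))
  mi <- resolve_selector(markers, gset$markers$name, gset$markers)
  si <- resolve_selector(samples, gset$samples$id)
  out <- permute_markers(gset, mi)
  out <- permute_samples(out, si)
  out
}

resolve_selector <- function(sel, ids, marker_map = NULL) {
  if (is.null(sel)) return(seq_along(ids))
  if (is.list(sel) && !is.null(sel$chrom)) {
    if (is.null(marker_map)) stop("region selectors apply to markers only")
    start <- if (is.null(sel$start)) -Inf else sel$start
    end <- if (is.null(sel$end)) Inf else sel$end
    return(which(marker_map$chrom == as.character(sel$chrom) &
                 marker_map$pos >= start & marker_map$pos <= end))
  }
  if (is.logical(sel)) {
    if (length(sel) != length(ids))
      stop("logical selector has wrong length")
    return(which(sel))
  }
  if (is.numeric(sel)) {
    if (any(sel < 1 | sel > length(ids)))
      stop("index selector out of range")
    return(as.integer(sel))
  }
  idx <- match(as.character(sel), ids)
  if (anyNA(idx))
    stop("unknown ids: ", paste(sel[is.na(idx)], collapse = ", "))
  idx
}

#' Tabulate genotype calls by sample or by marker
#'
#' Counts reference homozygotes (dosage 0), heterozygotes, alternate
#' homozygotes (dosage 2) and missing calls along one axis of the call
#' matrix.  Counts along each row of the result sum to the extent of the
#' other axis.
#'
#' @param gset a `genotypes` object.
#' @param axis `"sample"` (one row per sample) or `"marker"`.
#' @return data frame with columns `id`, `n_refhom`, `n_het`, `n_althom`,
#'   `n_missing`.
#' @export
genotype_counts <- function(gset, axis = c("sample", "marker")) {
  axis <- match.arg(axis)
  cl <- gset$calls
  margin <- if (axis == "sample") 2L else 1L
  cnt <- function(v) apply(cl, margin, function(z) sum(z == v, na.rm = TRUE))
  data.frame(
    id = if (axis == "sample") gset$samples$id else gset$markers$name,
    n_refhom = cnt(0L), n_het = cnt(1L), n_althom = cnt(2L),
    n_missing = apply(cl, margin, function(z) sum(is.na(z))),
    stringsAsFactors = FALSE, row.names = NULL)
}
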