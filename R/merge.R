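#' Merge two genotype datasets with allele harmonization
#'
#' Joins two datasets on shared marker names (verifying chromosome/position
#' agreement) and reconciles the second dataset's allele encoding to the
#' first's before concatenating samples:
#'
#' * identical (A, B) alleles: calls kept as-is;
#' * swapped alleles (B's A is A's B): dosages flipped `d -> 2 - d`;
#' * complementary alleles (the same SNP read off the reverse strand, e.g.
#'   A/G vs T/C): complemented, then reconciled as above;
#' * strand-ambiguous SNPs (A/T or C/G) whose encodings conflict cannot be
#'   resolved and are dropped; when the encodings already agree they are
#'   kept (conservative default);
#' * anything irreconcilable (e.g. A/G vs A/C) is dropped.
#'
#' The result contains the reconciled shared markers and the union of
#' samples; intensities are carried only when both inputs have them.
#'
#' @param a,b `genotypes` objects with disjoint sample ids.
#' @return a `genotypes` object; attribute `"dropped"` is a data frame of
#'   dropped markers and reasons.
#' @export
merge_sets <- function(a, b) {
  if (length(intersect(a$samples$id, b$samples$id)) > 0)
    stop("sample ids overlap between datasets")
  shared <- intersect(a$markers$name, b$markers$name)
  if (length(shared) == 0) stop("no shared markers")
  ai <- match(shared, a$markers$name)
  bi <- match(shared, b$markers$name)
  mka <- a$markers[ai, ]; mkb <- b$markers[bi, ]

  drop_reason <- rep(NA_character_, length(shared))
  flip <- rep(FALSE, length(shared))
  pos_bad <- mka$chrom != mkb$chrom | mka$pos != mkb$pos
  drop_reason[pos_bad] <- "position mismatch"
  amb <- function(x, y) paste0(pmin(x, y), pmax(x, y)) %in% c("AT", "CG")
  for (i in seq_along(shared)) {
    if (!is.na(drop_reason[i])) next
    aa <- c(mka$allele_A[i], mka$allele_B[i])
    bb <- c(mkb$allele_A[i], mkb$allele_B[i])
    if (anyNA(aa) || anyNA(bb)) { drop_reason[i] <- "unknown alleles"; next }
    if (identical(bb, aa)) next
    if (amb(aa[1], aa[2])) {
      # for an A/T or C/G SNP a strand flip is indistinguishable from an
      # allele swap, so any disagreement in encoding cannot be resolved
      drop_reason[i] <- "strand-ambiguous"
      next
    }
    if (identical(bb, rev(aa))) { flip[i] <- TRUE; next }
    cb <- unname(NUC_COMPLEMENT[bb])
    if (identical(cb, aa)) {
      next                               # reverse strand, same orientation
    } else if (identical(cb, rev(aa))) {
      flip[i] <- TRUE                    # reverse strand, swapped
    } else {
      drop_reason[i] <- "irreconcilable alleles"
    }
  }
  keep <- is.na(drop_reason)
  dropped <- data.frame(name = shared[!keep],
                        reason = drop_reason[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(dropped) > 0) {
    warning(nrow(dropped), " shared marker(s) dropped during merge")
    if (nrow(dropped) > length(shared) / 2)
      stop("more than half of shared markers irreconcilable: ",
           "the datasets likely use incompatible manifests")
  }
  shared <- shared[keep]; ai <- ai[keep]; bi <- bi[keep]; flip <- flip[keep]

  calls_b <- b$calls[bi, , drop = FALSE]
  if (any(flip)) calls_b[flip, ] <- 2L - calls_b[flip, , drop = FALSE]
  calls <- cbind(a$calls[ai, , drop = FALSE], calls_b)
  markers <- a$markers[ai, ]
  both_int <- !is.null(a$x) && !is.null(b$x) &&
    !is.null(a$y) && !is.null(b$y)
  x <- y <- NULL
  if (both_int) {
    # flipped markers have their channels swapped in b's encoding
    xb <- b$x[bi, , drop = FALSE]; yb <- b$y[bi, , drop = FALSE]
    if (any(flip)) {
      tmp <- xb[flip, , drop = FALSE]
      xb[flip, ] <- yb[flip, , drop = FALSE]
      yb[flip, ] <- tmp
    }
    x <- cbind(a$x[ai, , drop = FALSE], xb)
    y <- cbind(a$y[ai, , drop = FALSE], yb)
  }
  samples <- rbind(a$samples, b$samples)
  out <- genotypes(calls, markers, samples, x = x, y = y)
  attr(out, "dropped") <- dropped
  out
}

#' Recode genotypes against two parental lines
#'
#' Re-expresses calls as the dosage of the `parentB` allele, keeping only
#' markers where the two parents are opposite homozygotes (the informative
#' markers for a biparental cross).  Markers where either parent is
#' missing, heterozygous, or where both carry the same homozygous genotype
#' are masked to missing.
#'
#' @param gset a `genotypes` object containing both parent samples.
#' @param parentA_id,parentB_id sample ids of the two parental lines.
#' @return `gset` with recoded calls and attribute `"informative"`, the
#'   logical marker mask.
#' @export
recode_by_parents <- function(gset, parentA_id, parentB_id) {
  pa <- match(parentA_id, gset$samples$id)
  pb <- match(parentB_id, gset$samples$id)
  if (is.na(pa) || is.na(pb)) stop("parent sample(s) not present")
  da <- gset$calls[, pa]; db <- gset$calls[, pb]
  informative <- !is.na(da) & !is.na(db) &
    ((da == 0L & db == 2L) | (da == 2L & db == 0L))
  flip <- informative & da == 2L          # parentA carries the B allele
  calls <- gset$calls
  calls[flip, ] <- 2L - calls[flip, , drop = FALSE]
  calls[!informative, ] <- NA_integer_
  gset$calls <- calls
  gset <- set_dimnames(gset)
  attr(gset, "informative") <- informative
  gset
}
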