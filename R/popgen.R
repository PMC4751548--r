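#' Per-marker allele frequencies, heterozygosity and missingness
#'
#' @param gset a `genotypes` object.
#' @return data frame, one row per marker: `name`, `freq_B` (B-allele
#'   frequency among non-missing calls; `NA` for all-missing markers),
#'   `het_rate`, `missing_rate`, `n_called`.
#' @export
allele_freqs <- function(gset) {
  cl <- gset$calls
  n_sm <- ncol(cl)
  n_called <- rowSums(!is.na(cl))
  freq <- ifelse(n_called > 0, rowSums(cl, na.rm = TRUE) / (2 * n_called),
                 NA_real_)
  data.frame(name = gset$markers$name, freq_B = freq,
             het_rate = ifelse(n_called > 0,
                               rowSums(cl == 1L, na.rm = TRUE) / n_called,
                               NA_real_),
             missing_rate = 1 - n_called / n_sm,
             n_called = n_called,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise identity-by-state distance
#'
#' For each pair of samples, the proportion of alleles shared identical by
#' state, averaged over jointly non-missing markers: per marker the shared
#' fraction is `(2 - |d_i - d_j|) / 2` for B-allele dosages `d`.  The
#' distance reported is one minus that proportion, so identical samples are
#' at distance 0 and opposite homozygotes at distance 1.  Pairs with fewer
#' than `min_overlap` jointly observed markers get a missing entry.
#'
#' @param gset a `genotypes` object with at least 2 samples.
#' @param min_overlap minimum number of jointly non-missing markers.
#' @return list of class `ibs_dist`: `distance` and `sharing` (n x n
#'   symmetric matrices), `n_overlap` (jointly non-missing marker counts),
#'   `ids`.
#' @export
ibs_distance <- function(gset, min_overlap = 1) {
  cl <- gset$calls
  n <- ncol(cl)
  if (n < 2) stop("at least 2 samples required")
  obs <- !is.na(cl)
  cl0 <- cl; cl0[!obs] <- 0L
  n_overlap <- crossprod(obs)             # joint non-missing counts
  # sum over joint markers of |d_i - d_j|, via the identity
  # |a-b| = a + b - 2*min(a,b); computed per dosage level to stay matrixwise
  abs_sum <- matrix(0, n, n)
  for (di in 0:2) for (dj in 0:2) {
    if (di == dj) next
    Ai <- (cl0 == di) & obs
    Aj <- (cl0 == dj) & obs
    abs_sum <- abs_sum + abs(di - dj) * crossprod(Ai, Aj)
  }
  sharing <- ifelse(n_overlap > 0, (2 * n_overlap - abs_sum) / (2 * n_overlap),
                    NA_real_)
  dist <- 1 - sharing
  dist[n_overlap < min_overlap] <- NA_real_
  sharing[n_overlap < min_overlap] <- NA_real_
  diag(dist) <- ifelse(diag(n_overlap) >= min_overlap, 0, NA_real_)
  ids <- gset$samples$id
  dimnames(dist) <- dimnames(sharing) <- dimnames(n_overlap) <- list(ids, ids)
  structure(list(distance = dist, sharing = sharing,
                 n_overlap = n_overlap, ids = ids), class = "ibs_dist")
}

#' Hierarchical clustering order for a distance matrix
#'
#' Agglomerative clustering (average linkage by default, via
#' [stats::hclust()]) of an IBS distance matrix, returning the merge
#' history and a leaf order that places closely related samples adjacently
#' in a heatmap.
#'
#' @param dist an `ibs_dist` object or a symmetric distance matrix.
#' @param method linkage method passed to [stats::hclust()].
#' @return list: `order` (leaf order, integer), `labels`, `merge`, `height`,
#'   and the underlying `hclust` object.
#' @export
hclust_order <- function(dist, method = "average") {
  m <- if (inherits(dist, "ibs_dist")) dist$distance else dist
  if (anyNA(m))
    stop("distance matrix has missing entries; relax min_overlap")
  hc <- stats::hclust(stats::as.dist(m), method = method)
  list(order = hc$order, labels = hc$labels, merge = hc$merge,
       height = hc$height, hclust = hc)
}

#' Principal components of the genotype matrix
#'
#' Projects samples onto the top `k` principal components of the
#' (markers-as-variables) genotype matrix.  Missing calls are mean-imputed
#' per marker; markers are centered and optionally scaled by the binomial
#' dosage standard deviation `sqrt(2 p (1 - p))`.  Signs follow a
#' deterministic convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param gset a `genotypes` object.
#' @param k number of components, at most `min(n_samples, n_markers)`.
#' @param scale scale markers by dosage standard deviation (default
#'   `FALSE`).
#' @return list: `scores` (samples x k), `loadings` (markers x k),
#'   `var_explained` (length-k fractions, non-increasing).
#' @export
pca_genotypes <- function(gset, k = 2, scale = FALSE) {
  cl <- gset$calls
  n_sm <- ncol(cl); n_mk <- nrow(cl)
  if (k > min(n_sm, n_mk)) stop("k exceeds min(n_samples, n_markers)")
  G <- t(cl)                              # samples x markers
  mu <- colMeans(G, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(n_mk)) {
    miss <- is.na(G[, j])
    if (any(miss)) G[miss, j] <- mu[j]
  }
  G <- sweep(G, 2, mu)
  if (scale) {
    p <- mu / 2
    sd <- sqrt(pmax(2 * p * (1 - p), .Machine$double.eps))
    G <- sweep(G, 2, sd, "/")
  }
  if (all(abs(G) < .Machine$double.eps)) stop("zero-variance genotype matrix")
  pc <- stats::prcomp(G, center = FALSE, scale. = FALSE)
  keep <- seq_len(k)
  scores <- pc$x[, keep, drop = FALSE]
  loadings <- pc$rotation[, keep, drop = FALSE]
  for (j in keep) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- gset$samples$id
  rownames(loadings) <- gset$markers$name
  list(scores = scores, loadings = loadings,
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[keep])
}

# possible offspring dosage range given two parental dosages (autosomal
# biallelic inheritance); the possible set is always the contiguous range
mendel_range <- function(f, m) {
  lo <- (f == 2L) + (m == 2L)
  hi <- 2L - ((f == 0L) + (m == 0L))
  c(lo, hi)
}

#' Mendelian-inconsistency check for trios
#'
#' Tests each offspring genotype against its parents under biallelic
#' inheritance.  A marker is tested when the offspring and at least one
#' parent are non-missing.  With both parents, the offspring dosage must be
#' attainable from one allele per parent (e.g. parents 0 x 0 force
#' offspring 0, parents 0 x 2 force offspring 1).  With a single observed
#' parent the weaker shared-allele rule applies: parent and offspring may
#' not be opposite homozygotes.  X-chromosome markers of male offspring are
#' tested hemizygously against the mother only (the call, coded 0 or 2,
#' must match a maternal allele).
#'
#' @param gset a `genotypes` object.
#' @param trios optional data frame with columns `offspring`, `father`,
#'   `mother`; defaults to trios derived from the sample table's
#'   `father`/`mother` fields.  Trios referencing absent samples are
#'   skipped with a warning.
#' @return data frame, one row per trio: `offspring`, `father`, `mother`,
#'   `n_tested`, `n_inconsistent`, `inconsistency_rate`, plus attribute
#'   `"inconsistent_markers"` (named list of marker-name vectors).
#' @export
mendel_check <- function(gset, trios = NULL) {
  sm <- gset$samples
  if (is.null(trios)) {
    has <- !is.na(sm$father) | !is.na(sm$mother)
    trios <- data.frame(offspring = sm$id[has], father = sm$father[has],
                        mother = sm$mother[has], stringsAsFactors = FALSE)
  }
  ids <- sm$id
  chrom <- toupper(gset$markers$chrom)
  on_x <- chrom == "X"
  auto <- is_autosome(chrom)
  res <- list(); bad_markers <- list()
  for (t in seq_len(nrow(trios))) {
    o_id <- trios$offspring[t]
    f_id <- trios$father[t]; m_id <- trios$mother[t]
    oi <- match(o_id, ids)
    fi <- if (is.na(f_id)) NA_integer_ else match(f_id, ids)
    mi <- if (is.na(m_id)) NA_integer_ else match(m_id, ids)
    if (is.na(oi) || (!is.na(f_id) && is.na(fi)) ||
        (!is.na(m_id) && is.na(mi))) {
      warning("trio for '", o_id, "' references an absent sample; skipped")
      next
    }
    o <- gset$calls[, oi]
    f <- if (is.na(fi)) rep(NA_integer_, length(o)) else gset$calls[, fi]
    m <- if (is.na(mi)) rep(NA_integer_, length(o)) else gset$calls[, mi]
    o_male <- sm$sex[oi] == "male"
    tested <- !is.na(o) & (!is.na(f) | !is.na(m))
    scope <- if (o_male) auto | on_x else auto
    tested <- tested & scope
    incons <- logical(length(o))
    for (i in which(tested)) {
      if (o_male && on_x[i]) {
        # hemizygous: only the maternal contribution is tested
        if (is.na(m[i])) { tested[i] <- FALSE; next }
        incons[i] <- (m[i] == 0L && o[i] != 0L) ||
                     (m[i] == 2L && o[i] != 2L)
      } else if (!is.na(f[i]) && !is.na(m[i])) {
        rng <- mendel_range(f[i], m[i])
        incons[i] <- o[i] < rng[1] || o[i] > rng[2]
      } else {
        p <- if (is.na(f[i])) m[i] else f[i]
        incons[i] <- abs(o[i] - p) == 2L
      }
    }
    res[[t]] <- data.frame(offspring = o_id, father = f_id, mother = m_id,
                           n_tested = sum(tested),
                           n_inconsistent = sum(incons[tested]),
                           stringsAsFactors = FALSE)
    bad_markers[[o_id]] <- gset$markers$name[tested & incons]
  }
  out <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(offspring = character(0), father = character(0),
               mother = character(0), n_tested = integer(0),
               n_inconsistent = integer(0))
  out$inconsistency_rate <- ifelse(out$n_tested > 0,
                                   out$n_inconsistent / out$n_tested, NA_real_)
  rownames(out) <- NULL
  attr(out, "inconsistent_markers") <- bad_markers
  out
}
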