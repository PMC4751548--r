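#' Polar intensity coordinates
#'
#' Transforms two-channel intensities to the standard Illumina polar
#' coordinates: `theta = (2/pi) * atan2(y, x)`, which runs from 0 (pure A
#' signal) to 1 (pure B signal), and total intensity `R = x + y`.  Using the
#' two-argument arctangent means `x = 0` maps to theta exactly 1.
#'
#' @param x,y non-negative intensity vectors or matrices of equal shape.
#' @return list with components `theta` and `R`; `theta` is `NA` where
#'   `x == y == 0`.
#' @export
theta_r <- function(x, y) {
  if (any(x < 0 | y < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  theta <- (2 / pi) * atan2(y, x)
  theta[!is.na(x) & !is.na(y) & x == 0 & y == 0] <- NA_real_
  list(theta = theta, R = x + y)
}

# inverse of theta_r: split total intensity R into (x, y) so that
# theta_r(x, y)$theta == theta exactly.  Used by the simulator.
xy_from_theta_r <- function(theta, R) {
  x <- ifelse(theta >= 1, 0, R / (1 + tan(pi * theta / 2)))
  x <- pmin(pmax(x, 0), R)
  list(x = x, y = R - x)
}

#' Between-array quantile normalization
#'
#' Forces every column (array) of a one-channel intensity matrix to the same
#' distribution: the mean of the per-rank values across columns, with ties
#' averaged.  Delegates to [limma::normalizeQuantiles()].
#'
#' @param mat numeric matrix, markers x arrays.
#' @return matrix of the same shape with columns quantile-normalized.
#' @export
quantile_normalize_between <- function(mat) {
  if (!is.matrix(mat)) stop("'mat' must be a matrix")
  if (ncol(mat) < 2) {
    warning("fewer than 2 arrays: between-array normalization is a no-op")
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Thresholded within-array quantile normalization of one sample
#'
#' The tQN step proper: quantile-normalizes the x channel against the y
#' channel within a single array to remove Infinium dye bias.  The target
#' distribution is the mean of the two sorted channels; each channel is
#' mapped through it by (average) rank.  A multiplicative cap then bounds
#' how far any value may move upward: the normalized value may not exceed
#' `threshold` times the raw value.  Zeros pass through unchanged.
#'
#' @param x_col,y_col equal-length non-negative vectors over one sample's
#'   markers.
#' @param threshold multiplicative cap, > 1; `Inf` reproduces plain
#'   quantile normalization.
#' @return list with normalized vectors `x` and `y`.
#' @export
tqn_within <- function(x_col, y_col, threshold = 1.5) {
  if (length(x_col) != length(y_col))
    stop("channels must have equal length")
  if (any(x_col < 0 | y_col < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  if (threshold <= 1) stop("'threshold' must exceed 1")
  ok <- !is.na(x_col) & !is.na(y_col)
  x <- x_col[ok]; y <- y_col[ok]
  n <- length(x)
  xn <- x_col; yn <- y_col
  if (n > 0) {
    target <- (sort(x) + sort(y)) / 2
    map <- function(v) {
      r <- rank(v, ties.method = "average")
      if (n == 1) return(target)
      stats::approx(seq_len(n), target, xout = r)$y
    }
    vx <- pmin(map(x), threshold * x)
    vy <- pmin(map(y), threshold * y)
    vx[x == 0] <- 0
    vy[y == 0] <- 0
    xn[ok] <- vx
    yn[ok] <- vy
  }
  list(x = xn, y = yn)
}

#' Estimate genotype-cluster positions from reference samples
#'
#' For every marker, computes the median polar coordinates (theta, R) of the
#' reference samples carrying each genotype, after passing the reference
#' intensities through the identical normalization chain that will later be
#' applied to the study samples (optional between-array quantile
#' normalization, then per-sample thresholded quantile normalization).
#' These centroids anchor the BAF interpolation and the LRR reference level.
#'
#' Sparse classes are imputed: a missing heterozygote centroid is placed at
#' the midpoint of the two homozygote thetas with the mean of their R; a
#' missing homozygote mirrors the observed one about theta = 0.5 and copies
#' its R.  Markers where no centroid triple can be formed, or where the
#' triple is not monotone in theta, are excluded (all `NA`), and downstream
#' BAF/LRR are missing there.
#'
#' @param reference_gset a `genotypes` object with calls and x/y intensities.
#' @param min_cluster_size minimum reference count for a centroid to be used
#'   directly rather than imputed (default 3).
#' @param threshold,prenormalize normalization-chain parameters; see [tqn()].
#' @param provenance label recorded with the cluster table identifying the
#'   reference set.
#' @return data frame (one row per marker) with columns `name`, `theta_AA`,
#'   `theta_AB`, `theta_BB`, `r_AA`, `r_AB`, `r_BB`, `n_AA`, `n_AB`, `n_BB`,
#'   `imputed` (comma-separated class labels) and `provenance`.
#' @export
estimate_clusters <- function(reference_gset, min_cluster_size = 3,
                              threshold = 1.5, prenormalize = FALSE,
                              provenance = "reference") {
  g <- reference_gset
  if (is.null(g$x) || is.null(g$y))
    stop("reference set has no intensities")
  nt <- normalize_intensities(g, threshold, prenormalize)
  n_mk <- nrow(g$calls)
  out <- data.frame(name = g$markers$name,
                    theta_AA = NA_real_, theta_AB = NA_real_,
                    theta_BB = NA_real_,
                    r_AA = NA_real_, r_AB = NA_real_, r_BB = NA_real_,
                    n_AA = 0L, n_AB = 0L, n_BB = 0L,
                    imputed = "", provenance = provenance,
                    stringsAsFactors = FALSE)
  cls <- c("AA", "AB", "BB")
  for (i in seq_len(n_mk)) {
    d <- g$calls[i, ]
    th <- nt$theta[i, ]; rr <- nt$R[i, ]
    theta <- rep(NA_real_, 3); rval <- rep(NA_real_, 3); nn <- integer(3)
    for (k in 1:3) {
      sel <- !is.na(d) & d == (k - 1L) & !is.na(th)
      nn[k] <- sum(sel)
      if (nn[k] >= min_cluster_size) {
        theta[k] <- stats::median(th[sel])
        rval[k] <- stats::median(rr[sel])
      }
    }
    imp <- character(0)
    # mirror a missing homozygote about theta = 0.5
    if (is.na(theta[1]) && !is.na(theta[3])) {
      theta[1] <- 1 - theta[3]; rval[1] <- rval[3]; imp <- c(imp, "AA")
    } else if (is.na(theta[3]) && !is.na(theta[1])) {
      theta[3] <- 1 - theta[1]; rval[3] <- rval[1]; imp <- c(imp, "BB")
    }
    # heterozygote at the midpoint of the flanking homozygotes
    if (is.na(theta[2]) && !is.na(theta[1]) && !is.na(theta[3])) {
      theta[2] <- (theta[1] + theta[3]) / 2
      rval[2] <- (rval[1] + rval[3]) / 2
      imp <- c(imp, "AB")
    }
    if (anyNA(theta) || is.unsorted(theta)) {
      theta <- rep(NA_real_, 3); rval <- rep(NA_real_, 3); imp <- character(0)
    }
    out[i, c("theta_AA", "theta_AB", "theta_BB")] <- theta
    out[i, c("r_AA", "r_AB", "r_BB")] <- rval
    out[i, c("n_AA", "n_AB", "n_BB")] <- nn
    out$imputed[i] <- paste(imp, collapse = ",")
  }
  out
}

#' B-allele frequency from theta
#'
#' Piecewise-linear rescaling of theta anchored at the genotype cluster
#' centroids: BAF is 0 at and below `theta_AA`, 0.5 at `theta_AB`, 1 at and
#' above `theta_BB`, linear between.
#'
#' @param theta numeric vector of polar coordinates in `[0,1]`.
#' @param cluster one-row cluster record with `theta_AA`, `theta_AB`,
#'   `theta_BB` (a list or data-frame row).
#' @return BAF vector; `NA` where theta or the cluster is missing, or where
#'   the cluster is degenerate (coincident centroids) and theta falls inside
#'   the degenerate segment.
#' @export
baf_from_theta <- function(theta, cluster) {
  tAA <- cluster$theta_AA; tAB <- cluster$theta_AB; tBB <- cluster$theta_BB
  out <- rep(NA_real_, length(theta))
  if (is.na(tAA) || is.na(tAB) || is.na(tBB)) return(out)
  lo <- !is.na(theta) & theta <= tAA
  hi <- !is.na(theta) & theta >= tBB
  mid1 <- !is.na(theta) & theta > tAA & theta < tAB
  mid2 <- !is.na(theta) & theta >= tAB & theta < tBB
  out[lo] <- 0
  out[hi] <- 1
  if (any(mid1)) {
    if (tAB == tAA) {
      warning("degenerate cluster: theta_AA == theta_AB")
    } else {
      out[mid1] <- 0.5 * (theta[mid1] - tAA) / (tAB - tAA)
    }
  }
  if (any(mid2)) {
    if (tBB == tAB) {
      warning("degenerate cluster: theta_AB == theta_BB")
      out[mid2] <- NA_real_
    } else {
      out[mid2] <- 0.5 + 0.5 * (theta[mid2] - tAB) / (tBB - tAB)
    }
  }
  out
}

#' Log R ratio from total intensity
#'
#' The expected intensity R0 at the observed theta is the linear
#' interpolation of the three cluster (theta, R) centroids, clamped to the
#' nearest centroid beyond the outer clusters (no extrapolation).  LRR is
#' `log2(R / R0)`; missing where R or R0 is non-positive or the cluster is
#' unavailable.
#'
#' @inheritParams baf_from_theta
#' @param R total intensity vector, same length as `theta`.
#' @return LRR vector.
#' @export
lrr_from_r <- function(theta, R, cluster) {
  out <- rep(NA_real_, length(theta))
  tt <- c(cluster$theta_AA, cluster$theta_AB, cluster$theta_BB)
  rr <- c(cluster$r_AA, cluster$r_AB, cluster$r_BB)
  if (anyNA(tt) || anyNA(rr)) return(out)
  ok <- !is.na(theta) & !is.na(R) & R > 0
  if (!any(ok)) return(out)
  th <- pmin(pmax(theta[ok], tt[1]), tt[3])
  r0 <- if (tt[1] == tt[3]) {
    rep(mean(rr), length(th))
  } else {
    stats::approx(tt, rr, xout = th, ties = mean)$y
  }
  val <- ifelse(r0 > 0, log2(R[ok] / r0), NA_real_)
  out[ok] <- val
  out
}

# shared normalization chain: optional between-array QN per channel, then
# per-sample thresholded within-array QN, then polar coordinates
normalize_intensities <- function(gset, threshold = 1.5,
                                  prenormalize = FALSE) {
  x <- gset$x; y <- gset$y
  if (prenormalize && ncol(x) >= 2) {
    x <- quantile_normalize_between(x)
    y <- quantile_normalize_between(y)
  }
  for (j in seq_len(ncol(x))) {
    nj <- tqn_within(x[, j], y[, j], threshold)
    x[, j] <- nj$x; y[, j] <- nj$y
  }
  tr <- theta_r(x, y)
  list(x = x, y = y, theta = tr$theta, R = tr$R)
}

#' Thresholded quantile normalization with BAF/LRR computation
#'
#' Runs the full tQN chain on a `genotypes` object: optional preliminary
#' between-array quantile normalization of each channel, per-sample
#' thresholded quantile normalization of x against y, transformation to
#' polar coordinates, and computation of BAF and LRR against the reference
#' cluster positions in `cluster_table`.  Markers absent from the cluster
#' table (or with unusable centroids) get missing BAF/LRR.
#'
#' @param gset a `genotypes` object with x/y intensities.
#' @param cluster_table output of [estimate_clusters()] covering (a subset
#'   of) the markers of `gset`.
#' @param threshold multiplicative tQN cap (default 1.5).
#' @param prenormalize run between-array quantile normalization first
#'   (default `FALSE`).
#' @return `gset` with `x`/`y` replaced by their normalized values, `baf`
#'   and `lrr` matrices filled in, and the `normalized` flag set.
#' @export
tqn <- function(gset, cluster_table, threshold = 1.5, prenormalize = FALSE) {
  if (is.null(gset$x) || is.null(gset$y))
    stop("no intensities: tQN requires x and y matrices")
  nt <- normalize_intensities(gset, threshold, prenormalize)
  n_mk <- nrow(gset$calls); n_sm <- ncol(gset$calls)
  baf <- matrix(NA_real_, n_mk, n_sm)
  lrr <- matrix(NA_real_, n_mk, n_sm)
  idx <- match(gset$markers$name, cluster_table$name)
  for (i in seq_len(n_mk)) {
    ci <- idx[i]
    if (is.na(ci)) next
    cl <- cluster_table[ci, ]
    baf[i, ] <- baf_from_theta(nt$theta[i, ], cl)
    lrr[i, ] <- lrr_from_r(nt$theta[i, ], nt$R[i, ], cl)
  }
  gset$x <- nt$x; gset$y <- nt$y
  gset$baf <- baf; gset$lrr <- lrr
  gset$normalized <- TRUE
  set_dimnames(gset)
}
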