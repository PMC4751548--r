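#' Cluster-plot data for one marker
#'
#' The two-channel intensities of every sample at a single marker, with the
#' genotype call and QC flag attached — the ingredients of the classic
#' per-marker "cluster plot" used to audit call accuracy.
#'
#' @param gset a `genotypes` object with intensities.
#' @param marker marker name.
#' @return data frame: `id`, `x`, `y`, `theta`, `R`, `call`, `flag`.
#' @export
cluster_plot_data <- function(gset, marker) {
  if (is.null(gset$x) || is.null(gset$y)) stop("intensities required")
  i <- match(marker, gset$markers$name)
  if (is.na(i)) stop("unknown marker: ", marker)
  tr <- theta_r(gset$x[i, ], gset$y[i, ])
  data.frame(id = gset$samples$id, x = gset$x[i, ], y = gset$y[i, ],
             theta = tr$theta, R = tr$R, call = gset$calls[i, ],
             flag = gset$samples$qc_flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dotplot data for a genomic region
#'
#' Genotype calls over a region laid out at constant marker spacing, with
#' the true physical positions carried alongside for guide lines.  The
#' display dosage is flipped to counts of the reference (A) allele,
#' `2 - d`; missing calls yield `NA` cells.
#'
#' @param gset a `genotypes` object.
#' @param region `list(chrom =, start =, end =)`, 1-based closed interval.
#' @param flip_to_reference flip B-dosage to reference-allele counts for
#'   display (default `TRUE`).
#' @return data frame with one row per (marker, sample): `marker`, `index`
#'   (constant spacing), `pos_Mbp`, `id`, `dosage`.
#' @export
dotplot_data <- function(gset, region, flip_to_reference = TRUE) {
  sub <- subset_genotypes(gset, markers = region)
  n_mk <- nrow(sub$calls)
  if (n_mk == 0)
    return(data.frame(marker = character(0), index = integer(0),
                      pos_Mbp = numeric(0), id = character(0),
                      dosage = integer(0)))
  d <- sub$calls
  if (flip_to_reference) d <- 2L - d
  data.frame(marker = rep(sub$markers$name, ncol(d)),
             index = rep(seq_len(n_mk), ncol(d)),
             pos_Mbp = rep(sub$markers$pos / 1e6, ncol(d)),
             id = rep(sub$samples$id, each = n_mk),
             dosage = as.vector(d),
             stringsAsFactors = FALSE)
}

# centered running median with shrinking windows at the edges; NAs skipped
running_median <- function(v, window) {
  if (window %% 2 == 0) stop("smooth window must be odd")
  half <- (window - 1) / 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    w <- v[max(1, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else stats::median(w, na.rm = TRUE)
  }, numeric(1))
}

#' BAF/LRR track for one sample
#'
#' Per-marker BAF and LRR along the genome for one sample, with a centered
#' running-median smoothing trace (the red trace of the standard joint
#' BAF/LRR figure).  Edge positions use shrinking windows; missing values
#' are skipped within each window.
#'
#' @param gset a normalized `genotypes` object (see [tqn()]).
#' @param sample sample id.
#' @param smooth_window odd window width in markers (default 31).
#' @return data frame: `marker`, `chrom`, `pos`, `baf`, `lrr`,
#'   `baf_smooth`, `lrr_smooth`.
#' @export
baf_lrr_track <- function(gset, sample, smooth_window = 31) {
  if (is.null(gset$baf) || is.null(gset$lrr))
    stop("no normalized tracks: run tqn() first")
  j <- match(sample, gset$samples$id)
  if (is.na(j)) stop("unknown sample: ", sample)
  baf <- gset$baf[, j]; lrr <- gset$lrr[, j]
  sm_b <- numeric(0); sm_l <- numeric(0)
  for (ch in unique(gset$markers$chrom)) {
    sel <- gset$markers$chrom == ch
    sm_b <- c(sm_b, running_median(baf[sel], smooth_window))
    sm_l <- c(sm_l, running_median(lrr[sel], smooth_window))
  }
  data.frame(marker = gset$markers$name, chrom = gset$markers$chrom,
             pos = gset$markers$pos, baf = baf, lrr = lrr,
             baf_smooth = sm_b, lrr_smooth = sm_l,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mosaic-plot data for one or two markers
#'
#' One marker: per-genotype bar widths proportional to genotype frequency,
#' with the phenotype distribution (categorical) or mean (numeric) as
#' fill.  Two markers: block areas proportional to the joint two-locus
#' genotype frequency, fill = per-cell phenotype mean.  Samples with any
#' missing genotype at the chosen markers are excluded and counted.
#'
#' @param gset a `genotypes` object.
#' @param markers one or two marker names.
#' @param phenotype vector aligned to samples, or the name of a
#'   sample-table column.
#' @return data frame of blocks with `width` (one-marker) or `area`
#'   (two-marker) summing to 1, `n`, and `fill` (phenotype mean); attribute
#'   `"n_excluded"` counts samples dropped for missingness.
#' @export
mosaic_data <- function(gset, markers, phenotype = "phenotype") {
  if (!length(markers) %in% 1:2) stop("supply one or two markers")
  mi <- match(markers, gset$markers$name)
  if (anyNA(mi)) stop("unknown marker(s)")
  ph <- if (is.character(phenotype) && length(phenotype) == 1)
    gset$samples[[phenotype]] else phenotype
  if (is.null(ph) || all(is.na(ph))) stop("no phenotype available")
  g <- gset$calls[mi, , drop = FALSE]
  keep <- colSums(is.na(g)) == 0
  n_excluded <- sum(!keep)
  if (!any(keep)) stop("all genotypes missing at the chosen marker(s)")
  g <- g[, keep, drop = FALSE]
  ph <- ph[keep]
  if (length(mi) == 1) {
    out <- do.call(rbind, lapply(0:2, function(v) {
      sel <- g[1, ] == v
      data.frame(genotype1 = v, n = sum(sel),
                 width = mean(sel),
                 fill = if (any(sel)) mean(ph[sel], na.rm = TRUE) else NA_real_)
    }))
  } else {
    out <- do.call(rbind, lapply(0:2, function(v1) {
      do.call(rbind, lapply(0:2, function(v2) {
        sel <- g[1, ] == v1 & g[2, ] == v2
        data.frame(genotype1 = v1, genotype2 = v2, n = sum(sel),
                   area = mean(sel),
                   fill = if (any(sel)) mean(ph[sel], na.rm = TRUE)
                          else NA_real_)
      }))
    }))
  }
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}
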