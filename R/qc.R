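#' Per-sample quality-control statistics
#'
#' Computes, for every sample, the distribution of its genotype calls
#' (missing / heterozygous / homozygous counts and call rate), summaries of
#' total hybridization intensity R = x + y when intensities are present,
#' and the sex-chromosome statistics used by [infer_sex()]: the
#' heterozygosity rate among X-chromosome calls and the median R over
#' Y-chromosome markers.  Failed arrays show up as outliers in these
#' statistics — aberrant intensity distributions, excess missingness or
#' excess heterozygosity.
#'
#' Markers on the pseudoautosomal "XY" region are excluded from the
#' X-heterozygosity rate.
#'
#' @param gset a `genotypes` object.
#' @return data frame, one row per sample: `id`, `n_missing`, `n_het`,
#'   `n_hom`, `call_rate`, and when available `intensity_median`,
#'   `intensity_iqr`, `x_het_rate`, `y_intensity`.
#' @export
sample_qc <- function(gset) {
  cl <- gset$calls
  n_mk <- nrow(cl)
  n_missing <- colSums(is.na(cl))
  n_het <- colSums(cl == 1L, na.rm = TRUE)
  n_hom <- colSums(cl == 0L | cl == 2L, na.rm = TRUE)
  out <- data.frame(id = gset$samples$id,
                    n_missing = n_missing, n_het = n_het, n_hom = n_hom,
                    call_rate = 1 - n_missing / n_mk,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(gset$x) && !is.null(gset$y)) {
    R <- gset$x + gset$y
    out$intensity_median <- apply(R, 2, stats::median, na.rm = TRUE)
    out$intensity_iqr <- apply(R, 2, stats::IQR, na.rm = TRUE)
  }
  chrom <- toupper(gset$markers$chrom)
  on_x <- chrom == "X"
  if (any(on_x)) {
    xc <- cl[on_x, , drop = FALSE]
    out$x_het_rate <- colSums(xc == 1L, na.rm = TRUE) /
      pmax(colSums(!is.na(xc)), 1L)
  }
  on_y <- chrom == "Y"
  if (any(on_y) && !is.null(gset$x)) {
    Ry <- (gset$x + gset$y)[on_y, , drop = FALSE]
    out$y_intensity <- apply(Ry, 2, stats::median, na.rm = TRUE)
  }
  out
}

#' Infer sample sex from the sex chromosomes
#'
#' Males are hemizygous on X, so genuine heterozygous X calls should be
#' (nearly) absent; they also carry Y-marker signal when Y probes are on
#' the array.  A sample is called male when its X heterozygosity rate is
#' below `x_het_threshold` and, when Y intensity is available, above
#' `y_intensity_threshold`; female when X heterozygosity is at or above the
#' threshold and Y evidence is absent or low; otherwise unknown.
#' Discordance with the recorded metadata sex is a classic signature of
#' sample swaps or contamination.
#'
#' @param gset a `genotypes` object with X-chromosome markers.
#' @param x_het_threshold X-heterozygosity boundary (default 0.1).
#' @param y_intensity_threshold Y median-R boundary (default 0.275, midway
#'   between the female background level of ~0.05 and the hemizygous male
#'   signal of ~0.5 on an array normalized to R = 1 for diploid calls).
#' @return data frame: `id`, `x_het_rate`, `y_intensity` (`NA` when
#'   unavailable), `inferred_sex`, `recorded_sex`, `sex_concordant`
#'   (`"yes"`, `"no"` or `"unknown"`).
#' @export
infer_sex <- function(gset, x_het_threshold = 0.1,
                      y_intensity_threshold = 0.275) {
  qc <- sample_qc(gset)
  if (is.null(qc$x_het_rate)) {
    warning("no X-chromosome markers: sex cannot be inferred")
    qc$x_het_rate <- NA_real_
  }
  yint <- if (is.null(qc$y_intensity)) rep(NA_real_, nrow(qc)) else
    qc$y_intensity
  male_x <- !is.na(qc$x_het_rate) & qc$x_het_rate < x_het_threshold
  y_high <- !is.na(yint) & yint > y_intensity_threshold
  y_low <- !is.na(yint) & yint <= y_intensity_threshold
  inferred <- rep("unknown", nrow(qc))
  inferred[male_x & (y_high | is.na(yint))] <- "male"
  inferred[!male_x & !is.na(qc$x_het_rate) & !y_high] <- "female"
  recorded <- gset$samples$sex
  concord <- ifelse(inferred == "unknown" | recorded == "unknown",
                    "unknown", ifelse(inferred == recorded, "yes", "no"))
  data.frame(id = qc$id, x_het_rate = qc$x_het_rate, y_intensity = yint,
             inferred_sex = inferred, recorded_sex = recorded,
             sex_concordant = concord,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag failing samples against QC thresholds
#'
#' Marks each sample `pass` or `fail` against global or subgroup-specific
#' thresholds on missingness, heterozygosity (raw counts, matching
#' per-array totals) and median intensity.  When `group_by` names a
#' sample-table column, `thresholds` may be a named list of per-group
#' threshold sets; groups without an entry use the `".default"` entry if
#' present, otherwise pass.
#'
#' Flagging is monotone: relaxing any threshold can never turn a pass into
#' a fail.
#'
#' @param gset a `genotypes` object.
#' @param thresholds list with any of `max_missing`, `max_het`,
#'   `min_intensity`, `max_intensity`; or, with `group_by`, a named list of
#'   such lists keyed by group label.
#' @param group_by optional sample-table column name for subgroup-specific
#'   thresholds.
#' @return `gset` with `samples$qc_flag` updated.
#' @export
flag_samples <- function(gset, thresholds, group_by = NULL) {
  qc <- sample_qc(gset)
  n <- nrow(qc)
  grouped <- !is.null(group_by)
  if (grouped) {
    grp <- gset$samples[[group_by]]
    if (is.null(grp)) stop("no sample column '", group_by, "'")
    labels <- setdiff(names(thresholds), ".default")
    unknown <- setdiff(labels, unique(as.character(grp)))
    if (length(unknown) > 0)
      stop("thresholds name unknown group(s): ",
           paste(unknown, collapse = ", "))
  }
  fails <- logical(n)
  for (i in seq_len(n)) {
    th <- if (!grouped) thresholds else {
      g <- as.character(grp[i])
      if (!is.null(thresholds[[g]])) thresholds[[g]]
      else thresholds[[".default"]]
    }
    if (is.null(th)) next
    viol <- FALSE
    if (!is.null(th$max_missing)) viol <- viol || qc$n_missing[i] > th$max_missing
    if (!is.null(th$max_het)) viol <- viol || qc$n_het[i] > th$max_het
    if (!is.null(th$min_intensity) && !is.null(qc$intensity_median))
      viol <- viol || qc$intensity_median[i] < th$min_intensity
    if (!is.null(th$max_intensity) && !is.null(qc$intensity_median))
      viol <- viol || qc$intensity_median[i] > th$max_intensity
    fails[i] <- viol
  }
  gset$samples$qc_flag <- ifelse(fails, "fail", "pass")
  gset
}

#' Plot-ready QC summary data
#'
#' Returns the ingredients of the standard QC summary figure: the
#' per-sample call distribution (ordered by missingness, failed samples
#' marked) and a binned two-dimensional histogram of total intensity R
#' across samples, suitable for contouring.  The histogram counts sum to
#' `n_markers * n_samples`.
#'
#' @param gset a `genotypes` object.
#' @param n_bins number of R bins for the intensity histogram.
#' @return list with `call_distribution` (data frame) and, when intensities
#'   are present, `intensity_density` (list: `breaks`, `counts` matrix of
#'   samples x bins, in the same sample order as `call_distribution`).
#' @export
qc_summary_data <- function(gset, n_bins = 50) {
  cd <- genotype_counts(gset, "sample")
  cd$flag <- gset$samples$qc_flag
  ord <- order(cd$n_missing)
  cd <- cd[ord, , drop = FALSE]
  rownames(cd) <- NULL
  out <- list(call_distribution = cd)
  if (!is.null(gset$x) && !is.null(gset$y)) {
    R <- (gset$x + gset$y)[, ord, drop = FALSE]
    rng <- range(R, na.rm = TRUE)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    counts <- t(apply(R, 2, function(col) {
      col <- col[!is.na(col)]
      graphics::hist(col, breaks = breaks, plot = FALSE)$counts
    }))
    rownames(counts) <- cd$id
    out$intensity_density <- list(breaks = breaks, counts = counts)
  }
  out
}
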