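#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator.  The generator
#' emulates the standard Infinium intensity model: per genotype class,
#' two-channel intensities cluster around canonical polar centroids
#' (theta 0.05 / 0.5 / 0.95 for AA / AB / BB, total intensity R = 1) with
#' Gaussian noise, so that R = x + y is approximately 1 for a clean diploid
#' call.  Population structure is induced by logit-normal drift of marker
#' allele frequencies around shared ancestral frequencies.
#'
#' @param n_pops number of populations.
#' @param n_per_pop samples per population (scalar or vector of length
#'   `n_pops`).
#' @param n_markers number of autosomal markers.
#' @param n_markers_x,n_markers_y number of X- resp. Y-chromosome markers
#'   (default 0).
#' @param divergence scale of the per-population perturbation of ancestral
#'   allele frequencies, expressed on the allele-frequency scale: each
#'   population's frequencies drift by logit-normal noise with standard
#'   deviation `4 * divergence` on the logit scale, displacing intermediate
#'   frequencies by about `divergence`.  0 makes populations exchangeable.
#' @param cluster_theta,cluster_r canonical (theta, R) centroids for the
#'   AA/AB/BB genotype classes.
#' @param noise_sigma Gaussian standard deviation of simulated theta and R
#'   around their centroids.
#' @param missing_rate probability that a call is missing.
#' @param male_fraction fraction of samples simulated as male.
#' @param contamination optional data frame with columns `sample`, `with`,
#'   `fraction`: sample `sample`'s intensities are mixed with `with`'s at
#'   the given fraction.
#' @param seed integer seed; mandatory, so every generated dataset is
#'   reproducible.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 1, n_per_pop = 10, n_markers = 1000,
                       n_markers_x = 0, n_markers_y = 0,
                       divergence = 0, cluster_theta = c(0.05, 0.5, 0.95),
                       cluster_r = c(1, 1, 1), noise_sigma = 0.03,
                       missing_rate = 0, male_fraction = 0,
                       contamination = NULL, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  rates <- c(divergence = divergence, missing_rate = missing_rate,
             male_fraction = male_fraction)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0,1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  if (length(n_per_pop) == 1) n_per_pop <- rep(n_per_pop, n_pops)
  stopifnot(length(n_per_pop) == n_pops, n_markers + n_markers_x >= 1,
            length(cluster_theta) == 3, length(cluster_r) == 3)
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop,
                 n_markers = n_markers, n_markers_x = n_markers_x,
                 n_markers_y = n_markers_y, divergence = divergence,
                 cluster_theta = cluster_theta, cluster_r = cluster_r,
                 noise_sigma = noise_sigma, missing_rate = missing_rate,
                 male_fraction = male_fraction, contamination = contamination,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_marker_map <- function(config) {
  n_auto <- config$n_markers
  # spread autosomal markers over 19 autosomes (mouse-like), ~100 Mbp each
  chrom <- as.character(1 + (seq_len(n_auto) - 1) %% 19)
  pos <- 1e6 + ((seq_len(n_auto) - 1) %/% 19) * 5e4
  mk <- data.frame(name = sprintf("rs%05d", seq_len(n_auto)),
                   chrom = chrom, pos = as.integer(pos),
                   stringsAsFactors = FALSE)
  if (config$n_markers_x > 0) {
    mk <- rbind(mk, data.frame(
      name = sprintf("rsX%04d", seq_len(config$n_markers_x)),
      chrom = "X", pos = as.integer(1e6 + (seq_len(config$n_markers_x) - 1) * 5e4)))
  }
  if (config$n_markers_y > 0) {
    mk <- rbind(mk, data.frame(
      name = sprintf("rsY%04d", seq_len(config$n_markers_y)),
      chrom = "Y", pos = as.integer(1e6 + (seq_len(config$n_markers_y) - 1) * 5e4)))
  }
  n <- nrow(mk)
  alle <- matrix(c("A", "G", "A", "C", "T", "C", "T", "G"), ncol = 2,
                 byrow = TRUE)[1 + (seq_len(n) - 1) %% 4, , drop = FALSE]
  mk$cM <- NA_real_
  mk$allele_A <- alle[, 1]
  mk$allele_B <- alle[, 2]
  mk
}

#' Simulate genotypes with population structure
#'
#' Ancestral B-allele frequencies are drawn Uniform(0.05, 0.95) per marker;
#' each population perturbs them independently on the logit scale by
#' Normal(0, divergence) drift.  Genotypes are Binomial(2, p) draws from the
#' population frequency; X-chromosome genotypes of males are drawn haploid
#' and stored hemizygous-coded (dosage 0 or 2); male Y markers likewise,
#' while female Y calls are missing.  Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with the `genotypes` object (`gset`), the per-sample true
#'   population labels (`population`) and the per-population frequency
#'   matrix (`freqs`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mk <- sim_marker_map(config)
  n_mk <- nrow(mk)
  n_sm <- sum(config$n_per_pop)
  pop <- rep(seq_len(config$n_pops), config$n_per_pop)
  ids <- sprintf("pop%d_s%02d", pop,
                 as.integer(stats::ave(pop, pop, FUN = seq_along)))
  sex <- ifelse(seq_len(n_sm) <= round(config$male_fraction * n_sm),
                "male", "female")
  p0 <- stats::runif(n_mk, 0.05, 0.95)
  logit <- function(p) log(p / (1 - p))
  # divergence is on the allele-frequency scale: a drift of d displaces
  # intermediate frequencies by about d, so the logit-normal sd is d times
  # the inverse logistic slope at p = 0.5 (i.e. 4d)
  freqs <- vapply(seq_len(config$n_pops), function(k) {
    if (config$divergence == 0) p0
    else stats::plogis(logit(p0) +
                       stats::rnorm(n_mk, 0, 4 * config$divergence))
  }, numeric(n_mk))
  on_x <- mk$chrom == "X"
  on_y <- mk$chrom == "Y"
  calls <- matrix(NA_integer_, n_mk, n_sm)
  for (j in seq_len(n_sm)) {
    p <- freqs[, pop[j]]
    g <- stats::rbinom(n_mk, 2L, p)
    if (sex[j] == "male") {
      hap <- which(on_x | on_y)
      g[hap] <- 2L * stats::rbinom(length(hap), 1L, p[hap])
    } else if (any(on_y)) {
      g[on_y] <- NA_integer_
    }
    calls[, j] <- g
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(n_mk * n_sm) < config$missing_rate, n_mk, n_sm)
    calls[drop] <- NA_integer_
  }
  samples <- data.frame(id = ids, sex = sex, stringsAsFactors = FALSE)
  gset <- genotypes(calls, mk, samples)
  list(gset = gset, population = stats::setNames(pop, ids), freqs = freqs)
}

#' Simulate two-channel intensities for a genotype set
#'
#' For each call, draws polar coordinates around the genotype's canonical
#' centroid — theta from a Normal truncated to `[0,1]`, R from a Normal
#' floored at 0 — and inverts them exactly into channel intensities, so
#' that [theta_r()] recovers the simulated theta bit-exactly.  Male X and Y
#' markers use the homozygote-like hemizygous clusters with R scaled by
#' 0.5; female Y markers emit background (R around 0.05, theta uniform),
#' as do missing calls.  Contamination replaces a sample's intensities by a
#' `(1 - f, f)` mixture with another sample's.
#'
#' @param gset a `genotypes` object with calls.
#' @param config a [sim_config()]; uses the cluster model, `noise_sigma`,
#'   `contamination` and `seed` (offset so intensity noise is independent
#'   of the genotype draw).
#' @return `gset` with `x` and `y` matrices filled in.
#' @export
simulate_intensities <- function(gset, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_mk <- nrow(gset$calls); n_sm <- ncol(gset$calls)
  sigma <- config$noise_sigma
  th_c <- config$cluster_theta
  r_c <- config$cluster_r
  on_sex <- gset$markers$chrom %in% c("X", "Y")
  on_y <- gset$markers$chrom == "Y"
  male <- gset$samples$sex == "male"
  theta <- matrix(NA_real_, n_mk, n_sm)
  R <- matrix(NA_real_, n_mk, n_sm)
  for (j in seq_len(n_sm)) {
    g <- gset$calls[, j]
    mu_t <- th_c[g + 1L]
    mu_r <- r_c[g + 1L]
    if (male[j] && any(on_sex)) mu_r[on_sex] <- mu_r[on_sex] * 0.5
    bg <- is.na(g) | (!male[j] & on_y)
    mu_t[bg] <- stats::runif(sum(bg))
    mu_r[bg] <- ifelse(is.na(g[bg]) & !on_y[bg], 1, 0.05)
    tj <- mu_t + if (sigma > 0) stats::rnorm(n_mk, 0, sigma) else 0
    rj <- mu_r + if (sigma > 0) stats::rnorm(n_mk, 0, sigma) else 0
    theta[, j] <- pmin(pmax(tj, 0), 1)
    R[, j] <- pmax(rj, 0)
  }
  xy <- xy_from_theta_r(theta, R)
  x <- matrix(xy$x, n_mk, n_sm)
  y <- matrix(xy$y, n_mk, n_sm)
  if (!is.null(config$contamination)) {
    cc <- config$contamination
    for (k in seq_len(nrow(cc))) {
      i <- match(cc$sample[k], gset$samples$id)
      w <- match(cc$with[k], gset$samples$id)
      if (is.na(i) || is.na(w))
        stop("contamination refers to unknown sample")
      f <- cc$fraction[k]
      x[, i] <- (1 - f) * x[, i] + f * x[, w]
      y[, i] <- (1 - f) * y[, i] + f * y[, w]
    }
  }
  gset$x <- x; gset$y <- y
  set_dimnames(gset)
}

#' Simulate parent-offspring trios
#'
#' Parents are drawn from the population allele frequencies; each offspring
#' inherits one allele per parent per marker.  Optionally, a fixed number of
#' Mendelian errors is planted at known markers by replacing the offspring
#' call with a different dosage; planted positions are returned so tests
#' can compare detected against detectable errors.
#'
#' @param config a [sim_config()]; `n_per_pop` pairs of parents per
#'   population, each with one offspring.
#' @param n_trios number of trios to simulate.
#' @param planted_errors number of offspring calls to corrupt (autosomal
#'   markers only).
#' @return list with `gset` (parents then offspring, with `father`/`mother`
#'   fields set) and `planted` (data frame of trio id, marker, original and
#'   corrupted dosage).
#' @export
simulate_trios <- function(config, n_trios = 5, planted_errors = 0) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  mk <- sim_marker_map(config)
  auto <- which(is_autosome(mk$chrom))
  n_mk <- nrow(mk)
  p <- stats::runif(n_mk, 0.05, 0.95)
  draw <- function() stats::rbinom(n_mk, 2L, p)
  gametes <- function(g) ifelse(g == 0L, 0L, ifelse(g == 2L, 1L,
                                stats::rbinom(n_mk, 1L, 0.5)))
  ids <- character(0); cols <- list(); fa <- mo <- character(0)
  for (t in seq_len(n_trios)) {
    f <- draw(); m <- draw()
    o <- gametes(f) + gametes(m)
    ids <- c(ids, sprintf("fam%d_fa", t), sprintf("fam%d_mo", t),
             sprintf("fam%d_off", t))
    fa <- c(fa, NA, NA, sprintf("fam%d_fa", t))
    mo <- c(mo, NA, NA, sprintf("fam%d_mo", t))
    cols <- c(cols, list(f, m, o))
  }
  calls <- do.call(cbind, cols)
  planted <- data.frame(offspring = character(0), marker = character(0),
                        original = integer(0), corrupted = integer(0))
  if (planted_errors > 0) {
    sites <- data.frame(
      trio = sample(n_trios, planted_errors, replace = TRUE),
      marker = sample(auto, planted_errors, replace = FALSE))
    for (k in seq_len(nrow(sites))) {
      col <- 3 * sites$trio[k]
      i <- sites$marker[k]
      orig <- calls[i, col]
      calls[i, col] <- sample(setdiff(0:2, orig), 1)
      planted <- rbind(planted, data.frame(
        offspring = ids[col], marker = mk$name[i],
        original = orig, corrupted = calls[i, col]))
    }
  }
  samples <- data.frame(id = ids,
                        family = rep(sprintf("fam%d", seq_len(n_trios)),
                                     each = 3),
                        father = fa, mother = mo,
                        sex = rep(c("male", "female", "unknown"), n_trios),
                        stringsAsFactors = FALSE)
  list(gset = genotypes(calls, mk, samples), planted = planted)
}
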