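#' Haplotype-mosaic hidden Markov model
#'
#' Builds the HMM used to reconstruct a sample's chromosome as a mosaic of
#' segments copied from a panel of reference haplotypes, given a genetic
#' map.  In haploid mode the hidden states are the H panel haplotypes; in
#' diploid mode they are the H(H+1)/2 unordered haplotype pairs, with
#' transitions factoring as two independent haploid chromosomes.
#'
#' Between adjacent markers separated by `d` cM, each chromosome of
#' ancestry retains its current haplotype with probability
#' `exp(-jump_rate * d)`; otherwise an ancestry jump occurs and the new
#' haplotype is drawn uniformly from the panel (the usual
#' copying-process construction, whose infinite-distance limit is the
#' uniform distribution over haplotypes).  Emissions use a symmetric per-allele
#' error model: each allele of the state-implied genotype is observed
#' correctly with probability `1 - error_rate`, flipped otherwise; missing
#' observations are uninformative (likelihood 1 for every state).
#'
#' @param panel markers x H matrix of reference haplotype allele dosages
#'   (0/1), column names labelling the haplotypes.
#' @param map_cM per-marker genetic positions, non-decreasing.
#' @param jump_rate expected ancestry switches per cM (> 0).
#' @param error_rate per-allele genotyping/mutation error, in (0, 0.5).
#' @param mode `"haploid"` or `"diploid"`.
#' @return a list of class `hmm_spec`.
#' @export
build_hmm <- function(panel, map_cM, jump_rate, error_rate,
                      mode = c("haploid", "diploid")) {
  mode <- match.arg(mode)
  panel <- as.matrix(panel)
  if (nrow(panel) != length(map_cM))
    stop("panel and genetic map are misaligned")
  if (ncol(panel) < 2) stop("panel must contain at least 2 haplotypes")
  if (any(!panel %in% 0:1)) stop("panel dosages must be 0/1")
  if (is.unsorted(map_cM)) stop("map_cM must be non-decreasing")
  if (jump_rate <= 0) stop("jump_rate must be positive")
  if (error_rate <= 0 || error_rate >= 0.5)
    stop("error_rate must lie in (0, 0.5)")
  H <- ncol(panel)
  hap_names <- colnames(panel)
  if (is.null(hap_names)) hap_names <- paste0("hap", seq_len(H))
  if (mode == "haploid") {
    states <- data.frame(h1 = seq_len(H), h2 = NA_integer_,
                         label = hap_names, stringsAsFactors = FALSE)
  } else {
    pairs <- which(upper.tri(diag(H), diag = TRUE), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
    states <- data.frame(h1 = pairs[, "row"], h2 = pairs[, "col"],
                         label = paste(hap_names[pairs[, "row"]],
                                       hap_names[pairs[, "col"]],
                                       sep = "/"),
                         stringsAsFactors = FALSE)
  }
  structure(list(panel = panel, map_cM = as.numeric(map_cM),
                 jump_rate = jump_rate, error_rate = error_rate,
                 mode = mode, H = H, hap_names = hap_names,
                 states = states),
            class = "hmm_spec")
}

# haploid transition matrix for a gap of d cM: with probability
# exp(-jump_rate * d) the ancestry is retained; otherwise a jump occurs and
# the new haplotype is drawn uniformly from the panel (so the d -> Inf
# limit is the uniform distribution over all H haplotypes)
hap_transition <- function(H, jump_rate, d) {
  stay <- exp(-jump_rate * d)
  matrix((1 - stay) / H, H, H) + diag(stay, H)
}

#' Transition matrix between two adjacent markers
#'
#' @param hmm an `hmm_spec`.
#' @param d map distance in cM.
#' @return states x states stochastic matrix.
#' @export
transition_matrix <- function(hmm, d) {
  Th <- hap_transition(hmm$H, hmm$jump_rate, d)
  if (hmm$mode == "haploid") return(Th)
  st <- hmm$states
  n <- nrow(st)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a1 <- st$h1[i]; a2 <- st$h2[i]
    b1 <- st$h1[j]; b2 <- st$h2[j]
    # two indistinguishable chromosome-to-haplotype assignments for an
    # unordered target pair; collapse ordered-pair probabilities
    p <- Th[a1, b1] * Th[a2, b2]
    if (b1 != b2) p <- p + Th[a1, b2] * Th[a2, b1]
    out[i, j] <- p
  }
  out
}

# log-likelihood matrix: markers x states
emission_loglik <- function(hmm, obs) {
  eps <- hmm$error_rate
  n_mk <- nrow(hmm$panel)
  st <- hmm$states
  n_st <- nrow(st)
  ll <- matrix(0, n_mk, n_st)
  if (hmm$mode == "haploid") {
    # haploid observation in {0,1}: correct with prob 1-eps
    for (s in seq_len(n_st)) {
      h <- hmm$panel[, st$h1[s]]
      p <- ifelse(is.na(obs), 1, ifelse(obs == h, 1 - eps, eps))
      ll[, s] <- log(p)
    }
  } else {
    # diploid genotype dosage in {0,1,2}; per-allele symmetric error
    pmat <- function(t) switch(as.character(t),
      "0" = c((1 - eps)^2, 2 * eps * (1 - eps), eps^2),
      "1" = c(eps * (1 - eps), (1 - eps)^2 + eps^2, eps * (1 - eps)),
      "2" = c(eps^2, 2 * eps * (1 - eps), (1 - eps)^2))
    for (s in seq_len(n_st)) {
      t <- hmm$panel[, st$h1[s]] + hmm$panel[, st$h2[s]]
      p <- rep(1, n_mk)
      ok <- !is.na(obs)
      for (tv in 0:2) {
        sel <- ok & t == tv
        if (any(sel)) p[sel] <- pmat(tv)[obs[sel] + 1L]
      }
      ll[, s] <- log(p)
    }
  }
  ll
}

#' Viterbi decoding of a haplotype mosaic
#'
#' Maximum a posteriori state path through the HMM for one sample's
#' observed allele dosages (haploid mode: 0/1; diploid mode: genotype
#' dosages 0/1/2; `NA` allowed and uninformative).  Arithmetic is in log
#' space; ties break toward the lowest-index state.  The decoded path is
#' summarized into segments of constant ancestry.
#'
#' @param hmm an `hmm_spec`.
#' @param obs observed dosage vector aligned to the panel markers.
#' @return list of class `mosaic_path`: `path` (state index per marker),
#'   `labels` (state label per marker), `segments` (data frame with state,
#'   first/last marker index, cM span), `log_prob` (joint log probability
#'   of the decoded path).
#' @export
viterbi <- function(hmm, obs) {
  n_mk <- nrow(hmm$panel)
  if (length(obs) != n_mk) stop("observations misaligned with panel")
  if (all(is.na(obs)))
    warning("all observations missing: path follows the prior")
  n_st <- nrow(hmm$states)
  em <- emission_loglik(hmm, obs)
  delta <- matrix(-Inf, n_mk, n_st)
  psi <- matrix(1L, n_mk, n_st)
  delta[1, ] <- -log(n_st) + em[1, ]      # uniform prior over states
  for (i in seq_len(n_mk)[-1]) {
    d <- hmm$map_cM[i] - hmm$map_cM[i - 1]
    lt <- log(transition_matrix(hmm, d))
    for (s in seq_len(n_st)) {
      cand <- delta[i - 1, ] + lt[, s]
      best <- which.max(cand)             # which.max takes the lowest tie
      psi[i, s] <- best
      delta[i, s] <- cand[best] + em[i, s]
    }
  }
  path <- integer(n_mk)
  path[n_mk] <- which.max(delta[n_mk, ])
  for (i in rev(seq_len(n_mk - 1))) path[i] <- psi[i + 1, path[i + 1]]
  runs <- rle(path)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  segments <- data.frame(state = runs$values,
                         label = hmm$states$label[runs$values],
                         first_marker = starts, last_marker = ends,
                         cM_span = hmm$map_cM[ends] - hmm$map_cM[starts],
                         stringsAsFactors = FALSE)
  structure(list(path = path, labels = hmm$states$label[path],
                 segments = segments,
                 log_prob = max(delta[n_mk, ])),
            class = "mosaic_path")
}

#' Posterior state probabilities by forward-backward
#'
#' @inheritParams viterbi
#' @return markers x states matrix of posterior probabilities; rows sum
#'   to 1.
#' @export
posterior <- function(hmm, obs) {
  n_mk <- nrow(hmm$panel)
  if (length(obs) != n_mk) stop("observations misaligned with panel")
  n_st <- nrow(hmm$states)
  em <- exp(emission_loglik(hmm, obs))
  fwd <- matrix(0, n_mk, n_st)
  bwd <- matrix(0, n_mk, n_st)
  scale <- numeric(n_mk)
  f <- rep(1 / n_st, n_st) * em[1, ]
  scale[1] <- sum(f)
  fwd[1, ] <- f / scale[1]
  trans <- vector("list", n_mk)
  for (i in seq_len(n_mk)[-1]) {
    d <- hmm$map_cM[i] - hmm$map_cM[i - 1]
    trans[[i]] <- transition_matrix(hmm, d)
    f <- as.vector(fwd[i - 1, ] %*% trans[[i]]) * em[i, ]
    scale[i] <- sum(f)
    fwd[i, ] <- f / scale[i]
  }
  bwd[n_mk, ] <- 1
  for (i in rev(seq_len(n_mk - 1))) {
    b <- as.vector(trans[[i + 1]] %*% (em[i + 1, ] * bwd[i + 1, ]))
    bwd[i, ] <- b / sum(b)
  }
  post <- fwd * bwd
  post <- post / rowSums(post)
  colnames(post) <- hmm$states$label
  post
}

#' Simulate a haplotype mosaic from an HMM
#'
#' Draws a state path from the HMM's transition process and emits observed
#' dosages through its error model — the generative counterpart of
#' [viterbi()], used for parameter-recovery testing.
#'
#' @param hmm an `hmm_spec`.
#' @param seed integer seed.
#' @return list: `path` (true state index per marker), `obs` (emitted
#'   dosage vector).
#' @export
simulate_mosaic <- function(hmm, seed) {
  set.seed(seed)
  n_mk <- nrow(hmm$panel)
  n_st <- nrow(hmm$states)
  path <- integer(n_mk)
  path[1] <- sample.int(n_st, 1)
  for (i in seq_len(n_mk)[-1]) {
    d <- hmm$map_cM[i] - hmm$map_cM[i - 1]
    path[i] <- sample.int(n_st, 1,
                          prob = transition_matrix(hmm, d)[path[i - 1], ])
  }
  st <- hmm$states
  eps <- hmm$error_rate
  if (hmm$mode == "haploid") {
    true <- hmm$panel[cbind(seq_len(n_mk), st$h1[path])]
    flip <- stats::runif(n_mk) < eps
    obs <- ifelse(flip, 1L - true, true)
  } else {
    a1 <- hmm$panel[cbind(seq_len(n_mk), st$h1[path])]
    a2 <- hmm$panel[cbind(seq_len(n_mk), st$h2[path])]
    f1 <- stats::runif(n_mk) < eps
    f2 <- stats::runif(n_mk) < eps
    obs <- as.integer(ifelse(f1, 1L - a1, a1) + ifelse(f2, 1L - a2, a2))
  }
  list(path = path, obs = obs)
}
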