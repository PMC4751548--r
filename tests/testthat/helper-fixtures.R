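# small deterministic fixtures, built in code

tiny_map <- function(n = 4, chrom = "1", allele_A = "A", allele_B = "G") {
  data.frame(name = paste0("rs", seq_len(n)), chrom = chrom,
             pos = seq_len(n) * 1e6, allele_A = allele_A,
             allele_B = allele_B, stringsAsFactors = FALSE)
}

tiny_gset <- function(calls, chrom = "1", ...) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  mk <- tiny_map(nrow(calls), chrom = chrom, ...)
  sm <- data.frame(id = paste0("s", seq_len(ncol(calls))))
  genotypes(calls, mk, sm)
}

# simulated dataset with intensities under the canonical cluster model
sim_gset <- function(seed, n = 10, n_markers = 200, sigma = 0.03, ...) {
  cfg <- sim_config(n_pops = 1, n_per_pop = n, n_markers = n_markers,
                    noise_sigma = sigma, seed = seed, ...)
  sim <- simulate_genotypes(cfg)
  list(gset = simulate_intensities(sim$gset, cfg), cfg = cfg, sim = sim)
}

# one simulated batch split into reference samples (for cluster estimation)
# and study samples, sharing markers and allele frequencies
sim_ref_study <- function(seed, n_ref = 50, n_study = 20, n_markers = 2000,
                          sigma = 0.03, ...) {
  s <- sim_gset(seed, n = n_ref + n_study, n_markers = n_markers,
                sigma = sigma, ...)
  ids <- s$gset$samples$id
  list(ref = subset_genotypes(s$gset, samples = ids[seq_len(n_ref)]),
       study = subset_genotypes(s$gset, samples = ids[-seq_len(n_ref)]),
       cfg = s$cfg, sim = s$sim)
}
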