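# brute-force IBS oracle: count shared alleles locus by locus
ibs_oracle <- function(di, dj) {
  sh <- n <- 0
  for (k in seq_along(di)) {
    if (is.na(di[k]) || is.na(dj[k])) next
    # alleles as multisets of {A, B}
    ai <- c(rep("B", di[k]), rep("A", 2 - di[k]))
    aj <- c(rep("B", dj[k]), rep("A", 2 - dj[k]))
    shared <- sum(pmin(table(factor(ai, c("A", "B"))),
                       table(factor(aj, c("A", "B")))))
    sh <- sh + shared / 2
    n <- n + 1
  }
  if (n == 0) NA_real_ else 1 - sh / n
}

test_that("allele frequencies, het and missingness tabulate per marker", {
  g <- tiny_gset(matrix(c(0L, 0L, NA,
                          1L, 0L, NA,
                          2L, 0L, NA), 3, 3, byrow = TRUE))
  af <- allele_freqs(g)
  expect_equal(af$freq_B, c(0, 0.25, 0.5))
  expect_equal(af$het_rate, c(0, 0.5, 0))
  expect_equal(af$missing_rate, rep(1 / 3, 3))
  g2 <- tiny_gset(matrix(NA_integer_, 2, 3))
  expect_true(all(is.na(allele_freqs(g2)$freq_B)))
})

test_that("IBS distance equals the allele-counting oracle on all small instances", {
  # exhaustive: every pair of dosage vectors over m = 2 markers,
  # plus random instances at m = 4
  combos <- expand.grid(a1 = 0:2, a2 = 0:2, b1 = 0:2, b2 = 0:2)
  for (r in seq_len(nrow(combos))) {
    di <- c(combos$a1[r], combos$a2[r])
    dj <- c(combos$b1[r], combos$b2[r])
    g <- tiny_gset(cbind(di, dj))
    expect_equal(ibs_distance(g)$distance[1, 2], ibs_oracle(di, dj),
                 tolerance = 1e-12)
  }
  set.seed(71)
  for (rep in 1:20) {
    calls <- matrix(sample(c(0:2, NA), 8, replace = TRUE,
                           prob = c(rep(0.3, 3), 0.1)), 4, 2)
    g <- tiny_gset(calls)
    d <- ibs_distance(g)$distance[1, 2]
    expect_equal(d, ibs_oracle(calls[, 1], calls[, 2]), tolerance = 1e-12)
  }
})

test_that("IBS distance endpoints and overlap rules behave", {
  g <- tiny_gset(cbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_equal(ibs_distance(g)$distance[1, 2], 0)
  g2 <- tiny_gset(cbind(c(0L, 0L), c(2L, 2L)))
  expect_equal(ibs_distance(g2)$distance[1, 2], 1)
  # stated worked case: [0,1] vs [1,1] -> sharing 0.75
  g3 <- tiny_gset(cbind(c(0L, 1L), c(1L, 1L)))
  expect_equal(ibs_distance(g3)$sharing[1, 2], 0.75)
  expect_equal(ibs_distance(g3)$distance[1, 2], 0.25)
  # insufficient overlap -> missing entry
  g4 <- tiny_gset(cbind(c(0L, NA), c(NA, 1L)))
  expect_true(is.na(ibs_distance(g4, min_overlap = 1)$distance[1, 2]))
})

test_that("hierarchical clustering groups simulated populations contiguously", {
  # two clusters at distance 0 within, 1 between
  g <- tiny_gset(cbind(c(0L, 0L), c(0L, 0L), c(2L, 2L), c(2L, 2L)))
  h <- hclust_order(ibs_distance(g))
  expect_equal(h$height[1:2], c(0, 0))
  cfg <- sim_config(n_pops = 3, n_per_pop = 8, n_markers = 600,
                    divergence = 0.4, seed = 72)
  sim <- simulate_genotypes(cfg)
  h <- hclust_order(ibs_distance(sim$gset))
  runs <- rle(as.integer(sim$population[h$order]))
  expect_equal(sort(runs$lengths), c(8L, 8L, 8L))
  # n = 2: a single merge
  g2 <- tiny_gset(cbind(c(0L, 1L), c(1L, 1L)))
  expect_equal(nrow(hclust_order(ibs_distance(g2))$merge), 1L)
  # missing entries are refused with guidance
  g3 <- tiny_gset(cbind(c(0L, NA), c(NA, 1L), c(1L, 1L)))
  expect_error(hclust_order(ibs_distance(g3)), "min_overlap")
})

test_that("PCA separates simulated populations and is order-invariant", {
  cfg <- sim_config(n_pops = 3, n_per_pop = c(10, 9, 9), n_markers = 1000,
                    divergence = 0.3, seed = 73)
  sim <- simulate_genotypes(cfg)
  p <- pca_genotypes(sim$gset, 2)
  km <- stats::kmeans(p$scores, 3, nstart = 25)
  expect_equal(length(unique(paste(km$cluster, sim$population))), 3L)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1)
  # duplicated samples project identically
  g <- sim$gset
  sm <- rbind(g$samples, transform(g$samples[1, ], id = "dup"))
  dup <- genotypes(cbind(g$calls, g$calls[, 1]), g$markers, sm)
  p2 <- pca_genotypes(dup, 2)
  expect_equal(unname(p2$scores[1, ]), unname(p2$scores[29, ]))
  # marker-order permutation leaves projections unchanged (same sign rule)
  perm <- sample(nrow(g$calls))
  gp <- g
  gp$calls <- g$calls[perm, , drop = FALSE]
  gp$markers <- g$markers[perm, , drop = FALSE]
  gp <- genotypes(gp$calls, gp$markers, gp$samples)
  p3 <- pca_genotypes(gp, 2)
  expect_equal(abs(unname(p3$scores)), abs(unname(p$scores)),
               tolerance = 1e-8)
  expect_error(pca_genotypes(sim$gset, 100), "k exceeds")
  expect_error(pca_genotypes(tiny_gset(matrix(1L, 3, 3)), 2),
               "zero-variance")
})

test_that("divergence zero makes populations exchangeable in IBS", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 15, n_markers = 2000,
                    divergence = 0, seed = 74)
  sim <- simulate_genotypes(cfg)
  d <- ibs_distance(sim$gset)$distance
  pop <- sim$population
  between <- mean(d[pop == 1, pop == 2])
  within <- mean(d[pop == 1, pop == 1][upper.tri(diag(15))])
  expect_lt(abs(between - within), 0.01)
})

# gamete-enumeration oracle: all offspring dosages reachable from one
# allele per parent
mendel_oracle <- function(f, m, o) {
  alleles <- function(d) switch(as.character(d), "0" = 0L, "1" = 0:1,
                                "2" = 1L)
  possible <- unique(as.vector(outer(alleles(f), alleles(m), "+")))
  !(o %in% possible)
}

test_that("trio consistency equals gamete enumeration over all dosage triples", {
  for (f in 0:2) for (m in 0:2) for (o in 0:2) {
    calls <- matrix(c(f, m, o), 1, 3)
    g <- genotypes(calls, tiny_map(1),
                   data.frame(id = c("fa", "mo", "off"),
                              father = c(NA, NA, "fa"),
                              mother = c(NA, NA, "mo")))
    rep <- mendel_check(g)
    expect_equal(rep$n_inconsistent, sum(mendel_oracle(f, m, o)),
                 label = paste("trio", f, m, o))
  }
})

test_that("duos, hemizygous X and absent samples are handled", {
  # single parent 0, offspring 2 -> inconsistent (no shared allele)
  calls <- matrix(c(0L, 2L), 1, 2)
  g <- genotypes(calls, tiny_map(1),
                 data.frame(id = c("fa", "off"), father = c(NA, "fa")))
  expect_equal(mendel_check(g)$n_inconsistent, 1L)
  # male offspring X: call must match a maternal allele
  mk <- tiny_map(2); mk$chrom <- c("1", "X")
  calls <- matrix(c(1L, 0L,    # father
                    0L, 0L,    # mother (X hom A)
                    1L, 2L),   # son: X call B -> inconsistent
                  2, 3)
  g <- genotypes(calls, mk,
                 data.frame(id = c("fa", "mo", "son"),
                            father = c(NA, NA, "fa"),
                            mother = c(NA, NA, "mo"),
                            sex = c("male", "female", "male")))
  rep <- mendel_check(g)
  expect_equal(rep$n_tested, 2L)
  expect_equal(rep$n_inconsistent, 1L)
  # trio referencing an absent sample is skipped with a warning
  g2 <- tiny_gset(matrix(0L, 1, 1))
  g2$samples$father <- "ghost"
  expect_warning(rep2 <- mendel_check(g2), "absent")
  expect_equal(nrow(rep2), 0L)
})

test_that("planted trio errors are found exactly where detectable", {
  cfg <- sim_config(n_pops = 1, n_per_pop = 1, n_markers = 400, seed = 75)
  tr <- simulate_trios(cfg, n_trios = 4, planted_errors = 50)
  rep <- mendel_check(tr$gset)
  bad <- attr(rep, "inconsistent_markers")
  # detectability oracle: a planted corruption is detectable iff the
  # corrupted dosage violates the gamete rule for the actual parents
  expected <- character(0)
  for (k in seq_len(nrow(tr$planted))) {
    off <- tr$planted$offspring[k]
    mkr <- tr$planted$marker[k]
    i <- match(mkr, tr$gset$markers$name)
    fa <- tr$gset$calls[i, match(sub("off", "fa", off), tr$gset$samples$id)]
    mo <- tr$gset$calls[i, match(sub("off", "mo", off), tr$gset$samples$id)]
    if (mendel_oracle(fa, mo, tr$planted$corrupted[k]))
      expected <- c(expected, paste(off, mkr))
  }
  found <- unlist(lapply(names(bad), function(o) paste(o, bad[[o]])))
  expect_setequal(found, expected)
  # no planted errors -> no inconsistencies
  tr0 <- simulate_trios(cfg, n_trios = 4, planted_errors = 0)
  expect_equal(sum(mendel_check(tr0$gset)$n_inconsistent), 0L)
})
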