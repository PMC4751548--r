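test_that("theta/R polar coordinates hit the canonical anchor points", {
  expect_equal(theta_r(1, 0), list(theta = 0, R = 1))
  expect_equal(theta_r(0, 1), list(theta = 1, R = 1))
  expect_equal(theta_r(0.5, 0.5), list(theta = 0.5, R = 1))
  z <- theta_r(0, 0)
  expect_true(is.na(z$theta))
  expect_equal(z$R, 0)
  expect_error(theta_r(-1, 0), "non-negative")
})

test_that("between-array quantile normalization matches the sorted-mean oracle", {
  m <- cbind(c(1, 2, 3), c(3, 4, 5))
  out <- quantile_normalize_between(m)
  expect_equal(out, cbind(c(2, 3, 4), c(2, 3, 4)))
  # identical columns unchanged
  m2 <- cbind(c(5, 1, 3), c(5, 1, 3))
  expect_equal(quantile_normalize_between(m2), m2)
  expect_warning(quantile_normalize_between(matrix(1:3, 3, 1)), "no-op")
  # random matrices against an independently coded oracle
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(rexp(40), 10, 4)
    out <- quantile_normalize_between(m)
    target <- rowMeans(apply(m, 2, sort))
    for (j in 1:4)
      expect_equal(sort(out[, j]), target, tolerance = 1e-12)
  }
})

test_that("tqn_within applies the sorted-mean target and the multiplicative cap", {
  # x == y is a fixed point
  v <- c(0.2, 0.9, 0.4)
  r <- tqn_within(v, v, 1.5)
  expect_equal(r$x, v)
  expect_equal(r$y, v)
  # cap rule by direct application: target 2.5, x capped at 1.5*1
  r <- tqn_within(1, 4, 1.5)
  expect_equal(r$x, 1.5)
  expect_equal(r$y, 2.5)
  # infinite threshold reproduces plain quantile normalization
  set.seed(5)
  x <- rexp(50); y <- rexp(50)
  r <- tqn_within(x, y, Inf)
  target <- (sort(x) + sort(y)) / 2
  expect_equal(sort(r$x), target)
  expect_equal(sort(r$y), target)
  # zeros pass through
  r0 <- tqn_within(c(0, 1), c(2, 3), 1.5)
  expect_equal(r0$x[1], 0)
})

test_that("tqn_within never exceeds the threshold factor on random inputs", {
  set.seed(6)
  for (rep in 1:10) {
    x <- rexp(100); y <- rexp(100)
    thr <- sample(c(1.2, 1.5, 2), 1)
    r <- tqn_within(x, y, thr)
    expect_true(all(r$x <= thr * x + 1e-12))
    expect_true(all(r$y <= thr * y + 1e-12))
  }
})

test_that("BAF interpolation anchors at the cluster centroids", {
  cl <- list(theta_AA = 0.1, theta_AB = 0.5, theta_BB = 0.9)
  expect_equal(baf_from_theta(c(0.1, 0.5, 0.9), cl), c(0, 0.5, 1))
  # midway between AA and AB -> 0.25 (direct evaluation)
  expect_equal(baf_from_theta(0.3, cl), 0.25)
  expect_equal(baf_from_theta(c(0, 1), cl), c(0, 1))
  # monotone in theta for random valid clusters
  set.seed(8)
  for (rep in 1:10) {
    t3 <- sort(runif(3))
    cl <- list(theta_AA = t3[1], theta_AB = t3[2], theta_BB = t3[3])
    b <- baf_from_theta(seq(0, 1, 0.01), cl)
    expect_true(all(diff(b) >= -1e-12))
  }
})

test_that("LRR is zero at the expected intensity and log2-linear in R", {
  cl <- list(theta_AA = 0.1, theta_AB = 0.5, theta_BB = 0.9,
             r_AA = 1, r_AB = 1.2, r_BB = 1)
  # at theta_AB, R0 = 1.2
  expect_equal(lrr_from_r(0.5, 1.2, cl), 0)
  expect_equal(lrr_from_r(0.5, 2.4, cl), 1)
  expect_true(is.na(lrr_from_r(0.5, 0, cl)))
  # interpolated reference level halfway between AA and AB: R0 = 1.1
  expect_equal(lrr_from_r(0.3, 1.1, cl), 0)
  # clamped beyond the outer clusters
  expect_equal(lrr_from_r(0.01, 1, cl), 0)
})

test_that("cluster estimation recovers known centroids and imputes sparse classes", {
  # direct medians on a hand-built reference: marker 2 mirrors marker 1
  # about theta = 0.5, so each sample's channel multisets coincide and the
  # within-sample quantile normalization is an exact fixed point
  calls <- matrix(c(0L, 0L, 1L, 2L, 2L,
                    2L, 2L, 1L, 0L, 0L), 2, 5, byrow = TRUE)
  g <- genotypes(calls, tiny_map(2), data.frame(id = paste0("s", 1:5)))
  th <- c(0.06, 0.10, 0.50, 0.90, 0.94)
  xy <- snparray:::xy_from_theta_r(rbind(th, 1 - th), matrix(1, 2, 5))
  g$x <- matrix(xy$x, 2, 5); g$y <- matrix(xy$y, 2, 5)
  cl <- estimate_clusters(g, min_cluster_size = 1)
  expect_equal(cl$theta_AA, c(0.08, 0.08), tolerance = 1e-9)
  expect_equal(cl$theta_AB, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(cl$theta_BB, c(0.92, 0.92), tolerance = 1e-9)
  expect_equal(cl$n_AA, c(2L, 2L))

  # simulation recovery: 50 reference samples, sigma 0.03
  ref <- sim_gset(21, n = 50, n_markers = 300)
  cl <- estimate_clusters(ref$gset)
  expect_lt(median(abs(cl$theta_AB - 0.5), na.rm = TRUE), 0.02)
  expect_lt(median(abs(cl$theta_AA - 0.05), na.rm = TRUE), 0.02)
  expect_lt(median(abs(cl$theta_BB - 0.95), na.rm = TRUE), 0.02)

  # missing heterozygote imputed at the midpoint of the homozygotes
  calls2 <- matrix(c(0L, 0L, 0L, 2L, 2L, 2L), 1, 6)
  g2 <- genotypes(calls2, tiny_map(1), data.frame(id = paste0("s", 1:6)))
  th2 <- c(0.08, 0.1, 0.12, 0.88, 0.9, 0.92)
  xy2 <- snparray:::xy_from_theta_r(th2, rep(1, 6))
  g2$x <- matrix(xy2$x, 1, 6); g2$y <- matrix(xy2$y, 1, 6)
  cl2 <- estimate_clusters(g2, min_cluster_size = 3)
  expect_equal(cl2$theta_AB, (cl2$theta_AA + cl2$theta_BB) / 2)
  expect_match(cl2$imputed, "AB")

  # all reference calls missing -> marker excluded
  g3 <- g2
  g3$calls[] <- NA_integer_
  cl3 <- estimate_clusters(g3)
  expect_true(is.na(cl3$theta_AA))
})

test_that("full tQN chain calibrates BAF and LRR on simulated euploid samples", {
  s <- sim_ref_study(23, n_ref = 30, n_study = 8, n_markers = 800)
  cl <- estimate_clusters(s$ref)
  gn <- tqn(s$study, cl)
  expect_true(gn$normalized)
  expect_lt(max(abs(colMeans(gn$lrr, na.rm = TRUE))), 0.05)
  hets <- gn$calls == 1L
  expect_lt(abs(mean(gn$baf[hets], na.rm = TRUE) - 0.5), 0.02)
})

test_that("tqn requires intensities", {
  g <- tiny_gset(matrix(0L, 2, 2))
  expect_error(tqn(g, data.frame(name = "rs1")), "intensities")
})

test_that("contamination displaces homozygous-call BAF away from 0 and 1", {
  cfg <- sim_config(n_pops = 1, n_per_pop = 36, n_markers = 400,
                    noise_sigma = 0.03, seed = 33,
                    contamination = data.frame(sample = "pop1_s01",
                                               with = "pop1_s02",
                                               fraction = 0.1))
  sim <- simulate_genotypes(cfg)
  g <- simulate_intensities(sim$gset, cfg)
  ids <- g$samples$id
  ref <- subset_genotypes(g, samples = ids[7:36])
  gn <- tqn(subset_genotypes(g, samples = ids[1:6]), estimate_clusters(ref))
  hom_dev <- function(j) {
    hom <- which(gn$calls[, j] %in% c(0L, 2L))
    b <- gn$baf[hom, j]
    stats::median(pmin(b, 1 - b), na.rm = TRUE)
  }
  # contaminated sample's homozygote BAF is pulled inward by > 0.02
  # relative to a clean sample
  expect_gt(hom_dev(1), hom_dev(3) + 0.02)
})
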