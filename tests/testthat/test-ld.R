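test_that("pairwise r2 matches the Pearson formula on hand cases", {
  D <- rbind(c(0, 0, 2, 2), c(2, 2, 0, 0), c(0, 0, 2, 2))
  g <- make_geno(D)
  ld <- pairwise_r2(g, maf_floor = 0)
  expect_equal(unname(diag(ld$r2)), rep(1, 3))
  expect_equal(unname(ld$r2[1, 2]), 1)          # perfect negative correlation
  expect_equal(unname(ld$r2[1, 3]), 1)

  x <- c(0, 2, 2, 0, 2); y <- c(0, 2, 0, 0, 2)
  g2 <- make_geno(rbind(x, y))
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_hand, 2 / 3)
  expect_equal(unname(pairwise_r2(g2, maf_floor = 0)$r2[1, 2]), r_hand^2,
               tolerance = 1e-12)
})

test_that("monomorphic SNPs are rejected by name", {
  g <- make_geno(rbind(c(0, 0, 0, 0), c(0, 2, 0, 2)))
  expect_error(pairwise_r2(g, maf_floor = 0), "Chr01_1000")
})

test_that("background summaries follow the quantile arithmetic", {
  r2 <- c(rep(0.01, 19), 0.81)
  bg <- background_ld(r2 = r2)
  expect_equal(bg$mean_r2, 0.05)
  # type-7 95th percentile of sqrt(r2) over 20 values: h = 19*0.95 + 1 =
  # 19.05, so 0.95*x[19] + 0.05*x[20] = 0.1 + 0.05*0.8 = 0.14
  expect_equal(bg$bs_p95, 0.14^2, tolerance = 1e-12)

  flat <- background_ld(r2 = rep(0.2, 1000))
  expect_equal(flat$mean_r2, 0.2)
  expect_equal(flat$bs_p95, 0.2, tolerance = 1e-12)
})

test_that("background sampling is interchromosomal and seeded", {
  cfg <- sim_config(n_pops = 2, n_snps = 400, n_ind_per_pop = 60,
                    chrom_layout = data.frame(chrom = c("c1", "c2"),
                                              n_snps = c(200, 200),
                                              length = 1e6),
                    seed = 101)
  fr <- simulate_frequencies(cfg)
  g <- simulate_genotypes(fr)
  a <- background_ld(g, n_pairs = 2000, seed = 5)
  b <- background_ld(g, n_pairs = 2000, seed = 5)
  expect_identical(a$mean_r2, b$mean_r2)
  expect_identical(a$r2, b$r2)
  expect_true(a$mean_r2 >= 0 && a$mean_r2 <= 1)

  g1 <- make_geno(matrix(c(0, 2, 0, 2, 2, 0, 0, 2), 2, byrow = TRUE))
  expect_error(background_ld(g1, n_pairs = 10), "two chromosomes")
})

test_that("permutation test returns 1 for identical and the floor for separated samples", {
  expect_equal(permutation_ld_test(rep(0.3, 30), rep(0.3, 30),
                                   n_perm = 99, seed = 1)$p_value, 1)
  res <- permutation_ld_test(rep(0.9, 50) + runif(50, 0, 0.01),
                             rep(0.01, 50) + runif(50, 0, 0.005),
                             n_perm = 199, seed = 2)
  expect_equal(res$p_value, 1 / 200)
  expect_error(permutation_ld_test(numeric(0), 1:3), "empty")
  expect_error(permutation_ld_test(1:3 / 10, 1:3 / 10, n_perm = 0), "n_perm")
})

test_that("the cube-root transform changes the test only through the scale", {
  set.seed(3)
  a <- runif(40, 0.2, 0.6)
  b <- runif(40, 0.1, 0.5)
  p_raw <- permutation_ld_test(a, b, n_perm = 199, transform = identity,
                               seed = 7)$p_value
  # a common monotone rescaling applied to both samples with the transform
  # preserved gives the identical permutation decision pattern
  p_scaled <- permutation_ld_test(a^3, b^3, n_perm = 199, seed = 7)$p_value
  expect_equal(p_raw, p_scaled)
})

test_that("LD networks connect components above the threshold", {
  r2 <- matrix(0.1, 3, 3); diag(r2) <- 1
  r2[1, 2] <- r2[2, 1] <- 0.4
  r2[2, 3] <- r2[3, 2] <- 0.35
  ld <- make_ldm(r2, chrom = c("c1", "c2", "c3"), pos = c(1e6, 2e6, 3e6))
  net <- build_ld_network(ld, background = 0.10, multiple = 3)
  expect_equal(net$threshold, 0.30)
  expect_equal(length(unique(net$components)), 1L)   # {A,B,C} connected
  expect_equal(length(net$clusters), 1L)             # interchromosomal

  # empty edge set: singletons, no reported clusters
  net0 <- build_ld_network(ld, background = 0.5, multiple = 3)
  expect_equal(nrow(net0$edges), 0L)
  expect_equal(length(unique(net0$components)), 3L)
  expect_equal(length(net0$clusters), 0L)

  expect_error(build_ld_network(ld, 0.1, multiple = 0), "positive")
})

test_that("intra-chromosomal clusters must span the minimum distance", {
  r2 <- matrix(0, 2, 2); diag(r2) <- 1
  r2[1, 2] <- r2[2, 1] <- 0.9
  near <- make_ldm(r2, chrom = c("c1", "c1"), pos = c(1e6, 2e6))
  far <- make_ldm(r2, chrom = c("c1", "c1"), pos = c(1e6, 7e6))
  expect_equal(length(build_ld_network(near, 0.1)$clusters), 0L)
  expect_equal(length(build_ld_network(far, 0.1)$clusters), 1L)
})

test_that("raising the threshold never merges components", {
  set.seed(11)
  n <- 12
  M <- crossprod(matrix(runif(n * n), n))
  r2 <- cov2cor(M)^2; diag(r2) <- 1
  ld <- make_ldm(r2, chrom = rep(c("c1", "c2", "c3"), each = 4),
                 pos = rep(1:4 * 1e6, 3))
  lo <- build_ld_network(ld, background = 0.05, multiple = 2)
  hi <- build_ld_network(ld, background = 0.05, multiple = 6)
  # partition at the higher threshold refines the lower one
  ref <- tapply(lo$components[names(hi$components)], hi$components,
                function(v) length(unique(v)))
  expect_true(all(ref == 1))
  expect_gte(length(unique(hi$components)), length(unique(lo$components)))
})

test_that("correlated loci on different chromosomes cluster together", {
  set.seed(13)
  n <- 120
  base <- rbinom(n, 1, 0.5)
  flip <- runif(n) < 0.05
  snpA <- 2L * base
  snpB <- 2L * ifelse(flip, 1L - base, base)
  noise <- matrix(2L * rbinom(6 * n, 1, 0.5), 6)
  D <- rbind(snpA, noise[1:3, ], snpB, noise[4:6, ])
  g <- make_geno(D, chrom = rep(c("c1", "c2"), each = 4),
                 pos = rep(c(1, 8, 16, 24) * 1e6, 2))
  ld <- pairwise_r2(g, maf_floor = 0.05)
  net <- build_ld_network(ld, background = 0.05, multiple = 3)
  comp <- net$components
  expect_equal(unname(comp[["c1_1e+06"]]), unname(comp[["c2_1e+06"]]))
  expect_gte(length(net$clusters), 1L)
})

test_that("LD decay handles degenerate binnings", {
  D <- rbind(c(0, 0, 2, 2), c(0, 0, 2, 2), c(0, 2, 0, 2))
  g <- make_geno(D, pos = c(1000L, 2000L, 10000L))
  # max_dist below the minimum spacing: empty table
  expect_equal(nrow(ld_decay(g, max_dist = 500, maf_floor = 0)), 0L)
  # one pair per bin: bin mean equals that pair's r2
  dec <- ld_decay(g, max_dist = 10000, bins = 10, maf_floor = 0)
  expect_equal(dec$mean_r2[dec$n_pairs == 1][1], 1)   # the identical pair
})

test_that("LD pruning drops one of a correlated pair deterministically", {
  # all pairs below threshold: everything kept
  set.seed(17)
  D <- matrix(2L * rbinom(5 * 200, 1, 0.5), 5)
  g <- make_geno(D, pos = 1:5 * 100000L)
  kept <- ld_prune(g, threshold = 0.9, maf_floor = 0)
  expect_equal(kept, g$snps$id)

  # two perfectly correlated SNPs 1 kb apart, equal MAF: smaller position kept
  x <- 2L * rbinom(100, 1, 0.5)
  g2 <- make_geno(rbind(x, x), pos = c(5000L, 6000L))
  kept2 <- ld_prune(g2, threshold = 0.5, maf_floor = 0)
  expect_equal(kept2, "Chr01_5000")

  # idempotence
  sub <- make_geno(D[match(kept, g$snps$id), , drop = FALSE],
                   pos = g$snps$pos[match(kept, g$snps$id)])
  expect_equal(ld_prune(sub, threshold = 0.9, maf_floor = 0), kept)
})

test_that("signature peaks show elevated LD over random pairs on planted data", {
  # two planted loci with correlated frequency shifts across populations:
  # their dosage correlation exceeds background, detected by the
  # permutation contrast
  set.seed(19)
  cfg <- sim_config(n_pops = 6, n_snps = 600, n_ind_per_pop = 60,
                    chrom_layout = data.frame(chrom = c("c1", "c2"),
                                              n_snps = c(300, 300),
                                              length = 1e7),
                    frac_differentiated = 0, frac_associated = 0.1,
                    slope_range = c(0.8, 1), seed = 23)
  fr <- simulate_frequencies(cfg)
  g <- simulate_genotypes(fr)
  assoc <- fr$truth$snp[fr$truth$class == "associated"]
  assoc <- intersect(assoc, g$snps$id)[1:20]
  neutral <- sample(fr$truth$snp[fr$truth$class == "neutral"], 20)
  r2_assoc <- pairwise_r2(g, assoc, maf_floor = 0)$r2
  r2_rand <- pairwise_r2(g, neutral, maf_floor = 0)$r2
  a <- r2_assoc[upper.tri(r2_assoc)]
  b <- r2_rand[upper.tri(r2_rand)]
  expect_gt(mean(a), mean(b))
  p <- permutation_ld_test(a, b, n_perm = 499, seed = 29)$p_value
  expect_lt(p, 0.05)
})
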