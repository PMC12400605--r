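test_that("population allele counts honour ploidy convention and MAF floor", {
  g <- make_geno(matrix(c(0L, 2L), nrow = 1), pop = c("a", "a"))
  diploid <- population_allele_counts(g, maf_floor = 0, inbred = FALSE)
  expect_equal(unname(diploid$counts[1, 1]), 2)
  expect_equal(unname(diploid$totals[1, 1]), 4)
  haploid <- population_allele_counts(g, maf_floor = 0, inbred = TRUE)
  expect_equal(unname(haploid$counts[1, 1]), 1)
  expect_equal(unname(haploid$totals[1, 1]), 2)

  # pooled frequency 0.005 < floor 0.01 is dropped
  D <- matrix(0L, 2, 100)
  D[1, 1] <- 2L                       # SNP1 pooled freq 1/200
  D[2, ] <- 2L                        # SNP2 pooled freq > 0.5 kept
  g2 <- make_geno(D, pop = rep("a", 100))
  cts <- population_allele_counts(g2, maf_floor = 0.01)
  expect_equal(ncol(cts$counts), 1L)
  expect_equal(unname(cts$log["dropped_low_maf"]), 1L)

  expect_error(population_allele_counts(
    g, assignment = factor(c("a", "a"), levels = c("a", "b"))), "zero members")
})

test_that("population frequencies recover the simulated alpha", {
  cfg <- sim_config(n_pops = 3, n_snps = 400, n_ind_per_pop = 200,
                    frac_differentiated = 0, frac_associated = 0, seed = 31)
  fr <- simulate_frequencies(cfg)
  g <- simulate_genotypes(fr)
  cts <- population_allele_counts(g, maf_floor = 0)
  phat <- cts$counts / cts$totals
  se <- sqrt(fr$freq * (1 - fr$freq) / 200)
  cover <- mean(abs(phat - fr$freq) <= 1.96 * se + 1e-9)
  expect_gt(cover, 0.90)              # ~95% binomial coverage
})

test_that("Omega estimation recovers the centered generating covariance", {
  scale <- 0.01
  P <- 6
  cfg <- sim_config(n_pops = P, n_snps = 50000, omega = scale * diag(P),
                    n_ind_per_pop = 50, frac_differentiated = 0,
                    frac_associated = 0, seed = 41)
  fr <- simulate_frequencies(cfg)
  cts <- make_counts(fr$freq, totals = 1e6)   # frequency-level counts
  m <- estimate_omega(cts)
  # mean-centering projects out the common component: the estimator is
  # consistent for (1-d) A I A' + d diag(...), A = I - 11'/P
  A <- diag(P) - matrix(1 / P, P, P)
  target <- 0.95 * A + 0.05 * diag(diag(A))
  expect_lt(max(abs(m$omega / scale - target)), 0.08)
  ev <- eigen(m$omega, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("compound-symmetry generators leave the identifiable part intact", {
  scale <- 0.02; rho <- 0.5; P <- 4
  omega <- scale * ((1 - rho) * diag(P) + rho * matrix(1, P, P))
  cfg <- sim_config(n_pops = P, n_snps = 40000, omega = omega,
                    frac_differentiated = 0, frac_associated = 0, seed = 43)
  fr <- simulate_frequencies(cfg)
  m <- suppressWarnings(estimate_omega(make_counts(fr$freq, totals = 1e6)))
  # centered target: common rho component absorbed into pi-hat
  A <- diag(P) - matrix(1 / P, P, P)
  target <- A %*% omega %*% A
  target <- 0.95 * target + 0.05 * diag(diag(target))
  expect_lt(max(abs(m$omega - target)) / scale, 0.08)
})

test_that("duplicated populations drive their correlation to 1 - delta", {
  set.seed(44)
  P <- 3; J <- 2000
  p3 <- matrix(runif(J, 0.1, 0.9), 1)
  noise <- matrix(runif(J, 0.1, 0.9), 1)
  freq <- rbind(p3, p3, noise)        # pops 1 and 2 identical
  m <- estimate_omega(make_counts(freq, totals = 1e6), shrinkage = 0.05)
  corr <- cov2cor(m$omega)
  expect_equal(corr[1, 2], 0.95, tolerance = 0.01)
})

test_that("Omega estimation enforces its preconditions", {
  cfg <- sim_config(n_pops = 6, n_snps = 200, seed = 1)
  fr <- simulate_frequencies(cfg)
  expect_error(estimate_omega(make_counts(fr$freq)), "too few SNPs")
})

test_that("XtX matches hand and matrix-inverse oracles exactly", {
  m_id <- omega_model(diag(2), pi = 0.5)
  cts <- make_counts(matrix(c(0.8, 0.2), 2), totals = 100)
  expect_equal(unname(xtx_scan(cts, m_id)), 0.72, tolerance = 1e-12)

  m_cor <- omega_model(matrix(c(1, 0.5, 0.5, 1), 2), pi = 0.5)
  # z = (0.6, -0.6); inverse [[4/3,-2/3],[-2/3,4/3]]; XtX = 1.44
  expect_equal(unname(xtx_scan(cts, m_cor)), 1.44, tolerance = 1e-12)

  # brute-force z' solve(Omega) z on a random instance
  set.seed(50)
  P <- 5
  S <- crossprod(matrix(rnorm(P * P), P)) + diag(P)
  pi <- runif(8, 0.2, 0.8)
  freq <- matrix(runif(P * 8, 0.05, 0.95), P)
  m <- omega_model(S, pi = pi)
  got <- xtx_scan(make_counts(freq), m)
  want <- vapply(1:8, function(j) {
    z <- (freq[, j] - pi[j]) / sqrt(pi[j] * (1 - pi[j]))
    as.numeric(t(z) %*% solve(S) %*% z)
  }, numeric(1))
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("XtX is zero when all populations sit at the ancestral frequency", {
  m <- omega_model(diag(3), pi = c(0.3, 0.7))
  cts <- make_counts(matrix(c(0.3, 0.3, 0.3, 0.7, 0.7, 0.7), 3), 100)
  expect_equal(unname(xtx_scan(cts, m)), c(0, 0), tolerance = 1e-14)
})

test_that("XtX is invariant to population relabelling", {
  cfg <- sim_config(n_pops = 4, n_snps = 2000, seed = 52)
  fr <- simulate_frequencies(cfg)
  cts <- make_counts(fr$freq, 100)
  m <- suppressWarnings(estimate_omega(cts))
  x1 <- xtx_scan(cts, m)
  perm <- c(3, 1, 4, 2)
  cts_p <- make_counts(fr$freq[perm, ], 100)
  m_p <- list(omega = m$omega[perm, perm], pi = m$pi, delta = m$delta,
              pops = m$pops[perm], n_snps_used = m$n_snps_used,
              excluded = m$excluded)
  class(m_p) <- "omega_model"
  expect_equal(unname(xtx_scan(cts_p, m_p)), unname(x1), tolerance = 1e-10)
})

test_that("POD thresholds are reproducible quantiles of the null sample", {
  m <- omega_model(0.05 * diag(4), pi = runif(500, 0.1, 0.9))
  a <- pod_threshold(m, totals = rep(100, 4), n_pod = 2000, seed = 3)
  b <- pod_threshold(m, totals = rep(100, 4), n_pod = 2000, seed = 3)
  expect_identical(a$threshold, b$threshold)
  expect_identical(a$sample, b$sample)
  med <- pod_threshold(m, totals = rep(100, 4), n_pod = 2000, q = 0.5,
                       seed = 3)
  expect_equal(med$threshold, unname(quantile(med$sample, 0.5, type = 7)))
})

test_that("the POD null matches the chi-square limit in the mild-drift regime", {
  set.seed(60)
  m <- omega_model(0.01 * diag(6), pi = runif(2000, 0.05, 0.95))
  pod <- pod_threshold(m, totals = rep(1e4, 6), n_pod = 30000, seed = 61)
  expect_lt(abs(pod$threshold - qchisq(0.99, 5)), 0.5)
})

test_that("Bayes factors disfavour association for null and flat data", {
  m <- omega_model(diag(3), pi = 0.5)
  cts <- make_counts(matrix(0.5, 3, 4), 100)      # z = 0 everywhere
  cstar <- standardize_covariate(1:3)
  db <- bf_scan(cts, m, cstar, tau = 1)
  sxx <- sum(backsolve(chol(diag(3)), cstar, transpose = TRUE)^2)
  expect_equal(unname(db), rep(-5 * log10(1 + sxx), 4), tolerance = 1e-10)
  expect_true(all(db <= 0))

  # vanishing prior: BF -> 1, deciban -> 0
  cts2 <- make_counts(matrix(runif(12, 0.2, 0.8), 3), 100)
  expect_equal(unname(bf_scan(cts2, m, cstar, tau = 0,
                              pi = rep(0.5, 4))), rep(0, 4))
})

test_that("the closed-form Bayes factor equals numerical integration", {
  # worked small case: P=3, Omega=I, z=(-1,0,1), c*=(-sqrt(1.5),0,sqrt(1.5))
  m <- omega_model(diag(3), pi = 0.5)
  cts <- make_counts(matrix(c(0, 0.5, 1), 3), 100)
  cstar <- c(-sqrt(1.5), 0, sqrt(1.5))
  got <- bf_scan(cts, m, cstar, tau = 1)
  want <- bf_db_oracle(c(-1, 0, 1), cstar, diag(3), tau = 1)
  expect_equal(unname(got), want, tolerance = 1e-6)

  # property: 100 random small instances against the quadrature oracle
  set.seed(70)
  for (k in 1:100) {
    P <- sample(3:6, 1)
    S <- crossprod(matrix(rnorm(P * P), P)) / P + diag(P)
    cstar <- standardize_covariate(rnorm(P))
    pi <- runif(1, 0.2, 0.8)
    freq <- matrix(runif(P, 0.05, 0.95), P)
    tau <- runif(1, 0.2, 2)
    m <- omega_model(S, pi = pi)
    got <- bf_scan(make_counts(freq), m, cstar, tau = tau)
    z <- (freq[, 1] - pi) / sqrt(pi * (1 - pi))
    want <- bf_db_oracle(z, cstar, S, tau)
    expect_equal(unname(got), want, tolerance = 1e-6)
  }
})

test_that("Bayes-factor scoring validates the covariate", {
  m <- omega_model(diag(3), pi = 0.5)
  cts <- make_counts(matrix(0.5, 3, 2), 100)
  expect_error(bf_scan(cts, m, rep(1, 3)), "zero-variance")
  expect_error(bf_scan(cts, m, c(1, 2, 3)), "standardized")
})

test_that("consolidation averages runs and is order-invariant", {
  r1 <- data.frame(id = c("a", "b"), pos = c(1L, 2L), xtx = c(10, 4))
  r2 <- data.frame(id = c("a", "b"), pos = c(1L, 2L), xtx = c(20, 4))
  cons <- consolidate_runs(list(r1, r2))
  expect_equal(cons$xtx, c(15, 4))
  expect_equal(cons$xtx_sd, c(sqrt(50), 0))

  expect_equal(consolidate_runs(list(r2, r1))$xtx,
               consolidate_runs(list(r1, r2))$xtx)
  expect_identical(consolidate_runs(list(r1, r1))$xtx, r1$xtx)

  r3 <- data.frame(id = c("a", "c"), pos = c(1L, 2L), xtx = c(1, 1))
  expect_error(consolidate_runs(list(r1, r3)), "row 2")
})

test_that("the scan object assembles scores, thresholds and methods", {
  cfg <- sim_config(n_pops = 6, n_snps = 2500, n_ind_per_pop = 40, seed = 80)
  fr <- simulate_frequencies(cfg)
  g <- simulate_genotypes(fr)
  cts <- population_allele_counts(g)
  fit <- gea_scan(cts, six_region_covariates(), n_pod = 5000, seed = 81)
  expect_s3_class(fit, "gea_scan")
  expect_true(all(c("xtx", "xtx_pass", "bf_pc1", "bf_pc2") %in%
                    names(fit$scores)))
  expect_true(all(fit$scores$xtx >= 0))
  expect_identical(fit$scores$xtx_pass,
                   fit$scores$xtx > fit$pod$threshold)
  expect_output(print(fit), "XtX threshold")
  s <- summary(fit)
  expect_output(print(s), "scan summary")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
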