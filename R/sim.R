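#' Configuration for the synthetic landscape-genomics generator
#'
#' Builds and validates the configuration of the built-in data generator. The
#' generator emulates the statistical structure the downstream scan assumes:
#' per-population allele frequencies drawn around an ancestral frequency with
#' a shared covariance matrix Omega, a small fraction of loci with inflated
#' differentiation and/or a linear association with a population covariate,
#' and fully inbred genotypes.
#'
#' The default configuration describes a panel of six regional populations of
#' a selfing crop along a latitudinal gradient: compound-symmetry Omega with
#' drift scale 0.05 and correlation 0.25, 20,000 SNPs on 20 chromosomes,
#' 50 inbred lines per population, 1% of loci differentiated at
#' \code{lambda = 5} and 1% associated with the (standardized) latitude
#' covariate at standardized slopes drawn uniformly from ±[0.5, 1].
#'
#' @param n_pops Number of populations P.
#' @param n_snps Number of SNPs J.
#' @param n_ind_per_pop Inbred individuals simulated per population.
#' @param omega P x P symmetric positive-definite allele-frequency covariance
#'   matrix. Default \code{NULL} builds the compound-symmetry recipe
#'   \code{omega_scale * ((1 - omega_rho) * I + omega_rho * J)}.
#' @param omega_scale,omega_rho Drift scale and cross-population correlation of
#'   the default compound-symmetry Omega.
#' @param pi_prior Length-2 interval for the per-SNP ancestral frequency.
#' @param frac_differentiated Fraction of loci with Omega inflated by
#'   \code{lambda}.
#' @param frac_associated Fraction of loci with a covariate effect.
#' @param lambda Inflation factor (> 1) of Omega at differentiated loci.
#' @param slope_range Magnitude range of the standardized covariate slope at
#'   associated loci; realized frequency effect is
#'   \code{beta = slope * sqrt(pi * (1 - pi))} with random sign.
#' @param covariate_values Length-P covariate (e.g. region latitude). It is
#'   standardized internally to zero mean and unit variance (divisor P).
#' @param selfing_f Inbreeding coefficient in [0, 1]; 1 = fully inbred.
#' @param chrom_layout Data frame with columns \code{chrom}, \code{n_snps},
#'   \code{length} (bp). Default spreads \code{n_snps} over 20 chromosomes of
#'   50 Mb.
#' @param block_len_mean Mean haplotype segment length (bp) of the founder
#'   copy process used by [simulate_haplotype_panel()].
#' @param n_founders Number of founder haplotypes of the copy process.
#' @param mutation_rate Per-site mutation probability of the copy process.
#' @param seed Integer seed; all generator output is deterministic given it.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @seealso [simulate_frequencies()], [simulate_genotypes()],
#'   [simulate_haplotype_panel()], [write_dataset()]
#' @export
#' @examples
#' cfg <- sim_config(n_pops = 4, n_snps = 1000, seed = 1)
#' cfg
sim_config <- function(n_pops = 6L,
                       n_snps = 20000L,
                       n_ind_per_pop = 50L,
                       omega = NULL,
                       omega_scale = 0.05,
                       omega_rho = 0.25,
                       pi_prior = c(0.05, 0.95),
                       frac_differentiated = 0.01,
                       frac_associated = 0.01,
                       lambda = 5,
                       slope_range = c(0.5, 1),
                       covariate_values = NULL,
                       selfing_f = 1,
                       chrom_layout = NULL,
                       block_len_mean = 2e5,
                       n_founders = 4L,
                       mutation_rate = 1e-3,
                       seed = NULL) {
  P <- as.integer(n_pops)
  J <- as.integer(n_snps)
  if (P < 2L) stop2("'n_pops' must be >= 2")
  if (J < 1L) stop2("'n_snps' must be positive")
  if (n_ind_per_pop < 1L) stop2("'n_ind_per_pop' must be positive")

  if (is.null(omega)) {
    omega <- omega_scale * ((1 - omega_rho) * diag(P) +
                              omega_rho * matrix(1, P, P))
  }
  omega <- as.matrix(omega)
  if (!isTRUE(all.equal(dim(omega), c(P, P))))
    stop2("'omega' must be a ", P, " x ", P, " matrix")
  if (max(abs(omega - t(omega))) > 1e-8)
    stop2("'omega' must be symmetric")
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop2("'omega' is not positive definite (smallest eigenvalue ",
          format(min(ev)), ")")

  if (length(pi_prior) != 2L || pi_prior[1] >= pi_prior[2] ||
      pi_prior[1] <= 0 || pi_prior[2] >= 1)
    stop2("'pi_prior' must be an interval inside (0, 1)")

  fr <- c(frac_differentiated, frac_associated)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop2("locus fractions must lie in [0, 1] and sum to at most 1")
  if (frac_differentiated > 0 && lambda <= 1)
    stop2("'lambda' must exceed 1 for differentiated loci")
  if (length(slope_range) != 2L || slope_range[1] < 0 ||
      slope_range[1] > slope_range[2])
    stop2("'slope_range' must be an increasing non-negative interval")

  if (is.null(covariate_values)) {
    # latitudes of the six growing regions; otherwise an even gradient
    covariate_values <- if (P == 6L)
      c(49.55, 46.09, 42.49, 36.33, 32.21, 27.70)
    else seq(50, 25, length.out = P)
  }
  if (length(covariate_values) != P)
    stop2("'covariate_values' must have length n_pops = ", P,
          " (got ", length(covariate_values), ")")

  if (selfing_f < 0 || selfing_f > 1)
    stop2("'selfing_f' must lie in [0, 1]")

  if (is.null(chrom_layout)) {
    n_chr <- min(20L, J)
    per <- diff(round(seq(0, J, length.out = n_chr + 1L)))
    chrom_layout <- data.frame(
      chrom = sprintf("Chr%02d", seq_len(n_chr)),
      n_snps = as.integer(per),
      length = 5e7
    )
  }
  chrom_layout <- as.data.frame(chrom_layout)
  if (!all(c("chrom", "n_snps", "length") %in% names(chrom_layout)))
    stop2("'chrom_layout' needs columns chrom, n_snps, length")
  if (sum(chrom_layout$n_snps) != J)
    stop2("chrom_layout n_snps must sum to n_snps = ", J)
  if (any(chrom_layout$length <= 0)) stop2("chromosome lengths must be positive")

  if (block_len_mean <= 0) stop2("'block_len_mean' must be positive")
  if (n_founders < 2L) stop2("'n_founders' must be >= 2")

  structure(list(
    n_pops = P, n_snps = J, n_ind_per_pop = as.integer(n_ind_per_pop),
    omega = omega, pi_prior = pi_prior,
    frac_differentiated = frac_differentiated,
    frac_associated = frac_associated,
    lambda = lambda, slope_range = slope_range,
    covariate_values = covariate_values,
    selfing_f = selfing_f, chrom_layout = chrom_layout,
    block_len_mean = block_len_mean, n_founders = as.integer(n_founders),
    mutation_rate = mutation_rate,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic landscape-genomics configuration\n")
  cat(sprintf("  populations: %d  SNPs: %d  individuals/pop: %d\n",
              x$n_pops, x$n_snps, x$n_ind_per_pop))
  cat(sprintf("  Omega: drift %.3g (mean diagonal), mean correlation %.2f\n",
              mean(diag(x$omega)),
              mean(stats::cov2cor(x$omega)[lower.tri(x$omega)])))
  cat(sprintf("  differentiated: %.2g%% at lambda = %.3g; associated: %.2g%% at |slope| in [%.2g, %.2g]\n",
              100 * x$frac_differentiated, x$lambda,
              100 * x$frac_associated, x$slope_range[1], x$slope_range[2]))
  cat(sprintf("  selfing F = %.2g; %d chromosomes; seed %s\n",
              x$selfing_f, nrow(x$chrom_layout),
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Standardize a covariate to zero mean and unit population variance
#'
#' Centers and scales a length-P covariate using the population convention
#' (divisor P, not P - 1), matching the standardization applied to
#' environmental PC scores before the association scan.
#'
#' @param x Numeric vector.
#' @return Standardized vector with mean 0 and mean square 1.
#' @export
standardize_covariate <- function(x) {
  x <- as.numeric(x)
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop2("constant covariate cannot be standardized")
  (x - mean(x)) / s
}

#' Simulate population allele frequencies with a truth ledger
#'
#' Draws, for each SNP, an ancestral frequency from the configured prior and
#' population frequencies from a truncated Gaussian with covariance
#' \code{pi * (1 - pi) * lambda * Omega}. Differentiated loci have their
#' covariance inflated by \code{lambda}; associated loci receive an additional
#' linear shift \code{beta * c*} along the standardized covariate before
#' clipping to (1e-4, 1 - 1e-4).
#'
#' Truncation note: when the drift scale (diagonal of Omega) is large, clipping
#' at the frequency bounds compresses the realized covariance below the nominal
#' Omega; the generator is intended for the moderate-drift regime in which
#' truncation is rare.
#'
#' @param config A [sim_config()].
#' @return An object of class \code{pop_freqs}: list with \code{freq}
#'   (P x J matrix of alternate-allele frequencies), \code{snps}
#'   (data frame: chrom, pos, ref, alt), \code{truth} (per-SNP ledger:
#'   class, lambda, beta, slope), \code{covariate} (standardized),
#'   and the generating \code{config}.
#' @export
#' @examples
#' fr <- simulate_frequencies(sim_config(n_pops = 4, n_snps = 500, seed = 7))
#' dim(fr$freq)
#' table(fr$truth$class)
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  check_seed(config$seed)
  P <- config$n_pops
  J <- config$n_snps

  pi_j <- runif(J, config$pi_prior[1], config$pi_prior[2])

  n_diff <- round(J * config$frac_differentiated)
  n_assoc <- round(J * config$frac_associated)
  idx <- sample.int(J, n_diff + n_assoc)
  i_diff <- idx[seq_len(n_diff)]
  i_assoc <- idx[n_diff + seq_len(n_assoc)]

  lambda_j <- rep(1, J)
  lambda_j[i_diff] <- config$lambda
  slope_j <- numeric(J)
  if (n_assoc > 0) {
    slope_j[i_assoc] <- sample(c(-1, 1), n_assoc, replace = TRUE) *
      runif(n_assoc, config$slope_range[1], config$slope_range[2])
  }
  beta_j <- slope_j * sqrt(pi_j * (1 - pi_j))

  cls <- rep("neutral", J)
  cls[i_diff] <- "differentiated"
  cls[i_assoc] <- "associated"

  cstar <- standardize_covariate(config$covariate_values)

  # alpha_j = pi_j + sqrt(pi(1-pi) lambda) * L'u + beta_j * c*, clipped
  Lt <- t(chol(config$omega))                      # lower factor of Omega
  U <- matrix(rnorm(P * J), P, J)
  A <- Lt %*% U
  A <- A * rep(sqrt(pi_j * (1 - pi_j) * lambda_j), each = P)
  A <- A + rep(pi_j, each = P) + outer(cstar, beta_j)
  A <- pmin(pmax(A, FREQ_EPS), 1 - FREQ_EPS)

  snps <- sim_snp_table(config)
  rownames(A) <- paste0("pop", seq_len(P))

  truth <- data.frame(
    snp = snps$id, class = cls, lambda = lambda_j,
    beta = beta_j, slope = slope_j, pi = pi_j,
    stringsAsFactors = FALSE
  )

  structure(list(freq = A, snps = snps, truth = truth,
                 covariate = cstar, config = config),
            class = "pop_freqs")
}

# SNP metadata under the configured chromosome layout: strictly increasing
# positions within chromosomes, random ref/alt nucleotides.
sim_snp_table <- function(config) {
  lay <- config$chrom_layout
  parts <- lapply(seq_len(nrow(lay)), function(i) {
    n <- lay$n_snps[i]
    if (n == 0L) return(NULL)
    pos <- sort(sample.int(lay$length[i], n))
    data.frame(chrom = lay$chrom[i], pos = pos, stringsAsFactors = FALSE)
  })
  snps <- do.call(rbind, parts)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, nrow(snps), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1))
  snps$ref <- ref
  snps$alt <- unname(alt)
  snps$id <- paste0(snps$chrom, "_", snps$pos)
  rownames(snps) <- NULL
  snps
}

#' @export
print.pop_freqs <- function(x, ...) {
  cat(sprintf("Simulated population frequencies: %d populations x %d SNPs\n",
              nrow(x$freq), ncol(x$freq)))
  print(table(x$truth$class))
  invisible(x)
}

#' Simulate inbred genotypes from population frequencies
#'
#' Draws individual genotypes from the simulated population frequencies. With
#' full selfing (\code{selfing_f = 1}) each individual is homozygous: dosage
#' \code{2 * Bernoulli(alpha)}. With partial selfing the two alleles are drawn
#' with correlation \code{selfing_f}.
#'
#' @param freqs A \code{pop_freqs} object from [simulate_frequencies()].
#' @param config The generating [sim_config()] (defaults to the one stored in
#'   \code{freqs}).
#' @param seed Optional seed overriding the deterministic offset derived from
#'   the config seed.
#' @return An object of class \code{geno_matrix}: list with \code{dosage}
#'   (J x N matrix of 0/1/2), \code{snps}, \code{pop} (population of each
#'   individual), \code{ids}.
#' @export
simulate_genotypes <- function(freqs, config = freqs$config, seed = NULL) {
  stopifnot(inherits(freqs, "pop_freqs"))
  f <- config$selfing_f
  if (f < 0 || f > 1) stop2("'selfing_f' must lie in [0, 1]")
  if (is.null(seed)) {
    if (!is.null(config$seed)) set.seed(config$seed + 1L)
  } else check_seed(seed)

  P <- nrow(freqs$freq)
  J <- ncol(freqs$freq)
  n <- config$n_ind_per_pop
  N <- P * n
  pop <- rep(seq_len(P), each = n)
  ids <- sprintf("pop%d_i%03d", pop, sequence(rep(n, P)))

  dosage <- matrix(0L, J, N)
  for (p in seq_len(P)) {
    alpha <- freqs$freq[p, ]
    cols <- which(pop == p)
    a1 <- matrix(rbinom(J * n, 1L, alpha), J, n)
    if (f >= 1) {
      d <- 2L * a1
    } else {
      a2 <- matrix(rbinom(J * n, 1L, alpha), J, n)
      keep <- matrix(runif(J * n) < f, J, n)
      a2[keep] <- a1[keep]
      d <- a1 + a2
    }
    dosage[, cols] <- d
  }
  dimnames(dosage) <- list(freqs$snps$id, ids)

  structure(list(dosage = dosage, snps = freqs$snps,
                 pop = factor(paste0("pop", pop),
                              levels = paste0("pop", seq_len(P))),
                 ids = ids),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d SNPs x %d individuals (%d populations)\n",
              nrow(x$dosage), ncol(x$dosage), nlevels(x$pop)))
  het <- mean(x$dosage == 1L, na.rm = TRUE)
  cat(sprintf("  heterozygous calls: %.3g%%\n", 100 * het))
  invisible(x)
}
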