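#' Per-population allele counts from genotype dosages
#'
#' Collapses individual dosages to population-level alternate-allele counts
#' and totals, the scan's core input. For inbred panels each individual is
#' counted as a single haplotype (its two identical alleles carry no extra
#' information); set \code{inbred = FALSE} to count both alleles of outbred
#' material. SNPs whose pooled minor-allele frequency falls below
#' \code{maf_floor} are dropped and logged.
#'
#' @param geno A \code{geno_matrix}.
#' @param assignment Population of each individual: factor/character vector
#'   along columns of the dosage matrix. Defaults to \code{geno$pop}.
#' @param maf_floor Pooled MAF floor (default 0.01).
#' @param inbred Count each individual as one haplotype (default TRUE).
#' @return An object of class \code{pop_counts}: list with \code{counts} and
#'   \code{totals} (P x J), \code{snps}, \code{pops} and a filter \code{log}.
#' @export
population_allele_counts <- function(geno, assignment = geno$pop,
                                     maf_floor = 0.01, inbred = TRUE) {
  if (is.null(assignment))
    stop2("no population assignment available")
  assignment <- as.factor(assignment)
  if (length(assignment) != ncol(geno$dosage))
    stop2("assignment length does not match the number of individuals")
  sizes <- table(assignment)
  if (any(sizes == 0))
    stop2("population(s) with zero members: ",
          paste(names(sizes)[sizes == 0], collapse = ", "))

  D <- geno$dosage
  P <- nlevels(assignment)
  J <- nrow(D)
  counts <- matrix(0, P, J, dimnames = list(levels(assignment), rownames(D)))
  totals <- matrix(0, P, J, dimnames = dimnames(counts))
  for (p in seq_len(P)) {
    cols <- which(assignment == levels(assignment)[p])
    sub <- D[, cols, drop = FALSE]
    nonmiss <- !is.na(sub)
    sub[!nonmiss] <- 0
    if (inbred) {
      counts[p, ] <- rowSums(sub) / 2
      totals[p, ] <- rowSums(nonmiss)
    } else {
      counts[p, ] <- rowSums(sub)
      totals[p, ] <- 2 * rowSums(nonmiss)
    }
  }
  if (any(colSums(totals) == 0)) stop2("SNP(s) with zero called alleles")

  pooled <- colSums(counts) / colSums(totals)
  maf <- pmin(pooled, 1 - pooled)
  keep <- maf >= maf_floor
  out <- structure(list(
    counts = counts[, keep, drop = FALSE],
    totals = totals[, keep, drop = FALSE],
    snps = geno$snps[keep, , drop = FALSE],
    pops = levels(assignment),
    log = c(input_snps = J, dropped_low_maf = sum(!keep),
            retained = sum(keep))
  ), class = "pop_counts")
  rownames(out$snps) <- NULL
  out
}

#' @export
print.pop_counts <- function(x, ...) {
  cat(sprintf("Population allele counts: %d populations x %d SNPs\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  MAF filter: %d of %d SNPs dropped\n",
              x$log["dropped_low_maf"], x$log["input_snps"]))
  invisible(x)
}

# GLS estimate of the ancestral frequency per SNP under covariance Omega:
# pi_hat_j = (1' Omega^-1 p_j) / (1' Omega^-1 1)
gls_pi <- function(freq, omega) {
  w <- solve(omega, rep(1, nrow(omega)))
  as.numeric(crossprod(w, freq)) / sum(w)
}

# standardized frequencies z_j = (p_j - pi_j) / sqrt(pi_j (1 - pi_j))
std_freq <- function(freq, pi_hat) {
  pi_c <- pmin(pmax(pi_hat, FREQ_EPS), 1 - FREQ_EPS)
  sweep(sweep(freq, 2L, pi_c), 2L, sqrt(pi_c * (1 - pi_c)), "/")
}

#' Estimate the population allele-frequency covariance matrix
#'
#' Moment estimator with shrinkage for the P x P covariance matrix Omega of
#' standardized population allele frequencies, the null model of the scan.
#' Starting from the identity, it alternates a per-SNP GLS estimate of the
#' ancestral frequency with the sample covariance of standardized
#' frequencies, and shrinks the result towards its diagonal:
#' \code{omega_hat = (1 - delta) * S + delta * diag(S)}. SNPs whose ancestral
#' frequency estimate leaves (1e-3, 1 - 1e-3) are excluded from estimation
#' (with a warning) but are still scored downstream.
#'
#' @param counts A \code{pop_counts}.
#' @param shrinkage Shrinkage weight delta towards the diagonal (default
#'   0.05; must be > 0 to guarantee positive definiteness).
#' @param n_iter Number of GLS/covariance refinement passes (default 2).
#' @return An object of class \code{omega_model}: \code{omega} (P x P SPD),
#'   \code{pi} (per-SNP ancestral frequencies under the final Omega),
#'   \code{delta}, \code{pops}, \code{n_snps_used}, \code{excluded}.
#' @export
estimate_omega <- function(counts, shrinkage = 0.05, n_iter = 2L) {
  stopifnot(inherits(counts, "pop_counts"))
  P <- nrow(counts$counts)
  J <- ncol(counts$counts)
  if (J < 10 * P^2)
    stop2("too few SNPs to estimate Omega: need >= ", 10 * P^2, ", got ", J)
  if (shrinkage <= 0 || shrinkage >= 1)
    stop2("'shrinkage' must lie in (0, 1)")

  freq <- counts$counts / counts$totals
  omega <- diag(P)
  excl <- logical(J)
  for (it in seq_len(n_iter)) {
    pi_hat <- gls_pi(freq, omega)
    excl <- pi_hat <= PI_BAND[1] | pi_hat >= PI_BAND[2] | !is.finite(pi_hat)
    Z <- std_freq(freq[, !excl, drop = FALSE], pi_hat[!excl])
    S <- tcrossprod(Z) / ncol(Z)
    omega <- (1 - shrinkage) * S + shrinkage * diag(diag(S))
  }
  if (any(excl))
    warning(sum(excl), " SNP(s) with extreme ancestral frequency excluded ",
            "from Omega estimation", call. = FALSE)
  pi_hat <- gls_pi(freq, omega)

  structure(list(omega = omega, pi = pi_hat, delta = shrinkage,
                 pops = counts$pops, n_snps_used = sum(!excl),
                 excluded = which(excl)),
            class = "omega_model")
}

#' Construct an omega model directly
#'
#' Assembles an \code{omega_model} from a known covariance matrix and
#' ancestral frequencies, e.g. for scoring with an externally estimated null
#' model or in small worked examples.
#'
#' @param omega P x P symmetric positive-definite matrix.
#' @param pi Per-SNP ancestral frequencies in (0, 1).
#' @param pops Optional population labels.
#' @return An \code{omega_model}.
#' @export
omega_model <- function(omega, pi, pops = NULL) {
  omega <- as.matrix(omega)
  if (max(abs(omega - t(omega))) > 1e-8) stop2("'omega' must be symmetric")
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop2("'omega' is not positive definite (smallest eigenvalue ",
          format(min(ev)), ")")
  if (any(pi <= 0 | pi >= 1)) stop2("'pi' must lie strictly inside (0, 1)")
  structure(list(omega = omega, pi = as.numeric(pi), delta = NA_real_,
                 pops = pops %||% paste0("pop", seq_len(nrow(omega))),
                 n_snps_used = length(pi), excluded = integer(0)),
            class = "omega_model")
}

#' @export
print.omega_model <- function(x, digits = 3, ...) {
  P <- nrow(x$omega)
  cat(sprintf("Allele-frequency covariance model (%d populations)\n", P))
  cat(sprintf("  estimated from %d SNPs, shrinkage delta = %s\n",
              x$n_snps_used,
              if (is.na(x$delta)) "none (constructed)" else x$delta))
  cat("  Omega (correlation below diagonal):\n")
  M <- x$omega
  C <- stats::cov2cor(M)
  M[lower.tri(M)] <- C[lower.tri(C)]
  print(round(M, digits))
  invisible(x)
}

#' Simulate pseudo-observed allele counts from a fitted null model
#'
#' Draws neutral SNPs from the fitted covariance model: ancestral frequencies
#' resampled from the model's empirical distribution, population frequencies
#' from the truncated Gaussian with covariance \code{pi (1 - pi) Omega}, and
#' binomial sampling at the supplied per-population sample sizes. This is the
#' pseudo-observed-data (POD) generator used for significance calibration.
#'
#' @param object An \code{omega_model}.
#' @param nsim Number of SNPs to simulate.
#' @param seed Optional seed.
#' @param totals P x J matrix (or length-P vector) of allele totals to sample
#'   at; columns are resampled per simulated SNP when a matrix is given.
#' @param ... Unused.
#' @return A \code{pop_counts} with simulated counts (no MAF filter applied).
#' @export
simulate.omega_model <- function(object, nsim = 1, seed = NULL,
                                 totals, ...) {
  check_seed(seed)
  P <- nrow(object$omega)
  J <- as.integer(nsim)
  if (is.matrix(totals)) {
    tot <- totals[, sample.int(ncol(totals), J, replace = TRUE), drop = FALSE]
  } else {
    if (length(totals) != P) stop2("'totals' must have length ", P)
    tot <- matrix(totals, P, J)
  }
  pi_pool <- object$pi[object$pi > PI_BAND[1] & object$pi < PI_BAND[2]]
  pi_j <- sample(pi_pool, J, replace = TRUE)
  Lt <- t(chol(object$omega))
  A <- Lt %*% matrix(rnorm(P * J), P, J)
  A <- A * rep(sqrt(pi_j * (1 - pi_j)), each = P) + rep(pi_j, each = P)
  A <- pmin(pmax(A, FREQ_EPS), 1 - FREQ_EPS)
  cnt <- matrix(rbinom(P * J, as.vector(tot), as.vector(A)), P, J)
  snps <- data.frame(chrom = "POD", pos = seq_len(J), ref = "A", alt = "T",
                     id = paste0("pod_", seq_len(J)),
                     stringsAsFactors = FALSE)
  structure(list(counts = cnt, totals = tot, snps = snps,
                 pops = object$pops,
                 log = c(input_snps = J, dropped_low_maf = 0L, retained = J)),
            class = "pop_counts")
}
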