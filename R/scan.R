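#' SNP-specific differentiation statistic XtX
#'
#' Computes, for every SNP, the covariance-corrected differentiation
#' statistic \code{XtX = z' Omega^-1 z}, where \code{z} is the vector of
#' standardized population allele frequencies. XtX plays the role of a
#' SNP-specific FST that accounts for the shared history encoded in Omega;
#' under the neutral model with GLS centering it is approximately
#' chi-squared with P - 1 degrees of freedom.
#'
#' @param counts A \code{pop_counts}.
#' @param model An \code{omega_model} with matching population dimension.
#' @param pi Optional per-SNP ancestral frequencies. Default: the model's
#'   \code{pi} when its length matches, otherwise re-estimated by GLS under
#'   the model's Omega.
#' @return Named numeric vector of XtX values (>= 0), one per SNP.
#' @export
#' @examples
#' # two populations at frequencies 0.8 / 0.2 around pi = 0.5: XtX = 0.72
#' cts <- list(counts = matrix(c(80, 20), 2), totals = matrix(100, 2, 1),
#'             snps = NULL, pops = c("a", "b"))
#' class(cts) <- "pop_counts"
#' xtx_scan(cts, omega_model(diag(2), pi = 0.5))
xtx_scan <- function(counts, model, pi = NULL) {
  stopifnot(inherits(counts, "pop_counts"), inherits(model, "omega_model"))
  P <- nrow(counts$counts)
  if (nrow(model$omega) != P)
    stop2("model has ", nrow(model$omega), " populations, counts have ", P)
  freq <- counts$counts / counts$totals
  if (is.null(pi)) {
    pi <- if (length(model$pi) == ncol(freq)) model$pi
          else gls_pi(freq, model$omega)
  }
  Z <- std_freq(freq, pi)
  L <- t(chol(model$omega))              # lower factor, reused across SNPs
  W <- forwardsolve(L, Z)
  xtx <- colSums(W^2)
  names(xtx) <- counts$snps$id
  xtx
}

#' POD-calibrated significance threshold for XtX
#'
#' Simulates pseudo-observed data (PODs) from the fitted null model — by
#' default 100,000 neutral SNPs at the observed per-population sample sizes —
#' scores them with [xtx_scan()] (ancestral frequencies re-estimated by GLS,
#' exactly as for observed data) and returns the empirical \code{q}-quantile
#' of the null XtX sample as the significance threshold.
#'
#' @param model An \code{omega_model}.
#' @param totals Observed per-population allele totals (P x J matrix or
#'   length-P vector) at which PODs are sampled.
#' @param n_pod Number of POD SNPs (default 100,000).
#' @param q Quantile defining the threshold (default 0.99).
#' @param seed Seed for the POD simulation.
#' @return An object of class \code{pod_result}: \code{threshold},
#'   \code{sample} (the null XtX values), \code{q}, \code{n_pod},
#'   \code{seed}.
#' @export
pod_threshold <- function(model, totals, n_pod = 1e5, q = 0.99, seed = NULL) {
  stopifnot(inherits(model, "omega_model"))
  if (q <= 0 || q >= 1) stop2("'q' must lie in (0, 1)")
  pod <- simulate(model, nsim = n_pod, seed = seed, totals = totals)
  pi_pod <- gls_pi(pod$counts / pod$totals, model$omega)
  xtx <- xtx_scan(pod, model, pi = pi_pod)
  structure(list(threshold = unname(quantile(xtx, q, type = 7)),
                 sample = unname(xtx), q = q, n_pod = as.integer(n_pod),
                 seed = seed),
            class = "pod_result")
}

#' @export
print.pod_result <- function(x, ...) {
  cat(sprintf("POD calibration: %d simulated SNPs\n", x$n_pod))
  cat(sprintf("  XtX threshold at the %.4g%% quantile: %.3f\n",
              100 * x$q, x$threshold))
  invisible(x)
}

#' Bayes factors for covariate association (deciban)
#'
#' Scores each SNP for linear association between standardized population
#' allele frequencies and a standardized population covariate under the
#' covariance null model. Both sides are whitened with \code{Omega^(-1/2)};
#' the association model puts a Gaussian prior \code{beta ~ N(0, tau^2)} on
#' the regression slope, giving the closed-form Bayes factor
#' \deqn{BF = (1 + \tau^2 S_{xx})^{-1/2}
#'   \exp\left(\tfrac12 \tau^2 S_{xy}^2 / (1 + \tau^2 S_{xx})\right)}
#' with \eqn{S_{xx} = x'x}, \eqn{S_{xy} = x'y} on the whitened scale.
#' Reported as \code{10 * log10(BF)} (deciban): 10 dB is conventionally
#' "strong", 20 dB "decisive" support for association.
#'
#' @param counts A \code{pop_counts}.
#' @param model An \code{omega_model}.
#' @param covariate Length-P covariate, standardized to zero mean and unit
#'   variance (divisor P); see [standardize_covariate()].
#' @param tau Prior standard deviation of the slope. Default chooses
#'   \code{tau^2 = 0.1 * mean(diag(Omega))} — prior effect variance one tenth
#'   of the standardized-frequency variance.
#' @param pi Optional ancestral frequencies (as in [xtx_scan()]).
#' @return Named numeric vector of Bayes factors in deciban.
#' @export
bf_scan <- function(counts, model, covariate, tau = NULL, pi = NULL) {
  stopifnot(inherits(counts, "pop_counts"), inherits(model, "omega_model"))
  P <- nrow(counts$counts)
  if (length(covariate) != P)
    stop2("covariate has length ", length(covariate), ", expected ", P)
  if (sd(covariate) == 0) stop2("zero-variance covariate")
  if (abs(mean(covariate)) > 1e-6 ||
      abs(mean(covariate^2) - 1) > 1e-6)
    stop2("covariate must be standardized (zero mean, unit variance, ",
          "divisor P); see standardize_covariate()")
  if (is.null(tau)) tau <- sqrt(0.1 * mean(diag(model$omega)))
  if (tau < 0) stop2("'tau' must be non-negative")

  freq <- counts$counts / counts$totals
  if (is.null(pi)) {
    pi <- if (length(model$pi) == ncol(freq)) model$pi
          else gls_pi(freq, model$omega)
  }
  Z <- std_freq(freq, pi)
  L <- t(chol(model$omega))
  Y <- forwardsolve(L, Z)                 # whitened frequencies
  x <- forwardsolve(L, covariate)         # whitened covariate
  sxx <- sum(x^2)
  sxy <- as.numeric(crossprod(x, Y))
  g <- tau^2 * sxx
  log_bf <- -0.5 * log1p(g) + 0.5 * (tau^2 * sxy^2) / (1 + g)
  bf_db <- 10 * log_bf / log(10)
  names(bf_db) <- counts$snps$id
  bf_db
}

#' Consolidate replicate scan runs
#'
#' Averages per-SNP scores over replicate runs of the scan (the 5-run
#' protocol) and records the per-SNP standard deviation of each score.
#'
#' @param runs List of score data frames over identical SNP sets; each needs
#'   an \code{id} column plus numeric score columns.
#' @return Data frame with the per-SNP mean of every score column and
#'   companion \code{<col>_sd} columns.
#' @export
consolidate_runs <- function(runs) {
  if (length(runs) < 1L) stop2("no runs supplied")
  runs <- lapply(runs, as.data.frame)
  ids <- runs[[1]]$id
  if (is.null(ids)) stop2("runs must carry an 'id' column")
  for (k in seq_along(runs)[-1]) {
    if (!identical(runs[[k]]$id, ids)) {
      div <- which(runs[[k]]$id != ids)[1] %||% (length(ids) + 1L)
      stop2("run ", k, " covers a different SNP set (first divergence at ",
            "row ", div, ")")
    }
  }
  num_cols <- names(runs[[1]])[vapply(runs[[1]], is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("pos"))
  out <- runs[[1]][setdiff(names(runs[[1]]), num_cols)]
  for (cl in num_cols) {
    M <- vapply(runs, function(r) r[[cl]], numeric(length(ids)))
    M <- matrix(M, nrow = length(ids))
    out[[cl]] <- rowMeans(M)
    out[[paste0(cl, "_sd")]] <- apply(M, 1L, sd)
  }
  out
}

#' Covariance-aware genome scan for differentiation and association
#'
#' The package's central fitting function. From population allele counts it
#' estimates the allele-frequency covariance matrix Omega, computes per-SNP
#' XtX differentiation statistics, calibrates the XtX significance threshold
#' with pseudo-observed data, and scores association with each supplied
#' environmental covariate by closed-form Bayes factors in deciban.
#'
#' @param counts A \code{pop_counts} from [population_allele_counts()].
#' @param covariates Optional P x K matrix of standardized population
#'   covariates (e.g. from [scan_covariates()]); K Bayes-factor tracks are
#'   computed.
#' @param shrinkage,n_iter Passed to [estimate_omega()].
#' @param n_pod,q Passed to [pod_threshold()].
#' @param bf_cut Bayes-factor significance cut in deciban (default 10).
#' @param tau Prior slope scale for [bf_scan()] (default as documented
#'   there).
#' @param seed Seed for the POD simulation.
#' @return An object of class \code{gea_scan}: list with \code{scores} (data
#'   frame: chrom, pos, id, xtx, xtx_pass, one \code{bf_<name>} and
#'   \code{bf_<name>_pass} pair per covariate), \code{model}
#'   (the \code{omega_model}), \code{pod} (the \code{pod_result}),
#'   \code{bf_cut}, \code{covariates}.
#' @seealso [call_signatures()] to convert scores into regions.
#' @export
gea_scan <- function(counts, covariates = NULL, shrinkage = 0.05,
                     n_iter = 2L, n_pod = 1e5, q = 0.99, bf_cut = 10,
                     tau = NULL, seed = NULL) {
  stopifnot(inherits(counts, "pop_counts"))
  model <- estimate_omega(counts, shrinkage = shrinkage, n_iter = n_iter)
  xtx <- xtx_scan(counts, model)
  pod <- pod_threshold(model, totals = counts$totals, n_pod = n_pod, q = q,
                       seed = seed)
  scores <- data.frame(chrom = counts$snps$chrom, pos = counts$snps$pos,
                       id = counts$snps$id, xtx = unname(xtx),
                       xtx_pass = unname(xtx) > pod$threshold,
                       stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("PC", seq_len(ncol(covariates)))
    for (k in seq_len(ncol(covariates))) {
      nm <- tolower(colnames(covariates)[k])
      db <- bf_scan(counts, model, covariates[, k], tau = tau)
      scores[[paste0("bf_", nm)]] <- unname(db)
      scores[[paste0("bf_", nm, "_pass")]] <- unname(db) > bf_cut
    }
  }
  structure(list(scores = scores, model = model, pod = pod,
                 bf_cut = bf_cut, covariates = covariates),
            class = "gea_scan")
}

#' @export
print.gea_scan <- function(x, ...) {
  cat(sprintf("Genome scan: %d SNPs, %d populations\n",
              nrow(x$scores), nrow(x$model$omega)))
  cat(sprintf("  XtX threshold (POD %.4g%%): %.3f  (%d SNPs pass)\n",
              100 * x$pod$q, x$pod$threshold, sum(x$scores$xtx_pass)))
  for (nm in grep("^bf_.*_pass$", names(x$scores), value = TRUE)) {
    cat(sprintf("  %s > %.3g dB: %d SNPs\n",
                sub("_pass$", "", nm), x$bf_cut, sum(x$scores[[nm]])))
  }
  invisible(x)
}

#' @export
summary.gea_scan <- function(object, ...) {
  s <- object$scores
  bf_cols <- grep("^bf_", names(s), value = TRUE)
  bf_cols <- bf_cols[!grepl("_pass$", bf_cols)]
  out <- list(
    n_snps = nrow(s),
    n_pops = nrow(object$model$omega),
    xtx_threshold = object$pod$threshold,
    xtx_exceedance = mean(s$xtx_pass),
    xtx_quartiles = quantile(s$xtx, c(0.25, 0.5, 0.75)),
    bf_exceedance = vapply(bf_cols, function(cl)
      mean(s[[cl]] > object$bf_cut), numeric(1)),
    omega = object$model$omega
  )
  class(out) <- "summary.gea_scan"
  out
}

#' @export
print.summary.gea_scan <- function(x, ...) {
  cat(sprintf("Genome scan summary: %d SNPs, %d populations\n",
              x$n_snps, x$n_pops))
  cat(sprintf("  XtX median %.2f (IQR %.2f-%.2f); threshold %.2f; %.3g%% exceed\n",
              x$xtx_quartiles[2], x$xtx_quartiles[1], x$xtx_quartiles[3],
              x$xtx_threshold, 100 * x$xtx_exceedance))
  for (nm in names(x$bf_exceedance))
    cat(sprintf("  %s: %.3g%% of SNPs above the cut\n",
                nm, 100 * x$bf_exceedance[nm]))
  invisible(x)
}

#' Manhattan-style plot of scan scores
#'
#' @param x A \code{gea_scan}.
#' @param statistic Which track to draw: \code{"xtx"} or a Bayes-factor
#'   column name such as \code{"bf_pc1"}.
#' @param ... Passed to [graphics::plot.default()].
#' @export
plot.gea_scan <- function(x, statistic = "xtx", ...) {
  s <- x$scores
  if (!statistic %in% names(s)) stop2("no score column '", statistic, "'")
  chroms <- unique(s$chrom)
  offs <- setNames(cumsum(c(0, head(tapply(s$pos, s$chrom, max)[chroms], -1))),
                   chroms)
  gx <- s$pos + offs[s$chrom]
  col <- (match(s$chrom, chroms) %% 2L) + 1L
  plot.default(gx, s[[statistic]], pch = 16, cex = 0.4,
               col = c("grey30", "steelblue")[col],
               xlab = "genome position", ylab = statistic, ...)
  thr <- if (statistic == "xtx") x$pod$threshold else x$bf_cut
  abline(h = thr, lty = 3, col = "red")
  invisible(x)
}
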