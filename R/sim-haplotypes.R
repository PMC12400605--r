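#' Simulate an inbred haplotype panel with block structure
#'
#' Generates a local haplotype panel for one genomic region via a founder
#' copy process: each sample haplotype is a mosaic of a small set of founder
#' haplotypes, switching founders along the chromosome with a per-bp hazard
#' of \code{1 / block_len_mean} (so the switch probability across a gap of
#' \code{d} bp is \code{1 - exp(-d / block_len_mean)}), plus per-site
#' mutation. Populations weight the founders differently, so local block
#' frequencies follow a configurable gradient — the structure the
#' haplotype-block module is designed to detect.
#'
#' @param config A [sim_config()]; uses \code{n_pops}, \code{n_ind_per_pop},
#'   \code{block_len_mean}, \code{n_founders}, \code{mutation_rate},
#'   \code{seed}.
#' @param n_snps Number of SNPs in the region.
#' @param region_length Region length in bp.
#' @param founder_weights Optional P x F matrix of founder weights per
#'   population (rows are renormalized). Default is a smooth gradient: founder
#'   f is most frequent in populations at its position along the population
#'   axis, emulating a latitudinal cline of local haplotypes.
#' @param seed Optional seed; default derives from the config seed.
#'
#' @return An object of class \code{hap_panel}: list with \code{hap}
#'   (N x S 0/1 matrix, one haplotype per inbred accession), \code{pos}
#'   (positions, bp), \code{pop} (factor), \code{founders} (F x S matrix),
#'   \code{founder_path} (N x S founder index before mutation),
#'   \code{weights} (P x F).
#' @export
#' @examples
#' cfg <- sim_config(n_pops = 4, n_snps = 100, n_ind_per_pop = 30, seed = 3)
#' pan <- simulate_haplotype_panel(cfg, n_snps = 50)
#' dim(pan$hap)
simulate_haplotype_panel <- function(config, n_snps = 200L,
                                     region_length = 1e6,
                                     founder_weights = NULL,
                                     seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  P <- config$n_pops
  Fn <- config$n_founders
  if (Fn < 2L) stop2("'n_founders' must be >= 2")
  if (config$block_len_mean <= 0) stop2("'block_len_mean' must be positive")
  if (is.null(seed)) {
    if (!is.null(config$seed)) set.seed(config$seed + 2L)
  } else check_seed(seed)

  S <- as.integer(n_snps)
  pos <- sort(sample.int(region_length, S))

  if (is.null(founder_weights)) {
    # gradient: founders anchored along the population axis
    fpos <- seq(0, 1, length.out = Fn)
    ppos <- seq(0, 1, length.out = P)
    founder_weights <- outer(ppos, fpos,
                             function(a, b) exp(-(a - b)^2 / (2 * 0.25^2)))
  }
  founder_weights <- as.matrix(founder_weights)
  if (!all(dim(founder_weights) == c(P, Fn)))
    stop2("'founder_weights' must be ", P, " x ", Fn)
  if (any(founder_weights < 0) || any(rowSums(founder_weights) == 0))
    stop2("founder weights must be non-negative with positive row sums")
  W <- founder_weights / rowSums(founder_weights)

  founders <- matrix(rbinom(Fn * S, 1L, 0.5), Fn, S)

  n <- config$n_ind_per_pop
  N <- P * n
  pop <- rep(seq_len(P), each = n)
  p_switch <- c(0, 1 - exp(-diff(pos) / config$block_len_mean))

  path <- matrix(0L, N, S)
  for (i in seq_len(N)) {
    w <- W[pop[i], ]
    k <- sample.int(Fn, 1L, prob = w)
    sw <- runif(S) < p_switch
    sw[1] <- TRUE
    idx <- integer(S)
    for (s in seq_len(S)) {
      if (sw[s]) k <- sample.int(Fn, 1L, prob = w)
      idx[s] <- k
    }
    path[i, ] <- idx
  }
  hap <- matrix(founders[cbind(as.vector(path), rep(seq_len(S), each = N))],
                N, S)
  if (config$mutation_rate > 0) {
    flip <- matrix(runif(N * S) < config$mutation_rate, N, S)
    hap[flip] <- 1L - hap[flip]
  }

  structure(list(hap = hap, pos = pos,
                 pop = factor(paste0("pop", pop),
                              levels = paste0("pop", seq_len(P))),
                 founders = founders, founder_path = path, weights = W),
            class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("Haplotype panel: %d haplotypes x %d SNPs, %d founders\n",
              nrow(x$hap), ncol(x$hap), nrow(x$founders)))
  invisible(x)
}
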