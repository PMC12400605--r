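#' Pairwise linkage disequilibrium (r2) between SNPs
#'
#' Squared Pearson correlation of dosage vectors over pairwise-complete
#' observations. For fully inbred lines the composite dosage r2 equals the
#' haplotype r2; for heterozygous material it is the composite approximation
#' (documented limitation).
#'
#' @param geno A \code{geno_matrix}.
#' @param snps Optional character vector of SNP ids (default: all passing
#'   the MAF floor).
#' @param maf_floor MAF floor applied to the selected SNPs (default 0.05).
#' @return Object of class \code{ld_matrix}: list with \code{r2} (symmetric,
#'   unit diagonal) and \code{snps} metadata.
#' @export
pairwise_r2 <- function(geno, snps = NULL, maf_floor = 0.05) {
  D <- geno$dosage
  meta <- geno$snps
  if (!is.null(snps)) {
    idx <- match(snps, meta$id)
    if (anyNA(idx)) stop2("unknown SNP id(s): ",
                          paste(snps[is.na(idx)], collapse = ", "))
    D <- D[idx, , drop = FALSE]
    meta <- meta[idx, , drop = FALSE]
  }
  f <- rowMeans(D, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  mono <- maf == 0
  if (any(mono))
    stop2("monomorphic SNP(s) in set: ",
          paste(meta$id[mono], collapse = ", "))
  keep <- maf >= maf_floor
  D <- D[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  if (nrow(D) < 2L) stop2("fewer than 2 SNPs pass the MAF floor")
  r <- suppressWarnings(cor(t(D), use = "pairwise.complete.obs"))
  r2 <- r^2
  diag(r2) <- 1
  dimnames(r2) <- list(meta$id, meta$id)
  rownames(meta) <- NULL
  structure(list(r2 = r2, snps = meta), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  n <- nrow(x$r2)
  off <- x$r2[upper.tri(x$r2)]
  cat(sprintf("LD matrix: %d SNPs; mean off-diagonal r2 = %.3f\n",
              n, mean(off)))
  invisible(x)
}

#' Background LD from physically unlinked marker pairs
#'
#' Samples random interchromosomal SNP pairs (MAF >= 5%) and summarizes
#' their r2 two ways: the mean, and the unlinked-r2 reference statistic of
#' Breseghello & Sorrells — the square of the 95th percentile of the
#' square-root-transformed unlinked r2 values.
#'
#' @param geno A \code{geno_matrix} with at least two chromosomes.
#' @param n_pairs Number of random interchromosomal pairs (default 100,000).
#' @param maf_floor MAF floor (default 0.05).
#' @param seed Seed for pair sampling.
#' @param r2 Optional precomputed vector of unlinked-pair r2 values; when
#'   given, sampling is skipped and only the two summaries are computed.
#' @return Object of class \code{background_ld}: \code{mean_r2},
#'   \code{bs_p95}, \code{n_pairs}, \code{seed}.
#' @export
background_ld <- function(geno, n_pairs = 1e5, maf_floor = 0.05,
                          seed = NULL, r2 = NULL) {
  if (!is.null(r2)) {
    return(structure(list(mean_r2 = mean(r2, na.rm = TRUE),
                          bs_p95 = unname(quantile(sqrt(r2), 0.95,
                                                   type = 7,
                                                   na.rm = TRUE))^2,
                          n_pairs = length(r2), seed = seed, r2 = r2),
                     class = "background_ld"))
  }
  check_seed(seed)
  f <- rowMeans(geno$dosage, na.rm = TRUE) / 2
  keep <- pmin(f, 1 - f) >= maf_floor
  D <- geno$dosage[keep, , drop = FALSE]
  chrom <- geno$snps$chrom[keep]
  if (length(unique(chrom)) < 2L)
    stop2("background LD needs SNPs on at least two chromosomes")
  n <- nrow(D)
  i <- sample.int(n, n_pairs, replace = TRUE)
  j <- sample.int(n, n_pairs, replace = TRUE)
  ok <- chrom[i] != chrom[j]
  while (any(!ok)) {               # re-draw intra-chromosomal collisions
    j[!ok] <- sample.int(n, sum(!ok), replace = TRUE)
    ok <- chrom[i] != chrom[j]
  }
  r2 <- pair_r2(D, i, j)
  structure(list(mean_r2 = mean(r2, na.rm = TRUE),
                 bs_p95 = unname(quantile(sqrt(r2), 0.95, type = 7,
                                          na.rm = TRUE))^2,
                 n_pairs = as.integer(n_pairs), seed = seed,
                 r2 = r2),
            class = "background_ld")
}

# r2 for index pairs of rows of a dosage matrix (complete observations)
pair_r2 <- function(D, i, j) {
  vapply(seq_along(i), function(k) {
    suppressWarnings(cor(D[i[k], ], D[j[k], ],
                         use = "pairwise.complete.obs"))^2
  }, numeric(1))
}

#' @export
print.background_ld <- function(x, ...) {
  cat(sprintf(paste0("Background LD (%d interchromosomal pairs): ",
                     "mean r2 = %.4f, 95th-percentile statistic = %.4f\n"),
              x$n_pairs, x$mean_r2, x$bs_p95))
  invisible(x)
}

#' Permutation t-test of LD samples on the cube-root scale
#'
#' Two-sided permutation test of the difference in means between two r2
#' samples after a cube-root transform (which symmetrizes the skewed r2
#' distribution). The p-value uses the add-one rule:
#' \code{p = (1 + #permuted |t| >= observed |t|) / (n_perm + 1)}.
#'
#' @param a,b Numeric r2 samples.
#' @param n_perm Number of permutations (default 1,000).
#' @param transform Transform applied to both samples before testing
#'   (default cube root); use \code{identity} to test raw values.
#' @param seed Seed for the permutations.
#' @return List: \code{p_value}, \code{t_obs}, \code{mean_diff} (on the
#'   transformed scale), \code{n_perm}.
#' @export
permutation_ld_test <- function(a, b, n_perm = 1000L,
                                transform = function(x) x^(1 / 3),
                                seed = NULL) {
  if (length(a) == 0L || length(b) == 0L) stop2("empty sample")
  if (n_perm < 1L) stop2("'n_perm' must be >= 1")
  check_seed(seed)
  ta <- transform(a)
  tb <- transform(b)
  pool <- c(ta, tb)
  na <- length(ta)
  tstat <- function(xa, xb) {
    v <- stats::var(xa) / length(xa) + stats::var(xb) / length(xb)
    if (v == 0) return(0)
    (mean(xa) - mean(xb)) / sqrt(v)
  }
  t_obs <- tstat(ta, tb)
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    if (abs(tstat(pool[idx], pool[-idx])) >= abs(t_obs)) exceed <- exceed + 1L
  }
  list(p_value = (1 + exceed) / (n_perm + 1), t_obs = t_obs,
       mean_diff = mean(ta) - mean(tb), n_perm = as.integer(n_perm))
}

#' Threshold LD network over signature peak SNPs
#'
#' Builds a graph whose nodes are signature peak SNPs and whose edges connect
#' pairs with \code{r2 > multiple * background}; clusters are connected
#' components. Reported clusters are those consistent with long-range
#' epistatic structure: containing an interchromosomal edge, or
#' intra-chromosomal edges spanning at least \code{min_dist}.
#'
#' @param ld An \code{ld_matrix} over the peak SNPs.
#' @param background A \code{background_ld} (or a single number).
#' @param multiple Threshold multiple of the background (default 3).
#' @param background_stat Which background summary anchors the threshold:
#'   \code{"mean"} (default) or \code{"bs_p95"}.
#' @param min_dist Minimum intra-chromosomal span (bp) for a reported
#'   cluster (default 5 Mb).
#' @return Object of class \code{ld_network}: \code{edges} (data frame),
#'   \code{components} (membership vector), \code{clusters} (reported
#'   cluster ids), \code{threshold}, \code{graph} (igraph object).
#' @export
build_ld_network <- function(ld, background, multiple = 3,
                             background_stat = c("mean", "bs_p95"),
                             min_dist = 5e6) {
  stopifnot(inherits(ld, "ld_matrix"))
  if (multiple <= 0) stop2("'multiple' must be positive")
  background_stat <- match.arg(background_stat)
  bg <- if (inherits(background, "background_ld")) {
    if (background_stat == "mean") background$mean_r2 else background$bs_p95
  } else as.numeric(background)
  thr <- multiple * bg

  R <- ld$r2
  n <- nrow(R)
  ut <- which(upper.tri(R) & R > thr, arr.ind = TRUE)
  meta <- ld$snps
  edges <- data.frame(
    snp_a = meta$id[ut[, 1]], snp_b = meta$id[ut[, 2]],
    chrom_a = meta$chrom[ut[, 1]], chrom_b = meta$chrom[ut[, 2]],
    dist = ifelse(meta$chrom[ut[, 1]] == meta$chrom[ut[, 2]],
                  abs(meta$pos[ut[, 1]] - meta$pos[ut[, 2]]), NA_integer_),
    r2 = R[ut], stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    edges[c("snp_a", "snp_b")], directed = FALSE,
    vertices = data.frame(name = meta$id)
  )
  comp <- igraph::components(g)$membership

  qualifies <- vapply(seq_len(max(comp)), function(k) {
    e <- edges[comp[edges$snp_a] == k, , drop = FALSE]
    if (nrow(e) == 0L) return(FALSE)
    any(e$chrom_a != e$chrom_b) ||
      any(!is.na(e$dist) & e$dist >= min_dist)
  }, logical(1))

  structure(list(edges = edges, components = comp,
                 clusters = which(qualifies), threshold = thr,
                 background = bg, multiple = multiple,
                 min_dist = min_dist, graph = g),
            class = "ld_network")
}

#' @export
print.ld_network <- function(x, ...) {
  nontrivial <- sum(table(x$components) > 1)
  cat(sprintf(paste0("LD network: %d nodes, %d edges (r2 > %.4f); ",
                     "%d multi-node components, %d reported cluster(s)\n"),
              length(x$components), nrow(x$edges), x$threshold,
              nontrivial, length(x$clusters)))
  invisible(x)
}

#' LD decay with physical distance
#'
#' Mean r2 per distance bin over intra-chromosomal SNP pairs.
#'
#' @param geno A \code{geno_matrix}.
#' @param chrom Chromosome to analyze (default: all).
#' @param max_dist Maximum pair distance in bp.
#' @param bins Number of equal-width distance bins.
#' @param maf_floor MAF floor (default 0.05).
#' @param max_pairs Cap on sampled pairs per chromosome (default 200,000).
#' @param seed Seed used only if pair subsampling is needed.
#' @return Data frame: bin midpoint (\code{dist}), \code{mean_r2},
#'   \code{n_pairs}.
#' @export
ld_decay <- function(geno, chrom = NULL, max_dist = 1e6, bins = 20L,
                     maf_floor = 0.05, max_pairs = 2e5, seed = NULL) {
  check_seed(seed)
  f <- rowMeans(geno$dosage, na.rm = TRUE) / 2
  keep <- pmin(f, 1 - f) >= maf_floor
  if (!is.null(chrom)) keep <- keep & geno$snps$chrom %in% chrom
  D <- geno$dosage[keep, , drop = FALSE]
  meta <- geno$snps[keep, , drop = FALSE]
  if (is.unsorted(meta$pos[order(match(meta$chrom, unique(meta$chrom)))]) &&
      any(tapply(meta$pos, meta$chrom, is.unsorted)))
    stop2("positions must be sorted within chromosomes")

  ii <- jj <- integer(0)
  for (ch in unique(meta$chrom)) {
    w <- which(meta$chrom == ch)
    if (length(w) < 2L) next
    cmb <- utils::combn(w, 2L)
    d <- meta$pos[cmb[2, ]] - meta$pos[cmb[1, ]]
    ok <- d <= max_dist & d > 0
    ii <- c(ii, cmb[1, ok])
    jj <- c(jj, cmb[2, ok])
  }
  if (length(ii) == 0L)
    return(data.frame(dist = numeric(0), mean_r2 = numeric(0),
                      n_pairs = integer(0)))
  if (length(ii) > max_pairs) {
    pick <- sample.int(length(ii), max_pairs)
    ii <- ii[pick]; jj <- jj[pick]
  }
  d <- abs(meta$pos[jj] - meta$pos[ii])
  r2 <- pair_r2(D, ii, jj)
  br <- seq(0, max_dist, length.out = bins + 1L)
  bin <- cut(d, br, include.lowest = TRUE)
  agg <- tapply(r2, bin, mean, na.rm = TRUE)
  cnt <- tapply(r2, bin, length)
  mid <- (br[-1] + br[-length(br)]) / 2
  out <- data.frame(dist = mid, mean_r2 = as.numeric(agg),
                    n_pairs = as.integer(ifelse(is.na(cnt), 0L, cnt)))
  out[out$n_pairs > 0, , drop = FALSE]
}

#' Sliding-window LD pruning
#'
#' Greedy left-to-right pruning for structure analysis input: within each
#' sliding window of \code{window_snps} consecutive retained SNPs capped at
#' \code{window_bp} span, any pair with \code{r2 > threshold} drops the
#' member with the lower MAF (ties drop the larger position). Deterministic
#' and idempotent.
#'
#' @param geno A \code{geno_matrix}.
#' @param window_bp Window span cap in bp (default 500,000).
#' @param window_snps SNPs per window (default 10).
#' @param threshold r2 threshold; a number or a \code{background_ld} (its
#'   mean is used).
#' @param maf_floor MAF floor applied before pruning (default 0.05).
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(geno, window_bp = 5e5, window_snps = 10L, threshold,
                     maf_floor = 0.05) {
  if (inherits(threshold, "background_ld")) threshold <- threshold$mean_r2
  f <- rowMeans(geno$dosage, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep0 <- maf >= maf_floor
  meta <- geno$snps[keep0, , drop = FALSE]
  D <- geno$dosage[keep0, , drop = FALSE]
  maf <- maf[keep0]

  kept <- logical(nrow(meta))
  for (ch in unique(meta$chrom)) {
    w <- which(meta$chrom == ch)
    w <- w[order(meta$pos[w])]
    alive <- rep(TRUE, length(w))
    for (s in seq_along(w)) {
      if (!alive[s]) next
      live <- which(alive)
      live <- live[live >= s]
      win <- live[seq_len(min(window_snps, length(live)))]
      win <- win[meta$pos[w[win]] - meta$pos[w[s]] <= window_bp]
      if (length(win) < 2L) next
      for (t in win[-1]) {
        if (!alive[s]) break
        if (!alive[t]) next
        r2 <- suppressWarnings(cor(D[w[s], ], D[w[t], ],
                                   use = "pairwise.complete.obs"))^2
        if (!is.na(r2) && r2 > threshold) {
          drop <- if (maf[w[s]] < maf[w[t]]) s
                  else if (maf[w[t]] < maf[w[s]]) t
                  else if (meta$pos[w[s]] > meta$pos[w[t]]) s else t
          alive[drop] <- FALSE
        }
      }
    }
    kept[w[alive]] <- TRUE
  }
  meta$id[kept]
}
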