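#' Pipeline configuration
#'
#' Bundles the analysis constants of the full pipeline. The defaults are the
#' protocol values used throughout: MAF floors of 1% (scan) and 5% (LD),
#' 100,000-SNP POD calibration at the 99% quantile, a 10-deciban Bayes-factor
#' cut, 50 kb merging with 5 kb padding, a 3x-background LD-network threshold
#' with a 5 Mb distance filter, 1,000 permutations, FDR 0.05 and five
#' consolidated runs.
#'
#' @param maf_floor_scan,maf_floor_ld Pooled MAF floors.
#' @param n_pod,pod_q POD sample size and threshold quantile.
#' @param bf_cut Bayes-factor significance cut (deciban).
#' @param merge_dist,pad Region merging distance and boundary padding (bp).
#' @param ld_multiple,ld_min_dist LD-network threshold multiple and minimum
#'   cluster span (bp).
#' @param n_perm Permutations for LD contrasts.
#' @param fdr Enrichment FDR.
#' @param n_runs Replicate scan runs to consolidate.
#' @param seed Master seed.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(maf_floor_scan = 0.01, maf_floor_ld = 0.05,
                            n_pod = 1e5, pod_q = 0.99, bf_cut = 10,
                            merge_dist = 5e4, pad = 5e3,
                            ld_multiple = 3, ld_min_dist = 5e6,
                            n_perm = 1000L, fdr = 0.05, n_runs = 5L,
                            seed = 1L) {
  vals <- c(maf_floor_scan = maf_floor_scan, maf_floor_ld = maf_floor_ld,
            n_pod = n_pod, pod_q = pod_q, bf_cut = bf_cut,
            merge_dist = merge_dist, pad = pad, ld_multiple = ld_multiple,
            ld_min_dist = ld_min_dist, n_perm = n_perm, fdr = fdr,
            n_runs = n_runs)
  if (any(vals <= 0)) stop2("all pipeline thresholds must be positive")
  structure(as.list(c(vals, seed = as.integer(seed))),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-15s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# scan one scenario: counts -> n_runs gea_scan fits (POD seeds differ) ->
# consolidated scores + mean threshold
scan_scenario <- function(counts, covariates, config) {
  runs <- lapply(seq_len(config$n_runs), function(r)
    gea_scan(counts, covariates, n_pod = config$n_pod, q = config$pod_q,
             bf_cut = config$bf_cut, seed = config$seed + 100L * r))
  score_list <- lapply(runs, function(x)
    x$scores[!grepl("_pass$", names(x$scores))])
  cons <- consolidate_runs(score_list)
  thr <- mean(vapply(runs, function(x) x$pod$threshold, numeric(1)))
  list(scores = cons, threshold = thr, fit = runs[[1]])
}

recall_regions <- function(regions, truth_pos) {
  if (length(truth_pos$pos) == 0L) return(NA_real_)
  if (nrow(regions) == 0L) return(0)
  gr_t <- GenomicRanges::GRanges(truth_pos$chrom,
                                 IRanges::IRanges(truth_pos$pos,
                                                  truth_pos$pos))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_t, sig_granges(regions)))
  length(unique(S4Vectors::queryHits(hits))) / length(truth_pos$pos)
}

precision_regions <- function(regions, truth_pos) {
  if (nrow(regions) == 0L) return(NA_real_)
  gr_t <- GenomicRanges::GRanges(truth_pos$chrom,
                                 IRanges::IRanges(truth_pos$pos,
                                                  truth_pos$pos))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(sig_granges(regions), gr_t))
  length(unique(S4Vectors::queryHits(hits))) / nrow(regions)
}

#' Run the full synthetic-data pipeline
#'
#' End-to-end driver: simulates a dataset from \code{sim}, derives scan
#' covariates from the six-region environmental PCA (or the generator
#' covariate when the population count differs), scans two overlapping
#' scenarios (scenario A uses all populations, scenario B drops the first,
#' northernmost group), consolidates replicate runs, calls and classifies
#' signature regions, intersects the scenarios, runs the LD-network stage on
#' signature peaks and compares region calls against the generator's truth
#' ledger.
#'
#' @param sim A [sim_config()]; its seed is overridden by the pipeline
#'   seed.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, stage outputs (scores TSV,
#'   regions TSV/BED, edge list, summary JSON) are written there.
#' @return Object of class \code{pipeline_result}: list with \code{summary}
#'   (region/overlap/cluster counts, truth precision-recall, seed),
#'   \code{scenarios} (per-scenario scores, thresholds, regions),
#'   \code{ld}, \code{truth}, \code{config}.
#' @export
run_pipeline <- function(sim = sim_config(), config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"), inherits(config, "pipeline_config"))
  sim$seed <- config$seed
  freqs <- simulate_frequencies(sim)
  geno <- simulate_genotypes(freqs)

  P <- sim$n_pops
  covA <- if (P == 6L) {
    pca <- env_pca(china_region_env())
    scan_covariates(pca, k = 2L,
                    group_to_region = setNames(as.character(1:6),
                                               paste0("pop", 1:6)))
  } else {
    matrix(standardize_covariate(sim$covariate_values), ncol = 1,
           dimnames = list(paste0("pop", seq_len(P)), "PC1"))
  }

  scenarios <- list(
    A = levels(geno$pop),
    B = levels(geno$pop)[-1]          # shared transect minus the first group
  )
  chrom_lengths <- setNames(sim$chrom_layout$length, sim$chrom_layout$chrom)

  res <- list()
  for (sc in names(scenarios)) {
    keep <- geno$pop %in% scenarios[[sc]]
    sub <- structure(list(dosage = geno$dosage[, keep, drop = FALSE],
                          snps = geno$snps,
                          pop = droplevels(geno$pop[keep]),
                          ids = geno$ids[keep]),
                     class = "geno_matrix")
    counts <- population_allele_counts(sub,
                                       maf_floor = config$maf_floor_scan)
    cov_sc <- apply(covA[scenarios[[sc]], , drop = FALSE], 2L,
                    standardize_covariate)
    scn <- scan_scenario(counts, cov_sc, config)
    regions <- list(
      xtx = call_signatures(scn$scores, "xtx", scn$threshold,
                            merge_dist = config$merge_dist,
                            pad = config$pad,
                            chrom_lengths = chrom_lengths,
                            test = "XtX", scenario = sc)
    )
    for (bf in grep("^bf_", names(scn$scores), value = TRUE)) {
      if (grepl("_sd$", bf)) next
      regions[[bf]] <- call_signatures(scn$scores, bf, config$bf_cut,
                                       merge_dist = config$merge_dist,
                                       pad = config$pad,
                                       chrom_lengths = chrom_lengths,
                                       test = toupper(bf), scenario = sc)
    }
    combined <- combine_tests(regions$xtx, regions[names(regions) != "xtx"])
    res[[sc]] <- list(scores = scn$scores, threshold = scn$threshold,
                      regions = regions, combined = combined,
                      fit = scn$fit)
  }

  venn <- overlap_sets(res$A$regions$xtx, res$B$regions$xtx)

  # LD stage on scenario-A peaks
  ld <- NULL
  peaks <- res$A$regions$xtx$peak_pos
  peak_ids <- with(res$A$regions$xtx,
                   paste0(chrom, "_", peak_pos))
  peak_ids <- intersect(peak_ids, geno$snps$id)
  if (length(peak_ids) >= 2L && nrow(sim$chrom_layout) >= 2L) {
    ldm <- pairwise_r2(geno, peak_ids, maf_floor = 0)
    bg <- background_ld(geno, n_pairs = 2e4,
                        maf_floor = config$maf_floor_ld,
                        seed = config$seed + 7L)
    net <- build_ld_network(ldm, bg, multiple = config$ld_multiple,
                            min_dist = config$ld_min_dist)
    ld <- list(matrix = ldm, background = bg, network = net)
  }

  truth <- freqs$truth
  truth$chrom <- freqs$snps$chrom
  truth$pos <- freqs$snps$pos
  t_diff <- truth[truth$class == "differentiated", c("chrom", "pos")]
  t_assoc <- truth[truth$class == "associated", c("chrom", "pos")]
  bf1 <- grep("^bf_", names(res$A$regions), value = TRUE)[1]
  summary <- list(
    seed = config$seed,
    n_snps = nrow(res$A$scores),
    n_regions = lapply(res, function(r)
      vapply(r$regions, nrow, integer(1))),
    venn_xtx = as.list(venn),
    n_ld_clusters = if (is.null(ld)) NA_integer_
                    else length(ld$network$clusters),
    xtx_recall = recall_regions(res$A$regions$xtx, t_diff),
    xtx_precision = precision_regions(res$A$regions$xtx,
                                      truth[truth$class != "neutral",
                                            c("chrom", "pos")]),
    bf_recall = if (is.na(bf1)) NA_real_
                else recall_regions(res$A$regions[[bf1]], t_assoc)
  )

  out <- structure(list(summary = summary, scenarios = res, ld = ld,
                        truth = truth, config = config, sim = sim),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, geno, freqs, out_dir)
  out
}

write_pipeline_outputs <- function(result, geno, freqs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sc in names(result$scenarios)) {
    r <- result$scenarios[[sc]]
    write.table(r$scores, file.path(dir, paste0("scores_", sc, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(r$combined, file.path(dir, paste0("regions_", sc, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(r$regions$xtx) > 0)
      write_signatures_bed(r$regions$xtx,
                           file.path(dir, paste0("regions_", sc, ".bed")))
  }
  if (!is.null(result$ld))
    write.table(result$ld$network$edges, file.path(dir, "ld_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(result$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("Landscape-genomics pipeline result\n")
  cat(sprintf("  %d SNPs scanned; seed %d\n", s$n_snps, s$seed))
  for (sc in names(s$n_regions)) {
    cat(sprintf("  scenario %s regions: %s\n", sc,
                paste(names(s$n_regions[[sc]]), s$n_regions[[sc]],
                      sep = "=", collapse = ", ")))
  }
  cat(sprintf("  XtX Venn (A only / B only / overlap): %d / %d / %d\n",
              s$venn_xtx$a_only, s$venn_xtx$b_only, s$venn_xtx$overlap))
  cat(sprintf("  truth: XtX recall %.2f, precision %.2f; BF recall %.2f\n",
              s$xtx_recall, s$xtx_precision, s$bf_recall))
  invisible(x)
}
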