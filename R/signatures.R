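#' Call adaptation-signature regions from per-SNP scores
#'
#' Converts significant SNPs into genomic regions: on each chromosome,
#' consecutive passing SNPs separated by less than \code{merge_dist} are
#' merged into one signal (the boundary distance itself splits); region
#' boundaries are the outermost passing SNPs extended by \code{pad} on both
#' sides and clipped to the chromosome; the peak is the passing SNP with the
#' largest statistic (ties break to the smallest position). Coordinates are
#' 1-based inclusive.
#'
#' @param scores Data frame sorted by (chrom, pos) with columns \code{chrom},
#'   \code{pos} and the statistic column; typically \code{gea_scan$scores}.
#' @param statistic Name of the statistic column (e.g. \code{"xtx"},
#'   \code{"bf_pc1"}).
#' @param threshold Pass cut: a number, or a \code{pod_result}.
#' @param merge_dist Merge distance in bp (default 50,000); gaps
#'   \code{>= merge_dist} split.
#' @param pad Boundary padding in bp (default 5,000).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   clipping the padded boundaries.
#' @param test,scenario Labels stored with each region.
#' @return Data frame of class \code{signatures}: chrom, start, end,
#'   peak_pos, peak_value, n_snps_supporting, test, scenario.
#' @export
#' @examples
#' sc <- data.frame(chrom = "Chr01", pos = c(100e3, 140e3, 200e3),
#'                  xtx = c(20, 25, 18))
#' call_signatures(sc, "xtx", threshold = 15)
call_signatures <- function(scores, statistic = "xtx", threshold,
                            merge_dist = 5e4, pad = 5e3,
                            chrom_lengths = NULL,
                            test = toupper(statistic), scenario = NA) {
  if (inherits(threshold, "pod_result")) threshold <- threshold$threshold
  if (!all(c("chrom", "pos", statistic) %in% names(scores)))
    stop2("'scores' needs columns chrom, pos and '", statistic, "'")
  ord <- order(match(scores$chrom, unique(scores$chrom)), scores$pos)
  if (!identical(ord, seq_len(nrow(scores))))
    stop2("'scores' must be sorted by (chrom, pos)")

  pass <- scores[scores[[statistic]] > threshold, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), peak_pos = integer(0),
                      peak_value = numeric(0), n_snps_supporting = integer(0),
                      test = character(0), scenario = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(pass) == 0L)
    return(structure(empty, class = c("signatures", "data.frame")))

  out <- do.call(rbind, lapply(split(pass, pass$chrom), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(d$pos) >= merge_dist)))
    do.call(rbind, lapply(split(d, grp), function(g) {
      vals <- g[[statistic]]
      pk <- which(vals == max(vals))
      pk <- pk[which.min(g$pos[pk])]
      lim <- if (!is.null(chrom_lengths) && g$chrom[1] %in% names(chrom_lengths))
        chrom_lengths[[g$chrom[1]]] else Inf
      data.frame(chrom = g$chrom[1],
                 start = max(1, min(g$pos) - pad),
                 end = min(lim, max(g$pos) + pad),
                 peak_pos = g$pos[pk], peak_value = vals[pk],
                 n_snps_supporting = nrow(g),
                 test = test, scenario = as.character(scenario),
                 stringsAsFactors = FALSE)
    }))
  }))
  out <- out[order(match(out$chrom, unique(scores$chrom)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("signatures", "data.frame"))
}

#' @export
print.signatures <- function(x, ...) {
  cat(sprintf("Adaptation signatures: %d regions on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0) {
    cat(sprintf("  total span %.3g kb; median width %.3g kb\n",
                sum(x$end - x$start + 1) / 1e3,
                stats::median(x$end - x$start + 1) / 1e3))
    print.data.frame(head(as.data.frame(x), 10))
    if (nrow(x) > 10) cat("  ...\n")
  }
  invisible(x)
}

sig_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
}

check_disjoint <- function(x, label) {
  if (nrow(x) < 2L) return(invisible(TRUE))
  gr <- sig_granges(x)
  hits <- GenomicRanges::findOverlaps(gr, gr, minoverlap = 1L)
  if (length(hits) > length(gr))
    stop2("'", label, "' contains internally overlapping regions")
  invisible(TRUE)
}

#' Overlap counts between two signature sets
#'
#' Two regions overlap iff their 1-based inclusive intervals share at least
#' one bp on the same chromosome. Each region counts once; the overlap count
#' is the smaller side of the matched pairs, so the three Venn cells sum to
#' \code{|A| + |B| - overlap}.
#'
#' @param a,b \code{signatures} data frames, each internally non-overlapping.
#' @return Named vector: \code{a_only}, \code{b_only}, \code{overlap}.
#' @export
overlap_sets <- function(a, b) {
  check_disjoint(a, "a")
  check_disjoint(b, "b")
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(c(a_only = nrow(a), b_only = nrow(b), overlap = 0L))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(sig_granges(a), sig_granges(b),
                                minoverlap = 1L))
  n_a <- length(unique(S4Vectors::queryHits(hits)))
  n_b <- length(unique(S4Vectors::subjectHits(hits)))
  ov <- min(n_a, n_b)
  c(a_only = nrow(a) - n_a, b_only = nrow(b) - n_b, overlap = ov)
}

#' Classify signatures by supporting tests
#'
#' Annotates each differentiation (XtX) region with the association tests
#' whose regions it intersects, yielding the differentiation-only /
#' association-only / both classification, and appends association regions
#' not matched by any differentiation region.
#'
#' @param xtx_regions \code{signatures} from the XtX test.
#' @param bf_regions Named list of \code{signatures}, one per covariate.
#' @return Data frame of all regions with a \code{supported_by} column
#'   (comma-separated test labels) and a \code{class} column
#'   (\code{"differentiation-only"}, \code{"association-only"},
#'   \code{"both"}).
#' @export
combine_tests <- function(xtx_regions, bf_regions = list()) {
  xr <- as.data.frame(xtx_regions)
  if (nrow(xr) > 0) {
    xr$supported_by <- "XtX"
    xr$class <- "differentiation-only"
  } else {
    xr$supported_by <- character(0)
    xr$class <- character(0)
  }
  extra <- list()
  for (nm in names(bf_regions)) {
    br <- as.data.frame(bf_regions[[nm]])
    if (nrow(br) == 0L) next
    if (nrow(xr) > 0) {
      hits <- suppressWarnings(
        GenomicRanges::findOverlaps(sig_granges(xr), sig_granges(br),
                                    minoverlap = 1L))
      hit_x <- unique(S4Vectors::queryHits(hits))
      if (length(hit_x) > 0) {
        xr$supported_by[hit_x] <- paste(xr$supported_by[hit_x], nm, sep = ",")
        xr$class[hit_x] <- "both"
      }
      hit_b <- unique(S4Vectors::subjectHits(hits))
    } else hit_b <- integer(0)
    rest <- br[setdiff(seq_len(nrow(br)), hit_b), , drop = FALSE]
    if (nrow(rest) > 0) {
      rest$supported_by <- nm
      rest$class <- "association-only"
      extra[[nm]] <- rest
    }
  }
  out <- rbind(xr, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

#' Export signatures as BED (0-based half-open)
#'
#' The native \code{signatures} table is 1-based inclusive; this writes a
#' true BED file for interoperability.
#'
#' @param x \code{signatures} data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_signatures_bed <- function(x, path) {
  bed <- data.frame(chrom = x$chrom, start = x$start - 1L, end = x$end,
                    name = paste0(x$test, "_", seq_len(nrow(x))),
                    score = round(x$peak_value, 3))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
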