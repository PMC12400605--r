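#' Haplotype blocks within a signature region
#'
#' Clusters the local haplotypes of an inbred panel into non-overlapping
#' blocks by greedy consensus clustering: repeatedly take the most frequent
#' remaining haplotype string as consensus (ties break to the
#' lexicographically smallest), absorb all remaining haplotypes within
#' Hamming distance \code{max_mismatch}, and emit the cluster as a block if
#' its frequency is at least \code{min_freq}. Everything left is pooled as
#' "other". This is a transparent stand-in for heuristic block-detection
#' software; downstream comparisons operate on block frequencies, not on
#' algorithmic identity.
#'
#' @param panel A \code{hap_panel}, or a 0/1 haplotype matrix (rows =
#'   haplotypes).
#' @param region Optional column (SNP) indices restricting the region.
#' @param min_freq Minimum block frequency (default 0.05).
#' @param max_mismatch Maximum Hamming distance absorbed into a block
#'   (default 1).
#' @return Object of class \code{hap_blocks}: \code{blocks} (data frame:
#'   block, consensus, n, freq), \code{membership} (block index per
#'   haplotype; 0 = other), \code{n_hap}, \code{n_snps}.
#' @export
#' @examples
#' h <- rbind(matrix(rep(c(0, 1, 0, 1), 4), 4, byrow = TRUE),
#'            matrix(rep(c(1, 0, 1, 0), 2), 2, byrow = TRUE))
#' blocks_in_region(h, min_freq = 0.1, max_mismatch = 0)$blocks
blocks_in_region <- function(panel, region = NULL, min_freq = 0.05,
                             max_mismatch = 1L) {
  H <- if (inherits(panel, "hap_panel")) panel$hap else as.matrix(panel)
  if (!is.null(region)) H <- H[, region, drop = FALSE]
  if (ncol(H) == 0L) stop2("region contains no SNPs")
  N <- nrow(H)

  strings <- apply(H, 1L, paste, collapse = "")
  remaining <- rep(TRUE, N)
  membership <- integer(N)
  blocks <- list()
  b <- 0L
  while (any(remaining)) {
    tab <- table(strings[remaining])
    top <- max(tab)
    cons <- sort(names(tab)[tab == top])[1]
    cons_vec <- as.integer(strsplit(cons, "")[[1]])
    dist <- colSums(abs(t(H[remaining, , drop = FALSE]) - cons_vec))
    members <- which(remaining)[dist <= max_mismatch]
    if (length(members) / N < min_freq) break
    b <- b + 1L
    membership[members] <- b
    remaining[members] <- FALSE
    blocks[[b]] <- data.frame(block = b, consensus = cons,
                              n = length(members),
                              freq = length(members) / N,
                              stringsAsFactors = FALSE)
  }
  blocks <- if (b > 0) do.call(rbind, blocks)
            else data.frame(block = integer(0), consensus = character(0),
                            n = integer(0), freq = numeric(0))
  structure(list(blocks = blocks, membership = membership,
                 n_hap = N, n_snps = ncol(H)),
            class = "hap_blocks")
}

#' @export
print.hap_blocks <- function(x, ...) {
  cat(sprintf("Haplotype blocks: %d block(s) over %d SNPs, %d haplotypes ",
              nrow(x$blocks), x$n_snps, x$n_hap))
  cat(sprintf("(other: %.3g%%)\n", 100 * mean(x$membership == 0L)))
  if (nrow(x$blocks) > 0) print.data.frame(x$blocks)
  invisible(x)
}

#' Assign external haplotypes to existing block consensus sequences
#'
#' Projects haplotypes (e.g. of a cultivar panel) onto the block definitions
#' of a reference panel: each haplotype joins the nearest consensus within
#' \code{max_mismatch} (ties to the lower block index); otherwise "other"
#' (index 0).
#'
#' @param hap 0/1 haplotype matrix over the same SNPs as the blocks.
#' @param blocks A \code{hap_blocks} from the reference panel.
#' @param max_mismatch Maximum Hamming distance (default 1).
#' @return Integer membership vector (0 = other).
#' @export
assign_to_blocks <- function(hap, blocks, max_mismatch = 1L) {
  stopifnot(inherits(blocks, "hap_blocks"))
  H <- as.matrix(hap)
  if (ncol(H) != blocks$n_snps)
    stop2("haplotypes have ", ncol(H), " SNPs but blocks were built on ",
          blocks$n_snps)
  if (nrow(blocks$blocks) == 0L) return(integer(nrow(H)))
  cons <- t(vapply(blocks$blocks$consensus,
                   function(s) as.integer(strsplit(s, "")[[1]]),
                   integer(blocks$n_snps)))
  membership <- integer(nrow(H))
  for (i in seq_len(nrow(H))) {
    d <- rowSums(abs(sweep(cons, 2L, H[i, ])))
    k <- which.min(d)
    if (d[k] <= max_mismatch) membership[i] <- k
  }
  membership
}

#' Per-group haplotype block frequencies
#'
#' Fraction of each group's haplotypes belonging to each block. The
#' unassigned remainder appears as the \code{"other"} row, so columns sum
#' to 1.
#'
#' @param blocks A \code{hap_blocks}.
#' @param assignment Group factor along haplotypes (e.g. population, or
#'   maturity-group class of a cultivar panel).
#' @param membership Optional membership vector overriding the one stored in
#'   \code{blocks} (used when projecting another panel with
#'   [assign_to_blocks()]).
#' @return Matrix of class \code{block_freq_table}: rows = blocks (+
#'   "other"), columns = groups.
#' @export
block_frequencies <- function(blocks, assignment, membership = NULL) {
  stopifnot(inherits(blocks, "hap_blocks"))
  m <- membership %||% blocks$membership
  assignment <- as.factor(assignment)
  if (length(assignment) != length(m))
    stop2("assignment length does not match the number of haplotypes")
  empty <- levels(assignment)[tabulate(assignment,
                                       nlevels(assignment)) == 0L]
  if (length(empty) > 0)
    warning("empty group(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  nb <- nrow(blocks$blocks)
  tab <- vapply(levels(assignment), function(g) {
    mg <- m[assignment == g]
    if (length(mg) == 0L) return(numeric(nb + 1L))
    c(tabulate(mg, nb), sum(mg == 0L)) / length(mg)
  }, numeric(nb + 1L))
  rn <- c(if (nb > 0) paste0("block", seq_len(nb)), "other")
  tab <- matrix(tab, nrow = nb + 1L,
                dimnames = list(rn, levels(assignment)))
  structure(tab, class = c("block_freq_table", "matrix", "array"))
}

#' Latitudinal-gradient score of haplotype blocks
#'
#' Pearson correlation between each block's group frequencies and the group
#' latitudes. Constant frequency rows are undefined and flagged rather than
#' propagating NaN.
#'
#' @param table A \code{block_freq_table} (or numeric matrix, blocks in
#'   rows).
#' @param group_latitudes Latitude per group (column).
#' @return Data frame: block, r, defined (logical).
#' @export
gradient_correlation <- function(table, group_latitudes) {
  M <- unclass(table)
  if (ncol(M) < 3L) stop2("gradient correlation needs >= 3 groups")
  if (length(group_latitudes) != ncol(M))
    stop2("'group_latitudes' must have one value per group")
  r <- numeric(nrow(M))
  defined <- logical(nrow(M))
  for (i in seq_len(nrow(M))) {
    if (sd(M[i, ]) == 0 || sd(group_latitudes) == 0) {
      r[i] <- NA_real_
    } else {
      r[i] <- cor(M[i, ], group_latitudes)
      defined[i] <- TRUE
    }
  }
  data.frame(block = rownames(M), r = r, defined = defined,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Representation of adaptive blocks in cultivar panels
#'
#' Compares, block by block, the frequencies observed in the source
#' germplasm groups with those in one or more cultivar panels sharing the
#' same block definitions. A block is flagged \code{underrepresented} in a
#' panel when it dominates the northern source groups (maximum frequency at
#' least \code{northern_cut}) yet falls below \code{min_freq} in the panel,
#' and \code{selected} when the panel frequency reaches \code{fixation_cut}
#' (near fixation).
#'
#' @param source_table \code{block_freq_table} of the source germplasm
#'   groups.
#' @param cultivar_table \code{block_freq_table} of the cultivar panel(s);
#'   must share row (block) names with \code{source_table}.
#' @param northern_groups Columns of \code{source_table} forming the
#'   northern reference (default the first three).
#' @param min_freq Underrepresentation cut in the cultivar panel
#'   (default 0.05).
#' @param northern_cut Northern dominance cut (default 0.5).
#' @param fixation_cut Near-fixation cut (default 0.9).
#' @return Data frame: block, northern_max, one frequency column per
#'   cultivar panel, and per-panel \code{<panel>_status}
#'   (\code{"underrepresented"}, \code{"selected"} or \code{"-"}).
#' @export
representation_report <- function(source_table, cultivar_table,
                                  northern_groups = 1:3,
                                  min_freq = 0.05, northern_cut = 0.5,
                                  fixation_cut = 0.9) {
  S <- unclass(source_table)
  Cv <- unclass(cultivar_table)
  if (ncol(Cv) == 0L || nrow(Cv) == 0L) stop2("empty cultivar panel")
  if (!identical(rownames(S), rownames(Cv)))
    stop2("block definitions differ between the two tables")
  keep <- rownames(S) != "other"
  S <- S[keep, , drop = FALSE]
  Cv <- Cv[keep, , drop = FALSE]
  northern_max <- apply(S[, northern_groups, drop = FALSE], 1L, max)
  out <- data.frame(block = rownames(S), northern_max = northern_max,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (p in colnames(Cv)) {
    out[[p]] <- Cv[, p]
    status <- rep("-", nrow(out))
    status[northern_max >= northern_cut & Cv[, p] < min_freq] <-
      "underrepresented"
    status[Cv[, p] >= fixation_cut] <- "selected"
    out[[paste0(p, "_status")]] <- status
  }
  out
}
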