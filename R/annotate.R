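#' Germplasm-group assignment rules
#'
#' Loads the editable rules table mapping ancestry groups (plus maturity
#' group and provincial origin) to growing regions and scan scenarios. The
#' shipped default encodes the standard allocation for the Chinese genebank
#' groups: the two northeastern groups are subdivided by maturity rating
#' (MG 000-0 / I / II-III onto regions 1-3, region 1 existing only in
#' scenario A), the Yellow-River group maps to region 4, and the southern
#' group splits by province into the middle-lower Yangtze (region 5) and
#' lower subtropical (region 6) regions.
#'
#' @param path Optional path to a rules CSV with columns \code{group},
#'   \code{mg_min}, \code{mg_max}, \code{provinces} (pipe-separated),
#'   \code{region}, \code{scenarios}.
#' @return Data frame of rules.
#' @export
germplasm_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "germplasm_rules.csv",
                        package = "adaptscape", mustWork = TRUE)
  rules <- read.csv(path, colClasses = "character")
  rules$region <- as.integer(rules$region)
  rules
}

# maturity-group rating to ordinal scale: 000 < 00 < 0 < I < ... < X
MG_LEVELS <- c("000", "00", "0", "I", "II", "III", "IV", "V", "VI", "VII",
               "VIII", "IX", "X")

mg_ord <- function(mg) {
  out <- match(toupper(trimws(mg)), MG_LEVELS)
  out[is.na(mg) | trimws(mg) == ""] <- NA_integer_
  out
}

#' Assign accessions to germplasm groups, regions and scenarios
#'
#' Applies the ancestry threshold and passport rules: an accession is
#' considered for assignment when its maximum ancestry coefficient reaches
#' \code{min_ancestry}; the matching rule row then fixes its growing region
#' and scenario membership. Unassigned accessions carry a reason code.
#'
#' @param Q Ancestry matrix (accessions x groups; rows sum to 1, column
#'   names are group labels matching the rules table).
#' @param passports Data frame keyed by \code{accession} with optional
#'   \code{mg} (maturity rating) and \code{province} columns.
#' @param rules Rules table (default [germplasm_rules()]).
#' @param min_ancestry Ancestry threshold (default 0.8).
#' @return Data frame of class \code{germplasm_assignment}: accession,
#'   group, region, scenario (\code{"A"}, \code{"B"}, \code{"AB"} or NA),
#'   reason (NA when assigned).
#' @export
#' @examples
#' Q <- matrix(c(0.85, 0.15), 1, dimnames = list("acc1", c("K10.7", "K10.5")))
#' assign_groups(Q, data.frame(accession = "acc1", mg = "I"))
assign_groups <- function(Q, passports, rules = germplasm_rules(),
                          min_ancestry = 0.8) {
  Q <- as.matrix(Q)
  if (is.null(colnames(Q))) stop2("'Q' needs group labels as column names")
  bad <- abs(rowSums(Q) - 1) > 1e-3
  if (any(bad))
    stop2("ancestry rows not summing to 1: ",
          paste(head(rownames(Q)[bad] %||% which(bad), 5), collapse = ", "))
  acc <- rownames(Q) %||% as.character(seq_len(nrow(Q)))
  pp <- passports[match(acc, passports$accession), , drop = FALSE]

  res <- data.frame(accession = acc, group = NA_character_,
                    region = NA_integer_, scenario = NA_character_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  top <- max.col(Q, ties.method = "first")
  top_val <- Q[cbind(seq_len(nrow(Q)), top)]
  top_grp <- colnames(Q)[top]

  for (i in seq_len(nrow(Q))) {
    if (top_val[i] < min_ancestry) {
      res$reason[i] <- "low ancestry"
      next
    }
    g <- top_grp[i]
    cand <- rules[rules$group == g, , drop = FALSE]
    if (nrow(cand) == 0L) {
      res$reason[i] <- "no matching rule"
      next
    }
    res$group[i] <- g
    needs_mg <- any(cand$mg_min != "")
    needs_prov <- any(cand$provinces != "")
    mg <- if ("mg" %in% names(pp)) pp$mg[i] else NA
    prov <- if ("province" %in% names(pp)) pp$province[i] else NA
    hit <- NULL
    for (r in seq_len(nrow(cand))) {
      rule <- cand[r, ]
      if (rule$mg_min != "") {
        o <- mg_ord(mg)
        if (is.na(o)) next
        if (o < mg_ord(rule$mg_min) || o > mg_ord(rule$mg_max)) next
      }
      if (rule$provinces != "") {
        if (is.na(prov)) next
        if (!trimws(prov) %in% strsplit(rule$provinces, "|",
                                        fixed = TRUE)[[1]]) next
      }
      hit <- rule
      break
    }
    if (is.null(hit)) {
      res$group[i] <- NA_character_
      res$reason[i] <-
        if (needs_mg && is.na(mg_ord(mg))) "missing MG"
        else if (needs_prov && (is.na(prov) ||
                 !any(vapply(strsplit(cand$provinces, "|", fixed = TRUE),
                             function(p) trimws(prov) %in% p, logical(1)))))
          "province not listed"
        else "no matching rule"
      next
    }
    res$region[i] <- hit$region
    res$scenario[i] <- hit$scenarios
  }
  class(res) <- c("germplasm_assignment", "data.frame")
  res
}

#' Read gene models from a GFF3 file
#'
#' @param path GFF3 file.
#' @param feature Feature type to keep (default \code{"gene"}).
#' @return Data frame: gene_id, chrom, start, end, strand (1-based
#'   inclusive).
#' @export
read_gff_genes <- function(path, feature = "gene") {
  gff <- ape::read.gff(path)
  gff <- gff[gff$type == feature, , drop = FALSE]
  id <- sub(".*?ID=([^;]+).*", "\\1", gff$attributes)
  noid <- !grepl("ID=", gff$attributes)
  id[noid] <- paste0(feature, "_", seq_len(sum(noid)))
  data.frame(gene_id = id, chrom = as.character(gff$seqid),
             start = gff$start, end = gff$end,
             strand = as.character(gff$strand),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genes intersecting adaptation signatures
#'
#' Reports every gene model whose 1-based inclusive interval shares at least
#' one bp with a signature region.
#'
#' @param signatures \code{signatures} data frame.
#' @param genes Gene table from [read_gff_genes()] (gene_id, chrom, start,
#'   end).
#' @param chrom_map Optional named vector normalizing gene chromosome names
#'   to the signature naming.
#' @return Named list (one element per region, \code{"chrom:start-end"}) of
#'   gene-id vectors. Genes on chromosomes absent from the signature set are
#'   skipped; unmappable chromosome names trigger a warning.
#' @export
genes_in_signatures <- function(signatures, genes, chrom_map = NULL) {
  region_names <- sprintf("%s:%d-%d", signatures$chrom, signatures$start,
                          signatures$end)
  if (nrow(signatures) == 0L || nrow(genes) == 0L)
    return(setNames(rep(list(character(0)), nrow(signatures)), region_names))
  gch <- genes$chrom
  if (!is.null(chrom_map)) {
    mapped <- chrom_map[gch]
    gch <- ifelse(is.na(mapped), gch, mapped)
  }
  known <- gch %in% unique(signatures$chrom)
  if (!any(known))
    warning("no gene chromosome matches the signature chromosomes; ",
            "check 'chrom_map'", call. = FALSE)
  g <- genes[known, , drop = FALSE]
  gch <- gch[known]
  gr_genes <- GenomicRanges::GRanges(gch, IRanges::IRanges(g$start, g$end))
  gr_sig <- sig_granges(signatures)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_sig, gr_genes, minoverlap = 1L))
  out <- setNames(rep(list(character(0)), nrow(signatures)), region_names)
  if (length(hits) > 0) {
    sp <- split(g$gene_id[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    for (k in names(sp)) out[[as.integer(k)]] <- unique(sp[[k]])
  }
  out
}

#' Hypergeometric GO-term enrichment
#'
#' One-sided hypergeometric (upper-tail) enrichment of a query gene set
#' against a gene universe, with Benjamini-Hochberg control across terms.
#'
#' @param query Character vector of query genes (must be a subset of the
#'   universe).
#' @param universe Character vector of universe genes.
#' @param term2gene Data frame with columns \code{term}, \code{gene} (long
#'   format), or a named list of gene vectors.
#' @param fdr FDR level declaring significance (default 0.05).
#' @return Data frame sorted by p: term, term_size, overlap, p, q,
#'   significant.
#' @export
go_enrichment <- function(query, universe, term2gene, fdr = 0.05) {
  query <- unique(query)
  universe <- unique(universe)
  missing <- setdiff(query, universe)
  if (length(missing) > 0)
    stop2("query gene(s) absent from universe: ",
          paste(head(missing, 5), collapse = ", "),
          if (length(missing) > 5) " ...")
  if (is.data.frame(term2gene)) {
    term2gene <- split(term2gene$gene, term2gene$term)
  }
  term2gene <- lapply(term2gene, function(g) intersect(unique(g), universe))
  sizes <- lengths(term2gene)
  term2gene <- term2gene[sizes > 0]
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(term2gene), function(tm) {
    m <- length(term2gene[[tm]])
    k <- length(intersect(query, term2gene[[tm]]))
    p <- phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(term = tm, term_size = m, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), term_size = integer(0),
                      overlap = integer(0), p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q <= fdr
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Monte-Carlo overlap test between gene sets
#'
#' Draws random query-sized gene subsets of the universe and measures their
#' overlap with a target set, giving the null expectation of the overlap and
#' a one-sided p-value for an observed overlap (add-one smoothing, so the
#' smallest attainable p is \code{1 / (n_sims + 1)}).
#'
#' @param n_query Size of the query set.
#' @param target_set Target gene ids (or a single integer: the target-set
#'   size).
#' @param universe_size Number of genes in the universe.
#' @param observed Observed overlap (optional; p-value is NA without it).
#' @param n_sims Number of simulations (default 10,000).
#' @param seed Seed.
#' @return List: expected (MC mean), analytic (hypergeometric mean
#'   \code{n_query * m / universe_size}), p_value, sims (the overlap draws).
#' @export
gene_overlap_mc <- function(n_query, target_set, universe_size,
                            observed = NULL, n_sims = 1e4, seed = NULL) {
  if (n_sims < 1L) stop2("'n_sims' must be >= 1")
  if (n_query > universe_size) stop2("query larger than the universe")
  m <- if (is.character(target_set)) length(unique(target_set))
       else as.integer(target_set)
  if (m > universe_size) stop2("target set larger than the universe")
  check_seed(seed)
  sims <- vapply(seq_len(n_sims), function(k)
    sum(sample.int(universe_size, n_query) <= m), numeric(1))
  p <- if (is.null(observed)) NA_real_
       else (1 + sum(sims >= observed)) / (n_sims + 1)
  list(expected = mean(sims), analytic = n_query * m / universe_size,
       p_value = p, sims = sims)
}

#' Extract high/moderate-impact variants within signatures
#'
#' Consumes an effect-annotated VCF (e.g. annotated by an external effect
#' predictor writing an \code{ANN}/\code{EFF} INFO field with impact classes
#' HIGH/MODERATE/LOW/MODIFIER), reports the panel-wide impact-class
#' proportions and lists HIGH/MODERATE variants inside each signature
#' region.
#'
#' @param vcf_path Path to the annotated VCF.
#' @param signatures \code{signatures} data frame.
#' @param field INFO field carrying the annotation (default \code{"ANN"}).
#' @return List: \code{variants} (data frame: chrom, pos, impact, region),
#'   \code{proportions} (impact-class fractions over all annotated
#'   variants).
#' @export
high_impact_variants <- function(vcf_path, signatures, field = "ANN") {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  ann <- vcfR::extract.info(vcf, element = field)
  if (all(is.na(ann)))
    stop2("no '", field, "' annotation in the VCF INFO field; run an ",
          "external variant-effect annotator first")
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  impact <- rep(NA_character_, length(ann))
  for (cls in c("HIGH", "MODERATE", "LOW", "MODIFIER"))
    impact[is.na(impact) & grepl(cls, ann)] <- cls
  keep <- !is.na(impact)
  props <- table(factor(impact[keep],
                        levels = c("HIGH", "MODERATE", "LOW", "MODIFIER")))
  props <- props / sum(props)

  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  sel <- impact[keep] %in% c("HIGH", "MODERATE")
  vars <- data.frame(chrom = chrom[sel], pos = pos[sel],
                     impact = impact[keep][sel], region = NA_character_,
                     stringsAsFactors = FALSE)
  if (nrow(vars) > 0 && nrow(signatures) > 0) {
    gr_v <- GenomicRanges::GRanges(vars$chrom,
                                   IRanges::IRanges(vars$pos, vars$pos))
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gr_v, sig_granges(signatures)))
    vars$region[S4Vectors::queryHits(hits)] <-
      sprintf("%s:%d-%d",
              signatures$chrom[S4Vectors::subjectHits(hits)],
              signatures$start[S4Vectors::subjectHits(hits)],
              signatures$end[S4Vectors::subjectHits(hits)])
  }
  list(variants = vars[!is.na(vars$region), , drop = FALSE],
       proportions = c(props))
}
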