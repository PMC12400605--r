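#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCF v4.2 with GT genotypes (unphased) for a dosage matrix.
#' Dosage 0/1/2 maps to \code{0/0}, \code{0/1}, \code{1/1}; missing dosages to
#' \code{./.}.
#'
#' @param geno A \code{geno_matrix} (or list with \code{dosage}, \code{snps},
#'   \code{ids}).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(geno, path) {
  dosage <- geno$dosage
  snps <- geno$snps
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(dosage), ncol(dosage))
  ok <- !is.na(dosage)
  gt[ok] <- gt_code[as.character(dosage[ok])]

  body <- cbind(snps$chrom, snps$pos, snps$id, snps$ref, snps$alt,
                ".", "PASS", ".", "GT", gt)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=adaptscape",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$ids), collapse = "\t"),
    apply(body, 1L, paste, collapse = "\t")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Load biallelic SNP dosages from a VCF file
#'
#' Reads a VCF with \pkg{vcfR}, keeps biallelic SNPs only (multi-allelic
#' records are skipped and counted), converts GT calls to alternate-allele
#' dosages and applies an optional pooled minor-allele-frequency floor.
#'
#' @param path VCF file (optionally gzipped).
#' @param maf_floor Pooled MAF floor; SNPs below it are dropped. Default 0
#'   (no filter).
#' @return A \code{geno_matrix}: list with \code{dosage} (J x N), \code{snps}
#'   (chrom, pos, ref, alt, id), \code{ids}, \code{pop} (NULL until assigned)
#'   and \code{log} (named counts of skipped/dropped records).
#' @export
load_vcf_dosages <- function(path, maf_floor = 0) {
  if (!file.exists(path)) stop2("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  bi <- !is.na(alt) & !grepl(",", alt) & nchar(alt) == 1L & nchar(ref) == 1L
  n_multi <- sum(!bi)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  gt <- gt[bi, , drop = FALSE]
  fix <- fix[bi, , drop = FALSE]

  # dosage lookup over the handful of observed GT strings
  vals <- unique(as.vector(gt))
  dose1 <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  }
  lut <- vapply(vals, dose1, integer(1))
  dosage <- matrix(lut[match(as.vector(gt), vals)], nrow(gt), ncol(gt))
  colnames(dosage) <- colnames(gt)

  snps <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     id = fix[, "ID"], stringsAsFactors = FALSE)
  no_id <- is.na(snps$id) | snps$id == "."
  snps$id[no_id] <- paste0(snps$chrom[no_id], "_", snps$pos[no_id])
  rownames(dosage) <- snps$id

  n_low <- 0L
  if (maf_floor > 0 && nrow(dosage) > 0) {
    f <- rowMeans(dosage, na.rm = TRUE) / 2
    maf <- pmin(f, 1 - f)
    keep <- !is.na(maf) & maf >= maf_floor
    n_low <- sum(!keep)
    dosage <- dosage[keep, , drop = FALSE]
    snps <- snps[keep, , drop = FALSE]
    rownames(snps) <- NULL
  }

  structure(list(dosage = dosage, snps = snps, ids = colnames(dosage),
                 pop = NULL,
                 log = c(skipped_multiallelic = n_multi,
                         dropped_low_maf = n_low)),
            class = "geno_matrix")
}

#' Write a simulated dataset to disk
#'
#' Emits the file bundle the pipeline consumes: a VCF of genotypes, a
#' population table, an environment/covariate table and the truth ledger of
#' the generator. Genotype content round-trips bit-identically through
#' [load_vcf_dosages()].
#'
#' @param geno A \code{geno_matrix} from [simulate_genotypes()].
#' @param freqs The generating \code{pop_freqs} (supplies truth ledger and
#'   covariate); optional.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(geno, freqs = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             pops = file.path(dir, "populations.csv"))
  write_vcf(geno, paths["vcf"])
  write.csv(data.frame(id = geno$ids, population = as.character(geno$pop)),
            paths["pops"], row.names = FALSE, quote = FALSE)
  if (!is.null(freqs)) {
    paths["env"] <- file.path(dir, "environment.csv")
    paths["truth"] <- file.path(dir, "truth.csv")
    write.csv(data.frame(population = rownames(freqs$freq),
                         covariate = freqs$config$covariate_values,
                         covariate_std = freqs$covariate),
              paths["env"], row.names = FALSE, quote = FALSE)
    write.csv(freqs$truth, paths["truth"], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}
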