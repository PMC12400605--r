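# Shared fixture builders (everything is generated in code).

# pop_counts from an explicit frequency matrix at fixed totals
make_counts <- function(freq, totals = 100, chrom = "Chr01") {
  freq <- as.matrix(freq)
  P <- nrow(freq); J <- ncol(freq)
  tot <- matrix(totals, P, J)
  snps <- data.frame(chrom = chrom, pos = seq_len(J) * 1000L,
                     ref = "A", alt = "T",
                     id = paste0(chrom, "_", seq_len(J) * 1000L),
                     stringsAsFactors = FALSE)
  structure(list(counts = freq * tot, totals = tot, snps = snps,
                 pops = paste0("pop", seq_len(P)),
                 log = c(input_snps = J, dropped_low_maf = 0L,
                         retained = J)),
            class = "pop_counts")
}

# geno_matrix from an explicit dosage matrix
make_geno <- function(dosage, chrom = NULL, pos = NULL, pop = NULL) {
  dosage <- as.matrix(dosage)
  J <- nrow(dosage)
  if (is.null(chrom)) chrom <- rep("Chr01", J)
  if (is.null(pos)) pos <- seq_len(J) * 1000L
  snps <- data.frame(chrom = chrom, pos = as.integer(pos), ref = "A",
                     alt = "T", id = paste0(chrom, "_", pos),
                     stringsAsFactors = FALSE)
  rownames(dosage) <- snps$id
  ids <- sprintf("i%03d", seq_len(ncol(dosage)))
  colnames(dosage) <- ids
  structure(list(dosage = dosage, snps = snps, ids = ids,
                 pop = if (is.null(pop)) NULL else as.factor(pop)),
            class = "geno_matrix")
}

# ld_matrix from an explicit r2 matrix
make_ldm <- function(r2, chrom, pos) {
  ids <- paste0(chrom, "_", pos)
  dimnames(r2) <- list(ids, ids)
  structure(list(r2 = r2,
                 snps = data.frame(chrom = chrom, pos = as.integer(pos),
                                   id = ids, stringsAsFactors = FALSE)),
            class = "ld_matrix")
}

# numerical-quadrature oracle for the association Bayes factor:
# BF = int prod N(y_i; beta x_i, 1) N(beta; 0, tau^2) dbeta / prod N(y_i; 0, 1)
bf_quadrature <- function(y, x, tau) {
  num <- integrate(function(b) {
    vapply(b, function(bb)
      exp(sum(dnorm(y, bb * x, 1, log = TRUE))) * dnorm(bb, 0, tau),
      numeric(1))
  }, -Inf, Inf, rel.tol = 1e-10)$value
  den <- exp(sum(dnorm(y, 0, 1, log = TRUE)))
  num / den
}

# deciban BF via the quadrature oracle for a pop_counts column
bf_db_oracle <- function(z, cstar, omega, tau) {
  L <- t(chol(omega))
  y <- forwardsolve(L, z)
  x <- forwardsolve(L, cstar)
  10 * log10(bf_quadrature(y, x, tau))
}

# default six-region scan covariates from the shipped environmental table
six_region_covariates <- function() {
  pca <- env_pca(china_region_env())
  scan_covariates(pca, k = 2L,
                  group_to_region = setNames(as.character(1:6),
                                             paste0("pop", 1:6)))
}

# tiny VCF writer for annotation fixtures
write_ann_vcf <- function(path, chrom, pos, ann) {
  lines <- c("##fileformat=VCFv4.2",
             '##INFO=<ID=ANN,Number=.,Type=String,Description="Effect">',
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s1"), collapse = "\t"),
             paste(chrom, pos, ".", "A", "T", ".", "PASS",
                   ifelse(is.na(ann), ".", paste0("ANN=T|", ann)),
                   "GT", "0/0", sep = "\t"))
  writeLines(lines, path)
  path
}
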