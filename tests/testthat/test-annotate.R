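test_that("group assignment follows the ancestry and passport rules", {
  Q <- rbind(a1 = c(0.85, 0.10, 0.05, 0),
             a2 = c(0.60, 0.30, 0.10, 0),
             a3 = c(0.02, 0.03, 0.05, 0.90),
             a4 = c(0.90, 0.05, 0.05, 0))
  colnames(Q) <- c("K10.7", "K10.5", "K10.8", "K10.6")
  pp <- data.frame(accession = c("a1", "a2", "a3", "a4"),
                   mg = c("I", "I", NA, NA),
                   province = c(NA, NA, "Fujian", NA))
  res <- assign_groups(Q, pp)
  expect_equal(res$region, c(2L, NA, 6L, NA))
  expect_equal(res$scenario, c("A", NA, "AB", NA))
  expect_equal(res$reason, c(NA, "low ancestry", NA, "missing MG"))
  expect_equal(res$group[3], "K10.6")
})

test_that("province and rule mismatches give reason codes", {
  Q <- rbind(x1 = c(0.9, 0.1), x2 = c(0.95, 0.05))
  colnames(Q) <- c("K10.6", "K10.5")
  pp <- data.frame(accession = c("x1", "x2"),
                   province = c("Yunnan", NA))
  res <- assign_groups(Q, pp)
  expect_equal(res$reason[1], "province not listed")

  # K10.8 with MG 000: region 1 exists only for K10.7
  Q2 <- matrix(c(1), 1, dimnames = list("y", "K10.8"))
  res2 <- assign_groups(Q2, data.frame(accession = "y", mg = "000"))
  expect_true(is.na(res2$region))

  bad <- matrix(c(0.5, 0.1), 1, dimnames = list("z", c("K10.7", "K10.8")))
  expect_error(assign_groups(bad, pp), "summing")
})

test_that("assignment is total: every accession assigned or reasoned", {
  set.seed(55)
  groups <- c("K10.5", "K10.6", "K10.7", "K10.8", "K10.2")
  n <- 200
  Q <- matrix(rexp(n * 5), n)
  Q <- Q / rowSums(Q)
  # sharpen a random half so some rows pass the ancestry threshold
  hot <- sample(n, n / 2)
  Q[hot, ] <- 0.05
  Q[cbind(hot, sample(5, length(hot), TRUE))] <- 0.8
  colnames(Q) <- groups
  rownames(Q) <- paste0("acc", seq_len(n))
  mg_pool <- c(NA, "000", "0", "I", "II", "III", "V", "VIII")
  prov_pool <- c(NA, "Fujian", "Anhui", "Yunnan", "Hubei")
  pp <- data.frame(accession = rownames(Q),
                   mg = sample(mg_pool, n, TRUE),
                   province = sample(prov_pool, n, TRUE))
  res <- assign_groups(Q, pp)
  expect_true(all(!is.na(res$region) | !is.na(res$reason)))
  expect_true(all(is.na(res$region) | res$region %in% 1:6))
  # assigned accessions carry exactly one region and a scenario
  ok <- !is.na(res$region)
  expect_true(all(res$scenario[ok] %in% c("A", "B", "AB")))
})

test_that("gene intersection uses the closed-interval convention", {
  sig <- structure(data.frame(chrom = "Chr01", start = 150L, end = 300L,
                              peak_pos = 200L, peak_value = 1,
                              n_snps_supporting = 1L, test = "XtX",
                              scenario = "A"),
                   class = c("signatures", "data.frame"))
  genes <- data.frame(gene_id = c("g.in", "g.out", "g.edge"),
                      chrom = "Chr01",
                      start = c(100L, 301L, 300L),
                      end = c(200L, 400L, 400L))
  hits <- genes_in_signatures(sig, genes)
  expect_equal(hits[["Chr01:150-300"]], c("g.in", "g.edge"))

  expect_equal(genes_in_signatures(sig, genes[0, ])[[1]], character(0))
  expect_warning(genes_in_signatures(
    sig, data.frame(gene_id = "g", chrom = "scaffold9",
                    start = 1L, end = 2L)), "chrom")
})

test_that("GFF3 gene models round-trip through the reader", {
  path <- file.path(withr::local_tempdir(), "genes.gff3")
  writeLines(c("##gff-version 3",
               paste("Chr01", "src", "gene", "100", "200", ".", "+", ".",
                     "ID=gene1;Name=G1", sep = "\t"),
               paste("Chr01", "src", "mRNA", "100", "200", ".", "+", ".",
                     "ID=t1;Parent=gene1", sep = "\t"),
               paste("Chr02", "src", "gene", "900", "1200", ".", "-", ".",
                     "ID=gene2", sep = "\t")), path)
  genes <- read_gff_genes(path)
  expect_equal(genes$gene_id, c("gene1", "gene2"))
  expect_equal(genes$start, c(100L, 900L))
  expect_equal(genes$strand, c("+", "-"))
})

test_that("enrichment equals the closed-form hypergeometric tail", {
  universe <- paste0("g", 1:100)
  term <- list(t1 = paste0("g", 1:10))
  res <- go_enrichment(paste0("g", 1:10), universe, term)
  expect_equal(res$p, 1 / choose(100, 10), tolerance = 1e-10)
  expect_true(res$significant)

  # query = universe: every term fully overlaps, p = 1
  res2 <- go_enrichment(universe, universe, term)
  expect_equal(res2$p, 1)
  expect_equal(res2$overlap, 10L)

  # zero overlap: upper tail includes >= 0, p = 1
  res3 <- go_enrichment(paste0("g", 51:60), universe,
                        list(t1 = paste0("g", 1:5)))
  expect_equal(res3$p, 1)

  expect_error(go_enrichment("nope", universe, term), "nope")
})

test_that("BH adjustment is monotone and order-invariant", {
  set.seed(77)
  universe <- paste0("g", 1:400)
  terms <- lapply(1:12, function(k) sample(universe, 25))
  names(terms) <- paste0("t", 1:12)
  query <- unique(c(terms[[1]][1:15], sample(universe, 40)))
  res <- go_enrichment(query, universe, terms)
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
  res_rev <- go_enrichment(query, universe, rev(terms))
  expect_equal(res[order(res$term), c("p", "q")],
               res_rev[order(res_rev$term), c("p", "q")],
               ignore_attr = TRUE)
})

test_that("Monte-Carlo gene overlap matches the hypergeometric mean", {
  mc <- gene_overlap_mc(292, 6314, 58000, observed = 61, n_sims = 4000,
                        seed = 4)
  expect_equal(mc$analytic, 292 * 6314 / 58000, tolerance = 1e-12)
  expect_lt(abs(mc$expected - mc$analytic), 0.5)
  expect_lt(mc$p_value, 1e-3)        # 61 observed vs ~31.8 expected

  # law of large numbers: error shrinks with more simulations
  e1 <- abs(gene_overlap_mc(50, 100, 1000, n_sims = 50,
                            seed = 8)$expected - 5)
  e2 <- abs(gene_overlap_mc(50, 100, 1000, n_sims = 5000,
                            seed = 8)$expected - 5)
  expect_lt(e2, max(e1, 0.2))

  # degenerate: target = universe
  mc2 <- gene_overlap_mc(20, 100, 100, observed = 20, n_sims = 200, seed = 9)
  expect_equal(mc2$expected, 20)
  expect_equal(mc2$p_value, 1)
  expect_error(gene_overlap_mc(10, 5, 8), "universe")
  expect_error(gene_overlap_mc(10, 5, 100, n_sims = 0), "n_sims")
})

test_that("impact extraction reports proportions and regional variants", {
  dir <- withr::local_tempdir()
  n <- 1000
  impacts <- c(rep("HIGH", 3), rep("MODERATE", 57), rep("LOW", 440),
               rep("MODIFIER", 500))
  pos <- seq_len(n) * 100L
  path <- write_ann_vcf(file.path(dir, "ann.vcf"), "Chr01", pos, impacts)
  sig <- structure(data.frame(chrom = "Chr01", start = 1L, end = 350L,
                              peak_pos = 100L, peak_value = 1,
                              n_snps_supporting = 1L, test = "XtX",
                              scenario = "A"),
                   class = c("signatures", "data.frame"))
  res <- high_impact_variants(path, sig)
  expect_equal(unname(res$proportions[c("HIGH", "MODERATE")]),
               c(0.003, 0.057))
  # region covers positions 100-300: impacts HIGH at 100, 200, 300
  expect_equal(nrow(res$variants), 3L)
  expect_true(all(res$variants$impact == "HIGH"))

  # region with no annotated variants
  sig2 <- sig; sig2$start <- 999000L; sig2$end <- 999900L
  expect_equal(nrow(high_impact_variants(path, sig2)$variants), 0L)

  bare <- write_ann_vcf(file.path(dir, "bare.vcf"), "Chr01", 1:3 * 100L,
                        rep(NA, 3))
  expect_error(high_impact_variants(bare, sig), "annotator")
})
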