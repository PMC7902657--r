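test_that("weighted Pearson reduces to plain Pearson under unit weights", {
  set.seed(20)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- weighted_pearson(x, y, rep(1, n))$r
    expect_equal(r, oracle_pearson(x, y), tolerance = 1e-12)
    expect_equal(r, cor(x, y), tolerance = 1e-12)
  }
})

test_that("weighted Pearson matches a direct-sum oracle and is symmetric", {
  x <- c(0, 1, 2, 3); y <- c(0, 1, 1, 3); w <- c(1, 2, 2, 1)
  res <- weighted_pearson(x, y, w)
  expect_equal(res$r, oracle_weighted_pearson(x, y, w), tolerance = 1e-12)
  expect_equal(res$n, 4L)
  expect_equal(res$r, weighted_pearson(y, x, w)$r, tolerance = 1e-15)
  set.seed(21)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n); w <- runif(n, 0.1, 5)
    expect_equal(weighted_pearson(x, y, w)$r,
                 oracle_weighted_pearson(x, y, w), tolerance = 1e-12)
  }
  # identity, degeneracy, exactness of p at |r| = 1
  expect_equal(weighted_pearson(1:5, 1:5, runif(5, 1, 2))$r, 1)
  expect_equal(weighted_pearson(1:5, 1:5, rep(1, 5))$p, 0)
  expect_true(is.na(weighted_pearson(rep(1, 5), 1:5, rep(1, 5))$r))
  expect_equal(weighted_pearson(1:2, 1:2, c(1, 1))$n, 2L)
  expect_true(is.na(weighted_pearson(1:2, 1:2, c(1, 1))$r))
})

test_that("the marker screen honors inclusive fold change and FDR", {
  set.seed(22)
  b <- matrix(2^rnorm(80, 3, 0.1), 10, 8)
  a <- b
  a[1, ] <- b[1, ] * 4                    # fold exactly 4, clearly shifted
  rownames(a) <- rownames(b) <- sprintf("g%d", 1:10)
  colnames(a) <- sprintf("a%d", 1:8); colnames(b) <- sprintf("b%d", 1:8)
  expr <- cbind(a, b)
  sel <- select_stage_genes(expr, colnames(a), colnames(b), fc_min = 4,
                            fdr_max = 0.05)
  expect_true("g1" %in% sel$gene_ids)     # >= is inclusive
  expect_false("g2" %in% sel$gene_ids)    # identical distributions
  expect_equal(sel$table$fold[1], 4, tolerance = 1e-12)
  expect_error(select_stage_genes(expr, colnames(a), colnames(a)[1:3]),
               "overlap")
  # power on simulated ZGA genes at printed cutoffs
  cfg <- sim_config(seed = 23, chrom_sizes = c(chr1 = 5e6, chr2 = 5e6),
                    n_embryos = c(zygote = 12, "2cell" = 6),
                    n_genes = 200, n_zga_genes = 60, n_icm_genes = 0,
                    n_te_genes = 0, zga_fold = 8)
  met <- simulate_methylomes(cfg)
  ex <- simulate_expression(cfg, met$truth)
  lin <- ex$truth$lineage
  sel2 <- select_stage_genes(ex$expr, lin$cell_id[lin$stage == "2cell"],
                             lin$cell_id[lin$stage == "zygote"],
                             fc_min = 4, fdr_max = 0.01)
  zga <- ex$truth$genes$gene_id[ex$truth$genes$class == "ZGA"]
  expect_gte(mean(zga %in% sel2$gene_ids), 0.9)
})

test_that("candidate filtering applies the printed coverage rules", {
  ndrs <- data.frame(chrom = "chr1",
                     start = c(1000L, 2000L, 901000L, 1101000L),
                     end = c(1300L, 2300L, 901300L, 1101300L),
                     name = c("nd_ok", "nd_sparse", "nd_99kb", "nd_101kb"),
                     stringsAsFactors = FALSE)
  gm <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                   tss = 1000000L, tes = 1000500L, stringsAsFactors = FALSE)
  cells <- sprintf("c%d", 1:10)
  lev <- matrix(runif(40), 4, 10, dimnames = list(ndrs$name, cells))
  ns <- matrix(5L, 4, 10, dimnames = list(ndrs$name, cells))
  ns["nd_sparse", 1:8] <- 2L              # < 3 sites in 8/10 cells -> 20% obs
  expr <- matrix(runif(20, 1, 10), 2, 10,
                 dimnames = list(c("g1", "g2"), cells))
  expr["g2", 5:10] <- 0                   # TPM > 0 in only 4 cells
  acc <- list(level = lev, n_sites = ns)
  cand <- filter_candidates(ndrs, c("g1", "g2"), gm, acc, expr,
                            window = 1e5)
  # nd_99kb is 99 kb upstream of the TSS: candidate; nd_101kb is not
  expect_true(all(c("nd_99kb", "nd_101kb") %in% ndrs$name))
  expect_setequal(cand$ndr_id, c("nd_99kb"))
  expect_setequal(cand$gene_id, "g1")
  # nonvariable NDR dropped
  lev2 <- lev; lev2["nd_99kb", ] <- 0.5
  cand2 <- filter_candidates(ndrs, c("g1", "g2"), gm,
                             list(level = lev2, n_sites = ns), expr)
  expect_false("nd_99kb" %in% cand2$ndr_id)
})

test_that("BH adjustment is monotone and order-invariant", {
  set.seed(24)
  cells <- sprintf("c%d", 1:12)
  n <- 40
  lev <- matrix(runif(n * 12), n, 12,
                dimnames = list(sprintf("nd%02d", 1:n), cells))
  ns <- matrix(4L, n, 12, dimnames = dimnames(lev))
  expr <- matrix(rlnorm(n * 12), n, 12,
                 dimnames = list(sprintf("g%02d", 1:n), cells))
  cand <- structure(data.frame(ndr_id = rownames(lev),
                               gene_id = rownames(expr),
                               stringsAsFactors = FALSE),
                    level = lev, weight = ns, expr_used = expr)
  links <- link_cre_genes(cand)
  expect_equal(links$fdr, p.adjust(links$p, "BH"))
  o <- order(links$p)
  expect_true(all(diff(links$fdr[o]) >= -1e-15))
  perm <- sample(n)
  cand_p <- structure(cand[perm, ], level = lev, weight = ns,
                      expr_used = expr)
  links_p <- link_cre_genes(cand_p)
  expect_equal(links_p$fdr[match(links$ndr_id, links_p$ndr_id)], links$fdr)
  # single candidate: BH reduces to the raw p
  cand1 <- structure(cand[1, , drop = FALSE], level = lev, weight = ns,
                     expr_used = expr)
  l1 <- link_cre_genes(cand1)
  expect_equal(l1$fdr, l1$p)
  expect_equal(links$sign, ifelse(links$r_w >= 0, "positive", "negative"))
})

test_that("overlap enrichment recovers analytic expectations", {
  set.seed(25)
  genome <- c(chr1 = 1e6, chr2 = 1e6)
  obs <- data.frame(chrom = rep(c("chr1", "chr2"), each = 25),
                    start = rep(seq(10000, 490000, length.out = 25), 2))
  obs$start <- as.integer(obs$start)
  obs$end <- obs$start + 500L
  # annotation = whole genome -> ratio 0
  whole <- data.frame(chrom = c("chr1", "chr2"), start = 0L, end = 1e6L)
  expect_equal(as.numeric(overlap_enrichment(obs, whole, genome,
                                             n_random = 20, seed = 1)), 0)
  # observed inside an annotation covering 10% of the genome
  ann10 <- data.frame(chrom = "chr1", start = 0L, end = 2e5L)
  obs10 <- data.frame(chrom = "chr1",
                      start = as.integer(seq(1000, 190000, length.out = 50)))
  obs10$end <- obs10$start + 500L
  enr <- overlap_enrichment(obs10, ann10, genome, n_random = 200, seed = 2)
  expect_lt(abs(as.numeric(enr) - log2(1 / 0.1)), 0.5)
  # disjoint-by-construction observed set -> strongly negative, smoothed
  far <- data.frame(chrom = "chr2", start = 0L, end = 1000000L)
  enr2 <- overlap_enrichment(obs10, far, genome, n_random = 50, seed = 3)
  expect_lt(as.numeric(enr2), -2)
  expect_error(overlap_enrichment(obs10, far[0, ], genome), "empty")
})

test_that("end-to-end linking recovers implanted links at controlled FDR", {
  oc <- cre_operating_characteristics(71, r_true = 0.7, n_pairs = 300,
                                      n_cells = 20)
  expect_gte(oc$sensitivity, 0.8)
  expect_lte(oc$empirical_fdr, 0.15)
  oc0 <- cre_operating_characteristics(72, r_true = 0, n_pairs = 300,
                                       n_cells = 20)
  expect_lte(oc0$sig_fraction, 0.2)
})
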