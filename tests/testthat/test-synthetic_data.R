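# The generator is first-class code: its statistical contracts (seed
# determinism, complementary inheritance, coupling calibration, implanted
# truth) are tested like any other module.

small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, chrom_sizes = c(chr1 = 5e5, chr2 = 5e5),
             wcg_density = 2, gch_density = 10, n_embryos = c("4cell" = 2),
             n_ndrs = 20, n_genes = 30, n_zga_genes = 5, n_icm_genes = 0,
             n_te_genes = 0, n_allelic_tiles = 10, n_allelic_null = 20, ...)
}

test_that("a fixed seed reproduces the full dataset byte-identically", {
  d1 <- simulate_dataset(small_cfg(7))
  d2 <- simulate_dataset(small_cfg(7))
  expect_identical(lapply(d1$wcg_calls, `[[`, "records"),
                   lapply(d2$wcg_calls, `[[`, "records"))
  expect_identical(lapply(d1$gch_calls, `[[`, "records"),
                   lapply(d2$gch_calls, `[[`, "records"))
  expect_identical(d1$expr, d2$expr)
  expect_identical(d1$bin_counts, d2$bin_counts)
  expect_identical(d1$truth$lineage, d2$truth$lineage)
  d3 <- simulate_dataset(small_cfg(8))
  expect_false(identical(d1$expr, d3$expr))
})

test_that("inheritance is complementary: sister levels sum to the mother", {
  # tight founder, no clipping in practice: (d1 + d2)/2 must track the
  # founder (tiny variance) while (d1 - d2)/2 carries the deviation
  cfg <- sim_config(seed = 2, chrom_sizes = c(chr1 = 2e6),
                    n_embryos = c("2cell" = 6),
                    maintenance_efficiency = 0.3, sigma_dev = 0.15,
                    founder_beta = c(500, 500), meth_bin_size = 1e4)
  met <- simulate_methylomes(cfg)
  lv <- met$truth$bin_levels
  lin <- met$truth$lineage
  for (emb in unique(lin$embryo_id)) {
    cells <- lin$cell_id[lin$embryo_id == emb]
    mid <- (lv[, cells[1]] + lv[, cells[2]]) / 2
    dev <- (lv[, cells[1]] - lv[, cells[2]]) / 2
    expect_lt(sd(mid), 0.03)     # founder sd ~ 0.016
    expect_gt(sd(dev), 3 * sd(mid))
  }
})

test_that("perfect maintenance gives identical sister expectations", {
  cfg <- sim_config(seed = 3, chrom_sizes = c(chr1 = 2e6),
                    n_embryos = c("2cell" = 4), maintenance_efficiency = 1,
                    meth_bin_size = 1e4)
  met <- simulate_methylomes(cfg)
  lv <- met$truth$bin_levels
  lin <- met$truth$lineage
  for (emb in unique(lin$embryo_id)) {
    cells <- lin$cell_id[lin$embryo_id == emb]
    expect_identical(lv[, cells[1]], lv[, cells[2]])
  }
})

test_that("sister anti-correlation and cross-embryo independence emerge", {
  res <- lineage_recovery(11, "4cell", n_embryos = 12)
  expect_lt(res$mean_sister_r, -0.3)
  # cells from different embryos: independent founders -> r near 0
  cfg <- sim_config(seed = 12, n_embryos = c("4cell" = 3),
                    maintenance_efficiency = c(1, 0.3))
  met <- simulate_methylomes(cfg)
  bins <- bin_genome(cfg$chrom_sizes, 1e4)
  bm <- bin_methylation_matrix(met$calls, bins)
  corr <- pairwise_correlation(bm, "pearson")
  lin <- met$truth$lineage
  inter <- outer(lin$embryo_id, lin$embryo_id, "!=") & upper.tri(corr$values)
  expect_lt(max(abs(corr$values[inter])), 0.2)
})

test_that("increasing maintenance efficiency increases sister correlation", {
  sweep <- maintenance_sweep(5, efficiencies = c(0.2, 0.5, 0.8),
                             n_embryos = 8)
  expect_true(all(diff(sweep) > 0))
})

test_that("ZGA and lineage marker structure is present in expression", {
  cfg <- sim_config(seed = 4, chrom_sizes = c(chr1 = 5e6, chr2 = 5e6),
                    n_embryos = c(zygote = 12, "2cell" = 6,
                                  blastocyst = 1),
                    n_genes = 100, n_zga_genes = 30, n_icm_genes = 10,
                    n_te_genes = 10, zga_fold = 8)
  met <- simulate_methylomes(cfg)
  ex <- simulate_expression(cfg, met$truth)
  lin <- ex$truth$lineage
  zyg <- lin$cell_id[lin$stage == "zygote"]
  two <- lin$cell_id[lin$stage == "2cell"]
  cls <- ex$truth$genes$class
  ratio <- rowMeans(ex$expr[, two]) / rowMeans(ex$expr[, zyg])
  # ZGA genes: empirical 2-cell / zygote mean-TPM ratio >= 4 at fold 8
  expect_gt(mean(ratio[cls == "ZGA"] >= 4), 0.9)
  # non-ZGA genes: ratio near 1 on the log scale
  expect_lt(abs(mean(log2(ratio[cls == "other"]))), 0.5)
  # TE markers are not elevated in ICM cells
  icm <- lin$cell_id[!is.na(lin$lineage_class) & lin$lineage_class == "ICM"]
  te <- lin$cell_id[!is.na(lin$lineage_class) & lin$lineage_class == "TE"]
  te_ratio <- rowMeans(ex$expr[cls == "TE", te, drop = FALSE]) /
    rowMeans(ex$expr[cls == "TE", icm, drop = FALSE])
  expect_gt(median(te_ratio), 1.5)
})

test_that("accessibility coupling hits the target correlation", {
  oc <- cre_operating_characteristics(21, r_true = 0.7, n_pairs = 150,
                                      n_cells = 20)
  expect_lt(abs(oc$mean_r_true_links - 0.7), 0.25)
  # r_true = 0: constant generating rate -> near-zero realized correlation
  oc0 <- cre_operating_characteristics(22, r_true = 0, n_pairs = 150,
                                       n_cells = 20)
  expect_lt(abs(oc0$mean_r_true_links), 0.2)
})

test_that("background GCH sites methylate at p_bg", {
  cfg <- small_cfg(9, linked_fraction = 0)
  met <- simulate_methylomes(cfg)
  acc <- simulate_accessibility(cfg, NULL, met$truth)
  pooled <- aggregate_gch(acc$calls)
  gr_n <- nomere:::gi_to_gr(acc$truth$implanted_ndrs)
  gr_s <- GenomicRanges::GRanges(pooled$chrom,
                                 IRanges::IRanges(pooled$pos, pooled$pos))
  outside <- !IRanges::overlapsAny(gr_s, gr_n)
  lev <- sum(pooled$n_meth[outside]) /
    sum(pooled$n_meth[outside] + pooled$n_unmeth[outside])
  expect_lt(abs(lev - cfg$p_bg), 0.01)
  inside <- !outside
  lev_in <- sum(pooled$n_meth[inside]) /
    sum(pooled$n_meth[inside] + pooled$n_unmeth[inside])
  expect_gt(lev_in, 0.6)
})

test_that("CNV blocks shift counts and expression; overlap is rejected", {
  blocks <- data.frame(chrom = "chr1", start = 0, end = 3e5,
                       copy_ratio = 1.5)
  cfg <- small_cfg(13, cnv_blocks = blocks, cnv_bin_size = 5e4)
  d <- simulate_dataset(cfg)
  in_block <- d$bins$chrom == "chr1" & d$bins$end <= 3e5
  neutral <- !in_block
  obs_ratio <- mean(d$bin_counts[in_block, ]) / mean(d$bin_counts[neutral, ])
  expect_lt(abs(obs_ratio - 1.5), 0.1)
  # expression of genes inside the block is scaled
  gm <- d$truth$gene_models
  gin <- gm$gene_id[gm$chrom == "chr1" & pmin(gm$tss, gm$tes) <= 3e5]
  if (length(gin)) {
    fold <- d$expr_cnv[gin, , drop = FALSE] / d$expr[gin, , drop = FALSE]
    expect_true(all(abs(fold - 1.5) < 1e-12))
  }
  bad <- rbind(blocks, data.frame(chrom = "chr1", start = 2e5, end = 4e5,
                                  copy_ratio = 0.5))
  cfgb <- small_cfg(13, cnv_blocks = bad, cnv_bin_size = 5e4)
  met <- simulate_methylomes(cfgb)
  expect_error(simulate_allelic_and_cnv(cfgb, met$truth), "overlapping")
})

test_that("truth manifest is attrition-free", {
  d <- simulate_dataset(small_cfg(17))
  tr <- d$truth
  # every simulated cell appears in the lineage, and vice versa
  expect_setequal(names(d$wcg_calls), tr$lineage$cell_id)
  expect_setequal(names(d$gch_calls), tr$lineage$cell_id)
  expect_setequal(colnames(d$expr), tr$lineage$cell_id)
  # every truth record references an existing entity
  expect_true(all(tr$true_links$ndr_id %in% tr$implanted_ndrs$name))
  expect_true(all(tr$true_links$gene_id %in% rownames(d$expr)))
  expect_true(all(tr$allelic_truth$tile_id %in%
                    sprintf("%s:%d-%d", tr$allelic_truth$chrom,
                            tr$allelic_truth$start, tr$allelic_truth$end)))
  # invalid configs are rejected
  expect_error(sim_config(p_bg = 1.2), "\\[0,1\\]")
  expect_error(sim_config(read_depth = 0), "depth")
  expect_error(sim_config(n_embryos = c(morula = 2)), "unknown stage")
})
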