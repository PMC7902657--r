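test_that("bin methylation matrix pools counts and applies the site floor", {
  bins <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                     end = c(1000L, 2000L), name = c("b1", "b2"))
  cs <- toy_calls("c1", "chr1", c(100, 200, 300, 1500, 1600), "WCG",
                  c(2, 1, 0, 1, 1), c(2, 1, 2, 0, 0))
  bm <- bin_methylation_matrix(list(cs), bins, min_sites = 3)
  expect_equal(bm["c1", "b1"], 3 / 8)       # (2,2)+(1,1)+(0,2) pooled
  expect_true(is.na(bm["c1", "b2"]))        # only 2 sites < 3
  cs2 <- toy_calls("c2", "chr1", 1500, "WCG", 1, 0)
  bm2 <- bin_methylation_matrix(list(cs, cs2), bins)
  expect_true(is.na(bm2["c2", "b1"]))       # no sites in bin
})

test_that("pairwise correlation handles identity, mirrors and nulls", {
  set.seed(3)
  m <- rep(0.5, 2000)
  delta <- abs(rnorm(2000, 0, 0.1))
  mat <- rbind(a = m + delta, b = m - delta,
               c = runif(2000), d = runif(2000))
  corr <- pairwise_correlation(mat, "pearson")
  expect_equal(unname(diag(corr$values)), rep(1, 4))
  expect_equal(corr$values["a", "b"], -1)            # complementary, m constant
  expect_lt(abs(corr$values["c", "d"]), 0.2)         # independent rows
  expect_equal(corr$values, t(corr$values))
  mat2 <- rbind(x = 1:20, y = 1:20)
  expect_equal(pairwise_correlation(mat2, min_shared = 5)$values["x", "y"], 1)
  # too few shared bins -> missing
  mat3 <- rbind(x = c(1:5, rep(NA, 15)), y = c(rep(NA, 15), 1:5))
  expect_warning(c3 <- pairwise_correlation(mat3, min_shared = 10), "shared")
  expect_true(is.na(c3$values["x", "y"]))
})

test_that("4-cell matching picks the most anti-correlated pairing", {
  ids <- c("A", "B", "C", "D")
  v <- matrix(0.3, 4, 4, dimnames = list(ids, ids))
  v["A", "B"] <- v["B", "A"] <- -0.8
  v["C", "D"] <- v["D", "C"] <- -0.7
  diag(v) <- 1
  corr <- structure(list(cell_ids = ids, values = v, method = "pearson"),
                    class = "CorrelationMatrix")
  tree <- reconstruct_lineage(corr, "4cell")
  expect_equal(tree$sister_pairs, list(c("A", "B"), c("C", "D")))
  expect_equal(tree$objective, -1.5)
  expect_false(tree$tie)
  # 2 cells: trivially one pair
  corr2 <- structure(list(cell_ids = c("A", "B"),
                          values = matrix(c(1, .2, .2, 1), 2,
                                          dimnames = list(c("A", "B"),
                                                          c("A", "B"))),
                          method = "pearson"), class = "CorrelationMatrix")
  expect_equal(reconstruct_lineage(corr2, "2cell")$sister_pairs,
               list(c("A", "B")))
  expect_error(reconstruct_lineage(corr2, "4cell"), "expects 4 cells")
})

test_that("matching is exhaustive-optimal against an independent enumerator", {
  set.seed(9)
  expect_equal(length(oracle_matchings(4)), 3L)
  expect_equal(length(oracle_matchings(8)), 105L)
  for (rep in 1:10) {
    v <- matrix(runif(64, -1, 1), 8); v <- (v + t(v)) / 2; diag(v) <- 1
    ids <- sprintf("c%d", 1:8)
    dimnames(v) <- list(ids, ids)
    corr <- structure(list(cell_ids = ids, values = v, method = "pearson"),
                      class = "CorrelationMatrix")
    tree <- reconstruct_lineage(corr, "8cell")
    expect_equal(tree$objective[["pairing"]],
                 oracle_best_matching(v, minimize = FALSE)$score,
                 tolerance = 1e-12)
  }
  for (rep in 1:10) {
    v <- matrix(runif(16, -1, 1), 4); v <- (v + t(v)) / 2; diag(v) <- 1
    ids <- LETTERS[1:4]; dimnames(v) <- list(ids, ids)
    corr <- structure(list(cell_ids = ids, values = v, method = "pearson"),
                      class = "CorrelationMatrix")
    tree <- reconstruct_lineage(corr, "4cell")
    expect_equal(unname(tree$objective),
                 oracle_best_matching(v, minimize = TRUE)$score,
                 tolerance = 1e-12)
  }
})

test_that("recovered partition is invariant to cell order", {
  res <- lineage_recovery(41, "8cell", n_embryos = 1, detail = TRUE)
  emb <- res$embryos[[1]]
  v <- emb$corr$values
  set.seed(1)
  perm <- sample(nrow(v))
  vp <- v[perm, perm]
  corr_p <- structure(list(cell_ids = rownames(vp), values = vp,
                           method = "pearson"), class = "CorrelationMatrix")
  t1 <- reconstruct_lineage(emb$corr, "8cell")
  t2 <- reconstruct_lineage(corr_p, "8cell")
  canon <- function(tr) sort(vapply(tr$sister_pairs, paste,
                                    character(1), collapse = "|"))
  expect_equal(canon(t1), canon(t2))
})

test_that("8-cell sign pattern drives grandmother grouping", {
  # sisters +0.9, same-grandmother cross-pairs -0.5, others +0.2
  ids <- sprintf("c%d", 1:8)
  v <- matrix(0.2, 8, 8, dimnames = list(ids, ids))
  sisters <- list(c(1, 2), c(3, 4), c(5, 6), c(7, 8))
  for (s in sisters) v[s[1], s[2]] <- v[s[2], s[1]] <- 0.9
  for (i in 1:2) for (j in 3:4) v[i, j] <- v[j, i] <- -0.5
  for (i in 5:6) for (j in 7:8) v[i, j] <- v[j, i] <- -0.5
  diag(v) <- 1
  corr <- structure(list(cell_ids = ids, values = v, method = "pearson"),
                    class = "CorrelationMatrix")
  tree <- reconstruct_lineage(corr, "8cell")
  expect_equal(tree$sister_pairs,
               list(c("c1", "c2"), c("c3", "c4"), c("c5", "c6"),
                    c("c7", "c8")))
  expect_equal(tree$grandmother_groups, list(c(1, 2), c(3, 4)))
})

test_that("heterogeneity classes separate founder-driven structure", {
  # near-perfect maintenance: embryo founder differences dominate, so
  # intra-embryonic correlations exceed inter-embryonic ones
  cfg <- sim_config(seed = 43, n_embryos = c("4cell" = 6),
                    maintenance_efficiency = c(1, 0.9), meth_bin_size = 1e4)
  met <- simulate_methylomes(cfg)
  bins <- bin_genome(cfg$chrom_sizes, 2e5)    # 200-kb bins
  bm <- bin_methylation_matrix(met$calls, bins)
  emb <- setNames(met$truth$lineage$embryo_id, met$truth$lineage$cell_id)
  het <- heterogeneity_correlations(bm, emb, lineage = met$truth$lineage,
                                    method = "spearman")
  cmp <- compare_heterogeneity(het, "intra_embryonic", "inter_embryonic")
  expect_gt(cmp$mean_a, cmp$mean_b)
  expect_lt(cmp$p, 0.05)
  expect_true(any(het$class == "same_mother"))
  # degenerate inputs: identical cells -> all r = 1, test skipped
  matx <- matrix(rep(1:50, 4), nrow = 4, byrow = TRUE,
                 dimnames = list(sprintf("z%d", 1:4), NULL))
  embx <- setNames(c("e1", "e1", "e2", "e2"), rownames(matx))
  hetx <- heterogeneity_correlations(matx, embx)
  expect_true(all(hetx$r == 1))
  expect_message(cx <- compare_heterogeneity(hetx, "intra_embryonic",
                                             "inter_embryonic"),
                 "skipped")
  expect_true(is.na(cx$p))
})
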