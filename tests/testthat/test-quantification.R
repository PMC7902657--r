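test_that("region levels are read-pooled ratios, not site means", {
  cs <- toy_calls("c1", "chr1", c(150, 180, 500), "WCG",
                  c(3, 0, 5), c(1, 4, 0))
  regions <- data.frame(chrom = "chr1", start = c(100L, 300L, 450L),
                        end = c(200L, 400L, 550L),
                        name = c("r1", "r2", "r3"))
  rl <- region_level(cs, regions, "WCG")
  expect_equal(rl$level, c(3 / 8, NA, 1))   # pooled 3/8, empty NA, 5/5
  expect_equal(rl$n_sites, c(2L, 0L, 1L))
})

test_that("pooled levels match a site-level oracle on random regions", {
  set.seed(5)
  n <- 3000
  pos <- sort(sample.int(1e6, n))
  nm <- rpois(n, 3); nu <- rpois(n, 3)
  keep <- nm + nu > 0
  cs <- toy_calls("c", "chr1", pos[keep], "GCH", nm[keep], nu[keep])
  st <- sort(sample.int(9e5, 200))
  regions <- data.frame(chrom = "chr1", start = st,
                        end = st + sample(500:5000, 200, replace = TRUE),
                        name = sprintf("r%d", 1:200))
  rl <- region_level(cs, regions, "GCH")
  rec <- as.data.frame(cs$records)
  for (i in sample.int(200, 50)) {
    inside <- rec$pos > regions$start[i] & rec$pos <= regions$end[i]
    expected <- if (!any(inside)) NA_real_ else
      sum(rec$n_meth[inside]) / sum(rec$n_meth[inside] + rec$n_unmeth[inside])
    expect_identical(rl$level[i], expected)
  }
})

test_that("TSS windows are strand-aware with the documented geometry", {
  # + strand, TSS 10000: Met window (9000,10500], Acc window (9800,10100]
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(10000L, 10000L),
                      tes = c(15000L, 5000L), stringsAsFactors = FALSE)
  mk <- function(pos, ctx) toy_calls("c", "chr1", pos, ctx,
                                     rep(1, length(pos)), rep(0, length(pos)))
  # sites at the window edges for the plus-strand gene
  cs <- toy_calls("c", "chr1",
                  c(9000, 9001, 10500, 10501, 9800, 9801, 10100, 10101),
                  c("WCG", "WCG", "WCG", "WCG", "GCH", "GCH", "GCH", "GCH"),
                  1, 0)
  tm <- tss_metrics(cs, genes[1, ])
  # inclusive: 9001..10500 for Met (2 sites in), 9801..10100 for Acc
  reg_m <- region_level(cs, data.frame(chrom = "chr1", start = 9000L,
                                       end = 10500L, name = "w"), "WCG")
  expect_equal(reg_m$n_sites, 2L)
  expect_equal(tm$tss_met, 1)
  expect_equal(tm$tss_acc, 1)
  # strand symmetry: mirrored sites give the minus gene the same metrics
  cs_m <- toy_calls("c", "chr1", 2 * 10000 - c(9001, 10500, 9801, 10100),
                    c("WCG", "WCG", "GCH", "GCH"), c(1, 0, 1, 0), c(0, 1, 0, 1))
  tmm <- tss_metrics(cs_m, genes[2, ])
  expect_equal(tmm$tss_met, 0.5)
  expect_equal(tmm$tss_acc, 0.5)
})

test_that("genic profile geometry gives 48 flank and 99 body windows", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                      tss = 50000L, tes = 60000L, stringsAsFactors = FALSE)
  cs <- toy_calls("c", "chr1", seq(45000, 65000, by = 40), "WCG", 1, 1)
  tr <- genic_profile(cs, genes, "WCG")
  expect_equal(sum(tr$windows$zone == "up"), 48L)
  expect_equal(sum(tr$windows$zone == "body"), 99L)
  expect_equal(sum(tr$windows$zone == "down"), 48L)
  # uniform 50% methylation -> flat profile at exactly 0.5
  expect_true(all(tr$level == 0.5, na.rm = TRUE))
  expect_true(all(!is.na(tr$level)))
  # genes shorter than 100 bp are skipped with a warning
  tiny <- data.frame(gene_id = "t", chrom = "chr1", strand = "+",
                     tss = 1000L, tes = 1050L)
  expect_warning(genic_profile(cs, rbind(genes, tiny), "WCG"), "skipped")
})

test_that("minus-strand profiles mirror plus-strand profiles", {
  # same physical signal, gene annotated on either strand: the 5'->3'
  # profile of the minus gene equals the reversed plus profile
  set.seed(8)
  pos <- seq(40000, 70000, by = 25)
  lv <- rbinom(length(pos), 1, seq(0.1, 0.9, length.out = length(pos)))
  cs <- toy_calls("c", "chr1", pos, "WCG", lv, 1 - lv)
  gp <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                   tss = 50000L, tes = 60001L, stringsAsFactors = FALSE)
  gm <- data.frame(gene_id = "g", chrom = "chr1", strand = "-",
                   tss = 60001L, tes = 50000L, stringsAsFactors = FALSE)
  tp <- genic_profile(cs, gp, "WCG")
  tm <- genic_profile(cs, gm, "WCG")
  up_p <- tp$level[1, tp$windows$zone == "up"]
  dn_m <- tm$level[1, tm$windows$zone == "down"]
  expect_equal(unname(up_p), unname(rev(dn_m)))
})

test_that("profile-expression correlation behaves on constructed cases", {
  genes <- data.frame(gene_id = sprintf("g%d", 1:5), chrom = "chr1",
                      strand = "+",
                      tss = seq(1e5, 5e5, by = 1e5),
                      tes = seq(1e5, 5e5, by = 1e5) + 10000L,
                      stringsAsFactors = FALSE)
  # per-gene constant levels 0.1..0.5 across all windows
  recs <- do.call(rbind, lapply(1:5, function(i) {
    pos <- seq(genes$tss[i] - 2500, genes$tes[i] + 2500, by = 30)
    data.frame(chrom = "chr1", pos = pos, strand = "+", context = "WCG",
               n_meth = i, n_unmeth = 10 - i)
  }))
  cs <- CytosineCallSet("c1", recs)
  tr <- genic_profile(cs, genes, "WCG")
  lvl <- tr$level[, 10]
  expect_equal(unname(lvl), (1:5) / 10)
  # expression exactly linear in the level -> r = 1
  expr <- matrix(2^((1:5)) - 1, 5, 1,
                 dimnames = list(genes$gene_id, "c1"))
  pc <- profile_expression_correlation(tr, expr, weighted = FALSE)
  expect_true(all(abs(pc$r - 1) < 1e-9, na.rm = TRUE))
  # anti-monotone linear -> r = -1
  expr2 <- matrix(2^(5:1) - 1, 5, 1, dimnames = list(genes$gene_id, "c1"))
  pc2 <- profile_expression_correlation(tr, expr2, weighted = FALSE)
  expect_true(all(abs(pc2$r + 1) < 1e-9, na.rm = TRUE))
  # constant levels across genes -> missing (zero variance)
  recs3 <- recs; recs3$n_meth <- 5; recs3$n_unmeth <- 5
  tr3 <- genic_profile(CytosineCallSet("c1", recs3), genes, "WCG")
  pc3 <- profile_expression_correlation(tr3, expr, weighted = FALSE)
  expect_true(all(is.na(pc3$r)))
})
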