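## Self-benchmarks: operating characteristics of each pipeline stage on
## synthetic data with known ground truth. These functions build the
## scenario with the generator, run the corresponding analysis stage, and
## score the result against the truth manifest; they back the package's
## acceptance checks and are useful for sensitivity analyses.

# fraction of intervals in `a` matched by an interval in `b` at >= `frac`
# reciprocal overlap
reciprocal_overlap_rate <- function(a, b, frac = 0.5) {
  if (!nrow(a)) return(NA_real_)
  if (!nrow(b)) return(0)
  gr_a <- gi_to_gr(a); gr_b <- gi_to_gr(b)
  hits <- GenomicRanges::findOverlaps(gr_a, gr_b)
  if (!length(hits)) return(0)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_a)[qi],
                                           IRanges::ranges(gr_b)[si]))
  good <- ov >= frac * IRanges::width(gr_a)[qi] &
    ov >= frac * IRanges::width(gr_b)[si]
  length(unique(qi[good])) / nrow(a)
}

#' NDR-caller operating characteristics
#'
#' Null mode: a uniform-rate GCH genome (no NDRs) is scanned and the number
#' of called NDRs reported. Implanted mode: open regions at `p_open` are
#' implanted and recall/precision against the truth intervals (50%
#' reciprocal overlap) reported.
#'
#' @param seed RNG seed.
#' @param implanted implant NDRs (TRUE) or run the null genome (FALSE).
#' @param n_cells cells pooled (default 20).
#' @param n_ndrs implanted regions (default 200).
#' @param chrom_sizes genome (default 2 x 10 Mb).
#' @param p_bg,p_open,gch_read_depth signal parameters.
#' @return list `n_calls`, `recall`, `precision`, `n_windows`.
#' @export
ndr_operating_characteristics <- function(seed, implanted = TRUE,
                                          n_cells = 20L, n_ndrs = 200L,
                                          chrom_sizes = c(chr1 = 1e7,
                                                          chr2 = 1e7),
                                          p_bg = 0.25, p_open = 0.75,
                                          gch_read_depth = 10) {
  cfg <- sim_config(seed = seed, chrom_sizes = chrom_sizes,
                    wcg_density = 0.01, gch_density = 40,
                    gch_read_depth = gch_read_depth,
                    n_embryos = c("4cell" = ceiling(n_cells / 4)),
                    n_ndrs = if (implanted) n_ndrs else 0L,
                    linked_fraction = 0, p_bg = p_bg, p_open = p_open)
  met <- simulate_methylomes(cfg)
  acc <- simulate_accessibility(cfg, NULL, met$truth)
  pooled <- aggregate_gch(acc$calls[seq_len(min(n_cells, length(acc$calls)))])
  stats <- scan_windows(pooled, cfg$chrom_sizes)
  ndrs <- merge_significant_windows(stats, pooled)
  truth_iv <- acc$truth$implanted_ndrs
  list(n_calls = nrow(ndrs),
       recall = if (implanted) reciprocal_overlap_rate(truth_iv, ndrs) else NA_real_,
       precision = if (implanted) reciprocal_overlap_rate(ndrs, truth_iv) else NA_real_,
       n_windows = nrow(stats))
}

#' Lineage-recovery accuracy on simulated embryos
#'
#' Simulates embryos at the requested stage, reconstructs sister pairs (and,
#' for 8-cell embryos, grandmother groups) from 1 cell x bin methylation
#' correlations, and scores the recovered topology against the generator's
#' lineage.
#'
#' @param seed RNG seed.
#' @param stage `"4cell"` or `"8cell"`.
#' @param n_embryos number of embryos (default 50).
#' @param maintenance per-cleavage maintenance efficiencies; defaults
#'   `c(1, 0.3)` for 4-cell and `c(1, 0.3, 0.9)` for 8-cell.
#' @param sigma_dev deviation scale (default 0.15).
#' @param read_depth per-site coverage (default 20).
#' @param detail also return per-embryo correlation matrices and trees.
#' @return list `accuracy` (fraction of embryos with fully correct
#'   topology), `mean_sister_r`, `mean_nonsister_r`, and with
#'   `detail = TRUE` a list `embryos` of per-embryo pieces.
#' @export
lineage_recovery <- function(seed, stage = c("4cell", "8cell"),
                             n_embryos = 50L, maintenance = NULL,
                             sigma_dev = 0.15, read_depth = 20,
                             detail = FALSE) {
  stage <- match.arg(stage)
  maintenance <- maintenance %||%
    if (stage == "4cell") c(1, 0.3) else c(1, 0.3, 0.9)
  cfg <- sim_config(seed = seed,
                    n_embryos = setNames(n_embryos, stage),
                    maintenance_efficiency = maintenance,
                    sigma_dev = sigma_dev, read_depth = read_depth,
                    wcg_density = 1, meth_bin_size = 1e4)
  met <- simulate_methylomes(cfg)
  bins <- bin_genome(cfg$chrom_sizes, cfg$meth_bin_size)
  lin <- met$truth$lineage
  ok <- logical(n_embryos)
  sr <- nr <- numeric(0)
  embryos <- list()
  for (ei in seq_along(unique(lin$embryo_id))) {
    emb <- unique(lin$embryo_id)[ei]
    cells <- lin[lin$embryo_id == emb, ]
    bm <- bin_methylation_matrix(met$calls[cells$cell_id], bins)
    corr <- pairwise_correlation(bm, "pearson")
    tree <- reconstruct_lineage(corr, stage)
    true_pairs <- lapply(split(cells$cell_id, cells$mother_id), sort)
    got_pairs <- lapply(tree$sister_pairs, sort)
    pairs_ok <- setequal(lapply(true_pairs, paste, collapse = "|"),
                         lapply(got_pairs, paste, collapse = "|"))
    groups_ok <- TRUE
    if (stage == "8cell") {
      # grandmother groups are pairs of sister-pair indices
      pair_gm <- vapply(tree$sister_pairs, function(p)
        cells$grandmother_id[match(p[1], cells$cell_id)], character(1))
      groups_ok <- all(vapply(tree$grandmother_groups, function(g)
        pair_gm[g[1]] == pair_gm[g[2]], logical(1)))
    }
    ok[ei] <- pairs_ok && groups_ok
    is_sister <- outer(cells$mother_id, cells$mother_id, "==")
    ut <- upper.tri(corr$values)
    sr <- c(sr, corr$values[ut & is_sister])
    nr <- c(nr, corr$values[ut & !is_sister])
    if (detail)
      embryos[[emb]] <- list(corr = corr, tree = tree, cells = cells)
  }
  out <- list(accuracy = mean(ok), mean_sister_r = mean(sr),
              mean_nonsister_r = mean(nr))
  if (detail) out$embryos <- embryos
  out
}

#' CRE-linking operating characteristics
#'
#' Simulates NDR-gene pairs on a sparse genome (genes far apart so each NDR
#' is near its own gene), runs the filtering + weighted-correlation linking,
#' and scores significant links against the truth manifest.
#'
#' @param seed RNG seed.
#' @param r_true target accessibility-expression correlation (0 = null).
#' @param n_pairs number of simulated NDR-gene pairs (default 2000).
#' @param n_cells number of cells (default 20).
#' @param fdr_cut significance cutoff (default 0.1).
#' @return list `sensitivity` (significant true links / true links),
#'   `empirical_fdr` (false significant / significant), `sig_fraction`
#'   (significant / tested), `n_tested`, `mean_r_true_links`.
#' @export
cre_operating_characteristics <- function(seed, r_true = 0.7,
                                          n_pairs = 2000L, n_cells = 20L,
                                          fdr_cut = 0.1) {
  genome_mb <- max(500, n_pairs * 0.25)   # keep pairs well separated
  cfg <- sim_config(seed = seed,
                    chrom_sizes = c(chr1 = genome_mb / 2 * 1e6,
                                    chr2 = genome_mb / 2 * 1e6),
                    wcg_density = 0.01, gch_density = 0.05,
                    n_embryos = c("4cell" = ceiling(n_cells / 4)),
                    n_genes = n_pairs, n_zga_genes = 0, n_icm_genes = 0,
                    n_te_genes = 0, n_ndrs = n_pairs, linked_fraction = 1,
                    link_strength = r_true)
  met <- simulate_methylomes(cfg)
  ex <- simulate_expression(cfg, met$truth)
  acc <- simulate_accessibility(cfg, ex$expr, ex$truth)
  truth <- acc$truth
  ndrs <- truth$implanted_ndrs
  rlm <- region_level_matrix(acc$calls, ndrs, "GCH")
  cand <- filter_candidates(ndrs, rownames(ex$expr), truth$gene_models,
                            rlm, ex$expr)
  links <- link_cre_genes(cand, fdr_cut = fdr_cut)
  tkey <- paste(truth$true_links$ndr_id, truth$true_links$gene_id)
  key <- paste(links$ndr_id, links$gene_id)
  sig <- links$significant
  list(sensitivity = mean(tkey %in% key[sig]),
       empirical_fdr = if (any(sig)) mean(!(key[sig] %in% tkey)) else 0,
       sig_fraction = mean(sig),
       n_tested = nrow(links),
       mean_r_true_links = mean(links$r_w[key %in% tkey], na.rm = TRUE))
}

# site-level GCH call construction over a pool of 101-bp candidate sites:
# `hot` pool indices methylate at p_hot, the rest at p_bg
build_tf_scenario <- function(seed, n_pool = 2500L, n_hot = 500L,
                              n_cells = 10L, sites_per = 3L,
                              p_hot = 0.8, p_bg = 0.3, depth = 10) {
  set.seed(seed)
  pool <- data.frame(chrom = "chr1",
                     start = seq(0L, by = 200L, length.out = n_pool),
                     end = seq(0L, by = 200L, length.out = n_pool) + 101L,
                     name = sprintf("site%05d", seq_len(n_pool)))
  hot <- seq_len(n_hot)
  site_pool <- rep(seq_len(n_pool), each = sites_per)
  pos <- pool$start[site_pool] + rep(seq_len(sites_per) * 25L, n_pool)
  rate <- ifelse(site_pool %in% hot, p_hot, p_bg)
  calls <- lapply(seq_len(n_cells), function(ci) {
    cov <- rpois(length(pos), depth)
    keep <- cov > 0
    nm <- rbinom(sum(keep), cov[keep], rate[keep])
    CytosineCallSet(sprintf("tfcell%02d", ci), data.table(
      chrom = "chr1", pos = pos[keep] + 1L, strand = "+", context = "GCH",
      n_meth = nm, n_unmeth = cov[keep] - nm))
  })
  list(pool = pool, hot = hot, calls = calls)
}

#' TF-activity null calibration and implanted-signal check
#'
#' Builds a pool of 101-bp candidate sites with an implanted accessible TF
#' (site rate `p_hot` vs pool background `p_bg`), plus null TFs drawn as
#' random pool subsets, and scores them with the permutation z-score.
#'
#' @param seed RNG seed.
#' @param n_null_tfs number of null TFs (default 20).
#' @param n_perm permutations (default 1000).
#' @param n_cells cells (default 10).
#' @return list `frac_null_within3` (fraction of null TF x cell scores with
#'   `|z| <= 3`), `min_implanted_z`, `n_null_scores`.
#' @export
tf_operating_characteristics <- function(seed, n_null_tfs = 20L,
                                         n_perm = 1000L, n_cells = 10L) {
  sc <- build_tf_scenario(seed, n_cells = n_cells)
  set.seed(seed + 1L)
  tfbs <- c(list(implanted = sc$pool[sc$hot, ]),
            lapply(seq_len(n_null_tfs), function(i)
              sc$pool[sample.int(nrow(sc$pool), length(sc$hot)), ]))
  names(tfbs) <- c("implanted", sprintf("null%02d", seq_len(n_null_tfs)))
  z <- tf_activity_zscore(sc$calls, tfbs, sc$pool, n_perm = n_perm,
                          seed = seed + 2L)
  znull <- z$z[z$tf_name != "implanted" & !is.na(z$z)]
  zimp <- z$z[z$tf_name == "implanted"]
  list(frac_null_within3 = mean(abs(znull) <= 3),
       min_implanted_z = min(zimp),
       n_null_scores = length(znull))
}

#' CNV detection rate on implanted blocks
#'
#' Implants a 15-bin 1.5x gain and a 15-bin 0.5x loss (1-Mb bins), corrects
#' binned counts, segments with the strict thresholds, and reports the
#' fraction of cells in which each block is recovered with boundaries
#' within `boundary_tol` bins. `diploid = TRUE` runs the same genome without
#' blocks and reports the number of (spurious) calls.
#'
#' @param seed RNG seed.
#' @param n_cells number of cells (default 50).
#' @param depth_per_bin mean reads per neutral bin (default 1000).
#' @param diploid run without CNV blocks.
#' @param boundary_tol allowed boundary error in bins (default 2).
#' @return list `detection_rate`, `n_calls`, `n_false`, `max_boundary_err`.
#' @export
cnv_operating_characteristics <- function(seed, n_cells = 50L,
                                          depth_per_bin = 1000,
                                          diploid = FALSE,
                                          boundary_tol = 2L) {
  blocks <- if (diploid) NULL else
    data.frame(chrom = c("chr1", "chr2"), start = c(10e6, 30e6),
               end = c(25e6, 45e6), copy_ratio = c(1.5, 0.5))
  n8 <- ceiling(n_cells / 8)
  cfg <- sim_config(seed = seed, chrom_sizes = c(chr1 = 1e8, chr2 = 1e8),
                    wcg_density = 0.01, gch_density = 0.05,
                    n_embryos = c("8cell" = n8),
                    n_genes = 10, n_zga_genes = 0, n_icm_genes = 0,
                    n_te_genes = 0,
                    cnv_blocks = blocks, cnv_depth_per_bin = depth_per_bin)
  met <- simulate_methylomes(cfg)
  ac <- simulate_allelic_and_cnv(cfg, met$truth)
  cells <- colnames(ac$bin_counts)[seq_len(min(n_cells, ncol(ac$bin_counts)))]
  ratios <- correct_bin_counts(ac$bin_counts[, cells, drop = FALSE],
                               gc = ac$gc, mappability = ac$mappability)
  segs <- segment_and_call(ratios, ac$bins)
  if (diploid)
    return(list(detection_rate = NA_real_, n_calls = nrow(segs),
                n_false = nrow(segs), max_boundary_err = NA_real_))
  bw <- cfg$cnv_bin_size
  hit <- matrix(FALSE, length(cells), nrow(blocks),
                dimnames = list(cells, NULL))
  berr <- 0
  false_calls <- 0L
  for (i in seq_len(nrow(segs))) {
    matched <- FALSE
    for (b in seq_len(nrow(blocks))) {
      e_start <- abs(segs$start[i] - blocks$start[b]) / bw
      e_end <- abs(segs$end[i] - blocks$end[b]) / bw
      type_ok <- (blocks$copy_ratio[b] > 1) == (segs$call[i] == "gain")
      if (segs$chrom[i] == blocks$chrom[b] && type_ok &&
          e_start <= boundary_tol && e_end <= boundary_tol) {
        hit[segs$cell_id[i], b] <- TRUE
        berr <- max(berr, e_start, e_end)
        matched <- TRUE
      }
    }
    if (!matched) false_calls <- false_calls + 1L
  }
  list(detection_rate = mean(hit), n_calls = nrow(segs),
       n_false = false_calls, max_boundary_err = berr)
}

#' Allelic-test power and null calibration
#'
#' Power mode: tiles with implanted (0.8 vs 0.2) imbalance; reports the
#' fraction detected at `fdr < 0.01`. Null mode: balanced tiles only;
#' reports the significant fraction.
#'
#' @param seed RNG seed.
#' @param n_imbalanced,n_null tile counts.
#' @param n_cells cells (default 20).
#' @return list `power`, `null_sig_fraction`, `n_tiles_tested`.
#' @export
allelic_operating_characteristics <- function(seed, n_imbalanced = 500L,
                                              n_null = 500L, n_cells = 20L) {
  cfg <- sim_config(seed = seed, wcg_density = 0.01, gch_density = 0.05,
                    n_embryos = c("4cell" = ceiling(n_cells / 4)),
                    n_genes = 10, n_zga_genes = 0, n_icm_genes = 0,
                    n_te_genes = 0,
                    n_allelic_tiles = n_imbalanced, n_allelic_null = n_null)
  met <- simulate_methylomes(cfg)
  ac <- simulate_allelic_and_cnv(cfg, met$truth)
  cnt <- allelic_tile_counts(ac$mat_calls, ac$pat_calls)
  tst <- allelic_difference_test(cnt)
  at <- ac$truth$allelic_truth
  key <- sprintf("%s:%d-%d", tst$chrom, tst$start, tst$end)
  imb <- at$tile_id[at$imbalanced]
  is_imb <- key %in% imb
  list(power = if (any(is_imb)) mean(tst$significant[is_imb]) else NA_real_,
       null_sig_fraction = if (any(!is_imb)) mean(tst$significant[!is_imb])
       else NA_real_,
       n_tiles_tested = nrow(tst))
}

#' Same-mother correlation across a maintenance-efficiency sweep
#'
#' Simulates 4-cell embryos at several final-cleavage maintenance
#' efficiencies and reports the mean sister (same-mother) bin-methylation
#' correlation for each: better maintenance means more similar daughters.
#'
#' @param seed RNG seed.
#' @param efficiencies sweep values (default 0.2, 0.5, 0.8).
#' @param n_embryos embryos per point (default 15).
#' @return named numeric vector of mean same-mother correlations.
#' @export
maintenance_sweep <- function(seed, efficiencies = c(0.2, 0.5, 0.8),
                              n_embryos = 15L) {
  out <- vapply(seq_along(efficiencies), function(i) {
    lineage_recovery(seed + i, "4cell", n_embryos = n_embryos,
                     maintenance = c(1, efficiencies[i]))$mean_sister_r
  }, numeric(1))
  names(out) <- sprintf("me_%g", efficiencies)
  out
}
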