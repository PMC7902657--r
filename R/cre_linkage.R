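## NDR-to-gene linking by coverage-weighted Pearson correlation.

#' Weighted Pearson correlation with a t-test
#'
#' `r_w = sum w (x - xbar_w)(y - ybar_w) / sqrt(sum w (x - xbar_w)^2 * sum
#' w (y - ybar_w)^2)` with weighted means; significance from a two-sided
#' Student's t-test with `t = r sqrt((n - 2)/(1 - r^2))`, `n` = number of
#' contributing observations (weights do not shrink the degrees of freedom).
#'
#' @param x,y numeric vectors; `w` positive weights. Incomplete triples are
#'   dropped.
#' @return list `r`, `p`, `n`; `r` is NA when either weighted variance is
#'   zero; `p` is 0 exactly when `|r| = 1`.
#' @export
weighted_pearson <- function(x, y, w) {
  ok <- complete.cases(x, y, w) & w > 0
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  n <- length(x)
  if (n < 3L) return(list(r = NA_real_, p = NA_real_, n = n))
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  syy <- sum(w * (y - yb)^2)
  if (sxx == 0 || syy == 0) return(list(r = NA_real_, p = NA_real_, n = n))
  r <- sum(w * (x - xb) * (y - yb)) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

#' Built-in stage-marker gene screen
#'
#' Wilcoxon rank-sum on `log2(TPM + 1)` between two cell groups with BH
#' adjustment, combined with a mean-TPM fold-change cutoff (group A over
#' group B, inclusive `>=`). A user-supplied gene list can be passed
#' downstream instead of this screen.
#'
#' @param expr expression matrix (genes x cells, TPM).
#' @param group_a,group_b disjoint cell-id vectors (>= 3 cells each).
#' @param fc_min minimum mean-TPM fold change A/B (default 4).
#' @param fdr_max BH FDR cutoff (default 0.01).
#' @return list of class `GeneSelection`: `gene_ids`, `table` (per-gene
#'   fold/p/fdr), `rule`, `params`.
#' @export
select_stage_genes <- function(expr, group_a, group_b, fc_min = 4,
                               fdr_max = 0.01) {
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("need >= 3 cells per group")
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  la <- log2(a + 1); lb <- log2(b + 1)
  p <- vapply(seq_len(nrow(expr)), function(i) {
    if (sd(c(la[i, ], lb[i, ])) == 0) return(1)
    suppressWarnings(wilcox.test(la[i, ], lb[i, ])$p.value)
  }, numeric(1))
  fold <- rowMeans(a) / pmax(rowMeans(b), .Machine$double.eps)
  fdr <- p.adjust(p, "BH")
  tab <- data.frame(gene_id = rownames(expr), fold = fold, p = p, fdr = fdr,
                    stringsAsFactors = FALSE)
  sel <- tab$fold >= fc_min & tab$fdr < fdr_max
  structure(list(gene_ids = tab$gene_id[sel], table = tab,
                 rule = "wilcoxon + fold change screen",
                 params = list(fc_min = fc_min, fdr_max = fdr_max)),
            class = "GeneSelection")
}

#' Candidate NDR-gene pairs with filtered observations
#'
#' Applies the coverage and variability filters, then forms all (NDR, gene)
#' pairs with the NDR inside `[TSS - window, TES + window]` (strand-aware:
#' the window extends upstream of the TSS and downstream of the TES).
#'
#' Filters: per-cell NDR observations with fewer than `min_sites_per_cell`
#' covered sites are set missing; NDRs observed in fewer than
#' `min_cell_frac` of cells are dropped; NDRs and genes with zero variance
#' across the remaining cells are dropped; genes expressed (TPM > 0) in
#' fewer than `min_expr_cells` cells are dropped.
#'
#' @param ndrs NDR data.frame (needs `chrom,start,end,name`).
#' @param genes character vector of candidate gene ids or a `GeneSelection`.
#' @param gene_models gene model data.frame covering those genes.
#' @param acc region-level matrices from [region_level_matrix()] on the NDRs
#'   (GCH for accessibility links, WCG for methylation links; the site
#'   counts double as correlation weights).
#' @param expr expression matrix (TPM).
#' @param cells optional cell subset (default: columns shared by `acc` and
#'   `expr`).
#' @param window linking distance in bp (default 1e5).
#' @param min_sites_per_cell,min_cell_frac,min_expr_cells filter parameters.
#' @return data.frame of candidate pairs (`ndr_id`, `gene_id`) with
#'   attributes `level`, `weight` (filtered matrices) and `expr_used`.
#' @export
filter_candidates <- function(ndrs, genes, gene_models, acc, expr,
                              cells = NULL, window = 1e5,
                              min_sites_per_cell = 3L, min_cell_frac = 0.25,
                              min_expr_cells = 5L) {
  if (inherits(genes, "GeneSelection")) genes <- genes$gene_ids
  cells <- cells %||% intersect(colnames(acc$level), colnames(expr))
  if (length(cells) < 3L) stop("need >= 3 shared cells")
  lev <- acc$level[, cells, drop = FALSE]
  wt <- acc$n_sites[, cells, drop = FALSE]
  lev[wt < min_sites_per_cell] <- NA_real_
  obs_frac <- rowMeans(!is.na(lev))
  nd_var <- apply(lev, 1, function(v) if (sum(!is.na(v)) >= 2) var(v, na.rm = TRUE) else 0)
  keep_ndr <- obs_frac >= min_cell_frac & nd_var > 0
  genes <- intersect(genes, rownames(expr))
  ex <- expr[genes, cells, drop = FALSE]
  keep_gene <- rowSums(ex > 0) >= min_expr_cells & apply(ex, 1, var) > 0
  genes <- genes[keep_gene]
  ndr_keep <- ndrs[ndrs$name %in% rownames(lev)[keep_ndr], , drop = FALSE]
  gm <- gene_models[gene_models$gene_id %in% genes, , drop = FALSE]
  if (!nrow(ndr_keep) || !nrow(gm))
    return(structure(data.frame(ndr_id = character(), gene_id = character()),
                     level = lev, weight = wt, expr_used = ex))
  g_lo <- pmin(gm$tss, gm$tes) - 1L   # 0-based span of the gene
  g_hi <- pmax(gm$tss, gm$tes)
  gr_g <- GenomicRanges::GRanges(gm$chrom,
            IRanges::IRanges(pmax(1L, g_lo - as.integer(window) + 1L),
                             g_hi + as.integer(window)))
  hits <- GenomicRanges::findOverlaps(gi_to_gr(ndr_keep), gr_g)
  cand <- data.frame(
    ndr_id = ndr_keep$name[S4Vectors::queryHits(hits)],
    gene_id = gm$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  structure(cand, level = lev, weight = wt, expr_used = ex)
}

#' Link NDRs to genes by weighted correlation
#'
#' Weighted Pearson (weights = covered sites in the NDR per cell) between
#' each candidate NDR's level and its gene's expression (TPM, untransformed)
#' across cells, two-sided t-test, BH adjustment across all tested pairs of
#' the run; links with `fdr < fdr_cut` are flagged significant and signed.
#'
#' @param candidates output of [filter_candidates()].
#' @param fdr_cut significance cutoff on BH FDR (default 0.1).
#' @param min_cells minimum contributing cells per pair (default 3).
#' @return data.frame `ndr_id, gene_id, r_w, n_cells, p, fdr, sign,
#'   significant`.
#' @export
link_cre_genes <- function(candidates, fdr_cut = 0.1, min_cells = 3L) {
  lev <- attr(candidates, "level")
  wt <- attr(candidates, "weight")
  ex <- attr(candidates, "expr_used")
  n <- nrow(candidates)
  r <- p <- rep(NA_real_, n); nc <- integer(n)
  for (i in seq_len(n)) {
    x <- lev[candidates$ndr_id[i], ]
    y <- ex[candidates$gene_id[i], ]
    w <- wt[candidates$ndr_id[i], ]
    res <- weighted_pearson(x, y, w)
    r[i] <- res$r; p[i] <- res$p; nc[i] <- res$n
  }
  out <- data.frame(ndr_id = candidates$ndr_id, gene_id = candidates$gene_id,
                    r_w = r, n_cells = nc, p = p,
                    fdr = p.adjust(p, "BH"), stringsAsFactors = FALSE)
  out$sign <- ifelse(is.na(out$r_w), NA_character_,
                     ifelse(out$r_w >= 0, "positive", "negative"))
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_cut & nc >= min_cells
  out
}

#' Overlap enrichment of linked regions vs random regions
#'
#' `log2(observed overlap count / mean random overlap count)` where random
#' regions are length-matched intervals placed uniformly on the genome
#' (excluding the blacklist), the same number as observed, averaged over
#' `n_random` draws. Zero mean random overlap triggers add-one smoothing of
#' both counts (flagged in the `smoothed` attribute).
#'
#' @param observed interval data.frame (e.g. significant CREs).
#' @param annotation interval data.frame (repeats, histone peaks, ...).
#' @param chrom_sizes named chromosome lengths.
#' @param n_random number of random draws (default 100).
#' @param blacklist optional intervals excluded from random placement.
#' @param seed optional RNG seed for the draws.
#' @return numeric log2 ratio with attributes `observed`, `expected`,
#'   `smoothed`.
#' @export
overlap_enrichment <- function(observed, annotation, chrom_sizes,
                               n_random = 100L, blacklist = NULL,
                               seed = NULL) {
  if (is.null(annotation) || !nrow(annotation)) stop("empty annotation")
  stopifnot(n_random >= 1L)
  if (!is.null(seed)) set.seed(seed)
  gr_a <- GenomicRanges::reduce(gi_to_gr(annotation))
  # observed/annotation may live on disjoint chromosomes; that is a valid
  # (zero-overlap) configuration, not a user error
  n_obs <- sum(suppressWarnings(
    IRanges::overlapsAny(gi_to_gr(observed), gr_a)))
  widths <- observed$end - observed$start
  chroms <- names(chrom_sizes)
  csum <- cumsum(as.numeric(chrom_sizes))
  total <- csum[length(csum)]
  gr_bl <- if (!is.null(blacklist) && nrow(blacklist)) gi_to_gr(blacklist) else NULL
  draw <- function() {
    repeat {
      u <- runif(length(widths)) * total
      ci <- findInterval(u, c(0, csum), rightmost.closed = TRUE)
      off <- u - c(0, csum)[ci]
      st <- pmin(floor(off), chrom_sizes[ci] - widths)
      st <- pmax(st, 0)
      gr <- GenomicRanges::GRanges(chroms[ci],
              IRanges::IRanges(st + 1, st + widths))
      if (is.null(gr_bl) || !any(IRanges::overlapsAny(gr, gr_bl))) return(gr)
    }
  }
  rand_counts <- vapply(seq_len(n_random), function(i)
    sum(suppressWarnings(IRanges::overlapsAny(draw(), gr_a))), numeric(1))
  expected <- mean(rand_counts)
  smoothed <- expected == 0 || n_obs == 0
  if (smoothed) { expected <- expected + 1; n_obs <- n_obs + 1 }
  structure(log2(n_obs / expected), observed = n_obs, expected = expected,
            smoothed = smoothed)
}
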