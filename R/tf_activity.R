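## Per-cell TF activity as a permutation-background z-score.
##
## Raw activity is the pooled GCH accessibility over a TF's binding sites in
## one cell; the background distribution comes from resampling site sets of
## equal size from a candidate-site pool (the 101-bp site universe derived
## from distal NDRs), evaluated in the same cell:
## z = (ACC_TF - mean(ACC_bg)) / sd(ACC_bg).

#' Mean TFBS accessibility per cell
#'
#' Pooled GCH ratio over all covered sites of a TF's binding-site set; cells
#' covering fewer than `min_sites` of the set are missing.
#'
#' @param calls [CytosineCallSet()] or list (GCH context used).
#' @param sites interval data.frame of binding sites (merged motif hits
#'   extended +/- 50 bp from the center).
#' @param min_sites minimum covered sites per cell (default 10).
#' @return data.frame `cell_id, acc_tf, n_sites`.
#' @export
mean_tfbs_accessibility <- function(calls, sites, min_sites = 10L) {
  if (!nrow(sites)) stop("empty site set")
  calls <- as_call_list(calls)
  out <- lapply(calls, function(cs) {
    rc <- region_counts(cs$records, sites, "GCH")
    covered <- rc$n_sites > 0L
    tot <- sum(rc$n_meth) + sum(rc$n_unmeth)
    n_cov <- sum(rc$n_sites)
    data.frame(cell_id = cs$cell_id,
               acc_tf = if (n_cov >= min_sites && tot >= 1)
                 sum(rc$n_meth) / tot else NA_real_,
               n_sites = n_cov, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Sample background site sets from a pool
#'
#' Each permutation draws `k` sites uniformly without replacement from the
#' pool. Seeded and reproducible: permutation `j` is the `j`-th consecutive
#' `sample.int(pool_n, k)` after `set.seed(seed)`.
#'
#' @param pool_n pool size (number of candidate sites).
#' @param k background set size (= observed TF set size).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return integer matrix `n_perm x k` of pool indices.
#' @export
sample_background <- function(pool_n, k, n_perm = 1000L, seed = 1L) {
  if (pool_n < k) stop("pool smaller than requested set size")
  set.seed(seed)
  idx <- matrix(0L, n_perm, k)
  for (j in seq_len(n_perm)) idx[j, ] <- sample.int(pool_n, k)
  idx
}

#' TF activity z-scores
#'
#' For each TF and cell: observed pooled accessibility over the TF's sites,
#' background mean/sd from `n_perm` resampled site sets of equal size
#' (drawn once per TF from the pool, evaluated per cell on that cell's
#' covered sites), and `z = (acc_tf - bg_mean) / bg_sd` with the sample
#' (n-1) sd. Missing when the cell covers too few sites or `bg_sd = 0`.
#'
#' @param calls list of GCH [CytosineCallSet()].
#' @param tfbs_list named list of site interval data.frames, one per TF.
#' @param pool interval data.frame: the candidate site universe (e.g. 101-bp
#'   tiles over distal NDRs).
#' @param n_perm permutations per TF (default 1000).
#' @param seed base RNG seed; TF `i` uses `seed + i - 1`.
#' @param min_sites minimum covered sites per cell (default 10).
#' @return data.frame `tf_name, cell_id, acc_tf, bg_mean, bg_sd, z`.
#' @export
tf_activity_zscore <- function(calls, tfbs_list, pool, n_perm = 1000L,
                               seed = 1L, min_sites = 10L) {
  calls <- as_call_list(calls)
  if (is.null(names(tfbs_list)) || any(!nzchar(names(tfbs_list))))
    stop("tfbs_list must be named by TF")
  pool_n <- nrow(pool)
  # per-cell pooled counts per pool site
  pool_c <- pool_t <- matrix(0, pool_n, length(calls),
                             dimnames = list(NULL, names(calls)))
  for (ci in seq_along(calls)) {
    rc <- region_counts(calls[[ci]]$records, pool, "GCH")
    pool_c[, ci] <- rc$n_meth
    pool_t[, ci] <- rc$n_unmeth
  }
  out <- list()
  for (ti in seq_along(tfbs_list)) {
    tf <- names(tfbs_list)[ti]
    sites <- tfbs_list[[ti]]
    obs <- mean_tfbs_accessibility(calls, sites, min_sites = min_sites)
    k <- nrow(sites)
    idx <- sample_background(pool_n, k, n_perm = n_perm,
                             seed = as.integer(seed) + ti - 1L)
    for (ci in seq_along(calls)) {
      bc <- matrix(pool_c[, ci][idx], nrow = n_perm)
      bt <- matrix(pool_t[, ci][idx], nrow = n_perm)
      sc <- rowSums(bc); st <- rowSums(bt)
      bg <- ifelse(sc + st >= 1, sc / (sc + st), NA_real_)
      bg_mean <- mean(bg, na.rm = TRUE)
      bg_sd <- sd(bg, na.rm = TRUE)
      acc <- obs$acc_tf[ci]
      z <- if (!is.na(acc) && !is.na(bg_sd) && bg_sd > 0)
        (acc - bg_mean) / bg_sd else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        tf_name = tf, cell_id = obs$cell_id[ci], acc_tf = acc,
        bg_mean = bg_mean, bg_sd = bg_sd, z = z, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Two-group differential TF activity
#'
#' Convenience wrapper: Wilcoxon rank-sum on z-scores between two cell
#' groups per TF, BH-adjusted across TFs.
#'
#' @param scores output of [tf_activity_zscore()].
#' @param group_a,group_b cell-id vectors.
#' @param fdr_cut significance cutoff (default 0.1).
#' @return data.frame `tf_name, delta_z, p, fdr, significant`.
#' @export
tf_differential_activity <- function(scores, group_a, group_b,
                                     fdr_cut = 0.1) {
  tfs <- unique(scores$tf_name)
  rows <- lapply(tfs, function(tf) {
    za <- scores$z[scores$tf_name == tf & scores$cell_id %in% group_a]
    zb <- scores$z[scores$tf_name == tf & scores$cell_id %in% group_b]
    za <- za[!is.na(za)]; zb <- zb[!is.na(zb)]
    p <- if (length(za) >= 3 && length(zb) >= 3)
      suppressWarnings(wilcox.test(za, zb)$p.value) else NA_real_
    data.frame(tf_name = tf, delta_z = mean(za) - mean(zb), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, "BH")
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_cut
  out
}
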