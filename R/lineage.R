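## Blastomere lineage reconstruction from bin-methylation correlations.
##
## Maintenance failure partitions methylation complementarily between
## daughter cells, so the most recent cleavage leaves the strongest
## (anti-)correlation signature: at the 4-cell stage sisters are the most
## negatively correlated pair, while at the 8-cell stage sisters (separated
## only by the well-maintained third cleavage) correlate positively and
## cells of the same grandmother but different mothers correlate negatively.

#' Cell x bin methylation matrix
#'
#' Pooled WCG level per bin per cell; bins covering fewer than `min_sites`
#' sites in a cell are missing for that cell.
#'
#' @param calls list of WCG [CytosineCallSet()].
#' @param bins interval data.frame (e.g. [bin_genome()] at 1 Mb).
#' @param min_sites minimum covered sites per bin (default 3).
#' @return numeric matrix cells x bins.
#' @export
bin_methylation_matrix <- function(calls, bins, min_sites = 3L) {
  rl <- region_level_matrix(calls, bins, "WCG")
  lev <- rl$level
  lev[rl$n_sites < min_sites] <- NA_real_
  t(lev)
}

#' Pairwise-complete correlation between cells
#'
#' @param mat cells x features matrix (rows = cells).
#' @param method `"pearson"` or `"spearman"`.
#' @param min_shared pairs sharing fewer complete features are set missing
#'   (default 10).
#' @return list of class `CorrelationMatrix`: `cell_ids`, `method`, `values`
#'   (symmetric, unit diagonal), `n_shared` (complete observations per pair).
#' @export
pairwise_correlation <- function(mat, method = c("pearson", "spearman"),
                                 min_shared = 10L) {
  method <- match.arg(method)
  if (nrow(mat) < 2L) stop("need >= 2 cells")
  v <- suppressWarnings(cor(t(mat), use = "pairwise.complete.obs",
                            method = method))
  ok <- !is.na(mat)
  n_shared <- tcrossprod(ok * 1)
  if (anyNA(v[upper.tri(v)]))
    warning("cell pair(s) with no shared observations: entry missing")
  v[n_shared < min_shared] <- NA_real_
  diag(v) <- 1
  structure(list(cell_ids = rownames(mat), method = method, values = v,
                 n_shared = n_shared), class = "CorrelationMatrix")
}

# all perfect matchings of indices 1..n (n even): list of n/2 x 2 matrices
enumerate_matchings <- function(idx) {
  n <- length(idx)
  if (n == 0L) return(list(matrix(integer(), 0, 2)))
  first <- idx[1]
  out <- list()
  for (j in 2:n) {
    rest <- idx[-c(1, j)]
    for (m in enumerate_matchings(rest))
      out[[length(out) + 1L]] <- rbind(c(first, idx[j]), m)
  }
  out
}

matching_score <- function(m, cm) sum(cm[m])

#' Reconstruct sister pairs and grandmother groups in one embryo
#'
#' 4-cell (and late 4-cell) embryos: all 3 perfect matchings of the 4 cells
#' are enumerated and the matching minimizing the sum of within-pair
#' correlations is returned as the sister pairs (daughters of the same
#' 2-cell blastomere are the most anti-correlated). 8-cell embryos: all 105
#' matchings are enumerated and the matching maximizing the within-pair sum
#' gives the 4 sister pairs; pair-level correlation (mean of the 4
#' inter-cell correlations) is then minimized over the 3 pairings of the 4
#' pairs to give the grandmother groups. The search is exhaustive; ties are
#' broken deterministically by lexicographic cell-id order and flagged.
#'
#' @param corr [pairwise_correlation()] output for the embryo's cells.
#' @param stage `"4cell"`, `"late4cell"` or `"8cell"` (a 2-cell embryo is
#'   handled trivially).
#' @return list of class `LineageTree`: `stage`, `sister_pairs` (list of
#'   cell-id pairs), `grandmother_groups` (list of pair-index pairs, 8-cell
#'   only), `objective`, `tie` flags, `method = "methylation"`.
#' @export
reconstruct_lineage <- function(corr, stage = c("4cell", "late4cell",
                                                "8cell", "2cell")) {
  stage <- match.arg(stage)
  cm <- corr$values
  ids <- corr$cell_ids
  ord <- order(ids)          # lexicographic tie-break basis
  cm <- cm[ord, ord]; ids <- ids[ord]
  n <- length(ids)
  expect <- c("2cell" = 2L, "4cell" = 4L, "late4cell" = 4L, "8cell" = 8L)[[stage]]
  if (n != expect) stop("stage ", stage, " expects ", expect, " cells, got ", n)
  if (anyNA(cm)) stop("correlation matrix has missing entries")
  if (n == 2L)
    return(structure(list(stage = stage, sister_pairs = list(ids),
                          grandmother_groups = NULL, objective = cm[1, 2],
                          tie = FALSE, method = "methylation"),
                     class = "LineageTree"))
  matchings <- enumerate_matchings(seq_len(n))
  scores <- vapply(matchings, matching_score, numeric(1), cm = cm)
  best <- if (n == 4L) which(scores == min(scores)) else
    which(scores == max(scores))
  tie_pairs <- length(best) > 1L
  m <- matchings[[best[1]]]
  pairs <- lapply(seq_len(nrow(m)), function(i) ids[sort(m[i, ])])
  pairs <- pairs[order(vapply(pairs, `[`, character(1), 1))]
  groups <- NULL; tie_groups <- FALSE; obj <- scores[best[1]]
  if (n == 8L) {
    # pair-level correlation = mean of the 4 inter-cell correlations
    pc <- matrix(NA_real_, 4, 4)
    midx <- lapply(pairs, function(p) match(p, ids))
    for (i in 1:3) for (j in (i + 1):4)
      pc[i, j] <- pc[j, i] <- mean(cm[midx[[i]], midx[[j]]])
    gm <- enumerate_matchings(1:4)
    gs <- vapply(gm, matching_score, numeric(1), cm = pc)
    gbest <- which(gs == min(gs))
    tie_groups <- length(gbest) > 1L
    g <- gm[[gbest[1]]]
    groups <- lapply(seq_len(nrow(g)), function(i) sort(g[i, ]))
    groups <- groups[order(vapply(groups, `[`, numeric(1), 1))]
    obj <- c(pairing = scores[best[1]], grouping = gs[gbest[1]])
  }
  structure(list(stage = stage, sister_pairs = pairs,
                 grandmother_groups = groups, objective = obj,
                 tie = tie_pairs || tie_groups, method = "methylation"),
            class = "LineageTree")
}

#' @export
print.LineageTree <- function(x, ...) {
  cat(sprintf("<LineageTree> %s: %d sister pair(s)", x$stage,
              length(x$sister_pairs)))
  if (!is.null(x$grandmother_groups))
    cat(sprintf(", %d grandmother group(s)", length(x$grandmother_groups)))
  cat(if (x$tie) " [tie]\n" else "\n")
  invisible(x)
}

#' Transcriptome-based lineage variant
#'
#' Reuses the matching machinery with Spearman correlation on
#' `log2(TPM + 1)` and maximization at both levels (sisters and
#' same-grandmother cells are the most similar in expression).
#'
#' @param expr expression matrix (genes x cells) restricted to one embryo.
#' @param stage as in [reconstruct_lineage()].
#' @return `LineageTree` with `method = "transcriptome"`.
#' @export
reconstruct_lineage_expression <- function(expr, stage = c("4cell",
                                                           "late4cell",
                                                           "8cell", "2cell")) {
  stage <- match.arg(stage)
  mat <- t(log2(expr + 1))
  corr <- pairwise_correlation(mat, method = "spearman", min_shared = 3L)
  cm <- corr$values
  ids <- corr$cell_ids
  ord <- order(ids); cm <- cm[ord, ord]; ids <- ids[ord]
  n <- length(ids)
  if (n == 2L)
    return(structure(list(stage = stage, sister_pairs = list(ids),
                          grandmother_groups = NULL, objective = cm[1, 2],
                          tie = FALSE, method = "transcriptome"),
                     class = "LineageTree"))
  matchings <- enumerate_matchings(seq_len(n))
  scores <- vapply(matchings, matching_score, numeric(1), cm = cm)
  best <- which(scores == max(scores))
  m <- matchings[[best[1]]]
  pairs <- lapply(seq_len(nrow(m)), function(i) ids[sort(m[i, ])])
  pairs <- pairs[order(vapply(pairs, `[`, character(1), 1))]
  groups <- NULL; obj <- scores[best[1]]; tie_g <- FALSE
  if (n == 8L) {
    pc <- matrix(NA_real_, 4, 4)
    midx <- lapply(pairs, function(p) match(p, ids))
    for (i in 1:3) for (j in (i + 1):4)
      pc[i, j] <- pc[j, i] <- mean(cm[midx[[i]], midx[[j]]])
    gm <- enumerate_matchings(1:4)
    gs <- vapply(gm, matching_score, numeric(1), cm = pc)
    gbest <- which(gs == max(gs))
    tie_g <- length(gbest) > 1L
    g <- gm[[gbest[1]]]
    groups <- lapply(seq_len(nrow(g)), function(i) sort(g[i, ]))
    obj <- c(pairing = obj, grouping = gs[gbest[1]])
  }
  structure(list(stage = stage, sister_pairs = pairs,
                 grandmother_groups = groups, objective = obj,
                 tie = length(best) > 1L || tie_g, method = "transcriptome"),
            class = "LineageTree")
}

#' Intra/inter-embryo and kinship correlation distributions
#'
#' Assigns every unordered cell pair to relationship classes
#' (`intra_embryonic`, `inter_embryonic`, `same_mother`,
#' `same_grandmother` = same grandmother but different mothers) and reports
#' the pairwise correlation per pair and class.
#'
#' @param mat cells x features matrix (expression, binned methylation or NDR
#'   accessibility).
#' @param embryo_of named vector mapping cell id to embryo id.
#' @param lineage optional data.frame with `cell_id`, `mother_id`,
#'   `grandmother_id` enabling the kinship classes.
#' @param method correlation method (default `"spearman"`).
#' @param min_shared minimum shared features per pair.
#' @return data.frame `cell_a, cell_b, class, r` (one row per pair per
#'   class).
#' @export
heterogeneity_correlations <- function(mat, embryo_of, lineage = NULL,
                                       method = "spearman",
                                       min_shared = 10L) {
  corr <- pairwise_correlation(mat, method = method, min_shared = min_shared)
  ids <- corr$cell_ids
  if (any(!ids %in% names(embryo_of))) stop("embryo_of must cover all cells")
  mo <- gm <- NULL
  if (!is.null(lineage)) {
    mo <- setNames(lineage$mother_id, lineage$cell_id)
    gm <- setNames(lineage$grandmother_id, lineage$cell_id)
  }
  rows <- list()
  for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
    a <- ids[i]; b <- ids[j]; r <- corr$values[i, j]
    cls <- if (embryo_of[[a]] == embryo_of[[b]]) "intra_embryonic" else
      "inter_embryonic"
    if (!is.null(mo) && cls == "intra_embryonic") {
      if (!is.na(mo[[a]]) && identical(mo[[a]], mo[[b]]))
        cls <- c(cls, "same_mother")
      else if (!is.na(gm[[a]]) && identical(gm[[a]], gm[[b]]))
        cls <- c(cls, "same_grandmother")
    }
    rows[[length(rows) + 1L]] <- data.frame(cell_a = a, cell_b = b,
                                            class = cls, r = r,
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Welch t-test between correlation classes
#'
#' @param het output of [heterogeneity_correlations()].
#' @param class_a,class_b class labels to compare.
#' @return list `mean_a`, `mean_b`, `p` (NA with a message when a class has
#'   fewer than 2 pairs or the test is degenerate).
#' @export
compare_heterogeneity <- function(het, class_a, class_b) {
  a <- het$r[het$class == class_a & !is.na(het$r)]
  b <- het$r[het$class == class_b & !is.na(het$r)]
  out <- list(mean_a = mean(a), mean_b = mean(b), p = NA_real_)
  if (length(a) < 2L || length(b) < 2L) {
    message("class with < 2 pairs: test skipped")
    return(out)
  }
  if (sd(a) == 0 && sd(b) == 0) {
    message("degenerate (zero-variance) classes: test skipped")
    return(out)
  }
  out$p <- t.test(a, b)$p.value
  out
}
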