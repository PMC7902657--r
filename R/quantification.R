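## Methylation / accessibility quantification.
##
## All levels are read-pooled ratios: sum of methylated reads (C) divided by
## total covered reads over the sites of a region — never an average of
## per-site ratios.

# per-region pooled counts for one record table
region_counts <- function(records, regions, context = NULL) {
  rec <- records
  if (!is.null(context)) {
    keep <- rec[["context"]] == context   # plain vector: avoid NSE capture
    rec <- rec[keep, ]
  }
  n <- nrow(regions)
  out <- data.table(idx = seq_len(n), n_meth = 0, n_unmeth = 0, n_sites = 0L)
  if (!nrow(rec)) return(out)
  gr_s <- GenomicRanges::GRanges(rec$chrom, IRanges::IRanges(rec$pos, rec$pos))
  hits <- GenomicRanges::findOverlaps(gr_s, gi_to_gr(regions))
  if (!length(hits)) return(out)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  agg <- data.table(si = si, c = rec$n_meth[qi], t = rec$n_unmeth[qi])[
    , .(c = sum(c), t = sum(t), k = .N), by = si]
  out$n_meth[agg$si] <- agg$c
  out$n_unmeth[agg$si] <- agg$t
  out$n_sites[agg$si] <- agg$k
  out
}

#' Region-level methylation / accessibility
#'
#' @param calls a [CytosineCallSet()] or list of them.
#' @param regions interval data.frame (0-based half-open, `name` column used
#'   as region id).
#' @param context `"WCG"` (methylation) or `"GCH"` (accessibility).
#' @return data.frame `cell_id, region, context, level, n_sites`; `level` is
#'   NA for regions with no covered site.
#' @export
region_level <- function(calls, regions, context = c("WCG", "GCH")) {
  context <- match.arg(context)
  calls <- as_call_list(calls)
  validate_intervals(regions)
  rid <- regions$name %||% sprintf("region%d", seq_len(nrow(regions)))
  out <- lapply(calls, function(cs) {
    rc <- region_counts(cs$records, regions, context)
    tot <- rc$n_meth + rc$n_unmeth
    data.frame(cell_id = cs$cell_id, region = rid, context = context,
               level = ifelse(tot >= 1, rc$n_meth / tot, NA_real_),
               n_sites = rc$n_sites, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Region-level matrix across cells
#'
#' Matrix form of [region_level()] for many cells: one level matrix and one
#' site-count matrix, regions x cells.
#'
#' @inheritParams region_level
#' @return list with `level` and `n_sites` matrices.
#' @export
region_level_matrix <- function(calls, regions, context = c("WCG", "GCH")) {
  context <- match.arg(context)
  calls <- as_call_list(calls)
  rid <- regions$name %||% sprintf("region%d", seq_len(nrow(regions)))
  lev <- matrix(NA_real_, nrow(regions), length(calls),
                dimnames = list(rid, names(calls)))
  ns <- matrix(0L, nrow(regions), length(calls),
               dimnames = list(rid, names(calls)))
  for (ci in seq_along(calls)) {
    rc <- region_counts(calls[[ci]]$records, regions, context)
    tot <- rc$n_meth + rc$n_unmeth
    lev[, ci] <- ifelse(tot >= 1, rc$n_meth / tot, NA_real_)
    ns[, ci] <- rc$n_sites
  }
  list(level = lev, n_sites = ns)
}

# strand-aware TSS window: covers `up` bases upstream of (and including) the
# TSS boundary and `down` bases downstream, 0-based half-open
strand_window <- function(tss, strand, up, down) {
  plus <- strand == "+"
  data.frame(start = ifelse(plus, tss - up, tss - down - 1L),
             end = ifelse(plus, tss + down, tss + up - 1L))
}

#' TSS methylation and accessibility metrics
#'
#' Methylation: average WCG level within 1 kb upstream and 0.5 kb downstream
#' of the TSS. Accessibility: average GCH level within 200 bp upstream and
#' 100 bp downstream. Windows are strand-aware (mirrored on minus-strand
#' genes).
#'
#' @param calls [CytosineCallSet()] or list.
#' @param genes gene model data.frame.
#' @param met_window,acc_window `(upstream, downstream)` widths in bp.
#' @return data.frame `cell_id, gene_id, tss_met, tss_acc` (NA where no
#'   covered site).
#' @export
tss_metrics <- function(calls, genes, met_window = c(1000L, 500L),
                        acc_window = c(200L, 100L)) {
  calls <- as_call_list(calls)
  wm <- strand_window(genes$tss, genes$strand, met_window[1], met_window[2])
  wa <- strand_window(genes$tss, genes$strand, acc_window[1], acc_window[2])
  reg_m <- data.frame(chrom = genes$chrom, start = pmax(0L, wm$start),
                      end = wm$end, name = genes$gene_id)
  reg_a <- data.frame(chrom = genes$chrom, start = pmax(0L, wa$start),
                      end = wa$end, name = genes$gene_id)
  out <- lapply(calls, function(cs) {
    rm_ <- region_counts(cs$records, reg_m, "WCG")
    ra <- region_counts(cs$records, reg_a, "GCH")
    tm <- rm_$n_meth + rm_$n_unmeth
    ta <- ra$n_meth + ra$n_unmeth
    data.frame(cell_id = cs$cell_id, gene_id = genes$gene_id,
               tss_met = ifelse(tm >= 1, rm_$n_meth / tm, NA_real_),
               tss_acc = ifelse(ta >= 1, ra$n_meth / ta, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# running-window geometry for one gene, 5'->3' order, 0-based half-open
# genomic coordinates; zones: up (flank), body (fraction space), down
gene_profile_windows <- function(gene, flank, window, step,
                                 fractions, body_window, body_step) {
  n_fl <- floor((flank - window) / step) + 1L
  n_bd <- floor((fractions - body_window) / body_step) + 1L
  tss0 <- gene$tss - 1L
  tes0 <- gene$tes - 1L
  L <- abs(tes0 - tss0) + 1L
  fl_rel <- (seq_len(n_fl) - 1L) * step
  frac <- function(j) round(j * L / fractions)
  bd_a <- frac((seq_len(n_bd) - 1L) * body_step)
  bd_b <- frac((seq_len(n_bd) - 1L) * body_step + body_window)
  if (gene$strand == "+") {
    up_s <- tss0 - flank + fl_rel
    dn_s <- tes0 + 1L + fl_rel
    body_s <- tss0 + bd_a; body_e <- tss0 + bd_b
    st <- c(up_s, body_s, dn_s)
    en <- c(up_s + window, body_e, dn_s + window)
  } else {
    # minus strand: upstream is to the right of the TSS
    up_e <- tss0 + flank - fl_rel + 1L
    dn_e <- tes0 - fl_rel
    body_e <- tss0 - bd_a + 1L; body_s <- tss0 - bd_b + 1L
    st <- c(up_e - window, body_s, dn_e - window)
    en <- c(up_e, body_e, dn_e)
  }
  data.frame(win = seq_len(n_fl * 2L + n_bd),
             zone = rep(c("up", "body", "down"), c(n_fl, n_bd, n_fl)),
             chrom = gene$chrom, start = st, end = en,
             stringsAsFactors = FALSE)
}

#' Genic running-window profile
#'
#' Profiles levels from `flank` bp upstream of the TSS through the gene body
#' to `flank` bp downstream of the TES. Flank windows run in base space
#' (default 150 bp window, 50 bp step -> 48 windows per flank); the gene
#' body is divided into `fractions` equal fractions profiled with a
#' `body_window`-fraction window at `body_step`-fraction steps (defaults 2/1
#' over 100 fractions -> 99 body windows). Windows extending past a
#' chromosome end are truncated by coverage (no sites -> NA).
#'
#' @param calls a single [CytosineCallSet()].
#' @param genes gene model data.frame.
#' @param context `"WCG"` or `"GCH"`.
#' @param flank,window,step flank geometry (bp).
#' @param fractions,body_window,body_step body geometry (fraction units).
#' @param min_gene_length genes shorter than this are skipped with a warning.
#' @return list of class `ProfileTrack`: `windows` (win/zone metadata),
#'   `level` and `n_sites` matrices (genes x windows), `cell_id`, `context`.
#' @export
genic_profile <- function(calls, genes, context = c("WCG", "GCH"),
                          flank = 2500L, window = 150L, step = 50L,
                          fractions = 100L, body_window = 2L, body_step = 1L,
                          min_gene_length = 100L) {
  context <- match.arg(context)
  stopifnot(is_call_set(calls))
  short <- abs(genes$tes - genes$tss) + 1L < min_gene_length
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than ", min_gene_length, " bp skipped")
    genes <- genes[!short, , drop = FALSE]
  }
  wins <- lapply(seq_len(nrow(genes)), function(i)
    cbind(gene_id = genes$gene_id[i],
          gene_profile_windows(genes[i, ], flank, window, step,
                               fractions, body_window, body_step)))
  allw <- do.call(rbind, wins)
  allw$start <- pmax(0L, allw$start)
  ok <- allw$end > allw$start
  n_win <- max(allw$win)
  lev <- matrix(NA_real_, nrow(genes), n_win,
                dimnames = list(genes$gene_id, NULL))
  ns <- matrix(0L, nrow(genes), n_win, dimnames = list(genes$gene_id, NULL))
  rc <- region_counts(calls$records, allw[ok, c("chrom", "start", "end")],
                      context)
  tot <- rc$n_meth + rc$n_unmeth
  idx <- cbind(match(allw$gene_id[ok], genes$gene_id), allw$win[ok])
  lev[idx] <- ifelse(tot >= 1, rc$n_meth / tot, NA_real_)
  ns[idx] <- rc$n_sites
  structure(list(windows = unique(allw[, c("win", "zone")]),
                 level = lev, n_sites = ns,
                 cell_id = calls$cell_id, context = context),
            class = "ProfileTrack")
}

#' @export
print.ProfileTrack <- function(x, ...) {
  cat(sprintf("<ProfileTrack> cell '%s' (%s): %d genes x %d windows\n",
              x$cell_id, x$context, nrow(x$level), ncol(x$level)))
  invisible(x)
}

#' Average profile tracks across cells
#'
#' Window-wise mean of per-cell gene-average levels ("values from cells at
#' the same stage combined").
#'
#' @param tracks list of [genic_profile()] outputs on the same gene set.
#' @return data.frame `win, zone, level`.
#' @export
average_profile <- function(tracks) {
  per_cell <- vapply(tracks, function(t) colMeans(t$level, na.rm = TRUE),
                     numeric(ncol(tracks[[1]]$level)))
  data.frame(tracks[[1]]$windows, level = rowMeans(per_cell, na.rm = TRUE))
}

#' Per-window profile-vs-expression correlation in one cell
#'
#' For each running window, correlates the window's level across genes with
#' the (transformed) expression of those genes in the same cell. The
#' weighted variant (weights = covered sites per gene-window) is the
#' default; `weighted = FALSE` gives the plain Pearson.
#'
#' @param track [genic_profile()] output for one cell.
#' @param expr expression matrix (genes x cells, TPM).
#' @param cell_id cell to use (default the track's cell).
#' @param weighted use site-count-weighted Pearson (default TRUE).
#' @param transform expression transform applied before correlating.
#' @param min_genes minimum complete gene pairs per window (default 3).
#' @return data.frame `win, zone, r, n_genes`.
#' @export
profile_expression_correlation <- function(track, expr, cell_id = NULL,
                                           weighted = TRUE,
                                           transform = function(x) log2(x + 1),
                                           min_genes = 3L) {
  cell_id <- cell_id %||% track$cell_id
  if (!cell_id %in% colnames(expr)) stop("cell not in expression matrix: ", cell_id)
  genes <- intersect(rownames(track$level), rownames(expr))
  if (length(genes) < min_genes) stop("too few genes shared with expression")
  y_all <- transform(expr[genes, cell_id])
  lev <- track$level[genes, , drop = FALSE]
  ns <- track$n_sites[genes, , drop = FALSE]
  r <- rep(NA_real_, ncol(lev)); n <- integer(ncol(lev))
  for (w in seq_len(ncol(lev))) {
    ok <- !is.na(lev[, w]) & !is.na(y_all)
    n[w] <- sum(ok)
    if (n[w] < min_genes) next
    x <- lev[ok, w]; y <- y_all[ok]
    if (sd(x) == 0 || sd(y) == 0) next
    r[w] <- if (weighted) weighted_pearson(x, y, ns[ok, w])$r else cor(x, y)
  }
  data.frame(track$windows, r = r, n_genes = n)
}
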