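## Stage summaries and figure-parity tables.

#' Global per-cell methylation / accessibility levels
#'
#' Pooled-read global ratio per cell per context, with optional stage group
#' means.
#'
#' @param calls list of [CytosineCallSet()] (may hold both contexts).
#' @param stage_of optional named vector mapping cell id to stage.
#' @return data.frame `cell_id, stage, context, level, n_sites`; stage group
#'   means in the `group_means` attribute.
#' @export
global_levels <- function(calls, stage_of = NULL) {
  calls <- as_call_list(calls)
  rows <- lapply(calls, function(cs) {
    rec <- cs$records
    do.call(rbind, lapply(c("WCG", "GCH"), function(ctx) {
      sub <- rec[rec$context == ctx, ]
      data.frame(cell_id = cs$cell_id,
                 stage = if (is.null(stage_of)) "all" else
                   stage_of[[cs$cell_id]],
                 context = ctx,
                 level = if (nrow(sub))
                   sum(sub$n_meth) / sum(sub$n_meth + sub$n_unmeth)
                 else NA_real_,
                 n_sites = nrow(sub), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  gm <- aggregate(level ~ stage + context, data = out[!is.na(out$level), ],
                  FUN = mean)
  structure(out, group_means = gm)
}

#' Tidy volcano table from links or TF scores
#'
#' Deterministic ordering (ascending p, then id); labels attached to
#' significant rows. FDR exactly at the cutoff is not significant
#' (strict `<`).
#'
#' @param x a data.frame with an estimate column (`r_w`, `delta_z` or `z`),
#'   `p` and `fdr` columns, and an id column (`ndr_id`/`tf_name`).
#' @param fdr_cut significance cutoff (default 0.1).
#' @return data.frame `id, estimate, p, fdr, sign, significant, label`.
#' @export
export_volcano <- function(x, fdr_cut = 0.1) {
  est_col <- intersect(c("r_w", "delta_z", "z"), names(x))[1]
  id_col <- intersect(c("ndr_id", "tf_name"), names(x))[1]
  if (is.na(est_col) || is.na(id_col))
    stop("no estimate / id column recognized")
  out <- data.frame(id = character(), estimate = numeric(), p = numeric(),
                    fdr = numeric(), sign = character(),
                    significant = logical(), label = character(),
                    stringsAsFactors = FALSE)
  if (!nrow(x)) return(out)
  out <- data.frame(id = x[[id_col]], estimate = x[[est_col]], p = x$p,
                    fdr = x$fdr, stringsAsFactors = FALSE)
  out$sign <- ifelse(is.na(out$estimate), NA_character_,
                     ifelse(out$estimate >= 0, "positive", "negative"))
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_cut
  out$label <- ifelse(out$significant, out$id, "")
  out[order(out$p, out$id), , drop = FALSE]
}
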