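#' @importFrom data.table data.table fread fwrite setkey setkeyv as.data.table rbindlist setorder setattr := .N .SD .I setnames copy
#' @importFrom stats pchisq cor sd var median rbinom rpois rnorm runif rbeta rlnorm p.adjust fisher.test wilcox.test t.test pt qnorm quantile complete.cases setNames aggregate
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "chrom", "pos", "strand", "context", "n_meth", "n_unmeth", "start",
  "end", "name", "cell_id", "n_sites", "chi2", "p", "level", "win", "bin",
  "gene_id", "tss", "tes", "ndr_id", "tile_id", "allele", "stage", "J"
))

## ---------------------------------------------------------------------------
## Domain types
## ---------------------------------------------------------------------------

#' Per-cell cytosine call set
#'
#' Container for strand-resolved site-level methylation calls of one cell,
#' split by trinucleotide context: `WCG` sites report endogenous CpG
#' methylation, `GCH` sites report the exogenous GpC accessibility mark laid
#' down by the GpC methyltransferase.
#'
#' @param cell_id single cell identifier.
#' @param records data.frame/data.table with columns `chrom`, `pos` (1-based
#'   cytosine position), `strand` (`"+"`/`"-"`), `context` (`"WCG"`/`"GCH"`),
#'   `n_meth`, `n_unmeth` (read counts). Rows with zero total coverage are
#'   dropped.
#' @return object of class `CytosineCallSet`: a list with elements `cell_id`
#'   and `records` (a keyed data.table).
#' @export
CytosineCallSet <- function(cell_id, records) {
  stopifnot(is.character(cell_id), length(cell_id) == 1L, nzchar(cell_id))
  rec <- as.data.table(records)
  need <- c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  rec <- rec[, need, with = FALSE]
  if (nrow(rec)) {
    if (any(rec$n_meth < 0) || any(rec$n_unmeth < 0))
      stop("negative counts in records")
    bad <- setdiff(unique(rec$context), c("WCG", "GCH"))
    if (length(bad))
      stop("unknown context token(s): ", paste(bad, collapse = ", "))
    if (any(!rec$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    rec <- rec[n_meth + n_unmeth >= 1L]
    if (anyDuplicated(rec, by = c("chrom", "pos", "strand", "context")))
      stop("duplicate (chrom, pos, strand, context) records in cell ", cell_id)
  }
  setkeyv(rec, c("chrom", "pos"))
  structure(list(cell_id = cell_id, records = rec), class = "CytosineCallSet")
}

#' @export
print.CytosineCallSet <- function(x, ...) {
  tab <- table(x$records$context)
  cat(sprintf("<CytosineCallSet> cell '%s': %d sites (WCG %d, GCH %d)\n",
              x$cell_id, nrow(x$records),
              if ("WCG" %in% names(tab)) tab[["WCG"]] else 0L,
              if ("GCH" %in% names(tab)) tab[["GCH"]] else 0L))
  invisible(x)
}

is_call_set <- function(x) inherits(x, "CytosineCallSet")

# normalize 'calls' arguments: a single set or a list of sets -> named list
as_call_list <- function(calls) {
  if (is_call_set(calls)) calls <- list(calls)
  if (!length(calls) || !all(vapply(calls, is_call_set, logical(1))))
    stop("expected a CytosineCallSet or a list of them")
  names(calls) <- vapply(calls, `[[`, character(1), "cell_id")
  calls
}

#' Genomic intervals as a data.frame
#'
#' Intervals are 0-based half-open (BED convention) throughout the package;
#' cytosine positions are 1-based. Conversion happens only at read/write
#' boundaries and inside the GRanges bridge.
#'
#' @param chrom,start,end,name vectors (name optional).
#' @return data.frame with columns chrom, start, end, name.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  df$name <- if (is.null(name)) sprintf("iv%d", seq_len(nrow(df))) else as.character(name)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df)) {
    if (any(!nzchar(df$chrom))) stop("empty chromosome name")
    if (any(df$start < 0)) stop("interval start < 0")
    if (any(df$end <= df$start)) stop("interval end <= start")
  }
  invisible(df)
}

# 0-based half-open data.frame -> GRanges (1-based closed)
gi_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

gr_to_gi <- function(gr, name = NULL) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- name
  df
}

## ---------------------------------------------------------------------------
## Readers / writers
## ---------------------------------------------------------------------------

#' Read a per-cell cytosine call table
#'
#' Dialect: tab-separated with header
#' `chrom  pos  strand  n_meth  n_unmeth  context`, positions 1-based
#' (Bismark CX-report style), gzip-transparent. Records with zero coverage
#' are dropped on read.
#'
#' @param path file path.
#' @param cell_id cell identifier; default = file base name.
#' @param context_filter optional `"WCG"` or `"GCH"` to restrict records.
#' @return [CytosineCallSet()]
#' @export
read_cytosine_report <- function(path, cell_id = NULL, context_filter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  classes <- list(character = c("chrom", "strand", "context"),
                  integer = c("pos", "n_meth", "n_unmeth"))
  dt <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r"); on.exit(close(con))
    fread(text = readLines(con), sep = "\t", header = TRUE,
          colClasses = classes)
  } else fread(path, sep = "\t", header = TRUE, colClasses = classes)
  need <- c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context")
  if (!all(need %in% names(dt)))
    stop("malformed cytosine report (header) in ", path)
  bad <- which(is.na(dt$pos) | is.na(dt$n_meth) | is.na(dt$n_unmeth) |
                 !dt$strand %in% c("+", "-") | !dt$context %in% c("WCG", "GCH"))
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s", bad[1] + 1L, path))
  if (!is.null(context_filter)) {
    context_filter <- match.arg(context_filter, c("WCG", "GCH"))
    dt <- dt[context == context_filter]
  }
  CytosineCallSet(cell_id %||% sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path)), dt)
}

#' Write a cytosine call table
#' @param x CytosineCallSet
#' @param path output path (`.gz` suffix compresses).
#' @export
write_cytosine_report <- function(x, path) {
  stopifnot(is_call_set(x))
  fwrite(x$records[, .(chrom, pos, strand, n_meth, n_unmeth, context)],
         path, sep = "\t")
  invisible(path)
}

#' Read a BED3/BED4 interval file
#'
#' @param path BED file (no header), 0-based half-open.
#' @return data.frame of intervals; a 4th column is kept as `name`.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("BED file needs >= 3 columns: ", path)
  df <- data.frame(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
                   end = as.integer(dt[[3]]), stringsAsFactors = FALSE)
  if (ncol(dt) >= 4L) df$name <- as.character(dt[[4]])
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop(sprintf("interval end <= start at line %d of %s", bad[1], path))
  validate_intervals(df)
  df
}

#' Write intervals as BED
#' @param df interval data.frame (chrom, start, end, optional further columns).
#' @param path output path.
#' @export
write_intervals <- function(df, path) {
  validate_intervals(df)
  fwrite(as.data.table(df), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix (TPM)
#'
#' TSV with first column `gene_id`, remaining columns cells.
#' @param path file path.
#' @return numeric matrix genes x cells.
#' @export
read_expression_matrix <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative expression values in ", path)
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  m
}

#' @rdname read_expression_matrix
#' @param m matrix genes x cells.
#' @export
write_expression_matrix <- function(m, path) {
  dt <- data.table(gene_id = rownames(m))
  dt <- cbind(dt, as.data.table(m))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read / write gene models
#'
#' TSV `gene_id chrom strand tss tes` with header; tss/tes are 1-based and
#' stored in transcription orientation (tss > tes on the minus strand).
#' @param path file path.
#' @return data.frame of gene models.
#' @export
read_gene_models <- function(path) {
  df <- as.data.frame(fread(path, sep = "\t", header = TRUE))
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  if (!all(need %in% names(df))) stop("gene model table lacks columns in ", path)
  validate_gene_models(df[need])
}

validate_gene_models <- function(df) {
  if (any(df$tss == df$tes)) stop("gene with tss == tes")
  plus <- df$strand == "+"
  if (any(plus & df$tss >= df$tes) || any(!plus & df$tss <= df$tes))
    stop("tss/tes not in transcription orientation")
  df
}

#' @rdname read_gene_models
#' @param df gene model data.frame.
#' @export
write_gene_models <- function(df, path) {
  fwrite(as.data.table(df[, c("gene_id", "chrom", "strand", "tss", "tes")]),
         path, sep = "\t")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Genome binning and per-cell QC
## ---------------------------------------------------------------------------

#' Tile a genome into fixed-size bins
#'
#' Bins tile each chromosome from offset 0; the last bin is truncated at the
#' chromosome end. Order is the chromosome order of `chrom_sizes`, then start.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bases).
#' @param bin_size bin width in bases.
#' @return interval data.frame with `name` = `chrom:start-end`.
#' @export
bin_genome <- function(chrom_sizes, bin_size) {
  if (!length(chrom_sizes)) stop("empty chrom_sizes")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be named")
  bin_size <- as.integer(bin_size)
  if (bin_size <= 0L) stop("bin_size must be > 0")
  out <- lapply(names(chrom_sizes), function(ch) {
    len <- as.numeric(chrom_sizes[[ch]])
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + bin_size, len)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  df$name <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  df
}

#' Default per-cell QC thresholds
#'
#' RNA side: a cell fails with fewer than 9,500 genes detected, library size
#' below 0.1 million counts, mitochondrial fraction over 30%, or top-50
#' feature fraction over 40%. DNA side: a cell fails with fewer than 0.5
#' million covered WCG sites or 5 million covered GCH sites.
#'
#' @param min_genes,min_library,max_mito_frac,max_top50_frac RNA thresholds.
#' @param min_wcg_sites,min_gch_sites DNA thresholds.
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(min_genes = 9500, min_library = 1e5,
                          max_mito_frac = 0.30, max_top50_frac = 0.40,
                          min_wcg_sites = 5e5, min_gch_sites = 5e6) {
  as.list(environment())
}

#' Per-cell quality control
#'
#' Computes RNA and DNA QC metrics and pass flags for each cell present in
#' either input. The mitochondrial fraction is computed from expression
#' counts of a user-supplied mitochondrial gene set (an approximation to a
#' read-level fraction).
#'
#' @param expr expression matrix (genes x cells) or NULL.
#' @param calls list of [CytosineCallSet()] or NULL.
#' @param mito_gene_ids character vector of mitochondrial gene ids.
#' @param thresholds list from [qc_thresholds()].
#' @return data.frame, one row per cell, with metrics and `rna_pass`,
#'   `dna_pass` flags (NA where the modality is absent).
#' @export
qc_cells <- function(expr = NULL, calls = NULL, mito_gene_ids = character(),
                     thresholds = qc_thresholds()) {
  if (is.null(expr) && is.null(calls))
    stop("cell present in neither input: nothing to QC")
  rna_cells <- if (!is.null(expr)) colnames(expr) else character()
  calls <- if (!is.null(calls)) as_call_list(calls) else list()
  dna_cells <- names(calls)
  all_cells <- union(rna_cells, dna_cells)
  if (!length(all_cells)) stop("no cells found in inputs")
  th <- thresholds
  out <- lapply(all_cells, function(cl) {
    rep <- list(cell_id = cl, n_genes_detected = NA_integer_,
                library_counts = NA_real_, mito_fraction = NA_real_,
                top50_fraction = NA_real_, n_wcg_sites = NA_integer_,
                n_gch_sites = NA_integer_, rna_pass = NA, dna_pass = NA)
    if (cl %in% rna_cells) {
      v <- expr[, cl]
      rep$n_genes_detected <- sum(v > 0)
      rep$library_counts <- sum(v)
      rep$mito_fraction <- if (rep$library_counts > 0)
        sum(v[rownames(expr) %in% mito_gene_ids]) / rep$library_counts else 0
      rep$top50_fraction <- if (rep$library_counts > 0)
        sum(sort(v, decreasing = TRUE)[seq_len(min(50L, length(v)))]) /
          rep$library_counts else 0
      rep$rna_pass <- rep$n_genes_detected >= th$min_genes &&
        rep$library_counts >= th$min_library &&
        rep$mito_fraction <= th$max_mito_frac &&
        rep$top50_fraction <= th$max_top50_frac
    }
    if (cl %in% dna_cells) {
      ctx <- calls[[cl]]$records$context
      rep$n_wcg_sites <- sum(ctx == "WCG")
      rep$n_gch_sites <- sum(ctx == "GCH")
      rep$dna_pass <- rep$n_wcg_sites >= th$min_wcg_sites &&
        rep$n_gch_sites >= th$min_gch_sites
    }
    as.data.frame(rep, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
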