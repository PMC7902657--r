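## Lineage-structured synthetic single-cell multiomics with ground truth.
##
## The generator emulates the data structure the downstream modules assume:
## stage/embryo/lineage-structured WCG methylomes whose sister-cell
## deviations are complementary (maintenance-failure partition), background
## GCH accessibility with implanted open regions optionally coupled to a
## linked gene's expression, stage-structured expression with ZGA and
## ICM/TE marker sets, allele-tagged call tables with implanted imbalance,
## and copy-number blocks affecting both binned read counts and expression.

#' Simulation configuration
#'
#' All downstream scenario sizes are set here; the defaults describe a
#' desk-scale genome (2 chromosomes x 10 Mb) on which every stage of the
#' pipeline runs in seconds to minutes.
#'
#' @param seed integer RNG seed; every `simulate_*` entry point derives its
#'   stream deterministically from it.
#' @param chrom_sizes named vector of chromosome lengths (bases).
#' @param wcg_density,gch_density site densities (sites per kb).
#' @param read_depth,gch_read_depth mean per-site read coverage (Poisson) for
#'   WCG and GCH sites.
#' @param n_embryos named integer vector: embryos per stage; stages among
#'   `zygote`, `2cell`, `4cell`, `late4cell`, `8cell`, `blastocyst`.
#' @param maintenance_efficiency per-cleavage methylation maintenance in
#'   \[0,1\]; the last value is recycled for deeper cleavages. The deviation
#'   a daughter inherits at cleavage k is
#'   `(1 - maintenance_efficiency[k]) * |Normal(0, sigma_dev)|` per bin,
#'   partitioned complementarily between the two daughters.
#' @param sigma_dev scale of maintenance-failure deviations (methylation
#'   units).
#' @param founder_beta two shape parameters of the Beta distribution of
#'   founder (zygote) per-bin methylation.
#' @param meth_bin_size width of the latent methylation bins (bases).
#' @param p_bg,p_open GCH methylation rate of closed chromatin / open (NDR)
#'   chromatin.
#' @param n_ndrs number of implanted NDRs; `ndr_width` their width (bases).
#' @param linked_fraction fraction of NDRs coupled to a gene's expression.
#' @param link_strength target accessibility-expression correlation
#'   `r_true` in \[-1,1\] for linked NDRs.
#' @param n_genes,n_zga_genes,n_icm_genes,n_te_genes gene counts by class.
#' @param zga_fold 2-cell / zygote mean-TPM fold for ZGA genes (zygote mean
#'   is scaled down by this factor).
#' @param lineage_fold elevation factor of ICM/TE markers in their
#'   blastocyst cell class.
#' @param expr_log_mean,expr_log_sd gene-level log-TPM location/spread.
#' @param expr_noise_sd per-cell log-normal expression noise (log scale).
#' @param cnv_blocks NULL or data.frame `chrom,start,end,copy_ratio`
#'   (non-overlapping) applied to `cnv_cells` (NULL = all cells).
#' @param cnv_cells character vector of affected cell ids or NULL.
#' @param cnv_bin_size,cnv_depth_per_bin DNA read binning and mean reads per
#'   neutral bin.
#' @param gc_effect strength of GC bias on bin counts (0 = none; 1 = 2-fold
#'   across the simulated GC range).
#' @param n_allelic_tiles,n_allelic_null imbalanced / balanced 500-bp tiles
#'   to simulate; `allelic_rates` the (maternal, paternal) methylation rates
#'   of imbalanced tiles; `allelic_depth` mean per-allele per-site coverage.
#' @param tile_size allelic tile width (bases; fixed 0-anchored grid).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_sizes = c(chr1 = 1e7, chr2 = 1e7),
                       wcg_density = 1, gch_density = 40,
                       read_depth = 20, gch_read_depth = 10,
                       n_embryos = c("4cell" = 3, "8cell" = 3),
                       maintenance_efficiency = c(1, 0.3, 0.9),
                       sigma_dev = 0.15,
                       founder_beta = c(30, 30),
                       meth_bin_size = 1e4,
                       p_bg = 0.25, p_open = 0.75,
                       n_ndrs = 200, ndr_width = 300, ndr_site_density = 50,
                       linked_fraction = 0.5, link_strength = 0.7,
                       n_genes = 300, n_zga_genes = 50,
                       n_icm_genes = 25, n_te_genes = 25,
                       zga_fold = 8, lineage_fold = 4,
                       expr_log_mean = log(50), expr_log_sd = 1,
                       expr_noise_sd = 0.6,
                       cnv_blocks = NULL, cnv_cells = NULL,
                       cnv_bin_size = 1e6, cnv_depth_per_bin = 1000,
                       gc_effect = 0,
                       n_allelic_tiles = 50, n_allelic_null = 200,
                       allelic_rates = c(0.8, 0.2), allelic_depth = 5,
                       tile_size = 500) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$maintenance_efficiency, cfg$p_bg, cfg$p_open,
             cfg$linked_fraction, cfg$allelic_rates)
  if (any(probs < 0 | probs > 1)) stop("rates/probabilities must lie in [0,1]")
  if (abs(cfg$link_strength) > 1) stop("link_strength must lie in [-1,1]")
  if (cfg$wcg_density <= 0 || cfg$gch_density <= 0) stop("densities must be > 0")
  if (cfg$read_depth <= 0 || cfg$gch_read_depth <= 0) stop("non-positive depth")
  if (!is.null(cfg$cnv_blocks) && any(cfg$cnv_blocks$copy_ratio <= 0))
    stop("copy_ratio must be > 0")
  bad <- setdiff(names(cfg$n_embryos),
                 c("zygote", "2cell", "4cell", "late4cell", "8cell", "blastocyst"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (cfg$n_zga_genes + cfg$n_icm_genes + cfg$n_te_genes > cfg$n_genes)
    stop("gene class counts exceed n_genes")
  invisible(cfg)
}

# cleavage count per stage (blastocyst modeled at 16 cells)
stage_cleavages <- c(zygote = 0L, "2cell" = 1L, "4cell" = 2L,
                     late4cell = 2L, "8cell" = 3L, blastocyst = 4L)

with_sim_seed <- function(cfg, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(cfg$seed) + offset)
  expr
}

clip01 <- function(x) pmin(1, pmax(0, x))

# uniform random site positions (distinct, sorted) per chromosome
random_sites <- function(chrom_sizes, density_per_kb) {
  out <- lapply(names(chrom_sizes), function(ch) {
    n <- round(chrom_sizes[[ch]] / 1000 * density_per_kb)
    pos <- sort(sample.int(as.integer(chrom_sizes[[ch]]), n))
    data.table(chrom = ch, pos = pos,
               strand = sample(c("+", "-"), n, replace = TRUE))
  })
  rbindlist(out)
}

## ---------------------------------------------------------------------------
## Lineage + methylomes
## ---------------------------------------------------------------------------

# build the cell roster and lineage annotation for one config
simulate_lineage_table <- function(cfg) {
  rows <- list()
  for (stg in names(cfg$n_embryos)) {
    k <- stage_cleavages[[stg]]
    n_cells <- 2L^k
    for (e in seq_len(cfg$n_embryos[[stg]])) {
      emb <- sprintf("%s_E%d", stg, e)
      cell <- sprintf("%s_c%d", emb, seq_len(n_cells))
      mother <- if (k >= 1) sprintf("%s_m%d", emb, (seq_len(n_cells) + 1L) %/% 2L)
                else NA_character_
      gm_idx <- (seq_len(n_cells) + 3L) %/% 4L
      grandmother <- if (k >= 2) sprintf("%s_g%d", emb, gm_idx) else NA_character_
      lin_class <- if (stg == "blastocyst")
        sample(rep(c("ICM", "TE"), length.out = n_cells)) else NA_character_
      rows[[length(rows) + 1L]] <- data.table(
        cell_id = cell, embryo_id = emb, stage = stg,
        mother_id = mother, grandmother_id = grandmother,
        lineage_class = lin_class)
    }
  }
  rbindlist(rows)
}

# per-bin methylation levels for the 2^k cells of one embryo
embryo_bin_levels <- function(cfg, k, n_bins) {
  me <- cfg$maintenance_efficiency
  me <- me[pmin(seq_len(max(k, 1L)), length(me))]
  m <- matrix(rbeta(n_bins, cfg$founder_beta[1], cfg$founder_beta[2]), ncol = 1)
  if (k >= 1) for (cl in seq_len(k)) {
    nxt <- matrix(0, n_bins, 2L * ncol(m))
    for (j in seq_len(ncol(m))) {
      delta <- (1 - me[cl]) * abs(rnorm(n_bins, 0, cfg$sigma_dev))
      s <- sample(c(-1, 1), n_bins, replace = TRUE)
      nxt[, 2L * j - 1L] <- clip01(m[, j] + s * delta)
      nxt[, 2L * j]      <- clip01(m[, j] - s * delta)
    }
    m <- nxt
  }
  m
}

#' Simulate lineage-structured single-cell WCG methylomes
#'
#' A founder zygote draws per-bin methylation from a Beta distribution; at
#' each cleavage every bin's maintenance failure is partitioned
#' complementarily between the daughters (`m + delta` / `m - delta`, clipped
#' to \[0,1\]), so sister similarity is governed by the per-cleavage
#' maintenance efficiency. Site reads are binomial draws at the cell's bin
#' methylation with Poisson coverage.
#'
#' @param cfg [sim_config()].
#' @return list with `calls` (named list of WCG [CytosineCallSet()]) and
#'   `truth` (ground-truth manifest; see package vignette).
#' @export
simulate_methylomes <- function(cfg) {
  validate_sim_config(cfg)
  with_sim_seed(cfg, 0L, {
    lineage <- simulate_lineage_table(cfg)
    sites <- random_sites(cfg$chrom_sizes, cfg$wcg_density)
    bins <- bin_genome(cfg$chrom_sizes, cfg$meth_bin_size)
    # map sites to global bin index
    bdt <- as.data.table(bins)[, bin := .I]
    # bins are 0-based half-open, site positions 1-based
    site_bin <- bdt[sites, on = .(chrom, start < pos, end >= pos), bin]
    n_bins <- nrow(bins)

    calls <- list()
    levels_by_cell <- list()
    for (emb in unique(lineage$embryo_id)) {
      cells <- lineage[lineage$embryo_id == emb, ]
      k <- stage_cleavages[[cells$stage[1]]]
      lv <- embryo_bin_levels(cfg, k, n_bins)
      for (i in seq_len(nrow(cells))) {
        cl <- cells$cell_id[i]
        p_site <- lv[site_bin, i]
        cov <- rpois(nrow(sites), cfg$read_depth)
        keep <- cov > 0L
        nm <- rbinom(sum(keep), cov[keep], p_site[keep])
        calls[[cl]] <- CytosineCallSet(cl, data.table(
          chrom = sites$chrom[keep], pos = sites$pos[keep],
          strand = sites$strand[keep], context = "WCG",
          n_meth = nm, n_unmeth = cov[keep] - nm))
        levels_by_cell[[cl]] <- lv[, i]
      }
    }
    truth <- structure(list(
      config = cfg, lineage = as.data.frame(lineage),
      wcg_sites = sites, meth_bins = bins,
      bin_levels = do.call(cbind, levels_by_cell)), class = "SimTruth")
    list(calls = calls, truth = truth)
  })
}

#' @export
print.SimTruth <- function(x, ...) {
  cat(sprintf("<SimTruth> %d cells, %d embryos", nrow(x$lineage),
              length(unique(x$lineage$embryo_id))))
  if (!is.null(x$implanted_ndrs)) cat(sprintf(", %d NDRs", nrow(x$implanted_ndrs)))
  if (!is.null(x$true_links)) cat(sprintf(", %d links", nrow(x$true_links)))
  cat("\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Expression
## ---------------------------------------------------------------------------

#' Simulate a stage-structured expression matrix
#'
#' Log-normal TPM-scale values with gene-level means; ZGA genes have their
#' zygote mean divided by `zga_fold`; ICM/TE marker sets are elevated in
#' their blastocyst cell class; per-cell noise is independent. Gene models
#' (positions, strand) are drawn once and recorded in the truth manifest.
#'
#' @param cfg [sim_config()].
#' @param truth manifest from [simulate_methylomes()].
#' @return list with `expr` (genes x cells TPM matrix) and augmented `truth`
#'   (`gene_models`, `genes` with class labels).
#' @export
simulate_expression <- function(cfg, truth) {
  with_sim_seed(cfg, 1L, {
    lin <- truth$lineage
    ng <- cfg$n_genes
    if (cfg$n_zga_genes + cfg$n_icm_genes + cfg$n_te_genes > ng)
      stop("gene class counts exceed n_genes")
    gene_id <- sprintf("g%04d", seq_len(ng))
    klass <- rep("other", ng)
    klass[seq_len(cfg$n_zga_genes)] <- "ZGA"
    klass[cfg$n_zga_genes + seq_len(cfg$n_icm_genes)] <- "ICM"
    klass[cfg$n_zga_genes + cfg$n_icm_genes + seq_len(cfg$n_te_genes)] <- "TE"
    chrom <- sample(names(cfg$chrom_sizes), ng, replace = TRUE)
    len <- round(runif(ng, 2e3, 2e4))
    start1 <- vapply(seq_len(ng), function(i)
      sample.int(as.integer(cfg$chrom_sizes[[chrom[i]]] - len[i] - 1L), 1L),
      integer(1))
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    gene_models <- data.frame(
      gene_id = gene_id, chrom = chrom, strand = strand,
      tss = ifelse(strand == "+", start1, start1 + len),
      tes = ifelse(strand == "+", start1 + len, start1),
      stringsAsFactors = FALSE)

    base <- rnorm(ng, cfg$expr_log_mean, cfg$expr_log_sd)
    cells <- lin$cell_id
    logm <- matrix(base, ng, length(cells))
    zyg <- lin$stage == "zygote"
    logm[klass == "ZGA", zyg] <- logm[klass == "ZGA", zyg] - log(cfg$zga_fold)
    icm_cells <- !is.na(lin$lineage_class) & lin$lineage_class == "ICM"
    te_cells <- !is.na(lin$lineage_class) & lin$lineage_class == "TE"
    logm[klass == "ICM", icm_cells] <- logm[klass == "ICM", icm_cells] +
      log(cfg$lineage_fold)
    logm[klass == "TE", te_cells] <- logm[klass == "TE", te_cells] +
      log(cfg$lineage_fold)
    expr <- exp(logm + matrix(rnorm(length(logm), 0, cfg$expr_noise_sd),
                              nrow(logm)))
    dimnames(expr) <- list(gene_id, cells)
    truth$gene_models <- gene_models
    truth$genes <- data.frame(gene_id = gene_id, class = klass,
                              stringsAsFactors = FALSE)
    list(expr = expr, truth = truth)
  })
}

## ---------------------------------------------------------------------------
## Accessibility
## ---------------------------------------------------------------------------

# pick the logistic scale so that the predicted realized correlation between
# measured NDR accessibility and expression hits |r_target|
calibrate_logistic_scale <- function(z, y, p_bg, p_open, r_target,
                                     exp_sites, depth) {
  grid <- 10^seq(-1.5, 1.5, length.out = 60)
  mid <- (p_bg + p_open) / 2
  amp <- (p_open - p_bg) / 2
  pred <- vapply(grid, function(a) {
    rate <- mid + amp * (2 * stats::plogis(a * z) - 1)
    vw <- var(rate)
    if (vw == 0) return(0)
    vn <- mean(rate * (1 - rate)) / (exp_sites * depth)
    abs(cor(rate, y)) * sqrt(vw / (vw + vn))
  }, numeric(1))
  grid[which.min(abs(pred - abs(r_target)))]
}

#' Simulate per-cell GCH accessibility with implanted NDRs
#'
#' Background GCH sites methylate at rate `p_bg`; sites inside implanted
#' NDRs at an elevated rate. For linked NDRs the per-cell rate interpolates
#' `p_bg -> p_open` through a logistic function of the linked gene's
#' standardized log-expression, with the logistic scale calibrated per link
#' so the realized accessibility-expression correlation targets
#' `link_strength` (negative values invert the coupling). Unlinked NDRs are
#' open at the cell-independent rate `p_open`.
#'
#' @param cfg [sim_config()].
#' @param expr expression matrix from [simulate_expression()] (only needed
#'   when `linked_fraction > 0`).
#' @param truth manifest (augmented in place and returned).
#' @return list with `calls` (GCH [CytosineCallSet()] per cell) and `truth`
#'   gaining `gch_sites`, `implanted_ndrs`, `true_links`, `ndr_rates`.
#' @export
simulate_accessibility <- function(cfg, expr = NULL, truth) {
  with_sim_seed(cfg, 2L, {
    lin <- truth$lineage
    cells <- lin$cell_id
    sites <- random_sites(cfg$chrom_sizes, cfg$gch_density)
    n_sites <- nrow(sites)

    n_link <- round(cfg$linked_fraction * cfg$n_ndrs)
    if (n_link > 0 && is.null(expr))
      stop("expression matrix required for linked NDRs")
    if (n_link > 0 && !is.null(truth$gene_models)) {
      if (n_link > nrow(truth$gene_models))
        stop("more linked NDRs than genes")
      link_gene <- sample(truth$gene_models$gene_id, n_link)
      if (any(!link_gene %in% rownames(expr)))
        stop("linked gene absent from expression matrix")
    } else link_gene <- character()

    # place NDRs: linked ones near their gene's TSS, the rest uniform;
    # reject overlaps so implanted regions stay distinct
    placed <- data.table(chrom = character(), start = integer(), end = integer())
    place_one <- function(chrom = NULL, center = NULL) {
      for (try in 1:200) {
        ch <- chrom %||% sample(names(cfg$chrom_sizes), 1)
        limit <- as.integer(cfg$chrom_sizes[[ch]]) - cfg$ndr_width
        st <- if (is.null(center)) sample.int(limit, 1L) else
          min(max(0L, center + sample(-5e4:5e4, 1L)), limit)
        en <- st + cfg$ndr_width
        if (!nrow(placed[chrom == ch & start < en & end > st]))
          return(data.table(chrom = ch, start = as.integer(st), end = en))
      }
      stop("could not place NDR without overlap; genome too crowded")
    }
    if (cfg$n_ndrs == 0L) {
      calls <- vector("list", length(cells))
      names(calls) <- cells
      for (ci in seq_along(cells)) {
        cov <- rpois(n_sites, cfg$gch_read_depth)
        keep <- cov > 0L
        nm <- rbinom(sum(keep), cov[keep], cfg$p_bg)
        calls[[ci]] <- CytosineCallSet(cells[ci], data.table(
          chrom = sites$chrom[keep], pos = sites$pos[keep],
          strand = sites$strand[keep], context = "GCH",
          n_meth = nm, n_unmeth = cov[keep] - nm))
      }
      truth$gch_sites <- sites
      truth$implanted_ndrs <- data.frame(chrom = character(),
                                         start = integer(), end = integer(),
                                         name = character(),
                                         open_rate = numeric())
      truth$true_links <- NULL
      return(list(calls = calls, truth = truth))
    }
    ndr_list <- vector("list", cfg$n_ndrs)
    for (i in seq_len(cfg$n_ndrs)) {
      if (i <= n_link) {
        gm <- truth$gene_models[truth$gene_models$gene_id == link_gene[i], ]
        ndr_list[[i]] <- place_one(gm$chrom, gm$tss)
      } else ndr_list[[i]] <- place_one()
      placed <- rbindlist(list(placed, ndr_list[[i]]))
    }
    ndrs <- rbindlist(ndr_list)
    ndrs[, name := sprintf("sim_ndr%04d", .I)]

    # implant GCH sites inside each NDR at ndr_site_density (GpC-dense open
    # chromatin), in addition to whatever background sites fall inside
    n_per <- max(1L, round(cfg$ndr_width / 1000 * cfg$ndr_site_density))
    ndr_sites <- data.table(
      chrom = rep(ndrs$chrom, each = n_per),
      pos = rep(ndrs$start, each = n_per) +
        as.vector(vapply(seq_len(nrow(ndrs)), function(i)
          sample.int(cfg$ndr_width, n_per), integer(n_per))),
      strand = sample(c("+", "-"), n_per * nrow(ndrs), replace = TRUE))
    sites <- unique(rbindlist(list(sites, ndr_sites)), by = c("chrom", "pos"))
    setkeyv(sites, c("chrom", "pos"))
    n_sites <- nrow(sites)

    # per-cell open rate of each NDR
    rates <- matrix(cfg$p_open, cfg$n_ndrs, length(cells),
                    dimnames = list(ndrs$name, cells))
    exp_sites <- n_per + cfg$ndr_width / 1000 * cfg$gch_density
    links <- NULL
    if (n_link > 0) {
      mid <- (cfg$p_bg + cfg$p_open) / 2
      amp <- (cfg$p_open - cfg$p_bg) / 2
      sgn <- sign(cfg$link_strength)
      if (sgn == 0) sgn <- 1
      links <- data.frame(ndr_id = ndrs$name[seq_len(n_link)],
                          gene_id = link_gene,
                          r_true = cfg$link_strength,
                          sign = if (cfg$link_strength >= 0) "positive" else "negative",
                          stringsAsFactors = FALSE)
      for (i in seq_len(n_link)) {
        y <- expr[link_gene[i], cells]
        lz <- log2(y + 1)
        z <- if (sd(lz) > 0) (lz - mean(lz)) / sd(lz) else lz * 0
        if (cfg$link_strength == 0) {
          rates[i, ] <- mid
        } else {
          a <- calibrate_logistic_scale(z, y, cfg$p_bg, cfg$p_open,
                                        cfg$link_strength, exp_sites,
                                        cfg$gch_read_depth)
          rates[i, ] <- mid + amp * (2 * stats::plogis(a * sgn * z) - 1)
        }
      }
    }

    # site -> NDR assignment
    site_ndr <- rep(NA_integer_, n_sites)
    gr_s <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
    hits <- GenomicRanges::findOverlaps(gr_s, gi_to_gr(ndrs))
    site_ndr[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)

    calls <- vector("list", length(cells))
    names(calls) <- cells
    for (ci in seq_along(cells)) {
      rate <- rep(cfg$p_bg, n_sites)
      inside <- !is.na(site_ndr)
      rate[inside] <- rates[site_ndr[inside], ci]
      cov <- rpois(n_sites, cfg$gch_read_depth)
      keep <- cov > 0L
      nm <- rbinom(sum(keep), cov[keep], rate[keep])
      calls[[ci]] <- CytosineCallSet(cells[ci], data.table(
        chrom = sites$chrom[keep], pos = sites$pos[keep],
        strand = sites$strand[keep], context = "GCH",
        n_meth = nm, n_unmeth = cov[keep] - nm))
    }
    truth$gch_sites <- sites
    truth$implanted_ndrs <- cbind(as.data.frame(ndrs),
                                  open_rate = rowMeans(rates))
    truth$true_links <- links
    truth$ndr_rates <- rates
    list(calls = calls, truth = truth)
  })
}

## ---------------------------------------------------------------------------
## Allelic imbalance + CNV
## ---------------------------------------------------------------------------

#' Simulate allele-tagged calls and copy-number signal
#'
#' Maternal/paternal WCG call tables are generated on a set of 500-bp tiles:
#' imbalanced tiles use the configured (maternal, paternal) rates, balanced
#' tiles share a common Beta-distributed rate. Per-cell DNA read counts per
#' bin are Poisson with mean `depth * copy_ratio * gc_bias`; expression of
#' genes inside CNV blocks is scaled by the copy ratio for affected cells.
#'
#' @param cfg [sim_config()].
#' @param truth manifest (needs `gene_models` when CNV blocks overlap genes).
#' @param expr optional expression matrix to receive the CNV adjustment.
#' @return list with `mat_calls`, `pat_calls`, `bin_counts` (bins x cells),
#'   `bins`, `gc`, `mappability`, `expr` (adjusted copy) and updated `truth`
#'   (`allelic_truth`, `cnv_truth`).
#' @export
simulate_allelic_and_cnv <- function(cfg, truth, expr = NULL) {
  with_sim_seed(cfg, 3L, {
    lin <- truth$lineage
    cells <- lin$cell_id

    ## -- allelic tiles ----------------------------------------------------
    n_tiles <- cfg$n_allelic_tiles + cfg$n_allelic_null
    grid_n <- floor(min(cfg$chrom_sizes) / cfg$tile_size)
    ch <- sample(names(cfg$chrom_sizes), n_tiles, replace = TRUE)
    idx <- sample.int(grid_n - 1L, n_tiles, replace = TRUE)
    tiles <- data.table(chrom = ch, start = (idx - 1L) * cfg$tile_size,
                        end = idx * cfg$tile_size)
    tiles <- unique(tiles)[seq_len(min(n_tiles, .N))]
    n_imb <- min(cfg$n_allelic_tiles, nrow(tiles))
    common <- rbeta(nrow(tiles), 5, 5)
    al_truth <- data.frame(
      chrom = tiles$chrom, start = tiles$start, end = tiles$end,
      tile_id = sprintf("%s:%d-%d", tiles$chrom, tiles$start, tiles$end),
      mat_rate = ifelse(seq_len(nrow(tiles)) <= n_imb, cfg$allelic_rates[1], common),
      pat_rate = ifelse(seq_len(nrow(tiles)) <= n_imb, cfg$allelic_rates[2], common),
      imbalanced = seq_len(nrow(tiles)) <= n_imb, stringsAsFactors = FALSE)

    # dedicated CpG-dense site positions within each tile
    sites_per_tile <- 1L + rpois(nrow(tiles), 3)
    site_tab <- tiles[rep(seq_len(nrow(tiles)), sites_per_tile)]
    site_tab[, pos := start + sample.int(cfg$tile_size, .N, replace = TRUE)]
    site_tab <- unique(site_tab, by = c("chrom", "pos"))
    site_tab[, tile_id := sprintf("%s:%d-%d", chrom, start, end)]
    tidx <- match(site_tab$tile_id, al_truth$tile_id)

    gen_allele <- function(rate_col) {
      out <- vector("list", length(cells))
      names(out) <- cells
      for (ci in seq_along(cells)) {
        cov <- rpois(nrow(site_tab), cfg$allelic_depth)
        keep <- cov > 0L
        r <- al_truth[[rate_col]][tidx][keep]
        nm <- rbinom(sum(keep), cov[keep], r)
        out[[ci]] <- CytosineCallSet(cells[ci], data.table(
          chrom = site_tab$chrom[keep], pos = site_tab$pos[keep],
          strand = "+", context = "WCG",
          n_meth = nm, n_unmeth = cov[keep] - nm))
      }
      out
    }
    mat_calls <- gen_allele("mat_rate")
    pat_calls <- gen_allele("pat_rate")

    ## -- CNV bins ---------------------------------------------------------
    bins <- bin_genome(cfg$chrom_sizes, cfg$cnv_bin_size)
    gc <- runif(nrow(bins), 0.35, 0.55)
    mapp <- rep(1, nrow(bins))
    ratio <- rep(1, nrow(bins))
    cnv_cells <- cfg$cnv_cells %||% cells
    if (!is.null(cfg$cnv_blocks)) {
      blk <- cfg$cnv_blocks
      gr_b <- gi_to_gr(bins)
      gr_k <- gi_to_gr(blk)
      if (length(GenomicRanges::findOverlaps(gr_k, drop.self = TRUE,
                                             drop.redundant = TRUE)))
        stop("overlapping CNV blocks")
      hits <- GenomicRanges::findOverlaps(gr_b, gr_k)
      ratio[S4Vectors::queryHits(hits)] <- blk$copy_ratio[S4Vectors::subjectHits(hits)]
    }
    gc_mult <- 2^(cfg$gc_effect * (gc - 0.45) / 0.2)
    counts <- matrix(NA_integer_, nrow(bins), length(cells),
                     dimnames = list(bins$name, cells))
    for (ci in seq_along(cells)) {
      r <- if (cells[ci] %in% cnv_cells) ratio else rep(1, nrow(bins))
      counts[, ci] <- rpois(nrow(bins), cfg$cnv_depth_per_bin * r * gc_mult)
    }

    if (!is.null(expr) && !is.null(cfg$cnv_blocks) && !is.null(truth$gene_models)) {
      gm <- truth$gene_models
      gene_start <- pmin(gm$tss, gm$tes)
      gr_g <- GenomicRanges::GRanges(gm$chrom,
                IRanges::IRanges(gene_start, pmax(gm$tss, gm$tes)))
      hits <- GenomicRanges::findOverlaps(gr_g, gi_to_gr(cfg$cnv_blocks))
      aff <- intersect(colnames(expr), cnv_cells)
      for (h in seq_along(hits)) {
        g <- gm$gene_id[S4Vectors::queryHits(hits)[h]]
        cr <- cfg$cnv_blocks$copy_ratio[S4Vectors::subjectHits(hits)[h]]
        expr[g, aff] <- expr[g, aff] * cr
      }
    }

    truth$allelic_truth <- al_truth
    truth$cnv_truth <- list(blocks = cfg$cnv_blocks, cells = cnv_cells,
                            bin_ratio = ratio, bins = bins)
    list(mat_calls = mat_calls, pat_calls = pat_calls,
         bin_counts = counts, bins = bins, gc = gc, mappability = mapp,
         expr = expr, truth = truth)
  })
}

#' Run the full generator
#'
#' Convenience wrapper running methylomes, expression, accessibility and
#' allelic/CNV simulation in sequence under one seed.
#'
#' @param cfg [sim_config()].
#' @return list with `wcg_calls`, `gch_calls`, `expr`, `mat_calls`,
#'   `pat_calls`, `bin_counts`, `bins`, `gc`, `mappability` and the complete
#'   `truth` manifest.
#' @export
simulate_dataset <- function(cfg) {
  met <- simulate_methylomes(cfg)
  ex <- simulate_expression(cfg, met$truth)
  acc <- simulate_accessibility(cfg, ex$expr, ex$truth)
  ac <- simulate_allelic_and_cnv(cfg, acc$truth, ex$expr)
  list(wcg_calls = met$calls, gch_calls = acc$calls, expr = ex$expr,
       mat_calls = ac$mat_calls, pat_calls = ac$pat_calls,
       bin_counts = ac$bin_counts, bins = ac$bins, gc = ac$gc,
       mappability = ac$mappability, expr_cnv = ac$expr, truth = ac$truth)
}
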