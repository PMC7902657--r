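# Independent oracles used to cross-check the implementation. These are
# deliberately written as direct, unoptimized evaluations of the defining
# formulas and never share code with the package internals.

oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

oracle_weighted_pearson <- function(x, y, w) {
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  num <- sum(w * (x - xb) * (y - yb))
  num / sqrt(sum(w * (x - xb)^2) * sum(w * (y - yb)^2))
}

# two-sided Fisher exact p by exhaustive enumeration of the hypergeometric
# support at fixed margins (R's relative-error convention for "as extreme")
oracle_fisher_two_sided <- function(a, b, c, d) {
  m1 <- a + b; k <- a + c; n <- a + b + c + d
  lo <- max(0L, k - (n - m1)); hi <- min(k, m1)
  support <- lo:hi
  dens <- dhyper(support, m1, n - m1, k)
  sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
}

# exact two-sided binomial tail (doubled smaller tail, capped at 1)
oracle_binom_two_sided <- function(c, n, p) {
  up <- pbinom(c - 1, n, p, lower.tail = FALSE)
  lo <- pbinom(c, n, p)
  min(1, 2 * min(up, lo))
}

# all perfect matchings of 1..n via permutation enumeration (independent of
# the package's recursive construction)
oracle_matchings <- function(n) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  seen <- new.env()
  res <- list()
  for (p in perms(seq_len(n))) {
    m <- matrix(p, ncol = 2, byrow = TRUE)
    m <- t(apply(m, 1, sort))
    m <- m[order(m[, 1]), , drop = FALSE]
    key <- paste(t(m), collapse = ",")
    if (is.null(seen[[key]])) { seen[[key]] <- TRUE; res[[length(res) + 1]] <- m }
  }
  res
}

oracle_best_matching <- function(cm, minimize = TRUE) {
  ms <- oracle_matchings(nrow(cm))
  sc <- vapply(ms, function(m) sum(cm[m]), numeric(1))
  best <- if (minimize) min(sc) else max(sc)
  list(score = best, matching = ms[[which(sc == best)[1]]])
}

# brute-force TF z-score: plain loops over records, same RNG protocol as
# sample_background (set.seed(seed); consecutive sample.int draws)
oracle_tf_z <- function(cell, sites, pool, n_perm, seed, min_sites = 10) {
  rec <- as.data.frame(cell$records)
  rec <- rec[rec$context == "GCH", ]
  pooled_over <- function(iv) {
    cs <- ts <- 0; n <- 0
    for (i in seq_len(nrow(iv))) {
      inside <- rec$chrom == iv$chrom[i] & rec$pos > iv$start[i] &
        rec$pos <= iv$end[i]
      cs <- cs + sum(rec$n_meth[inside])
      ts <- ts + sum(rec$n_unmeth[inside])
      n <- n + sum(inside)
    }
    list(acc = if (n >= min_sites && cs + ts >= 1) cs / (cs + ts) else NA,
         n = n)
  }
  # per-pool-site counts for fast background evaluation
  site_c <- site_t <- numeric(nrow(pool))
  for (i in seq_len(nrow(pool))) {
    inside <- rec$chrom == pool$chrom[i] & rec$pos > pool$start[i] &
      rec$pos <= pool$end[i]
    site_c[i] <- sum(rec$n_meth[inside])
    site_t[i] <- sum(rec$n_unmeth[inside])
  }
  obs <- pooled_over(sites)
  set.seed(seed)
  bg <- numeric(n_perm)
  for (j in seq_len(n_perm)) {
    idx <- sample.int(nrow(pool), nrow(sites))
    bg[j] <- sum(site_c[idx]) / (sum(site_c[idx]) + sum(site_t[idx]))
  }
  if (is.na(obs$acc) || sd(bg) == 0) return(NA_real_)
  (obs$acc - mean(bg)) / sd(bg)
}

# moving average of x over index window +/- k, truncated at the ends
oracle_moving_average <- function(x, k) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - k):min(n, i + k)]), numeric(1))
}

# convenience: build a CytosineCallSet from vectors
toy_calls <- function(cell_id, chrom, pos, context, n_meth, n_unmeth,
                      strand = "+") {
  CytosineCallSet(cell_id, data.frame(
    chrom = chrom, pos = pos, strand = strand, context = context,
    n_meth = n_meth, n_unmeth = n_unmeth, stringsAsFactors = FALSE))
}
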