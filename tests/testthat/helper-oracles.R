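# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# O(n^3) brute-force complete-linkage agglomeration on Euclidean
# distances; returns the sorted merge heights.
brute_complete_linkage_heights <- function(mat) {
  clusters <- as.list(seq_len(nrow(mat)))
  d <- function(i, j) sqrt(sum((mat[i, ] - mat[j, ])^2))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        h <- max(outer(clusters[[a]], clusters[[b]], Vectorize(d)))
        if (h < best_h) {
          best_h <- h
          best <- c(a, b)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    heights <- c(heights, best_h)
  }
  sort(heights)
}

# Grid-search 4PL oracle: for each (log ec50, hill) on a grid, bottom and
# top follow from an analytic linear least-squares solve; the grid is
# refined around the incumbent three times.
grid_4pl <- function(doses, viability, n_grid = 40, refinements = 3) {
  sse_at <- function(lec50, hill) {
    w <- 1 / (1 + (doses / exp(lec50))^hill)
    X <- cbind(1, w)          # v ~ bottom + span * w
    fit <- stats::lm.fit(X, viability)
    sum(fit$residuals^2)
  }
  l_lo <- min(log(doses)) - 2
  l_hi <- max(log(doses)) + 2
  h_lo <- 0.1
  h_hi <- 6
  best <- c(lec50 = NA, hill = NA)
  for (r in seq_len(refinements + 1)) {
    ls <- seq(l_lo, l_hi, length.out = n_grid)
    hs <- seq(h_lo, h_hi, length.out = n_grid)
    sse <- outer(ls, hs, Vectorize(sse_at))
    idx <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    best <- c(lec50 = ls[idx[1]], hill = hs[idx[2]])
    dl <- diff(ls)[1]
    dh <- diff(hs)[1]
    l_lo <- best[1] - 2 * dl; l_hi <- best[1] + 2 * dl
    h_lo <- max(1e-3, best[2] - 2 * dh); h_hi <- best[2] + 2 * dh
  }
  # final local polish with a generic optimizer on the 2-parameter surface
  opt <- stats::optim(best, function(p) sse_at(p[1], p[2]),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  list(ec50 = exp(opt$par[1]), hill = opt$par[2], sse = opt$value)
}

# Brute-force direct-target oracle: all genes x all peaks, explicit
# per-pair distance arithmetic.
brute_direct_targets <- function(peaks, tss_table, degs,
                                 max_dist = 10000, min_abs_lfc = 1.5) {
  called <- character(0)
  for (i in seq_len(nrow(degs))) {
    if (abs(degs$log2_fold_change[i]) <= min_abs_lfc) next
    g <- degs$gene_id[i]
    t <- tss_table[tss_table$gene_id == g, ]
    if (!nrow(t)) next
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != t$chrom) next
      s <- peaks$start[j]; e <- peaks$end[j]; x <- t$tss
      d <- if (x >= s && x < e) 0 else min(abs(x - s), abs(x - (e - 1)))
      if (d < max_dist) {
        called <- c(called, g)
        break
      }
    }
  }
  sort(unique(called))
}

# Random peak/TSS/DEG instance for oracle-equality checks.
random_instance <- function(seed, n_peaks = 60, n_genes = 60) {
  set.seed(seed)
  peaks <- data.frame(
    chrom = sample(c("chr1", "chr2"), n_peaks, replace = TRUE),
    start = sample.int(2e6, n_peaks),
    fold_enrichment = runif(n_peaks, 4, 20),
    pileup = sample(10:120, n_peaks, replace = TRUE),
    q_value = 10^runif(n_peaks, -6, -1), stringsAsFactors = FALSE)
  peaks$end <- peaks$start + sample(150:600, n_peaks, replace = TRUE)
  tss <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
    tss = sample.int(2e6, n_genes),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  degs <- data.frame(gene_id = tss$gene_id,
                     log2_fold_change = rnorm(n_genes, 0, 2),
                     stringsAsFactors = FALSE)
  list(peaks = peaks, tss = tss, degs = degs)
}

# Shared tiny fixtures ---------------------------------------------------

noiseless_config <- function(seed = 1, ...) {
  sim_config(seed = seed, noise_cv = 0, ...)
}

one_compound_truth <- function(ed50 = 1, hill = 1, emax = 1,
                               lines = "lineA") {
  compound_truth("CMPD", stats::setNames(
    rep(list(list(ed50 = ed50, hill = hill, emax = emax)), length(lines)),
    lines))
}
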