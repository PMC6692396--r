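# Independent oracles: straight-line, loop-based implementations kept
# deliberately separate from the package's code paths.

# geNorm M values by direct pair enumeration over log2 quantities
oracle_genorm_m <- function(q) {
  lq <- log2(q)
  genes <- colnames(q)
  m <- numeric(length(genes))
  names(m) <- genes
  for (j in genes) {
    sds <- c()
    for (k in setdiff(genes, j)) {
      sds <- c(sds, stats::sd(lq[, j] - lq[, k]))
    }
    m[j] <- mean(sds)
  }
  m
}

# comparative delta-Ct scores by direct pair enumeration over raw Ct
oracle_delta_ct_scores <- function(ct_mat) {
  genes <- colnames(ct_mat)
  sc <- numeric(length(genes))
  names(sc) <- genes
  for (j in genes) {
    sds <- c()
    for (k in setdiff(genes, j)) {
      sds <- c(sds, stats::sd(ct_mat[, j] - ct_mat[, k]))
    }
    sc[j] <- mean(sds)
  }
  sc
}

# Mann-Whitney AUC by explicit O(n^2) pair counting with half-credit ties
oracle_auc_pairs <- function(pos, neg) {
  wins <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) wins <- wins + 1
      else if (p == q) wins <- wins + 0.5
    }
  }
  wins / (length(pos) * length(neg))
}

# Youden maximizer by exhaustive enumeration of all midpoint cuts
# (positives score high); returns the best J and the deterministic
# tie-broken threshold (higher sensitivity first, then lower threshold)
oracle_youden <- function(pos, neg) {
  s <- sort(unique(c(pos, neg)))
  cuts <- c(-Inf, if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2, Inf)
  best <- list(j = -Inf, threshold = NA, sensitivity = NA,
               specificity = NA)
  for (t in cuts) {
    sens <- mean(pos >= t)
    spec <- mean(neg < t)
    j <- sens + spec - 1
    better <- j > best$j ||
      (j == best$j && (sens > best$sensitivity ||
                         (sens == best$sensitivity &&
                            t < best$threshold)))
    if (better) {
      best <- list(j = j, threshold = t, sensitivity = sens,
                   specificity = spec)
    }
  }
  best
}

# Andersen (2004) grouped NormFinder stability, literal step-by-step
# transcription with explicit loops
oracle_normfinder_rho <- function(q, groups) {
  x <- log2(q)
  groups <- factor(groups)
  lev <- levels(groups)
  k <- ncol(x)
  m <- length(lev)
  var_g <- matrix(NA_real_, m, k)
  mean_g <- matrix(NA_real_, m, k)
  ngr <- integer(m)
  for (gi in seq_len(m)) {
    xg <- x[groups == lev[gi], , drop = FALSE]
    n <- nrow(xg)
    ngr[gi] <- n
    sample_means <- rowMeans(xg)
    gene_means <- colMeans(xg)
    grand <- mean(xg)
    a <- numeric(k)
    for (j in seq_len(k)) {
      r <- xg[, j] - gene_means[j] - sample_means + grand
      a[j] <- sum(r^2) / (n - 1)
    }
    b <- sum(a)
    for (j in seq_len(k)) {
      var_g[gi, j] <- max((a[j] - b / (k * (k - 1))) / (1 - 2 / k), 0)
    }
    mean_g[gi, ] <- gene_means
  }
  gm_gene <- colMeans(mean_g)
  gm_group <- rowMeans(mean_g)
  gm <- mean(mean_g)
  dif <- matrix(NA_real_, m, k)
  for (gi in seq_len(m)) {
    for (j in seq_len(k)) {
      dif[gi, j] <- mean_g[gi, j] - gm_group[gi] - gm_gene[j] + gm
    }
  }
  va <- var_g / ngr
  tau <- max(sum(dif^2) / ((m - 1) * (k - 1)) - mean(va), 0)
  rho <- numeric(k)
  for (j in seq_len(k)) {
    acc <- 0
    for (gi in seq_len(m)) {
      shrink <- if (tau + va[gi, j] > 0) tau / (tau + va[gi, j]) else 0
      d_new <- dif[gi, j] * shrink
      v_new <- va[gi, j] + va[gi, j] * shrink
      acc <- acc + abs(d_new) + sqrt(v_new)
    }
    rho[j] <- acc / m
  }
  names(rho) <- colnames(x)
  rho
}

# small deterministic ct_table builder
toy_ct_table <- function(mat, groups = NULL) {
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("S%d", seq_len(nrow(mat)))
  }
  meta <- NULL
  if (!is.null(groups)) {
    meta <- data.frame(sample_id = rownames(mat), group = groups,
                       stringsAsFactors = FALSE)
  }
  ct_table(mat, meta)
}

# replicate-level measurements data frame from per-entry replicate lists
toy_measurements <- function(...) {
  entries <- list(...)
  do.call(rbind, lapply(entries, function(e) {
    data.frame(sample_id = e$sample, gene = e$gene,
               replicate = seq_along(e$cts), ct = e$cts,
               detected = !is.na(e$cts), stringsAsFactors = FALSE)
  }))
}
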