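#' Relative quantities from Ct values
#'
#' Converts a Ct table to relative quantities \eqn{Q = E^{Ct_{min} - Ct}}
#' per gene, with amplification efficiency \eqn{E} (2.0 = 100\%). The best
#' expressed sample of every gene gets Q = 1; all Q lie in (0, 1]. geNorm
#' and NormFinder operate on these quantities; BestKeeper and the
#' comparative delta-Ct method use raw Ct.
#'
#' @param ct A \code{\link{ct_table}}.
#' @param efficiency Fold amplification per cycle, in (1, 2]. Default 2.
#' @return Numeric samples x genes matrix with attribute
#'   \code{"efficiency"}; missing Ct entries propagate as \code{NA}.
#' @export
relative_quantities <- function(ct, efficiency = 2.0) {
  stopifnot(inherits(ct, "ct_table"))
  if (!is.numeric(efficiency) || efficiency <= 1 || efficiency > 2) {
    stop("parameter error: efficiency must lie in (1, 2]")
  }
  m <- ct$ct
  if (any(colSums(!is.na(m)) == 0L)) {
    stop("fully-missing gene column(s): ",
         paste(colnames(m)[colSums(!is.na(m)) == 0L], collapse = ", "))
  }
  mins <- apply(m, 2, min, na.rm = TRUE)
  q <- efficiency^(sweep(-m, 2, mins, `+`))   # E^(Ctmin - Ct)
  attr(q, "efficiency") <- efficiency
  q
}

.stability_report <- function(gene, score, rank, method) {
  out <- data.frame(gene = gene, score = score, rank = rank,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- method
  class(out) <- c("stability_report", "data.frame")
  out
}

# Average ranks (ties = mean rank), deterministic gene-name tiebreak
# applied only to ordering, not to the rank values themselves.
.avg_rank <- function(score) rank(score, ties.method = "average")

#' geNorm stability values (M) with iterative-exclusion ranking
#'
#' For each gene j the M value is the mean, over all other genes k, of the
#' standard deviation across samples of \eqn{\log_2(Q_j / Q_k)}. Lower M =
#' more stable. The ranking follows the original algorithm: repeatedly
#' exclude the gene with the highest M and recompute on the survivors until
#' two genes remain; those two share the top rank (1.5 each).
#'
#' @param q Relative-quantity matrix from \code{\link{relative_quantities}}.
#' @return A \code{stability_report} (columns \code{gene, score, rank});
#'   \code{score} is the M value computed on the full panel.
#' @export
genorm_stability <- function(q) {
  if (ncol(q) < 3L) {
    stop("algorithm error: geNorm requires at least 3 genes")
  }
  lq <- log2(q)
  m_values <- function(cols) {
    vapply(cols, function(j) {
      mean(vapply(setdiff(cols, j), function(k) {
        stats::sd(lq[, j] - lq[, k], na.rm = TRUE)
      }, numeric(1)))
    }, numeric(1))
  }
  genes <- colnames(q)
  full_m <- m_values(genes)
  names(full_m) <- genes
  # iterative exclusion; worst (highest M) out first, name as tiebreak
  remaining <- genes
  exclusion_order <- character(0)
  while (length(remaining) > 2L) {
    m <- m_values(remaining)
    worst <- remaining[order(-m, remaining)][1L]
    exclusion_order <- c(worst, exclusion_order)
    remaining <- setdiff(remaining, worst)
  }
  rk <- numeric(length(genes))
  names(rk) <- genes
  rk[remaining] <- 1.5
  if (length(exclusion_order) > 0L) {
    rk[exclusion_order] <- seq(3L, length.out = length(exclusion_order))
  }
  .stability_report(genes, unname(full_m[genes]), unname(rk[genes]),
                    "geNorm")
}

#' geNorm pairwise variation V(n/n+1)
#'
#' The classic criterion for how many reference genes to include: V(n/n+1)
#' is the SD across samples of the log2 ratio of the normalization factors
#' (geometric means) built from the n and n+1 most stable genes. Values
#' below 0.15 conventionally indicate no benefit from the extra gene.
#' Provided for completeness; the pipeline default fixes three references.
#'
#' @param q Relative-quantity matrix.
#' @param ranking Optional character vector of genes from most to least
#'   stable; defaults to the geNorm iterative ranking.
#' @return Data frame with columns \code{n} and \code{v} (V(n/n+1)).
#' @export
genorm_pairwise_variation <- function(q, ranking = NULL) {
  if (is.null(ranking)) {
    rep <- genorm_stability(q)
    ranking <- rep$gene[order(rep$rank, rep$score)]
  }
  lq <- log2(q)
  nf <- function(k) rowMeans(lq[, ranking[seq_len(k)], drop = FALSE])
  ns <- seq(2L, length(ranking) - 1L)
  v <- vapply(ns, function(n) {
    stats::sd(nf(n) - nf(n + 1L), na.rm = TRUE)
  }, numeric(1))
  data.frame(n = ns, v = v)
}

#' NormFinder stability values
#'
#' Model-based stability estimation on log2 relative quantities. The
#' grouped variant decomposes the data into gene, sample, and gene-by-group
#' effects, estimates the intragroup variance of each gene within each
#' group and the intergroup bias of each gene, shrinks the bias by its
#' sampling variance, and reports the stability value
#' \eqn{\rho = |bias| + \sqrt{var}} averaged over groups (lower = more
#' stable). The ungrouped variant returns the square root of the estimated
#' gene variance.
#'
#' @param q Relative-quantity matrix (samples x genes).
#' @param groups Factor/character of group labels per sample, or a metadata
#'   data frame with columns \code{sample_id, group}; \code{NULL} for the
#'   ungrouped variant.
#' @param fallback_ungrouped If \code{TRUE}, a group with fewer than 2
#'   samples triggers a warning and the ungrouped variant instead of an
#'   error.
#' @return A \code{stability_report}.
#' @export
normfinder_stability <- function(q, groups = NULL,
                                 fallback_ungrouped = FALSE) {
  x <- log2(q)
  k <- ncol(x)
  if (k < 2L) stop("algorithm error: NormFinder requires >= 2 genes")
  if (is.data.frame(groups)) {
    groups <- groups$group[match(rownames(q), groups$sample_id)]
  }
  if (!is.null(groups)) {
    groups <- factor(groups)
    if (any(table(groups) < 2L)) {
      if (fallback_ungrouped) {
        warning("group with < 2 samples; falling back to ungrouped variant")
        groups <- NULL
      } else {
        stop("grouped variant error: every group needs >= 2 samples")
      }
    }
  }
  genes <- colnames(x)
  if (is.null(groups)) {
    v <- .normfinder_var(x)
    score <- sqrt(pmax(v, 0))
  } else {
    score <- .normfinder_rho(x, groups)
  }
  .stability_report(genes, unname(score), .avg_rank(score), "NormFinder")
}

# Andersen et al. (2004) variance estimator, single group.
# x: samples x genes, log scale. Returns per-gene variance estimates
# (may be negative before clipping; caller clips).
.normfinder_var <- function(x) {
  k <- ncol(x)
  mej <- rowMeans(x, na.rm = TRUE)       # per-sample mean over genes
  mei <- colMeans(x, na.rm = TRUE)       # per-gene mean over samples
  me <- mean(mej, na.rm = TRUE)
  n <- colSums(!is.na(x))
  r <- sweep(sweep(x, 1, mej), 2, mei) + me   # double-centered residuals
  a <- colSums(r^2, na.rm = TRUE) / (n - 1)
  b <- sum(a, na.rm = TRUE)
  (a - b / (k * (k - 1))) / (1 - 2 / k)
}

# Grouped stability rho: shrunken |intergroup bias| + intragroup SD,
# averaged over groups.
.normfinder_rho <- function(x, groups) {
  k <- ncol(x)
  lev <- levels(groups)
  m <- length(lev)
  ngr <- as.integer(table(groups))
  var_g <- matrix(0, nrow = m, ncol = k)        # intragroup variances
  meigr <- matrix(0, nrow = m, ncol = k)        # group x gene means
  for (i in seq_len(m)) {
    xi <- x[groups == lev[i], , drop = FALSE]
    var_g[i, ] <- pmax(.normfinder_var(xi), 0)
    meigr[i, ] <- colMeans(xi, na.rm = TRUE)
  }
  if (m == 1L) return(sqrt(var_g[1L, ]))
  # gene x group interaction (intergroup bias), double-centered group means
  m1i <- colMeans(meigr)
  m1j <- rowMeans(meigr)
  m1 <- mean(m1j)
  dif <- sweep(sweep(meigr, 1, m1j), 2, m1i) + m1   # m x k
  va <- sweep(var_g, 1, ngr, `/`)                   # var of group means
  tau <- max(sum(dif^2) / ((m - 1) * (k - 1)) - mean(va), 0)
  denom <- tau + va
  shrink <- ifelse(denom > 0, tau / denom, 0)   # 0/0: no signal, no bias
  dnew <- dif * shrink
  vanew <- va + va * shrink
  colMeans(abs(dnew) + sqrt(vanew))
}

#' BestKeeper descriptive statistics
#'
#' Per-gene descriptive statistics on raw Ct: n, geometric and arithmetic
#' mean, min, max, dispersion, CV\% and the Pearson correlation of each
#' gene with the BestKeeper index (the per-sample geometric mean of all
#' candidate Cts). The original tool's "SD" is the mean absolute deviation
#' from the arithmetic mean (default here); a classic sample SD is
#' available via \code{sd_type = "classic"}. Genes rank ascending by the
#' dispersion statistic.
#'
#' @param ct A \code{\link{ct_table}} restricted to the candidate genes.
#' @param sd_type \code{"mad"} (original tool, default) or
#'   \code{"classic"}.
#' @return A \code{stability_report} whose \code{details} attribute holds
#'   the full statistics table (including \code{r} vs the index).
#' @export
bestkeeper_stats <- function(ct, sd_type = c("mad", "classic")) {
  sd_type <- match.arg(sd_type)
  m <- ct$ct
  if (nrow(m) < 2L) stop("BestKeeper requires >= 2 samples")
  if (any(m[!is.na(m)] <= 0)) {
    stop("domain error: nonpositive Ct (geometric mean undefined)")
  }
  disp <- function(v) {
    v <- v[!is.na(v)]
    if (sd_type == "mad") mean(abs(v - mean(v))) else stats::sd(v)
  }
  idx <- exp(rowMeans(log(m), na.rm = TRUE))   # BestKeeper index
  details <- data.frame(
    gene = colnames(m),
    n = colSums(!is.na(m)),
    geo_mean = exp(colMeans(log(m), na.rm = TRUE)),
    mean = colMeans(m, na.rm = TRUE),
    min = apply(m, 2, min, na.rm = TRUE),
    max = apply(m, 2, max, na.rm = TRUE),
    sd = apply(m, 2, disp),
    stringsAsFactors = FALSE
  )
  details$cv_pct <- 100 * details$sd / details$mean
  details$r <- apply(m, 2, function(v) {
    ok <- !is.na(v)
    if (stats::sd(v[ok]) == 0 || stats::sd(idx[ok]) == 0) return(NA_real_)
    stats::cor(v[ok], idx[ok])
  })
  rownames(details) <- NULL
  rep <- .stability_report(details$gene, details$sd, .avg_rank(details$sd),
                           "BestKeeper")
  attr(rep, "details") <- details
  rep
}

#' Comparative delta-Ct stability
#'
#' For every ordered gene pair (j, k) the per-sample difference
#' \eqn{Ct_j - Ct_k} is formed and its SD across samples computed. A gene's
#' score is the mean of the SDs over all pairs involving it; lower = more
#' stable. A per-sample global offset common to all genes cancels exactly.
#'
#' @param ct A \code{\link{ct_table}}.
#' @return A \code{stability_report}.
#' @export
delta_ct_stability <- function(ct) {
  m <- ct$ct
  if (ncol(m) < 2L || nrow(m) < 2L) {
    stop("comparative delta-Ct requires >= 2 genes and >= 2 samples")
  }
  genes <- colnames(m)
  score <- vapply(genes, function(j) {
    mean(vapply(setdiff(genes, j), function(k) {
      stats::sd(m[, j] - m[, k], na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  .stability_report(genes, unname(score), .avg_rank(score), "deltaCt")
}

#' Comprehensive geometric-mean-of-ranks ranking
#'
#' Combines per-method rankings into a final ranking: each gene's
#' comprehensive score is the geometric mean of its ranks across methods
#' (the RefFinder-style weighting); final ranks ascend by that score.
#'
#' @param reports A list of \code{stability_report}s (or a list of named
#'   rank vectors) covering the same gene set.
#' @return A \code{stability_report} with method \code{"comprehensive"}.
#' @export
comprehensive_ranking <- function(reports) {
  ranks <- lapply(reports, function(r) {
    if (inherits(r, "stability_report")) {
      stats::setNames(r$rank, r$gene)
    } else {
      if (is.null(names(r))) stop("rank vectors must be named by gene")
      r
    }
  })
  genes <- sort(names(ranks[[1L]]))
  for (r in ranks) {
    if (!setequal(names(r), genes)) {
      stop("integrity error: rank vectors cover different gene sets")
    }
  }
  mat <- vapply(ranks, function(r) r[genes], numeric(length(genes)))
  score <- exp(rowMeans(log(mat)))
  .stability_report(genes, unname(score), .avg_rank(score),
                    "comprehensive")
}

#' Correlation matrix of stability scores or rankings
#'
#' Pairwise Pearson correlation (and r-squared) between score/rank vectors,
#' e.g. to compare stability methods. A zero-variance vector yields
#' \code{NA} against everything but itself.
#'
#' @param vectors Named list of equal-length numeric vectors, or a numeric
#'   matrix with vectors in columns.
#' @return List with matrices \code{r} and \code{r2}.
#' @export
ranking_correlation <- function(vectors) {
  if (is.list(vectors)) {
    vectors <- do.call(cbind, vectors)
  }
  if (nrow(vectors) < 3L) stop("need >= 3 observations per vector")
  p <- ncol(vectors)
  r <- matrix(NA_real_, p, p,
              dimnames = list(colnames(vectors), colnames(vectors)))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) { r[i, j] <- 1; next }
      ok <- stats::complete.cases(vectors[, c(i, j)])
      vi <- vectors[ok, i]; vj <- vectors[ok, j]
      if (stats::sd(vi) == 0 || stats::sd(vj) == 0) next
      r[i, j] <- stats::cor(vi, vj)
    }
  }
  list(r = r, r2 = r^2)
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability_report (", attr(x, "method"), ")\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
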