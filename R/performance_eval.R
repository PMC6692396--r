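#' Empirical ROC curve and trapezoidal AUC
#'
#' Builds the empirical ROC of a score against binary labels. Candidate
#' thresholds are midpoints between adjacent distinct scores plus -Inf/+Inf
#' sentinels; a sample is called positive when its score is >= the
#' threshold (the "higher = positive" orientation; set
#' \code{direction = "<"} for scores where the positive class is low). The
#' AUC is the trapezoid over the empirical curve and equals the
#' tie-corrected Mann-Whitney probability
#' \eqn{P(X_{pos} > X_{neg}) + P(X_{pos} = X_{neg})/2}.
#'
#' @param scores Numeric vector, or a \code{drs_result} (its \code{score}
#'   and \code{group} columns are used).
#' @param labels Class labels aligned with \code{scores}; ignored when
#'   \code{scores} is a \code{drs_result} carrying groups, unless supplied.
#' @param positive Label of the positive class (default \code{"viral"},
#'   the high-score class of the qPCR-scale DRS).
#' @param direction \code{">"} when positives score high (default),
#'   \code{"<"} when they score low.
#' @return List of class \code{roc_curve}: \code{roc} (data frame
#'   \code{threshold, sensitivity, specificity, fpr, tpr}), \code{auc},
#'   \code{positive}, \code{direction}, \code{n_positive},
#'   \code{n_negative}.
#' @export
roc_and_auc <- function(scores, labels = NULL, positive = "viral",
                        direction = c(">", "<")) {
  direction <- match.arg(direction)
  if (inherits(scores, "drs_result")) {
    if (is.null(labels)) labels <- scores$group
    scores <- scores$score
  }
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (direction == "<") scores <- -scores
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("ROC undefined: one of the classes is empty")
  }
  thr <- .candidate_cuts(scores)
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  roc <- data.frame(threshold = thr, sensitivity = sens,
                    specificity = spec, fpr = 1 - spec, tpr = sens)
  roc <- roc[order(roc$fpr, roc$tpr), ]
  rownames(roc) <- NULL
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  structure(list(roc = roc, auc = auc, positive = positive,
                 direction = direction,
                 n_positive = length(pos), n_negative = length(neg)),
            class = "roc_curve")
}

# midpoints between adjacent distinct scores, with infinite sentinels
.candidate_cuts <- function(scores) {
  s <- sort(unique(scores))
  if (length(s) == 1L) return(c(-Inf, Inf))
  c(-Inf, (utils::head(s, -1) + utils::tail(s, -1)) / 2, Inf)
}

#' Mann-Whitney AUC (rank-based, independent of the ROC sweep)
#'
#' Tie-corrected two-sample rank statistic:
#' \eqn{(U + T/2) / (n_1 n_0)} where U counts positive-negative pairs with
#' the positive scoring strictly higher and T the tied pairs. Serves as the
#' package's second, independent route to the AUC.
#'
#' @param pos,neg Numeric score vectors for the positive and negative
#'   class.
#' @return The AUC as a single number.
#' @export
auc_mann_whitney <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos); n0 <- length(neg)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Youden optimal cut-point
#'
#' Threshold maximizing \eqn{J = sensitivity + specificity - 1} over the
#' candidate cuts of the ROC. Ties are broken toward higher sensitivity,
#' then toward the lower threshold (deterministic).
#'
#' @param roc A \code{roc_curve} from \code{\link{roc_and_auc}}.
#' @return List \code{threshold, sensitivity, specificity, youden_j}. The
#'   threshold refers to the (possibly direction-flipped) score axis used
#'   by the ROC; for \code{direction = "<"} it applies to \code{-score}.
#' @export
youden_cutpoint <- function(roc) {
  df <- roc$roc
  j <- df$sensitivity + df$specificity - 1
  best <- which(j == max(j))
  best <- best[order(-df$sensitivity[best], df$threshold[best])][1L]
  list(threshold = df$threshold[best],
       sensitivity = df$sensitivity[best],
       specificity = df$specificity[best],
       youden_j = j[best])
}

#' Stratified bootstrap percentile confidence interval
#'
#' Resamples with replacement within each class (preserving class sizes,
#' so no resample can lose a class) and returns the percentile interval of
#' a metric.
#'
#' @param metric Function \code{(scores, labels) -> numeric(1)}.
#' @param scores,labels Aligned score and label vectors.
#' @param n_boot Number of bootstrap replicates (>= 200; default 2000).
#' @param seed Integer seed; the interval is reproducible given the seed.
#' @param level Confidence level (default 0.95).
#' @return List \code{lower, upper, level, n_boot, seed, replicates}
#'   (replicates = the bootstrap metric values).
#' @export
bootstrap_ci <- function(metric, scores, labels, n_boot = 2000, seed = 1,
                         level = 0.95) {
  if (n_boot < 200) stop("n_boot must be >= 200")
  classes <- split(seq_along(scores), labels)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- unlist(lapply(classes, function(ix) {
      ix[sample.int(length(ix), replace = TRUE)]
    }), use.names = FALSE)
    metric(scores[idx], labels[idx])
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7))
  list(lower = ci[1L], upper = ci[2L], level = level, n_boot = n_boot,
       seed = seed, replicates = reps)
}

#' Predictive values from confusion counts
#'
#' \eqn{PPV = TP/(TP+FP)}, \eqn{NPV = TN/(TN+FN)}. A zero denominator
#' yields \code{NA} (undefined), never 0.
#'
#' @param tp,fp,tn,fn Nonnegative confusion-matrix counts.
#' @return List \code{ppv, npv}.
#' @export
predictive_values <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  ppv <- if (tp + fp > 0) unname(tp / (tp + fp)) else NA_real_
  npv <- if (tn + fn > 0) unname(tn / (tn + fn)) else NA_real_
  list(ppv = ppv, npv = npv)
}

#' Full classification performance report
#'
#' Computes the ROC/AUC of a score (viral-high orientation by default),
#' the Youden cut-point, sensitivity/specificity at the cut, PPV/NPV under
#' the clinical convention that a POSITIVE call means bacterial infection
#' (on the qPCR-scale DRS a sample is called bacterial when its score falls
#' below the cut-point), and stratified-bootstrap percentile CIs for AUC,
#' sensitivity and specificity.
#'
#' @param scores A \code{drs_result} or numeric vector.
#' @param labels Labels (needed when \code{scores} is a bare vector).
#' @param positive High-score class for the ROC (default \code{"viral"}).
#' @param call_positive Class reported as the clinical "positive" call for
#'   PPV/NPV (default \code{"bacterial"}).
#' @param n_boot,seed,level Bootstrap settings (see
#'   \code{\link{bootstrap_ci}}).
#' @return List of class \code{performance_report}.
#' @export
evaluate_performance <- function(scores, labels = NULL,
                                 positive = "viral",
                                 call_positive = "bacterial",
                                 n_boot = 2000, seed = 1, level = 0.95) {
  if (inherits(scores, "drs_result")) {
    if (is.null(labels)) labels <- scores$group
    scores <- scores$score
  }
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  roc <- roc_and_auc(scores, labels, positive = positive)
  cut <- youden_cutpoint(roc)
  # clinical confusion matrix: call 'call_positive' when score is on that
  # class's side of the cut (below it when call_positive is the low class)
  low_side <- call_positive != positive
  called_pos <- if (low_side) scores < cut$threshold else
    scores >= cut$threshold
  is_pos <- labels == call_positive
  tp <- sum(called_pos & is_pos); fp <- sum(called_pos & !is_pos)
  tn <- sum(!called_pos & !is_pos); fn <- sum(!called_pos & is_pos)
  pv <- predictive_values(tp, fp, tn, fn)
  auc_ci <- bootstrap_ci(function(s, l) roc_and_auc(s, l, positive)$auc,
                         scores, labels, n_boot, seed, level)
  sens_spec_boot <- bootstrap_ci(function(s, l) {
    r <- roc_and_auc(s, l, positive)
    youden_cutpoint(r)$sensitivity
  }, scores, labels, n_boot, seed + 1L, level)
  spec_boot <- bootstrap_ci(function(s, l) {
    r <- roc_and_auc(s, l, positive)
    youden_cutpoint(r)$specificity
  }, scores, labels, n_boot, seed + 2L, level)
  structure(list(
    auc = roc$auc,
    auc_ci = c(auc_ci$lower, auc_ci$upper),
    cutpoint = cut$threshold,
    sensitivity = cut$sensitivity,
    sensitivity_ci = c(sens_spec_boot$lower, sens_spec_boot$upper),
    specificity = cut$specificity,
    specificity_ci = c(spec_boot$lower, spec_boot$upper),
    ppv = pv$ppv, npv = pv$npv,
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    n_positive = roc$n_positive, n_negative = roc$n_negative,
    positive = positive, call_positive = call_positive,
    n_boot = n_boot, seed = seed, level = level,
    roc = roc
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  fmt <- function(v) sprintf("%.3f", v)
  cat("performance_report (positive class for ROC: ", x$positive,
      "; clinical positive call: ", x$call_positive, ")\n", sep = "")
  cat("  AUC:        ", fmt(x$auc), " [", fmt(x$auc_ci[1]), ", ",
      fmt(x$auc_ci[2]), "]\n", sep = "")
  cat("  cut-point:  ", fmt(x$cutpoint), "\n", sep = "")
  cat("  sensitivity:", fmt(x$sensitivity), " [", fmt(x$sensitivity_ci[1]),
      ", ", fmt(x$sensitivity_ci[2]), "]\n", sep = "")
  cat("  specificity:", fmt(x$specificity), " [", fmt(x$specificity_ci[1]),
      ", ", fmt(x$specificity_ci[2]), "]\n", sep = "")
  cat("  PPV: ", fmt(x$ppv), "  NPV: ", fmt(x$npv), "\n", sep = "")
  invisible(x)
}

#' Group comparison with an assumption-driven decision tree
#'
#' Two groups: Shapiro-Wilk normality per group at alpha, then an F test of
#' variance equality, then Student's t (normal, homoscedastic), Welch's t
#' (normal, heteroscedastic) or Wilcoxon rank-sum (non-normal). Three or
#' more groups: normality per group, then a Breusch-Pagan-style test of
#' homoscedasticity across groups; normal + homoscedastic -> one-way ANOVA
#' with Tukey HSD; normal + heteroscedastic -> Welch's heteroscedastic
#' ANOVA with Games-Howell; non-normal -> Kruskal-Wallis with Games-Howell.
#' Groups smaller than 3 cannot be tested for normality and route the
#' whole comparison to the nonparametric branch with a warning. The trace
#' records every branch taken.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels aligned with \code{values}.
#' @param alpha Significance level for the assumption checks (default
#'   0.05).
#' @return List of class \code{group_comparison}: \code{test} (name of the
#'   final test), \code{statistic}, \code{p_value}, \code{posthoc}
#'   (pairwise table or \code{NULL}), \code{trace} (named list of the
#'   assumption p-values and branch decisions).
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need >= 2 groups")
  sizes <- table(groups)
  trace <- list(n_groups = k, sizes = as.integer(sizes))
  small <- any(sizes < 3L)
  if (small) {
    warning("group with < 3 observations: falling back to nonparametric")
    trace$normality <- NA
    normal <- FALSE
  } else {
    sw <- vapply(levels(groups), function(g) {
      v <- values[groups == g]
      if (stats::sd(v) == 0) return(0)   # degenerate: clearly non-normal
      stats::shapiro.test(v)$p.value
    }, numeric(1))
    trace$shapiro_p <- sw
    normal <- all(sw > alpha)
    trace$normality <- normal
  }
  if (k == 2L) {
    g1 <- values[groups == levels(groups)[1L]]
    g2 <- values[groups == levels(groups)[2L]]
    if (!normal) {
      tt <- stats::wilcox.test(g1, g2, exact = FALSE, correct = TRUE)
      trace$branch <- "wilcoxon"
      return(.group_comparison("Wilcoxon rank-sum", tt$statistic,
                               tt$p.value, NULL, trace))
    }
    ft <- stats::var.test(g1, g2)
    trace$f_test_p <- ft$p.value
    equal_var <- ft$p.value > alpha
    trace$equal_variances <- equal_var
    tt <- stats::t.test(g1, g2, var.equal = equal_var)
    trace$branch <- if (equal_var) "student_t" else "welch_t"
    return(.group_comparison(
      if (equal_var) "Student t" else "Welch t",
      tt$statistic, tt$p.value, NULL, trace))
  }
  # multi-group
  if (normal) {
    bp <- breusch_pagan_groups(values, groups)
    trace$breusch_pagan_p <- bp$p.value
    homosc <- bp$p.value > alpha
    trace$homoscedastic <- homosc
    if (homosc) {
      fit <- stats::aov(values ~ groups)
      an <- summary(fit)[[1L]]
      tk <- stats::TukeyHSD(fit)$groups
      trace$branch <- "anova_tukey"
      posthoc <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                            p_value = tk[, "p adj"], row.names = NULL)
      return(.group_comparison("one-way ANOVA", an[["F value"]][1L],
                               an[["Pr(>F)"]][1L], posthoc, trace))
    }
    wt <- stats::oneway.test(values ~ groups, var.equal = FALSE)
    trace$branch <- "welch_anova_games_howell"
    return(.group_comparison("Welch ANOVA", wt$statistic, wt$p.value,
                             games_howell(values, groups), trace))
  }
  kw <- stats::kruskal.test(values, groups)
  trace$branch <- "kruskal_games_howell"
  .group_comparison("Kruskal-Wallis", kw$statistic, kw$p.value,
                    games_howell(values, groups), trace)
}

.group_comparison <- function(test, statistic, p_value, posthoc, trace) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), posthoc = posthoc,
                 trace = trace),
            class = "group_comparison")
}

#' Breusch-Pagan-style homoscedasticity test across groups
#'
#' Lagrange-multiplier test regressing the squared OLS residuals of the
#' group-means model on the group factor: \eqn{LM = n R^2 \sim \chi^2_{k-1}}
#' under homoscedasticity.
#'
#' @param values Numeric vector.
#' @param groups Factor of group labels.
#' @return List \code{statistic, df, p.value}.
#' @export
breusch_pagan_groups <- function(values, groups) {
  groups <- factor(groups)
  res <- values - stats::ave(values, groups)
  u2 <- res^2
  aux <- stats::lm(u2 ~ groups)
  r2 <- summary(aux)$r.squared
  stat <- length(values) * r2
  df <- nlevels(groups) - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' Pairwise comparisons that assume neither equal variances nor equal group
#' sizes: for groups i, j the statistic is
#' \eqn{t = (\bar x_i - \bar x_j) / \sqrt{s_i^2/n_i + s_j^2/n_j}} with
#' Welch degrees of freedom, referred to the studentized range distribution
#' (\eqn{q = t \sqrt 2}) with the total number of groups.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @return Data frame \code{pair, diff, se, t, df, p_value}.
#' @export
games_howell <- function(values, groups) {
  groups <- droplevels(factor(groups))
  lev <- levels(groups)
  k <- length(lev)
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  n <- tapply(values, groups, length)
  out <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      se2 <- v[i] / n[i] + v[j] / n[j]
      tstat <- (m[i] - m[j]) / sqrt(se2)
      df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                       (v[j] / n[j])^2 / (n[j] - 1))
      p <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                         lower.tail = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        pair = paste(lev[i], lev[j], sep = "-"),
        diff = unname(m[i] - m[j]), se = sqrt(se2),
        t = unname(tstat), df = unname(df), p_value = unname(p),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' DRS stability across reference-gene options
#'
#' Given the DRS of the same samples computed under several reference-gene
#' options, returns the Pearson r / r-squared matrices between the DRS
#' vectors, a Kruskal-Wallis test of differences between options, and
#' Games-Howell pairwise post-hoc comparisons.
#'
#' @param drs_list Named list of \code{drs_result}s (or numeric vectors)
#'   over the same samples, one per reference option.
#' @return List \code{r, r2, kruskal, games_howell}.
#' @export
drs_stability_matrix <- function(drs_list) {
  vecs <- lapply(drs_list, function(d) {
    if (inherits(d, "drs_result")) d$score else d
  })
  lens <- lengths(vecs)
  if (length(unique(lens)) != 1L) {
    stop("all reference options must cover the same samples")
  }
  cors <- ranking_correlation(vecs)
  stacked <- unlist(vecs, use.names = FALSE)
  opt <- rep(names(vecs), times = lens)
  kw <- stats::kruskal.test(stacked, factor(opt))
  list(r = cors$r, r2 = cors$r2,
       kruskal = list(statistic = unname(kw$statistic),
                      p_value = kw$p.value),
       games_howell = games_howell(stacked, opt))
}
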