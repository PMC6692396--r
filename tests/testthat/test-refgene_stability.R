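make_toy_q <- function(seed = 1, n = 4, genes = 3) {
  set.seed(seed)
  mat <- matrix(round(runif(n * genes, 22, 30), 2), n, genes,
                dimnames = list(sprintf("S%d", 1:n),
                                sprintf("G%d", 1:genes)))
  relative_quantities(toy_ct_table(mat))
}

test_that("relative quantities follow Q = E^(Ctmin - Ct)", {
  m <- matrix(c(20, 21, 22), 3, 1, dimnames = list(paste0("S", 1:3), "A"))
  q <- relative_quantities(toy_ct_table(m))
  expect_equal(unname(q[, "A"]), c(1, 0.5, 0.25))

  const <- matrix(rep(25, 3), 3, 1,
                  dimnames = list(paste0("S", 1:3), "A"))
  expect_equal(unname(relative_quantities(toy_ct_table(const))[, "A"]),
               rep(1, 3))

  m2 <- matrix(c(30, 31), 2, 1, dimnames = list(c("S1", "S2"), "A"))
  q2 <- relative_quantities(toy_ct_table(m2), efficiency = 1.9)
  expect_equal(unname(q2[, "A"]), c(1, 1 / 1.9))

  expect_error(relative_quantities(toy_ct_table(m), efficiency = 1),
               "efficiency")
  expect_error(relative_quantities(toy_ct_table(m), efficiency = 0.9),
               "efficiency")
})

test_that("geNorm M values match the brute-force pairwise oracle", {
  q <- make_toy_q(seed = 101)
  rep <- genorm_stability(q)
  oracle <- oracle_genorm_m(q)
  expect_equal(setNames(rep$score, rep$gene)[names(oracle)], oracle,
               tolerance = 1e-12)
})

test_that("geNorm requires 3 genes; constant-difference pair has zero
           pairwise variation", {
  m <- matrix(c(20, 22, 24, 23, 25, 27), 3, 2,
              dimnames = list(paste0("S", 1:3), c("A", "B")))
  q2 <- relative_quantities(toy_ct_table(m))
  expect_error(genorm_stability(q2), "3 genes")
  # with a third (noisy) gene, the constant-offset pair A,B survive last
  set.seed(5)
  m3 <- cbind(m, C = m[, "A"] + rnorm(3, sd = 2))
  m3[m3 <= 0 | m3 >= 40] <- 30
  q3 <- relative_quantities(toy_ct_table(m3))
  lq <- log2(q3)
  expect_equal(sd(lq[, "A"] - lq[, "B"]), 0, tolerance = 1e-12)
  rep3 <- genorm_stability(q3)
  expect_equal(sort(rep3$gene[rep3$rank < 2]), c("A", "B"))
})

test_that("duplicating a gene column makes the pair the final survivors", {
  set.seed(77)
  m <- matrix(round(runif(5 * 3, 20, 32), 2), 5, 3,
              dimnames = list(sprintf("S%d", 1:5), c("A", "B", "C")))
  m <- cbind(m, Adup = m[, "A"])
  q <- relative_quantities(toy_ct_table(m))
  rep <- genorm_stability(q)
  expect_equal(sort(rep$gene[rep$rank < 2]), c("A", "Adup"))
})

test_that("NormFinder matches the step-by-step Andersen oracle", {
  set.seed(202)
  n_per <- 4
  groups <- rep(c("bacterial", "viral"), each = n_per)
  m <- matrix(round(runif(2 * n_per * 3, 22, 30), 2), 2 * n_per, 3,
              dimnames = list(sprintf("S%d", 1:(2 * n_per)),
                              c("A", "B", "C")))
  q <- relative_quantities(toy_ct_table(m, groups))
  rep <- normfinder_stability(q, groups)
  oracle <- oracle_normfinder_rho(q, groups)
  expect_equal(setNames(rep$score, rep$gene)[names(oracle)], oracle,
               tolerance = 1e-12)
})

test_that("NormFinder gives stability 0 to a deterministic zero-variance
           fixture and is invariant to gene-level constant shifts", {
  # gene Z constant; genes B, C carry exactly opposing residuals so the
  # per-sample mean is flat and Z's intragroup variance estimate is zero;
  # group means identical so the bias term vanishes too
  n_per <- 4
  groups <- rep(c("bacterial", "viral"), each = n_per)
  eps <- c(0.3, -0.1, -0.4, 0.2)
  mb <- cbind(Z = rep(25, n_per), B = 27 + eps, C = 29 - eps)
  mv <- cbind(Z = rep(25, n_per), B = 27 + rev(eps), C = 29 - rev(eps))
  m <- rbind(mb, mv)
  rownames(m) <- sprintf("S%d", 1:(2 * n_per))
  q <- relative_quantities(toy_ct_table(m, groups))
  rep <- normfinder_stability(q, groups)
  expect_equal(rep$score[rep$gene == "Z"], 0, tolerance = 1e-12)
  expect_equal(min(rep$rank), rep$rank[rep$gene == "Z"])

  # adding a constant to one gene's Ct in ALL samples leaves rho unchanged
  set.seed(303)
  m2 <- matrix(round(runif(8 * 3, 22, 30), 2), 8, 3,
               dimnames = list(sprintf("S%d", 1:8), c("A", "B", "C")))
  q2 <- relative_quantities(toy_ct_table(m2, groups))
  m3 <- m2
  m3[, "B"] <- m3[, "B"] + 3
  q3 <- relative_quantities(toy_ct_table(m3, groups))
  r2 <- normfinder_stability(q2, groups)
  r3 <- normfinder_stability(q3, groups)
  expect_equal(r2$score, r3$score, tolerance = 1e-10)
})

test_that("NormFinder grouped variant rejects singleton groups unless a
           fallback is requested", {
  groups <- c("bacterial", "viral", "viral", "viral")
  m <- matrix(round(runif(4 * 3, 22, 30), 2), 4, 3,
              dimnames = list(sprintf("S%d", 1:4), c("A", "B", "C")))
  q <- relative_quantities(toy_ct_table(m, groups))
  expect_error(normfinder_stability(q, groups), ">= 2 samples")
  expect_warning(rep <- normfinder_stability(q, groups,
                                             fallback_ungrouped = TRUE),
                 "ungrouped")
  expect_s3_class(rep, "stability_report")
})

test_that("BestKeeper statistics match a hand-computed 2x3 oracle", {
  m <- matrix(c(20, 22, 24,
                28, 27, 29), 3, 2,
              dimnames = list(paste0("S", 1:3), c("A", "B")))
  rep <- bestkeeper_stats(toy_ct_table(m))
  det <- attr(rep, "details")
  # mean absolute deviation around the mean
  expect_equal(det$sd[det$gene == "A"], mean(abs(c(20, 22, 24) - 22)))
  expect_equal(det$sd[det$gene == "B"], mean(abs(c(28, 27, 29) - 28)))
  expect_equal(det$geo_mean[det$gene == "A"], prod(c(20, 22, 24))^(1 / 3))
  idx <- sqrt(c(20 * 28, 22 * 27, 24 * 29))
  expect_equal(det$r[det$gene == "A"], cor(c(20, 22, 24), idx))
  expect_equal(det$r[det$gene == "B"], cor(c(28, 27, 29), idx))
  # classic SD option
  cl <- attr(bestkeeper_stats(toy_ct_table(m), sd_type = "classic"),
             "details")
  expect_equal(cl$sd[cl$gene == "A"], sd(c(20, 22, 24)))
})

test_that("BestKeeper: constant gene ranks first; engineered SD ladder is
           recovered in expectation", {
  set.seed(9)
  m <- cbind(K = rep(25, 6),
             N = 25 + rnorm(6))
  m <- cbind(m, L = 25 + rnorm(6, sd = 2))
  rownames(m) <- sprintf("S%d", 1:6)
  rep <- bestkeeper_stats(toy_ct_table(m))
  expect_equal(rep$score[rep$gene == "K"], 0)
  expect_equal(rep$rank[rep$gene == "K"], 1)

  sds <- c(PGK1 = 0.843, GUSB = 0.907, TBP = 0.997, GAPDH = 1.200,
           ACTB = 1.483)
  set.seed(123)
  n <- 200
  m2 <- sapply(names(sds), function(g) 26 + rnorm(n, sd = sds[g]))
  rownames(m2) <- sprintf("S%03d", 1:n)
  rep2 <- bestkeeper_stats(toy_ct_table(m2))
  expect_equal(rep2$gene[order(rep2$rank)],
               c("PGK1", "GUSB", "TBP", "GAPDH", "ACTB"))
  expect_error(
    bestkeeper_stats(toy_ct_table(
      matrix(c(-1, 20, 20, 20), 2, 2,
             dimnames = list(c("S1", "S2"), c("A", "B"))), NULL)),
    "(nonpositive|0, cycle_cap)")
})

test_that("comparative delta-Ct scores equal the brute-force oracle and
           cancel per-sample offsets", {
  set.seed(404)
  m <- matrix(round(runif(4 * 3, 22, 30), 2), 4, 3,
              dimnames = list(sprintf("S%d", 1:4), c("A", "B", "C")))
  rep <- delta_ct_stability(toy_ct_table(m))
  oracle <- oracle_delta_ct_scores(m)
  expect_equal(setNames(rep$score, rep$gene)[names(oracle)], oracle,
               tolerance = 1e-12)
  # per-sample global offset cancels in every pairwise difference
  off <- c(1.3, -0.7, 0.2, 2.1)
  rep_off <- delta_ct_stability(toy_ct_table(m + off))
  expect_equal(rep_off$score, rep$score, tolerance = 1e-12)
})

test_that("duplicated gene lowers both copies' delta-Ct scores relative to
           an uncorrelated substitute", {
  set.seed(505)
  base <- matrix(round(runif(6 * 2, 22, 30), 2), 6, 2,
                 dimnames = list(sprintf("S%d", 1:6), c("A", "B")))
  dup <- cbind(base, A2 = base[, "A"])
  unc <- cbind(base, A2 = round(runif(6, 22, 30), 2))
  r_dup <- delta_ct_stability(toy_ct_table(dup))
  r_unc <- delta_ct_stability(toy_ct_table(unc))
  for (g in c("A", "A2")) {
    expect_lt(r_dup$score[r_dup$gene == g], r_unc$score[r_unc$gene == g])
  }
})

test_that("comprehensive ranking is the geometric mean of ranks", {
  mk <- function(r) setNames(r, c("A", "B", "C", "D", "E"))
  all1 <- replicate(4, mk(1:5), simplify = FALSE)
  rep <- comprehensive_ranking(all1)
  expect_equal(setNames(rep$score, rep$gene)[c("A", "E")],
               c(A = 1, E = 5))
  expect_equal(rep$rank, 1:5)

  mixed <- list(mk(c(1, 2, 3, 4, 5)), mk(c(2, 1, 3, 4, 5)),
                mk(c(4, 2, 3, 1, 5)), mk(c(8, 2, 3, 4, 5)))
  rep2 <- comprehensive_ranking(mixed)
  expect_equal(rep2$score[rep2$gene == "A"], (1 * 2 * 4 * 8)^(1 / 4))
  expect_equal(rep2$score[rep2$gene == "A"], 2 * sqrt(2),
               tolerance = 1e-12)

  bad <- list(mk(1:5), setNames(1:5, c("A", "B", "C", "D", "X")))
  expect_error(comprehensive_ranking(bad), "different gene sets")

  # score bounded by min and max of the input ranks
  set.seed(606)
  for (i in 1:20) {
    rks <- replicate(4, mk(sample(5)), simplify = FALSE)
    rep3 <- comprehensive_ranking(rks)
    mat <- sapply(rks, function(r) r[rep3$gene])
    expect_true(all(rep3$score >= apply(mat, 1, min) - 1e-12))
    expect_true(all(rep3$score <= apply(mat, 1, max) + 1e-12))
  }
})

test_that("ranking correlation has unit diagonal, handles reversal and
           degenerate vectors", {
  v <- c(1, 2, 3, 4, 5)
  out <- ranking_correlation(list(a = v, b = rev(v), c = v))
  expect_equal(unname(diag(out$r)), rep(1, 3))
  expect_equal(out$r["a", "b"], -1)
  expect_equal(out$r["a", "c"], 1)
  expect_equal(out$r2["a", "b"], 1)

  x <- c(1.32, 1.41, 2.91, 3.72, 5.00)
  y <- c(1.1, 1.5, 2.2, 4.0, 4.9)
  out2 <- ranking_correlation(list(x = x, y = y))
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out2$r["x", "y"], num / den, tolerance = 1e-12)

  out3 <- ranking_correlation(list(a = v, flat = rep(2, 5)))
  expect_true(is.na(out3$r["a", "flat"]))
  expect_equal(out3$r["flat", "flat"], 1)
})

test_that("all four stability rankings are invariant to per-gene additive
           Ct offsets", {
  coh <- generate_cohort(default_paper_spec(), seed = 21)
  tab <- suppressWarnings(
    qc_replicates(coh$measurements, meta = coh$meta))$ct_table
  refs <- c("ACTB", "GAPDH", "PGK1", "GUSB", "TBP")
  base_tab <- ct_table(tab$ct[, refs], tab$meta)
  shift <- c(ACTB = 1.0, GAPDH = -2.0, PGK1 = 0.5, GUSB = 3.0, TBP = 0)
  shifted <- sweep(tab$ct[, refs], 2, -shift[refs], `+`)
  shift_tab <- ct_table(shifted, tab$meta)

  rank_of <- function(rep) setNames(rep$rank, rep$gene)[refs]
  q0 <- relative_quantities(base_tab)
  q1 <- relative_quantities(shift_tab)
  expect_equal(rank_of(genorm_stability(q0)),
               rank_of(genorm_stability(q1)))
  expect_equal(rank_of(normfinder_stability(q0, base_tab$meta)),
               rank_of(normfinder_stability(q1, shift_tab$meta)))
  expect_equal(rank_of(bestkeeper_stats(base_tab)),
               rank_of(bestkeeper_stats(shift_tab)))
  expect_equal(rank_of(delta_ct_stability(base_tab)),
               rank_of(delta_ct_stability(shift_tab)))
})

test_that("a gene with doubled noise SD is ranked last by all methods in
           at least 19 of 20 seeds at n = 50", {
  spec0 <- default_paper_spec()
  genes <- spec0$genes[spec0$genes$role == "reference", ]
  genes$bio_sd <- 0.9
  genes$bio_sd[genes$gene == "ACTB"] <- 1.8  # k = 2 noise multiplier
  # add one dummy target to satisfy the spec contract
  genes <- rbind(genes, data.frame(
    gene = "T1", role = "target", mean_bacterial = 30, mean_viral = 30,
    mean_control = 30, bio_sd = 1))
  hits <- 0L
  for (s in 1:20) {
    sp <- cohort_spec(17, 17, 16, genes, tech_sd = 0.15, offset_sd = 0.5)
    coh <- generate_cohort(sp, seed = 900 + s)
    tab <- suppressWarnings(
      qc_replicates(coh$measurements, meta = coh$meta))$ct_table
    cand <- ct_table(tab$ct[, genes$gene[genes$role == "reference"]],
                     tab$meta)
    q <- relative_quantities(cand)
    last_all <- all(vapply(list(
      genorm_stability(q),
      normfinder_stability(q, cand$meta),
      bestkeeper_stats(cand),
      delta_ct_stability(cand)
    ), function(rep) rep$gene[which.max(rep$rank)] == "ACTB", logical(1)))
    if (last_all) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("geNorm pairwise variation V(n/n+1) is finite and small when an
           extra stable gene adds nothing", {
  set.seed(31)
  n <- 40
  m <- sapply(1:4, function(i) 25 + rnorm(n, sd = 0.3))
  colnames(m) <- paste0("G", 1:4)
  rownames(m) <- sprintf("S%d", 1:n)
  v <- genorm_pairwise_variation(relative_quantities(toy_ct_table(m)))
  expect_equal(v$n, c(2, 3))
  expect_true(all(v$v < 0.15))
})
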