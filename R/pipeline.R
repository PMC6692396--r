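#' Pipeline configuration
#'
#' Collects everything \code{\link{run_pipeline}} needs: the input data (a
#' replicate-level measurement table plus metadata, e.g. from
#' \code{\link{read_ct_table}} or \code{\link{generate_cohort}}), the
#' reference-gene candidates, the two target genes, and evaluation
#' settings.
#'
#' @param measurements Replicate-level data frame (\code{sample_id, gene,
#'   replicate, ct, detected}).
#' @param meta Sample metadata (\code{sample_id, group}).
#' @param reference_candidates Candidate reference genes; default: every
#'   gene that is not a target.
#' @param targets Target genes, FAM89A first, IFI44L second.
#' @param n_references Number of top-ranked references used for
#'   normalization (default 3, the study's choice).
#' @param sd_threshold Replicate-SD QC threshold (default 0.5).
#' @param efficiency Amplification efficiency (default 2).
#' @param grouped_normfinder Use the grouped NormFinder variant (default
#'   TRUE).
#' @param positive ROC positive class (default \code{"viral"}).
#' @param call_positive Clinical positive call for PPV/NPV (default
#'   \code{"bacterial"}).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Root seed; per-stage seeds are derived from it and logged.
#' @param ci_level Confidence level (default 0.95).
#' @param log_base DRS log base (default 10).
#' @param out_dir Output directory, or \code{NULL} to skip writing files.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(measurements, meta,
                            reference_candidates = NULL,
                            targets = c("FAM89A", "IFI44L"),
                            n_references = 3, sd_threshold = 0.5,
                            efficiency = 2, grouped_normfinder = TRUE,
                            positive = "viral",
                            call_positive = "bacterial",
                            n_boot = 2000, seed = 1, ci_level = 0.95,
                            log_base = 10, out_dir = NULL) {
  genes <- unique(measurements$gene)
  if (is.null(reference_candidates)) {
    reference_candidates <- setdiff(genes, targets)
  }
  if (length(intersect(targets, reference_candidates)) > 0L) {
    stop("parameter error: targets cannot be reference candidates")
  }
  if (n_references > length(reference_candidates)) {
    stop("parameter error: n_references exceeds candidate count")
  }
  structure(list(measurements = measurements, meta = meta,
                 reference_candidates = reference_candidates,
                 targets = targets, n_references = n_references,
                 sd_threshold = sd_threshold, efficiency = efficiency,
                 grouped_normfinder = grouped_normfinder,
                 positive = positive, call_positive = call_positive,
                 n_boot = n_boot, seed = seed, ci_level = ci_level,
                 log_base = log_base, out_dir = out_dir),
            class = "pipeline_config")
}

# deterministic per-stage seed derivation from the root seed
.stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1013 * k) %% 2147483647L)
}

#' Run the full DRS analysis pipeline
#'
#' Stages: replicate QC and aggregation; reference-gene stability by all
#' four methods plus the comprehensive geometric-mean ranking; selection of
#' the top-k references; delta-Ct for both targets; 2^-ddCt fold change
#' against the control group (when present); two-transcript and
#' one-transcript DRS; ROC/AUC, Youden cut-point, bootstrap CIs and
#' predictive values on the viral-vs-bacterial contrast; and DRS stability
#' across single- and multi-reference options. Deterministic given the
#' config and its seed. When \code{out_dir} is set, per-stage CSV/JSON
#' reports and a JSON manifest are written.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return List of class \code{pipeline_result} with elements \code{qc},
#'   \code{stability} (per-method reports + comprehensive),
#'   \code{references} (chosen trio), \code{delta_ct}, \code{fold_change},
#'   \code{drs} (both variants), \code{performance} (both variants),
#'   \code{reference_option_aucs}, \code{drs_stability}, \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- character(0)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  qc <- run_stage("qc_replicates", qc_replicates(
    config$measurements, meta = config$meta,
    sd_threshold = config$sd_threshold))
  tab <- qc$ct_table
  stages <- c(stages, "qc_replicates")

  cand_tab <- ct_table(
    tab$ct[, config$reference_candidates, drop = FALSE], tab$meta)
  stability <- run_stage("stability", {
    q <- relative_quantities(cand_tab, config$efficiency)
    groups <- if (config$grouped_normfinder) cand_tab$meta else NULL
    reports <- list(
      geNorm = genorm_stability(q),
      NormFinder = normfinder_stability(q, groups),
      BestKeeper = bestkeeper_stats(cand_tab),
      deltaCt = delta_ct_stability(cand_tab)
    )
    reports$comprehensive <- comprehensive_ranking(reports[1:4])
    reports
  })
  stages <- c(stages, "stability")

  comp <- stability$comprehensive
  refs <- comp$gene[order(comp$rank, comp$gene)][
    seq_len(config$n_references)]
  stages <- c(stages, "reference_selection")

  fam <- config$targets[1L]
  ifi <- config$targets[2L]
  dct_fam <- run_stage("delta_ct", delta_ct(tab, fam, refs))
  dct_ifi <- run_stage("delta_ct", delta_ct(tab, ifi, refs))
  stages <- c(stages, "delta_ct")

  fc <- NULL
  if (!is.null(tab$meta) && "control" %in% tab$meta$group) {
    fc <- run_stage("fold_change", list(
      fam89a = fold_change(dct_fam, "control"),
      ifi44l = fold_change(dct_ifi, "control")
    ))
    stages <- c(stages, "fold_change")
  }

  drs <- run_stage("drs", list(
    two_transcript = drs_two_transcript(dct_fam, dct_ifi,
                                        base = config$log_base),
    one_transcript = drs_one_transcript(dct_ifi, base = config$log_base)
  ))
  stages <- c(stages, "drs")

  vb <- function(d) d[d$group %in% c("viral", "bacterial"), ]
  perf <- run_stage("performance", list(
    two_transcript = evaluate_performance(
      vb(drs$two_transcript), positive = config$positive,
      call_positive = config$call_positive, n_boot = config$n_boot,
      seed = .stage_seed(config$seed, 1L), level = config$ci_level),
    one_transcript = evaluate_performance(
      vb(drs$one_transcript), positive = config$positive,
      call_positive = config$call_positive, n_boot = config$n_boot,
      seed = .stage_seed(config$seed, 2L), level = config$ci_level)
  ))
  stages <- c(stages, "performance")

  ref_options <- reference_options(refs, config$reference_candidates,
                                   comp)
  stab <- run_stage("drs_stability", {
    skipped <- character(0)
    drs_by_option <- list()
    for (oname in names(ref_options)) {
      # a reference option can push delta-Ct past the -offset log-domain
      # bound for extreme samples; such options are excluded and recorded
      d <- tryCatch(
        drs_two_transcript(delta_ct(tab, fam, ref_options[[oname]]),
                           delta_ct(tab, ifi, ref_options[[oname]]),
                           base = config$log_base),
        error = function(e) {
          warning("reference option '", oname, "' skipped: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(d)) skipped <- c(skipped, oname)
      else drs_by_option[[oname]] <- d
    }
    if (length(drs_by_option) < 2L) {
      stop("fewer than 2 usable reference options")
    }
    common <- Reduce(intersect, lapply(drs_by_option,
                                       function(d) d$sample_id))
    drs_by_option <- lapply(drs_by_option, function(d) {
      d[match(common, d$sample_id), ]
    })
    aucs <- vapply(drs_by_option, function(d) {
      roc_and_auc(vb(d), positive = config$positive)$auc
    }, numeric(1))
    list(matrix = drs_stability_matrix(drs_by_option),
         reference_option_aucs = aucs, skipped_options = skipped)
  })
  stages <- c(stages, "drs_stability")

  manifest <- list(
    package_version = as.character(utils::packageVersion("qpcrDRS")),
    seed = config$seed,
    stage_seeds = stats::setNames(
      vapply(1:2, function(k) .stage_seed(config$seed, k), integer(1)),
      c("performance_two_transcript", "performance_one_transcript")),
    stages = stages,
    references = refs,
    reference_options = lapply(ref_options, identity),
    skipped_reference_options = stab$skipped_options,
    n_samples = nrow(tab$ct),
    config_hash = .config_hash(config)
  )
  result <- structure(list(
    qc = qc$qc_report, ct_table = tab, stability = stability,
    references = refs, delta_ct = list(fam89a = dct_fam,
                                       ifi44l = dct_ifi),
    fold_change = fc, drs = drs, performance = perf,
    reference_option_aucs = stab$reference_option_aucs,
    drs_stability = stab$matrix, manifest = manifest
  ), class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    write_pipeline_reports(result, config$out_dir)
  }
  result
}

#' Reference-gene option set for the DRS stability analysis
#'
#' Builds the Table-2-style set of normalization options: every single
#' candidate gene, plus the nested multi-gene combinations of the
#' comprehensive ranking (top-2, top-3, ..., up to one less than the full
#' candidate panel).
#'
#' @param refs Chosen top references (unused; kept for clarity of call
#'   sites).
#' @param candidates All candidate genes.
#' @param comprehensive Comprehensive \code{stability_report}.
#' @return Named list of character vectors.
#' @export
reference_options <- function(refs, candidates, comprehensive) {
  ranked <- comprehensive$gene[order(comprehensive$rank,
                                     comprehensive$gene)]
  single <- stats::setNames(as.list(candidates), candidates)
  multi <- list()
  for (k in 2:(length(ranked) - 1L)) {
    rr <- ranked[seq_len(k)]
    multi[[paste(rr, collapse = "-")]] <- rr
  }
  c(single, multi)
}

# stable content hash of the config (polynomial rolling hash mod 2^31-1
# over a deparsed copy, measurements included); manifest provenance only
.config_hash <- function(config) {
  x <- config
  x$out_dir <- NULL
  s <- paste(utils::capture.output(utils::str(x, digits.d = 17)),
             collapse = "\n")
  bytes <- utf8ToInt(s)
  m <- 2147483647
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% m
  sprintf("%08x", h)
}

#' Write pipeline reports to disk
#'
#' Emits per-stage CSV/JSON files plus \code{manifest.json}. Numeric JSON
#' output is written with full precision so repeated runs with the same
#' config are byte-identical.
#'
#' @param result A \code{pipeline_result}.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
write_pipeline_reports <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wjson <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <<- c(files, p)
  }
  wcsv(result$qc, "qc_report.csv")
  stab <- do.call(rbind, lapply(names(result$stability), function(m) {
    r <- result$stability[[m]]
    data.frame(gene = r$gene, method = m, score = r$score, rank = r$rank,
               stringsAsFactors = FALSE)
  }))
  wcsv(stab, "stability.csv")
  wcsv(rbind(
    cbind(target = attr(result$delta_ct$fam89a, "target"),
          result$delta_ct$fam89a),
    cbind(target = attr(result$delta_ct$ifi44l, "target"),
          result$delta_ct$ifi44l)
  ), "delta_ct.csv")
  if (!is.null(result$fold_change)) {
    wcsv(rbind(
      cbind(target = attr(result$fold_change$fam89a, "target"),
            result$fold_change$fam89a),
      cbind(target = attr(result$fold_change$ifi44l, "target"),
            result$fold_change$ifi44l)
    ), "fold_change.csv")
  }
  drs_df <- do.call(rbind, lapply(names(result$drs), function(v) {
    d <- result$drs[[v]]
    data.frame(sample_id = d$sample_id, group = d$group, variant = v,
               score = d$score,
               refs = paste(attr(d, "refs"), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  wcsv(drs_df, "drs.csv")
  perf_json <- lapply(result$performance, function(p) {
    p$roc <- NULL
    p$replicates <- NULL
    unclass(p)
  })
  wjson(perf_json, "performance.json")
  wcsv(result$performance$two_transcript$roc$roc, "roc_two_transcript.csv")
  wjson(list(
    reference_option_aucs = as.list(result$reference_option_aucs),
    r2 = as.data.frame(result$drs_stability$r2),
    kruskal = result$drs_stability$kruskal,
    games_howell = result$drs_stability$games_howell
  ), "drs_stability.json")
  wjson(result$manifest, "manifest.json")
  invisible(files)
}
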