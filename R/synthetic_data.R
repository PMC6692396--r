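#' Specify a synthetic qPCR cohort
#'
#' Describes the generative model of a febrile-children qPCR cohort: three
#' clinical groups (bacterial, viral, control), a gene panel with per-group
#' mean Ct and between-sample biological SD per gene, triplicate technical
#' noise, and a per-sample global Ct offset that models RNA-input
#' variation (removed exactly by delta-Ct normalization).
#'
#' Sampling model per sample s and gene g:
#' \deqn{Ct_{sgr} = \mu_{g,group(s)} + b_{sg} + o_s + e_{sgr}}
#' with biological effect \eqn{b_{sg} \sim N(0, bio\_sd_g)}, global offset
#' \eqn{o_s \sim N(0, offset\_sd)} and technical replicate noise
#' \eqn{e_{sgr} \sim N(0, tech\_sd)}. Replicates at or above the cycle cap
#' are censored as undetected.
#'
#' @param n_bacterial,n_viral,n_control Group sizes.
#' @param genes Data frame with columns \code{gene, role} (\code{reference}
#'   or \code{target}), \code{mean_bacterial, mean_viral, mean_control}
#'   (Ct), \code{bio_sd} (between-sample SD, Ct units).
#' @param tech_sd Technical replicate SD (Ct units).
#' @param offset_sd SD of the per-sample global Ct offset (Ct units).
#' @param n_replicates Technical replicates per (sample, gene).
#' @param cycle_cap PCR cycle cap; larger Ct values are censored.
#' @return Object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_bacterial, n_viral, n_control, genes,
                        tech_sd = 0.15, offset_sd = 0.5,
                        n_replicates = 3, cycle_cap = 40) {
  stopifnot(n_bacterial >= 0, n_viral >= 0, n_control >= 0,
            tech_sd >= 0, offset_sd >= 0, n_replicates >= 1,
            cycle_cap > 0)
  need <- c("gene", "role", "mean_bacterial", "mean_viral",
            "mean_control", "bio_sd")
  if (!all(need %in% names(genes))) {
    stop("parameter error: genes must have columns ",
         paste(need, collapse = ", "))
  }
  if (any(genes$bio_sd < 0)) stop("parameter error: negative bio_sd")
  mu <- as.matrix(genes[, c("mean_bacterial", "mean_viral",
                            "mean_control")])
  if (any(mu <= 0 | mu >= cycle_cap)) {
    stop("parameter error: group mean Ct must lie in (0, cycle_cap)")
  }
  if (sum(genes$role == "reference") < 2L ||
      sum(genes$role == "target") < 1L) {
    stop("parameter error: need >= 2 reference and >= 1 target gene")
  }
  structure(list(n_bacterial = n_bacterial, n_viral = n_viral,
                 n_control = n_control, genes = genes, tech_sd = tech_sd,
                 offset_sd = offset_sd, n_replicates = n_replicates,
                 cycle_cap = cycle_cap),
            class = "cohort_spec")
}

#' Default cohort specification calibrated to the study design
#'
#' Returns the generator defaults that emulate the study cohort:
#' \itemize{
#'   \item group sizes 14 bacterial / 11 viral / 10 control (n = 35);
#'   \item five candidate reference genes spanning mean Ct 21.6 (ACTB,
#'     highest expressed) to 29.7 (TBP, lowest expressed), with
#'     between-sample SDs on the reported stability ladder
#'     PGK1 0.843 < GUSB 0.907 < TBP 0.997 < GAPDH 1.200 < ACTB 1.483
#'     (identical means across groups: reference genes are condition
#'     independent by assumption);
#'   \item FAM89A, a low-expressed target (overall mean Ct 33.11) mildly
#'     up-regulated in bacterial samples (group mean 1.5 cycles below the
#'     others), biological SD 2.0;
#'   \item IFI44L, a high-expressed target (overall mean Ct 27.67) strongly
#'     up-regulated in viral samples (group mean 5 cycles below the
#'     others), biological SD 1.5;
#'   \item triplicates with technical SD 0.15, per-sample global offset SD
#'     0.5, cycle cap 40.
#' }
#' Group means of the targets are chosen so the weighted overall means
#' reproduce 33.11 / 27.67 given the group sizes, and so the resulting
#' two-transcript DRS medians land near the reported 0.104 (bacterial) and
#' 0.315 (viral).
#'
#' @return A \code{\link{cohort_spec}}.
#' @export
default_paper_spec <- function() {
  genes <- data.frame(
    gene = c("ACTB", "GAPDH", "PGK1", "GUSB", "TBP", "FAM89A", "IFI44L"),
    role = c(rep("reference", 5), "target", "target"),
    mean_bacterial = c(21.6, 23.5, 25.0, 27.5, 29.7, 32.21, 29.2414),
    mean_viral     = c(21.6, 23.5, 25.0, 27.5, 29.7, 33.71, 24.2414),
    mean_control   = c(21.6, 23.5, 25.0, 27.5, 29.7, 33.71, 29.2414),
    bio_sd = c(1.483, 1.200, 0.843, 0.907, 0.997, 2.0, 1.5),
    stringsAsFactors = FALSE
  )
  cohort_spec(n_bacterial = 14, n_viral = 11, n_control = 10,
              genes = genes, tech_sd = 0.15, offset_sd = 0.5,
              n_replicates = 3, cycle_cap = 40)
}

#' Generate a synthetic qPCR cohort
#'
#' Draws a cohort from a \code{\link{cohort_spec}} (see its help for the
#' sampling model). Deterministic given \code{seed}.
#'
#' @param spec A \code{cohort_spec}.
#' @param seed Integer seed.
#' @return List with \code{measurements} (replicate-level data frame as
#'   from \code{\link{read_ct_table}}), \code{meta} (sample metadata) and
#'   \code{truth} (latent per-sample offsets and noise-free biological Ct
#'   values).
#' @export
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  groups <- rep(c("bacterial", "viral", "control"),
                c(spec$n_bacterial, spec$n_viral, spec$n_control))
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  meta <- data.frame(sample_id = ids, group = groups,
                     stringsAsFactors = FALSE)
  genes <- spec$genes
  offsets <- stats::rnorm(n, 0, spec$offset_sd)
  bio <- matrix(NA_real_, n, nrow(genes),
                dimnames = list(ids, genes$gene))
  for (g in seq_len(nrow(genes))) {
    mu_by_group <- c(bacterial = genes$mean_bacterial[g],
                     viral = genes$mean_viral[g],
                     control = genes$mean_control[g])
    bio[, g] <- mu_by_group[groups] + stats::rnorm(n, 0, genes$bio_sd[g]) +
      offsets
  }
  reps <- spec$n_replicates
  meas <- expand.grid(replicate = seq_len(reps), gene = genes$gene,
                      sample_id = ids, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("sample_id", "gene",
                                                  "replicate")]
  latent <- bio[cbind(meas$sample_id, meas$gene)]
  ct <- latent + stats::rnorm(nrow(meas), 0, spec$tech_sd)
  detected <- ct < spec$cycle_cap & ct > 0
  ct[!detected] <- NA_real_
  meas$ct <- ct
  meas$detected <- detected
  list(measurements = meas, meta = meta,
       truth = list(offsets = stats::setNames(offsets, ids),
                    biological_ct = bio, seed = seed, spec = spec))
}

#' Generate a synthetic expression-intensity matrix
#'
#' Stand-in for microarray/RNA-seq validation inputs: per-gene additive
#' shifts on a log-intensity scale with Gaussian noise. FAM89A gets a
#' (weak) positive shift in bacterial samples, IFI44L a (strong) positive
#' shift in viral samples.
#'
#' @param n_bacterial,n_viral Group sizes.
#' @param fam89a_shift Log-intensity increase of FAM89A in bacterial
#'   samples (default 0.5).
#' @param ifi44l_shift Log-intensity increase of IFI44L in viral samples
#'   (default 2).
#' @param baseline Baseline log-intensity for both genes (default 8).
#' @param noise_sd Per-sample noise SD on the log scale (default 1).
#' @param seed Integer seed.
#' @return List with \code{expr} (samples x 2 matrix, columns FAM89A and
#'   IFI44L) and \code{meta}.
#' @export
generate_expression_matrix <- function(n_bacterial, n_viral,
                                       fam89a_shift = 0.5,
                                       ifi44l_shift = 2,
                                       baseline = 8, noise_sd = 1,
                                       seed = 1) {
  set.seed(seed)
  groups <- rep(c("bacterial", "viral"), c(n_bacterial, n_viral))
  n <- length(groups)
  ids <- sprintf("E%03d", seq_len(n))
  fam <- baseline + fam89a_shift * (groups == "bacterial") +
    stats::rnorm(n, 0, noise_sd)
  ifi <- baseline + ifi44l_shift * (groups == "viral") +
    stats::rnorm(n, 0, noise_sd)
  expr <- cbind(FAM89A = fam, IFI44L = ifi)
  rownames(expr) <- ids
  list(expr = expr,
       meta = data.frame(sample_id = ids, group = groups,
                         stringsAsFactors = FALSE))
}
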