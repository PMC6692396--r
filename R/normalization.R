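#' Delta-Ct normalization of a target gene
#'
#' Per-sample normalized expression: \eqn{\Delta Ct = Ct_{target} -
#' mean(Ct_{refs})}. The arithmetic mean of reference Ct values equals the
#' geometric mean of their linear quantities, the geNorm convention. Sign
#' convention: target minus reference, so a HIGHER delta-Ct means LOWER
#' expression (Ct scale is inverted relative to abundance). Samples missing
#' the target or any reference Ct are dropped with a message.
#'
#' @param ct A \code{\link{ct_table}}.
#' @param target Target gene symbol.
#' @param refs Character vector of reference gene symbols (non-empty, no
#'   duplicates, must not contain the target).
#' @return A data frame \code{sample_id, group, delta_ct} of class
#'   \code{delta_ct}, with attributes \code{target} and \code{refs}.
#' @export
delta_ct <- function(ct, target, refs) {
  stopifnot(inherits(ct, "ct_table"))
  if (length(refs) == 0L) stop("parameter error: empty reference set")
  if (anyDuplicated(refs)) {
    stop("parameter error: duplicate reference gene(s): ",
         paste(unique(refs[duplicated(refs)]), collapse = ", "))
  }
  if (target %in% refs) {
    stop("parameter error: target gene cannot be a reference")
  }
  missing_genes <- setdiff(c(target, refs), colnames(ct$ct))
  if (length(missing_genes) > 0L) {
    stop("gene(s) not in table: ", paste(missing_genes, collapse = ", "))
  }
  ref_mean <- rowMeans(ct$ct[, refs, drop = FALSE])
  dct <- ct$ct[, target] - ref_mean
  ok <- !is.na(dct)
  if (any(!ok)) {
    message("delta_ct: dropped ", sum(!ok), " sample(s) with missing Ct: ",
            paste(rownames(ct$ct)[!ok], collapse = ", "))
  }
  out <- data.frame(
    sample_id = rownames(ct$ct)[ok],
    group = if (!is.null(ct$meta)) ct$meta$group[ok] else NA_character_,
    delta_ct = unname(dct[ok]),
    stringsAsFactors = FALSE
  )
  attr(out, "target") <- target
  attr(out, "refs") <- refs
  class(out) <- c("delta_ct", "data.frame")
  out
}

#' Fold change by the 2^-ddCt method
#'
#' \eqn{\Delta\Delta Ct} is each sample's delta-Ct minus the mean delta-Ct
#' of the calibrator group; the fold change versus the calibrator is
#' \eqn{2^{-\Delta\Delta Ct}}.
#'
#' @param dct A \code{\link{delta_ct}} result.
#' @param calibrator Group label used as calibrator (default
#'   \code{"control"}).
#' @param meta Optional metadata to supply group labels when \code{dct}
#'   lacks them.
#' @return Data frame \code{sample_id, group, delta_ct, delta_delta_ct,
#'   fold_change} with attribute \code{calibrator}.
#' @export
fold_change <- function(dct, calibrator = "control", meta = NULL) {
  grp <- dct$group
  if (all(is.na(grp)) && !is.null(meta)) {
    grp <- meta$group[match(dct$sample_id, meta$sample_id)]
  }
  cal <- grp == calibrator & !is.na(dct$delta_ct)
  if (!any(cal, na.rm = TRUE)) {
    stop("parameter error: calibrator group '", calibrator,
         "' has no sample with defined delta-Ct")
  }
  ddct <- dct$delta_ct - mean(dct$delta_ct[which(cal)])
  out <- data.frame(
    sample_id = dct$sample_id,
    group = grp,
    delta_ct = dct$delta_ct,
    delta_delta_ct = ddct,
    fold_change = 2^(-ddct),
    stringsAsFactors = FALSE
  )
  attr(out, "calibrator") <- calibrator
  attr(out, "target") <- attr(dct, "target")
  attr(out, "refs") <- attr(dct, "refs")
  out
}
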