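#' Two-transcript Disease Risk Score (qPCR scale)
#'
#' \eqn{DRS = \log(\Delta Ct_{FAM89A} + 10) - \log(\Delta Ct_{IFI44L} +
#' 10)} per sample. The +10 offset rescales delta-Ct to avoid negative
#' arguments before the log; it is a fixed constant of the method (the
#' published cut-points are only meaningful at offset 10), so overriding it
#' requires the explicit \code{offset} argument. The log base (default 10)
#' rescales all scores by a positive constant and leaves rankings, ROC
#' curves and AUC unchanged. On this scale viral samples score HIGH: high
#' IFI44L expression means low \eqn{Ct} hence low \eqn{\Delta Ct_{IFI44L}}.
#'
#' @param dct_fam89a,dct_ifi44l \code{\link{delta_ct}} results for FAM89A
#'   and IFI44L, computed against the same reference set.
#' @param base Logarithm base (default 10).
#' @param offset Scale increment added to delta-Ct before the log (default
#'   10; change only deliberately).
#' @return Data frame \code{sample_id, group, score} of class
#'   \code{drs_result} with attributes \code{variant}, \code{refs},
#'   \code{base}, \code{offset}.
#' @export
drs_two_transcript <- function(dct_fam89a, dct_ifi44l, base = 10,
                               offset = 10) {
  if (!identical(sort(attr(dct_fam89a, "refs")),
                 sort(attr(dct_ifi44l, "refs")))) {
    stop("both delta-Ct vectors must use the same reference set")
  }
  common <- intersect(dct_fam89a$sample_id, dct_ifi44l$sample_id)
  f <- dct_fam89a[match(common, dct_fam89a$sample_id), ]
  i <- dct_ifi44l[match(common, dct_ifi44l$sample_id), ]
  .check_drs_domain(f$delta_ct, common, offset, "FAM89A")
  .check_drs_domain(i$delta_ct, common, offset, "IFI44L")
  score <- log(f$delta_ct + offset, base) - log(i$delta_ct + offset, base)
  .drs_result(common, f$group, score, "two_transcript_qpcr",
              attr(dct_fam89a, "refs"), base, offset)
}

#' One-transcript Disease Risk Score (IFI44L only, qPCR scale)
#'
#' \eqn{DRS = -\log(\Delta Ct_{IFI44L} + 10)}. The negative sign keeps the
#' score oriented like the two-transcript variant (higher = viral).
#'
#' @inheritParams drs_two_transcript
#' @return A \code{drs_result} with variant \code{one_transcript_qpcr}.
#' @export
drs_one_transcript <- function(dct_ifi44l, base = 10, offset = 10) {
  .check_drs_domain(dct_ifi44l$delta_ct, dct_ifi44l$sample_id, offset,
                    "IFI44L")
  score <- -log(dct_ifi44l$delta_ct + offset, base)
  .drs_result(dct_ifi44l$sample_id, dct_ifi44l$group, score,
              "one_transcript_qpcr", attr(dct_ifi44l, "refs"), base,
              offset)
}

.check_drs_domain <- function(dct, ids, offset, gene) {
  bad <- which(dct <= -offset)
  if (length(bad) > 0L) {
    stop("domain error: delta-Ct of ", gene, " <= -", offset,
         " for sample(s): ", paste(ids[bad], collapse = ", "))
  }
}

.drs_result <- function(sample_id, group, score, variant, refs, base,
                        offset) {
  out <- data.frame(sample_id = sample_id, group = group, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "variant") <- variant
  attr(out, "refs") <- refs
  attr(out, "base") <- base
  attr(out, "offset") <- offset
  class(out) <- c("drs_result", "data.frame")
  out
}

#' Disease Risk Score on an expression-intensity matrix
#'
#' Intensity-scale variant for validation on microarray/RNA-seq style
#' log-expression values, where higher values mean higher expression (the
#' opposite of the Ct scale). The two-transcript score
#' \eqn{expr_{FAM89A} - expr_{IFI44L}} is therefore HIGH in bacterial
#' samples, opposite in orientation to the qPCR-scale score. The
#' one-transcript score is taken as \eqn{-expr_{IFI44L}}, which shares that
#' bacterial-high orientation, so the two intensity variants agree with
#' each other and mirror the qPCR variants; the evaluation layer handles
#' score direction explicitly, so classification performance is unaffected.
#'
#' @param expr_fam89a,expr_ifi44l Named numeric vectors of per-sample
#'   log-intensities (names = sample ids); \code{expr_fam89a} may be
#'   \code{NULL} for the one-transcript variant.
#' @param variant \code{"two_transcript"} or \code{"one_transcript"}.
#' @param groups Optional metadata (\code{sample_id, group}) or vector of
#'   labels aligned with the expression vectors.
#' @return A \code{drs_result} with variant
#'   \code{two_transcript_intensity} or \code{one_transcript_intensity}.
#' @export
drs_expression_matrix <- function(expr_fam89a = NULL, expr_ifi44l,
                                  variant = c("two_transcript",
                                              "one_transcript"),
                                  groups = NULL) {
  variant <- match.arg(variant)
  ids <- names(expr_ifi44l)
  if (is.null(ids)) ids <- paste0("S", seq_along(expr_ifi44l))
  if (variant == "two_transcript") {
    if (is.null(expr_fam89a)) {
      stop("two-transcript intensity variant needs FAM89A values")
    }
    if (!is.null(names(expr_fam89a))) {
      expr_fam89a <- expr_fam89a[ids]
    }
    score <- unname(expr_fam89a - expr_ifi44l)
    tag <- "two_transcript_intensity"
  } else {
    score <- unname(-expr_ifi44l)
    tag <- "one_transcript_intensity"
  }
  grp <- NA_character_
  if (!is.null(groups)) {
    grp <- if (is.data.frame(groups)) {
      groups$group[match(ids, groups$sample_id)]
    } else as.character(groups)
  }
  .drs_result(ids, grp, score, tag, character(0), NA_real_, NA_real_)
}
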