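#' Read raw qPCR threshold-cycle measurements from CSV
#'
#' Parses replicate-level Ct values from a long- or wide-format CSV file.
#' Non-numeric Ct cells (e.g. \code{"Undetermined"}) and values at or above
#' the cycle cap are treated as undetected replicates: they carry no numeric
#' Ct and are excluded from downstream replicate means and SDs.
#'
#' @param path Path to a CSV file (RFC-4180, with header).
#' @param format \code{"long"}: columns \code{sample_id, gene, replicate, ct}
#'   and optionally \code{group}. \code{"wide"}: columns
#'   \code{sample_id, replicate} (optionally \code{group}) plus one column
#'   per gene.
#' @param meta Optional data frame with columns \code{sample_id} and
#'   \code{group}; overrides any group column in the Ct file.
#' @param cycle_cap Maximum PCR cycle; Ct values \code{>= cycle_cap} are
#'   censored as undetected. Default 40 (the standard 40-cycle program).
#'
#' @return A list with components:
#'   \describe{
#'     \item{measurements}{data frame \code{sample_id, gene, replicate, ct,
#'       detected}; \code{ct} is \code{NA} for undetected replicates.}
#'     \item{meta}{data frame \code{sample_id, group} or \code{NULL} when no
#'       group information is available.}
#'   }
#' @export
read_ct_table <- function(path, format = c("long", "wide"), meta = NULL,
                          cycle_cap = 40) {
  format <- match.arg(format)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (format == "long") {
    required <- c("sample_id", "gene", "replicate", "ct")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0L) {
      stop("format error: missing required column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    out <- data.frame(
      sample_id = raw$sample_id,
      gene = raw$gene,
      replicate = as.integer(raw$replicate),
      ct = .parse_ct(raw$ct, cycle_cap),
      stringsAsFactors = FALSE
    )
    file_meta <- if ("group" %in% names(raw)) {
      unique(data.frame(sample_id = raw$sample_id, group = raw$group,
                        stringsAsFactors = FALSE))
    } else NULL
  } else {
    required <- c("sample_id", "replicate")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0L) {
      stop("format error: missing required column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    gene_cols <- setdiff(names(raw), c("sample_id", "replicate", "group"))
    if (length(gene_cols) == 0L) stop("format error: no gene columns found")
    out <- do.call(rbind, lapply(gene_cols, function(g) {
      data.frame(sample_id = raw$sample_id, gene = g,
                 replicate = as.integer(raw$replicate),
                 ct = .parse_ct(raw[[g]], cycle_cap),
                 stringsAsFactors = FALSE)
    }))
    file_meta <- if ("group" %in% names(raw)) {
      unique(data.frame(sample_id = raw$sample_id, group = raw$group,
                        stringsAsFactors = FALSE))
    } else NULL
  }
  key <- paste(out$sample_id, out$gene, out$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("integrity error: duplicate (sample, gene, replicate) key(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }
  out$detected <- !is.na(out$ct)
  meta <- if (!is.null(meta)) meta else file_meta
  if (!is.null(meta)) meta <- validate_sample_meta(meta)
  rownames(out) <- NULL
  list(measurements = out, meta = meta)
}

# Non-numeric cells (e.g. "Undetermined") and Ct >= cycle cap -> NA.
.parse_ct <- function(x, cycle_cap) {
  ct <- suppressWarnings(as.numeric(x))
  ct[!is.na(ct) & (ct <= 0 | ct >= cycle_cap)] <- NA_real_
  ct
}

#' Validate a sample metadata table
#'
#' Checks that sample ids are unique and that each group label is one of
#' \code{viral}, \code{bacterial}, \code{control}.
#'
#' @param meta Data frame with columns \code{sample_id}, \code{group}.
#' @return The validated data frame (row names dropped, columns reordered).
#' @export
validate_sample_meta <- function(meta) {
  if (!all(c("sample_id", "group") %in% names(meta))) {
    stop("format error: meta must have columns sample_id and group")
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("integrity error: duplicate sample_id in metadata")
  }
  allowed <- c("viral", "bacterial", "control")
  bad <- setdiff(unique(meta$group), allowed)
  if (length(bad) > 0L) {
    stop("format error: unknown group label(s): ",
         paste(bad, collapse = ", "), " (allowed: ",
         paste(allowed, collapse = ", "), ")")
  }
  out <- data.frame(sample_id = as.character(meta$sample_id),
                    group = as.character(meta$group),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Replicate quality control and aggregation to a Ct table
#'
#' Aggregates replicate-level measurements to one Ct per (sample, gene) as
#' the arithmetic mean of detected replicates, after flagging entries whose
#' replicate standard deviation exceeds \code{sd_threshold}. The study
#' protocol repeats such assays; a reanalysis cannot, so by default failing
#' entries are masked as missing (set \code{on_fail = "keep"} to retain the
#' mean with a warning).
#'
#' @param measurements Replicate-level data frame as returned by
#'   \code{\link{read_ct_table}} (columns \code{sample_id, gene, replicate,
#'   ct, detected}).
#' @param meta Sample metadata (\code{sample_id}, \code{group}); optional.
#' @param sd_threshold Replicate SD threshold in Ct units (default 0.5).
#' @param sd_type \code{"sample"} (n-1 denominator, default) or
#'   \code{"population"} (n denominator).
#' @param on_fail \code{"mask"} (default) or \code{"keep"}.
#'
#' @return A list with \code{ct_table} (see \code{\link{ct_table}}) and
#'   \code{qc_report}, a data frame with one row per (sample, gene):
#'   \code{sample_id, gene, n_detected, n_total, mean_ct, sd_ct, pass,
#'   masked}.
#' @export
qc_replicates <- function(measurements, meta = NULL, sd_threshold = 0.5,
                          sd_type = c("sample", "population"),
                          on_fail = c("mask", "keep")) {
  sd_type <- match.arg(sd_type)
  on_fail <- match.arg(on_fail)
  stopifnot(sd_threshold > 0)
  sample_ids <- unique(measurements$sample_id)
  genes <- unique(measurements$gene)
  key <- interaction(factor(measurements$sample_id, levels = sample_ids),
                     factor(measurements$gene, levels = genes),
                     drop = FALSE, lex.order = FALSE)
  split_ct <- split(measurements$ct, key)
  grid <- expand.grid(sample_id = sample_ids, gene = genes,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  stats_list <- lapply(split_ct, function(cts) {
    det <- cts[!is.na(cts)]
    n <- length(det)
    m <- if (n >= 1L) mean(det) else NA_real_
    s <- if (n >= 2L) {
      if (sd_type == "sample") stats::sd(det)
      else sqrt(mean((det - m)^2))
    } else NA_real_
    c(n_detected = n, n_total = length(cts), mean_ct = m, sd_ct = s)
  })
  st <- do.call(rbind, stats_list)
  qc <- cbind(grid, as.data.frame(st))
  qc$pass <- is.na(qc$sd_ct) | qc$sd_ct <= sd_threshold
  qc$masked <- (qc$n_detected == 0L) | (!qc$pass & on_fail == "mask")
  if (any(!qc$pass) && on_fail == "keep") {
    warning(sum(!qc$pass), " (sample, gene) entr",
            if (sum(!qc$pass) == 1) "y" else "ies",
            " exceed the replicate SD threshold but were kept")
  }
  if (any(qc$n_detected == 0L)) {
    warning(sum(qc$n_detected == 0L),
            " (sample, gene) entr",
            if (sum(qc$n_detected == 0L) == 1) "y has" else "ies have",
            " no detected replicate; entry set missing")
  }
  ct <- matrix(NA_real_, nrow = length(sample_ids), ncol = length(genes),
               dimnames = list(sample_ids, genes))
  keep <- !qc$masked & qc$n_detected >= 1L
  ct[cbind(match(qc$sample_id[keep], sample_ids),
           match(qc$gene[keep], genes))] <- qc$mean_ct[keep]
  tab <- ct_table(ct, meta)
  rownames(qc) <- NULL
  list(ct_table = tab, qc_report = qc)
}

#' Construct a Ct table
#'
#' The pipeline's central container: a samples x genes matrix of aggregated
#' threshold-cycle values with optional group metadata. Missing entries are
#' \code{NA}.
#'
#' @param ct Numeric matrix, samples in rows (row names = sample ids),
#'   genes in columns (column names = gene symbols).
#' @param meta Optional data frame \code{sample_id, group}.
#' @param cycle_cap Upper bound for valid Ct values (default 40).
#' @return An object of class \code{ct_table}: a list with elements
#'   \code{ct} and \code{meta}.
#' @export
ct_table <- function(ct, meta = NULL, cycle_cap = 40) {
  stopifnot(is.matrix(ct), is.numeric(ct))
  if (is.null(rownames(ct)) || is.null(colnames(ct))) {
    stop("ct matrix must have sample row names and gene column names")
  }
  finite <- ct[!is.na(ct)]
  if (any(finite <= 0 | finite > cycle_cap)) {
    stop("ct values must lie in (0, cycle_cap]")
  }
  if (!is.null(meta)) {
    meta <- validate_sample_meta(meta)
    if (!all(rownames(ct) %in% meta$sample_id)) {
      stop("integrity error: samples missing from metadata: ",
           paste(setdiff(rownames(ct), meta$sample_id), collapse = ", "))
    }
    meta <- meta[match(rownames(ct), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(ct = ct, meta = meta), class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat("ct_table:", nrow(x$ct), "samples x", ncol(x$ct), "genes\n")
  if (!is.null(x$meta)) {
    tb <- table(x$meta$group)
    cat("groups:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  cat("missing entries:", sum(is.na(x$ct)), "\n")
  invisible(x)
}

#' Write / read an aggregated Ct table as CSV
#'
#' Values are serialized with 17 significant digits so a write/read round
#' trip is bit-exact.
#'
#' @param x A \code{ct_table}.
#' @param path Output CSV path.
#' @return \code{write_ct_table} returns \code{path} invisibly;
#'   \code{read_ct_matrix} returns a \code{ct_table}.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  df <- data.frame(sample_id = rownames(x$ct), stringsAsFactors = FALSE)
  df$group <- if (!is.null(x$meta)) x$meta$group else NA_character_
  for (g in colnames(x$ct)) {
    df[[g]] <- ifelse(is.na(x$ct[, g]), "", sprintf("%.17g", x$ct[, g]))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!"sample_id" %in% names(df)) {
    stop("format error: missing sample_id column")
  }
  gene_cols <- setdiff(names(df), c("sample_id", "group"))
  ct <- sapply(gene_cols, function(g) {
    v <- df[[g]]
    v[v == ""] <- NA_character_
    as.numeric(v)
  })
  ct <- matrix(ct, nrow = nrow(df),
               dimnames = list(df$sample_id, gene_cols))
  meta <- NULL
  if ("group" %in% names(df) && !all(is.na(df$group)) &&
      !all(df$group == "NA")) {
    meta <- data.frame(sample_id = df$sample_id, group = df$group,
                       stringsAsFactors = FALSE)
  }
  ct_table(ct, meta)
}
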