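#' Construct an expression matrix
#'
#' A thin S3 container around a numeric feature x sample matrix carrying a
#' flag for whether values are already on the log2 scale. Row names are
#' feature (gene or probe) identifiers, column names are sample identifiers;
#' identifiers are treated as opaque strings throughout (no probe-to-gene
#' collapsing is ever applied implicitly).
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   complete row and column names. All entries must be finite: missing
#'   values are rejected, not imputed.
#' @param is_log2 Logical flag; `TRUE` if `values` are log2 expression.
#' @return An object of class `expr_mat` (a numeric matrix with an
#'   `is_log2` attribute).
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' expression_matrix(m, is_log2 = FALSE)
#' @export
expression_matrix <- function(values, is_log2 = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs feature row names and sample column names",
         call. = FALSE)
  }
  if (nrow(values) < 1L) stop("need at least one feature", call. = FALSE)
  if (ncol(values) < 2L) stop("need at least two samples", call. = FALSE)
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f)) {
    stop("duplicate feature id(s): ", paste(dup_f, collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at feature '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
         call. = FALSE)
  }
  stopifnot(is.logical(is_log2), length(is_log2) == 1L, !is.na(is_log2))
  structure(values, is_log2 = is_log2, class = c("expr_mat", class(values)))
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d features x %d samples (%s scale)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "is_log2"))) "log2" else "linear"))
  invisible(x)
}

#' Query or set the log2-scale flag of an expression matrix
#' @param x An `expr_mat`.
#' @return Logical scalar.
#' @export
is_log2 <- function(x) isTRUE(attr(x, "is_log2"))

# strip class/attr to a plain matrix (internal)
as_plain_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "is_log2") <- NULL
  y
}

#' Read an expression matrix from tab-separated text
#'
#' Expects the layout used by GEO/firebrowse exports: first row sample ids,
#' first column feature ids, tab delimiters. Any non-numeric or missing cell
#' is an error naming its row and column; duplicated identifiers are errors.
#'
#' @param path Path to a TSV file.
#' @param is_log2 Whether the stored values are already log2-scaled.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, is_log2 = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          row.names = NULL)
  if (ncol(df) < 3L) stop("expression file needs >= 2 sample columns",
                          call. = FALSE)
  feats <- df[[1L]]
  dup <- unique(feats[duplicated(feats)])
  if (length(dup)) {
    stop("duplicate feature id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(df[-1L])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-numeric cell '%s' at feature '%s', sample '%s' in %s",
      vals[bad[1L], bad[2L]], feats[bad[1L]], colnames(vals)[bad[2L]], path),
      call. = FALSE)
  }
  dimnames(num) <- list(feats, colnames(vals))
  expression_matrix(num, is_log2 = is_log2)
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression()]; the pair round-trips valid files
#' cell-for-cell.
#'
#' @param x An `expr_mat`.
#' @param path Output path.
#' @param feature_col Header for the feature-id column.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path, feature_col = "feature_id") {
  stopifnot(inherits(x, "expr_mat"))
  m <- as_plain_matrix(x)
  df <- data.frame(feature_col = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform an expression matrix
#'
#' @param x An `expr_mat` on the linear scale.
#' @param offset Pseudo-value added before taking logs. Use 1 for count-like
#'   data and 0 for background-corrected microarray intensities.
#' @return The matrix with `values <- log2(values + offset)` and
#'   `is_log2 = TRUE`.
#' @export
log2_transform <- function(x, offset = 0) {
  stopifnot(inherits(x, "expr_mat"))
  if (is_log2(x)) stop("matrix is already on the log2 scale", call. = FALSE)
  m <- as_plain_matrix(x) + offset
  if (any(m <= 0)) {
    stop("nonpositive value after offset ", offset,
         "; log2 undefined", call. = FALSE)
  }
  expression_matrix(log2(m), is_log2 = TRUE)
}

#' Construct / validate a clinical table
#'
#' Per-sample survival and tissue annotations. `os_event` uses the
#' convention 1 = death observed, 0 = censored. Time units are carried as
#' opaque metadata and never converted.
#'
#' @param df Data frame with columns `sample_id`, `os_time`, `os_event`,
#'   `tissue` (values `"tumor"`/`"normal"`) and optionally `pair_id` linking
#'   each tumor to its matched normal.
#' @param time_units Free-text unit label (e.g. `"days"`, `"months"`).
#' @return The validated data frame, classed `clinical_tbl`, with a
#'   `time_units` attribute.
#' @export
clinical_table <- function(df, time_units = "days") {
  req <- c("sample_id", "os_time", "os_event", "tissue")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in clinical table", call. = FALSE)
  }
  if (any(!is.finite(df$os_time)) || any(df$os_time < 0)) {
    stop("os_time must be finite and >= 0", call. = FALSE)
  }
  if (!all(df$os_event %in% c(0, 1))) {
    stop("os_event must be coded 0 (censored) / 1 (death)", call. = FALSE)
  }
  if (!all(df$tissue %in% c("tumor", "normal"))) {
    stop("tissue must be 'tumor' or 'normal'", call. = FALSE)
  }
  if (!is.null(df$pair_id)) {
    has <- !is.na(df$pair_id)
    if (any(has)) {
      tab <- table(df$pair_id[has], df$tissue[has])
      if (!all(c("tumor", "normal") %in% colnames(tab)) || !all(tab == 1L)) {
        stop("each pair_id must link exactly one tumor and one normal sample",
             call. = FALSE)
      }
    }
  }
  structure(df, time_units = time_units,
            class = c("clinical_tbl", "data.frame"))
}

#' Read / write a clinical table (TSV)
#' @param path TSV path with header columns `sample_id`, `os_time`,
#'   `os_event`, `tissue` and optionally `pair_id`.
#' @inheritParams clinical_table
#' @return A `clinical_tbl`.
#' @export
read_clinical <- function(path, time_units = "days") {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  clinical_table(df, time_units = time_units)
}

#' @rdname read_clinical
#' @param x A `clinical_tbl`.
#' @export
write_clinical <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' MSigDB dialect: one set per line, fields tab-separated as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Lines with fewer than
#' three fields (i.e. no members) are errors reported with their line
#' number.
#'
#' @param path GMT file path.
#' @return A named list of character vectors (one per gene set), with set
#'   descriptions in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sets <- vector("list", length(lines))
  nm <- desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L) {
      stop(sprintf("GMT line %d has < 3 fields (no members)", i),
           call. = FALSE)
    }
    nm[i] <- f[1L]
    desc[i] <- f[2L]
    mem <- unique(f[-(1:2)])
    sets[[i]] <- mem
  }
  if (anyDuplicated(nm)) stop("duplicate gene-set names in GMT",
                              call. = FALSE)
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(desc, nm)
  sets
}

#' Write a gene-set collection as GMT
#' @param collection Named list of character vectors; descriptions taken
#'   from a `"descriptions"` attribute when present, else `"na"`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    members <- collection[[nm]]
    if (!length(members)) stop("gene set '", nm, "' is empty", call. = FALSE)
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write a pre-ranked RNK file
#'
#' Two-column tab-separated list (feature, statistic) sorted by the
#' statistic in descending order, ties broken by feature id so the file is
#' bit-stable — the input format pre-ranked enrichment tools consume.
#'
#' @param ranked Named numeric vector (names = feature ids) or two-column
#'   data frame `(feature, statistic)`.
#' @param path Output path.
#' @return Invisibly, the sorted data frame that was written.
#' @export
write_rnk <- function(ranked, path) {
  if (is.data.frame(ranked)) {
    stopifnot(ncol(ranked) >= 2L)
    feat <- as.character(ranked[[1L]])
    stat <- as.numeric(ranked[[2L]])
  } else {
    stopifnot(is.numeric(ranked), !is.null(names(ranked)))
    feat <- names(ranked)
    stat <- as.numeric(ranked)
  }
  if (any(!is.finite(stat))) {
    stop("non-finite ranking statistic for: ",
         paste(feat[!is.finite(stat)], collapse = ", "), call. = FALSE)
  }
  ord <- order(-stat, feat, method = "radix")
  out <- data.frame(feature = feat[ord], statistic = stat[ord],
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(out)
}

#' Align an expression matrix with a clinical table
#'
#' Restricts both objects to the intersection of their sample ids, in the
#' same order, and reports how many samples were dropped from each side.
#' Idempotent: aligning twice equals aligning once.
#'
#' @param expr An `expr_mat`.
#' @param clinical A `clinical_tbl`.
#' @return List with elements `expr`, `clinical`, `dropped_expr`,
#'   `dropped_clinical`.
#' @export
align_samples <- function(expr, clinical) {
  stopifnot(inherits(expr, "expr_mat"), inherits(clinical, "clinical_tbl"))
  common <- intersect(colnames(expr), clinical$sample_id)
  if (!length(common)) {
    stop("no overlap between expression and clinical sample ids",
         call. = FALSE)
  }
  d_e <- ncol(expr) - length(common)
  d_c <- nrow(clinical) - length(common)
  if (d_e || d_c) {
    message(sprintf("align_samples: dropped %d expression, %d clinical samples",
                    d_e, d_c))
  }
  e2 <- expression_matrix(as_plain_matrix(expr)[, common, drop = FALSE],
                          is_log2 = is_log2(expr))
  c2 <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  rownames(c2) <- NULL
  list(expr = e2,
       clinical = clinical_table(as.data.frame(c2),
                                 time_units = attr(clinical, "time_units")),
       dropped_expr = d_e, dropped_clinical = d_c)
}

#' Collapse probe-level rows to genes by maximum mean expression
#'
#' Optional utility, off by default in every pipeline: for each gene keep
#' the probe with the highest mean expression. Probe-level analysis is the
#' default because anchors are probe ids.
#'
#' @param x An `expr_mat` whose rows are probes.
#' @param probe2gene Named character vector mapping probe id to gene symbol.
#' @return An `expr_mat` with one row per gene.
#' @export
collapse_by_max_mean <- function(x, probe2gene) {
  stopifnot(inherits(x, "expr_mat"))
  m <- as_plain_matrix(x)
  keep <- rownames(m) %in% names(probe2gene)
  m <- m[keep, , drop = FALSE]
  gene <- probe2gene[rownames(m)]
  mu <- rowMeans(m)
  pick <- vapply(split(seq_len(nrow(m)), gene),
                 function(idx) idx[which.max(mu[idx])], integer(1L))
  out <- m[pick, , drop = FALSE]
  rownames(out) <- names(pick)
  expression_matrix(out, is_log2 = is_log2(x))
}
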