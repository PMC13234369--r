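#' Anchor-gene co-expression signature
#'
#' Builds the co-expression signature of an anchor feature (e.g. an AK3
#' probe): Pearson correlation between the anchor row and every other
#' feature across samples, with membership defined purely by the magnitude
#' rule r <= -threshold or r >= threshold. Two-sided P values from the
#' t-distribution with n - 2 df accompany each r but play no part in
#' membership, and no multiple-testing correction is applied to membership.
#'
#' @param x An `expr_mat` (log2 recommended).
#' @param anchor_id Feature id of the anchor; must be present and
#'   nonconstant. The anchor is excluded from its own signature.
#' @param threshold Absolute-correlation membership cutoff (default 0.3).
#' @param samples Optional character vector restricting which samples enter
#'   the correlations (e.g. tumor-only); default all columns.
#' @return Object of class `gene_signature`: list with `anchor`,
#'   `threshold`, `records` (data frame feature/r/p/passed ranked by r
#'   descending), `n_signature`, `skipped` (zero-variance features), `n`
#'   (samples used).
#' @export
build_gene_signature <- function(x, anchor_id, threshold = 0.3,
                                 samples = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  m <- as_plain_matrix(x)
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing)) {
      stop("unknown sample id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    m <- m[, samples, drop = FALSE]
  }
  n <- ncol(m)
  if (n < 3L) stop("signature needs >= 3 samples", call. = FALSE)
  if (!anchor_id %in% rownames(m)) {
    stop("anchor feature '", anchor_id, "' not in the matrix", call. = FALSE)
  }
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  a <- m[anchor_id, ]
  a_c <- a - mean(a)
  a_ss <- sum(a_c^2)
  if (a_ss == 0) stop("anchor '", anchor_id, "' is constant", call. = FALSE)

  others <- m[setdiff(rownames(m), anchor_id), , drop = FALSE]
  oc <- others - rowMeans(others)
  o_ss <- rowSums(oc^2)
  skipped <- rownames(others)[o_ss == 0]
  keep <- o_ss > 0
  oc <- oc[keep, , drop = FALSE]
  r <- as.vector(oc %*% a_c) / sqrt(o_ss[keep] * a_ss)
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-12] <- 0
  passed <- r <= -threshold | r >= threshold
  rec <- data.frame(feature = rownames(oc), r = r, p = p, passed = passed,
                    stringsAsFactors = FALSE)
  rec <- rec[order(-rec$r, rec$feature, method = "radix"), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(anchor = anchor_id, threshold = threshold, records = rec,
                 n_signature = sum(passed), skipped = skipped, n = n),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf(
    "<gene_signature> anchor '%s': %d/%d features pass |r| >= %g (n = %d samples)\n",
    x$anchor, x$n_signature, nrow(x$records), x$threshold, x$n))
  invisible(x)
}

#' Signature members as a character vector
#' @param sig A `gene_signature`.
#' @return Feature ids with `passed == TRUE`, ranked by r descending.
#' @export
signature_members <- function(sig) {
  stopifnot(inherits(sig, "gene_signature"))
  sig$records$feature[sig$records$passed]
}

#' Rank features by tumor-vs-normal log2 fold change
#'
#' Per-feature statistic mean(log2 tumor) - mean(log2 normal), sorted
#' descending with ties broken by feature id — the pre-ranking used as
#' input to enrichment tools (see [write_rnk()]).
#'
#' @param x An `expr_mat` on the log2 scale.
#' @param tumor_ids,normal_ids Sample ids of the two phenotypes.
#' @return Data frame `(feature, log2fc)` in ranked order.
#' @export
rank_by_fold_change <- function(x, tumor_ids, normal_ids) {
  stopifnot(inherits(x, "expr_mat"))
  if (!is_log2(x)) stop("fold-change ranking expects log2 expression",
                        call. = FALSE)
  if (!length(tumor_ids) || !length(normal_ids)) {
    stop("both phenotype groups must be non-empty", call. = FALSE)
  }
  m <- as_plain_matrix(x)
  bad <- setdiff(c(tumor_ids, normal_ids), colnames(m))
  if (length(bad)) stop("unknown sample id(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  fc <- rowMeans(m[, tumor_ids, drop = FALSE]) -
    rowMeans(m[, normal_ids, drop = FALSE])
  ord <- order(-fc, names(fc), method = "radix")
  data.frame(feature = names(fc)[ord], log2fc = unname(fc)[ord],
             stringsAsFactors = FALSE)
}
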