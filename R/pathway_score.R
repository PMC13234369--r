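#' PDH complex genes appended to the OxPhos gene set
#'
#' The pyruvate dehydrogenase complex members added to
#' KEGG_OXIDATIVE_PHOSPHORYLATION when building the OxPhos score gene set.
#' @format Character vector of 5 gene symbols.
#' @export
PDH_COMPLEX_GENES <- c("PDHA1", "PDHB", "DLAT", "DLD", "PDHX")

#' Augment a KEGG OxPhos gene set with the PDH complex
#'
#' @param kegg_oxphos Character vector of OxPhos gene identifiers (e.g. the
#'   KEGG_OXIDATIVE_PHOSPHORYLATION members).
#' @return The union of `kegg_oxphos` and [PDH_COMPLEX_GENES], duplicates
#'   removed, input order preserved.
#' @export
build_oxphos_geneset <- function(kegg_oxphos = character()) {
  union(as.character(kegg_oxphos), PDH_COMPLEX_GENES)
}

#' Per-gene z-scoring of an expression matrix
#'
#' Centers and scales each gene (row) across samples so that every retained
#' row has mean 0 and SD 1 — the standardization applied before PCA-based
#' pathway scoring. Genes with zero variance carry no sample-ordering
#' information and are dropped with a warning.
#'
#' @param x An `expr_mat` on the log2 scale.
#' @param sd_type `"sample"` (n − 1 denominator, the default, matching
#'   common PCA practice) or `"population"` (n denominator).
#' @return A z-scored `expr_mat` (still flagged log2; the z-transform is a
#'   per-gene affine map of log2 values).
#' @export
zscore_genes <- function(x, sd_type = c("sample", "population")) {
  stopifnot(inherits(x, "expr_mat"))
  sd_type <- match.arg(sd_type)
  if (!is_log2(x)) {
    stop("z-scoring expects log2 expression; run log2_transform() first",
         call. = FALSE)
  }
  m <- as_plain_matrix(x)
  n <- ncol(m)
  if (n < 2L) stop("z-scoring needs >= 2 samples", call. = FALSE)
  mu <- rowMeans(m)
  cm <- m - mu
  ss <- rowSums(cm^2)
  sdv <- sqrt(ss / if (sd_type == "sample") n - 1L else n)
  zero <- sdv == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance gene(s): ",
            paste(utils::head(rownames(m)[zero], 5L), collapse = ", "),
            if (sum(zero) > 5L) ", ..." else "", call. = FALSE)
    cm <- cm[!zero, , drop = FALSE]
    sdv <- sdv[!zero]
  }
  if (!nrow(cm)) stop("all genes have zero variance", call. = FALSE)
  expression_matrix(cm / sdv, is_log2 = TRUE)
}

#' Single-sample pathway activity score (oriented PC1)
#'
#' Computes the per-sample pathway score for a gene set: the set's genes are
#' extracted from the log2 matrix, z-scored per gene, and PCA is run with
#' genes as variables and samples as observations; each sample's projection
#' on the first principal component is its pathway score. Because PC1 is
#' defined only up to sign, the component is oriented by `orientation` so
#' that "high score" deterministically means "high pathway expression".
#'
#' @param x An `expr_mat` on the log2 scale (samples in columns).
#' @param gene_set Character vector of feature ids, or a single element of a
#'   [read_gmt()] collection.
#' @param orientation Sign rule for PC1:
#'   * `"mean-z"` (default): orient so the scores correlate non-negatively
#'     with the per-sample mean z-score of the set's genes;
#'   * `"anchor:<id>"`: orient so the loading of feature `<id>` is >= 0;
#'   * `"none"`: keep the (deterministic but arbitrary) eigenvector sign
#'     returned by the decomposition.
#' @param pathway_name Label stored in the result.
#' @param sd_type Passed to [zscore_genes()].
#' @return An object of class `pathway_score`: list with `pathway_name`,
#'   `scores` (named per-sample vector, mean 0), `loadings` (named per-gene
#'   PC1 weights), `explained_variance_fraction`, `orientation_sign`,
#'   `genes_used`, `genes_missing`, `genes_dropped` (zero variance).
#' @export
compute_pathway_score <- function(x, gene_set, orientation = "mean-z",
                                  pathway_name = "pathway",
                                  sd_type = c("sample", "population")) {
  stopifnot(inherits(x, "expr_mat"))
  sd_type <- match.arg(sd_type)
  if (!is_log2(x)) {
    stop("pathway scoring expects log2 expression", call. = FALSE)
  }
  gene_set <- unique(as.character(gene_set))
  if (ncol(x) < 3L) stop("pathway scoring needs >= 3 samples", call. = FALSE)
  present <- intersect(gene_set, rownames(x))
  missing <- setdiff(gene_set, present)
  if (!length(present)) {
    stop("no member of gene set '", pathway_name, "' found in the matrix",
         call. = FALSE)
  }
  if (length(missing)) {
    warning(length(missing), " gene(s) of '", pathway_name,
            "' absent from the matrix", call. = FALSE)
  }
  sub <- expression_matrix(
    as_plain_matrix(x)[present, , drop = FALSE], is_log2 = TRUE)
  z <- suppressWarnings(zscore_genes(sub, sd_type = sd_type))
  dropped <- setdiff(present, rownames(z))
  used <- rownames(z)
  if (length(used) < 2L) {
    stop("fewer than 2 usable (nonzero-variance) genes for '",
         pathway_name, "'", call. = FALSE)
  }
  # samples as observations, genes as variables; data already standardized
  pc <- stats::prcomp(t(as_plain_matrix(z)), center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1L]
  loadings <- pc$rotation[, 1L]
  evf <- pc$sdev[1L]^2 / sum(pc$sdev^2)

  sign_rule <- 1
  if (identical(orientation, "mean-z")) {
    meanz <- colMeans(as_plain_matrix(z))
    s <- sum(scores * meanz)   # scores are mean 0, so this is prop. to cov
    if (s < 0) sign_rule <- -1
  } else if (startsWith(orientation, "anchor:")) {
    anchor <- sub("^anchor:", "", orientation)
    if (!anchor %in% names(loadings)) {
      stop("orientation anchor '", anchor, "' not among usable genes",
           call. = FALSE)
    }
    if (loadings[[anchor]] < 0) sign_rule <- -1
  } else if (!identical(orientation, "none")) {
    stop("unknown orientation rule: ", orientation, call. = FALSE)
  }
  scores <- scores * sign_rule
  loadings <- loadings * sign_rule
  # center exactly: projections of column-centered data are mean 0 already,
  # but guard against accumulated rounding
  scores <- scores - mean(scores)

  structure(list(
    pathway_name = pathway_name,
    scores = scores,
    loadings = loadings,
    explained_variance_fraction = evf,
    orientation_sign = sign_rule,
    genes_used = used,
    genes_missing = missing,
    genes_dropped = dropped
  ), class = "pathway_score")
}

#' @export
print.pathway_score <- function(x, ...) {
  cat(sprintf(
    "<pathway_score> '%s': %d samples, %d genes used (%d missing, %d dropped)\n",
    x$pathway_name, length(x$scores), length(x$genes_used),
    length(x$genes_missing), length(x$genes_dropped)))
  cat(sprintf("  PC1 explains %.1f%% of variance; orientation sign %+d\n",
              100 * x$explained_variance_fraction, x$orientation_sign))
  invisible(x)
}
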