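#' Run the end-to-end reproduction pipeline
#'
#' Orchestrates the full transcriptome recipe on one cohort: pathway
#' scores (OxPhos with PDH augmentation, plus any other configured sets),
#' all pairwise score correlations, the anchor-gene signature, fold-change
#' pre-ranking when both tissues are present, minimum-p survival
#' stratification for the anchor and every score, and the 2x2 two-marker
#' stratification for the first two configured sets. Every stage writes a
#' TSV/JSON artifact into the run directory and logs one structured line;
#' a manifest records every parameter, seed and chosen cutoff so a run can
#' be reproduced exactly.
#'
#' @param config Either a named list or the path to a YAML file with
#'   entries:
#'   * `expr`: path to an expression TSV (or an `expr_mat`);
#'   * `expr_is_log2`: whether stored values are log2 (default `TRUE`);
#'   * `log2_offset`: offset used when `expr_is_log2` is `FALSE`
#'     (default 0);
#'   * `clinical`: path to a clinical TSV (or a `clinical_tbl`);
#'   * `gmt`: path to a GMT file (or a named list of gene sets);
#'   * `gene_sets`: character vector of set names to score (first entry is
#'     treated as the OxPhos set and augmented with the PDH complex unless
#'     `add_pdh = FALSE`);
#'   * `anchor_id`: anchor feature for the signature (required);
#'   * `signature_threshold`: |r| membership cutoff (default 0.3);
#'   * `orientation`: PC1 orientation rule (default `"mean-z"`);
#'   * `min_group_fraction`, `min_group_size`: cutpoint floors
#'     (defaults 0.05, 10);
#'   * `n_permutations`: permutation correction count (default 0, off);
#'   * `two_marker_mode`: `"minp"` or `"median"` (default `"minp"`);
#'   * `seed`: integer seed recorded and used for any permutation draw
#'     (default 1).
#'   Enrichment-tool constants (P < 0.05, FDR < 0.25) are recorded in the
#'   manifest as metadata only; enrichment itself is external.
#' @param out_dir Output directory (created; must not exist or be empty).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(expr_is_log2 = TRUE, log2_offset = 0,
                   signature_threshold = 0.3, orientation = "mean-z",
                   min_group_fraction = 0.05, min_group_size = 10L,
                   n_permutations = 0L, two_marker_mode = "minp",
                   add_pdh = TRUE, seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }

  # -- validation before any compute --------------------------------------
  for (nm in c("expr", "clinical", "gmt", "gene_sets", "anchor_id")) {
    if (is.null(config[[nm]])) {
      stop("pipeline config missing required entry '", nm, "'",
           call. = FALSE)
    }
  }
  for (nm in c("expr", "clinical", "gmt")) {
    if (is.character(config[[nm]]) && !file.exists(config[[nm]])) {
      stop("pipeline config: path for '", nm, "' does not exist: ",
           config[[nm]], call. = FALSE)
    }
  }
  if (dir.exists(out_dir) && length(list.files(out_dir))) {
    stop("out_dir exists and is not empty: ", out_dir, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  log_line <- function(...) message(sprintf(...))
  manifest <- list(package_version = as.character(
                     utils::packageVersion("pathstrat")),
                   r_version = R.version.string,
                   seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("expr", "clinical", "gmt"))],
                   enrichment_constants = list(p = 0.05, fdr = 0.25),
                   low_rule = "low = marker <= cutoff",
                   stages = list())

  # -- load ---------------------------------------------------------------
  io <- stage("load", function() {
    expr <- if (inherits(config$expr, "expr_mat")) config$expr else
      read_expression(config$expr, is_log2 = config$expr_is_log2)
    if (!is_log2(expr)) expr <- log2_transform(expr, config$log2_offset)
    clinical <- if (inherits(config$clinical, "clinical_tbl"))
      config$clinical else read_clinical(config$clinical)
    gmt <- if (is.list(config$gmt)) config$gmt else read_gmt(config$gmt)
    missing_sets <- setdiff(config$gene_sets, names(gmt))
    if (length(missing_sets)) {
      stop("gene set(s) not in GMT: ", paste(missing_sets, collapse = ", "))
    }
    al <- align_samples(expr, clinical)
    list(expr = al$expr, clinical = al$clinical, gmt = gmt,
         dropped = c(expr = al$dropped_expr, clinical = al$dropped_clinical))
  })
  log_line("load: %d features x %d samples; dropped %d expr / %d clinical",
           nrow(io$expr), ncol(io$expr), io$dropped[1L], io$dropped[2L])
  manifest$stages$load <- list(n_features = nrow(io$expr),
                               n_samples = ncol(io$expr),
                               dropped = as.list(io$dropped))

  # -- pathway scores -----------------------------------------------------
  scores <- stage("scores", function() {
    out <- list()
    for (i in seq_along(config$gene_sets)) {
      nm <- config$gene_sets[[i]]
      members <- io$gmt[[nm]]
      if (i == 1L && isTRUE(config$add_pdh)) {
        members <- build_oxphos_geneset(members)
      }
      out[[nm]] <- suppressWarnings(compute_pathway_score(
        io$expr, members, orientation = config$orientation,
        pathway_name = nm))
    }
    out
  })
  score_mat <- do.call(cbind, lapply(scores, `[[`, "scores"))
  utils::write.table(
    data.frame(sample_id = rownames(score_mat), score_mat,
               check.names = FALSE),
    file.path(out_dir, "pathway_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(scores, function(s) list(
      explained_variance_fraction = s$explained_variance_fraction,
      orientation_sign = s$orientation_sign,
      loadings = as.list(s$loadings),
      genes_used = s$genes_used, genes_missing = s$genes_missing)),
    file.path(out_dir, "pathway_scores_meta.json"), auto_unbox = TRUE,
    digits = NA)
  for (s in scores) {
    log_line("scores: %s used %d genes (evf %.3f, sign %+d)", s$pathway_name,
             length(s$genes_used), s$explained_variance_fraction,
             s$orientation_sign)
  }
  manifest$stages$scores <- lapply(scores, function(s) list(
    genes_used = length(s$genes_used), genes_missing = length(s$genes_missing),
    genes_dropped = length(s$genes_dropped),
    explained_variance_fraction = s$explained_variance_fraction,
    orientation_sign = s$orientation_sign))

  # -- pairwise score correlations ----------------------------------------
  correlations <- stage("correlations", function() {
    nms <- colnames(score_mat)
    out <- list()
    if (length(nms) >= 2L) {
      for (i in seq_len(length(nms) - 1L)) for (j in (i + 1L):length(nms)) {
        key <- paste(nms[i], nms[j], sep = "~")
        out[[key]] <- pearson_with_regression(score_mat[, i], score_mat[, j])
      }
    }
    out
  })
  jsonlite::write_json(
    lapply(correlations, function(cr) list(r = cr$r, p = cr$p, n = cr$n,
                                           slope = cr$slope,
                                           intercept = cr$intercept)),
    file.path(out_dir, "score_correlations.json"), auto_unbox = TRUE,
    digits = NA)
  for (key in names(correlations)) {
    log_line("correlations: %s r = %.4f (p = %.3g)", key,
             correlations[[key]]$r, correlations[[key]]$p)
  }

  # -- anchor signature ---------------------------------------------------
  signature <- stage("signature", function() {
    build_gene_signature(io$expr, config$anchor_id,
                         threshold = config$signature_threshold)
  })
  utils::write.table(signature$records,
                     file.path(out_dir, "signature.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("signature: %d/%d features pass |r| >= %g",
           signature$n_signature, nrow(signature$records),
           signature$threshold)
  manifest$stages$signature <- list(anchor = config$anchor_id,
                                    threshold = config$signature_threshold,
                                    n_signature = signature$n_signature,
                                    n_skipped = length(signature$skipped))

  # -- fold-change pre-ranking (needs both tissues) -----------------------
  tumor_ids <- io$clinical$sample_id[io$clinical$tissue == "tumor"]
  normal_ids <- io$clinical$sample_id[io$clinical$tissue == "normal"]
  ranking <- NULL
  if (length(tumor_ids) && length(normal_ids)) {
    ranking <- stage("rank", function() {
      rank_by_fold_change(io$expr, tumor_ids, normal_ids)
    })
    write_rnk(ranking, file.path(out_dir, "tumor_vs_normal.rnk"))
    log_line("rank: wrote %d features (T = %d, N = %d)", nrow(ranking),
             length(tumor_ids), length(normal_ids))
  }

  # -- survival stratification (tumor samples) ----------------------------
  surv_clin <- io$clinical[io$clinical$tissue == "tumor", , drop = FALSE]
  stratifications <- list()
  strat2 <- NULL
  if (nrow(surv_clin) >= 4L * config$min_group_size && sum(surv_clin$os_event)) {
    idx <- match(surv_clin$sample_id, colnames(io$expr))
    markers <- c(
      stats::setNames(list(as_plain_matrix(io$expr)[config$anchor_id, idx]),
                      config$anchor_id),
      lapply(scores, function(s) unname(s$scores[idx])))
    stratifications <- stage("cutpoint", function() {
      out <- list()
      for (nm in names(markers)) {
        out[[nm]] <- minp_cutoff(
          markers[[nm]], surv_clin$os_time, surv_clin$os_event,
          min_group_fraction = config$min_group_fraction,
          min_group_size = config$min_group_size,
          n_permutations = config$n_permutations,
          marker_name = nm, seed = config$seed)
      }
      out
    })
    for (nm in names(stratifications)) {
      st <- stratifications[[nm]]
      utils::write.table(st$scan,
                         file.path(out_dir, paste0("scan_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(sample_id = surv_clin$sample_id, group = st$labels),
        file.path(out_dir, paste0("groups_", nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      for (grp in levels(st$labels)) {
        sel <- st$labels == grp
        km <- km_estimate(surv_clin$os_time[sel], surv_clin$os_event[sel])
        utils::write.table(km$table,
                           file.path(out_dir,
                                     paste0("km_", nm, "_", grp, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      log_line("cutpoint: %s cutoff %.4g (n = %d, %d; low, high), p = %.3g",
               nm, st$cutoff, st$group_sizes[["low"]],
               st$group_sizes[["high"]], st$logrank$p)
      manifest$stages$cutpoint[[nm]] <- list(
        cutoff = st$cutoff,
        n_low = st$group_sizes[["low"]], n_high = st$group_sizes[["high"]],
        p = st$logrank$p, p_adjusted = st$p_adjusted)
    }

    if (length(scores) >= 2L) {
      strat2 <- stage("two_marker", function() {
        stratify_two_markers(
          markers[[names(scores)[1L]]], markers[[names(scores)[2L]]],
          surv_clin$os_time, surv_clin$os_event,
          mode = config$two_marker_mode, names = names(scores)[1:2],
          min_group_fraction = config$min_group_fraction,
          min_group_size = config$min_group_size)
      })
      utils::write.table(
        data.frame(sample_id = surv_clin$sample_id, group = strat2$labels),
        file.path(out_dir, "groups_two_marker.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      log_line("two_marker: overall 4-group log-rank p = %.3g",
               strat2$logrank$p)
      manifest$stages$two_marker <- list(
        cutoffs = as.list(strat2$cutoffs),
        group_sizes = as.list(as.integer(strat2$group_sizes)),
        p = strat2$logrank$p)
    }
  } else {
    log_line("cutpoint: skipped (needs >= %d tumor samples with events)",
             4L * config$min_group_size)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(scores = scores, correlations = correlations,
                 signature = signature, ranking = ranking,
                 stratifications = stratifications,
                 two_marker = strat2, manifest = manifest,
                 out_dir = out_dir))
}
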