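#' Configuration for the latent-factor expression simulator
#'
#' The generator plants exactly the structure the scoring pipeline assumes:
#' each pathway is a latent per-sample factor, its member genes load on
#' that factor with gene-specific positive loadings, factors across
#' pathways are jointly multivariate normal with a specified correlation
#' matrix (by default OxPhos and Wnt at rho = -0.7), an anchor gene tracks
#' its own latent factor with a planted set of true signature genes
#' correlated to it, and everything is observed through i.i.d. Gaussian
#' noise on the log2 scale.
#'
#' Defaults describe the emulated cohort: 226 samples (a LUAD microarray
#' cohort size), 50 genes per pathway with loadings N(1, 0.25^2) and noise
#' SD 0.5 (per-gene signal-to-noise about 2), 100 true signature genes at
#' correlation 0.5 with the anchor over 500 background genes, and a tumor
#' shift of -1 log2 unit on the anchor for paired designs.
#'
#' @param n_samples Number of samples (subjects in paired designs).
#' @param n_background_genes Genes with no planted structure.
#' @param pathways Named list; each element a list with `n_genes`,
#'   `loading_mean`, `loading_sd`.
#' @param factor_correlation Correlation matrix across pathway factors
#'   (symmetric positive-definite, unit diagonal), dimnames matching
#'   `names(pathways)`.
#' @param anchor List with `id`, `n_signature_genes`, `rho` (true Pearson
#'   correlation of each planted signature gene with the anchor).
#' @param noise_sd Residual SD on the log2 scale.
#' @param base_mean,base_mean_sd Per-gene baseline log2 means mu_g are drawn
#'   from N(base_mean, base_mean_sd^2).
#' @param tumor_shift Named numeric vector of per-gene tumor-minus-normal
#'   shifts applied in paired designs (default: anchor down by 1).
#' @param seed Default seed used when a generator is called without one.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 226L,
                       n_background_genes = 500L,
                       pathways = list(
                         OxPhos = list(n_genes = 50L, loading_mean = 1,
                                       loading_sd = 0.25),
                         Wnt = list(n_genes = 50L, loading_mean = 1,
                                    loading_sd = 0.25)),
                       factor_correlation = NULL,
                       anchor = list(id = "AK3", n_signature_genes = 100L,
                                     rho = 0.5),
                       noise_sd = 0.5,
                       base_mean = 8, base_mean_sd = 2,
                       tumor_shift = NULL,
                       seed = 1L) {
  np <- length(pathways)
  if (is.null(factor_correlation)) {
    factor_correlation <- diag(np)
    dimnames(factor_correlation) <- list(names(pathways), names(pathways))
    if (all(c("OxPhos", "Wnt") %in% names(pathways))) {
      factor_correlation["OxPhos", "Wnt"] <-
        factor_correlation["Wnt", "OxPhos"] <- -0.7
    }
  }
  if (!isSymmetric(unname(factor_correlation)) ||
      any(abs(diag(factor_correlation) - 1) > 1e-12)) {
    stop("factor_correlation must be symmetric with unit diagonal",
         call. = FALSE)
  }
  if (min(eigen(factor_correlation, symmetric = TRUE,
                only.values = TRUE)$values) <= 1e-10) {
    stop("factor_correlation must be positive-definite", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (is.null(tumor_shift)) {
    tumor_shift <- stats::setNames(-1, anchor$id)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_background_genes = as.integer(n_background_genes),
                 pathways = pathways,
                 factor_correlation = factor_correlation,
                 anchor = anchor, noise_sd = noise_sd,
                 base_mean = base_mean, base_mean_sd = base_mean_sd,
                 tumor_shift = tumor_shift, seed = as.integer(seed)),
            class = "sim_config")
}

#' Configuration for the proportional-hazards survival simulator
#'
#' Event times follow a Weibull proportional-hazards model with baseline
#' hazard `h0` (exponential when `shape = 1`); censoring is uniform on
#' (0, `censor_max`). The linear predictor is either `beta * marker`
#' (log-linear effect) or, when `planted_percentile` is set, a threshold
#' effect: hazard multiplied by `hazard_ratio` for samples above that
#' marker percentile.
#'
#' @param h0 Baseline hazard (> 0); default 0.1 per time unit.
#' @param beta Log-hazard coefficient per unit marker (used when no
#'   threshold is planted).
#' @param censor_max Upper bound of the uniform censoring distribution.
#' @param planted_percentile Optional percentile in (0, 1) at which a
#'   threshold effect is planted.
#' @param hazard_ratio Hazard ratio across the planted threshold.
#' @param shape Weibull shape (1 = exponential).
#' @param time_units Unit label carried into the clinical table.
#' @return A validated list of class `survival_sim_config`.
#' @export
survival_sim_config <- function(h0 = 0.1, beta = 0, censor_max = 30,
                                planted_percentile = NULL, hazard_ratio = 3,
                                shape = 1, time_units = "months") {
  if (h0 <= 0) stop("h0 must be > 0", call. = FALSE)
  if (censor_max <= 0) stop("censor_max must be > 0", call. = FALSE)
  if (shape <= 0) stop("shape must be > 0", call. = FALSE)
  if (!is.null(planted_percentile) &&
      (planted_percentile <= 0 || planted_percentile >= 1)) {
    stop("planted_percentile must lie in (0, 1)", call. = FALSE)
  }
  structure(list(h0 = h0, beta = beta, censor_max = censor_max,
                 planted_percentile = planted_percentile,
                 hazard_ratio = hazard_ratio, shape = shape,
                 time_units = time_units),
            class = "survival_sim_config")
}

# shared core: draw factors, loadings and the gene x sample matrix
sim_draw <- function(config, n, sample_ids) {
  pw <- config$pathways
  np <- length(pw)
  fac <- MASS::mvrnorm(n, mu = rep(0, np), Sigma = config$factor_correlation)
  fac <- matrix(fac, nrow = n, ncol = np,
                dimnames = list(sample_ids, names(pw)))
  u <- stats::rnorm(n)                      # anchor latent factor

  rows <- list()
  loadings <- list()
  for (p in names(pw)) {
    g <- pw[[p]]$n_genes
    lam <- stats::rnorm(g, pw[[p]]$loading_mean, pw[[p]]$loading_sd)
    ids <- sprintf("%s_g%03d", p, seq_len(g))
    mu <- stats::rnorm(g, config$base_mean, config$base_mean_sd)
    rows[[p]] <- mu + lam %o% fac[, p] +
      matrix(stats::rnorm(g * n, 0, config$noise_sd), g, n)
    rownames(rows[[p]]) <- ids
    loadings[[p]] <- stats::setNames(lam, ids)
  }

  a <- config$anchor
  anchor_row <- matrix(stats::rnorm(1, config$base_mean,
                                    config$base_mean_sd) + u,
                       nrow = 1, dimnames = list(a$id, NULL))
  m_sig <- a$n_signature_genes
  sig_ids <- character(0)
  if (m_sig > 0) {
    # beta chosen so cor(beta*u + noise, u) equals the planted rho exactly
    beta_sig <- config$noise_sd * a$rho / sqrt(1 - a$rho^2)
    sig_ids <- sprintf("SIG_g%03d", seq_len(m_sig))
    mu <- stats::rnorm(m_sig, config$base_mean, config$base_mean_sd)
    sig_rows <- mu + matrix(rep(beta_sig * u, each = m_sig), m_sig, n) +
      matrix(stats::rnorm(m_sig * n, 0, config$noise_sd), m_sig, n)
    rownames(sig_rows) <- sig_ids
  } else {
    sig_rows <- matrix(0, 0, n)
  }

  nb <- config$n_background_genes
  bg_ids <- character(0)
  if (nb > 0) {
    bg_ids <- sprintf("BG_g%03d", seq_len(nb))
    mu <- stats::rnorm(nb, config$base_mean, config$base_mean_sd)
    bg_rows <- mu + matrix(stats::rnorm(nb * n, 0, config$noise_sd), nb, n)
    rownames(bg_rows) <- bg_ids
  } else {
    bg_rows <- matrix(0, 0, n)
  }

  values <- rbind(do.call(rbind, rows), anchor_row, sig_rows, bg_rows)
  colnames(values) <- sample_ids
  list(values = values, factors = fac, anchor_factor = u,
       loadings = loadings, signature_genes = sig_ids,
       background_genes = bg_ids)
}

#' Simulate a latent-factor expression matrix
#'
#' Draws `x[g, s] = mu_g + lambda_g * f[pathway(g), s] + eps[g, s]` on the
#' log2 scale, with pathway factors jointly normal at the configured
#' correlation, plus an anchor gene, its planted signature genes and
#' unstructured background genes. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return List with `expr` (an `expr_mat`, `is_log2 = TRUE`) and `truth`
#'   (factors, anchor factor, loadings, signature/background gene ids,
#'   config, seed) — everything needed to score downstream recovery.
#' @export
gen_expression <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  drawn <- sim_draw(config, n, ids)
  list(expr = expression_matrix(drawn$values, is_log2 = TRUE),
       truth = c(drawn[c("factors", "anchor_factor", "loadings",
                         "signature_genes", "background_genes")],
                 list(config = config, seed = seed)))
}

#' Simulate right-censored survival tied to a marker
#'
#' Event times from the configured Weibull proportional-hazards model:
#' `T = (E / (h0 * m))^(1/shape)` with `E ~ Exp(1)` and hazard multiplier
#' `m = exp(beta * marker)` (or `hazard_ratio^[marker > planted quantile]`
#' for threshold designs); censoring `C ~ U(0, censor_max)`;
#' `os_time = min(T, C)`, `os_event = 1[T <= C]`.
#'
#' @param marker Named numeric vector of marker values (names become
#'   sample ids; unnamed markers get `S0001`...).
#' @param config A [survival_sim_config()].
#' @param seed Integer seed.
#' @return A `clinical_tbl` (all rows `tissue = "tumor"`), with the true
#'   event time and censoring time in attribute `"truth"`.
#' @export
gen_survival <- function(marker, config = survival_sim_config(), seed = 1L) {
  stopifnot(inherits(config, "survival_sim_config"))
  if (any(!is.finite(marker))) stop("marker must be finite", call. = FALSE)
  set.seed(seed)
  n <- length(marker)
  ids <- names(marker)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
  if (!is.null(config$planted_percentile)) {
    thr <- stats::quantile(marker, config$planted_percentile, names = FALSE)
    mult <- ifelse(marker > thr, config$hazard_ratio, 1)
  } else {
    mult <- exp(config$beta * marker)
  }
  e <- stats::rexp(n, rate = 1)
  t_true <- (e / (config$h0 * mult))^(1 / config$shape)
  cens <- stats::runif(n, 0, config$censor_max)
  tbl <- clinical_table(
    data.frame(sample_id = ids,
               os_time = pmin(t_true, cens),
               os_event = as.integer(t_true <= cens),
               tissue = "tumor",
               stringsAsFactors = FALSE),
    time_units = config$time_units)
  attr(tbl, "truth") <- data.frame(sample_id = ids, event_time = t_true,
                                   censor_time = cens)
  tbl
}

#' Simulate a matched tumor/normal paired cohort
#'
#' Each subject contributes a tumor and a normal column sharing a latent
#' profile (factors, anchor factor) but with independent measurement
#' noise; tumor columns additionally receive the configured per-gene
#' shifts (by default the anchor gene is 1 log2 unit lower in tumor).
#'
#' @param config A [sim_config()]; `n_samples` is the number of subjects.
#' @param surv_config A [survival_sim_config()] used to attach per-subject
#'   survival (shared by the pair).
#' @param seed Integer seed.
#' @return List with `expr` (`expr_mat`, columns `<pair>_T` / `<pair>_N`),
#'   `clinical` (a `clinical_tbl` with `pair_id`), and `truth`.
#' @export
gen_paired_cohort <- function(config = sim_config(),
                              surv_config = survival_sim_config(),
                              seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_samples
  pair_ids <- sprintf("P%04d", seq_len(n))
  drawn <- sim_draw(config, n, pair_ids)    # latent per-subject profiles
  base <- drawn$values
  g <- nrow(base)
  noise_t <- matrix(stats::rnorm(g * n, 0, config$noise_sd), g, n)
  noise_n <- matrix(stats::rnorm(g * n, 0, config$noise_sd), g, n)
  shift <- stats::setNames(rep(0, g), rownames(base))
  known <- intersect(names(config$tumor_shift), rownames(base))
  shift[known] <- config$tumor_shift[known]
  tum <- base + noise_t + shift
  nor <- base + noise_n
  colnames(tum) <- paste0(pair_ids, "_T")
  colnames(nor) <- paste0(pair_ids, "_N")
  values <- cbind(tum, nor)

  # per-subject survival tied to the anchor's latent factor
  marker <- stats::setNames(drawn$anchor_factor, pair_ids)
  surv <- gen_survival(marker, surv_config,
                       seed = seed + 1L)
  clin <- data.frame(
    sample_id = c(colnames(tum), colnames(nor)),
    os_time = rep(surv$os_time, 2L),
    os_event = rep(surv$os_event, 2L),
    tissue = rep(c("tumor", "normal"), each = n),
    pair_id = rep(pair_ids, 2L),
    stringsAsFactors = FALSE)
  list(expr = expression_matrix(values, is_log2 = TRUE),
       clinical = clinical_table(clin, time_units = surv_config$time_units),
       truth = c(drawn[c("factors", "anchor_factor", "loadings",
                         "signature_genes", "background_genes")],
                 list(tumor_shift = shift, config = config, seed = seed)))
}

#' Simulate two correlated fluorescence channels
#'
#' Bivariate normal pixel pairs at correlation `rho` with a full ROI mask;
#' the expected co-localization percentage is (rho + 1) / 2 * 100.
#'
#' @param rho Target correlation, in (-1, 1).
#' @param n_pixels Number of pixels.
#' @param seed Integer seed.
#' @return List with `channel_a`, `channel_b` (numeric vectors), `mask`
#'   (all `TRUE`).
#' @export
gen_coloc_field <- function(rho, n_pixels = 10000L, seed = 1L) {
  if (abs(rho) >= 1) stop("rho must lie strictly in (-1, 1)", call. = FALSE)
  set.seed(seed)
  z1 <- stats::rnorm(n_pixels)
  z2 <- stats::rnorm(n_pixels)
  list(channel_a = z1,
       channel_b = rho * z1 + sqrt(1 - rho^2) * z2,
       mask = rep(TRUE, n_pixels))
}
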