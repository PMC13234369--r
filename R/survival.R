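#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival estimate under right-censoring, computed with
#' [survival::survfit()] and repackaged as a plain step-function table.
#' Subjects censored at an event time remain in the risk set at that time.
#' With no censoring the estimate equals the empirical survival function.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = death observed, 0 = censored).
#' @return Object of class `km_estimate`: `table` (data frame `time`,
#'   `at_risk`, `deaths`, `censored`, `survival`), `n` (cohort size).
#'   Survival at time 0 is 1 by convention.
#' @export
km_estimate <- function(times, events) {
  check_surv_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  tab <- data.frame(time = fit$time, at_risk = fit$n.risk,
                    deaths = fit$n.event, censored = fit$n.censor,
                    survival = fit$surv)
  structure(list(table = tab, n = length(times)), class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> n = %d, %d deaths over %d distinct times\n",
              x$n, sum(x$table$deaths), nrow(x$table)))
  invisible(x)
}

#' Evaluate a KM estimate at arbitrary times
#' @param km A `km_estimate`.
#' @param t Times at which to evaluate S(t).
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_estimate"))
  ev <- km$table[km$table$deaths > 0, , drop = FALSE]
  vapply(t, function(ti) {
    idx <- which(ev$time <= ti)
    if (!length(idx)) 1 else ev$survival[max(idx)]
  }, numeric(1L))
}

check_surv_input <- function(times, events) {
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("survival times must be finite and >= 0", call. = FALSE)
  }
  if (!all(events %in% c(0, 1))) {
    stop("events must be coded 0 (censored) / 1 (death)", call. = FALSE)
  }
  if (length(times) != length(events) || length(times) < 1L) {
    stop("times and events must be non-empty and equal length", call. = FALSE)
  }
  invisible(TRUE)
}

#' Unweighted k-group log-rank test
#'
#' Classic (unweighted) log-rank chi-square comparing event distributions
#' across k groups: observed minus expected deaths per group at every
#' distinct event time with the hypergeometric variance, df = k - 1,
#' P value from the chi-square upper tail. Invariant to group relabeling
#' and to any strictly monotone transform of time.
#'
#' @param times,events Survival input as in [km_estimate()].
#' @param groups Group labels (factor or vector), >= 2 non-empty levels.
#' @return An `assoc_test` with `kind = "logrank"`, plus per-group
#'   `observed` and `expected` death counts.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv_input(times, events)
  g <- factor(groups)
  if (length(g) != length(times)) stop("groups length mismatch", call. = FALSE)
  g <- droplevels(g)
  k <- nlevels(g)
  if (k < 2L) stop("need >= 2 non-empty groups", call. = FALSE)
  if (sum(events) == 0) stop("no events; log-rank undefined", call. = FALSE)

  dt <- sort(unique(times[events == 1]))
  O <- E <- stats::setNames(numeric(k), levels(g))
  V <- matrix(0, k, k, dimnames = list(levels(g), levels(g)))
  for (tj in dt) {
    at_risk <- times >= tj
    nj <- sum(at_risk)
    dj <- sum(events == 1 & times == tj)
    ngj <- vapply(levels(g), function(l) sum(at_risk & g == l), numeric(1L))
    dgj <- vapply(levels(g), function(l) {
      sum(events == 1 & times == tj & g == l)
    }, numeric(1L))
    O <- O + dgj
    E <- E + dj * ngj / nj
    if (nj > 1) {
      cj <- dj * (nj - dj) / (nj - 1)
      V <- V + cj * (diag(ngj, k) * nj - outer(ngj, ngj)) / nj^2
    }
  }
  idx <- seq_len(k - 1L)
  oe <- (O - E)[idx]
  Vs <- V[idx, idx, drop = FALSE]
  chisq <- tryCatch(
    drop(crossprod(oe, solve(Vs, oe))),
    error = function(e) drop(crossprod(oe, MASS::ginv(Vs) %*% oe)))
  p <- stats::pchisq(chisq, df = k - 1L, lower.tail = FALSE)
  new_assoc_test("logrank", chisq, p, k - 1L, length(times),
                 list(observed = O, expected = E))
}

#' Pairwise two-group log-rank tests
#' @inheritParams logrank_test
#' @return Data frame with one row per group pair: `group1`, `group2`,
#'   `chisq`, `p` (unadjusted).
#' @export
pairwise_logrank <- function(times, events, groups) {
  g <- droplevels(factor(groups))
  pairs <- utils::combn(levels(g), 2L)
  out <- apply(pairs, 2L, function(pr) {
    sel <- g %in% pr
    lt <- logrank_test(times[sel], events[sel], droplevels(g[sel]))
    c(chisq = lt$statistic, p = lt$p)
  })
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             chisq = out["chisq", ], p = out["p", ],
             stringsAsFactors = FALSE)
}

# --- vectorized two-group log-rank scan -----------------------------------
#
# The min-p cutpoint procedure evaluates a two-group log-rank test at every
# candidate cutoff of a continuous marker, and the permutation correction
# repeats the whole scan hundreds of times. Recomputing risk sets per
# cutoff is quadratic waste: with samples sorted by marker, the low group
# at cutoff index m is the first m rows, so the per-event-time group risk
# and death counts for *all* cutoffs are column cumulative sums of the
# at-risk and death indicator matrices. One cumsum + two matrix-vector
# products give every candidate's chi-square at once.

logrank_scan_prep <- function(times, events) {
  dt <- sort(unique(times[events == 1]))
  M <- outer(times, dt, ">=") * 1          # n x k: subject at risk at t_j
  Dm <- outer(times, dt, "==") * events    # n x k: subject dies at t_j
  d <- colSums(Dm)
  nr <- colSums(M)
  cj <- ifelse(nr > 1, d * (nr - d) / (nr - 1), 0)
  list(M = M, Dm = Dm, event = as.numeric(events),
       w_e = d / nr, w_v1 = cj / nr, w_v2 = cj / nr^2)
}

# cumulative-selection matrix: row i sums over the cand_m[i] lowest-marker
# subjects; built once per scan, reused across permutations
logrank_scan_selector <- function(cand_m, n) {
  outer(cand_m, seq_len(n), ">=") * 1
}

# chi-squares for all candidate low-group sizes, given row order `ord`
# (increasing marker) and the selector matrix from logrank_scan_selector().
# Zero-variance candidates return chisq 0.
logrank_scan_chisq <- function(prep, ord, C) {
  rank_of <- integer(length(ord))
  rank_of[ord] <- seq_along(ord)           # subject -> marker rank
  Cp <- C[, rank_of, drop = FALSE]
  N1 <- Cp %*% prep$M            # candidates x event-times: low at risk
  O <- drop(Cp %*% prep$event)
  E <- drop(N1 %*% prep$w_e)
  V <- drop(N1 %*% prep$w_v1) - drop((N1 * N1) %*% prep$w_v2)
  oe <- O - E
  ifelse(V > 0, oe^2 / V, 0)
}

#' Minimum-p log-rank cutpoint stratification
#'
#' Dichotomizes a continuous marker (expression of a gene, a pathway score)
#' at the cutoff minimizing the two-group log-rank P value. Candidate
#' cutoffs are the midpoints between consecutive distinct sorted marker
#' values, filtered so both groups hold at least `min_group_fraction` of
#' the cohort and at least `min_group_size` subjects. "low" means
#' marker <= cutoff. Ties in P are broken by the more balanced split, then
#' by the smaller cutoff, so the result is deterministic.
#'
#' The reported minimum P value is a raw log-rank P and is anti-conservative
#' because the cutoff was chosen to minimize it; an optional permutation
#' correction (`n_permutations > 0`) re-runs the full scan on
#' marker-permuted data and reports the fraction of permuted scans whose
#' minimum P is as small as the observed one. The correction is off by
#' default.
#'
#' @param marker Numeric marker, >= 2 distinct values.
#' @param times,events Survival input as in [km_estimate()].
#' @param min_group_fraction Size floor for each group as a fraction of the
#'   cohort, in `[0, 0.5)`; default 0.05.
#' @param min_group_size Absolute per-group size floor; default 10.
#' @param n_permutations Number of label permutations for the
#'   selection-bias-corrected P (0 = off).
#' @param marker_name Label stored in the result.
#' @param seed Optional seed for the permutation draw.
#' @return Object of class `surv_stratification`: `marker_name`, `cutoff`,
#'   `labels` (factor low/high, low = marker <= cutoff), `group_sizes`,
#'   `logrank` (an `assoc_test` at the chosen cutoff), `scan` (data frame
#'   `cutoff`, `n_low`, `n_high`, `chisq`, `p` over every candidate),
#'   `p_adjusted` (permutation-corrected P or `NA`), `n_permutations`.
#' @export
minp_cutoff <- function(marker, times, events, min_group_fraction = 0.05,
                        min_group_size = 10L, n_permutations = 0L,
                        marker_name = "marker", seed = NULL) {
  check_surv_input(times, events)
  n <- length(marker)
  if (n != length(times)) stop("marker length mismatch", call. = FALSE)
  if (any(!is.finite(marker))) stop("marker must be finite", call. = FALSE)
  if (length(unique(marker)) < 2L) {
    stop("marker is constant; no cutoff exists", call. = FALSE)
  }
  if (min_group_fraction < 0 || min_group_fraction >= 0.5) {
    stop("min_group_fraction must lie in [0, 0.5)", call. = FALSE)
  }
  if (sum(events) == 0) stop("no events; log-rank undefined", call. = FALSE)

  ord <- order(marker)
  ms <- marker[ord]
  floor_n <- max(ceiling(min_group_fraction * n), min_group_size)
  cand_m <- which(ms[-n] < ms[-1L])          # low-group sizes at distinct gaps
  cand_m <- cand_m[cand_m >= floor_n & (n - cand_m) >= floor_n]
  if (!length(cand_m)) {
    stop("no candidate cutoff satisfies the group-size floor", call. = FALSE)
  }
  cutoffs <- (ms[cand_m] + ms[cand_m + 1L]) / 2

  prep <- logrank_scan_prep(times, events)
  Csel <- logrank_scan_selector(cand_m, n)
  chisq <- logrank_scan_chisq(prep, ord, Csel)
  pvals <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
  scan <- data.frame(cutoff = cutoffs, n_low = cand_m, n_high = n - cand_m,
                     chisq = chisq, p = pvals)

  # argmin with deterministic tie-breaks: balance, then smaller cutoff
  best <- which(pvals == min(pvals))
  if (length(best) > 1L) {
    bal <- abs(cand_m[best] - n / 2)
    best <- best[bal == min(bal)]
    best <- best[which.min(cutoffs[best])]
  }
  cutoff <- cutoffs[best]
  labels <- factor(ifelse(marker <= cutoff, "low", "high"),
                   levels = c("low", "high"))
  lr <- logrank_test(times, events, labels)

  p_adj <- NA_real_
  if (n_permutations > 0L) {
    if (!is.null(seed)) set.seed(seed)
    obs_min <- min(pvals)
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      perm_ord <- sample.int(n)             # random marker assignment
      ch <- logrank_scan_chisq(prep, perm_ord, Csel)
      if (max(ch) >= max(chisq)) hits <- hits + 1L
    }
    p_adj <- (hits + 1L) / (n_permutations + 1L)
  }

  structure(list(marker_name = marker_name, cutoff = cutoff,
                 labels = labels,
                 group_sizes = table(labels),
                 logrank = lr, scan = scan,
                 p_adjusted = p_adj, n_permutations = n_permutations,
                 min_group_fraction = min_group_fraction,
                 min_group_size = min_group_size,
                 low_rule = "low = marker <= cutoff"),
            class = "surv_stratification")
}

#' @export
print.surv_stratification <- function(x, ...) {
  cat(sprintf("<surv_stratification> %s at cutoff %.4g (%s)\n",
              x$marker_name, x$cutoff, x$low_rule))
  cat(sprintf("  groups: %s; log-rank chisq = %.3f, p = %.3g\n",
              paste(sprintf("%s = %d", names(x$group_sizes), x$group_sizes),
                    collapse = ", "),
              x$logrank$statistic, x$logrank$p))
  if (!is.na(x$p_adjusted)) {
    cat(sprintf("  permutation-adjusted p = %.3g (%d permutations)\n",
                x$p_adjusted, x$n_permutations))
  }
  invisible(x)
}

#' Two-marker 2x2 survival stratification
#'
#' Dichotomizes two markers on the same cohort (each by its own min-p
#' cutoff, or at its median) and compares the four combined groups
#' (e.g. OxPhos^high:Wnt^low) with an overall k-group log-rank test.
#' Pairwise two-group tests are available via [pairwise_logrank()] on the
#' returned labels.
#'
#' @param marker1,marker2 Numeric markers on the same samples.
#' @param times,events Survival input.
#' @param mode `"minp"` (default) or `"median"` per-marker dichotomization.
#' @param names Length-2 character vector naming the markers.
#' @param ... Passed to [minp_cutoff()] in `"minp"` mode.
#' @return Object of class `surv_stratification2`: `cutoffs`, `labels`
#'   (factor with 4 levels `name1^low:name2^low`, ...), `group_sizes`,
#'   `logrank` (overall 4-group test), `per_marker` (the two
#'   single-marker stratifications in `"minp"` mode).
#' @export
stratify_two_markers <- function(marker1, marker2, times, events,
                                 mode = c("minp", "median"),
                                 names = c("marker1", "marker2"), ...) {
  mode <- match.arg(mode)
  check_surv_input(times, events)
  stopifnot(length(marker1) == length(times),
            length(marker2) == length(times))
  per_marker <- NULL
  if (mode == "minp") {
    s1 <- minp_cutoff(marker1, times, events, marker_name = names[1L], ...)
    s2 <- minp_cutoff(marker2, times, events, marker_name = names[2L], ...)
    cut1 <- s1$cutoff; cut2 <- s2$cutoff
    per_marker <- list(s1, s2)
  } else {
    cut1 <- stats::median(marker1)
    cut2 <- stats::median(marker2)
  }
  l1 <- ifelse(marker1 <= cut1, "low", "high")
  l2 <- ifelse(marker2 <= cut2, "low", "high")
  lv <- as.vector(outer(c("low", "high"), c("low", "high"),
                        function(a, b) paste0(names[1L], "^", a, ":",
                                              names[2L], "^", b)))
  labels <- factor(paste0(names[1L], "^", l1, ":", names[2L], "^", l2),
                   levels = lv)
  empty <- levels(labels)[table(labels) == 0L]
  if (length(empty)) {
    stop("empty combined group(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  lr <- logrank_test(times, events, labels)
  structure(list(marker_names = names,
                 cutoffs = stats::setNames(c(cut1, cut2), names),
                 mode = mode, labels = labels,
                 group_sizes = table(labels), logrank = lr,
                 per_marker = per_marker,
                 low_rule = "low = marker <= cutoff"),
            class = "surv_stratification2")
}

#' @export
print.surv_stratification2 <- function(x, ...) {
  cat(sprintf("<surv_stratification2> %s x %s (%s cutoffs)\n",
              x$marker_names[1L], x$marker_names[2L], x$mode))
  print(x$group_sizes)
  cat(sprintf("  overall log-rank chisq = %.3f (df %d), p = %.3g\n",
              x$logrank$statistic, x$logrank$df, x$logrank$p))
  invisible(x)
}
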