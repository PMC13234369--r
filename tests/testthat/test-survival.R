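test_that("KM estimate equals empirical survival without censoring", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$table$survival, c(2/3, 1/3, 0))
  expect_equal(km$table$at_risk, c(3, 2, 1))
  expect_equal(km_survival_at(km, c(0, 1, 2.5, 10)), c(1, 2/3, 1/3, 0))

  # all censored: survival identically 1
  kmc <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(kmc$table$survival == 1))

  # larger no-censoring cohort equals 1 - ecdf at event times
  set.seed(41)
  t10 <- sample(1:50, 12)
  km2 <- km_estimate(t10, rep(1, 12))
  expect_equal(km2$table$survival,
               1 - ecdf(t10)(sort(unique(t10))), tolerance = 1e-12)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), ">= 0")
})

test_that("KM matches the hand-computed product-limit table under censoring", {
  # subjects: 1 death, 2 censored, 3 death, 4 censored, 5 death, 6 death
  km <- km_estimate(1:6, c(1, 0, 1, 0, 1, 1))
  ev <- km$table[km$table$deaths > 0, ]
  # hand product-limit: 5/6, 5/6*3/4 = 5/8, 5/8*1/2 = 5/16, 0
  expect_equal(ev$time, c(1, 3, 5, 6))
  expect_equal(ev$survival, c(5/6, 5/8, 5/16, 0), tolerance = 1e-12)
  expect_equal(ev$at_risk, c(6, 4, 2, 1))
})

test_that("log-rank matches the hand-tabulated O-E/V oracle and survdiff", {
  time <- 1:6
  ev <- rep(1, 6)
  g <- rep(c("A", "B"), each = 3)
  res <- logrank_test(time, ev, g)
  # hand tabulation: O_A = 3, E_A = 0.5 + 0.4 + 0.25 = 1.15,
  # V = 0.25 + 0.24 + 0.1875 = 0.6775 -> chisq = 1.85^2 / 0.6775
  expect_equal(res$statistic, 5.051661, tolerance = 1e-6)
  expect_equal(res$p, 0.02460235, tolerance = 1e-6)
  expect_equal(unname(res$observed["A"]), 3)
  expect_equal(unname(res$expected["A"]), 1.15, tolerance = 1e-12)

  # identical groups: statistic 0, p 1
  same <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(1, 6), g)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  # independent cross-check against survival::survdiff, incl. k = 3 groups
  set.seed(43)
  tt <- rexp(60, 0.1); cc <- runif(60, 0, 20)
  evs <- as.integer(tt <= cc); tm <- pmin(tt, cc)
  g3 <- sample(c("x", "y", "z"), 60, replace = TRUE)
  mine <- logrank_test(tm, evs, g3)
  ref <- survival::survdiff(survival::Surv(tm, evs) ~ g3)
  expect_equal(mine$statistic, ref$chisq, tolerance = 1e-10)
  expect_equal(mine$df, 2)

  expect_error(logrank_test(tm, rep(0, 60), g3), "no events")
})

test_that("log-rank is invariant to group order and monotone time transforms", {
  set.seed(47)
  tm <- rexp(40, 0.2); evs <- rbinom(40, 1, 0.8)
  g <- rep(c("A", "B"), 20)
  a <- logrank_test(tm, evs, g)
  b <- logrank_test(tm, evs, ifelse(g == "A", "B", "A"))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  mono <- logrank_test(log1p(tm)^3, evs, g)
  expect_equal(a$statistic, mono$statistic, tolerance = 1e-12)
})

test_that("permutation reference distribution agrees with the chi-square p", {
  set.seed(53)
  n <- 40
  tm <- rexp(n, 0.1); cc <- runif(n, 0, 25)
  evs <- as.integer(tm <= cc); tm <- pmin(tm, cc)
  g <- rep(c("A", "B"), each = n / 2)
  obs <- logrank_test(tm, evs, g)
  perm <- replicate(500, {
    logrank_test(tm, evs, sample(g))$statistic
  })
  p_perm <- mean(perm >= obs$statistic)
  expect_lt(abs(p_perm - obs$p), 0.05)
})

test_that("min-p scan enumerates exactly the brute-force candidate set", {
  set.seed(59)
  n <- 12
  marker <- rnorm(n)
  tm <- rexp(n, 0.2); evs <- rbinom(n, 1, 0.9)
  evs[1] <- 1                              # ensure at least one event
  st <- minp_cutoff(marker, tm, evs, min_group_fraction = 0,
                    min_group_size = 2)
  # brute force: every midpoint between consecutive distinct sorted values
  ms <- sort(unique(marker))
  mids <- (ms[-length(ms)] + ms[-1]) / 2
  keep <- vapply(mids, function(ct) min(sum(marker <= ct),
                                        sum(marker > ct)) >= 2, logical(1))
  expect_equal(st$scan$cutoff, mids[keep], tolerance = 1e-12)
  for (i in seq_len(nrow(st$scan))) {
    ref <- survival::survdiff(
      survival::Surv(tm, evs) ~ (marker <= st$scan$cutoff[i]))
    expect_equal(st$scan$chisq[i], ref$chisq, tolerance = 1e-8)
  }
  # self-consistency: reported p is the scan minimum
  expect_equal(st$logrank$p, min(st$scan$p), tolerance = 1e-12)
  # low = marker <= cutoff
  expect_identical(as.vector(st$labels),
                   ifelse(marker <= st$cutoff, "low", "high"))

  expect_error(minp_cutoff(rep(1, n), tm, evs), "constant")
  expect_error(minp_cutoff(marker, tm, evs, min_group_size = 7), "floor")
})

test_that("min-p cutpoint recovers a planted threshold effect", {
  set.seed(61)
  n <- 400
  marker <- rnorm(n)
  clin <- gen_survival(marker,
                       survival_sim_config(h0 = 0.1, censor_max = 30,
                                           planted_percentile = 0.4,
                                           hazard_ratio = 3),
                       seed = 62)
  st <- minp_cutoff(marker, clin$os_time, clin$os_event,
                    marker_name = "score")
  recovered_pct <- mean(marker <= st$cutoff)
  expect_lt(abs(recovered_pct - 0.4), 0.05)
  # high-hazard group (above cutoff) dies faster
  km_low <- km_estimate(clin$os_time[st$labels == "low"],
                        clin$os_event[st$labels == "low"])
  km_high <- km_estimate(clin$os_time[st$labels == "high"],
                         clin$os_event[st$labels == "high"])
  expect_gt(km_survival_at(km_low, 10), km_survival_at(km_high, 10))
})

test_that("two-marker stratification builds four labeled groups", {
  set.seed(67)
  n <- 120
  m1 <- rnorm(n); m2 <- rnorm(n)
  clin <- gen_survival(m1, survival_sim_config(beta = 0.8), seed = 68)
  st <- stratify_two_markers(m1, m2, clin$os_time, clin$os_event,
                             mode = "median", names = c("OxPhos", "Wnt"))
  expect_equal(sum(st$group_sizes), n)
  expect_true(all(st$group_sizes >= 1))
  expect_identical(levels(st$labels),
                   c("OxPhos^low:Wnt^low", "OxPhos^high:Wnt^low",
                     "OxPhos^low:Wnt^high", "OxPhos^high:Wnt^high"))
  expect_equal(st$logrank$df, 3)

  # degenerate: marker2 = marker1 leaves two empty combined groups
  expect_error(stratify_two_markers(m1, m1, clin$os_time, clin$os_event,
                                    mode = "median"), "empty combined")

  # only marker1 carries hazard: 4-group test beats marker2's 2-group test
  st2_p <- logrank_test(clin$os_time, clin$os_event,
                        ifelse(m2 <= median(m2), "low", "high"))$p
  expect_lt(st$logrank$p, st2_p)

  # minp mode records the per-marker scans
  stm <- stratify_two_markers(m1, m2, clin$os_time, clin$os_event,
                              mode = "minp", names = c("OxPhos", "Wnt"))
  expect_length(stm$per_marker, 2)
  expect_s3_class(stm$per_marker[[1]], "surv_stratification")
})
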