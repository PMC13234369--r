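test_that("generators are pure functions of config and seed", {
  cfg <- sim_config(n_samples = 30, n_background_genes = 20,
                    anchor = list(id = "AK3", n_signature_genes = 10,
                                  rho = 0.5))
  a <- gen_expression(cfg, seed = 101)
  b <- gen_expression(cfg, seed = 101)
  expect_identical(unclass(a$expr)[, ], unclass(b$expr)[, ])
  expect_identical(a$truth$factors, b$truth$factors)
  c_ <- gen_expression(cfg, seed = 102)
  expect_false(identical(unclass(a$expr)[, ], unclass(c_$expr)[, ]))

  px1 <- gen_coloc_field(0.3, 500, seed = 5)
  px2 <- gen_coloc_field(0.3, 500, seed = 5)
  expect_identical(px1$channel_b, px2$channel_b)
  expect_error(gen_coloc_field(1, 100), "strictly")
})

test_that("config invariants are enforced", {
  bad_corr <- matrix(c(1, -0.99, 0.99, -0.99, 1, 0.99, 0.99, 0.99, 1), 3, 3)
  expect_error(sim_config(pathways = list(A = list(n_genes = 5,
                                                   loading_mean = 1,
                                                   loading_sd = 0.2),
                                          B = list(n_genes = 5,
                                                   loading_mean = 1,
                                                   loading_sd = 0.2),
                                          C = list(n_genes = 5,
                                                   loading_mean = 1,
                                                   loading_sd = 0.2)),
                          factor_correlation = bad_corr),
               "positive-definite")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(survival_sim_config(h0 = -1), "h0")
  expect_error(survival_sim_config(planted_percentile = 1.2),
               "planted_percentile")
})

test_that("noiseless single-pathway data is recovered perfectly by PC1", {
  cfg <- sim_config(n_samples = 40, n_background_genes = 0,
                    pathways = list(P = list(n_genes = 10, loading_mean = 1,
                                             loading_sd = 0.2)),
                    factor_correlation = matrix(1, 1, 1,
                                                dimnames = list("P", "P")),
                    anchor = list(id = "AK3", n_signature_genes = 0,
                                  rho = 0.5),
                    noise_sd = 1e-8)
  gx <- gen_expression(cfg, seed = 103)
  ps <- compute_pathway_score(gx$expr, grep("^P_", rownames(gx$expr),
                                            value = TRUE))
  expect_gt(abs(cor(ps$scores, gx$truth$factors[, "P"])), 1 - 1e-9)
  expect_gt(ps$explained_variance_fraction, 1 - 1e-9)
})

test_that("survival generator respects its proportional-hazards contract", {
  set.seed(107)
  marker <- rnorm(300)
  clin <- gen_survival(marker, survival_sim_config(h0 = 0.1, beta = 1,
                                                   censor_max = 30),
                       seed = 108)
  expect_s3_class(clin, "clinical_tbl")
  expect_true(all(clin$os_time >= 0))
  truth <- attr(clin, "truth")
  expect_equal(clin$os_time, pmin(truth$event_time, truth$censor_time))
  expect_equal(clin$os_event,
               as.integer(truth$event_time <= truth$censor_time))
  # high-hazard (high-marker) subjects die earlier on average
  hi <- marker > median(marker)
  expect_lt(mean(truth$event_time[hi]), mean(truth$event_time[!hi]))

  # censoring vanishes as censor_max grows
  clin_far <- gen_survival(marker, survival_sim_config(h0 = 0.1, beta = 0,
                                                       censor_max = 1e6),
                           seed = 109)
  expect_gt(mean(clin_far$os_event), 0.999)
})

test_that("paired cohorts carry a perfect matching and the planted shift", {
  cfg <- sim_config(n_samples = 100, n_background_genes = 10,
                    anchor = list(id = "AK3", n_signature_genes = 0,
                                  rho = 0.5),
                    noise_sd = 0.5)
  pc <- gen_paired_cohort(cfg, seed = 111)
  cl <- pc$clinical
  expect_equal(nrow(cl), 200)
  # pair ids form a perfect tumor/normal matching
  tab <- table(cl$pair_id, cl$tissue)
  expect_true(all(tab == 1))
  # anchor gene down in tumor by about |delta| = 1
  pairs <- sort(unique(cl$pair_id))
  tum <- paste0(pairs, "_T")
  nor <- paste0(pairs, "_N")
  ak3_t <- unclass(pc$expr)["AK3", tum]
  ak3_n <- unclass(pc$expr)["AK3", nor]
  res <- paired_ttest(ak3_t, ak3_n)
  expect_lt(res$p, 0.001)
  expect_lt(res$mean_difference, 0)
  expect_equal(res$mean_difference, -1, tolerance = 0.25)

  # an unshifted background gene shows no paired effect at this n
  bg <- unclass(pc$expr)["BG_g001", ]
  res_bg <- paired_ttest(bg[tum], bg[nor])
  expect_gt(res_bg$p, 0.001)
})

test_that("planted factor correlation propagates to the generated scores", {
  cfg <- sim_config(n_samples = 100, n_background_genes = 0,
                    anchor = list(id = "AK3", n_signature_genes = 0,
                                  rho = 0.5))
  gx <- gen_expression(cfg, seed = 113)
  f <- gx$truth$factors
  expect_lt(cor(f[, "OxPhos"], f[, "Wnt"]), -0.4)   # planted rho = -0.7
})
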