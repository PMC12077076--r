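test_that("cohort generation is bit-identical for a fixed config", {
  cfg <- tiny_config(seed = 11L, n_samples = 300L,
                     group_sizes = c(control = 3L, case = 3L))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(lapply(a$series, `[[`, "values"),
                   lapply(b$series, `[[`, "values"))
})

test_that("subject streams are invariant to the sizes of other groups", {
  small <- generate_cohort(tiny_config(seed = 12L, n_samples = 300L,
                                       group_sizes = c(control = 3L, case = 2L)))
  large <- generate_cohort(tiny_config(seed = 12L, n_samples = 300L,
                                       group_sizes = c(control = 5L, case = 4L,
                                                       subthreshold = 2L)))
  expect_identical(small$series[["control_002"]]$values,
                   large$series[["control_002"]]$values)
  row_s <- small$subjects[small$subjects$subject_id == "case_001", ]
  row_l <- large$subjects[large$subjects$subject_id == "case_001", ]
  rownames(row_s) <- rownames(row_l) <- NULL
  expect_identical(row_s, row_l)
})

test_that("config validation rejects impossible edge placements and groups", {
  expect_error(desk_config(n_sensors = 4L, n_effect_edges = 4L,
                           n_nuisance_edges = 3L), "disjoint")
  expect_error(desk_config(group_sizes = c(control = 30L)), "case")
  expect_error(cohort_config(group_sizes = c(control = 5L, case = 5L,
                                             ptsd = 3L)), "unknown group")
})

test_that("ground truth is internally consistent", {
  cfg <- tiny_config(seed = 13L, n_samples = 300L)
  gt <- generate_cohort(cfg)$ground_truth
  expect_identical(nrow(gt$effect_edges), cfg$n_effect_edges)
  key <- function(m) paste(m[, 1], m[, 2])
  expect_length(intersect(key(gt$effect_edges), key(gt$nuisance_edges)), 0)
  expect_true(all(gt$magnitudes[grep("^control", names(gt$magnitudes))] == 0))
  expect_true(all(gt$magnitudes[grep("^case", names(gt$magnitudes))] == 1))
})

test_that("generated sensors are strongly autocorrelated at lag 1", {
  ts <- generate_subject_timeseries(6, 800, diag(6), seed = 14)
  r1 <- apply(ts$values, 1, function(v) acf(v, lag.max = 1, plot = FALSE)$acf[2])
  expect_true(all(r1 > 0.3))
})

test_that("identity coupling yields near-independent innovations", {
  ts <- generate_subject_timeseries(10, 2000, diag(10), seed = 15)
  innov <- prewhiten(ts, fast_pw())
  cc <- crosscorr_matrix(innov)
  off <- abs(cc[upper.tri(cc)])
  expect_gte(mean(off < 3 / sqrt(ncol(innov$values))), 0.95)
})

test_that("a single strong planted pair dominates the partial correlations", {
  omega <- diag(6)
  omega[1, 2] <- omega[2, 1] <- -0.8
  coupling <- stats::cov2cor(solve(omega))
  ts <- generate_subject_timeseries(6, 3000, coupling, seed = 16)
  z <- compute_sni(ts, fast_pw())
  expect_identical(which.max(abs(z[upper.tri(z)])),
                   which(upper.tri(z), arr.ind = TRUE) |>
                     (\(ix) which(ix[, 1] == 1 & ix[, 2] == 2))())
})

test_that("non-PSD coupling and short series are rejected", {
  bad <- diag(3); bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(generate_subject_timeseries(3, 100, bad, seed = 1),
               "eigenvalue")
  expect_error(generate_subject_timeseries(10, 10, diag(10), seed = 1),
               "exceed")
})

test_that("null effect leaves planted-edge SNI equal between groups", {
  diffs <- vapply(1:8, function(seed) {
    cfg <- tiny_config(seed = seed, n_sensors = 8L, n_samples = 500L,
                       group_sizes = c(control = 5L, case = 5L),
                       n_effect_edges = 3L, n_nuisance_edges = 0L,
                       effect_shift = 0, age_slope = 0, gender_shift = 0)
    coh <- generate_cohort(cfg)
    sni <- lapply(coh$series, compute_sni, cfg = fast_pw())
    ee <- coh$ground_truth$effect_edges
    vals <- vapply(sni, function(z) mean(z[ee]), numeric(1))
    grp <- coh$subjects$group
    mean(vals[grp == "case"]) - mean(vals[grp == "control"])
  }, numeric(1))
  # pooled over seeds the case-control difference is centred on zero
  expect_gt(t.test(diffs)$p.value, 0.01)
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("planted effect magnitude is recovered on effect edges", {
  # the desk-scale study cohort: 24 sensors, 30+30 subjects, 12 edges,
  # shift 1.0, edge noise 0.2, seed 7
  obj <- desk_pipeline_objects()
  ee <- obj$cohort$ground_truth$effect_edges
  vals <- vapply(obj$sni_raw, function(z) mean(z[ee]), numeric(1))
  grp <- obj$cohort$subjects$group
  diff <- mean(vals[grp == "case"]) - mean(vals[grp == "control"])
  expect_lt(abs(diff - 1.0), 0.15)
})

test_that("severity scores stay in the instrument range and track magnitude", {
  cfg <- tiny_config(seed = 17L, n_samples = 300L,
                     group_sizes = c(control = 4L, case = 8L,
                                     full_recovery = 8L))
  coh <- generate_cohort(cfg)
  sev <- coh$subjects$severity_score
  expect_true(all(is.na(sev[coh$subjects$group == "control"])))
  sev_ok <- sev[!is.na(sev)]
  expect_true(all(sev_ok >= 0 & sev_ok <= 80))
  m <- coh$ground_truth$magnitudes[coh$subjects$subject_id]
  expect_gt(cor(sev, m, use = "complete.obs"), 0)
})
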