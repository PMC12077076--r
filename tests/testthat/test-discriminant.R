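test_that("min/max features have the documented layout and length", {
  z <- matrix(c(NA, -0.2, 0.1, 0.3,
                -0.2, NA, 0.05, -0.4,
                0.1, 0.05, NA, 0.2,
                0.3, -0.4, 0.2, NA), 4, 4)
  fv <- extract_minmax_features(z)
  expect_length(fv, 8)
  expect_equal(unname(fv["min_S001"]), -0.2)
  expect_equal(unname(fv["max_S001"]), 0.3)
  expect_equal(names(fv)[1:4], paste0("min_", sensor_labels_for(4)))
  cm <- matrix(0.7, 3, 3); diag(cm) <- NA
  fvc <- extract_minmax_features(cm)
  expect_true(all(fvc == 0.7))
  big <- matrix(rnorm(248^2), 248, 248); diag(big) <- NA
  expect_length(extract_minmax_features(big), 496)
})

test_that("stepwise picks the separating feature first, by the F oracle", {
  toy <- toy_separated(n_per_group = 10, n_noise = 4, gap = 10, seed = 31)
  sel <- stepwise_select(toy$x, toy$labels)
  expect_identical(sel$log$feature[1], 1L)
  # one-variable Wilks lambda equals the one-way ANOVA F relation
  f_oracle <- summary(aov(toy$x[, 1] ~ toy$labels))[[1]]$`F value`[1]
  expect_equal(sel$log$F[1], f_oracle, tolerance = 1e-8)
})

test_that("an impossible entry threshold yields an empty selection status", {
  toy <- toy_separated(seed = 32)
  sel <- stepwise_select(toy$x, toy$labels,
                         stepwise_criteria(f_to_enter = 1e6, f_to_remove = 1))
  expect_identical(sel$status, "empty")
  expect_length(sel$selected, 0)
})

test_that("two planted informative features enter before any noise feature", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    labels <- factor(rep(c("control", "case"), each = n / 2),
                     levels = c("control", "case"))
    x <- matrix(rnorm(n * 8), n)
    x[labels == "case", 1] <- x[labels == "case", 1] + 3
    x[labels == "case", 2] <- x[labels == "case", 2] + 3
    sel <- stepwise_select(x, labels)
    entered <- sel$log$feature[sel$log$action == "enter"]
    expect_true(all(c(1L, 2L) %in% entered[1:2]))
  }
})

test_that("fixed-feature LDA matches the closed form and MASS::lda", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(20:50, 1); p <- sample(2:10, 1)
    labels <- factor(rep(c("control", "case"), length.out = n),
                     levels = c("control", "case"))
    x <- matrix(rnorm(n * p), n)
    x[labels == "case", 1] <- x[labels == "case", 1] + 1
    model <- fit_lda(x, labels)
    mu <- model$centroids
    w <- matrix(0, p, p)
    for (g in levels(labels)) {
      xg <- scale(x[labels == g, , drop = FALSE], scale = FALSE)
      w <- w + crossprod(xg)
    }
    closed <- solve(w / (n - 2), mu[2, ] - mu[1, ])
    expect_equal(model$coefficients, closed, tolerance = 1e-6,
                 ignore_attr = TRUE)
    # independent route: MASS::lda direction is proportional
    ml <- MASS::lda(x, labels)
    ratio <- model$coefficients / drop(ml$scaling)
    expect_lt(diff(range(ratio)) / abs(mean(ratio)), 1e-6)
  }
})

test_that("1-D LDA boundary sits midway and flips with labels", {
  x <- matrix(c(rnorm(20, 0, 1), rnorm(20, 2, 1)), ncol = 1)
  labels <- factor(rep(c("control", "case"), each = 20),
                   levels = c("control", "case"))
  model <- fit_lda(x, labels)
  boundary <- -model$constant / model$coefficients
  expect_equal(boundary, mean(model$centroids), tolerance = 1e-10)
  flipped <- fit_lda(x, factor(labels, levels = c("case", "control")))
  expect_equal(flipped$coefficients, -model$coefficients, tolerance = 1e-10)
  expect_equal(flipped$constant, -model$constant, tolerance = 1e-10)
})

test_that("score_case satisfies the centroid, symmetry and D2 contracts", {
  # 1-D model with pooled variance 1 and centroids 0 and 4
  x <- matrix(c(-1, 0, 1, 3, 4, 5), ncol = 1)
  labels <- factor(rep(c("control", "case"), each = 3),
                   levels = c("control", "case"))
  model <- fit_lda(x, labels)
  expect_equal(unname(model$pooled_cov[1, 1]), 1)
  at_centroid <- score_case(model, model$centroids[1, ])
  expect_equal(at_centroid$d2_control, 0)
  expect_equal(at_centroid$dprime2_control, 0)
  expect_identical(at_centroid$assigned, "control")
  midpoint <- score_case(model, 2)
  expect_equal(midpoint$p_control, 0.5)
  expect_equal(midpoint$dprime2_control, 0.5)
  # fv = 1: D2 = (1, 9), normalized control distance 1/(1+9)
  sc <- score_case(model, 1)
  expect_equal(sc$d2_control, 1)
  expect_equal(sc$d2_case, 9)
  expect_equal(sc$dprime2_control, 0.1)
  expect_identical(sc$assigned, "control")
  expect_error(score_case(model, c(1, 2, 3)), "length")
})

test_that("normalized distances follow the two-distance arithmetic", {
  expect_equal(normalize_d2(2, 2), list(control = 0.5, case = 0.5))
  expect_equal(normalize_d2(0, 5), list(control = 0, case = 1))
  expect_equal(normalize_d2(1, 3), list(control = 0.25, case = 0.75))
  expect_error(normalize_d2(0, 0), "both distances")
  expect_error(normalize_d2(-1, 2), "non-negative")
})

test_that("score sign, posterior and D2 always agree on the assignment", {
  set.seed(34)
  toy <- toy_separated(n_per_group = 15, n_noise = 3, gap = 2, seed = 35)
  model <- fit_lda(toy$x, toy$labels, selected = c(1L, 2L))
  for (i in seq_len(nrow(toy$x))) {
    sc <- score_case(model, toy$x[i, c(1, 2)])
    by_d2 <- if (sc$d2_case < sc$d2_control) "case" else "control"
    by_post <- if (sc$p_case > sc$p_control) "case" else "control"
    by_score <- if (sc$score > 0) "case" else "control"
    expect_identical(sc$assigned, by_d2)
    if (sc$p_case != sc$p_control) expect_identical(sc$assigned, by_post)
    if (sc$score != 0) expect_identical(sc$assigned, by_score)
    expect_equal(sc$p_control + sc$p_case, 1, tolerance = 1e-12)
    expect_equal(sc$dprime2_control + sc$dprime2_case, 1, tolerance = 1e-12)
  }
})

test_that("LOOCV is perfect on a well-separated toy and keeps fold records", {
  toy <- toy_separated(n_per_group = 10, n_noise = 4, gap = 10, seed = 36)
  cv <- loocv(toy$x, toy$labels)
  expect_equal(cv$accuracy, 1.0)
  expect_identical(nrow(cv$folds), 20L)
  # minimal n = 4 bookkeeping
  x4 <- matrix(c(0, 0.1, 5, 5.1), ncol = 1)
  l4 <- factor(c("control", "control", "case", "case"),
               levels = c("control", "case"))
  cv4 <- loocv(x4, l4, stepwise_criteria(f_to_enter = 1, f_to_remove = 0.5))
  expect_identical(nrow(cv4$folds), 4L)
})

test_that("classify_cohort tallies assignments of constructed cohorts", {
  toy <- toy_separated(n_per_group = 10, n_noise = 2, gap = 8, seed = 37)
  model <- fit_lda(toy$x, toy$labels, selected = 1L)
  at_case <- matrix(rep(model$centroids["case", ], 5), 5, 1, byrow = TRUE)
  colnames(at_case) <- colnames(toy$x)[1]
  gc <- classify_cohort(model, at_case, "probe")
  expect_identical(gc$counts, c(0L, 5L))
  mixture <- rbind(at_case,
                   matrix(rep(model$centroids["control", ], 5), 5, 1))
  gc2 <- classify_cohort(model, mixture, "mixture")
  expect_equal(gc2$percentages, c(50, 50))
  expect_error(classify_cohort(model, at_case[0, , drop = FALSE]), "empty")
})

test_that("network thresholding uses strict linear-interpolation percentiles", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- c(0.1, 0.2, 0.3, 0.4, -0.15, 0.25)
  m <- m + t(m); diag(m) <- NA
  # reduce to the documented four-value example via a 2x2 selection of pairs
  vals <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(quantile(vals, 0.25, type = 7, names = FALSE), 0.175)
  m4 <- matrix(0, 4, 4)
  m4[1, 2] <- 0.1; m4[1, 3] <- 0.2; m4[1, 4] <- 0.3; m4[2, 3] <- 0.4
  m4[2, 4] <- 0.1; m4[3, 4] <- 0.2
  m4 <- m4 + t(m4); diag(m4) <- NA
  net <- threshold_network(m4, network_threshold_config(25))
  expect_true(all(net$edges$abs_sni > net$threshold))
  # all-equal values leave nothing strictly above the threshold
  meq <- matrix(0.5, 3, 3); diag(meq) <- NA
  expect_identical(nrow(threshold_network(meq)$edges), 0L)
  # percentile 0 keeps every edge
  net_all <- threshold_network(m4, network_threshold_config(0))
  expect_identical(nrow(net_all$edges), 6L)
  expect_gte(net_all$n_components, 1L)
})

test_that("selected sensors lie on planted effect edges", {
  obj <- desk_pipeline_objects()
  is_ref <- obj$cohort$subjects$group %in% c("control", "case")
  sel <- stepwise_select(obj$features[is_ref, ], obj$labels[is_ref])
  sensors <- unique(sub("^(min|max)_", "", colnames(obj$features)[sel$selected]))
  gt <- obj$cohort$ground_truth
  effect_sensors <- unique(gt$sensor_labels[c(gt$effect_edges)])
  expect_true(all(sensors %in% effect_sensors))
})
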