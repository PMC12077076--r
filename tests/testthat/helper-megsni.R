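# Shared fixtures and oracles, all generated in code at test time.

# Fast prewhitening for small simulated series.
fast_pw <- function(order = c(2L, 1L, 1L)) {
  prewhiten_config(order = order, fallback_order = c(1L, 1L, 0L))
}

# Small cohort for pipeline-level tests.
tiny_config <- function(seed, ...) {
  defaults <- list(n_sensors = 12L, n_samples = 800L,
                   group_sizes = c(control = 10L, case = 10L),
                   n_effect_edges = 4L, n_nuisance_edges = 3L,
                   master_seed = seed)
  do.call(desk_config, utils::modifyList(defaults, list(...)))
}

# Brute-force partial correlation oracle: correlation of the residuals from
# regressing each pair of variables on all the remaining ones.
pcor_brute <- function(x) {
  n <- ncol(x)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      others <- x[, -c(i, j), drop = FALSE]
      ri <- if (ncol(others)) stats::lm.fit(cbind(1, others), x[, i])$residuals else x[, i] - mean(x[, i])
      rj <- if (ncol(others)) stats::lm.fit(cbind(1, others), x[, j])$residuals else x[, j] - mean(x[, j])
      out[i, j] <- out[j, i] <- cor(ri, rj)
    }
  }
  out
}

# Toy feature matrix: one strongly separated feature plus pure-noise
# features, for stepwise/LOOCV tests.
toy_separated <- function(n_per_group = 10L, n_noise = 4L, gap = 10,
                          seed = 42L) {
  set.seed(seed)
  n <- 2L * n_per_group
  x <- cbind(c(rnorm(n_per_group, 0), rnorm(n_per_group, gap)),
             matrix(rnorm(n * n_noise), n))
  colnames(x) <- c("signal", paste0("noise", seq_len(n_noise)))
  labels <- factor(rep(c("control", "case"), each = n_per_group),
                   levels = c("control", "case"))
  list(x = x, labels = labels)
}

# The desk-scale study cohort and its derived objects are expensive
# (~1,500 ARIMA fits), so they are computed once per test run and shared.
.desk_cache <- new.env(parent = emptyenv())

desk_pipeline_objects <- function() {
  if (!is.null(.desk_cache$obj)) return(.desk_cache$obj)
  cfg <- desk_config(master_seed = 7L)
  cohort <- generate_cohort(cfg)
  pw <- prewhiten_config(order = c(10L, 1L, 3L))
  sni_raw <- lapply(cohort$series, compute_sni, cfg = pw)
  adj <- fit_adjustment(sni_raw, cohort$subjects)
  sni_adj <- setNames(lapply(seq_along(sni_raw), function(i) {
    apply_adjustment(adj, sni_raw[[i]], cohort$subjects[i, ])
  }), cohort$subjects$subject_id)
  features <- feature_matrix(sni_adj)
  labels <- factor(cohort$subjects$group, levels = c("control", "case"))
  .desk_cache$obj <- list(config = cfg, cohort = cohort, sni_raw = sni_raw,
                          adjustment = adj, sni = sni_adj,
                          features = features, labels = labels)
  .desk_cache$obj
}
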