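#' Cohort simulation settings
#'
#' Builds the configuration for [generate_cohort()]. Defaults mirror the
#' acquisition and group structure of the MEG study the package models:
#' 248 axial gradiometer sensors sampled at 1017.25 Hz for 60 s, and five
#' diagnostic groups (control, current PTSD-like "case", subthreshold,
#' partial recovery, full recovery). [desk_config()] gives a reduced-scale
#' preset suitable for routine testing.
#'
#' The planted signal lives in the partial-correlation (SNI) domain: each
#' effect edge carries a Fisher-z coupling of `effect_shift` times a
#' group-dependent factor, plus between-subject noise of SD `edge_noise_sd`.
#' Nuisance edges carry linear age and additive gender effects. Severity
#' scores follow a linear model in the subject's planted effect magnitude,
#' clipped to the 0--80 instrument range; controls have no score.
#'
#' @param n_sensors number of sensors (channels).
#' @param n_samples samples per sensor (60 s at 1017.25 Hz by default).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param group_sizes named integer vector of subjects per diagnostic group;
#'   must contain at least `control` and `case`.
#' @param n_effect_edges number of sensor pairs carrying the group effect.
#' @param effect_shift mean SNI shift (z-units) on effect edges between the
#'   two reference groups.
#' @param edge_noise_sd between-subject SD of edge coupling (z-units).
#' @param n_nuisance_edges number of sensor pairs carrying age/gender effects.
#' @param age_range min/max subject age in years (uniform draw).
#' @param age_slope SNI change per year of age on nuisance edges (z/yr).
#' @param gender_shift additive SNI offset for female subjects on nuisance
#'   edges (z-units).
#' @param p_female probability a subject is female.
#' @param group_factors multipliers applied to `effect_shift` per non-control
#'   group. `case` and `subthreshold` are scalars; `partial_recovery` and
#'   `full_recovery` are mixtures: a fraction `frac_on` of subjects at factor
#'   1, the remainder at 0, reflecting the mixed recovery outcomes the
#'   discriminant is meant to resolve.
#' @param severity_model list with `intercept`, `slope`, `noise_sd`: severity
#'   = intercept + slope * planted magnitude + Gaussian noise, clipped to
#'   \[0, 80\].
#' @param persistence lag-1 coefficient of the latent AR(1) sources.
#' @param sensor_noise_sd SD of independent white sensor noise (innovation
#'   units; source innovations have unit SD).
#' @param master_seed integer master seed; per-subject streams are derived
#'   by a counter-based split, so subject k of a group is invariant to
#'   cohort size.
#' @return a `cohort_config` list.
#' @seealso [generate_cohort()], [generate_subject_timeseries()]
#' @export
cohort_config <- function(n_sensors = 248L,
                          n_samples = 61035L,
                          sampling_rate_hz = 1017.25,
                          group_sizes = c(control = 87L, case = 88L,
                                          subthreshold = 13L,
                                          partial_recovery = 19L,
                                          full_recovery = 12L),
                          n_effect_edges = 12L,
                          effect_shift = 1.0,
                          edge_noise_sd = 0.2,
                          n_nuisance_edges = 8L,
                          age_range = c(30, 70),
                          age_slope = 0.005,
                          gender_shift = 0.2,
                          p_female = 0.15,
                          group_factors = list(case = 1.0,
                                               subthreshold = 0.8,
                                               partial_recovery = list(frac_on = 0.75),
                                               full_recovery = list(frac_on = 0.5)),
                          severity_model = list(intercept = 12, slope = 38,
                                                noise_sd = 8),
                          persistence = 0.95,
                          sensor_noise_sd = 0.1,
                          master_seed = 1L) {
  n_sensors <- as.integer(n_sensors)
  n_samples <- as.integer(n_samples)
  if (n_sensors < 2L || n_samples < 2L) {
    stop("n_sensors and n_samples must both be >= 2")
  }
  if (!all(c("control", "case") %in% names(group_sizes))) {
    stop("group_sizes must contain at least the labels 'control' and 'case'")
  }
  bad <- setdiff(names(group_sizes), cohort_group_levels())
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(cohort_group_levels(), collapse = ", "))
  }
  if (group_sizes[["control"]] < 2L || group_sizes[["case"]] < 2L) {
    stop("reference groups 'control' and 'case' need >= 2 subjects each")
  }
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  npairs <- n_sensors * (n_sensors - 1L) / 2
  if (n_effect_edges < 1L || n_effect_edges > npairs) {
    stop("n_effect_edges must be in [1, n_sensors*(n_sensors-1)/2]")
  }
  if (n_effect_edges + n_nuisance_edges > npairs) {
    stop("effect edges cannot be placed disjoint from nuisance edges: ",
         n_effect_edges, " + ", n_nuisance_edges, " > ", npairs, " pairs")
  }
  if (edge_noise_sd <= 0) stop("edge_noise_sd must be positive")
  if (severity_model$noise_sd <= 0) stop("severity noise_sd must be positive")
  if (length(age_range) != 2L || diff(age_range) < 0) {
    stop("age_range must be (min, max) with min <= max")
  }
  structure(list(
    n_sensors = n_sensors, n_samples = n_samples,
    sampling_rate_hz = sampling_rate_hz,
    group_sizes = group_sizes,
    n_effect_edges = as.integer(n_effect_edges),
    effect_shift = effect_shift, edge_noise_sd = edge_noise_sd,
    n_nuisance_edges = as.integer(n_nuisance_edges),
    age_range = age_range, age_slope = age_slope,
    gender_shift = gender_shift, p_female = p_female,
    group_factors = group_factors, severity_model = severity_model,
    persistence = persistence, sensor_noise_sd = sensor_noise_sd,
    master_seed = as.integer(master_seed)
  ), class = "cohort_config")
}

#' @rdname cohort_config
#' @param ... overrides passed on to [cohort_config()].
#' @export
desk_config <- function(...) {
  defaults <- list(n_sensors = 24L, n_samples = 4000L,
                   group_sizes = c(control = 30L, case = 30L),
                   n_effect_edges = 12L)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

cohort_group_levels <- function() {
  c("control", "case", "subthreshold", "partial_recovery", "full_recovery")
}

#' One subject's multichannel sensor recording
#'
#' Lightweight container for a sensors-by-samples matrix with sampling
#' metadata. Rows are sensors, columns are time samples.
#'
#' @param values numeric matrix, sensors in rows.
#' @param sampling_rate_hz positive sampling rate.
#' @param sensor_labels character labels, one per row.
#' @return a `sensor_ts` object.
#' @export
sensor_ts <- function(values, sampling_rate_hz = 1017.25,
                      sensor_labels = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("sensor time series must not contain missing values")
  if (is.null(sensor_labels)) sensor_labels <- sensor_labels_for(nrow(values))
  if (length(sensor_labels) != nrow(values)) {
    stop("sensor_labels length must equal the number of rows")
  }
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  rownames(values) <- sensor_labels
  structure(list(values = values, sampling_rate_hz = sampling_rate_hz,
                 sensor_labels = sensor_labels),
            class = "sensor_ts")
}

#' @export
print.sensor_ts <- function(x, ...) {
  cat(sprintf("<sensor_ts> %d sensors x %d samples @ %.2f Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$sampling_rate_hz,
              ncol(x$values) / x$sampling_rate_hz))
  invisible(x)
}

#' Simulate one subject's sensor time series
#'
#' Latent unit-variance Gaussian innovations with correlation `coupling` are
#' drawn, each passed through an AR(1) filter (`persistence`), and
#' independent white sensor noise is added. Because every sensor carries the
#' same autoregressive dynamics, the zero-lag correlation of the innovations
#' recovered by prewhitening equals `coupling`, so partial correlations (and
#' hence SNI values) planted in the precision domain survive the round trip
#' through the time domain.
#'
#' @param n_sensors,n_samples dimensions of the output matrix.
#' @param coupling symmetric positive-semidefinite matrix (after diagonal
#'   loading) giving the innovation correlation structure.
#' @param seed integer seed for this subject's stream.
#' @param persistence AR(1) coefficient of the latent sources.
#' @param sensor_noise_sd SD of added white sensor noise.
#' @param sampling_rate_hz sampling rate recorded in the result.
#' @param burn_in AR warm-up samples discarded.
#' @return a [sensor_ts()].
#' @export
generate_subject_timeseries <- function(n_sensors, n_samples, coupling, seed,
                                        persistence = 0.95,
                                        sensor_noise_sd = 0.1,
                                        sampling_rate_hz = 1017.25,
                                        burn_in = 200L) {
  n_sensors <- as.integer(n_sensors)
  n_samples <- as.integer(n_samples)
  if (n_samples <= n_sensors) {
    stop("n_samples (", n_samples, ") must exceed n_sensors (", n_sensors, ")")
  }
  coupling <- as.matrix(coupling)
  if (!isTRUE(all.equal(coupling, t(coupling), tolerance = 1e-10))) {
    stop("coupling matrix must be symmetric")
  }
  if (nrow(coupling) != n_sensors) stop("coupling must be n_sensors x n_sensors")
  ev <- eigen(coupling, symmetric = TRUE, only.values = TRUE)$values
  min_ev <- min(ev)
  if (min_ev < -1e-8) {
    stop(sprintf(
      "coupling matrix is not positive semidefinite after diagonal loading (offending eigenvalue %.6g)",
      min_ev))
  }
  load <- max(0, 1e-10 - min_ev) + 1e-12
  cc <- stats::cov2cor(coupling + diag(load, n_sensors))
  ch <- chol(cc)
  with_seed(seed, {
    total <- n_samples + burn_in
    innov <- matrix(rnorm(total * n_sensors), total, n_sensors) %*% ch
    x <- apply(innov, 2L, function(e) {
      as.numeric(stats::filter(e, persistence, method = "recursive"))
    })
    x <- x[(burn_in + 1L):total, , drop = FALSE]
    if (sensor_noise_sd > 0) {
      x <- x + matrix(rnorm(n_samples * n_sensors, sd = sensor_noise_sd),
                      n_samples, n_sensors)
    }
    sensor_ts(t(x), sampling_rate_hz = sampling_rate_hz)
  })
}

# Per-subject planted magnitude for a diagnostic group. Mixture groups draw
# their on/off state from the subject's own stream.
group_magnitude <- function(group, group_factors) {
  switch(group,
         control = 0,
         case = group_factors$case,
         subthreshold = group_factors$subthreshold,
         partial_recovery = {
           if (runif(1) < group_factors$partial_recovery$frac_on) 1 else 0
         },
         full_recovery = {
           if (runif(1) < group_factors$full_recovery$frac_on) 1 else 0
         },
         stop("unknown group: ", group))
}

# Precision matrix with planted partial correlations: unit diagonal,
# Omega[i,j] = -tanh(z_ij). Because partial correlations are invariant to
# diagonal scaling of the precision matrix, PCC_ij = tanh(z_ij) exactly.
#
# Positive definiteness: the effect edges form a sensor-disjoint matching
# (2x2 blocks, always PD for |rho| < 1), so when nuisance edges chaining
# onto effect sensors push the matrix off PD, only the nuisance entries are
# shrunk (bisection on the smallest eigenvalue) -- the planted effect
# partials stay exact. A residual non-PD matrix (overflow effect edges
# chaining among themselves) falls back to a global shrink, erroring below
# 0.7 where the planted values would be heavily distorted.
coupling_from_edges <- function(n_sensors, effect_edges, z_eff,
                                nuisance_edges, z_nui) {
  fill <- function(base, edges, z) {
    for (e in seq_len(nrow(edges))) {
      rho <- tanh(z[e])
      base[edges[e, 1L], edges[e, 2L]] <- -rho
      base[edges[e, 2L], edges[e, 1L]] <- -rho
    }
    base
  }
  min_ev <- function(m) min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  omega_eff <- fill(diag(n_sensors), effect_edges, z_eff)
  build <- function(s) fill(omega_eff, nuisance_edges, atanh(s * tanh(z_nui)))
  omega <- build(1)
  if (min_ev(omega) < 1e-3) {
    if (min_ev(omega_eff) >= 1e-3) {
      lo <- 0; hi <- 1
      for (it in 1:25) {
        mid <- (lo + hi) / 2
        if (min_ev(build(mid)) >= 1e-3) lo <- mid else hi <- mid
      }
      omega <- build(lo)
    } else {
      me <- min_ev(omega)
      s <- (1 - 1e-3) / (1 - me)
      if (s < 0.7) {
        stop(sprintf(
          "planted precision matrix is not positive definite (offending eigenvalue %.6g); reduce effect_shift or edge density",
          me))
      }
      omega <- diag(n_sensors) + s * (omega - diag(n_sensors))
    }
  }
  stats::cov2cor(solve(omega))
}

# Effect edges are drawn as a sensor-disjoint random matching wherever
# possible, so the large planted partial correlations do not stack on one
# sensor; overflow edges and nuisance edges are uniform over the remaining
# pairs.
draw_edges <- function(n_sensors, n_effect, n_nuisance) {
  pairs <- pair_index(n_sensors)
  pair_id <- function(i, j) ((j - 1L) * (j - 2L)) %/% 2L + i  # i < j
  perm <- sample.int(n_sensors)
  n_match <- min(n_effect, n_sensors %/% 2L)
  eff <- t(vapply(seq_len(n_match), function(k) {
    sort(c(perm[2L * k - 1L], perm[2L * k]))
  }, integer(2)))
  used <- pair_id(eff[, 1L], eff[, 2L])
  remaining <- setdiff(seq_len(nrow(pairs)), used)
  extra_n <- n_effect - n_match + n_nuisance
  extra <- if (extra_n > 0L) sample(remaining, extra_n) else integer(0)
  if (n_effect > n_match) {
    eff <- rbind(eff, pairs[extra[seq_len(n_effect - n_match)], , drop = FALSE])
  }
  nui <- if (n_nuisance > 0L) {
    pairs[extra[(n_effect - n_match + 1L):extra_n], , drop = FALSE]
  } else matrix(integer(0), 0L, 2L)
  list(effect = unname(eff), nuisance = unname(nui))
}

#' Generate a synthetic MEG-like cohort with planted connectivity effects
#'
#' Draws subjects per the configured group sizes, plants a group-dependent
#' SNI shift on a random set of effect edges and age/gender effects on a
#' disjoint set of nuisance edges, simulates each subject's sensor time
#' series, and assigns severity scores that increase with the planted effect
#' magnitude. All randomness derives from `config$master_seed` through
#' counter-based per-subject streams, so identical configurations reproduce
#' bit-identical cohorts and subject k of a group does not depend on the
#' sizes of other groups.
#'
#' @param config a [cohort_config()].
#' @return a list with `subjects` (data frame: subject_id, group, age,
#'   gender, severity_score), `series` (named list of [sensor_ts()]), and
#'   `ground_truth` (effect edges, nuisance edges, per-subject planted
#'   magnitudes and the planted edge z-values).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_sensors
  edges <- with_seed(derive_seed(config$master_seed, "edges"), {
    draw_edges(n, config$n_effect_edges, config$n_nuisance_edges)
  })
  effect_edges <- edges$effect
  nuisance_edges <- edges$nuisance
  age_mid <- mean(config$age_range)

  subjects <- list()
  series <- list()
  magnitudes <- numeric(0)
  planted_z <- list()
  for (grp in names(config$group_sizes)) {
    for (i in seq_len(config$group_sizes[[grp]])) {
      sid <- sprintf("%s_%03d", grp, i)
      covariates <- with_seed(derive_seed(config$master_seed,
                                          paste0("subject:", grp), i), {
        age <- runif(1, config$age_range[1], config$age_range[2])
        gender <- if (runif(1) < config$p_female) "female" else "male"
        mag <- group_magnitude(grp, config$group_factors)
        z_eff <- config$effect_shift * mag +
          rnorm(config$n_effect_edges, 0, config$edge_noise_sd)
        z_nui <- if (config$n_nuisance_edges > 0L) {
          config$age_slope * (age - age_mid) +
            config$gender_shift * (gender == "female") +
            rnorm(config$n_nuisance_edges, 0, config$edge_noise_sd)
        } else numeric(0)
        sev <- if (grp == "control") NA_real_ else {
          s <- config$severity_model$intercept +
            config$severity_model$slope * mag +
            rnorm(1, 0, config$severity_model$noise_sd)
          min(max(s, 0), 80)
        }
        list(age = age, gender = gender, mag = mag,
             z = c(z_eff, z_nui), severity = sev)
      })
      n_eff <- config$n_effect_edges
      coupling <- coupling_from_edges(
        n, effect_edges, covariates$z[seq_len(n_eff)],
        nuisance_edges, covariates$z[seq_len(length(covariates$z) - n_eff) + n_eff])
      series[[sid]] <- generate_subject_timeseries(
        n, config$n_samples, coupling,
        seed = derive_seed(config$master_seed, paste0("ts:", grp), i),
        persistence = config$persistence,
        sensor_noise_sd = config$sensor_noise_sd,
        sampling_rate_hz = config$sampling_rate_hz)
      subjects[[sid]] <- data.frame(
        subject_id = sid, group = grp, age = covariates$age,
        gender = covariates$gender, severity_score = covariates$severity,
        stringsAsFactors = FALSE)
      magnitudes[sid] <- covariates$mag
      planted_z[[sid]] <- covariates$z
    }
  }
  subjects <- do.call(rbind, subjects)
  rownames(subjects) <- NULL
  list(subjects = subjects,
       series = series,
       ground_truth = list(
         effect_edges = effect_edges,
         nuisance_edges = nuisance_edges,
         magnitudes = magnitudes,
         planted_z = do.call(rbind, planted_z),
         sensor_labels = sensor_labels_for(n)))
}

#' Write a cohort to disk
#'
#' Writes the metadata CSV (`subject_id,group,age,gender,severity_score`,
#' empty field = missing), one tab-delimited matrix per subject (sensors as
#' rows), the ground truth as JSON, and a manifest listing every file with
#' its MD5 checksum.
#'
#' @param cohort list with `subjects`, `series` and optionally
#'   `ground_truth`, as returned by [generate_cohort()].
#' @param out_dir output directory, created if needed.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the manifest path, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, out_dir, overwrite = FALSE) {
  stopifnot(is.list(cohort), !is.null(cohort$subjects), !is.null(cohort$series))
  if (nrow(cohort$subjects) != length(cohort$series)) {
    stop("subjects table and series list have inconsistent lengths")
  }
  if (dir.exists(out_dir) && length(dir(out_dir, all.files = TRUE, no.. = TRUE))) {
    if (!overwrite) {
      stop("output directory ", out_dir,
           " exists and is not empty; use overwrite = TRUE")
    }
  }
  dir.create(file.path(out_dir, "series"), recursive = TRUE, showWarnings = FALSE)

  meta_path <- file.path(out_dir, "metadata.csv")
  write.csv(cohort$subjects, meta_path, row.names = FALSE, na = "")

  series_files <- character(0)
  for (sid in cohort$subjects$subject_id) {
    p <- file.path("series", paste0(sid, ".tsv"))
    write.table(cohort$series[[sid]]$values, file.path(out_dir, p),
                sep = "\t", row.names = FALSE, col.names = FALSE)
    series_files <- c(series_files, p)
  }

  files <- c("metadata.csv", series_files)
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    jsonlite::write_json(
      list(effect_edges = gt$effect_edges,
           nuisance_edges = gt$nuisance_edges,
           magnitudes = as.list(gt$magnitudes),
           sensor_labels = gt$sensor_labels),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, "ground_truth.json")
  }

  checksums <- unname(tools::md5sum(file.path(out_dir, files)))
  sr <- cohort$series[[1L]]$sampling_rate_hz
  manifest <- list(
    n_subjects = nrow(cohort$subjects),
    n_sensors = nrow(cohort$series[[1L]]$values),
    n_samples = ncol(cohort$series[[1L]]$values),
    sampling_rate_hz = sr,
    sensor_labels = cohort$series[[1L]]$sensor_labels,
    files = data.frame(path = files, md5 = checksums,
                       stringsAsFactors = FALSE))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}
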