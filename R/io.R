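#' Read a cohort written by [write_cohort()]
#'
#' Verifies the manifest checksums, parses and validates the metadata CSV
#' (malformed rows are reported with their line numbers), and loads the
#' per-subject time-series matrices.
#'
#' @param dir cohort directory containing `manifest.json`.
#' @param verify check MD5 checksums against the manifest.
#' @return list with `subjects`, `series` (named list of [sensor_ts()]) and
#'   `ground_truth` (or `NULL` when absent).
#' @export
read_cohort <- function(dir, verify = TRUE) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  paths <- file.path(dir, manifest$files$path)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing cohort file(s): ",
         paste(manifest$files$path[missing], collapse = ", "))
  }
  if (verify) {
    sums <- unname(tools::md5sum(paths))
    bad <- sums != manifest$files$md5
    if (any(bad)) {
      stop("checksum mismatch for: ",
           paste(manifest$files$path[bad], collapse = ", "))
    }
  }
  meta <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE,
                   colClasses = "character")
  required <- c("subject_id", "group", "age", "gender", "severity_score")
  if (!all(required %in% names(meta))) {
    stop("metadata.csv must have columns ", paste(required, collapse = ", "))
  }
  age <- suppressWarnings(as.numeric(meta$age))
  bad_age <- which(is.na(age) & nzchar(meta$age))
  if (length(bad_age)) {
    stop("non-numeric age in metadata.csv row(s) ",
         paste(bad_age + 1L, collapse = ", "), " (header is row 1)")
  }
  sev <- suppressWarnings(as.numeric(meta$severity_score))
  bad_sev <- which(is.na(sev) & nzchar(meta$severity_score))
  if (length(bad_sev)) {
    stop("non-numeric severity_score in metadata.csv row(s) ",
         paste(bad_sev + 1L, collapse = ", "))
  }
  allowed <- cohort_group_levels()
  bad_grp <- which(!meta$group %in% allowed)
  if (length(bad_grp)) {
    stop("unknown group label(s) in metadata.csv row(s) ",
         paste(bad_grp + 1L, collapse = ", "),
         "; allowed labels: ", paste(allowed, collapse = ", "))
  }
  subjects <- data.frame(subject_id = meta$subject_id, group = meta$group,
                         age = age, gender = meta$gender,
                         severity_score = sev, stringsAsFactors = FALSE)

  sr <- manifest$sampling_rate_hz
  labels <- manifest$sensor_labels
  series <- setNames(lapply(subjects$subject_id, function(sid) {
    p <- file.path(dir, "series", paste0(sid, ".tsv"))
    m <- as.matrix(read.table(p, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    sensor_ts(m, sampling_rate_hz = sr, sensor_labels = labels)
  }), subjects$subject_id)

  gt_path <- file.path(dir, "ground_truth.json")
  ground_truth <- if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    gt$magnitudes <- unlist(gt$magnitudes)
    gt
  } else NULL
  list(subjects = subjects, series = series, ground_truth = ground_truth)
}

#' Write / read an SNI matrix as delimited text
#'
#' Square tab-delimited text with the masked diagonal written as `NaN`.
#'
#' @param sni SNI matrix.
#' @param path file path.
#' @return `write_sni_matrix()` the path invisibly; `read_sni_matrix()` the
#'   matrix with the diagonal masked as `NA`.
#' @export
write_sni_matrix <- function(sni, path) {
  m <- as.matrix(sni)
  m[is.na(m)] <- NaN
  write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sni_matrix
#' @export
read_sni_matrix <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- list(sensor_labels_for(nrow(m)), sensor_labels_for(nrow(m)))
  m
}

#' Serialize / restore a discriminant model as JSON
#'
#' @param model a [fit_lda()] model.
#' @param path JSON file path.
#' @return `write_discriminant_model()` the path invisibly;
#'   `read_discriminant_model()` the model.
#' @export
write_discriminant_model <- function(model, path) {
  stopifnot(inherits(model, "discriminant_model"))
  obj <- list(selected = model$selected,
              feature_names = model$feature_names,
              full_length = model$full_length,
              coefficients = model$coefficients,
              constant = model$constant,
              centroids = model$centroids,
              pooled_cov = model$pooled_cov,
              groups = model$groups,
              priors = model$priors,
              n_per_group = model$n_per_group,
              ridge_applied = model$ridge_applied)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_discriminant_model
#' @export
read_discriminant_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- length(obj$selected)
  centroids <- if (is.matrix(obj$centroids)) obj$centroids else
    do.call(rbind, obj$centroids)
  dimnames(centroids) <- list(obj$groups, obj$feature_names)
  sp <- obj$pooled_cov
  if (!is.matrix(sp)) sp <- matrix(unlist(sp), k, k, byrow = TRUE)
  dimnames(sp) <- list(obj$feature_names, obj$feature_names)
  structure(list(selected = as.integer(obj$selected),
                 feature_names = obj$feature_names,
                 full_length = as.integer(obj$full_length),
                 coefficients = setNames(as.numeric(obj$coefficients),
                                         obj$feature_names),
                 constant = obj$constant,
                 centroids = centroids,
                 pooled_cov = sp, pooled_cov_inv = solve(sp),
                 groups = obj$groups, priors = as.numeric(obj$priors),
                 n_per_group = as.integer(obj$n_per_group),
                 ridge_applied = isTRUE(obj$ridge_applied)),
            class = "discriminant_model")
}
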