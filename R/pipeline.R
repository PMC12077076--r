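#' Pipeline settings
#'
#' Bundles the stage configurations for [run_pipeline()].
#'
#' @param reference_groups the two diagnostic groups that train the
#'   discriminant; the first is the reference ("control") side.
#' @param prewhiten a [prewhiten_config()].
#' @param criteria a [stepwise_criteria()].
#' @param threshold a [network_threshold_config()].
#' @param ridge ridge loading for the partial-correlation stage.
#' @param adjust fit and apply the age/gender adjustment.
#' @param run_loocv run leave-one-out cross-validation on the reference
#'   groups (selection inside each fold).
#' @param out_dir optional output directory for the report bundle.
#' @param master_seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(reference_groups = c("control", "case"),
                            prewhiten = prewhiten_config(),
                            criteria = stepwise_criteria(),
                            threshold = network_threshold_config(),
                            ridge = 1e-6,
                            adjust = TRUE,
                            run_loocv = TRUE,
                            out_dir = NULL,
                            master_seed = NA_integer_) {
  if (length(unique(reference_groups)) != 2L) {
    stop("reference_groups must name exactly two distinct groups")
  }
  structure(list(reference_groups = reference_groups, prewhiten = prewhiten,
                 criteria = criteria, threshold = threshold, ridge = ridge,
                 adjust = adjust, run_loocv = run_loocv, out_dir = out_dir,
                 master_seed = master_seed),
            class = "pipeline_config")
}

#' Run the full SNI classification pipeline
#'
#' Executes, in order: per-subject SNI computation (prewhitening, partial
#' correlations, Fisher z), age/gender adjustment fitted on the reference
#' groups and applied to all subjects, per-sensor min/max feature
#' extraction, stepwise LDA on the reference groups, leave-one-out
#' cross-validation with selection inside each fold, scoring of every
#' subject (discriminant score, posteriors, Mahalanobis D2 and normalized
#' distances), classification of the held-out diagnostic groups, the
#' thresholded feature-sensor network, and severity statistics. Any stage
#' error aborts with the stage name; partially written outputs are removed.
#'
#' @param cohort a cohort directory (see [read_cohort()]) or an in-memory
#'   list with `subjects` and `series`.
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list (invisibly when written to disk):
#'   `model`, `selection`, `loocv`, `results` (per-case data frame),
#'   `group_classifications`, `network`, `severity`, `summary`, `timings`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, stage) {
    timings[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
  }

  written <- character(0)
  emit <- function(path, writer) {
    writer(path)
    written <<- c(written, path)
  }
  on_error_cleanup <- function(e) {
    unlink(written)
    stop(e)
  }

  tryCatch({
    t0 <- tic()
    if (is.character(cohort)) cohort <- read_cohort(cohort)
    subjects <- cohort$subjects
    ref <- config$reference_groups
    present <- unique(subjects$group)
    if (!all(ref %in% present)) {
      stop("[config] reference group(s) not present in metadata: ",
           paste(setdiff(ref, present), collapse = ", "))
    }
    toc(t0, "read")

    t0 <- tic()
    sni_list <- lapply(cohort$series, function(ts) {
      compute_sni(ts, config$prewhiten, ridge = config$ridge)
    })
    toc(t0, "sni")

    t0 <- tic()
    is_ref <- subjects$group %in% ref
    if (config$adjust) {
      adj_model <- fit_adjustment(sni_list[is_ref], subjects[is_ref, ])
      sni_list <- lapply(seq_along(sni_list), function(i) {
        apply_adjustment(adj_model, sni_list[[i]], subjects[i, ])
      })
      names(sni_list) <- subjects$subject_id
    } else {
      adj_model <- NULL
    }
    toc(t0, "adjust")

    t0 <- tic()
    features <- feature_matrix(sni_list)
    toc(t0, "features")

    t0 <- tic()
    ref_feat <- features[is_ref, , drop = FALSE]
    ref_labels <- factor(subjects$group[is_ref], levels = ref)
    selection <- stepwise_select(ref_feat, ref_labels, config$criteria)
    if (selection$status == "empty") {
      stop("[stepwise] no feature met the entry criterion")
    }
    model <- fit_lda(ref_feat, ref_labels, selection$selected)
    toc(t0, "train")

    t0 <- tic()
    cv <- if (config$run_loocv) {
      loocv(ref_feat, ref_labels, config$criteria,
            subject_ids = subjects$subject_id[is_ref])
    } else NULL
    toc(t0, "loocv")

    t0 <- tic()
    all_scores <- classify_cohort(model, features, group_label = "all")$results
    results <- cbind(subject_id = subjects$subject_id,
                     group = subjects$group,
                     all_scores[, setdiff(names(all_scores), "subject_id")],
                     stringsAsFactors = FALSE)
    heldout <- setdiff(present, ref)
    group_classifications <- setNames(lapply(heldout, function(g) {
      classify_cohort(model, features[subjects$group == g, , drop = FALSE],
                      group_label = g)
    }), heldout)
    toc(t0, "classify")

    t0 <- tic()
    feat_sensors <- unique(sub("^(min|max)_", "", model$feature_names))
    network <- if (length(feat_sensors) >= 2L) {
      mean_sni <- Reduce(`+`, sni_list[is_ref]) / sum(is_ref)
      threshold_network(mean_sni[feat_sensors, feat_sensors, drop = FALSE],
                        config$threshold)
    } else NULL
    toc(t0, "network")

    t0 <- tic()
    d2_ref_col <- paste0("d2_", ref[1L])
    has_sev <- !is.na(subjects$severity_score)
    severity <- list()
    if (sum(has_sev) >= 3L) {
      severity$association <- severity_association(
        subjects$severity_score[has_sev], results[[d2_ref_col]][has_sev])
      by_assigned <- split(subjects$severity_score[has_sev],
                           results$assigned[has_sev])
      if (length(by_assigned) == 2L &&
          all(vapply(by_assigned, function(v) sum(!is.na(v)) >= 2L, logical(1)))) {
        severity$comparison <- group_ttest(
          by_assigned[[ref[1L]]], by_assigned[[ref[2L]]],
          group_names = paste("classified as", ref))
      }
    }
    summary_tables <- summarize_groups(results, subjects,
                                       d2_column = d2_ref_col)
    toc(t0, "severity")

    report <- structure(list(
      model = model, selection = selection, adjustment = adj_model,
      loocv = cv, results = results,
      group_classifications = group_classifications,
      network = network, severity = severity, summary = summary_tables,
      reference_groups = ref, timings = timings,
      config = config), class = "pipeline_report")

    if (!is.null(config$out_dir)) {
      out <- config$out_dir
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      emit(file.path(out, "resolved_config.json"), function(p) {
        cfg <- config
        cfg$out_dir <- NULL
        jsonlite::write_json(unclass_deep(cfg), p, auto_unbox = TRUE,
                             digits = NA, null = "null")
      })
      emit(file.path(out, "model.json"), function(p) {
        write_discriminant_model(model, p)
      })
      emit(file.path(out, "results.csv"), function(p) {
        write.csv(results, p, row.names = FALSE)
      })
      if (!is.null(cv)) {
        emit(file.path(out, "loocv.csv"), function(p) {
          write.csv(cv$folds, p, row.names = FALSE)
        })
      }
      emit(file.path(out, "summary_d2.csv"), function(p) {
        write.csv(summary_tables$d2_table, p, row.names = FALSE)
      })
      emit(file.path(out, "assignment_summary.csv"), function(p) {
        write.csv(summary_tables$assignment_table, p, row.names = FALSE)
      })
      if (length(severity)) {
        emit(file.path(out, "severity.json"), function(p) {
          jsonlite::write_json(unclass_deep(severity), p, auto_unbox = TRUE,
                               digits = NA)
        })
      }
      if (!is.null(network)) {
        emit(file.path(out, "network.csv"), function(p) {
          write.csv(network$edges, p, row.names = FALSE)
        })
      }
      emit(file.path(out, "run_log.txt"), function(p) {
        lines <- c(
          sprintf("megsni pipeline run, %s", format(t_start)),
          sprintf("master_seed: %s", config$master_seed),
          sprintf("reference groups: %s", paste(ref, collapse = " vs ")),
          sprintf("prewhiten order: (%s), method %s",
                  paste(config$prewhiten$order, collapse = ","),
                  config$prewhiten$estimation_method),
          sprintf("stepwise: F-enter %.3g, F-remove %.3g",
                  config$criteria$f_to_enter, config$criteria$f_to_remove),
          sprintf("selected features (%d): %s", length(model$selected),
                  paste(model$feature_names, collapse = ", ")),
          if (!is.null(cv)) sprintf("LOOCV accuracy: %.4f", cv$accuracy),
          "stage timings (s):",
          sprintf("  %s: %.2f", names(timings), unlist(timings)))
        writeLines(lines, p)
      })
    }
    invisible(report)
  }, error = on_error_cleanup)
}

# Recursively strip S3 classes so jsonlite serializes plain lists.
unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %s vs %s\n", x$reference_groups[1L],
              x$reference_groups[2L]))
  cat(sprintf("  selected features: %d\n", length(x$model$selected)))
  if (!is.null(x$loocv)) {
    cat(sprintf("  LOOCV accuracy: %.1f%%\n", 100 * x$loocv$accuracy))
  }
  for (gc in x$group_classifications) print(gc)
  if (!is.null(x$severity$association)) {
    cat("  severity vs D2(control): "); print(x$severity$association)
  }
  invisible(x)
}
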