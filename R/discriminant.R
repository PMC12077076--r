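#' Per-sensor min/max SNI features
#'
#' For each sensor, the minimum and maximum of its n-1 SNI values with all
#' other sensors. The returned vector holds all minima in sensor order,
#' then all maxima, so its length is 2 x n_sensors (496 at the full
#' 248-sensor scale).
#'
#' @param sni SNI matrix (masked diagonal).
#' @return named numeric vector `min_<label>...max_<label>`.
#' @export
extract_minmax_features <- function(sni) {
  sni <- as.matrix(sni)
  n <- nrow(sni)
  if (n < 2L) stop("need at least 2 sensors")
  if (any(rowSums(!is.na(sni)) == 0L)) {
    labs <- rownames(sni) %||% sensor_labels_for(n)
    stop("fully masked sensor row(s): ",
         paste(labs[rowSums(!is.na(sni)) == 0L], collapse = ", "))
  }
  labs <- rownames(sni) %||% sensor_labels_for(n)
  mins <- apply(sni, 1L, min, na.rm = TRUE)
  maxs <- apply(sni, 1L, max, na.rm = TRUE)
  setNames(c(mins, maxs), c(paste0("min_", labs), paste0("max_", labs)))
}

#' Stack per-subject feature vectors into a matrix
#'
#' @param sni_list list of SNI matrices.
#' @return subjects x features matrix.
#' @export
feature_matrix <- function(sni_list) {
  rows <- lapply(sni_list, extract_minmax_features)
  out <- do.call(rbind, rows)
  rownames(out) <- names(sni_list)
  out
}

#' Stepwise selection settings
#'
#' Entry/removal thresholds for the Wilks' lambda stepwise discriminant
#' procedure. The defaults (F-to-enter 3.84, F-to-remove 2.71) are the
#' conventional defaults of classical stepwise discriminant software.
#'
#' @param f_to_enter minimum partial F for a feature to enter.
#' @param f_to_remove partial F below which an entered feature is removed;
#'   must be smaller than `f_to_enter` to prevent cycling.
#' @param max_steps cap on enter/remove actions.
#' @return a `stepwise_criteria` list.
#' @export
stepwise_criteria <- function(f_to_enter = 3.84, f_to_remove = 2.71,
                              max_steps = 1000L) {
  if (f_to_enter <= 0 || f_to_remove <= 0) stop("F thresholds must be positive")
  if (f_to_remove >= f_to_enter) {
    stop("f_to_remove must be smaller than f_to_enter (prevents cycling)")
  }
  structure(list(f_to_enter = f_to_enter, f_to_remove = f_to_remove,
                 max_steps = as.integer(max_steps)),
            class = "stepwise_criteria")
}

# Wilks' lambda machinery: within-group (W) and total (T) cross-product
# matrices computed once; Lambda(S) = det(W_S) / det(T_S).
sscp_matrices <- function(x, labels) {
  xt <- scale(x, center = TRUE, scale = FALSE)
  tot <- crossprod(xt)
  w <- matrix(0, ncol(x), ncol(x))
  for (g in levels(labels)) {
    xg <- x[labels == g, , drop = FALSE]
    xg <- scale(xg, center = TRUE, scale = FALSE)
    w <- w + crossprod(xg)
  }
  list(W = w, T = tot)
}

wilks_lambda <- function(sscp, s) {
  if (!length(s)) return(1)
  dw <- det(sscp$W[s, s, drop = FALSE])
  dt <- det(sscp$T[s, s, drop = FALSE])
  if (!is.finite(dt) || dt <= 1e-300) return(NA_real_)
  if (!is.finite(dw) || dw < 0) return(NA_real_)
  dw / dt
}

#' Stepwise feature selection by Wilks' lambda
#'
#' Greedy add/remove selection for a two-group discriminant. At each step
#' every in-model feature whose partial F falls below `f_to_remove` is
#' removed (smallest first), then the candidate with the largest partial F
#' enters if it reaches `f_to_enter`; ties break toward the lowest feature
#' index. The partial F statistics are the classical lambda-ratio tests
#' F_enter = (n - g - k) (Lambda_k / Lambda_{k+1} - 1) / (g - 1) and the
#' analogous removal test, with g = 2 groups and k features in the model.
#'
#' @param features subjects x features numeric matrix.
#' @param labels two-level factor (or coercible) of group membership.
#' @param criteria a [stepwise_criteria()].
#' @return a `stepwise_selection` list: `selected` (sorted indices),
#'   `order_entered`, `status` (`"ok"` or `"empty"` when no feature meets
#'   the entry criterion), and a step `log` with lambda and F per action.
#' @export
stepwise_select <- function(features, labels, criteria = stepwise_criteria()) {
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("stepwise_select requires exactly two groups")
  if (any(table(labels) < 2L)) stop("each group needs at least 2 subjects")
  n <- nrow(features)
  g <- 2L
  p <- ncol(features)
  sscp <- sscp_matrices(features, labels)

  selected <- integer(0)
  log_rows <- list()
  lambda_cur <- 1
  steps <- 0L
  repeat {
    changed <- FALSE
    # removal phase
    while (length(selected) > 1L && steps < criteria$max_steps) {
      k <- length(selected)
      f_rem <- vapply(selected, function(j) {
        lam_wo <- wilks_lambda(sscp, setdiff(selected, j))
        if (is.na(lam_wo) || lambda_cur <= 0) return(Inf)
        (n - g - k + 1) / (g - 1) * (lam_wo / lambda_cur - 1)
      }, numeric(1))
      worst <- which(f_rem == min(f_rem))[1L]
      if (f_rem[worst] < criteria$f_to_remove) {
        j <- selected[worst]
        selected <- setdiff(selected, j)
        lambda_cur <- wilks_lambda(sscp, selected)
        steps <- steps + 1L
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          step = steps, action = "remove", feature = j,
          lambda = lambda_cur, F = f_rem[worst])
        changed <- TRUE
      } else break
    }
    # entry phase
    if (steps >= criteria$max_steps) break
    k <- length(selected)
    if (n - g - k < 1L) break
    cands <- setdiff(seq_len(p), selected)
    if (!length(cands)) break
    f_ent <- vapply(cands, function(j) {
      lam_new <- wilks_lambda(sscp, c(selected, j))
      if (is.na(lam_new)) return(-Inf)            # collinear candidate
      if (lam_new < 1e-14) return(Inf)            # complete separation
      (n - g - k) / (g - 1) * (lambda_cur / lam_new - 1)
    }, numeric(1))
    best <- which(f_ent == max(f_ent))[1L]
    if (is.finite(f_ent[best]) || f_ent[best] == Inf) {
      if (f_ent[best] >= criteria$f_to_enter) {
        j <- cands[best]
        selected <- c(selected, j)
        lambda_cur <- wilks_lambda(sscp, selected)
        steps <- steps + 1L
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          step = steps, action = "enter", feature = j,
          lambda = lambda_cur, F = f_ent[best])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(step = integer(0), action = character(0), feature = integer(0),
               lambda = numeric(0), F = numeric(0))
  order_entered <- log_df$feature[log_df$action == "enter"]
  order_entered <- order_entered[order_entered %in% selected]
  structure(list(selected = sort(selected),
                 order_entered = order_entered,
                 status = if (length(selected)) "ok" else "empty",
                 lambda = lambda_cur,
                 log = log_df,
                 feature_names = colnames(features)),
            class = "stepwise_selection")
}

#' Fit a two-class linear discriminant on selected features
#'
#' Equal-prior two-group LDA: group centroids and pooled within-group
#' covariance in the selected-feature space, with discriminant direction
#' a = S_pooled^{-1} (mu_2 - mu_1) and constant centring the boundary
#' between the centroids. The first factor level is the reference group
#' (control); positive scores indicate the second group.
#'
#' @param features subjects x features matrix (full feature space).
#' @param labels two-level factor; first level is the reference (control).
#' @param selected feature column indices to use (default: all).
#' @param ridge covariance loading; `NULL` (default) auto-loads a singular
#'   pooled covariance by 1e-8 * trace/p and flags it, `0` errors instead.
#' @return a `discriminant_model`.
#' @export
fit_lda <- function(features, labels, selected = seq_len(ncol(features)),
                    ridge = NULL) {
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("fit_lda requires exactly two groups")
  if (!length(selected)) stop("selection is empty; nothing to fit")
  x <- features[, selected, drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  groups <- levels(labels)
  mu <- rbind(colMeans(x[labels == groups[1L], , drop = FALSE]),
              colMeans(x[labels == groups[2L], , drop = FALSE]))
  rownames(mu) <- groups
  w <- matrix(0, k, k)
  for (g in groups) {
    xg <- scale(x[labels == g, , drop = FALSE], center = TRUE, scale = FALSE)
    w <- w + crossprod(xg)
  }
  sp <- w / (n - 2L)
  ridge_applied <- FALSE
  ok <- is.finite(rcond(sp)) && rcond(sp) > .Machine$double.eps * 10
  if (!ok) {
    if (!is.null(ridge) && ridge == 0) {
      stop("singular pooled covariance; supply a positive ridge or allow auto-loading")
    }
    load <- ridge %||% (1e-8 * sum(diag(sp)) / k)
    sp <- sp + diag(load, k)
    ridge_applied <- TRUE
    if (rcond(sp) <= .Machine$double.eps * 10) {
      stop("pooled covariance remains singular after ridge loading")
    }
  }
  sp_inv <- solve(sp)
  a <- drop(sp_inv %*% (mu[2L, ] - mu[1L, ]))
  const <- -sum(a * (mu[1L, ] + mu[2L, ])) / 2
  structure(list(selected = selected,
                 feature_names = colnames(features)[selected],
                 full_length = ncol(features),
                 coefficients = a, constant = const,
                 centroids = mu, pooled_cov = sp, pooled_cov_inv = sp_inv,
                 groups = groups, priors = c(0.5, 0.5),
                 n_per_group = as.integer(table(labels)[groups]),
                 ridge_applied = ridge_applied),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> %s vs %s, %d features: %s\n",
              x$groups[1L], x$groups[2L], length(x$selected),
              paste(utils::head(x$feature_names, 6L), collapse = ", ")))
  invisible(x)
}

#' Normalize a pair of Mahalanobis distances to the 0-1 range
#'
#' Each squared distance is divided by the sum of the two, giving
#' complementary values that add to 1 exactly: a case's normalized distance
#' from the control centroid and from the case centroid.
#'
#' @param d2_control,d2_case non-negative squared Mahalanobis distances.
#' @return list with `control` and `case` components summing to 1.
#' @export
normalize_d2 <- function(d2_control, d2_case) {
  if (any(d2_control < 0) || any(d2_case < 0)) stop("D2 values must be non-negative")
  tot <- d2_control + d2_case
  if (any(tot == 0)) {
    stop("both distances are zero (identical centroids); normalization undefined")
  }
  list(control = d2_control / tot, case = d2_case / tot)
}

#' Score one case with a fitted discriminant model
#'
#' Computes the discriminant score, the squared Mahalanobis distance to
#' each group centroid under the pooled covariance, equal-prior Gaussian
#' posteriors, normalized distances, and the assigned group (smaller D2;
#' ties go to the reference group). These three views agree by
#' construction: the score's sign, the larger posterior and the smaller D2
#' all name the same group.
#'
#' @param model a [fit_lda()] model.
#' @param fv feature vector of full length (subset internally) or of the
#'   selected length.
#' @param subject_id optional identifier carried into the result.
#' @return one-row data frame: `subject_id`, `score`, then `p_<group>`,
#'   `d2_<group>`, `dprime2_<group>` for each group, and `assigned`.
#' @export
score_case <- function(model, fv, subject_id = NA_character_) {
  stopifnot(inherits(model, "discriminant_model"))
  fv <- as.numeric(fv)
  k <- length(model$selected)
  x <- if (length(fv) == model$full_length) {
    fv[model$selected]
  } else if (length(fv) == k) {
    fv
  } else {
    stop("feature vector length ", length(fv), " matches neither the full (",
         model$full_length, ") nor the selected (", k, ") feature space")
  }
  score <- sum(model$coefficients * x) + model$constant
  d2 <- c(mahalanobis(x, model$centroids[1L, ], model$pooled_cov_inv,
                      inverted = TRUE),
          mahalanobis(x, model$centroids[2L, ], model$pooled_cov_inv,
                      inverted = TRUE))
  d2 <- pmax(d2, 0)
  lg <- -d2 / 2
  post <- exp(lg - max(lg)); post <- post / sum(post)
  dp <- normalize_d2(d2[1L], d2[2L])
  assigned <- if (d2[2L] < d2[1L]) model$groups[2L] else model$groups[1L]
  out <- data.frame(subject_id = subject_id, score = score,
                    stringsAsFactors = FALSE)
  out[paste0("p_", model$groups)] <- as.list(post)
  out[paste0("d2_", model$groups)] <- as.list(d2)
  out[paste0("dprime2_", model$groups)] <- list(dp$control, dp$case)
  out$assigned <- assigned
  out
}

#' Leave-one-out cross-validation with selection inside each fold
#'
#' For every subject, the stepwise selection and the discriminant fit are
#' re-run on the remaining subjects and the held-out subject is classified.
#' Folds whose selection is empty are classified by the prior (ties go to
#' the reference group, the first factor level) and flagged.
#'
#' @inheritParams stepwise_select
#' @param subject_ids optional identifiers for the fold records.
#' @return list with `accuracy` and a per-fold data frame (`subject_id`,
#'   `true`, `assigned`, `score`, `n_selected`, `empty_selection`).
#' @export
loocv <- function(features, labels, criteria = stepwise_criteria(),
                  subject_ids = NULL) {
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  n <- nrow(features)
  if (n < 4L) stop("LOOCV needs at least 4 subjects")
  if (is.null(subject_ids)) subject_ids <- rownames(features) %||% as.character(seq_len(n))
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    # a fold whose training set degenerates (e.g. a singleton group at
    # minimal n) is treated like an empty selection and judged by the prior
    sel <- tryCatch(
      stepwise_select(features[-i, , drop = FALSE], labels[-i], criteria),
      error = function(e) list(status = "empty"))
    if (sel$status == "empty") {
      folds[[i]] <- data.frame(subject_id = subject_ids[i],
                               true = as.character(labels[i]),
                               assigned = levels(labels)[1L],
                               score = NA_real_, n_selected = 0L,
                               empty_selection = TRUE,
                               stringsAsFactors = FALSE)
      next
    }
    model <- fit_lda(features[-i, , drop = FALSE], labels[-i], sel$selected)
    sc <- score_case(model, features[i, ], subject_id = subject_ids[i])
    folds[[i]] <- data.frame(subject_id = subject_ids[i],
                             true = as.character(labels[i]),
                             assigned = sc$assigned, score = sc$score,
                             n_selected = length(sel$selected),
                             empty_selection = FALSE,
                             stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, folds)
  list(accuracy = mean(folds$assigned == folds$true), folds = folds)
}

#' Classify a held-out cohort with a fitted discriminant model
#'
#' Scores each case and tallies how many were assigned to each reference
#' group, in the "k of n (p%) classified as control" form.
#'
#' @param model a [fit_lda()] model trained on the reference groups.
#' @param features feature matrix of the held-out cohort (full feature
#'   space), one row per case.
#' @param group_label label of the cohort being classified (bookkeeping).
#' @return a `group_classification` list: `group`, per-case `results`,
#'   assignment `counts` and `percentages`, and `n`.
#' @export
classify_cohort <- function(model, features, group_label = NA_character_) {
  features <- as.matrix(features)
  if (!nrow(features)) stop("empty cohort")
  ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  results <- do.call(rbind, lapply(seq_len(nrow(features)), function(i) {
    score_case(model, features[i, ], subject_id = ids[i])
  }))
  counts <- table(factor(results$assigned, levels = model$groups))
  structure(list(group = group_label, results = results,
                 counts = as.integer(counts),
                 percentages = 100 * as.integer(counts) / nrow(features),
                 reference_groups = model$groups, n = nrow(features)),
            class = "group_classification")
}

#' @export
print.group_classification <- function(x, ...) {
  cat(sprintf("<group_classification> %s (n = %d):\n", x$group, x$n))
  for (i in seq_along(x$reference_groups)) {
    cat(sprintf("  %d of %d (%.1f%%) classified as %s\n",
                x$counts[i], x$n, x$percentages[i], x$reference_groups[i]))
  }
  invisible(x)
}

#' Network threshold settings
#'
#' @param percentile percentile (default 25) of the |SNI| distribution over
#'   connections among the feature-sensors; connections strictly above it
#'   are retained. Percentile 0 retains every connection.
#' @return a `network_threshold_config`.
#' @export
network_threshold_config <- function(percentile = 25) {
  if (percentile < 0 || percentile >= 100) stop("percentile must be in [0, 100)")
  structure(list(percentile = percentile), class = "network_threshold_config")
}

# Connected components over an edge list by breadth-first search.
edge_components <- function(n, edges) {
  comp <- integer(n)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1L]; j <- edges[e, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L && length(adj[[s]])) {
      cur <- cur + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        if (comp[v] != 0L) next
        comp[v] <- cur
        queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
      }
    }
  }
  comp
}

#' Threshold a connectivity network among feature-sensors
#'
#' Computes the given percentile (linear interpolation) of the |SNI|
#' distribution over all connections among the supplied sensors and retains
#' the edges strictly above it, reporting the connected components these
#' edges form.
#'
#' @param sni_sub SNI submatrix over the feature-sensors (symmetric,
#'   masked diagonal).
#' @param cfg a [network_threshold_config()].
#' @return list with `threshold`, an `edges` data frame (from, to, sni,
#'   abs_sni), `components` (per-sensor membership, 0 = isolated) and
#'   `n_components`.
#' @export
threshold_network <- function(sni_sub, cfg = network_threshold_config()) {
  sni_sub <- as.matrix(sni_sub)
  n <- nrow(sni_sub)
  if (n < 2L) stop("need at least 2 feature-sensors")
  labs <- rownames(sni_sub) %||% sensor_labels_for(n)
  pi <- pair_index(n)
  vals <- upper_vec(sni_sub)
  thr <- if (cfg$percentile == 0) -Inf else {
    quantile(abs(vals), cfg$percentile / 100, type = 7, names = FALSE)
  }
  keep <- abs(vals) > thr
  edges <- data.frame(from = labs[pi[keep, 1L]], to = labs[pi[keep, 2L]],
                      sni = vals[keep], abs_sni = abs(vals)[keep],
                      stringsAsFactors = FALSE)
  comp <- edge_components(n, pi[keep, , drop = FALSE])
  names(comp) <- labs
  list(threshold = thr, edges = edges, components = comp,
       n_components = if (any(comp > 0L)) max(comp) else 0L)
}
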