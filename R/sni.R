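#' Prewhitening settings
#'
#' Configuration for the per-sensor ARIMA fit whose residuals (innovations)
#' feed the zero-lag correlation stage. The default order (50, 1, 3) follows
#' standard practice for 60-s MEG recordings at ~1 kHz; short desk-scale
#' series use smaller AR orders.
#'
#' Estimation methods:
#' \describe{
#'   \item{`"hr"`}{Hannan–Rissanen two-stage least squares: a long
#'     autoregression supplies residual regressors, then the ARMA
#'     coefficients are estimated by OLS on lagged values and lagged
#'     residuals. Closed-form, fast, and consistent; the default because the
#'     pipeline fits hundreds of high-order models per cohort and only the
#'     innovations, not the coefficients, are consumed downstream.}
#'   \item{`"css"`}{conditional sum of squares via [stats::arima()].}
#'   \item{`"css-ml"`}{CSS initialisation with maximum-likelihood
#'     refinement via [stats::arima()].}
#' }
#'
#' @param order integer (p, d, q); d must be 0 or 1 and p + d + q >= 1.
#' @param estimation_method one of `"hr"`, `"css"`, `"css-ml"`.
#' @param fallback_order order used (and flagged) for sensors whose primary
#'   fit fails or does not converge.
#' @return a `prewhiten_config` list.
#' @export
prewhiten_config <- function(order = c(50L, 1L, 3L),
                             estimation_method = c("hr", "css", "css-ml"),
                             fallback_order = c(10L, 1L, 3L)) {
  estimation_method <- match.arg(estimation_method)
  check_order <- function(o, what) {
    o <- as.integer(o)
    if (length(o) != 3L || any(o < 0L)) stop(what, " must be three non-negative integers (p, d, q)")
    if (!o[2L] %in% c(0L, 1L)) stop(what, ": d must be 0 or 1")
    if (sum(o) < 1L) stop(what, ": p + d + q must be >= 1")
    o
  }
  structure(list(order = check_order(order, "order"),
                 estimation_method = estimation_method,
                 fallback_order = check_order(fallback_order, "fallback_order")),
            class = "prewhiten_config")
}

# Hannan–Rissanen ARMA(p, q) fit on a (possibly differenced) series.
# Returns innovations of the same length as y; the first max(p, q) values
# sit on the recursion's zero-initialised transient and are dropped later
# by the caller's uniform truncation.
hr_fit <- function(y, p, q, include_mean) {
  n <- length(y)
  if (p == 0L && q == 0L) {
    return(list(innov = y, converged = TRUE))
  }
  e0 <- NULL
  if (q > 0L) {
    long_ar <- min(n %/% 4L, max(20L, p + q + floor(10 * log10(n))))
    a <- stats::ar.yw(y, aic = FALSE, order.max = long_ar, demean = TRUE)
    e0 <- as.numeric(a$resid)
    e0[is.na(e0)] <- 0
  }
  k <- max(p, q)
  idx <- (k + 1L):n
  X <- matrix(0, length(idx), p + q)
  if (p > 0L) for (i in seq_len(p)) X[, i] <- y[idx - i]
  if (q > 0L) for (j in seq_len(q)) X[, p + j] <- e0[idx - j]
  D <- if (include_mean) cbind(1, X) else X
  fit <- tryCatch(stats::.lm.fit(D, y[idx]), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) {
    return(list(innov = NULL, converged = FALSE))
  }
  cf <- fit$coefficients
  off <- if (include_mean) 1L else 0L
  mu <- if (include_mean) cf[1L] else 0
  phi <- if (p > 0L) cf[(off + 1L):(off + p)] else numeric(0)
  theta <- if (q > 0L) cf[(off + p + 1L):(off + p + q)] else numeric(0)
  z <- y - mu
  if (p > 0L) {
    ar_part <- as.numeric(stats::filter(y, phi, method = "convolution",
                                        sides = 1L))
    ar_lag <- c(0, head(ar_part, -1L))
    ar_lag[is.na(ar_lag)] <- 0
    z <- y - mu - ar_lag
  }
  innov <- if (q > 0L) {
    as.numeric(stats::filter(z, -theta, method = "recursive"))
  } else z
  list(innov = innov, converged = all(is.finite(innov)))
}

# One sensor's ARIMA innovations for a given (p, d, q) and method.
fit_one_sensor <- function(x, order, method) {
  p <- order[1L]; d <- order[2L]; q <- order[3L]
  if (method == "hr") {
    y <- if (d > 0L) diff(x, differences = d) else x
    res <- hr_fit(y, p, q, include_mean = (d == 0L))
    res$order <- order
    return(res)
  }
  am <- if (method == "css") "CSS" else "CSS-ML"
  fit <- tryCatch(
    suppressWarnings(stats::arima(x, order = order, method = am,
                                  include.mean = (d == 0L))),
    error = function(e) NULL)
  if (is.null(fit) || (!is.null(fit$code) && fit$code != 0)) {
    return(list(innov = NULL, converged = FALSE, order = order))
  }
  innov <- as.numeric(fit$residuals)
  if (d > 0L) innov <- innov[-seq_len(d)]
  list(innov = innov, converged = all(is.finite(innov)), order = order)
}

#' Prewhiten sensor time series with per-sensor ARIMA fits
#'
#' Fits a univariate ARIMA(p, d, q) model to every sensor and returns the
#' innovations (one-step-ahead residuals), so that remaining cross-sensor
#' correlation reflects instantaneous coupling rather than shared
#' autocorrelation. Sensors whose primary fit fails fall back to
#' `cfg$fallback_order` and are flagged in the diagnostics. Innovations are
#' truncated uniformly across sensors by d + max(p + q) initial samples so
#' that zero-lag correlations use identical time indices.
#'
#' @param ts a [sensor_ts()].
#' @param cfg a [prewhiten_config()].
#' @return an `innovation_series` list: `values` (sensors x m residual
#'   matrix), `diagnostics` (per-sensor data frame: converged, fallback,
#'   order used, residual variance), `sampling_rate_hz`, `sensor_labels`.
#' @export
prewhiten <- function(ts, cfg = prewhiten_config()) {
  stopifnot(inherits(ts, "sensor_ts"), inherits(cfg, "prewhiten_config"))
  x <- ts$values
  n_samples <- ncol(x)
  d <- cfg$order[2L]
  vars <- apply(x, 1L, var)
  if (any(vars == 0)) {
    stop("constant sensor(s): ",
         paste(ts$sensor_labels[vars == 0], collapse = ", "))
  }
  min_len <- 10L * max(cfg$order[1L], cfg$order[3L], 1L)
  if (n_samples - d <= min_len) {
    stop("series too short for order (", paste(cfg$order, collapse = ","),
         "): need > ", min_len, " samples after differencing, have ",
         n_samples - d)
  }
  fits <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    f <- fit_one_sensor(x[i, ], cfg$order, cfg$estimation_method)
    f$fallback <- FALSE
    if (!f$converged) {
      f <- fit_one_sensor(x[i, ], cfg$fallback_order, cfg$estimation_method)
      f$fallback <- TRUE
      if (!f$converged) {
        stop("sensor ", ts$sensor_labels[i],
             ": ARIMA fit failed for both primary and fallback orders")
      }
    }
    fits[[i]] <- f
  }
  # uniform truncation so all sensors share time indices
  trunc <- max(vapply(fits, function(f) f$order[1L] + f$order[3L], integer(1)))
  m <- n_samples - d - trunc
  values <- t(vapply(fits, function(f) f$innov[(trunc + 1L):(trunc + m)],
                     numeric(m)))
  rownames(values) <- ts$sensor_labels
  diagnostics <- data.frame(
    sensor = ts$sensor_labels,
    converged = vapply(fits, function(f) f$converged, logical(1)),
    fallback = vapply(fits, function(f) f$fallback, logical(1)),
    p = vapply(fits, function(f) f$order[1L], integer(1)),
    d = d,
    q = vapply(fits, function(f) f$order[3L], integer(1)),
    resid_var = apply(values, 1L, var),
    stringsAsFactors = FALSE)
  structure(list(values = values, diagnostics = diagnostics,
                 sampling_rate_hz = ts$sampling_rate_hz,
                 sensor_labels = ts$sensor_labels),
            class = "innovation_series")
}

#' Number of unordered sensor pairs
#'
#' @param n_sensors sensor count (>= 2).
#' @return n(n-1)/2.
#' @examples
#' count_pairs(248) # 30628
#' @export
count_pairs <- function(n_sensors) {
  n_sensors <- as.integer(n_sensors)
  if (length(n_sensors) != 1L || is.na(n_sensors) || n_sensors < 2L) {
    stop("n_sensors must be a single integer >= 2")
  }
  (n_sensors * (n_sensors - 1L)) %/% 2L
}

#' Zero-lag cross-correlation matrix of innovations
#'
#' Pearson correlation of every sensor pair at simultaneous samples.
#'
#' @param innov an `innovation_series` from [prewhiten()], or a numeric
#'   matrix with sensors as rows.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
crosscorr_matrix <- function(innov) {
  values <- if (inherits(innov, "innovation_series")) innov$values else as.matrix(innov)
  vars <- apply(values, 1L, var)
  if (any(vars == 0)) {
    labs <- rownames(values) %||% as.character(seq_len(nrow(values)))
    stop("zero-variance innovation row(s): ",
         paste(labs[vars == 0], collapse = ", "))
  }
  r <- cor(t(values))
  (r + t(r)) / 2
}

#' Partial zero-lag cross-correlations from the precision matrix
#'
#' The partial correlation of sensors i and j given all remaining sensors,
#' computed as PCC_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj) where Omega is
#' the inverse of the (optionally ridge-loaded) correlation matrix. This
#' equals the correlation of the residuals from regressing i and j on all
#' other sensors.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param ridge non-negative diagonal loading added before inversion;
#'   the small default stabilises desk-scale cases where the sample size
#'   does not dwarf the sensor count.
#' @return symmetric matrix of partial correlations, diagonal `NA` (the
#'   self-partial-correlation is undefined for this statistic).
#' @export
partial_corr_matrix <- function(corr, ridge = 1e-6) {
  corr <- as.matrix(corr)
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8))) {
    stop("correlation matrix must be symmetric")
  }
  if (any(abs(diag(corr) - 1) > 1e-8)) {
    stop("correlation matrix must have unit diagonal")
  }
  if (ridge < 0) stop("ridge must be non-negative")
  n <- nrow(corr)
  loaded <- corr + diag(ridge, n)
  rc <- rcond(loaded)
  if (rc < .Machine$double.eps * 100) {
    stop(sprintf(
      "correlation matrix is numerically singular (condition number ~ %.3g); supply a positive ridge",
      1 / rc))
  }
  omega <- solve(loaded)
  p <- -omega / sqrt(outer(diag(omega), diag(omega)))
  p <- (p + t(p)) / 2
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(corr)
  p
}

#' Fisher z-transform of a partial-correlation matrix
#'
#' `z = atanh(r)`, variance-stabilising the correlation scale. Inputs are
#' clipped to |r| <= 1 - 1e-12 so the result is finite everywhere; the
#' masked diagonal stays `NA`.
#'
#' @param pcc matrix of (partial) correlations in \[-1, 1\].
#' @return matrix of Fisher z values (the SNI matrix when `pcc` holds
#'   partial zero-lag cross-correlations).
#' @export
fisher_z_matrix <- function(pcc) {
  pcc <- as.matrix(pcc)
  if (any(abs(pcc) > 1 + 1e-9, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  lim <- 1 - 1e-12
  atanh(pmin(pmax(pcc, -lim), lim))
}

#' Compute a subject's SNI matrix end to end
#'
#' Composition of the processing chain: ARIMA prewhitening, pairwise
#' zero-lag cross-correlations of the innovations, partial correlations via
#' the precision matrix, and the Fisher z-transform. The result is the
#' symmetric matrix of synchronous neural interactions z_ij.
#'
#' @inheritParams prewhiten
#' @inheritParams partial_corr_matrix
#' @return SNI matrix (diagonal `NA`) with the prewhitening diagnostics
#'   attached as attribute `"prewhiten"`.
#' @export
compute_sni <- function(ts, cfg = prewhiten_config(), ridge = 1e-6) {
  innov <- tryCatch(prewhiten(ts, cfg), error = function(e) abort_stage("prewhiten", e))
  cc <- tryCatch(crosscorr_matrix(innov), error = function(e) abort_stage("crosscorr", e))
  pc <- tryCatch(partial_corr_matrix(cc, ridge = ridge),
                 error = function(e) abort_stage("partial_corr", e))
  z <- tryCatch(fisher_z_matrix(pc), error = function(e) abort_stage("fisher_z", e))
  attr(z, "prewhiten") <- innov$diagnostics
  z
}
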