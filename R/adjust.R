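#' Fit the age/gender adjustment model for SNI values
#'
#' For every unordered sensor pair, ordinary least squares of the SNI value
#' on centred age and a gender indicator over the supplied (reference-group)
#' subjects. The fitted coefficients are later subtracted from raw SNI
#' values by [apply_adjustment()], including for subjects outside the
#' training groups, so held-out diagnostic groups are adjusted with
#' reference-group coefficients.
#'
#' @param sni_stack list of SNI matrices, one per subject, all the same size.
#' @param subjects data frame with columns `age` and `gender` aligned with
#'   `sni_stack`; a `group` column, when present, is recorded in the model.
#' @return an `sni_adjustment` model: per-pair intercept, age slope (per
#'   year) and gender offset, the training age mean and reference gender.
#'   With a single gender in the training sample the gender term is dropped
#'   with a warning and flagged.
#' @export
fit_adjustment <- function(sni_stack, subjects) {
  if (length(sni_stack) < 3L) stop("need at least 3 subjects to fit the adjustment")
  if (length(sni_stack) != nrow(subjects)) {
    stop("sni_stack and subjects have inconsistent lengths")
  }
  if (anyNA(subjects$age)) stop("missing age in training subjects")
  if (anyNA(subjects$gender)) stop("missing gender in training subjects")
  n_sensors <- nrow(sni_stack[[1L]])
  y <- t(vapply(sni_stack, upper_vec, numeric(count_pairs(n_sensors))))

  age_mean <- mean(subjects$age)
  genders <- sort(unique(as.character(subjects$gender)))
  reference_gender <- genders[1L]
  gender_term <- length(genders) > 1L
  if (!gender_term) {
    warning("single gender in training sample; gender term dropped")
  }
  age_term <- var(subjects$age) > 0   # constant age: slope is identically 0
  x <- cbind(intercept = rep(1, nrow(subjects)))
  if (age_term) x <- cbind(x, age = subjects$age - age_mean)
  if (gender_term) {
    x <- cbind(x, gender = as.numeric(subjects$gender != reference_gender))
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    stop("collinear covariates: age and gender are not separable in this sample")
  }
  beta <- qr.coef(qx, y)
  if (!age_term) beta <- rbind(beta, age = 0)
  structure(list(
    n_sensors = n_sensors,
    pair_labels = pair_labels(n_sensors),
    intercept = beta["intercept", ],
    age_slope = beta["age", ],
    gender_offset = if (gender_term) beta["gender", ] else rep(0, ncol(y)),
    age_mean = age_mean,
    reference_gender = reference_gender,
    gender_term = gender_term,
    groups_used = unique(as.character(subjects$group %||% NA_character_))
  ), class = "sni_adjustment")
}

#' Remove age and gender effects from one subject's SNI matrix
#'
#' Subtracts the fitted age slope times centred age and the gender offset;
#' the per-pair intercept is retained so adjusted values stay on the SNI
#' scale. A subject at the training mean age with the reference gender is
#' returned unchanged.
#'
#' @param model an [fit_adjustment()] model.
#' @param sni the subject's SNI matrix.
#' @param subject one-row data frame (or list) with `age` and `gender`.
#' @return adjusted SNI matrix, same shape and masking as the input.
#' @export
apply_adjustment <- function(model, sni, subject) {
  stopifnot(inherits(model, "sni_adjustment"))
  if (nrow(sni) != model$n_sensors) {
    stop("SNI matrix size does not match the fitted adjustment model")
  }
  age <- subject$age
  gender <- subject$gender
  if (is.null(age) || is.na(age)) stop("subject is missing the age covariate")
  if (model$gender_term && (is.null(gender) || is.na(gender))) {
    stop("subject is missing the gender covariate")
  }
  v <- upper_vec(sni) -
    model$age_slope * (age - model$age_mean) -
    model$gender_offset * as.numeric(!identical(as.character(gender),
                                                model$reference_gender))
  out <- sym_from_upper(v, model$n_sensors, diag_value = NA_real_)
  dimnames(out) <- dimnames(sni)
  out
}
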