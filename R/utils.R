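# Internal helpers shared across modules.

# Counter-based seed derivation: subject k's stream depends only on the
# master seed, a stream tag and k, so generated subjects are invariant to
# cohort size and generation order. Uses a Weyl-style integer hash folded
# into the 31-bit range accepted by set.seed().
derive_seed <- function(master_seed, stream, counter = 0L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- as.double(master_seed %% 2147483647)
  tag <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  h <- (h * 1103515245 + tag) %% 2147483647
  h <- (h * 1103515245 + as.double(counter) * 12345 + 12345) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

sensor_labels_for <- function(n) sprintf("S%03d", seq_len(n))

# All unordered sensor pairs (i < j), as a 2-column integer matrix in
# column-major upper-triangle order (the order upper.tri() vectorizes in).
pair_index <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

pair_labels <- function(n) {
  lab <- sensor_labels_for(n)
  pi <- pair_index(n)
  paste(lab[pi[, 1L]], lab[pi[, 2L]], sep = "-")
}

# Extract the upper triangle in the canonical pair order.
upper_vec <- function(m) m[upper.tri(m)]

# Rebuild a symmetric matrix (diagonal `diag_value`) from its upper triangle.
sym_from_upper <- function(v, n, diag_value = NA_real_) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_stage <- function(stage, e) {
  stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
}
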