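# Internal helpers shared across modules.

# Deterministic fan-out of a master seed into per-stage / per-replicate seeds.
# Kept strictly below 2^31 so the result is always a valid R integer seed.
sub_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(seed) * 48271 + counter) %% 2147483647)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

check_prob <- function(x, name, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 ||
      (if (allow_one) x > 1 else x >= 1)) {
    abort(sprintf("`%s` must be a probability in [0,%s]", name,
                  if (allow_one) "1" else "1)"))
  }
  invisible(x)
}

# log-determinant via Cholesky; returns NA if not positive definite
log_det_pd <- function(S) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) return(NA_real_)
  2 * sum(log(diag(R)))
}

# key for caching statistics of a variable (index) set; "k" prefix keeps
# the empty set a valid environment key
set_key <- function(idx) paste0("k", paste(sort(idx), collapse = ","))
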