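# Internal helpers shared across modules.

# Largest seed we ever hand to set.seed(): R integers are 32-bit.
.MAX_SEED <- 2147483646L

#' @noRd
local_seed_if <- function(seed, .local_envir = parent.frame()) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::local_seed(as.integer(seed), .local_envir = .local_envir)
  }
  invisible(NULL)
}

# Deterministically derive `k` independent child seeds from a master seed.
# Children are drawn up-front so dropping one consumer never shifts another.
#' @noRd
derive_seeds <- function(seed, k, labels = NULL) {
  seeds <- withr::with_seed(as.integer(seed), sample.int(.MAX_SEED, k))
  if (!is.null(labels)) names(seeds) <- labels
  seeds
}

#' @noRd
stop_param <- function(...) stop(..., call. = FALSE)

#' @noRd
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_param(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

#' @noRd
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_param(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  as.numeric(x)
}
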