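# Group-level outcome statistics.

#' Gini coefficient of a payoff vector
#'
#' Population (uncorrected) Gini,
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`, computed via the sorted-data
#' identity. `G = 0` for a constant vector; an all-zero vector is defined to
#' have `G = 0`. Bounded by `(n - 1) / n`.
#'
#' @param x Non-empty numeric vector of non-negative payoffs.
#' @return Gini coefficient in `[0, 1)`.
#' @export
#' @examples
#' gini_coefficient(c(1, 1, 2, 2))        # 1/6
#' gini_coefficient(c(1, rep(0, 15)))     # 15/16
gini_coefficient <- function(x) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stop_param("`x` must be a non-empty numeric vector without NA")
  }
  if (any(x < 0)) stop_param("Gini is undefined for negative payoffs")
  n <- length(x)
  total <- sum(x)
  if (total == 0) return(0)
  xs <- sort(x)
  2 * sum(seq_len(n) * xs) / (n * total) - (n + 1) / n
}

#' Summary statistics of a group payoff vector
#'
#' @param payoffs Non-empty numeric vector of agent payoffs.
#' @return Named numeric vector with `max_payoff`, `mean_payoff`,
#'   `min_payoff` and `gini`.
#' @export
payoff_summary <- function(payoffs) {
  if (!is.numeric(payoffs) || length(payoffs) == 0L || anyNA(payoffs)) {
    stop_param("`payoffs` must be a non-empty numeric vector without NA")
  }
  c(max_payoff = max(payoffs), mean_payoff = mean(payoffs),
    min_payoff = min(payoffs), gini = gini_coefficient(payoffs))
}
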