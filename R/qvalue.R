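#' Storey q-values with a fixed lambda
#'
#' Positive false discovery rate control. The null proportion is estimated
#' as `pi0 = #{p > lambda} / (m * (1 - lambda))`, clamped to `[1/m, 1]`, and
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`, clamped to at most 1; tied
#' p-values share a q-value. With `pi0 = 1` (e.g. `lambda = 0`) this is the
#' Benjamini–Hochberg adjustment. The estimator is valid for the discrete
#' p-values produced by overlap counts, where discreteness makes p-values
#' stochastically larger than uniform and the procedure conservative.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param lambda tuning parameter in \[0, 1) (default 0.5).
#' @return numeric vector of q-values in input order.
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  if (length(p) == 0L) return(numeric())
  stopifnot(all(p > 0), all(p <= 1), lambda >= 0, lambda < 1)
  m <- length(p)
  pi0 <- sum(p > lambda) / (m * (1 - lambda))
  pi0 <- min(1, max(1 / m, pi0))
  o <- order(p)
  q_sorted <- rev(cummin(rev(pi0 * m * p[o] / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  # ties share the (minimum, identical by monotonicity) q-value
  q
}
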