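#' Alternation score of a pattern
#'
#' Sum of the absolute differences of adjacent pattern values over the
#' `div = l - 1` divisors, divided by the number of discretization levels N:
#' `a.s = sum_j |e_j - e_{j+1}| / N`.  The wrap-around (last, first) couple
#' used by the MORA search is deliberately not part of this score.
#'
#' @param pattern a [binary_pattern] of length >= 2.
#' @return scalar alternation score.
#' @export
alternation_score <- function(pattern) {
  v <- pattern$values
  if (length(v) < 2L) stop_mora("alternation score needs length >= 2")
  sum(abs(diff(v))) / pattern$n_levels
}

#' Length-normalized (absolute) alternation score
#'
#' `w.s = a.s / div`, which makes patterns of different lengths comparable;
#' its maximum over binary patterns of a given length is 1/2, attained only
#' by the two fully oscillating sequences.
#'
#' @inheritParams alternation_score
#' @return scalar in `[0, (n_levels-1)/n_levels]`.
#' @export
normalized_score <- function(pattern) {
  alternation_score(pattern) / (length(pattern$values) - 1L)
}

#' Ideal (fully oscillating) pattern
#'
#' The alternating max/min series over Sigma = {0..N-1}, starting at the
#' maximum: `(N-1), 0, (N-1), 0, ...`.  It is the unique maximizer (up to the
#' 0<->1 relabeling for N = 2) of the normalized alternation score for its
#' length.
#'
#' @param l pattern length (>= 2).
#' @param n_levels number of discretization levels (>= 2).
#' @return a [binary_pattern].
#' @export
ideal_pattern <- function(l, n_levels = 2L) {
  if (l < 2L) stop_mora("ideal pattern needs length >= 2")
  vals <- rep(c(n_levels - 1L, 0L), length.out = l)
  binary_pattern(vals, paste0("id", seq_len(l)), n_levels)
}

#' Oscillation similarity of a pattern to the ideal
#'
#' Computes the alternation score (`a_s`), its normalized form (`w_s`), the
#' Manhattan distance `d` of the observed score profile from the ideal
#' pattern of the same length, and the similarity index
#' `sigma_obs = 1 - d` in \[0, 1\].  For the two-level field
#' `d = N * (w.s(ideal) - w.s(observed))`; for N > 2 the same distance is
#' taken on the per-level-fraction scale (each level contributes 1/|Sigma|),
#' i.e. divided by `max(Sigma) = N - 1`, so that the min-max ideal series
#' reaches `sigma_obs = 1` exactly for every N.
#'
#' @inheritParams alternation_score
#' @return object of class `oscillation_score`: list with fields `a_s`,
#'   `w_s`, `d`, `sigma_obs`, `l`, `div`, `n_levels`.
#' @export
similarity <- function(pattern) {
  a_s <- alternation_score(pattern)
  l <- length(pattern$values)
  div <- l - 1L
  w_s <- a_s / div
  N <- pattern$n_levels
  w_id <- normalized_score(ideal_pattern(l, N))
  d <- N * (w_id - w_s) / (N - 1L)
  structure(list(a_s = a_s, w_s = w_s, d = d, sigma_obs = 1 - d,
                 l = l, div = div, n_levels = N),
            class = "oscillation_score")
}

#' @export
print.oscillation_score <- function(x, ...) {
  cat(sprintf(
    "<oscillation_score> l=%d N=%d  a.s=%.4g  w.s=%.4g  d=%.4g  sigma_obs=%.4g\n",
    x$l, x$n_levels, x$a_s, x$w_s, x$d, x$sigma_obs))
  invisible(x)
}
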