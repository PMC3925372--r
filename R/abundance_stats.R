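#' Per-15-million read-count normalization
#'
#' Scales a raw tag count by the library's clean-read total to an
#' expression value per 15 million clean reads:
#' `count / clean_total * 15e6`.
#'
#' @param count nonnegative integer vector of raw tag counts.
#' @param clean_total positive scalar (or vector) of clean-read totals.
#' @return numeric vector of normalized expression values.
#' @export
#' @examples
#' normalize_expression(100, 7.5e6) # 200
normalize_expression <- function(count, clean_total) {
  if (any(clean_total <= 0)) .stopf("clean_total must be > 0")
  if (any(count < 0)) .stopf("counts must be nonnegative")
  count / clean_total * 15e6
}

#' Tag-count sampling probability p(y | x)
#'
#' Probability of observing `y` counts of a tag in the treatment library
#' given `x` counts in the control library, under the exact tag-sampling
#' model for two libraries of clean-read depth `N1` (control) and `N2`
#' (treatment):
#'
#' \deqn{p(y|x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!}\,
#'   \frac{1}{(1+N_2/N_1)^{x+y+1}}}
#'
#' Evaluated in log space via `lgamma`, so it is finite and accurate for
#' counts up to at least 1e7. Vectorised over `y`.
#'
#' @param x control count (scalar, >= 0).
#' @param y treatment count(s) (>= 0).
#' @param N1,N2 clean-read totals of control and treatment (> 0).
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
#' @examples
#' ac_probability(5, 5, 1e7, 1e7) # 63/512
ac_probability <- function(x, y, N1, N2) {
  if (x < 0 || any(y < 0)) .stopf("counts must be nonnegative")
  if (N1 <= 0 || N2 <= 0) .stopf("library totals must be positive")
  logr <- log(N2) - log(N1)
  # log(1 + r) computed stably for both tiny and huge N2/N1
  log1pr <- if (logr > 0) logr + log1p(exp(-logr)) else log1p(exp(logr))
  lp <- y * logr + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1pr
  exp(lp)
}

#' Two-tailed p-value for a tag-count difference
#'
#' Accumulates `q = sum_{y'=0..y} p(y'|x)` and doubles the smaller tail:
#' `p = 2q` when `q <= 0.5`, else `p = 2(1-q)`; the result is clipped to
#' \[0, 1\] (doubling can exceed 1 when the observation sits at the mode).
#'
#' @inheritParams ac_probability
#' @param y treatment count (scalar, >= 0).
#' @return two-tailed p-value in \[0, 1\].
#' @export
two_tailed_p <- function(x, y, N1, N2) {
  if (x < 0 || y < 0) .stopf("counts must be nonnegative")
  if (N1 <= 0 || N2 <= 0) .stopf("library totals must be positive")
  # accumulate the lower tail; chunked so y up to 1e7 stays within memory
  q <- 0
  step <- 1e6
  lo <- 0
  while (lo <= y) {
    hi <- min(lo + step - 1, y)
    q <- q + sum(ac_probability(x, lo:hi, N1, N2))
    lo <- hi + 1
  }
  p <- if (q > 0.5) 2 * (1 - q) else 2 * q
  min(max(p, 0), 1)
}

#' Differential-abundance call for one tag across two libraries
#'
#' Computes per-15M normalized expression for both libraries, the log2
#' ratio treatment/control, the two-tailed p-value, and the
#' classification used throughout the pipeline: `up` when
#' `log2_ratio > 1` and `p < 0.05`, `down` when `log2_ratio < -1` and
#' `p < 0.05`, otherwise `equal` (strict inequalities).
#'
#' When one normalized value is zero, half a read (`0.5 / clean_total *
#' 15e6`) is substituted for the ratio only — never for the p-value.
#' When both counts are zero the call is `equal` with `p = 1`.
#'
#' @param id feature/tag identifier vector.
#' @param x,y integer count vectors in control and treatment.
#' @param N1,N2 clean-read totals of the two libraries.
#' @param log2_cutoff,p_cutoff strict call thresholds; defaults 1 and
#'   0.05. A Benjamini-Hochberg column is reported for transparency but
#'   never used for the calls, which rest on the raw p-value.
#' @return a data.frame with columns `id, x, y, N1, N2, norm_x, norm_y,
#'   log2fc, p, bh_fdr, call`.
#' @export
classify_de <- function(id, x, y, N1, N2, log2_cutoff = 1,
                        p_cutoff = 0.05) {
  stopifnot(length(x) == length(y), length(id) == length(x))
  if (any(x < 0) || any(y < 0)) .stopf("counts must be nonnegative")
  norm_x <- normalize_expression(x, N1)
  norm_y <- normalize_expression(y, N2)
  # half-read pseudocount, ratio only
  rx <- ifelse(norm_x == 0, 0.5 / N1 * 15e6, norm_x)
  ry <- ifelse(norm_y == 0, 0.5 / N2 * 15e6, norm_y)
  log2fc <- log2(ry / rx)
  p <- vapply(seq_along(x), function(i) two_tailed_p(x[i], y[i], N1, N2),
              numeric(1))
  both_zero <- x == 0 & y == 0
  p[both_zero] <- 1
  log2fc[both_zero] <- 0
  call <- rep("equal", length(x))
  call[log2fc > log2_cutoff & p < p_cutoff] <- "up"
  call[log2fc < -log2_cutoff & p < p_cutoff] <- "down"
  data.frame(
    id = as.character(id), x = x, y = y, N1 = N1, N2 = N2,
    norm_x = norm_x, norm_y = norm_y, log2fc = log2fc, p = p,
    bh_fdr = p.adjust(p, method = "BH"), call = call,
    stringsAsFactors = FALSE
  )
}

#' Fold-change percent between two signal values
#'
#' `round(100 * treatment / control)` to the nearest integer, rounding
#' halves away from zero — the convention used for microarray
#' fold-change columns.
#'
#' @param treatment_signal,control_signal numeric vectors; control must
#'   be positive.
#' @return integer percent vector.
#' @export
#' @examples
#' fold_change_percent(2319, 1543) # 150
fold_change_percent <- function(treatment_signal, control_signal) {
  if (any(control_signal <= 0)) .stopf("control signal must be positive")
  as.integer(.round_half_away(100 * treatment_signal / control_signal))
}
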