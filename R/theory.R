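#' Closed-form SNR for a negative-binomial gene
#'
#' Signal-to-noise ratio of a two-group comparison where group 1 has mean
#' `mu1`, group 2 has mean `mu1 / fold`, and both share the NB dispersion
#' `alpha` (variance `mu + alpha * mu^2`):
#' \deqn{SNR = \frac{\mu_1 - \mu_2}{\sqrt{\mu_1 + \alpha\mu_1^2} +
#'   \sqrt{\mu_2 + \alpha\mu_2^2}}}
#' The convention is `mu1 >= mu2`, i.e. `fold >= 1`; callers handle the sign
#' of down-regulation themselves. `alpha = 0` is the exact Poisson case.
#'
#' @param mu1 positive numeric, mean of the larger group (recycled).
#' @param fold numeric >= 1, fold change `mu1 / mu2`.
#' @param alpha non-negative numeric, NB dispersion.
#' @return numeric vector of SNR values.
#' @seealso [snr_upper_bound()], [snr_lower_bound()], [snr_poisson_limit()]
#' @export
#' @examples
#' snr_analytic(100, 2, 0)    # Poisson: 50 / (10 + sqrt(50))
#' snr_analytic(100, 2, 0.1)  # bounded by 1 / sqrt(0.1)
snr_analytic <- function(mu1, fold, alpha) {
  stopifnot(is.numeric(mu1), is.numeric(fold), is.numeric(alpha))
  if (any(mu1 <= 0)) stop("'mu1' must be positive")
  if (any(fold < 1)) stop("'fold' must be >= 1 (group 1 holds the larger mean)")
  if (any(alpha < 0)) stop("'alpha' must be non-negative")
  mu2 <- mu1 / fold
  (mu1 - mu2) / (sqrt(mu1 + alpha * mu1^2) + sqrt(mu2 + alpha * mu2^2))
}

#' Upper bound of the SNR: min(1/sqrt(alpha), sqrt(mu1))
#'
#' For any fold change, the SNR of an NB gene is bounded above by
#' `min(1/sqrt(alpha), sqrt(mu1))`. The `1/sqrt(alpha)` branch is what caps
#' the score of highly expressed genes once dispersion is appreciable; the
#' `sqrt(mu1)` branch is why a residual "local" bias survives at small
#' counts. For `alpha = 0` the bound is `sqrt(mu1)` (Poisson branch, no
#' division by zero).
#'
#' @inheritParams snr_analytic
#' @return numeric vector of bounds.
#' @export
snr_upper_bound <- function(mu1, alpha) {
  stopifnot(is.numeric(mu1), is.numeric(alpha))
  if (any(mu1 <= 0)) stop("'mu1' must be positive")
  if (any(alpha < 0)) stop("'alpha' must be non-negative")
  n <- max(length(mu1), length(alpha))
  mu1 <- rep_len(mu1, n)
  alpha <- rep_len(alpha, n)
  out <- sqrt(mu1)
  pos <- alpha > 0
  out[pos] <- pmin(1 / sqrt(alpha[pos]), sqrt(mu1[pos]))
  out
}

#' Lower bounds of the SNR
#'
#' Two companion lower bounds for `fold > 1`:
#' * `intermediate`: the tight form `(1 - 1/sqrt(fold)) / sqrt(1/mu1 + alpha)`,
#'   which always sits below [snr_analytic()].
#' * `envelope`: `c(fold) * min(1/sqrt(alpha), sqrt(mu1))` with
#'   `c(f) = (1 - 1/sqrt(f)) / sqrt(2)`, obtained from the intermediate form
#'   via `1/(1/mu1 + alpha) >= 1/(2 max(1/mu1, alpha))`.
#'
#' @inheritParams snr_analytic
#' @return data.frame with columns `intermediate` and `envelope`.
#' @export
snr_lower_bound <- function(mu1, fold, alpha) {
  stopifnot(is.numeric(mu1), is.numeric(fold), is.numeric(alpha))
  if (any(mu1 <= 0)) stop("'mu1' must be positive")
  if (any(fold <= 1)) stop("'fold' must be > 1 (the bound is vacuous at 1)")
  if (any(alpha < 0)) stop("'alpha' must be non-negative")
  n <- max(length(mu1), length(fold), length(alpha))
  mu1 <- rep_len(mu1, n); fold <- rep_len(fold, n); alpha <- rep_len(alpha, n)
  cf <- (1 - 1 / sqrt(fold)) / sqrt(2)
  env <- sqrt(mu1)
  pos <- alpha > 0
  env[pos] <- pmin(1 / sqrt(alpha[pos]), sqrt(mu1[pos]))
  data.frame(
    intermediate = (1 - 1 / sqrt(fold)) / sqrt(1 / mu1 + alpha),
    envelope = cf * env
  )
}

#' Ratio of the upper- to lower-bound fold-change coefficients
#'
#' `((1 - 1/f) / (1 + 1/f)) / (1 - 1/sqrt(f))` for `f > 1`. This ratio is
#' tightly pinched in (1, 1.21) for every fold change, which is what makes
#' the pair of SNR bounds informative: the SNR cannot escape a narrow band
#' around `1/sqrt(alpha)` once the mean count is large.
#'
#' @param fold numeric > 1.
#' @return numeric vector of ratios.
#' @export
coefficient_ratio <- function(fold) {
  stopifnot(is.numeric(fold))
  if (any(fold <= 1)) stop("'fold' must be > 1")
  ((1 - 1 / fold) / (1 + 1 / fold)) / (1 - 1 / sqrt(fold))
}

#' Poisson-limit SNR: sqrt(mu1) - sqrt(mu2)
#'
#' As dispersion tends to zero the SNR collapses to
#' `(mu1 - mu2)/(sqrt(mu1) + sqrt(mu2)) = sqrt(mu1) - sqrt(mu2)`, which grows
#' without bound in the mean count: the read count bias of technical
#' replicates.
#'
#' @param mu1,mu2 non-negative numerics.
#' @return numeric vector.
#' @export
snr_poisson_limit <- function(mu1, mu2) {
  stopifnot(is.numeric(mu1), is.numeric(mu2))
  if (any(mu1 < 0) || any(mu2 < 0)) stop("means must be non-negative")
  sqrt(mu1) - sqrt(mu2)
}

#' SNR as a function of gene length
#'
#' With expected count proportional to transcript abundance times length,
#' `mu1 = c_prop * n_transcripts * length`, the SNR inherits the same bounds:
#' proportional to `sqrt(length)` under the Poisson model (gene length bias)
#' but capped at `1/sqrt(alpha)` for any length once dispersion is positive.
#'
#' @param c_prop positive proportionality constant.
#' @param n_transcripts positive transcript abundance.
#' @param length positive gene length.
#' @inheritParams snr_analytic
#' @return numeric vector of SNR values.
#' @export
snr_length <- function(c_prop, n_transcripts, length, fold, alpha) {
  if (any(c_prop <= 0) || any(n_transcripts <= 0) || any(length <= 0))
    stop("'c_prop', 'n_transcripts' and 'length' must be positive")
  if (any(fold < 1)) stop("'fold' must be >= 1")
  ifelse(fold == 1, 0,
         snr_analytic(c_prop * n_transcripts * length, pmax(fold, 1), alpha))
}

#' Tabulate analytic SNR curves with their bounds
#'
#' Cartesian evaluation of [snr_analytic()] over grids of fold change,
#' dispersion and group-1 mean, with the upper bound and (for `fold > 1`)
#' the intermediate lower bound attached. Suitable for plotting SNR-vs-count
#' curves per dispersion level.
#'
#' @param fold_list,alpha_list,mu_grid non-empty numeric grids.
#' @return data.frame with columns `mu1`, `fold`, `alpha`, `snr`, `upper`,
#'   `lower` (NA where `fold == 1`).
#' @export
theory_curve <- function(fold_list, alpha_list, mu_grid) {
  if (length(fold_list) == 0 || length(alpha_list) == 0 || length(mu_grid) == 0)
    stop("grids must be non-empty")
  g <- expand.grid(mu1 = mu_grid, fold = fold_list, alpha = alpha_list,
                   KEEP.OUT.ATTRS = FALSE)
  g$snr <- snr_analytic(g$mu1, g$fold, g$alpha)
  g$upper <- snr_upper_bound(g$mu1, g$alpha)
  g$lower <- NA_real_
  gt1 <- g$fold > 1
  if (any(gt1))
    g$lower[gt1] <- snr_lower_bound(g$mu1[gt1], g$fold[gt1], g$alpha[gt1])$intermediate
  g
}
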