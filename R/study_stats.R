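#' Power analysis parameters for a two-group comparison
#'
#' Defaults encode the study design this package reproduces: 80% power, 5%
#' two-sided type I error, an expected 1.5-fold change over a unit baseline
#' (absolute difference 0.5) and a standard deviation of 0.3.
#'
#' @param power Target power, in (0, 1).
#' @param alpha Two-sided type I error rate, in (0, 1).
#' @param fold_change Expected fold change over a baseline mean of 1, > 0
#'   and != 1.
#' @param sd Common standard deviation on the same scale.
#' @return A validated list of class \code{PowerParams}.
#' @export
power_params <- function(power = 0.80, alpha = 0.05, fold_change = 1.5,
                         sd = 0.3) {
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1,
            fold_change > 0, sd > 0)
  structure(list(power = power, alpha = alpha, fold_change = fold_change,
                 sd = sd), class = "PowerParams")
}

#' Two-group sample size (normal approximation)
#'
#' Standardized difference \eqn{d = (fold\_change - 1)/sd} against a unit
#' baseline, then the classical normal-approximation formula
#' \deqn{n = \lceil 2 (z_{1-\alpha/2} + z_{power})^2 / d^2 \rceil}
#' per group, with a floor of 2. At the package defaults (0.80, 0.05,
#' 1.5-fold, sd 0.3) this gives 6 per group. A noncentral-t iteration
#' (\code{method = "t"}, via \code{\link[stats]{power.t.test}}) is slightly
#' stricter and available for comparison.
#'
#' @param params A \code{\link{power_params}} object.
#' @param method \code{"normal"} (default) or \code{"t"}.
#' @return Integer sample size per group.
#' @export
sample_size_two_group <- function(params = power_params(),
                                  method = c("normal", "t")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "PowerParams"))
  if (params$fold_change == 1) stop("zero effect size: fold_change = 1")
  d <- abs(params$fold_change - 1) / params$sd
  if (method == "t") {
    n <- stats::power.t.test(delta = abs(params$fold_change - 1),
                             sd = params$sd, sig.level = params$alpha,
                             power = params$power)$n
    return(max(2L, as.integer(ceiling(n))))
  }
  z_a <- stats::qnorm(1 - params$alpha / 2)
  z_b <- stats::qnorm(params$power)
  max(2L, as.integer(ceiling(2 * (z_a + z_b)^2 / d^2)))
}

#' qPCR relative expression from a Delta-Delta-Ct value
#'
#' Computes \code{2^ddct} fold change versus the control group. The sign
#' convention is explicit: under \code{orientation = "enrichment"} (default)
#' the input is oriented so that lower target Ct than control (i.e. more
#' transcript) yields a fold change above 1 — pass
#' \code{ddct = -(dCt_treated - dCt_control)} or equivalently a
#' pre-negated value. \code{orientation = "raw_difference"} applies the
#' textbook \code{2^-ddct} to the raw difference
#' \code{dCt_treated - dCt_control} instead.
#'
#' @param ddct Finite numeric Delta-Delta-Ct value(s).
#' @param orientation \code{"enrichment"} or \code{"raw_difference"}.
#' @return Positive fold change(s).
#' @export
relative_expression <- function(ddct,
                                orientation = c("enrichment",
                                                "raw_difference")) {
  orientation <- match.arg(orientation)
  if (any(!is.finite(ddct))) stop("ddct must be finite")
  if (orientation == "raw_difference") 2^(-ddct) else 2^ddct
}
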