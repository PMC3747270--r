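#' Liability threshold geometry for a disease design
#'
#' Computes the truncated-normal quantities of the liability threshold
#' model for a disease with population prevalence `K`, analysed in a
#' sample containing a proportion `P` of cases.  Liability is standard
#' normal in the population; individuals are affected when their
#' liability exceeds the threshold `t = qnorm(1 - K)`.
#'
#' The returned moments are the building blocks of every power and
#' accuracy formula in the package: the mean liability of cases
#' (`i_case = z/K`, the selection intensity) and of controls
#' (`i_ctrl = -z/(1 - K)`), the within-group liability variances after
#' truncation, and the liability variance of the `P:(1-P)` case-control
#' mixture (`var_lcc`), which exceeds 1 whenever cases are over-sampled
#' (`P > K`).
#'
#' @param K Population disease prevalence, strictly in (0, 1).
#' @param P Proportion of cases in the analysed sample, strictly in
#'   (0, 1).  Defaults to `K` (a population sample).
#'
#' @return An object of class `"liability_design"`: a list with elements
#'   `K`, `P`, `t` (threshold), `z` (standard normal density at `t`),
#'   `i_case`, `i_ctrl` (mean liability of cases/controls), `v_case`,
#'   `v_ctrl` (within-group liability variances), and `var_lcc`
#'   (liability variance in the case-control mixture).
#'
#' @examples
#' liability_design(K = 0.01, P = 0.5)
#' # no ascertainment: the mixture variance stays at 1
#' liability_design(K = 0.1, P = 0.1)$var_lcc
#'
#' @export
liability_design <- function(K, P = K) {
  check_probability(K, "K")
  check_probability(P, "P")
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  i_case <- z / K
  i_ctrl <- -z / (1 - K)
  # variance of a standard normal truncated above (cases) / below (controls)
  v_case <- 1 - i_case * (i_case - t)
  v_ctrl <- 1 + t * i_ctrl - i_ctrl^2
  var_lcc <- P * v_case + (1 - P) * v_ctrl +
    P * (1 - P) * (i_case - i_ctrl)^2
  structure(
    list(K = K, P = P, t = t, z = z,
         i_case = i_case, i_ctrl = i_ctrl,
         v_case = v_case, v_ctrl = v_ctrl,
         var_lcc = var_lcc),
    class = "liability_design"
  )
}

#' @export
print.liability_design <- function(x, ...) {
  cat("Liability threshold design\n")
  cat(sprintf("  prevalence K = %g, case proportion P = %g\n", x$K, x$P))
  cat(sprintf("  threshold t = %.5f, density z = %.5f\n", x$t, x$z))
  cat(sprintf("  mean liability: cases %.5f, controls %.5f\n",
              x$i_case, x$i_ctrl))
  cat(sprintf("  liability variance: cases %.5f, controls %.5f\n",
              x$v_case, x$v_ctrl))
  cat(sprintf("  case-control mixture liability variance = %.5f\n",
              x$var_lcc))
  invisible(x)
}

# Probabilities are required strictly inside (0,1); extreme values are
# rejected because z/K (and z/(1-K)) lose all precision there.
check_probability <- function(x, name, eps = 1e-8) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x <= eps || x >= 1 - eps)
    stop(sprintf("'%s' must lie strictly inside (0, 1); got %g", name, x),
         call. = FALSE)
  invisible(x)
}

check_proportion01 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]; got %s",
                 name, format(x)), call. = FALSE)
  invisible(x)
}

#' Liability-scale to observed-scale variance transformation
#'
#' Transforms a proportion of variance on the (unobserved) liability
#' scale to the corresponding proportion on the 0/1 observed disease
#' scale.  `h2_observed()` applies the classical population
#' transformation `h2 * z^2 / (K (1 - K))`; `h2_observed_cc()` applies
#' the case-control extension `h2 * z^2 * P (1 - P) / (K^2 (1 - K)^2)`,
#' which additionally accounts for the ascertainment of cases to a
#' sample proportion `P` different from the population prevalence `K`.
#'
#' The two transformations differ exactly by the factor
#' `P (1 - P) / (K (1 - K))` and coincide when `P = K`.
#'
#' @param h2 Proportion of liability variance explained (in \[0, 1\]) by
#'   a marker, a set of markers, or all genetic effects.
#' @param K Population disease prevalence, strictly in (0, 1).
#' @param P Proportion of cases in the case-control sample, strictly in
#'   (0, 1).
#'
#' @return The variance proportion on the 0/1 observed scale.  Note the
#'   case-control value is not bounded by 1: strong ascertainment at low
#'   prevalence can push it above 1 (it is a ratio of variances on
#'   different scales, not a heritability of the sample).
#'
#' @examples
#' h2_observed(0.5, K = 0.1)
#' h2_observed_cc(0.5, K = 0.01, P = 0.5)
#'
#' @export
h2_observed <- function(h2, K) {
  check_proportion01(h2, "h2")
  check_probability(K, "K")
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  h2 * z^2 / (K * (1 - K))
}

#' @rdname h2_observed
#' @export
h2_observed_cc <- function(h2, K, P) {
  check_proportion01(h2, "h2")
  check_probability(K, "K")
  check_probability(P, "P")
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  h2 * z^2 * P * (1 - P) / (K^2 * (1 - K)^2)
}

#' Liability-scale variance components under case-control ascertainment
#'
#' Over-sampling cases truncates the liability distribution within each
#' group and separates the group means, so both the genetic and the
#' residual variance on the liability scale differ from their population
#' values in an ascertained sample.  These functions return the
#' liability-scale genetic and residual variance in a sample with case
#' proportion `P`, using the mixture decomposition: within-group
#' variance shrunk by selection on liability, plus between-group
#' variance from the case/control means of the genetic (resp. residual)
#' values.
#'
#' For `h2` of appreciable size and strong ascertainment the genetic
#' variance is inflated relative to its population value `h2`; as
#' `h2 -> 0` the inflation disappears.  `residual_variance_cc()` is the
#' mirror image with `h2` replaced by `1 - h2`.
#'
#' @inheritParams h2_observed
#'
#' @return Liability-scale variance (a single number).
#'
#' @examples
#' genetic_variance_cc(0.5, K = 0.01, P = 0.5)   # inflated above 0.5
#' residual_variance_cc(0.5, K = 0.01, P = 0.5)  # symmetric at h2 = 0.5
#'
#' @export
genetic_variance_cc <- function(h2, K, P) {
  check_proportion01(h2, "h2")
  d <- liability_design(K, P)
  h2 * (P * (1 - h2 * (1 - d$v_case)) +
          (1 - P) * (1 - h2 * (1 - d$v_ctrl))) +
    P * (1 - P) * h2^2 * (d$i_case - d$i_ctrl)^2
}

#' @rdname genetic_variance_cc
#' @export
residual_variance_cc <- function(h2, K, P) {
  check_proportion01(h2, "h2")
  r2 <- 1 - h2
  d <- liability_design(K, P)
  r2 * (P * (1 - r2 * (1 - d$v_case)) +
          (1 - P) * (1 - r2 * (1 - d$v_ctrl))) +
    P * (1 - P) * r2^2 * (d$i_case - d$i_ctrl)^2
}
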