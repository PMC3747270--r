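#' Non-centrality parameters for five GWAS designs
#'
#' The 1-df chi-square association test of a marker (or marker set)
#' explaining a proportion `q2` of liability variance has a
#' non-centrality parameter (NCP) that depends on the study design:
#'
#' * `ncp_qt_pop()` — quantitative response in a population sample:
#'   `N * q2`.
#' * `ncp_bt_pop()` — binary (0/1) response in a population sample:
#'   `N` times the observed-scale variance proportion at prevalence `K`.
#' * `ncp_bt_cc()` — binary response in an ascertained case-control
#'   sample with case proportion `P`: `N` times the case-control
#'   observed-scale variance proportion.  This is the small-`q2`
#'   simplification; `exact = TRUE` replaces `q2` by the
#'   ascertainment-inflated genetic variance
#'   [genetic_variance_cc()] of the tested marker set.
#' * `ncp_qt_cc()` — quantitative (liability) response in an ascertained
#'   case-control sample.  The default is the full regression form: the
#'   proportion of response variance explained in the ascertained
#'   sample is `R2 = q2 * v / (1 + q2 * (v - 1))` with
#'   `v = var_lcc(K, P)` (covariance of liability and genetic value
#'   scales with `v`, while the marker variance itself is mildly
#'   inflated), and the regression NCP is `N * R2 / (1 - R2)`.
#'   `exact = FALSE` gives the small-`q2` approximation `N * q2 * v`.
#' * `ncp_qb_cc()` — quantitative response recorded for cases only,
#'   zero for controls (e.g. a severity score measured in cases): the
#'   response is a mixture of zero and an upper-truncated normal, and
#'   the NCP follows from its variance and its covariance with the
#'   marker.
#'
#' @param N Total sample size (number of individuals).
#' @param q2 Proportion of liability (or trait) variance explained by
#'   the tested marker or marker set, strictly in (0, 1); `q2 = 0` is
#'   allowed and gives NCP 0.
#' @param K Population disease prevalence, strictly in (0, 1).
#' @param P Proportion of cases in the case-control sample (default
#'   0.5).
#' @param exact Use the ascertainment-inflation-aware form rather than
#'   the small-`q2` approximation (see Details above for each design).
#'
#' @return The non-centrality parameter, a non-negative number.
#'
#' @examples
#' ncp_qt_pop(2000, 0.001)                     # 2
#' ncp_bt_cc(2000, 0.001, K = 0.01, P = 0.5)   # 3.62
#' chisq_power(ncp_qt_cc(2000, 0.001, K = 0.1), alpha = 0.05)
#'
#' @seealso [chisq_power()], [gwas_power()]
#' @name ncp
NULL

check_power_args <- function(N, q2, alpha = NULL) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N < 1)
    stop("'N' must be a single number >= 1", call. = FALSE)
  if (!is.numeric(q2) || length(q2) != 1L || !is.finite(q2) ||
      q2 < 0 || q2 >= 1)
    stop("'q2' must be a single number in [0, 1)", call. = FALSE)
  if (!is.null(alpha)) {
    if (!is.numeric(alpha) || length(alpha) != 1L ||
        alpha <= 0 || alpha >= 1)
      stop("'alpha' must be a single number strictly inside (0, 1)",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname ncp
#' @export
ncp_qt_pop <- function(N, q2) {
  check_power_args(N, q2)
  N * q2
}

#' @rdname ncp
#' @export
ncp_bt_pop <- function(N, q2, K) {
  check_power_args(N, q2)
  N * h2_observed(q2, K)
}

#' @rdname ncp
#' @export
ncp_bt_cc <- function(N, q2, K, P = 0.5, exact = FALSE) {
  check_power_args(N, q2)
  q2_eff <- if (exact) genetic_variance_cc(q2, K, P) else q2
  N * h2_observed_cc(1, K, P) * q2_eff
}

#' @rdname ncp
#' @export
ncp_qt_cc <- function(N, q2, K, P = 0.5, exact = TRUE) {
  check_power_args(N, q2)
  v <- liability_design(K, P)$var_lcc
  if (!exact) return(N * q2 * v)
  r2 <- q2 * v / (1 + q2 * (v - 1))
  N * r2 / (1 - r2)
}

#' @rdname ncp
#' @export
ncp_qb_cc <- function(N, q2, K, P = 0.5) {
  check_power_args(N, q2)
  d <- liability_design(K, P)
  # response: liability for cases, 0 for controls; its covariance with
  # the marker set is q2 * cov_term and its variance is var_y
  cov_term <- P * d$v_case +
    P * (1 - P) * d$i_case * (d$i_case - d$i_ctrl)
  var_y <- P * d$v_case + P * (1 - P) * d$i_case^2
  N * q2 * cov_term^2 / var_y
}

#' Power of the 1-df chi-square association test
#'
#' Upper-tail mass of the noncentral chi-square distribution beyond the
#' central critical value at significance level `alpha`.
#'
#' @param ncp Non-centrality parameter (non-negative).
#' @param alpha Significance level, strictly in (0, 1).
#' @param df Degrees of freedom (1 for a single-marker or single-set
#'   association test).
#'
#' @return Power, a probability in \[`alpha`, 1\].
#'
#' @examples
#' chisq_power(2, alpha = 0.05)       # 0.293
#' chisq_power(0, alpha = 0.05)       # alpha under the null
#'
#' @export
chisq_power <- function(ncp, alpha = 0.05, df = 1) {
  if (any(!is.finite(ncp)) || any(ncp < 0))
    stop("'ncp' must be finite and non-negative", call. = FALSE)
  check_power_args(1, 0, alpha)
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = ncp, lower.tail = FALSE)
}

#' Analytic power for a grid of GWAS designs
#'
#' Convenience wrapper: computes NCP and power for every combination of
#' the supplied parameter values and returns them as a data frame, one
#' row per combination.
#'
#' @param design Character vector among `"QT_POP"`, `"BT_POP"`,
#'   `"BT_CC"`, `"QT_CC"`, `"QB_CC"`.
#' @param N,q2,alpha,K,P Parameter values (each may be a vector; the
#'   full factorial grid is evaluated).  `K` is ignored for `QT_POP`
#'   and `P` for the population designs.
#' @param exact Passed on to [ncp_bt_cc()] / [ncp_qt_cc()]; `NULL`
#'   keeps each design's default.
#'
#' @return A data frame with columns `design`, `K`, `P`, `N`, `q2`,
#'   `alpha`, `ncp`, `power`.
#'
#' @examples
#' gwas_power("BT_CC", N = 2000, q2 = 0.001, K = 0.01, P = 0.5)
#'
#' @export
gwas_power <- function(design, N, q2, alpha = 0.05, K = NA, P = 0.5,
                       exact = NULL) {
  design <- match.arg(design, gwas_designs(), several.ok = TRUE)
  grid <- expand.grid(design = design, K = K, P = P, N = N, q2 = q2,
                      alpha = alpha, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0L)
    stop("empty parameter grid", call. = FALSE)
  grid$ncp <- vapply(seq_len(nrow(grid)), function(r) {
    with(grid[r, ], {
      needs_K <- design != "QT_POP"
      if (needs_K && !is.finite(K))
        stop(sprintf("design %s requires a prevalence K", design),
             call. = FALSE)
      switch(design,
        QT_POP = ncp_qt_pop(N, q2),
        BT_POP = ncp_bt_pop(N, q2, K),
        BT_CC  = if (is.null(exact)) ncp_bt_cc(N, q2, K, P)
                 else ncp_bt_cc(N, q2, K, P, exact = exact),
        QT_CC  = if (is.null(exact)) ncp_qt_cc(N, q2, K, P)
                 else ncp_qt_cc(N, q2, K, P, exact = exact),
        QB_CC  = ncp_qb_cc(N, q2, K, P))
    })
  }, numeric(1))
  grid$power <- mapply(chisq_power, grid$ncp, grid$alpha)
  grid[, c("design", "K", "P", "N", "q2", "alpha", "ncp", "power")]
}

gwas_designs <- function() c("QT_POP", "BT_POP", "BT_CC", "QT_CC", "QB_CC")
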