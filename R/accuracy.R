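#' Expected genomic prediction accuracy
#'
#' Expected correlation between true and estimated genetic values when
#' marker effects are estimated by per-marker least squares on `N`
#' training records and a predictor is built from `M` markers.  All
#' three forms share the structure `r^2 = N * h2w / (N * h2w + M)`,
#' where `h2w` is the variance proportion on the scale the regression
#' is run on:
#'
#' * `accuracy_quantitative()` — quantitative trait: `h2w = h2`
#'   (residual variance approximated by the phenotypic variance, 1).
#'   Equivalently `r^2 = tau * h2 / (tau * h2 + 1)` with `tau = N / M`.
#' * `accuracy_disease_population()` — disease analysed as 0/1 in a
#'   population sample: `h2w` is the observed-scale transformation
#'   [h2_observed()] at prevalence `K` (residual variance
#'   `K (1 - K)`).
#' * `accuracy_disease_cc()` — disease analysed as 0/1 in an
#'   ascertained case-control sample with case proportion `P`:
#'   `h2w` is the case-control transformation [h2_observed_cc()]
#'   (residual variance `P (1 - P)`; the per-marker ascertainment
#'   inflation factor is taken as 1, which holds when the genetic
#'   variance is spread over a sufficient number of markers).
#'
#' At `P = K` the case-control form reduces to the population form.
#'
#' @param N Training-sample size (number of records).
#' @param M Number of markers in the predictor.
#' @param h2 Proportion of variance explained by the `M` markers
#'   jointly, on the liability scale for the disease forms, in
#'   \[0, 1\].
#' @param K Population disease prevalence, strictly in (0, 1).
#' @param P Proportion of cases in the training sample (default 0.5).
#'
#' @return A data frame with one row and columns `r` (expected
#'   correlation between true and estimated genetic values), `r2`
#'   (its square) and `h2_working` (the variance proportion used on
#'   the working scale).
#'
#' @examples
#' accuracy_quantitative(N = 2000, M = 2000, h2 = 0.5)
#' accuracy_disease_population(2000, 2000, h2 = 0.5, K = 0.1)
#' accuracy_disease_cc(2000, 2000, h2 = 0.5, K = 0.01, P = 0.5)
#'
#' @name prediction_accuracy
NULL

check_accuracy_args <- function(N, M, h2) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N < 1)
    stop("'N' must be a single number >= 1", call. = FALSE)
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M) || M < 1)
    stop("'M' must be a single number >= 1", call. = FALSE)
  check_proportion01(h2, "h2")
  invisible(TRUE)
}

accuracy_result <- function(N, M, h2w) {
  r2 <- N * h2w / (N * h2w + M)
  data.frame(r = sqrt(r2), r2 = r2, h2_working = h2w)
}

#' @rdname prediction_accuracy
#' @export
accuracy_quantitative <- function(N, M, h2) {
  check_accuracy_args(N, M, h2)
  accuracy_result(N, M, h2)
}

#' @rdname prediction_accuracy
#' @export
accuracy_disease_population <- function(N, M, h2, K) {
  check_accuracy_args(N, M, h2)
  accuracy_result(N, M, h2_observed(h2, K))
}

#' @rdname prediction_accuracy
#' @export
accuracy_disease_cc <- function(N, M, h2, K, P = 0.5) {
  check_accuracy_args(N, M, h2)
  if (M < 20)
    warning("the case-control accuracy formula assumes the genetic ",
            "variance is spread over a sufficient number of markers ",
            "(around 20 or more); M = ", M, call. = FALSE)
  accuracy_result(N, M, h2_observed_cc(h2, K, P))
}

#' Accuracy for a grid of designs
#'
#' Wrapper evaluating one of the expected-accuracy formulas over the
#' full factorial grid of the supplied parameters.
#'
#' @param method One of `"quantitative"`, `"population"`, `"cc"`.
#' @param N,M,h2,K,P Parameter vectors; the factorial grid is
#'   evaluated.  `K` is ignored for `"quantitative"`, `P` for
#'   everything but `"cc"`.
#'
#' @return Data frame with columns `method`, `N`, `M`, `h2`, `K`, `P`,
#'   `r`, `r2`.
#'
#' @examples
#' gwas_accuracy("cc", N = 2000, M = 2000, h2 = 0.5,
#'               K = c(0.01, 0.1), P = 0.5)
#'
#' @export
gwas_accuracy <- function(method, N, M, h2, K = NA, P = 0.5) {
  method <- match.arg(method, c("quantitative", "population", "cc"),
                      several.ok = TRUE)
  grid <- expand.grid(method = method, N = N, M = M, h2 = h2, K = K,
                      P = P, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0L)
    stop("empty parameter grid", call. = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    with(grid[r, ], {
      if (method != "quantitative" && !is.finite(K))
        stop(sprintf("method '%s' requires a prevalence K", method),
             call. = FALSE)
      switch(method,
        quantitative = accuracy_quantitative(N, M, h2),
        population   = accuracy_disease_population(N, M, h2, K),
        cc           = accuracy_disease_cc(N, M, h2, K, P))
    })
  })
  res <- do.call(rbind, res)
  cbind(grid, res[, c("r", "r2")])
}
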