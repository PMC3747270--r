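#' Reproduce the validation tables and power curves
#'
#' One-command reproduction of the package's reference results: the
#' expected-vs-observed power table (`"table1"`), the
#' prediction-accuracy tables over prevalence (`"table2"`),
#' heritability (`"table3"`) and the sample-to-marker ratio
#' (`"table4"`), and the genome-wide-threshold power curves
#' (`"figure1"`).  Each table pairs the analytic expectation with a
#' simulation estimate and its empirical standard error.
#'
#' The defaults run at desk scale (`reps = 20`); `full = TRUE`
#' restores 100 replicates.  Low-prevalence ascertained scenarios are
#' expensive (each replicate draws about `N * P / K` individuals), so
#' the prevalence grids can be restricted via the arguments.
#'
#' @param table_id One of `"table1"`, `"table2"`, `"table3"`,
#'   `"table4"`, `"figure1"`.
#' @param reps Simulation replicates per scenario.
#' @param seed Master seed for the simulation columns.
#' @param full Use 100 replicates regardless of `reps`.
#' @param simulate Include the simulation columns (`observed`, `se`);
#'   if `FALSE` only the analytic column is computed.
#' @param ... Passed to the per-table worker: `K_values`, `q2_values`
#'   for `"table1"`, `prevalences` for `"table2"`, `h2_values` for
#'   `"table3"`, `tau` for `"table4"`.
#'
#' @return A data frame; analytic values in `expected`, simulation in
#'   `observed` and `se`.
#'
#' @examples
#' reproduce_table("table2", simulate = FALSE)
#' head(reproduce_table("figure1"))
#'
#' @export
reproduce_table <- function(table_id, reps = 20, seed = 1,
                            full = FALSE, simulate = TRUE, ...) {
  table_id <- match.arg(table_id, c("table1", "table2", "table3",
                                    "table4", "figure1"))
  if (full) reps <- 100
  switch(table_id,
    table1  = reproduce_power_table(reps, seed, simulate, ...),
    table2  = reproduce_accuracy_table(reps, seed, simulate,
                                       vary = "K", ...),
    table3  = reproduce_accuracy_table(reps, seed, simulate,
                                       vary = "h2", ...),
    table4  = reproduce_accuracy_table(reps, seed, simulate,
                                       vary = "tau", ...),
    figure1 = figure1_curves(...))
}

reproduce_power_table <- function(reps, seed, simulate,
                                  K_values = c(0.1, 0.01, 0.001),
                                  q2_values = c(1e-4, 5e-4, 1e-3),
                                  N = 2000, M = 100, alpha = 0.05) {
  designs <- c("BT_POP", "BT_CC", "QT_POP", "QT_CC")
  grid <- expand.grid(K = K_values, q2 = q2_values, design = designs,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(r) {
    K <- grid$K[r]; q2 <- grid$q2[r]; design <- grid$design[r]
    cc <- grepl("_CC$", design)
    expected <- gwas_power(design, N = N, q2 = q2, alpha = alpha,
                           K = K, P = if (cc) 0.5 else K)$power
    obs <- se <- NA_real_
    if (simulate) {
      cfg <- sim_config(M = M, N = N, h2 = q2 * M, K = K,
                        P = if (cc) 0.5 else NULL,
                        design = if (grepl("^BT", design)) "BT" else "QT",
                        ascertained = cc, n_replicates = reps,
                        alpha = alpha,
                        seed = replicate_seed(seed, r * 1000L))
      s <- empirical_power(cfg)
      obs <- s$estimate; se <- s$se
    }
    data.frame(design = design, K = K, q2 = q2, N = N, alpha = alpha,
               expected = expected, observed = obs, se = se)
  })
  do.call(rbind, out)
}

reproduce_accuracy_table <- function(reps, seed, simulate, vary,
                                     prevalences = c(0.001, 0.01, 0.1,
                                                     0.2, 0.5),
                                     h2_values = c(0.1, 0.5, 0.9),
                                     tau = c(0.02, 1, 5)) {
  scen <- switch(vary,
    K   = data.frame(K = prevalences, h2 = 0.5, N = 2000, M = 2000),
    h2  = data.frame(K = 0.01, h2 = h2_values, N = 2000, M = 2000),
    tau = data.frame(K = 0.01, h2 = 0.5,
                     N = c(100, 2000, 2000)[match(tau, c(0.02, 1, 5))],
                     M = c(5000, 2000, 400)[match(tau, c(0.02, 1, 5))]))
  out <- lapply(seq_len(nrow(scen)), function(r) {
    s <- scen[r, ]
    res <- lapply(c("population", "cc"), function(method) {
      expected <- gwas_accuracy(method, N = s$N, M = s$M, h2 = s$h2,
                                K = s$K, P = 0.5)$r
      obs <- se <- NA_real_
      if (simulate) {
        cfg <- sim_config(M = s$M, N = s$N, h2 = s$h2, K = s$K,
                          P = if (method == "cc") 0.5 else NULL,
                          ascertained = method == "cc",
                          n_replicates = reps,
                          seed = replicate_seed(seed, r * 1000L +
                                                  (method == "cc")),
                          N_validation = 2000)
        a <- empirical_accuracy(cfg)
        obs <- a$estimate; se <- a$se
      }
      data.frame(method = method, K = s$K, P = 0.5, N = s$N, M = s$M,
                 tau = s$N / s$M, h2 = s$h2, expected = expected,
                 observed = obs, se = se)
    })
    do.call(rbind, res)
  })
  do.call(rbind, out)
}

#' Analytic power curves at the genome-wide threshold
#'
#' Power of the four main designs as a function of the variance
#' explained by the tested marker set, at the genome-wide significance
#' threshold, for each prevalence.
#'
#' @param q2_values Grid of variance proportions to sweep.
#' @param K_values Prevalences.
#' @param N Sample size.
#' @param alpha Significance threshold (default genome-wide, 5e-8).
#'
#' @return Data frame with columns `design`, `K`, `q2`, `power`.
#'
#' @export
figure1_curves <- function(q2_values = seq(5e-4, 2e-2, by = 5e-4),
                           K_values = c(0.1, 0.01, 0.001),
                           N = 2000, alpha = 5e-8) {
  designs <- c("QT_POP", "BT_POP", "BT_CC", "QT_CC")
  out <- lapply(K_values, function(K) {
    res <- lapply(designs, function(d) {
      cc <- grepl("_CC$", d)
      data.frame(design = d, K = K, q2 = q2_values,
                 power = gwas_power(d, N = N, q2 = q2_values,
                                    alpha = alpha, K = K,
                                    P = if (cc) 0.5 else K)$power)
    })
    do.call(rbind, res)
  })
  do.call(rbind, out)
}
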