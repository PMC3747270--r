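#' Simulation scenario for a liability-threshold cohort
#'
#' Bundles and validates all parameters of a simulation scenario: an
#' additive multilocus architecture of `M` independent biallelic
#' markers, liability = genetic value + normal residual, disease status
#' by thresholding at prevalence `K`, and optional case-control
#' ascertainment to a case proportion `P`.
#'
#' @param M Number of independent markers.
#' @param N Analysed sample size.
#' @param h2 Total proportion of liability variance explained by the
#'   `M` markers jointly, in \[0, 1).
#' @param K Population disease prevalence.
#' @param P Case proportion in the analysed sample.  Defaults to 0.5
#'   when `ascertained = TRUE` and to `K` otherwise.
#' @param allele_freq Allele frequency shared by all markers
#'   (default 0.5).
#' @param effect_distribution Distribution of per-marker allele
#'   effects: `"equal"` (all identical, the default), `"normal"` or
#'   `"exponential"`.  Effects are always rescaled so the genetic
#'   variance equals `h2` in expectation.
#' @param design Response coding: `"BT"` (0/1 status), `"QT"`
#'   (liability), `"QB"` (liability for cases, 0 for controls).
#' @param ascertained Sample cases and controls to fixed quotas
#'   `N * P` and `N * (1 - P)` by rejection from the population model.
#' @param n_replicates Number of simulation replicates.
#' @param alpha Significance level for association tests.
#' @param seed Master seed; each replicate uses a seed derived from it,
#'   so results for replicate `i` do not depend on `n_replicates`.
#' @param N_validation Size of the population validation sample used by
#'   [empirical_accuracy()].
#' @param max_draws Budget of population draws per replicate for
#'   quota-filling under ascertainment.
#'
#' @return An object of class `"sim_config"` (a validated list).
#'
#' @examples
#' sim_config(M = 100, N = 2000, h2 = 0.1, K = 0.1,
#'            ascertained = TRUE, n_replicates = 20)
#'
#' @export
sim_config <- function(M = 100, N = 2000, h2 = 0.1, K = 0.1, P = NULL,
                       allele_freq = 0.5,
                       effect_distribution = c("equal", "normal",
                                               "exponential"),
                       design = c("BT", "QT", "QB"),
                       ascertained = FALSE,
                       n_replicates = 100, alpha = 0.05, seed = 1L,
                       N_validation = 2000, max_draws = 1e7) {
  effect_distribution <- match.arg(effect_distribution)
  design <- match.arg(design)
  if (!is.numeric(M) || M < 1) stop("'M' must be >= 1", call. = FALSE)
  if (!is.numeric(N) || N < 2) stop("'N' must be >= 2", call. = FALSE)
  if (!is.numeric(h2) || h2 < 0 || h2 >= 1)
    stop("'h2' must lie in [0, 1)", call. = FALSE)
  check_probability(K, "K")
  if (is.null(P)) P <- if (ascertained) 0.5 else K
  check_probability(P, "P")
  check_probability(allele_freq, "allele_freq")
  if (n_replicates < 1) stop("'n_replicates' must be >= 1", call. = FALSE)
  check_power_args(1, 0, alpha)
  if (!is.numeric(seed) || !is.finite(seed))
    stop("'seed' must be a finite number", call. = FALSE)
  structure(
    list(M = as.integer(M), N = as.integer(N), h2 = h2, K = K, P = P,
         allele_freq = allele_freq,
         effect_distribution = effect_distribution, design = design,
         ascertained = isTRUE(ascertained),
         n_replicates = as.integer(n_replicates), alpha = alpha,
         seed = as.integer(seed),
         N_validation = as.integer(N_validation),
         max_draws = max_draws),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation scenario\n")
  cat(sprintf("  markers M = %d, sample N = %d, h2 = %g\n",
              x$M, x$N, x$h2))
  cat(sprintf("  prevalence K = %g, case proportion P = %g, %s\n",
              x$K, x$P,
              if (x$ascertained) "ascertained case-control sampling"
              else "population sampling"))
  cat(sprintf("  response %s, effects %s, allele frequency %g\n",
              x$design, x$effect_distribution, x$allele_freq))
  cat(sprintf("  %d replicates, alpha = %g, seed = %d\n",
              x$n_replicates, x$alpha, x$seed))
  invisible(x)
}

# Deterministic per-replicate seed: prefix-stable in the replicate
# count and always below 2^31.
replicate_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * i) %% 2147483647)
}

# Per-marker allele substitution effects, rescaled so the genotypic
# variance sums to h2 exactly (2p(1-p) variance per marker count).
marker_effects <- function(M, h2, p,
                           distribution = c("equal", "normal",
                                            "exponential")) {
  distribution <- match.arg(distribution)
  if (h2 == 0) return(numeric(M))
  raw <- switch(distribution,
    equal       = rep(1, M),
    normal      = stats::rnorm(M),
    exponential = stats::rexp(M))
  raw * sqrt(h2 / sum(raw^2 * 2 * p * (1 - p)))
}

genotype_matrix <- function(n, M, p) {
  matrix(stats::rbinom(n * M, 2L, p), nrow = n, ncol = M)
}

#' Simulate a liability-threshold cohort
#'
#' Draws a cohort under the scenario in `config`: genotypes are
#' independent Binomial(2, `allele_freq`) counts, genetic values are
#' the centred genotype scores weighted by the marker effects, the
#' residual is normal with variance `1 - h2`, and individuals whose
#' liability exceeds the prevalence threshold are cases.  Under
#' ascertainment, population batches are drawn until the case and
#' control quotas `N * P` and `N * (1 - P)` are filled.
#'
#' Uses the current RNG state; seed via `set.seed()` or use the
#' replicate drivers [empirical_power()] / [empirical_accuracy()],
#' which manage per-replicate seeds themselves.
#'
#' @param config A [sim_config()] object.
#' @param beta Optional vector of `M` per-marker effects to reuse
#'   (e.g. to score a validation sample with the training
#'   architecture); by default effects are drawn from
#'   `config$effect_distribution`.
#'
#' @return An object of class `"gwas_cohort"`: list with the `N x M`
#'   genotype matrix, per-individual genetic value `g`, residual `e`,
#'   `liability`, logical `status`, the `response` vector under the
#'   configured coding, the effect vector `beta`, the number of
#'   population `draws` consumed, and the `config`.
#'
#' @examples
#' cfg <- sim_config(M = 50, N = 200, h2 = 0.1, K = 0.1,
#'                   ascertained = TRUE)
#' set.seed(1)
#' coh <- simulate_cohort(cfg)
#' mean(coh$status)  # exactly P under ascertainment
#'
#' @export
simulate_cohort <- function(config, beta = NULL) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$allele_freq
  M <- config$M
  if (is.null(beta))
    beta <- marker_effects(M, config$h2, p, config$effect_distribution)
  if (length(beta) != M)
    stop("'beta' must have one effect per marker", call. = FALSE)
  thr <- stats::qnorm(1 - config$K)
  sd_e <- sqrt(1 - config$h2)
  offset <- 2 * p * sum(beta)  # centres g at zero

  draw_batch <- function(n) {
    X <- genotype_matrix(n, M, p)
    g <- drop(X %*% beta) - offset
    e <- stats::rnorm(n, 0, sd_e)
    y <- g + e
    list(X = X, g = g, e = e, y = y, case = y > thr)
  }

  if (!config$ascertained) {
    b <- draw_batch(config$N)
    draws <- config$N
    X <- b$X; g <- b$g; e <- b$e; y <- b$y; case <- b$case
  } else {
    n_case <- as.integer(round(config$N * config$P))
    n_ctrl <- config$N - n_case
    parts <- list()
    got_case <- 0L; got_ctrl <- 0L; draws <- 0L
    while (got_case < n_case || got_ctrl < n_ctrl) {
      need_case <- n_case - got_case
      need_ctrl <- n_ctrl - got_ctrl
      nb <- ceiling(1.1 * max(need_case / config$K,
                              need_ctrl / (1 - config$K)))
      nb <- min(max(nb, 1000), 50000)
      if (draws + nb > config$max_draws)
        stop(sprintf(paste0(
          "ascertainment budget exhausted after %d population draws ",
          "(K = %g, P = %g, N = %d); raise 'max_draws'"),
          draws, config$K, config$P, config$N), call. = FALSE)
      b <- draw_batch(nb)
      draws <- draws + nb
      keep_case <- which(b$case)[seq_len(min(need_case, sum(b$case)))]
      keep_ctrl <- which(!b$case)[seq_len(min(need_ctrl, sum(!b$case)))]
      keep <- c(keep_case, keep_ctrl)
      if (length(keep)) {
        parts[[length(parts) + 1L]] <-
          list(X = b$X[keep, , drop = FALSE], g = b$g[keep],
               e = b$e[keep], y = b$y[keep], case = b$case[keep])
        got_case <- got_case + length(keep_case)
        got_ctrl <- got_ctrl + length(keep_ctrl)
      }
    }
    X <- do.call(rbind, lapply(parts, `[[`, "X"))
    g <- unlist(lapply(parts, `[[`, "g"))
    e <- unlist(lapply(parts, `[[`, "e"))
    y <- unlist(lapply(parts, `[[`, "y"))
    case <- unlist(lapply(parts, `[[`, "case"))
  }

  response <- switch(config$design,
    BT = as.numeric(case),
    QT = y,
    QB = ifelse(case, y, 0))

  structure(
    list(genotypes = X, g = g, e = e, liability = y, status = case,
         response = response, beta = beta, draws = draws,
         config = config),
    class = "gwas_cohort")
}

#' @export
print.gwas_cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated cohort: %d individuals x %d markers (%d cases, %s)\n",
    nrow(x$genotypes), ncol(x$genotypes), sum(x$status),
    if (x$config$ascertained) "ascertained" else "population sample"))
  invisible(x)
}

#' Per-marker association scan
#'
#' Tests each marker against the response by simple linear regression,
#' using the score-test statistic `N * r^2` (with `r` the sample
#' correlation between genotype count and response) referred to a
#' 1-df chi-square distribution.  This is asymptotically equivalent to
#' the OLS squared t statistic and matches the degrees of freedom of
#' the analytic non-centrality framework.  Monomorphic markers get
#' statistic 0 and p-value 1.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param response Optional response vector overriding the cohort's
#'   configured coding (e.g. to score the same cohort under several
#'   codings).
#'
#' @return Data frame with columns `marker`, `statistic`, `p_value`.
#'
#' @export
association_scan <- function(cohort, response = NULL) {
  stopifnot(inherits(cohort, "gwas_cohort"))
  y <- if (is.null(response)) cohort$response else response
  X <- cohort$genotypes
  n <- nrow(X)
  if (length(y) != n)
    stop("response length does not match the cohort", call. = FALSE)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  if (syy == 0) stop("response has zero variance", call. = FALSE)
  xm <- colMeans(X)
  sxy <- drop(crossprod(X, yc))            # X'yc = Xc'yc since sum(yc)=0
  sxx <- colSums(X^2) - n * xm^2
  mono <- sxx <= 0
  r2 <- rep(0, ncol(X))
  r2[!mono] <- (sxy[!mono]^2) / (sxx[!mono] * syy)
  stat <- n * r2
  data.frame(marker = seq_len(ncol(X)), statistic = stat,
             p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

sim_summary <- function(statistic, estimate, se, se_replicate,
                        n_replicates, n_tests, config) {
  structure(
    list(statistic = statistic, estimate = estimate, se = se,
         se_replicate = se_replicate, n_replicates = n_replicates,
         n_tests = n_tests, seed = config$seed, config = config),
    class = "gwas_sim_summary")
}

#' @export
print.gwas_sim_summary <- function(x, ...) {
  cat(sprintf("Empirical %s: %.4f (SE %.4f", x$statistic, x$estimate,
              x$se))
  if (!is.na(x$se_replicate))
    cat(sprintf(", replicate-level SE %.4f", x$se_replicate))
  cat(sprintf(") over %d replicates, seed %d\n", x$n_replicates,
              x$seed))
  invisible(x)
}

#' Empirical power over simulation replicates
#'
#' Simulates `n_replicates` cohorts under `config`, scans every marker
#' in each, and reports the fraction of all marker tests with
#' p-value below `config$alpha`.  Two standard errors are reported:
#' the binomial SE over the pooled tests (the convention used when
#' quoting power over `replicates x markers` tests) and the
#' replicate-level SE of the per-replicate power estimates.
#'
#' @param config A [sim_config()] object.
#'
#' @return A `"gwas_sim_summary"` with `estimate` (power), `se`
#'   (binomial over all tests), `se_replicate`, `n_replicates`,
#'   `n_tests` and the scenario echo.
#'
#' @examples
#' cfg <- sim_config(M = 50, N = 500, h2 = 0.05, K = 0.1,
#'                   ascertained = TRUE, n_replicates = 5, seed = 7)
#' empirical_power(cfg)
#'
#' @export
empirical_power <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  per_rep <- numeric(config$n_replicates)
  hits <- 0L
  for (i in seq_len(config$n_replicates)) {
    set.seed(replicate_seed(config$seed, i))
    cohort <- simulate_cohort(config)
    if (stats::var(cohort$response) == 0) {
      # e.g. a rare-disease population replicate with no cases: no
      # marker can be declared associated
      per_rep[i] <- 0
      next
    }
    scan <- association_scan(cohort)
    sig <- scan$p_value < config$alpha
    per_rep[i] <- mean(sig)
    hits <- hits + sum(sig)
  }
  n_tests <- config$n_replicates * config$M
  est <- hits / n_tests
  se_bin <- sqrt(est * (1 - est) / n_tests)
  se_rep <- if (config$n_replicates > 1)
    stats::sd(per_rep) / sqrt(config$n_replicates) else NA_real_
  sim_summary("power", est, se_bin, se_rep, config$n_replicates,
              n_tests, config)
}

#' Empirical genomic prediction accuracy over simulation replicates
#'
#' Per replicate: simulate a training cohort under `config` (typically
#' ascertained case-control), estimate each marker's allele
#' substitution effect by marginal per-marker regression of the 0/1
#' disease status on genotype count, build the predictor
#' `ghat = X beta_hat` in an independent, unascertained population
#' validation sample of `config$N_validation` individuals drawn with
#' the same marker effects, and record the correlation between the
#' validation sample's true genetic values and `ghat`.  The summary is
#' the replicate mean and its standard error.
#'
#' Training always uses the 0/1 status coding — the expected-accuracy
#' theory is derived on the observed scale; the `QT`/`QB` codings are
#' power-only.
#'
#' @param config A [sim_config()] object.
#'
#' @return A `"gwas_sim_summary"` with `estimate` (mean correlation),
#'   `se` (replicate-level), `n_replicates` and the scenario echo.
#'
#' @examples
#' cfg <- sim_config(M = 200, N = 400, h2 = 0.5, K = 0.1,
#'                   ascertained = TRUE, n_replicates = 3, seed = 11,
#'                   N_validation = 400)
#' empirical_accuracy(cfg)
#'
#' @export
empirical_accuracy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  val_config <- config
  val_config$ascertained <- FALSE
  val_config$P <- config$K
  val_config$N <- config$N_validation
  r_rep <- numeric(config$n_replicates)
  for (i in seq_len(config$n_replicates)) {
    set.seed(replicate_seed(config$seed, i))
    beta <- marker_effects(config$M, config$h2, config$allele_freq,
                           config$effect_distribution)
    train <- simulate_cohort(config, beta = beta)
    y <- as.numeric(train$status)
    X <- train$genotypes
    n <- nrow(X)
    yc <- y - mean(y)
    xm <- colMeans(X)
    sxx <- colSums(X^2) - n * xm^2
    bhat <- numeric(config$M)
    ok <- sxx > 0
    bhat[ok] <- drop(crossprod(X, yc))[ok] / sxx[ok]
    valid <- simulate_cohort(val_config, beta = beta)
    ghat <- drop(valid$genotypes %*% bhat)
    r_rep[i] <- if (stats::sd(ghat) == 0 || stats::sd(valid$g) == 0)
      0 else stats::cor(valid$g, ghat)
  }
  est <- mean(r_rep)
  se <- if (config$n_replicates > 1)
    stats::sd(r_rep) / sqrt(config$n_replicates) else NA_real_
  sim_summary("accuracy", est, se, se, config$n_replicates,
              config$n_replicates, config)
}

#' Export a simulated cohort as tab-delimited text
#'
#' Writes the genotype matrix (individuals x markers, header row of
#' marker IDs) and a phenotype table (`id`, `g`, `liability`, `status`,
#' `response`) as two TSV files.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param genotype_file,phenotype_file Output paths.
#'
#' @return Invisibly, the two paths.
#'
#' @export
export_cohort <- function(cohort, genotype_file, phenotype_file) {
  stopifnot(inherits(cohort, "gwas_cohort"))
  X <- cohort$genotypes
  colnames(X) <- sprintf("snp%d", seq_len(ncol(X)))
  utils::write.table(X, genotype_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pheno <- data.frame(id = seq_len(nrow(X)), g = cohort$g,
                      liability = cohort$liability,
                      status = as.integer(cohort$status),
                      response = cohort$response)
  utils::write.table(pheno, phenotype_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genotype_file, phenotype_file))
}
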