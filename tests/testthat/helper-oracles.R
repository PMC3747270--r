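# Independent oracles used across the suite.

# Truncated standard-normal moments by numerical integration (upper
# tail for cases, lower tail for controls).
integrate_moment <- function(fun, lower, upper) {
  stats::integrate(fun, lower, upper, rel.tol = 1e-12,
                   abs.tol = 1e-14)$value
}

truncated_moments_oracle <- function(K) {
  t <- qnorm(1 - K)
  m_case <- integrate_moment(function(x) x * dnorm(x), t, Inf) / K
  m_ctrl <- integrate_moment(function(x) x * dnorm(x), -Inf, t) / (1 - K)
  v_case <- integrate_moment(function(x) (x - m_case)^2 * dnorm(x),
                             t, Inf) / K
  v_ctrl <- integrate_moment(function(x) (x - m_ctrl)^2 * dnorm(x),
                             -Inf, t) / (1 - K)
  list(t = t, m_case = m_case, m_ctrl = m_ctrl,
       v_case = v_case, v_ctrl = v_ctrl)
}

# Mixture liability variance from the integration oracle.
var_lcc_oracle <- function(K, P) {
  o <- truncated_moments_oracle(K)
  P * o$v_case + (1 - P) * o$v_ctrl +
    P * (1 - P) * (o$m_case - o$m_ctrl)^2
}

# Monte-Carlo sample of (g, e, liability) under exact-quota
# case-control ascertainment; used to check the ascertained variance
# decomposition against an oracle that knows nothing of the closed
# forms.
mc_ascertained_sample <- function(h2, K, P, n_each = 5e5) {
  t <- qnorm(1 - K)
  n_case <- round(n_each * P)
  n_ctrl <- n_each - n_case
  draw_group <- function(n_target, want_case) {
    g <- numeric(0); e <- numeric(0)
    while (length(g) < n_target) {
      gi <- rnorm(2e5, 0, sqrt(h2))
      ei <- rnorm(2e5, 0, sqrt(1 - h2))
      keep <- if (want_case) (gi + ei) > t else (gi + ei) <= t
      g <- c(g, gi[keep]); e <- c(e, ei[keep])
    }
    list(g = g[1:n_target], e = e[1:n_target])
  }
  cs <- draw_group(n_case, TRUE)
  ct <- draw_group(n_ctrl, FALSE)
  list(g = c(cs$g, ct$g), e = c(cs$e, ct$e),
       y = c(cs$g + cs$e, ct$g + ct$e))
}

# Naive per-marker OLS scan (lm per marker): the textbook route the
# fast score-test scan is checked against.
ols_scan_oracle <- function(X, y) {
  t2 <- apply(X, 2, function(x) {
    if (var(x) == 0) return(0)
    summary(lm(y ~ x))$coefficients["x", "t value"]^2
  })
  t2
}

# Expected power cells for the reference power table (N = 2000,
# alpha = 0.05, P = 0.5 in case-control designs), as printed at three
# decimals; rows K x q2, one block per design.
reference_power_cells <- function() {
  cells <- rbind(
    c(0.058, 0.090, 0.131), c(0.052, 0.058, 0.067), c(0.050, 0.051, 0.053),
    c(0.072, 0.164, 0.281), c(0.092, 0.270, 0.478), c(0.117, 0.392, 0.664),
    c(0.073, 0.170, 0.293), c(0.073, 0.170, 0.293), c(0.073, 0.170, 0.293),
    c(0.082, 0.218, 0.386), c(0.105, 0.333, 0.579), c(0.130, 0.451, 0.738))
  data.frame(
    design = rep(c("BT_POP", "BT_CC", "QT_POP", "QT_CC"), each = 9),
    K = rep(rep(c(0.1, 0.01, 0.001), each = 3), 4),
    q2 = rep(c(1e-4, 5e-4, 1e-3), 12),
    expected = as.vector(t(cells)))
}

# Expected accuracy cells (population / case-control closed forms) for
# the reference accuracy tables, printed at three decimals.
reference_accuracy_cells <- function() {
  rbind(
    # prevalence sweep: N = M = 2000, h2 = 0.5, P = 0.5
    data.frame(N = 2000, M = 2000, h2 = 0.5, P = 0.5,
               K = c(0.001, 0.01, 0.1, 0.2, 0.5),
               pop = c(0.075, 0.186, 0.382, 0.444, 0.491),
               cc = c(0.766, 0.689, 0.568, 0.526, 0.491)),
    # heritability sweep: K = 0.01
    data.frame(N = 2000, M = 2000, h2 = c(0.1, 0.5, 0.9), P = 0.5,
               K = 0.01,
               pop = c(0.084, 0.186, 0.246),
               cc = c(0.392, 0.689, 0.787)),
    # sample-to-marker ratio sweep: K = 0.01, h2 = 0.5
    data.frame(N = c(100, 2000, 2000), M = c(5000, 2000, 400),
               h2 = 0.5, P = 0.5, K = 0.01,
               pop = c(0.027, 0.186, 0.390),
               cc = c(0.133, 0.689, 0.905)))
}
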