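# Shared oracles and fixtures, built in code.

# Brute-force numeric optimum of a model curve: dense log-spaced grid around
# a hint, refined with stats::optimize on the bracketing interval.
# Independent of the analytic inflection formulas it checks.
numeric_optimum <- function(m, lower, upper, maximize = TRUE, n_grid = 2000L) {
  g <- exp(seq(log(lower), log(upper), length.out = n_grid))
  v <- eval_model(m, g)
  i <- if (maximize) which.max(v) else which.min(v)
  bracket <- c(g[max(1L, i - 1L)], g[min(n_grid, i + 1L)])
  o <- stats::optimize(function(z) eval_model(m, z), interval = bracket,
                       maximum = maximize, tol = 1e-12)
  if (maximize) o$maximum else o$minimum
}

# Random valid parameter draws per family (A, C > 0 with B > 0 > D gives a
# guaranteed interior minimum for the power family).
draw_power <- function() {
  power_series_model(A = runif(1, 0.5, 5), B = runif(1, 0.3, 3),
                     C = runif(1, 0.5, 5), D = runif(1, -3, -0.3))
}
draw_lognormal <- function() {
  lognormal_model(amplitude = runif(1, 10, 100),
                  geo_mean = runif(1, 5, 30), geo_sd = runif(1, 1.05, 2.5))
}
# cubic built from prescribed stationary points r1 < r2 (b3 > 0: max at r1)
draw_cubic <- function() {
  r1 <- runif(1, 2, 10); r2 <- r1 + runif(1, 2, 10); b3 <- runif(1, 0.2, 2)
  list(model = cubic_model(b0 = runif(1, -5, 5), b1 = 3 * b3 * r1 * r2,
                           b2 = -1.5 * b3 * (r1 + r2), b3 = b3),
       r1 = r1, r2 = r2)
}

# Tiny two-diet fixture for I/O and digestibility unit tests.
toy_diets <- function() {
  list(diet_formulation("A", c(methionine = 9.5, cysteine = 4.4), marker = 1,
                        dry_matter = 0.9),
       diet_formulation("B", c(methionine = 21.5, cysteine = 4.2), marker = 1,
                        dry_matter = 0.9))
}
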