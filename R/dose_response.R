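# Dose-response model families, analytic inflection/breakpoint estimation,
# least-squares fitting with a deterministic multi-start grid, and AIC-based
# model selection.
#
# Families:
#   power      Y = A*x^B + C*x^D                      (4 parameters)
#   lognormal  Y = (A/x) * exp(-0.5*(ln(x/gm)/ln(gsd))^2)  (3 parameters)
#   cubic      Y = b0 + b1*x + b2*x^2 + b3*x^3        (4 parameters)
#   segmented  bent-cable two-phase line with a quadratic "gentle connection"
#              blend at the breakpoint                (4 parameters; blend
#              width fixed, not counted)
#
# For least squares: SSE, R^2 = 1 - SSE/TSS, SE of estimate = sqrt(SSE/(n-k)),
# AIC = n*ln(SSE/n) + 2k, AICc = AIC + 2k(k+1)/(n-k-1).

# ---- model types -------------------------------------------------------------

#' Power-series dose-response model
#'
#' `Y = A*x^B + C*x^D`. The exponents must differ, otherwise the stationary
#' point is undefined.
#'
#' @param A,C coefficients.
#' @param B,D exponents, `B != D`.
#' @return An object of classes `power_series_model`, `dose_response_model`.
#' @export
power_series_model <- function(A, B, C, D) {
  stop_if(abs(B - D) < 1e-12, "exponents B and D must differ")
  structure(list(A = A, B = B, C = C, D = D),
            class = c("power_series_model", "dose_response_model"))
}

#' Lognormal dose-response model
#'
#' `Y = (A/x) * exp(-0.5 * (ln(x/geo_mean) / ln(geo_sd))^2)`: a Gaussian in
#' ln(x) scaled by 1/x, i.e. a lognormal density shape with amplitude `A`.
#'
#' @param amplitude amplitude/area parameter `A`.
#' @param geo_mean geometric mean, dose units, > 0.
#' @param geo_sd geometric standard deviation, dimensionless, > 1 (so that
#'   `ln(geo_sd) > 0` and the curve has a finite mode).
#' @return An object of classes `lognormal_model`, `dose_response_model`.
#' @export
lognormal_model <- function(amplitude, geo_mean, geo_sd) {
  stop_if(geo_mean <= 0, "geo_mean must be positive")
  stop_if(geo_sd <= 1, "geo_sd must exceed 1")
  structure(list(amplitude = amplitude, geo_mean = geo_mean, geo_sd = geo_sd),
            class = c("lognormal_model", "dose_response_model"))
}

#' Third-order polynomial dose-response model
#'
#' `Y = b0 + b1*x + b2*x^2 + b3*x^3`.
#'
#' @param b0,b1,b2,b3 polynomial coefficients (intercept through cubic term).
#' @return An object of classes `cubic_model`, `dose_response_model`.
#' @export
cubic_model <- function(b0, b1, b2, b3) {
  structure(list(b0 = b0, b1 = b1, b2 = b2, b3 = b3),
            class = c("cubic_model", "dose_response_model"))
}

#' Segmented (bent-cable) dose-response model
#'
#' Two-phase linear model with breakpoint `breakpoint`; when
#' `blend_width > 0` the hinge is replaced by a quadratic arc of that width,
#' giving a continuous first derivative (a "gentle connection").
#'
#' @param breakpoint breakpoint location, dose units.
#' @param slope1,slope2 slopes before and after the breakpoint.
#' @param intercept response value of the first segment extrapolated to x = 0.
#' @param blend_width full width of the quadratic blend (0 = sharp hinge).
#' @return An object of classes `segmented_model`, `dose_response_model`.
#' @export
segmented_model <- function(breakpoint, slope1, slope2, intercept,
                            blend_width = 0) {
  stop_if(blend_width < 0, "blend_width must be >= 0")
  structure(list(breakpoint = breakpoint, slope1 = slope1, slope2 = slope2,
                 intercept = intercept, blend_width = blend_width),
            class = c("segmented_model", "dose_response_model"))
}

# bent-cable basis: 0 left of the blend, (x - x0) right of it, quadratic arc
# inside; first derivative is continuous for w > 0.
bent_basis <- function(x, x0, w) {
  if (w <= 0) return(pmax(x - x0, 0))
  d <- w / 2
  ifelse(x <= x0 - d, 0,
         ifelse(x >= x0 + d, x - x0, (x - x0 + d)^2 / (4 * d)))
}

#' Evaluate a dose-response model
#'
#' @param m a model object created by one of the model constructors.
#' @param x dose(s); must be > 0 for the lognormal family and for power-series
#'   models with non-integer exponents.
#' @return Model value(s).
#' @export
eval_model <- function(m, x) UseMethod("eval_model")

#' @export
eval_model.power_series_model <- function(m, x) {
  if ((m$B %% 1 != 0 || m$D %% 1 != 0) && any(x <= 0))
    stop("power-series with non-integer exponents requires x > 0", call. = FALSE)
  m$A * x^m$B + m$C * x^m$D
}

#' @export
eval_model.lognormal_model <- function(m, x) {
  stop_if(any(x <= 0), "lognormal model requires x > 0")
  s <- log(m$geo_sd)
  (m$amplitude / x) * exp(-0.5 * ((log(x / m$geo_mean)) / s)^2)
}

#' @export
eval_model.cubic_model <- function(m, x) {
  m$b0 + m$b1 * x + m$b2 * x^2 + m$b3 * x^3
}

#' @export
eval_model.segmented_model <- function(m, x) {
  m$intercept + m$slope1 * x +
    (m$slope2 - m$slope1) * bent_basis(x, m$breakpoint, m$blend_width)
}

# ---- analytic inflections ----------------------------------------------------

#' Stationary point of a power-series model
#'
#' Setting `dY/dx = A*B*x^(B-1) + C*D*x^(D-1) = 0` gives
#' `x* = (-(D*C)/(B*A))^(1/(B-D))`. The result is asserted to be a numerical
#' stationary point (relative derivative below `tol`).
#'
#' @param m a [power_series_model()].
#' @param tol tolerance for the stationary-point assertion.
#' @return The stationary dose.
#' @export
inflection_power_series <- function(m, tol = 1e-6) {
  stop_if(m$A == 0 || m$B == 0, "A and B must be non-zero")
  radicand <- -(m$D * m$C) / (m$B * m$A)
  stop_if(radicand <= 0, "no real stationary point (radicand not positive)")
  x <- radicand^(1 / (m$B - m$D))
  dy <- m$A * m$B * x^(m$B - 1) + m$C * m$D * x^(m$D - 1)
  scale <- abs(m$A * m$B * x^(m$B - 1)) + abs(m$C * m$D * x^(m$D - 1))
  stop_if(scale > 0 && abs(dy) / scale > tol,
          "computed point is not stationary (check parameters)")
  x
}

#' Mode of a lognormal dose-response model
#'
#' The curve `(A/x)*Gaussian-in-ln(x)` peaks at
#' `exp(ln(geo_mean) - ln(geo_sd)^2)`.
#'
#' @param m a [lognormal_model()].
#' @return The dose at the peak.
#' @export
inflection_lognormal <- function(m) {
  stop_if(m$geo_sd <= 1, "geo_sd must exceed 1")
  exp(log(m$geo_mean) - log(m$geo_sd)^2)
}

#' Stationary points of a cubic model
#'
#' Roots of `b1 + 2*b2*x + 3*b3*x^2`, i.e.
#' `x = (-b2 +- sqrt(b2^2 - 3*b1*b3)) / (3*b3)`. The root lying inside
#' `dose_range` whose curvature matches `objective` is returned; both roots
#' are attached as an attribute. A zero discriminant yields a saddle, which is
#' flagged via attribute `saddle`.
#'
#' @param m a [cubic_model()] with `b3 != 0`.
#' @param dose_range numeric length-2 interval in which the stationary point
#'   must lie.
#' @param objective `"maximize"` or `"minimize"`.
#' @return The selected stationary dose, with attributes `roots` and `saddle`.
#' @export
inflection_cubic <- function(m, dose_range, objective = c("maximize", "minimize")) {
  objective <- match.arg(objective)
  stop_if(m$b3 == 0, "b3 must be non-zero for a cubic stationary point")
  disc <- m$b2^2 - 3 * m$b1 * m$b3
  stop_if(disc < 0, "negative discriminant: no real stationary point")
  roots <- sort((-m$b2 + c(-1, 1) * sqrt(disc)) / (3 * m$b3))
  if (disc == 0) {
    x <- roots[1L]
    stop_if(x < min(dose_range) || x > max(dose_range),
            "saddle point outside dose range")
    return(structure(x, roots = roots, saddle = TRUE))
  }
  curv <- 2 * m$b2 + 6 * m$b3 * roots
  want <- if (objective == "maximize") curv < 0 else curv > 0
  inside <- roots >= min(dose_range) & roots <= max(dose_range)
  pick <- which(want & inside)
  stop_if(length(pick) == 0L,
          sprintf("no stationary point matching '%s' inside the dose range",
                  objective))
  structure(roots[pick[1L]], roots = roots, saddle = FALSE)
}

#' Stationary point / breakpoint of any fitted model
#'
#' Dispatches on the model family; for segmented models this is the
#' breakpoint.
#'
#' @param m a `dose_response_model`.
#' @param dose_range interval for the cubic root selection.
#' @param objective `"maximize"` or `"minimize"` (cubic only).
#' @return The stationary dose.
#' @export
inflection_point <- function(m, dose_range = NULL,
                             objective = c("maximize", "minimize")) {
  objective <- match.arg(objective)
  switch(class(m)[1L],
         power_series_model = inflection_power_series(m),
         lognormal_model = inflection_lognormal(m),
         cubic_model = inflection_cubic(m, dose_range, objective),
         segmented_model = m$breakpoint,
         stop("unknown model class", call. = FALSE))
}

# ---- fitting -----------------------------------------------------------------

fit_stats <- function(dose, response, weights, fitted, k) {
  res <- response - fitted
  sse <- sum(weights * res^2)
  tss <- sum(weights * (response - stats::weighted.mean(response, weights))^2)
  n <- length(response)
  list(sse = sse,
       r2 = if (tss > 0) 1 - sse / tss else NA_real_,
       se_estimate = if (n > k) sqrt(sse / (n - k)) else NA_real_,
       aic = n * log(sse / n) + 2 * k,
       aicc = if (n - k - 1 > 0) n * log(sse / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
              else NA_real_,
       n = n, k = k)
}

# Solve the conditionally linear coefficients given a basis matrix; returns
# list(coef, sse) or NULL on a singular system.
profiled_ls <- function(X, y, w) {
  sw <- sqrt(w)
  fit <- tryCatch(stats::lm.fit(X * sw, y * sw), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients))) return(NULL)
  list(coef = fit$coefficients, sse = sum(fit$residuals^2))
}

polish <- function(par, fn) {
  o1 <- stats::optim(par, fn, method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 4000))
  o2 <- tryCatch(stats::optim(o1$par, fn, method = "BFGS",
                              control = list(reltol = 1e-14, maxit = 500)),
                 error = function(e) o1)
  if (o2$value <= o1$value) o2 else o1
}

fit_power_family <- function(dose, response, weights, starts = NULL) {
  stop_if(any(dose <= 0), "power-series fitting requires doses > 0")
  obj <- function(p) {
    B <- p[1L]; D <- p[2L]
    if (!is.finite(B) || !is.finite(D) || abs(B - D) < 1e-6 ||
        max(abs(c(B, D))) > 12) return(1e12)
    X <- cbind(dose^B, dose^D)
    if (any(!is.finite(X))) return(1e12)
    ls <- profiled_ls(X, response, weights)
    if (is.null(ls)) return(1e12)
    ls$sse
  }
  if (is.null(starts)) {
    grid <- expand.grid(B = c(0.3, 1, 2, 3), D = c(-2, -1, -0.3, 0.5, 1.5))
    grid <- grid[abs(grid$B - grid$D) > 0.2, ]
    starts <- lapply(seq_len(nrow(grid)), function(i) as.numeric(grid[i, ]))
  }
  best <- NULL
  for (s in starts) {
    o <- polish(s, obj)
    if (is.null(best) || o$value < best$value) best <- o
  }
  stop_if(is.null(best) || best$value >= 1e12, "power-series fit did not converge")
  B <- best$par[1L]; D <- best$par[2L]
  ls <- profiled_ls(cbind(dose^B, dose^D), response, weights)
  if (B < D) {  # canonical order: larger exponent first
    m <- power_series_model(A = ls$coef[2L], B = D, C = ls$coef[1L], D = B)
  } else {
    m <- power_series_model(A = ls$coef[1L], B = B, C = ls$coef[2L], D = D)
  }
  m
}

fit_lognormal_family <- function(dose, response, weights, starts = NULL) {
  stop_if(any(dose <= 0), "lognormal fitting requires doses > 0")
  basis <- function(lgm, s) (1 / dose) * exp(-0.5 * ((log(dose) - lgm) / s)^2)
  obj <- function(p) {
    if (!all(is.finite(p))) return(1e12)
    s <- exp(p[2L])
    if (s < 1e-6 || s > 20) return(1e12)
    f <- basis(p[1L], s)
    ls <- profiled_ls(cbind(f), response, weights)
    if (is.null(ls)) return(1e12)
    ls$sse
  }
  if (is.null(starts)) {
    qs <- stats::quantile(dose, c(0.25, 0.5, 0.75), names = FALSE)
    grid <- expand.grid(lgm = log(qs), ls = log(log(c(1.1, 1.5, 2.5))))
    starts <- lapply(seq_len(nrow(grid)), function(i) as.numeric(grid[i, ]))
  }
  best <- NULL
  for (s in starts) {
    o <- polish(s, obj)
    if (is.null(best) || o$value < best$value) best <- o
  }
  stop_if(is.null(best) || best$value >= 1e12, "lognormal fit did not converge")
  lgm <- best$par[1L]; s <- exp(best$par[2L])
  ls <- profiled_ls(cbind(basis(lgm, s)), response, weights)
  lognormal_model(amplitude = unname(ls$coef[1L]), geo_mean = exp(lgm),
                  geo_sd = exp(s))
}

fit_cubic_family <- function(dose, response, weights) {
  X <- cbind(1, dose, dose^2, dose^3)
  ls <- profiled_ls(X, response, weights)
  stop_if(is.null(ls), "cubic fit is singular")
  cubic_model(b0 = unname(ls$coef[1L]), b1 = unname(ls$coef[2L]),
              b2 = unname(ls$coef[3L]), b3 = unname(ls$coef[4L]))
}

#' Fit a dose-response model family by least squares
#'
#' Nonlinear families use profiled linear coefficients and a deterministic
#' multi-start grid (documented per family in the methods vignette), so the
#' result is reproducible for given data; `seed` is accepted for interface
#' stability and forwarded where a family uses randomness (none do by
#' default).
#'
#' The fit report carries SSE, `R^2 = 1 - SSE/TSS`,
#' `SE of estimate = sqrt(SSE/(n-k))`, `AIC = n*ln(SSE/n) + 2k` and the
#' small-sample `AICc`, plus the analytic inflection/breakpoint and a flag
#' when that point falls outside the observed dose range.
#'
#' @param family `"power"`, `"lognormal"`, `"cubic"` or `"segmented"`.
#' @param dose,response numeric vectors of equal length.
#' @param weights optional non-negative case weights.
#' @param starts optional list of start vectors overriding the default grid
#'   (power: `c(B, D)`; lognormal: `c(log geo_mean, log log geo_sd)`).
#' @param seed integer; recorded in the fit object.
#' @param objective `"maximize"` or `"minimize"`; controls which cubic
#'   stationary point is reported.
#' @param blend_width segmented family only; see [fit_segmented()].
#' @return An object of class `dose_response_fit`.
#' @export
fit_model <- function(family = c("power", "lognormal", "cubic", "segmented"),
                      dose, response, weights = NULL, starts = NULL,
                      seed = 1L, objective = c("maximize", "minimize"),
                      blend_width = NULL) {
  family <- match.arg(family)
  objective <- match.arg(objective)
  stop_if(length(dose) != length(response), "dose and response lengths differ")
  ok <- is.finite(dose) & is.finite(response)
  dose <- dose[ok]; response <- response[ok]
  if (is.null(weights)) weights <- rep(1, length(dose)) else weights <- weights[ok]
  k <- c(power = 4L, lognormal = 3L, cubic = 4L, segmented = 4L)[[family]]
  ndist <- length(unique(dose))
  min_dist <- if (family == "segmented") 5L else k  # saturated fits allowed
  stop_if(ndist < min_dist,
          sprintf("%s family needs >= %d distinct doses (got %d)",
                  family, min_dist, ndist))
  if (family == "segmented")
    return(fit_segmented(dose, response, blend_width = blend_width,
                         weights = weights, seed = seed, objective = objective))
  m <- switch(family,
              power = fit_power_family(dose, response, weights, starts),
              lognormal = fit_lognormal_family(dose, response, weights, starts),
              cubic = fit_cubic_family(dose, response, weights))
  make_fit(family, m, dose, response, weights, k, objective, seed)
}

make_fit <- function(family, m, dose, response, weights, k, objective, seed,
                     flags = character()) {
  st <- fit_stats(dose, response, weights, eval_model(m, dose), k)
  infl <- tryCatch(
    as.numeric(inflection_point(m, dose_range = range(dose), objective = objective)),
    error = function(e) {
      flags <<- c(flags, paste("no inflection:", conditionMessage(e)))
      NA_real_
    })
  extrapolated <- !is.na(infl) && (infl < min(dose) || infl > max(dose))
  structure(list(family = family, params = m, sse = st$sse, r2 = st$r2,
                 se_estimate = st$se_estimate, aic = st$aic, aicc = st$aicc,
                 inflection = infl, extrapolated = extrapolated,
                 n = st$n, k = st$k, objective = objective, seed = seed,
                 converged = TRUE, flags = flags,
                 dose_range = range(dose)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit [%s], n = %d, k = %d\n", x$family, x$n, x$k))
  cat(sprintf("  SSE %.6g  R2 %.4f  SE %.4g  AIC %.3f  AICc %.3f\n",
              x$sse, x$r2, x$se_estimate, x$aic, x$aicc))
  cat(sprintf("  inflection/breakpoint: %.6g%s\n", x$inflection,
              if (isTRUE(x$extrapolated)) " (extrapolated)" else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.dose_response_fit <- function(x, ...) {
  data.frame(family = x$family, sse = x$sse, r2 = x$r2,
             se_estimate = x$se_estimate, aic = x$aic, aicc = x$aicc,
             inflection = x$inflection, extrapolated = x$extrapolated,
             n = x$n, k = x$k, stringsAsFactors = FALSE)
}

#' Fit a segmented (bent-cable) regression with a gentle connection
#'
#' Two-phase linear model whose hinge is smoothed by a quadratic arc of width
#' `blend_width` (continuous first derivative). The breakpoint is profiled
#' over a dose grid -- the model is linear in the remaining coefficients --
#' and then refined by golden-section search around the best grid point.
#'
#' If the two-segment model does not improve on a straight line the
#' breakpoint is unidentifiable: the fit is returned with `slope2 == slope1`,
#' an `NA` breakpoint and the flag `"breakpoint unidentifiable"`.
#'
#' @param dose,response numeric vectors; >= 5 distinct doses.
#' @param blend_width full width of the quadratic blend; default 10% of the
#'   observed dose span.
#' @param weights optional case weights.
#' @param seed integer; recorded in the fit object.
#' @param objective recorded; the breakpoint itself is objective-free.
#' @return An object of class `dose_response_fit`.
#' @export
fit_segmented <- function(dose, response, blend_width = NULL, weights = NULL,
                          seed = 1L, objective = c("maximize", "minimize")) {
  objective <- match.arg(objective)
  stop_if(length(unique(dose)) < 5L, "segmented family needs >= 5 distinct doses")
  if (is.null(weights)) weights <- rep(1, length(dose))
  span <- diff(range(dose))
  if (is.null(blend_width)) blend_width <- 0.1 * span
  lo <- min(dose) + max(blend_width / 2, 0.02 * span)
  hi <- max(dose) - max(blend_width / 2, 0.02 * span)
  sse_at <- function(x0) {
    ls <- profiled_ls(cbind(1, dose, bent_basis(dose, x0, blend_width)),
                      response, weights)
    if (is.null(ls)) Inf else ls$sse
  }
  grid <- seq(lo, hi, length.out = 101L)
  sses <- vapply(grid, sse_at, 0)
  i <- which.min(sses)
  bracket <- c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)])
  opt <- stats::optimize(sse_at, interval = bracket, tol = 1e-10)
  x0 <- opt$minimum
  ls <- profiled_ls(cbind(1, dose, bent_basis(dose, x0, blend_width)),
                    response, weights)
  stop_if(is.null(ls), "segmented fit did not converge")
  line <- profiled_ls(cbind(1, dose), response, weights)
  tss <- sum(weights * (response - stats::weighted.mean(response, weights))^2)
  improvement <- if (line$sse > 1e-12 * max(tss, 1)) 1 - ls$sse / line$sse else 0
  flags <- character()
  if (improvement < 1e-7) {
    flags <- "breakpoint unidentifiable"
    m <- segmented_model(breakpoint = NA_real_, slope1 = unname(line$coef[2L]),
                         slope2 = unname(line$coef[2L]),
                         intercept = unname(line$coef[1L]),
                         blend_width = blend_width)
    st <- fit_stats(dose, response, weights,
                    m$intercept + m$slope1 * dose, k = 4L)
  } else {
    m <- segmented_model(breakpoint = x0, slope1 = unname(ls$coef[2L]),
                         slope2 = unname(ls$coef[2L] + ls$coef[3L]),
                         intercept = unname(ls$coef[1L]),
                         blend_width = blend_width)
    st <- fit_stats(dose, response, weights, eval_model(m, dose), k = 4L)
  }
  structure(list(family = "segmented", params = m, sse = st$sse, r2 = st$r2,
                 se_estimate = st$se_estimate, aic = st$aic, aicc = st$aicc,
                 inflection = m$breakpoint,
                 extrapolated = FALSE, n = st$n, k = st$k,
                 objective = objective, seed = seed, converged = TRUE,
                 flags = flags, dose_range = range(dose)),
            class = "dose_response_fit")
}

#' Select the best admissible dose-response fit
#'
#' Screens out non-converged fits, fits whose inflection is missing or falls
#' outside the observed dose range (extrapolated), then returns the minimum
#' AIC; ties are broken by fewer parameters, then by lower SSE.
#'
#' @param fits list of `dose_response_fit` objects.
#' @return The selected `dose_response_fit`.
#' @export
select_model <- function(fits) {
  stop_if(length(fits) == 0L, "no fits supplied")
  ok <- vapply(fits, function(f)
    isTRUE(f$converged) && !isTRUE(f$extrapolated) &&
      is.finite(f$inflection) &&
      (is.finite(f$aic) || f$aic == -Inf), TRUE)
  fits <- fits[ok]
  stop_if(length(fits) == 0L, "no admissible fit")
  aic <- vapply(fits, `[[`, 0, "aic")
  kk <- vapply(fits, function(f) as.numeric(f$k), 0)
  sse <- vapply(fits, `[[`, 0, "sse")
  fits[[order(aic, kk, sse)[1L]]]
}

# mean cysteine dose on one basis over the included diets
mean_cys_on_basis <- function(dose_tab, b, ids) {
  mean(dose_tab$cys[dose_tab$basis == b & dose_tab$diet_id %in% ids])
}

#' Estimate nutrient requirements from a feeding trial
#'
#' Full pipeline: computes tank-level responses (SGR, FCR), builds the dose
#' table per basis, fits the configured model families, selects by AIC, and
#' reports the analytic inflection/breakpoint as the methionine requirement
#' converted to both TSAA scales using the mean cysteine dose on the matching
#' basis.
#'
#' Diets forming a taurine contrast rather than a methionine level (taurine
#' content at least twice the trial minimum) are excluded by default;
#' override with `exclude_diets`.
#'
#' @param diets list of [diet_formulation()].
#' @param tanks list of [tank_record()].
#' @param adc an [adc_table()]; required for non-dietary bases.
#' @param response responses to analyse, subset of `c("sgr", "fcr")`.
#' @param basis dose bases to analyse.
#' @param families model families to fit.
#' @param fit_level `"tank"` (default) fits tank-level points; `"diet"` fits
#'   diet means.
#' @param exclude_diets character vector of diet ids to drop, or `"auto"`
#'   (default) for the taurine-contrast rule, or `NULL` to keep all diets.
#' @param mw a [molecular_weights()] object.
#' @param seed integer seed recorded in the fits.
#' @param blend_width passed to the segmented family.
#' @return A data frame of class `requirement_estimate` with one row per
#'   response x basis, and the underlying fits in attribute `fits`.
#' @export
estimate_requirement <- function(diets, tanks, adc = NULL,
                                 response = c("sgr", "fcr"),
                                 basis = "dietary",
                                 families = c("lognormal", "power", "cubic",
                                              "segmented"),
                                 fit_level = c("tank", "diet"),
                                 exclude_diets = "auto",
                                 mw = molecular_weights(), seed = 1L,
                                 blend_width = NULL) {
  response <- match.arg(response, several.ok = TRUE)
  basis <- match.arg(basis, c("dietary", "digestible", "daily_intake"),
                     several.ok = TRUE)
  fit_level <- match.arg(fit_level)
  if (identical(exclude_diets, "auto")) {
    tau <- vapply(diets, function(d)
      if ("taurine" %in% names(d$nutrients)) diet_nutrient(d, "taurine")
      else NA_real_, 0)
    exclude_diets <- if (all(is.na(tau))) character() else
      diet_ids(diets)[!is.na(tau) & tau >= 2 * min(tau, na.rm = TRUE)]
  }
  keep <- setdiff(diet_ids(diets), exclude_diets)
  diets_k <- diets[diet_ids(diets) %in% keep]
  tanks_k <- tanks[vapply(tanks, `[[`, "", "diet_id") %in% keep]
  dose_tab <- tsaa_dose_table(diets_k, adc = adc, tanks = tanks_k,
                              basis = basis, mw = mw)
  perf <- tank_performance(tanks_k)
  all_fits <- list()
  rows <- list()
  for (b in basis) {
    dmap <- dose_tab[dose_tab$basis == b, ]
    dose_of <- stats::setNames(dmap$met, dmap$diet_id)
    for (resp in response) {
      if (fit_level == "tank") {
        x <- dose_of[perf$diet_id]
        y <- perf[[resp]]
      } else {
        agg <- tapply(perf[[resp]], perf$diet_id, mean, na.rm = TRUE)
        x <- dose_of[names(agg)]
        y <- as.numeric(agg)
      }
      obj <- if (resp == "fcr") "minimize" else "maximize"
      fits <- list()
      for (fam in families) {
        f <- tryCatch(
          fit_model(fam, x, y, seed = seed, objective = obj,
                    blend_width = blend_width),
          error = function(e) {
            warning(sprintf("%s fit failed for %s/%s: %s", fam, resp, b,
                            conditionMessage(e)), call. = FALSE)
            NULL
          })
        if (!is.null(f)) fits[[fam]] <- f
      }
      best <- select_model(fits)
      met_req <- best$inflection
      cys_b <- mean_cys_on_basis(dose_tab, b, keep)
      rows[[paste(resp, b)]] <- data.frame(
        response = resp, basis = b, met_requirement = met_req,
        cys_constant = cys_b,
        tsaa_met_plus_cys = tsaa_met_plus_cys(met_req, cys_b),
        tsaa_met_equivalent = tsaa_met_equivalent(met_req, cys_b, mw),
        model_family = best$family, r2 = best$r2, aic = best$aic,
        n = best$n, stringsAsFactors = FALSE)
      all_fits[[paste(resp, b, sep = "_")]] <- fits
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("requirement_estimate", "data.frame")
  attr(out, "fits") <- all_fits
  attr(out, "fit_level") <- fit_level
  attr(out, "excluded_diets") <- exclude_diets
  out
}

#' Bootstrap confidence interval for a requirement estimate
#'
#' Case-resamples tanks within diets, re-runs [estimate_requirement()] for a
#' single response/basis pair, and returns the percentile interval of the
#' methionine requirement.
#'
#' @inheritParams estimate_requirement
#' @param n_boot number of bootstrap replicates.
#' @param level confidence level.
#' @param response,basis single response and basis to bootstrap.
#' @return A list with `ci_low`, `ci_high`, `level`, `n_boot` and the vector
#'   of bootstrap requirements (failed replicates dropped).
#' @export
bootstrap_requirement <- function(diets, tanks, adc = NULL, response = "sgr",
                                  basis = "dietary",
                                  families = c("lognormal", "power", "cubic",
                                               "segmented"),
                                  exclude_diets = "auto", n_boot = 2000L,
                                  level = 0.95, mw = molecular_weights(),
                                  seed = 1L) {
  set.seed(seed)
  tank_diet <- vapply(tanks, `[[`, "", "diet_id")
  by_diet <- split(seq_along(tanks), tank_diet)
  reqs <- rep(NA_real_, n_boot)
  for (i in seq_len(n_boot)) {
    idx <- unlist(lapply(by_diet, function(ii) sample(ii, length(ii), replace = TRUE)))
    est <- tryCatch(
      suppressWarnings(
        estimate_requirement(diets, tanks[idx], adc = adc, response = response,
                             basis = basis, families = families,
                             exclude_diets = exclude_diets, mw = mw, seed = seed)),
      error = function(e) NULL)
    if (!is.null(est)) reqs[i] <- est$met_requirement[1L]
  }
  reqs_ok <- reqs[is.finite(reqs)]
  stop_if(length(reqs_ok) < 2L, "bootstrap produced no usable replicates")
  alpha <- (1 - level) / 2
  qs <- stats::quantile(reqs_ok, c(alpha, 1 - alpha), names = FALSE)
  list(ci_low = qs[1L], ci_high = qs[2L], level = level, n_boot = n_boot,
       replicates = reqs_ok)
}
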