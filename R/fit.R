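#' Fit an asymptotic model to an accumulation curve
#'
#' The rewiring process is expected to be asymptotic: most interactions are
#' restored well before rewiring time. This fits a saturating model to the
#' cumulative richness values (taken at bin midpoints) by least squares, for
#' descriptive extrapolation of the accumulation — not formal inference.
#'
#' Models:
#' \describe{
#'   \item{`michaelis_menten`}{the Clench model `R(t) = a t / (b + t)`:
#'     `a` is the asymptotic richness, `b` the time at which half of it is
#'     accumulated.}
#'   \item{`negative_exponential`}{`R(t) = a (1 - exp(-k t))`: `a` the
#'     asymptote, `k` the per-month approach rate.}
#' }
#'
#' Estimation uses [stats::nls()] (algorithm `"port"`) with both parameters
#' bounded positive; starting values are `a0 = max(cumulative)` and, for the
#' half-saturation/rate, the median first-observation time. A constant curve
#' or a non-converging fit returns a no-fit sentinel (class
#' `asymptotic_fit_failure`) describing the failure and the starting values
#' used, never an error.
#'
#' @param curve an [accumulation_curve()], or a data frame with columns `t`
#'   and `richness`.
#' @param model `"michaelis_menten"` (default, Clench) or
#'   `"negative_exponential"`.
#' @return an `asymptotic_fit`: list with `model`, `asymptote`,
#'   `rate_or_halfsat`, `residual_sse`, the underlying `nls` object and the
#'   fitted data; or an `asymptotic_fit_failure` sentinel.
#' @seealso [time_to_fraction()]
#' @examples
#' t <- 1:24
#' curve <- data.frame(t = t, richness = 50 * t / (3 + t))
#' fit <- fit_accumulation(curve)
#' fit$asymptote  # ~50
#' @export
fit_accumulation <- function(curve,
                             model = c("michaelis_menten",
                                       "negative_exponential")) {
  model <- match.arg(model)
  if (inherits(curve, "accumulation_curve")) {
    t <- (curve$bin_start + curve$bin_end) / 2
    y <- as.numeric(curve$cumulative)
    t_half0 <- if (nrow(curve$first_observation) > 0) {
      stats::median(curve$first_observation$first_time)
    } else NA_real_
  } else if (is.data.frame(curve) && all(c("t", "richness") %in% names(curve))) {
    t <- curve$t
    y <- as.numeric(curve$richness)
    t_half0 <- NA_real_
  } else {
    stop("curve must be an accumulation_curve or a data frame with columns ",
         "'t' and 'richness'")
  }
  nz <- y > 0
  if (length(unique(t[nz])) < 3L) {
    stop("need at least 3 distinct non-zero bins to fit an asymptotic model")
  }
  if (max(y) == min(y)) {
    return(no_fit(model, "degenerate curve: cumulative richness is constant"))
  }

  a0 <- max(y)
  b0 <- if (is.finite(t_half0) && t_half0 > 0) t_half0 else stats::median(t[nz])
  start <- switch(model,
    michaelis_menten = list(a = a0, b = b0),
    negative_exponential = list(a = a0, k = 1 / b0)
  )
  formula <- switch(model,
    michaelis_menten = y ~ a * t / (b + t),
    negative_exponential = y ~ a * (1 - exp(-k * t))
  )
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    stats::nls(formula, data = dat, start = start, algorithm = "port",
               lower = rep(1e-9, 2), control = stats::nls.control(
                 maxiter = 200, warnOnly = FALSE)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(no_fit(model, paste0("nls did not converge: ",
                                conditionMessage(fit)),
                  start = start, lower = 1e-9))
  }
  cf <- stats::coef(fit)
  structure(
    list(model = model,
         asymptote = unname(cf["a"]),
         rate_or_halfsat = unname(cf[if (model == "michaelis_menten") "b" else "k"]),
         residual_sse = sum(stats::residuals(fit)^2),
         fit = fit, data = dat),
    class = "asymptotic_fit"
  )
}

no_fit <- function(model, reason, start = NULL, lower = NULL) {
  structure(list(model = model, reason = reason, start = start, lower = lower),
            class = "asymptotic_fit_failure")
}

#' @export
print.asymptotic_fit <- function(x, ...) {
  lab <- if (x$model == "michaelis_menten") "half-saturation time b (months)"
         else "rate k (1/month)"
  cat("Asymptotic accumulation fit (", x$model, ")\n",
      "  asymptote a: ", format(x$asymptote, digits = 5), " species\n",
      "  ", lab, ": ", format(x$rate_or_halfsat, digits = 5), "\n",
      "  residual SSE: ", format(x$residual_sse, digits = 5), "\n", sep = "")
  invisible(x)
}

#' @export
print.asymptotic_fit_failure <- function(x, ...) {
  cat("No asymptotic fit (", x$model, "): ", x$reason, "\n", sep = "")
  if (!is.null(x$start)) {
    cat("  starting values: ",
        paste(names(x$start), unlist(x$start), sep = " = ", collapse = ", "),
        "; lower bounds ", x$lower, "\n", sep = "")
  }
  invisible(x)
}

#' @export
predict.asymptotic_fit <- function(object, t, ...) {
  a <- object$asymptote
  p <- object$rate_or_halfsat
  switch(object$model,
         michaelis_menten = a * t / (p + t),
         negative_exponential = a * (1 - exp(-p * t)))
}

#' Time to reach a fraction of the fitted asymptote
#'
#' Inverts the fitted accumulation model: the time at which the curve reaches
#' `q * asymptote`. Both models approach their asymptote only in the limit,
#' so `q = 1` (or more) has no finite solution: those entries are returned as
#' `NA` with a warning — the asymptote is never attained in finite time.
#'
#' @param fit an [fit_accumulation()] result.
#' @param q fraction(s) of the asymptote, in (0, 1); values >= 1 yield `NA`.
#' @return named numeric vector of times in months.
#' @examples
#' curve <- data.frame(t = 1:24, richness = 50 * (1:24) / (3 + 1:24))
#' fit <- fit_accumulation(curve)
#' time_to_fraction(fit, c(0.5, 0.9))
#' @export
time_to_fraction <- function(fit, q) {
  if (inherits(fit, "asymptotic_fit_failure")) {
    stop("cannot invert a failed fit: ", fit$reason)
  }
  stopifnot(inherits(fit, "asymptotic_fit"))
  if (any(q <= 0)) stop("fractions must be positive")
  unattainable <- q >= 1
  if (any(unattainable)) {
    warning("asymptote never attained in finite time for q >= 1; ",
            "returning NA for those fractions")
  }
  p <- fit$rate_or_halfsat
  out <- switch(fit$model,
    michaelis_menten = q * p / (1 - q),
    negative_exponential = -log(1 - q) / p
  )
  out[unattainable] <- NA_real_
  names(out) <- paste0("q", q)
  out
}
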