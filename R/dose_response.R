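#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{r(c) = bottom + (top - bottom) / (1 + (c / IC50)^{hill})}
#' with the concentration axis handled on log10 scale (the fit parameter is
#' `log10(IC50)`), using Levenberg-Marquardt (`minpack.lm::nlsLM`) from a
#' grid of starting values (hill in both directions and magnitudes,
#' `log10(IC50)` across the tested range). The best-RSS solution is kept.
#' After fitting, the asymptotes are ordered so `bottom <= top` (hill sign
#' flips accordingly; the curve is unchanged).
#'
#' `converged` is `FALSE` when all starts fail, the responses are flat, or
#' the fitted IC50 falls outside the tested concentration range by more than
#' a factor of 100.
#'
#' @param concentrations positive dose levels (replicates allowed; >= 4
#'   distinct values required).
#' @param responses responses at those doses (e.g. viable counts normalized
#'   to control), >= 0.
#' @return an object of class `dose_response_fit` with elements `ic50`,
#'   `hill`, `top`, `bottom`, `rss`, `converged`, `data`.
#' @export
fit_dose_response <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses))
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (any(responses < 0)) stop("responses must be >= 0")
  if (length(unique(concentrations)) < 4L)
    stop("need >= 4 distinct concentrations")
  lc <- log10(concentrations)
  out <- structure(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                        bottom = NA_real_, rss = NA_real_, converged = FALSE,
                        data = data.frame(concentration = concentrations,
                                          response = responses)),
                   class = "dose_response_fit")
  if (stats::var(responses) < 1e-20) return(out)
  df <- data.frame(lc = lc, r = responses)
  top0 <- max(responses); bot0 <- min(responses)
  starts <- expand.grid(hill = c(-4, -2, -1, -0.5, 0.5, 1, 2, 4),
                        lic50 = seq(min(lc), max(lc), length.out = 5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      r ~ bottom + (top - bottom) / (1 + 10^((lc - lic50) * hill)),
      data = df,
      start = list(top = top0, bottom = bot0,
                   lic50 = starts$lic50[i], hill = starts$hill[i]),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(rss = rss, coef = stats::coef(fit))
    }
  }
  if (is.null(best)) return(out)
  co <- best$coef
  top <- co[["top"]]; bottom <- co[["bottom"]]
  hill <- co[["hill"]]; ic50 <- 10^co[["lic50"]]
  if (bottom > top) { tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill }
  out$ic50 <- ic50; out$hill <- hill; out$top <- top; out$bottom <- bottom
  out$rss <- best$rss
  rng <- range(concentrations)
  out$converged <- is.finite(ic50) && ic50 > 0 &&
    ic50 >= rng[1] / 100 && ic50 <= rng[2] * 100 && abs(hill) > 1e-6
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("4PL dose-response fit\n")
  if (x$converged) {
    cat(sprintf("  IC50   : %.4g\n  hill   : %.3f\n  top    : %.3f\n  bottom : %.3f\n  RSS    : %.4g\n",
                x$ic50, x$hill, x$top, x$bottom, x$rss))
  } else cat("  not converged\n")
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill, top = object$top,
    bottom = object$bottom)
}

#' Predict responses from a 4PL fit
#' @param object a `dose_response_fit`.
#' @param newdata optional vector of concentrations (defaults to the fitted
#'   data's concentrations).
#' @param ... unused.
#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("fit did not converge")
  conc <- if (is.null(newdata)) object$data$concentration else newdata
  object$bottom + (object$top - object$bottom) /
    (1 + (conc / object$ic50)^object$hill)
}

#' Plot a 4PL dose-response fit
#' @param x a `dose_response_fit`.
#' @param ... passed to `plot`.
#' @export
plot.dose_response_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$concentration, d$response, log = "x",
                 xlab = "concentration", ylab = "response", ...)
  if (x$converged) {
    cc <- 10^seq(log10(min(d$concentration)), log10(max(d$concentration)),
                 length.out = 200)
    graphics::lines(cc, predict(x, cc), col = "red3")
    graphics::abline(v = x$ic50, lty = 2, col = "grey40")
  }
  invisible(x)
}
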