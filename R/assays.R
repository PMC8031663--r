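#' Fit a Hill-equation binding isotherm
#'
#' Nonlinear least squares of
#' `response = bottom + (top - bottom) * x^h / (kd^h + x^h)` to an MST-style
#' dose-response table. Initialisation: `bottom`/`top` from the response
#' extremes, `kd` from the concentration whose response is nearest the
#' half-range, `h = 1`. Bounds: `kd` in `[min(x)/100, 100*max(x)]`, `h` in
#' `[0.2, 5]`. Replicate tables should be averaged pointwise before fitting
#' (see `average_replicates`). On non-convergence the best iterate is
#' returned with `converged = FALSE` and a warning.
#'
#' @param curve Tibble with `concentration` (> 0, >= 6 points) and
#'   `response`.
#' @param fix_h Fix the Hill coefficient at 1 instead of fitting it.
#' @return A `hill_fit` object: `kd`, `hill_h`, `top`, `bottom`, `se_kd`
#'   (curvature-based), `converged`, plus the underlying `nls` fit.
#' @export
#' @examples
#' curve <- simulate_binding_curve(kd = 5e-6, noise_sd = 0)
#' fit_hill(curve)
fit_hill <- function(curve, fix_h = FALSE) {
  x <- curve$concentration
  y <- curve$response
  if (length(x) < 6L || any(x <= 0)) {
    abort("'curve' needs >= 6 strictly positive concentrations",
          class = "mirexport_parameter_error")
  }
  if (length(unique(y)) == 1L) {
    abort("responses are all equal; nothing to fit", class = "mirexport_value_error")
  }
  # fit on geometric-mean-scaled concentrations so kd is O(1) for the
  # optimizer whatever the units; rescale afterwards (exact equivariance)
  xs <- exp(mean(log(x)))
  x <- x / xs
  bottom0 <- min(y); top0 <- max(y)
  kd0 <- x[which.min(abs(y - (top0 + bottom0) / 2))]
  lower <- c(kd = min(x) / 100, h = 0.2, top = -Inf, bottom = -Inf)
  upper <- c(kd = 100 * max(x), h = 5, top = Inf, bottom = Inf)
  start <- list(kd = kd0, h = 1, top = top0, bottom = bottom0)
  if (fix_h) {
    formula <- y ~ bottom + (top - bottom) * x / (kd + x)
    start$h <- NULL
    lower <- lower[c("kd", "top", "bottom")]
    upper <- upper[c("kd", "top", "bottom")]
  } else {
    formula <- y ~ bottom + (top - bottom) * x^h / (kd^h + x^h)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data.frame(x = x, y = y),
                      start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn("fit_hill: optimizer failed to converge; returning start values")
    out <- list(kd = kd0 * xs, hill_h = 1, top = top0,
                bottom = bottom0, se_kd = NA_real_, converged = FALSE,
                fit = NULL, data = curve)
    class(out) <- "hill_fit"
    return(out)
  }
  est <- coef(fit)
  se_kd <- tryCatch(xs * sqrt(vcov(fit)["kd", "kd"]),
                    error = function(e) NA_real_)
  converged <- isTRUE(fit$convInfo$isConv)
  if (!converged) warn("fit_hill: optimizer reported non-convergence")
  out <- list(kd = unname(est["kd"]) * xs,
              hill_h = if (fix_h) 1 else unname(est["h"]),
              top = unname(est["top"]), bottom = unname(est["bottom"]),
              se_kd = se_kd, converged = converged, fit = fit, data = curve)
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: Kd = %.4g (se %.3g), h = %.3f, range [%.3g, %.3g]%s\n",
              x$kd, x$se_kd, x$hill_h, x$bottom, x$top,
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("kd", "hill_h", "top", "bottom"),
         estimate = c(x$kd, x$hill_h, x$top, x$bottom),
         std.error = c(x$se_kd, rep(NA_real_, 3)))
}

#' @export
glance.hill_fit <- function(x, ...) {
  rss <- if (is.null(x$fit)) NA_real_ else sum(stats::resid(x$fit)^2)
  tibble(kd = x$kd, hill_h = x$hill_h, se_kd = x$se_kd,
         rss = rss, converged = x$converged)
}

#' Predicted Hill response
#'
#' @param object A `hill_fit`.
#' @param newdata Optional tibble with `concentration`.
#' @param ... Unused.
#' @return Numeric vector of fitted responses.
#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  x <- (newdata %||% object$data)$concentration
  object$bottom + (object$top - object$bottom) *
    x^object$hill_h / (object$kd^object$hill_h + x^object$hill_h)
}

#' @export
autoplot.hill_fit <- function(object, ...) {
  grid <- tibble(concentration = exp(seq(log(min(object$data$concentration)),
                                         log(max(object$data$concentration)),
                                         length.out = 200)))
  grid$response <- predict(object, grid)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration, y = .data$response)) +
    ggplot2::geom_line(data = grid, colour = "#0072B2") +
    ggplot2::geom_point(...) +
    ggplot2::geom_vline(xintercept = object$kd, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ligand concentration", y = "response",
                  title = sprintf("Kd = %.3g, h = %.2f", object$kd, object$hill_h))
}

#' Average replicate dose-response curves pointwise
#'
#' @param curves Tibble with `concentration`, `response` and a `replicate`
#'   column.
#' @return A tibble of per-concentration mean responses.
#' @export
average_replicates <- function(curves) {
  curves |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(response = mean(.data$response), .groups = "drop")
}

#' Poisson-corrected droplet digital PCR concentration
#'
#' From `k` positive droplets of `n`, the mean copies per droplet is
#' `lambda = -ln(1 - k/n)` and the concentration `lambda / v` copies/uL,
#' with a 95% interval from the exact (Clopper-Pearson) binomial interval on
#' `k/n` propagated through the same transform. Saturation (`k = n`) is an
#' error instructing dilution.
#'
#' @param k Positive droplet count.
#' @param n Total droplet count (> 0).
#' @param v Droplet volume in uL (QX200 convention 8.5e-4).
#' @return A one-row tibble: `positive_droplets`, `total_droplets`,
#'   `droplet_volume`, `lambda`, `copies_per_ul`, `ci95_lo`, `ci95_hi`.
#' @export
#' @examples
#' ddpcr_concentration(k = 5000, n = 20000)
ddpcr_concentration <- function(k, n, v = 8.5e-4) {
  k <- check_count(k, "k")
  n <- check_count(n, "n")
  if (n == 0L) abort("'n' must be > 0", class = "mirexport_parameter_error")
  if (k > n) abort("'k' cannot exceed 'n'", class = "mirexport_parameter_error")
  if (k == n) {
    abort("all droplets positive (saturation): dilute the sample and repeat",
          class = "mirexport_value_error")
  }
  if (v <= 0) abort("'v' must be > 0", class = "mirexport_parameter_error")
  lambda <- -log(1 - k / n)
  # exact binomial interval on the positive fraction, pushed through the
  # same -ln(1 - p)/v transform (monotone, so endpoints map to endpoints)
  p_lo <- if (k == 0) 0 else qbeta(0.025, k, n - k + 1)
  p_hi <- qbeta(0.975, k + 1, n - k)
  tibble(positive_droplets = k, total_droplets = n, droplet_volume = v,
         lambda = lambda,
         copies_per_ul = lambda / v,
         ci95_lo = -log(1 - p_lo) / v,
         ci95_hi = -log(1 - p_hi) / v)
}
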