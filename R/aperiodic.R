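#' Fit the 1/f aperiodic component of a region-averaged spectrum
#'
#' Fits a straight line to (log10 frequency, log10 power) over the full
#' 2-20 Hz grid.  The `robust` method runs iteratively reweighted least
#' squares with a Tukey bisquare loss (tuning constant 4.685) and a median
#' absolute deviation residual scale re-estimated each iteration, so that
#' periodic oscillatory components — above all the alpha peak — are treated
#' as outliers and effectively excluded from the line.  The `ols` method is
#' the ordinary least-squares baseline for comparison.
#'
#' Iteration stops when the largest weight change is below `tol` or after
#' `max_iter` iterations (the last iterate is returned with
#' `converged = FALSE`).
#'
#' @param avg_spec A single-channel [power_spectrum()] (e.g. the
#'   frontal-region average), strictly positive on every bin.
#' @param method `"robust"` (default) or `"ols"`.
#' @param tol Convergence tolerance on the bisquare weights.
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `aperiodic_fit`: `offset` (log10 power at
#'   1 Hz), `slope` (log10 power per log10 Hz; negative for 1/f spectra),
#'   `inlier_mask` (length-181 logical; bins with non-zero bisquare weight),
#'   `weights`, `method`, `rmse_inliers`, `converged`, `n_iter`.
#' @examples
#' sp <- synth_spectrum(exponent = 0.95, noise_sigma = 0, alpha_amp = 0, seed = 1)
#' fit_aperiodic(sp)$slope  # -0.95 to machine precision
#' @export
fit_aperiodic <- function(avg_spec, method = c("robust", "ols"),
                          tol = 1e-8, max_iter = 100L) {
  method <- match.arg(method)
  if (!inherits(avg_spec, "power_spectrum")) abort("`avg_spec` must be a power_spectrum.")
  if (nrow(avg_spec$power) != 1L) {
    abort("`avg_spec` must be single-channel; use region_average_spectrum() first.")
  }
  p <- as.vector(avg_spec$power)
  if (any(p <= 0)) abort("All power bins must be strictly positive for the log-log fit.")
  x <- log10(avg_spec$freqs)
  y <- log10(p)
  X <- cbind(1, x)
  ols <- lm.wfit(X, y, w = rep(1, length(y)))
  if (method == "ols") {
    r <- y - X %*% ols$coefficients
    return(new_aperiodic_fit(ols$coefficients, rep(TRUE, length(y)),
                             rep(1, length(y)), "ols",
                             sqrt(mean(r^2)), TRUE, 0L))
  }
  cc <- 4.685
  beta <- ols$coefficients
  w_prev <- rep(1, length(y))
  converged <- FALSE
  iter <- 0L
  w <- w_prev
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- as.vector(y - X %*% beta)
    if (max(abs(r)) < 1e-10) {  # numerically exact fit: nothing to reweight
      w <- rep(1, length(y))
      converged <- TRUE
      break
    }
    s <- max(mad(r, center = 0), 1e-12)
    u <- r / (cc * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) < 2) {  # degenerate: all bins rejected; keep previous iterate
      w <- w_prev
      break
    }
    beta_prev <- beta
    fit <- lm.wfit(X, y, w = w)
    beta <- fit$coefficients
    if (max(abs(w - w_prev)) < tol || max(abs(beta - beta_prev)) < 1e-12) {
      converged <- TRUE
      break
    }
    w_prev <- w
  }
  if (!converged) {
    warn(sprintf("Robust aperiodic fit did not converge in %d iterations; returning last iterate.",
                 max_iter))
  }
  inlier <- w > 0
  if (mean(inlier) < 0.5) {
    warn("More than half of the spectrum bins were flagged as outliers.")
  }
  r <- as.vector(y - X %*% beta)
  new_aperiodic_fit(beta, inlier, w, "robust",
                    sqrt(mean(r[inlier]^2)), converged, iter)
}

new_aperiodic_fit <- function(beta, inlier, weights, method, rmse, converged, n_iter) {
  structure(
    list(offset = unname(beta[1]), slope = unname(beta[2]),
         inlier_mask = unname(inlier), weights = unname(weights),
         method = method, rmse_inliers = rmse,
         converged = converged, n_iter = n_iter),
    class = "aperiodic_fit"
  )
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit:%s> slope = %.4f, offset = %.4f, %d/%d inliers\n",
              x$method, x$slope, x$offset, sum(x$inlier_mask), length(x$inlier_mask)))
  invisible(x)
}

# aperiodic model evaluated on the linear power scale
aperiodic_power <- function(fit, freqs) 10^(fit$offset + fit$slope * log10(freqs))

#' @export
tidy.aperiodic_fit <- function(x, ...) {
  tibble::tibble(term = c("offset", "slope"),
                 estimate = c(x$offset, x$slope))
}

#' @export
glance.aperiodic_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, offset = x$offset, method = x$method,
                 n_inliers = sum(x$inlier_mask),
                 rmse_inliers = x$rmse_inliers, converged = x$converged,
                 n_iter = x$n_iter)
}

#' Compare two aperiodic fits
#'
#' Slope change between a pre- and a post-treatment fit, labelled `steeper`
#' when the slope became more negative by more than `tol`, `flatter` when it
#' became more positive, `unchanged` otherwise.
#'
#' @param pre_fit,post_fit [fit_aperiodic()] results from the same method.
#' @param tol Dead band on the slope delta, Hz-free log-log units.
#' @return One-row tibble: `slope_pre`, `slope_post`, `delta`, `direction`.
#' @examples
#' sp1 <- synth_spectrum(exponent = 0.61, noise_sigma = 0, alpha_amp = 0, seed = 1)
#' sp2 <- synth_spectrum(exponent = 0.95, noise_sigma = 0, alpha_amp = 0, seed = 1)
#' aperiodic_change(fit_aperiodic(sp1), fit_aperiodic(sp2))  # steeper
#' @export
aperiodic_change <- function(pre_fit, post_fit, tol = 0.02) {
  if (!inherits(pre_fit, "aperiodic_fit") || !inherits(post_fit, "aperiodic_fit")) {
    abort("Both arguments must be aperiodic_fit objects.")
  }
  if (pre_fit$method != post_fit$method) {
    abort("Cannot compare fits from different methods (robust vs ols).")
  }
  delta <- post_fit$slope - pre_fit$slope
  direction <- if (delta < -tol) "steeper" else if (delta > tol) "flatter" else "unchanged"
  tibble::tibble(slope_pre = pre_fit$slope, slope_post = post_fit$slope,
                 delta = delta, direction = direction)
}

#' Plot an aperiodic fit over its spectrum
#'
#' @param object An [fit_aperiodic()] result.
#' @param spec The single-channel [power_spectrum()] the fit was computed on.
#' @param ... Unused.
#' @return A ggplot of log10 power vs log10 frequency with the fitted line;
#'   outlier bins are marked.
#' @export
autoplot.aperiodic_fit <- function(object, spec, ...) {
  df <- tibble::tibble(
    log_f = log10(spec$freqs),
    log_p = log10(as.vector(spec$power)),
    inlier = object$inlier_mask
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_f, y = .data$log_p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$inlier), size = 0.8) +
    ggplot2::geom_abline(intercept = object$offset, slope = object$slope) +
    ggplot2::labs(x = "log10 frequency (Hz)", y = "log10 power",
                  colour = "inlier") +
    ggplot2::theme_minimal()
}

#' Serialize an aperiodic fit to JSON
#'
#' @param fit An [fit_aperiodic()] result.
#' @return A JSON string with offset, slope, method, n_inliers, rmse_inliers.
#' @export
aperiodic_json <- function(fit) {
  jsonlite::toJSON(list(offset = fit$offset, slope = fit$slope,
                        method = fit$method, n_inliers = sum(fit$inlier_mask),
                        rmse_inliers = fit$rmse_inliers),
                   auto_unbox = TRUE, digits = NA)
}
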