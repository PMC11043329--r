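# Best-fit models for difference profiles: sum of two Lorentzians for
# two-peak spans, constrained smoothing spline for multi-peak spans, and
# the spectral diagnostic that rules out Fourier smoothing.

lorentzian <- function(x, A, x0, gamma) {
  A / (1 + ((x - x0) / gamma)^2)
}

lorentz2_eval <- function(x, p) {
  p["b"] + lorentzian(x, p["A1"], p["x01"], p["g1"]) +
    lorentzian(x, p["A2"], p["x02"], p["g2"])
}

bin_signal <- function(x, y, nb) {
  idx <- cut(seq_along(y), breaks = nb, labels = FALSE)
  list(x = unname(vapply(split(x, idx), mean, numeric(1))),
       y = unname(vapply(split(y, idx), mean, numeric(1))))
}

# Interior local extrema of the coarsely binned signal, largest |y| first.
coarse_extrema <- function(x, y, bin = 50) {
  b <- bin_signal(x, y, max(3L, floor(length(y) / bin)))
  n <- length(b$y)
  ext <- which(
    (c(0, diff(b$y)) >= 0 & c(diff(b$y), 0) <= 0) |
    (c(0, diff(b$y)) <= 0 & c(diff(b$y), 0) >= 0))
  ext <- ext[ext > 1L & ext < n]
  if (!length(ext)) ext <- c(which.max(b$y), which.min(b$y))
  ord <- ext[order(-abs(b$y[ext]))]
  list(x = b$x[ord], y = b$y[ord])
}

# Candidate peak seeds for the two-Lorentzian multi-start: coarse interior
# extrema plus the global max and min of a finer binning (catches lobes
# sitting at the span boundary).
seed_candidates <- function(x, y) {
  ce <- coarse_extrema(x, y)
  fb <- bin_signal(x, y, max(8L, floor(length(y) / 25)))
  cx <- c(ce$x, fb$x[which.max(fb$y)], fb$x[which.min(fb$y)])
  cy <- c(ce$y, max(fb$y), min(fb$y))
  keep <- !duplicated(round(cx))
  list(x = cx[keep], y = cy[keep])
}

#' Number of coarse peaks in a span
#'
#' Counts local extrema of the 50-bp-binned signal; used to decide
#' between the two-Lorentzian model (at most two extrema) and the
#' constrained spline (more).
#'
#' @param x,y Offsets and values over the span.
#' @param bin Coarse bin width (bp).
#' @return Integer extrema count.
#' @export
coarse_peak_count <- function(x, y, bin = 50) {
  length(coarse_extrema(x, y, bin)$x)
}

rss_of <- function(y, fitted) sum((y - fitted)^2)

#' Fit a sum of two Lorentzians to a difference-profile span
#'
#' Least-squares fit of
#' `y = b + A1 / (1 + ((x - x01)/g1)^2) + A2 / (1 + ((x - x02)/g2)^2)`,
#' the two-peak model used for spans showing a paired loss/gain
#' signature. Amplitudes are signed (a loss lobe has negative A), centers
#' are in promoter offsets, and half-widths `g` are positive.
#'
#' Starting values come from a deterministic multi-start grid: the two
#' centers are seeded at the two largest-|y| coarse extrema, amplitudes
#' at the signal values there, and half-widths over `gamma_grid`; the fit
#' with the smallest residual sum of squares wins. A single-Lorentzian
#' fit is embedded as a candidate (`A2 = 0`), which guarantees the
#' two-component RSS never exceeds the one-component RSS.
#'
#' @param x Numeric offsets.
#' @param y Signal over the span.
#' @param gamma_grid Half-width starting values in bp.
#' @return Object of class `lorentz_fit` with elements `coefficients`
#'   (named `b, A1, x01, g1, A2, x02, g2`), `fitted`, `residuals`,
#'   `rss`, `r.squared`, `rss_single` (best single-Lorentzian RSS),
#'   `converged`, and the data.
#' @examples
#' x <- -600:-300
#' y <- -0.3 / (1 + ((x + 550) / 40)^2) + 0.4 / (1 + ((x + 420) / 35)^2)
#' fit <- fit_two_lorentzians(x, y)
#' coef(fit)
#' @export
fit_two_lorentzians <- function(x, y, gamma_grid = c(25, 50, 100)) {
  stopifnot(length(x) == length(y), length(x) >= 8L)
  ext <- seed_candidates(x, y)
  cand <- seq_len(min(3L, length(ext$x)))
  c1 <- ext$x[1L]
  a1 <- ext$y[1L]
  b0 <- stats::median(y)

  pairs <- list()
  for (i in cand) for (j in cand)
    if (i < j) pairs[[length(pairs) + 1L]] <- c(i, j)
  if (!length(pairs)) pairs <- list(c(1L, 1L))
  starts <- list()
  for (pr in pairs) for (g1 in gamma_grid) for (g2 in gamma_grid)
    starts[[length(starts) + 1L]] <-
      c(b = b0, A1 = ext$y[pr[1L]] - b0, x01 = ext$x[pr[1L]], g1 = g1,
        A2 = ext$y[pr[2L]] - b0, x02 = ext$x[pr[2L]], g2 = g2)

  run_fit <- function(st, fix_a2_zero = FALSE) {
    dat <- data.frame(x = x, y = y)
    lower <- c(-Inf, -Inf, min(x) - 500, 1, -Inf, min(x) - 500, 1)
    upper <- c(Inf, Inf, max(x) + 500, diff(range(x)) + 1,
               Inf, max(x) + 500, diff(range(x)) + 1)
    tryCatch({
      fit <- minpack.lm::nlsLM(
        y ~ b + A1 / (1 + ((x - x01) / g1)^2) + A2 / (1 + ((x - x02) / g2)^2),
        data = dat, start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))
      p <- stats::coef(fit)
      list(par = p, rss = rss_of(y, lorentz2_eval(x, p)), converged = TRUE)
    }, error = function(e) {
      list(par = st, rss = rss_of(y, lorentz2_eval(x, st)),
           converged = FALSE)
    })
  }

  cands <- lapply(starts, run_fit)

  # single-Lorentzian reference (nested model)
  single <- lapply(gamma_grid, function(g) {
    dat <- data.frame(x = x, y = y)
    tryCatch({
      fit <- minpack.lm::nlsLM(
        y ~ b + A1 / (1 + ((x - x01) / g1)^2), data = dat,
        start = list(b = b0, A1 = a1 - b0, x01 = c1, g1 = g),
        lower = c(-Inf, -Inf, min(x) - 500, 1),
        upper = c(Inf, Inf, max(x) + 500, diff(range(x)) + 1),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      p <- stats::coef(fit)
      fitted1 <- p["b"] + lorentzian(x, p["A1"], p["x01"], p["g1"])
      list(par = p, rss = rss_of(y, fitted1))
    }, error = function(e) {
      p <- c(b = b0, A1 = a1 - b0, x01 = c1, g1 = g)
      list(par = p,
           rss = rss_of(y, p["b"] + lorentzian(x, p["A1"], p["x01"], p["g1"])))
    })
  })
  best1 <- single[[which.min(vapply(single, `[[`, numeric(1), "rss"))]]
  # embed the single fit as a two-component candidate with A2 = 0
  emb <- c(best1$par[c("b", "A1", "x01", "g1")],
           A2 = 0, x02 = unname(best1$par["x01"]),
           g2 = unname(best1$par["g1"]))
  names(emb) <- c("b", "A1", "x01", "g1", "A2", "x02", "g2")
  cands[[length(cands) + 1L]] <- list(par = emb,
                                      rss = best1$rss, converged = TRUE)
  cands[[length(cands) + 1L]] <- run_fit(emb)

  rssv <- vapply(cands, `[[`, numeric(1), "rss")
  conv <- vapply(cands, `[[`, logical(1), "converged")
  near <- which(rssv <= min(rssv) * (1 + 1e-9) + 1e-300)
  pick <- if (any(conv[near])) near[conv[near]][1L] else near[1L]
  best <- cands[[pick]]
  if (!best$converged)
    warnf("two-Lorentzian fit did not converge; returning best multi-start candidate")
  fitted <- lorentz2_eval(x, best$par)
  tss_ <- sum((y - mean(y))^2)
  structure(
    list(coefficients = best$par, fitted = fitted, residuals = y - fitted,
         rss = best$rss,
         r.squared = if (tss_ > 0) 1 - best$rss / tss_ else NA_real_,
         rss_single = best1$rss, converged = best$converged,
         x = x, y = y),
    class = "lorentz_fit")
}

#' @export
print.lorentz_fit <- function(x, ...) {
  cat("Two-Lorentzian least-squares fit\n")
  p <- x$coefficients
  cat(sprintf("  peak 1: A = %.4g, center = %.1f bp, half-width = %.1f bp\n",
              p["A1"], p["x01"], p["g1"]))
  cat(sprintf("  peak 2: A = %.4g, center = %.1f bp, half-width = %.1f bp\n",
              p["A2"], p["x02"], p["g2"]))
  cat(sprintf("  baseline %.4g; RSS %.4g (single-Lorentzian RSS %.4g); R^2 %.3f\n",
              p["b"], x$rss, x$rss_single, x$r.squared))
  if (!x$converged) cat("  [did not converge]\n")
  invisible(x)
}

#' @export
coef.lorentz_fit <- function(object, ...) object$coefficients

#' @export
fitted.lorentz_fit <- function(object, ...) object$fitted

#' @export
residuals.lorentz_fit <- function(object, ...) object$residuals

#' @export
predict.lorentz_fit <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$x
        else if (is.list(newdata)) newdata$x else newdata
  lorentz2_eval(xx, object$coefficients)
}

#' Fit a constrained smoothing spline
#'
#' Cubic smoothing spline minimising `RSS + lambda * roughness`
#' (generalised cross-validation chooses `lambda` when it is `NULL`),
#' post-constrained so the fitted curve preserves a property of the data:
#' `"integral"` (default; the fitted values are shifted by a constant so
#' their sum equals the data's sum — difference profiles must keep their
#' near-zero total), `"nonneg"` (clamped at 0, for occupancy profiles),
#' or `"none"`.
#'
#' @param x,y Offsets and values over the span (at least 4 points).
#' @param lambda Smoothing penalty; `NULL` for GCV.
#' @param constraint `"integral"`, `"nonneg"` or `"none"`.
#' @param all_knots Place a knot at every distinct `x` (needed for the
#'   interpolation limit `lambda -> 0`).
#' @return Object of class `cspline_fit` with `fitted`, `residuals`,
#'   `rss`, `lambda`, `shift`, and the underlying `smooth.spline` object.
#' @export
fit_constrained_spline <- function(x, y, lambda = NULL,
                                   constraint = c("integral", "nonneg", "none"),
                                   all_knots = FALSE) {
  constraint <- match.arg(constraint)
  if (length(x) < 4L)
    stopf("spline fit needs at least 4 points (got %d)", length(x))
  sm <- if (is.null(lambda))
    stats::smooth.spline(x, y, cv = FALSE, all.knots = all_knots)
  else
    stats::smooth.spline(x, y, lambda = lambda, all.knots = all_knots)
  fitted <- stats::predict(sm, x)$y
  shift <- 0
  if (constraint == "integral") {
    shift <- (sum(y) - sum(fitted)) / length(y)
    fitted <- fitted + shift
  } else if (constraint == "nonneg") {
    fitted <- pmax(fitted, 0)
  }
  structure(
    list(spline = sm, fitted = fitted, residuals = y - fitted,
         rss = rss_of(y, fitted), lambda = sm$lambda, shift = shift,
         constraint = constraint, x = x, y = y),
    class = "cspline_fit")
}

#' @export
print.cspline_fit <- function(x, ...) {
  cat("Constrained smoothing spline fit\n")
  cat(sprintf("  lambda = %.4g (%s), constraint = %s, RSS = %.4g\n",
              x$lambda,
              if (is.null(attr(x, "user_lambda"))) "GCV" else "fixed",
              x$constraint, x$rss))
  invisible(x)
}

#' @export
fitted.cspline_fit <- function(object, ...) object$fitted

#' @export
residuals.cspline_fit <- function(object, ...) object$residuals

#' @export
predict.cspline_fit <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$x
        else if (is.list(newdata)) newdata$x else newdata
  out <- stats::predict(object$spline, xx)$y + object$shift
  if (object$constraint == "nonneg") out <- pmax(out, 0)
  out
}

#' Dominant non-DC spectral frequency
#'
#' Discrete Fourier magnitude argmax excluding the zero frequency, in
#' cycles per bp. A signal whose power is not concentrated (the peak bin
#' carries less than `min_power_frac` of total non-DC power) is flagged
#' as having no periodic structure — the behaviour of an unsmoothed
#' 1-bp-resolution difference profile, whose spectrum is dominated by the
#' observation window itself, which is why spectral smoothing is not used
#' for regression here.
#'
#' @param y Finite numeric vector.
#' @param min_power_frac Concentration threshold (default 0.1).
#' @return List with `frequency` (cycles/bp, `NA` if no non-DC
#'   component), `period` (bp), `power_frac`, and `periodic` (logical).
#' @export
dominant_frequency <- function(y, min_power_frac = 0.1) {
  stopifnot(all(is.finite(y)))
  n <- length(y)
  mag2 <- Mod(stats::fft(y - mean(y)))^2
  ks <- seq_len(floor(n / 2))
  pw <- mag2[ks + 1L]
  tot <- sum(pw)
  if (tot <= n * 1e-24 * max(1, sum(y^2)))
    return(list(frequency = NA_real_, period = NA_real_,
                power_frac = NA_real_, periodic = FALSE))
  k <- ks[which.max(pw)]
  frac <- max(pw) / tot
  list(frequency = k / n, period = n / k, power_frac = frac,
       periodic = frac >= min_power_frac)
}
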