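#' @title FRAP normalization and recovery-rate fitting
#' @name frap
NULL

#' Normalize a FRAP recovery series
#'
#' The bleached-ROI series is first divided by a control ROI (cancelling
#' acquisition drift and photobleaching of the whole field), then rescaled
#' between the prebleach level (mean of the 10 frames immediately before the
#' bleach) and the signal at the designated first postbleach frame:
#' `out = (r - r_post) / (r_pre - r_post)`, i.e. 0 at the postbleach frame
#' and 1 at full recovery. Very fast initial recovery is excluded by placing
#' the first postbleach frame ~1 s after the bleach.
#'
#' @param bleach_roi,control_roi Aligned intensity series.
#' @param bleach_index Frame index of the bleach event (frames before it are
#'   prebleach; at least 10 required).
#' @param post_index First postbleach frame used as the recovery origin
#'   (default `bleach_index + 2`, i.e. 1 s at 0.5 s frame intervals).
#' @return A numeric vector (same length as input) of normalized recovery;
#'   attribute `post_index` records the origin frame.
#' @export
normalize_frap <- function(bleach_roi, control_roi, bleach_index,
                           post_index = bleach_index + 2) {
  stopifnot(length(bleach_roi) == length(control_roi),
            bleach_index > 10, post_index > bleach_index,
            post_index <= length(bleach_roi))
  r <- bleach_roi / control_roi
  r_pre <- mean(r[(bleach_index - 10):(bleach_index - 1)])
  r_post <- r[post_index]
  if (abs(r_pre - r_post) < 1e-12 * abs(r_pre)) {
    stop("no bleach detected: prebleach and postbleach levels coincide")
  }
  structure((r - r_post) / (r_pre - r_post), post_index = post_index)
}

#' Fit a single-exponential recovery rate
#'
#' Least-squares fit of `y(t) = plateau * (1 - exp(-k (t - t0)))` to a
#' normalized recovery series, from the postbleach origin onward.
#'
#' @param t Times (seconds), same length as `y`.
#' @param y Normalized recovery (from [normalize_frap()]).
#' @param fit_plateau Allow the plateau to differ from 1 (default FALSE).
#' @return A list: `k` (1/s), `plateau`, `rss`.
#' @export
fit_frap_rate <- function(t, y, fit_plateau = FALSE) {
  stopifnot(length(t) == length(y), length(t) >= 3)
  t0 <- t[1]
  rss_k <- function(k, plateau = 1) {
    sum((plateau * (1 - exp(-k * (t - t0))) - y)^2)
  }
  if (!fit_plateau) {
    opt <- stats::optimize(rss_k, c(1e-6, 10), tol = 1e-12)
    list(k = opt$minimum, plateau = 1, rss = opt$objective)
  } else {
    o <- stats::optim(c(log(0.01), 1), function(th) rss_k(exp(th[1]), th[2]),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
    list(k = exp(o$par[1]), plateau = o$par[2], rss = o$value)
  }
}
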