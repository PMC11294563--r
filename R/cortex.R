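#' @title Decomposition of straightened-cortex images
#' @description Models a straightened cortical image (cross-membrane axis H,
#'   default 50 px, by arc-length axis L) as the sum of two tensor products:
#'   a uniform cytoplasmic concentration times a cross-membrane cytoplasmic
#'   signal profile, plus a per-position membrane concentration times a
#'   membrane signal profile. The profiles are learned from training images
#'   by gradient descent (adaptive-moment steps); per-image concentrations
#'   are then recovered either by the same gradient descent or by the exact
#'   linear least-squares solution (the profiles being fixed makes the
#'   problem linear). Orientation convention: row 1 is the extracellular
#'   side, row H the cell interior; arc position 1 is the anterior pole and
#'   the posterior pole sits at L/2 (the arc wraps).
#' @name cortex
NULL

#' Signal-profile pair
#'
#' @param s_cyt Length-H cytoplasmic profile. Normalization: the mean of the
#'   5 innermost (interior-side) pixels is 1, so cytoplasmic concentrations
#'   read in raw intensity units.
#' @param s_mem Length-H membrane profile, max = 1.
#' @param provenance Optional list (training size, iterations, final loss).
#' @return List of class `"signal_profiles"`.
#' @export
signal_profiles <- function(s_cyt, s_mem, provenance = NULL) {
  stopifnot(length(s_cyt) == length(s_mem), all(is.finite(s_cyt)),
            all(is.finite(s_mem)))
  structure(list(s_cyt = as.numeric(s_cyt), s_mem = as.numeric(s_mem),
                 provenance = provenance),
            class = "signal_profiles")
}

#' Initial profile shapes
#'
#' The conventional starting shapes: an error function (a Gaussian-blurred
#' step from outside to inside) for the cytoplasmic profile and a Gaussian
#' for the membrane profile, both centred on the membrane position H/2 with
#' width 2 px.
#'
#' @param H Cross-membrane height in pixels (default 50).
#' @param centre Membrane position (default H/2).
#' @param width Gaussian sigma / erf width in pixels (default 2).
#' @return A [signal_profiles()] object.
#' @export
initial_profiles <- function(H = 50, centre = H / 2, width = 2) {
  h <- seq_len(H)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  s_cyt <- (1 + erf((h - centre) / (width * sqrt(2)))) / 2
  s_mem <- exp(-(h - centre)^2 / (2 * width^2))
  signal_profiles(.normalize_cyt(s_cyt), s_mem / max(s_mem))
}

.normalize_cyt <- function(s_cyt) {
  H <- length(s_cyt)
  plateau <- mean(s_cyt[(H - 4):H])
  if (plateau <= 0) stop("cytoplasmic profile has a nonpositive interior plateau")
  s_cyt / plateau
}

#' Forward model: simulate a straightened-cortex image
#'
#' `pixel[h, l] = c_cyt * s_cyt[h] + c_mem[l] * s_mem[h] (+ noise)`. This is
#' the exact forward model used in training and quantification; the
#' noiseless call is shared code with the fitting loss.
#'
#' @param c_cyt Scalar uniform cytoplasmic concentration (raw units).
#' @param c_mem Length-L membrane concentration profile.
#' @param profiles A [signal_profiles()] object.
#' @param noise_sd Additive Gaussian pixel noise SD (default 0).
#' @return An H x L intensity matrix.
#' @export
simulate_cortex_image <- function(c_cyt, c_mem, profiles, noise_sd = 0) {
  stopifnot(inherits(profiles, "signal_profiles"), length(c_cyt) == 1)
  H <- length(profiles$s_cyt)
  L <- length(c_mem)
  img <- c_cyt * profiles$s_cyt %o% rep(1, L) + profiles$s_mem %o% c_mem
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(H * L, sd = noise_sd), H, L)
  }
  img
}

# Adaptive-moment gradient descent on a flat numeric parameter vector.
# grad_fn(theta) must return list(loss = scalar, grad = vector like theta).
# Convergence: relative loss change < tol across a `window`-iteration span
# (or loss negligible relative to its starting value); sustained loss
# increase across a window is treated as divergence.
.adam <- function(theta, grad_fn, lr = 0.005, max_iter = 20000,
                  tol = 1e-6, window = 100) {
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_hist <- rep(NA_real_, max_iter)
  loss0 <- NA_real_
  best <- Inf
  best_theta <- theta
  for (it in seq_len(max_iter)) {
    g <- grad_fn(theta)
    if (it == 1) loss0 <- g$loss
    if (g$loss < best) {
      best <- g$loss
      best_theta <- theta
    }
    best_hist[it] <- best
    m <- b1 * m + (1 - b1) * g$grad
    v <- b2 * v + (1 - b2) * g$grad^2
    theta <- theta - lr * (m / (1 - b1^it)) / (sqrt(v / (1 - b2^it)) + eps)
    if (best <= 1e-24 * max(loss0, .Machine$double.xmin)) break
    if (it > window) {
      prev <- best_hist[it - window]
      if (prev - best < tol * best) break # best no longer improving
      if (g$loss > 2 * loss0 && g$loss > 1e6 * best) {
        stop(sprintf(
          "optimization diverged at iteration %d (loss %.4g, started at %.4g)",
          it, g$loss, loss0))
      }
    }
  }
  list(theta = best_theta, loss = best, iterations = it)
}

#' Train the cytoplasmic signal profile
#'
#' Stage one of profile training: gradient descent on a batch of
#' cytoplasm-only images (no membrane signal) with a shared `s_cyt` and one
#' free `c_cyt` per image, minimizing the mean squared pixel error. The
#' membrane term is fixed to zero. The returned profile carries the
#' plateau-equals-1 normalization.
#'
#' @param images List of H x L matrices (L may vary between images).
#' @param H Expected cross-membrane height (default 50).
#' @param init Initial profiles (default [initial_profiles()]).
#' @param lr,max_iter,tol Optimizer settings (learning rate 0.005).
#' @return A list: `s_cyt`, per-image `c_cyt`, `loss`, `iterations`.
#' @export
train_cyt_profile <- function(images, H = 50, init = initial_profiles(H),
                              lr = 0.005, max_iter = 20000, tol = 1e-6) {
  stopifnot(is.list(images), length(images) >= 2,
            all(vapply(images, nrow, integer(1)) == H))
  n_pix <- sum(vapply(images, length, integer(1)))
  K <- length(images)
  theta0 <- c(init$s_cyt,
              vapply(images, function(im) mean(im[(H - 4):H, ]), numeric(1)))
  grad_fn <- function(th) {
    s <- th[seq_len(H)]
    cc <- th[H + seq_len(K)]
    loss <- 0
    g_s <- numeric(H)
    g_c <- numeric(K)
    for (k in seq_len(K)) {
      R <- cc[k] * s - images[[k]] # recycles s down columns
      loss <- loss + sum(R^2)
      rs <- rowSums(R)
      g_s <- g_s + 2 * cc[k] * rs
      g_c[k] <- 2 * sum(rs * s)
    }
    list(loss = loss / n_pix, grad = c(g_s, g_c) / n_pix)
  }
  fit <- .adam(theta0, grad_fn, lr = lr, max_iter = max_iter, tol = tol)
  s <- fit$theta[seq_len(H)]
  plateau <- mean(s[(H - 4):H])
  list(s_cyt = s / plateau, c_cyt = fit$theta[H + seq_len(K)] * plateau,
       loss = fit$loss, iterations = fit$iterations)
}

#' Train the membrane signal profile
#'
#' Stage two: gradient descent on polarized images with a shared `s_mem`,
#' per-image uniform `c_cyt` and per-image membrane profiles `c_mem` free,
#' and `s_cyt` fixed to the stage-one profile. Identifiability comes from
#' the along-arc contrast of the membrane signal (anterior vs posterior);
#' training sets without such contrast are rejected.
#'
#' @param images List of H x L matrices with along-arc membrane contrast.
#' @param s_cyt Fixed cytoplasmic profile from [train_cyt_profile()].
#' @param init Initial profiles (membrane part used).
#' @param lr,max_iter,tol Optimizer settings.
#' @param min_contrast Minimum relative along-arc SD of column means required
#'   (identifiability guard, default 0.01).
#' @return A list: `s_mem`, per-image `c_cyt` and `c_mem`, `loss`,
#'   `iterations`, and assembled `profiles`.
#' @export
train_mem_profile <- function(images, s_cyt,
                              init = initial_profiles(length(s_cyt)),
                              lr = 0.005, max_iter = 20000, tol = 1e-6,
                              min_contrast = 0.01) {
  H <- length(s_cyt)
  stopifnot(is.list(images), length(images) >= 1,
            all(vapply(images, nrow, integer(1)) == H))
  contrast <- vapply(images, function(im) {
    cm <- colMeans(im)
    stats::sd(cm) / mean(cm)
  }, numeric(1))
  if (all(contrast < min_contrast)) {
    stop("no along-arc contrast in any training image: ",
         "membrane and cytoplasmic profiles are not separable")
  }
  n_pix <- sum(vapply(images, length, integer(1)))
  K <- length(images)
  Ls <- vapply(images, ncol, integer(1))
  m_off <- H + K + c(0, cumsum(Ls))[seq_len(K)] # start offsets of each c_mem
  theta0 <- c(
    init$s_mem,
    vapply(images, function(im) mean(im[(H - 4):H, ]), numeric(1)),
    unlist(lapply(images, function(im) {
      pmax(colMeans(im) - mean(im[(H - 4):H, ]), 0)
    }))
  )
  grad_fn <- function(th) {
    s <- th[seq_len(H)]
    cc <- th[H + seq_len(K)]
    loss <- 0
    g <- numeric(length(th))
    g_s <- numeric(H)
    for (k in seq_len(K)) {
      mk <- th[m_off[k] + seq_len(Ls[k])]
      R <- cc[k] * s_cyt + s %o% mk - images[[k]]
      loss <- loss + sum(R^2)
      g_s <- g_s + 2 * as.numeric(R %*% mk)
      g[H + k] <- 2 * sum(rowSums(R) * s_cyt)
      g[m_off[k] + seq_len(Ls[k])] <- 2 * as.numeric(crossprod(R, s))
    }
    g[seq_len(H)] <- g_s
    list(loss = loss / n_pix, grad = g / n_pix)
  }
  fit <- .adam(theta0, grad_fn, lr = lr, max_iter = max_iter, tol = tol)
  s <- fit$theta[seq_len(H)]
  peak <- max(s)
  profiles <- signal_profiles(
    s_cyt, s / peak,
    provenance = list(n_images = K, iterations = fit$iterations,
                      loss = fit$loss))
  list(s_mem = s / peak, c_cyt = fit$theta[H + seq_len(K)],
       c_mem = lapply(seq_len(K), function(k) {
         fit$theta[m_off[k] + seq_len(Ls[k])] * peak
       }),
       loss = fit$loss, iterations = fit$iterations, profiles = profiles)
}

#' Quantify membrane and cytoplasmic concentrations in one image
#'
#' With the signal profiles fixed the decomposition is a linear
#' least-squares problem: one shared cytoplasmic amplitude plus one membrane
#' amplitude per arc position. `method = "lsq"` (default) solves the normal
#' equations exactly after profiling out the per-column membrane amplitudes;
#' `method = "adam"` runs the same gradient descent used in training and
#' converges to the same optimum. Negative concentration estimates are
#' reported (flagged), never clipped.
#'
#' @param image H x L intensity matrix.
#' @param profiles Trained [signal_profiles()].
#' @param method `"lsq"` or `"adam"`.
#' @param lr,max_iter,tol Optimizer settings for the adam path (tighter
#'   default tolerance than training, so the two methods agree closely).
#' @return A list of class `"quant_result"`: `c_cyt` (scalar), `c_mem`
#'   (length L), `loss` (mean squared residual), `negative` flag.
#' @export
quantify_image <- function(image, profiles, method = c("lsq", "adam"),
                           lr = 0.005, max_iter = 50000, tol = 1e-10) {
  method <- match.arg(method)
  A <- profiles$s_cyt
  B <- profiles$s_mem
  stopifnot(nrow(image) == length(A))
  L <- ncol(image)
  b2 <- sum(B^2)
  if (b2 == 0 || sum(A^2) == 0) stop("degenerate signal profiles")
  # A-tilde: component of s_cyt orthogonal to s_mem
  At <- A - sum(A * B) / b2 * B
  if (sum(At^2) < 1e-12 * sum(A^2)) {
    stop("signal profiles are collinear: decomposition is singular")
  }
  if (method == "lsq") {
    c_cyt <- sum(crossprod(image, At)) / (L * sum(At^2))
    c_mem <- as.numeric(crossprod(image, B) - c_cyt * sum(A * B)) / b2
  } else {
    H <- length(A)
    theta0 <- c(mean(image[(H - 4):H, ]), numeric(L))
    n_pix <- length(image)
    grad_fn <- function(th) {
      R <- th[1] * A + B %o% th[-1] - image
      list(loss = sum(R^2) / n_pix,
           grad = c(2 * sum(rowSums(R) * A),
                    2 * as.numeric(crossprod(R, B))) / n_pix)
    }
    fit <- .adam(theta0, grad_fn, lr = lr, max_iter = max_iter, tol = tol,
                 window = 200)
    c_cyt <- fit$theta[1]
    c_mem <- fit$theta[-1]
  }
  resid <- c_cyt * A + B %o% c_mem - image
  structure(
    list(c_cyt = c_cyt, c_mem = c_mem, loss = mean(resid^2),
         negative = c_cyt < 0 || any(c_mem < 0), units = "au"),
    class = "quant_result"
  )
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("Quantified image: c_cyt = %.4g, c_mem mean = %.4g (loss %.4g)%s\n",
              x$c_cyt, mean(x$c_mem), x$loss,
              if (x$negative) " [negative estimates flagged]" else ""))
  invisible(x)
}

#' Membrane/cytoplasm unit conversion factor from an optogenetic pair
#'
#' Redistributing a conserved pool from cytoplasm to membrane gives
#' `T = C + psi c M` before and `T = C' + psi c M'` after, so
#' `c = (C - C') / (psi (M' - M))` converts raw membrane units into
#' cytoplasm-commensurate units.
#'
#' @param C,C_after Mean cytoplasmic signal before/after recruitment (raw
#'   units).
#' @param M,M_after Mean membrane signal before/after.
#' @param psi Surface-to-volume ratio, 1/m.
#' @return Conversion factor (metres).
#' @examples
#' calibrate_units(100, 80, 50, 150, 0.174e6) # ~1.15e-6 m
#' @export
calibrate_units <- function(C, C_after, M, M_after, psi) {
  stopifnot(psi > 0)
  if (M_after == M) stop("no membrane redistribution (M' = M): cannot calibrate")
  (C - C_after) / (psi * (M_after - M))
}

#' Polarity metrics from a quantified image
#'
#' Windows are fractions of the arc length; the arc wraps, the posterior
#' pole sits at `L/2`, and "posterior-most q" means the window of arc
#' fraction `q` centred on the posterior pole.
#'
#' @param result A [quantify_image()] result (or list with `c_cyt`, `c_mem`).
#' @param factor Membrane-to-cytoplasm unit conversion from
#'   [calibrate_units()], in metres (use `1` for already-consistent units).
#' @param psi Surface-to-volume ratio, 1/m.
#' @param posterior_frac Arc fraction for the posterior window (default 0.2).
#' @param peak_frac Arc fraction for the peak window (default 0.2).
#' @param mc_smooth Odd rolling-mean width (px) for the local M:C profile
#'   (default 21; 1 disables).
#' @return A list: `posterior_mem` (mean membrane concentration in the
#'   posterior window, cytoplasm units), `posterior_mc` (posterior M:C
#'   ratio), `fraction_pm` (psi c Mbar / (C + psi c Mbar), whole membrane),
#'   `fraction_posterior_pm` (same restricted to the posterior 50%),
#'   `peak_mem` (highest mean over any `peak_frac` window), `local_mc`
#'   (length-L anterior-to-posterior M:C profile).
#' @export
polarity_metrics <- function(result, factor = 1, psi,
                             posterior_frac = 0.2, peak_frac = 0.2,
                             mc_smooth = 21) {
  c_mem <- result$c_mem * factor * psi # cytoplasm-volume units per arc px
  c_cyt <- result$c_cyt
  L <- length(c_mem)
  w <- max(1L, round(posterior_frac * L))
  if (w > L) stop("posterior window exceeds arc length")
  post_idx <- .wrap_window(L, centre = floor(L / 2) + 1L, width = w)
  posterior_mem <- mean(c_mem[post_idx])

  mean_mem <- mean(c_mem)
  fraction_pm <- mean_mem / (c_cyt + mean_mem)
  half_idx <- .wrap_window(L, centre = floor(L / 2) + 1L,
                           width = max(1L, round(0.5 * L)))
  post_mem_half <- mean(c_mem[half_idx]) * length(half_idx) / L
  fraction_posterior_pm <- post_mem_half / (c_cyt + mean_mem)

  wp <- max(1L, round(peak_frac * L))
  if (wp > L) stop("peak window exceeds arc length")
  circ <- c(c_mem, c_mem[seq_len(wp - 1)])
  peak_mem <- max(stats::filter(circ, rep(1 / wp, wp), sides = 1)[wp:(L + wp - 1)])

  mc <- c_mem / c_cyt
  if (mc_smooth > 1) {
    k <- mc_smooth
    circ_mc <- c(mc[(L - (k %/% 2) + 1):L], mc, mc[seq_len(k %/% 2)])
    mc <- as.numeric(stats::filter(circ_mc, rep(1 / k, k), sides = 2))[
      (k %/% 2 + 1):(k %/% 2 + L)]
  }
  list(posterior_mem = posterior_mem, posterior_mc = posterior_mem / c_cyt,
       fraction_pm = fraction_pm,
       fraction_posterior_pm = fraction_posterior_pm,
       peak_mem = peak_mem, local_mc = mc)
}

.wrap_window <- function(L, centre, width) {
  offsets <- seq_len(width) - (width %/% 2) - 1L
  ((centre - 1L + offsets) %% L) + 1L
}
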