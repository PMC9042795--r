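#' FRAP trace container
#'
#' A fluorescence-recovery-after-photobleaching time series: ROI intensity,
#' optional reference-ROI and background series, and the index of the first
#' post-bleach frame. All series share length; time is strictly increasing;
#' at least one pre-bleach frame is required.
#'
#' @param time_s Time stamps (seconds), strictly increasing.
#' @param roi Bleached-ROI intensities.
#' @param reference Optional unbleached reference-ROI intensities (used to
#'   correct acquisition photobleaching).
#' @param background Optional background intensities.
#' @param bleach_index Index of the first post-bleach frame (>= 2).
#' @return A `frap_trace` object.
#' @export
frap_trace <- function(time_s, roi, reference = NULL, background = NULL,
                       bleach_index) {
  n <- length(time_s)
  if (length(roi) != n) stop("time_s and roi must share length")
  if (!is.null(reference) && length(reference) != n) {
    stop("reference must share length with roi")
  }
  if (!is.null(background) && length(background) != n) {
    stop("background must share length with roi")
  }
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 2L || bleach_index > n) {
    stop("bleach_index must leave at least one pre-bleach frame")
  }
  structure(list(time_s = as.numeric(time_s), roi = as.numeric(roi),
                 reference = if (is.null(reference)) NULL else
                   as.numeric(reference),
                 background = if (is.null(background)) NULL else
                   as.numeric(background),
                 bleach_index = bleach_index),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat("frap_trace:", length(x$time_s), "frames,",
      x$bleach_index - 1L, "pre-bleach,",
      if (is.null(x$reference)) "no reference" else "with reference", "\n")
  invisible(x)
}

#' Double-normalize a FRAP trace
#'
#' Standard double normalization with full-scale rescaling: background (if
#' provided) is subtracted from the ROI and reference; the ROI is divided
#' frame-wise by the reference (correcting acquisition photobleaching); the
#' ratio is divided by its pre-bleach mean so the pre-bleach plateau is 1;
#' finally the trace is rescaled affinely so the first post-bleach frame
#' maps to 0 while the plateau stays 1 ("scaling the dynamic range from 0
#' to 1"). Without a reference, single normalization is used with a
#' warning. Normalization is idempotent.
#'
#' The rescale is an affine map: it leaves the recovery time constant and
#' the immobile fraction unchanged, but re-expresses `I0` and `I1`
#' (`I0 -> (I0 - b)/(1 - b)`, `I1 -> I1/(1 - b)` with `b` the first
#' post-bleach value). Set `rescale = FALSE` to stop after double
#' normalization (pre-bleach plateau = 1), the units in which simulated
#' ground-truth parameters are defined.
#'
#' @param trace A [frap_trace()].
#' @param rescale Pin the first post-bleach frame to 0 (full-scale
#'   normalization, the default).
#' @return A normalized [frap_trace()] (reference set to 1, background
#'   dropped), with attributes `prebleach_mean` and `first_postbleach`
#'   recording the anchors.
#' @export
normalize_trace <- function(trace, rescale = TRUE) {
  stopifnot(inherits(trace, "frap_trace"))
  roi <- trace$roi
  ref <- trace$reference
  if (!is.null(trace$background)) {
    roi <- roi - trace$background
    if (!is.null(ref)) ref <- ref - trace$background
  }
  if (is.null(ref)) {
    warning("no reference ROI: using single normalization ",
            "(no acquisition-bleaching correction)")
    ratio <- roi
  } else {
    if (any(ref <= 0)) {
      stop("reference contains non-positive values after background ",
           "subtraction")
    }
    ratio <- roi / ref
  }
  pre <- seq_len(trace$bleach_index - 1L)
  pre_mean <- mean(ratio[pre])
  if (pre_mean <= 0) stop("non-positive pre-bleach mean")
  ratio <- ratio / pre_mean
  b <- ratio[trace$bleach_index]
  if (b >= mean(ratio[pre])) {
    warning("no bleach detected: first post-bleach frame is not below the ",
            "pre-bleach mean")
  }
  if (rescale) {
    if (abs(1 - b) < .Machine$double.eps * 100) {
      stop("degenerate trace: pre-bleach plateau equals the bleach frame")
    }
    norm <- (ratio - b) / (1 - b)
  } else {
    norm <- ratio
  }
  out <- frap_trace(time_s = trace$time_s, roi = norm,
                    reference = rep(1, length(norm)),
                    bleach_index = trace$bleach_index)
  attr(out, "prebleach_mean") <- pre_mean
  attr(out, "first_postbleach") <- b
  out
}

#' Immobile fraction from recovery parameters
#'
#' The share of fluorescence that never recovers after bleaching:
#' `(1 - I0 - I1) / (1 - I0)`.
#'
#' @param I0 Normalized intensity just after bleach (< 1).
#' @param I1 Dynamic range of recovery.
#' @return The immobile fraction.
#' @examples
#' immobile_fraction(0.2, 0.5)  # 0.375
#' @export
immobile_fraction <- function(I0, I1) {
  if (any(I0 >= 1)) stop("I0 must be < 1")
  (1 - I0 - I1) / (1 - I0)
}

#' Recovery half-time
#'
#' `t_half = tau * ln(2)`: the time after bleaching at which the recovery
#' reaches half of its dynamic range (`I0 + I1/2`).
#'
#' @param tau Recovery time constant (seconds, > 0).
#' @return The half-time in seconds.
#' @export
half_time <- function(tau) {
  if (any(tau <= 0)) stop("tau must be > 0")
  tau * log(2)
}

#' Fit the single-exponential recovery model to a normalized FRAP trace
#'
#' Least-squares fit of `FRAP(t) = I0 + I1 * (1 - exp(-(t - t_bleach)/tau))`
#' over the post-bleach frames, with `t_bleach` the timestamp of the first
#' post-bleach frame. Initialization is deterministic: `I0` from the first
#' post-bleach value, `I1` from the final recovery level, and `tau` from a
#' linear scan for the time at which the trace reaches
#' `I0 + (1 - 1/e) * I1`. Derived quantities ([immobile_fraction()],
#' [half_time()]) and the residual RMS are reported.
#'
#' @param trace A normalized [frap_trace()] (see [normalize_trace()]) with
#'   at least 4 post-bleach frames.
#' @param max_restarts Jittered restarts before giving up on convergence.
#' @return A `frap_fit` list: `I0`, `I1`, `tau`, `immobile_fraction`,
#'   `t_half`, `residual_rms`, `t_bleach`, `n_post`.
#' @export
fit_recovery <- function(trace, max_restarts = 5L) {
  stopifnot(inherits(trace, "frap_trace"))
  post <- seq.int(trace$bleach_index, length(trace$time_s))
  if (length(post) < 4) stop("need at least 4 post-bleach frames")
  tb <- trace$time_s[trace$bleach_index]
  t_rel <- trace$time_s[post] - tb
  y <- trace$roi[post]
  I0_init <- y[1]
  I1_init <- max(mean(y[max(1, length(y) - 4):length(y)]) - I0_init, 1e-3)
  target <- I0_init + (1 - exp(-1)) * I1_init
  idx <- which(y >= target)
  tau_init <- if (length(idx) > 0 && t_rel[min(idx)] > 0) {
    t_rel[min(idx)]
  } else {
    max(t_rel) / 3
  }
  df <- data.frame(t = t_rel, y = y)
  best <- NULL
  best_rss <- Inf
  start <- list(I0 = I0_init, I1 = I1_init, tau = tau_init)
  for (attempt in seq_len(max_restarts + 1L)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ I0 + I1 * (1 - exp(-t / tau)), data = df,
                        start = start,
                        lower = c(I0 = -Inf, I1 = 0, tau = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
      break
    }
    # deterministic jitter of the start values on failure
    f <- 1 + 0.3 * attempt * c(1, -1, 1)
    start <- list(I0 = I0_init * f[1] + 0.01 * attempt,
                  I1 = I1_init * abs(f[2]), tau = tau_init * f[3])
  }
  if (is.null(best)) {
    stop("recovery fit did not converge after ", max_restarts,
         " restarts (best residual sum of squares: ",
         signif(best_rss, 4), ")")
  }
  p <- coef(best)
  structure(list(I0 = unname(p["I0"]), I1 = unname(p["I1"]),
                 tau = unname(p["tau"]),
                 immobile_fraction = immobile_fraction(unname(p["I0"]),
                                                       unname(p["I1"])),
                 t_half = half_time(unname(p["tau"])),
                 residual_rms = sqrt(mean(residuals(best)^2)),
                 t_bleach = tb, n_post = length(post)),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(paste0("FRAP fit: I0 = %.4f, I1 = %.4f, tau = %.3f s\n",
                     "immobile fraction = %.4f, t1/2 = %.3f s, ",
                     "residual RMS = %.2e\n"),
              x$I0, x$I1, x$tau, x$immobile_fraction, x$t_half,
              x$residual_rms))
  invisible(x)
}

#' Read or write FRAP traces as CSV
#'
#' CSV columns: `time_s`, `roi`, and optionally `reference` and
#' `background`; the bleach index is stored in a `bleach_index` column
#' (constant) so the file is self-contained.
#'
#' @param trace A [frap_trace()].
#' @param path CSV path.
#' @return `read_frap_trace` returns a [frap_trace()].
#' @export
write_frap_trace <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  df <- data.frame(time_s = trace$time_s, roi = trace$roi)
  if (!is.null(trace$reference)) df$reference <- trace$reference
  if (!is.null(trace$background)) df$background <- trace$background
  df$bleach_index <- trace$bleach_index
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_trace
#' @export
read_frap_trace <- function(path) {
  df <- read.csv(path)
  frap_trace(time_s = df$time_s, roi = df$roi,
             reference = df$reference, background = df$background,
             bleach_index = df$bleach_index[1])
}
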