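AVOGADRO <- 6.02214076e23

# One EM run for a 1D K-component Gaussian mixture from a fixed start.
# Asserts the log-likelihood is non-decreasing at every iteration.
em_gaussian_1d <- function(x, means, sds, weights, tol = 1e-8,
                           max_iter = 1000L) {
  n <- length(x)
  K <- length(means)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k) {
      weights[k] * dnorm(x, means[k], sds[k])
    }, numeric(n))
    dens <- matrix(dens, n, K)
    rs <- rowSums(dens)
    rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    if (ll < ll_old - 1e-6 * max(1, abs(ll_old))) {
      stop("EM log-likelihood decreased; numerical failure")
    }
    resp <- dens / rs
    nk <- colSums(resp)
    if (any(nk < 1e-12)) stop("degenerate component: vanishing weight")
    means_new <- colSums(resp * x) / nk
    sds_new <- sqrt(colSums(resp * (x - rep(means_new, each = n))^2) / nk)
    if (any(sds_new < 1e-10 * max(abs(x)))) {
      stop("degenerate component: sd collapsed to 0")
    }
    weights <- nk / n
    means <- means_new
    sds <- sds_new
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * max(1, abs(ll))) {
      return(list(means = means, sds = sds, weights = weights,
                  loglik = ll, iterations = iter, converged = TRUE))
    }
    ll_old <- ll
  }
  list(means = means, sds = sds, weights = weights, loglik = ll_old,
       iterations = max_iter, converged = FALSE)
}

#' Fit a 1D Gaussian mixture to an intensity distribution
#'
#' Expectation-maximization fit of a K-component Gaussian mixture, the
#' model used to decompose single-molecule FISH spot intensities into
#' copy-number populations. Initialization is deterministic
#' (quantile-spaced means, pooled SD, uniform weights); degenerate runs are
#' restarted with seed-derived jittered means (up to 10 restarts). When a
#' range of K is supplied, K is selected by the Bayesian information
#' criterion.
#'
#' @param intensities Numeric vector (n >= 10 K).
#' @param K Component count, or an integer range (e.g. `1:4`) to select by
#'   BIC.
#' @param seed Integer seed for restart jitter.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return A `mixture_model` list: `K`, `means`, `sds`, `weights` (sorted
#'   by increasing mean), `loglik`, `bic`, `n`.
#' @export
fit_gaussian_mixture <- function(intensities, K = 1:4, seed = 1L,
                                 tol = 1e-8, max_iter = 1000L) {
  x <- as.numeric(intensities)
  if (any(!is.finite(x))) stop("intensities must be finite")
  fits <- list()
  for (k in sort(unique(as.integer(K)))) {
    if (length(x) < 10 * k) {
      if (length(fits) == 0 && k == min(K)) {
        stop("need at least 10 observations per mixture component (n = ",
             length(x), ", K = ", k, ")")
      }
      next
    }
    fit <- fit_one_k(x, k, seed, tol, max_iter)
    fit$bic <- -2 * fit$loglik + (3 * k - 1) * log(length(x))
    fit$K <- k
    fits[[length(fits) + 1L]] <- fit
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
  ord <- order(best$means)
  structure(list(K = best$K, means = best$means[ord], sds = best$sds[ord],
                 weights = best$weights[ord], loglik = best$loglik,
                 bic = best$bic, n = length(x)),
            class = "mixture_model")
}

fit_one_k <- function(x, k, seed, tol, max_iter) {
  if (k == 1L) {
    m <- mean(x); s <- sd(x)
    if (is.na(s) || s == 0) s <- max(abs(m) * 1e-6, 1e-12)
    ll <- sum(dnorm(x, m, s, log = TRUE))
    return(list(means = m, sds = s, weights = 1, loglik = ll,
                iterations = 0L, converged = TRUE))
  }
  means0 <- as.numeric(quantile(x, probs = (seq_len(k) - 0.5) / k))
  s0 <- sd(x) / k
  if (s0 == 0) s0 <- max(abs(mean(x)) * 1e-6, 1e-12)
  set.seed(derive_seed(seed, "em"))
  for (attempt in 0:10) {
    means <- if (attempt == 0) means0 else
      means0 * (1 + runif(k, -0.1, 0.1))
    fit <- tryCatch(
      em_gaussian_1d(x, means, rep(s0, k), rep(1 / k, k), tol, max_iter),
      error = function(e) e)
    if (!inherits(fit, "error")) return(fit)
  }
  stop("EM failed after 10 jittered restarts: ", conditionMessage(fit))
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("Gaussian mixture (K =", x$K, ", n =", x$n, "):\n")
  for (k in seq_len(x$K)) {
    cat(sprintf("  component %d: mean %.4g, sd %.4g, weight %.3f\n",
                k, x$means[k], x$sds[k], x$weights[k]))
  }
  invisible(x)
}

#' Unit intensity of a single molecule
#'
#' The mean of the mixture component carrying the largest weight: in
#' nurse-cell smFISH data the dominant population is single mRNAs, so this
#' component's mean is the intensity of one molecule. Weight ties break
#' toward the smaller mean (encoding the same single-molecule prior).
#'
#' @param model A `mixture_model` from [fit_gaussian_mixture()].
#' @return The unit intensity (intensity units per molecule).
#' @export
unit_intensity <- function(model) {
  stopifnot(inherits(model, "mixture_model"))
  w_max <- max(model$weights)
  cand <- which(model$weights >= w_max - 1e-12)
  model$means[cand[which.min(model$means[cand])]]
}

#' Copy number from intensity and unit intensity
#'
#' @param granule_intensity Intensities of granules (vectorized).
#' @param unit Intensity of a single molecule (> 0).
#' @return A data frame with `raw` (intensity/unit) and `rounded` (nearest
#'   non-negative integer).
#' @export
copy_number <- function(granule_intensity, unit) {
  if (unit <= 0) stop("unit intensity must be > 0")
  raw <- granule_intensity / unit
  data.frame(raw = raw, rounded = pmax(0L, as.integer(round(raw))))
}

#' Molar concentration from copy number and volume
#'
#' `copies / (N_A * volume)` with Avogadro's number
#' `N_A = 6.02214076e23`.
#'
#' @param copies Molecule count(s).
#' @param volume_liters Volume(s) in litres (> 0).
#' @return Molar concentration (M).
#' @examples
#' molar_concentration(1, 1e-15)  # ~1.66 nM
#' @export
molar_concentration <- function(copies, volume_liters) {
  if (any(volume_liters <= 0)) stop("volume must be > 0")
  copies / (AVOGADRO * volume_liters)
}

#' Sphere volume in litres from a diameter in nm
#'
#' Convenience for converting measured granule diameters to the volumes
#' used in molar-concentration estimates.
#'
#' @param diameter_nm Sphere diameter (nm).
#' @return Volume in litres.
#' @export
sphere_volume_liters <- function(diameter_nm) {
  r_dm <- diameter_nm / 2 * 1e-8  # nm -> dm; 1 L = 1 dm^3
  4 / 3 * pi * r_dm^3
}

#' Fit a linear fluorophore calibration curve
#'
#' Ordinary least squares of mean frame intensity on known molar
#' concentration, as produced by imaging a recombinant-fluorophore dilution
#' ladder under fixed optical settings.
#'
#' @param concentration_M Known molar concentrations (>= 2 distinct).
#' @param mean_intensity Mean frame intensities.
#' @return A `calibration_curve` list: `slope` (intensity per molar),
#'   `intercept`, `r_squared`, `concentration_range`.
#' @export
fit_calibration_curve <- function(concentration_M, mean_intensity) {
  if (length(unique(concentration_M)) < 2) {
    stop("need at least 2 distinct concentrations")
  }
  if (length(concentration_M) != length(mean_intensity)) {
    stop("concentration and intensity vectors must share length")
  }
  fit <- lm(mean_intensity ~ concentration_M)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 concentration_range = range(concentration_M)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(paste0("calibration curve: intensity = %.4g x [M] + %.4g ",
                     "(r^2 = %.4f)\nfitted range: %.3g - %.3g M\n"),
              x$slope, x$intercept, x$r_squared,
              x$concentration_range[1], x$concentration_range[2]))
  invisible(x)
}

#' Protein concentration from a calibration curve
#'
#' Inverts the linear calibration: `(intensity - intercept) / slope`.
#' Values outside the curve's fitted concentration range are flagged as
#' extrapolated.
#'
#' @param granule_mean_intensity Mean granule intensities.
#' @param curve A `calibration_curve` from [fit_calibration_curve()].
#' @return A data frame with `concentration_M` and `extrapolated`.
#' @export
protein_concentration <- function(granule_mean_intensity, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be positive")
  conc <- (granule_mean_intensity - curve$intercept) / curve$slope
  data.frame(concentration_M = conc,
             extrapolated = conc < curve$concentration_range[1] |
               conc > curve$concentration_range[2])
}
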