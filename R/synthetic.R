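# Synthetic reflectance pixels: correlated Gaussian classes around the
# published per-class band means, with an analytic Bayes-accuracy oracle.

# Published per-class mean surface reflectance (rhos) at the seven band
# centres 412/469/555/645/859/1240/2130 nm; the separability of the two
# classes rests almost entirely on the 859 and 1240 nm bands.
SARG_RHOS_MEANS <- rbind(
  without = c(0.131517, 0.134890, 0.141123, 0.124477, 0.227052, 0.207291,
              0.085164),
  with    = c(0.114489, 0.120900, 0.133097, 0.116607, 0.247237, 0.233480,
              0.084166))
colnames(SARG_RHOS_MEANS) <- as.character(SARG_WAVELENGTHS)

#' Configuration for the synthetic pixel generator
#'
#' Two classes of 14-dimensional reflectance vectors (7 rhos + 7 rhot) are
#' drawn as class mean + correlated Gaussian noise.  The default class
#' means are the published per-class rhos band means; top-of-atmosphere
#' (rhot) means default to the rhos means plus a fixed additive atmospheric
#' offset, an explicit stand-in since per-class rhot means were never
#' published.
#'
#' Noise model: for pixel i, band b,
#' `x[i,b] = mu[class,b] + noise_scale * (sqrt(rho)*z[i] + sqrt(1-rho)*e[i,b])`
#' with `z` a per-pixel common factor shared by all 14 bands and `e`
#' idiosyncratic, both standard normal, `rho = band_correlation`.  Each
#' band's marginal standard deviation is exactly `noise_scale`; any two
#' bands of one pixel have correlation `band_correlation`.  Values are
#' clipped to the physical range [0, 1.5].
#'
#' @param seed integer seed; generation is a pure function of it.
#' @param n_per_class pixels per class (default 2250, matching the scale of
#'   the 4,515-pixel study table).
#' @param class_means optional 2 x 14 matrix (rows `without`, `with`;
#'   columns rhos 412..2130 then rhot 412..2130) overriding the defaults.
#' @param noise_scale per-band standard deviation (default 0.02).
#' @param band_correlation common-factor correlation between bands within a
#'   pixel, in [0, 1) (default 0.5).
#' @param rhot_offset additive offset used to derive default rhot means
#'   from the rhos means (default +0.02); ignored when `class_means` is
#'   supplied.
#' @return object of class `sim_config`.
#' @seealso [simulate_pixels()], [bayes_accuracy()]
#' @export
sim_config <- function(seed, n_per_class = 2250L, class_means = NULL,
                       noise_scale = 0.02, band_correlation = 0.5,
                       rhot_offset = 0.02) {
  stopifnot(is_count(n_per_class), noise_scale >= 0,
            band_correlation >= 0, band_correlation < 1)
  if (is.null(class_means)) {
    class_means <- cbind(SARG_RHOS_MEANS, SARG_RHOS_MEANS + rhot_offset)
    colnames(class_means) <- feature_cols()
  } else {
    class_means <- as.matrix(class_means)
    if (!all(dim(class_means) == c(2L, 14L)))
      stop("`class_means` must be a 2 x 14 matrix", call. = FALSE)
    if (is.null(rownames(class_means)))
      rownames(class_means) <- c("without", "with")
    colnames(class_means) <- feature_cols()
  }
  structure(list(seed = as.integer(seed),
                 n_per_class = as.integer(n_per_class),
                 class_means = class_means,
                 noise_scale = noise_scale,
                 band_correlation = band_correlation),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> seed=%d, n_per_class=%d, noise_scale=%g, ",
                     "band_correlation=%g\n"),
              x$seed, x$n_per_class, x$noise_scale, x$band_correlation))
  invisible(x)
}

#' Generate a labeled synthetic pixel table
#'
#' Draws `2 * n_per_class` pixels (class 0 rows first, then class 1) from
#' the Gaussian mixture described in [sim_config()].  Bit-identical for a
#' given config; the caller's RNG state is untouched.
#'
#' @param config a [sim_config()].
#' @return a [spectral_dataset()].
#' @export
simulate_pixels <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_per_class
  if (n == 0L) {
    df <- as.data.frame(matrix(numeric(0), 0L, 14L,
                               dimnames = list(NULL, feature_cols())))
    df$label <- integer(0)
    return(structure(df, band_wavelengths = SARG_WAVELENGTHS,
                     class = c("spectral_dataset", "data.frame")))
  }
  rho <- config$band_correlation
  s <- config$noise_scale
  with_seed(config$seed, {
    blocks <- lapply(c("without", "with"), function(cl) {
      mu <- config$class_means[cl, ]
      z <- stats::rnorm(n)                       # common factor, one per pixel
      e <- matrix(stats::rnorm(n * 14L), n, 14L) # idiosyncratic
      x <- matrix(mu, n, 14L, byrow = TRUE) +
        s * (sqrt(rho) * z + sqrt(1 - rho) * e)
      x
    })
    x <- pmin(pmax(do.call(rbind, blocks), 0), 1.5)
    colnames(x) <- feature_cols()
    df <- as.data.frame(x)
    df$label <- rep(c(0L, 1L), each = n)
    spectral_dataset(df)
  })
}

#' Optimal (Bayes) accuracy of the configured mixture
#'
#' For the equal-covariance, equal-prior two-class Gaussian mixture of
#' [sim_config()], the best possible classifier is linear and its accuracy
#' has the closed form `pnorm(d/2)` where `d` is the Mahalanobis distance
#' between the class means under the common covariance
#' `noise_scale^2 * ((1-rho) I + rho J)`.  Used in the test suite as a
#' ceiling that no trained classifier should meaningfully exceed.
#' Clipping to [0, 1.5] is ignored (the means sit many standard deviations
#' inside the range at realistic noise levels).
#'
#' @param config a [sim_config()].
#' @return accuracy in [0.5, 1]; exactly 1 when `noise_scale = 0` with
#'   distinct means, 0.5 when the class means coincide.
#' @export
bayes_accuracy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  delta <- config$class_means["with", ] - config$class_means["without", ]
  if (all(delta == 0)) return(0.5)
  if (config$noise_scale == 0) return(1.0)
  rho <- config$band_correlation
  p <- length(delta)
  sigma <- config$noise_scale^2 * ((1 - rho) * diag(p) + rho)
  d <- sqrt(drop(crossprod(delta, solve(sigma, delta))))
  stats::pnorm(d / 2)
}
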