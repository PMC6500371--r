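# Floating Algae Index: NIR departure from a red->SWIR linear baseline.

#' Floating Algae Index for one band triple
#'
#' FAI is the NIR reflectance minus the value, at the NIR wavelength, of
#' the straight line joining the red and SWIR reflectances:
#' `FAI = R_nir - [R_red + (R_swir - R_red) * (l_nir - l_red)/(l_swir - l_red)]`.
#' For the MODIS triple (645, 859, 1240 nm) the interpolation factor is
#' 214/595.  Floating vegetation lifts the NIR band above the baseline, so
#' FAI is elevated over algal mats and near zero over clear water.  All
#' arguments are vectorized.
#'
#' @param red reflectance at the red band (645 nm).
#' @param nir reflectance at the near-infrared band (859 nm).
#' @param swir reflectance at the shortwave-infrared band (1240 nm).
#' @param wavelengths band centres in nm, strictly increasing (default
#'   `c(645, 859, 1240)`).
#' @return FAI value(s), dimensionless.
#' @examples
#' fai_pixel(0.2, 0.2, 0.2)       # flat spectrum: 0
#' fai_pixel(0.1, 0.3, 0.1)       # equal red/swir baseline: 0.2
#' @export
fai_pixel <- function(red, nir, swir, wavelengths = c(645, 859, 1240)) {
  stopifnot(length(wavelengths) == 3L, all(diff(wavelengths) > 0))
  f <- (wavelengths[2] - wavelengths[1]) / (wavelengths[3] - wavelengths[1])
  nir - (red + (swir - red) * f)
}

#' Per-pixel FAI over a dataset
#'
#' Applies [fai_pixel()] to the 645/859/1240 nm bands of the requested
#' reflectance family, one value per pixel, order preserved.  Surface
#' reflectance (`rhos`) is the default: it is the atmospherically corrected
#' quantity conventionally fed to FAI; `rhot` is exposed so the choice can
#' be cross-checked.
#'
#' @param ds a [spectral_dataset()] (non-empty).
#' @param band_family `"rhos"` or `"rhot"`.
#' @return numeric vector, `nrow(ds)` long.
#' @export
fai <- function(ds, band_family = c("rhos", "rhot")) {
  band_family <- match.arg(band_family)
  if (nrow(ds) == 0L) stop_nodata("empty dataset: no pixels to compute FAI on")
  df <- as.data.frame(ds)
  fai_pixel(df[[paste0(band_family, "_645")]],
            df[[paste0(band_family, "_859")]],
            df[[paste0(band_family, "_1240")]])
}

#' Summary statistics of a set of FAI values
#'
#' Count, mean, standard deviation (sample, n-1 denominator), minimum,
#' quartiles (linear interpolation between order statistics, the
#' `quantile(type = 7)` convention used by mainstream table-summary
#' tooling), median and maximum.
#'
#' @param values numeric vector of per-pixel FAI values (non-empty, finite).
#' @param class_label optional 0/1 tag carried along for printing.
#' @return object of class `fai_summary`.
#' @export
fai_summary <- function(values, class_label = NA_integer_) {
  if (length(values) == 0L) stop_nodata("no FAI values to summarize")
  stopifnot(all(is.finite(values)))
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(class_label = class_label,
                 n_pixels = length(values),
                 mean = mean(values),
                 std = stats::sd(values),
                 min = min(values),
                 q25 = q[1], median = q[2], q75 = q[3],
                 max = max(values)),
            class = "fai_summary")
}

#' @export
print.fai_summary <- function(x, digits = 6, ...) {
  hdr <- if (is.na(x$class_label)) "FAI summary"
  else sprintf("FAI summary, class %d (%s)", x$class_label,
               if (x$class_label == 1L) "Sargassum" else "no Sargassum")
  cat(hdr, "\n")
  v <- c(pixels = x$n_pixels, mean = x$mean, std = x$std, min = x$min,
         `25%` = x$q25, `50%` = x$median, `75%` = x$q75, max = x$max)
  print(round(v, digits))
  invisible(x)
}

#' Per-class FAI summary table
#'
#' One [fai_summary()] per class, printed in the conventional
#' pixels/mean/std/min/25%/50%/75%/max row order with the Sargassum class
#' first.
#'
#' @inheritParams fai
#' @return object of class `fai_table`: list with elements `with` and
#'   `without`.
#' @export
fai_by_class <- function(ds, band_family = c("rhos", "rhot")) {
  band_family <- match.arg(band_family)
  v <- fai(ds, band_family)
  structure(list(
    with = fai_summary(v[ds$label == 1L], class_label = 1L),
    without = fai_summary(v[ds$label == 0L], class_label = 0L),
    band_family = band_family),
    class = "fai_table")
}

#' @export
print.fai_table <- function(x, digits = 6, ...) {
  cat(sprintf("FAI index per class (%s bands)\n", x$band_family))
  grab <- function(s) c(s$n_pixels, s$mean, s$std, s$min, s$q25, s$median,
                        s$q75, s$max)
  tab <- cbind(`FAI Sargassum` = grab(x$with),
               `FAI without Sargassum` = grab(x$without))
  rownames(tab) <- c("pixels", "mean", "std", "min", "25%", "50%", "75%",
                     "max")
  print(round(tab, digits))
  invisible(x)
}
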