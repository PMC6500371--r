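#' Labeled reflectance-pixel tables
#'
#' A `spectral_dataset` holds one row per 1-km coastal MODIS pixel with 14
#' reflectance attributes -- surface reflectance (`rhos_412 ... rhos_2130`)
#' and top-of-atmosphere reflectance (`rhot_412 ... rhot_2130`) at the seven
#' band centres 412, 469, 555, 645, 859, 1240 and 2130 nm -- plus a binary
#' `label` (1 = Sargassum present, 0 = absent) and optional `lat`, `lon`,
#' `date` metadata.  It is a plain `data.frame` subclass: all the usual
#' subsetting and inspection tools apply.
#'
#' @param df a data.frame with the canonical columns (see Details).
#' @return an object of class `spectral_dataset`.
#' @details Required columns: `rhos_<wl>` and `rhot_<wl>` for the seven
#'   wavelengths, all finite numerics, and `label` in \{0, 1\}.  Optional
#'   metadata columns `lat`, `lon`, `date` may be missing or `NA`; missing
#'   reflectances are rejected (cloudy pixels are assumed discarded
#'   upstream of this table).
#' @seealso [read_pixels()], [simulate_pixels()], [class_counts()],
#'   [band_means()], [validate_pixels()]
#' @export
spectral_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c(feature_cols(), "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df$label <- normalize_labels(df$label)
  rep <- validate_pixels(df)
  bad <- rep$checks[rep$checks$n_offenders > 0L, , drop = FALSE]
  if (nrow(bad)) {
    first <- bad[1L, ]
    stop(sprintf("invalid dataset: check '%s' fails for %d row(s), e.g. row %s",
                 first$check, first$n_offenders,
                 strsplit(first$rows, ",")[[1]][1]), call. = FALSE)
  }
  keep <- c(need, intersect(c("lat", "lon", "date"), names(df)))
  out <- df[, keep, drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            band_wavelengths = SARG_WAVELENGTHS,
            class = c("spectral_dataset", "data.frame"))
}

# Accept {0,1}, {"without","with"}, {FALSE,TRUE} (case-insensitive strings);
# anything else is a validation error.
normalize_labels <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    lx <- tolower(trimws(x))
    map <- c(without = 0L, with = 1L, "false" = 0L, "true" = 1L,
             "0" = 0L, "1" = 1L)
    bad <- !(lx %in% names(map))
    if (any(bad))
      stop("unknown label value(s): ",
           paste(unique(x[bad])[seq_len(min(3L, length(unique(x[bad]))))],
                 collapse = ", "),
           " at row(s) ", paste(utils::head(which(bad), 5L), collapse = ", "),
           call. = FALSE)
    return(unname(map[lx]))
  }
  if (is.numeric(x)) {
    bad <- !(x %in% c(0, 1))
    if (any(bad))
      stop("unknown label value(s) at row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
    return(as.integer(x))
  }
  stop("label column has unsupported type: ", class(x)[1], call. = FALSE)
}

#' Read a labeled reflectance pixel table from delimited text
#'
#' Reads a UTF-8 delimited file (comma by default, tab accepted) with a
#' header row into a [spectral_dataset()].  Because published pixel tables
#' rarely use one canonical set of headers, a `schema` mapping renames the
#' file's columns: a named character vector or list whose names are the
#' canonical column names (`rhos_412`, ..., `label`, `lat`, `lon`, `date`)
#' and whose values are the headers actually present in the file.
#'
#' @param path file to read.
#' @param schema optional named character vector/list mapping canonical
#'   column names to the file's headers; canonical names absent from the
#'   mapping are looked up verbatim.
#' @param delim field delimiter; `NULL` (default) picks `\t` for `.tsv`/
#'   `.tab` files and `,` otherwise.
#' @return a [spectral_dataset()], one pixel per file row, row order
#'   preserved.  Label encodings \{0,1\}, \{"without","with"\} and
#'   \{FALSE,TRUE\} are normalized to 0/1.
#' @export
read_pixels <- function(path, schema = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim))
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"",
                          fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    schema <- unlist(schema)
    missing_src <- setdiff(unname(schema), names(df))
    if (length(missing_src))
      stop("schema refers to column(s) absent from file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    idx <- match(unname(schema), names(df))
    names(df)[idx] <- names(schema)
  }
  need <- c(feature_cols(), "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) {
    # header-only file: an empty, but well-formed, dataset
    empty <- df[, intersect(c(need, "lat", "lon", "date"), names(df)),
                drop = FALSE]
    empty$label <- integer(0)
    for (cc in feature_cols()) empty[[cc]] <- numeric(0)
    return(structure(empty, band_wavelengths = SARG_WAVELENGTHS,
                     class = c("spectral_dataset", "data.frame")))
  }
  for (cc in feature_cols()) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("column '%s' is not numeric at row(s) %s", cc,
                     paste(utils::head(bad, 5L), collapse = ", ")),
             call. = FALSE)
      v <- vn
    }
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-finite reflectance in column '%s' at row(s) %s", cc,
                   paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    df[[cc]] <- v
  }
  spectral_dataset(df)
}

#' Write a pixel table as delimited text
#'
#' Inverse of [read_pixels()]: values survive a write/read round trip to
#' better than 1e-12.
#'
#' @param ds a [spectral_dataset()].
#' @param path output file.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_pixels <- function(ds, path, delim = ",") {
  stopifnot(inherits(ds, "spectral_dataset"))
  df <- as.data.frame(ds)
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-class pixel counts
#'
#' @param ds a [spectral_dataset()] (or data.frame with a 0/1 `label`).
#' @return named integer vector `c(n_with = ..., n_without = ...)`; the two
#'   always sum to the number of pixels.
#' @export
class_counts <- function(ds) {
  stopifnot("label" %in% names(ds))
  c(n_with = sum(ds$label == 1L), n_without = sum(ds$label == 0L))
}

#' Per-class, per-band mean reflectance
#'
#' Arithmetic mean of each of the seven bands of one reflectance family
#' over the pixels of one class -- the row of a class-means table for that
#' family.
#'
#' @param ds a [spectral_dataset()].
#' @param class_label 0 or 1.
#' @param band_family `"rhos"` (surface) or `"rhot"` (top-of-atmosphere).
#' @return an object of class `band_summary`: list with `band_family`,
#'   `class_label`, and `per_band_mean` (named by wavelength in nm).
#' @export
band_means <- function(ds, class_label, band_family = c("rhos", "rhot")) {
  band_family <- match.arg(band_family)
  stopifnot(class_label %in% c(0L, 1L))
  sub <- ds[ds$label == class_label, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop_nodata(sprintf("no pixels with label %d: cannot compute band means",
                        class_label))
  cols <- paste0(band_family, "_", SARG_WAVELENGTHS)
  m <- colMeans(as.matrix(sub[, cols, drop = FALSE]))
  names(m) <- as.character(SARG_WAVELENGTHS)
  structure(list(band_family = band_family,
                 class_label = as.integer(class_label),
                 per_band_mean = m),
            class = "band_summary")
}

#' @export
print.band_summary <- function(x, digits = 6, ...) {
  cat(sprintf("Per-band mean %s reflectance, class %d (%s)\n",
              x$band_family, x$class_label,
              if (x$class_label == 1L) "Sargassum" else "no Sargassum"))
  print(round(x$per_band_mean, digits))
  invisible(x)
}

#' Validate a pixel table without modifying it
#'
#' Report-only invariant checks: every reflectance finite, label in
#' \{0, 1\}, exactly 14 reflectance columns present.  Accepts raw
#' data.frames so that broken inputs can be diagnosed before construction.
#'
#' @param ds a `spectral_dataset` or data.frame with canonical columns.
#' @return object of class `pixel_validation`: `$ok` and a `$checks`
#'   data.frame with per-check offender counts and row indices.
#' @export
validate_pixels <- function(ds) {
  df <- as.data.frame(ds)
  checks <- list()
  for (fam in c("rhos", "rhot")) {
    cols <- intersect(paste0(fam, "_", SARG_WAVELENGTHS), names(df))
    if (length(cols) < 7L) {
      checks[[paste0("columns_", fam)]] <- seq_len(max(1L, nrow(df)))
      next
    }
    m <- as.matrix(df[, cols, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
    checks[[paste0("finite_", fam)]] <- which(!apply(is.finite(m), 1L, all))
  }
  lab <- df[["label"]]
  checks[["label_domain"]] <-
    if (is.null(lab)) seq_len(max(1L, nrow(df)))
    else {
      ok <- tryCatch({
        l2 <- suppressWarnings(normalize_labels(lab)); l2 %in% c(0L, 1L)
      }, error = function(e) NULL)
      if (is.null(ok)) # per-row fallback for mixed/bad encodings
        ok <- vapply(seq_along(lab), function(i)
          isTRUE(tryCatch(normalize_labels(lab[i]) %in% c(0L, 1L),
                          error = function(e) FALSE)),
          logical(1))
      which(!ok)
    }
  tab <- data.frame(
    check = names(checks),
    n_offenders = vapply(checks, length, integer(1)),
    rows = vapply(checks, function(i)
      paste(utils::head(i, 10L), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(ok = all(tab$n_offenders == 0L), checks = tab,
                 n_rows = nrow(df)),
            class = "pixel_validation")
}

#' @export
print.pixel_validation <- function(x, ...) {
  cat(sprintf("Pixel table validation: %d rows, %s\n", x$n_rows,
              if (x$ok) "all checks pass" else "FAILURES found"))
  print(x$checks, row.names = FALSE)
  invisible(x)
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf(
    "<spectral_dataset> %d pixels (%d with Sargassum, %d without), 14 bands\n",
    nrow(x), cc[["n_with"]], cc[["n_without"]]))
  if (nrow(x)) print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' @export
summary.spectral_dataset <- function(object, ...) {
  cc <- class_counts(object)
  means <- list()
  for (fam in c("rhos", "rhot")) for (cl in c(0L, 1L))
    if (cc[[if (cl == 1L) "n_with" else "n_without"]] > 0L)
      means[[paste0(fam, "_class", cl)]] <-
        band_means(object, cl, fam)$per_band_mean
  structure(list(n = nrow(object), counts = cc, means = means),
            class = "summary.spectral_dataset")
}

#' @export
print.summary.spectral_dataset <- function(x, ...) {
  cat("Instances:", x$n, "\n")
  cat("  with Sargassum:   ", x$counts[["n_with"]], "\n")
  cat("  without Sargassum:", x$counts[["n_without"]], "\n")
  if (length(x$means)) {
    cat("Per-class band means:\n")
    print(round(do.call(rbind, x$means), 6))
  }
  invisible(x)
}

# 14-column feature matrix in canonical order [rhos 412..2130, rhot 412..2130]
features <- function(ds) {
  as.matrix(as.data.frame(ds)[, feature_cols(), drop = FALSE])
}
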