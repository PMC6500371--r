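# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# MODIS band centres (nm) used throughout; order is fixed for rhos and rhot.
SARG_WAVELENGTHS <- c(412L, 469L, 555L, 645L, 859L, 1240L, 2130L)

rhos_cols <- function() paste0("rhos_", SARG_WAVELENGTHS)
rhot_cols <- function() paste0("rhot_", SARG_WAVELENGTHS)
feature_cols <- function() c(rhos_cols(), rhot_cols())

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards, so generation is a pure function of seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nodata <- function(msg) {
  stop(structure(class = c("sargnet_nodata_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}
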