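# Shared fixture builders: everything is generated in code at test time.

# Published per-class mean rhos at 412..2130 nm, used as anchor values.
TAB_RHOS_WITHOUT <- c(0.131517, 0.134890, 0.141123, 0.124477, 0.227052,
                      0.207291, 0.085164)
TAB_RHOS_WITH <- c(0.114489, 0.120900, 0.133097, 0.116607, 0.247237,
                   0.233480, 0.084166)

# A small raw data.frame in the canonical schema with arbitrary class sizes.
raw_pixel_df <- function(n_with, n_without, seed = 99) {
  n <- n_with + n_without
  set.seed(seed)
  df <- as.data.frame(matrix(round(runif(n * 14, 0.01, 0.4), 6), n, 14))
  names(df) <- c(paste0("rhos_", c(412, 469, 555, 645, 859, 1240, 2130)),
                 paste0("rhot_", c(412, 469, 555, 645, 859, 1240, 2130)))
  df$label <- rep(c(1L, 0L), c(n_with, n_without))
  df
}

write_pixel_csv <- function(df, path = tempfile(fileext = ".csv"),
                            sep = ",") {
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# Fast training config for smoke-scale fits.
smoke_config <- function(epochs, seed = 1, batch_size = 50, ...) {
  training_config(epochs = epochs, batch_size = batch_size, seed = seed,
                  standardize_inputs = TRUE, ...)
}
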