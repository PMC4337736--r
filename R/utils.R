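#' @keywords internal
"_PACKAGE"

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a stage-level seed from a master seed
#'
#' All randomness in the package flows from one master seed; per-stage seeds
#' are derived deterministically so a stage can be re-run in isolation and
#' reproduce the pipeline's draws. Results stay below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param offset non-negative integer identifying the stage or replicate
#' @return an integer seed
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset))
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(offset) * 16807 + 1) %%
               2147483629)
}

# Write a data.frame as UTF-8 TSV with Unix newlines and full precision.
write_tsv_full <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  txt <- c(paste(colnames(df), collapse = "\t"),
           do.call(paste, c(lapply(df, format_col), sep = "\t")))
  writeLines(txt, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

format_col <- function(x) {
  if (is.double(x)) {
    format(x, digits = 17, trim = TRUE)
  } else {
    as.character(x)
  }
}
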