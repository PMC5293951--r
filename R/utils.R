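#' Derive a stream of child seeds from a master seed
#'
#' Deterministic seed splitting: child seeds are successive states of a
#' Lehmer (MINSTD) generator started at the master seed, so every cell of a
#' grid or every simulated history gets its own reproducible stream without
#' touching R's global generator state. All values stay below 2^31 - 1.
#'
#' @param master Master seed (positive integer).
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  m <- 2147483647
  x <- as.double(master %% m)
  if (x == 0) x <- 1
  out <- integer(n)
  for (i in seq_len(n)) {
    x <- (x * 48271) %% m
    out[i] <- as.integer(x)
  }
  out
}

#' Write a data frame as tab-separated values
#'
#' TSV with a header row, LF line endings and numeric columns formatted to 6
#' significant digits.
#'
#' @param df A data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_tsv6 <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) signif(v, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a tab-separated table and require columns
#' @noRd
read_tsv_cols <- function(path, cols) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("input table %s is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  df
}
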