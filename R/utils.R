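#' Reverse complement of a plain nucleotide sequence
#'
#' Complements A/C/G/T (N maps to N) and reverses. For degenerate IUPAC
#' consensi use [reverse_complement()].
#'
#' @param x character vector of sequences over A,C,G,T,N.
#' @return character vector of reverse-complemented sequences.
#' @keywords internal
revcomp_dna <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1),
         USE.NAMES = FALSE)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x)

#' Write a data frame as TSV with comment header lines
#'
#' All pipeline outputs share this format: `#`-prefixed provenance lines
#' (package version, seed, parameters), then a header row, then tab-separated
#' data with LF line endings. Coordinates in these files are 0-based
#' half-open.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param comments character vector of comment lines (without the leading
#'   `#`).
#' @return invisibly, `path`.
#' @export
write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con, sep = "\n")
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) format(col, digits = 15, trim = TRUE, scientific = NA)
      else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

#' @noRd
read_tsv_commented <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
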