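#' Write a table as CSV with provenance metadata
#'
#' Writes one comment line `# lfpbold seed=<seed> digest=<hash>` followed
#' by a standard one-line-header CSV.  The digest is a deterministic hash
#' of the generating configuration (any R object), so an output file can
#' be matched to the settings that produced it.
#'
#' @param x data frame.
#' @param path output path.
#' @param seed seed recorded in the metadata line (NA if none).
#' @param config object whose digest is recorded (NULL for none).
#' @export
write_lfpbold_csv <- function(x, path, seed = NA, config = NULL) {
  digest <- if (is.null(config)) "none"
            else substream_seed(0, paste(deparse(config), collapse = ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lfpbold seed=%s digest=%s", seed, digest), con)
  write.csv(x, con, row.names = FALSE)
}

#' Read a CSV written by [write_lfpbold_csv()]
#'
#' Plain CSVs without the metadata line are accepted too.
#'
#' @param path input path.
#' @return data frame, with attributes `seed` and `digest` when a
#'   metadata line is present.
#' @export
read_lfpbold_csv <- function(path) {
  first <- readLines(path, n = 1)
  out <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (startsWith(first, "# lfpbold")) {
    m <- regmatches(first, regexec("seed=(\\S+) digest=(\\S+)", first))[[1]]
    if (length(m) == 3) {
      attr(out, "seed") <- m[2]
      attr(out, "digest") <- m[3]
    }
  }
  out
}
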