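#' Read / write BED4 intervals
#'
#' Minimal BED support for interval exchange: columns `chrom`, `start`,
#' `end` (0-based half-open) and an optional `name`.  Extra columns in the
#' file are ignored on read.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  info <- file.info(path)
  if (info$size == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), name = character()))
  }
  x <- read.table(path, sep = "\t", header = FALSE,
                  colClasses = "character", quote = "",
                  comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(x) < 3L) abort("BED file must have at least 3 columns")
  out <- tibble(
    chrom = x[[1L]],
    start = as.integer(x[[2L]]),
    end = as.integer(x[[3L]]),
    name = if (ncol(x) >= 4L) x[[4L]] else NA_character_
  )
  if (any(is.na(out$start)) || any(is.na(out$end)) ||
      any(out$start < 0) || any(out$start >= out$end)) {
    abort("BED intervals must satisfy 0 <= start < end")
  }
  out
}

#' @rdname read_bed
#' @param intervals A tibble with columns `chrom`, `start`, `end` and
#'   optionally `name` (plus, optionally, `score` and `strand` for BED6).
#' @return `write_bed()` returns `path` invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start < 0) || any(intervals$start >= intervals$end)) {
    abort("BED intervals must satisfy 0 <= start < end")
  }
  cols <- list(intervals$chrom, intervals$start, intervals$end)
  if ("name" %in% names(intervals)) {
    cols <- c(cols, list(intervals$name))
    if (all(c("score", "strand") %in% names(intervals))) {
      cols <- c(cols, list(intervals$score, intervals$strand))
    }
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
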