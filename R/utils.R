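# shared internal helpers

# Total length of the union of 0-based half-open intervals.
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  sum(IRanges::width(ir))
}

# Intersection length of two 0-based half-open interval sets.
interval_intersect_length <- function(s1, e1, s2, e2) {
  if (length(s1) == 0L || length(s2) == 0L) return(0L)
  a <- IRanges::reduce(IRanges::IRanges(start = s1 + 1L, end = e1))
  b <- IRanges::reduce(IRanges::IRanges(start = s2 + 1L, end = e2))
  sum(IRanges::width(IRanges::intersect(a, b)))
}

#' Scaffold N50
#'
#' Largest length L such that sequences of length >= L together cover at
#' least half of the total length.
#'
#' @param lengths Positive integer vector of sequence lengths.
#' @return A single number (NA for empty input).
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) return(NA_real_)
  stopifnot(all(lengths > 0))
  srt <- sort(lengths, decreasing = TRUE)
  idx <- which(cumsum(as.numeric(srt)) >= sum(as.numeric(srt)) / 2)[1L]
  srt[idx]
}

# Uppercase a genome-like object into a DNAStringSet, with unique names.
as_genome <- function(x, what = "genome") {
  if (is.character(x)) {
    if (is.null(names(x))) abort(paste0(what, ": sequences must be named"))
    x <- Biostrings::DNAStringSet(toupper(x))
  }
  if (!methods::is(x, "DNAStringSet")) {
    abort(paste0(what, ": expected a DNAStringSet or named character vector"))
  }
  nm <- names(x)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    abort(paste0(what, ": every sequence must be named"))
  }
  if (anyDuplicated(nm)) {
    abort(paste0(what, ": duplicate sequence name '",
                 nm[duplicated(nm)][1L], "'"))
  }
  x
}

genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

genome_strings <- function(genome) {
  setNames(as.character(genome), names(genome))
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}
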