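#' Read a genome from a FASTA file
#'
#' Sequences are uppercased and IUPAC ambiguity codes other than N are
#' replaced by N, so that downstream code only ever sees A/C/G/T/N.
#' Sequence names are the first whitespace-delimited token of each header.
#'
#' @param path Path to a (optionally gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique names.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  seqs <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) {
        abort(paste0("invalid FASTA in '", path, "': ", conditionMessage(e)))
      }
    ),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        abort(paste0("invalid FASTA in '", path, "': non-IUPAC characters (",
                     conditionMessage(w), ")"))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(seqs) == 0L) abort(paste0("empty FASTA file: ", path))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    abort(paste0("duplicate sequence name in '", path, "': '",
                 names(seqs)[duplicated(names(seqs))][1L], "'"))
  }
  gapped <- Biostrings::alphabetFrequency(seqs)[, c("-", "+", "."), drop = FALSE]
  if (any(gapped > 0)) {
    bad <- names(seqs)[which(rowSums(gapped) > 0)[1L]]
    abort(paste0("record '", bad, "' contains gap characters"))
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  Biostrings::replaceAmbiguities(seqs, new = "N")
}

#' Write sequences to a FASTA file
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, filepath = path, width = 70L)
  invisible(path)
}

#' Sequence sizes of a genome
#'
#' One row per sequence, in input order (the `faSize` step of genome
#' preprocessing).
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @return A tibble with columns `name` and `length`.
#' @export
compute_sizes <- function(genome) {
  if (length(genome) == 0L) {
    return(tibble(name = character(), length = integer()))
  }
  genome <- as_genome(genome)
  tibble(name = names(genome), length = Biostrings::width(genome))
}
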