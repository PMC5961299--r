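#' Aligner parameters
#'
#' Scoring and mode parameters for the built-in seed-and-extend local
#' aligner used to place conserved elements on a genome.
#'
#' @param min_identity Minimum alignment identity, `matches / (matches +
#'   misMatches)`, for a locus to be reported (default 0.90, the aligner's
#'   default minimum sequence identity for conserved elements).
#' @param fast_mode Gapless extension only (the `-fastMap` analog).  Limited
#'   to queries of at most 5000 bases; longer queries must be split first.
#' @param match,mismatch Per-base scores (positive numbers; mismatch is
#'   subtracted).
#' @param gap_open,gap_ext Affine gap penalties (positive numbers; a gap of
#'   length L costs `gap_open + L * gap_ext`).
#' @param band_width Half-width, in bases, of the extension band around the
#'   seed diagonals; bounds how much indel drift an alignment can have.
#' @return A list of class `aligner_params`.
#' @export
aligner_params <- function(min_identity = 0.90, fast_mode = FALSE,
                           match = 1L, mismatch = 1L, gap_open = 3L,
                           gap_ext = 1L, band_width = 32L) {
  stopifnot(min_identity > 0, min_identity <= 1, match > 0, mismatch > 0,
            gap_open >= 0, gap_ext >= 0, band_width >= 1)
  structure(
    list(min_identity = min_identity, fast_mode = fast_mode,
         match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext),
         band_width = as.integer(band_width)),
    class = "aligner_params"
  )
}

#' Build a k-mer seed index over a genome
#'
#' Every N-free k-mer sampled at stride `step` is recorded with its
#' positions.  K-mers whose genome-wide occurrence count (counted at every
#' offset) exceeds `occ_threshold` are removed from the index entirely --
#' the analog of excluding over-represented seeds with an `ooc` file.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param k Seed length in bases (4--16).
#' @param step Sampling stride over genome positions.
#' @param occ_threshold Maximum genome-wide count for a k-mer to seed;
#'   `Inf` disables masking.
#' @return An object of class `seed_index`.  It holds an external pointer
#'   and therefore cannot be serialized; rebuild rather than save it.
#' @export
build_index <- function(genome, k = 11L, step = 5L, occ_threshold = Inf) {
  genome <- as_genome(genome)
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L) {
    abort("cannot index an empty genome")
  }
  ptr <- sa_build_index(names(genome), genome_strings(genome),
                        as.integer(k), as.integer(step), occ_threshold)
  structure(
    list(ptr = ptr, k = as.integer(k), step = as.integer(step),
         occ_threshold = occ_threshold, seq_names = names(genome),
         seq_sizes = genome_lengths(genome)),
    class = "seed_index"
  )
}

#' @rdname build_index
#' @param index A `seed_index`.
#' @param kmer A k-mer string to look up.
#' @return `index_lookup()` returns a tibble of `(name, offset)` positions
#'   (0-based) where the k-mer is indexed; empty for masked or absent
#'   k-mers.
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "seed_index"))
  hit <- sa_index_lookup(index$ptr, toupper(kmer))
  tibble(name = index$seq_names[hit$sid], offset = hit$offset)
}

#' @export
print.seed_index <- function(x, ...) {
  info <- sa_index_info(x$ptr)
  cat("seed_index: k=", x$k, " step=", x$step,
      " occ_threshold=", x$occ_threshold,
      " | ", info$n_kmers, " k-mers, ", info$n_positions,
      " positions over ", length(x$seq_names), " sequence(s)\n", sep = "")
  invisible(x)
}

#' Align a query against an indexed genome
#'
#' Both strands are searched (the reverse complement is aligned for "-"
#' records).  Seed hits are clustered by diagonal band into candidate loci
#' and each locus is extended into at most one alignment -- a banded
#' affine-gap local alignment, or a gapless extension in fast mode.  Loci
#' below `min_identity` are discarded.
#'
#' @param query A DNA string (at least `2 * k` bases).
#' @param index A `seed_index` from [build_index()].
#' @param params An [aligner_params()] object.
#' @param qname Query name for the output records.
#' @return A PSL tibble, sorted by `(tName, tStart)`.
#' @export
align_query <- function(query, index, params = aligner_params(),
                        qname = "query") {
  stopifnot(inherits(index, "seed_index"))
  query <- toupper(as.character(query))
  qsize <- nchar(query)
  if (qsize < 2L * index$k) {
    abort(paste0("query '", qname, "' is shorter than 2k = ", 2L * index$k,
                 " bases and cannot be aligned reliably"))
  }
  if (params$fast_mode && qsize > 5000L) {
    abort(paste0("query '", qname, "' is longer than 5000 bases: fast mode ",
                 "is gapless and limited to 5 Kb -- split the query first ",
                 "(see split_long_hce())"))
  }
  recs <- sa_align_query(index$ptr, query, params$min_identity,
                         params$fast_mode, params$match, params$mismatch,
                         params$gap_open, params$gap_ext, params$band_width)
  if (length(recs) == 0L) return(psl_empty())
  rows <- lapply(recs, function(r) {
    if (r$strand == "+") {
      qstart <- r$qStartAligned
      qend <- r$qEndAligned
    } else {
      qstart <- qsize - r$qEndAligned
      qend <- qsize - r$qStartAligned
    }
    tibble(
      matches = r$matches, misMatches = r$misMatches, repMatches = 0L,
      nCount = r$nCount, qNumInsert = r$qNumInsert,
      qBaseInsert = r$qBaseInsert, tNumInsert = r$tNumInsert,
      tBaseInsert = r$tBaseInsert, strand = r$strand, qName = qname,
      qSize = qsize, qStart = qstart, qEnd = qend,
      tName = index$seq_names[r$sid],
      tSize = unname(index$seq_sizes[r$sid]),
      tStart = r$tStart, tEnd = r$tEnd,
      blockCount = length(r$blockSizes),
      blockSizes = list(r$blockSizes), qStarts = list(r$qStarts),
      tStarts = list(r$tStarts)
    )
  })
  out <- bind_rows(rows) %>% arrange(.data$tName, .data$tStart)
  validate_psl(out)
  out
}

#' Align a set of queries
#'
#' Applies [align_query()] to every sequence and canonicalizes the output
#' order by `(qName, tName, tStart)`, so results do not depend on how the
#' queries were partitioned.
#'
#' @param queries A named character vector or [Biostrings::DNAStringSet].
#' @inheritParams align_query
#' @return A PSL tibble.
#' @export
align_queries <- function(queries, index, params = aligner_params()) {
  queries <- genome_strings(as_genome(queries, what = "queries"))
  out <- lapply(names(queries), function(nm) {
    align_query(queries[[nm]], index, params, qname = nm)
  })
  bind_rows(c(list(psl_empty()), out)) %>%
    arrange(.data$qName, .data$tName, .data$tStart)
}
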