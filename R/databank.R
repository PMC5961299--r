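#' @name hce
#' @title Highly conserved element (HCE) sets
#'
#' @description
#' HCE sets are tibbles with one element per row: `hce_id`, `sequence`,
#' and optional source coordinates `src_name`, `src_start`, `src_end` on
#' the genome the elements were originally extracted from.  An HCE
#' *databank* is the subset of a set that places uniquely and perfectly on
#' a chosen reference genome, together with those placements.
NULL

#' Read an HCE set from FASTA (+ optional BED of source coordinates)
#'
#' @param fasta_path Multi-FASTA of element sequences.
#' @param bed_path Optional BED4 file whose `name` column matches the FASTA
#'   ids, giving each element's source coordinates.
#' @return An HCE tibble (see [hce]).
#' @export
read_hce <- function(fasta_path, bed_path = NULL) {
  seqs <- read_fasta(fasta_path)
  out <- tibble(
    hce_id = names(seqs),
    sequence = as.character(seqs),
    src_name = NA_character_,
    src_start = NA_integer_,
    src_end = NA_integer_
  )
  if (!is.null(bed_path)) {
    bed <- read_bed(bed_path)
    m <- match(out$hce_id, bed$name)
    out$src_name <- bed$chrom[m]
    out$src_start <- bed$start[m]
    out$src_end <- bed$end[m]
  }
  out
}

as_hce <- function(hces) {
  stopifnot(all(c("hce_id", "sequence") %in% names(hces)))
  if (anyDuplicated(hces$hce_id)) {
    abort(paste0("duplicate HCE id: '",
                 hces$hce_id[duplicated(hces$hce_id)][1L], "'"))
  }
  for (col in c("src_name", "src_start", "src_end")) {
    if (!col %in% names(hces)) {
      hces[[col]] <- if (col == "src_name") NA_character_ else NA_integer_
    }
  }
  hces
}

#' Drop elements shorter than a minimum length
#'
#' Conserved elements shorter than 40 bp are too unspecific to serve as
#' anchors and are excluded by default.
#'
#' @param hces An HCE tibble.
#' @param min_len Minimum element length in bases.
#' @return The filtered tibble, input order preserved.
#' @export
filter_min_length <- function(hces, min_len = 40L) {
  hces <- as_hce(hces)
  hces[nchar(hces$sequence) >= min_len, , drop = FALSE]
}

#' Split long elements into shorter fragments
#'
#' Elements longer than `max_len` are cut left-to-right into consecutive
#' pieces of `piece` bases.  A final remainder of at least `min_len` bases
#' becomes its own fragment; a shorter remainder is appended to the last
#' piece.  Fragment ids are `<id>__partN` and source coordinates are offset
#' accordingly.  Two splitting regimes are used in practice: breaking
#' elements > 500 bp into 250 bp pieces (which align better), and breaking
#' elements > 5 Kb before gapless fast-mode alignment (which cannot handle
#' longer queries).
#'
#' @param hces An HCE tibble.
#' @param max_len Length above which an element is split.
#' @param piece Fragment length.
#' @param min_len Minimum length for a stand-alone remainder fragment.
#' @return An HCE tibble with long elements replaced by their fragments.
#' @export
split_long_hce <- function(hces, max_len = 500L, piece = 250L,
                           min_len = 40L) {
  stopifnot(piece >= min_len)
  hces <- as_hce(hces)
  rows <- lapply(seq_len(nrow(hces)), function(i) {
    r <- hces[i, ]
    len <- nchar(r$sequence)
    if (len <= max_len) return(r)
    starts <- seq(1L, len, by = piece)
    ends <- pmin(starts + piece - 1L, len)
    nfrag <- length(starts)
    if (nfrag > 1L && (ends[nfrag] - starts[nfrag] + 1L) < min_len) {
      ends[nfrag - 1L] <- ends[nfrag]
      starts <- starts[-nfrag]
      ends <- ends[-nfrag]
      nfrag <- nfrag - 1L
    }
    tibble(
      hce_id = paste0(r$hce_id, "__part", seq_len(nfrag)),
      sequence = substring(r$sequence, starts, ends),
      src_name = r$src_name,
      src_start = if (is.na(r$src_start)) NA_integer_ else
        r$src_start + starts - 1L,
      src_end = if (is.na(r$src_start)) NA_integer_ else
        r$src_start + ends
    )
  })
  bind_rows(rows)
}

#' Build the reference-specific HCE databank
#'
#' Aligns every element to the reference and keeps only elements with
#' exactly one *passing* placement, where passing means 100% identity
#' (zero mismatches within aligned blocks; gaps may slightly lengthen the
#' placement) over at least `min_coverage` of the element length.
#' Elements with two or more passing placements are multi-mappers and are
#' excluded.  With `strict_unique = TRUE` multiplicity is instead counted
#' over all reported alignments, including sub-threshold ones.
#'
#' @param hces An HCE tibble.
#' @param reference Reference genome ([Biostrings::DNAStringSet] or named
#'   character vector), assembled in chromosomes.
#' @param params [aligner_params()] controlling the reference alignment.
#' @param min_coverage Minimum fraction of the element length that must be
#'   aligned (default 0.99).
#' @param strict_unique Count sub-threshold alignments toward multiplicity.
#' @param index Optionally, a prebuilt `seed_index` of the reference.
#' @return An object of class `hce_databank`: entries, their reference
#'   alignments (PSL) and summary statistics.  See also [tidy.hce_databank()].
#' @export
build_databank <- function(hces, reference, params = aligner_params(),
                           min_coverage = 0.99, strict_unique = FALSE,
                           index = NULL) {
  hces <- as_hce(hces)
  reference <- as_genome(reference, what = "reference")
  if (length(reference) == 0L) abort("reference genome is empty")
  if (is.null(index)) index <- build_index(reference)
  hces <- hces[order(hces$hce_id), , drop = FALSE]  # order-independence

  aln <- align_queries(setNames(hces$sequence, hces$hce_id), index, params)
  aln$identity <- psl_identity(aln)
  aln$coverage <- psl_coverage(aln)
  passing <- aln %>%
    filter(.data$identity >= 1, .data$coverage >= min_coverage)

  mult_src <- if (strict_unique) aln else passing
  multiplicity <- table(mult_src$qName)
  n_pass <- table(passing$qName)
  unique_ids <- names(n_pass)[n_pass == 1L &
                                multiplicity[names(n_pass)] == 1L]
  multi_ids <- names(multiplicity)[multiplicity >= 2L &
                                     names(multiplicity) %in% names(n_pass)]

  kept <- passing %>% filter(.data$qName %in% unique_ids)
  entries <- kept %>%
    left_join(hces, by = c(qName = "hce_id")) %>%
    mutate(hce_id = .data$qName, chrom = .data$tName,
           start = .data$tStart, end = .data$tEnd) %>%
    select("hce_id", "sequence", "chrom", "start", "end", "strand",
           "src_name", "src_start", "src_end") %>%
    arrange(.data$chrom, .data$start)
  alignments <- kept %>%
    select(dplyr::all_of(psl_cols)) %>%
    arrange(.data$tName, .data$tStart)

  ref_len <- sum(as.numeric(Biostrings::width(reference)))
  covered <- sum(vapply(split(entries, entries$chrom), function(d) {
    interval_union_length(d$start, d$end)
  }, numeric(1L)))
  lens <- nchar(entries$sequence)
  stats <- list(
    n_input = nrow(hces),
    n_mapped = length(unique(passing$qName)),
    n_unique = nrow(entries),
    n_multi = length(multi_ids),
    total_length = sum(lens),
    min_length = if (length(lens)) min(lens) else NA_integer_,
    max_length = if (length(lens)) max(lens) else NA_integer_,
    median_length = if (length(lens)) median(lens) else NA_real_,
    genome_fraction = covered / ref_len
  )

  structure(
    list(entries = entries, alignments = alignments, stats = stats,
         ref_sizes = compute_sizes(reference), params = params,
         min_coverage = min_coverage, strict_unique = strict_unique),
    class = "hce_databank"
  )
}

#' @export
print.hce_databank <- function(x, ...) {
  s <- x$stats
  cat("hce_databank: ", s$n_unique, " uniquely placed elements (",
      s$n_mapped, " mapped, ", s$n_multi, " multi-mapped, of ", s$n_input,
      " input)\n", sep = "")
  cat(sprintf("  total %d bp | length %s-%s (median %s) | %.2f%% of reference covered\n",
              s$total_length, s$min_length, s$max_length,
              format(s$median_length), 100 * s$genome_fraction))
  invisible(x)
}

#' Tidy and summarize an HCE databank
#'
#' `tidy()` returns the entry table (one row per databank element with its
#' reference placement); `glance()` returns a one-row tibble of the
#' summary statistics (counts, length distribution, and the fraction of
#' the reference covered by placements).
#'
#' @param x An `hce_databank`.
#' @param ... Unused.
#' @export
tidy.hce_databank <- function(x, ...) {
  x$entries
}

#' @rdname tidy.hce_databank
#' @export
glance.hce_databank <- function(x, ...) {
  as_tibble(x$stats)
}

#' Write a databank to disk
#'
#' Emits `<prefix>.fa` (element sequences), `<prefix>.bed` (reference
#' placements), `<prefix>.psl` (reference alignments) and `<prefix>.stats.tsv`.
#'
#' @param databank An `hce_databank`.
#' @param prefix Output path prefix.
#' @return The four paths, invisibly.
#' @export
write_databank <- function(databank, prefix) {
  stopifnot(inherits(databank, "hce_databank"))
  e <- databank$entries
  paths <- paste0(prefix, c(".fa", ".bed", ".psl", ".stats.tsv"))
  write_fasta(setNames(e$sequence, e$hce_id), paths[1L])
  write_bed(tibble(chrom = e$chrom, start = e$start, end = e$end,
                   name = e$hce_id, score = 0L, strand = e$strand),
            paths[2L])
  write_psl(databank$alignments, paths[3L])
  write.table(glance(databank), paths[4L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
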