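#' @name psl
#' @title PSL alignment tables
#'
#' @description
#' Pairwise local alignments are carried through the pipeline as tibbles in
#' PSL (Pattern Space Layout) form: one row per alignment, the standard 21
#' columns, with the three per-block columns (`blockSizes`, `qStarts`,
#' `tStarts`) held as integer list-columns.  All coordinates are 0-based
#' half-open.  For `strand == "-"` the per-block `qStarts` are coordinates
#' on the reversed query, while the top-level `qStart`/`qEnd` are always on
#' the forward query (the standard PSL convention).
NULL

psl_cols <- c(
  "matches", "misMatches", "repMatches", "nCount",
  "qNumInsert", "qBaseInsert", "tNumInsert", "tBaseInsert",
  "strand", "qName", "qSize", "qStart", "qEnd",
  "tName", "tSize", "tStart", "tEnd",
  "blockCount", "blockSizes", "qStarts", "tStarts"
)

#' An empty PSL tibble
#'
#' @return A zero-row tibble with the 21 PSL columns.
#' @export
psl_empty <- function() {
  tibble(
    matches = integer(), misMatches = integer(), repMatches = integer(),
    nCount = integer(), qNumInsert = integer(), qBaseInsert = integer(),
    tNumInsert = integer(), tBaseInsert = integer(), strand = character(),
    qName = character(), qSize = integer(), qStart = integer(),
    qEnd = integer(), tName = character(), tSize = integer(),
    tStart = integer(), tEnd = integer(), blockCount = integer(),
    blockSizes = list(), qStarts = list(), tStarts = list()
  )
}

#' Validate a PSL table
#'
#' Checks the structural invariants of every record: coordinate ordering
#' and bounds, sorted non-overlapping blocks, the block-sum identity
#' `sum(blockSizes) == matches + misMatches + repMatches + nCount`, and
#' consistency of the top-level query span with the block list under the
#' strand convention.
#'
#' @param psl A PSL tibble.
#' @return `psl`, invisibly, or an error naming the first offending record.
#' @export
validate_psl <- function(psl) {
  stopifnot(all(psl_cols %in% names(psl)))
  for (i in seq_len(nrow(psl))) {
    r <- psl[i, ]
    bs <- r$blockSizes[[1L]]
    qs <- r$qStarts[[1L]]
    ts <- r$tStarts[[1L]]
    fail <- function(msg) {
      abort(paste0("invalid PSL record ", i, " (", r$qName, " vs ", r$tName,
                   "): ", msg))
    }
    if (!(r$strand %in% c("+", "-"))) fail("strand must be '+' or '-'")
    if (!(r$qStart < r$qEnd && r$qEnd <= r$qSize)) {
      fail("query coordinates out of order or out of bounds")
    }
    if (!(r$tStart < r$tEnd && r$tEnd <= r$tSize)) {
      fail("target coordinates out of order or out of bounds")
    }
    if (length(bs) != r$blockCount || length(qs) != r$blockCount ||
        length(ts) != r$blockCount) {
      fail("block lists do not match blockCount")
    }
    if (any(bs <= 0)) fail("non-positive block size")
    if (sum(bs) != r$matches + r$misMatches + r$repMatches + r$nCount) {
      fail("sum(blockSizes) != matches + misMatches + repMatches + nCount")
    }
    if (r$blockCount > 1L) {
      if (any(diff(qs) < head(bs, -1L)) || any(diff(ts) < head(bs, -1L))) {
        fail("blocks not sorted or overlapping")
      }
    }
    if (ts[1L] != r$tStart || ts[r$blockCount] + bs[r$blockCount] != r$tEnd) {
      fail("target block span does not match tStart/tEnd")
    }
    if (r$strand == "+") {
      ok <- qs[1L] == r$qStart &&
        qs[r$blockCount] + bs[r$blockCount] == r$qEnd
    } else {
      ok <- qs[1L] == r$qSize - r$qEnd &&
        qs[r$blockCount] + bs[r$blockCount] == r$qSize - r$qStart
    }
    if (!ok) fail("query block span does not match qStart/qEnd under strand")
  }
  invisible(psl)
}

#' Read a PSL file
#'
#' Accepts files with or without the `psLayout version 3` header.
#'
#' @param path Path to a PSL file.
#' @return A validated PSL tibble.
#' @export
read_psl <- function(path) {
  if (!file.exists(path)) abort(paste0("PSL file not found: ", path))
  lines <- readLines(path)
  if (length(lines) > 0L && grepl("^psLayout", lines[1L])) {
    dashes <- grep("^-{10,}", lines)
    if (length(dashes) == 0L) abort("malformed psLayout header")
    lines <- lines[-seq_len(dashes[1L])]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(psl_empty())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21L)) {
    abort(paste0("PSL line ", which(nf != 21L)[1L], " has ",
                 nf[nf != 21L][1L], " fields (expected 21)"))
  }
  m <- do.call(rbind, fields)
  ints <- function(j) as.integer(m[, j])
  split_ints <- function(j) {
    lapply(strsplit(m[, j], ",", fixed = TRUE), as.integer)
  }
  psl <- tibble(
    matches = ints(1), misMatches = ints(2), repMatches = ints(3),
    nCount = ints(4), qNumInsert = ints(5), qBaseInsert = ints(6),
    tNumInsert = ints(7), tBaseInsert = ints(8), strand = m[, 9],
    qName = m[, 10], qSize = ints(11), qStart = ints(12), qEnd = ints(13),
    tName = m[, 14], tSize = ints(15), tStart = ints(16), tEnd = ints(17),
    blockCount = ints(18), blockSizes = split_ints(19),
    qStarts = split_ints(20), tStarts = split_ints(21)
  )
  validate_psl(psl)
  psl
}

#' Write a PSL file
#'
#' Emits headerless tab-separated PSL; round-trips with [read_psl()]
#' byte-for-byte.
#'
#' @param psl A PSL tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psl <- function(psl, path) {
  validate_psl(psl)
  comma <- function(col) {
    vapply(col, function(v) paste0(paste(v, collapse = ","), ","), "")
  }
  lines <- paste(
    psl$matches, psl$misMatches, psl$repMatches, psl$nCount,
    psl$qNumInsert, psl$qBaseInsert, psl$tNumInsert, psl$tBaseInsert,
    psl$strand, psl$qName, psl$qSize, psl$qStart, psl$qEnd,
    psl$tName, psl$tSize, psl$tStart, psl$tEnd,
    psl$blockCount, comma(psl$blockSizes), comma(psl$qStarts),
    comma(psl$tStarts),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Alignment identity and query coverage of PSL records
#'
#' Identity is `matches / (matches + misMatches)` (1 when the denominator
#' is zero, e.g. an all-N alignment); coverage is the fraction of the query
#' inside aligned blocks, `(matches + misMatches + nCount) / qSize`.
#' Gap-penalized identity (in the spirit of BLAT's milliBad score, which
#' charges internal insertions) is available via `gap_penalized = TRUE`.
#'
#' @param psl A PSL tibble.
#' @param gap_penalized Charge query/target insertions in the denominator.
#' @return A numeric vector, one value per record.
#' @export
psl_identity <- function(psl, gap_penalized = FALSE) {
  denom <- psl$matches + psl$misMatches
  if (gap_penalized) denom <- denom + psl$qNumInsert + psl$tNumInsert
  ifelse(denom == 0, 1, psl$matches / denom)
}

#' @rdname psl_identity
#' @export
psl_coverage <- function(psl) {
  (psl$matches + psl$misMatches + psl$nCount) / psl$qSize
}
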