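#' Anchor filtering parameters
#'
#' @param min_identity Minimum alignment identity when mapping databank
#'   elements to the target (default 0.90).  For divergent genome pairs
#'   this can be relaxed to 0.80.
#' @param min_ali Minimum fraction of the element length that must align
#'   (default 0.95; as low as 0.80 for divergent pairs).
#' @return A list of class `anchor_params`.
#' @export
anchor_params <- function(min_identity = 0.90, min_ali = 0.95) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_ali >= 0.5, min_ali <= 1)
  structure(list(min_identity = min_identity, min_ali = min_ali),
            class = "anchor_params")
}

#' Align the databank against the target genome
#'
#' Every databank element is aligned to the target with the built-in
#' aligner at `params$min_identity`; raw records are returned sorted by
#' target position, ready for [filter_anchors()].
#'
#' @param databank An `hce_databank` from [build_databank()].
#' @param target Target (scaffold-level) genome.
#' @param params An [anchor_params()] object.
#' @param aligner An [aligner_params()] object; its `min_identity` is
#'   overridden by `params$min_identity`.
#' @param index Optionally a prebuilt `seed_index` of the target.
#' @return A PSL tibble sorted by `(tName, tStart)`.
#' @export
map_databank <- function(databank, target, params = anchor_params(),
                         aligner = aligner_params(), index = NULL) {
  stopifnot(inherits(databank, "hce_databank"))
  if (nrow(databank$entries) == 0L) abort("databank is empty")
  target <- as_genome(target, what = "target")
  if (length(target) == 0L) abort("target genome is empty")
  aligner$min_identity <- params$min_identity
  if (is.null(index)) {
    index <- build_index(target)
  }
  queries <- setNames(databank$entries$sequence, databank$entries$hce_id)
  align_queries(queries, index, aligner) %>%
    arrange(.data$tName, .data$tStart)
}

#' Filter target alignments into anchors
#'
#' Records covering less than `min_ali` of their element are dropped;
#' elements that still align to two or more target positions are dropped
#' entirely (they are not unique landmarks).  Each surviving element is
#' joined with its reference placement from the databank to form an
#' anchor: one element bridging exactly one reference interval and one
#' target interval.
#'
#' @param records PSL records from [map_databank()].
#' @param databank The `hce_databank` the records were mapped from.
#' @param params An [anchor_params()] object.
#' @param strict_unique Count sub-threshold alignments toward target
#'   multiplicity (off by default, matching [build_databank()]).
#' @return An anchor tibble sorted by `(scaffold, tgt_start)` with columns
#'   `hce_id`, `ref_chrom`, `ref_start`, `ref_end`, `ref_strand`,
#'   `scaffold`, `tgt_start`, `tgt_end`, `tgt_strand`, `identity`,
#'   `coverage`, `scaffold_length`, `chrom_length`.
#' @export
filter_anchors <- function(records, databank, params = anchor_params(),
                           strict_unique = FALSE) {
  stopifnot(inherits(databank, "hce_databank"))
  entries <- databank$entries
  unknown <- setdiff(unique(records$qName), entries$hce_id)
  if (length(unknown) > 0L) {
    abort(paste0("alignment record references an element absent from the ",
                 "databank: '", unknown[1L], "'"))
  }
  if (nrow(records) == 0L) return(anchor_empty())
  records$identity <- psl_identity(records)
  records$coverage <- psl_coverage(records)
  passing <- records %>% filter(.data$coverage >= params$min_ali)
  mult_src <- if (strict_unique) records else passing
  mult <- table(mult_src$qName)
  keep_ids <- names(mult)[mult == 1L]
  surv <- passing %>%
    filter(.data$qName %in% keep_ids) %>%
    group_by(.data$qName) %>% filter(n() == 1L) %>% ungroup()
  anchors <- surv %>%
    left_join(entries, by = c(qName = "hce_id")) %>%
    mutate(
      hce_id = .data$qName,
      ref_chrom = .data$chrom, ref_start = .data$start,
      ref_end = .data$end, ref_strand = .data$strand.y,
      scaffold = .data$tName, tgt_start = .data$tStart,
      tgt_end = .data$tEnd, tgt_strand = .data$strand.x,
      scaffold_length = .data$tSize
    ) %>%
    left_join(databank$ref_sizes, by = c(ref_chrom = "name")) %>%
    rename(chrom_length = "length") %>%
    select("hce_id", "ref_chrom", "ref_start", "ref_end", "ref_strand",
           "scaffold", "tgt_start", "tgt_end", "tgt_strand",
           "identity", "coverage", "scaffold_length", "chrom_length") %>%
    arrange(.data$scaffold, .data$tgt_start)
  anchors
}

anchor_empty <- function() {
  tibble(
    hce_id = character(), ref_chrom = character(), ref_start = integer(),
    ref_end = integer(), ref_strand = character(), scaffold = character(),
    tgt_start = integer(), tgt_end = integer(), tgt_strand = character(),
    identity = numeric(), coverage = numeric(),
    scaffold_length = integer(), chrom_length = integer()
  )
}

#' Transfer anchors onto the reference frame
#'
#' Swaps each anchor into a reference-frame alignment record (query =
#' scaffold, target = chromosome), composing the element's reference and
#' target orientations ("+" x "-" = "-", etc.).  Each anchor yields one
#' gapless block of length `min(ref span, target span)`, start-anchored
#' after orientation; sub-anchor block structure is deliberately
#' collapsed, since chaining only needs the anchor geometry.
#'
#' @param anchors An anchor tibble from [filter_anchors()].
#' @return A PSL tibble with one single-block record per anchor, sorted by
#'   `(tName, qName, tStart)`, suitable for [chain_blocks()].
#' @export
transfer_to_reference <- function(anchors) {
  if (nrow(anchors) == 0L) return(psl_empty())
  strand <- ifelse(anchors$ref_strand == anchors$tgt_strand, "+", "-")
  len <- pmin(anchors$ref_end - anchors$ref_start,
              anchors$tgt_end - anchors$tgt_start)
  t0 <- anchors$ref_start
  q0 <- ifelse(strand == "+", anchors$tgt_start, anchors$tgt_end - len)
  matches <- as.integer(round(anchors$identity * len))
  out <- tibble(
    matches = matches, misMatches = len - matches, repMatches = 0L,
    nCount = 0L, qNumInsert = 0L, qBaseInsert = 0L, tNumInsert = 0L,
    tBaseInsert = 0L, strand = strand, qName = anchors$scaffold,
    qSize = anchors$scaffold_length, qStart = q0, qEnd = q0 + len,
    tName = anchors$ref_chrom, tSize = anchors$chrom_length,
    tStart = t0, tEnd = t0 + len, blockCount = 1L,
    blockSizes = as.list(as.integer(len)),
    qStarts = as.list(as.integer(ifelse(strand == "+", q0,
                                        anchors$scaffold_length - (q0 + len)))),
    tStarts = as.list(as.integer(t0))
  ) %>%
    arrange(.data$tName, .data$qName, .data$tStart)
  validate_psl(out)
  out
}
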