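#' Homologous block sets
#'
#' A block set is a tibble of homologous blocks with columns `scaffold`,
#' `chrom`, `ref_start`, `ref_end`, `q_start`, `q_end`, where the
#' scaffold-side interval is always on the forward scaffold.  Blocks are
#' derived from net fills ([blocks_from_net()]) or from reference-frame
#' PSL records ([blocks_from_psl()]).
#'
#' @param net A `scaf_net`.
#' @param scaffold_sizes Tibble `(name, length)` of scaffold sizes, needed
#'   to convert reversed-query fill coordinates to forward coordinates.
#' @return A block-set tibble.
#' @export
blocks_from_net <- function(net, scaffold_sizes) {
  fills <- net_fills(net)
  if (nrow(fills) == 0L) return(block_set_empty())
  len <- scaffold_sizes$length[match(fills$qName, scaffold_sizes$name)]
  if (anyNA(len)) {
    abort(paste0("scaffold '", fills$qName[which(is.na(len))[1L]],
                 "' missing from scaffold_sizes"))
  }
  tibble(
    scaffold = fills$qName,
    chrom = fills$chrom,
    ref_start = fills$tStart, ref_end = fills$tEnd,
    q_start = ifelse(fills$qStrand == "+", fills$qStart, len - fills$qEnd),
    q_end = ifelse(fills$qStrand == "+", fills$qEnd, len - fills$qStart)
  )
}

#' @rdname blocks_from_net
#' @param psl A PSL tibble with query = scaffold, target = chromosome.
#' @export
blocks_from_psl <- function(psl) {
  if (nrow(psl) == 0L) return(block_set_empty())
  tibble(
    scaffold = psl$qName, chrom = psl$tName,
    ref_start = psl$tStart, ref_end = psl$tEnd,
    q_start = psl$qStart, q_end = psl$qEnd
  )
}

block_set_empty <- function() {
  tibble(scaffold = character(), chrom = character(),
         ref_start = integer(), ref_end = integer(),
         q_start = integer(), q_end = integer())
}

#' Intersecting fraction of homologous blocks
#'
#' Compares a test mapping against a baseline mapping on scaffold
#' coordinates.  For every scaffold in the baseline, `Z` is the number of
#' scaffold bases covered by baseline blocks and `C` the number of bases
#' covered by both mappings (interval intersection after normalizing each
#' set to non-overlapping intervals).  The aggregate statistic is
#' `sum(C) / sum(Z)` over the compared scaffolds; the printed formula
#' "sum of C/Z" read literally is a sum of per-scaffold ratios, which can
#' exceed 1, so the bounded base-weighted form is used as the headline
#' number and the per-scaffold mean ratio is reported alongside.
#'
#' @param test,baseline Block-set tibbles (see [blocks_from_net()]).
#' @param all_baseline Compare against every baseline scaffold (default);
#'   with `FALSE`, only scaffolds present in both mappings are compared.
#' @return An object of class `scaf_fresult`; see [tidy.scaf_fresult()].
#' @export
intersecting_fraction <- function(test, baseline, all_baseline = TRUE) {
  if (nrow(baseline) == 0L) abort("baseline block set is empty")
  scafs <- unique(baseline$scaffold)
  if (!all_baseline) scafs <- intersect(scafs, unique(test$scaffold))
  per <- lapply(scafs, function(s) {
    b <- baseline[baseline$scaffold == s, ]
    t <- test[test$scaffold == s, ]
    Z <- interval_union_length(b$q_start, b$q_end)
    C <- interval_intersect_length(t$q_start, t$q_end, b$q_start, b$q_end)
    tibble(scaffold = s, C = C, Z = Z,
           ratio = if (Z > 0) C / Z else NA_real_)
  })
  per <- bind_rows(per)
  flagged <- per$scaffold[per$Z == 0]
  used <- per[per$Z > 0, ]
  structure(
    list(
      per_scaffold = per,
      n = nrow(used),
      aggregate_F = sum(used$C) / sum(used$Z),
      mean_ratio = mean(used$ratio),
      zero_baseline_scaffolds = flagged,
      definition = "aggregate_F = sum(C)/sum(Z); mean_ratio = mean(C/Z)"
    ),
    class = "scaf_fresult"
  )
}

#' @export
print.scaf_fresult <- function(x, ...) {
  cat(sprintf(
    "intersecting fraction over %d scaffold(s): F = %.4f (mean C/Z = %.4f)\n",
    x$n, x$aggregate_F, x$mean_ratio))
  if (length(x$zero_baseline_scaffolds)) {
    cat("  excluded (baseline Z = 0):",
        length(x$zero_baseline_scaffolds), "scaffold(s)\n")
  }
  invisible(x)
}

#' Tidy and summarize an intersecting-fraction result
#'
#' `tidy()` returns per-scaffold `C`, `Z` and `C/Z`; `glance()` returns a
#' one-row tibble with the aggregate statistic.
#'
#' @param x A `scaf_fresult`.
#' @param ... Unused.
#' @export
tidy.scaf_fresult <- function(x, ...) {
  x$per_scaffold
}

#' @rdname tidy.scaf_fresult
#' @export
glance.scaf_fresult <- function(x, ...) {
  tibble(n = x$n, aggregate_F = x$aggregate_F, mean_ratio = x$mean_ratio,
         n_zero_baseline = length(x$zero_baseline_scaffolds))
}

#' Classify mapping inconsistencies between two reports
#'
#' Compares two [scaffold_report()] tables scaffold by scaffold and emits
#' one row per disagreement: `PARTIAL_SPLIT` when one mapping splits a
#' scaffold across two or more chromosomes while the other assigns a
#' single chromosome (the typical disagreement between an anchor-based
#' mapping and a base-level aligner); `FULL_CONFLICT` when the
#' single-chromosome assignments differ outright; `BOUNDARY` when the
#' assignment agrees but a block end differs by more than
#' `boundary_tol` bases (overlapping adjacent alignments scored
#' differently).
#'
#' @param test_report,baseline_report Tables from [scaffold_report()].
#' @param boundary_tol Tolerance in bases for `BOUNDARY` calls.
#' @return A tibble `(scaffold, class, detail)`, empty when the reports
#'   agree.
#' @export
find_inconsistencies <- function(test_report, baseline_report,
                                 boundary_tol = 1000L) {
  shared <- intersect(unique(test_report$scaffold),
                      unique(baseline_report$scaffold))
  rows <- list()
  for (s in shared) {
    tr <- test_report[test_report$scaffold == s, ]
    br <- baseline_report[baseline_report$scaffold == s, ]
    tc <- sort(unique(tr$chromosome))
    bc <- sort(unique(br$chromosome))
    if (identical(tc, bc)) {
      if (length(tc) == 1L) {
        dstart <- abs(tr$ref_start[1L] - br$ref_start[1L])
        dend <- abs(tr$ref_end[1L] - br$ref_end[1L])
        if (dstart > boundary_tol || dend > boundary_tol) {
          rows[[length(rows) + 1L]] <- tibble(
            scaffold = s, class = "BOUNDARY",
            detail = sprintf("%s: start delta %d, end delta %d",
                             tc, dstart, dend))
        }
      }
      next
    }
    if ((length(tc) >= 2L && length(bc) == 1L && bc %in% tc) ||
        (length(bc) >= 2L && length(tc) == 1L && tc %in% bc)) {
      rows[[length(rows) + 1L]] <- tibble(
        scaffold = s, class = "PARTIAL_SPLIT",
        detail = sprintf("test: {%s}; baseline: {%s}",
                         paste(tc, collapse = ","),
                         paste(bc, collapse = ",")))
    } else {
      rows[[length(rows) + 1L]] <- tibble(
        scaffold = s, class = "FULL_CONFLICT",
        detail = sprintf("test: {%s}; baseline: {%s}",
                         paste(tc, collapse = ","),
                         paste(bc, collapse = ",")))
    }
  }
  if (length(rows) == 0L) {
    return(tibble(scaffold = character(), class = character(),
                  detail = character()))
  }
  bind_rows(rows)
}

#' Scaffold summary statistics
#'
#' Restricted to scaffolds of at least `min_len` bases: counts of mapped
#' and unmapped scaffolds and the mapped-length distribution (total, N50,
#' median, max, min).
#'
#' @param scaffolds Tibble `(name, length)` of all target scaffolds.
#' @param mapped Character vector of mapped scaffold names.
#' @param min_len Minimum scaffold length considered (default 10 Kb).
#' @return A one-row tibble.
#' @export
scaffold_stats <- function(scaffolds, mapped, min_len = 10000L) {
  stopifnot(all(c("name", "length") %in% names(scaffolds)),
            all(scaffolds$length > 0))
  big <- scaffolds[scaffolds$length >= min_len, ]
  is_mapped <- big$name %in% mapped
  ml <- big$length[is_mapped]
  tibble(
    n_considered = nrow(big),
    n_mapped = sum(is_mapped),
    n_unmapped = sum(!is_mapped),
    total_length = sum(as.numeric(big$length)),
    mapped_length = sum(as.numeric(ml)),
    mapped_fraction = if (nrow(big) > 0)
      sum(as.numeric(ml)) / sum(as.numeric(big$length)) else NA_real_,
    n50 = n50(ml),
    median_length = if (length(ml)) median(ml) else NA_real_,
    max_length = if (length(ml)) max(ml) else NA_integer_,
    min_length = if (length(ml)) min(ml) else NA_integer_
  )
}
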