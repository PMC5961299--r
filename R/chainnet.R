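#' Gap scoring model for co-linear chaining
#'
#' Chain scores are `sum(block length) * per_base_score` minus a cost for
#' each inter-block gap.  The gap cost is piecewise-linear in
#' `max(dt, dq)` (the larger of the target- and query-side gaps), with a
#' flat opening surcharge when both sides gap at once.  Two presets are
#' provided: `"loose"`, which joins anchors across larger gaps and is the
#' preset used for anchor-based mapping, and `"medium"` (three-fold
#' steeper), the preset typical for base-level whole-genome chains.  The
#' preset names follow the UCSC `-linearGap` convention; the numeric
#' tables are this package's configuration and are documented defaults,
#' not values taken from elsewhere.
#'
#' @param preset `"loose"` or `"medium"`, or `"custom"` with explicit
#'   `breakpoints`/`slopes`.
#' @param per_base_score Points per aligned base.
#' @param gap_open Opening surcharge applied when `min(dt, dq) > 0`.
#' @param breakpoints Increasing gap sizes at which the slope changes.
#' @param slopes Cost per gap base within each piece.
#' @param max_gap Gap size beyond which blocks are never joined.
#' @return A list of class `gap_model` with a vectorized cost table.
#' @export
linear_gap_model <- function(preset = c("loose", "medium", "custom"),
                             per_base_score = 100,
                             gap_open = 400,
                             breakpoints = c(0, 100, 1000, 10000),
                             slopes = NULL,
                             max_gap = 1e6) {
  preset <- match.arg(preset)
  if (is.null(slopes)) {
    slopes <- switch(preset,
      loose = c(30, 3, 1, 0.3),
      medium = 3 * c(30, 3, 1, 0.3),
      custom = abort("custom gap model requires explicit slopes")
    )
  }
  stopifnot(length(breakpoints) == length(slopes),
            !is.unsorted(breakpoints), breakpoints[1L] == 0,
            all(slopes >= 0), per_base_score > 0, gap_open >= 0)
  cum <- c(0, cumsum(slopes[-length(slopes)] * diff(breakpoints)))
  structure(
    list(preset = preset, per_base_score = per_base_score,
         gap_open = gap_open, breakpoints = breakpoints, slopes = slopes,
         cum = cum, max_gap = max_gap),
    class = "gap_model"
  )
}

#' @rdname linear_gap_model
#' @param model A `gap_model`.
#' @param dt,dq Non-negative gap lengths on the target and query side.
#' @return `gap_cost()` returns the (vectorized) cost in score points;
#'   `gap_cost(model, 0, 0)` is 0.
#' @export
gap_cost <- function(model, dt, dq) {
  stopifnot(inherits(model, "gap_model"), all(dt >= 0), all(dq >= 0))
  g <- pmax(dt, dq)
  i <- findInterval(g, model$breakpoints)
  base <- model$cum[i] + model$slopes[i] * (g - model$breakpoints[i])
  base + ifelse(pmin(dt, dq) > 0, model$gap_open, 0)
}

#' Chaining parameters
#'
#' @param min_score Minimum chain score to keep (default 3000, the
#'   standard chain-construction threshold).
#' @param gap_model A [linear_gap_model()].
#' @param max_gap Override for the model's maximum joinable gap.
#' @return A list of class `chain_params`.
#' @export
chain_params <- function(min_score = 3000,
                         gap_model = linear_gap_model("loose"),
                         max_gap = NULL) {
  stopifnot(min_score >= 0, inherits(gap_model, "gap_model"))
  if (!is.null(max_gap)) gap_model$max_gap <- max_gap
  structure(list(min_score = min_score, gap_model = gap_model),
            class = "chain_params")
}

# strand-adjusted block table from gapless single-block PSL records
blocks_from_psl_records <- function(records) {
  stopifnot(all(records$blockCount == 1L))
  size <- vapply(records$blockSizes, `[`, integer(1L), 1L)
  q0 <- ifelse(records$strand == "+", records$qStart,
               records$qSize - records$qEnd)
  tibble(
    tName = records$tName, tSize = records$tSize,
    qName = records$qName, qSize = records$qSize,
    strand = records$strand,
    t0 = records$tStart, t1 = records$tStart + size,
    q0 = q0, q1 = q0 + size, len = size
  )
}

# maximum-score chains for one (chromosome, scaffold, orientation) group,
# extracted greedily best-first; each block used at most once
chain_group <- function(blk, params) {
  gm <- params$gap_model
  pbs <- gm$per_base_score
  out <- list()
  blk <- blk %>% arrange(.data$t0, .data$q0)
  remaining <- rep(TRUE, nrow(blk))
  while (any(remaining)) {
    idx <- which(remaining)
    b <- blk[idx, ]
    n <- nrow(b)
    dp <- b$len * pbs
    prev <- rep(0L, n)
    if (n > 1L) {
      for (i in 2:n) {
        for (j in 1:(i - 1L)) {
          if (b$t0[i] <= b$t0[j] || b$t1[i] <= b$t1[j] ||
              b$q0[i] <= b$q0[j] || b$q1[i] <= b$q1[j]) next
          dt <- max(0L, b$t0[i] - b$t1[j])
          dq <- max(0L, b$q0[i] - b$q1[j])
          if (max(dt, dq) > gm$max_gap) next
          cand <- dp[j] - gap_cost(gm, dt, dq) + b$len[i] * pbs
          if (cand > dp[i]) { dp[i] <- cand; prev[i] <- j }
        }
      }
    }
    best <- which.max(dp)
    if (dp[best] < params$min_score) break
    path <- integer(0L)
    k <- best
    while (k != 0L) { path <- c(k, path); k <- prev[k] }
    out[[length(out) + 1L]] <- emit_chain(b[path, ], params)
    remaining[idx[path]] <- FALSE
  }
  out
}

# trim overlapping consecutive blocks at the overlap midpoint and build
# the chain row; the stored score re-scores the emitted geometry
emit_chain <- function(b, params) {
  gm <- params$gap_model
  repeat {
    dropped <- FALSE
    if (nrow(b) > 1L) {
      for (i in 1:(nrow(b) - 1L)) {
        o <- max(b$t1[i] - b$t0[i + 1L], b$q1[i] - b$q0[i + 1L], 0L)
        if (o > 0L) {
          a <- ceiling(o / 2); z <- o - a
          b$t1[i] <- b$t1[i] - a; b$q1[i] <- b$q1[i] - a
          b$len[i] <- b$len[i] - a
          b$t0[i + 1L] <- b$t0[i + 1L] + z; b$q0[i + 1L] <- b$q0[i + 1L] + z
          b$len[i + 1L] <- b$len[i + 1L] - z
        }
      }
      bad <- which(b$len <= 0L)
      if (length(bad) > 0L) { b <- b[-bad[1L], ]; dropped <- TRUE }
    }
    if (!dropped) break
  }
  if (nrow(b) == 0L) return(NULL)
  nb <- nrow(b)
  dt <- c(b$t0[-1L] - b$t1[-nb], 0L)
  dq <- c(b$q0[-1L] - b$q1[-nb], 0L)
  score <- sum(b$len) * gm$per_base_score -
    sum(gap_cost(gm, head(dt, -1L), head(dq, -1L)))
  tibble(
    chain_id = NA_integer_, score = score,
    tName = b$tName[1L], tSize = b$tSize[1L],
    tStart = b$t0[1L], tEnd = b$t1[nb],
    qName = b$qName[1L], qSize = b$qSize[1L], qStrand = b$strand[1L],
    qStart = b$q0[1L], qEnd = b$q1[nb],
    blocks = list(tibble(size = b$len, dt = dt, dq = dq))
  )
}

#' Chain co-linear anchor blocks
#'
#' Groups gapless reference-frame alignment blocks by (chromosome,
#' scaffold, orientation) and, within each group, finds maximum-score
#' co-linear chains by sparse dynamic programming: successive blocks must
#' strictly increase in both reference and orientation-adjusted scaffold
#' coordinates, and each gap is charged by the [linear_gap_model()].
#' Chains are extracted greedily best-first (each block belongs to at most
#' one chain), chains scoring below `min_score` are discarded, and any
#' residual overlap between consecutive blocks is trimmed at the overlap
#' midpoint.  Chain ids are assigned in descending score order.
#'
#' @param records A PSL tibble of single-block records (query = scaffold,
#'   target = chromosome), e.g. from [transfer_to_reference()].
#' @param params A [chain_params()] object.
#' @return A chain tibble of class `scaf_chains` (see [chain_net_formats]).
#' @export
chain_blocks <- function(records, params = chain_params()) {
  if (nrow(records) == 0L) return(chain_empty())
  validate_psl(records)
  blk <- blocks_from_psl_records(records)
  groups <- split(blk, paste(blk$tName, blk$qName, blk$strand, sep = "\r"))
  rows <- unlist(lapply(groups, chain_group, params = params),
                 recursive = FALSE)
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(chain_empty())
  chains <- bind_rows(rows) %>%
    filter(.data$score >= params$min_score) %>%
    arrange(desc(.data$score), .data$tName, .data$tStart) %>%
    mutate(chain_id = row_number())
  class(chains) <- c("scaf_chains", class(chains))
  validate_chains(chains)
  chains
}

#' Re-score a chain against a gap model
#'
#' Independent re-scoring of emitted chain geometry:
#' `sum(size) * per_base_score - sum(gap_cost(dt, dq))`.
#'
#' @param chains A chain tibble.
#' @param gap_model A [linear_gap_model()].
#' @return Numeric vector of scores, one per chain.
#' @export
rescore_chains <- function(chains, gap_model = linear_gap_model("loose")) {
  vapply(chains$blocks, function(b) {
    nb <- nrow(b)
    sum(b$size) * gap_model$per_base_score -
      sum(gap_cost(gap_model, b$dt[-nb], b$dq[-nb]))
  }, numeric(1L))
}

# absolute block intervals of one chain row (target and adjusted query)
chain_block_coords <- function(r) {
  b <- r$blocks[[1L]]
  tb <- r$tStart + cumsum(c(0L, head(b$size + b$dt, -1L)))
  qb <- r$qStart + cumsum(c(0L, head(b$size + b$dq, -1L)))
  tibble(tb = tb, te = tb + b$size, qb = qb, qe = qb + b$size)
}

#' Net chains into a per-chromosome hierarchy
#'
#' Greedy by descending score: each chain contributes the pieces of its
#' reference span that fall inside currently unfilled gaps of at least
#' `min_space` bases (pieces are snapped to the chain's aligned bases).
#' Contributed pieces become `fill` nodes; the chain's internal gaps of at
#' least `min_space` bases become `gap` children that later, lower-scoring
#' chains may fill.  Chains contributing nothing are omitted.
#'
#' @param chains A chain tibble from [chain_blocks()].
#' @param ref_sizes Tibble `(name, length)` of reference chromosome sizes
#'   (see [compute_sizes()]).
#' @param min_space Minimum gap size worth filling, in bases.
#' @return A `scaf_net` object.
#' @export
net_chains <- function(chains, ref_sizes, min_space = 25L) {
  stopifnot(all(c("name", "length") %in% names(ref_sizes)))
  chains <- chains %>% arrange(desc(.data$score), .data$chain_id)
  net <- list()
  for (chrom in unique(chains$tName)) {
    size <- ref_sizes$length[match(chrom, ref_sizes$name)]
    if (is.na(size)) abort(paste0("chromosome '", chrom,
                                  "' missing from ref_sizes"))
    sub <- chains[chains$tName == chrom, ]
    # registry of gap nodes and their unfilled sub-intervals
    gap_nodes <- list(`0` = list(id = 0L, parent_fill = NA_integer_,
                                 level = 0L, tStart = 0L, tEnd = size))
    open <- list(list(gap_id = 0L, s = 0L, e = size))
    fills <- list()
    next_gap_id <- 1L
    for (ci in seq_len(nrow(sub))) {
      r <- sub[ci, ]
      bc <- chain_block_coords(r)
      new_open <- list()
      for (o in open) {
        p0 <- max(o$s, r$tStart); p1 <- min(o$e, r$tEnd)
        if (p1 - p0 < min_space) { new_open <- c(new_open, list(o)); next }
        # snap the piece to aligned bases of the chain
        inb <- which(bc$te > p0 & bc$tb < p1)
        if (length(inb) == 0L) { new_open <- c(new_open, list(o)); next }
        f0 <- max(p0, bc$tb[inb[1L]])
        f1 <- min(p1, bc$te[inb[length(inb)]])
        if (f1 - f0 < min_space) { new_open <- c(new_open, list(o)); next }
        gl <- gap_nodes[[as.character(o$gap_id)]]$level
        # query range of the piece via the linear block geometry
        k0 <- inb[1L]; k1 <- inb[length(inb)]
        qlo <- bc$qb[k0] + (f0 - bc$tb[k0])
        qhi <- bc$qb[k1] + (f1 - bc$tb[k1])
        fid <- length(fills) + 1L
        fills[[fid]] <- list(
          id = fid, parent_gap = o$gap_id, level = gl + 1L,
          tStart = f0, tEnd = f1, qName = r$qName, qStrand = r$qStrand,
          qStart = qlo, qEnd = qhi, chain_id = r$chain_id, chrom = chrom
        )
        # unfilled remainders of this gap interval stay open
        if (f0 > o$s) new_open <- c(new_open, list(list(gap_id = o$gap_id,
                                                        s = o$s, e = f0)))
        if (o$e > f1) new_open <- c(new_open, list(list(gap_id = o$gap_id,
                                                        s = f1, e = o$e)))
        # the chain's internal gaps inside the piece become new gap nodes
        if (length(inb) > 1L) {
          for (g in seq_len(length(inb) - 1L)) {
            gs <- bc$te[inb[g]]; ge <- bc$tb[inb[g + 1L]]
            if (ge - gs >= min_space && gs >= f0 && ge <= f1) {
              gid <- next_gap_id; next_gap_id <- next_gap_id + 1L
              gap_nodes[[as.character(gid)]] <- list(
                id = gid, parent_fill = fid, level = gl + 1L,
                tStart = gs, tEnd = ge)
              new_open <- c(new_open, list(list(gap_id = gid, s = gs, e = ge)))
            }
          }
        }
      }
      open <- new_open
    }
    net[[chrom]] <- list(
      chrom = chrom, size = size,
      children = build_net_tree(0L, gap_nodes, fills)
    )
  }
  structure(net, class = "scaf_net")
}

# assemble fill nodes under gap `gid` (recursively)
build_net_tree <- function(gid, gap_nodes, fills) {
  mine <- Filter(function(f) f$parent_gap == gid, fills)
  mine <- mine[order(vapply(mine, function(f) f$tStart, numeric(1L)))]
  lapply(mine, function(f) {
    gaps <- Filter(function(g) identical(g$parent_fill, f$id), gap_nodes)
    gaps <- gaps[order(vapply(gaps, function(g) g$tStart, numeric(1L)))]
    children <- lapply(gaps, function(g) {
      net_node(kind = "gap", level = g$level, tStart = g$tStart,
               tEnd = g$tEnd,
               children = build_net_tree(g$id, gap_nodes, fills))
    })
    net_node(kind = "fill", level = f$level, tStart = f$tStart,
             tEnd = f$tEnd, qName = f$qName, qStrand = f$qStrand,
             qStart = f$qStart, qEnd = f$qEnd, chain_id = f$chain_id,
             children = children)
  })
}

#' Annotate net fills with their syntenic relationship
#'
#' Top-level fills are labeled `"top"`.  Every deeper fill is compared
#' with its nearest ancestor fill: same scaffold and orientation is
#' `"syn"`, same scaffold but flipped orientation is `"inv"`, and a
#' different scaffold is `"nonSyn"`.
#'
#' @param net A `scaf_net`.
#' @return The net with `type_label` set on every fill.
#' @export
annotate_syntenic <- function(net) {
  stopifnot(inherits(net, "scaf_net"))
  label <- function(node, parent_fill) {
    if (node$kind == "fill") {
      node$type_label <- if (is.null(parent_fill)) {
        "top"
      } else if (node$qName == parent_fill$qName) {
        if (node$qStrand == parent_fill$qStrand) "syn" else "inv"
      } else {
        "nonSyn"
      }
      parent_fill <- node
    }
    node$children <- lapply(node$children, label, parent_fill = parent_fill)
    node
  }
  for (chrom in names(net)) {
    net[[chrom]]$children <- lapply(net[[chrom]]$children, label,
                                    parent_fill = NULL)
  }
  net
}

#' Flatten the fill nodes of a net
#'
#' @param net A `scaf_net`.
#' @return A tibble with one row per fill: `chrom`, `level`, `tStart`,
#'   `tEnd`, `qName`, `qStrand`, `qStart`, `qEnd`, `chain_id`,
#'   `type_label`.
#' @export
net_fills <- function(net) {
  stopifnot(inherits(net, "scaf_net"))
  rows <- list()
  walk <- function(node, chrom) {
    if (node$kind == "fill") {
      rows[[length(rows) + 1L]] <<- tibble(
        chrom = chrom, level = node$level, tStart = node$tStart,
        tEnd = node$tEnd, qName = node$qName, qStrand = node$qStrand,
        qStart = node$qStart, qEnd = node$qEnd, chain_id = node$chain_id,
        type_label = node$type_label %||% NA_character_
      )
    }
    for (ch in node$children) walk(ch, chrom)
  }
  for (chromnet in net) for (ch in chromnet$children) walk(ch, chromnet$chrom)
  if (length(rows) == 0L) {
    return(tibble(chrom = character(), level = integer(),
                  tStart = integer(), tEnd = integer(), qName = character(),
                  qStrand = character(), qStart = integer(),
                  qEnd = integer(), chain_id = integer(),
                  type_label = character()))
  }
  bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-scaffold anchoring report
#'
#' One row per (scaffold, chromosome) pair appearing in any net fill:
#' assigned reference span, orientation (majority by aligned length),
#' number of supporting anchors, scaffold length, fraction of the
#' scaffold inside fills, and whether the scaffold is split across
#' chromosomes.  Scaffolds without anchors do not appear.
#'
#' @param net A `scaf_net` (after [annotate_syntenic()] or not).
#' @param anchors The anchor tibble the chains were built from
#'   (see [filter_anchors()]).
#' @return A tibble with columns `scaffold`, `chromosome`, `ref_start`,
#'   `ref_end`, `strand`, `n_anchors`, `scaffold_length`,
#'   `covered_fraction`, `split_flag`.
#' @export
scaffold_report <- function(net, anchors) {
  fills <- net_fills(net)
  if (nrow(fills) == 0L) {
    return(tibble(scaffold = character(), chromosome = character(),
                  ref_start = integer(), ref_end = integer(),
                  strand = character(), n_anchors = integer(),
                  scaffold_length = integer(), covered_fraction = numeric(),
                  split_flag = logical()))
  }
  sizes <- anchors %>% distinct(.data$scaffold, .data$scaffold_length)
  fills <- fills %>%
    left_join(sizes, by = c(qName = "scaffold")) %>%
    mutate(
      fwd_q0 = ifelse(.data$qStrand == "+", .data$qStart,
                      .data$scaffold_length - .data$qEnd),
      fwd_q1 = ifelse(.data$qStrand == "+", .data$qEnd,
                      .data$scaffold_length - .data$qStart)
    )
  n_anch <- anchors %>%
    group_by(scaffold = .data$scaffold, chromosome = .data$ref_chrom) %>%
    summarise(n_anchors = n(), .groups = "drop")
  rep <- fills %>%
    group_by(scaffold = .data$qName, chromosome = .data$chrom) %>%
    summarise(
      ref_start = min(.data$tStart),
      ref_end = max(.data$tEnd),
      strand = {
        w <- tapply(.data$qEnd - .data$qStart, .data$qStrand, sum)
        names(w)[which.max(w)]
      },
      scaffold_length = .data$scaffold_length[1L],
      covered_fraction = interval_union_length(.data$fwd_q0, .data$fwd_q1) /
        .data$scaffold_length[1L],
      .groups = "drop"
    ) %>%
    left_join(n_anch, by = c("scaffold", "chromosome")) %>%
    mutate(n_anchors = ifelse(is.na(.data$n_anchors), 0L, .data$n_anchors)) %>%
    group_by(.data$scaffold) %>%
    mutate(split_flag = dplyr::n_distinct(.data$chromosome) > 1L) %>%
    ungroup() %>%
    select("scaffold", "chromosome", "ref_start", "ref_end", "strand",
           "n_anchors", "scaffold_length", "covered_fraction",
           "split_flag") %>%
    arrange(.data$chromosome, .data$ref_start)
  rep
}
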