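# fixture generators and independent oracles shared across tests

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, positions) {
  v <- strsplit(s, "")[[1]]
  for (p in positions) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  paste(v, collapse = "")
}

# introduce paired substitutions every `block` bases, leaving seedable
# clean runs between them; 2 mutations per 13 bases ~ 85% identity
mutate_blockwise <- function(s, block = 13L, per_block = 2L) {
  n <- nchar(s)
  pos <- unlist(lapply(seq(0L, n - block, by = block), function(b) {
    b + seq_len(per_block)
  }))
  mutate_seq(s, pos)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# plant `pieces` (named character vector) into a random host sequence at
# the given 0-based starts, overwriting the background
plant_genome <- function(len, pieces = character(0), starts = integer(0)) {
  v <- strsplit(rand_seq(len), "")[[1]]
  for (i in seq_along(pieces)) {
    pv <- strsplit(pieces[[i]], "")[[1]]
    v[(starts[i] + 1):(starts[i] + length(pv))] <- pv
  }
  paste(v, collapse = "")
}

# one random, invariant-satisfying PSL record
random_psl_record <- function() {
  strand <- sample(c("+", "-"), 1)
  nb <- sample(1:4, 1)
  sizes <- sample(5:60, nb, replace = TRUE)
  qgaps <- if (nb > 1) sample(0:20, nb - 1, replace = TRUE) else integer(0)
  tgaps <- if (nb > 1) sample(0:20, nb - 1, replace = TRUE) else integer(0)
  qs <- cumsum(c(sample(0:30, 1), head(sizes, -1) + qgaps))
  ts <- cumsum(c(sample(0:30, 1), head(sizes, -1) + tgaps))
  qa_end <- qs[nb] + sizes[nb]
  qsize <- qa_end + sample(0:25, 1)
  tsize <- ts[nb] + sizes[nb] + sample(0:25, 1)
  total <- sum(sizes)
  ncount <- sample(0:min(3, total - 1), 1)
  mis <- sample(0:(total - ncount - 1), 1)
  matches <- total - ncount - mis
  if (strand == "+") {
    qstart <- qs[1]; qend <- qa_end
  } else {
    qstart <- qsize - qa_end; qend <- qsize - qs[1]
  }
  tibble::tibble(
    matches = matches, misMatches = mis, repMatches = 0L, nCount = ncount,
    qNumInsert = sum(qgaps > 0), qBaseInsert = sum(qgaps),
    tNumInsert = sum(tgaps > 0), tBaseInsert = sum(tgaps),
    strand = strand, qName = paste0("q", sample(1e4, 1)),
    qSize = qsize, qStart = qstart, qEnd = qend,
    tName = paste0("t", sample(1e4, 1)), tSize = tsize,
    tStart = ts[1], tEnd = ts[nb] + sizes[nb],
    blockCount = nb, blockSizes = list(as.integer(sizes)),
    qStarts = list(as.integer(qs)), tStarts = list(as.integer(ts))
  )
}

# random gapless single-block reference-frame records for chaining tests,
# all on one chromosome/scaffold/orientation; blocks never overlap in
# either coordinate (overlap trimming is tested separately), but their
# relative order varies so co-linearity is not guaranteed
random_block_instance <- function(n, tsize = 1000000L, qsize = 1000000L) {
  size <- sample(20:200, n, replace = TRUE)
  t0 <- 1000L + cumsum(sample(0:2000, n, replace = TRUE) +
                         c(0L, head(size, -1L)))
  perm <- sample(n)
  q0 <- integer(n)
  cur <- 500L
  for (i in perm) {
    q0[i] <- cur + sample(0:2000, 1)
    cur <- q0[i] + size[i]
  }
  tibble::tibble(
    matches = size, misMatches = 0L, repMatches = 0L, nCount = 0L,
    qNumInsert = 0L, qBaseInsert = 0L, tNumInsert = 0L, tBaseInsert = 0L,
    strand = "+", qName = "scafA", qSize = qsize, qStart = q0,
    qEnd = q0 + size, tName = "chr1", tSize = tsize, tStart = t0,
    tEnd = t0 + size, blockCount = 1L,
    blockSizes = lapply(size, identity),
    qStarts = lapply(q0, identity), tStarts = lapply(t0, identity)
  )
}

# exhaustive chaining oracle: enumerate every co-linear path through the
# blocks (DFS over the precedence DAG) and return the best path score
brute_force_chain_score <- function(records, params) {
  gm <- params$gap_model
  size <- vapply(records$blockSizes, `[`, integer(1), 1)
  q0 <- ifelse(records$strand == "+", records$qStart,
               records$qSize - records$qEnd)
  b <- data.frame(t0 = records$tStart, t1 = records$tStart + size,
                  q0 = q0, q1 = q0 + size, len = size)
  n <- nrow(b)
  can_follow <- function(j, i) {
    if (b$t0[i] <= b$t0[j] || b$t1[i] <= b$t1[j] ||
        b$q0[i] <= b$q0[j] || b$q1[i] <= b$q1[j]) return(FALSE)
    dt <- max(0, b$t0[i] - b$t1[j]); dq <- max(0, b$q0[i] - b$q1[j])
    max(dt, dq) <= gm$max_gap
  }
  link_cost <- function(j, i) {
    gap_cost(gm, max(0, b$t0[i] - b$t1[j]), max(0, b$q0[i] - b$q1[j]))
  }
  best <- -Inf
  extend <- function(last, score) {
    best <<- max(best, score)
    for (i in seq_len(n)) {
      if (can_follow(last, i)) {
        extend(i, score + b$len[i] * gm$per_base_score - link_cost(last, i))
      }
    }
  }
  for (s in seq_len(n)) extend(s, b$len[s] * gm$per_base_score)
  best
}

# reference implementation of the stated netting rule, operating on a
# per-base claim vector: chains (in descending score order) claim the
# unclaimed runs of >= min_space bases inside their span, snapped to
# aligned bases, leaving their own internal gaps of >= min_space open
net_oracle_coverage <- function(chains, ref_sizes, min_space = 25L) {
  chains <- dplyr::arrange(chains, dplyr::desc(score), chain_id)
  out <- list()
  for (chrom in unique(chains$tName)) {
    size <- ref_sizes$length[match(chrom, ref_sizes$name)]
    claimed <- integer(size)  # chain_id claiming each base, 0 = free
    sub <- chains[chains$tName == chrom, ]
    for (ci in seq_len(nrow(sub))) {
      r <- sub[ci, ]
      blk <- r$blocks[[1]]
      bt <- r$tStart + cumsum(c(0L, head(blk$size + blk$dt, -1)))
      be <- bt + blk$size
      aligned <- logical(size)
      for (k in seq_along(bt)) aligned[(bt[k] + 1):be[k]] <- TRUE
      big_gap <- logical(size)
      if (nrow(blk) > 1) {
        for (k in seq_len(nrow(blk) - 1)) {
          if (bt[k + 1] - be[k] >= min_space) {
            big_gap[(be[k] + 1):bt[k + 1]] <- TRUE
          }
        }
      }
      span <- (r$tStart + 1):r$tEnd
      free <- span[claimed[span] == 0L]
      if (length(free) == 0) next
      runs <- split(free, cumsum(c(1L, diff(free) != 1L)))
      for (run in runs) {
        in_aln <- run[aligned[run]]
        if (length(in_aln) == 0) next
        piece <- seq(min(in_aln), max(in_aln))
        if (length(piece) < min_space) next
        take <- piece[!big_gap[piece]]
        claimed[take] <- r$chain_id
      }
    }
    out[[chrom]] <- claimed
  }
  out
}

# per-chain claimed bases implied by a scaf_net object
net_fill_coverage <- function(net, ref_sizes) {
  out <- list()
  for (chromnet in net) {
    size <- chromnet$size
    claimed <- integer(size)
    walk <- function(node) {
      if (node$kind == "fill") {
        claimed[(node$tStart + 1):node$tEnd] <<- node$chain_id
      }
      for (ch in node$children) walk(ch)
    }
    # fills claim their extent; child gap nodes carve it out again, and
    # deeper fills reclaim -- walking depth-first in order achieves this
    walk2 <- function(node) {
      if (node$kind == "fill") {
        claimed[(node$tStart + 1):node$tEnd] <<- node$chain_id
        for (ch in node$children) {
          if (ch$kind == "gap") claimed[(ch$tStart + 1):ch$tEnd] <<- 0L
        }
        for (ch in node$children) walk2(ch)
      } else {
        for (ch in node$children) walk2(ch)
      }
    }
    for (ch in chromnet$children) walk2(ch)
    out[[chromnet$chrom]] <- claimed
  }
  out
}

# direct-definition N50 oracle
n50_oracle <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  min(lengths)
}
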