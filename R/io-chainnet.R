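#' @name chain_net_formats
#' @title UCSC chain and net text layouts
#'
#' @description
#' Chains are tibbles with one row per chain: `chain_id`, `score`, target
#' (`tName`, `tSize`, `tStart`, `tEnd`; target strand is always "+") and
#' query (`qName`, `qSize`, `qStrand`, `qStart`, `qEnd`) coordinates, plus
#' a `blocks` list-column of tibbles `(size, dt, dq)` where `dt`/`dq` are
#' the gaps after each block (0 for the last).  When `qStrand == "-"`,
#' `qStart`/`qEnd` and block offsets are on the reversed query, as in the
#' UCSC chain format.
#'
#' Nets are a per-chromosome hierarchy of `fill` and `gap` nodes (class
#' `scaf_net`); on disk each level of nesting is indented by one extra
#' leading space, as written by chainNet.
NULL

validate_chains <- function(chains) {
  need <- c("chain_id", "score", "tName", "tSize", "tStart", "tEnd",
            "qName", "qSize", "qStrand", "qStart", "qEnd", "blocks")
  stopifnot(all(need %in% names(chains)))
  for (i in seq_len(nrow(chains))) {
    r <- chains[i, ]
    b <- r$blocks[[1L]]
    fail <- function(msg) abort(paste0("invalid chain ", r$chain_id, ": ", msg))
    if (nrow(b) == 0L) fail("no blocks")
    if (any(b$size <= 0)) fail("non-positive block size")
    if (any(b$dt < 0) || any(b$dq < 0)) fail("negative gap")
    if (b$dt[nrow(b)] != 0 || b$dq[nrow(b)] != 0) {
      fail("last block must have zero trailing gaps")
    }
    if (sum(b$size) + sum(b$dt) != r$tEnd - r$tStart) {
      fail("blocks do not sum to the target span")
    }
    if (sum(b$size) + sum(b$dq) != r$qEnd - r$qStart) {
      fail("blocks do not sum to the query span")
    }
  }
  invisible(chains)
}

#' Write chains to a UCSC chain file
#'
#' @param chains A chain tibble (see [chain_net_formats]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  validate_chains(chains)
  out <- character(0L)
  for (i in seq_len(nrow(chains))) {
    r <- chains[i, ]
    b <- r$blocks[[1L]]
    header <- paste("chain", format(r$score, scientific = FALSE, trim = TRUE),
                    r$tName, r$tSize, "+", r$tStart, r$tEnd,
                    r$qName, r$qSize, r$qStrand, r$qStart, r$qEnd,
                    r$chain_id)
    nb <- nrow(b)
    body <- if (nb > 1L) {
      c(paste(b$size[-nb], b$dt[-nb], b$dq[-nb]), as.character(b$size[nb]))
    } else {
      as.character(b$size[1L])
    }
    out <- c(out, header, body, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a UCSC chain file
#'
#' @param path Path to a chain file.
#' @return A chain tibble.
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) abort(paste0("chain file not found: ", path))
  lines <- readLines(path)
  heads <- grep("^chain\\b", lines)
  rows <- vector("list", length(heads))
  for (j in seq_along(heads)) {
    h <- strsplit(lines[heads[j]], "\\s+")[[1L]]
    if (length(h) != 13L) abort(paste0("malformed chain header at line ",
                                       heads[j]))
    i <- heads[j] + 1L
    sizes <- integer(0L); dts <- integer(0L); dqs <- integer(0L)
    while (i <= length(lines) && nzchar(trimws(lines[i]))) {
      f <- as.integer(strsplit(trimws(lines[i]), "\\s+")[[1L]])
      sizes <- c(sizes, f[1L])
      dts <- c(dts, if (length(f) > 1L) f[2L] else 0L)
      dqs <- c(dqs, if (length(f) > 2L) f[3L] else 0L)
      i <- i + 1L
    }
    rows[[j]] <- tibble(
      chain_id = as.integer(h[13L]), score = as.numeric(h[2L]),
      tName = h[3L], tSize = as.integer(h[4L]),
      tStart = as.integer(h[6L]), tEnd = as.integer(h[7L]),
      qName = h[8L], qSize = as.integer(h[9L]), qStrand = h[10L],
      qStart = as.integer(h[11L]), qEnd = as.integer(h[12L]),
      blocks = list(tibble(size = sizes, dt = dts, dq = dqs))
    )
  }
  chains <- if (length(rows)) bind_rows(rows) else chain_empty()
  class(chains) <- c("scaf_chains", class(chains))
  validate_chains(chains)
  chains
}

chain_empty <- function() {
  out <- tibble(
    chain_id = integer(), score = numeric(), tName = character(),
    tSize = integer(), tStart = integer(), tEnd = integer(),
    qName = character(), qSize = integer(), qStrand = character(),
    qStart = integer(), qEnd = integer(), blocks = list()
  )
  class(out) <- c("scaf_chains", class(out))
  out
}

# ---- nets -------------------------------------------------------------

net_node <- function(kind, level, tStart, tEnd, qName = NA_character_,
                     qStrand = NA_character_, qStart = NA_integer_,
                     qEnd = NA_integer_, chain_id = NA_integer_,
                     type_label = NA_character_, children = list()) {
  list(kind = kind, level = level, tStart = tStart, tEnd = tEnd,
       qName = qName, qStrand = qStrand, qStart = qStart, qEnd = qEnd,
       chain_id = chain_id, type_label = type_label, children = children)
}

validate_net_children <- function(children, lo, hi, where) {
  if (length(children) == 0L) return(invisible(TRUE))
  st <- vapply(children, function(x) x$tStart, numeric(1L))
  en <- vapply(children, function(x) x$tEnd, numeric(1L))
  if (any(st < lo) || any(en > hi)) {
    abort(paste0("net node outside its parent interval at ", where))
  }
  fills <- vapply(children, function(x) x$kind == "fill", logical(1L))
  if (sum(fills) > 1L) {
    fs <- sort(st[fills]); fe <- en[fills][order(st[fills])]
    if (any(fs[-1L] < fe[-length(fe)])) {
      abort(paste0("overlapping sibling fills at ", where))
    }
  }
  for (ch in children) {
    validate_net_children(ch$children, ch$tStart, ch$tEnd,
                          paste0(where, " > ", ch$kind, "@", ch$tStart))
  }
  invisible(TRUE)
}

validate_net <- function(net) {
  stopifnot(inherits(net, "scaf_net"))
  for (chromnet in net) {
    validate_net_children(chromnet$children, 0, chromnet$size,
                          chromnet$chrom)
  }
  invisible(net)
}

net_line <- function(node) {
  if (node$kind == "fill") {
    s <- paste("fill", node$tStart, node$tEnd - node$tStart, node$qName,
               node$qStrand, node$qStart, node$qEnd - node$qStart,
               "id", node$chain_id)
    if (!is.na(node$type_label)) s <- paste(s, "type", node$type_label)
    s
  } else {
    paste("gap", node$tStart, node$tEnd - node$tStart)
  }
}

render_net_node <- function(node, depth) {
  lines <- paste0(strrep(" ", depth), net_line(node))
  for (ch in node$children) {
    lines <- c(lines, render_net_node(ch, depth + 1L))
  }
  lines
}

#' Write nets to a UCSC net file
#'
#' @param net A `scaf_net` object (see [chain_net_formats]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_net <- function(net, path) {
  validate_net(net)
  out <- character(0L)
  for (chromnet in net) {
    out <- c(out, paste("net", chromnet$chrom, chromnet$size))
    for (ch in chromnet$children) {
      out <- c(out, render_net_node(ch, 1L))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a UCSC net file
#'
#' @param path Path to a net file.
#' @return A `scaf_net` object.
#' @export
read_net <- function(path) {
  if (!file.exists(path)) abort(paste0("net file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  net <- list()
  # stack of environments holding nodes under construction, by depth
  cur_chrom <- NULL
  stack <- list()
  finish_to_depth <- function(depth) {
    while (length(stack) > depth) {
      node <- stack[[length(stack)]]
      stack[[length(stack)]] <<- NULL
      if (length(stack) > 0L) {
        parent <- stack[[length(stack)]]
        parent$children <- c(parent$children, list(as.list(node)))
        stack[[length(stack)]] <<- parent
      } else {
        cur_chrom$children <<- c(cur_chrom$children, list(as.list(node)))
      }
    }
  }
  flush_chrom <- function() {
    finish_to_depth(0L)
    if (!is.null(cur_chrom)) net[[length(net) + 1L]] <<- cur_chrom
  }
  for (line in lines) {
    if (grepl("^net ", line)) {
      flush_chrom()
      f <- strsplit(line, "\\s+")[[1L]]
      cur_chrom <- list(chrom = f[2L], size = as.integer(f[3L]),
                        children = list())
      next
    }
    depth <- nchar(line) - nchar(sub("^ +", "", line))
    f <- strsplit(trimws(line), "\\s+")[[1L]]
    finish_to_depth(depth - 1L)
    if (f[1L] == "fill") {
      kv <- if (length(f) > 7L) f[8:length(f)] else character(0L)
      attrs <- if (length(kv) >= 2L) {
        setNames(kv[seq(2L, length(kv), by = 2L)],
                 kv[seq(1L, length(kv), by = 2L)])
      } else c()
      node <- net_node(
        kind = "fill", level = (depth + 1L) %/% 2L,
        tStart = as.integer(f[2L]), tEnd = as.integer(f[2L]) + as.integer(f[3L]),
        qName = f[4L], qStrand = f[5L], qStart = as.integer(f[6L]),
        qEnd = as.integer(f[6L]) + as.integer(f[7L]),
        chain_id = if ("id" %in% names(attrs)) as.integer(attrs[["id"]]) else NA_integer_,
        type_label = if ("type" %in% names(attrs)) attrs[["type"]] else NA_character_
      )
    } else if (f[1L] == "gap") {
      node <- net_node(kind = "gap", level = depth %/% 2L,
                       tStart = as.integer(f[2L]),
                       tEnd = as.integer(f[2L]) + as.integer(f[3L]))
    } else {
      abort(paste0("unrecognized net line: ", line))
    }
    stack[[depth]] <- node
  }
  flush_chrom()
  names(net) <- vapply(net, function(x) x$chrom, "")
  class(net) <- "scaf_net"
  validate_net(net)
  net
}
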