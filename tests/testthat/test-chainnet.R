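mk_blocks <- function(t0, q0, size, strand = "+", qsize = 100000L,
                      tsize = 1000000L, qname = "scafA", tname = "chr1") {
  n <- length(t0)
  size <- rep_len(size, n)
  strand <- rep_len(strand, n)
  qs <- ifelse(strand == "+", q0, qsize - (q0 + size))
  tibble::tibble(
    matches = as.integer(size), misMatches = 0L, repMatches = 0L,
    nCount = 0L, qNumInsert = 0L, qBaseInsert = 0L, tNumInsert = 0L,
    tBaseInsert = 0L, strand = strand, qName = qname, qSize = qsize,
    qStart = as.integer(q0), qEnd = as.integer(q0 + size), tName = tname,
    tSize = tsize, tStart = as.integer(t0), tEnd = as.integer(t0 + size),
    blockCount = 1L, blockSizes = lapply(as.integer(size), identity),
    qStarts = lapply(as.integer(qs), identity),
    tStarts = lapply(as.integer(t0), identity)
  )
}

test_that("gap costs are zero at zero, monotone, and charge double-sided opens", {
  gm <- linear_gap_model("loose")
  expect_equal(gap_cost(gm, 0, 0), 0)
  g <- gap_cost(gm, c(10, 100, 1000, 20000), 0)
  expect_true(all(diff(g) > 0))
  expect_equal(gap_cost(gm, 100, 0), 3000)
  expect_equal(gap_cost(gm, 50, 50), 50 * 30 + 400)  # opening surcharge
  med <- linear_gap_model("medium")
  expect_equal(gap_cost(med, 100, 0), 9000)
})

test_that("three co-linear blocks chain together with the hand-computed score", {
  ps <- mk_blocks(t0 = c(1000, 1200, 1400), q0 = c(500, 700, 900), size = 100)
  chains <- chain_blocks(ps)
  expect_equal(nrow(chains), 1L)
  gm <- chain_params()$gap_model
  hand <- 300 * gm$per_base_score - 2 * gap_cost(gm, 100, 100)
  expect_equal(chains$score, hand)
  expect_equal(nrow(chains$blocks[[1]]), 3L)
  # exhaustive enumeration over subsets agrees
  expect_equal(chains$score, brute_force_chain_score(ps, chain_params()))
})

test_that("order-inconsistent blocks are never joined", {
  ps <- mk_blocks(t0 = c(1000, 2000), q0 = c(5000, 1000), size = 300)
  chains <- chain_blocks(ps)
  expect_true(all(vapply(chains$blocks, nrow, integer(1)) == 1L))
  expect_equal(nrow(chains), 2L)  # 300 * 100 = 30000 >= min_score each
})

test_that("chains below min_score are discarded", {
  ps <- mk_blocks(t0 = 1000, q0 = 500, size = 20)
  expect_equal(nrow(chain_blocks(ps)), 0L)  # 2000 < 3000
  expect_equal(nrow(chain_blocks(ps, chain_params(min_score = 1000))), 1L)
})

test_that("stored chain scores equal independent re-scoring", {
  set.seed(50)
  for (i in 1:10) {
    ps <- random_block_instance(sample(3:10, 1))
    chains <- chain_blocks(ps, chain_params(min_score = 0))
    if (nrow(chains) == 0) next
    expect_equal(chains$score, rescore_chains(chains))
  }
})

test_that("DP chaining matches brute-force optimal chaining on small instances", {
  set.seed(51)
  params <- chain_params(min_score = 0)
  for (i in 1:60) {
    ps <- random_block_instance(sample(2:8, 1))
    chains <- chain_blocks(ps, params)
    expect_equal(max(chains$score), brute_force_chain_score(ps, params))
  }
})

test_that("removing a block never increases the best chain score", {
  set.seed(52)
  params <- chain_params(min_score = 0)
  for (i in 1:10) {
    ps <- random_block_instance(6)
    full <- max(chain_blocks(ps, params)$score)
    drop1 <- max(chain_blocks(ps[-sample(6, 1), ], params)$score)
    expect_lte(drop1, full)
  }
})

test_that("overlapping consecutive blocks are trimmed at the overlap midpoint", {
  ps <- mk_blocks(t0 = c(1000, 1080), q0 = c(500, 580), size = 100)
  chains <- chain_blocks(ps, chain_params(min_score = 0))
  expect_equal(nrow(chains), 1L)
  b <- chains$blocks[[1]]
  expect_equal(b$size, c(90L, 90L))
  expect_equal(b$dt, c(0L, 0L))
  expect_equal(chains$tEnd - chains$tStart, sum(b$size))
  expect_silent(write_chain(chains, tempfile()))
})

test_that("a single chain nets as one top-level fill spanning its extent", {
  ps <- mk_blocks(t0 = c(1000, 1500), q0 = c(100, 600), size = 200)
  chains <- chain_blocks(ps)
  sizes <- tibble::tibble(name = "chr1", length = 1000000L)
  net <- net_chains(chains, sizes)
  expect_length(net$chr1$children, 1L)
  top <- net$chr1$children[[1]]
  expect_equal(top$kind, "fill")
  expect_equal(top$level, 1L)
  expect_equal(c(top$tStart, top$tEnd), c(1000L, 1700L))
  # its 300-base internal gap is recorded and open
  expect_length(top$children, 1L)
  expect_equal(top$children[[1]]$kind, "gap")
  expect_equal(c(top$children[[1]]$tStart, top$children[[1]]$tEnd),
               c(1200L, 1500L))
})

test_that("a lower-scoring chain fills a qualifying gap at level two", {
  big <- mk_blocks(t0 = c(1000, 5000), q0 = c(100, 4100), size = 1000)
  small <- mk_blocks(t0 = 2500, q0 = 200, size = 500, qname = "scafB")
  chains <- chain_blocks(dplyr::bind_rows(big, small))
  expect_equal(nrow(chains), 2L)
  sizes <- tibble::tibble(name = "chr1", length = 1000000L)
  net <- net_chains(chains, sizes)
  expect_length(net$chr1$children, 1L)
  gap <- net$chr1$children[[1]]$children[[1]]
  expect_equal(gap$kind, "gap")
  inner <- gap$children[[1]]
  expect_equal(inner$kind, "fill")
  expect_equal(inner$level, 2L)
  expect_equal(inner$qName, "scafB")
  expect_equal(c(inner$tStart, inner$tEnd), c(2500L, 3000L))
})

test_that("a chain wholly covered by higher fills is absent from the net", {
  big <- mk_blocks(t0 = 1000, q0 = 100, size = 2000)
  shadow <- mk_blocks(t0 = 1400, q0 = 300, size = 800, qname = "scafB")
  chains <- chain_blocks(dplyr::bind_rows(big, shadow))
  net <- net_chains(chains, tibble::tibble(name = "chr1", length = 1e6))
  fills <- net_fills(net)
  expect_equal(fills$qName, "scafA")
})

test_that("netting matches the per-base reference implementation on random sets", {
  set.seed(53)
  sizes <- tibble::tibble(name = "chr1", length = 50000L)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    size <- sample(30:400, n, replace = TRUE)
    t0 <- sample.int(48000L, n)
    ps <- mk_blocks(t0 = t0, q0 = sample.int(90000L, n), size = size,
                    qname = sample(paste0("s", 1:3), n, replace = TRUE),
                    tsize = 50000L)
    # per-scaffold groups may chain; keep every chain via min_score 0
    chains <- chain_blocks(ps, chain_params(min_score = 0))
    if (nrow(chains) == 0) next
    net <- net_chains(chains, sizes)
    expect_silent(validate_net(net))
    got <- net_fill_coverage(net, sizes)
    want <- net_oracle_coverage(chains, sizes)
    expect_equal(got, want)
  }
})

test_that("syntenic annotation labels top, syn, inv and nonSyn fills", {
  mk_fill <- function(level, q, strand, chain_id, t0, t1, children = list()) {
    net_node("fill", level, t0, t1, qName = q, qStrand = strand,
             qStart = 0L, qEnd = t1 - t0, chain_id = chain_id,
             children = children)
  }
  gap_with <- function(level, t0, t1, fill) {
    net_node("gap", level, t0, t1, children = list(fill))
  }
  top <- mk_fill(1L, "sA", "+", 1L, 0L, 1000L, children = list(
    gap_with(1L, 100L, 300L, mk_fill(2L, "sA", "+", 2L, 120L, 280L)),
    gap_with(1L, 400L, 600L, mk_fill(2L, "sA", "-", 3L, 420L, 580L)),
    gap_with(1L, 700L, 900L, mk_fill(2L, "sB", "+", 4L, 720L, 880L))
  ))
  net <- structure(list(chr1 = list(chrom = "chr1", size = 2000L,
                                    children = list(top))),
                   class = "scaf_net")
  ann <- annotate_syntenic(net)
  f <- net_fills(ann)
  expect_equal(f$type_label[f$chain_id == 1L], "top")
  expect_equal(f$type_label[f$chain_id == 2L], "syn")
  expect_equal(f$type_label[f$chain_id == 3L], "inv")
  expect_equal(f$type_label[f$chain_id == 4L], "nonSyn")
})

test_that("the scaffold report aggregates fills and supporting anchors", {
  set.seed(54)
  # 12 anchors of one scaffold on chr1, 3 of another on two chromosomes
  t0 <- seq(1000, 34000, by = 3000)
  ps <- mk_blocks(t0 = t0, q0 = t0 - 900, size = 200, qsize = 40000L)
  ps2 <- dplyr::bind_rows(
    mk_blocks(t0 = c(50000, 52000), q0 = c(100, 2100), size = 400,
              qname = "scafB", qsize = 20000L),
    mk_blocks(t0 = c(9000, 11000), q0 = c(8000, 10000), size = 400,
              qname = "scafB", qsize = 20000L, tname = "chr2"))
  all_ps <- dplyr::bind_rows(ps, ps2)
  chains <- chain_blocks(all_ps)
  sizes <- tibble::tibble(name = c("chr1", "chr2"), length = c(1e6, 1e6))
  net <- annotate_syntenic(net_chains(chains, sizes))
  anchors <- tibble::tibble(
    hce_id = paste0("a", seq_len(nrow(all_ps))),
    ref_chrom = all_ps$tName, ref_start = all_ps$tStart,
    ref_end = all_ps$tEnd, ref_strand = "+",
    scaffold = all_ps$qName, tgt_start = all_ps$qStart,
    tgt_end = all_ps$qEnd, tgt_strand = all_ps$strand,
    identity = 1, coverage = 1, scaffold_length = all_ps$qSize,
    chrom_length = 1000000L)
  rep <- scaffold_report(net, anchors)
  a_row <- rep[rep$scaffold == "scafA", ]
  expect_equal(nrow(a_row), 1L)
  expect_equal(a_row$chromosome, "chr1")
  expect_equal(a_row$n_anchors, 12L)
  expect_false(a_row$split_flag)
  b_rows <- rep[rep$scaffold == "scafB", ]
  expect_equal(sort(b_rows$chromosome), c("chr1", "chr2"))
  expect_true(all(b_rows$split_flag))
  # a scaffold absent from the nets is absent from the report
  expect_false("scafC" %in% rep$scaffold)
})
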