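# local Smith-Waterman oracle with the aligner's default scoring
sw_oracle_score <- function(query, window) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    pattern = query, subject = window, type = "local",
    substitutionMatrix = mat, gapOpening = 3, gapExtension = 1,
    scoreOnly = TRUE)
}

test_that("the seed index samples positions, masks over-represented and N k-mers", {
  idx <- build_index(c(s = "ACGTACGT"), k = 4, step = 1)
  hit <- index_lookup(idx, "ACGT")
  expect_equal(hit$offset, c(0L, 4L))
  expect_equal(hit$name, c("s", "s"))

  masked <- build_index(c(s = "ACGTACGT"), k = 4, step = 1,
                        occ_threshold = 1)
  expect_equal(nrow(index_lookup(masked, "ACGT")), 0L)
  expect_equal(nrow(index_lookup(masked, "CGTA")), 1L)

  with_n <- build_index(c(s = "ACGTNACGT"), k = 4, step = 1)
  expect_equal(nrow(index_lookup(with_n, "GTNA")), 0L)

  expect_error(build_index(character(0)), "named")
  expect_error(build_index(c(s = "ACGT"), k = 3), "between 4 and 16")
})

test_that("an exact query yields one record per occurrence", {
  set.seed(5)
  piece <- rand_seq(200)
  g <- c(chr = plant_genome(30000, c(piece, piece), c(4000L, 21000L)))
  idx <- build_index(g)
  res <- align_query(piece, idx, qname = "e")
  full <- res[res$matches == 200, ]
  expect_equal(nrow(full), 2L)
  expect_equal(full$tStart, c(4000L, 21000L))
  expect_equal(full$strand, c("+", "+"))
  expect_equal(full$blockCount, c(1L, 1L))
  expect_equal(full$misMatches, c(0L, 0L))
})

test_that("reverse-complement queries hit the same interval on the minus strand", {
  set.seed(6)
  piece <- rand_seq(200)
  g <- c(chr = plant_genome(30000, piece, 12000L))
  idx <- build_index(g)
  fwd <- align_query(piece, idx, qname = "f")
  rev <- align_query(revcomp(piece), idx, qname = "r")
  fwd <- fwd[fwd$matches == 200, ]
  rev <- rev[rev$matches == 200, ]
  expect_equal(fwd$strand, "+")
  expect_equal(rev$strand, "-")
  expect_equal(rev$tStart, fwd$tStart)
  expect_equal(rev$tEnd, fwd$tEnd)
  expect_equal(rev$qStart, 0L)
  expect_equal(rev$qEnd, 200L)
})

test_that("substituted queries report the planted mismatch structure", {
  set.seed(7)
  piece <- rand_seq(200)
  g <- c(chr = plant_genome(30000, piece, 9000L))
  idx <- build_index(g)
  q <- mutate_seq(piece, seq(10, 200, by = 20))  # 10 substitutions
  res <- align_query(q, idx, qname = "m")
  res <- res[res$tStart < 9200 & res$tEnd > 9000, ]
  expect_equal(nrow(res), 1L)
  expect_equal(res$matches, 190L)
  expect_equal(res$misMatches, 10L)
  expect_equal(psl_identity(res), 0.95)
  # the reported score equals the exhaustive local-alignment optimum on
  # the candidate window
  window <- substr(g[["chr"]], 9000 - 50, 9200 + 50)
  expect_equal(res$matches - res$misMatches, sw_oracle_score(q, window))
})

test_that("alignments with identity below min_identity are discarded", {
  set.seed(8)
  piece <- rand_seq(200)
  g <- c(chr = plant_genome(30000, piece, 9000L))
  idx <- build_index(g)
  q85 <- mutate_blockwise(piece)  # ~85% identity, seedable runs between
  strict <- align_query(q85, idx, aligner_params(min_identity = 0.90), "q")
  strict <- strict[strict$misMatches > 0, ]
  expect_equal(nrow(strict), 0L)
  relaxed <- align_query(q85, idx, aligner_params(min_identity = 0.80), "q")
  relaxed <- relaxed[relaxed$misMatches > 0, ]
  expect_equal(nrow(relaxed), 1L)
  expect_lt(psl_identity(relaxed), 0.90)
  expect_gte(psl_identity(relaxed), 0.80)
})

test_that("identity and coverage follow their PSL definitions", {
  r <- random_psl_record()
  r$matches <- 95L; r$misMatches <- 5L; r$nCount <- 0L
  expect_equal(psl_identity(r), 0.95)
  r2 <- random_psl_record()
  r2$matches <- 190L; r2$misMatches <- 8L; r2$nCount <- 0L; r2$qSize <- 200L
  expect_equal(psl_coverage(r2), 0.99)
  # all-N alignment: identity 1 by convention, coverage counts nCount
  r3 <- random_psl_record()
  r3$matches <- 0L; r3$misMatches <- 0L; r3$nCount <- 50L; r3$qSize <- 100L
  expect_equal(psl_identity(r3), 1)
  expect_equal(psl_coverage(r3), 0.5)
})

test_that("query length limits are enforced with explanatory errors", {
  idx <- build_index(c(s = rand_seq(1000)))
  expect_error(align_query("ACGTACGTACGTACGTACGT", idx), "shorter than 2k")
  long_q <- rand_seq(5001)
  expect_error(align_query(long_q, idx, aligner_params(fast_mode = TRUE)),
               "split the query")
})

test_that("strand symmetry holds over random planted queries", {
  set.seed(9)
  for (i in 1:5) {
    piece <- rand_seq(sample(100:400, 1))
    g <- c(chr = plant_genome(20000, piece, 5000L))
    idx <- build_index(g)
    q <- mutate_seq(piece, sample(nchar(piece), 3))
    fwd <- align_query(q, idx, qname = "q")
    rev <- align_query(revcomp(q), idx, qname = "q")
    flip <- function(s) c(`+` = "-", `-` = "+")[s]
    expect_equal(fwd[, c("tStart", "tEnd", "matches")],
                 rev[, c("tStart", "tEnd", "matches")])
    expect_equal(unname(flip(fwd$strand)), rev$strand)
  }
})

test_that("reported scores match a full Smith-Waterman on small instances", {
  set.seed(10)
  for (i in 1:6) {
    qlen <- sample(c(100, 250, 500), 1)
    piece <- rand_seq(qlen)
    start <- sample(2000:40000, 1)
    g <- c(chr = plant_genome(50000, piece, start))
    idx <- build_index(g)
    # mutations: substitutions plus one small indel
    q <- mutate_seq(piece, sample(qlen, max(1, round(qlen * 0.03))))
    if (i %% 2 == 0) {
      cut <- sample(20:(qlen - 25), 1)
      q <- paste0(substr(q, 1, cut), substr(q, cut + 4, qlen))
    }
    res <- align_query(q, idx, qname = "q")
    res <- res[res$tEnd > start & res$tStart < start + qlen, ]
    expect_equal(nrow(res), 1L)  # the planted locus is never missed
    window <- substr(g[["chr"]], max(1, start - 60), start + qlen + 60)
    oracle <- sw_oracle_score(q, window)
    score <- res$matches - res$misMatches -
      3 * (res$qNumInsert + res$tNumInsert) -
      (res$qBaseInsert + res$tBaseInsert)
    expect_gte(score, oracle - 3)  # within one gap-open of the optimum
    expect_lte(score, oracle)
  }
})

test_that("fast-mode output is a gapless subset of default-mode output", {
  set.seed(11)
  piece <- rand_seq(300)
  g <- c(chr = plant_genome(20000, piece, 8000L))
  idx <- build_index(g)
  q <- mutate_seq(piece, c(50, 150, 250))
  full <- align_query(q, idx, aligner_params(), "q")
  fast <- align_query(q, idx, aligner_params(fast_mode = TRUE), "q")
  expect_true(all(fast$blockCount == 1L))
  key <- function(d) paste(d$tName, d$tStart, d$tEnd, d$strand)
  gapless_full <- full[full$blockCount == 1L, ]
  expect_true(all(key(fast) %in% key(gapless_full)))
})

test_that("results are independent of query partitioning", {
  set.seed(12)
  pieces <- setNames(vapply(rep(150, 4), rand_seq, ""), paste0("h", 1:4))
  g <- c(chr = plant_genome(30000, pieces, c(2000L, 9000L, 15000L, 22000L)))
  idx <- build_index(g)
  all_at_once <- align_queries(pieces, idx)
  one_by_one <- dplyr::bind_rows(lapply(sample(names(pieces)), function(n) {
    align_query(pieces[[n]], idx, qname = n)
  })) |> dplyr::arrange(qName, tName, tStart)
  expect_equal(all_at_once, one_by_one)
})
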