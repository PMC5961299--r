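# build a small databank + target pair with known planted structure
anchoring_fixture <- function(seed = 30) {
  set.seed(seed)
  pieces <- vapply(rep(200, 5), rand_seq, "")
  ref <- c(chr1 = plant_genome(20000, pieces[1:3], c(1000L, 5000L, 9000L)),
           chr2 = plant_genome(20000, pieces[4:5], c(2000L, 8000L)))
  hces <- tibble::tibble(hce_id = paste0("h", 1:5), sequence = pieces)
  db <- build_databank(hces, ref)
  list(pieces = pieces, ref = ref, hces = hces, db = db)
}

test_that("databank elements map to their planted target loci", {
  fx <- anchoring_fixture()
  tgt <- c(scafA = plant_genome(12000, fx$pieces[1:2], c(500L, 6000L)),
           scafB = plant_genome(8000, fx$pieces[4], 3000L))
  rec <- map_databank(fx$db, tgt)
  full <- rec[psl_coverage(rec) >= 0.95, ]
  expect_equal(sort(unique(full$qName)), c("h1", "h2", "h4"))
  expect_equal(full$tName[full$qName == "h4"], "scafB")
  expect_true(all(psl_identity(full) == 1))
  # h3/h5 absent from target: no high-coverage records
  expect_false(any(c("h3", "h5") %in% full$qName))
})

test_that("identity relaxation recovers diverged loci", {
  fx <- anchoring_fixture(31)
  diverged <- mutate_blockwise(fx$pieces[1])  # ~85% identity
  tgt <- c(scafA = plant_genome(10000, diverged, 4000L))
  strict <- map_databank(fx$db, tgt, anchor_params(min_identity = 0.90))
  expect_equal(sum(strict$qName == "h1" & strict$misMatches > 0), 0L)
  relaxed <- map_databank(fx$db, tgt, anchor_params(min_identity = 0.80,
                                                    min_ali = 0.80))
  hit <- relaxed[relaxed$qName == "h1" & relaxed$misMatches > 0, ]
  expect_equal(nrow(hit), 1L)
  expect_lt(psl_identity(hit), 0.90)
})

test_that("anchors require coverage and target uniqueness", {
  fx <- anchoring_fixture(32)
  # h1 planted twice in the target, h2 planted truncated (86% coverage)
  trunc <- substr(fx$pieces[2], 1, 172)
  tgt <- c(scafA = plant_genome(12000, c(fx$pieces[1], trunc), c(500L, 6000L)),
           scafB = plant_genome(8000, c(fx$pieces[1], fx$pieces[4]),
                                c(1000L, 5000L)))
  rec <- map_databank(fx$db, tgt)
  anchors <- filter_anchors(rec, fx$db)
  expect_equal(anchors$hce_id, "h4")   # h1 multi-maps, h2 undercovers
  relaxed <- filter_anchors(rec, fx$db, anchor_params(min_ali = 0.80))
  expect_setequal(relaxed$hce_id, c("h2", "h4"))
  # anchors come back sorted by target position
  expect_equal(anchors, dplyr::arrange(anchors, scaffold, tgt_start))
})

test_that("unknown alignment ids are a consistency error", {
  fx <- anchoring_fixture(33)
  tgt <- c(scafA = plant_genome(9000, fx$pieces[1], 2000L))
  rec <- map_databank(fx$db, tgt)
  rec$qName[1] <- "mystery"
  expect_error(filter_anchors(rec, fx$db), "absent from the databank")
})

test_that("ten planted elements yield ten anchors in target order", {
  set.seed(34)
  pieces <- vapply(rep(150, 10), rand_seq, "")
  ref <- c(chr1 = plant_genome(40000, pieces,
                               as.integer(seq(1000, 35000, length.out = 10))))
  db <- build_databank(tibble::tibble(hce_id = paste0("h", 1:10),
                                      sequence = pieces), ref)
  tgt_starts <- as.integer(seq(500, 26000, length.out = 10))
  tgt <- c(scaf = plant_genome(30000, pieces[sample(10)], tgt_starts))
  anchors <- filter_anchors(map_databank(db, tgt), db)
  expect_equal(nrow(anchors), 10L)
  expect_equal(anchors$tgt_start, sort(anchors$tgt_start))
  expect_equal(anyDuplicated(anchors$hce_id), 0L)
})

test_that("transfer composes placements into reference-frame records", {
  a <- tibble::tibble(
    hce_id = "h1", ref_chrom = "chr1", ref_start = 1000L, ref_end = 1200L,
    ref_strand = "+", scaffold = "scaf7", tgt_start = 500L, tgt_end = 700L,
    tgt_strand = "+", identity = 1, coverage = 1,
    scaffold_length = 5000L, chrom_length = 100000L
  )
  p <- transfer_to_reference(a)
  expect_equal(p$tName, "chr1")
  expect_equal(c(p$tStart, p$tEnd), c(1000L, 1200L))
  expect_equal(p$qName, "scaf7")
  expect_equal(c(p$qStart, p$qEnd), c(500L, 700L))
  expect_equal(p$strand, "+")
  expect_equal(p$blockSizes[[1]], 200L)

  # opposite target orientation: "-" record with reversed-query starts
  b <- a
  b$tgt_strand <- "-"
  pb <- transfer_to_reference(b)
  expect_equal(pb$strand, "-")
  expect_equal(pb$qStarts[[1]], 5000L - 700L)
  expect_equal(c(pb$qStart, pb$qEnd), c(500L, 700L))

  # both placements reversed compose back to "+"
  d <- b
  d$ref_strand <- "-"
  expect_equal(transfer_to_reference(d)$strand, "+")

  # unequal spans: the shorter span wins, start-anchored
  e <- a
  e$tgt_end <- 697L
  pe <- transfer_to_reference(e)
  expect_equal(pe$blockSizes[[1]], 197L)
  expect_equal(c(pe$tStart, pe$tEnd), c(1000L, 1197L))
})

test_that("transfer preserves anchor count and id uniqueness", {
  fx <- anchoring_fixture(35)
  tgt <- c(scafA = plant_genome(12000, fx$pieces[c(1, 3)], c(700L, 7000L)),
           scafB = plant_genome(9000, revcomp(fx$pieces[4]), 2500L))
  anchors <- filter_anchors(map_databank(fx$db, tgt), fx$db)
  p <- transfer_to_reference(anchors)
  expect_equal(nrow(p), nrow(anchors))
  expect_equal(anyDuplicated(paste(p$qName, p$tStart)), 0L)
  # the reverse-complement planting comes through as a "-" record
  expect_equal(p$strand[p$qName == "scafB"], "-")
  expect_silent(validate_psl(p))
})

test_that("relaxing thresholds never loses anchors", {
  set.seed(36)
  pieces <- vapply(rep(180, 8), rand_seq, "")
  ref <- c(chr1 = plant_genome(30000, pieces,
                               as.integer(seq(1000, 26000, length.out = 8))))
  db <- build_databank(tibble::tibble(hce_id = paste0("h", 1:8),
                                      sequence = pieces), ref)
  # target with variable divergence per element
  mut <- lapply(1:8, function(i) {
    mutate_seq(pieces[i], sample(180, round(180 * (i - 1) * 0.02)))
  })
  tgt <- c(scaf = plant_genome(35000, unlist(mut),
                               as.integer(seq(800, 30000, length.out = 8))))
  n_anchors <- function(mi, ma) {
    idx <- build_index(tgt)
    rec <- map_databank(db, tgt, anchor_params(mi, ma), index = idx)
    nrow(filter_anchors(rec, db, anchor_params(mi, ma)))
  }
  strict <- n_anchors(0.90, 0.95)
  relaxed <- n_anchors(0.80, 0.80)
  expect_gte(relaxed, strict)
  expect_gt(relaxed, 0)
})
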