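# small, fast simulation settings used across these tests
tiny_params <- function(seed = 1, ...) {
  sim_params(seed = seed, n_chromosomes = 2, chromosome_length = 1.5e5,
             n_hce = 60, hce_spacing_min = 300, n_inversions = 1,
             n_translocations = 1, inversion_len_range = c(1e4, 3e4),
             translocation_len_range = c(8e3, 2e4),
             scaffold_n50_target = 2e4, ...)
}

test_that("simulation is fully deterministic under a fixed seed", {
  s1 <- simulate_genome_pair(tiny_params(seed = 5))
  s2 <- simulate_genome_pair(tiny_params(seed = 5))
  expect_identical(as.character(s1$reference), as.character(s2$reference))
  expect_identical(as.character(s1$target), as.character(s2$target))
  expect_identical(s1$truth$scaffolds, s2$truth$scaffolds)
  s3 <- simulate_genome_pair(tiny_params(seed = 6))
  expect_false(identical(as.character(s1$reference),
                         as.character(s3$reference)))
})

test_that("duplicated elements get a second placement in the BED", {
  p <- sim_params(seed = 2, n_chromosomes = 2, chromosome_length = 3e5,
                  n_hce = 100, dup_fraction = 0.05, repeat_fraction = 0,
                  hce_spacing_min = 300)
  ref <- generate_reference(p)
  expect_equal(nrow(ref$placements), 105L)
  expect_equal(nrow(ref$hce), 100L)
  twice <- table(ref$placements$hce_id)
  expect_equal(sum(twice == 2), 5L)
  # the two copies carry identical sequence
  for (did in names(twice)[twice == 2]) {
    pls <- ref$placements[ref$placements$hce_id == did, ]
    s <- vapply(seq_len(2), function(i) {
      substr(as.character(ref$genome[[pls$chrom[i]]]),
             pls$start[i] + 1, pls$end[i])
    }, "")
    expect_equal(s[1], s[2])
  }
})

test_that("planted elements respect the minimum spacing", {
  p <- tiny_params(seed = 3)
  ref <- generate_reference(p)
  for (ch in unique(ref$placements$chrom)) {
    pl <- dplyr::arrange(ref$placements[ref$placements$chrom == ch, ], start)
    if (nrow(pl) > 1) {
      gaps <- pl$start[-1] - pl$end[-nrow(pl)]
      expect_true(all(gaps >= p$hce_spacing_min))
    }
  }
})

test_that("a zero-rate evolution reproduces the reference exactly", {
  p <- sim_params(seed = 4, n_chromosomes = 2, chromosome_length = 1e5,
                  n_hce = 40, background_divergence = 1e-9,
                  hce_divergence = 0, indel_rate = 0, hce_indel_rate = 0,
                  n_inversions = 0, n_translocations = 0,
                  scaffold_n50_target = 4e5, hce_spacing_min = 300)
  sim <- simulate_genome_pair(p)
  expect_equal(length(sim$target), 2L)
  tgt <- sort(as.character(sim$target))
  ref <- sort(as.character(sim$reference))
  expect_equal(unname(tgt), unname(ref))
  expect_true(all(sim$truth$scaffolds$orientation == "+"))
  expect_true(all(sim$truth$hce_map$frac_intact == 1))
})

test_that("realized divergence matches the nominal rates within 3 SE", {
  p <- sim_params(seed = 7, n_chromosomes = 1, chromosome_length = 4e5,
                  n_hce = 150, background_divergence = 0.08,
                  hce_divergence = 0.01, indel_rate = 0,
                  hce_indel_rate = 0, n_inversions = 0,
                  n_translocations = 0, scaffold_n50_target = 1.6e6,
                  hce_spacing_min = 300, dup_fraction = 0,
                  repeat_fraction = 0)
  sim <- simulate_genome_pair(p)
  ref <- strsplit(as.character(sim$reference[[1]]), "")[[1]]
  tgt <- strsplit(as.character(sim$target[[1]]), "")[[1]]
  expect_equal(length(ref), length(tgt))  # no indels
  in_hce <- logical(length(ref))
  for (i in seq_len(nrow(sim$placements))) {
    in_hce[(sim$placements$start[i] + 1):sim$placements$end[i]] <- TRUE
  }
  mm <- ref != tgt
  bg_n <- sum(!in_hce); bg_rate <- mean(mm[!in_hce])
  hce_n <- sum(in_hce); hce_rate <- mean(mm[in_hce])
  expect_lt(abs(bg_rate - 0.08), 3 * sqrt(0.08 * 0.92 / bg_n))
  expect_lt(abs(hce_rate - 0.01), 3 * sqrt(0.01 * 0.99 / hce_n))
})

test_that("an inversion flips truth orientation and reverse-complements sequence", {
  p <- sim_params(seed = 8, n_chromosomes = 1, chromosome_length = 2e5,
                  n_hce = 50, background_divergence = 1e-9,
                  hce_divergence = 0, indel_rate = 0, hce_indel_rate = 0,
                  n_inversions = 1, n_translocations = 0,
                  inversion_len_range = c(4e4, 6e4),
                  scaffold_n50_target = 2e4, hce_spacing_min = 300)
  sim <- simulate_genome_pair(p)
  inv <- sim$truth$rearrangements
  expect_equal(inv$type, "inversion")
  # scaffolds wholly inside the inverted segment are "-" in truth
  inside <- sim$truth$scaffolds$ref_start >= inv$start &
    sim$truth$scaffolds$ref_end <= inv$end &
    sim$truth$scaffolds$frac_majority == 1
  expect_gt(sum(inside), 0)
  expect_true(all(sim$truth$scaffolds$orientation[inside] == "-"))
  # their sequence equals the reverse complement of their reference span
  i <- which(inside)[1]
  tr <- sim$truth$scaffolds[i, ]
  refseq <- substr(as.character(sim$reference[[tr$chrom]]),
                   tr$ref_start + 1, tr$ref_end)
  expect_equal(as.character(sim$target[[tr$scaffold]]), revcomp(refseq))
})

test_that("truth coordinates recover each planted element from the target", {
  sim <- simulate_genome_pair(tiny_params(seed = 9))
  hm <- sim$truth$hce_map
  hm <- hm[hm$frac_intact == 1 & hm$strand == "+", ]
  expect_gt(nrow(hm), 10)
  hce_by_id <- setNames(sim$hce$sequence, sim$hce$hce_id)
  p <- sim$params
  for (i in head(seq_len(nrow(hm)), 10)) {
    got <- substr(as.character(sim$target[[hm$scaffold[i]]]),
                  hm$start[i] + 1, hm$end[i])
    want <- hce_by_id[[hm$hce_id[i]]]
    # same length (no indels within an intact element) and low divergence
    expect_equal(nchar(got), nchar(want))
    mism <- mean(strsplit(got, "")[[1]] != strsplit(want, "")[[1]])
    expect_lte(mism, 0.08)
  }
})

test_that("recovery scoring counts assignments, orientations and ordering", {
  truth <- list(
    scaffolds = tibble::tibble(
      scaffold = paste0("s", 1:50), length = 20000L,
      chrom = rep(c("chr1", "chr2"), each = 25),
      ref_start = rep(seq(0, 240000, by = 10000), 2)[1:50],
      ref_end = rep(seq(0, 240000, by = 10000), 2)[1:50] + 9000L,
      orientation = "+", frac_majority = 1),
    hce_map = tibble::tibble(
      hce_id = paste0("h", 1:150), scaffold = rep(paste0("s", 1:50), 3),
      start = 0L, end = 100L, strand = "+", frac_intact = 1)
  )
  perfect <- tibble::tibble(
    scaffold = truth$scaffolds$scaffold,
    chromosome = truth$scaffolds$chrom,
    ref_start = truth$scaffolds$ref_start,
    ref_end = truth$scaffolds$ref_end,
    strand = "+", n_anchors = 3L, scaffold_length = 20000L,
    covered_fraction = 0.9, split_flag = FALSE)
  m <- score_recovery(perfect, truth)
  expect_equal(m$n_eligible, 50L)
  expect_equal(m$assignment_accuracy, 1)
  expect_equal(m$orientation_accuracy, 1)
  expect_equal(m$ordering_concordance, 1)

  empty <- perfect[0, ]
  m0 <- score_recovery(empty, truth)
  expect_equal(m0$assignment_and_orientation, 0)

  one_wrong <- perfect
  one_wrong$chromosome[1] <- "chr9"
  m1 <- score_recovery(one_wrong, truth)
  expect_equal(m1$assignment_accuracy, 49 / 50)
})
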