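#' Simulation parameters for a synthetic genome pair
#'
#' The generator emulates the statistical structure that conserved-element
#' anchoring exploits: highly conserved elements (low divergence) embedded
#' in a diverged background, with indels, a few large rearrangements, and
#' a scaffold-level fragmentation of the target.  Defaults describe a
#' mammal-like desk-scale pair: two 5 Mb chromosomes carrying 2000
#' elements, 8% background and 1% element substitution divergence, five
#' inversions, two translocations, and a target scaffold N50 around
#' 150 Kb.
#'
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @param n_chromosomes,chromosome_length Reference shape.
#' @param n_hce Number of conserved elements to plant.
#' @param hce_len_min,hce_len_median,hce_len_max Element length
#'   distribution (log-normal around the median, clamped).
#' @param hce_spacing_min Minimum gap between planted elements, in bases.
#' @param background_divergence,hce_divergence Substitution rates outside
#'   and inside elements (the latter must be lower).
#' @param indel_rate,hce_indel_rate Per-base indel initiation rates
#'   outside and inside elements.
#' @param indel_mean_len,indel_max_len Geometric indel length model.
#' @param n_inversions,n_translocations Large rearrangements applied to
#'   the target before fragmentation.
#' @param inversion_len_range,translocation_len_range Segment lengths.
#' @param scaffold_n50_target Target N50 of the fragmented scaffolds;
#'   breakpoints are resampled until the realized N50 is within 20%.
#' @param dup_fraction Fraction of elements planted at two reference
#'   locations (exercises the uniqueness filters).
#' @param repeat_fraction Fraction of elements built from a repeated motif
#'   that is also scattered through the background (exercises seed
#'   masking).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length = 5e6,
                       n_hce = 2000L,
                       hce_len_min = 40L,
                       hce_len_median = 250L,
                       hce_len_max = 2000L,
                       hce_spacing_min = 500L,
                       background_divergence = 0.08,
                       hce_divergence = 0.01,
                       indel_rate = 5e-4,
                       hce_indel_rate = 5e-5,
                       indel_mean_len = 2,
                       indel_max_len = 20L,
                       n_inversions = 5L,
                       n_translocations = 2L,
                       inversion_len_range = c(5e4, 5e5),
                       translocation_len_range = c(5e4, 3e5),
                       scaffold_n50_target = 150000,
                       dup_fraction = 0.02,
                       repeat_fraction = 0.005) {
  stopifnot(hce_divergence < background_divergence,
            background_divergence >= 0, background_divergence < 1,
            hce_divergence >= 0, indel_rate >= 0, indel_rate < 1,
            n_chromosomes >= 1, chromosome_length > 0, n_hce >= 0,
            hce_len_min >= 1, dup_fraction >= 0, dup_fraction < 1,
            repeat_fraction >= 0, repeat_fraction < 1)
  p <- as.list(environment())
  class(p) <- "sim_params"
  p
}

BASES <- c("A", "C", "G", "T")

random_chars <- function(n) sample(BASES, n, replace = TRUE)

comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# place k non-overlapping intervals of the given lengths on [1, L] with
# pairwise (and boundary) gaps of at least `spacing`; returns starts
place_intervals <- function(L, lens, spacing) {
  k <- length(lens)
  if (k == 0L) return(integer(0L))
  slack <- L - sum(lens) - (k + 1L) * spacing
  if (slack < 0) {
    abort("requested HCE mass exceeds chromosome capacity")
  }
  u <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
  spacing * seq_len(k) + cumsum(c(0L, lens[-k])) + u + 1L
}

#' Generate a reference genome with planted conserved elements
#'
#' Background sequence is i.i.d. uniform; element intervals are placed
#' non-overlapping with at least `hce_spacing_min` bases between them, a
#' `dup_fraction` of elements is copied to a second location, and a
#' `repeat_fraction` is built from a motif that is also scattered through
#' the background.
#'
#' @param params A [sim_params()] object.
#' @return A list with `genome` (DNAStringSet), `hce` (HCE tibble),
#'   `placements` (BED-style tibble of all plantings, duplicated ids
#'   appearing twice), and `params`.
#' @export
generate_reference <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  p <- params

  n <- p$n_hce
  n_dup <- round(p$dup_fraction * n)
  n_rep <- round(p$repeat_fraction * n)
  lens <- pmin(pmax(round(stats::rlnorm(n, log(p$hce_len_median), 0.6)),
                    p$hce_len_min), p$hce_len_max)
  ids <- sprintf("hce_%05d", seq_len(n))
  dup_ids <- if (n_dup > 0) sample(ids, n_dup) else character(0L)
  rep_ids <- if (n_rep > 0) {
    sample(setdiff(ids, dup_ids), min(n_rep, n - n_dup))
  } else character(0L)

  # one placement per element plus one extra per duplicated element
  place_id <- c(ids, dup_ids)
  place_len <- c(lens, lens[match(dup_ids, ids)])
  chrom_of <- sample.int(p$n_chromosomes, length(place_id), replace = TRUE,
                         prob = rep(1, p$n_chromosomes))

  chroms <- vector("list", p$n_chromosomes)
  names(chroms) <- sprintf("chr%d", seq_len(p$n_chromosomes))
  placements <- vector("list", length(place_id))
  for (c_i in seq_len(p$n_chromosomes)) {
    v <- random_chars(p$chromosome_length)
    sel <- which(chrom_of == c_i)
    ord <- sel[sample.int(length(sel))]
    starts <- place_intervals(p$chromosome_length, place_len[ord],
                              p$hce_spacing_min)
    for (j in seq_along(ord)) {
      placements[[ord[j]]] <- tibble(
        hce_id = place_id[ord[j]], chrom = names(chroms)[c_i],
        start = starts[j] - 1L, end = starts[j] - 1L + place_len[ord[j]]
      )
    }
    chroms[[c_i]] <- v
  }
  placements <- bind_rows(placements)

  # repeat elements: overwrite their primary interval with a tandem motif
  # and scatter the motif through the background
  for (rid in rep_ids) {
    pr <- placements[placements$hce_id == rid, ][1L, ]
    len <- pr$end - pr$start
    motif <- random_chars(25L)
    tandem <- rep(motif, length.out = len)
    chroms[[pr$chrom]][(pr$start + 1L):pr$end] <- tandem
    c_i <- sample.int(p$n_chromosomes, 1L)
    spots <- sample.int(p$chromosome_length - 25L, 80L)
    for (s in spots) {
      near <- placements$chrom == names(chroms)[c_i] &
        placements$start - 50L < s + 25L & s < placements$end + 50L
      if (!any(near)) chroms[[c_i]][(s + 1L):(s + 25L)] <- motif
    }
  }

  # duplicated elements: copy the primary sequence to the second interval
  for (did in dup_ids) {
    pls <- placements[placements$hce_id == did, ]
    src <- pls[1L, ]; dst <- pls[2L, ]
    seqc <- chroms[[src$chrom]][(src$start + 1L):src$end]
    chroms[[dst$chrom]][(dst$start + 1L):dst$end] <- seqc
  }

  primary <- placements[!duplicated(placements$hce_id), ]
  primary <- primary[match(ids, primary$hce_id), ]
  hce_seq <- vapply(seq_len(n), function(i) {
    paste(chroms[[primary$chrom[i]]][(primary$start[i] + 1L):primary$end[i]],
          collapse = "")
  }, "")
  hce <- tibble(hce_id = ids, sequence = hce_seq,
                src_name = primary$chrom, src_start = primary$start,
                src_end = primary$end)

  genome <- Biostrings::DNAStringSet(
    vapply(chroms, paste, "", collapse = ""))
  names(genome) <- names(chroms)
  list(genome = genome, hce = hce, placements = placements, params = params)
}

# insert `pieces[[i]]` (character vectors) after index `at[i]` of v;
# map values for inserted bases are 0 (no reference origin)
splice_insertions <- function(v, m, at, pieces) {
  if (length(at) == 0L) return(list(v = v, m = m))
  ord <- order(at)
  at <- at[ord]; pieces <- pieces[ord]
  bounds <- c(0L, at, length(v))
  out_v <- vector("list", 2L * length(at) + 1L)
  out_m <- vector("list", 2L * length(at) + 1L)
  for (i in seq_len(length(at) + 1L)) {
    lo <- bounds[i] + 1L; hi <- bounds[i + 1L]
    seg <- if (lo <= hi) lo:hi else integer(0L)
    out_v[[2L * i - 1L]] <- v[seg]
    out_m[[2L * i - 1L]] <- m[seg]
    if (i <= length(at)) {
      out_v[[2L * i]] <- pieces[[i]]
      out_m[[2L * i]] <- rep(0, length(pieces[[i]]))
    }
  }
  list(v = unlist(out_v, use.names = FALSE),
       m = unlist(out_m, use.names = FALSE))
}

#' Evolve a reference into a scaffold-level target with known truth
#'
#' Applies substitutions (at the background rate outside elements and the
#' conserved rate inside), indels, inversions and translocations, then
#' fragments the evolved chromosomes into scaffolds approximating the
#' target N50.  A signed per-base origin map is carried through every
#' edit, so the returned ground truth knows each scaffold's true
#' chromosome, span and orientation and each planted element's target
#' coordinates.
#'
#' @param reference Result of [generate_reference()] (or a compatible
#'   list with `genome`, `placements`, `params`).
#' @return A list with `target` (DNAStringSet of scaffolds) and `truth`
#'   (list of `scaffolds`, `hce_map`, `rearrangements` tibbles).
#' @export
evolve_target <- function(reference) {
  p <- reference$params
  set.seed(p$seed + 1L)
  genome <- reference$genome
  placements <- reference$placements
  chrom_names <- names(genome)
  L_c <- Biostrings::width(genome)
  starts_g <- cumsum(c(0, as.numeric(L_c)))  # global offsets

  vs <- vector("list", length(genome))
  ms <- vector("list", length(genome))
  for (c_i in seq_along(genome)) {
    L <- L_c[c_i]
    v <- strsplit(as.character(genome[[c_i]]), "")[[1L]]
    m <- starts_g[c_i] + seq_len(L)  # signed global origin

    in_hce <- logical(L)
    pl <- placements[placements$chrom == chrom_names[c_i], ]
    for (j in seq_len(nrow(pl))) in_hce[(pl$start[j] + 1L):pl$end[j]] <- TRUE

    # substitutions
    sub_rate <- ifelse(in_hce, p$hce_divergence, p$background_divergence)
    pos <- which(runif(L) < sub_rate)
    if (length(pos) > 0L) {
      cur <- match(v[pos], BASES)
      shift <- sample.int(3L, length(pos), replace = TRUE)
      v[pos] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
    }

    # indels
    ind_rate <- ifelse(in_hce, p$hce_indel_rate, p$indel_rate)
    ipos <- which(runif(L) < ind_rate)
    if (length(ipos) > 0L) {
      ilen <- pmin(1L + rgeom(length(ipos), 1 / p$indel_mean_len),
                   p$indel_max_len)
      is_del <- runif(length(ipos)) < 0.5
      del_mask <- logical(L)
      for (j in which(is_del)) {
        del_mask[ipos[j]:min(L, ipos[j] + ilen[j] - 1L)] <- TRUE
      }
      keep <- !del_mask
      kcum <- cumsum(keep)
      ins_j <- which(!is_del & !del_mask[ipos])
      at <- kcum[ipos[ins_j]]
      pieces <- lapply(ilen[ins_j], random_chars)
      sp <- splice_insertions(v[keep], m[keep], at, pieces)
      v <- sp$v; m <- sp$m
    }
    vs[[c_i]] <- v
    ms[[c_i]] <- m
  }

  # large rearrangements
  rearr <- list()
  if (p$n_inversions > 0) {
    for (i in seq_len(p$n_inversions)) {
      c_i <- sample.int(length(vs), 1L,
                        prob = vapply(vs, length, numeric(1L)))
      L <- length(vs[[c_i]])
      len <- min(round(runif(1, p$inversion_len_range[1L],
                             p$inversion_len_range[2L])), L - 2L)
      a <- sample.int(L - len, 1L)
      idx <- a:(a + len - 1L)
      vs[[c_i]][idx] <- unname(comp_map[rev(vs[[c_i]][idx])])
      ms[[c_i]][idx] <- -rev(ms[[c_i]][idx])
      rearr[[length(rearr) + 1L]] <- tibble(
        type = "inversion", chrom_from = chrom_names[c_i],
        start = a - 1L, end = a - 1L + len,
        chrom_to = chrom_names[c_i], insert_pos = NA_integer_)
    }
  }
  if (p$n_translocations > 0) {
    for (i in seq_len(p$n_translocations)) {
      c_i <- sample.int(length(vs), 1L,
                        prob = vapply(vs, length, numeric(1L)))
      L <- length(vs[[c_i]])
      len <- min(round(runif(1, p$translocation_len_range[1L],
                             p$translocation_len_range[2L])), L %/% 4L)
      a <- sample.int(L - len, 1L)
      idx <- a:(a + len - 1L)
      seg_v <- vs[[c_i]][idx]; seg_m <- ms[[c_i]][idx]
      vs[[c_i]] <- vs[[c_i]][-idx]; ms[[c_i]] <- ms[[c_i]][-idx]
      dest <- if (length(vs) > 1L) {
        sample(setdiff(seq_along(vs), c_i), 1L)
      } else c_i
      at <- sample.int(length(vs[[dest]]), 1L)
      sp <- splice_insertions(vs[[dest]], ms[[dest]], at, list(seg_v))
      vs[[dest]] <- sp$v
      # splice_insertions zeroes inserted map values; restore the origin
      ms[[dest]] <- sp$m
      ms[[dest]][(at + 1L):(at + len)] <- seg_m
      rearr[[length(rearr) + 1L]] <- tibble(
        type = "translocation", chrom_from = chrom_names[c_i],
        start = a - 1L, end = a - 1L + len,
        chrom_to = chrom_names[dest], insert_pos = at)
    }
  }

  # fragment into scaffolds approximating the N50 target
  mean_target <- p$scaffold_n50_target / 1.7
  best <- NULL
  for (try_i in 1:60) {
    cuts <- lapply(vs, function(v) {
      L <- length(v)
      k <- max(1L, round(L / mean_target))
      if (k == 1L) return(integer(0L))
      sort(sample.int(L - 1L, k - 1L))
    })
    lens <- unlist(lapply(seq_along(vs), function(c_i) {
      diff(c(0L, cuts[[c_i]], length(vs[[c_i]])))
    }))
    realized <- n50(lens)
    if (is.null(best) ||
        abs(realized - p$scaffold_n50_target) < abs(best$n50 - p$scaffold_n50_target)) {
      best <- list(cuts = cuts, n50 = realized)
    }
    if (abs(realized - p$scaffold_n50_target) <= 0.2 * p$scaffold_n50_target)
      break
  }
  cuts <- best$cuts

  scaff_v <- list(); scaff_m <- list()
  for (c_i in seq_along(vs)) {
    bounds <- c(0L, cuts[[c_i]], length(vs[[c_i]]))
    for (j in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[j] + 1L):bounds[j + 1L]
      scaff_v[[length(scaff_v) + 1L]] <- vs[[c_i]][idx]
      scaff_m[[length(scaff_m) + 1L]] <- ms[[c_i]][idx]
    }
  }
  perm <- sample.int(length(scaff_v))
  scaff_v <- scaff_v[perm]; scaff_m <- scaff_m[perm]
  scaf_names <- sprintf("scaffold_%04d", seq_along(scaff_v))

  target <- Biostrings::DNAStringSet(
    vapply(scaff_v, paste, "", collapse = ""))
  names(target) <- scaf_names

  # ground truth per scaffold
  total_ref <- sum(L_c)
  chrom_id_of <- function(g) findInterval(g - 0.5, starts_g)
  scaff_rows <- vector("list", length(scaff_v))
  for (i in seq_along(scaff_m)) {
    m <- scaff_m[[i]]
    gm <- m[m != 0]
    if (length(gm) == 0L) {
      scaff_rows[[i]] <- tibble(
        scaffold = scaf_names[i], length = length(m),
        chrom = NA_character_, ref_start = NA_integer_,
        ref_end = NA_integer_, orientation = NA_character_,
        frac_majority = 0)
      next
    }
    cid <- chrom_id_of(abs(gm))
    tab <- tabulate(cid, nbins = length(L_c))
    cmax <- which.max(tab)
    sel <- cid == cmax
    loc <- abs(gm[sel]) - starts_g[cmax]
    ori <- if (mean(gm[sel] > 0) >= 0.5) "+" else "-"
    scaff_rows[[i]] <- tibble(
      scaffold = scaf_names[i], length = length(m),
      chrom = chrom_names[cmax],
      ref_start = as.integer(min(loc) - 1L),
      ref_end = as.integer(max(loc)),
      orientation = ori,
      frac_majority = tab[cmax] / length(m))
  }
  scaffolds_truth <- bind_rows(scaff_rows)

  # ground truth per planted element: reverse lookup from reference
  ref2scaf <- integer(total_ref); ref2pos <- integer(total_ref)
  ref2sign <- integer(total_ref)
  for (i in seq_along(scaff_m)) {
    m <- scaff_m[[i]]
    nz <- which(m != 0)
    g <- abs(m[nz])
    ref2scaf[g] <- i
    ref2pos[g] <- nz
    ref2sign[g] <- sign(m[nz])
  }
  hce_rows <- vector("list", nrow(placements))
  for (j in seq_len(nrow(placements))) {
    c_i <- match(placements$chrom[j], chrom_names)
    g <- (starts_g[c_i] + placements$start[j] + 1L):
      (starts_g[c_i] + placements$end[j])
    sc <- ref2scaf[g]
    ok <- sc != 0L
    if (!any(ok)) next
    s_tab <- tabulate(sc[ok], nbins = length(scaff_v))
    s_i <- which.max(s_tab)
    posn <- ref2pos[g][sc == s_i]
    sgn <- ref2sign[g][sc == s_i]
    hce_rows[[j]] <- tibble(
      hce_id = placements$hce_id[j],
      scaffold = scaf_names[s_i],
      start = as.integer(min(posn) - 1L),
      end = as.integer(max(posn)),
      strand = if (mean(sgn > 0) >= 0.5) "+" else "-",
      frac_intact = length(posn) / length(g))
  }
  hce_map <- bind_rows(hce_rows)

  truth <- list(
    scaffolds = scaffolds_truth,
    hce_map = hce_map,
    rearrangements = if (length(rearr)) bind_rows(rearr) else
      tibble(type = character(), chrom_from = character(),
             start = integer(), end = integer(), chrom_to = character(),
             insert_pos = integer()),
    params = p
  )
  list(target = target, truth = truth)
}

#' Simulate a full reference/target/HCE triple
#'
#' Convenience wrapper: [generate_reference()] then [evolve_target()].
#'
#' @param params A [sim_params()] object.
#' @return A list with `reference`, `target` (DNAStringSet), `hce` (HCE
#'   tibble), `placements`, `truth`, and `params`.
#' @export
simulate_genome_pair <- function(params = sim_params()) {
  ref <- generate_reference(params)
  evo <- evolve_target(ref)
  list(reference = ref$genome, target = evo$target, hce = ref$hce,
       placements = ref$placements, truth = evo$truth, params = params)
}

#' Write a simulated triple to disk
#'
#' Emits `reference.fa`, `target.fa`, `hce.fa`, `hce.bed` and
#' `truth.json` under `dir`.
#'
#' @param sim Result of [simulate_genome_pair()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$reference, file.path(dir, "reference.fa"))
  write_fasta(sim$target, file.path(dir, "target.fa"))
  write_fasta(setNames(sim$hce$sequence, sim$hce$hce_id),
              file.path(dir, "hce.fa"))
  write_bed(tibble(chrom = sim$placements$chrom,
                   start = sim$placements$start,
                   end = sim$placements$end,
                   name = sim$placements$hce_id),
            file.path(dir, "hce.bed"))
  jsonlite::write_json(
    list(scaffolds = sim$truth$scaffolds, hce_map = sim$truth$hce_map,
         rearrangements = sim$truth$rearrangements,
         params = unclass(sim$params)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Score a scaffold report against simulation truth
#'
#' Over truth scaffolds of at least `min_len` bases carrying at least
#' `min_anchors` planted elements: the fraction assigned to the correct
#' chromosome, the fraction (of correctly assigned) with the correct
#' orientation, the fraction with both, and the ordering concordance --
#' the scaffold-count-weighted mean, over chromosomes, of the Kendall
#' correlation between predicted and true reference positions of the
#' correctly assigned scaffolds.
#'
#' @param report A [scaffold_report()] table.
#' @param truth The `truth` element of [simulate_genome_pair()].
#' @param min_len Minimum scaffold length considered (default 10 Kb).
#' @param min_anchors Minimum planted elements for eligibility.
#' @return A one-row tibble of recovery metrics.
#' @export
score_recovery <- function(report, truth, min_len = 10000L,
                           min_anchors = 2L) {
  counts <- truth$hce_map %>%
    filter(.data$frac_intact >= 0.5) %>%
    group_by(.data$scaffold) %>%
    summarise(n_hce = n(), .groups = "drop")
  elig <- truth$scaffolds %>%
    filter(.data$length >= min_len, !is.na(.data$chrom)) %>%
    left_join(counts, by = "scaffold") %>%
    filter(!is.na(.data$n_hce), .data$n_hce >= min_anchors)
  if (nrow(elig) == 0L) {
    return(tibble(n_eligible = 0L, assignment_accuracy = NA_real_,
                  orientation_accuracy = NA_real_,
                  assignment_and_orientation = NA_real_,
                  ordering_concordance = NA_real_))
  }
  main <- report %>%
    group_by(.data$scaffold) %>%
    slice(which.max(.data$covered_fraction)) %>%
    ungroup()
  j <- elig %>%
    left_join(main, by = "scaffold", suffix = c("_true", "_pred"))
  assigned_ok <- !is.na(j$chromosome) & j$chromosome == j$chrom
  orient_ok <- assigned_ok & !is.na(j$strand) & j$strand == j$orientation
  # ordering among correctly assigned scaffolds, per chromosome
  taus <- c(); wts <- c()
  for (ch in unique(j$chrom[assigned_ok])) {
    sub <- j[assigned_ok & j$chrom == ch, ]
    if (nrow(sub) >= 2L) {
      tau <- suppressWarnings(
        stats::cor(sub$ref_start_true, sub$ref_start_pred,
                   method = "kendall"))
      if (!is.na(tau)) { taus <- c(taus, tau); wts <- c(wts, nrow(sub)) }
    }
  }
  tibble(
    n_eligible = nrow(elig),
    assignment_accuracy = mean(assigned_ok),
    orientation_accuracy = if (any(assigned_ok))
      sum(orient_ok) / sum(assigned_ok) else NA_real_,
    assignment_and_orientation = mean(orient_ok),
    ordering_concordance = if (length(taus))
      sum(taus * wts) / sum(wts) else NA_real_
  )
}
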