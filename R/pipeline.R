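#' Pipeline run configuration
#'
#' Collects every input and parameter of an end-to-end anchoring run.
#' Genomes and the element set may be given as file paths (FASTA / BED)
#' or as in-memory objects.
#'
#' @param reference Chromosome-level reference genome (path or
#'   DNAStringSet).
#' @param target Scaffold-level target genome (path or DNAStringSet).
#' @param hce HCE set (path to multi-FASTA, or an HCE tibble).
#' @param out_dir Output directory; created if missing.
#' @param hce_bed Optional BED of element source coordinates.
#' @param aligner [aligner_params()].
#' @param anchor [anchor_params()].
#' @param chain [chain_params()].
#' @param min_hce_len Minimum element length (elements shorter are
#'   dropped before databank construction).
#' @param split_max_len Elements longer than this are split into
#'   `split_piece`-base fragments before alignment.  `NULL` means: split
#'   only above 5 Kb, and only when `aligner$fast_mode` is on (the
#'   fast-mode query limit).
#' @param split_piece Fragment size used when splitting.
#' @param occ_threshold Seed masking threshold passed to [build_index()].
#' @param min_space Netting gap threshold, in bases.
#' @param databank Optionally a prebuilt `hce_databank`, skipping
#'   databank construction.
#' @param keep_intermediates Keep intermediate files in `out_dir`.
#' @return A list of class `run_config`.
#' @export
anchor_config <- function(reference, target, hce, out_dir,
                          hce_bed = NULL,
                          aligner = aligner_params(),
                          anchor = anchor_params(),
                          chain = chain_params(),
                          min_hce_len = 40L,
                          split_max_len = NULL,
                          split_piece = 250L,
                          occ_threshold = Inf,
                          min_space = 25L,
                          databank = NULL,
                          keep_intermediates = TRUE) {
  structure(
    list(reference = reference, target = target, hce = hce,
         hce_bed = hce_bed, out_dir = out_dir, aligner = aligner,
         anchor = anchor, chain = chain, min_hce_len = min_hce_len,
         split_max_len = split_max_len, split_piece = split_piece,
         occ_threshold = occ_threshold, min_space = min_space,
         databank = databank, keep_intermediates = keep_intermediates),
    class = "run_config"
  )
}

load_genome_input <- function(x, what) {
  if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    read_fasta(x)
  } else {
    as_genome(x, what = what)
  }
}

load_hce_input <- function(hce, hce_bed) {
  if (is.data.frame(hce)) as_hce(hce) else read_hce(hce, hce_bed)
}

#' Pre-flight validation of a run configuration
#'
#' Checks that every input parses, that the reference has at least one
#' sequence (warning above 200: a fragmented reference multiplies running
#' time), and that element ids are unique.  Problems are returned, not
#' raised, so a caller can present them all at once.
#'
#' @param config A [anchor_config()] object.
#' @return A tibble `(severity, problem)`; empty when the configuration
#'   is clean.
#' @export
validate_inputs <- function(config) {
  probs <- list()
  note <- function(severity, problem) {
    probs[[length(probs) + 1L]] <<- tibble(severity = severity,
                                           problem = problem)
  }
  ref <- tryCatch(load_genome_input(config$reference, "reference"),
                  error = function(e) {
                    note("error", paste0("reference: ", conditionMessage(e)))
                    NULL
                  })
  if (!is.null(ref)) {
    if (length(ref) < 1L) note("error", "reference has no sequences")
    if (length(ref) > 200L) {
      note("warning", paste0(
        "reference has ", length(ref), " sequences; a highly fragmented ",
        "reference can dramatically increase running time"))
    }
  }
  tryCatch(load_genome_input(config$target, "target"),
           error = function(e) {
             note("error", paste0("target: ", conditionMessage(e)))
             NULL
           })
  hce <- tryCatch(load_hce_input(config$hce, config$hce_bed),
                  error = function(e) {
                    note("error", paste0("hce: ", conditionMessage(e)))
                    NULL
                  })
  if (is.data.frame(config$hce) && anyDuplicated(config$hce$hce_id)) {
    note("error", paste0("duplicate HCE id: '",
                         config$hce$hce_id[duplicated(config$hce$hce_id)][1L],
                         "'"))
  }
  if (length(probs) == 0L) {
    return(tibble(severity = character(), problem = character()))
  }
  bind_rows(probs)
}

#' Run the anchoring pipeline end to end
#'
#' Preprocess genomes, build (or load) the HCE databank, align it to the
#' target, filter anchors, transfer them to the reference frame, chain,
#' net, annotate, and write the per-scaffold report.  A JSON manifest
#' records parameters, input digests, and the element/anchor counts at
#' every filter step.
#'
#' @param config A [anchor_config()] object.
#' @param quiet Suppress progress messages.
#' @return An object of class `scaf_run`: `report`, `anchors`, `chains`,
#'   `net`, `databank`, `manifest`, and the output file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  probs <- validate_inputs(config)
  if (any(probs$severity == "error")) {
    abort(paste0("invalid inputs:\n  ",
                 paste(probs$problem[probs$severity == "error"],
                       collapse = "\n  ")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0L)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }

  digest_of <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      unname(tools::md5sum(x))
    } else NA_character_
  }

  say("stage 1: preprocessing genomes")
  reference <- load_genome_input(config$reference, "reference")
  target <- load_genome_input(config$target, "target")
  ref_sizes <- compute_sizes(reference)
  tgt_sizes <- compute_sizes(target)
  hces <- load_hce_input(config$hce, config$hce_bed)

  counts <- list(hce_in = nrow(hces))
  hces <- filter_min_length(hces, config$min_hce_len)
  counts$hce_min_length <- nrow(hces)
  split_max <- config$split_max_len
  if (is.null(split_max)) {
    split_max <- if (config$aligner$fast_mode) 5000L else Inf
  }
  if (is.finite(split_max)) {
    hces <- split_long_hce(hces, max_len = split_max,
                           piece = config$split_piece,
                           min_len = config$min_hce_len)
  }
  counts$hce_after_split <- nrow(hces)

  if (is.null(config$databank)) {
    say("databank: aligning ", nrow(hces), " elements to the reference")
    ref_index <- build_index(reference,
                             occ_threshold = config$occ_threshold)
    databank <- build_databank(hces, reference, params = config$aligner,
                               index = ref_index)
  } else {
    databank <- config$databank
  }
  counts$databank_mapped <- databank$stats$n_mapped
  counts$databank_unique <- databank$stats$n_unique

  say("stage 2: aligning databank (", counts$databank_unique,
      " elements) to the target")
  tgt_index <- build_index(target, occ_threshold = config$occ_threshold)
  records <- map_databank(databank, target, params = config$anchor,
                          aligner = config$aligner, index = tgt_index)
  counts$target_alignments <- nrow(records)

  say("stage 3: filtering anchors")
  anchors <- filter_anchors(records, databank, params = config$anchor)
  counts$anchors <- nrow(anchors)

  say("stage 4: transferring anchors onto the reference")
  ref_psl <- transfer_to_reference(anchors)

  say("stage 5: chaining and netting")
  chains <- chain_blocks(ref_psl, params = config$chain)
  counts$chains <- nrow(chains)
  net <- net_chains(chains, ref_sizes, min_space = config$min_space)
  net <- annotate_syntenic(net)
  report <- scaffold_report(net, anchors)
  counts$netted_scaffolds <- length(unique(report$scaffold))

  paths <- list(
    anchors_psl = file.path(config$out_dir, "anchors_ref.psl"),
    anchors_bed = file.path(config$out_dir, "anchors.bed"),
    chains = file.path(config$out_dir, "anchors.chain"),
    net = file.path(config$out_dir, "anchors.net"),
    report = file.path(config$out_dir, "report.tsv"),
    manifest = file.path(config$out_dir, "manifest.json"),
    log = log_path
  )
  if (config$keep_intermediates) {
    paths$databank <- write_databank(
      databank, file.path(config$out_dir, "databank"))
  }
  write_psl(ref_psl, paths$anchors_psl)
  write_bed(
    bind_rows(
      tibble(chrom = anchors$ref_chrom, start = anchors$ref_start,
             end = anchors$ref_end, name = anchors$hce_id, score = 0L,
             strand = anchors$ref_strand),
      tibble(chrom = anchors$scaffold, start = anchors$tgt_start,
             end = anchors$tgt_end, name = anchors$hce_id, score = 0L,
             strand = anchors$tgt_strand)
    ),
    paths$anchors_bed)
  write_chain(chains, paths$chains)
  write_net(net, paths$net)
  write.table(report, paths$report, sep = "\t", quote = FALSE,
              row.names = FALSE)

  manifest <- list(
    inputs = list(
      reference = if (is.character(config$reference)) config$reference else "<in-memory>",
      target = if (is.character(config$target)) config$target else "<in-memory>",
      hce = if (is.character(config$hce)) config$hce else "<in-memory>",
      reference_md5 = digest_of(config$reference),
      target_md5 = digest_of(config$target),
      hce_md5 = digest_of(config$hce)
    ),
    params = list(
      aligner = unclass(config$aligner),
      anchor = unclass(config$anchor),
      chain = list(min_score = config$chain$min_score,
                   gap_preset = config$chain$gap_model$preset),
      min_hce_len = config$min_hce_len,
      split_max_len = if (is.finite(split_max)) split_max else "none",
      occ_threshold = if (is.finite(config$occ_threshold))
        config$occ_threshold else "none",
      min_space = config$min_space
    ),
    counts = counts
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("done: ", counts$netted_scaffolds, " scaffolds anchored")
  writeLines(log_lines, log_path)

  structure(
    list(report = report, anchors = anchors, chains = chains, net = net,
         databank = databank, manifest = manifest, paths = paths,
         ref_sizes = ref_sizes, tgt_sizes = tgt_sizes),
    class = "scaf_run"
  )
}

#' @export
print.scaf_run <- function(x, ...) {
  cm <- x$manifest$counts
  cat("scaf_run: ", cm$anchors, " anchors -> ", cm$chains, " chains -> ",
      cm$netted_scaffolds, " scaffolds anchored\n", sep = "")
  invisible(x)
}
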