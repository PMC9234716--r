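#' Write a complete synthetic fixture bundle
#'
#' Generates ground-truth-annotated inputs for every pipeline stage into one
#' directory, with a single seed fanned out to per-stage seeds by fixed
#' offsets so each stage is independently reproducible. Defaults mirror the
#' benchmark conditions used throughout the package:
#'
#' * alignment of 20 foreground and 50 background rows, 560 columns, with 43
#'   planted specificity-determining columns that include the six pocket
#'   positions 231, 281, 288, 316, 447 and 529, plus 3 redundant duplicates
#'   and 2 short length outliers;
#' * a C3-symmetric toy trimer with those six positions planted at the
#'   subunit interface;
#' * dose-response tables for four channels at EC50s of 3.4 uM, 350 nM,
#'   2 uM and 340 nM (5 recordings each, 5% multiplicative noise);
#' * 14 paired recordings planted at a potency ratio of 0.64 (5% noise) and
#'   7 paired recordings planted at a fold-enhancement of 10 (10% noise).
#'
#' @param seed Master seed.
#' @param out_dir Directory to create/fill.
#' @return Invisibly, a list with the file paths and the planted truth.
#' @export
make_fixture_bundle <- function(seed = 7, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  pocket <- c(231L, 281L, 288L, 316L, 447L, 529L)

  planted <- with_seed(seed + 10, {
    sort(c(pocket, sample(setdiff(1:560, pocket), 43 - length(pocket))))
  })
  msa <- simulate_msa(msa_sim_config(
    n_foreground = 20, n_background = 50, n_columns = 560,
    planted_columns = planted, within_class_noise = 0,
    n_redundant_duplicates = 3, n_length_outliers = 2, seed = seed + 11
  ))
  write_fasta(msa$alignment$seqs, p("alignment.fasta"))
  write_clades(msa$alignment$labels, p("clades.tsv"))

  tri <- simulate_trimer(560, pocket, interface_radius = 8, seed = seed + 12)
  write_structure_pdb(tri$structure, p("trimer.pdb"))

  channels <- list(
    aplysia_fanac     = list(ec50 = 3.4e-6, ladder = 10^seq(-7, -4, 0.5)),
    capitella_fanac   = list(ec50 = 350e-9, ladder = 10^seq(-8, -5, 0.5)),
    capitella_wanac   = list(ec50 = 2e-6,   ladder = 10^seq(-7, -4, 0.5)),
    malacoceros_wanac = list(ec50 = 340e-9, ladder = 10^seq(-8, -5, 0.5))
  )
  dr <- do.call(rbind, lapply(seq_along(channels), function(i) {
    ch <- channels[[i]]
    d <- simulate_dose_response(ch$ec50, 1, 1, ch$ladder, n_recordings = 5,
                                noise_sd_fraction = 0.05, seed = seed + 12 + i)
    d$channel <- names(channels)[i]
    d$recording_id <- paste(names(channels)[i], d$recording_id, sep = ".")
    d
  }))
  utils::write.table(dr, p("dose_response.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ratio_pairs <- simulate_potency_ratio_traces(
    true_ratio = 0.64, n_recordings = 14, noise_sd_fraction = 0.05,
    seed = seed + 17
  )
  write_paired_traces(ratio_pairs, p("ratio_traces"),
                      metadata = list(protocol = "paired potency ratio",
                                      conc_a_M = 3e-6, conc_b_M = 30e-6))
  enh_pairs <- simulate_enhancement_traces(
    true_fold = 10, n_recordings = 7, noise_sd_fraction = 0.10,
    seed = seed + 18
  )
  write_paired_traces(enh_pairs, p("enhancement_traces"),
                      metadata = list(protocol = "paired fold enhancement"))

  truth <- list(
    sdp_columns = planted,
    pocket_residues = pocket,
    duplicate_ids = msa$truth$duplicate_ids,
    outlier_ids = msa$truth$outlier_ids,
    true_ec50_M = vapply(channels, `[[`, numeric(1), "ec50"),
    true_ratio = 0.64,
    true_fold_enhancement = 10
  )
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)

  cfg <- list(
    alignment = p("alignment.fasta"),
    clades = p("clades.tsv"),
    reference_id = "fg_001",
    structure = p("trimer.pdb"),
    ephys = list(
      dose_response = p("dose_response.tsv"),
      ratio_traces = p("ratio_traces"),
      enhancement_traces = p("enhancement_traces")
    ),
    seed = seed,
    out_dir = file.path(out_dir, "screen")
  )
  yaml::write_yaml(cfg, p("pipeline.yaml"))

  invisible(list(
    dir = out_dir, config = p("pipeline.yaml"), truth = truth,
    files = list(alignment = p("alignment.fasta"), clades = p("clades.tsv"),
                 structure = p("trimer.pdb"),
                 dose_response = p("dose_response.tsv"),
                 ratio_traces = p("ratio_traces"),
                 enhancement_traces = p("enhancement_traces"),
                 truth = p("truth.json"))
  ))
}

#' Run the end-to-end screen
#'
#' Executes curation, the clade-contrast scan, vicinal grouping and mutation
#' proposal, structure mapping (if a structure is supplied) and the
#' electrophysiology statistics (if ephys inputs are supplied), and writes a
#' JSON manifest plus human-readable TSVs to the output directory. Every
#' number in the TSVs is derivable from the manifest alone. A stage failure
#' halts the run with the stage name and cause.
#'
#' @param config Either a path to a YAML file or a named list with elements
#'   `alignment` (gapped FASTA path), `clades` (TSV path), `reference_id`,
#'   optional `structure` (PDB path), optional `ephys` (list with any of
#'   `dose_response`, `ratio_traces`, `enhancement_traces` paths), optional
#'   `curation` / `scan` / `structure_opts` parameter lists, `seed`, and
#'   `out_dir`.
#' @return Invisibly, the manifest list.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("alignment", "clades", "reference_id", "out_dir")
  if (!all(need %in% names(config))) {
    stop("config needs at least: ", paste(need, collapse = ", "), call. = FALSE)
  }
  seed <- if (is.null(config$seed)) 1 else config$seed
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  manifest <- list(
    package = "peptidegate",
    version = as.character(utils::packageVersion("peptidegate")),
    seed = seed,
    inputs = config[c("alignment", "clades", "reference_id", "structure")],
    parameters = list()
  )

  # --- curation ---------------------------------------------------------
  cur_cfg <- utils::modifyList(
    list(min_length = 300, max_length = 1000, identity_threshold = 0.90),
    if (is.null(config$curation)) list() else config$curation
  )
  manifest$parameters$curation <- cur_cfg
  cur <- stage("curation", {
    seqs <- read_fasta(config$alignment)
    curate_sequences(seqs, cur_cfg$min_length, cur_cfg$max_length,
                     cur_cfg$identity_threshold)
  })
  manifest$curation <- list(
    n_input = nrow(cur$report),
    n_kept = sum(cur$report$action == "kept"),
    removed = cur$report[cur$report$action == "removed", c("id", "detail")]
  )
  utils::write.table(cur$report, file.path(out_dir, "curation_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- scan -------------------------------------------------------------
  scan_cfg_in <- if (is.null(config$scan)) list() else config$scan
  scan_cfg <- do.call(scan_config, c(list(reference_id = config$reference_id),
                                     scan_cfg_in))
  manifest$parameters$scan <- scan_cfg[setdiff(names(scan_cfg), "reference_id")]
  candidates <- stage("scan", {
    labels <- read_clades(config$clades)
    if (!config$reference_id %in% names(cur$kept)) {
      stop(sprintf("reference id '%s' not among curated sequences",
                   config$reference_id))
    }
    aln <- clade_alignment(cur$kept, labels[names(cur$kept)])
    scan_alignment(aln, scan_cfg)
  })
  groups <- group_vicinal(candidates$ref_number)
  manifest$scan <- list(
    n_candidates = nrow(candidates),
    candidates = as.data.frame(candidates),
    vicinal_groups = groups
  )
  write_candidates(candidates, file.path(out_dir, "candidates"))

  # --- structure mapping ------------------------------------------------
  if (!is.null(config$structure)) {
    st_cfg <- utils::modifyList(
      list(atom_mode = "CA", cutoff = NULL, linkage_cutoff = 12, chain = "A"),
      if (is.null(config$structure_opts)) list() else config$structure_opts
    )
    res <- stage("structure_mapping", {
      st <- read_structure_pdb(config$structure)
      rep <- detect_interface_residues(st, candidates$ref_number,
                                       cutoff = st_cfg$cutoff,
                                       atom_mode = st_cfg$atom_mode,
                                       chain = st_cfg$chain)
      list(report = rep,
           pockets = cluster_pockets(rep, st, st_cfg$linkage_cutoff,
                                     st_cfg$chain))
    })
    manifest$parameters$structure <- list(
      atom_mode = st_cfg$atom_mode,
      cutoff = attr(res$report, "cutoff"),
      linkage_cutoff = st_cfg$linkage_cutoff
    )
    manifest$structure <- list(
      interfacial = res$report$ref_number[res$report$interfacial],
      report = as.data.frame(res$report),
      pockets = res$pockets
    )
    utils::write.table(as.data.frame(res$report),
                       file.path(out_dir, "pocket_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    manifest$structure <- "skipped"
  }

  # --- electrophysiology ------------------------------------------------
  if (!is.null(config$ephys)) {
    eph <- config$ephys
    manifest$ephys <- list()
    if (!is.null(eph$dose_response)) {
      fits <- stage("hill_fits", {
        dr <- utils::read.delim(eph$dose_response, stringsAsFactors = FALSE)
        by_ch <- split(dr, if ("channel" %in% names(dr)) dr$channel else "all")
        lapply(by_ch, function(d) fit_hill_by_recording(d)$summary)
      })
      summary_df <- do.call(rbind, fits)
      summary_df <- cbind(channel = rownames(summary_df), summary_df)
      rownames(summary_df) <- NULL
      manifest$ephys$hill <- summary_df
      utils::write.table(summary_df, file.path(out_dir, "hill_fits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(eph$ratio_traces)) {
      pr <- stage("potency_ratio", {
        potency_ratio(peaks_from_pairs(read_paired_traces(eph$ratio_traces)))
      })
      manifest$ephys$potency_ratio <- pr[c("ratio", "sem", "n", "n_excluded")]
    }
    if (!is.null(eph$enhancement_traces)) {
      er <- stage("enhancement", {
        enhancement_ratio(peaks_from_pairs(read_paired_traces(eph$enhancement_traces)))
      })
      manifest$ephys$enhancement <- er[c("fold", "sem", "n", "n_flagged")]
    }
  } else {
    manifest$ephys <- "skipped"
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(manifest)
}
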