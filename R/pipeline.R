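#' Pipeline configuration
#'
#' Flat key-value configuration for the pipeline stages. Unknown keys are
#' rejected; every run persists the resolved configuration in a manifest.
#'
#' @param ... overrides of the defaults (see Details).
#' @details Recognised keys and defaults:
#' `clustering_threshold` (0.95), `rbh_min_score` (50), `gap_open` (11),
#' `gap_extend` (1), `hmm_gap_threshold` (0.5), `hmm_pseudocount` (1),
#' `bits_threshold` (20), `min_orf_aa` (50), `yvad_threshold` (15),
#' `seed` (1).
#' @return A list of class `gsdm_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(clustering_threshold = 0.95, rbh_min_score = 50,
                   gap_open = 11, gap_extend = 1,
                   hmm_gap_threshold = 0.5, hmm_pseudocount = 1,
                   bits_threshold = 20, min_orf_aa = 50,
                   yvad_threshold = 15, seed = 1)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(ov)] <- ov
  structure(defaults, class = "gsdm_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file of flat key-values.
#' @return A `gsdm_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.align_params_from <- function(config) {
  align_params(gap_open = config$gap_open, gap_extend = config$gap_extend)
}

.write_manifest <- function(out_dir, stage, config, counts = NULL) {
  manifest <- list(tool = "gasderminevo",
                   version = as.character(utils::packageVersion("gasderminevo")),
                   stage = stage, config = unclass(config), counts = counts)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Pipeline stage: simulate
#'
#' Writes a synthetic dataset bundle (see [generate_dataset()]).
#'
#' @param sim_config a [simulation_config()].
#' @param out_dir output directory.
#' @return The [generate_dataset()] result, invisibly.
#' @export
pipeline_simulate <- function(sim_config, out_dir) {
  invisible(generate_dataset(sim_config, out_dir))
}

#' Pipeline stage: curate
#'
#' Reads proteins and metadata, removes redundancy by greedy identity
#' clustering, aligns the cluster representatives, trims partial rows, and
#' writes `clusters.tsv`, `curated_alignment.fasta` and a manifest with
#' reconciling record counts.
#'
#' @param fasta path to the protein FASTA.
#' @param metadata path to the metadata TSV (optional; `NULL` to use
#'   header metadata).
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @param family_clades clade labels regarded as family members for the
#'   alignment step; `NULL` aligns everything (decoys included).
#' @return List with `clusters`, `msa`, `counts`, invisibly.
#' @export
pipeline_curate <- function(fasta, metadata = NULL, out_dir,
                            config = pipeline_config(),
                            family_clades = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- read_fasta(fasta)
  if (!is.null(metadata)) {
    md <- read_metadata(metadata)
    records <- records |>
      dplyr::select("id", "sequence") |>
      dplyr::inner_join(md, by = "id") |>
      dplyr::select("id", "taxon", "clade", "sequence")
  }
  n_in <- nrow(records)
  if (!is.null(family_clades)) {
    records <- records[records$clade %in% family_clades, ]
  }
  n_family <- nrow(records)
  if (n_family == 0) stop("no family records after clade filtering",
                          call. = FALSE)
  params <- .align_params_from(config)
  clusters <- greedy_cluster(records, config$clustering_threshold, params)
  reps <- records[records$id %in% unique(clusters$representative_id), ]
  msa <- progressive_align(reps, params = params)
  n_aligned <- length(msa$ids)
  msa <- trim_partial(msa)
  n_kept <- length(msa$ids)
  utils::write.table(clusters, file.path(out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_alignment(msa, file.path(out_dir, "curated_alignment.fasta"))
  counts <- list(input = n_in, non_family_removed = n_in - n_family,
                 redundant_removed = n_family - n_aligned,
                 partial_removed = n_aligned - n_kept, surviving = n_kept)
  .write_manifest(out_dir, "curate", config, counts)
  invisible(list(clusters = clusters, msa = msa, counts = counts))
}

#' Pipeline stage: build-hmm
#'
#' Builds a profile HMM from a curated alignment and writes it as JSON.
#'
#' @param alignment path to an aligned FASTA.
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return The `gsdm_profile_hmm`, invisibly.
#' @export
pipeline_build_hmm <- function(alignment, out_dir,
                               config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  msa <- read_alignment(alignment)
  hmm <- build_profile(msa, config$hmm_gap_threshold, config$hmm_pseudocount)
  write_profile_json(hmm, file.path(out_dir, "profile.json"))
  .write_manifest(out_dir, "build_hmm", config,
                  list(rows = length(msa$ids), n_match = hmm$n_match))
  invisible(hmm)
}

#' Pipeline stage: scan
#'
#' Scans proteins (and optionally nucleotide contigs in all six frames)
#' with a serialized profile and writes `hits.tsv`.
#'
#' @param profile path to a profile JSON.
#' @param fasta path to a protein FASTA (or `NULL`).
#' @param contigs path to a nucleotide FASTA (or `NULL`).
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return The hit tibble, invisibly.
#' @export
pipeline_scan <- function(profile, fasta = NULL, contigs = NULL, out_dir,
                          config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hmm <- read_profile_json(profile)
  hits <- list()
  n_in <- 0L
  if (!is.null(fasta)) {
    records <- read_fasta(fasta)
    n_in <- n_in + nrow(records)
    hits[[length(hits) + 1]] <-
      scan_proteins(hmm, records, config$bits_threshold)
  }
  if (!is.null(contigs)) {
    lines <- Biostrings::readBStringSet(contigs)
    n_in <- n_in + length(lines)
    for (i in seq_along(lines)) {
      h <- six_frame_scan(as.character(lines[[i]]), hmm,
                          config$min_orf_aa, config$bits_threshold,
                          contig_id = sub("\\s.*$", "", names(lines)[i]))
      hits[[length(hits) + 1]] <- h[, c("sequence_id", "bits", "start",
                                        "end", "frame")]
    }
  }
  hits <- dplyr::bind_rows(hits)
  utils::write.table(hits, file.path(out_dir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_manifest(out_dir, "scan", config,
                  list(input = n_in,
                       surviving = length(unique(hits$sequence_id)),
                       removed = n_in - length(unique(hits$sequence_id))))
  invisible(hits)
}

#' Pipeline stage: tree
#'
#' Poisson-corrected distances, neighbor joining, midpoint rooting, and a
#' per-clade monophyly report; writes `tree.nwk` and
#' `monophyly_report.tsv`.
#'
#' @param alignment path to an aligned FASTA.
#' @param metadata path to the metadata TSV (for clade labels).
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return List with `tree` (rooted `phylo`) and `monophyly` tibble,
#'   invisibly.
#' @export
pipeline_tree <- function(alignment, metadata, out_dir,
                          config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  msa <- read_alignment(alignment)
  md <- read_metadata(metadata)
  D <- poisson_distance(msa)
  tree <- midpoint_root(neighbor_joining(D))
  clades <- md[md$id %in% msa$ids, ]
  mono <- clades |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(monophyletic = vapply(.data$clade, function(cl) {
      is_monophyletic(tree, clades$id[clades$clade == cl])
    }, logical(1)))
  write_newick(tree, file.path(out_dir, "tree.nwk"))
  utils::write.table(mono, file.path(out_dir, "monophyly_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(out_dir, "tree", config,
                  list(input = length(msa$ids), surviving = length(msa$ids)))
  invisible(list(tree = tree, monophyly = mono))
}

#' Pipeline stage: motifs
#'
#' Projects reference boundaries through the alignment, extracts and
#' classifies linker tetrapeptides, and writes `sites.tsv`, per-clade
#' `logos/<clade>.json` and `clade_summary.tsv`.
#'
#' @param alignment path to an aligned FASTA.
#' @param metadata path to the metadata TSV.
#' @param boundaries path to a boundaries YAML (see [write_boundaries()]).
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return List with `sites`, `summary`, invisibly.
#' @export
pipeline_motifs <- function(alignment, metadata, boundaries, out_dir,
                            config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  msa <- read_alignment(alignment)
  md <- read_metadata(metadata)
  ref <- read_boundaries(boundaries)
  records <- tibble(id = msa$ids,
                    sequence = gsub("-", "", msa$rows, fixed = TRUE)) |>
    dplyr::left_join(md, by = "id") |>
    dplyr::mutate(clade = dplyr::coalesce(.data$clade, ""))
  sites <- extract_linker_sites(msa, records, ref, config$yvad_threshold)
  summary <- clade_summary(sites, records)
  utils::write.table(sites, file.path(out_dir, "sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dir.create(file.path(out_dir, "logos"), showWarnings = FALSE)
  for (cl in unique(sites$clade)) {
    sub <- sites[sites$clade == cl, ]
    if (nrow(sub) > 0) {
      write_logo_json(build_logo(sub),
                      file.path(out_dir, "logos", paste0(cl, ".json")))
    }
  }
  utils::write.table(summary, file.path(out_dir, "clade_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(out_dir, "motifs", config,
                  list(input = length(msa$ids), surviving = length(msa$ids),
                       n_sites = nrow(sites), n_clades = nrow(summary)))
  invisible(list(sites = sites, summary = summary))
}

#' Pipeline stage: report
#'
#' Collects the stage manifests under a run directory into one
#' reconciling report (JSON plus human-readable text).
#'
#' @param run_dir directory containing the stage outputs.
#' @return The report list, invisibly.
#' @export
pipeline_report <- function(run_dir) {
  manifests <- list.files(run_dir, pattern = "_manifest\\.json$",
                          recursive = TRUE, full.names = TRUE)
  stages <- lapply(manifests, jsonlite::read_json)
  names(stages) <- vapply(stages, function(s) s$stage, character(1))
  for (s in stages) {
    cnt <- s$counts
    if (!is.null(cnt$input) && !is.null(cnt$surviving)) {
      removed <- sum(unlist(cnt[grepl("removed", names(cnt))]))
      if (cnt$input != cnt$surviving + removed) {
        stop("stage '", s$stage, "' counts do not reconcile", call. = FALSE)
      }
    }
  }
  report <- list(tool = "gasderminevo",
                 version = as.character(utils::packageVersion("gasderminevo")),
                 stages = stages)
  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  txt <- c("gasderminevo run report",
           vapply(stages, function(s) {
             paste0("  ", s$stage, ": ",
                    paste(names(s$counts), unlist(s$counts), sep = "=",
                          collapse = ", "))
           }, character(1)))
  writeLines(txt, file.path(run_dir, "report.txt"))
  invisible(report)
}
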