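#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a clade-structured
#' species tree, gasdermin-like proteins built as a conserved N-terminal
#' domain, a poorly conserved variable-length linker and a conserved
#' C-terminal domain, clade-specific tetrapeptides planted in a fraction
#' of linkers (followed by the glycine-proline context typical of
#' caspase-1 substrates), and unrelated decoy proteins.
#'
#' @param seed integer seed; a fixed seed makes the whole bundle
#'   byte-identical across runs.
#' @param clades tibble with columns `name`, `n_taxa`, `motif`,
#'   `planted_fraction`. The default plants YVAD in birds and
#'   bulky-P4 tetrapeptides elsewhere, in every linker.
#' @param birth_rate per-lineage speciation rate of the pure-birth clade
#'   trees (events per unit time).
#' @param branch_scale expected substitutions per site per unit time.
#' @param stem_length time length of the stem branch joining each clade to
#'   the root; with the default `branch_scale` the clade-separating
#'   branches are 0.3 expected substitutions per site.
#' @param nterm_length,cterm_length domain lengths in residues.
#' @param linker_length_range length-2 integer range of linker lengths.
#' @param n_decoys number of decoy proteins.
#' @param decoy_length_range length-2 integer range of decoy lengths.
#' @param ortho_divergence extra divergence (expected substitutions per
#'   site) used to derive the second copy of each ortholog pair.
#' @param contigs also emit nucleotide contigs embedding back-translated
#'   family members (default `FALSE`).
#' @param contig_flank random flanking nucleotides per contig side.
#' @return A list of class `gsdm_sim_config`.
#' @export
simulation_config <- function(
    seed = 1,
    clades = tibble(name = c("bird", "reptile", "amphibian", "mammal"),
                    n_taxa = 8L,
                    motif = c("YVAD", "FVSD", "FASD", "FLTD"),
                    planted_fraction = 1.0),
    birth_rate = 1, branch_scale = 0.06, stem_length = 5,
    nterm_length = 90, linker_length_range = c(15, 30),
    cterm_length = 110, n_decoys = 12, decoy_length_range = c(150, 300),
    ortho_divergence = 0.02, contigs = FALSE, contig_flank = 30) {
  stopifnot(all(c("name", "n_taxa", "motif", "planted_fraction") %in%
                  names(clades)),
            all(clades$planted_fraction >= 0 & clades$planted_fraction <= 1),
            nterm_length > 0, cterm_length > 0,
            linker_length_range[1] >= min(nchar(clades$motif)) + 2,
            linker_length_range[1] <= linker_length_range[2],
            birth_rate > 0, branch_scale >= 0, n_decoys >= 0)
  structure(list(seed = as.integer(seed), clades = as_tibble(clades),
                 birth_rate = birth_rate, branch_scale = branch_scale,
                 stem_length = stem_length, nterm_length = nterm_length,
                 linker_length_range = linker_length_range,
                 cterm_length = cterm_length, n_decoys = n_decoys,
                 decoy_length_range = decoy_length_range,
                 ortho_divergence = ortho_divergence,
                 contigs = contigs, contig_flank = contig_flank),
            class = "gsdm_sim_config")
}

#' Simulate a pure-birth (Yule) species tree
#'
#' Starts from two lineages; while fewer than `n_taxa` lineages exist, an
#' exponential waiting time with rate `k * birth_rate` (k = current
#' lineage count) elapses and a uniformly chosen lineage splits. After the
#' n-th lineage appears a final exponential waiting time with rate
#' `n * birth_rate` elapses, so the expected root-to-tip depth is
#' `sum_{k=2..n} 1 / (k * birth_rate)`.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param birth_rate per-lineage speciation rate.
#' @param seed optional seed (`set.seed` when non-`NULL`).
#' @param tip_prefix prefix for leaf labels (`t1`, `t2`, ... by default).
#' @return A rooted `phylo` tree with branch lengths in time units.
#' @export
simulate_yule_tree <- function(n_taxa, birth_rate = 1, seed = NULL,
                               tip_prefix = "t") {
  stopifnot(n_taxa >= 2, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  # active lineages: birth time of each
  birth <- c(0, 0)
  parent_node <- c(1L, 1L)     # provisional internal-node id of parent
  next_node <- 2L
  node_parent <- c(NA_integer_)   # parent of each internal node
  node_time <- c(0)               # time of each internal node
  t_now <- 0
  while (length(birth) < n_taxa) {
    k <- length(birth)
    t_now <- t_now + stats::rexp(1, rate = k * birth_rate)
    i <- sample.int(k, 1)
    next_node <- next_node + 1L
    node_parent[next_node - 1L] <- NA  # placeholder growth
    node_time[next_node - 1L] <- t_now
    # new internal node replaces lineage i
    new_id <- next_node - 1L
    node_parent[new_id] <- parent_node[i]
    birth <- c(birth[-i], t_now, t_now)
    parent_node <- c(parent_node[-i], new_id, new_id)
  }
  t_now <- t_now + stats::rexp(1, rate = n_taxa * birth_rate)

  n_int <- next_node - 1L
  tip_ids <- seq_len(n_taxa)
  int_ids <- n_taxa + seq_len(n_int)
  edges <- matrix(0L, 0, 2)
  lengths <- numeric(0)
  for (j in seq_along(birth)) {
    edges <- rbind(edges, c(int_ids[parent_node[j]], tip_ids[j]))
    lengths <- c(lengths, t_now - birth[j])
  }
  if (n_int > 1) {
    for (v in 2:n_int) {
      edges <- rbind(edges, c(int_ids[node_parent[v]], int_ids[v]))
      lengths <- c(lengths, node_time[v] - node_time[node_parent[v]])
    }
  }
  tree <- list(edge = edges, edge.length = lengths,
               tip.label = paste0(tip_prefix, seq_len(n_taxa)),
               Nnode = n_int)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  ape::reorder.phylo(tree)
}

#' Evolve a protein down a tree under the 20-state Jukes-Cantor analog
#'
#' Along a branch of scaled length `d = t * branch_scale` each site
#' differs from its parent with probability
#' `p(d) = (19/20) (1 - exp(-20 d / 19))`; a differing site is replaced
#' uniformly by one of the 19 alternative residues. No indels.
#'
#' @param root_sequence amino-acid string at the root.
#' @param tree a `phylo` tree with branch lengths in time units.
#' @param branch_scale expected substitutions per site per unit time.
#' @param seed optional seed.
#' @return Named character vector of leaf sequences.
#' @export
evolve_protein <- function(root_sequence, tree, branch_scale = 1,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(tree, "phylo"), nzchar(root_sequence))
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- strsplit(root_sequence, "")[[1]]
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    d <- tree$edge.length[e] * branch_scale
    seqs[[child]] <- .mutate_jc20(seqs[[par]], d)
  }
  setNames(vapply(seqs[seq_len(n_tip)], paste, character(1), collapse = ""),
           tree$tip.label)
}

#' Substitution probability of the 20-state Jukes-Cantor analog
#' @param d expected substitutions per site.
#' @return Probability that a site differs from its ancestor.
#' @export
jc20_p <- function(d) (19 / 20) * (1 - exp(-20 * d / 19))

.mutate_jc20 <- function(chars, d) {
  p <- jc20_p(d)
  hit <- stats::runif(length(chars)) < p
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(c0) {
      sample(setdiff(AA20, c0), 1)
    }, character(1))
  }
  chars
}

.random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# positions (in the given window) of aspartates whose P4 residue is bulky
# or itself an aspartate, i.e. would classify caspase-1- or caspase-3-like
.caspase_like_positions <- function(chars) {
  dpos <- which(chars == "D")
  dpos <- dpos[dpos >= 4]
  if (length(dpos) == 0) return(integer(0))
  dpos[chars[dpos - 3] %in% c(bulky_p4_set(), "D")]
}

#' Plant gasdermin-like architecture onto evolved domain sequences
#'
#' Each family protein is assembled as the evolved N-terminal domain, a
#' freshly drawn (hence poorly conserved) linker, and the evolved
#' C-terminal domain. With probability `planted_fraction` the clade's
#' tetrapeptide motif is inserted at a clade-constant offset inside the
#' linker, followed by a `GP` P1'/P2' context; all remaining linker
#' sequence is rejection-sampled so that no unplanted aspartate carries a
#' bulky or aspartate P4, making scanner precision exactly measurable.
#'
#' @param leaf_sequences named character vector of evolved domain
#'   sequences (N-domain and C-domain concatenated), names =
#'   `<clade>_<tip>`.
#' @param config a [simulation_config()].
#' @param seed optional seed.
#' @return A list with `records` (tibble id, taxon, clade, sequence),
#'   `sites` (planted-site truth: sequence_id, p1_position, tetrapeptide,
#'   clade) and `linkers` (truth intervals: sequence_id, start, end).
#' @export
plant_gasdermin <- function(leaf_sequences, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(config, "gsdm_sim_config"))
  nl <- config$nterm_length
  lr <- config$linker_length_range
  clades <- config$clades
  if (any(nchar(clades$motif) + 2 > lr[1])) {
    stop("motif longer than the shortest linker", call. = FALSE)
  }
  clade_of <- sub("_[^_]+$", "", names(leaf_sequences))
  stopifnot(all(clade_of %in% clades$name))
  # clade-constant motif offset within the linker (left filler length)
  offsets <- setNames(vapply(clades$name, function(cn) {
    mlen <- nchar(clades$motif[clades$name == cn])
    sample.int(lr[1] - mlen - 2 + 1, 1) - 1L
  }, integer(1)), clades$name)

  recs <- list(); sites <- list(); linkers <- list()
  for (i in seq_along(leaf_sequences)) {
    id <- names(leaf_sequences)[i]
    cl <- clade_of[i]
    crow <- clades[clades$name == cl, ]
    dom <- leaf_sequences[[i]]
    ndom <- substr(dom, 1, nl)
    cdom <- substr(dom, nl + 1, nchar(dom))
    llen <- sample(seq(lr[1], lr[2]), 1)
    plant <- stats::runif(1) < crow$planted_fraction
    repeat {
      if (plant) {
        left <- offsets[[cl]]
        motif <- crow$motif
        right <- llen - left - nchar(motif) - 2
        linker_chars <- c(sample(AA20, left, replace = TRUE),
                          strsplit(motif, "")[[1]], "G", "P",
                          sample(AA20, right, replace = TRUE))
        planted_rel <- left + nchar(motif)
      } else {
        linker_chars <- sample(AA20, llen, replace = TRUE)
        planted_rel <- NA_integer_
      }
      # unplanted linker aspartates must stay non-caspase-like; the
      # planted D is the motif's own P1 and is exempt. The N-domain tail
      # is included so it can serve as P4 context for linker aspartates;
      # C-domain aspartates are not linker sites and are not checked.
      ctx <- c(strsplit(substring(ndom, nl - 2, nl), "")[[1]], linker_chars)
      bad <- .caspase_like_positions(ctx)
      allowed <- if (plant) 3L + planted_rel else integer(0)
      if (length(setdiff(bad, allowed)) == 0) break
    }
    linker <- paste(linker_chars, collapse = "")
    seqfull <- paste0(ndom, linker, cdom)
    recs[[i]] <- tibble(id = id, taxon = paste0("synthetic_", id),
                        clade = cl, sequence = seqfull)
    linkers[[i]] <- tibble(sequence_id = id, start = nl + 1L,
                           end = nl + as.integer(llen))
    if (plant) {
      p1 <- nl + planted_rel
      sites[[length(sites) + 1]] <-
        tibble(sequence_id = id, p1_position = as.integer(p1),
               tetrapeptide = crow$motif, clade = cl)
    }
  }
  truth_sites <- if (length(sites)) dplyr::bind_rows(sites) else
    tibble(sequence_id = character(), p1_position = integer(),
           tetrapeptide = character(), clade = character())
  list(records = dplyr::bind_rows(recs), sites = truth_sites,
       linkers = dplyr::bind_rows(linkers))
}

#' Generate unrelated decoy proteins
#'
#' Independent uniform-composition proteins labelled clade `decoy`.
#'
#' @param n number of decoys.
#' @param length_range length-2 integer range.
#' @param seed optional seed.
#' @return Tibble of protein records.
#' @export
make_decoys <- function(n, length_range = c(150, 300), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) {
    return(tibble(id = character(), taxon = character(),
                  clade = character(), sequence = character()))
  }
  tibble(id = paste0("decoy", seq_len(n)),
         taxon = "synthetic_decoy", clade = "decoy",
         sequence = vapply(seq_len(n), function(i) {
           .random_protein(sample(seq(length_range[1], length_range[2]), 1))
         }, character(1)))
}

# alphabetically first codon per residue (deterministic back-translation)
.codon_table_first <- function() {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T"))[, 3:1], 1, paste,
                  collapse = "")
  codons <- sort(codons)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(codons), no.init.codon = TRUE))
  tapply(codons, aa, function(x) sort(x)[1])
}

back_translate <- function(protein) {
  tab <- .codon_table_first()
  paste(tab[strsplit(protein, "")[[1]]], collapse = "")
}

#' Generate the full synthetic dataset bundle
#'
#' Builds the clade-structured species tree (per-clade pure-birth trees on
#' stem branches joined at the root), evolves the domain sequences, plants
#' linkers and motifs, adds decoys and an orthologous second copy of every
#' family protein, optionally embeds back-translated family members in
#' nucleotide contigs, and (when `out_dir` is given) writes the bundle:
#' `proteins.fasta`, `orthologs_b.fasta`, `metadata.tsv`,
#' `truth_sites.tsv`, `truth_linkers.tsv`, `truth_orthologs.tsv`,
#' `true_tree.nwk`, `manifest.json` and optionally `contigs.fasta` +
#' `truth_contigs.tsv`.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional output directory (created if needed).
#' @return A list with `records`, `orthologs_b`, `decoys`, `truth` (list:
#'   `tree`, `sites`, `linkers`, `ortholog_pairs`, `contigs`), `contigs`
#'   (tibble or `NULL`) and `paths` (when written).
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "gsdm_sim_config"))
  set.seed(config$seed)

  # species tree: per-clade Yule trees on stems joined at the root
  subtrees <- lapply(seq_len(nrow(config$clades)), function(i) {
    simulate_yule_tree(config$clades$n_taxa[i], config$birth_rate,
                       tip_prefix = paste0(config$clades$name[i], "_t"))
  })
  tree <- if (length(subtrees) == 1) {
    subtrees[[1]]
  } else {
    stems <- vapply(subtrees, function(tr) {
      sub("\\);$", paste0("):", config$stem_length, ""),
          ape::write.tree(tr))
    }, character(1))
    read_newick(paste0("(", paste(stems, collapse = ","), ");"))
  }

  root_seq <- .random_protein(config$nterm_length + config$cterm_length)
  leaf_dom <- evolve_protein(root_seq, tree, config$branch_scale)
  planted <- plant_gasdermin(leaf_dom, config)
  records <- planted$records
  decoys <- make_decoys(config$n_decoys, config$decoy_length_range)

  # ortholog set B: each family protein evolved a little further
  ob <- records
  ob$sequence <- vapply(records$sequence, function(s) {
    paste(.mutate_jc20(strsplit(s, "")[[1]], config$ortho_divergence),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
  ob$id <- paste0(records$id, "_b")
  ortholog_pairs <- tibble(id_a = records$id, id_b = ob$id)

  contigs <- NULL
  truth_contigs <- NULL
  if (isTRUE(config$contigs)) {
    picks <- records |> dplyr::group_by(.data$clade) |> dplyr::slice(1) |>
      dplyr::ungroup()
    frames <- rep_len(c(1L, 2L, 3L, -1L, -2L, -3L), nrow(picks))
    rows <- purrr::map(seq_len(nrow(picks)), function(i) {
      cds <- back_translate(picks$sequence[i])
      fl1 <- paste(sample(c("A", "C", "G", "T"), config$contig_flank,
                          replace = TRUE), collapse = "")
      fl2 <- paste(sample(c("A", "C", "G", "T"), config$contig_flank,
                          replace = TRUE), collapse = "")
      f <- frames[i]
      lead <- abs(f) - 1L
      fwd <- paste0(fl1, strrep("A", lead), "TAA", cds, "TAA", fl2)
      # the planted ORF begins right after the TAA stop in frame
      seqn <- if (f > 0) fwd else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
      tibble(contig_id = paste0("contig_", picks$id[i]), sequence = seqn,
             sequence_id = picks$id[i], frame = f)
    })
    cdf <- dplyr::bind_rows(rows)
    contigs <- cdf[, c("contig_id", "sequence")]
    truth_contigs <- cdf[, c("contig_id", "sequence_id", "frame")]
  }

  truth <- list(tree = tree, sites = planted$sites,
                linkers = planted$linkers,
                ortholog_pairs = ortholog_pairs, contigs = truth_contigs)
  # every planted site must lie inside its recorded linker
  chk <- dplyr::inner_join(planted$sites, planted$linkers,
                           by = "sequence_id")
  stopifnot(all(chk$p1_position >= chk$start & chk$p1_position <= chk$end))

  out <- list(records = records, orthologs_b = ob, decoys = decoys,
              truth = truth, contigs = contigs, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_fasta(dplyr::bind_rows(records, decoys), p("proteins.fasta"))
    write_fasta(ob, p("orthologs_b.fasta"))
    write_metadata(dplyr::bind_rows(records, decoys)[, c("id", "taxon", "clade")],
                   p("metadata.tsv"))
    utils::write.table(planted$sites, p("truth_sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(planted$linkers, p("truth_linkers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ortholog_pairs, p("truth_orthologs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_newick(tree, p("true_tree.nwk"))
    if (!is.null(contigs)) {
      writeLines(paste0(">", contigs$contig_id, "\n", contigs$sequence),
                 p("contigs.fasta"))
      utils::write.table(truth_contigs, p("truth_contigs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    manifest <- list(tool = "gasderminevo",
                     version = as.character(utils::packageVersion("gasderminevo")),
                     seed = config$seed,
                     config = unclass(config)[setdiff(names(unclass(config)),
                                                      "clades")],
                     clades = config$clades)
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    out$paths <- setNames(file.path(out_dir,
                                    list.files(out_dir)), list.files(out_dir))
  }
  out
}
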