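#' Read protein records from a FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file into a tibble of protein
#' records. The header token before the first whitespace becomes the record
#' id; the remainder of the header is parsed as `taxon=..;clade=..`
#' key-value metadata when present, otherwise taxon and clade are empty
#' strings. Sequences are uppercased and validated against the 20-letter
#' amino-acid alphabet plus `X`.
#'
#' @param path path to a FASTA file.
#' @return A tibble with columns `id`, `taxon`, `clade`, `sequence`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    return(tibble(id = character(), taxon = character(),
                  clade = character(), sequence = character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate sequence id in FASTA: '", dup, "'", call. = FALSE)
  }
  meta <- .parse_header_meta(headers)
  seqs <- toupper(as.character(set))
  .validate_sequences(seqs, ids)
  tibble(id = unname(ids), taxon = meta$taxon, clade = meta$clade,
         sequence = unname(seqs))
}

.parse_header_meta <- function(headers) {
  rest <- sub("^\\S+\\s*", "", headers)
  get_kv <- function(key) {
    m <- regmatches(rest, regexpr(paste0(key, "=[^;[:space:]]+"), rest))
    out <- character(length(rest))
    hit <- grepl(paste0(key, "="), rest)
    out[hit] <- sub(paste0("^", key, "="), "",
                    regmatches(rest, regexpr(paste0(key, "=[^;[:space:]]+"), rest)))
    out
  }
  list(taxon = get_kv("taxon"), clade = get_kv("clade"))
}

.validate_sequences <- function(seqs, ids) {
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for id '", ids[nchar(seqs) == 0][1], "'", call. = FALSE)
  }
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("illegal character '", substr(seqs[i], bad[i], bad[i]),
         "' at position ", bad[i], " in sequence '", ids[i], "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: metadata (when non-empty) is serialised into
#' the header as `taxon=..;clade=..`.
#'
#' @param records tibble with columns `id`, `sequence` and optionally
#'   `taxon`, `clade`.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  taxon <- if ("taxon" %in% names(records)) records$taxon else ""
  clade <- if ("clade" %in% names(records)) records$clade else ""
  meta <- ifelse(taxon == "" & clade == "", "",
                 paste0(" taxon=", taxon, ";clade=", clade))
  set <- Biostrings::BStringSet(setNames(records$sequence,
                                         paste0(records$id, meta)))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read / write the per-sequence metadata table
#'
#' Tab-separated table with columns `id`, `taxon`, `clade`.
#'
#' @param path file path.
#' @return A tibble (for the reader); `path` invisibly (for the writer).
#' @export
read_metadata <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("id", "taxon", "clade") %in% names(df)))
  as_tibble(df)
}

#' @rdname read_metadata
#' @param metadata tibble with columns `id`, `taxon`, `clade`.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata[, c("id", "taxon", "clade")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fraction of identical residues between two sequences
#'
#' Globally aligns the two sequences (affine gaps) and returns the number
#' of identical aligned residue pairs divided by the length of the shorter
#' sequence (the CD-HIT identity convention).
#'
#' @param a,b amino-acid strings.
#' @param params alignment parameters, see [align_params()].
#' @return A fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  aln <- global_align(a, b, params)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  matches <- sum(ca == cb & ca != "-")
  matches / min(nchar(a), nchar(b))
}

#' Greedy incremental identity clustering
#'
#' Removes redundancy the way CD-HIT does at desk scale: records are sorted
#' longest-first (ties by id), and each record joins the first existing
#' cluster whose representative it matches at `identity_threshold` or
#' better, otherwise it founds a new cluster. The representative of every
#' cluster is therefore its longest member.
#'
#' @param records tibble of protein records.
#' @param identity_threshold fraction in (0, 1\]; default 0.95.
#' @param params alignment parameters used by [pairwise_identity()].
#' @return A tibble with columns `representative_id`, `member_id`.
#' @export
greedy_cluster <- function(records, identity_threshold = 0.95,
                           params = align_params()) {
  stopifnot(nrow(records) >= 1,
            identity_threshold > 0, identity_threshold <= 1)
  ord <- order(-nchar(records$sequence), records$id)
  recs <- records[ord, ]
  reps <- character(0)
  rep_seq <- character(0)
  member_rep <- character(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    assigned <- NA_character_
    for (j in seq_along(reps)) {
      if (pairwise_identity(recs$sequence[i], rep_seq[j], params) >=
          identity_threshold) {
        assigned <- reps[j]
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, recs$id[i])
      rep_seq <- c(rep_seq, recs$sequence[i])
      assigned <- recs$id[i]
    }
    member_rep[i] <- assigned
  }
  tibble(representative_id = member_rep, member_id = recs$id)
}

#' Reciprocal-best-hit ortholog pairing
#'
#' For every sequence in `set_a`, finds its best local-alignment match in
#' `set_b` and vice versa; a pair is emitted when the two best hits are
#' mutual and the alignment score reaches `min_score`. Score ties are
#' broken by lexicographic id (and reported via a message).
#'
#' @param set_a,set_b tibbles of protein records.
#' @param min_score minimum raw local-alignment score (default 50).
#' @param params alignment parameters.
#' @return A tibble with columns `id_a`, `id_b`, `score`, one row per
#'   reciprocal pair; each id appears at most once.
#' @export
reciprocal_best_hits <- function(set_a, set_b, min_score = 50,
                                 params = align_params()) {
  if (nrow(set_a) == 0 || nrow(set_b) == 0) {
    return(tibble(id_a = character(), id_b = character(), score = numeric()))
  }
  a <- set_a[order(set_a$id), ]
  b <- set_b[order(set_b$id), ]
  S <- matrix(0, nrow(a), nrow(b), dimnames = list(a$id, b$id))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      S[i, j] <- local_align(a$sequence[i], b$sequence[j], params)$score
    }
  }
  best_b <- apply(S, 1, function(r) {
    w <- which(r == max(r))
    if (length(w) > 1) message("reciprocal_best_hits: score tie broken by id")
    w[1]
  })
  best_a <- apply(S, 2, function(cl) which(cl == max(cl))[1])
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    j <- best_b[i]
    if (best_a[j] == i && S[i, j] >= min_score) {
      pairs[[length(pairs) + 1]] <-
        tibble(id_a = a$id[i], id_b = b$id[j], score = S[i, j])
    }
  }
  if (length(pairs) == 0) {
    return(tibble(id_a = character(), id_b = character(), score = numeric()))
  }
  dplyr::bind_rows(pairs)
}

#' Remove partial sequences from an alignment
#'
#' Drops every row whose non-gap residue count is below half the alignment
#' length or whose gap fraction exceeds one half (both criteria strict, so
#' a row sitting exactly at 50 percent is retained). The column set is
#' unchanged; the operation is idempotent.
#'
#' @param msa a [gsdm_msa] multiple alignment.
#' @return The trimmed alignment.
#' @export
trim_partial <- function(msa) {
  stopifnot(inherits(msa, "gsdm_msa"), length(msa$ids) >= 1)
  w <- msa_width(msa)
  nongap <- nchar(gsub("-", "", msa$rows, fixed = TRUE))
  gap_frac <- (w - nongap) / w
  keep <- !(nongap < 0.5 * w | gap_frac > 0.5)
  if (!any(keep)) stop("empty alignment after trimming", call. = FALSE)
  new_msa(msa$ids[keep], msa$rows[keep], check_all_gap = FALSE)
}
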