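#' Choose match columns for profile construction
#'
#' Columns whose gap fraction is at most `gap_threshold` become match
#' states of the profile HMM, in column order.
#'
#' @param msa a [new_msa()] alignment.
#' @param gap_threshold fraction in (0, 1); default 0.5.
#' @return Integer vector of column indices.
#' @export
assign_match_columns <- function(msa, gap_threshold = 0.5) {
  stopifnot(inherits(msa, "gsdm_msa"),
            gap_threshold > 0, gap_threshold < 1)
  m <- as.matrix(msa)
  gap_frac <- colMeans(m == "-")
  idx <- which(gap_frac <= gap_threshold)
  if (length(idx) == 0) stop("no match columns at gap threshold ",
                             gap_threshold, call. = FALSE)
  idx
}

#' Build a profile HMM from a curated alignment
#'
#' Constructs a match/insert/delete profile hidden Markov model in the
#' standard way: match columns are chosen by gap fraction, emission
#' probabilities are background-weighted pseudocount-smoothed column
#' counts, and transition probabilities are pseudocount-smoothed counts of
#' the state paths implied by each row. The background defaults to the
#' uniform distribution over the 20 amino acids.
#'
#' @param msa a [new_msa()] alignment.
#' @param gap_threshold match-column gap threshold (default 0.5).
#' @param pseudocount pseudocount weight (default 1; Laplace-style,
#'   background-weighted for emissions).
#' @param background numeric probability vector over the 20 amino acids.
#' @return An object of class `gsdm_profile_hmm`.
#' @export
build_profile <- function(msa, gap_threshold = 0.5, pseudocount = 1,
                          background = rep(1 / 20, 20)) {
  stopifnot(inherits(msa, "gsdm_msa"), length(background) == 20,
            abs(sum(background) - 1) < 1e-9, pseudocount >= 0)
  match_cols <- assign_match_columns(msa, gap_threshold)
  m <- as.matrix(msa)
  L <- length(match_cols)
  n_col <- ncol(m)
  bg <- setNames(as.numeric(background), AA20)

  count_residues <- function(chars) {
    tab <- table(factor(chars[chars %in% AA20], levels = AA20))
    as.numeric(tab)
  }

  match_em <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (k in seq_len(L)) {
    cnt <- count_residues(m[, match_cols[k]])
    match_em[k, ] <- (cnt + pseudocount * bg) / (sum(cnt) + pseudocount)
  }

  # insert state k sits between match columns k and k+1 (I0 before M1)
  col_state <- findInterval(seq_len(n_col), match_cols)  # insert slot index
  insert_em <- matrix(0, L + 1, 20, dimnames = list(NULL, AA20))
  for (k in 0:L) {
    cols <- setdiff(which(col_state == k), match_cols)
    chars <- if (length(cols)) as.vector(m[, cols, drop = FALSE]) else character(0)
    cnt <- count_residues(chars)
    insert_em[k + 1, ] <- (cnt + pseudocount * bg) / (sum(cnt) + pseudocount)
  }

  # transition counts from per-row state paths
  is_match_col <- seq_len(n_col) %in% match_cols
  cM <- matrix(0, L + 1, 3)  # from M_k to (M_{k+1}|E, I_k, D_{k+1})
  cI <- matrix(0, L + 1, 3)
  cD <- matrix(0, L + 1, 3)
  for (r in seq_len(nrow(m))) {
    prev <- c("M", 0)
    for (j in seq_len(n_col)) {
      ch <- m[r, j]
      k_here <- col_state[j]
      if (is_match_col[j]) {
        this <- if (ch == "-") c("D", k_here) else c("M", k_here)
      } else {
        if (ch == "-") next
        this <- c("I", k_here)
      }
      pk <- as.integer(prev[2]) + 1
      slot <- switch(this[1], M = 1, I = 2, D = 3)
      if (prev[1] == "M") cM[pk, slot] <- cM[pk, slot] + 1
      if (prev[1] == "I") cI[pk, slot] <- cI[pk, slot] + 1
      if (prev[1] == "D") cD[pk, slot] <- cD[pk, slot] + 1
      prev <- this
    }
    pk <- as.integer(prev[2]) + 1  # transition to end
    if (prev[1] == "M") cM[pk, 1] <- cM[pk, 1] + 1
    if (prev[1] == "I") cI[pk, 1] <- cI[pk, 1] + 1
    if (prev[1] == "D") cD[pk, 1] <- cD[pk, 1] + 1
  }

  norm_tr <- function(cnt) {
    out <- matrix(0, L + 1, 3)
    for (k in seq_len(L + 1)) {
      valid <- if (k == L + 1) c(TRUE, TRUE, FALSE) else c(TRUE, TRUE, TRUE)
      v <- cnt[k, ] + pseudocount * valid
      out[k, valid] <- v[valid] / sum(v[valid])
    }
    out
  }
  tM <- norm_tr(cM); tI <- norm_tr(cI); tD <- norm_tr(cD)
  tD[1, ] <- 0  # D_0 does not exist

  hmm <- structure(list(n_match = L, match_emissions = match_em,
                        insert_emissions = insert_em,
                        tM = tM, tI = tI, tD = tD,
                        background = bg, match_columns = match_cols),
                   class = "gsdm_profile_hmm")
  .validate_hmm(hmm)
  hmm
}

.validate_hmm <- function(hmm) {
  stopifnot(hmm$n_match >= 1,
            all(abs(rowSums(hmm$match_emissions) - 1) < 1e-9),
            all(abs(rowSums(hmm$insert_emissions) - 1) < 1e-9),
            all(hmm$match_emissions > 0))
  tr_rows <- rbind(hmm$tM, hmm$tI, hmm$tD[-1, , drop = FALSE])
  stopifnot(all(abs(rowSums(tr_rows) - 1) < 1e-9))
  invisible(hmm)
}

#' @export
print.gsdm_profile_hmm <- function(x, ...) {
  cat("<gsdm_profile_hmm> ", x$n_match, " match states; consensus: ",
      consensus(x), "\n", sep = "")
  invisible(x)
}

.encode_seq <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  code <- match(ch, c(AA20, "X"))
  if (anyNA(code)) {
    stop("illegal character '", ch[which(is.na(code))[1]], "' in sequence",
         call. = FALSE)
  }
  code
}

.hmm_log_matrices <- function(hmm) {
  match_lo <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  ins_lo <- log2(sweep(hmm$insert_emissions, 2, hmm$background, "/"))
  list(match_lo = cbind(match_lo, 0),  # X scores 0 (uninformative)
       ins_lo = cbind(ins_lo, 0),
       tM = log2(hmm$tM), tI = log2(hmm$tI), tD = log2(hmm$tD))
}

#' Viterbi score and state path
#'
#' Scores a sequence against a profile HMM in local mode: free flanking
#' states let the model match anywhere inside the sequence, and the score
#' is the log2-odds (bits) of the best state path against the background.
#'
#' @param seq amino-acid string.
#' @param hmm a [build_profile()] model.
#' @return A list with `bits`, a tibble `path` (columns `state`, `k`,
#'   `position`; position 0 for delete states), and the 1-based `start`,
#'   `end` of the matched segment.
#' @export
viterbi <- function(seq, hmm) {
  stopifnot(nzchar(seq), inherits(hmm, "gsdm_profile_hmm"))
  lm <- .hmm_log_matrices(hmm)
  res <- .hmm_viterbi_cpp(.encode_seq(seq), lm$match_lo, lm$ins_lo,
                          lm$tM, lm$tI, lm$tD)
  list(bits = res$score,
       path = tibble(state = c("M", "I", "D")[res$state_type + 1],
                     k = res$state_k, position = res$seq_pos),
       start = res$start, end = res$end)
}

#' Forward (total log-odds) score
#'
#' Log2 of the summed odds over all state paths; always at least the
#' Viterbi score.
#'
#' @inheritParams viterbi
#' @return Bits (numeric scalar).
#' @export
forward <- function(seq, hmm) {
  stopifnot(nzchar(seq), inherits(hmm, "gsdm_profile_hmm"))
  lm <- .hmm_log_matrices(hmm)
  .hmm_forward_cpp(.encode_seq(seq), lm$match_lo, lm$ins_lo,
                   lm$tM, lm$tI, lm$tD)
}

#' Scan protein records with a profile HMM
#'
#' Computes the best (Viterbi) hit per record and keeps those reaching the
#' bit threshold, sorted by descending score.
#'
#' @param hmm a profile HMM.
#' @param records tibble of protein records.
#' @param bits_threshold minimum bit score (default 20).
#' @return Tibble with columns `sequence_id`, `bits`, `start`, `end`,
#'   `frame` (0 for protein input).
#' @export
scan_proteins <- function(hmm, records, bits_threshold = 20) {
  if (nrow(records) == 0) {
    return(tibble(sequence_id = character(), bits = numeric(),
                  start = integer(), end = integer(), frame = integer()))
  }
  hits <- purrr::map(seq_len(nrow(records)), function(i) {
    v <- viterbi(records$sequence[i], hmm)
    tibble(sequence_id = records$id[i], bits = v$bits,
           start = v$start, end = v$end, frame = 0L)
  })
  dplyr::bind_rows(hits) |>
    dplyr::filter(.data$bits >= bits_threshold) |>
    dplyr::arrange(dplyr::desc(.data$bits))
}

#' Six-frame translation scan of a nucleotide contig
#'
#' Translates all six reading frames with the standard genetic code,
#' splits at stop codons, and scans every open reading frame of at least
#' `min_orf_aa` residues with the profile. Hit coordinates are reported in
#' the amino-acid space of the ORF; `orf_offset` gives the ORF's 0-based
#' start within its frame translation.
#'
#' @param contig nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param hmm a profile HMM.
#' @param min_orf_aa minimum ORF length in residues (default 50).
#' @param bits_threshold minimum bit score (default 20).
#' @param contig_id id used in the output (default `"contig"`).
#' @return Tibble with columns `sequence_id`, `bits`, `start`, `end`,
#'   `frame`, `orf_offset`, sorted by descending score.
#' @export
six_frame_scan <- function(contig, hmm, min_orf_aa = 50, bits_threshold = 20,
                           contig_id = "contig") {
  contig <- toupper(contig)
  bad <- regexpr("[^ACGTN]", contig)
  if (bad > 0) {
    stop("non-nucleotide character '", substr(contig, bad, bad),
         "' at position ", bad, call. = FALSE)
  }
  out <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    s <- if (frame > 0) contig else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(contig)))
    off <- abs(frame)
    len <- nchar(s) - off + 1
    len <- len - (len %% 3)
    if (len < 3) next
    sub <- substr(s, off, off + len - 1)
    aa <- suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAString(sub),
                            if.fuzzy.codon = "solve")))
    orfs <- strsplit(aa, "*", fixed = TRUE)[[1]]
    offset <- 0L
    for (orf in orfs) {
      if (nchar(orf) >= min_orf_aa) {
        v <- viterbi(orf, hmm)
        if (v$bits >= bits_threshold) {
          out[[length(out) + 1]] <- tibble(
            sequence_id = contig_id, bits = v$bits,
            start = v$start, end = v$end, frame = frame,
            orf_offset = offset)
        }
      }
      offset <- offset + nchar(orf) + 1L
    }
  }
  if (length(out) == 0) {
    return(tibble(sequence_id = character(), bits = numeric(),
                  start = integer(), end = integer(), frame = integer(),
                  orf_offset = integer()))
  }
  dplyr::bind_rows(out) |> dplyr::arrange(dplyr::desc(.data$bits))
}

#' Consensus sequence of a profile HMM
#'
#' The highest-probability residue of each match state; ties are broken
#' alphabetically.
#'
#' @param hmm a profile HMM.
#' @return An amino-acid string of length `n_match`.
#' @export
consensus <- function(hmm) {
  stopifnot(inherits(hmm, "gsdm_profile_hmm"))
  paste(apply(hmm$match_emissions, 1, function(p) {
    cand <- AA20[p >= max(p) - 1e-12]
    sort(cand)[1]
  }), collapse = "")
}

#' Serialise / read a profile HMM as JSON
#'
#' Versioned JSON schema carrying match count, emissions, transitions and
#' background.
#'
#' @param hmm a profile HMM.
#' @param path file path.
#' @return `path` invisibly (writer); a `gsdm_profile_hmm` (reader).
#' @export
write_profile_json <- function(hmm, path) {
  obj <- list(schema = "gasderminevo-profile-1",
              n_match = hmm$n_match,
              match_emissions = hmm$match_emissions,
              insert_emissions = hmm$insert_emissions,
              tM = hmm$tM, tI = hmm$tI, tD = hmm$tD,
              background = as.numeric(hmm$background),
              match_columns = hmm$match_columns)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "gasderminevo-profile-1")) {
    stop("unrecognised profile schema", call. = FALSE)
  }
  fixm <- function(m, nc = 20) {
    m <- as.matrix(m)
    colnames(m) <- if (nc == 20) AA20 else NULL
    m
  }
  hmm <- structure(list(
    n_match = as.integer(obj$n_match),
    match_emissions = fixm(obj$match_emissions),
    insert_emissions = fixm(obj$insert_emissions),
    tM = fixm(obj$tM, 3), tI = fixm(obj$tI, 3), tD = fixm(obj$tD, 3),
    background = setNames(as.numeric(obj$background), AA20),
    match_columns = as.integer(obj$match_columns)),
    class = "gsdm_profile_hmm")
  .validate_hmm(hmm)
  hmm
}
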