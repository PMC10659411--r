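# Independent oracles used across the suite. These deliberately use naive
# exhaustive enumeration (never the package's dynamic programming) so that
# agreement is meaningful.

# --- exhaustive affine-gap global alignment ---------------------------------
# enumerate every alignment path from (0,0) to (n,m); affine cost
# open + L*extend per gap; returns the optimal score.
brute_global_score <- function(a, b, sub = blosum62(), open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i == n && j == m) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i < n && j < m) {
      rec(i + 1, j + 1, "M", acc + sub[ca[i + 1], cb[j + 1]])
    }
    if (i < n) {
      cost <- if (last == "U") ext else open + ext
      rec(i + 1, j, "U", acc - cost)
    }
    if (j < m) {
      cost <- if (last == "L") ext else open + ext
      rec(i, j + 1, "L", acc - cost)
    }
  }
  rec(0, 0, "S", 0)
  best
}

# exhaustive local score: best global score over all substring pairs, or 0
brute_local_score <- function(a, b, sub = blosum62(), open = 11, ext = 1) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i1 in seq_len(na)) for (i2 in i1:na) {
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      s <- brute_global_score(substr(a, i1, i2), substr(b, j1, j2),
                              sub, open, ext)
      best <- max(best, s)
    }
  }
  best
}

# --- exhaustive profile-HMM path enumeration --------------------------------
# enumerate every (entry flank, model path, exit flank) combination for a
# sequence against an hmm; returns all path log2-odds scores.
brute_hmm_path_scores <- function(seq, hmm) {
  chars <- strsplit(seq, "")[[1]]
  codes <- match(chars, c(AA20, "X"))
  n <- length(codes)
  L <- hmm$n_match
  em_lo <- function(k, x) {
    if (x == 21) return(0)
    log2(hmm$match_emissions[k, x] / hmm$background[x])
  }
  ins_lo <- function(k, x) {
    if (x == 21) return(0)
    log2(hmm$insert_emissions[k + 1, x] / hmm$background[x])
  }
  tr <- function(mat, k, slot) log2(mat[k + 1, slot])
  scores <- numeric(0)
  # DFS from state (type, k) having consumed `pos` residues, accumulated acc
  dfs <- function(type, k, pos, acc) {
    if (!is.finite(acc)) return(invisible())
    tmat <- switch(type, M = hmm$tM, I = hmm$tI, D = hmm$tD)
    # to M_{k+1} (or E when k == L)
    if (k == L) {
      scores <<- c(scores, acc + tr(tmat, k, 1))  # exit; rest is free flank
    } else if (pos < n) {
      dfs("M", k + 1, pos + 1,
          acc + tr(tmat, k, 1) + em_lo(k + 1, codes[pos + 1]))
    }
    # to I_k
    if (pos < n) {
      dfs("I", k, pos + 1, acc + tr(tmat, k, 2) + ins_lo(k, codes[pos + 1]))
    }
    # to D_{k+1}
    if (k < L) {
      dfs("D", k + 1, pos, acc + tr(tmat, k, 3))
    }
    invisible()
  }
  for (entry in 0:n) dfs("M", 0, entry, 0)  # begin after `entry` flank residues
  scores
}

brute_viterbi_bits <- function(seq, hmm) max(brute_hmm_path_scores(seq, hmm))
brute_forward_bits <- function(seq, hmm) {
  s <- brute_hmm_path_scores(seq, hmm)
  log2(sum(2^s))
}

# --- small shared fixtures --------------------------------------------------
toy_records <- function() {
  tibble::tibble(
    id = c("a", "b", "c"),
    taxon = c("tax_a", "tax_b", "tax_c"),
    clade = c("bird", "bird", "reptile"),
    sequence = c("MKVLQAW", "MKVLQW", "MKVAQAW"))
}

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

small_sim_config <- function(seed = 1, ...) {
  simulation_config(
    seed = seed,
    clades = tibble::tibble(name = c("bird", "reptile"),
                            n_taxa = 4L,
                            motif = c("YVAD", "FVSD"),
                            planted_fraction = 1.0),
    nterm_length = 40, cterm_length = 50,
    linker_length_range = c(10, 16), n_decoys = 4,
    decoy_length_range = c(80, 120), ...)
}
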