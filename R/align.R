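#' Optimal global alignment with affine gaps
#'
#' Needleman-Wunsch-style global alignment of two amino-acid strings under
#' a substitution matrix and affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_extend`). Traceback ties are broken deterministically
#' in the order diagonal, then up, then left.
#'
#' @param a,b amino-acid strings (non-empty).
#' @param params alignment parameters, see [align_params()].
#' @return A list of class `gsdm_alignment` with elements `aligned_a`,
#'   `aligned_b` (gapped strings) and `score`.
#' @export
#' @examples
#' global_align("MKVLQ", "MKQ")$score
global_align <- function(a, b, params = align_params()) {
  .check_seq_pair(a, b)
  S <- .pair_score_matrix(a, b, params$matrix)
  res <- .affine_align_cpp(S, params$gap_open, params$gap_extend, FALSE)
  .alignment_from_path(a, b, res)
}

#' Optimal local alignment with affine gaps
#'
#' Smith-Waterman-style local alignment. The empty alignment (score 0) is
#' returned when no residue pairing scores positively.
#'
#' @inheritParams global_align
#' @return A `gsdm_alignment` list; `aligned_a`/`aligned_b` are empty
#'   strings when the optimum is the empty alignment.
#' @export
local_align <- function(a, b, params = align_params()) {
  .check_seq_pair(a, b)
  S <- .pair_score_matrix(a, b, params$matrix)
  res <- .affine_align_cpp(S, params$gap_open, params$gap_extend, TRUE)
  .alignment_from_path(a, b, res)
}

.check_seq_pair <- function(a, b) {
  if (!is.character(a) || !is.character(b) || !nzchar(a) || !nzchar(b)) {
    stop("both sequences must be non-empty strings", call. = FALSE)
  }
}

.pair_score_matrix <- function(a, b, sub) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (!all(ca %in% rownames(sub)) || !all(cb %in% rownames(sub))) {
    stop("sequence contains residues outside the substitution matrix",
         call. = FALSE)
  }
  sub[ca, cb, drop = FALSE]
}

.alignment_from_path <- function(a, b, res) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ai <- res$a_idx
  bi <- res$b_idx
  aligned_a <- paste(ifelse(ai == 0, "-", ca[pmax(ai, 1)]), collapse = "")
  aligned_b <- paste(ifelse(bi == 0, "-", cb[pmax(bi, 1)]), collapse = "")
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = res$score),
            class = "gsdm_alignment")
}

#' @export
print.gsdm_alignment <- function(x, ...) {
  cat("<gsdm_alignment> score =", x$score, "\n")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Shared k-mer distance matrix
#'
#' Distance between two sequences is `1 - shared / min(n_a, n_b)` where
#' `shared` counts distinct k-mers present in both and `n_a`, `n_b` count
#' distinct k-mers of each sequence. Used to seed the progressive-alignment
#' guide tree.
#'
#' @param records tibble of protein records.
#' @param k word length (default 3); every sequence must be at least k long.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
kmer_distance_matrix <- function(records, k = 3) {
  stopifnot(k >= 1)
  if (any(nchar(records$sequence) < k)) {
    stop("sequence shorter than k = ", k, call. = FALSE)
  }
  kmers <- lapply(records$sequence, function(s) {
    unique(substring(s, seq_len(nchar(s) - k + 1), seq_len(nchar(s) - k + 1) + k - 1))
  })
  n <- nrow(records)
  D <- matrix(0, n, n, dimnames = list(records$id, records$id))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        shared <- length(intersect(kmers[[i]], kmers[[j]]))
        d <- 1 - shared / min(length(kmers[[i]]), length(kmers[[j]]))
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  D
}

#' Progressive multiple alignment
#'
#' UPGMA-guided progressive profile-profile alignment: leaves of the guide
#' tree are aligned pairwise and internal nodes align the two child
#' profiles with average-linkage column scores (gap characters contribute
#' zero to the column score) under the same affine gap penalties as
#' [global_align()]. Row order in the result follows the input order.
#'
#' @param records tibble of protein records.
#' @param guide optional guide tree (`phylo`) whose tip labels equal the
#'   record ids; when `NULL` a UPGMA tree on [kmer_distance_matrix()]
#'   (k = 3) is used.
#' @param params alignment parameters.
#' @return A [new_msa()] multiple alignment.
#' @export
progressive_align <- function(records, guide = NULL, params = align_params()) {
  stopifnot(nrow(records) >= 1)
  if (nrow(records) == 1) {
    return(new_msa(records$id, records$sequence))
  }
  if (is.null(guide)) {
    k <- min(3, min(nchar(records$sequence)))
    D <- kmer_distance_matrix(records, k = k)
    guide <- ape::as.phylo(stats::hclust(stats::as.dist(D), method = "average"))
  }
  if (!setequal(guide$tip.label, records$id)) {
    stop("guide tree leaves do not match record ids", call. = FALSE)
  }
  seqs <- setNames(records$sequence, records$id)

  tree <- ape::reorder.phylo(guide, "postorder")
  n_tip <- length(tree$tip.label)
  profiles <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) {
    profiles[[i]] <- list(ids = tree$tip.label[i],
                          rows = unname(seqs[tree$tip.label[i]]))
  }
  # merge children at each internal node in postorder
  for (node in unique(tree$edge[, 1])) {
    children <- tree$edge[tree$edge[, 1] == node, 2]
    prof <- profiles[[children[1]]]
    for (ch in children[-1]) {
      prof <- .align_profiles(prof, profiles[[ch]], params)
    }
    profiles[[node]] <- prof
  }
  root <- n_tip + 1
  out <- profiles[[root]]
  ord <- match(records$id, out$ids)
  msa <- new_msa(out$ids[ord], out$rows[ord])
  # construction contract: de-gapping reproduces the inputs
  stopifnot(identical(gsub("-", "", msa$rows, fixed = TRUE),
                      unname(records$sequence)))
  msa
}

# average-linkage profile-profile alignment via the same affine DP
.align_profiles <- function(pa, pb, params) {
  syms <- c(AA20, "X", "-")
  CA <- .profile_counts(pa$rows, syms)
  CB <- .profile_counts(pb$rows, syms)
  M <- matrix(0, length(syms), length(syms), dimnames = list(syms, syms))
  M[1:21, 1:21] <- params$matrix[syms[1:21], syms[1:21]]
  S <- t(CA) %*% M %*% CB / (length(pa$rows) * length(pb$rows))
  res <- .affine_align_cpp(S, params$gap_open, params$gap_extend, FALSE)
  wa <- nchar(pa$rows[1]); wb <- nchar(pb$rows[1])
  rows_a <- .expand_rows(pa$rows, res$a_idx, wa)
  rows_b <- .expand_rows(pb$rows, res$b_idx, wb)
  list(ids = c(pa$ids, pb$ids), rows = c(rows_a, rows_b))
}

.profile_counts <- function(rows, syms) {
  m <- msa_matrix_chr(rows)
  counts <- matrix(0L, length(syms), ncol(m), dimnames = list(syms, NULL))
  for (s in seq_along(syms)) counts[s, ] <- colSums(m == syms[s])
  counts
}

.expand_rows <- function(rows, idx, width) {
  # idx: per output column, source column (0 = gap column inserted)
  vapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    paste(ifelse(idx == 0, "-", ch[pmax(idx, 1)]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
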