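#' Poisson-corrected protein distance matrix
#'
#' For every pair of rows, the mismatch fraction `p` is computed over the
#' columns where both rows carry a residue (gapped columns are excluded
#' pairwise, not listwise) and corrected to `d = -ln(1 - p)`. `p` is capped
#' at 0.95 to keep distances finite; a message reports when the cap is
#' applied.
#'
#' @param msa a [new_msa()] alignment with at least 2 rows.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = row ids.
#' @export
poisson_distance <- function(msa) {
  stopifnot(inherits(msa, "gsdm_msa"), length(msa$ids) >= 2)
  m <- as.matrix(msa)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  capped <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable columns between '", msa$ids[i], "' and '",
             msa$ids[j], "'", call. = FALSE)
      }
      p <- mean(m[i, ok] != m[j, ok])
      if (p > 0.95) { p <- 0.95; capped <- capped + 1L }
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  if (capped > 0) message("poisson_distance: capped p at 0.95 for ",
                          capped, " pair(s)")
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (Studier-Keppler Q criterion) on a labelled
#' symmetric distance matrix. Negative branch lengths, which NJ can
#' produce, are clamped to zero and the total clamped deficit is reported
#' via a message. The result is unrooted.
#'
#' @param D symmetric numeric matrix (>= 3 taxa) with dimnames.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) >= 3, !is.null(rownames(D)))
  if (any(!is.finite(D))) stop("non-finite distances", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix not symmetric",
                                       call. = FALSE)
  tree <- ape::nj(stats::as.dist(D))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message("neighbor_joining: clamped ", sum(neg),
            " negative branch length(s), total deficit ",
            signif(-sum(tree$edge.length[neg]), 4))
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path.
#'
#' @param tree a `phylo` tree.
#' @return A rooted `phylo` tree with unchanged unrooted topology.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  phangorn::midpoint(tree)
}

#' Exact monophyly test
#'
#' `TRUE` iff some node of the (rooted) tree has exactly `labels` as its
#' leaf descendants.
#'
#' @param tree a rooted `phylo` tree.
#' @param labels character vector, a subset of the tree's tip labels.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(labels %in% tree$tip.label)) {
    stop("labels not in tree: ",
         paste(setdiff(labels, tree$tip.label), collapse = ", "),
         call. = FALSE)
  }
  ape::is.monophyletic(tree, labels)
}

#' Robinson-Foulds distance
#'
#' Number of bipartitions present in exactly one of two trees over the
#' same leaf set.
#'
#' @param t1,t2 `phylo` trees with identical tip labels.
#' @return Integer count.
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label)) {
    stop("leaf sets differ between the two trees", call. = FALSE)
  }
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}

#' Read a tree from Newick text
#'
#' @param text Newick string (terminated by `;`).
#' @return A `phylo` tree.
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0) stop("unbalanced parenthesis at offset ", i, call. = FALSE)
  }
  if (depth != 0) stop("unbalanced parentheses: ", depth,
                       " unclosed at end of input", call. = FALSE)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick text", call. = FALSE)
  tree
}

#' Write a tree as Newick text
#'
#' @param tree a `phylo` tree.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
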