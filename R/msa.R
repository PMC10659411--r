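#' Multiple sequence alignment container
#'
#' A light container for an aligned protein family: an ordered vector of
#' row ids and the equal-length gapped rows (`-` as the gap character).
#' De-gapping any row reproduces the sequence it was built from.
#'
#' @param ids character vector of unique row ids.
#' @param rows character vector of equal-length gapped sequences.
#' @param check_all_gap drop/forbid nothing, but when `TRUE` (the default)
#'   construction fails if an all-gap column is present.
#' @return An object of class `gsdm_msa`.
#' @export
new_msa <- function(ids, rows, check_all_gap = TRUE) {
  stopifnot(length(ids) == length(rows), !anyDuplicated(ids),
            length(ids) >= 1)
  if (length(unique(nchar(rows))) != 1) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  if (check_all_gap && nchar(rows[1]) > 0) {
    m <- msa_matrix_chr(rows)
    if (any(colSums(m != "-") == 0)) {
      stop("alignment contains an all-gap column", call. = FALSE)
    }
  }
  structure(list(ids = as.character(ids), rows = unname(as.character(rows))),
            class = "gsdm_msa")
}

msa_matrix_chr <- function(rows) {
  do.call(rbind, strsplit(rows, ""))
}

#' @export
print.gsdm_msa <- function(x, ...) {
  cat("<gsdm_msa> ", length(x$ids), " rows x ", msa_width(x), " columns\n",
      sep = "")
  show <- utils::head(seq_along(x$ids), 6)
  for (i in show) {
    r <- x$rows[i]
    if (nchar(r) > 60) r <- paste0(substr(r, 1, 57), "...")
    cat(format(x$ids[i], width = 14), r, "\n")
  }
  if (length(x$ids) > 6) cat("  ... ", length(x$ids) - 6, " more rows\n")
  invisible(x)
}

#' Alignment width (number of columns)
#' @param msa a `gsdm_msa`.
#' @return Integer column count.
#' @export
msa_width <- function(msa) nchar(msa$rows[1])

#' @export
as.matrix.gsdm_msa <- function(x, ...) {
  m <- msa_matrix_chr(x$rows)
  rownames(m) <- x$ids
  m
}

#' @importFrom tibble as_tibble
#' @method as_tibble gsdm_msa
#' @export
as_tibble.gsdm_msa <- function(x, ...) {
  tibble(id = x$ids, aligned = x$rows,
         sequence = gsub("-", "", x$rows, fixed = TRUE))
}

#' Read / write an alignment in aligned-FASTA format
#'
#' @param path file path.
#' @return A `gsdm_msa` (reader); `path` invisibly (writer).
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty alignment file", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  new_msa(ids, toupper(as.character(set)), check_all_gap = FALSE)
}

#' @rdname read_alignment
#' @param msa a `gsdm_msa`.
#' @export
write_alignment <- function(msa, path) {
  set <- Biostrings::BStringSet(setNames(msa$rows, msa$ids))
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}
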