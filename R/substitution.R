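#' BLOSUM62 substitution matrix over the 20 amino acids plus X
#'
#' Returns the BLOSUM62 substitution matrix restricted to the 20 standard
#' amino acids plus the unknown-residue code `X`. `X` scores 0 against every
#' residue (including itself), so unknown residues neither reward nor
#' penalise an alignment.
#'
#' @return A 21 x 21 integer-valued matrix with dimnames.
#' @export
#' @examples
#' blosum62()["Y", "V"]
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    m <- env$BLOSUM62[c(AA20, "X"), c(AA20, "X")]
    m["X", ] <- 0
    m[, "X"] <- 0
    .pkg_cache$blosum62 <- m
  }
  .pkg_cache$blosum62
}

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values; positive values are hydrophobic
#' (isoleucine, 4.5) and negative hydrophilic (arginine, -4.5).
#'
#' @return Named numeric vector over the 20 amino acids.
#' @export
kyte_doolittle_scale <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

#' Alignment scoring parameters
#'
#' Bundles a substitution matrix with affine gap penalties. A gap of length
#' L costs `gap_open + L * gap_extend` (BLAST-style).
#'
#' @param matrix substitution matrix (default [blosum62()]).
#' @param gap_open gap opening penalty (positive number, default 11).
#' @param gap_extend gap extension penalty per residue (default 1).
#' @return A list of class `gsdm_align_params`.
#' @export
align_params <- function(matrix = blosum62(), gap_open = 11, gap_extend = 1) {
  stopifnot(is.matrix(matrix), gap_open >= 0, gap_extend >= 0)
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "gsdm_align_params")
}
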