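#' Reference structural boundaries
#'
#' Bundles the residue indices, in a chosen reference protein, of the end
#' of strand beta-11 and the start of helix alpha-5 (the interdomain
#' linker lies strictly between them), plus optional ranges for the
#' alpha-7'/alpha-8 interhelix hydropathy window and for N-terminal
#' caspase-3 site scanning. All coordinates are 1-based inclusive.
#'
#' @param reference_id id of the reference sequence.
#' @param beta11_end residue index of the last beta-11 residue.
#' @param alpha5_start residue index of the first alpha-5 residue.
#' @param alpha7p_alpha8_range optional length-2 integer vector.
#' @param nterm_range optional length-2 integer vector.
#' @return A list of class `gsdm_boundaries`.
#' @export
reference_boundaries <- function(reference_id, beta11_end, alpha5_start,
                                 alpha7p_alpha8_range = NULL,
                                 nterm_range = NULL) {
  stopifnot(is.character(reference_id), beta11_end >= 1,
            beta11_end < alpha5_start)
  chk_range <- function(r) {
    if (!is.null(r)) stopifnot(length(r) == 2, r[1] >= 1, r[1] <= r[2])
    r
  }
  structure(list(reference_id = reference_id,
                 beta11_end = as.integer(beta11_end),
                 alpha5_start = as.integer(alpha5_start),
                 alpha7p_alpha8_range = chk_range(alpha7p_alpha8_range),
                 nterm_range = chk_range(nterm_range)),
            class = "gsdm_boundaries")
}

#' Read / write reference boundaries as YAML
#'
#' @param path file path.
#' @return A `gsdm_boundaries` (reader); `path` invisibly (writer).
#' @export
read_boundaries <- function(path) {
  y <- yaml::read_yaml(path)
  reference_boundaries(y$reference_id, y$beta11_end, y$alpha5_start,
                       if (!is.null(y$alpha7p_alpha8_range))
                         as.integer(unlist(y$alpha7p_alpha8_range)),
                       if (!is.null(y$nterm_range))
                         as.integer(unlist(y$nterm_range)))
}

#' @rdname read_boundaries
#' @param boundaries a `gsdm_boundaries` object.
#' @export
write_boundaries <- function(boundaries, path) {
  yaml::write_yaml(unclass(boundaries), path)
  invisible(path)
}

#' Project linker boundaries through an alignment
#'
#' Locates the alignment columns holding the reference's last beta-11
#' residue and first alpha-5 residue, and defines, for every row, the
#' linker as the ungapped residues strictly between those two columns,
#' reported in that row's own 1-based coordinates. Rows with no residue in
#' the projected interval get an `NA` annotation rather than an error.
#'
#' @param msa a [new_msa()] alignment containing the reference row.
#' @param ref a [reference_boundaries()] object.
#' @return Tibble with columns `sequence_id`, `start`, `end` (`NA` for
#'   empty projections).
#' @export
project_boundaries <- function(msa, ref) {
  stopifnot(inherits(msa, "gsdm_msa"), inherits(ref, "gsdm_boundaries"))
  ri <- match(ref$reference_id, msa$ids)
  if (is.na(ri)) {
    stop("reference row '", ref$reference_id, "' not in alignment",
         call. = FALSE)
  }
  m <- as.matrix(msa)
  ref_nongap <- which(m[ri, ] != "-")
  if (ref$alpha5_start > length(ref_nongap)) {
    stop("boundaries exceed reference length", call. = FALSE)
  }
  col_b <- ref_nongap[ref$beta11_end]
  col_a <- ref_nongap[ref$alpha5_start]
  purrr::map_dfr(seq_along(msa$ids), function(r) {
    row <- m[r, ]
    inside <- if (col_a - col_b >= 2) {
      sum(row[(col_b + 1):(col_a - 1)] != "-")
    } else 0L
    if (inside == 0) {
      return(tibble(sequence_id = msa$ids[r], start = NA_integer_,
                    end = NA_integer_))
    }
    before <- sum(row[seq_len(col_b)] != "-")
    tibble(sequence_id = msa$ids[r], start = before + 1L,
           end = before + as.integer(inside))
  })
}

#' Extract candidate cleavage tetrapeptides from a linker
#'
#' Emits one site per aspartate in the linker: the tetrapeptide is the
#' four residues of the full protein ending at that aspartate (P4, P3,
#' P2, P1; left-padded with `X` when the aspartate lies within the first
#' three residues), and the P1'/P2' context is read from the full protein
#' (`X` past the C-terminus). Sites are ordered by P1 position.
#'
#' @param record one-row tibble (or list) with `id` and `sequence`.
#' @param linker list/row with `start`, `end` (1-based inclusive, valid for
#'   the record), or `NA` for no linker.
#' @return Tibble with columns `sequence_id`, `tetrapeptide`,
#'   `p1_position`, `p1_prime`, `p2_prime`.
#' @export
find_tetrapeptide_sites <- function(record, linker) {
  empty <- tibble(sequence_id = character(), tetrapeptide = character(),
                  p1_position = integer(), p1_prime = character(),
                  p2_prime = character())
  if (is.na(linker$start) || is.na(linker$end)) return(empty)
  seq <- record$sequence
  n <- nchar(seq)
  stopifnot(linker$start >= 1, linker$start <= linker$end, linker$end <= n)
  chars <- strsplit(seq, "")[[1]]
  dpos <- which(chars == "D")
  dpos <- dpos[dpos >= linker$start & dpos <= linker$end]
  if (length(dpos) == 0) return(empty)
  at <- function(p) ifelse(p >= 1 & p <= n, chars[pmax(pmin(p, n), 1)], "X")
  tibble(sequence_id = record$id,
         tetrapeptide = vapply(dpos, function(p) {
           paste(at(c(p - 3, p - 2, p - 1, p)), collapse = "")
         }, character(1)),
         p1_position = as.integer(dpos),
         p1_prime = at(dpos + 1),
         p2_prime = at(dpos + 2))
}

#' Bulky residues accepted at P4 by caspase-1
#' @return Character vector.
#' @export
bulky_p4_set <- function() c("F", "W", "Y", "L", "I", "V", "M")

#' Classify tetrapeptide sites by caspase preference
#'
#' Rule-based classification of P4..P1 tetrapeptides ending at an
#' aspartate: `caspase3_like` when P4 is itself an aspartate (the DxxD
#' apoptotic-caspase motif), otherwise `caspase1_like` when P4 is bulky
#' (default set F, W, Y, L, I, V, M), otherwise `other_asp`. A small
#' integer score ranks sites by additional context preferences of
#' caspase-1 (small P1', glycine P1', proline P2') but never changes the
#' class.
#'
#' @param sites tibble from [find_tetrapeptide_sites()].
#' @param bulky character vector of bulky P4 residues.
#' @return The input tibble with `site_class` and `score` columns added.
#' @export
classify_sites <- function(sites, bulky = bulky_p4_set()) {
  if (nrow(sites) == 0) {
    return(dplyr::mutate(sites, site_class = character(), score = integer()))
  }
  if (any(nchar(sites$tetrapeptide) != 4) ||
      any(substr(sites$tetrapeptide, 4, 4) != "D")) {
    stop("malformed tetrapeptide: must be 4 characters ending in D",
         call. = FALSE)
  }
  p4 <- substr(sites$tetrapeptide, 1, 1)
  p1p <- sites$p1_prime
  p2p <- sites$p2_prime
  dplyr::mutate(sites,
    site_class = dplyr::case_when(
      p4 == "D" ~ "caspase3_like",
      p4 %in% bulky ~ "caspase1_like",
      TRUE ~ "other_asp"),
    score = 2L * (p4 %in% bulky) + 2L * (p1p %in% c("G", "A", "S")) +
      1L * (p1p == "G") + 1L * (p2p == "P"))
}

#' Classify a single tetrapeptide string
#'
#' Convenience wrapper around [classify_sites()] for a bare tetrapeptide.
#'
#' @param tetrapeptide 4-character string ending in `D`.
#' @param p1_prime,p2_prime downstream context characters (default `X`).
#' @inheritParams classify_sites
#' @return One-row tibble with `site_class` and `score`.
#' @export
classify_tetrapeptide <- function(tetrapeptide, p1_prime = "X",
                                  p2_prime = "X", bulky = bulky_p4_set()) {
  classify_sites(tibble(sequence_id = "query", tetrapeptide = tetrapeptide,
                        p1_position = 4L, p1_prime = p1_prime,
                        p2_prime = p2_prime), bulky = bulky)
}

#' YVAD-likeness of tetrapeptides
#'
#' A tetrapeptide is called YVAD-like when its summed position-wise
#' BLOSUM62 similarity to `YVAD` reaches the threshold (default 15; the
#' self-similarity of YVAD is 21).
#'
#' @param tetrapeptides character vector of 4-letter tetrapeptides.
#' @param threshold minimum summed similarity (default 15).
#' @return Logical vector.
#' @export
is_yvad_like <- function(tetrapeptides, threshold = 15) {
  stopifnot(all(nchar(tetrapeptides) == 4))
  sub <- blosum62()
  ref <- c("Y", "V", "A", "D")
  vapply(tetrapeptides, function(tp) {
    ch <- strsplit(tp, "")[[1]]
    sum(sub[cbind(ch, ref)]) >= threshold
  }, logical(1), USE.NAMES = FALSE)
}

#' Scan an N-terminal range for caspase-3 (DxxD) sites
#'
#' Finds DxxD tetrapeptides lying entirely within `nterm_range` of the
#' record's sequence; the site class is `caspase3_like` by construction.
#' This targets the apoptotic-caspase inactivation sites reported in
#' gasdermin N-terminal pore-forming domains.
#'
#' @param record one-row tibble/list with `id` and `sequence`.
#' @param nterm_range length-2 integer vector, 1-based inclusive.
#' @return Tibble in the same shape as [classify_sites()] output.
#' @export
scan_caspase3_nterm <- function(record, nterm_range) {
  stopifnot(length(nterm_range) == 2, nterm_range[1] >= 1,
            nterm_range[1] <= nterm_range[2])
  seq <- record$sequence
  n <- nchar(seq)
  hi <- min(nterm_range[2], n)
  chars <- strsplit(seq, "")[[1]]
  dpos <- which(chars == "D")
  dpos <- dpos[dpos - 3 >= nterm_range[1] & dpos <= hi &
                 chars[pmax(dpos - 3, 1)] == "D"]
  out <- find_tetrapeptide_sites(record,
                                 list(start = nterm_range[1], end = hi))
  out <- out[out$p1_position %in% dpos, , drop = FALSE]
  classify_sites(out)
}

#' Build a P4..P1 sequence logo
#'
#' Per-position relative frequencies over the 20 amino acids (unknown
#' residues are excluded and the remainder renormalised) and information
#' content `IC = log2(20) - H - e_n`, where `H` is the positional Shannon
#' entropy in bits and `e_n = (s - 1) / (2 ln2 n)` with `s = 20` is the
#' small-sample correction (disable with `correction = FALSE`). IC is
#' floored at zero.
#'
#' @param sites tibble with a `tetrapeptide` column (>= 1 row).
#' @param correction apply the small-sample correction (default `TRUE`).
#' @return An object of class `gsdm_logo`: list with `position_labels`,
#'   `frequency_matrix` (4 x 20), `information_content`, `n_sequences`.
#' @export
build_logo <- function(sites, correction = TRUE) {
  if (nrow(sites) == 0) stop("no sites to build a logo from", call. = FALSE)
  tp <- sites$tetrapeptide
  stopifnot(all(nchar(tp) == 4))
  n <- length(tp)
  freq <- matrix(0, 4, 20, dimnames = list(c("P4", "P3", "P2", "P1"), AA20))
  ic <- numeric(4)
  e_n <- if (correction) (20 - 1) / (2 * log(2) * n) else 0
  for (i in 1:4) {
    ch <- substr(tp, i, i)
    cnt <- table(factor(ch[ch %in% AA20], levels = AA20))
    if (sum(cnt) == 0) stop("position ", i, " has only unknown residues",
                            call. = FALSE)
    f <- as.numeric(cnt) / sum(cnt)
    freq[i, ] <- f
    h <- -sum(ifelse(f > 0, f * log2(f), 0))
    ic[i] <- max(log2(20) - h - e_n, 0)
  }
  structure(list(position_labels = c("P4", "P3", "P2", "P1"),
                 frequency_matrix = freq, information_content = ic,
                 n_sequences = n),
            class = "gsdm_logo")
}

#' @export
print.gsdm_logo <- function(x, ...) {
  cat("<gsdm_logo> n =", x$n_sequences, "sites\n")
  cat(" IC (bits):", paste(x$position_labels,
                           sprintf("%.3f", x$information_content),
                           collapse = "  "), "\n")
  invisible(x)
}

#' Serialise a sequence logo as JSON
#' @param logo a `gsdm_logo`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_logo_json <- function(logo, path) {
  jsonlite::write_json(list(schema = "gasderminevo-logo-1",
                            position_labels = logo$position_labels,
                            residues = AA20,
                            frequency_matrix = logo$frequency_matrix,
                            information_content = logo$information_content,
                            n_sequences = logo$n_sequences),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding-window mean of per-residue hydropathy values.
#'
#' @param sequence amino-acid string (no `X`; unknown residues score 0).
#' @param window odd window size, at most the sequence length (default 9).
#' @return Numeric vector of length `nchar(sequence) - window + 1`; entry
#'   i is the mean over residues i .. i + window - 1.
#' @export
hydropathy_profile <- function(sequence, window = 9) {
  n <- nchar(sequence)
  stopifnot(window %% 2 == 1, window <= n, window >= 1)
  kd <- kyte_doolittle_scale()
  vals <- kd[strsplit(sequence, "")[[1]]]
  vals[is.na(vals)] <- 0
  as.numeric(stats::filter(vals, rep(1 / window, window),
                           sides = 2))[((window - 1) / 2 + 1):(n - (window - 1) / 2)]
}

#' Per-clade cleavage-site summary
#'
#' Counts, per clade, the number of sequences, the number with at least
#' one caspase-1-like site, the number with at least one YVAD-like
#' caspase-1-like site, and the YVAD-like fraction (one vote per record,
#' however many qualifying sites it carries).
#'
#' @param sites classified site tibble (with `yvad_like` column; when
#'   absent it is computed at the default threshold).
#' @param records tibble of protein records with `id`, `clade`.
#' @return Tibble with columns `clade`, `n_sequences`,
#'   `n_with_caspase1_like`, `n_yvad_like`, `fraction_yvad_like`.
#' @export
clade_summary <- function(sites, records) {
  if (!"yvad_like" %in% names(sites)) {
    sites$yvad_like <- is_yvad_like(sites$tetrapeptide) &
      sites$site_class == "caspase1_like"
  }
  per_seq <- sites |>
    dplyr::group_by(.data$sequence_id) |>
    dplyr::summarise(
      any_c1 = any(.data$site_class == "caspase1_like"),
      any_yvad = any(.data$yvad_like), .groups = "drop")
  records |>
    dplyr::left_join(per_seq, by = c(id = "sequence_id")) |>
    dplyr::mutate(any_c1 = dplyr::coalesce(.data$any_c1, FALSE),
                  any_yvad = dplyr::coalesce(.data$any_yvad, FALSE)) |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(n_sequences = dplyr::n(),
                     n_with_caspase1_like = sum(.data$any_c1),
                     n_yvad_like = sum(.data$any_yvad),
                     fraction_yvad_like = mean(.data$any_yvad),
                     .groups = "drop")
}

#' Full linker-motif site table for an aligned family
#'
#' Convenience pipeline step: project boundaries, extract every linker
#' tetrapeptide, classify, and flag YVAD-likeness.
#'
#' @param msa a [new_msa()] alignment.
#' @param records record tibble covering the alignment rows.
#' @param ref a [reference_boundaries()] object.
#' @param yvad_threshold threshold passed to [is_yvad_like()].
#' @return Classified site tibble with `clade` and `yvad_like` columns.
#' @export
extract_linker_sites <- function(msa, records, ref, yvad_threshold = 15) {
  linkers <- project_boundaries(msa, ref)
  sites <- purrr::map_dfr(seq_len(nrow(linkers)), function(i) {
    rec <- records[records$id == linkers$sequence_id[i], ]
    if (nrow(rec) == 0) return(NULL)
    find_tetrapeptide_sites(rec[1, ], linkers[i, ])
  })
  if (nrow(sites) == 0) {
    sites <- tibble(sequence_id = character(), tetrapeptide = character(),
                    p1_position = integer(), p1_prime = character(),
                    p2_prime = character())
  }
  sites <- classify_sites(sites)
  sites$yvad_like <- if (nrow(sites)) {
    is_yvad_like(sites$tetrapeptide, yvad_threshold) &
      sites$site_class == "caspase1_like"
  } else logical(0)
  dplyr::left_join(sites, records[, c("id", "clade")],
                   by = c(sequence_id = "id")) |>
    dplyr::relocate("clade", .after = "sequence_id")
}
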