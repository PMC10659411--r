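#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a sequence logo into position/residue rows
#'
#' @param x a `gsdm_logo`.
#' @param ... unused.
#' @return Tibble with `position`, `residue`, `frequency`, `bits` (the
#'   residue's share of the positional information content, the quantity a
#'   stacked logo letter represents).
#' @method tidy gsdm_logo
#' @export
tidy.gsdm_logo <- function(x, ...) {
  purrr::map_dfr(seq_along(x$position_labels), function(i) {
    tibble(position = factor(x$position_labels[i],
                             levels = x$position_labels),
           residue = AA20,
           frequency = x$frequency_matrix[i, ],
           bits = x$frequency_matrix[i, ] * x$information_content[i])
  })
}

#' @rdname tidy.gsdm_logo
#' @method glance gsdm_logo
#' @export
glance.gsdm_logo <- function(x, ...) {
  tibble(n_sequences = x$n_sequences,
         total_bits = sum(x$information_content),
         max_bits = max(x$information_content))
}

#' Tidy a profile HMM into per-state emission rows
#'
#' @param x a `gsdm_profile_hmm`.
#' @param ... unused.
#' @return Tibble with `state`, `residue`, `probability`.
#' @method tidy gsdm_profile_hmm
#' @export
tidy.gsdm_profile_hmm <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n_match), function(k) {
    tibble(state = k, residue = AA20,
           probability = x$match_emissions[k, ])
  })
}

#' @rdname tidy.gsdm_profile_hmm
#' @method glance gsdm_profile_hmm
#' @export
glance.gsdm_profile_hmm <- function(x, ...) {
  tibble(n_match = x$n_match,
         consensus = consensus(x),
         mean_match_entropy = mean(apply(x$match_emissions, 1, function(p) {
           -sum(p * log2(p))
         })))
}

#' @method glance gsdm_msa
#' @export
glance.gsdm_msa <- function(x, ...) {
  m <- as.matrix(x)
  tibble(n_rows = nrow(m), n_columns = ncol(m),
         gap_fraction = mean(m == "-"))
}

#' Plot the information content of a sequence logo
#'
#' Stacked per-residue information content by position, the matrix form
#' of the classic sequence-logo rendering.
#'
#' @param object a `gsdm_logo`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot gsdm_logo
#' @export
autoplot.gsdm_logo <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$bits > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits,
                                   fill = .data$residue)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.1) +
    ggplot2::labs(x = NULL, y = "information content (bits)",
                  title = paste0("Tetrapeptide logo (n = ",
                                 object$n_sequences, ")")) +
    ggplot2::theme_minimal()
}

#' Plot a per-clade cleavage-site summary
#'
#' @param object tibble from [clade_summary()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_clade_summary <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("clade", "n_with_caspase1_like", "n_yvad_like")],
    cols = -"clade", names_to = "measure", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$clade, y = .data$count,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "sequences") +
    ggplot2::theme_minimal()
}

#' Plot a hydropathy profile
#'
#' @param sequence amino-acid string.
#' @param window odd window size (default 9).
#' @return A ggplot object of the Kyte-Doolittle sliding-window profile.
#' @export
plot_hydropathy <- function(sequence, window = 9) {
  prof <- hydropathy_profile(sequence, window)
  half <- (window - 1) / 2
  df <- tibble(position = seq_along(prof) + half, hydropathy = prof)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$hydropathy)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue (window centre)",
                  y = "Kyte-Doolittle hydropathy") +
    ggplot2::theme_minimal()
}
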