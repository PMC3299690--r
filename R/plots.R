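#' Plot a chronology as an age ladder
#'
#' @param object A `chronology` tibble from [node_distance()], [helix_ages()]
#'   or [domain_ages()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chronology <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::mutate(id = factor(.data$id, levels = rev(unique(.data$id))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$nd, y = .data$id)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$id),
                          colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$nd), size = 2) +
    ggplot2::scale_colour_gradient(low = "blue", high = "red",
                                   limits = c(0, 1)) +
    ggplot2::labs(x = "relative age (nd)", y = NULL, colour = "nd") +
    ggplot2::theme_minimal()
}

#' Plot an event timeline
#'
#' @param object A `timeline` from [assemble_timeline()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.timeline <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$nd, y = .data$class,
                                    label = .data$id)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$nd), size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 2.8) +
    ggplot2::scale_colour_gradient(low = "blue", high = "red",
                                   limits = c(0, 1)) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "relative age (nd)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heat-map of a ribozyme similarity screen
#'
#' Tiles of Z-scores over the helix x substructure grid with significant
#' cells outlined.
#'
#' @param results The `results` tibble from [screen_matrix()].
#' @return A ggplot.
#' @export
plot_zscreen <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$part, y = .data$helix,
                                        fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(results, .data$significant),
                       fill = NA, colour = "black", linewidth = 0.8) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Histogram of the random-tree length distribution behind g1
#'
#' @param object A `parsimony_fit` from [fit_stats()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.parsimony_fit <- function(object, ...) {
  if (is.null(object$random_lengths)) {
    stop("fit carries no random-tree lengths (n_random_trees = 0)",
         call. = FALSE)
  }
  dat <- tibble::tibble(length = object$random_lengths)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$length, colour = "firebrick") +
    ggplot2::labs(x = "tree length (steps)", y = "random topologies",
                  subtitle = sprintf("observed L = %d, g1 = %.3f",
                                     object$length, object$g1)) +
    ggplot2::theme_minimal()
}
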