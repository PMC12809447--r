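# ggplot2 displays for the main result types.

#' Plot a fractal-dimension curve
#'
#' @param curve Tibble from [fractal_curve()] (or a list of them, named by
#'   model, for comparison).
#' @return A ggplot: d^f versus rho0, ideally a narrow parabola peaking
#'   near 3 at rho0 = 0.
#' @export
plot_fractal_curve <- function(curve) {
  if (!is.data.frame(curve)) {
    curve <- dplyr::bind_rows(curve, .id = "model")
  } else {
    curve$model <- "model"
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$rho0, y = .data$df,
                                      colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = expression(rho[0] ~ (e ~ ring(A)^-3)),
                  y = expression(d^f), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Refinement convergence trace
#'
#' @param object A `fraghar_refinement`.
#' @param ... Unused.
#' @return A ggplot of wR2 per cycle.
#' @export
autoplot.fraghar_refinement <- function(object, ...) {
  d <- tibble::tibble(cycle = seq_along(object$trace), wr2 = object$trace)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cycle, y = .data$wr2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "cycle", y = "wR2") +
    ggplot2::theme_minimal()
}

#' Fragment size accounting
#'
#' Bar chart of per-fragment atom counts by role; with residue-based
#' fragmentation the fragment count grows linearly with system size while
#' each fragment stays bounded.
#'
#' @param manifest Tibble from [fragment_manifest()].
#' @return A ggplot.
#' @export
plot_fragment_sizes <- function(manifest) {
  d <- tidyr::pivot_longer(
    manifest[, c("id", "n_central", "n_cap", "n_junction", "n_hb_extension")],
    -"id", names_to = "role", values_to = "atoms")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$id, y = .data$atoms,
                                  fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "atoms per fragment", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
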