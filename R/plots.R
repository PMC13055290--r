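#' Seasonal flux curves by treatment
#'
#' @param fluxes tibble from [chamber_fluxes()] with a `treatment` column.
#' @return A ggplot object: mean flux (+/- SE ribbon) over time per treatment.
#' @export
plot_flux_season <- function(fluxes) {
  d <- fluxes |>
    dplyr::group_by(.data$treatment, .data$date) |>
    dplyr::summarise(mean_flux = mean(.data$flux),
                     se = sd(.data$flux) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$date, y = .data$mean_flux,
                                  colour = .data$treatment, fill = .data$treatment)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_flux - .data$se,
                                      ymax = .data$mean_flux + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = expression(CH[4]~flux~(mg~m^-2~h^-1))) +
    ggplot2::theme_bw()
}

#' @rdname ncm_fit
#' @param object an `ncm_fit`.
#' @method autoplot ncm_fit
#' @export
autoplot.ncm_fit <- function(object, ...) {
  st <- dplyr::filter(object$stats, !is.na(.data$pred))
  curve <- tibble::tibble(
    p = exp(seq(log(min(st$p)), log(max(st$p)), length.out = 200))
  )
  curve$pred <- ncm_predict(curve$p, object$Nm, object$d)
  ggplot2::ggplot(st, ggplot2::aes(x = .data$p, y = .data$freq)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$partition), alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$pred),
                       colour = "black", linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(above = "#2166ac", neutral = "grey55",
                                            below = "#b2182b")) +
    ggplot2::labs(x = "Mean relative abundance (log10)",
                  y = "Occurrence frequency",
                  colour = NULL,
                  subtitle = sprintf("m = %.3g, Nm = %.0f, R2 = %.3f",
                                     object$m, object$Nm, object$R2)) +
    ggplot2::theme_bw()
}

#' @rdname build_network
#' @param object a `cooc_network`.
#' @method autoplot cooc_network
#' @export
autoplot.cooc_network <- function(object, ...) {
  if (nrow(object$edges) == 0) {
    return(ggplot2::ggplot() + ggplot2::labs(title = "Empty network") + ggplot2::theme_void())
  }
  set.seed(1)
  lay <- igraph::layout_with_fr(object$graph)
  nd <- tibble::tibble(asv_id = igraph::V(object$graph)$name,
                       x = lay[, 1], y = lay[, 2])
  ed <- object$edges |>
    dplyr::left_join(nd, by = c(from = "asv_id")) |>
    dplyr::left_join(nd, by = c(to = "asv_id"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_to, yend = .data$y_to,
                                       colour = .data$sign), alpha = 0.6) +
    ggplot2::geom_point(data = nd, ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::scale_colour_manual(values = c(positive = "#2166ac", negative = "#b2182b")) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "Edge sign")
}
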