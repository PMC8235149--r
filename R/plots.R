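#' Plot a simulated season's water balance
#'
#' Depletion trace against the RAW trigger and TAW capacity lines, with
#' irrigation events marked on the turn days they were taken.
#'
#' @param object A `season_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.season_sim <- function(object, ...) {
  d <- object$daily
  ggplot2::ggplot(d, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_hline(yintercept = object$params$taw,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = object$params$raw,
                        linetype = "dotdash", colour = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$dr_final)) +
    ggplot2::geom_point(
      data = d[d$irrigation > 0, ],
      ggplot2::aes(y = .data$dr_initial + .data$etc),
      shape = 25, fill = "steelblue", size = 2
    ) +
    ggplot2::annotate("text", x = min(d$date), y = object$params$raw,
                      label = "RAW", vjust = -0.5, hjust = 0, size = 3) +
    ggplot2::annotate("text", x = min(d$date), y = object$params$taw,
                      label = "TAW", vjust = -0.5, hjust = 0, size = 3) +
    ggplot2::labs(x = NULL, y = "root-zone depletion (mm)",
                  title = sprintf("Season water balance (%s policy)",
                                  object$params$policy)) +
    ggplot2::theme_minimal()
}

#' Daily ET0 and ETc of a simulated season
#'
#' @param sim A `season_sim`.
#' @return A ggplot.
#' @export
plot_et_series <- function(sim) {
  stopifnot(inherits(sim, "season_sim"))
  d <- sim$daily |>
    dplyr::select("date", "et0", "etc") |>
    tidyr::pivot_longer(c("et0", "etc"), names_to = "series",
                        values_to = "mm")
  ggplot2::ggplot(d, ggplot2::aes(.data$date, .data$mm,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(et0 = "grey30",
                                            etc = "darkgreen"),
                                 labels = c(et0 = "ET0 (reference)",
                                            etc = "ETc (crop)")) +
    ggplot2::labs(x = NULL, y = "evapotranspiration (mm/day)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Compare seasonal water use between policies
#'
#' @param sims Named list of `season_sim` objects.
#' @return A ggplot bar chart of total irrigation volume.
#' @export
plot_water_use <- function(sims) {
  stopifnot(length(sims) >= 1, all(vapply(sims, inherits, TRUE, "season_sim")))
  d <- dplyr::bind_rows(lapply(sims, glance), .id = "run")
  ggplot2::ggplot(d, ggplot2::aes(.data$run, .data$total_volume_l / 1000)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::labs(x = NULL, y = "seasonal irrigation (m³)") +
    ggplot2::theme_minimal()
}
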