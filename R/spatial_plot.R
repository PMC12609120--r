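#' Spatial plot of endocrine objects in a section
#'
#' Draws one point per EO at its centroid; point size grows with the EO
#' bin, and color encodes either the bin or the hormone-content class.
#' The header carries the donor, region, and clinical annotations, matching
#' the way section maps are presented in islet morphometry work.
#'
#' @param profile A [section_profile()].
#' @param color_by `"bin"` or `"class"`.
#' @param age_years,group,duration_years Optional donor annotations for the
#'   subtitle.
#' @return A ggplot object.
#' @export
spatial_plot <- function(profile, color_by = c("bin", "class"),
                         age_years = NULL, group = NULL,
                         duration_years = NULL) {
  stopifnot(inherits(profile, "section_profile"))
  color_by <- match.arg(color_by)
  obj <- profile$objects
  sub <- paste(c(
    if (!is.null(age_years)) paste0("age ", age_years, " y"),
    if (!is.null(group)) paste0("group ", group),
    if (!is.null(duration_years)) paste0("duration ", duration_years, " y")),
    collapse = " | ")
  p <- ggplot2::ggplot()
  if (nrow(obj)) {
    df <- data.frame(x = obj$centroid_x_um, y = obj$centroid_y_um,
                     bin = obj$eo_bin, class = obj$content_class)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      (if (color_by == "bin")
        ggplot2::geom_point(ggplot2::aes(size = .data$bin,
                                         color = .data$bin), alpha = 0.8)
       else
        ggplot2::geom_point(ggplot2::aes(size = .data$bin,
                                         color = .data$class), alpha = 0.8)) +
      ggplot2::scale_size_continuous(name = "EO bin", limits = c(0, 9),
                                     range = c(0.5, 6))
    if (color_by == "bin")
      p <- p + ggplot2::scale_color_viridis_c(name = "EO bin",
                                              limits = c(0, 9))
    else
      p <- p + ggplot2::scale_color_manual(
        name = "EO content",
        values = c(InsOnly = "#B15928", InsGluc = "#6A3D9A",
                   GlucOnly = "#E31A1C"),
        drop = FALSE)
  }
  p +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = paste0(profile$donor_id, " | ", profile$region, " | ",
                     profile$section_id),
      subtitle = if (nzchar(sub)) sub else NULL,
      x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
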