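# BOILED-Egg ADME classification: gastrointestinal absorption and
# blood-brain-barrier permeation predicted from two descriptors (WLOGP
# and TPSA) via two ellipse boundaries in the TPSA x WLOGP plane.

boiled_egg_ellipses <- function() {
  path <- system.file("extdata", "boiled_egg_ellipses.tsv",
                      package = "pharmscreen")
  tibble::as_tibble(utils::read.delim(path, comment.char = "#"))
}

# Strict-interior point-in-ellipse test.
in_ellipse <- function(x, y, e) {
  th <- e$angle * pi / 180
  dx <- x - e$cx
  dy <- y - e$cy
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / (e$width / 2))^2 + (v / (e$height / 2))^2 < 1
}

#' BOILED-Egg classification
#'
#' Classifies compounds by predicted passive gastrointestinal
#' absorption and blood-brain-barrier permeation from WLOGP and TPSA.
#' A point strictly inside the yolk ellipse is predicted BBB-permeant;
#' a point inside the white (GI) ellipse but not the yolk has high
#' predicted GI absorption without BBB permeation; anything else is
#' "outside" (poor predicted absorption). Boundary points are treated
#' by the strict-interior rule (on the boundary = not inside).
#'
#' @param wlogp,tpsa Numeric vectors (recycled to equal length).
#' @param ellipses Ellipse parameter table; default: the shipped
#'   reconstruction of the published boundaries.
#' @return Tibble: `wlogp`, `tpsa`, `gi_absorbed`, `bbb_permeant`,
#'   `region` (`"yolk"`, `"white"`, `"outside"`).
#' @export
boiled_egg <- function(wlogp, tpsa, ellipses = boiled_egg_ellipses()) {
  n <- max(length(wlogp), length(tpsa))
  wlogp <- rep_len(wlogp, n)
  tpsa <- rep_len(tpsa, n)
  stopifnot(all(is.finite(wlogp)), all(is.finite(tpsa)))
  gi_e <- ellipses[ellipses$region == "gi", ]
  bbb_e <- ellipses[ellipses$region == "bbb", ]
  gi <- in_ellipse(tpsa, wlogp, gi_e)
  bbb <- in_ellipse(tpsa, wlogp, bbb_e)
  tibble::tibble(
    wlogp = wlogp, tpsa = tpsa,
    gi_absorbed = gi, bbb_permeant = bbb,
    region = dplyr::case_when(bbb ~ "yolk", gi ~ "white", TRUE ~ "outside"))
}

#' BOILED-Egg plot
#'
#' @param egg Classification tibble from [boiled_egg()] (or a
#'   descriptor tibble with `wlogp` and `tpsa` columns).
#' @param label Optional point labels.
#' @return A ggplot object.
#' @export
plot_boiled_egg <- function(egg, label = NULL) {
  if (!all(c("region") %in% names(egg))) {
    egg <- boiled_egg(egg$wlogp, egg$tpsa)
  }
  ell <- boiled_egg_ellipses()
  ell_path <- function(e, n = 200) {
    th <- e$angle * pi / 180
    t <- seq(0, 2 * pi, length.out = n)
    u <- (e$width / 2) * cos(t)
    v <- (e$height / 2) * sin(t)
    tibble::tibble(x = e$cx + u * cos(th) - v * sin(th),
                   y = e$cy + u * sin(th) + v * cos(th),
                   region = e$region)
  }
  shells <- dplyr::bind_rows(ell_path(ell[ell$region == "gi", ]),
                             ell_path(ell[ell$region == "bbb", ]))
  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = shells[shells$region == "gi", ],
      ggplot2::aes(x = .data$x, y = .data$y), fill = "white", colour = "grey40") +
    ggplot2::geom_polygon(
      data = shells[shells$region == "bbb", ],
      ggplot2::aes(x = .data$x, y = .data$y), fill = "#F8D568", colour = "grey40") +
    ggplot2::geom_point(
      data = egg,
      ggplot2::aes(x = .data$tpsa, y = .data$wlogp, colour = .data$region)) +
    ggplot2::scale_colour_manual(values = c(
      yolk = "#B8860B", white = "grey20", outside = "#B22222")) +
    ggplot2::labs(x = expression(TPSA ~ (ring(A)^2)), y = "WLOGP",
                  colour = "region") +
    ggplot2::theme_minimal()
  if (!is.null(label)) {
    p <- p + ggplot2::geom_text(
      data = cbind(egg, .lab = label),
      ggplot2::aes(x = .data$tpsa, y = .data$wlogp, label = .data$.lab),
      vjust = -0.8, size = 3)
  }
  p
}
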