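# Broom-style tidiers and plot methods for the package result types.

#' @export
tidy.ph4_screen <- function(x, ...) {
  tibble::as_tibble(x[, c("model", "molecule_id", "conformer", "matched",
                          "rmsd", "n_optional", "reason")])
}

#' @export
glance.ph4_screen <- function(x, ...) {
  x %>%
    dplyr::group_by(.data$model) %>%
    dplyr::summarise(n_molecules = dplyr::n(),
                     n_hits = sum(.data$matched),
                     hit_rate = mean(.data$matched),
                     mean_rmsd = mean(.data$rmsd[.data$matched]),
                     .groups = "drop")
}

#' @export
tidy.ph4_filter_report <- function(x, ...) {
  tibble::as_tibble(x$report)
}

#' @export
glance.ph4_filter_report <- function(x, ...) {
  tibble::tibble(n_in = nrow(x$report), n_pass = sum(x$report$pass),
                 pass_rate = mean(x$report$pass),
                 n_stages_enabled = sum(x$stages$enabled))
}

#' @export
tidy.ph4_model <- function(x, ...) {
  dplyr::mutate(x$features, model = x$name, .before = 1)
}

#' @export
glance.ph4_model <- function(x, ...) {
  tibble::tibble(model = x$name, n_features = nrow(x$features),
                 n_essential = sum(x$features$essential),
                 n_exclusions = nrow(x$exclusions),
                 span = max(stats::dist(model_coords(x))))
}

#' @export
tidy.ph4_interactions <- function(x, ...) {
  x$per_residue
}

#' @export
glance.ph4_interactions <- function(x, ...) {
  tibble::tibble(target = x$target, type2_pass = x$type2_pass,
                 n_satisfied = sum(x$per_residue$satisfied),
                 n_required = nrow(x$per_residue),
                 back_pocket_contacts = x$contacts)
}

#' Funnel plot of a filtration cascade
#'
#' @param object A `ph4_filter_report`.
#' @param ... Unused.
#' @return A ggplot object (stage survivor counts in cascade order).
#' @export
autoplot.ph4_filter_report <- function(object, ...) {
  st <- object$stages
  st$stage <- factor(st$stage, levels = st$stage)
  ggplot2::ggplot(st, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "molecules surviving",
                  title = "Hit-filtration cascade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Bar chart of the model-assessment metric battery
#'
#' @param rows Metric rows from [compute_metrics()].
#' @param metric Which metric to plot (default `"f1"`).
#' @return A ggplot object ordered by the metric.
#' @export
plot_metric_battery <- function(rows, metric = "f1") {
  stopifnot(metric %in% c("se", "sp", "ya", "e", "acc", "dr", "f1"))
  rows <- rows[order(-rows[[metric]]), ]
  rows$model <- factor(rows$model, levels = rows$model)
  ggplot2::ggplot(rows,
                  ggplot2::aes(x = .data$model, y = .data[[metric]])) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
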