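# ggplot2 renderings of the screen outputs. Figures are views of the
# result tibbles, never the source of any number.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_step
#'   geom_hline scale_fill_gradient2 labs theme_minimal element_text theme
NULL

#' Heatmap of per-type delta PSI for ranked events
#'
#' Mirrors the events-by-cancer-types screen matrix: one tile per (event,
#' cancer type) colored by delta PSI; unquantified cells are blank.
#'
#' @param object A `pan_cancer_rank` from [rank_events()].
#' @param max_events Show at most this many top events (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pan_cancer_rank <- function(object, max_events = 25, ...) {
  by_type <- attr(object, "by_type")
  if (is.null(by_type)) abort("autoplot.pan_cancer_rank: missing by_type attribute")
  keep <- head(object$event_id, max_events)
  dat <- by_type |>
    filter(event_id %in% keep, quantified) |>
    mutate(event_id = factor(event_id, levels = rev(keep)))
  ggplot(dat, aes(x = cancer_type, y = event_id, fill = delta_psi)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         limits = c(-1, 1), name = "ΔPSI") +
    labs(x = NULL, y = NULL,
         title = "Tumor-normal ΔPSI across cancer types") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Dot plot of the splicing-factor screen
#'
#' Factors ordered by their summary correlation (most negative first).
#'
#' @param object A `factor_ranking` from [screen_factors()].
#' @param highlight Factor symbol(s) to label in red (default none).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.factor_ranking <- function(object, highlight = character(0), ...) {
  dat <- as_tibble(object) |>
    mutate(flag = factor_gene %in% highlight)
  ggplot(dat, aes(x = rank, y = summary_r, color = flag)) +
    geom_point(show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "#B2182B")) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    labs(x = "factor rank", y = "median Pearson r across cancer types",
         title = "Splicing-factor screen") +
    theme_minimal()
}

#' Step plot of a Kaplan-Meier curve
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = time, y = surv)) +
    geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time (days)", y = "survival probability",
         title = "Kaplan-Meier estimate") +
    theme_minimal()
}

#' Overlayed Kaplan-Meier curves for several groups
#'
#' @param clinical Tibble with `time`, `event` and a grouping column.
#' @param group Grouping column name (default `"group"`).
#' @return A ggplot object.
#' @export
plot_km_groups <- function(clinical, group = "group") {
  curves <- clinical |>
    group_by(group = .data[[group]]) |>
    group_modify(~ as_tibble(km_estimate(.x))) |>
    ungroup()
  ggplot(curves, aes(x = time, y = surv, color = group)) +
    geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time (days)", y = "survival probability", color = NULL) +
    theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
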