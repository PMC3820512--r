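#' Tidy the arc table of a flow solution
#'
#' @param x A `flow_solution`.
#' @param ... Unused.
#' @return Tibble of arcs with weight, capacity, cost, flow and activity.
#' @export
tidy.flow_solution <- function(x, ...) {
  x$arcs |>
    select("from", "to", "weight", "capacity", "cost", "flow", "active",
           "aux")
}

#' One-row summary of a flow solution
#'
#' @param x A `flow_solution`.
#' @param ... Unused.
#' @return Tibble with the objective, total S outflow, active counts and
#'   the operating point.
#' @export
glance.flow_solution <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    total_flow = total_outflow(x),
    n_active_arcs = sum(x$arcs$active & !x$arcs$aux),
    n_active_sources = sum(x$arcs$active & x$arcs$from == SOURCE_NODE),
    n_genes_flow_gt1 = sum(x$node_flows$high_confidence),
    mode = x$mode, kappa1 = x$kappa1, kappa2 = x$kappa2,
    status = x$status
  )
}

#' @export
tidy.stability_report <- function(x, ...) x$arcs

#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(
    frac_arcs_unchanged = x$frac_arcs_unchanged,
    frac_nodes_unchanged = x$frac_nodes_unchanged,
    n_lp = x$n_lp, tolerance = x$tolerance, objective = x$objective
  )
}

#' @export
tidy.significance_table <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.significance_table <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_significant = sum(x$p_value < 0.05),
    R = attr(x, "R"),
    n_failed_runs = attr(x, "n_failed") %||% 0L
  )
}

#' @export
tidy.kappa_sweep <- function(x, ...) x$grid

#' Node-flow plot of a flow solution
#'
#' Bar plot of the highest node flows, coloured by stage; the dashed line
#' marks the flow > 1 high-confidence cutoff.
#'
#' @param object A `flow_solution`.
#' @param n_top Number of genes shown (default 25).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flow_solution <- function(object, n_top = 25, ...) {
  df <- object$node_flows |>
    filter(.data$flow > 0) |>
    dplyr::slice_max(.data$flow, n = n_top, with_ties = FALSE) |>
    mutate(stage = dplyr::coalesce(.data$stage, "none"),
           gene = factor(.data$gene, rev(.data$gene)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flow, y = .data$gene,
                                   fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "node flow (sum of incoming arc flows)", y = NULL,
                  fill = "stage") +
    ggplot2::theme_minimal()
}

#' Kappa sweep heat map
#'
#' Tile plot of the number of active source genes over the
#' (kappa1, kappa2) grid, with the selected operating point outlined.
#'
#' @param object A `kappa_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kappa_sweep <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$kappa1, y = .data$kappa2,
                               fill = .data$n_sources)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = object$grid |>
        filter(.data$kappa1 == object$kappa1,
               .data$kappa2 == object$kappa2),
      colour = "red", linewidth = 1, fill = NA
    ) +
    ggplot2::labs(x = expression(kappa[1]), y = expression(kappa[2]),
                  fill = "active\nsources") +
    ggplot2::theme_minimal()
}

#' Flow versus randomization p-value
#'
#' Scatter of per-gene node flow against randomization p-value; the
#' expected inverse relationship (high flow, low p) is the reliability
#' signature of the optimal sub-network.
#'
#' @param object A `significance_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.significance_table <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$flow, y = .data$p_value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "node flow", y = "randomization p-value") +
    ggplot2::theme_minimal()
}
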