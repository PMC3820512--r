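SOURCE_NODE <- "S"
SINK_NODE <- "T"

flow_modes <- c("temporal_strict", "temporal_aggregate", "responsenet")

#' Default capacity rule
#'
#' Capacity of a stage-dependent arc: relative fold change plus relative
#' abundance of the governing gene, both normalized by the mean over that
#' gene's stage set, so a gene twice as induced (or twice as abundant) as
#' its stage average gets proportionally more capacity.
#'
#' @param lfc,abund Gene's max absolute log fold change and mean abundance.
#' @param group_lfc,group_abund Stage-set means of the same quantities.
#' @return Numeric capacities.
#' @export
capacity_default <- function(lfc, abund, group_lfc, group_abund) {
  a <- if (group_lfc > 0) lfc / group_lfc else 0
  b <- if (group_abund > 0) abund / group_abund else 0
  a + b
}

#' Default cost adjustment for stage-touching arcs
#'
#' Reliability weights of arcs touching staged genes are adjusted to
#' correspond to their capacities: a capacity-proportional bonus, capped at
#' 0.8 so that the resulting cost `1 - w'` never drops below 0.2 (no
#' zero-cost cycles).
#'
#' @param w Scaled reliability weight.
#' @param cap Arc capacity.
#' @return Adjusted weight `w'` in `[0, 0.8]`.
#' @export
cost_adjust_default <- function(w, cap) {
  pmin(0.8, w * pmax(1, cap))
}

#' Low-level flow problem constructor
#'
#' Wires a ready-made arc table (capacities and costs already assigned)
#' into a single-commodity flow problem: an auxiliary source S with arcs to
#' every T1 gene, an auxiliary sink T fed by every T3 gene, and the mode
#' deciding how the intermediate-regulator transit requirement is realized
#' at solve time. Direct arcs between T1 and T3 genes are removed.
#'
#' @param arcs Tibble with columns `from`, `to`, `capacity`, `cost` and
#'   optionally `weight`, `type`, `db`.
#' @param t1,t2,t3 Character vectors: the three stage sets (disjoint,
#'   non-empty).
#' @param source_capacity,sink_capacity Named numeric vectors giving the
#'   capacity of the S arc of each T1 gene and the sink arc of each T3
#'   gene.
#' @param kappa1 Source-reward constant (reward per unit of S outflow).
#' @param kappa2 T2-capacity tuning constant (stored for provenance; the
#'   tuning term is applied by [build_flow_problem()]).
#' @param mode One of `"temporal_strict"` (layered transit guarantee,
#'   default), `"temporal_aggregate"` (aggregate linear transit
#'   constraint), `"responsenet"` (no transit requirement).
#' @param gamma Source reward used in responsenet mode (defaults to
#'   `kappa1`).
#' @param aux_cost Cost on auxiliary S/T arcs (default 0.2, i.e. full 0.8
#'   reliability).
#' @param eps_t2 Aggregate-mode transit fraction: total T2 inflow must be
#'   at least `eps_t2` times the S outflow (default 1).
#' @param staging Optional staging tibble kept for provenance.
#' @return A `flow_problem`.
#' @export
flow_problem <- function(arcs, t1, t2, t3, source_capacity, sink_capacity,
                         kappa1 = 0.5, kappa2 = 0,
                         mode = flow_modes, gamma = kappa1,
                         aux_cost = 0.2, eps_t2 = 1, staging = NULL) {
  mode <- match.arg(mode)
  if (length(t1) == 0 || length(t2) == 0 || length(t3) == 0) {
    abort_infeasible("every stage set must be non-empty")
  }
  if (anyDuplicated(c(t1, t2, t3)) > 0) {
    abort_input("stage sets must be disjoint")
  }
  if (kappa1 < 0 || kappa2 < 0) abort_input("kappa1 and kappa2 must be >= 0")
  nodes <- unique(c(arcs$from, arcs$to, t1, t2, t3))
  if (any(c(SOURCE_NODE, SINK_NODE) %in% nodes)) {
    abort_input("gene identifiers 'S' and 'T' collide with the auxiliary terminals; rename them")
  }
  if (any(arcs$capacity < 0)) abort_input("capacities must be >= 0")
  if (any(arcs$cost <= 0)) abort_input("arc costs must be strictly positive")
  if (!"weight" %in% names(arcs)) arcs$weight <- NA_real_
  # direct edges between T1 and T3 are excluded (both directions)
  arcs <- arcs |>
    filter(!(.data$from %in% t1 & .data$to %in% t3),
           !(.data$from %in% t3 & .data$to %in% t1)) |>
    mutate(aux = FALSE)
  s_arcs <- tibble::tibble(
    from = SOURCE_NODE, to = t1, weight = NA_real_,
    capacity = unname(source_capacity[t1]), cost = aux_cost, aux = TRUE
  )
  t_arcs <- tibble::tibble(
    from = t3, to = SINK_NODE, weight = NA_real_,
    capacity = unname(sink_capacity[t3]), cost = aux_cost, aux = TRUE
  )
  if (anyNA(s_arcs$capacity) || anyNA(t_arcs$capacity)) {
    abort_input("source_capacity / sink_capacity must name every T1 / T3 gene")
  }
  all_arcs <- bind_rows(arcs, s_arcs, t_arcs) |>
    arrange(.data$from, .data$to)
  structure(
    list(arcs = all_arcs,
         stages = list(T1 = t1, T2 = t2, T3 = t3),
         kappa1 = kappa1, kappa2 = kappa2, gamma = gamma,
         mode = mode, eps_t2 = eps_t2, aux_cost = aux_cost,
         staging = staging),
    class = "flow_problem"
  )
}

#' @export
print.flow_problem <- function(x, ...) {
  ns <- lengths(x$stages)
  cat("<flow_problem> mode=", x$mode,
      " kappa1=", x$kappa1, " kappa2=", x$kappa2,
      "\n  ", nrow(x$arcs), " arcs; |T1|=", ns[1], " |T2|=", ns[2],
      " |T3|=", ns[3], "\n", sep = "")
  invisible(x)
}

#' Build the flow problem from a network and staged genes
#'
#' Assigns capacities and costs per the temporal flow model:
#'
#' * S -> T1 arcs and T3 -> T arcs get capacity
#'   `F_g/<F>_stage + e_g/<e>_stage` of the staged gene (fold-change term
#'   plus abundance term, stage-mean normalized);
#' * arcs incident to a T2 gene get the same two terms of the T2 gene only,
#'   plus the tuning term `kappa2 * w`;
#' * all remaining network arcs get a constant capacity (default 1).
#'
#' Costs are `1 - w` with the weights of stage-touching arcs first adjusted
#' to correspond to their capacities ([cost_adjust_default()]), so costs
#' lie in `[0.2, 1]`. In responsenet mode the costs are identical but all
#' network arc capacities are 1 and the transit requirement is dropped.
#' Staged genes absent from the network are dropped with a warning.
#'
#' @param network A `scored_network`.
#' @param staging Output of [stage_genes()] (columns `gene`, `stage`,
#'   `max_abs_lfc`, `mean_abund`).
#' @inheritParams flow_problem
#' @param other_capacity Capacity of arcs not governed by a staged gene
#'   (default 1).
#' @param capacity_fun Capacity rule, signature as [capacity_default()].
#' @param cost_adjust_fun Weight adjustment rule, signature as
#'   [cost_adjust_default()].
#' @return A `flow_problem`.
#' @export
build_flow_problem <- function(network, staging, kappa1 = 0.5, kappa2 = 0,
                               mode = flow_modes, gamma = kappa1,
                               other_capacity = 1,
                               capacity_fun = capacity_default,
                               cost_adjust_fun = cost_adjust_default,
                               aux_cost = 0.2, eps_t2 = 1) {
  mode <- match.arg(mode)
  missing_genes <- setdiff(staging$gene, network$nodes)
  if (length(missing_genes) > 0) {
    warn(paste0(length(missing_genes),
                " staged gene(s) absent from the network were dropped: ",
                paste(head(missing_genes, 5), collapse = ", ")))
    staging <- filter(staging, .data$gene %in% network$nodes)
  }
  stages <- split(staging$gene, factor(staging$stage, c("T1", "T2", "T3")))
  if (any(lengths(stages) == 0)) {
    abort_infeasible(paste0(
      "empty stage set(s) after matching to the network: ",
      paste(names(stages)[lengths(stages) == 0], collapse = ", ")
    ))
  }
  gmeans <- staging |>
    group_by(.data$stage) |>
    summarise(g_lfc = mean(.data$max_abs_lfc),
              g_abund = mean(.data$mean_abund), .groups = "drop")
  st <- staging |>
    left_join(gmeans, by = "stage") |>
    mutate(base_cap = purrr::pmap_dbl(
      list(.data$max_abs_lfc, .data$mean_abund, .data$g_lfc, .data$g_abund),
      capacity_fun
    ))
  cap_of <- setNames(st$base_cap, st$gene)
  stage_of <- setNames(as.character(st$stage), st$gene)

  arcs <- network$arcs |>
    mutate(
      from_stage = unname(stage_of[.data$from]),
      to_stage = unname(stage_of[.data$to]),
      # T2-incident arcs are governed by the T2 gene (target first);
      # temporal capacities are computed in every mode because the cost
      # adjustment refers to them even in responsenet mode
      cap_temporal = dplyr::case_when(
        !is.na(.data$to_stage) & .data$to_stage == "T2" ~
          unname(cap_of[.data$to]) + kappa2 * .data$weight,
        !is.na(.data$from_stage) & .data$from_stage == "T2" ~
          unname(cap_of[.data$from]) + kappa2 * .data$weight,
        TRUE ~ other_capacity
      ),
      touches_stage = !is.na(.data$from_stage) | !is.na(.data$to_stage),
      w_adj = ifelse(.data$touches_stage,
                     cost_adjust_fun(.data$weight, .data$cap_temporal),
                     .data$weight),
      cost = 1 - .data$w_adj,
      capacity = if (mode == "responsenet") other_capacity else
        .data$cap_temporal
    ) |>
    select("from", "to", "type", "db", "weight", "capacity", "cost")

  flow_problem(
    arcs,
    t1 = stages$T1, t2 = stages$T2, t3 = stages$T3,
    source_capacity = cap_of[stages$T1],
    sink_capacity = cap_of[stages$T3],
    kappa1 = kappa1, kappa2 = kappa2, mode = mode, gamma = gamma,
    aux_cost = aux_cost, eps_t2 = eps_t2, staging = staging
  )
}
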