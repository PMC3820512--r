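# Expand a flow problem into the plain arc list handed to the solver.
#
# temporal_strict uses a two-layer transform: every non-T2 gene is split
# into a pre-transit and a post-transit copy, network arcs are copied
# within each layer, T2 genes are single nodes that receive arcs from both
# layers but emit only into the post layer, S feeds the pre layer and T
# drains the post layer. Every unit of S->T flow therefore crosses at
# least one T2 gene. responsenet mode keeps the single-layer graph.
expand_problem <- function(problem) {
  arcs <- problem$arcs
  t2 <- problem$stages$T2
  genes <- setdiff(unique(c(arcs$from, arcs$to)), c(SOURCE_NODE, SINK_NODE))
  reward <- if (problem$mode == "responsenet") problem$gamma else problem$kappa1

  if (problem$mode == "temporal_strict") {
    split_genes <- setdiff(genes, t2)
    labels <- c(SOURCE_NODE, SINK_NODE, t2,
                paste0(split_genes, "|pre"), paste0(split_genes, "|post"))
    gene_of <- c(SOURCE_NODE, SINK_NODE, t2, split_genes, split_genes)
    idx <- setNames(seq_along(labels), labels)
    pre <- function(g) {
      out <- paste0(g, "|pre")
      out[g %in% t2] <- g[g %in% t2]
      out
    }
    post <- function(g) {
      out <- paste0(g, "|post")
      out[g %in% t2] <- g[g %in% t2]
      out
    }

    net <- arcs |> mutate(orig = dplyr::row_number()) |> filter(!.data$aux)
    u2 <- net$from %in% t2
    # arcs not leaving a T2 gene exist in both layers (pre copies land on
    # the T2 node itself when the target is T2); arcs leaving a T2 gene
    # land in the post layer only
    exp_arcs <- bind_rows(
      tibble::tibble(from = pre(net$from[!u2]), to = pre(net$to[!u2]),
                     capacity = net$capacity[!u2], cost = net$cost[!u2],
                     orig = net$orig[!u2]),
      tibble::tibble(from = post(net$from[!u2]), to = post(net$to[!u2]),
                     capacity = net$capacity[!u2], cost = net$cost[!u2],
                     orig = net$orig[!u2]),
      tibble::tibble(from = net$from[u2], to = post(net$to[u2]),
                     capacity = net$capacity[u2], cost = net$cost[u2],
                     orig = net$orig[u2])
    )
    aux <- arcs |> mutate(orig = dplyr::row_number()) |> filter(.data$aux)
    s_rows <- aux |> filter(.data$from == SOURCE_NODE)
    t_rows <- aux |> filter(.data$to == SINK_NODE)
    exp_arcs <- bind_rows(
      exp_arcs,
      tibble::tibble(from = SOURCE_NODE, to = pre(s_rows$to),
                     capacity = s_rows$capacity,
                     cost = s_rows$cost - reward, orig = s_rows$orig),
      tibble::tibble(from = post(t_rows$from), to = SINK_NODE,
                     capacity = t_rows$capacity, cost = t_rows$cost,
                     orig = t_rows$orig)
    )
  } else {
    labels <- c(SOURCE_NODE, SINK_NODE, genes)
    gene_of <- labels
    idx <- setNames(seq_along(labels), labels)
    exp_arcs <- arcs |>
      mutate(orig = dplyr::row_number(),
             cost = ifelse(.data$aux & .data$from == SOURCE_NODE,
                           .data$cost - reward, .data$cost)) |>
      select("from", "to", "capacity", "cost", "orig")
  }
  list(
    labels = labels, gene_of = gene_of,
    arcs = exp_arcs |>
      mutate(from_i = unname(idx[.data$from]), to_i = unname(idx[.data$to])),
    s_idx = unname(idx[SOURCE_NODE]), t_idx = unname(idx[SINK_NODE]),
    reward = reward
  )
}

node_flow_table <- function(problem, arcs_with_flow, active_tol) {
  genes <- setdiff(unique(c(problem$arcs$from, problem$arcs$to)),
                   c(SOURCE_NODE, SINK_NODE))
  stage_of <- c(
    setNames(rep("T1", length(problem$stages$T1)), problem$stages$T1),
    setNames(rep("T2", length(problem$stages$T2)), problem$stages$T2),
    setNames(rep("T3", length(problem$stages$T3)), problem$stages$T3)
  )
  inflow <- arcs_with_flow |>
    filter(.data$to != SINK_NODE) |>
    group_by(gene = .data$to) |>
    summarise(flow = sum(.data$flow), .groups = "drop")
  tibble::tibble(gene = genes) |>
    left_join(inflow, by = "gene") |>
    mutate(flow = dplyr::coalesce(.data$flow, 0),
           stage = unname(stage_of[.data$gene]),
           high_confidence = .data$flow > 1) |>
    arrange(desc(.data$flow), .data$gene) |>
    select("gene", "stage", "flow", "high_confidence")
}

#' Solve the minimum-cost flow problem
#'
#' Minimizes `sum(a_ij * f_ij) - kappa1 * sum(f_Sg)` subject to flow
#' conservation, capacity bounds and (in the temporal modes) the
#' requirement that flow transits at least one intermediate regulator.
#' `temporal_strict` enforces the transit requirement structurally via a
#' two-layer graph; `temporal_aggregate` instead adds the linear constraint
#' that total T2 inflow is at least `eps_t2` times the S outflow;
#' `responsenet` drops it (with `gamma` as the source reward).
#'
#' @param problem A `flow_problem`.
#' @param active_tol Flow above which an arc counts as active (default
#'   1e-6).
#' @param tol Numerical tolerance of the solver (default 1e-9).
#' @return A `flow_solution` with elements `arcs` (the problem arcs plus
#'   `flow` and `active`), `node_flows` (gene, stage, flow,
#'   high_confidence), `objective`, `status`, `mode` and solver internals.
#' @export
solve_flow <- function(problem, active_tol = 1e-6, tol = 1e-9) {
  if (problem$mode == "temporal_aggregate") {
    return(solve_aggregate(problem, active_tol = active_tol, tol = tol))
  }
  ex <- expand_problem(problem)
  res <- mcf_solve_cpp(
    n = length(ex$labels), from = ex$arcs$from_i, to = ex$arcs$to_i,
    cap = ex$arcs$capacity, cost = ex$arcs$cost,
    s = ex$s_idx, t = ex$t_idx, tol = tol
  )
  ex$arcs$flow <- res$flow
  orig_flow <- rep(0, nrow(problem$arcs))
  agg <- tapply(ex$arcs$flow, ex$arcs$orig, sum)
  orig_flow[as.integer(names(agg))] <- as.numeric(agg)
  arcs <- problem$arcs |>
    mutate(flow = orig_flow, active = .data$flow > active_tol)
  structure(
    list(
      arcs = arcs,
      node_flows = node_flow_table(problem, arcs, active_tol),
      objective = res$objective,
      status = "optimal",
      mode = problem$mode,
      kappa1 = problem$kappa1, kappa2 = problem$kappa2,
      gamma = problem$gamma,
      problem = problem,
      internal = list(labels = ex$labels, gene_of = ex$gene_of,
                      arcs = ex$arcs, potential = res$potential,
                      s_idx = ex$s_idx, t_idx = ex$t_idx,
                      reward = ex$reward, active_tol = active_tol, tol = tol)
    ),
    class = "flow_solution"
  )
}

# temporal_aggregate: the transit requirement as one aggregate linear
# constraint; a general (non-flow) LP, solved with the dense simplex from
# pracma. Suited to the small and medium instances this literal-LP variant
# exists for; the layered strict mode scales further.
solve_aggregate <- function(problem, active_tol = 1e-6, tol = 1e-9) {
  arcs <- problem$arcs |> mutate(orig = dplyr::row_number())
  m <- nrow(arcs)
  reward <- problem$kappa1
  cost_eff <- arcs$cost - ifelse(arcs$aux & arcs$from == SOURCE_NODE,
                                 reward, 0)
  nodes <- setdiff(unique(c(arcs$from, arcs$to)), c(SOURCE_NODE, SINK_NODE))
  A3 <- matrix(0, length(nodes), m)
  for (k in seq_along(nodes)) {
    A3[k, ] <- (arcs$to == nodes[k]) - (arcs$from == nodes[k])
  }
  a2 <- as.numeric(arcs$to %in% problem$stages$T2) -
    problem$eps_t2 * as.numeric(arcs$from == SOURCE_NODE)
  fit <- pracma::linprog(
    cc = cost_eff,
    A = rbind(diag(m), -matrix(a2, nrow = 1)),
    b = c(arcs$capacity, 0),
    Aeq = A3, beq = rep(0, length(nodes)),
    maxiter = 100 * (m + length(nodes))
  )
  if (!is.null(fit$errno) && fit$errno < 0) {
    if (fit$errno == -2) {
      abort_infeasible("aggregate-mode LP is infeasible")
    }
    abort_internal(paste0("aggregate-mode LP failed: ", fit$message))
  }
  flow <- pmax(0, as.numeric(fit$x))
  arcs_out <- problem$arcs |>
    mutate(flow = flow, active = flow > active_tol)
  structure(
    list(
      arcs = arcs_out,
      node_flows = node_flow_table(problem, arcs_out, active_tol),
      objective = sum(cost_eff * flow),
      status = "optimal",
      mode = problem$mode,
      kappa1 = problem$kappa1, kappa2 = problem$kappa2,
      gamma = problem$gamma,
      problem = problem,
      internal = list(
        labels = c(SOURCE_NODE, SINK_NODE, nodes),
        gene_of = c(SOURCE_NODE, SINK_NODE, nodes),
        arcs = arcs |>
          mutate(flow = flow, cost = cost_eff,
                 from_i = match(.data$from, c(SOURCE_NODE, SINK_NODE, nodes)),
                 to_i = match(.data$to, c(SOURCE_NODE, SINK_NODE, nodes))) |>
          select("from", "to", "capacity", "cost", "orig", "from_i", "to_i",
                 "flow"),
        potential = NULL,
        s_idx = 1L, t_idx = 2L, reward = reward,
        active_tol = active_tol, tol = tol)
    ),
    class = "flow_solution"
  )
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution> mode=", x$mode, " objective=",
      signif(x$objective, 6), "\n  total S outflow: ",
      signif(total_outflow(x), 6), "; active arcs: ",
      sum(x$arcs$active), "; genes with flow > 1: ",
      sum(x$node_flows$high_confidence), "\n", sep = "")
  invisible(x)
}

#' Total flow leaving the auxiliary source
#' @param solution A `flow_solution`.
#' @return Numeric scalar.
#' @export
total_outflow <- function(solution) {
  sum(solution$arcs$flow[solution$arcs$from == SOURCE_NODE])
}

#' Per-gene node flows
#'
#' Node flow is the sum of the flows of all incoming arcs (the auxiliary S
#' arc of a T1 gene counts). Genes with flow above 1 are flagged as
#' high-confidence.
#'
#' @param solution A `flow_solution`.
#' @return Tibble `gene`, `stage`, `flow`, `high_confidence`.
#' @export
node_flows <- function(solution) solution$node_flows

#' Maximum conservation violation over non-terminal nodes
#'
#' @param solution A `flow_solution`.
#' @return Largest relative imbalance `|in - out| / (1 + in)` over genes
#'   that are not pure sources/sinks of the wiring (T1 genes receive from
#'   S, T3 genes send to T, so every gene is interior).
#' @export
conservation_violation <- function(solution) {
  arcs <- solution$internal$arcs
  nodes <- setdiff(seq_along(solution$internal$labels),
                   c(solution$internal$s_idx, solution$internal$t_idx))
  inflow <- tapply(arcs$flow, arcs$to_i, sum)
  outflow <- tapply(arcs$flow, arcs$from_i, sum)
  get <- function(tab, i) {
    v <- tab[as.character(i)]
    ifelse(is.na(v), 0, v)
  }
  max(abs(get(inflow, nodes) - get(outflow, nodes)) /
        (1 + get(inflow, nodes)), 0)
}

#' Decompose a solved flow into source-to-sink paths
#'
#' Standard path stripping on the solved (layered, in strict mode) graph:
#' repeatedly follows the largest remaining arc flow from S to T and
#' subtracts the bottleneck. Path flows sum to the S outflow; in strict
#' mode every path provably contains at least one T2 gene.
#'
#' @param solution A `flow_solution`.
#' @param tol Flow below which an arc is treated as empty.
#' @return Tibble with list-column `path` (gene sequences, terminals
#'   dropped), `flow` and `contains_t2`.
#' @export
decompose_flow <- function(solution, tol = 1e-9) {
  ex <- solution$internal
  arcs <- ex$arcs
  f <- arcs$flow
  n_nodes <- length(ex$labels)
  out_of <- split(seq_len(nrow(arcs)), arcs$from_i)
  t2 <- solution$problem$stages$T2
  paths <- list()
  flows <- numeric(0)
  repeat {
    s_arcs <- out_of[[as.character(ex$s_idx)]]
    s_arcs <- s_arcs[f[s_arcs] > tol]
    if (length(s_arcs) == 0) break
    node <- ex$s_idx
    arc_seq <- integer(0)
    steps <- 0
    while (node != ex$t_idx) {
      cand <- out_of[[as.character(node)]]
      cand <- cand[f[cand] > tol]
      if (length(cand) == 0 || steps > n_nodes + 1) {
        abort_internal("flow decomposition failed: conservation violated or cycle flow present")
      }
      nxt <- cand[order(-f[cand], arcs$to_i[cand])][1]
      arc_seq <- c(arc_seq, nxt)
      node <- arcs$to_i[nxt]
      steps <- steps + 1
    }
    b <- min(f[arc_seq])
    f[arc_seq] <- f[arc_seq] - b
    genes <- ex$gene_of[c(arcs$from_i[arc_seq], ex$t_idx)]
    genes <- genes[!genes %in% c(SOURCE_NODE, SINK_NODE)]
    genes <- genes[c(TRUE, genes[-1] != genes[-length(genes)])]
    paths <- c(paths, list(genes))
    flows <- c(flows, b)
  }
  if (sum(f) > 1e-6) {
    abort_internal("flow decomposition left residual (cycle) flow")
  }
  tibble::tibble(
    path = paths, flow = flows,
    contains_t2 = purrr::map_lgl(paths, ~ any(.x %in% t2))
  )
}

#' Sweep the kappa grid and pick the operating point
#'
#' Solves the flow problem for every (kappa1, kappa2) combination and,
#' among solutions whose active sub-network contains fewer than
#' `unreliable_cap` unreliable arcs (scaled weight below
#' `unreliable_weight`), returns the one activating the most source genes;
#' ties go to the smaller kappa1 then kappa2. If no grid point meets the
#' cap, the minimal-violation solution is returned with a warning.
#'
#' @param network A `scored_network`.
#' @param staging Output of [stage_genes()].
#' @param kappa1,kappa2 Grid values (defaults 0 to 5 by 0.5).
#' @param mode Flow mode passed to [build_flow_problem()].
#' @param unreliable_weight Weight below which an active arc counts as
#'   unreliable (default 0.5).
#' @param unreliable_cap Maximum tolerated unreliable fraction (default
#'   0.01).
#' @param ... Further arguments for [build_flow_problem()].
#' @return A `kappa_sweep`: list with the selected `solution`, `kappa1`,
#'   `kappa2` and the full `grid` tibble of metrics.
#' @export
sweep_kappa <- function(network, staging, kappa1 = seq(0, 5, by = 0.5),
                        kappa2 = seq(0, 5, by = 0.5),
                        mode = "temporal_strict",
                        unreliable_weight = 0.5, unreliable_cap = 0.01,
                        ...) {
  if (length(kappa1) == 0 || length(kappa2) == 0) {
    abort_input("kappa grid must be non-empty")
  }
  grid <- tidyr::expand_grid(kappa1 = kappa1, kappa2 = kappa2)
  metrics <- purrr::pmap(grid, function(kappa1, kappa2) {
    sol <- solve_flow(build_flow_problem(
      network, staging, kappa1 = kappa1, kappa2 = kappa2, mode = mode, ...
    ))
    act <- sol$arcs |> filter(.data$active, !.data$aux)
    n_sources <- sum(sol$arcs$active & sol$arcs$from == SOURCE_NODE)
    frac <- if (nrow(act) == 0) 0 else
      mean(act$weight < unreliable_weight)
    tibble::tibble(n_sources = n_sources, n_active_arcs = nrow(act),
                   unreliable_frac = frac, objective = sol$objective)
  }) |> bind_rows()
  grid <- bind_cols(grid, metrics) |>
    mutate(meets_cap = .data$unreliable_frac < unreliable_cap)
  pick <- if (any(grid$meets_cap)) {
    grid |> filter(.data$meets_cap) |>
      arrange(desc(.data$n_sources), .data$kappa1, .data$kappa2) |>
      dplyr::slice(1)
  } else {
    warn("no kappa combination met the unreliable-edge cap; returning the minimal-violation solution")
    grid |>
      arrange(.data$unreliable_frac, desc(.data$n_sources), .data$kappa1,
              .data$kappa2) |>
      dplyr::slice(1)
  }
  best <- solve_flow(build_flow_problem(
    network, staging, kappa1 = pick$kappa1, kappa2 = pick$kappa2,
    mode = mode, ...
  ))
  structure(
    list(solution = best, kappa1 = pick$kappa1, kappa2 = pick$kappa2,
         grid = grid),
    class = "kappa_sweep"
  )
}

#' @export
print.kappa_sweep <- function(x, ...) {
  cat("<kappa_sweep> ", nrow(x$grid), " combinations; selected kappa1=",
      x$kappa1, " kappa2=", x$kappa2, " (",
      x$grid$n_sources[x$grid$kappa1 == x$kappa1 &
                         x$grid$kappa2 == x$kappa2][1],
      " active sources)\n", sep = "")
  invisible(x)
}

#' Non-temporal ResponseNet baseline
#'
#' Builds and solves the flow problem without the intermediate-regulator
#' requirement: internal arc capacities are 1 and `gamma` replaces the
#' source reward.
#'
#' @inheritParams build_flow_problem
#' @param gamma Source reward.
#' @param ... Further arguments for [build_flow_problem()].
#' @return A `flow_solution`.
#' @export
responsenet_solve <- function(network, staging, gamma = 0.5, ...) {
  solve_flow(build_flow_problem(network, staging, mode = "responsenet",
                                gamma = gamma, ...))
}
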