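#' Random stage assignment over network genes
#'
#' Samples disjoint T1/T2/T3 sets uniformly without replacement from the
#' network genes and attaches constant expression statistics, producing a
#' staging table exchangeable with the internal draws of
#' [randomization_pvalues()]. Used for null-calibration experiments.
#'
#' @param network A `scored_network`.
#' @param sizes Integer vector of length 3: stage sizes.
#' @param lfc,abund Constant statistics given to every sampled gene.
#' @return A staging tibble as from [stage_genes()].
#' @export
random_staging <- function(network, sizes, lfc = 1.5, abund = 20) {
  genes <- network$nodes
  if (sum(sizes) > length(genes)) {
    abort_input("stage sizes exceed the number of network genes")
  }
  pick <- sample(genes, sum(sizes))
  tibble::tibble(
    gene = pick,
    stage = factor(rep(c("T1", "T2", "T3"), times = sizes),
                   levels = c("T1", "T2", "T3")),
    max_abs_lfc = lfc,
    peak_time = NA_real_,
    mean_abund = abund
  )
}

#' Randomization-based per-gene p-values
#'
#' Re-solves the flow problem `R` times with stage sets of the original
#' sizes sampled uniformly without replacement from all network genes. A
#' run qualifies for gene g when g's node flow is at least its flow in the
#' optimal solution and every network arc incident to g that is active in
#' the optimal sub-network is also active in the run. The p-value is the
#' qualifying fraction. Sampled genes keep their real expression statistics
#' where available (from `stats` or the original staging); others receive
#' the stage-median statistics so capacities stay well defined.
#'
#' @param network A `scored_network` (the one the optimal run used, i.e.
#'   after any knockout).
#' @param staging The staging of the optimal run.
#' @param solution The optimal `flow_solution`.
#' @param R Number of randomizations (paper-scale default 5000; desk runs
#'   use 100-200).
#' @param seed Random seed (optional).
#' @param stats Optional [gene_stats()] table supplying real statistics for
#'   genes outside `staging`.
#' @param ... Further arguments for [build_flow_problem()].
#' @return A `significance_table`: tibble `gene`, `flow`, `n_qualifying`,
#'   `n_present` (runs where the gene carried any flow), `p_value`, with
#'   attributes `R` and `seed`.
#' @export
randomization_pvalues <- function(network, staging, solution, R = 5000,
                                  seed = NULL, stats = NULL, ...) {
  if (R < 1) abort_input("R must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sizes <- stage_counts(staging)
  if (sum(sizes) > length(network$nodes)) {
    abort_input("network smaller than the combined stage sets")
  }
  active_tol <- solution$internal$active_tol

  # real statistics where available, stage-median imputation otherwise
  lookup <- staging |> select("gene", "max_abs_lfc", "mean_abund")
  if (!is.null(stats)) {
    lookup <- bind_rows(
      lookup,
      stats |> select("gene", "max_abs_lfc", "mean_abund")
    ) |> distinct(.data$gene, .keep_all = TRUE)
  }
  med <- staging |>
    group_by(.data$stage) |>
    summarise(m_lfc = median(.data$max_abs_lfc),
              m_abund = median(.data$mean_abund), .groups = "drop")

  opt <- solution$node_flows |> filter(.data$flow > active_tol)
  act <- solution$arcs |> filter(.data$active, !.data$aux)
  incident <- lapply(setNames(opt$gene, opt$gene), function(g) {
    which(act$from == g | act$to == g)
  })
  act_keys <- paste(act$from, act$to)

  counts <- setNames(integer(nrow(opt)), opt$gene)
  present <- setNames(integer(nrow(opt)), opt$gene)
  n_failed <- 0L
  for (r in seq_len(R)) {
    pick <- sample(network$nodes, sum(sizes))
    rnd <- tibble::tibble(
      gene = pick,
      stage = factor(rep(c("T1", "T2", "T3"), times = sizes),
                     levels = c("T1", "T2", "T3"))
    ) |>
      left_join(lookup, by = "gene") |>
      left_join(med, by = "stage") |>
      mutate(max_abs_lfc = dplyr::coalesce(.data$max_abs_lfc, .data$m_lfc),
             mean_abund = dplyr::coalesce(.data$mean_abund, .data$m_abund)) |>
      select("gene", "stage", "max_abs_lfc", "mean_abund")
    sol_r <- tryCatch(
      solve_flow(build_flow_problem(
        network, rnd, kappa1 = solution$kappa1, kappa2 = solution$kappa2,
        mode = solution$mode, gamma = solution$gamma, ...
      ), active_tol = active_tol),
      tempoflow_infeasible_error = function(e) NULL
    )
    if (is.null(sol_r)) {
      n_failed <- n_failed + 1L
      next
    }
    nf_r <- setNames(sol_r$node_flows$flow, sol_r$node_flows$gene)
    seen <- opt$gene[!is.na(nf_r[opt$gene]) & nf_r[opt$gene] > active_tol]
    present[seen] <- present[seen] + 1L
    act_r <- sol_r$arcs |> filter(.data$active, !.data$aux)
    act_r_keys <- paste(act_r$from, act_r$to)
    arcs_ok <- act_keys %in% act_r_keys
    for (k in seq_len(nrow(opt))) {
      g <- opt$gene[k]
      fg <- nf_r[g]
      if (!is.na(fg) && fg >= opt$flow[k] - 1e-9 &&
          all(arcs_ok[incident[[g]]])) {
        counts[k] <- counts[k] + 1L
      }
    }
  }
  if (n_failed > 0) {
    warn(paste0(n_failed,
                " random run(s) were infeasible and counted as non-qualifying"))
  }
  structure(
    tibble::tibble(
      gene = opt$gene,
      flow = opt$flow,
      n_qualifying = unname(counts),
      n_present = unname(present),
      p_value = unname(counts) / R
    ),
    R = R, seed = seed, n_failed = n_failed,
    class = c("significance_table", class(tibble::tibble()))
  )
}

# Residual graph of the solved problem restricted to zero-reduced-cost
# arcs; alternate optima are exactly the circulations of this graph, so
# per-arc flow bounds at the fixed optimal objective reduce to max-flow
# computations in it (the network-flow form of fixing the objective and
# alternately maximizing / minimizing each arc flow).
zero_rc_residual <- function(solution, cap_tol = 1e-9, rc_tol = 1e-7) {
  ex <- solution$internal
  if (is.null(ex$potential)) {
    abort_input("stability analysis needs a flow-mode solution (temporal_strict or responsenet)")
  }
  arcs <- ex$arcs
  pot <- ex$potential
  rc <- arcs$cost + pot[arcs$from_i] - pot[arcs$to_i]
  total <- total_outflow(solution)
  res <- bind_rows(
    tibble::tibble(from_i = arcs$from_i, to_i = arcs$to_i,
                   cap = arcs$capacity - arcs$flow, rc = rc,
                   arc = seq_len(nrow(arcs)), dir = 1L),
    tibble::tibble(from_i = arcs$to_i, to_i = arcs$from_i,
                   cap = arcs$flow, rc = -rc,
                   arc = seq_len(nrow(arcs)), dir = -1L),
    # the implicit zero-cost return arc closing the circulation
    tibble::tibble(from_i = ex$t_idx, to_i = ex$s_idx,
                   cap = total + sum(arcs$capacity), rc = pot[ex$t_idx] - pot[ex$s_idx],
                   arc = NA_integer_, dir = 1L),
    tibble::tibble(from_i = ex$s_idx, to_i = ex$t_idx,
                   cap = total, rc = pot[ex$s_idx] - pot[ex$t_idx],
                   arc = NA_integer_, dir = -1L)
  )
  res |> filter(.data$cap > cap_tol, abs(.data$rc) <= rc_tol)
}

res_maxflow <- function(res, n_nodes, s, t, drop_arc) {
  keep <- res |> filter(is.na(.data$arc) | .data$arc != drop_arc)
  if (nrow(keep) == 0 || s == t) return(0)
  g <- igraph::graph_from_edgelist(
    as.matrix(keep[, c("from_i", "to_i")]), directed = TRUE
  )
  if (igraph::vcount(g) < n_nodes) {
    g <- igraph::add_vertices(g, n_nodes - igraph::vcount(g))
  }
  igraph::max_flow(g, source = s, target = t,
                   capacity = keep$cap)$value
}

#' Alternate-optima stability bounds
#'
#' Fixes the optimization score at the optimum and, for every active arc,
#' maximizes and minimizes its flow over the alternate optimal solutions
#' (the flux-variability scheme of fixing the objective and re-optimizing
#' per arc; computed here exactly through max-flows in the
#' zero-reduced-cost residual graph, whose circulations are precisely the
#' objective-preserving flow changes). An arc is unchanged when
#' `f_max - f_min < tolerance`; a node is unchanged when all its incident
#' active arcs are.
#'
#' @param solution A solved `flow_solution` (temporal_strict or
#'   responsenet mode).
#' @param tolerance Width below which an arc counts as unchanged (default
#'   1e-6).
#' @param rc_tol Reduced-cost tolerance defining the zero-cost residual
#'   subgraph.
#' @return A `stability_report`: list with `arcs` (from, to, flow, f_min,
#'   f_max, unchanged), `nodes`, unchanged fractions and the number of
#'   bound problems solved (`n_lp` = 2 per active arc).
#' @export
stability_analysis <- function(solution, tolerance = 1e-6, rc_tol = 1e-7) {
  ex <- solution$internal
  res <- zero_rc_residual(solution, rc_tol = rc_tol)
  n_nodes <- length(ex$labels)
  act_idx <- which(solution$arcs$active)
  arcs_exp <- ex$arcs

  bounds <- purrr::map(act_idx, function(i) {
    copies <- which(arcs_exp$orig == i)
    up <- 0
    down <- 0
    for (e in copies) {
      u <- arcs_exp$from_i[e]
      v <- arcs_exp$to_i[e]
      rescap <- arcs_exp$capacity[e] - arcs_exp$flow[e]
      fwd_in <- any(res$arc == e & res$dir == 1L, na.rm = TRUE)
      rev_in <- any(res$arc == e & res$dir == -1L, na.rm = TRUE)
      if (fwd_in && rescap > 1e-9) {
        up <- up + min(rescap, res_maxflow(res, n_nodes, v, u, e))
      }
      if (rev_in && arcs_exp$flow[e] > 1e-9) {
        down <- down + min(arcs_exp$flow[e],
                           res_maxflow(res, n_nodes, u, v, e))
      }
    }
    f <- solution$arcs$flow[i]
    tibble::tibble(f_min = max(0, f - down), f_max = f + up)
  }) |> bind_rows()

  arcs_out <- solution$arcs[act_idx, c("from", "to", "flow")] |>
    bind_cols(bounds) |>
    mutate(unchanged = (.data$f_max - .data$f_min) < tolerance)
  genes <- setdiff(unique(c(arcs_out$from, arcs_out$to)),
                   c(SOURCE_NODE, SINK_NODE))
  nodes_out <- tibble::tibble(
    gene = genes,
    unchanged = purrr::map_lgl(genes, function(g) {
      all(arcs_out$unchanged[arcs_out$from == g | arcs_out$to == g])
    })
  )
  structure(
    list(
      arcs = arcs_out, nodes = nodes_out,
      frac_arcs_unchanged = if (nrow(arcs_out) == 0) NA_real_ else
        mean(arcs_out$unchanged),
      frac_nodes_unchanged = if (nrow(nodes_out) == 0) NA_real_ else
        mean(nodes_out$unchanged),
      n_lp = 2L * length(act_idx),
      tolerance = tolerance,
      objective = solution$objective
    ),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> ", nrow(x$arcs), " active arcs, ", x$n_lp,
      " bound problems\n  unchanged: ",
      round(100 * x$frac_arcs_unchanged, 1), "% of arcs, ",
      round(100 * x$frac_nodes_unchanged, 1), "% of nodes (tolerance ",
      x$tolerance, ")\n", sep = "")
  invisible(x)
}
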