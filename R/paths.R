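active_network_arcs <- function(solution) {
  solution$arcs |> filter(.data$active, !.data$aux)
}

#' Flow-derived arc lengths (Opsahl weighting)
#'
#' Lengths for shortest-path extraction in the optimal sub-network: the
#' mean flow over active arcs divided by the arc's flow, so high-flow arcs
#' are short. Auxiliary and inactive arcs are excluded.
#'
#' @param solution A `flow_solution`.
#' @return Tibble `from`, `to`, `flow`, `length` (empty if no active arc).
#' @export
opsahl_lengths <- function(solution) {
  act <- active_network_arcs(solution)
  if (nrow(act) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          flow = numeric(), length = numeric()))
  }
  fbar <- mean(act$flow)
  act |>
    mutate(length = fbar / .data$flow) |>
    select("from", "to", "flow", "length")
}

# Hop-bounded shortest path by dynamic programming over (node, hops)
# states; the hop cap is a hard constraint, so plain Dijkstra does not
# apply. Ties break to the lexicographically smallest node sequence.
hop_bounded_paths <- function(lengths, source, hop_cap) {
  best <- list()
  best[[source]] <- list(len = 0, path = source)
  frontier <- best
  for (h in seq_len(hop_cap)) {
    nxt <- list()
    for (u in names(frontier)) {
      st <- frontier[[u]]
      out <- lengths[lengths$from == u, ]
      for (k in seq_len(nrow(out))) {
        v <- out$to[k]
        if (v %in% st$path) next  # simple paths only
        cand <- list(len = st$len + out$length[k], path = c(st$path, v))
        cur <- nxt[[v]]
        if (is.null(cur) || cand$len < cur$len - 1e-12 ||
            (abs(cand$len - cur$len) <= 1e-12 &&
             paste(cand$path, collapse = "\r") <
               paste(cur$path, collapse = "\r"))) {
          nxt[[v]] <- cand
        }
      }
    }
    for (v in names(nxt)) {
      cur <- best[[v]]
      cand <- nxt[[v]]
      if (is.null(cur) || cand$len < cur$len - 1e-12 ||
          (abs(cand$len - cur$len) <= 1e-12 &&
           paste(cand$path, collapse = "\r") <
             paste(cur$path, collapse = "\r"))) {
        best[[v]] <- cand
      }
    }
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  best
}

#' Shortest paths between stage groups in the optimal sub-network
#'
#' For every ordered pair of endpoint genes drawn from a stage pair,
#' reports the minimum-length path with at most `hop_cap` arcs under the
#' Opsahl lengths, computed by a hop-bounded dynamic program. Unreachable
#' pairs (within the cap) are omitted.
#'
#' @param solution A `flow_solution`.
#' @param hop_cap Maximum number of arcs per path (default 3).
#' @param pairs `"consecutive"` (T1 to T2 and T2 to T3; default) or
#'   `"all"` ordered stage pairs.
#' @return Tibble `from`, `to`, `from_stage`, `to_stage`, `length`,
#'   `hops`, list-column `path`.
#' @export
stage_paths <- function(solution, hop_cap = 3,
                        pairs = c("consecutive", "all")) {
  pairs <- match.arg(pairs)
  if (hop_cap < 1) abort_input("hop_cap must be >= 1")
  lens <- opsahl_lengths(solution)
  stages <- solution$problem$stages
  present <- unique(c(lens$from, lens$to))
  stage_pairs <- if (pairs == "consecutive") {
    list(c("T1", "T2"), c("T2", "T3"))
  } else {
    list(c("T1", "T2"), c("T2", "T3"), c("T1", "T3"),
         c("T2", "T1"), c("T3", "T2"), c("T3", "T1"))
  }
  out <- list()
  for (sp in stage_pairs) {
    srcs <- intersect(stages[[sp[1]]], present)
    tgts <- intersect(stages[[sp[2]]], present)
    for (s0 in srcs) {
      best <- hop_bounded_paths(lens, s0, hop_cap)
      for (t0 in setdiff(tgts, s0)) {
        st <- best[[t0]]
        if (is.null(st)) next
        out[[length(out) + 1]] <- tibble::tibble(
          from = s0, to = t0, from_stage = sp[1], to_stage = sp[2],
          length = st$len, hops = length(st$path) - 1L,
          path = list(st$path)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          from_stage = character(), to_stage = character(),
                          length = numeric(), hops = integer(),
                          path = list()))
  }
  bind_rows(out)
}

longest_path_dfs <- function(adj, node, visited, depth_cap) {
  if (depth_cap == 0) return(0L)
  outs <- adj[[node]]
  best <- 0L
  for (v in outs) {
    if (v %in% visited) next
    best <- max(best, 1L + longest_path_dfs(adj, v, c(visited, v),
                                            depth_cap - 1L))
  }
  best
}

#' Longest directed path shared with each reference pathway
#'
#' For each reference pathway (a directed edge list), finds the longest
#' directed path whose arcs all lie both in the active sub-network and in
#' the pathway, by depth-limited search on the arc intersection.
#'
#' @param solution A `flow_solution`.
#' @param reference Tibble `pathway`, `from`, `to` of directed reference
#'   edges.
#' @param depth_cap Maximum path length searched, in arcs (default 8).
#' @return Tibble `pathway`, `longest_match` (arcs; 0 when the arc sets
#'   are disjoint).
#' @export
match_reference_paths <- function(solution, reference, depth_cap = 8) {
  if (nrow(reference) == 0) {
    return(tibble::tibble(pathway = character(), longest_match = integer()))
  }
  act <- active_network_arcs(solution) |> select("from", "to")
  reference |>
    group_by(.data$pathway) |>
    group_modify(function(df, key) {
      inter <- inner_join(act, df |> select("from", "to"),
                          by = c("from", "to")) |> distinct()
      if (nrow(inter) == 0) return(tibble::tibble(longest_match = 0L))
      adj <- split(inter$to, inter$from)
      nodes <- unique(c(inter$from, inter$to))
      best <- max(vapply(nodes, function(v) {
        longest_path_dfs(adj, v, v, depth_cap)
      }, integer(1)))
      tibble::tibble(longest_match = best)
    }) |>
    ungroup()
}

#' Pathway membership overlap of predicted paths
#'
#' Fraction of predicted paths having at least `k` member genes
#' co-occurring in a single reference gene set, plus the fraction fully
#' contained in one set.
#'
#' @param path_set Output of [stage_paths()].
#' @param gene_sets Tibble `pathway`, `gene`.
#' @param k Minimum number of co-occurring genes (default 2).
#' @return One-row tibble `n_paths`, `k`, `frac_at_least_k`,
#'   `frac_all_in_one`; fractions are `NA` when there are no paths.
#' @export
pathway_overlap <- function(path_set, gene_sets, k = 2) {
  if (k < 2) abort_input("k must be >= 2")
  if (nrow(path_set) == 0) {
    return(tibble::tibble(n_paths = 0L, k = k,
                          frac_at_least_k = NA_real_,
                          frac_all_in_one = NA_real_))
  }
  sets <- split(gene_sets$gene, gene_sets$pathway)
  per_path <- purrr::map_df(path_set$path, function(p) {
    ov <- vapply(sets, function(s) length(intersect(p, s)), integer(1))
    m <- if (length(ov) == 0) 0L else max(ov)
    tibble::tibble(max_overlap = m, all_in_one = m == length(unique(p)))
  })
  tibble::tibble(
    n_paths = nrow(path_set), k = k,
    frac_at_least_k = mean(per_path$max_overlap >= k),
    frac_all_in_one = mean(per_path$all_in_one)
  )
}
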