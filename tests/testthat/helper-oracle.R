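# Independent oracles for the flow solver.
#
# brute_force_optimum(): exhaustive enumeration of integral flows on the
# solver's own expanded graph, via simple S->T paths and integral path
# flows (optimal flows are cycle-free because all non-source arc costs are
# strictly positive, and only negative-total-cost paths can carry flow at
# an optimum). Returns the minimum objective and whether the optimal
# arc-flow vector is unique among integral flows.
#
# lp_reference(): the same LP solved with pracma::linprog (dense simplex),
# for real-valued capacity cross-checks; returns NULL if the dense solver
# fails to converge so callers can skip the instance.

enumerate_st_paths <- function(arcs, s, t, max_paths = 400) {
  paths <- list()
  dfs <- function(node, used, arc_seq) {
    if (length(paths) >= max_paths) return()
    if (node == t) {
      paths[[length(paths) + 1]] <<- arc_seq
      return()
    }
    for (k in which(arcs$from_i == node)) {
      v <- arcs$to_i[k]
      if (v %in% used) next
      dfs(v, c(used, v), c(arc_seq, k))
    }
  }
  dfs(s, s, integer(0))
  paths
}

brute_force_optimum <- function(problem) {
  ex <- tempoflow:::expand_problem(problem)
  arcs <- ex$arcs
  paths <- enumerate_st_paths(arcs, ex$s_idx, ex$t_idx)
  path_cost <- vapply(paths, function(p) sum(arcs$cost[p]), numeric(1))
  # zero-cost paths would make the "negative paths only" pruning unsound;
  # the instance generators avoid them, but be safe
  if (any(abs(path_cost) <= 1e-9)) return(NULL)
  neg <- which(path_cost < 0)  # only negative-cost paths carry optimal flow
  m <- nrow(arcs)
  best <- 0  # zero flow is always feasible with objective 0
  best_loads <- list(rep(0, m))
  rec <- function(i, load, obj) {
    if (abs(obj - best) < 1e-9) {
      best_loads[[length(best_loads) + 1]] <<- load
    } else if (obj < best) {
      best <<- obj
      best_loads <<- list(load)
    }
    if (i > length(neg)) return()
    p <- paths[[neg[i]]]
    maxx <- floor(min(arcs$capacity[p] - load[p]) + 1e-9)
    if (maxx >= 1) {
      for (x in seq_len(maxx)) {
        l2 <- load
        l2[p] <- l2[p] + x
        rec(i + 1, l2, obj + x * path_cost[neg[i]])
      }
    }
    rec(i + 1, load, obj)
  }
  rec(1, rep(0, m), 0)
  keys <- unique(vapply(best_loads, function(l) paste(l, collapse = ","),
                        character(1)))
  # per-original-arc flow bounds over the optimal set: the feasible region
  # is an integral polytope (network matrix), so every vertex of the
  # optimal face is one of the enumerated integral optima and the per-arc
  # extrema over them equal the LP flow-variability bounds
  loads <- unique(best_loads)
  olev <- sort(unique(arcs$orig))
  orig_load <- function(l) {
    vapply(split(l, factor(arcs$orig, levels = olev)), sum, numeric(1))
  }
  per_orig <- vapply(loads, orig_load, numeric(length(olev)))
  if (is.null(dim(per_orig))) per_orig <- matrix(per_orig, nrow = 1)
  bounds <- tibble::tibble(
    orig = olev,
    f_min = unname(apply(per_orig, 1, min)),
    f_max = unname(apply(per_orig, 1, max))
  )
  list(objective = best, unique = length(keys) == 1,
       n_paths = length(paths), bounds = bounds)
}

conservation_matrix <- function(ex) {
  arcs <- ex$arcs
  nodes <- setdiff(seq_along(ex$labels), c(ex$s_idx, ex$t_idx))
  A <- matrix(0, length(nodes), nrow(arcs))
  for (k in seq_along(nodes)) {
    A[k, ] <- (arcs$to_i == nodes[k]) - (arcs$from_i == nodes[k])
  }
  A
}

lp_reference <- function(problem) {
  ex <- tempoflow:::expand_problem(problem)
  arcs <- ex$arcs
  m <- nrow(arcs)
  A3 <- conservation_matrix(ex)
  fit <- pracma::linprog(cc = arcs$cost, A = diag(m), b = arcs$capacity,
                         Aeq = A3, beq = rep(0, nrow(A3)),
                         maxiter = 500 * m)
  if (is.null(fit$errno) || fit$errno < 0) return(NULL)
  list(objective = fit$fval, flow = as.numeric(fit$x))
}

# Random stage-layered DAG instance: T1 -> (mid) -> T2 -> (mid) -> T3 with
# skip arcs, integral capacities <= cap_max, costs in [0.2, 1].
random_instance <- function(seed, n_t1 = 2, n_t2 = 2, n_t3 = 2,
                            n_mid = 1, cap_max = 3, arc_prob = 0.6,
                            kappa1 = NULL, mode = "temporal_strict",
                            integral = TRUE) {
  set.seed(seed)
  t1 <- paste0("a", seq_len(n_t1))
  t2 <- paste0("m", seq_len(n_t2))
  t3 <- paste0("b", seq_len(n_t3))
  u1 <- if (n_mid > 0) paste0("u", seq_len(n_mid)) else character(0)
  u2 <- if (n_mid > 0) paste0("v", seq_len(n_mid)) else character(0)
  layer_pairs <- rbind(
    expand.grid(from = t1, to = c(u1, t2), stringsAsFactors = FALSE),
    expand.grid(from = u1, to = t2, stringsAsFactors = FALSE),
    expand.grid(from = t2, to = c(u2, t3), stringsAsFactors = FALSE),
    expand.grid(from = u2, to = t3, stringsAsFactors = FALSE),
    expand.grid(from = t1, to = t3, stringsAsFactors = FALSE)  # dropped
  )
  keep <- runif(nrow(layer_pairs)) < arc_prob
  arcs <- tibble::as_tibble(layer_pairs[keep, ])
  if (nrow(arcs) == 0) return(NULL)
  rcap <- function(n) if (integral) sample(1:cap_max, n, replace = TRUE) else
    round(runif(n, 0.3, cap_max), 3)
  arcs <- arcs |>
    dplyr::mutate(capacity = rcap(dplyr::n()),
                  cost = round(runif(dplyr::n(), 0.2, 1), 3))
  kappa1 <- kappa1 %||% sample(c(1, 1.5, 2, 3), 1)
  flow_problem(
    arcs, t1 = t1, t2 = t2, t3 = t3,
    source_capacity = setNames(rcap(n_t1), t1),
    sink_capacity = setNames(rcap(n_t3), t3),
    kappa1 = kappa1, mode = mode
  )
}

`%||%` <- rlang::`%||%`

# exhaustive hop-capped path enumeration used as the shortest-path oracle
enum_paths <- function(lengths, s0, t0, cap) {
  out <- list()
  walk <- function(node, len, path) {
    if (node == t0 && length(path) > 1) {
      out[[length(out) + 1]] <<- list(len = len, path = path)
    }
    if (length(path) - 1 >= cap) return()
    for (k in which(lengths$from == node)) {
      v <- lengths$to[k]
      if (v %in% path) next
      walk(v, len + lengths$length[k], c(path, v))
    }
  }
  walk(s0, 0, s0)
  out
}

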