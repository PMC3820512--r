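# Constructed fixtures shared across test files.

# Diamond: the cheap route S -> A -> X -> D -> T bypasses the T2 gene M;
# the dearer route S -> A -> M -> D -> T transits it. Strict mode must use
# M, responsenet mode prefers X.
make_diamond_problem <- function(mode = "temporal_strict", kappa1 = 2,
                                 cap = 1) {
  arcs <- tibble::tibble(
    from = c("A", "A", "M", "X"),
    to = c("M", "X", "D", "D"),
    capacity = cap,
    cost = c(0.3, 0.25, 0.3, 0.25)
  )
  flow_problem(arcs, t1 = "A", t2 = "M", t3 = "D",
               source_capacity = c(A = cap), sink_capacity = c(D = cap),
               kappa1 = kappa1, mode = mode, gamma = kappa1)
}

# Two identical-cost parallel routes through different T2 genes sharing
# the single unit of source capacity: classic symmetric alternate optima.
make_parallel_problem <- function(kappa1 = 2) {
  arcs <- tibble::tibble(
    from = c("A", "A", "M1", "M2"),
    to = c("M1", "M2", "D", "D"),
    capacity = 1,
    cost = 0.3
  )
  flow_problem(arcs, t1 = "A", t2 = c("M1", "M2"), t3 = "D",
               source_capacity = c(A = 1), sink_capacity = c(D = 2),
               kappa1 = kappa1, mode = "temporal_strict")
}

# Single unique path S -> A -> M -> D -> T (distinct costs, no ties).
make_path_problem <- function(kappa1 = 2) {
  arcs <- tibble::tibble(
    from = c("A", "M"), to = c("M", "D"),
    capacity = c(2, 2), cost = c(0.31, 0.4)
  )
  flow_problem(arcs, t1 = "A", t2 = "M", t3 = "D",
               source_capacity = c(A = 1.5), sink_capacity = c(D = 2),
               kappa1 = kappa1, mode = "temporal_strict")
}

# Small hand-written expression table exercising all three filters.
make_filter_expr <- function() {
  tibble::tibble(
    gene = c("induced", "low", "flat", "late_peak", "early_peak"),
    `0` = c(15, 1, 12, 10, 10),
    `0.5` = c(15, 1, 12, 10, 45),
    `1` = c(15, 1, 12, 10, 30),
    `2` = c(15, 1, 12, 11, 10),
    `3` = c(64, 1, 12, 12, 10),
    `4` = c(15, 1, 12, 13, 10),
    `6` = c(15, 1, 12, 30, 10),
    `8` = c(15, 1, 12, 55, 10)
  )
}
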