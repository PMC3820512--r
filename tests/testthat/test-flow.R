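test_that("strict mode transits the T2 gene, responsenet takes the cheap bypass", {
  strict <- solve_flow(make_diamond_problem("temporal_strict"))
  rn <- solve_flow(make_diamond_problem("responsenet"))
  f_strict <- strict$arcs
  f_rn <- rn$arcs
  arc_flow <- function(sol, u, v) {
    sol$arcs$flow[sol$arcs$from == u & sol$arcs$to == v]
  }
  expect_equal(arc_flow(strict, "A", "M"), 1)
  expect_equal(arc_flow(strict, "A", "X"), 0)
  expect_equal(arc_flow(rn, "A", "X"), 1)
  expect_equal(arc_flow(rn, "A", "M"), 0)
  # aggregate mode also forces the transit on this instance
  agg <- solve_flow(make_diamond_problem("temporal_aggregate"))
  expect_equal(arc_flow(agg, "A", "M"), 1)
  # the relaxation can only improve the objective
  expect_lte(rn$objective, strict$objective + 1e-12)
})

test_that("zero source capacity gives the zero flow with objective 0", {
  pr <- make_diamond_problem(cap = 1)
  pr$arcs$capacity[pr$arcs$from == "S"] <- 0
  sol <- solve_flow(pr)
  expect_equal(sum(sol$arcs$flow), 0)
  expect_equal(sol$objective, 0)
})

test_that("solver equals exhaustive integral enumeration on small instances", {
  n_checked <- 0
  for (seed in 1:60) {
    for (mode in c("temporal_strict", "responsenet")) {
      pr <- random_instance(seed, mode = mode)
      if (is.null(pr)) next
      oracle <- brute_force_optimum(pr)
      if (is.null(oracle)) next
      sol <- solve_flow(pr)
      expect_equal(sol$objective, oracle$objective, tolerance = 1e-9,
                   label = paste("seed", seed, mode))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 40)
})

test_that("solver agrees with an independent dense-simplex LP solution", {
  n_checked <- 0
  for (seed in 101:130) {
    pr <- random_instance(seed, integral = FALSE,
                          mode = sample(c("temporal_strict", "responsenet"), 1))
    if (is.null(pr)) next
    ref <- lp_reference(pr)
    sol <- solve_flow(pr)
    expect_equal(sol$objective, ref$objective, tolerance = 1e-8,
                 label = paste("seed", seed))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 20)
})

test_that("every solve conserves flow and respects capacities", {
  for (seed in 201:230) {
    pr <- random_instance(seed, integral = FALSE,
                          mode = sample(c("temporal_strict", "responsenet"), 1))
    if (is.null(pr)) next
    sol <- solve_flow(pr)
    expect_lt(conservation_violation(sol), 1e-9)
    expect_true(all(sol$arcs$flow <= sol$arcs$capacity + 1e-9))
    expect_true(all(sol$arcs$flow >= 0))
    expect_equal(total_outflow(sol),
                 sum(sol$arcs$flow[sol$arcs$to == "T"]), tolerance = 1e-9)
  }
})

test_that("strict-mode decompositions never bypass the T2 stage", {
  for (seed in 301:320) {
    pr <- random_instance(seed, mode = "temporal_strict")
    if (is.null(pr)) next
    sol <- solve_flow(pr)
    dec <- decompose_flow(sol)
    if (nrow(dec) == 0) next
    expect_true(all(dec$contains_t2), label = paste("seed", seed))
    expect_equal(sum(dec$flow), total_outflow(sol), tolerance = 1e-9)
  }
})

test_that("flow decomposition bookkeeping matches constructed instances", {
  # unique path: one decomposed path carrying the whole flow
  sol <- solve_flow(make_path_problem())
  dec <- decompose_flow(sol)
  expect_equal(nrow(dec), 1)
  expect_equal(dec$flow, 1.5)  # source capacity is the bottleneck
  expect_equal(dec$path[[1]], c("A", "M", "D"))
  # two arc-disjoint unit paths
  arcs <- tibble::tibble(
    from = c("A1", "A2", "M1", "M2"), to = c("M1", "M2", "D1", "D2"),
    capacity = 1, cost = 0.3
  )
  pr <- flow_problem(arcs, t1 = c("A1", "A2"), t2 = c("M1", "M2"),
                     t3 = c("D1", "D2"),
                     source_capacity = c(A1 = 1, A2 = 1),
                     sink_capacity = c(D1 = 1, D2 = 1), kappa1 = 2)
  dec2 <- decompose_flow(solve_flow(pr))
  expect_equal(nrow(dec2), 2)
  expect_equal(sum(dec2$flow), 2)
})

test_that("node flows combine incoming arc flows", {
  sol <- solve_flow(make_diamond_problem())
  nf <- setNames(sol$node_flows$flow, sol$node_flows$gene)
  # source-layer gene: its only in-arc is the S arc
  expect_equal(nf[["A"]],
               sol$arcs$flow[sol$arcs$from == "S" & sol$arcs$to == "A"])
  expect_equal(nf[["D"]], 1)  # one unit in from M
  expect_equal(nf[["X"]], 0)  # bypass unused in strict mode
  # isolated genes score zero
  arcs <- tibble::tibble(from = c("A", "M", "lone"),
                         to = c("M", "D", "lone2"),
                         capacity = c(2, 2, 1), cost = c(0.3, 0.3, 0.5))
  pr <- flow_problem(arcs, t1 = "A", t2 = "M", t3 = "D",
                     source_capacity = c(A = 1), sink_capacity = c(D = 1),
                     kappa1 = 2)
  nf2 <- node_flows(solve_flow(pr))
  expect_equal(nf2$flow[nf2$gene == "lone2"], 0)
})

test_that("raising kappa1 never shrinks the total source outflow", {
  for (seed in 401:410) {
    pr <- random_instance(seed, integral = FALSE, kappa1 = 0)
    if (is.null(pr)) next
    prev <- -Inf
    for (k1 in seq(0, 3, by = 0.5)) {
      pr$kappa1 <- k1
      out <- total_outflow(solve_flow(pr))
      expect_gte(out, prev - 1e-8)
      prev <- out
    }
  }
})

test_that("aggregate mode agrees with the layered LP when both bind", {
  # on stage-layered DAGs every path crosses T2 at most once, so the
  # aggregate constraint with eps = 1 enforces the same requirement
  for (seed in 501:508) {
    pr <- random_instance(seed, n_mid = 0, integral = FALSE)
    if (is.null(pr)) next
    pr_ag <- pr
    pr_ag$mode <- "temporal_aggregate"
    s1 <- solve_flow(pr)
    s2 <- solve_flow(pr_ag)
    expect_equal(s1$objective, s2$objective, tolerance = 1e-7,
                 label = paste("seed", seed))
  }
})
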