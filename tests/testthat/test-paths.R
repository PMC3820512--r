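test_that("opsahl lengths normalize by the mean active flow", {
  sol <- solve_flow(make_parallel_problem())
  # hand instance: set flows directly through a fake solution arc table
  lens <- opsahl_lengths(sol)
  expect_equal(mean(lens$flow / lens$flow[1]) * lens$length[1] *
                 lens$flow[1] / mean(lens$flow), 1)
  # f_bar = 2, f = 4 -> 0.5; f = f_bar -> 1
  fake <- sol
  fake$arcs <- tibble::tibble(
    from = c("a", "b"), to = c("b", "c"), weight = 0.5,
    capacity = 10, cost = 0.2, aux = FALSE,
    flow = c(4, 0), active = c(TRUE, FALSE)
  )
  l1 <- opsahl_lengths(fake)
  expect_equal(l1$length, 1)  # single active arc: f = f_bar
  fake$arcs$flow <- c(4, 0.0000001)
  fake$arcs$active <- c(TRUE, TRUE)
  fake$arcs$flow[2] <- 0  # inactive arcs are excluded outright
  fake$arcs$active[2] <- FALSE
  expect_equal(nrow(opsahl_lengths(fake)), 1)
})

test_that("arcs at mean flow have length exactly one", {
  fx <- simulate_cascade_data(n_nodes = 50, n_cascades = 4, seed = 21)
  net <- fx$interactions |> scale_scores() |> build_network()
  st <- stage_genes(fx$expression)
  sol <- solve_flow(build_flow_problem(net, st, kappa1 = 2))
  lens <- opsahl_lengths(sol)
  fbar <- mean(lens$flow)
  at_mean <- abs(lens$flow - fbar) < 1e-12
  expect_equal(lens$length[at_mean], rep(1, sum(at_mean)))
  expect_equal(lens$length, fbar / lens$flow)
})

test_that("hop-capped stage paths match exhaustive enumeration", {
  for (seed in 701:712) {
    fx <- simulate_cascade_data(n_nodes = 12, n_cascades = 2,
                                arc_density = 0.25, seed = seed)
    net <- fx$interactions |> scale_scores() |> build_network()
    st <- stage_genes(fx$expression)
    st <- st[st$gene %in% net$nodes, ]
    if (length(unique(st$stage[!is.na(st$stage)])) < 3) next
    sol <- try(solve_flow(build_flow_problem(net, st, kappa1 = 3)),
               silent = TRUE)
    if (inherits(sol, "try-error")) next
    lens <- opsahl_lengths(sol)
    if (nrow(lens) == 0) next
    ps <- stage_paths(sol, hop_cap = 3, pairs = "all")
    stages <- sol$problem$stages
    for (sp in list(c("T1", "T2"), c("T2", "T3"), c("T1", "T3"))) {
      for (s0 in intersect(stages[[sp[1]]], unique(c(lens$from, lens$to)))) {
        for (t0 in setdiff(intersect(stages[[sp[2]]],
                                     unique(c(lens$from, lens$to))), s0)) {
          ref <- enum_paths(lens, s0, t0, 3)
          got <- ps[ps$from == s0 & ps$to == t0 &
                      ps$from_stage == sp[1], ]
          if (length(ref) == 0) {
            expect_equal(nrow(got), 0)
          } else {
            best <- min(vapply(ref, `[[`, numeric(1), "len"))
            expect_equal(nrow(got), 1)
            expect_equal(got$length, best, tolerance = 1e-9)
          }
        }
      }
    }
  }
})

test_that("paths longer than the hop cap are omitted", {
  # chain of four arcs; capping at 3 hops hides the endpoint pair
  sol <- solve_flow(make_path_problem())
  lens <- tibble::tibble(
    from = c("a", "b", "c", "d"), to = c("b", "c", "d", "e"),
    flow = 1, length = 1
  )
  ref3 <- enum_paths(lens, "a", "e", 3)
  ref4 <- enum_paths(lens, "a", "e", 4)
  expect_equal(length(ref3), 0)
  expect_equal(length(ref4), 1)
  # and through the public interface
  fake <- sol
  fake$arcs <- lens |>
    mutate(weight = 0.8, capacity = 2, cost = 0.2, aux = FALSE,
           active = TRUE)
  fake$problem$stages <- list(T1 = "a", T2 = "c", T3 = "e")
  ps <- stage_paths(fake, hop_cap = 3, pairs = "all")
  expect_false(any(ps$from == "a" & ps$to == "e"))
  # single-arc connection is its own shortest path
  expect_true(any(ps$from == "c" & ps$to == "e" & ps$hops == 2))
})

test_that("reference-pathway matching finds planted directed paths", {
  # active sub-network containing a planted 5-arc cascade
  chain <- c("x1", "x2", "x3", "x4", "x5", "x6")
  sol <- solve_flow(make_path_problem())
  sol$arcs <- tibble::tibble(
    from = chain[-6], to = chain[-1], weight = 0.8, capacity = 2,
    cost = 0.2, aux = FALSE, flow = 1.5, active = TRUE
  )
  ref <- tibble::tibble(pathway = "planted", from = chain[-6],
                        to = chain[-1])
  expect_equal(match_reference_paths(sol, ref)$longest_match, 5L)
  # the active sub-network as its own reference: longest path in itself
  ref2 <- sol$arcs |> select(from, to) |> mutate(pathway = "self")
  expect_equal(match_reference_paths(sol, ref2)$longest_match, 5L)
  # disjoint namespaces match nothing
  ref3 <- tibble::tibble(pathway = "alien", from = "q1", to = "q2")
  expect_equal(match_reference_paths(sol, ref3)$longest_match, 0L)
  # monotone in the reference: adding edges never shortens the match
  ref4 <- bind_rows(ref3 |> mutate(pathway = "mix"),
                    ref |> mutate(pathway = "mix") |> dplyr::slice(1:3))
  m1 <- match_reference_paths(sol, ref4)$longest_match
  ref5 <- bind_rows(ref4, ref |> mutate(pathway = "mix"))
  m2 <- match_reference_paths(sol, ref5)$longest_match
  expect_gte(m2, m1)
  expect_equal(nrow(match_reference_paths(sol, ref[0, ])), 0)
})

test_that("pathway overlap fractions behave at the extremes", {
  paths <- tibble::tibble(
    from = "a", to = "c", from_stage = "T1", to_stage = "T2",
    length = 2, hops = 2L, path = list(c("a", "b", "c"))
  )
  full <- tibble::tibble(pathway = "p1", gene = c("a", "b", "c"))
  expect_equal(pathway_overlap(paths, full)$frac_at_least_k, 1)
  expect_equal(pathway_overlap(paths, full)$frac_all_in_one, 1)
  singles <- tibble::tibble(pathway = paste0("p", 1:3),
                            gene = c("a", "b", "c"))
  expect_equal(pathway_overlap(paths, singles, k = 2)$frac_at_least_k, 0)
  empty <- pathway_overlap(paths[0, ], full)
  expect_equal(empty$n_paths, 0L)
  expect_true(is.na(empty$frac_at_least_k))
})
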