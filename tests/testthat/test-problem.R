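toy_network <- function(arcs) {
  structure(list(arcs = arcs,
                 nodes = sort(unique(c(arcs$from, arcs$to)))),
            class = "scored_network")
}

toy_staging <- function() {
  tibble::tibble(
    gene = c("p", "q", "r"),
    stage = factor(c("T1", "T2", "T3"), c("T1", "T2", "T3")),
    max_abs_lfc = c(2, 1.5, 3),
    peak_time = c(1, 3, 8),
    mean_abund = c(30, 10, 20)
  )
}

test_that("capacities follow the stage-dependent rules", {
  arcs <- tibble::tibble(
    from = c("p", "q", "x"), to = c("q", "r", "y"),
    type = "tf_target", db = "d", weight = c(0.5, 0.6, 0.8)
  )
  pr <- build_flow_problem(toy_network(arcs), toy_staging(),
                           kappa1 = 1, kappa2 = 0)
  a <- pr$arcs
  # singleton stage groups: base capacity = F/F + e/e = 2
  expect_equal(a$capacity[a$from == "S"], 2)            # S -> T1 gene
  expect_equal(a$capacity[a$to == "T"], 2)              # T3 gene -> T
  expect_equal(a$capacity[a$from == "p" & a$to == "q"], 2)  # T2-incident
  expect_equal(a$capacity[a$from == "x"], 1)            # unstaged arc
  # kappa2 adds w to T2-incident capacities only
  pr2 <- build_flow_problem(toy_network(arcs), toy_staging(),
                            kappa1 = 1, kappa2 = 2)
  a2 <- pr2$arcs
  expect_equal(a2$capacity[a2$from == "p" & a2$to == "q"], 2 + 2 * 0.5)
  expect_equal(a2$capacity[a2$from == "x"], 1)
})

test_that("costs are 1 - w with capacity-bonus on stage-touching arcs", {
  arcs <- tibble::tibble(
    from = c("p", "q", "x"), to = c("q", "r", "y"),
    type = "tf_target", db = "d", weight = c(0.5, 0.6, 0.8)
  )
  pr <- build_flow_problem(toy_network(arcs), toy_staging(),
                           kappa1 = 1, kappa2 = 0)
  a <- pr$arcs
  # unstaged arc with w = 0.8 keeps cost 1 - 0.8 = 0.2
  expect_equal(a$cost[a$from == "x"], 0.2)
  # stage-touching arc: w' = min(0.8, w * cap) = min(0.8, 1.0) -> cost 0.2
  expect_equal(a$cost[a$from == "p" & a$to == "q"], 0.2)
  expect_true(all(a$cost >= 0.2 - 1e-12 & a$cost <= 1))
  # auxiliary arcs carry the fixed 0.2 cost
  expect_equal(unique(a$cost[a$aux]), 0.2)
})

test_that("direct T1-T3 arcs are excluded and terminals wired correctly", {
  arcs <- tibble::tibble(
    from = c("p", "q", "p", "r"), to = c("q", "r", "r", "p"),
    type = "tf_target", db = "d", weight = 0.5
  )
  pr <- build_flow_problem(toy_network(arcs), toy_staging(), kappa1 = 1)
  a <- pr$arcs
  expect_false(any(a$from == "p" & a$to == "r"))
  expect_false(any(a$from == "r" & a$to == "p"))
  expect_equal(a$to[a$from == "S"], "p")
  expect_equal(a$from[a$to == "T"], "r")
  # no arcs between terminals and T2
  expect_false(any(a$from == "S" & a$to == "q"))
  expect_false(any(a$from == "q" & a$to == "T"))
})

test_that("responsenet mode caps internal arcs at 1 with identical costs", {
  arcs <- tibble::tibble(
    from = c("p", "q"), to = c("q", "r"),
    type = "tf_target", db = "d", weight = c(0.5, 0.6)
  )
  tmp <- build_flow_problem(toy_network(arcs), toy_staging(), kappa1 = 1)
  rn <- build_flow_problem(toy_network(arcs), toy_staging(), kappa1 = 1,
                           mode = "responsenet")
  a_t <- tmp$arcs |> dplyr::filter(!aux)
  a_r <- rn$arcs |> dplyr::filter(!aux)
  expect_equal(a_r$capacity, rep(1, nrow(a_r)))
  expect_equal(a_r$cost, a_t$cost)  # "identical edge costs"
  expect_equal(rn$arcs$capacity[rn$arcs$aux],
               tmp$arcs$capacity[tmp$arcs$aux])
})

test_that("degenerate stagings are rejected", {
  arcs <- tibble::tibble(from = "p", to = "q", type = "tf_target",
                         db = "d", weight = 0.5)
  st <- toy_staging()[1:2, ]  # no T3 gene
  expect_error(build_flow_problem(toy_network(arcs), st, kappa1 = 1),
               class = "tempoflow_infeasible_error")
  # staged genes missing from the network are dropped with a warning
  st2 <- toy_staging() |>
    dplyr::bind_rows(tibble::tibble(gene = "ghost", stage = factor("T1", c("T1", "T2", "T3")),
                                    max_abs_lfc = 1, peak_time = 1,
                                    mean_abund = 5))
  arcs2 <- tibble::tibble(from = c("p", "q"), to = c("q", "r"),
                          type = "tf_target", db = "d", weight = 0.5)
  expect_warning(build_flow_problem(toy_network(arcs2), st2, kappa1 = 1),
                 "dropped")
})
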