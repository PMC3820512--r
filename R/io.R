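#' Read a gene-by-time expression matrix
#'
#' Tab-delimited, header row `gene<TAB>t0<TAB>t1...` with the remaining
#' column names parseable as sampling times in hours; time 0 required.
#'
#' @param file Path.
#' @return Validated expression tibble.
#' @export
read_expression <- function(file) {
  if (!file.exists(file)) abort_input(paste0("file not found: ", file))
  expr <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
  names(expr)[1] <- "gene"
  bad <- readr::problems(expr)
  if (nrow(bad) > 0) {
    abort_input(paste0("malformed expression file ", file, " at line(s): ",
                       paste(head(unique(bad$row), 5), collapse = ", ")))
  }
  validate_expression(expr)
  expr
}

#' Write an expression matrix
#' @param expr Expression tibble.
#' @param file Path.
#' @export
write_expression <- function(expr, file) {
  readr::write_tsv(expr, file)
  invisible(file)
}

#' Read an interaction table
#'
#' Tab-delimited with columns `source`, `target`, `type`, `db`, `score` —
#' the generic stand-in for exports of scored interaction databases.
#'
#' @param file Path.
#' @return Validated interaction tibble.
#' @export
read_interactions <- function(file) {
  if (!file.exists(file)) abort_input(paste0("file not found: ", file))
  recs <- readr::read_tsv(
    file, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      source = readr::col_character(), target = readr::col_character(),
      type = readr::col_character(), db = readr::col_character(),
      score = readr::col_double()
    )
  )
  bad <- readr::problems(recs)
  if (nrow(bad) > 0) {
    abort_input(paste0("malformed interaction file ", file, " at line(s): ",
                       paste(head(unique(bad$row + 1), 5), collapse = ", ")))
  }
  validate_interactions(recs)
  recs
}

#' Write an interaction table / a scored network
#' @param x Interaction tibble or `scored_network`.
#' @param file Path.
#' @export
write_interactions <- function(x, file) {
  if (inherits(x, "scored_network")) x <- x$arcs
  readr::write_tsv(x, file)
  invisible(file)
}

#' Read a reference pathway edge list (`pathway`, `from`, `to`)
#' @param file Path.
#' @return Tibble.
#' @export
read_pathway_edges <- function(file) {
  if (!file.exists(file)) abort_input(paste0("file not found: ", file))
  readr::read_tsv(file, show_col_types = FALSE, progress = FALSE,
                  col_types = "ccc")
}

#' Read pathway gene sets (`pathway`, `gene`)
#' @param file Path.
#' @return Tibble.
#' @export
read_gene_sets <- function(file) {
  if (!file.exists(file)) abort_input(paste0("file not found: ", file))
  readr::read_tsv(file, show_col_types = FALSE, progress = FALSE,
                  col_types = "cc")
}

#' Pipeline run configuration
#'
#' Collects and validates every tunable of an end-to-end run. Inputs may
#' be file paths or in-memory tibbles.
#'
#' @param expression Expression table or path.
#' @param interactions Interaction table or path.
#' @param out_dir Output directory (created if needed); NULL disables
#'   writing.
#' @param used_times Time points used (default: all in the matrix).
#' @param windows Stage windows.
#' @param pseudocount Fold-change pseudocount (fpkm).
#' @param kappa1,kappa2 Operating point (ignored when `sweep = TRUE`).
#' @param sweep If TRUE, select the operating point by [sweep_kappa()].
#' @param mode Flow mode.
#' @param gamma ResponseNet reward (defaults to `kappa1`).
#' @param knockout Genes deleted from the network before solving.
#' @param n_random Randomization count for significance (0 skips).
#' @param stability If TRUE, run [stability_analysis()].
#' @param hop_cap Path extraction hop cap.
#' @param seed Seed for all randomness of the run.
#' @param rename Optional node-rename table (`old`, `new`) or path.
#' @return A `run_config` list.
#' @export
run_config <- function(expression, interactions, out_dir = NULL,
                       used_times = NULL, windows = stage_windows(),
                       pseudocount = 1, kappa1 = 0.5, kappa2 = 0,
                       sweep = FALSE, mode = "temporal_strict",
                       gamma = NULL, knockout = character(),
                       n_random = 0, stability = TRUE, hop_cap = 3,
                       seed = 1, rename = NULL) {
  structure(
    list(expression = expression, interactions = interactions,
         out_dir = out_dir, used_times = used_times, windows = windows,
         pseudocount = pseudocount, kappa1 = kappa1, kappa2 = kappa2,
         sweep = sweep, mode = mode, gamma = gamma %||% kappa1,
         knockout = knockout, n_random = n_random, stability = stability,
         hop_cap = hop_cap, seed = seed, rename = rename),
    class = "run_config"
  )
}

#' Run the full inference pipeline
#'
#' Expression prep, network assembly, optional knockout deletion, solve
#' (or kappa sweep), optional randomization significance and stability,
#' and path extraction. When `out_dir` is set, writes the stats, network,
#' arc, node, path, significance and stability tables as TSV plus a JSON
#' run manifest stamped with the configuration hash and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `stats`, `staging`, `network`,
#'   `solution`, `sweep`, `significance`, `stability`, `paths`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  expr <- if (is.character(config$expression)) {
    read_expression(config$expression)
  } else {
    validate_expression(config$expression)
  }
  recs <- if (is.character(config$interactions)) {
    read_interactions(config$interactions)
  } else {
    validate_interactions(config$interactions)
  }
  rename <- config$rename
  if (is.character(rename)) {
    rename <- readr::read_tsv(rename, show_col_types = FALSE,
                              col_types = "cc")
  }

  stats <- gene_stats(expr, used_times = config$used_times,
                      pseudocount = config$pseudocount)
  staging <- stats |>
    filter_genes() |>
    assign_stages(config$windows) |>
    select("gene", "stage", "max_abs_lfc", "peak_time", "mean_abund")

  network <- recs |> scale_scores() |> build_network(rename = rename)
  if (length(config$knockout) > 0) {
    network <- apply_knockout(network, config$knockout)
    staging <- filter(staging, !.data$gene %in% config$knockout)
  }

  sweep <- NULL
  if (isTRUE(config$sweep)) {
    sweep <- sweep_kappa(network, staging, mode = config$mode,
                         gamma = config$gamma)
    solution <- sweep$solution
  } else {
    solution <- solve_flow(build_flow_problem(
      network, staging, kappa1 = config$kappa1, kappa2 = config$kappa2,
      mode = config$mode, gamma = config$gamma
    ))
  }

  significance <- NULL
  if (config$n_random > 0) {
    significance <- randomization_pvalues(
      network, staging, solution, R = config$n_random,
      seed = config$seed, stats = stats
    )
  }
  stability <- NULL
  if (isTRUE(config$stability) && config$mode != "temporal_aggregate") {
    stability <- stability_analysis(solution)
  }
  paths <- stage_paths(solution, hop_cap = config$hop_cap)

  manifest <- list(
    package = "tempoflow",
    seed = config$seed,
    mode = config$mode,
    kappa1 = solution$kappa1, kappa2 = solution$kappa2,
    gamma = config$gamma,
    sweep = isTRUE(config$sweep),
    knockout = config$knockout,
    n_random = config$n_random,
    objective = solution$objective,
    status = solution$status,
    total_outflow = total_outflow(solution),
    n_staged = nrow(staging),
    stage_counts = as.list(stage_counts(staging)),
    solver = "successive shortest paths",
    config_hash = rlang::hash(config)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    readr::write_tsv(stats, p("gene_stats.tsv"))
    readr::write_tsv(staging, p("staging.tsv"))
    write_interactions(network, p("network.tsv"))
    readr::write_tsv(tidy(solution), p("arcs.tsv"))
    node_tab <- solution$node_flows
    if (!is.null(significance)) {
      node_tab <- node_tab |>
        left_join(significance |> select("gene", "p_value"), by = "gene")
    } else {
      node_tab$p_value <- NA_real_
    }
    readr::write_tsv(node_tab, p("nodes.tsv"))
    readr::write_tsv(
      paths |> mutate(path = purrr::map_chr(.data$path, paste,
                                            collapse = ";")),
      p("paths.tsv")
    )
    if (!is.null(significance)) {
      readr::write_tsv(as_tibble(significance), p("significance.tsv"))
    }
    if (!is.null(stability)) {
      readr::write_tsv(stability$arcs, p("stability.tsv"))
    }
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  invisible(list(stats = stats, staging = staging, network = network,
                 solution = solution, sweep = sweep,
                 significance = significance, stability = stability,
                 paths = paths, manifest = manifest))
}
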