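#' Recognised interaction types
#'
#' `ppi` records become bidirectional arc pairs; all other types
#' (transcription factor-target, post-translational modification,
#' functional association, inhibition) are single directed arcs.
#'
#' @export
interaction_types <- c("ppi", "tf_target", "ptm", "functional", "inhibition")

validate_interactions <- function(records, need_weight = FALSE) {
  req <- c("source", "target", "type", "db", "score")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) {
    abort_input(paste0("interaction table lacks column(s): ",
                       paste(miss, collapse = ", ")))
  }
  bad <- which(!nzchar(records$source) | !nzchar(records$target) |
                 is.na(records$source) | is.na(records$target))
  if (length(bad) > 0) {
    abort_input(paste0("empty node identifier at row(s): ",
                       paste(head(bad, 5), collapse = ", ")))
  }
  bad_type <- which(!records$type %in% interaction_types)
  if (length(bad_type) > 0) {
    abort_input(paste0(
      "unknown interaction type '", records$type[bad_type[1]],
      "' at row(s): ", paste(head(bad_type, 5), collapse = ", ")
    ))
  }
  if (any(is.na(records$score)) || any(records$score < 0)) {
    abort_input("raw reliability scores must be non-negative")
  }
  if (need_weight && !"weight" %in% names(records)) {
    abort_input("records must carry a 'weight' column; run scale_scores() first")
  }
  invisible(records)
}

#' Scale raw reliability scores per source database
#'
#' Min-max scales the raw reliability score of every record onto
#' `[0, target_max]` within its source database, so that incomparable
#' score dialects become a common edge-reliability scale. Sources with a
#' constant score (including curated sources using the 999 sentinel) map
#' uniformly to `target_max`.
#'
#' @param records Interaction tibble with columns `source`, `target`,
#'   `type`, `db`, `score`.
#' @param target_max Upper end of the scaled range (default 0.8).
#' @return `records` with a `weight` column in `[0, target_max]`.
#' @export
#' @examples
#' recs <- tibble::tibble(source = c("a", "b", "c"), target = "d",
#'                        type = "tf_target", db = "x", score = c(0, 5, 10))
#' scale_scores(recs)$weight
scale_scores <- function(records, target_max = 0.8) {
  validate_interactions(records)
  records |>
    group_by(.data$db) |>
    mutate(weight = {
      rng <- range(.data$score)
      if (diff(rng) <= 0) {
        rep(target_max, dplyr::n())
      } else {
        target_max * (.data$score - rng[1]) / (rng[2] - rng[1])
      }
    }) |>
    ungroup()
}

#' Build the directed scored network
#'
#' Turns scaled interaction records into a directed network: every `ppi`
#' record contributes arcs in both directions with equal weight, every
#' other record exactly one arc. Gene and protein identifiers share one
#' node namespace; an optional rename map (two columns `old`, `new`)
#' merges identifiers (e.g. an externally computed ortholog map).
#' Duplicate arcs collapse, keeping the maximum weight.
#'
#' @param records Output of [scale_scores()].
#' @param rename Optional tibble with columns `old`, `new`.
#' @return A `scored_network`: list with `arcs` (tibble `from`, `to`,
#'   `type`, `db`, `weight`) and `nodes`.
#' @export
build_network <- function(records, rename = NULL) {
  validate_interactions(records, need_weight = TRUE)
  if (any(records$weight < 0 | records$weight > 0.8 + 1e-12)) {
    abort_input("scaled weights must lie in [0, 0.8]")
  }
  fwd <- records |>
    select(from = "source", to = "target", "type", "db", "weight")
  rev <- records |>
    filter(.data$type == "ppi") |>
    select(from = "target", to = "source", "type", "db", "weight")
  arcs <- bind_rows(fwd, rev)
  if (!is.null(rename)) {
    map <- setNames(rename$new, rename$old)
    sub <- function(x) ifelse(x %in% names(map), unname(map[x]), x)
    arcs <- arcs |> mutate(from = sub(.data$from), to = sub(.data$to))
  }
  arcs <- arcs |>
    filter(.data$from != .data$to) |>
    arrange(.data$from, .data$to, desc(.data$weight), .data$db) |>
    distinct(.data$from, .data$to, .keep_all = TRUE)
  structure(
    list(arcs = arcs, nodes = sort(unique(c(arcs$from, arcs$to)))),
    class = "scored_network"
  )
}

#' @export
print.scored_network <- function(x, ...) {
  cat("<scored_network> ", length(x$nodes), " nodes, ",
      nrow(x$arcs), " arcs (w in [",
      round(min(x$arcs$weight), 3), ", ", round(max(x$arcs$weight), 3),
      "])\n", sep = "")
  invisible(x)
}

#' Genes of a scored network
#' @param network A `scored_network`.
#' @return Character vector of node identifiers.
#' @export
network_genes <- function(network) network$nodes

#' Delete knocked-out genes from a network
#'
#' Removes each listed node and every arc incident to it, emulating the
#' analysis of knockout samples (e.g. removing MyD88 before solving on
#' MyD88-knockout expression data). The input network is untouched.
#'
#' @param network A `scored_network`.
#' @param genes Character vector of nodes to delete.
#' @param strict If TRUE, a listed gene absent from the network is an
#'   error; otherwise a warning plus no-op for that gene.
#' @return A new `scored_network`.
#' @export
apply_knockout <- function(network, genes, strict = FALSE) {
  absent <- setdiff(genes, network$nodes)
  if (length(absent) > 0) {
    msg <- paste0("knockout gene(s) not in network: ",
                  paste(absent, collapse = ", "))
    if (strict) abort_input(msg) else warn(msg)
  }
  arcs <- network$arcs |>
    filter(!.data$from %in% genes, !.data$to %in% genes)
  structure(
    list(arcs = arcs, nodes = setdiff(network$nodes, genes)),
    class = "scored_network"
  )
}
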