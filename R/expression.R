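#' Stage windows for a three-stage time course
#'
#' The response is partitioned into three stages by the sampling time (in
#' hours) at which a gene shows its largest absolute log fold change:
#' initial response genes (T1), intermediate regulators (T2) and late
#' effectors (T3). The defaults are the 0.5-8 h LPS time course windows;
#' any disjoint triple covering the non-zero sampling times may be used.
#'
#' @param t1,t2,t3 Numeric vectors of sampling times (hours) belonging to
#'   each stage window. Must be disjoint.
#' @return A named list of the three windows.
#' @export
#' @examples
#' stage_windows()
stage_windows <- function(t1 = c(0.5, 1), t2 = c(2, 3, 4), t3 = c(6, 8)) {
  w <- list(T1 = as.numeric(t1), T2 = as.numeric(t2), T3 = as.numeric(t3))
  all_t <- unlist(w)
  if (anyDuplicated(all_t) > 0) {
    abort_input("stage windows must be disjoint")
  }
  w
}

#' Sampling times of an expression matrix
#'
#' @param expr Expression tibble: a `gene` column plus one numeric column
#'   per sampling time, named by the time in hours (e.g. `"0"`, `"0.5"`).
#' @return Numeric vector of times, in column order.
#' @export
expression_times <- function(expr) {
  nm <- setdiff(names(expr), "gene")
  tt <- suppressWarnings(as.numeric(nm))
  if (anyNA(tt)) {
    abort_input(paste0(
      "expression columns other than 'gene' must be named by sampling time ",
      "in hours; offending columns: ",
      paste(nm[is.na(tt)], collapse = ", ")
    ))
  }
  tt
}

#' Validate an expression matrix
#'
#' Checks the invariants of the gene-by-time abundance table: a `gene`
#' column with unique identifiers, strictly increasing sampling times
#' including time 0, and non-negative abundances (fpkm-like units).
#'
#' @inheritParams expression_times
#' @return `expr`, invisibly, if valid; otherwise an input error.
#' @export
validate_expression <- function(expr) {
  if (!is.data.frame(expr) || !"gene" %in% names(expr)) {
    abort_input("expression table must have a 'gene' column")
  }
  if (anyDuplicated(expr$gene) > 0) {
    dup <- unique(expr$gene[duplicated(expr$gene)])
    abort_input(paste0("duplicate gene identifiers: ",
                       paste(head(dup, 5), collapse = ", ")))
  }
  tt <- expression_times(expr)
  if (length(tt) < 2 || any(diff(tt) <= 0)) {
    abort_input("sampling times must be strictly increasing")
  }
  if (!0 %in% tt) {
    abort_input("expression table must include the time-0 baseline column")
  }
  vals <- as.matrix(expr[setdiff(names(expr), "gene")])
  if (anyNA(vals)) abort_input("expression values must not be missing")
  if (any(vals < 0)) abort_input("expression values must be non-negative")
  invisible(expr)
}

#' Per-time absolute log fold changes
#'
#' For each gene and each used non-zero time point j, computes
#' `|log2((e_ij + pseudocount) / (e_i0 + pseudocount))|`. The pseudocount
#' keeps fold changes finite when the baseline is zero.
#'
#' @inheritParams expression_times
#' @param used_times Times to use (must be a subset of the matrix times).
#'   Defaults to all times. Time 0 is always the baseline and never a
#'   fold-change term.
#' @param pseudocount Abundance added to numerator and denominator before
#'   taking the log (fpkm; default 1). Must be > 0 unless all baselines are
#'   positive.
#' @param log_base Base of the logarithm (default 2, so a 2-fold change has
#'   absolute log fold change 1).
#' @return Long tibble with columns `gene`, `time`, `abs_lfc`.
#' @export
fold_changes <- function(expr, used_times = NULL, pseudocount = 1,
                         log_base = 2) {
  validate_expression(expr)
  tt <- expression_times(expr)
  used_times <- if (is.null(used_times)) tt else as.numeric(used_times)
  if (!all(used_times %in% tt)) {
    abort_input("used_times must be a subset of the matrix sampling times")
  }
  if (pseudocount < 0) abort_input("pseudocount must be >= 0")
  fc_times <- setdiff(used_times, 0)
  cols <- setdiff(names(expr), "gene")
  t_of <- setNames(tt, cols)
  base_col <- cols[t_of == 0]
  long <- expr |>
    tidyr::pivot_longer(-"gene", names_to = "time_col", values_to = "abund") |>
    mutate(time = t_of[.data$time_col])
  base <- long |>
    filter(.data$time == 0) |>
    select("gene", e0 = "abund")
  long |>
    filter(.data$time %in% fc_times) |>
    left_join(base, by = "gene") |>
    mutate(abs_lfc = abs(log((.data$abund + pseudocount) /
                               (.data$e0 + pseudocount), base = log_base))) |>
    select("gene", "time", "abs_lfc")
}

#' Per-gene expression statistics
#'
#' Computes, per gene, the maximum absolute log fold change over the used
#' time points (`max_abs_lfc`), the earliest time at which that maximum is
#' attained (`peak_time`), the mean abundance over the used time points
#' including the baseline (`mean_abund`), and the three expression filters:
#'
#' * `pass_min2`: at least `min_abund_low` fpkm (default 2) in at least
#'   50% of the used time points (baseline included);
#' * `pass_min10`: at least `min_abund_high` fpkm (default 10) at 2 or more
#'   time points;
#' * `pass_fc`: absolute fold change greater than `fold_change_min`
#'   (default 2, i.e. `max_abs_lfc > 1` in log2) at one or more time points.
#'
#' `passes_filters` is the conjunction of the three.
#'
#' @inheritParams fold_changes
#' @param min_abund_low,min_abund_high,fold_change_min Filter thresholds
#'   (fpkm, fpkm, linear fold).
#' @param low_frac Fraction of used time points required at
#'   `min_abund_low` (default 0.5).
#' @return Tibble with one row per gene.
#' @export
#' @examples
#' expr <- tibble::tibble(gene = "a", `0` = 10, `1` = 20, `2` = 10)
#' gene_stats(expr)
gene_stats <- function(expr, used_times = NULL, pseudocount = 1,
                       log_base = 2, min_abund_low = 2, min_abund_high = 10,
                       low_frac = 0.5, fold_change_min = 2) {
  validate_expression(expr)
  tt <- expression_times(expr)
  used_times <- if (is.null(used_times)) tt else as.numeric(used_times)
  used_all <- sort(union(0, used_times))
  fc <- fold_changes(expr, used_times, pseudocount, log_base)
  lfc_cut <- log(fold_change_min, base = log_base)

  peak <- fc |>
    group_by(.data$gene) |>
    arrange(.data$time, .by_group = TRUE) |>
    summarise(
      max_abs_lfc = max(.data$abs_lfc),
      # ties broken toward the earliest time point
      peak_time = .data$time[which.max(.data$abs_lfc)],
      .groups = "drop"
    )

  cols <- setdiff(names(expr), "gene")
  t_of <- setNames(expression_times(expr), cols)
  use_cols <- cols[t_of %in% used_all]
  vals <- as.matrix(expr[use_cols])
  abund <- tibble::tibble(
    gene = expr$gene,
    mean_abund = rowMeans(vals),
    n_low = rowSums(vals >= min_abund_low),
    n_high = rowSums(vals >= min_abund_high)
  )

  n_used <- length(used_all)
  abund |>
    left_join(peak, by = "gene") |>
    mutate(
      max_abs_lfc = dplyr::coalesce(.data$max_abs_lfc, 0),
      pass_min2 = .data$n_low >= low_frac * n_used,
      pass_min10 = .data$n_high >= 2,
      pass_fc = .data$max_abs_lfc > lfc_cut,
      passes_filters = .data$pass_min2 & .data$pass_min10 & .data$pass_fc
    ) |>
    select("gene", "max_abs_lfc", "peak_time", "mean_abund",
           "pass_min2", "pass_min10", "pass_fc", "passes_filters")
}

#' Keep genes passing all expression filters
#'
#' @param stats Output of [gene_stats()].
#' @return The rows of `stats` with `passes_filters` TRUE.
#' @export
filter_genes <- function(stats) {
  filter(stats, .data$passes_filters)
}

#' Assign filtered genes to stages
#'
#' Each gene passing the filters is assigned to the stage window containing
#' the time of its highest absolute fold change (`peak_time`; ties were
#' already broken toward the earliest time). Genes not passing the filters
#' get `NA`.
#'
#' @param stats Output of [gene_stats()].
#' @param windows Output of [stage_windows()].
#' @return `stats` with a `stage` factor column (levels T1, T2, T3).
#' @export
assign_stages <- function(stats, windows = stage_windows()) {
  lookup <- unlist(lapply(names(windows), function(nm) {
    setNames(rep(nm, length(windows[[nm]])), windows[[nm]])
  }))
  stage <- unname(lookup[as.character(stats$peak_time)])
  bad <- stats$passes_filters & is.na(stage) & !is.na(stats$peak_time)
  if (any(bad)) {
    abort_input(paste0(
      "peak time of filtered gene(s) lies in no stage window: ",
      paste(head(stats$gene[bad], 5), collapse = ", ")
    ))
  }
  stats |>
    mutate(stage = factor(ifelse(.data$passes_filters, stage, NA),
                          levels = names(windows)))
}

#' Filter and stage a time-course expression matrix
#'
#' Convenience wrapper: [gene_stats()], then [filter_genes()], then
#' [assign_stages()].
#'
#' @inheritParams gene_stats
#' @inheritParams assign_stages
#' @return Tibble of staged genes: `gene`, `stage`, `max_abs_lfc`,
#'   `peak_time`, `mean_abund`.
#' @export
stage_genes <- function(expr, used_times = NULL, windows = stage_windows(),
                        pseudocount = 1, log_base = 2, ...) {
  gene_stats(expr, used_times = used_times, pseudocount = pseudocount,
             log_base = log_base, ...) |>
    filter_genes() |>
    assign_stages(windows) |>
    select("gene", "stage", "max_abs_lfc", "peak_time", "mean_abund")
}

#' Stage counts
#'
#' @param staging Output of [stage_genes()].
#' @return Named integer vector of counts for T1, T2, T3.
#' @export
stage_counts <- function(staging) {
  out <- table(factor(staging$stage, levels = c("T1", "T2", "T3")))
  setNames(as.integer(out), names(out))
}
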