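#' Resolve linear counts at circle boundaries
#'
#' A circle's linearly spliced counterpart is quantified from the linear
#' splice counts observed at its two host boundaries (the `start` and `end`
#' coordinates). The default rule takes the maximum of the two boundary
#' counts — the conservative choice, giving the smallest circular-to-linear
#' ratio; `mean` and `min` are available. Boundaries with no entry in the
#' linear table contribute 0.
#'
#' @param junctions Junction tibble (`junction_id`, `chrom`, `start`, `end`).
#' @param linear Boundary-count tibble (`sample_id`, `chrom`, `pos`,
#'   `count`), e.g. from [read_linear_table()].
#' @param rule One of `"max"`, `"mean"`, `"min"`.
#' @param sample_ids Samples to resolve; defaults to those present in
#'   `linear`.
#' @return Long tibble `junction_id`, `sample_id`, `count` covering every
#'   junction x sample pair.
#' @export
resolve_linear_counts <- function(junctions, linear,
                                  rule = c("max", "mean", "min"),
                                  sample_ids = NULL) {
  rule <- match.arg(rule)
  jx <- junctions |> distinct(.data$junction_id, .data$chrom, .data$start, .data$end)
  if (is.null(sample_ids)) sample_ids <- unique(linear$sample_id)
  grid <- tidyr::expand_grid(jx, sample_id = sample_ids)
  lookup <- function(grid, pos_col, out) {
    grid |>
      left_join(linear |> rename(!!out := "count"),
                by = c(sample_id = "sample_id", chrom = "chrom",
                       setNames("pos", pos_col)))
  }
  grid |>
    lookup("start", "left_count") |>
    lookup("end", "right_count") |>
    mutate(
      left_count = tidyr::replace_na(.data$left_count, 0),
      right_count = tidyr::replace_na(.data$right_count, 0),
      count = switch(rule,
        max = pmax(.data$left_count, .data$right_count),
        min = pmin(.data$left_count, .data$right_count),
        mean = (.data$left_count + .data$right_count) / 2)
    ) |>
    select("junction_id", "sample_id", "count")
}

#' Counts per million
#'
#' Adds a `cpm` column: `count / library_size * 1e6`. The denominator is the
#' externally supplied total mapped read count from the sample table, not
#' the within-matrix column sum.
#'
#' @param counts Long tibble with `sample_id` and `count` columns.
#' @param samples Sample tibble with `sample_id` and `library_size`.
#' @return `counts` with a `cpm` column appended.
#' @export
cpm <- function(counts, samples) {
  if (any(samples$library_size <= 0)) abort("library sizes must be positive")
  out <- counts |>
    left_join(samples |> select("sample_id", "library_size"), by = "sample_id")
  if (any(is.na(out$library_size))) {
    abort("counts contain sample_ids missing from the sample table")
  }
  out |>
    mutate(cpm = .data$count / .data$library_size * 1e6) |>
    select(-"library_size")
}

#' Circular-to-linear relative expression
#'
#' Entrywise `log2((CPM_circular + 1) / (CPM_linear + 1))`. The +1
#' pseudo-counts keep every entry finite; the statistic is antisymmetric in
#' its two arguments and zero where they agree.
#'
#' @param circ_cpm,lin_cpm Long tibbles with a shared feature id column, a
#'   `sample_id` column and a `cpm` column, aligned on the same features and
#'   samples.
#' @return Long tibble with the id columns, `sample_id` and `rel_expr`.
#' @export
relative_expression <- function(circ_cpm, lin_cpm) {
  keys <- setdiff(intersect(names(circ_cpm), names(lin_cpm)),
                  c("cpm", "count"))
  if (!"sample_id" %in% keys) abort("both matrices need a sample_id column")
  joined <- inner_join(circ_cpm |> select(all_of(keys), circ = "cpm"),
                       lin_cpm |> select(all_of(keys), lin = "cpm"),
                       by = keys)
  if (nrow(joined) != nrow(circ_cpm) || nrow(joined) != nrow(lin_cpm)) {
    abort("circular and linear matrices are not aligned (shape mismatch)")
  }
  joined |>
    mutate(rel_expr = log2((.data$circ + 1) / (.data$lin + 1))) |>
    select(-"circ", -"lin")
}

#' Quantify relative expression for a cohort
#'
#' Convenience pipeline: completes the circular count grid (absent
#' junction/sample pairs count 0), resolves linear boundary counts,
#' normalizes both to CPM and returns the relative-expression table.
#'
#' @param junctions Junction tibble (`junction_id`, `chrom`, `start`, `end`).
#' @param circ_counts Long circular counts (`junction_id`, `sample_id`,
#'   `count`); missing pairs are treated as 0.
#' @param linear Boundary-count tibble (see [resolve_linear_counts()]).
#' @param samples Sample tibble with library sizes.
#' @param rule Linear-count resolution rule.
#' @return Long tibble `junction_id`, `sample_id`, `rel_expr`.
#' @export
quantify_relative_expression <- function(junctions, circ_counts, linear,
                                         samples, rule = "max") {
  full_circ <- circ_counts |>
    complete(junction_id = unique(junctions$junction_id),
             sample_id = samples$sample_id,
             fill = list(count = 0)) |>
    filter(.data$junction_id %in% junctions$junction_id)
  lin <- resolve_linear_counts(junctions, linear, rule = rule,
                               sample_ids = samples$sample_id)
  relative_expression(cpm(full_circ, samples), cpm(lin, samples))
}
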