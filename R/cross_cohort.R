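#' Unify coordinate conventions across cohorts
#'
#' Published circRNA lists disagree on whether the start coordinate is
#' 0-based or 1-based; `one_based` inputs have their starts decremented by 1
#' to reach the package convention. An optional coordinate `mapper` (e.g. a
#' genome-build liftover hook) is then applied to every interval; the
#' default is the identity. A mapper is a function taking and returning the
#' interval tibble, marking unmappable rows with `NA` in `chrom` — those are
#' dropped and counted in the `n_dropped` attribute.
#'
#' @param junctions Interval tibble (`chrom`, `start`, `end`, ...).
#' @param start_convention `"zero_based"` or `"one_based"`.
#' @param mapper Optional coordinate-mapping function.
#' @return The unified tibble, with attribute `n_dropped`.
#' @export
unify_coordinates <- function(junctions,
                              start_convention = c("zero_based", "one_based"),
                              mapper = NULL) {
  if (length(start_convention) == 1 &&
      !start_convention %in% c("zero_based", "one_based")) {
    abort(paste0("unknown start convention '", start_convention,
                 "' (configuration error)"))
  }
  start_convention <- match.arg(start_convention)
  out <- junctions
  if (start_convention == "one_based") out$start <- out$start - 1L
  n_dropped <- 0L
  if (!is.null(mapper)) {
    out <- mapper(out)
    drop <- is.na(out$chrom)
    n_dropped <- sum(drop)
    out <- out[!drop, ]
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Match circRNA junctions between two cohorts
#'
#' Matches unified junction sets on identical `(chrom, start, end)` keys
#' within `tolerance` bases per coordinate (exact key join at tolerance 0);
#' each query junction matches at most one reference entry. Strand is not
#' compared (published lists often omit or disagree on it). Recall
#' percentages are rounded to the nearest integer.
#'
#' @param query,reference Interval tibbles, both already unified.
#' @param tolerance Maximum absolute coordinate difference (>= 0).
#' @return One-row tibble `n_query`, `n_reference`, `n_matched`,
#'   `recall_vs_reference`, `recall_vs_query` (percent).
#' @export
match_junctions <- function(query, reference, tolerance = 0) {
  if (tolerance < 0) abort("tolerance must be >= 0")
  q <- query |> distinct(.data$chrom, .data$start, .data$end)
  r <- reference |> distinct(.data$chrom, .data$start, .data$end)
  if (tolerance == 0) {
    n_matched <- nrow(dplyr::semi_join(q, r, by = c("chrom", "start", "end")))
  } else {
    used <- rep(FALSE, nrow(r))
    n_matched <- 0L
    for (i in seq_len(nrow(q))) {
      cand <- which(!used & r$chrom == q$chrom[i] &
                      abs(r$start - q$start[i]) <= tolerance &
                      abs(r$end - q$end[i]) <= tolerance)
      if (length(cand) > 0) {
        used[cand[1]] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
  }
  tibble(
    n_query = nrow(q), n_reference = nrow(r), n_matched = n_matched,
    recall_vs_reference = round(100 * n_matched / nrow(r)),
    recall_vs_query = round(100 * n_matched / nrow(q))
  )
}

#' Grade-wise relative detection frequency
#'
#' For each junction detected in at least `min_samples` samples, computes
#' per grade grouping `freq(c, g) = (n_cg / N_c) / (N_g / N)`: the share of
#' the junction's carriers that fall in group `g`, normalized by the group's
#' share of the cohort. A junction present in every sample scores 1 in every
#' group, and the frequencies of a junction average to 1 when weighted by
#' group prevalence.
#'
#' @param occurrence Tibble `junction_id`, `sample_id`: the samples in which
#'   each junction was detected (post-filter).
#' @param samples Sample tibble with a `grade` column.
#' @param grouping Named character vector mapping grades to group labels
#'   (default: G1/G2 low, G3 high).
#' @param min_samples Minimum number of carrier samples.
#' @return Long tibble `junction_id`, `group`, `freq`.
#' @export
relative_frequency <- function(occurrence, samples,
                               grouping = c(G1 = "low", G2 = "low", G3 = "high"),
                               min_samples = 3) {
  if (!all(unique(samples$grade) %in% names(grouping))) {
    abort("grouping must cover all grades in the sample table")
  }
  unknown <- setdiff(unique(occurrence$sample_id), samples$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("occurrence references unknown sample_id: ", unknown[1]))
  }
  smp <- samples |> mutate(group = unname(grouping[.data$grade]))
  group_sizes <- smp |> count(.data$group, name = "n_group")
  if (any(group_sizes$n_group == 0) ||
      length(setdiff(unique(unname(grouping)), group_sizes$group)) > 0) {
    abort("empty grade group")
  }
  n_total <- nrow(smp)
  occ <- occurrence |> distinct(.data$junction_id, .data$sample_id) |>
    left_join(smp |> select("sample_id", "group"), by = "sample_id")
  carriers <- occ |> count(.data$junction_id, name = "n_carriers") |>
    filter(.data$n_carriers >= min_samples)
  occ |>
    filter(.data$junction_id %in% carriers$junction_id) |>
    count(.data$junction_id, .data$group, name = "n_cg") |>
    complete(junction_id = carriers$junction_id,
             group = group_sizes$group, fill = list(n_cg = 0L)) |>
    left_join(carriers, by = "junction_id") |>
    left_join(group_sizes, by = "group") |>
    mutate(freq = (.data$n_cg / .data$n_carriers) /
             (.data$n_group / n_total)) |>
    select("junction_id", "group", "freq") |>
    arrange(.data$junction_id, .data$group)
}

#' Correlate grade-wise frequencies between cohorts
#'
#' Pearson correlation of the per-junction relative frequencies of the
#' junctions shared by two cohorts. By default only the high-grade
#' frequencies are correlated (the grade-specific tendency); with
#' `stacked = TRUE` the high and low pairs are stacked.
#'
#' @param freq_a,freq_b Frequency tibbles from [relative_frequency()].
#' @param group Group label to correlate on.
#' @param stacked Stack all groups' pairs instead.
#' @return One-row tibble `r`, `p_value`, `n` (junction pairs used).
#' @export
correlate_cohort_frequencies <- function(freq_a, freq_b, group = "high",
                                         stacked = FALSE) {
  keys <- if (stacked) c("junction_id", "group") else "junction_id"
  a <- if (stacked) freq_a else freq_a |> filter(.data$group == !!group)
  b <- if (stacked) freq_b else freq_b |> filter(.data$group == !!group)
  joined <- inner_join(a |> select(all_of(keys), fa = "freq"),
                       b |> select(all_of(keys), fb = "freq"), by = keys)
  if (dplyr::n_distinct(joined$junction_id) < 3) {
    abort("fewer than 3 shared junctions after filtering")
  }
  pearson_cor(joined$fa, joined$fb)
}

#' Per-sample detection table
#'
#' Converts long circular counts into the occurrence table used for
#' grade-wise frequency analysis: a junction is detected in a sample if
#' supported by at least `min_reads` back-spliced reads there.
#'
#' @param counts Long tibble `junction_id`, `sample_id`, `count`.
#' @param min_reads Per-sample detection threshold.
#' @return Tibble `junction_id`, `sample_id` of detections.
#' @export
occurrence_table <- function(counts, min_reads = 4) {
  counts |> filter(.data$count >= min_reads) |>
    distinct(.data$junction_id, .data$sample_id)
}
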