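#' Filter miRNA target sites to conserved seed-match lengths
#'
#' Retains sites of length 7 or 8 bp — the canonical conserved seed-match
#' site lengths — and drops everything else. Idempotent. The retention
#' fraction is attached as attribute `retention_pct` and summarized by
#' [site_filter_summary()].
#'
#' @param sites Site tibble with `start`/`end` (and optionally a
#'   precomputed `site_length`).
#' @return The filtered tibble with a `site_length` column.
#' @export
filter_sites <- function(sites) {
  x <- sites |> mutate(site_length = .data$end - .data$start)
  out <- x |> filter(.data$site_length %in% c(7L, 8L))
  attr(out, "retention_pct") <-
    if (nrow(x) == 0) NA_real_ else round(100 * nrow(out) / nrow(x), 2)
  out
}

#' @rdname filter_sites
#' @return For `site_filter_summary()`: a one-row tibble `n_total`,
#'   `n_retained`, `n_long`, `n_short`, `retention_pct` (two decimals).
#' @export
site_filter_summary <- function(sites) {
  x <- sites |> mutate(site_length = .data$end - .data$start)
  kept <- sum(x$site_length %in% c(7L, 8L))
  tibble(
    n_total = nrow(x), n_retained = kept,
    n_long = sum(x$site_length > 8L), n_short = sum(x$site_length < 7L),
    retention_pct = round(100 * kept / nrow(x), 2)
  )
}

#' Overlap miRNA sites with circRNA intervals
#'
#' Emits a (circle, site) pair iff the site interval is fully contained in
#' the circle interval on the same chromosome — a sponge site must lie
#' entirely on the circle. Strand is ignored by default (coordinate-level
#' matching); `stranded = TRUE` additionally requires equal strands. Each
#' pair appears at most once. If an annotation is supplied, sites that do
#' not fall inside any exon are flagged `intron_located` (they still count:
#' matching is purely genomic).
#'
#' @param junctions Junction tibble (`junction_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param sites Site tibble (`chrom`, `start`, `end`, `mirna_family`, ...).
#' @param stranded Require matching strands (needs `strand` in `sites`).
#' @param annotation Optional `circ_annotation` for the intron flag.
#' @return Tibble with one row per (circle, site) pair: junction columns
#'   plus `site_start`, `site_end`, `mirna_family`, `site_length` and
#'   optionally `intron_located`.
#' @export
overlap_sites <- function(junctions, sites, stranded = FALSE,
                          annotation = NULL) {
  jx <- junctions |>
    distinct(.data$junction_id, .data$chrom, .data$start, .data$end,
             .data$strand)
  st <- sites |> distinct() |>
    mutate(site_length = .data$end - .data$start)
  if (nrow(jx) == 0 || nrow(st) == 0) {
    return(tibble(junction_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  site_start = integer(), site_end = integer(),
                  mirna_family = character(), site_length = integer()))
  }
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(st), as_granges(jx),
                                type = "within"))
  out <- dplyr::bind_cols(
    jx[S4Vectors::subjectHits(hits), ],
    st[S4Vectors::queryHits(hits), ] |>
      select(site_start = "start", site_end = "end", "mirna_family",
             "site_length", site_strand = dplyr::any_of("strand"))
  )
  if (stranded) {
    if (!"site_strand" %in% names(out)) abort("stranded matching needs site strands")
    out <- out |> filter(.data$strand == .data$site_strand)
  }
  out <- out |> select(-dplyr::any_of("site_strand")) |> distinct()
  if (!is.null(annotation)) {
    in_exon <- suppressWarnings(IRanges::overlapsAny(
      as_granges(out |> select("chrom", start = "site_start", end = "site_end")),
      as_granges(annotation$exons), type = "within"))
    out$intron_located <- !in_exon
  }
  out |> arrange(.data$junction_id, .data$site_start, .data$mirna_family)
}

#' Summarize potential miRNA sponges
#'
#' Aggregates (circle, site) pairs into: total counts of distinct circles,
#' host genes and miRNA families with at least one site; a recurrence
#' ranking of families by the number of distinct circles carrying them
#' (descending, ties broken alphabetically); and flags for host genes that
#' are differentially expressed at both the circRNA and the mRNA level.
#'
#' @param pairs Pair tibble from [overlap_sites()], carrying a `host_gene`
#'   column (join it from the classified junctions).
#' @param de_circles Character vector of DE circle `junction_id`s.
#' @param genes_de Character vector of gene-level DE gene ids.
#' @return Named list `totals` (one-row tibble), `recurrence` (tibble
#'   `mirna_family`, `n_circles`), `host_flags` (tibble `host_gene`,
#'   `de_both`).
#' @export
summarize_sponges <- function(pairs, de_circles = character(),
                              genes_de = character()) {
  if (!"host_gene" %in% names(pairs)) {
    pairs$host_gene <- NA_character_
  }
  totals <- tibble(
    n_circles = dplyr::n_distinct(pairs$junction_id),
    n_host_genes = dplyr::n_distinct(pairs$host_gene[!is.na(pairs$host_gene)]),
    n_mirna_families = dplyr::n_distinct(pairs$mirna_family)
  )
  recurrence <- pairs |>
    distinct(.data$mirna_family, .data$junction_id) |>
    count(.data$mirna_family, name = "n_circles") |>
    arrange(desc(.data$n_circles), .data$mirna_family)
  de_hosts <- pairs |>
    filter(.data$junction_id %in% de_circles, !is.na(.data$host_gene)) |>
    pull("host_gene")
  host_flags <- pairs |>
    filter(!is.na(.data$host_gene)) |>
    distinct(.data$host_gene) |>
    mutate(de_both = .data$host_gene %in% de_hosts &
             .data$host_gene %in% genes_de)
  list(totals = totals, recurrence = recurrence, host_flags = host_flags)
}
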