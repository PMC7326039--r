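#' Call back-splice junctions from chimeric records
#'
#' A chimeric record supports a back-splice if and only if both segments lie
#' on the same chromosome and strand and the acceptor lies upstream of the
#' donor in transcription orientation (head-to-tail): on `+`,
#' `pos_donor > pos_acceptor`; on `-`, `pos_donor < pos_acceptor`. The circle
#' interval spans from the acceptor site to the donor site (half-open);
#' records spanning more than `max_span` bases, trans-chromosomal records,
#' strand-discordant records and canonical linear-orientation records are
#' skipped (their count is recorded). Duplicate `read_id`s within a sample
#' count once (PCR-duplicate robustness).
#'
#' @param records Chimeric record tibble (see [read_chimeric_table()]).
#' @param max_span Maximum circle span in bases.
#' @param dedup_reads Collapse duplicate (sample, read) pairs before calling.
#' @return Long tibble `junction_id`, `chrom`, `start`, `end`, `strand`,
#'   `sample_id`, `count`, sorted by coordinate, with attribute `n_skipped`
#'   (records not contributing to any junction). The sum of all counts plus
#'   `n_skipped` equals `nrow(records)`.
#' @export
call_backsplices <- function(records, max_span = 1e6, dedup_reads = TRUE) {
  if (max_span <= 0) abort("max_span must be > 0")
  n_in <- nrow(records)
  x <- records
  if (dedup_reads) {
    # a PCR duplicate re-reports the identical record, so deduplication on
    # the full record is order-independent
    x <- x |> distinct(.data$sample_id, .data$read_id, .data$chrom_donor,
                       .data$pos_donor, .data$strand_donor,
                       .data$chrom_acceptor, .data$pos_acceptor,
                       .data$strand_acceptor, .keep_all = TRUE)
  }
  x <- x |>
    filter(.data$chrom_donor == .data$chrom_acceptor,
           .data$strand_donor == .data$strand_acceptor,
           .data$strand_donor %in% c("+", "-"),
           ifelse(.data$strand_donor == "+",
                  .data$pos_donor > .data$pos_acceptor,
                  .data$pos_donor < .data$pos_acceptor)) |>
    mutate(chrom = .data$chrom_donor,
           strand = .data$strand_donor,
           start = pmin(.data$pos_donor, .data$pos_acceptor),
           end = pmax(.data$pos_donor, .data$pos_acceptor)) |>
    filter(.data$end - .data$start <= max_span)
  out <- x |>
    count(.data$chrom, .data$start, .data$end, .data$strand, .data$sample_id,
          name = "count") |>
    mutate(junction_id = junction_key(.data$chrom, .data$start, .data$end,
                                      .data$strand)) |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand, .data$sample_id) |>
    select("junction_id", "chrom", "start", "end", "strand", "sample_id", "count")
  n_skipped <- n_in - sum(out$count)
  if (n_skipped > 0) {
    inform(paste0(n_skipped, " of ", n_in,
                  " chimeric records did not support a back-splice (skipped)"))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Filter junctions on read support
#'
#' Retains a junction iff at least `min_samples` samples support it with at
#' least `min_reads` back-spliced reads (default: >= 4 reads in >= 1 sample,
#' the high-confidence threshold). Row order is preserved.
#'
#' @param junctions Long junction-count tibble from [call_backsplices()].
#' @param min_reads Minimum supporting reads in a sample (>= 1).
#' @param min_samples Minimum number of samples reaching `min_reads`.
#' @return The filtered long tibble.
#' @export
filter_junctions <- function(junctions, min_reads = 4, min_samples = 1) {
  if (min_reads < 1) abort("min_reads must be >= 1 (configuration error)")
  keep <- junctions |>
    group_by(.data$junction_id) |>
    summarise(ok = sum(.data$count >= min_reads) >= min_samples,
              .groups = "drop") |>
    filter(.data$ok) |>
    pull("junction_id")
  junctions |> filter(.data$junction_id %in% keep)
}

#' Classify the genomic context of junctions
#'
#' Each junction side (the `start` base and the `end - 1` base) is labeled
#' `exonic` if it falls inside any exon, else `intronic` if inside a gene
#' body, else `intergenic`. The junction-level `context` is `exonic` iff
#' both sides are exonic, `intergenic` iff both are intergenic, otherwise
#' `intronic`; the side pair is retained as `context_pair`. `host_gene` is
#' assigned when both sides fall inside the same gene body.
#'
#' @param junctions Tibble with `junction_id`, `chrom`, `start`, `end`
#'   (duplicated junction_ids are collapsed).
#' @param annotation A `circ_annotation`.
#' @return One row per junction with `context_start`, `context_end`,
#'   `context_pair`, `context`, `host_gene` columns added.
#' @export
classify_context <- function(junctions, annotation) {
  jx <- junctions |>
    distinct(across(dplyr::any_of(c("junction_id", "chrom", "start", "end",
                                    "strand"))))
  side_class <- function(pos) {
    pts <- points_as_granges(jx$chrom, pos)
    ex <- as_granges(annotation$exons)
    gn <- as_granges(annotation$genes)
    in_exon <- IRanges::overlapsAny(pts, ex)
    hit_gene <- GenomicRanges::findOverlaps(pts, gn, select = "first")
    list(label = ifelse(in_exon, "exonic",
                        ifelse(!is.na(hit_gene), "intronic", "intergenic")),
         gene = ifelse(is.na(hit_gene), NA_character_,
                       annotation$genes$gene_id[hit_gene]))
  }
  left <- side_class(jx$start)
  right <- side_class(jx$end - 1L)
  jx |>
    mutate(
      context_start = left$label,
      context_end = right$label,
      context_pair = paste0(left$label, ":", right$label),
      context = ifelse(left$label == "exonic" & right$label == "exonic", "exonic",
                ifelse(left$label == "intergenic" & right$label == "intergenic",
                       "intergenic", "intronic")),
      host_gene = ifelse(!is.na(left$gene) & !is.na(right$gene) &
                           left$gene == right$gene, left$gene, NA_character_)
    )
}

#' Positional bias of exonic circRNAs within the mRNA body
#'
#' For each mature-mRNA region class (CDS, 5'UTR, 3'UTR), computes the
#' fraction of exonic circRNAs whose interval overlaps at least 1 bp of that
#' class. Classes are not mutually exclusive: a circle spanning a UTR/CDS
#' boundary counts in both, so fractions need not sum to 1.
#'
#' @param junctions Tibble of exonic junctions (`junction_id`, `chrom`,
#'   `start`, `end`); must be non-empty.
#' @param annotation A `circ_annotation`.
#' @return Tibble `region` (CDS/UTR5/UTR3), `n_overlapping`, `fraction`.
#' @export
positional_bias <- function(junctions, annotation) {
  jx <- junctions |> distinct(.data$junction_id, .data$chrom, .data$start, .data$end)
  if (nrow(jx) == 0) abort("no exonic junctions: fractions undefined")
  gr <- as_granges(jx)
  frac <- function(tab) {
    if (nrow(tab) == 0) return(0L)
    sum(IRanges::overlapsAny(gr, as_granges(tab)))
  }
  n <- c(CDS = frac(annotation$cds), UTR5 = frac(annotation$utr5),
         UTR3 = frac(annotation$utr3))
  tibble(region = names(n), n_overlapping = as.integer(n),
         fraction = as.numeric(n) / nrow(jx))
}

#' Candidates-per-host-gene summary
#'
#' Counts distinct junctions and distinct host genes (junctions without a
#' host are excluded from the gene count) and their ratio.
#'
#' @param junctions Tibble with `junction_id` and `host_gene`.
#' @return Tibble `n_junctions`, `n_host_genes`, `junctions_per_gene`.
#' @export
host_summary <- function(junctions) {
  jx <- junctions |> distinct(.data$junction_id, .data$host_gene)
  hosts <- unique(jx$host_gene[!is.na(jx$host_gene)])
  tibble(n_junctions = nrow(jx), n_host_genes = length(hosts),
         junctions_per_gene = round(nrow(jx) / length(hosts), 2))
}
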