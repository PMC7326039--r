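#' Annotation database
#'
#' Bundles gene models for context classification and positional-bias
#' analysis: gene bodies, exons, and the CDS / 5'UTR / 3'UTR partition of the
#' exonic space. All tables use the package-wide 0-based half-open
#' convention. Invariants enforced: every feature interval lies inside its
#' gene's interval, and the CDS and UTR regions of a gene do not overlap
#' each other.
#'
#' @param genes Tibble `gene_id`, `gene_name`, `chrom`, `start`, `end`, `strand`.
#' @param exons,cds,utr5,utr3 Tibbles `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @return An object of class `circ_annotation`.
#' @export
annotation_db <- function(genes, exons, cds, utr5, utr3) {
  genes <- as_tibble(genes); validate_intervals(genes, require_strand = TRUE)
  if (anyDuplicated(genes$gene_id)) abort("gene_ids must be unique")
  parts <- list(exons = as_tibble(exons), cds = as_tibble(cds),
                utr5 = as_tibble(utr5), utr3 = as_tibble(utr3))
  span <- genes |> select("gene_id", g_start = "start", g_end = "end")
  for (nm in names(parts)) {
    p <- parts[[nm]]
    if (nrow(p) == 0) next
    validate_intervals(p)
    chk <- p |> left_join(span, by = "gene_id")
    if (any(is.na(chk$g_start))) abort(paste0(nm, " references unknown gene_id"))
    if (any(chk$start < chk$g_start | chk$end > chk$g_end)) {
      abort(paste0(nm, " interval falls outside its gene interval"))
    }
  }
  regions <- bind_rows(cds = parts$cds, utr5 = parts$utr5, utr3 = parts$utr3,
                       .id = "region")
  if (nrow(regions) > 1) {
    by_gene <- split(regions, regions$gene_id)
    for (g in by_gene) {
      g <- g[order(g$start), ]
      if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)] &
                             g$chrom[-1] == g$chrom[-nrow(g)])) {
        abort(paste0("CDS/UTR regions overlap within gene ", g$gene_id[1]))
      }
    }
  }
  structure(c(list(genes = genes), parts), class = "circ_annotation")
}

#' @export
print.circ_annotation <- function(x, ...) {
  cat("<circ_annotation> ", nrow(x$genes), " genes, ", nrow(x$exons),
      " exons on ", length(unique(x$genes$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Read and write GTF-lite annotation
#'
#' GTF-lite is a tab-separated file with columns `chrom`, `source`,
#' `feature` (one of gene, exon, CDS, five_prime_utr, three_prime_utr),
#' `start` (1-based), `end` (inclusive), `strand`, `gene_id`, `gene_name`.
#' Coordinates are converted to 0-based half-open on read (start - 1).
#'
#' @param path Path to the GTF-lite file.
#' @return A [annotation_db()] object.
#' @export
read_gtf_lite <- function(path) {
  x <- readr::read_tsv(path,
    col_names = c("chrom", "source", "feature", "start", "end", "strand",
                  "gene_id", "gene_name"),
    col_types = "ccciiccc", progress = FALSE)
  known <- c("gene", "exon", "CDS", "five_prime_utr", "three_prime_utr")
  bad <- which(!x$feature %in% known)
  if (length(bad) > 0) {
    abort(paste0("unknown feature '", x$feature[bad[1]], "' at line ", bad[1],
                 " of ", path))
  }
  x <- x |> mutate(start = .data$start - 1L)
  pick <- function(f) {
    x |> filter(.data$feature == f) |>
      select("gene_id", "gene_name", "chrom", "start", "end", "strand")
  }
  genes <- pick("gene")
  annotation_db(
    genes = genes,
    exons = pick("exon") |> select(-"gene_name"),
    cds = pick("CDS") |> select(-"gene_name"),
    utr5 = pick("five_prime_utr") |> select(-"gene_name"),
    utr3 = pick("three_prime_utr") |> select(-"gene_name")
  )
}

#' @rdname read_gtf_lite
#' @param annotation A `circ_annotation` object.
#' @export
write_gtf_lite <- function(annotation, path) {
  stopifnot(inherits(annotation, "circ_annotation"))
  nm <- annotation$genes |> select("gene_id", "gene_name")
  one <- function(tab, feature) {
    tab |> left_join(nm, by = "gene_id") |>
      mutate(source = "circgrade", feature = feature) |>
      select("chrom", "source", "feature", "start", "end", "strand",
             "gene_id", "gene_name")
  }
  out <- bind_rows(
    one(annotation$genes |> select(-"gene_name"), "gene"),
    one(annotation$exons, "exon"),
    one(annotation$cds, "CDS"),
    one(annotation$utr5, "five_prime_utr"),
    one(annotation$utr3, "three_prime_utr")
  ) |> mutate(start = .data$start + 1L)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
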