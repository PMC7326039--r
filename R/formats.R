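#' Read a chimeric junction table
#'
#' Parses the simplified chimeric-record TSV emitted by a split-read aligner
#' stand-in: one row per supporting read, with the donor side (3' end of the
#' upstream-aligned segment) and acceptor side (5' end of the downstream
#' segment) of a candidate non-linear alignment. Positions are 1-based in the
#' file and shifted to the package's 0-based convention on read.
#'
#' @param path Path to a TSV with header columns `sample_id`, `chrom_donor`,
#'   `pos_donor`, `strand_donor`, `chrom_acceptor`, `pos_acceptor`,
#'   `strand_acceptor`, `read_id`.
#' @return A tibble of chimeric records with 0-based positions; row count is
#'   preserved.
#' @export
read_chimeric_table <- function(path) {
  cols <- c("sample_id", "chrom_donor", "pos_donor", "strand_donor",
            "chrom_acceptor", "pos_acceptor", "strand_acceptor", "read_id")
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!identical(names(x), cols)) {
    abort(paste0("chimeric table must have columns: ", paste(cols, collapse = ", ")))
  }
  for (pc in c("pos_donor", "pos_acceptor")) {
    bad <- which(!grepl("^[0-9]+$", x[[pc]]))
    if (length(bad) > 0) {
      abort(paste0("malformed ", pc, " at line ", bad[1] + 1L,
                   " of ", path, ": '", x[[pc]][bad[1]], "' is not a position"))
    }
  }
  for (sc in c("strand_donor", "strand_acceptor")) {
    bad <- which(!x[[sc]] %in% c("+", "-"))
    if (length(bad) > 0) {
      abort(paste0("unknown strand symbol '", x[[sc]][bad[1]], "' at line ",
                   bad[1] + 1L, " of ", path))
    }
  }
  x |>
    mutate(
      pos_donor = as.integer(.data$pos_donor) - 1L,
      pos_acceptor = as.integer(.data$pos_acceptor) - 1L
    )
}

#' @rdname read_chimeric_table
#' @param records A tibble of chimeric records (0-based positions).
#' @export
write_chimeric_table <- function(records, path) {
  records |>
    mutate(pos_donor = .data$pos_donor + 1L,
           pos_acceptor = .data$pos_acceptor + 1L) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Read and write BED intervals
#'
#' BED3/BED6 reader and writer. BED is already 0-based half-open, so
#' coordinates pass through unchanged; `write_bed(read_bed(f))` is
#' byte-identical to `f` for canonical (tab-separated, newline-terminated)
#' fixtures.
#'
#' @param path Path to a headerless BED3+ file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE,
                       col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (ncol(x) < 3) abort("BED requires at least 3 columns")
  names(x)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  if (ncol(x) > 3) names(x)[4:min(6, ncol(x))] <- extra[seq_len(min(3, ncol(x) - 3))]
  x <- x |> mutate(start = as.integer(.data$start), end = as.integer(.data$end))
  if ("score" %in% names(x)) x$score <- as.numeric(x$score)
  validate_intervals(x)
  x
}

#' @rdname read_bed
#' @param x Interval tibble as returned by [read_bed()].
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  out <- x[, keep]
  if ("score" %in% names(out)) {
    out$score <- ifelse(out$score == floor(out$score),
                        format(as.integer(out$score)), format(out$score))
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read pathway gene sets (GMT)
#'
#' @param path Tab-separated GMT file: set name, description, then member
#'   genes. Duplicate members within a set are dropped (first occurrence
#'   kept); set order follows the file.
#' @return A tibble with columns `name`, `description` and a list-column
#'   `genes` of unique member symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[lines != ""]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad) > 0) {
    abort(paste0("GMT line ", bad[1], " has fewer than 3 columns"))
  }
  tibble(
    name = map_chr(parts, 1),
    description = map_chr(parts, 2),
    genes = map(parts, function(p) {
      g <- unique(p[-(1:2)])
      g <- g[g != ""]
      if (length(g) == 0) abort("GMT set with empty member list")
      g
    })
  )
}

#' @rdname read_gmt
#' @param sets Tibble of gene sets as returned by [read_gmt()].
#' @export
write_gmt <- function(sets, path) {
  lines <- pmap(list(sets$name, sets$description, sets$genes),
                function(n, d, g) paste(c(n, d, g), collapse = "\t"))
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read and write the sample table
#'
#' @param path TSV with columns `sample_id`, `grade` (G1/G2/G3),
#'   `stage_class` (NMIBC/MIBC) and `library_size` (total mapped reads used
#'   as the CPM denominator).
#' @return A tibble, one row per sample.
#' @export
read_sample_table <- function(path) {
  x <- readr::read_tsv(path, col_types = "cccd", progress = FALSE)
  needed <- c("sample_id", "grade", "stage_class", "library_size")
  if (!identical(names(x), needed)) {
    abort(paste0("sample table must have columns: ", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(x$sample_id)) abort("sample_ids must be unique")
  if (any(!x$grade %in% c("G1", "G2", "G3"))) abort("grade must be G1, G2 or G3")
  if (any(!x$stage_class %in% c("NMIBC", "MIBC"))) abort("stage_class must be NMIBC or MIBC")
  if (any(x$library_size <= 0)) abort("library_size must be positive")
  x |> mutate(library_size = as.integer(.data$library_size))
}

#' @rdname read_sample_table
#' @param samples Sample tibble.
#' @export
write_sample_table <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read and write linear splice-boundary counts
#'
#' The linear table carries, per sample, the number of linearly spliced reads
#' observed at each annotated splice boundary. Positions are 1-based in the
#' file and 0-based in memory, matching the junction coordinates they are
#' later joined against.
#'
#' @param path TSV with columns `sample_id`, `chrom`, `pos`, `count`.
#' @return A tibble with 0-based `pos`.
#' @export
read_linear_table <- function(path) {
  x <- readr::read_tsv(path, col_types = "ccii", progress = FALSE)
  needed <- c("sample_id", "chrom", "pos", "count")
  if (!identical(names(x), needed)) {
    abort(paste0("linear table must have columns: ", paste(needed, collapse = ", ")))
  }
  if (any(x$count < 0)) abort("linear counts must be non-negative")
  x |> mutate(pos = .data$pos - 1L)
}

#' @rdname read_linear_table
#' @param linear Linear-count tibble (0-based `pos`).
#' @export
write_linear_table <- function(linear, path) {
  linear |> mutate(pos = .data$pos + 1L) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Read and write miRNA target-site tables
#'
#' TargetScan-style conserved-site table. Coordinates are 0-based half-open
#' both on disk and in memory.
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `mirna_family`,
#'   `gene_symbol`.
#' @return A tibble with an added `site_length` column (`end - start`).
#' @export
read_site_table <- function(path) {
  x <- readr::read_tsv(path, col_types = "ciicc", progress = FALSE)
  needed <- c("chrom", "start", "end", "mirna_family", "gene_symbol")
  if (!identical(names(x), needed)) {
    abort(paste0("site table must have columns: ", paste(needed, collapse = ", ")))
  }
  validate_intervals(x)
  x |> mutate(site_length = .data$end - .data$start)
}

#' @rdname read_site_table
#' @param sites Site tibble.
#' @export
write_site_table <- function(sites, path) {
  sites |>
    select(all_of(c("chrom", "start", "end", "mirna_family", "gene_symbol"))) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Read and write count matrices
#'
#' On disk a count matrix is a wide TSV (first column `feature_id`, one
#' column per sample); in memory it is a long tibble
#' (`feature_id`, `sample_id`, `count`), the shape the dplyr verbs operate on.
#'
#' @param path Path to the wide TSV.
#' @return Long count tibble.
#' @export
read_count_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (names(x)[1] != "feature_id") abort("first column must be feature_id")
  x |> pivot_longer(-"feature_id", names_to = "sample_id", values_to = "count")
}

#' @rdname read_count_matrix
#' @param counts Long count tibble (`feature_id`, `sample_id`, `count`).
#' @export
write_count_matrix <- function(counts, path) {
  counts |>
    pivot_wider(id_cols = "feature_id", names_from = "sample_id",
                values_from = "count") |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}
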