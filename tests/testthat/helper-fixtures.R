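suppressPackageStartupMessages(library(dplyr))

# small shared annotation: 40 genes on 2 chromosomes
fixture_annotation <- function(seed = 42) {
  generate_annotation(n_genes = 40, exons_per_gene_range = c(2, 6),
                      chrom_count = 2, seed = seed)
}

# hand-built two-gene annotation with known coordinates for context tests:
#   GA (+, chr1): exons [100,200) and [400,500); UTR5 [100,130), CDS
#   [130,200)+[400,470), UTR3 [470,500)
#   GB (-, chr2): single exon [1000,1300); UTR3 [1000,1045), CDS
#   [1045,1255), UTR5 [1255,1300)
toy_annotation <- function() {
  annotation_db(
    genes = tibble(
      gene_id = c("GA", "GB"), gene_name = c("ALPHA", "BETA"),
      chrom = c("chr1", "chr2"), start = c(100L, 1000L),
      end = c(500L, 1300L), strand = c("+", "-")),
    exons = tibble(
      gene_id = c("GA", "GA", "GB"), chrom = c("chr1", "chr1", "chr2"),
      start = c(100L, 400L, 1000L), end = c(200L, 500L, 1300L),
      strand = c("+", "+", "-"), exon_rank = c(1L, 2L, 1L)),
    cds = tibble(
      gene_id = c("GA", "GA", "GB"), chrom = c("chr1", "chr1", "chr2"),
      start = c(130L, 400L, 1045L), end = c(200L, 470L, 1255L),
      strand = c("+", "+", "-")),
    utr5 = tibble(gene_id = c("GA", "GB"), chrom = c("chr1", "chr2"),
                  start = c(100L, 1255L), end = c(130L, 1300L),
                  strand = c("+", "-")),
    utr3 = tibble(gene_id = c("GA", "GB"), chrom = c("chr1", "chr2"),
                  start = c(470L, 1000L), end = c(500L, 1300L) - c(0L, 255L),
                  strand = c("+", "-"))
  )
}

# one chimeric record row
chimeric_row <- function(sample_id = "s1", chrom_d = "chr1", pos_d = 500L,
                         strand_d = "+", chrom_a = chrom_d, pos_a = 100L,
                         strand_a = strand_d, read_id = "r1") {
  tibble(sample_id = sample_id, chrom_donor = chrom_d, pos_donor = pos_d,
         strand_donor = strand_d, chrom_acceptor = chrom_a,
         pos_acceptor = pos_a, strand_acceptor = strand_a, read_id = read_id)
}

# ---- independent brute-force oracles ---------------------------------------

# back-splice calling: row-by-row application of the head-to-tail rule,
# accumulating counts in an environment keyed by junction x sample
oracle_backsplices <- function(records, max_span = 1e6) {
  seen_reads <- character(0)
  counts <- list()
  skipped <- 0L
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    rk <- paste(r$sample_id, r$read_id, r$chrom_donor, r$pos_donor,
                r$strand_donor, r$chrom_acceptor, r$pos_acceptor,
                r$strand_acceptor)
    if (rk %in% seen_reads) { skipped <- skipped + 1L; next }
    seen_reads <- c(seen_reads, rk)
    ok <- r$chrom_donor == r$chrom_acceptor &&
      r$strand_donor == r$strand_acceptor &&
      ((r$strand_donor == "+" && r$pos_donor > r$pos_acceptor) ||
         (r$strand_donor == "-" && r$pos_donor < r$pos_acceptor))
    if (ok) {
      s <- min(r$pos_donor, r$pos_acceptor)
      e <- max(r$pos_donor, r$pos_acceptor)
      ok <- (e - s) <= max_span
    }
    if (!ok) { skipped <- skipped + 1L; next }
    key <- paste(r$chrom_donor, s, e, r$strand_donor, r$sample_id, sep = "|")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  list(counts = counts, skipped = skipped)
}

# random chimeric fixture mixing qualifying and non-qualifying records
random_chimeric <- function(n, seed) {
  withr::with_seed(seed, {
    pos1 <- sample(1:2000, n, replace = TRUE)
    pos2 <- sample(1:2000, n, replace = TRUE)
    tibble(
      sample_id = sample(c("s1", "s2", "s3"), n, replace = TRUE),
      chrom_donor = sample(c("chr1", "chr2"), n, replace = TRUE),
      pos_donor = pos1,
      strand_donor = sample(c("+", "-"), n, replace = TRUE),
      chrom_acceptor = sample(c("chr1", "chr2"), n, replace = TRUE),
      pos_acceptor = pos2,
      strand_acceptor = sample(c("+", "-"), n, replace = TRUE),
      read_id = paste0("r", sample(seq_len(ceiling(n * 0.9)), n, replace = TRUE))
    )
  })
}

# site containment: quadratic all-pairs scan
oracle_containment <- function(junctions, sites) {
  out <- list()
  for (i in seq_len(nrow(junctions))) {
    for (j in seq_len(nrow(sites))) {
      if (junctions$chrom[i] == sites$chrom[j] &&
          sites$start[j] >= junctions$start[i] &&
          sites$end[j] <= junctions$end[i]) {
        out[[length(out) + 1L]] <-
          paste(junctions$junction_id[i], sites$start[j], sites$end[j],
                sites$mirna_family[j], sep = "|")
      }
    }
  }
  as.character(sort(unique(unlist(out))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
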