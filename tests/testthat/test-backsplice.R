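test_that("head-to-tail orientation defines a back-splice", {
  # + strand, acceptor upstream of donor -> circle [100, 500)
  out <- call_backsplices(chimeric_row(pos_d = 500L, pos_a = 100L))
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 100L)
  expect_equal(out$end, 500L)
  expect_equal(out$strand, "+")
  expect_equal(out$count, 1L)

  # canonical linear splice orientation yields nothing
  expect_equal(nrow(suppressMessages(
    call_backsplices(chimeric_row(pos_d = 100L, pos_a = 500L)))), 0L)

  # trans-chromosomal chimeras are skipped
  expect_equal(nrow(suppressMessages(call_backsplices(
    chimeric_row(chrom_d = "chr1", chrom_a = "chr2", pos_d = 500L,
                 pos_a = 100L)))), 0L)

  # on the minus strand the orientation flips
  minus <- call_backsplices(chimeric_row(pos_d = 100L, pos_a = 500L,
                                         strand_d = "-", strand_a = "-"))
  expect_equal(minus$start, 100L)
  expect_equal(minus$end, 500L)
  expect_equal(minus$strand, "-")
  expect_equal(nrow(suppressMessages(call_backsplices(
    chimeric_row(pos_d = 500L, pos_a = 100L, strand_d = "-", strand_a = "-")))),
    0L)
})

test_that("identical junctions merge with per-sample counts and spans cap", {
  recs <- bind_rows(
    chimeric_row(read_id = "r1"), chimeric_row(read_id = "r2"),
    chimeric_row(sample_id = "s2", read_id = "r1"),
    chimeric_row(read_id = "r1")  # duplicate read in s1: counted once
  )
  out <- suppressMessages(call_backsplices(recs))
  expect_equal(out$count[out$sample_id == "s1"], 2L)
  expect_equal(out$count[out$sample_id == "s2"], 1L)
  expect_equal(attr(out, "n_skipped"), 1L)

  wide <- chimeric_row(pos_d = 5000L, pos_a = 100L)
  expect_equal(nrow(suppressMessages(call_backsplices(wide, max_span = 1000))), 0L)
  expect_error(call_backsplices(wide, max_span = 0), "max_span")
})

test_that("calling matches the brute-force oracle and conserves records", {
  for (s in 1:25) {
    recs <- random_chimeric(n = 60, seed = s)
    out <- suppressMessages(call_backsplices(recs))
    oracle <- oracle_backsplices(recs)
    got <- setNames(out$count,
                    paste(out$chrom, out$start, out$end, out$strand,
                          out$sample_id, sep = "|"))
    expect_equal(sort(names(got)), sort(names(oracle$counts)))
    expect_equal(got[sort(names(got))],
                 unlist(oracle$counts)[sort(names(got))])
    expect_equal(sum(out$count) + attr(out, "n_skipped"), nrow(recs))
    # permutation invariance
    perm <- suppressMessages(call_backsplices(recs[sample(nrow(recs)), ]))
    expect_equal(perm |> arrange(junction_id, sample_id),
                 out |> arrange(junction_id, sample_id))
  }
})

test_that("read-support filter applies the min-reads/min-samples predicate", {
  jx <- tibble(
    junction_id = c("a", "b", "b", "c", "c"),
    chrom = "chr1", start = 1L, end = 10L, strand = "+",
    sample_id = c("s1", "s1", "s2", "s1", "s2"),
    count = c(4L, 3L, 3L, 2L, 2L)
  )
  kept <- filter_junctions(jx)
  expect_equal(unique(kept$junction_id), "a")  # boundary: exactly 4 reads
  kept2 <- filter_junctions(jx, min_reads = 2, min_samples = 2)
  expect_setequal(unique(kept2$junction_id), c("b", "c"))
  expect_error(filter_junctions(jx, min_reads = 0), "min_reads")
})

test_that("context classification labels sides and assigns host genes", {
  ann <- toy_annotation()
  jx <- tibble(
    junction_id = c("both_exonic", "intergenic", "mixed"),
    chrom = "chr1",
    start = c(150L, 600L, 150L), end = c(450L, 900L, 250L), strand = "+"
  )
  cc <- classify_context(jx, ann)
  cc <- cc[match(jx$junction_id, cc$junction_id), ]
  expect_equal(cc$context, c("exonic", "intergenic", "intronic"))
  expect_equal(cc$context_pair,
               c("exonic:exonic", "intergenic:intergenic", "exonic:intronic"))
  expect_equal(cc$host_gene, c("GA", NA, "GA"))
})

test_that("positional bias counts 1-bp overlaps non-exclusively", {
  ann <- toy_annotation()
  # circle inside CDS only; circle spanning UTR5+CDS boundary
  jx <- tibble(junction_id = c("cds_only", "utr5_cds"), chrom = "chr1",
               start = c(130L, 110L), end = c(190L, 190L), strand = "+")
  bias <- positional_bias(jx[1, ], ann)
  expect_equal(bias$fraction[bias$region == "CDS"], 1)
  expect_equal(bias$fraction[bias$region == "UTR5"], 0)
  expect_equal(bias$fraction[bias$region == "UTR3"], 0)
  both <- positional_bias(jx, ann)
  expect_equal(both$fraction[both$region == "CDS"], 1)
  expect_equal(both$fraction[both$region == "UTR5"], 0.5)
  expect_error(positional_bias(jx[0, ], ann), "undefined")
})

test_that("positional bias matches brute-force overlap enumeration", {
  ann <- fixture_annotation()
  co <- generate_cohort(ann, n_junctions = 100, include_chimeric = FALSE,
                        spike = spike_config(n_spiked = 0), seed = 8)
  exonic <- co$junctions |> filter(context == "exonic")
  bias <- positional_bias(exonic, ann)
  overlaps1bp <- function(tab) {
    purrr::map_lgl(seq_len(nrow(exonic)), function(i) {
      any(tab$chrom == exonic$chrom[i] & tab$start < exonic$end[i] &
            tab$end > exonic$start[i])
    })
  }
  expect_equal(bias$fraction[bias$region == "CDS"],
               mean(overlaps1bp(ann$cds)))
  expect_equal(bias$fraction[bias$region == "UTR5"],
               mean(overlaps1bp(ann$utr5)))
  expect_equal(bias$fraction[bias$region == "UTR3"],
               mean(overlaps1bp(ann$utr3)))
})

test_that("well-supported spiked junctions survive call + filter", {
  ann <- fixture_annotation()
  hit <- purrr::map_lgl(1:5, function(s) {
    co <- generate_cohort(ann, n_junctions = 40,
                          spike = spike_config(n_spiked = 10),
                          circ_baseline = c(meanlog = log(10), sdlog = 0.3),
                          seed = s)
    called <- suppressMessages(call_backsplices(co$chimeric)) |>
      filter_junctions()
    spiked <- co$truth$junction_id[co$truth$is_spiked]
    all(spiked %in% called$junction_id)
  })
  expect_true(all(hit))
})

test_that("host summary counts junctions per host gene", {
  jx <- tibble(junction_id = paste0("j", 1:5),
               host_gene = c("A", "A", "B", NA, "C"))
  hs <- host_summary(jx)
  expect_equal(hs$n_junctions, 5L)
  expect_equal(hs$n_host_genes, 3L)
  expect_equal(hs$junctions_per_gene, round(5 / 3, 2))
})
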