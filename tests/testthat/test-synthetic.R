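test_that("annotation generation is deterministic and validates input", {
  a <- generate_annotation(n_genes = 10, seed = 1)
  b <- generate_annotation(n_genes = 10, seed = 1)
  expect_identical(a, b)
  expect_error(generate_annotation(n_genes = 0), "n_genes")
  expect_error(generate_annotation(n_genes = 5000, chrom_count = 1,
                                   chrom_length = 1e4),
               "packing")
})

test_that("a single-exon gene is tiled by UTR5 + CDS + UTR3", {
  ann <- generate_annotation(n_genes = 1, exons_per_gene_range = c(1, 1),
                             seed = 3)
  exon <- ann$exons
  regions <- bind_rows(ann$utr5, ann$cds, ann$utr3) |> arrange(start)
  expect_equal(min(regions$start), exon$start)
  expect_equal(max(regions$end), exon$end)
  # contiguous, non-overlapping tiling
  expect_equal(regions$start[-1], regions$end[-nrow(regions)])
  expect_equal(sum(regions$end - regions$start), exon$end - exon$start)
})

test_that("cohort generation is deterministic and writes identical files", {
  ann <- fixture_annotation()
  co1 <- generate_cohort(ann, n_junctions = 60,
                         spike = spike_config(n_spiked = 5), seed = 2)
  co2 <- generate_cohort(ann, n_junctions = 60,
                         spike = spike_config(n_spiked = 5), seed = 2)
  expect_identical(co1, co2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(co1, d1); write_cohort(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("default sampling plan reproduces the 58-sample grade structure", {
  ann <- fixture_annotation()
  co <- generate_cohort(ann, n_junctions = 20, include_chimeric = FALSE,
                        spike = spike_config(n_spiked = 0), seed = 1)
  expect_equal(nrow(co$samples), 58L)
  expect_equal(as.integer(table(co$samples$grade)[c("G1", "G2", "G3")]),
               c(17L, 5L, 36L))
  mibc <- co$samples |> filter(stage_class == "MIBC")
  expect_equal(nrow(mibc), 6L)
  expect_true(all(mibc$grade == "G3"))
})

test_that("a null spike leaves all true group means equal across grades", {
  ann <- fixture_annotation()
  co <- generate_cohort(ann, n_junctions = 50, include_chimeric = FALSE,
                        spike = spike_config(n_spiked = 10, effect_size = 0),
                        seed = 4)
  expect_equal(co$truth$true_mean_G1, co$truth$true_mean_G2)
  expect_equal(co$truth$true_mean_G1, co$truth$true_mean_G3)
  expect_equal(sum(co$truth$is_spiked), 10L)
  expect_error(
    generate_cohort(ann, n_junctions = 5, spike = spike_config(n_spiked = 6)),
    "n_spiked")
})

test_that("genomic-context mix tracks the configured proportions", {
  ann <- generate_annotation(n_genes = 150, seed = 9)
  co <- generate_cohort(ann, n_junctions = 1000, include_chimeric = FALSE,
                        spike = spike_config(n_spiked = 0), seed = 9)
  mix <- table(co$junctions$context) / nrow(co$junctions)
  expect_lt(abs(mix[["exonic"]] - 0.94), 0.02)
  expect_lt(abs(mix[["intronic"]] - 0.04), 0.02)
  expect_lt(abs(mix[["intergenic"]] - 0.02), 0.02)
  # generator labels agree with coordinate-based classification
  cc <- classify_context(co$junctions, ann)
  expect_equal(cc$context[match(co$junctions$junction_id, cc$junction_id)],
               co$junctions$context)
})

test_that("spiked mean relative-expression shift converges to the effect size", {
  ann <- fixture_annotation()
  plan <- sample_plan(n_per_grade = c(G1 = 200, G2 = 2, G3 = 200), n_mibc = 0)
  co <- generate_cohort(ann, n_junctions = 150, plan = plan,
                        spike = spike_config(n_spiked = 60, effect_size = 1,
                                             prop_up = 1),
                        include_chimeric = FALSE, seed = 6)
  re <- quantify_relative_expression(co$junctions, co$circ_counts, co$linear,
                                     co$samples) |>
    left_join(co$samples |> select(sample_id, grade), by = "sample_id") |>
    filter(grade %in% c("G1", "G3"))
  delta <- re |>
    group_by(junction_id, grade) |>
    summarise(m = mean(rel_expr), .groups = "drop") |>
    tidyr::pivot_wider(names_from = grade, values_from = m) |>
    left_join(co$truth, by = "junction_id")
  emp <- delta |> filter(is_spiked) |> summarise(d = mean(G3 - G1)) |> pull(d)
  expect_lt(abs(emp - 1), 0.1)
  null_d <- delta |> filter(!is_spiked) |> summarise(d = mean(G3 - G1)) |> pull(d)
  expect_lt(abs(null_d), 0.1)
})

test_that("site tables honor the length mix and placement contract", {
  ann <- fixture_annotation()
  s0 <- generate_site_table(ann, 500, frac_long = 0, seed = 1)
  expect_true(all(s0$site_length %in% c(7L, 8L)))
  expect_identical(s0, generate_site_table(ann, 500, frac_long = 0, seed = 1))
  expect_error(generate_site_table(ann, 0), "n_sites")
  # every site inside a gene body
  genes <- ann$genes
  hit <- purrr::map_lgl(seq_len(nrow(s0)), function(i) {
    any(genes$chrom == s0$chrom[i] & genes$start <= s0$start[i] &
          genes$end >= s0$end[i])
  })
  expect_true(all(hit))
  s1 <- generate_site_table(ann, 1000, frac_long = 0.05, seed = 2)
  expect_equal(sum(s1$site_length > 8), 50L)
})

test_that("reference cohorts contain the configured matched fraction", {
  ann <- fixture_annotation()
  co <- generate_cohort(ann, n_junctions = 200, include_chimeric = FALSE,
                        spike = spike_config(n_spiked = 0), seed = 5)
  jx <- co$junctions

  ref_all <- generate_reference_cohort(jx, match_fraction = 1,
                                       coordinate_offset = 0, seed = 1)
  expect_setequal(junction_key(ref_all$chrom, ref_all$start, ref_all$end),
                  junction_key(jx$chrom, jx$start, jx$end))

  ref_none <- generate_reference_cohort(jx, match_fraction = 0, seed = 1)
  expect_equal(match_junctions(jx, unify_coordinates(ref_none))$n_matched, 0L)

  # brute-force set intersection after removing the +1 offset
  ref_half <- generate_reference_cohort(jx, match_fraction = 0.5,
                                        coordinate_offset = 1, seed = 3)
  unified <- unify_coordinates(ref_half, "one_based")
  brute <- length(intersect(
    junction_key(jx$chrom, jx$start, jx$end),
    junction_key(unified$chrom, unified$start, unified$end)))
  expect_equal(brute, 100L)
  expect_equal(match_junctions(jx, unified)$n_matched, 100L)

  expect_error(generate_reference_cohort(jx[0, ], 0.5), "empty")
  expect_error(generate_reference_cohort(jx, 0.5, coordinate_offset = 2),
               "offset")
})
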