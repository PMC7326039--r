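make_rel_expr <- function(values_by_group, feature_id = "f1") {
  # values_by_group: named list grade -> numeric vector of sample values
  smp <- tibble(
    sample_id = paste0("s", seq_len(sum(lengths(values_by_group)))),
    grade = rep(names(values_by_group), lengths(values_by_group)),
    stage_class = "NMIBC", library_size = 1000L
  )
  list(samples = smp,
       rel = tibble(feature_id = feature_id, sample_id = smp$sample_id,
                    rel_expr = unlist(values_by_group, use.names = FALSE)))
}

test_that("identical groups give F = 0 and p = 1", {
  d <- make_rel_expr(list(G1 = c(1, 2, 3), G3 = c(1, 2, 3)))
  res <- anova_per_feature(d$rel, d$samples)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$mean_G1, 2)
  expect_equal(res$mean_G3, 2)
})

test_that("well-separated groups give a vanishing p-value", {
  withr::with_seed(1, {
    d <- make_rel_expr(list(G1 = rnorm(4, 0, 1e-3), G3 = rnorm(4, 5, 1e-3)))
  })
  res <- anova_per_feature(d$rel, d$samples)
  expect_lt(res$p_value, 1e-6)
})

test_that("the vectorized ANOVA reproduces stats::aov per feature", {
  withr::with_seed(7, {
    smp <- tibble(sample_id = paste0("s", 1:12),
                  grade = rep(c("G1", "G2", "G3"), each = 4),
                  stage_class = "NMIBC", library_size = 1L)
    rel <- tidyr::expand_grid(feature_id = paste0("f", 1:6),
                              sample_id = smp$sample_id) |>
      mutate(rel_expr = rnorm(72))
  })
  res <- anova_per_feature(rel, smp)
  for (f in unique(rel$feature_id)) {
    sub <- rel |> filter(feature_id == f) |>
      left_join(smp, by = "sample_id")
    fit <- summary(stats::aov(rel_expr ~ grade, data = sub))[[1]]
    i <- which(res$feature_id == f)
    expect_equal(res$statistic[i], fit$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p_value[i], fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("hand-sized three-group ANOVA matches textbook mean squares", {
  d <- make_rel_expr(list(G1 = c(1, 2, 3), G2 = c(2, 3, 4), G3 = c(5, 6, 7)))
  res <- anova_per_feature(d$rel, d$samples)
  # group means 2, 3, 6; grand mean 11/3
  ssb <- 3 * ((2 - 11/3)^2 + (3 - 11/3)^2 + (6 - 11/3)^2)
  ssw <- 6  # each group contributes (1-0)^2 + 0 + (1-0)^2 = 2
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$statistic, f_hand)
  expect_equal(res$p_value, pf(f_hand, 2, 6, lower.tail = FALSE))
})

test_that("degenerate groupings are rejected by name", {
  d <- make_rel_expr(list(G1 = c(1, 2, 3), G2 = 1, G3 = c(1, 2, 3)))
  expect_error(anova_per_feature(d$rel, d$samples), "G2")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # permutation equivariance
  withr::with_seed(3, {
    p <- runif(50)
    perm <- sample(50)
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  })
})

test_that("significant-set algebra matches direct set operations", {
  res <- tibble(feature_id = paste0("c", 1:6),
                host_gene = c("A", "A", "B", "C", "D", "E"),
                adjusted_p = c(0.01, 0.02, 0.03, 0.04, 0.049, 0.6))
  sets <- significant_sets(res, genes_de = c("B", "C", "Z"),
                           all_circle_hosts = c("A", "B", "C", "D", "E"))
  expect_setequal(sets$de_circles, paste0("c", 1:5))
  expect_setequal(sets$de_circle_hosts, c("A", "B", "C", "D"))
  expect_setequal(sets$de_genes_with_circles, c("B", "C"))
  expect_setequal(sets$circles_decoupled_from_host, c("c1", "c2", "c5"))

  none <- significant_sets(res |> mutate(adjusted_p = 0.9),
                           genes_de = "B", all_circle_hosts = character(0))
  expect_equal(lengths(none), setNames(rep(0L, 4), names(none)))

  all_de <- significant_sets(res, genes_de = c("A", "B", "C", "D", "E"),
                             all_circle_hosts = c("A", "B"))
  expect_equal(length(all_de$circles_decoupled_from_host), 0L)
})

test_that("type-I error is calibrated on a modest null cohort", {
  ann <- fixture_annotation()
  co <- generate_cohort(ann, n_junctions = 1500,
                        spike = spike_config(n_spiked = 0),
                        include_chimeric = FALSE, seed = 21)
  re <- quantify_relative_expression(co$junctions, co$circ_counts, co$linear,
                                     co$samples)
  res <- anova_per_feature(re, co$samples)
  expect_lt(abs(mean(res$p_value < 0.05) - 0.05), 0.02)
})

test_that("clustering recovers separable blocks and ignores sample order", {
  rel <- tidyr::expand_grid(feature_id = paste0("f", 1:6),
                            sample_id = paste0("s", 1:6)) |>
    mutate(rel_expr = ifelse(feature_id %in% c("f1", "f2", "f3"), 5, -5) +
             ifelse(sample_id %in% c("s1", "s2"), 0.2, 0))
  cl <- cluster_matrix(rel)
  blocks <- split(cl$feature_clusters$feature_id, cl$feature_clusters$cluster)
  expect_setequal(blocks[["1"]], c("f1", "f2", "f3"))
  expect_setequal(blocks[["2"]], c("f4", "f5", "f6"))

  perm <- rel[sample(nrow(rel)), ]
  cl2 <- cluster_matrix(perm)
  # identical partition as sets (the A/B labels follow input order)
  part <- function(cl) unname(lapply(
    split(cl$sample_groups$sample_id, cl$sample_groups$group), sort))
  expect_true(setequal(part(cl2), part(cl)))

  expect_error(cluster_matrix(rel |> mutate(rel_expr = 1)), "constant")
  expect_error(cluster_matrix(rel |> filter(feature_id == "f1")), ">= 2")
})

test_that("a G3-only spike signature clusters the G3 samples together", {
  ann <- fixture_annotation()
  co <- generate_cohort(ann, n_junctions = 300,
                        spike = spike_config(n_spiked = 60, effect_size = 2),
                        include_chimeric = FALSE, seed = 11)
  re <- quantify_relative_expression(co$junctions, co$circ_counts, co$linear,
                                     co$samples)
  spiked <- co$truth$junction_id[co$truth$is_spiked]
  cl <- cluster_matrix(re |> filter(junction_id %in% spiked))
  purity <- cl$sample_groups |>
    left_join(co$samples, by = "sample_id") |>
    group_by(group) |>
    summarise(fr_g3 = mean(grade == "G3"))
  expect_gt(max(purity$fr_g3), 0.9)
})

test_that("cluster objects expose tidy, glance and autoplot views", {
  rel <- tidyr::expand_grid(feature_id = paste0("f", 1:4),
                            sample_id = paste0("s", 1:4)) |>
    mutate(rel_expr = seq_len(16) %% 5)
  cl <- cluster_matrix(rel)
  td <- tidy(cl)
  expect_equal(nrow(td), 8L)
  expect_setequal(unique(td$type), c("sample", "feature"))
  gl <- glance(cl)
  expect_equal(gl$n_features, 4L)
  expect_equal(gl$n_samples, 4L)
  expect_s3_class(autoplot(cl), "ggplot")
})

test_that("gene-level ANOVA stand-in flags a shifted gene", {
  smp <- tibble(sample_id = paste0("s", 1:12),
                grade = rep(c("G1", "G2", "G3"), each = 4),
                stage_class = "NMIBC", library_size = 1000L)
  counts <- tidyr::expand_grid(feature_id = c("flat", "shifted"),
                               sample_id = smp$sample_id) |>
    mutate(count = ifelse(feature_id == "shifted" &
                            sample_id %in% smp$sample_id[9:12], 800L, 100L))
  res <- differential_genes(counts, smp)
  expect_lt(res$adjusted_p[res$feature_id == "shifted"], 0.01)
  expect_equal(res$p_value[res$feature_id == "flat"], 1)
})
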