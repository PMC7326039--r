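#' Per-feature one-way ANOVA on relative expression
#'
#' Fixed-effects one-way ANOVA of each feature's values against the sample
#' grouping (tumor grade by default), computed from the between/within sums
#' of squares with p-values from the F distribution; results are identical
#' to `stats::aov` fit feature by feature but vectorized over thousands of
#' features. Features with zero variance within every group and equal group
#' means get `statistic = 0`, `p_value = 1`. P-values are
#' Benjamini-Hochberg adjusted across features.
#'
#' @param rel_expr Long tibble with a feature id column (first non-reserved
#'   column), `sample_id` and a value column.
#' @param samples Sample tibble carrying the grouping column.
#' @param grouping Name of the grouping column in `samples` (default
#'   `"grade"`). Every group must have >= 2 samples.
#' @param value_col Name of the value column in `rel_expr`.
#' @param nmibc_only Drop MIBC samples before testing (the default keeps all
#'   samples, MIBC carrying their G3 label).
#' @return Tibble `feature_id`, `statistic`, `df_between`, `df_within`,
#'   `p_value`, `adjusted_p` and one `mean_<group>` column per group.
#' @export
anova_per_feature <- function(rel_expr, samples, grouping = "grade",
                              value_col = "rel_expr", nmibc_only = FALSE) {
  if (nmibc_only) samples <- samples |> filter(.data$stage_class == "NMIBC")
  id_col <- setdiff(names(rel_expr), c("sample_id", value_col, "chrom",
                                       "start", "end", "strand"))[1]
  x <- rel_expr |>
    filter(.data$sample_id %in% samples$sample_id) |>
    left_join(samples |> select("sample_id", group = all_of(grouping)),
              by = "sample_id")
  sizes <- x |> distinct(.data$sample_id, .data$group) |> count(.data$group)
  small <- sizes$group[sizes$n < 2]
  if (length(small) > 0) {
    abort(paste0("group '", small[1], "' has fewer than 2 samples"))
  }
  if (nrow(sizes) < 2) abort("need at least 2 groups")
  wide <- x |>
    pivot_wider(id_cols = all_of(id_col), names_from = "sample_id",
                values_from = all_of(value_col))
  m <- as.matrix(wide[, -1])
  ord <- match(colnames(m), x$sample_id[!duplicated(x$sample_id)])
  g <- factor((x |> distinct(.data$sample_id, .data$group))$group[ord])
  k <- nlevels(g); n <- ncol(m)
  gm <- vapply(levels(g), function(l) rowMeans(m[, g == l, drop = FALSE]),
               numeric(nrow(m)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1, dimnames = list(NULL, levels(g)))
  ng <- as.numeric(table(g))
  grand <- rowMeans(m)
  ssb <- rowSums(sweep((gm - grand)^2, 2, ng, "*"))
  sst <- rowSums((m - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(fstat, k - 1, n - k, lower.tail = FALSE)
  degenerate <- ssw < 1e-12 & ssb < 1e-12
  fstat[degenerate] <- 0; p[degenerate] <- 1
  p[ssw < 1e-12 & ssb >= 1e-12] <- 0
  res <- tibble(feature_id = wide[[1]], statistic = fstat,
                df_between = k - 1, df_within = n - k,
                p_value = p, adjusted_p = bh_adjust(p))
  means <- as_tibble(gm)
  names(means) <- paste0("mean_", levels(g))
  dplyr::bind_cols(res, means)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Set algebra between DE circles and DE genes
#'
#' Given per-feature ANOVA results carrying host genes, a gene-level DE list
#' and the universe of circle host genes, computes: the significantly
#' differentially (relative-)expressed circles; their unique host genes; the
#' DE genes that host any circle; and the DE circles decoupled from their
#' host (host not itself DE at the gene level).
#'
#' @param results ANOVA result tibble with `feature_id`, `adjusted_p` and a
#'   `host_gene` column.
#' @param genes_de Character vector of gene-level DE gene ids.
#' @param all_circle_hosts Character vector: host genes of all detected
#'   circles.
#' @param alpha Adjusted-p threshold.
#' @return Named list `de_circles`, `de_circle_hosts`,
#'   `de_genes_with_circles`, `circles_decoupled_from_host`.
#' @export
significant_sets <- function(results, genes_de, all_circle_hosts,
                             alpha = 0.05) {
  if (!"host_gene" %in% names(results)) {
    abort("results must carry a host_gene column")
  }
  de <- results |> filter(.data$adjusted_p < alpha)
  list(
    de_circles = de$feature_id,
    de_circle_hosts = unique(de$host_gene[!is.na(de$host_gene)]),
    de_genes_with_circles = intersect(genes_de, all_circle_hosts),
    circles_decoupled_from_host =
      de$feature_id[is.na(de$host_gene) | !(de$host_gene %in% genes_de)]
  )
}

#' Gene-level differential expression (ANOVA stand-in)
#'
#' Applies the same per-feature one-way ANOVA to `log2(CPM + 1)` gene
#' counts, serving as the gene-level DE input to [significant_sets()].
#'
#' @param gene_counts Long tibble `feature_id`, `sample_id`, `count`.
#' @param samples Sample tibble with `library_size` and the grouping column.
#' @param grouping Grouping column name.
#' @return ANOVA result tibble (see [anova_per_feature()]).
#' @export
differential_genes <- function(gene_counts, samples, grouping = "grade") {
  expr <- cpm(gene_counts, samples) |>
    mutate(log_expr = log2(.data$cpm + 1)) |>
    select(-"count", -"cpm")
  anova_per_feature(expr, samples, grouping = grouping, value_col = "log_expr")
}
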