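#' Cluster the discriminative relative-expression matrix
#'
#' Agglomerative hierarchical clustering (average linkage, Euclidean
#' distance) of both features (rows) and samples (columns), as used for
#' heatmap displays of grade-discriminating circRNAs. Cutting each tree at
#' its top split yields two sample groups (A/B) and two feature clusters
#' (1/2). Group A is the group containing the first sample in input order;
#' cluster 1 the one containing the first feature (a deterministic
#' tie-break, so relabeling cannot depend on permutation of the input).
#'
#' @param rel_expr Long tibble with a feature id column, `sample_id` and a
#'   value column; needs >= 2 features and >= 2 samples.
#' @param value_col Name of the value column.
#' @return An object of class `circ_clust` with elements `feature_hclust`,
#'   `sample_hclust`, `sample_groups` (tibble `sample_id`, `group`),
#'   `feature_clusters` (tibble `feature_id`, `cluster`) and `matrix`.
#' @export
cluster_matrix <- function(rel_expr, value_col = "rel_expr") {
  id_col <- setdiff(names(rel_expr), c("sample_id", value_col))[1]
  wide <- rel_expr |>
    pivot_wider(id_cols = all_of(id_col), names_from = "sample_id",
                values_from = all_of(value_col))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide[[1]]
  if (nrow(m) < 2 || ncol(m) < 2) abort("need >= 2 features and >= 2 samples")
  if (max(m) - min(m) < 1e-12) abort("constant matrix: distances degenerate")
  hc_f <- hclust(dist(m), method = "average")
  hc_s <- hclust(dist(t(m)), method = "average")
  cut_f <- cutree(hc_f, k = 2)
  cut_s <- cutree(hc_s, k = 2)
  # relabel so the first feature/sample in input order defines cluster 1 / group A
  f_lab <- ifelse(cut_f == cut_f[1], "1", "2")
  s_lab <- ifelse(cut_s == cut_s[1], "A", "B")
  structure(list(
    feature_hclust = hc_f, sample_hclust = hc_s,
    sample_groups = tibble(sample_id = colnames(m), group = unname(s_lab)),
    feature_clusters = tibble(feature_id = rownames(m), cluster = unname(f_lab)),
    matrix = m
  ), class = "circ_clust")
}

#' @export
print.circ_clust <- function(x, ...) {
  cat("<circ_clust> ", nrow(x$matrix), " features x ", ncol(x$matrix),
      " samples; sample groups: ",
      paste(table(x$sample_groups$group), collapse = "/"),
      "; feature clusters: ",
      paste(table(x$feature_clusters$cluster), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' @describeIn cluster_matrix Tidy the cluster assignments: one row per item
#'   with `item`, `type` (`"sample"`/`"feature"`) and `group`.
#' @param x A `circ_clust` object.
#' @param ... Unused.
#' @method tidy circ_clust
#' @export
tidy.circ_clust <- function(x, ...) {
  bind_rows(
    x$sample_groups |> rename(item = "sample_id", group = "group") |>
      mutate(type = "sample"),
    x$feature_clusters |> rename(item = "feature_id", group = "cluster") |>
      mutate(type = "feature")
  ) |> select("item", "type", "group")
}

#' @describeIn cluster_matrix One-row summary: dimensions and top-split
#'   heights of both dendrograms.
#' @method glance circ_clust
#' @export
glance.circ_clust <- function(x, ...) {
  tibble(
    n_features = nrow(x$matrix), n_samples = ncol(x$matrix),
    feature_top_height = max(x$feature_hclust$height),
    sample_top_height = max(x$sample_hclust$height)
  )
}

#' @describeIn cluster_matrix Heatmap of the matrix with rows and columns in
#'   dendrogram-leaf order, annotated by the two-way cuts.
#' @param object A `circ_clust` object.
#' @method autoplot circ_clust
#' @export
autoplot.circ_clust <- function(object, ...) {
  m <- object$matrix
  df <- as_tibble(m, rownames = "feature_id") |>
    pivot_longer(-"feature_id", names_to = "sample_id", values_to = "value") |>
    left_join(object$sample_groups, by = "sample_id") |>
    mutate(
      feature_id = factor(.data$feature_id,
                          levels = rownames(m)[object$feature_hclust$order]),
      sample_id = factor(.data$sample_id,
                         levels = colnames(m)[object$sample_hclust$order])
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$feature_id,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", name = "log2 C/L") +
    ggplot2::facet_grid(. ~ group, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "sample", y = "circRNA") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
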