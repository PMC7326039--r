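#' Pathway signature score
#'
#' Per-sample pathway activity: the geometric mean, over the set's member
#' genes, of expression plus a pseudo-count. The pseudo-count is the
#' smallest strictly positive expression value observed across the member
#' genes and samples (a raw minimum of zero would collapse the geometric
#' mean). Member genes absent from the matrix are dropped with a warning.
#'
#' @param gene_expr Long expression tibble (`gene_id`, `sample_id`, `expr`),
#'   typically CPM.
#' @param genes Character vector of member gene ids.
#' @return Tibble `sample_id`, `score`.
#' @export
signature_score <- function(gene_expr, genes) {
  present <- intersect(genes, unique(gene_expr$gene_id))
  missing <- setdiff(genes, present)
  if (length(present) == 0) abort("no member genes present in the matrix")
  if (length(missing) > 0) {
    warn(paste0(length(missing), " member gene(s) absent from the matrix: ",
                paste(utils::head(missing, 5), collapse = ", ")))
  }
  sub <- gene_expr |> filter(.data$gene_id %in% present)
  pos <- sub$expr[sub$expr > 0]
  if (length(pos) == 0) abort("all member expression values are zero: no positive pseudo-count")
  pseudo <- min(pos)
  sub |>
    group_by(.data$sample_id) |>
    summarise(score = exp(mean(log(.data$expr + pseudo))), .groups = "drop")
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation with the p-value from the t transform
#' (`stats::cor.test`).
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return One-row tibble `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("zero variance")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Correlate circRNAs with pathway activity and parental genes
#'
#' For each pathway, circles hosted by a member gene are correlated with the
#' pathway signature score and with their parental gene's expression: three
#' comparisons per in-pathway circle, labeled `circ_expr_vs_score`
#' (log2(CPM+1) circle expression vs score), `rel_expr_vs_score` (relative
#' expression vs score) and `circ_expr_vs_host_expr` (circle vs parental
#' gene log2(CPM+1)). Circles on genes absent from every pathway yield no
#' records. No multiple-testing correction is applied by default (raw
#' p-value counts are reported in the field's convention); `adjust = TRUE`
#' adds a BH-adjusted column.
#'
#' @param circ_cpm Long circle CPM tibble (`junction_id`, `sample_id`,
#'   `cpm`).
#' @param rel_expr Long relative-expression tibble (`junction_id`,
#'   `sample_id`, `rel_expr`).
#' @param gene_expr Long gene CPM tibble (`gene_id`, `sample_id`, `expr`).
#' @param sets Gene-set tibble from [read_gmt()] (`name`, `genes`
#'   list-column).
#' @param hosts Tibble `junction_id`, `host_gene` for the circles.
#' @param adjust Add a BH-adjusted p-value column.
#' @return Tibble of correlation records: `set`, `junction_id`, `host_gene`,
#'   `comparison`, `r`, `p_value`, `n`.
#' @export
pathway_correlations <- function(circ_cpm, rel_expr, gene_expr, sets, hosts,
                                 adjust = FALSE) {
  n_samp <- dplyr::n_distinct(circ_cpm$sample_id)
  if (n_samp < 3) abort("fewer than 3 samples")
  circ_log <- circ_cpm |> mutate(log_expr = log2(.data$cpm + 1))
  gene_log <- gene_expr |> mutate(log_expr = log2(.data$expr + 1))
  recs <- purrr::map2(sets$name, sets$genes, function(set_name, members) {
    members <- intersect(members, unique(gene_expr$gene_id))
    if (length(members) == 0) return(NULL)
    in_set <- hosts |> filter(.data$host_gene %in% members)
    if (nrow(in_set) == 0) return(NULL)
    score <- signature_score(gene_expr, members)
    purrr::map2(in_set$junction_id, in_set$host_gene, function(jid, host) {
      ce <- circ_log |> filter(.data$junction_id == jid) |>
        arrange(.data$sample_id)
      re <- rel_expr |> filter(.data$junction_id == jid) |>
        arrange(.data$sample_id)
      sc <- score |> arrange(.data$sample_id)
      he <- gene_log |> filter(.data$gene_id == host) |>
        arrange(.data$sample_id)
      one <- function(comparison, x, y) {
        r <- tryCatch(pearson_cor(x, y), error = function(e) NULL)
        if (is.null(r)) return(NULL)
        r |> mutate(set = set_name, junction_id = jid, host_gene = host,
                    comparison = comparison)
      }
      bind_rows(
        one("circ_expr_vs_score", ce$log_expr, sc$score),
        one("rel_expr_vs_score", re$rel_expr, sc$score),
        one("circ_expr_vs_host_expr", ce$log_expr, he$log_expr)
      )
    }) |> bind_rows()
  }) |> bind_rows()
  if (nrow(recs) == 0) {
    return(tibble(set = character(), junction_id = character(),
                  host_gene = character(), comparison = character(),
                  r = numeric(), p_value = numeric(), n = integer()))
  }
  recs <- recs |>
    select("set", "junction_id", "host_gene", "comparison", "r", "p_value", "n")
  if (adjust) recs <- recs |> mutate(adjusted_p = bh_adjust(.data$p_value))
  recs
}
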