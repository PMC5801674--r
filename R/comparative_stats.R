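# Cohort-level comparison: the genes-by-genomes identity matrix and
# per-gene distribution summaries (10th/25th/50th/75th/90th percentiles
# with outliers outside the whiskers), matching the presence/absence-
# with-identity matrix and boxplot conventions used for real surveys.

#' Build the genes-by-genomes identity matrix
#'
#' One row per reference label (plus any auxiliary labels observed as
#' insertions), one column per genome; cells carry the identity percent
#' of the assigned slot, `NA` for absent slots, and auxiliary rows are
#' populated only where the corresponding insertion was identified.
#' Row order follows the reference cluster, column order the input order.
#'
#' @param architectures List of `eps_architecture` objects.
#' @return List with `wide` (tibble, `label` + one column per genome) and
#'   `long` (tibble `genome_id`/`label`/`status`/`identity_pct`).
#' @export
build_identity_matrix <- function(architectures) {
  stopifnot(length(architectures) >= 1)
  long_slots <- purrr::map_dfr(architectures, function(a) {
    tidy(a) |> select("genome_id", "label", "status", "identity_pct")
  })
  aux <- purrr::map_dfr(architectures, function(a) {
    if (nrow(a$insertions) == 0) return(tibble())
    tibble(
      genome_id = a$genome_id,
      label = unlist(a$insertions$assigned),
      status = "EXTRA",
      identity_pct = NA_real_
    ) |> filter(!is.na(.data$label), .data$label != "UNKNOWN")
  })
  long <- bind_rows(long_slots, aux)
  label_order <- c(
    intersect(eps_labels(), unique(long$label)),
    setdiff(unique(long$label), eps_labels())
  )
  genome_order <- vapply(architectures, `[[`, character(1), "genome_id")
  long <- long |>
    mutate(label = factor(.data$label, levels = label_order),
           genome_id = factor(.data$genome_id, levels = genome_order)) |>
    arrange(.data$label, .data$genome_id)
  wide <- long |>
    filter(.data$status != "EXTRA") |>
    select("label", "genome_id", "identity_pct") |>
    tidyr::pivot_wider(names_from = "genome_id",
                       values_from = "identity_pct")
  list(wide = wide, long = long)
}

#' Percentile summary of one gene's identity values
#'
#' Five percentiles (10/25/50/75/90) by type-7 linear interpolation
#' between order statistics; values outside the whisker range are
#' reported as outliers. Absent cells must be excluded before calling
#' (the summary uses exactly the present values).
#'
#' @param values Numeric vector of identity percents (no NAs).
#' @param ids Optional identifiers parallel to `values` (genome ids) used
#'   to name outliers.
#' @return One-row tibble: `n`, `p10`, `p25`, `p50`, `p75`, `p90`,
#'   `outliers` (list column of tibbles `id`/`value`).
#' @export
summarize_gene <- function(values, ids = NULL) {
  stopifnot(length(values) >= 1, !anyNA(values))
  ids <- ids %||% as.character(seq_along(values))
  q <- quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7,
                names = FALSE)
  out <- values < q[1] | values > q[5]
  tibble(
    n = length(values),
    p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5],
    outliers = list(tibble(id = ids[out], value = values[out]))
  )
}

#' Per-gene summaries over a cohort
#'
#' Applies [summarize_gene()] to every reference label over the long
#' identity table, excluding absent cells. Also works for MinLrap/MaxLrap
#' vectors via the `value_col` argument.
#'
#' @param long Long table from [build_identity_matrix()], or any tibble
#'   with `label`, `genome_id` and a value column.
#' @param value_col Name of the value column (default `identity_pct`).
#' @return Tibble with one row per label carrying the percentile columns.
#' @export
summarize_genes <- function(long, value_col = "identity_pct") {
  long |>
    filter(!is.na(.data[[value_col]])) |>
    group_by(.data$label) |>
    group_modify(~ summarize_gene(.x[[value_col]],
                                  as.character(.x$genome_id))) |>
    ungroup()
}

#' @importFrom dplyr group_modify
NULL

#' Heatmap of the identity matrix
#'
#' Genomes on the x axis, genes on the y axis, fill by identity percent;
#' absent slots are blank, non-PRESENT statuses are marked.
#'
#' @param im Result of [build_identity_matrix()].
#' @return A ggplot object.
#' @export
plot_identity_matrix <- function(im) {
  d <- im$long |> filter(.data$status != "EXTRA")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genome_id, y = .data$label,
                                  fill = .data$identity_pct)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_point(
      data = d |> filter(!.data$status %in% c("PRESENT", "ABSENT")),
      ggplot2::aes(shape = .data$status), size = 1.6, color = "white"
    ) +
    ggplot2::scale_fill_gradient(low = "mistyrose", high = "black",
                                 na.value = "white", limits = c(0, 100)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = NULL, y = NULL, fill = "identity %",
                  shape = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Per-gene distribution boxplots
#'
#' Boxes span p25-p75 with the median line, whiskers the 10th and 90th
#' percentiles, and dots the outliers - the same convention as the
#' published per-gene identity distributions.
#'
#' @param summaries Tibble from [summarize_genes()].
#' @param ylab Axis label.
#' @return A ggplot object.
#' @export
plot_gene_distributions <- function(summaries, ylab = "identity %") {
  outliers <- summaries |>
    select("label", "outliers") |>
    tidyr::unnest(cols = "outliers")
  ggplot2::ggplot(summaries, ggplot2::aes(x = .data$label)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$p10, lower = .data$p25,
                   middle = .data$p50, upper = .data$p75,
                   ymax = .data$p90),
      stat = "identity", width = 0.6, fill = "grey90"
    ) +
    (if (nrow(outliers) > 0)
      ggplot2::geom_point(data = outliers,
                          ggplot2::aes(y = .data$value), size = 1)
     else NULL) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}
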