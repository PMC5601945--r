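#' Tidy and summarize an evaluated model grid
#'
#' `tidy()` returns the grid as a plain tibble of model descriptors and
#' metrics (the `snp_ids` list-column dropped); `glance()` returns a
#' one-row summary with the grid size and the best model under
#' [select_best_model()] without a performance screen.
#'
#' @param x An `ma_grid` from [evaluate_grid()] / [external_cv()].
#' @param ... Unused.
#' @export
tidy.ma_grid <- function(x, ...) {
  dplyr::select(as_tibble(x), -dplyr::any_of("snp_ids"))
}

#' @rdname tidy.ma_grid
#' @export
glance.ma_grid <- function(x, ...) {
  best <- select_best_model(x, screen = NULL)
  tibble(
    n_models = nrow(x), n_evaluable = sum(x$evaluable),
    best_model_id = best$model_id, best_auc = best$auc,
    best_tpr = best$tpr, best_delta_r2 = best$delta_r2,
    best_n_snps = best$n_snps
  )
}

#' Heatmap of grid discriminatory ability
#'
#' One tile per model, p-value threshold on the x axis and filter group
#' on the y axis, filled by the chosen metric and faceted by model
#' family — a compact view of how prediction quality moves across the
#' threshold grid.
#'
#' @param object An `ma_grid`.
#' @param metric `"auc"` (default), `"tpr"` or `"delta_r2"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ma_grid <- function(object, metric = c("auc", "tpr", "delta_r2"),
                             ...) {
  metric <- match.arg(metric)
  df <- tidy.ma_grid(object)
  df$p_f <- factor(format_r2(df$p_threshold),
                   levels = format_r2(sort(unique(df$p_threshold))))
  df$group <- ifelse(df$filter_kind == "total_by_maf",
                     paste0("MAF<", format_r2(df$maf_cutoff)),
                     paste0("r2<", format_r2(df$r2_threshold)))
  df$family <- paste(toupper(df$score_type),
                     ifelse(df$filter_kind == "total_by_maf",
                            "total SNPs", "LD-independent"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_f, y = .data$group,
                                   fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$family),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_viridis_c(name = metric) +
    ggplot2::labs(x = "association p-value threshold", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Score density by case-control status
#'
#' Density plot of a per-subject score (wGRS, PRS or MAC) split by
#' status — the in-sample/out-of-sample separation view.
#'
#' @param scores A tibble with a score column and a `status` column
#'   (e.g. [compute_wgrs()] or [compute_mac()] output).
#' @param score Name of the score column (default `"score"`, falling
#'   back to `"mac"`).
#' @return A ggplot object.
#' @export
plot_score_density <- function(scores, score = NULL) {
  score <- score %||% if ("score" %in% names(scores)) "score" else "mac"
  ggplot2::ggplot(scores, ggplot2::aes(x = .data[[score]],
                                       fill = .data$status,
                                       colour = .data$status)) +
    ggplot2::geom_density(alpha = 0.3) +
    ggplot2::labs(x = score) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.score_vector <- function(object, ...) plot_score_density(object)
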