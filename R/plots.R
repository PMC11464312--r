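# ggplot2 views and broom-style summaries of the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.erf_de <- function(object, lfc_min = 1, fdr_max = 0.05, ...) {
  df <- object %>% mutate(neglog_fdr = -log10(pmax(.data$fdr, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neglog_fdr,
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(fdr_max), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "#D55E00", down = "#0072B2",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR",
                  title = unique(object$contrast)[1]) +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::glance
glance.erf_de <- function(x, ...) {
  tibble(
    contrast = unique(x$contrast)[1],
    n_genes = nrow(x),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down"),
    n_flagged = sum(nzchar(x$flag))
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.erf_response <- function(object, ...) {
  df <- object %>% filter(.data$class != "none") %>%
    dplyr::count(.data$class, name = "n_genes")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n_genes,
                                   fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "response class", y = "genes",
                  title = "Treatment-response classes") +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::glance
glance.erf_response <- function(x, ...) {
  tibble(
    n_tfs = nrow(x),
    K1 = sum(x$class == "K1"),
    K2 = sum(x$class == "K2"),
    K3 = sum(x$class == "K3"),
    none = sum(x$class == "none")
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.erf_edges <- function(object, ...) {
  deg <- object %>% dplyr::count(.data$tf_id, .data$class, name = "degree")
  ggplot2::ggplot(deg, ggplot2::aes(x = stats::reorder(.data$tf_id, -.data$degree),
                                    y = .data$degree, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "regulator", y = "out-degree",
                  title = "Regulator out-degree") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @exportS3Method generics::glance
glance.erf_edges <- function(x, ...) {
  tibble(
    n_edges = nrow(x),
    n_tfs = dplyr::n_distinct(x$tf_id),
    n_targets = dplyr::n_distinct(x$target_id),
    mean_abs_r = if (nrow(x) == 0) NA_real_ else mean(abs(x$r)),
    frac_negative = if (nrow(x) == 0) NA_real_ else mean(x$r < 0)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.erf_enrichment <- function(object, fdr_max = 0.05, top = 15, ...) {
  df <- object %>% arrange(.data$p) %>% head(top) %>%
    mutate(ratio = .data$k / .data$n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio,
                                   y = stats::reorder(.data$term, -.data$p),
                                   size = .data$k, colour = -log10(.data$fdr))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "gene ratio", y = NULL, colour = "-log10 FDR",
                  size = "overlap", title = "Term enrichment") +
    ggplot2::theme_minimal()
}

#' Bar chart of the K1/K2/K3 target-set Venn regions
#' @param hubs An `erf_hubs` object from [score_hubs()].
#' @return A ggplot object.
#' @export
plot_target_overlap <- function(hubs) {
  stopifnot(inherits(hubs, "erf_hubs"))
  df <- hubs$venn %>% mutate(region = factor(.data$region, levels = .data$region))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$size)) +
    ggplot2::geom_col(fill = "#009E73") +
    ggplot2::labs(x = "target-set region", y = "genes",
                  title = "Downstream target-set overlap") +
    ggplot2::theme_minimal()
}
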