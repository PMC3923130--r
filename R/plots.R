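#' Stacked-bar plot of divergence-bin composition across stages
#'
#' @param comp Fractions matrix from [stage_composition()] (bins x
#'   stages).
#' @return A ggplot object.
#' @export
plot_stage_composition <- function(comp) {
  df <- data.frame(bin = rep(rownames(comp), ncol(comp)),
                   stage = rep(colnames(comp), each = nrow(comp)),
                   fraction = as.vector(comp))
  df$stage <- factor(df$stage, levels = colnames(comp))
  df$bin <- factor(df$bin, levels = rev(rownames(comp)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$fraction,
                                   fill = .data$bin)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1,
                               name = "divergence") +
    ggplot2::labs(x = "developmental stage",
                  y = "fraction of microRNA expression") +
    ggplot2::theme_minimal()
}

#' Per-stage TAI/TDI profile plot
#'
#' Index value per developmental stage with +/- 1 bootstrap SD error
#' bars.
#'
#' @param idx Data frame from [stage_indices()].
#' @param which `"TDI"` (default) or `"TAI"`.
#' @return A ggplot object.
#' @export
plot_stage_indices <- function(idx, which = c("TDI", "TAI")) {
  which <- match.arg(which)
  df <- data.frame(stage = idx$stage, value = idx[[which]],
                   sd = idx[[paste0(which, "_sd")]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$value,
                                   group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$sd,
                                        ymax = .data$value + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = "developmental stage", y = which) +
    ggplot2::theme_minimal()
}
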