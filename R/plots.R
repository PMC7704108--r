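# ggplot2 views of the main result types.

#' Lollipop plot of a bisulfite clone set
#'
#' Filled circles are methylated CpGs, open circles unmethylated, grey
#' crosses missing calls; one horizontal line per sequenced clone.
#'
#' @param clones A [clone_set()].
#' @return A ggplot object.
#' @export
plot_lollipop <- function(clones) {
  df <- tidy(clones)
  df$clone_id <- factor(df$clone_id, levels = rev(rownames(clones$calls)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cpg_pos, y = .data$clone_id)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$clone_id),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$call,
                                     shape = .data$call), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(M = 21, U = 21, "." = 4)) +
    ggplot2::scale_fill_manual(values = c(M = "black", U = "white",
                                          "." = "grey50")) +
    ggplot2::labs(x = "CpG position (bp)", y = NULL,
                  title = paste0(clones$locus$id, " bisulfite clones")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @export
autoplot.demeth_profile <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = tidyr::pivot_longer(object$points, c("level_t0", "level_t12"),
                                 names_to = "curve", values_to = "level"),
      ggplot2::aes(x = .data$dist, y = .data$level, colour = .data$curve),
      alpha = 0.25, size = 0.8) +
    ggplot2::geom_line(data = long,
                       ggplot2::aes(x = .data$dist, y = .data$level,
                                    colour = .data$curve),
                       linewidth = 1) +
    ggplot2::scale_colour_manual(
      values = c(level_t0 = "steelblue", level_t12 = "forestgreen",
                 t0 = "steelblue", t12 = "forestgreen", diff = "firebrick"),
      breaks = c("t0", "t12", "diff"),
      labels = c("0 h", "12 d", "difference")) +
    ggplot2::labs(x = "distance to kappaB motif (bp)",
                  y = "methylation level", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.memory_calls <- function(object, ...) {
  th <- attr(object, "thresholds")
  df <- mutate(tidy(object), class = dplyr::case_when(
    .data$memory ~ "memory",
    .data$responsive ~ "responsive",
    TRUE ~ "other"))
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$fold_12h_vs_0h),
                                   y = log2(.data$fold_second_vs_first),
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = log2(th$ratio_min),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(memory = "firebrick",
                                            responsive = "steelblue",
                                            other = "grey60")) +
    ggplot2::labs(x = "log2 fold (first induction vs naive)",
                  y = "log2 fold (second vs first induction)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot averaged signal profiles per peak group
#'
#' @param profile Result of [aggregate_profile()].
#' @return A ggplot object.
#' @export
plot_signal_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$offset, y = .data$value,
                               colour = factor(.data$group))) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = "distance to motif center (bp)", y = "signal",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
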