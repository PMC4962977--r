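#' Genome overview of NTR calls
#'
#' One horizontal track per chromosome with calls drawn as strand-coloured
#' segments, a quick positional sanity check of a discovery run.
#'
#' @param object An `ntr_discovery` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ntr_discovery
#' @export
autoplot.ntr_discovery <- function(object, ...) {
  calls <- object$calls
  calls$chrom <- factor(calls$chrom,
                        levels = unique(calls$chrom[natural_chrom_order(calls$chrom)]))
  ggplot2::ggplot(calls) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$chrom,
                   yend = .data$chrom, colour = .data$strand),
      linewidth = 3
    ) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "strand",
                  title = sprintf("%d NTR calls", nrow(calls))) +
    ggplot2::theme_minimal()
}

#' Expression profiles of NTR calls across stages
#'
#' Line plot of per-NTR expression over the ordered stages, optionally
#' after per-row standard scaling (the representation used when comparing
#' profile shapes across NTRs of different absolute levels).
#'
#' @param mat FPKM tibble from [fpkm_matrix()].
#' @param scaled Scale each row to mean 0, sd 1 first (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_expression_profiles <- function(mat, scaled = TRUE) {
  stages <- setdiff(names(mat), "ntr_id")
  if (scaled) mat <- scale_rows(mat)
  long <- tidyr::pivot_longer(mat, cols = dplyr::all_of(stages),
                              names_to = "stage", values_to = "value")
  long$stage <- factor(long$stage, levels = stages)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$value,
                                     group = .data$ntr_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = NULL,
                  y = if (scaled) "scaled FPKM (per NTR)" else "FPKM") +
    ggplot2::theme_minimal()
}

#' Layout of a simulated genome
#'
#' Shows placed genes, planted NTR models, and decoy spots along each
#' simulated chromosome.
#'
#' @param object An `ntr_sim` object from [simulate_reads()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ntr_sim
#' @export
autoplot.ntr_sim <- function(object, ...) {
  models <- bind_rows(
    mutate(object$genes, type = "gene"),
    mutate(object$ntr_models, type = "NTR"),
    mutate(object$decoys, type = "decoy")
  )
  ggplot2::ggplot(models) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$chrom,
                   yend = .data$chrom, colour = .data$type),
      linewidth = 3
    ) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
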