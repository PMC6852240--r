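# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_point
#'   facet_wrap labs scale_fill_viridis_c theme_minimal
#' @export
ggplot2::autoplot

#' Plot the per-residue score profile of a score table
#'
#' One track per available score along the chain.
#' @param object A `score_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.score_table <- function(object, ...) {
  long <- object |>
    select("chain", "resno", "tjet", "pc", "cv", "nip01") |>
    tidyr::pivot_longer(c("tjet", "pc", "cv", "nip01"),
                        names_to = "score", values_to = "value") |>
    filter(!is.na(.data$value))
  ggplot(long, aes(x = .data$resno, y = .data$value,
                   colour = .data$score)) +
    ggplot2::geom_line() +
    facet_wrap(~chain, scales = "free_x") +
    labs(x = "residue", y = "score (0-1 scale)", colour = NULL) +
    theme_minimal()
}

#' Plot predicted patches as a residue map
#'
#' Residues along the chain, coloured by layer, one row per patch.
#' @param object A `surf_patches` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surf_patches <- function(object, ...) {
  ggplot(object, aes(x = .data$resno,
                     y = factor(paste(.data$strategy, .data$patch_id)),
                     fill = .data$layer)) +
    geom_tile(height = 0.8) +
    labs(x = "residue", y = "patch", fill = "layer") +
    theme_minimal()
}

#' Plot per-region best-match performance
#'
#' @param object A `surf_eval` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surf_eval <- function(object, ...) {
  long <- object |>
    select("region", "precision", "recall", "f1") |>
    tidyr::pivot_longer(-"region", names_to = "metric")
  ggplot(long, aes(x = .data$region, y = .data$value,
                   fill = .data$metric)) +
    geom_col(position = "dodge") +
    labs(x = "interacting region", y = NULL, fill = NULL) +
    theme_minimal()
}
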