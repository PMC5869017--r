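#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PAS PSSM into a long tibble
#'
#' @param x A `pas_pssm`.
#' @param ... Unused.
#' @return A tibble: `position`, `base` (RNA alphabet), `f` (foreground
#'   frequency), `g` (background), `m` (log2 ratio).
#' @export
tidy.pas_pssm <- function(x, ...) {
  bases <- rownames(x$m)
  tidyr::expand_grid(base = bases, position = x$positions) |>
    dplyr::mutate(
      f = as.numeric(t(x$f)[cbind(match(.data$position, x$positions),
                                  match(.data$base, bases))]),
      g = unname(x$g[.data$base]),
      m = as.numeric(t(x$m)[cbind(match(.data$position, x$positions),
                                  match(.data$base, bases))]),
      base = chartr("T", "U", .data$base)
    )
}

#' @rdname tidy.pas_pssm
#' @return For `glance()`: a one-row tibble with `n_sequences`, `width`,
#'   `pseudocount`, `max_score`, `min_score` (the extreme attainable PAS
#'   scores).
#' @export
glance.pas_pssm <- function(x, ...) {
  tibble::tibble(
    n_sequences = x$n_sequences,
    width = length(x$positions),
    pseudocount = x$pseudocount,
    max_score = sum(apply(x$m, 2, max)),
    min_score = sum(apply(x$m, 2, min))
  )
}

#' Summarise a hexamer discovery run
#'
#' @param x A `hexamer_discovery` tibble from [discover_pas_hexamers()].
#' @param ... Unused.
#' @return One row: `n_tested`, `n_accepted`, `top_hexamer`, `top_fold`,
#'   `top_p`.
#' @export
glance.hexamer_discovery <- function(x, ...) {
  acc <- x[which(x$accepted), ]
  tibble::tibble(
    n_tested = nrow(x),
    n_accepted = nrow(acc),
    top_hexamer = if (nrow(acc)) acc$hexamer[which.min(acc$rank)] else NA_character_,
    top_fold = if (nrow(acc)) acc$fold[which.min(acc$rank)] else NA_real_,
    top_p = if (nrow(acc)) acc$p_value[which.min(acc$rank)] else NA_real_
  )
}

#' Heatmap of a PAS PSSM
#'
#' @param object A `pas_pssm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pas_pssm <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$position, .data$base, fill = .data$m)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "position relative to poly(A) site", y = NULL,
                  fill = expression(log[2](f / g))) +
    ggplot2::theme_minimal()
}

#' Line plot of nucleotide composition around poly(A) sites
#'
#' @param object A `nucleotide_profile` from [nucleotide_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nucleotide_profile <- function(object, ...) {
  tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("A", "C", "G", "U"), names_to = "base", values_to = "freq") |>
    ggplot2::ggplot(ggplot2::aes(.data$position, .data$freq, colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "position relative to mapped 3' end", y = "frequency") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of codon bias against premature termination
#'
#' Plots each gene's CBI (or CAI) against its log10 normalized ORF/3'UTR
#' termination ratio, the genome-wide relationship between codon usage and
#' premature cleavage and polyadenylation.
#'
#' @param gene_table Output of [gene_termination_table()].
#' @param indices Output of [gene_codon_indices()].
#' @param index `"cbi"` or `"cai"`.
#' @return A ggplot.
#' @export
plot_termination_vs_codon_bias <- function(gene_table, indices, index = c("cbi", "cai")) {
  index <- match.arg(index)
  dplyr::inner_join(gene_table, indices, by = "gene_id") |>
    dplyr::filter(is.finite(.data$log10_ratio)) |>
    ggplot2::ggplot(ggplot2::aes(.data[[index]], .data$log10_ratio)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "firebrick") +
    ggplot2::labs(x = toupper(index),
                  y = expression(log[10] ~ "normalized ORF/3'UTR termination ratio")) +
    ggplot2::theme_minimal()
}

#' Bar plot of the most enriched codons or codon pairs
#'
#' @param enrichment An enrichment tibble (from [ncuf()], [ncpf()] or
#'   [rcuf()]).
#' @param top_n Number of units to show from each extreme (default 10).
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment, top_n = 10) {
  d <- enrichment |>
    dplyr::filter(.data$flag == "ok") |>
    dplyr::arrange(dplyr::desc(.data$log2_ratio))
  d <- dplyr::bind_rows(utils::head(d, top_n), utils::tail(d, top_n)) |>
    dplyr::distinct() |>
    dplyr::mutate(unit = stats::reorder(chartr("T", "U", .data$unit), .data$log2_ratio))
  ggplot2::ggplot(d, ggplot2::aes(.data$unit, .data$log2_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(log[2] ~ "enrichment")) +
    ggplot2::theme_minimal()
}
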