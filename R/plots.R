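#' Plot a PWM as a simple sequence logo
#'
#' Letter heights are each base's share of the column's information content
#' (bits), stacked smallest-first as in standard logos.
#'
#' @param object A [pwm()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pwm <- function(object, ...) {
  df <- tidy(object) |>
    left_join(tibble(position = seq_len(pwm_length(object)),
                     ic = pwm_ic(object)), by = "position") |>
    mutate(height = .data$prob * .data$ic) |>
    group_by(.data$position) |>
    arrange(.data$height, .by_group = TRUE) |>
    mutate(ymax = cumsum(.data$height), ymin = .data$ymax - .data$height,
           ymid = (.data$ymin + .data$ymax) / 2) |>
    ungroup()
  ggplot2::ggplot(df) +
    ggplot2::geom_text(
      ggplot2::aes(x = .data$position, y = .data$ymid, label = .data$base,
                   colour = .data$base, size = .data$height),
      fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size(range = c(0, 10)) +
    ggplot2::scale_colour_manual(values = c(A = "#109648", C = "#255C99",
                                            G = "#F7B32B", T = "#D62839")) +
    ggplot2::scale_x_continuous(breaks = seq_len(pwm_length(object))) +
    ggplot2::labs(x = "position", y = "information (bits)",
                  title = object$name) +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}

#' E vs Z scatter for a k-mer score table
#'
#' @param object A `kmer_table` with `E` and `Z` columns.
#' @param e_cutoff Reference line for the significance cutoff.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.kmer_table <- function(object, e_cutoff = 0.45, ...) {
  if (!all(c("E", "Z") %in% names(object))) {
    abort("autoplot.kmer_table needs both E and Z columns")
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$Z, y = .data$E)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = e_cutoff, linetype = 2,
                        colour = "#D62839") +
    ggplot2::labs(x = "8-mer Z-score", y = "8-mer E-score") +
    ggplot2::theme_minimal()
}

#' Stereospecificity plot of a composite-motif scan
#'
#' Observed match counts by spacing, faceted by arrangement, with the null
#' mean +/- sd band; passing configurations are highlighted.
#'
#' @param object A `cm_scan` result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cm_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$spacing)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$null_mean - .data$null_sd,
                   ymax = .data$null_mean + .data$null_sd),
      fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_mean), colour = "grey40") +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$observed, colour = .data$passes)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "#D62839")) +
    ggplot2::facet_wrap(~arrangement) +
    ggplot2::labs(x = "spacing (bp)", y = "peaks with pattern",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Forest plot of TF-family odds ratios
#'
#' @param x A tibble of [family_odds_ratio()] rows.
#' @return A ggplot with log-scaled odds ratios and 95% CIs.
#' @export
plot_family_enrichment <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$odds_ratio, y = .data$family)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
tidy.cm_scan <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.cm_scan <- function(x, ...) {
  tibble(
    n_patterns = nrow(x),
    n_passing = sum(x$passes),
    top_arrangement = x$arrangement[which.max(x$z)],
    top_spacing = x$spacing[which.max(x$z)],
    max_z = max(x$z),
    null_model = attr(x, "null_model") %||% NA_character_,
    n_patterns_tested = attr(x, "n_patterns_tested") %||% nrow(x)
  )
}

#' @export
tidy.motif_clusters <- function(x, ...) {
  x |>
    select("cluster_id", "members", "n_members", "mean_internal_r") |>
    unnest("members") |>
    rename(member = "members")
}

#' @export
glance.motif_clusters <- function(x, ...) {
  tibble(n_clusters = nrow(x),
         n_motifs = sum(x$n_members),
         min_internal_r = min(x$mean_internal_r))
}
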