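#' Plot a bootstrap richness distribution
#'
#' Histogram of the pseudoreplicate pooled-richness values, with the observed
#' pooled richness marked.
#'
#' @param object A `lepisurv_bootstrap`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lepisurv_bootstrap <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$richness)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed_richness, linetype = 2) +
    ggplot2::labs(
      x = "pooled species richness per pseudoreplicate", y = "pseudoreplicates",
      title = sprintf(
        "Bootstrap richness: %s (%d draws of %d %ss)",
        object$source, object$n_boot, object$n_units, object$unit
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot the site-incidence frequency distribution
#'
#' For each structured method, the number of species observed at exactly k
#' sites -- the common-versus-rare profile of the community as each method
#' sees it.
#'
#' @param object A `lepisurv_incidence` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lepisurv_incidence <- function(object, ...) {
  df <- tibble(
    method = rep(c("Pollard walk", "Malaise trap"), each = nrow(object)),
    incidence = c(object$pollard_sites, object$malaise_sites)
  ) |>
    dplyr::filter(.data$incidence > 0) |>
    dplyr::count(.data$method, .data$incidence)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$incidence, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "number of sites where observed", y = "species") +
    ggplot2::theme_minimal()
}

#' Per-site richness and diversity boxplots
#'
#' Boxplots of per-site species richness and Shannon diversity for both
#' structured methods, from a pooled survey table.
#'
#' @param survey A `lepisurv_survey` containing both methods.
#' @return A ggplot.
#' @export
plot_site_stats <- function(survey) {
  stats <- dplyr::bind_rows(
    per_site_stats(survey, "pollard"),
    per_site_stats(survey, "malaise")
  ) |>
    tidyr::pivot_longer(c("richness", "shannon_h"),
      names_to = "measure", values_to = "value"
    ) |>
    dplyr::mutate(measure = dplyr::recode(.data$measure,
      richness = "species richness", shannon_h = "Shannon H (nats)"
    ))
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
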