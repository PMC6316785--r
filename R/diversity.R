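#' Shannon diversity index
#'
#' Computes Shannon's H = -sum(p_i log p_i) in natural-log units (nats) over
#' the species with positive counts, where p_i is the relative abundance
#' count_i / total. H is 0 for a single species and at most log(S) for S
#' species, attained by the uniform composition; it is invariant to scaling
#' all counts by a common factor.
#'
#' @param counts Numeric vector of non-negative abundances; at least one must
#'   be positive.
#' @return Shannon's H in nats.
#' @examples
#' shannon_h(c(5, 5, 5, 5)) # log(4)
#' shannon_h(10)            # 0
#' @export
shannon_h <- function(counts) {
  if (length(counts) == 0 || any(is.na(counts)) || any(counts < 0)) {
    stop_validation("counts must be non-negative and non-missing")
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop_validation("at least one count must be positive")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Per-site richness and Shannon diversity for one survey method
#'
#' For each site surveyed by `method`, reports the species richness (number
#' of species with positive count) and Shannon's H of the site's abundance
#' vector. A site whose rows are all zero-count is reported with richness 0
#' and H missing (H is undefined without individuals); sites with exactly one
#' species have H = 0.
#'
#' @param survey A `lepisurv_survey` table.
#' @param method `"pollard"` or `"malaise"`.
#' @return A tibble with columns `site_id`, `method`, `richness`, `shannon_h`,
#'   one row per site appearing in `survey` under `method`.
#' @export
per_site_stats <- function(survey, method) {
  stopifnot(inherits(survey, "lepisurv_survey"))
  if (length(method) != 1 || !method %in% SURVEY_METHODS) {
    stop_config(paste0("unknown method; expected one of: ", paste(SURVEY_METHODS, collapse = ", ")))
  }
  survey |>
    dplyr::filter(.data$method == !!method) |>
    dplyr::group_by(site_id = .data$site_id) |>
    dplyr::summarise(
      method = !!method,
      richness = sum(.data$count > 0),
      shannon_h = if (sum(.data$count) > 0) shannon_h(.data$count) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$site_id)
}

#' Mean per-site species richness from an incidence summary
#'
#' The mean over sites of per-site richness equals the column sum of species
#' site-incidences divided by the number of sites: each species contributes 1
#' to the richness of exactly as many sites as its incidence. That identity
#' lets the per-site mean be recovered from incidence data alone, without the
#' unpublished per-site records. Only the structured methods have site
#' semantics; incidental observation counts are not site incidences, so
#' `source = "inat"` is an error.
#'
#' @param summary A `lepisurv_incidence` table.
#' @param source `"pollard"` or `"malaise"`.
#' @param sites Number of sites; defaults to [n_sites()] of `summary`.
#' @return Mean per-site richness (species).
#' @examples
#' mean_richness_from_incidence(load_incidence_summary(), "pollard") # 181/16
#' @export
mean_richness_from_incidence <- function(summary, source, sites = NULL) {
  stopifnot(inherits(summary, "lepisurv_incidence"))
  if (length(source) != 1 || !source %in% SURVEY_METHODS) {
    stop_config("source must be 'pollard' or 'malaise': incidental observation counts are observations, not site incidences")
  }
  sites <- sites %||% n_sites(summary)
  if (sites < 1) stop_config("sites must be >= 1")
  sum(incidence_column(summary, source)) / sites
}

incidence_column <- function(summary, source) {
  col <- switch(source,
    pollard = "pollard_sites", malaise = "malaise_sites", inat = "inat_observations",
    stop_config(paste0("unknown source '", source, "'"))
  )
  summary[[col]]
}

#' Pooled species richness of one data source
#'
#' Number of species with a positive entry for the source in a
#' species-by-source incidence summary.
#'
#' @param summary A `lepisurv_incidence` table.
#' @param source `"pollard"`, `"malaise"` or `"inat"`.
#' @return Integer species count.
#' @export
source_richness <- function(summary, source) {
  stopifnot(inherits(summary, "lepisurv_incidence"))
  sum(incidence_column(summary, source) > 0)
}

#' Singleton species of a structured survey method
#'
#' Counts species recorded at exactly one site under the given method --
#' the rare tail of the incidence distribution.
#'
#' @inheritParams mean_richness_from_incidence
#' @return Integer count of singleton species.
#' @export
singleton_count <- function(summary, source) {
  stopifnot(inherits(summary, "lepisurv_incidence"))
  if (length(source) != 1 || !source %in% SURVEY_METHODS) {
    stop_config("source must be 'pollard' or 'malaise'")
  }
  sum(incidence_column(summary, source) == 1)
}

#' Species exclusive to one data source
#'
#' Species with a positive entry for `source` and zero entries for every
#' other source.
#'
#' @param summary A `lepisurv_incidence` table.
#' @param source `"pollard"`, `"malaise"` or `"inat"`.
#' @return A tibble of the exclusive species (`family`, `species`).
#' @examples
#' exclusive_species(load_incidence_summary(), "inat")
#' @export
exclusive_species <- function(summary, source) {
  stopifnot(inherits(summary, "lepisurv_incidence"))
  if (!source %in% INCIDENCE_SOURCES) stop_config(paste0("unknown source '", source, "'"))
  others <- setdiff(INCIDENCE_SOURCES, source)
  keep <- incidence_column(summary, source) > 0
  for (o in others) keep <- keep & incidence_column(summary, o) == 0
  tibble(family = summary$family[keep], species = summary$species[keep])
}

#' Paired t-test between per-site values of two survey methods
#'
#' The standard paired design: a one-sample t-test on the site-wise
#' differences d = x - y, with t = mean(d) / (sd(d) / sqrt(n)), df = n - 1,
#' and a two-sided p-value. Values must be aligned by site; passing named
#' vectors (names = site ids) aligns them explicitly and errors on mismatched
#' site sets.
#'
#' @param x,y Numeric per-site values (e.g. per-site richness under two
#'   methods), equal length >= 2, optionally named by site id.
#' @return A `lepisurv_test` object with fields `statistic`, `df`, `p_value`,
#'   `mean_difference`, `method`; see [tidy()] and [glance()].
#' @examples
#' paired_t_test(c(4, 6, 8, 9), c(1, 2, 3, 4))
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  if (length(x) < 2) stop_validation("need at least 2 paired values")
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y))) stop_validation("x and y cover different sites")
    y <- y[names(x)]
  }
  d <- x - y
  if (isTRUE(all.equal(sd(d), 0)) || sd(d) == 0) {
    stop_degenerate("differences have zero variance; paired t-test undefined")
  }
  ht <- t.test(x, y, paired = TRUE, alternative = "two.sided")
  new_lepisurv_test(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, mean_difference = unname(ht$estimate),
    method = "paired t-test (one-sample on site-wise differences)"
  )
}

new_lepisurv_test <- function(statistic, df, p_value, mean_difference, method,
                              note = NULL) {
  structure(
    list(
      statistic = statistic, df = df, p_value = p_value,
      mean_difference = mean_difference, method = method, note = note
    ),
    class = "lepisurv_test"
  )
}

#' @export
print.lepisurv_test <- function(x, ...) {
  cat(x$method, "\n", sep = "")
  cat(sprintf(
    "t = %.4g, df = %s, p = %.4g, mean difference = %.4g\n",
    x$statistic, format(x$df), x$p_value, x$mean_difference
  ))
  if (!is.null(x$note)) cat("note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Tidy a lepisurv test result
#'
#' @param x A `lepisurv_test` object.
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `df`, `p_value`,
#'   `mean_difference`, `method`.
#' @method tidy lepisurv_test
#' @export
tidy.lepisurv_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    mean_difference = x$mean_difference, method = x$method
  )
}

#' @rdname tidy.lepisurv_test
#' @method glance lepisurv_test
#' @export
glance.lepisurv_test <- function(x, ...) tidy.lepisurv_test(x)
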