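# run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

draw_seed <- function() sample.int(.Machine$integer.max, 1L)

#' Per-site species sets for one survey method
#'
#' Collapses a survey table to the set of species with positive count at each
#' site -- the resampling unit of the site bootstrap.
#'
#' @param survey A `lepisurv_survey` table.
#' @param method `"pollard"` or `"malaise"`.
#' @return A named list of character vectors, one per site.
#' @export
site_species_sets <- function(survey, method) {
  stopifnot(inherits(survey, "lepisurv_survey"))
  if (length(method) != 1 || !method %in% SURVEY_METHODS) {
    stop_config("unknown method")
  }
  rows <- survey[survey$method == method & survey$count > 0, ]
  sites <- sort(unique(survey$site_id[survey$method == method]))
  sets <- lapply(sites, function(s) sort(unique(rows$species[rows$site_id == s])))
  setNames(sets, sites)
}

new_bootstrap_result <- function(source, unit, n_units, observed_richness,
                                 richness_values, seed) {
  structure(
    list(
      source = source, unit = unit, n_boot = length(richness_values),
      n_units = n_units, observed_richness = observed_richness,
      richness_values = as.integer(richness_values), seed = as.integer(seed)
    ),
    class = "lepisurv_bootstrap"
  )
}

#' Bootstrap pooled species richness over sites
#'
#' Generates a distribution of pooled species richness for a sample-based
#' survey method by resampling whole sites: each pseudoreplicate draws
#' `length(site_sets)` sites with replacement and records the size of the
#' union of their species sets. A pseudoreplicate can therefore never contain
#' a species absent from the observed data, and never exceeds the observed
#' pooled richness. Fully reproducible given `seed` (Mersenne-Twister); the
#' caller's RNG state is left untouched.
#'
#' @param site_sets Per-site species sets, as from [site_species_sets()];
#'   at least one site.
#' @param n_boot Number of pseudoreplicates (default 1000).
#' @param seed Integer RNG seed; if `NULL`, one is drawn from the current RNG
#'   stream and recorded in the result.
#' @param source Label carried into the result.
#' @return A `lepisurv_bootstrap` object; see [tidy.lepisurv_bootstrap()].
#' @examples
#' boot <- bootstrap_site_richness(
#'   list(a = c("x", "y"), b = c("y", "z")), n_boot = 100, seed = 1
#' )
#' mean(boot$richness_values)
#' @export
bootstrap_site_richness <- function(site_sets, n_boot = 1000, seed = NULL,
                                    source = "sites") {
  if (!is.list(site_sets) || length(site_sets) == 0) {
    stop_validation("site_sets must be a non-empty list of species sets")
  }
  if (n_boot < 1) stop_validation("n_boot must be >= 1")
  seed <- seed %||% draw_seed()
  sets <- lapply(site_sets, function(s) unique(as.character(s)))
  n <- length(sets)
  values <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      length(unique(unlist(sets[idx], use.names = FALSE)))
    }, integer(1))
  })
  new_bootstrap_result(
    source = source, unit = "site", n_units = n,
    observed_richness = length(unique(unlist(sets, use.names = FALSE))),
    richness_values = values, seed = seed
  )
}

#' Bootstrap pooled species richness over individual observations
#'
#' The observation-based analogue of [bootstrap_site_richness()] for
#' presence-only incidental data, where the resampling unit is the single
#' observation: each pseudoreplicate draws `length(species)` records with
#' replacement and records the number of distinct species drawn.
#'
#' @param species Character vector of the species label of every observed
#'   record (one element per record, repeats expected).
#' @inheritParams bootstrap_site_richness
#' @return A `lepisurv_bootstrap` object.
#' @export
bootstrap_observation_richness <- function(species, n_boot = 1000, seed = NULL,
                                           source = "observations") {
  species <- as.character(species)
  if (length(species) == 0) stop_validation("need at least one observation")
  if (n_boot < 1) stop_validation("n_boot must be >= 1")
  seed <- seed %||% draw_seed()
  n <- length(species)
  values <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      length(unique(species[sample.int(n, n, replace = TRUE)]))
    }, integer(1))
  })
  new_bootstrap_result(
    source = source, unit = "observation", n_units = n,
    observed_richness = length(unique(species)),
    richness_values = values, seed = seed
  )
}

#' Compare two bootstrap richness distributions
#'
#' A two-sample t-test between the pseudoreplicate richness values of two
#' bootstrap results (pooled-variance by default, matching the equal-variance
#' convention of the paired comparisons; Welch via `var_equal = FALSE`).
#' Alternatively, `b` may be a single observed richness value, in which case
#' a one-sample t-test of `a`'s distribution against that value is run.
#'
#' The p-value is flagged as anti-conservative in the result's `note`:
#' bootstrap pseudoreplicates are not independent samples, so these tests
#' mirror a common field procedure rather than a calibrated inference.
#'
#' @param a A `lepisurv_bootstrap`.
#' @param b A `lepisurv_bootstrap`, or a single numeric richness value.
#' @param var_equal Pool the variances? Default `TRUE`.
#' @return A `lepisurv_test` with `mean_difference = mean(a) - mean(b)`.
#' @export
compare_bootstrap <- function(a, b, var_equal = TRUE) {
  stopifnot(inherits(a, "lepisurv_bootstrap"))
  note <- "p-value is anti-conservative: bootstrap pseudoreplicates are not independent samples"
  if (is.numeric(b) && length(b) == 1) {
    if (a$n_boot < 2) stop_validation("need n_boot >= 2")
    if (sd(a$richness_values) == 0) {
      stop_degenerate("bootstrap distribution is constant; t-test undefined")
    }
    ht <- t.test(a$richness_values, mu = b, alternative = "two.sided")
    return(new_lepisurv_test(
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p_value = ht$p.value, mean_difference = mean(a$richness_values) - b,
      method = sprintf("one-sample t-test: bootstrap richness of '%s' vs observed %g", a$source, b),
      note = note
    ))
  }
  stopifnot(inherits(b, "lepisurv_bootstrap"))
  if (a$n_boot < 2 || b$n_boot < 2) stop_validation("need n_boot >= 2 in both results")
  if (sd(c(a$richness_values - mean(a$richness_values),
           b$richness_values - mean(b$richness_values))) == 0) {
    stop_degenerate("both bootstrap distributions are constant; t-test undefined")
  }
  ht <- t.test(a$richness_values, b$richness_values,
               var.equal = isTRUE(var_equal), alternative = "two.sided")
  new_lepisurv_test(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_difference = mean(a$richness_values) - mean(b$richness_values),
    method = sprintf(
      "two-sample t-test (%s): bootstrap richness of '%s' vs '%s'",
      if (isTRUE(var_equal)) "pooled variance" else "Welch", a$source, b$source
    ),
    note = note
  )
}

#' @export
print.lepisurv_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Bootstrap pooled richness: source '%s', %d pseudoreplicates over %d %ss (seed %d)\n",
    x$source, x$n_boot, x$n_units, x$unit, x$seed
  ))
  cat(sprintf(
    "observed richness %d; pseudoreplicate mean %.3f, sd %.3f\n",
    x$observed_richness, mean(x$richness_values), sd(x$richness_values)
  ))
  invisible(x)
}

#' Tidy and summarise bootstrap results
#'
#' `tidy()` returns one row per pseudoreplicate; `glance()` one summary row
#' (mean, sd, quantiles of the richness distribution).
#'
#' @param x A `lepisurv_bootstrap`.
#' @param ... Unused.
#' @method tidy lepisurv_bootstrap
#' @export
tidy.lepisurv_bootstrap <- function(x, ...) {
  tibble(
    source = x$source, replicate = seq_len(x$n_boot),
    richness = x$richness_values
  )
}

#' @rdname tidy.lepisurv_bootstrap
#' @method glance lepisurv_bootstrap
#' @export
glance.lepisurv_bootstrap <- function(x, ...) {
  q <- stats::quantile(x$richness_values, c(0.025, 0.5, 0.975), names = FALSE)
  tibble(
    source = x$source, unit = x$unit, n_boot = x$n_boot, n_units = x$n_units,
    observed_richness = x$observed_richness,
    mean_richness = mean(x$richness_values), sd_richness = sd(x$richness_values),
    q025 = q[1], median = q[2], q975 = q[3], seed = x$seed
  )
}
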