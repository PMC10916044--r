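# broom-style accessors for fitted objects.

#' Tidy a row-linear consensus fit
#'
#' @param x a `rowlinear_fit` tibble.
#' @param ... unused.
#' @return tibble with one row per (site, platform): `site`, `platform`,
#'   `term` columns flattened as `alpha`, `sensitivity`, `precision`,
#'   `n_samples`.
#' @export
tidy.rowlinear_fit <- function(x, ...) {
  as_tibble(unclass(x))
}

#' One-row-per-platform summary of a row-linear fit
#'
#' @param x a `rowlinear_fit` tibble.
#' @param ... unused.
#' @return tibble per platform: mean/median sensitivity, median
#'   precision, number of sites.
#' @export
glance.rowlinear_fit <- function(x, ...) {
  as_tibble(unclass(x)) |>
    group_by(.data$platform) |>
    summarise(n_sites = dplyr::n_distinct(.data$site),
              mean_sensitivity = mean(.data$sensitivity),
              median_sensitivity = median(.data$sensitivity),
              median_precision = median(.data$precision),
              .groups = "drop")
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
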