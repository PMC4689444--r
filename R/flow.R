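# Nuclear DNA content from flow cytometry. Sample nuclei are co-stained
# with an internal standard of known 2C DNA amount; the ratio of G0/G1
# fluorescence peak means, scaled by the standard's 2C value, gives the
# sample's 2C amount in picograms, converted to genome length with the
# standard relation 1 pg ~ 978 Mbp.

#' Shipped internal flow-cytometry standards
#'
#' 2C DNA amounts (pg) of the common internal standards: chicken red blood
#' cells, soybean, rice (cv. Nipponbare) and Arabidopsis.
#'
#' @return Named numeric vector of 2C values in picograms.
#' @export
flow_standards <- function() {
  c(chicken_rbc = 2.5, soybean = 2.45, rice = 0.96, arabidopsis = 0.36)
}

#' Estimate 2C DNA content from peak-mean replicates
#'
#' For each replicate, `2C = (sample peak mean / standard peak mean) *
#' standard 2C pg`; replicates (all genotypes pooled, equally weighted)
#' give the mean and standard deviation. The estimate is scale-invariant:
#' rescaling all fluorescence values leaves it unchanged.
#'
#' @param data Tibble with columns `sample_label`, `sample_peak_mean`,
#'   `standard_peak_mean`, and either `standard_name` (one of
#'   [flow_standards()]) or `standard_2c_pg`.
#' @param pg_per_mbp_constant Mbp per pg used for the genome-size column
#'   (default 978).
#' @return A `flow_estimate` object; `tidy()` returns the per-sample
#'   table (`sample_label`, `n_replicates`, `mean_2c_pg`, `sd_2c_pg`,
#'   `size_1n_mbp`).
#' @export
#' @examples
#' tidy(estimate_2c(tibble::tibble(
#'   sample_label = "black walnut",
#'   standard_name = "chicken_rbc",
#'   sample_peak_mean = c(142, 141, 143, 142),
#'   standard_peak_mean = c(250, 249, 251, 250))))
estimate_2c <- function(data, pg_per_mbp_constant = 978) {
  stopifnot(all(c("sample_label", "sample_peak_mean",
                  "standard_peak_mean") %in% names(data)))
  if (!"standard_2c_pg" %in% names(data)) {
    std <- flow_standards()
    unknown <- setdiff(unique(data$standard_name), names(std))
    if (length(unknown) > 0) {
      abort(paste0("unknown standard(s): ", paste(unknown, collapse = ", "),
                   "; supply standard_2c_pg for custom standards"))
    }
    data <- mutate(data, standard_2c_pg = std[.data$standard_name])
  }
  if (any(data$sample_peak_mean <= 0) || any(data$standard_peak_mean <= 0)) {
    abort("peak means must be positive")
  }
  est <- data %>%
    mutate(rep_2c_pg = .data$sample_peak_mean / .data$standard_peak_mean *
             .data$standard_2c_pg) %>%
    group_by(.data$sample_label) %>%
    summarise(n_replicates = n(),
              mean_2c_pg = mean(.data$rep_2c_pg),
              sd_2c_pg = stats::sd(.data$rep_2c_pg),
              .groups = "drop") %>%
    mutate(size_1n_mbp = pg_to_mbp(.data$mean_2c_pg,
                                   constant = pg_per_mbp_constant))
  structure(list(estimates = est, constant = pg_per_mbp_constant),
            class = "flow_estimate")
}

#' @export
tidy.flow_estimate <- function(x, ...) x$estimates

#' @export
glance.flow_estimate <- function(x, ...) {
  tibble(n_samples = nrow(x$estimates), pg_per_mbp_constant = x$constant)
}

#' @export
print.flow_estimate <- function(x, ...) {
  cat("Flow-cytometry 2C estimates (1 pg =", x$constant, "Mbp):\n")
  print(x$estimates)
  invisible(x)
}

#' Convert a 2C DNA amount to a haploid genome size
#'
#' `(pg_2c / 2) * constant`, rounded to the nearest Mbp, with the standard
#' relation of 978 Mbp per picogram.
#'
#' @param pg_2c 2C DNA amount in picograms (must be positive).
#' @param constant Mbp per pg (default 978).
#' @return Haploid (1n) genome size in Mbp, rounded to the nearest Mbp.
#' @export
#' @examples
#' pg_to_mbp(2.00)  # 978
pg_to_mbp <- function(pg_2c, constant = 978) {
  if (any(pg_2c <= 0)) abort("pg_2c must be positive")
  round(pg_2c / 2 * constant)
}

#' Average of literature genome-size estimates
#'
#' Arithmetic mean of published sizes, rounded to the nearest Mbp; used as
#' a rough size when a species has congeneric but no direct measurements.
#'
#' @param sizes_mbp Numeric vector of genome sizes in Mbp (nonempty).
#' @return Mean size in Mbp, rounded to the nearest Mbp.
#' @export
#' @examples
#' literature_average(c(905, 1614))
literature_average <- function(sizes_mbp) {
  if (length(sizes_mbp) == 0) abort("no sizes supplied")
  round(mean(sizes_mbp))
}
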