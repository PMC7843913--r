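#' Maximum achievable total of a scale
#'
#' Computed from the implemented band tables and component ranges, not
#' hard-coded: INCNS 44, GCS 15, FOUR 16, APACHE II 71 (creatinine points
#' doubled under acute renal failure contribute to the maximum).
#'
#' @param scale One of `"incns"`, `"gcs"`, `"four"`, `"apache2"`
#'   (case-insensitive; vectorized).
#' @return Integer vector of maxima.
#' @examples
#' max_score(c("incns", "apache2", "gcs", "four"))
#' @export
max_score <- function(scale) {
  vapply(tolower(scale), function(s) {
    switch(s,
      incns = sum(incns_item_max()),
      gcs = sum(vapply(.gcs_component_range, max, integer(1))),
      four = sum(vapply(.four_component_range, max, integer(1))),
      apache2 = {
        aps_max <- vapply(.apache2_bands, function(v) max(v$points), integer(1))
        aps_max <- aps_max[setdiff(names(aps_max), "pao2")] # one oxygenation route
        aps_max[["creatinine"]] <- aps_max[["creatinine"]] * 2L  # ARF doubling
        gcs_item_max <- 15L - sum(vapply(.gcs_component_range, min, integer(1)))
        sum(aps_max) + gcs_item_max + max(.apache2_age$points) +
          max(.apache2_chronic)
      },
      abort(paste0("unknown scale `", s, "`"))
    )
  }, integer(1), USE.NAMES = FALSE)
}

#' Orientation of a scale with respect to adverse outcome
#'
#' INCNS and APACHE II increase with severity (`"higher_is_positive"`); GCS
#' and FOUR decrease (`"lower_is_positive"`).
#'
#' @param scale Scale name(s), as in [max_score()].
#' @return Character vector of orientations.
#' @export
scale_orientation <- function(scale) {
  vapply(tolower(scale), function(s) {
    switch(s,
      incns = , apache2 = "higher_is_positive",
      gcs = , four = "lower_is_positive",
      abort(paste0("unknown scale `", s, "`"))
    )
  }, character(1), USE.NAMES = FALSE)
}
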