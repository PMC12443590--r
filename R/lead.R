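# Population statistics behind the paddle-lead geometry.

#' Lead length covering the hemodynamic hotspot for a population fraction
#'
#' Treats the targeted spinal segment lengths as independent normals, so
#' their sum is N(sum of means, sum of variances); the lead length covering
#' a fraction `coverage` of the population is the corresponding normal
#' quantile `sum(mean) + qnorm(coverage) * sqrt(sum(sd^2))`.
#'
#' @param mean_mm Per-segment mean lengths in mm (> 0).
#' @param sd_mm Per-segment standard deviations in mm (>= 0).
#' @param coverage Population fraction in (0, 1) (default 0.95).
#' @return Required length in mm.
#' @examples
#' coverage_length(c(20, 20, 20), c(1, 1, 1))  # 62.85 mm
#' @export
coverage_length <- function(mean_mm, sd_mm, coverage = 0.95) {
  if (length(mean_mm) < 1 || length(sd_mm) != length(mean_mm)) {
    stop("need matching non-empty mean and sd vectors", call. = FALSE)
  }
  if (any(mean_mm <= 0) || any(sd_mm < 0)) {
    stop("means must be > 0 and sds >= 0", call. = FALSE)
  }
  if (!is.finite(coverage) || coverage <= 0 || coverage >= 1) {
    stop("coverage must be in (0, 1)", call. = FALSE)
  }
  sum(mean_mm) + stats::qnorm(coverage) * sqrt(sum(sd_mm^2))
}

#' Normalized rostrocaudal electrode position
#'
#' Signed distance from the center of the hemodynamic hotspot, normalized
#' by the participant's spinal length measured from T9 to the conus.
#' Rostral displacement is positive.
#'
#' @param distance_mm Signed distance from the hotspot center in mm
#'   (rostral positive).
#' @param spinal_length_mm T9-to-conus spinal length in mm (> 0).
#' @return Dimensionless normalized position.
#' @examples
#' normalized_position(15, 150)  # 0.1
#' @export
normalized_position <- function(distance_mm, spinal_length_mm) {
  if (!is.finite(spinal_length_mm) || spinal_length_mm <= 0) {
    stop("spinal length must be > 0 mm", call. = FALSE)
  }
  distance_mm / spinal_length_mm
}

#' Read per-segment length statistics from CSV
#'
#' Expects columns `label`, `mean_mm`, `sd_mm`.
#'
#' @param path CSV path.
#' @return A data frame of segment statistics.
#' @export
read_segment_stats <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "mean_mm", "sd_mm")
  if (!all(need %in% names(df))) {
    stop("segment stats CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}
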