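#' Decision thresholds for prophage activity calls
#'
#' Bundles every tunable cutoff of the activity decision into one validated
#' configuration object. The defaults are deliberately conservative: a
#' prophage must show at least twice the host's mean coverage, with a medium
#' or larger effect size, before it is considered active.
#'
#' @param min_ratio Minimum prophage/host mean coverage ratio for an active
#'   call. Default 2.0; can be reduced to 1.75 for increased sensitivity.
#'   Must be > 1.
#' @param min_effect Minimum Cohen's d effect size (magnitude) of the
#'   coverage difference. Default 0.70, the lower bound of a "medium" effect.
#' @param min_prophage_mean Minimum mean read depth over the prophage region
#'   for the prophage to be considered present in the sample. Default 1.0.
#' @param min_breadth Minimum fraction of prophage positions with depth >= 1.
#'   Default 0.50. Must lie in (0, 1].
#' @param min_region_len Minimum length, in nucleotides, of both the prophage
#'   region and the residual host region after masking. Default 1000.
#' @param mask_len Number of coverage values masked (excluded from all
#'   statistics) at each scaffold end, in nucleotides. Default 150,
#'   a generalized short-read length; set to the actual read length to trim
#'   by read length instead. 0 disables masking.
#' @param min_identity Minimum alignment percent identity for a read to be
#'   retained, in [0, 100]. Default 97.
#'
#' @return An object of class \code{activity_thresholds}: a named list with
#'   the fields above.
#'
#' @details All threshold comparisons downstream are closed bounds: a value
#'   exactly at the cutoff passes.
#'
#' @examples
#' activity_thresholds()
#' activity_thresholds(min_ratio = 1.75)  # sensitive setting
#' @export
activity_thresholds <- function(min_ratio = 2.0,
                                min_effect = 0.70,
                                min_prophage_mean = 1.0,
                                min_breadth = 0.50,
                                min_region_len = 1000,
                                mask_len = 150,
                                min_identity = 97) {
  stopifnot(is.numeric(min_ratio), length(min_ratio) == 1L,
            is.numeric(min_effect), length(min_effect) == 1L,
            is.numeric(min_prophage_mean), length(min_prophage_mean) == 1L,
            is.numeric(min_breadth), length(min_breadth) == 1L,
            is.numeric(min_region_len), length(min_region_len) == 1L,
            is.numeric(mask_len), length(mask_len) == 1L,
            is.numeric(min_identity), length(min_identity) == 1L)
  if (min_ratio <= 1)
    stop("`min_ratio` must be > 1 (a ratio of 1 is the dormant expectation)")
  if (min_effect < 0)
    stop("`min_effect` must be >= 0")
  if (min_breadth <= 0 || min_breadth > 1)
    stop("`min_breadth` must lie in (0, 1]")
  if (min_region_len <= 0)
    stop("`min_region_len` must be > 0")
  if (mask_len < 0)
    stop("`mask_len` must be >= 0")
  if (min_identity < 0 || min_identity > 100)
    stop("`min_identity` must lie in [0, 100]")
  structure(list(min_ratio = as.numeric(min_ratio),
                 min_effect = as.numeric(min_effect),
                 min_prophage_mean = as.numeric(min_prophage_mean),
                 min_breadth = as.numeric(min_breadth),
                 min_region_len = as.integer(min_region_len),
                 mask_len = as.integer(mask_len),
                 min_identity = as.numeric(min_identity)),
            class = "activity_thresholds")
}

#' @export
print.activity_thresholds <- function(x, ...) {
  cat("Prophage activity thresholds:\n")
  cat(sprintf("  prophage/host coverage ratio >= %.2f\n", x$min_ratio))
  cat(sprintf("  Cohen's d effect size        >= %.2f\n", x$min_effect))
  cat(sprintf("  prophage mean coverage       >= %.2f\n", x$min_prophage_mean))
  cat(sprintf("  prophage coverage breadth    >= %.2f\n", x$min_breadth))
  cat(sprintf("  min prophage/host length     %d nt\n", x$min_region_len))
  cat(sprintf("  scaffold end mask            %d nt\n", x$mask_len))
  cat(sprintf("  read percent identity        >= %.1f\n", x$min_identity))
  invisible(x)
}
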