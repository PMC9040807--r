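#' Interior of a scaffold after end masking
#'
#' Coverage values at scaffold ends are unreliable, particularly on partial
#' metagenomic scaffolds, so a fixed number of positions at each end is
#' masked (excluded from every statistic; the underlying depths are never
#' altered).
#'
#' @param scaffold_length Scaffold length in nucleotides.
#' @param mask_len Positions masked at each end (default 150).
#' @return An \code{IRanges} of the interior positions
#'   \code{[mask_len + 1, L - mask_len]}, or \code{NULL} when no interior
#'   remains (scaffold unanalyzable).
#' @examples
#' interior_range(10000, 150)  # 9700 positions
#' @export
interior_range <- function(scaffold_length, mask_len = 150L) {
  L <- as.integer(scaffold_length)
  mask <- as.integer(mask_len)
  stopifnot(L >= 1L, mask >= 0L)
  if (L <= 2L * mask) return(NULL)
  IRanges::IRanges(mask + 1L, L - mask)
}

#' Segment the host region of a scaffold
#'
#' The host region is every interior position outside all prophage intervals,
#' treated as one cohesive sequence. Every prophage on the scaffold is
#' compared against this identical prophage-excluded host region, so
#' co-resident prophages never interfere with each other's statistics. The
#' host may flank a prophage on one or both sides.
#'
#' @param scaffold_length Scaffold length in nucleotides.
#' @param prophage_ranges \code{IRanges} of prophage intervals (1-based
#'   inclusive), or a data frame with \code{start}/\code{stop} columns.
#' @param mask_len End mask length (default 150).
#' @return An \code{IRanges} of host positions (possibly empty).
#' @export
segment_host <- function(scaffold_length, prophage_ranges, mask_len = 150L) {
  interior <- interior_range(scaffold_length, mask_len)
  if (is.null(interior))
    return(IRanges::IRanges())
  if (is.data.frame(prophage_ranges))
    prophage_ranges <- IRanges::IRanges(prophage_ranges$start,
                                        prophage_ranges$stop)
  IRanges::setdiff(interior, prophage_ranges)
}

#' Summary statistics of read depth over a region
#'
#' Mean, median, population standard deviation and breadth (fraction of
#' positions with depth >= 1) of per-nucleotide depth over exactly the given
#' positions, zero-coverage positions included.
#'
#' @param depth Integer (or numeric) per-nucleotide depth vector for the
#'   whole scaffold.
#' @param region \code{IRanges} of positions to summarize, or an integer
#'   vector of 1-based positions.
#' @return A \code{region_summary}: list with \code{mean}, \code{median},
#'   \code{sd}, \code{breadth}, \code{n_positions}.
#' @examples
#' summarize_region(c(0, 0, 10, 10), IRanges::IRanges(1, 4))
#' @export
summarize_region <- function(depth, region) {
  pos <- if (inherits(region, "IRanges")) {
    if (length(region) == 0L) integer() else
      base::sequence(IRanges::width(region), from = IRanges::start(region))
  } else as.integer(region)
  if (length(pos) == 0L)
    stop("cannot summarize an empty region")
  if (min(pos) < 1L || max(pos) > length(depth))
    stop("region positions fall outside the depth profile")
  d <- as.numeric(depth[pos])
  mu <- mean(d)
  structure(list(mean = mu,
                 median = stats::median(d),
                 sd = sqrt(mean((d - mu)^2)),
                 breadth = mean(d >= 1),
                 n_positions = length(d)),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf(
    "Region of %d positions: mean %.4f, median %.4f, sd %.4f, breadth %.4f\n",
    x$n_positions, x$mean, x$median, x$sd, x$breadth))
  invisible(x)
}

#' Prophage/host coverage ratio
#'
#' Mean prophage depth divided by mean host depth: near 1 for a dormant
#' prophage replicating passively with the host genome, above 1 when the
#' phage genome is independently replicating.
#'
#' @param prophage,host \code{region_summary} objects.
#' @return The ratio, or \code{NA} when the host region has zero mean
#'   coverage (the ratio is then undefined and the downstream call is
#'   "ambiguous").
#' @export
coverage_ratio <- function(prophage, host) {
  stopifnot(inherits(prophage, "region_summary"),
            inherits(host, "region_summary"))
  if (host$mean == 0) return(NA_real_)
  prophage$mean / host$mean
}

#' Cohen's d effect size of the coverage difference
#'
#' Standardized mean difference between host and prophage depth
#' distributions,
#' \deqn{d = \frac{|\bar X_{host} - \bar X_{prophage}|}
#'   {\sqrt{(S_{host}^2 + S_{prophage}^2)/2}},}
#' reported as a magnitude: the effect size gauges how significant the
#' coverage difference is, whichever region is higher. When both standard
#' deviations are zero, d is 0 for equal means and \code{Inf} (the limit of
#' the formula) for unequal means.
#'
#' @param host,prophage \code{region_summary} objects (or any lists with
#'   \code{mean} and \code{sd} fields).
#' @return Non-negative effect size.
#' @examples
#' cohens_d(list(mean = 10, sd = 5), list(mean = 20, sd = 5))  # 2
#' @export
cohens_d <- function(host, prophage) {
  pooled <- sqrt((host$sd^2 + prophage$sd^2) / 2)
  diff <- abs(host$mean - prophage$mean)
  if (pooled == 0) {
    if (diff == 0) return(0)
    return(Inf)
  }
  diff / pooled
}
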