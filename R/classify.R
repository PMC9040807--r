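#' Activity call from decision metrics
#'
#' The core decision tree over the four decision metrics. The coverage ratio
#' and effect size jointly decide activity; the prophage's minimum mean
#' coverage and breadth decide whether the prophage is present in the sample
#' at all. All comparisons are closed bounds (a value exactly at a cutoff
#' passes).
#'
#' \itemize{
#'   \item ratio and effect both pass: \code{"active"} when the
#'     presence gates (mean coverage, breadth) also pass, else
#'     \code{"ambiguous"};
#'   \item ratio or effect fails, presence gates fail: \code{"not present"}
#'     (insufficient evidence the prophage is in the sample);
#'   \item ratio or effect fails, presence gates pass: \code{"dormant"};
#'   \item ratio undefined (host region uncovered): \code{"ambiguous"} when
#'     the presence gates pass, \code{"not present"} otherwise — never
#'     \code{"active"}.
#' }
#'
#' @param ratio Prophage/host mean coverage ratio (\code{NA} if undefined).
#' @param effect Cohen's d effect size (magnitude).
#' @param prophage_mean Mean depth over the prophage region.
#' @param prophage_breadth Fraction of prophage positions with depth >= 1.
#' @param thresholds An [activity_thresholds()] object.
#' @return List with \code{category} (one of \code{"active"},
#'   \code{"ambiguous"}, \code{"dormant"}, \code{"not present"}) and
#'   \code{reason} (which criteria passed/failed).
#' @examples
#' t <- activity_thresholds()
#' classify_call(2.08, 1.55, 60, 1.0, t)$category  # "active"
#' classify_call(1.02, 0.10, 60, 1.0, t)$category  # "dormant"
#' @export
classify_call <- function(ratio, effect, prophage_mean, prophage_breadth,
                          thresholds = activity_thresholds()) {
  stopifnot(inherits(thresholds, "activity_thresholds"))
  present <- prophage_mean >= thresholds$min_prophage_mean &&
    prophage_breadth >= thresholds$min_breadth
  if (is.na(ratio)) {
    category <- if (present) "ambiguous" else "not present"
    return(list(category = category,
                reason = paste0("host region uncovered; ratio undefined",
                                if (!present) "; prophage coverage/breadth below minimum")))
  }
  metrics <- ratio >= thresholds$min_ratio && effect >= thresholds$min_effect
  tok <- c(sprintf("ratio %s", if (ratio >= thresholds$min_ratio) "pass" else "fail"),
           sprintf("effect %s", if (effect >= thresholds$min_effect) "pass" else "fail"),
           sprintf("coverage %s", if (prophage_mean >= thresholds$min_prophage_mean) "pass" else "fail"),
           sprintf("breadth %s", if (prophage_breadth >= thresholds$min_breadth) "pass" else "fail"))
  reason <- paste(tok, collapse = "; ")
  category <- if (metrics) {
    if (present) "active" else "ambiguous"
  } else if (!present) "not present" else "dormant"
  list(category = category, reason = reason)
}

#' Classify one prophage/host summary pair
#'
#' Computes the prophage/host coverage ratio and Cohen's d effect size from
#' the two region summaries and applies the decision tree of
#' [classify_call()].
#'
#' @param prophage,host \code{region_summary} objects for the prophage
#'   region and the prophage-excluded host region.
#' @param thresholds An [activity_thresholds()] object.
#' @return An \code{activity_result}: list with \code{ratio},
#'   \code{effect_size_d}, \code{category}, \code{reason},
#'   \code{prophage_summary}, \code{host_summary}.
#' @export
classify_activity <- function(prophage, host,
                              thresholds = activity_thresholds()) {
  stopifnot(inherits(prophage, "region_summary"),
            inherits(host, "region_summary"))
  ratio <- coverage_ratio(prophage, host)
  d <- cohens_d(host, prophage)
  call <- classify_call(ratio, d, prophage$mean, prophage$breadth, thresholds)
  structure(list(ratio = ratio, effect_size_d = d,
                 category = call$category, reason = call$reason,
                 prophage_summary = prophage, host_summary = host),
            class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("Prophage activity call: %s\n", x$category))
  cat(sprintf("  ratio %.4f, Cohen's d %.4f\n",
              if (is.na(x$ratio)) NA_real_ else x$ratio, x$effect_size_d))
  cat(sprintf("  prophage mean %.4f (breadth %.4f), host mean %.4f\n",
              x$prophage_summary$mean, x$prophage_summary$breadth,
              x$host_summary$mean))
  cat("  ", x$reason, "\n", sep = "")
  invisible(x)
}
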