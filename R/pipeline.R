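#' Estimate prophage activity from read coverage
#'
#' End-to-end pipeline: parse and validate prophage coordinates, obtain a
#' read alignment (either supplied as SAM/BAM or produced by an external
#' aligner from FASTA + FASTQ), filter reads by alignment percent identity,
#' extract per-nucleotide depth (zeros included), mask scaffold-end
#' coverage, segment the prophage-excluded host region, compute region
#' statistics, and call each prophage active, dormant, ambiguous or not
#' present. The core computation is deterministic: identical inputs give
#' identical results, regardless of thread count.
#'
#' @param coordinates Prophage coordinates: a path to a manual coordinate
#'   table or VIBRANT coordinate table/results directory (auto-detected from
#'   the header unless \code{coordinate_format} is given), or a
#'   \code{prophage_coords} data frame.
#' @param alignment Path to a pre-generated SAM or BAM alignment. Exactly
#'   one of \code{alignment} or \code{fasta} + \code{reads1} must be given.
#' @param fasta Path to the host scaffold FASTA (read-alignment mode).
#' @param reads1,reads2 FASTQ read paths for the alignment mode (single or
#'   paired; optionally gzipped).
#' @param thresholds An [activity_thresholds()] object.
#' @param coordinate_format \code{"auto"}, \code{"manual"} or
#'   \code{"vibrant"}.
#' @param aligner,threads Passed to [align_reads()] in read mode.
#' @param out_prefix Work-file prefix for alignment intermediates.
#' @return A \code{prophage_activity} object: list with \code{results} (one
#'   data-frame row per prophage, ordered by scaffold then start, holding
#'   coordinates, region statistics, ratio, Cohen's d, category and reason),
#'   \code{thresholds}, and \code{manifest} (input mode, coordinate source,
#'   read filter counts, per-category counts, stage timings).
#' @examples
#' \dontrun{
#' res <- estimate_activity("coords.tsv", alignment = "sample.bam")
#' summary(res)
#' write_activity_table(res, "activity.tsv")
#' }
#' @export
estimate_activity <- function(coordinates,
                              alignment = NULL,
                              fasta = NULL, reads1 = NULL, reads2 = NULL,
                              thresholds = activity_thresholds(),
                              coordinate_format = c("auto", "manual", "vibrant"),
                              aligner = "auto", threads = 1L,
                              out_prefix = tempfile("prophager_")) {
  coordinate_format <- match.arg(coordinate_format)
  read_mode <- !is.null(fasta) || !is.null(reads1)
  if (!is.null(alignment) && read_mode)
    stop("supply either a pre-generated alignment or FASTA + reads, not both")
  if (is.null(alignment) && !read_mode)
    stop("no read or alignment input supplied: ",
         "give `alignment` (SAM/BAM) or `fasta` + `reads1`")
  if (read_mode && (is.null(fasta) || is.null(reads1)))
    stop("read-alignment mode needs both `fasta` and `reads1`")

  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  coords <- .resolve_coordinates(coordinates, coordinate_format)
  coord_source <- attr(coords, "source") %||% "data.frame"
  tick("parse_coordinates")

  align_cmd <- NA_character_
  if (read_mode) {
    alignment <- align_reads(fasta, reads1, reads2, aligner = aligner,
                             threads = threads, out_prefix = out_prefix)
    align_cmd <- attr(alignment, "command")
    tick("align_reads")
  }
  bam <- .as_bam(alignment)
  scaffold_lengths <- scaffold_lengths_from_alignment(bam)

  scafset <- validate_coordinates(coords, scaffold_lengths, thresholds)
  tick("validate_coordinates")

  filtered <- filter_alignments(bam, min_identity = thresholds$min_identity)
  tick("filter_alignments")

  depth <- compute_depth(filtered, scaffold_lengths)
  tick("compute_depth")

  results <- classify_all(scafset, depth, thresholds)
  tick("classify")

  category_counts <- table(factor(results$category,
                                  levels = c("active", "ambiguous",
                                             "dormant", "not present")))
  manifest <- list(
    input_mode = if (read_mode) "reads+fasta" else "alignment",
    alignment_command = align_cmd,
    coordinate_source = coord_source,
    thresholds = thresholds,
    read_counts = filtered$counts,
    category_counts = as.list(category_counts),
    timings = as.list(timings))
  structure(list(results = results, thresholds = thresholds,
                 manifest = manifest),
            class = "prophage_activity")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.resolve_coordinates <- function(coordinates, coordinate_format) {
  if (is.data.frame(coordinates)) {
    stopifnot(all(c("prophage_id", "scaffold_id", "start", "stop") %in%
                    names(coordinates)))
    return(coordinates)
  }
  stopifnot(is.character(coordinates), length(coordinates) == 1L)
  if (!file.exists(coordinates))
    stop("coordinate input not found: ", coordinates)
  fmt <- coordinate_format
  if (fmt == "auto") {
    fmt <- if (dir.exists(coordinates)) "vibrant" else {
      header <- readLines(coordinates, n = 1L)
      if (grepl("nucleotide.start", header) ||
          grepl("nucleotide start", header, fixed = TRUE))
        "vibrant" else "manual"
    }
  }
  coords <- switch(fmt,
                   manual = read_prophage_table(coordinates),
                   vibrant = read_vibrant_table(coordinates))
  attr(coords, "source") <- fmt
  coords
}

#' Classify every admitted prophage on every scaffold
#'
#' Applies end masking, host segmentation and region summarization per
#' scaffold, then the activity decision per prophage. Prophages flagged
#' unanalyzable at validation are reported as \code{"not present"} with the
#' validation reason. Rows are ordered deterministically by scaffold id then
#' start.
#'
#' @param scafset A \code{scaffold_set} from [validate_coordinates()].
#' @param depth \code{depth_profiles} from [compute_depth()].
#' @param thresholds An [activity_thresholds()] object.
#' @return Data frame with one row per prophage: coordinates, region sizes,
#'   prophage and host mean/median/sd, prophage breadth, ratio, Cohen's d,
#'   category, reason.
#' @export
classify_all <- function(scafset, depth, thresholds = activity_thresholds()) {
  stopifnot(inherits(scafset, "scaffold_set"))
  n <- nrow(scafset)
  na <- rep(NA_real_, n)
  res <- data.frame(
    prophage_id = scafset$prophage_id, scaffold_id = scafset$scaffold_id,
    start = scafset$start, stop = scafset$stop,
    prophage_length = scafset$stop - scafset$start + 1L,
    host_length = rep(NA_integer_, n),
    prophage_mean = na, prophage_median = na, prophage_sd = na,
    host_mean = na, host_median = na, host_sd = na,
    prophage_breadth = na, ratio = na, cohens_d = na,
    category = rep("not present", n), reason = scafset$reason,
    stringsAsFactors = FALSE)
  if (n == 0L) return(res)

  for (sc in unique(scafset$scaffold_id)) {
    idx <- which(scafset$scaffold_id == sc)
    live <- idx[scafset$analyzable[idx]]
    if (!length(live)) next
    prof <- depth[[sc]]
    if (is.null(prof))
      stop("no depth profile for scaffold ", sc)
    L <- scafset$scaffold_length[idx[1L]]
    all_iv <- IRanges::IRanges(scafset$start[idx], scafset$stop[idx])
    host_region <- segment_host(L, all_iv, thresholds$mask_len)
    host_sum <- summarize_region(prof, host_region)
    interior <- interior_range(L, thresholds$mask_len)
    for (i in live) {
      pro_region <- IRanges::intersect(
        IRanges::IRanges(scafset$start[i], scafset$stop[i]), interior)
      pro_sum <- summarize_region(prof, pro_region)
      ar <- classify_activity(pro_sum, host_sum, thresholds)
      res$host_length[i] <- host_sum$n_positions
      res$prophage_mean[i] <- pro_sum$mean
      res$prophage_median[i] <- pro_sum$median
      res$prophage_sd[i] <- pro_sum$sd
      res$host_mean[i] <- host_sum$mean
      res$host_median[i] <- host_sum$median
      res$host_sd[i] <- host_sum$sd
      res$prophage_breadth[i] <- pro_sum$breadth
      res$ratio[i] <- ar$ratio
      res$cohens_d[i] <- ar$effect_size_d
      res$category[i] <- ar$category
      res$reason[i] <- ar$reason
    }
  }
  res[order(res$scaffold_id, res$start), , drop = FALSE]
}

#' Write the per-prophage results table
#'
#' Tab-separated, one row per prophage, stable column order, floating-point
#' values fixed at 4 decimals, \code{"NA"} for undefined values (e.g. the
#' ratio of a prophage that is not present). Re-running on identical inputs
#' produces a byte-identical file.
#'
#' @param x A \code{prophage_activity} object or the \code{results} data
#'   frame from one.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_activity_table <- function(x, path) {
  res <- if (inherits(x, "prophage_activity")) x$results else x
  num4 <- function(v) ifelse(is.na(v), "NA",
                             ifelse(is.infinite(v), "Inf",
                                    formatC(v, format = "f", digits = 4)))
  int0 <- function(v) ifelse(is.na(v), "NA", format(v, scientific = FALSE))
  cols <- c("prophage", "scaffold", "start", "stop", "prophage_length",
            "host_length", "prophage_mean_cov", "prophage_median_cov",
            "prophage_sd_cov", "host_mean_cov", "host_median_cov",
            "host_sd_cov", "prophage_cov_breadth", "prophage_host_ratio",
            "cohens_d", "activity", "reason")
  body <- paste(res$prophage_id, res$scaffold_id, int0(res$start),
                int0(res$stop), int0(res$prophage_length),
                int0(res$host_length), num4(res$prophage_mean),
                num4(res$prophage_median), num4(res$prophage_sd),
                num4(res$host_mean), num4(res$host_median),
                num4(res$host_sd), num4(res$prophage_breadth),
                num4(res$ratio), num4(res$cohens_d), res$category,
                res$reason, sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = "\t"), body), con)
  invisible(path)
}

#' Write a plain-text run log
#'
#' Records the manifest of a run: input mode, coordinate source, effective
#' thresholds, read filter counts, per-category prophage counts and stage
#' timings.
#'
#' @param x A \code{prophage_activity} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_run_log <- function(x, path) {
  stopifnot(inherits(x, "prophage_activity"))
  m <- x$manifest
  t <- x$thresholds
  rc <- m$read_counts
  lines <- c(
    "prophager run log",
    sprintf("input mode: %s", m$input_mode),
    sprintf("alignment command: %s", m$alignment_command),
    sprintf("coordinate source: %s", m$coordinate_source),
    sprintf("thresholds: min_ratio=%.2f min_effect=%.2f min_prophage_mean=%.2f min_breadth=%.2f min_region_len=%d mask_len=%d min_identity=%.1f",
            t$min_ratio, t$min_effect, t$min_prophage_mean, t$min_breadth,
            t$min_region_len, t$mask_len, t$min_identity),
    sprintf("alignment records: total=%d unmapped/secondary=%d no_NM=%d below_identity=%d retained=%d",
            rc$total, rc$excluded_unmapped_secondary, rc$missing_nm_tag,
            rc$below_identity, rc$retained),
    sprintf("calls: %s", paste(sprintf("%s=%d", names(m$category_counts),
                                       unlist(m$category_counts)),
                               collapse = " ")),
    sprintf("timings (s): %s", paste(sprintf("%s=%.3f", names(m$timings),
                                             unlist(m$timings)),
                                     collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.prophage_activity <- function(x, ...) {
  cc <- x$manifest$category_counts
  cat(sprintf("Prophage activity estimate: %d prophage(s) on %d scaffold(s)\n",
              nrow(x$results), length(unique(x$results$scaffold_id))))
  cat(sprintf("  active %d | ambiguous %d | dormant %d | not present %d\n",
              cc[["active"]], cc[["ambiguous"]], cc[["dormant"]],
              cc[["not present"]]))
  cat(sprintf("  thresholds: ratio >= %.2f, Cohen's d >= %.2f\n",
              x$thresholds$min_ratio, x$thresholds$min_effect))
  invisible(x)
}

#' @export
summary.prophage_activity <- function(object, ...) {
  print(object)
  res <- object$results
  if (nrow(res)) {
    cat("\nPer-prophage calls:\n")
    show <- res[, c("prophage_id", "scaffold_id", "ratio", "cohens_d",
                    "prophage_mean", "prophage_breadth", "category")]
    show$ratio <- round(show$ratio, 3)
    show$cohens_d <- round(show$cohens_d, 3)
    show$prophage_mean <- round(show$prophage_mean, 3)
    show$prophage_breadth <- round(show$prophage_breadth, 3)
    print(show, row.names = FALSE)
  }
  invisible(res)
}

#' @export
as.data.frame.prophage_activity <- function(x, ...) x$results
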