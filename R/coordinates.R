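#' Read a manual prophage coordinate table
#'
#' Parses the tab-separated manual coordinate dialect: a header line
#' \code{scaffold  fragment  start  stop} followed by one prophage per row.
#' Coordinates are 1-based inclusive, the convention of prophage-prediction
#' tools. Rows whose start exceeds their stop are treated as unordered
#' interval ends and swapped with a warning.
#'
#' @param path Path to the tab-separated coordinate file.
#' @return A \code{prophage_coords} data frame with columns
#'   \code{prophage_id}, \code{scaffold_id}, \code{start}, \code{stop}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("scaffold\tfragment\tstart\tstop",
#'              "scafA\tscafA_fragment_1\t2001\t4000"), tf)
#' read_prophage_table(tf)
#' @seealso [read_vibrant_table()] for VIBRANT result tables,
#'   [write_prophage_table()] for the inverse operation.
#' @export
read_prophage_table <- function(path) {
  if (!file.exists(path))
    stop("coordinate file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  required <- c("scaffold", "fragment", "start", "stop")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("coordinate file is missing required column(s): ",
         paste(missing, collapse = ", "),
         " (expected tab-separated header 'scaffold fragment start stop')")
  .finalize_coords(scaffold = tab$scaffold, fragment = tab$fragment,
                   start = tab$start, stop = tab$stop, path = path)
}

#' Read a VIBRANT integrated-prophage coordinate table
#'
#' Accepts either the coordinate table itself or a VIBRANT results directory,
#' in which case the \code{*integrated_prophage_coordinates*.tsv} file is
#' located inside it. The table's \code{nucleotide start} / \code{nucleotide
#' stop} columns are used; the \code{<scaffold>_fragment_<n>} naming
#' convention of the \code{fragment} column is preserved as the prophage id.
#'
#' @param path Path to a VIBRANT coordinate table (TSV) or to a VIBRANT
#'   results directory containing one.
#' @return A \code{prophage_coords} data frame (see [read_prophage_table()]).
#' @export
read_vibrant_table <- function(path) {
  if (!file.exists(path))
    stop("VIBRANT path not found: ", path)
  if (dir.exists(path)) {
    hits <- list.files(path, pattern = "integrated_prophage_coordinates.*\\.tsv$",
                       recursive = TRUE, full.names = TRUE)
    if (!length(hits))
      stop("no integrated prophage coordinate table (",
           "*integrated_prophage_coordinates*.tsv) found under ", path,
           "; alternatively supply a manual coordinate file ",
           "(columns: scaffold fragment start stop)")
    path <- hits[[1L]]
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  scol <- intersect(c("nucleotide start", "nucleotide_start"), names(tab))
  ecol <- intersect(c("nucleotide stop", "nucleotide_stop"), names(tab))
  if (!all(c("scaffold", "fragment") %in% names(tab)) ||
      !length(scol) || !length(ecol))
    stop("unrecognized VIBRANT column layout in ", path,
         " (need columns: scaffold, fragment, nucleotide start, nucleotide stop)")
  .finalize_coords(scaffold = tab$scaffold, fragment = tab$fragment,
                   start = tab[[scol[1L]]], stop = tab[[ecol[1L]]],
                   path = path)
}

# Shared validation/normalization for both coordinate dialects.
.finalize_coords <- function(scaffold, fragment, start, stop, path) {
  n <- length(fragment)
  if (n == 0L) {
    warning("zero prophages were supplied in ", path)
    out <- data.frame(prophage_id = character(), scaffold_id = character(),
                      start = integer(), stop = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("prophage_coords", "data.frame")
    return(out)
  }
  start_n <- suppressWarnings(as.numeric(start))
  stop_n <- suppressWarnings(as.numeric(stop))
  bad <- which(is.na(start_n) | is.na(stop_n) |
                 start_n != floor(start_n) | stop_n != floor(stop_n) |
                 start_n < 1 | stop_n < 1)
  if (length(bad))
    stop("non-integer or non-positive coordinates in ", path,
         " at data row(s): ", paste(bad, collapse = ", "),
         " (file line(s): ", paste(bad + 1L, collapse = ", "), ")")
  dup <- fragment[duplicated(fragment)]
  if (length(dup))
    stop("duplicate prophage fragment id(s): ",
         paste(unique(dup), collapse = ", "))
  swapped <- start_n > stop_n
  if (any(swapped)) {
    warning(sum(swapped), " row(s) had start > stop; interval ends swapped: ",
            paste(fragment[swapped], collapse = ", "))
    tmp <- start_n[swapped]
    start_n[swapped] <- stop_n[swapped]
    stop_n[swapped] <- tmp
  }
  out <- data.frame(prophage_id = as.character(fragment),
                    scaffold_id = as.character(scaffold),
                    start = as.integer(start_n),
                    stop = as.integer(stop_n),
                    stringsAsFactors = FALSE)
  class(out) <- c("prophage_coords", "data.frame")
  out
}

#' Write prophage coordinates in the manual table dialect
#'
#' @param coords A \code{prophage_coords} data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_prophage_table <- function(coords, path) {
  stopifnot(is.data.frame(coords),
            all(c("prophage_id", "scaffold_id", "start", "stop") %in%
                  names(coords)))
  lines <- c("scaffold\tfragment\tstart\tstop",
             sprintf("%s\t%s\t%d\t%d", coords$scaffold_id,
                     coords$prophage_id, as.integer(coords$start),
                     as.integer(coords$stop)))
  writeLines(lines, path)
  invisible(path)
}

#' Attach prophage coordinates to scaffolds and validate analyzability
#'
#' Groups coordinates by scaffold and applies the admission rules: the
#' prophage region and the residual host region (scaffold minus all prophage
#' intervals, minus the end masks) must each reach the minimum length.
#' Prophages failing a rule are flagged unanalyzable with an explicit reason
#' rather than dropped. Coordinates extending beyond the scaffold end are
#' clipped with a warning; overlapping prophage intervals on one scaffold are
#' an error, since the host-segmentation model assumes disjoint intervals.
#'
#' @param coords A \code{prophage_coords} data frame.
#' @param scaffold_lengths Named integer vector of scaffold lengths
#'   (names are scaffold ids), from the FASTA or the alignment header.
#' @param thresholds An [activity_thresholds()] object supplying
#'   \code{min_region_len} and \code{mask_len}.
#' @return A \code{scaffold_set} data frame: the input columns plus
#'   \code{scaffold_length}, \code{analyzable} (logical) and \code{reason}
#'   (character, \code{NA} when analyzable), ordered by scaffold then start.
#' @export
validate_coordinates <- function(coords, scaffold_lengths,
                                 thresholds = activity_thresholds()) {
  stopifnot(is.data.frame(coords), inherits(thresholds, "activity_thresholds"))
  unmatched <- setdiff(unique(coords$scaffold_id), names(scaffold_lengths))
  if (length(unmatched))
    stop("scaffold id(s) in coordinates absent from scaffold lengths: ",
         paste(unmatched, collapse = ", "))
  coords <- coords[order(coords$scaffold_id, coords$start), , drop = FALSE]
  L <- as.integer(scaffold_lengths[coords$scaffold_id])
  clip <- coords$stop > L | coords$start > L
  if (any(clip)) {
    warning("coordinate(s) beyond scaffold end clipped to the scaffold: ",
            paste(coords$prophage_id[clip], collapse = ", "))
    coords$stop <- pmin(coords$stop, L)
    coords$start <- pmin(coords$start, L)
  }

  mask <- thresholds$mask_len
  minlen <- thresholds$min_region_len
  analyzable <- rep(TRUE, nrow(coords))
  reason <- rep(NA_character_, nrow(coords))

  for (sc in unique(coords$scaffold_id)) {
    idx <- which(coords$scaffold_id == sc)
    len <- as.integer(scaffold_lengths[[sc]])
    iv <- IRanges::IRanges(coords$start[idx], coords$stop[idx])
    ov <- IRanges::findOverlaps(iv, drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov))
      stop("overlapping prophage intervals on scaffold ", sc, ": ",
           paste(coords$prophage_id[idx][unique(c(
             S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov)))],
             collapse = ", "),
           " (prophage regions must be disjoint)")
    interior <- interior_range(len, mask)
    if (is.null(interior)) {
      analyzable[idx] <- FALSE
      reason[idx] <- sprintf(
        "scaffold shorter than twice the %d nt end mask", mask)
      next
    }
    host <- IRanges::setdiff(interior, iv)
    host_len <- sum(IRanges::width(host))
    # per-prophage positions surviving the end mask (interior is one range)
    pro_len <- pmax(0L, pmin(coords$stop[idx], IRanges::end(interior)) -
                      pmax(coords$start[idx], IRanges::start(interior)) + 1L)
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (coords$stop[i] - coords$start[i] + 1L < minlen) {
        analyzable[i] <- FALSE
        reason[i] <- sprintf("prophage below %s", .fmt_kb(minlen))
      } else if (pro_len[k] < minlen) {
        analyzable[i] <- FALSE
        reason[i] <- sprintf("prophage region below %s after end masking",
                             .fmt_kb(minlen))
      } else if (host_len < minlen) {
        analyzable[i] <- FALSE
        reason[i] <- sprintf("host below %s", .fmt_kb(minlen))
      }
    }
  }
  coords$scaffold_length <- L
  coords$analyzable <- analyzable
  coords$reason <- reason
  class(coords) <- c("scaffold_set", "prophage_coords", "data.frame")
  attr(coords, "scaffold_lengths") <- scaffold_lengths
  coords
}

.fmt_kb <- function(n) {
  if (n %% 1000L == 0L) sprintf("%d kb", n %/% 1000L) else sprintf("%d nt", n)
}

#' Scaffold lengths from a FASTA file
#'
#' @param fasta Path to a (multi-record) FASTA file.
#' @return Named integer vector of sequence lengths.
#' @export
scaffold_lengths_from_fasta <- function(fasta) {
  Biostrings::fasta.seqlengths(fasta)
}

#' Scaffold lengths from a SAM/BAM header
#'
#' @param alignment Path to a SAM or BAM file.
#' @return Named integer vector of reference sequence lengths.
#' @export
scaffold_lengths_from_alignment <- function(alignment) {
  bam <- .as_bam(alignment)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]
  hdr$targets
}
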