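#' Alignment percent identity from column counts
#'
#' Percent identity of an aligned read is computed from the length of the
#' alignment in columns \code{l} (read bases plus gap columns), the number of
#' gap columns \code{g} (inserted plus deleted bases) and the number of
#' mismatched columns \code{m}:
#' \deqn{\mathrm{identity} = \frac{l - g - m}{l} \times 100\%}
#'
#' @param l Alignment length in columns; must be > 0.
#' @param g Gap columns (insertions + deletions); >= 0.
#' @param m Mismatch columns; >= 0. \code{g + m} must not exceed \code{l}.
#' @return Percent identity in [0, 100]. Vectorized over all arguments.
#' @examples
#' percent_identity(100, 1, 2)  # 97
#' @export
percent_identity <- function(l, g, m) {
  if (any(l <= 0))
    stop("percent identity undefined for alignment length l = 0")
  if (any(g < 0) || any(m < 0))
    stop("gap and mismatch counts must be >= 0")
  if (any(g + m > l))
    stop("g + m must not exceed the alignment length l")
  (l - g - m) / l * 100
}

# Convert SAM to (sorted) BAM if needed; BAM paths pass through.
.as_bam <- function(alignment) {
  stopifnot(length(alignment) == 1L, file.exists(alignment))
  first <- readBin(alignment, "raw", n = 2L)
  is_bgzf <- length(first) == 2L && first[1L] == as.raw(0x1f) &&
    first[2L] == as.raw(0x8b)
  if (is_bgzf) return(alignment)
  Rsamtools::asBam(alignment, destination = tempfile("prophager_aln"),
                   overwrite = TRUE, indexDestination = FALSE)
}

#' Align short reads to host scaffolds
#'
#' Thin orchestration over an external short-read aligner (bowtie2, bwa mem
#' or minimap2 short-read preset, whichever is first found on the PATH when
#' \code{aligner = "auto"}), producing a BAM file. All downstream computation
#' consumes standard SAM/BAM, so a user-supplied alignment is equivalent to
#' the output of this step. The aligner is run in its default end-to-end /
#' single-best-alignment mode and the exact command line is logged and
#' attached to the result.
#'
#' @param fasta Path to the host scaffold FASTA.
#' @param reads1 Path to FASTQ reads (single-end, interleaved, or mate 1).
#'   May be gzip-compressed.
#' @param reads2 Optional path to mate-2 FASTQ for paired input.
#' @param aligner One of \code{"auto"}, \code{"bowtie2"}, \code{"bwa"},
#'   \code{"minimap2"}.
#' @param threads Threads passed to the external aligner (the downstream
#'   depth arithmetic is single-threaded and thread-count invariant).
#' @param out_prefix Prefix for the index/SAM/BAM work files.
#' @return Path to the BAM file, with attribute \code{"command"} holding the
#'   logged aligner invocation.
#' @export
align_reads <- function(fasta, reads1, reads2 = NULL,
                        aligner = c("auto", "bowtie2", "bwa", "minimap2"),
                        threads = 1L, out_prefix = tempfile("prophager_aln")) {
  aligner <- match.arg(aligner)
  stopifnot(file.exists(fasta), file.exists(reads1))
  if (!is.null(reads2)) stopifnot(file.exists(reads2))
  for (rf in c(reads1, reads2)) {
    con <- if (grepl("\\.gz$", rf)) gzfile(rf, "rt") else file(rf, "rt")
    n <- length(readLines(con, n = 4L))
    close(con)
    if (n == 0L)
      stop("reads file is empty: ", rf)
  }
  if (aligner == "auto") {
    for (cand in c("bowtie2", "bwa", "minimap2")) {
      if (nzchar(Sys.which(cand))) { aligner <- cand; break }
    }
    if (aligner == "auto")
      stop("no supported read aligner found on PATH ",
           "(looked for bowtie2, bwa, minimap2)")
  }
  if (!nzchar(Sys.which(aligner)))
    stop("required aligner executable not found on PATH: ", aligner)

  sam <- paste0(out_prefix, ".sam")
  threads <- as.integer(threads)
  cmd <- switch(aligner,
    bowtie2 = {
      idx <- paste0(out_prefix, ".idx")
      st <- system2("bowtie2-build", c("--quiet", shQuote(fasta), shQuote(idx)),
                    stdout = FALSE, stderr = FALSE)
      if (st != 0L) stop("bowtie2-build failed with exit status ", st)
      args <- c("-x", shQuote(idx), "-p", threads, "-S", shQuote(sam),
                if (is.null(reads2)) c("-U", shQuote(reads1))
                else c("-1", shQuote(reads1), "-2", shQuote(reads2)))
      list(exe = "bowtie2", args = args, stdout = "")
    },
    bwa = {
      err <- tempfile()
      st <- system2("bwa", c("index", "-p", shQuote(out_prefix),
                             shQuote(fasta)), stdout = FALSE, stderr = err)
      if (st != 0L)
        stop("bwa index failed: ", paste(readLines(err), collapse = "\n"))
      args <- c("mem", "-t", threads, shQuote(out_prefix), shQuote(reads1),
                if (!is.null(reads2)) shQuote(reads2))
      list(exe = "bwa", args = args, stdout = sam)
    },
    minimap2 = {
      args <- c("-ax", "sr", "--secondary=no", "-t", threads, shQuote(fasta),
                shQuote(reads1), if (!is.null(reads2)) shQuote(reads2))
      list(exe = "minimap2", args = args, stdout = sam)
    })
  cmdline <- paste(cmd$exe, paste(cmd$args, collapse = " "))
  message("aligning reads: ", cmdline)
  err <- tempfile()
  status <- system2(cmd$exe, cmd$args, stdout = cmd$stdout, stderr = err)
  if (status != 0L)
    stop(cmd$exe, " exited with status ", status, ":\n",
         paste(readLines(err, warn = FALSE), collapse = "\n"))
  bam <- Rsamtools::asBam(sam, destination = paste0(out_prefix, ".sorted"),
                          overwrite = TRUE, indexDestination = FALSE)
  unlink(sam)
  structure(bam, command = cmdline)
}

#' Filter aligned reads by percent identity
#'
#' Reads the alignment, drops unmapped, secondary and supplementary records,
#' derives the percent-identity components per retained record from its CIGAR
#' string and \code{NM} (edit distance) tag, and removes records whose
#' identity falls below the threshold. The threshold is a closed lower bound:
#' a read at exactly \code{min_identity} is retained. Both mates of a pair
#' are treated as independent records; duplicate-marked reads are retained;
#' no mapping-quality filter is applied.
#'
#' @details Per record, the alignment length \code{l} counts CIGAR
#'   M/=/X/I/D columns (soft-clipped bases are not alignment columns), the
#'   gap count \code{g} is the inserted plus deleted bases (I + D), and the
#'   mismatch count \code{m} is the recorded edit distance minus \code{g}.
#'   Records lacking an \code{NM} tag cannot be scored and are excluded with
#'   a run-level warning.
#'
#' @param alignment Path to a SAM or BAM file.
#' @param min_identity Minimum percent identity, default 97.
#' @return A \code{filtered_alignments} object: list with
#'   \code{alignments} (a \code{GAlignments} of retained records),
#'   \code{identity} (their percent identities), and \code{counts}
#'   (total records, excluded unmapped/secondary/supplementary, records
#'   without an NM tag, records below the identity threshold, retained).
#' @export
filter_alignments <- function(alignment, min_identity = 97) {
  bam <- .as_bam(alignment)
  total <- Rsamtools::countBam(bam)$records
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, tag = "NM", what = "qname")
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  n_mapped <- length(gal)

  nm <- S4Vectors::mcols(gal)$NM
  no_tag <- is.na(nm)
  if (any(no_tag))
    warning(sum(no_tag), " aligned record(s) lack an NM tag and were ",
            "excluded from identity filtering")
  gal <- gal[!no_tag]
  nm <- nm[!no_tag]

  ops <- GenomicAlignments::cigarOpTable(GenomicAlignments::cigar(gal))
  l <- ops[, "M"] + ops[, "="] + ops[, "X"] + ops[, "I"] + ops[, "D"]
  g <- ops[, "I"] + ops[, "D"]
  m <- pmax(nm - g, 0L)
  pid <- percent_identity(l, g, m)

  keep <- pid >= min_identity
  structure(list(
    alignments = gal[keep],
    identity = pid[keep],
    counts = list(total = total,
                  excluded_unmapped_secondary = total - n_mapped,
                  missing_nm_tag = sum(no_tag),
                  below_identity = sum(!keep),
                  retained = sum(keep)),
    min_identity = min_identity),
    class = "filtered_alignments")
}

#' @export
print.filtered_alignments <- function(x, ...) {
  ct <- x$counts
  cat(sprintf(
    "Filtered alignments: %d retained of %d records (identity >= %.1f%%)\n",
    ct$retained, ct$total, x$min_identity))
  cat(sprintf("  excluded: %d unmapped/secondary/supplementary, %d without NM, %d below identity\n",
              ct$excluded_unmapped_secondary, ct$missing_nm_tag,
              ct$below_identity))
  invisible(x)
}

#' Per-read view of a filtered alignment
#'
#' @param x A \code{filtered_alignments} object.
#' @return Data frame with one row per retained record: reference id,
#'   1-based leftmost position, CIGAR, and percent identity.
#' @export
alignment_view <- function(x) {
  stopifnot(inherits(x, "filtered_alignments"))
  gal <- x$alignments
  data.frame(scaffold_id = as.character(GenomicAlignments::seqnames(gal)),
             pos = GenomicAlignments::start(gal),
             cigar = GenomicAlignments::cigar(gal),
             identity = x$identity,
             stringsAsFactors = FALSE)
}

#' Per-nucleotide depth profiles from retained reads
#'
#' Computes, for every scaffold, the number of retained reads whose aligned
#' read bases cover each nucleotide, zeros included. Deletion columns inside
#' a read do not contribute depth: only reference intervals consuming read
#' bases (CIGAR M/=/X) are counted.
#'
#' @param x A \code{filtered_alignments} object.
#' @param scaffold_lengths Named integer vector of scaffold lengths; every
#'   reference a read maps to must be present.
#' @return A named list of integer depth vectors (one per scaffold in
#'   \code{scaffold_lengths}, full length, zero-filled), class
#'   \code{depth_profiles}.
#' @export
compute_depth <- function(x, scaffold_lengths) {
  stopifnot(inherits(x, "filtered_alignments"))
  gal <- x$alignments
  refs <- as.character(GenomicAlignments::seqnames(gal))
  unknown <- setdiff(unique(refs), names(scaffold_lengths))
  if (length(unknown))
    stop("read(s) reference scaffold(s) absent from the lengths map: ",
         paste(unknown, collapse = ", "))

  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(gal), pos = GenomicAlignments::start(gal),
    ops = c("M", "=", "X"))
  flat <- unlist(blocks, use.names = FALSE)
  fac <- factor(rep(refs, S4Vectors::elementNROWS(blocks)),
                levels = names(scaffold_lengths))
  by_ref <- S4Vectors::split(flat, fac)

  out <- vector("list", length(scaffold_lengths))
  names(out) <- names(scaffold_lengths)
  for (sc in names(scaffold_lengths)) {
    out[[sc]] <- as.integer(IRanges::coverage(
      by_ref[[sc]], width = as.integer(scaffold_lengths[[sc]])))
  }
  structure(out, class = "depth_profiles")
}
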