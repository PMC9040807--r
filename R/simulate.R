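#' Define a synthetic prophage-coverage scenario
#'
#' A scenario describes one host scaffold with implanted prophage intervals
#' and a read-sampling process with a controlled prophage:host depth ratio:
#' read starts are drawn uniformly within the host region at a count giving
#' \code{host_depth} mean coverage, and uniformly within each prophage
#' interval at a count giving \code{ratio * host_depth}. A dormant prophage
#' corresponds to \code{ratio = 1} (one prophage genome copy per host
#' genome), an active one to \code{ratio > 1}, an absent one to
#' \code{ratio = 0}. Sampling is uniform by design: the statistics under
#' test assume no positional bias model.
#'
#' @param seed Integer seed; every sampling step is reproducible from it.
#' @param scaffold_length Host scaffold length in nucleotides.
#' @param prophage_intervals List of \code{c(start, stop)} 1-based inclusive
#'   intervals; must be disjoint, each at least 1 kb (the analysis floor),
#'   and within the scaffold.
#' @param host_depth Mean read depth over the host region (x coverage).
#' @param ratio True prophage/host depth ratio R >= 0.
#' @param read_length Read length in nucleotides (default 150).
#' @param substitution_rate Per-base substitution error probability
#'   (default 0; at 0 every simulated read aligns at 100\% identity).
#' @param paired Emit paired reads (fragments with two mates) instead of
#'   single-end reads.
#' @param insert_size Outer fragment length for paired mode (default 400).
#' @param scaffold_id Name of the simulated scaffold.
#' @return A \code{sim_scenario} list.
#' @examples
#' sim_scenario(seed = 1, ratio = 4)
#' @export
sim_scenario <- function(seed,
                         scaffold_length = 50000L,
                         prophage_intervals = list(c(20001L, 30000L)),
                         host_depth = 20,
                         ratio = 1,
                         read_length = 150L,
                         substitution_rate = 0,
                         paired = FALSE,
                         insert_size = 400L,
                         scaffold_id = "sim_scaffold") {
  L <- as.integer(scaffold_length)
  iv <- do.call(rbind, lapply(prophage_intervals, function(x)
    as.integer(x[1:2])))
  if (any(iv[, 1] > iv[, 2]) || any(iv[, 1] < 1L) || any(iv[, 2] > L))
    stop("scenario error: prophage interval outside the scaffold or reversed")
  if (any(iv[, 2] - iv[, 1] + 1L < 1000L))
    stop("scenario error: prophage interval shorter than the 1 kb analysis floor")
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1] <= iv[-nrow(iv), 2]))
    stop("scenario error: prophage intervals overlap")
  if (ratio < 0)
    stop("scenario error: ratio must be >= 0")
  if (host_depth <= 0)
    stop("scenario error: host_depth must be > 0")
  if (substitution_rate < 0 || substitution_rate >= 1)
    stop("scenario error: substitution_rate must lie in [0, 1)")
  structure(list(seed = as.integer(seed), scaffold_length = L,
                 prophage_intervals = iv, host_depth = host_depth,
                 ratio = ratio, read_length = as.integer(read_length),
                 substitution_rate = substitution_rate,
                 paired = isTRUE(paired),
                 insert_size = as.integer(insert_size),
                 scaffold_id = scaffold_id),
            class = "sim_scenario")
}

# Run code under a seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate the scenario's genome: FASTA plus coordinate table
#'
#' Writes a uniform-random A/C/G/T scaffold of the scenario's length and a
#' manual-dialect coordinate TSV for its prophage intervals. Byte-identical
#' across runs with the same scenario.
#'
#' @param scenario A [sim_scenario()] object.
#' @param dir Output directory (created if missing).
#' @return List with \code{fasta}, \code{coords} (paths), \code{sequence}
#'   (the scaffold as a character string) and \code{scenario}.
#' @export
sim_genome <- function(scenario, dir = tempfile("sim_genome_")) {
  stopifnot(inherits(scenario, "sim_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seq <- .with_seed(scenario$seed, paste(
    sample(c("A", "C", "G", "T"), scenario$scaffold_length, replace = TRUE),
    collapse = ""))
  fasta <- file.path(dir, "scaffolds.fasta")
  dna <- Biostrings::DNAStringSet(seq)
  names(dna) <- scenario$scaffold_id
  Biostrings::writeXStringSet(dna, fasta, width = 70L)
  iv <- scenario$prophage_intervals
  coords <- data.frame(
    prophage_id = sprintf("%s_fragment_%d", scenario$scaffold_id,
                          seq_len(nrow(iv))),
    scaffold_id = scenario$scaffold_id,
    start = iv[, 1], stop = iv[, 2], stringsAsFactors = FALSE)
  coords_path <- file.path(dir, "prophage_coordinates.tsv")
  write_prophage_table(coords, coords_path)
  list(fasta = fasta, coords = coords_path, sequence = seq,
       scenario = scenario)
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

# Draw read placements for a scenario: one row per SAM record.
.draw_reads <- function(scenario) {
  L <- scenario$scaffold_length
  rl <- scenario$read_length
  iv <- scenario$prophage_intervals
  pro_pos <- unlist(lapply(seq_len(nrow(iv)),
                           function(i) iv[i, 1]:iv[i, 2]), use.names = FALSE)
  host_pos <- setdiff(seq_len(L), pro_pos)

  if (scenario$paired) {
    ins <- scenario$insert_size
    stopifnot(ins >= rl)
    host_starts_ok <- host_pos[host_pos <= L - ins + 1L]
    n_host <- round(scenario$host_depth * length(host_pos) / (2 * rl))
    fs <- sample(host_starts_ok, n_host, replace = TRUE)
    for (i in seq_len(nrow(iv))) {
      wid <- iv[i, 2] - iv[i, 1] + 1L
      n_i <- round(scenario$ratio * scenario$host_depth * wid / (2 * rl))
      if (n_i > 0) {
        if (iv[i, 2] - ins + 1L < iv[i, 1])
          stop("scenario error: insert size exceeds a prophage interval")
        fs <- c(fs, sample(iv[i, 1]:(iv[i, 2] - ins + 1L), n_i,
                           replace = TRUE))
      }
    }
    n_frag <- length(fs)
    qname <- sprintf("frag_%06d", seq_len(n_frag))
    data.frame(qname = rep(qname, each = 2L),
               start = as.vector(rbind(fs, fs + ins - rl)),
               strand = rep(c("+", "-"), n_frag),
               mate = rep(c(1L, 2L), n_frag),
               stringsAsFactors = FALSE)
  } else {
    host_starts_ok <- host_pos[host_pos <= L - rl + 1L]
    n_host <- round(scenario$host_depth * length(host_pos) / rl)
    starts <- sample(host_starts_ok, n_host, replace = TRUE)
    for (i in seq_len(nrow(iv))) {
      wid <- iv[i, 2] - iv[i, 1] + 1L
      n_i <- round(scenario$ratio * scenario$host_depth * wid / rl)
      if (n_i > 0)
        starts <- c(starts, sample(iv[i, 1]:(iv[i, 2] - rl + 1L), n_i,
                                   replace = TRUE))
    }
    n <- length(starts)
    data.frame(qname = sprintf("read_%06d", seq_len(n)),
               start = starts,
               strand = sample(c("+", "-"), n, replace = TRUE),
               mate = rep(0L, n),
               stringsAsFactors = FALSE)
  }
}

#' Simulate reads for a scenario
#'
#' Emits FASTQ reads and/or a direct SAM alignment with exact coordinates
#' (CIGAR all-match, NM = number of substitutions introduced), the latter
#' allowing depth and statistics tests to bypass the external aligner. In
#' paired mode the FASTQ is a proper R1/R2 pair while the SAM carries both
#' mates as independent single-end records (depth counts mates
#' independently).
#'
#' @param scenario A [sim_scenario()] object.
#' @param genome Result of [sim_genome()] for the same scenario.
#' @param dir Output directory (created if missing).
#' @param formats Any of \code{"fastq"}, \code{"sam"}.
#' @return List with paths \code{fastq} (and \code{fastq2} when paired),
#'   \code{sam} (when requested), and \code{reads}, the placement table
#'   (qname, 1-based start, strand, substitution count per record).
#' @export
sim_reads <- function(scenario, genome, dir = tempfile("sim_reads_"),
                      formats = c("fastq", "sam")) {
  stopifnot(inherits(scenario, "sim_scenario"),
            identical(genome$scenario$seed, scenario$seed))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rl <- scenario$read_length

  reads <- .with_seed(scenario$seed + 1L, {
    tab <- .draw_reads(scenario)
    tab$nsub <- if (scenario$substitution_rate > 0)
      stats::rbinom(nrow(tab), rl, scenario$substitution_rate)
    else rep(0L, nrow(tab))
    tab$seq <- substring(genome$sequence, tab$start, tab$start + rl - 1L)
    mut <- which(tab$nsub > 0L)
    for (i in mut) {
      chars <- strsplit(tab$seq[i], "")[[1L]]
      at <- sample(rl, tab$nsub[i])
      chars[at] <- vapply(chars[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
      tab$seq[i] <- paste(chars, collapse = "")
    }
    tab
  })

  out <- list(reads = reads[, c("qname", "start", "strand", "nsub")])
  qual <- strrep("I", rl)
  if ("fastq" %in% formats) {
    read_seq <- ifelse(reads$strand == "+", reads$seq, .revcomp(reads$seq))
    if (scenario$paired) {
      m1 <- reads$mate == 1L
      fq1 <- file.path(dir, "reads_R1.fastq")
      fq2 <- file.path(dir, "reads_R2.fastq")
      writeLines(as.vector(rbind(paste0("@", reads$qname[m1]),
                                 read_seq[m1], "+", qual)), fq1)
      writeLines(as.vector(rbind(paste0("@", reads$qname[!m1]),
                                 read_seq[!m1], "+", qual)), fq2)
      out$fastq <- fq1
      out$fastq2 <- fq2
    } else {
      fq <- file.path(dir, "reads.fastq")
      writeLines(as.vector(rbind(paste0("@", reads$qname),
                                 read_seq, "+", qual)), fq)
      out$fastq <- fq
    }
  }
  if ("sam" %in% formats) {
    sam <- file.path(dir, "reads.sam")
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", scenario$scaffold_id,
                        scenario$scaffold_length))
    recs <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                    reads$qname, ifelse(reads$strand == "+", 0L, 16L),
                    scenario$scaffold_id, reads$start, rl, reads$seq, qual,
                    reads$nsub)
    writeLines(c(header, recs), sam)
    out$sam <- sam
  }
  out
}

#' Randomly subsample a FASTQ file (or pair)
#'
#' Keeps each read — or read pair, mates always kept or dropped together —
#' independently with the given probability, under a seed.
#'
#' @param fastq1 Input FASTQ path.
#' @param fraction Keep probability in (0, 1].
#' @param seed Integer seed.
#' @param fastq2 Optional mate-2 FASTQ; record i of both files is one pair.
#' @param out1,out2 Output paths (defaults next to a tempfile).
#' @return List with \code{fastq} (and \code{fastq2}), \code{n_in},
#'   \code{n_out}, and \code{kept_names} (read names retained, without the
#'   leading \code{@}).
#' @export
subsample_fastq <- function(fastq1, fraction, seed, fastq2 = NULL,
                            out1 = tempfile("subsample_", fileext = ".fastq"),
                            out2 = if (!is.null(fastq2))
                              tempfile("subsample_R2_", fileext = ".fastq")) {
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]")
  l1 <- readLines(fastq1)
  if (length(l1) %% 4L != 0L)
    stop("malformed FASTQ (line count not a multiple of 4): ", fastq1)
  n <- length(l1) %/% 4L
  keep <- if (fraction == 1) rep(TRUE, n)
  else .with_seed(seed, stats::runif(n) < fraction)
  sel <- rep(keep, each = 4L)
  writeLines(l1[sel], out1)
  out <- list(fastq = out1, n_in = n, n_out = sum(keep),
              kept_names = sub("^@", "",
                               sub("[/ ].*$", "", l1[seq(1L, by = 4L,
                                                         length.out = n)][keep])))
  if (!is.null(fastq2)) {
    l2 <- readLines(fastq2)
    if (length(l2) != length(l1))
      stop("paired FASTQ files differ in record count")
    writeLines(l2[sel], out2)
    out$fastq2 <- out2
  }
  out
}

# Subset a SAM file to records whose qname is in `qnames` (headers kept).
# Per-read alignment is independent of the other reads present, so this is
# the exact alignment of the corresponding subsampled read set.
.subset_sam <- function(sam_in, sam_out, qnames) {
  lines <- readLines(sam_in)
  is_header <- startsWith(lines, "@")
  qn <- sub("\t.*$", "", lines[!is_header])
  writeLines(c(lines[is_header], lines[!is_header][qn %in% qnames]), sam_out)
  invisible(sam_out)
}
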