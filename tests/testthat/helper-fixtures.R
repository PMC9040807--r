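# Fixture builders and independent brute-force oracles.
# The oracles deliberately avoid the package's depth/statistics machinery
# (and the Bioconductor CIGAR utilities it uses): they re-derive every
# quantity by walking CIGAR strings character by character.

# Write a SAM file from a read table. Columns: qname, flag, rname, pos,
# cigar, nm (NA = omit the NM tag).
write_sam_fixture <- function(path, lengths, reads) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lengths),
                      as.integer(lengths)))
  recs <- vapply(seq_len(nrow(reads)), function(i) {
    base <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                    reads$qname[i], reads$flag[i], reads$rname[i],
                    reads$pos[i], reads$cigar[i])
    if (!is.na(reads$nm[i])) paste0(base, sprintf("\tNM:i:%d", reads$nm[i]))
    else base
  }, character(1L))
  writeLines(c(header, recs), path)
  path
}

# Parse a CIGAR into (lengths, ops) without GenomicAlignments.
parse_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1L]]
  tokens <- regmatches(cigar, list(m))[[1L]]
  list(len = as.integer(sub("[A-Z=]$", "", tokens)),
       op = sub("^[0-9]+", "", tokens))
}

# Brute-force per-position depth recount: for every read, walk its CIGAR and
# increment every reference position consuming a read base (M, =, X).
brute_depth <- function(reads, lengths) {
  out <- lapply(lengths, function(L) integer(L))
  for (i in seq_len(nrow(reads))) {
    ref <- reads$rname[i]
    pos <- reads$pos[i]
    cg <- parse_cigar(reads$cigar[i])
    for (k in seq_along(cg$op)) {
      op <- cg$op[k]; len <- cg$len[k]
      if (op %in% c("M", "=", "X")) {
        for (p in pos:(pos + len - 1L)) out[[ref]][p] <- out[[ref]][p] + 1L
        pos <- pos + len
      } else if (op %in% c("D", "N")) {
        pos <- pos + len
      }
      # I, S, H, P consume no reference
    }
  }
  out
}

# Brute-force identity components from CIGAR + NM.
brute_identity <- function(cigar, nm) {
  cg <- parse_cigar(cigar)
  l <- sum(cg$len[cg$op %in% c("M", "=", "X", "I", "D")])
  g <- sum(cg$len[cg$op %in% c("I", "D")])
  m <- max(nm - g, 0L)
  (l - g - m) / l * 100
}

# Reference-consuming aligned bases (M/=/X) of one read, for conservation.
brute_ref_bases <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "=", "X")])
}

# Random gapless/indel read table on one scaffold, for oracle tests.
random_read_table <- function(n, L, scaffold = "scaf", with_indels = TRUE) {
  reads <- data.frame(qname = sprintf("r%04d", seq_len(n)),
                      flag = 0L, rname = scaffold, pos = 0L,
                      cigar = "", nm = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (with_indels && stats::runif(1) < 0.5) {
      m1 <- sample(20:60, 1L); m2 <- sample(20:60, 1L)
      gap <- sample(1:5, 1L)
      op <- sample(c("I", "D"), 1L)
      sclip <- if (stats::runif(1) < 0.3) sprintf("%dS", sample(1:8, 1L)) else ""
      cigar <- sprintf("%s%dM%d%s%dM", sclip, m1, gap, op, m2)
      span <- m1 + m2 + if (op == "D") gap else 0L
      nm_extra <- sample(0:3, 1L)
      nm <- gap + nm_extra
    } else {
      m1 <- sample(40:100, 1L)
      cigar <- sprintf("%dM", m1)
      span <- m1
      nm <- sample(0:4, 1L)
    }
    reads$pos[i] <- sample(seq_len(L - span), 1L)
    reads$cigar[i] <- cigar
    reads$nm[i] <- nm
  }
  reads
}

# Streaming (Welford) recomputation of mean/sd plus median/breadth, as an
# independent check of summarize_region.
streaming_summary <- function(values) {
  n <- 0L; mean <- 0; m2 <- 0; covered <- 0L
  for (v in values) {
    n <- n + 1L
    delta <- v - mean
    mean <- mean + delta / n
    m2 <- m2 + delta * (v - mean)
    if (v >= 1) covered <- covered + 1L
  }
  s <- sort(values)
  med <- if (n %% 2L == 1L) s[(n + 1L) %/% 2L]
  else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
  list(mean = mean, median = med, sd = sqrt(m2 / n), breadth = covered / n,
       n_positions = n)
}

# Small default thresholds for toy scaffolds (short regions allowed).
toy_thresholds <- function(...) {
  activity_thresholds(min_region_len = 10, mask_len = 0, ...)
}
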