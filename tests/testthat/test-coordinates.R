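test_that("manual coordinate tables parse, normalize and validate", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("scaffold\tfragment\tstart\tstop",
               "scafA\tscafA_fragment_1\t2001\t4000",
               "scafB\tscafB_fragment_1\t5000\t3000"), tf)
  expect_warning(coords <- read_prophage_table(tf), "swapped")
  expect_s3_class(coords, "prophage_coords")
  expect_equal(coords$prophage_id, c("scafA_fragment_1", "scafB_fragment_1"))
  expect_equal(coords$scaffold_id, c("scafA", "scafB"))
  expect_equal(coords$start, c(2001L, 3000L))  # reversed row normalized
  expect_equal(coords$stop, c(4000L, 5000L))

  # header only: empty collection plus a warning
  writeLines("scaffold\tfragment\tstart\tstop", tf)
  expect_warning(empty <- read_prophage_table(tf), "zero prophages")
  expect_equal(nrow(empty), 0L)

  # missing column named in the error
  writeLines(c("scaffold\tfragment\tstart", "a\tb\t1"), tf)
  expect_error(read_prophage_table(tf), "stop")

  # non-integer coordinates reported with row/line number
  writeLines(c("scaffold\tfragment\tstart\tstop",
               "scafA\tf1\t100x\t2000"), tf)
  expect_error(read_prophage_table(tf), "row")

  # duplicate fragment ids rejected
  writeLines(c("scaffold\tfragment\tstart\tstop",
               "scafA\tf1\t1\t2000", "scafA\tf1\t3000\t5000"), tf)
  expect_error(read_prophage_table(tf), "duplicate")
})

test_that("VIBRANT coordinate tables are located and parsed", {
  dir <- tempfile("vibrant_")
  dir.create(file.path(dir, "VIBRANT_results"), recursive = TRUE)
  tab <- file.path(dir, "VIBRANT_results",
                   "NODE_integrated_prophage_coordinates.tsv")
  writeLines(c(paste("scaffold", "fragment", "protein start", "protein stop",
                     "protein length", "nucleotide start", "nucleotide stop",
                     "nucleotide length", sep = "\t"),
               paste("NODE_12", "NODE_12_fragment_1", "3", "40", "38",
                     "10500", "48200", "37701", sep = "\t"),
               paste("NODE_12", "NODE_12_fragment_2", "60", "80", "21",
                     "52000", "60000", "8001", sep = "\t")), tab)
  # direct table path
  coords <- read_vibrant_table(tab)
  expect_equal(coords$prophage_id[1], "NODE_12_fragment_1")
  expect_equal(coords$start, c(10500L, 52000L))
  expect_equal(coords$stop, c(48200L, 60000L))
  # two fragments on one scaffold stay independent records
  expect_equal(coords$scaffold_id, c("NODE_12", "NODE_12"))
  # directory search finds the same table
  expect_equal(read_vibrant_table(dir), coords)
  # directory without a coordinate table suggests the manual format
  empty_dir <- tempfile("novibrant_")
  dir.create(empty_dir)
  expect_error(read_vibrant_table(empty_dir), "manual")
})

test_that("coordinate validation applies the 1 kb floors and bounds", {
  t <- activity_thresholds()
  coords <- data.frame(
    prophage_id = c("short", "hostless", "ok", "overhang"),
    scaffold_id = c("s1", "s2", "s3", "s4"),
    start = c(1001L, 1001L, 2001L, 95000L),
    stop = c(1800L, 2900L, 4000L, 101000L),
    stringsAsFactors = FALSE)
  lens <- c(s1 = 100000L, s2 = 3000L, s3 = 100000L, s4 = 100000L)
  expect_warning(set <- validate_coordinates(coords, lens, t), "clipped")
  set <- set[match(coords$prophage_id, set$prophage_id), ]
  expect_false(set$analyzable[1])
  expect_match(set$reason[1], "prophage below 1 kb")
  # s2: host after 150 nt masks = [151,1000] u [2901,2850] = 850 < 1000
  expect_false(set$analyzable[2])
  expect_match(set$reason[2], "host below 1 kb")
  expect_true(set$analyzable[3])
  expect_true(is.na(set$reason[3]))
  # clipped to scaffold end, still analyzable
  expect_equal(set$stop[4], 100000L)
  expect_true(set$analyzable[4])

  # unmatched scaffold ids are an error listing them
  expect_error(validate_coordinates(coords, lens[-1], t), "s1")

  # overlapping prophages on one scaffold are rejected
  ov <- data.frame(prophage_id = c("a", "b"), scaffold_id = "s",
                   start = c(2001L, 3500L), stop = c(4000L, 6000L),
                   stringsAsFactors = FALSE)
  expect_error(validate_coordinates(ov, c(s = 50000L), t), "overlap")
})

test_that("coordinates round-trip through the manual table format", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(1:6, 1)
    coords <- data.frame(
      prophage_id = sprintf("scaf%d_fragment_%d", seq_len(n), seq_len(n)),
      scaffold_id = sprintf("scaf%d", seq_len(n)),
      start = sample(1:5000, n),
      stop = 0L, stringsAsFactors = FALSE)
    coords$stop <- coords$start + sample(1000:9000, n)
    class(coords) <- c("prophage_coords", "data.frame")
    tf <- tempfile(fileext = ".tsv")
    write_prophage_table(coords, tf)
    again <- read_prophage_table(tf)
    expect_equal(as.data.frame(again), as.data.frame(coords))
  }
})

test_that("host segments plus prophage intervals tile the scaffold", {
  set.seed(7)
  for (rep in 1:20) {
    L <- sample(5000:20000, 1)
    n <- sample(1:3, 1)
    # lay out disjoint intervals left to right
    starts <- sort(sample(seq_len(L - 1500L), n))
    stops <- integer(n)
    ok <- TRUE
    for (i in seq_len(n)) {
      lo <- starts[i]
      hi <- min(L, lo + sample(1000:3000, 1))
      stops[i] <- hi
      if (i < n && hi >= starts[i + 1]) { ok <- FALSE; break }
    }
    if (!ok) next
    iv <- IRanges::IRanges(starts, stops)
    host <- segment_host(L, iv, mask_len = 0)
    host_pos <- unlist(lapply(seq_along(host), function(k)
      IRanges::start(host)[k]:IRanges::end(host)[k]))
    pro_pos <- unlist(lapply(seq_len(n), function(k) starts[k]:stops[k]))
    expect_equal(sort(c(host_pos, pro_pos)), seq_len(L))
    expect_length(intersect(host_pos, pro_pos), 0L)
  }
})
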