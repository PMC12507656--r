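test_that("reading a count matrix and metadata round-trips and validates", {
  dir <- withr::local_tempdir()
  m <- matrix(c(5L, 0L, 3L, 7L), 2,
              dimnames = list(c("s1", "s2"), c("o1", "o2")))
  md <- data.frame(sample_id = c("s1", "s2"), site = c("A", "A"),
                   year = c(2000, 2001))
  write.table(data.frame(id = rownames(m), m), file.path(dir, "c.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(md, file.path(dir, "md.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ot <- read_otu_table(file.path(dir, "c.tsv"), file.path(dir, "md.tsv"))
  expect_s3_class(ot, "otu_table")
  expect_equal(dim(ot$counts), c(2, 2))
  expect_equal(ot$samples$reads_total, c(8L, 7L))

  # transposed orientation is auto-detected
  write.table(data.frame(id = colnames(m), t(m)), file.path(dir, "ct.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ot2 <- read_otu_table(file.path(dir, "ct.tsv"), file.path(dir, "md.tsv"))
  expect_equal(ot2$counts, ot$counts)

  # full write/read round trip preserves counts and metadata exactly
  write_otu_table(ot, file.path(dir, "w.tsv"), file.path(dir, "wmd.tsv"))
  ot3 <- read_otu_table(file.path(dir, "w.tsv"), file.path(dir, "wmd.tsv"))
  expect_identical(ot3$counts, ot$counts)
  expect_identical(ot3$samples, ot$samples)
})

test_that("table construction rejects malformed input", {
  m <- matrix(c(-3L, 1L, 2L, 4L), 2,
              dimnames = list(c("s1", "s2"), c("o1", "o2")))
  md <- data.frame(sample_id = c("s1", "s2"), site = "A", year = 2000:2001)
  expect_error(otu_table(m, md), "negative count")
  m2 <- abs(m)
  expect_error(otu_table(m2, md[1, , drop = FALSE]), "s2")
  m3 <- m2; colnames(m3) <- c("o1", "o1")
  expect_error(otu_table(m3, md), "duplicate OTU id")
})

test_that("dataset filters apply the four retention rules in order", {
  # siteB sampled 4 years only -> removed by rule (1)
  sites <- c(rep("A", 6), rep("B", 4))
  years <- c(2001:2006, 2001:2004)
  counts <- matrix(100L, 10, 3,
                   dimnames = list(paste0(sites, "_", years), paste0("o", 1:3)))
  tb <- make_table(counts, sites, years)
  ft <- filter_dataset(tb)
  expect_setequal(unique(ft$samples$site), "A")
  expect_equal(attr(ft, "filter_log")$site_years, 4)

  # 10 sites, 2010 sampled at 4 of them (40% < 50%) -> year removed
  sites <- c(rep(paste0("s", 1:10), each = 5), paste0("s", 1:4))
  years <- c(rep(2001:2005, 10), rep(2010, 4))
  counts <- matrix(100L, length(sites), 2,
                   dimnames = list(paste0(sites, "_", years, "_",
                                          seq_along(sites)),
                                   c("o1", "o2")))
  tb <- otu_table(counts, data.frame(sample_id = rownames(counts),
                                     site = sites, year = years))
  ft <- filter_dataset(tb)
  expect_false(2010 %in% ft$samples$year)

  # isolation: retained years {1990, 1991, 1995} -> 1995 is > 2 from 1991
  sites <- rep("A", 3 * 5); yrs3 <- c(1990, 1991, 1995)
  sites <- rep(paste0("s", 1:5), each = 3)
  years <- rep(yrs3, 5)
  counts <- matrix(100L, length(sites), 2,
                   dimnames = list(paste0(sites, "_", years),
                                   c("o1", "o2")))
  tb <- otu_table(counts, data.frame(sample_id = rownames(counts),
                                     site = sites, year = years))
  ft <- filter_dataset(tb, filter_config(min_years_per_site = 3))
  expect_setequal(unique(ft$samples$year), c(1990, 1991))

  # read coverage: 40 reads when the median is 100 -> sample dropped
  sites <- rep("A", 6); years <- 2001:2006
  counts <- matrix(50L, 6, 2,
                   dimnames = list(paste0("A_", years), c("o1", "o2")))
  counts[6, ] <- c(30L, 10L)   # reads_total 40 vs median 100
  tb <- make_table(counts, sites, years)
  ft <- filter_dataset(tb)
  expect_equal(nrow(ft$counts), 5)
  expect_false("A_2006" %in% rownames(ft$counts))

  expect_error(
    filter_dataset(make_table(matrix(10L, 2, 2,
                                     dimnames = list(c("A_1", "A_2"), NULL)),
                              c("A", "A"), c(2001, 2002))),
    "no data survive")
})

test_that("filtering is idempotent", {
  tb <- make_rich_table(ns = 4, ny = 7, seed = 3)
  f1 <- filter_dataset(tb)
  f2 <- filter_dataset(f1)
  expect_identical(f1$counts, f2$counts)
  expect_identical(f1$samples, f2$samples)
})

test_that("presence threshold is inclusive and relative to sample depth", {
  counts <- matrix(c(5L, 10L, 0L, 99985L), 1, 4,
                   dimnames = list("A_2001", paste0("o", 1:4)))
  tb <- make_table(counts, "A", 2001)
  occ <- to_occurrence(tb, presence_threshold = 1e-4)
  # 5 reads of 100000 = 0.005% -> absent; 10 reads = 0.01% -> present
  expect_equal(as.integer(occ$mats$A["2001", ]), c(0L, 1L, 0L, 1L))

  expect_error(to_occurrence(make_table(
    matrix(0L, 1, 2, dimnames = list("A_2001", NULL)), "A", 2001)),
    "zero total reads")
})

test_that("replicate samples combine by union (default) or intersection", {
  counts <- rbind(c(100L, 0L, 900L), c(0L, 100L, 900L))
  rownames(counts) <- c("r1", "r2"); colnames(counts) <- paste0("o", 1:3)
  md <- data.frame(sample_id = c("r1", "r2"), site = "A", year = 2001)
  tb <- otu_table(counts, md)
  expect_equal(as.integer(to_occurrence(tb)$mats$A["2001", ]), c(1L, 1L, 1L))
  expect_equal(
    as.integer(to_occurrence(tb, replicates = "intersection")$mats$A["2001", ]),
    c(0L, 0L, 1L))
})

test_that("presence is monotone in counts", {
  set.seed(5)
  for (i in 1:20) {
    counts <- matrix(rpois(8, 40), 2, 4)
    counts[counts < 1] <- 1
    rownames(counts) <- c("A_2001", "A_2002")
    colnames(counts) <- paste0("o", 1:4)
    tb <- make_table(counts, c("A", "A"), c(2001, 2002))
    p1 <- to_occurrence(tb)$mats$A
    bumped <- counts; bumped[1, 2] <- bumped[1, 2] + 50L
    tb2 <- make_table(bumped, c("A", "A"), c(2001, 2002))
    p2 <- to_occurrence(tb2)$mats$A
    expect_gte(p2["2001", 2], p1["2001", 2])
  }
})

test_that("occurrence tensors round-trip through long TSV + sidecar", {
  occ <- random_occ(11)
  dir <- withr::local_tempdir()
  write_occurrence(occ, file.path(dir, "occ.tsv"),
                   filter_log = list(site_years = 0))
  occ2 <- read_occurrence(file.path(dir, "occ.tsv"))
  expect_identical(occ2$mats, occ$mats)
  expect_identical(occ2$otu_ids, occ$otu_ids)
})
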