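#' OTU read-count table with sample metadata
#'
#' Container for a metabarcoding OTU table: an integer count matrix with one
#' row per sample and one column per OTU, plus per-sample metadata (site and
#' calendar year). All downstream stages (filtering, presence/absence
#' conversion, diversity, inference) consume this object.
#'
#' @param counts integer matrix, samples in rows, OTUs in columns. Row and
#'   column names are required and must match `metadata$sample_id` and be
#'   unique, respectively.
#' @param metadata data frame with columns `sample_id`, `site`, `year`
#'   (calendar year), one row per sample.
#' @param year_range allowed range of calendar years, used for validation.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix), `samples` (data frame with `sample_id`, `site`,
#'   `year`, `reads_total`) and `otu_ids`.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 7L), 2, dimnames = list(c("s1", "s2"), c("o1", "o2")))
#' md <- data.frame(sample_id = c("s1", "s2"), site = "A", year = c(2000, 2001))
#' ot <- otu_table(m, md)
#' ot$samples$reads_total
#' @export
otu_table <- function(counts, metadata, year_range = c(1900L, 2100L)) {
  if (!is.matrix(counts)) stop2("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop2("`counts` must have sample row names and OTU column names")
  if (anyDuplicated(colnames(counts)))
    stop2("duplicate OTU id: ",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyDuplicated(rownames(counts))) stop2("duplicate sample id in counts")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop2("negative count or non-finite value in counts matrix")
  if (any(counts != round(counts))) stop2("non-integer count in counts matrix")
  storage.mode(counts) <- "integer"

  need <- c("sample_id", "site", "year")
  if (!all(need %in% names(metadata)))
    stop2("metadata must have columns ", paste(need, collapse = ", "))
  metadata$sample_id <- as.character(metadata$sample_id)
  missing_md <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing_md))
    stop2("sample(s) in counts missing from metadata: ",
          paste(missing_md, collapse = ", "))
  md <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  md$year <- as.integer(md$year)
  if (any(is.na(md$year)) || any(md$year < year_range[1]) || any(md$year > year_range[2]))
    stop2("sample year missing or outside [", year_range[1], ", ", year_range[2], "]")
  samples <- data.frame(
    sample_id   = md$sample_id,
    site        = as.character(md$site),
    year        = md$year,
    reads_total = as.integer(rowSums(counts)),
    stringsAsFactors = FALSE
  )
  structure(
    list(counts = counts, samples = samples, otu_ids = colnames(counts)),
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs\n")
  cat("  sites:", length(unique(x$samples$site)),
      " years:", min(x$samples$year), "-", max(x$samples$year), "\n")
  cat("  reads/sample: median", stats::median(x$samples$reads_total),
      " range", min(x$samples$reads_total), "-", max(x$samples$reads_total), "\n")
  invisible(x)
}

#' Read an OTU table and its sample metadata from tabular files
#'
#' The count file is a tab-separated matrix with OTU ids on one axis and
#' sample ids on the other; the orientation is auto-detected by matching
#' ids against the metadata. The metadata file (TSV or CSV, detected from
#' the extension) must contain columns `sample_id`, `site`, `year`.
#'
#' @param counts_path path to the count matrix (TSV, first column = row ids).
#' @param metadata_path path to the sample metadata table.
#' @param year_range allowed calendar-year range.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(counts_path, metadata_path, year_range = c(1900L, 2100L)) {
  if (!file.exists(counts_path)) stop2("counts file not found: ", counts_path)
  if (!file.exists(metadata_path)) stop2("metadata file not found: ", metadata_path)
  sep <- if (grepl("\\.csv$", metadata_path, ignore.case = TRUE)) "," else "\t"
  md <- utils::read.table(metadata_path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  raw <- utils::read.table(counts_path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  if (!is.numeric(m)) stop2("malformed count matrix: non-numeric entries")
  ids <- as.character(md$sample_id)
  # rows = samples wanted; transpose when samples sit in columns
  row_hits <- mean(rownames(m) %in% ids)
  col_hits <- mean(colnames(m) %in% ids)
  if (col_hits > row_hits) m <- t(m)
  otu_table(m, md, year_range = year_range)
}

#' Write an OTU table to tabular files
#'
#' Inverse of [read_otu_table()]: counts as a TSV matrix (samples in rows)
#' and metadata as TSV. Round-trips exactly.
#'
#' @param x an [otu_table()].
#' @param counts_path,metadata_path output paths.
#' @return `x`, invisibly.
#' @export
write_otu_table <- function(x, counts_path, metadata_path) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples[, c("sample_id", "site", "year")], metadata_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Dataset filtering configuration
#'
#' Defaults encode the standard retention rules for natural-sampler
#' time series: sites sampled in at least 5 distinct years; sampling years
#' covered by at least half of the retained sites; calendar years more than
#' 2 years away from every other retained year dropped as isolated; samples
#' with fewer than half the median read total dropped; an OTU counted as
#' present when it reaches at least 0.01% of the sample's reads.
#'
#' @param min_years_per_site minimum distinct sampled years per retained site.
#' @param min_site_fraction_per_year minimum fraction of retained sites a
#'   retained year must be sampled at, in (0, 1].
#' @param max_isolation_gap maximum tolerated distance (years) to the nearest
#'   other retained year.
#' @param min_read_fraction_of_median read-coverage cutoff relative to the
#'   median `reads_total`, in (0, 1].
#' @param presence_threshold relative-abundance presence cutoff (inclusive).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_years_per_site = 5L,
                          min_site_fraction_per_year = 0.5,
                          max_isolation_gap = 2L,
                          min_read_fraction_of_median = 0.5,
                          presence_threshold = 1e-4) {
  stopifnot(is_count(min_years_per_site), min_years_per_site >= 1,
            is_count(max_isolation_gap), max_isolation_gap >= 1)
  for (p in c(min_site_fraction_per_year, min_read_fraction_of_median, presence_threshold))
    if (!(is.numeric(p) && p > 0 && p <= 1)) stop2("proportions must lie in (0, 1]")
  structure(list(
    min_years_per_site = as.integer(min_years_per_site),
    min_site_fraction_per_year = min_site_fraction_per_year,
    max_isolation_gap = as.integer(max_isolation_gap),
    min_read_fraction_of_median = min_read_fraction_of_median,
    presence_threshold = presence_threshold
  ), class = "filter_config")
}

#' Apply the dataset retention rules to an OTU table
#'
#' One pass, in fixed order: (1) drop sites sampled in fewer than
#' `min_years_per_site` distinct years; (2) drop years sampled at fewer than
#' `min_site_fraction_per_year` of the retained sites; (3) drop years more
#' than `max_isolation_gap` years from their nearest retained neighbour
#' (evaluated on the pooled calendar years of the dataset); (4) drop samples
#' whose `reads_total` is below `min_read_fraction_of_median` times the
#' median read total of the samples surviving (1)-(3). Removal counts per
#' step are attached as attribute `filter_log` and logged.
#'
#' @param x an [otu_table()].
#' @param cfg a [filter_config()].
#' @return The filtered [otu_table()] with attribute `filter_log`.
#' @export
filter_dataset <- function(x, cfg = filter_config()) {
  stopifnot(inherits(x, "otu_table"), inherits(cfg, "filter_config"))
  sm <- x$samples
  keep <- rep(TRUE, nrow(sm))
  log <- list()

  # (1) site longevity
  yrs_per_site <- tapply(sm$year, sm$site, function(y) length(unique(y)))
  bad_sites <- names(yrs_per_site)[yrs_per_site < cfg$min_years_per_site]
  rm1 <- keep & sm$site %in% bad_sites
  keep <- keep & !rm1
  log$site_years <- sum(rm1)

  # (2) year coverage across retained sites
  n_sites <- length(unique(sm$site[keep]))
  site_per_year <- tapply(sm$site[keep], sm$year[keep], function(s) length(unique(s)))
  bad_years <- as.integer(names(site_per_year)[
    site_per_year < cfg$min_site_fraction_per_year * n_sites])
  rm2 <- keep & sm$year %in% bad_years
  keep <- keep & !rm2
  log$year_coverage <- sum(rm2)

  # (3) isolated calendar years, pooled across sites
  yrs <- sort(unique(sm$year[keep]))
  iso <- vapply(yrs, function(y) {
    others <- yrs[yrs != y]
    if (!length(others)) return(TRUE)
    min(abs(others - y)) > cfg$max_isolation_gap
  }, logical(1))
  rm3 <- keep & sm$year %in% yrs[iso]
  keep <- keep & !rm3
  log$isolated_years <- sum(rm3)

  # (4) read coverage, median over samples surviving (1)-(3)
  if (any(keep)) {
    med <- stats::median(sm$reads_total[keep])
    rm4 <- keep & sm$reads_total < cfg$min_read_fraction_of_median * med
    keep <- keep & !rm4
    log$read_coverage <- sum(rm4)
  } else log$read_coverage <- 0L

  if (!any(keep)) stop2("no data survive filters")
  ed_log("filter_dataset: removed ",
         paste(names(log), unlist(log), sep = "=", collapse = ", "),
         "; retained ", sum(keep), "/", nrow(sm), " samples")
  out <- otu_table(x$counts[keep, , drop = FALSE], sm[keep, , drop = FALSE])
  attr(out, "filter_log") <- log
  out
}

#' Convert a filtered OTU table to a binary occurrence tensor
#'
#' An OTU is scored present in a sample when its count is at least
#' `presence_threshold` of the sample's total reads (inclusive). Replicate
#' samples sharing a (site, year) cell are combined by union of presence
#' (default) or intersection.
#'
#' @param x a filtered [otu_table()]; samples with zero reads are an error.
#' @param presence_threshold relative-abundance cutoff in (0, 1).
#' @param replicates how to combine replicate samples within a (site, year)
#'   cell: `"union"` (default) or `"intersection"`.
#' @return An object of class `occ_tensor`: list with `otu_ids`, `scheme`
#'   (data frame of existing `site`, `year` cells) and `mats`, a named list
#'   (one entry per site) of binary integer matrices, years in rows (row
#'   names = calendar years) and OTUs in columns.
#' @export
to_occurrence <- function(x, presence_threshold = 1e-4, replicates = c("union", "intersection")) {
  stopifnot(inherits(x, "otu_table"))
  replicates <- match.arg(replicates)
  if (!(presence_threshold > 0 && presence_threshold < 1))
    stop2("presence_threshold must lie in (0, 1)")
  if (any(x$samples$reads_total == 0)) stop2("sample with zero total reads")
  rel <- x$counts / x$samples$reads_total
  pres <- (rel >= presence_threshold) * 1L
  sm <- x$samples
  sites <- sort(unique(sm$site))
  mats <- lapply(sites, function(s) {
    rows <- which(sm$site == s)
    yrs <- sort(unique(sm$year[rows]))
    m <- matrix(0L, length(yrs), ncol(pres), dimnames = list(yrs, colnames(pres)))
    for (i in seq_along(yrs)) {
      reps <- rows[sm$year[rows] == yrs[i]]
      block <- pres[reps, , drop = FALSE]
      m[i, ] <- if (replicates == "union") as.integer(colSums(block) > 0)
                else as.integer(colSums(block) == nrow(block))
    }
    m
  })
  names(mats) <- sites
  if (any(sm$site %in% sites & duplicated(sm[c("site", "year")])))
    ed_log("to_occurrence: replicate (site, year) samples combined by ", replicates)
  scheme <- do.call(rbind, lapply(sites, function(s)
    data.frame(site = s, year = as.integer(rownames(mats[[s]])),
               stringsAsFactors = FALSE)))
  structure(list(otu_ids = colnames(pres), scheme = scheme, mats = mats),
            class = "occ_tensor")
}

#' Construct an occurrence tensor directly from binary site matrices
#'
#' @param mats named list (by site) of binary matrices, years in row names,
#'   OTUs in columns (shared column order across sites).
#' @return An `occ_tensor`.
#' @export
occ_tensor <- function(mats) {
  stopifnot(is.list(mats), !is.null(names(mats)))
  ids <- colnames(mats[[1]])
  if (is.null(ids)) {
    ids <- paste0("otu", seq_len(ncol(mats[[1]])))
    mats <- lapply(mats, function(m) { colnames(m) <- ids; m })
  }
  for (m in mats) {
    stopifnot(identical(colnames(m), ids), !is.null(rownames(m)))
    if (!all(m %in% c(0L, 1L))) stop2("occurrence matrices must be binary")
  }
  mats <- lapply(mats, function(m) { storage.mode(m) <- "integer"; m })
  scheme <- do.call(rbind, lapply(names(mats), function(s)
    data.frame(site = s, year = as.integer(rownames(mats[[s]])),
               stringsAsFactors = FALSE)))
  structure(list(otu_ids = ids, scheme = scheme, mats = mats), class = "occ_tensor")
}

#' @export
print.occ_tensor <- function(x, ...) {
  cat("occ_tensor:", length(x$mats), "sites,", nrow(x$scheme), "site-year cells,",
      length(x$otu_ids), "OTUs\n")
  invisible(x)
}

#' Write an occurrence tensor as long-format TSV plus JSON sidecar
#'
#' The TSV holds one row per present (site, year, otu) triple with a
#' constant `present = 1` column; absences are implied by the sidecar, which
#' records the full OTU catalogue, the sampling scheme and (optionally) the
#' filter log, so [read_occurrence()] reconstructs the tensor exactly.
#'
#' @param occ an `occ_tensor`.
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @param filter_log optional list recorded in the sidecar.
#' @return `occ`, invisibly.
#' @export
write_occurrence <- function(occ, path, filter_log = NULL) {
  stopifnot(inherits(occ, "occ_tensor"))
  rows <- do.call(rbind, lapply(names(occ$mats), function(s) {
    m <- occ$mats[[s]]
    idx <- which(m == 1L, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(site = s, year = as.integer(rownames(m))[idx[, 1]],
               otu = colnames(m)[idx[, 2]], present = 1L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(site = character(), year = integer(),
                       otu = character(), present = integer())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(otu_ids = occ$otu_ids,
                  scheme = occ$scheme,
                  filter_log = filter_log)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(occ)
}

#' Read an occurrence tensor written by [write_occurrence()]
#'
#' @param path TSV path (sidecar expected at `<path>.json`).
#' @return An `occ_tensor`.
#' @export
read_occurrence <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  ids <- as.character(side$otu_ids)
  scheme <- side$scheme
  mats <- lapply(split(scheme, scheme$site), function(sc) {
    yrs <- sort(sc$year)
    m <- matrix(0L, length(yrs), length(ids), dimnames = list(yrs, ids))
    sub <- long[long$site == sc$site[1], , drop = FALSE]
    if (nrow(sub))
      m[cbind(match(sub$year, yrs), match(sub$otu, ids))] <- 1L
    m
  })
  occ_tensor(mats)
}
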