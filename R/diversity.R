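#' Local OTU richness of one (site, year) cell
#'
#' @param occ an `occ_tensor`.
#' @param site,year the cell; an error if the cell was not sampled.
#' @return Integer richness.
#' @export
alpha_richness <- function(occ, site, year) {
  m <- occ$mats[[as.character(site)]]
  if (is.null(m)) stop2("unknown site: ", site)
  i <- match(as.character(year), rownames(m))
  if (is.na(i)) stop2("cell (", site, ", ", year, ") was not sampled")
  sum(m[i, ])
}

#' Jaccard dissimilarity between two communities
#'
#' Full Jaccard distance (u_a + u_b) / (s + u_a + u_b) where `s` is the
#' number of shared OTUs and `u_a`, `u_b` the numbers unique to each side.
#' Presence/absence only.
#'
#' @param a,b binary vectors (or OTU-id character vectors) describing the
#'   two communities.
#' @return Numeric distance in `[0, 1]` with attribute `components`
#'   (named `s`, `u_a`, `u_b`). Both-empty input returns `NA` with a
#'   warning; such pairs are excluded from trend regressions upstream.
#' @examples
#' jaccard_distance(c("A", "B", "C"), c("B", "C", "D"))  # 0.5
#' @export
jaccard_distance <- function(a, b) {
  cmp <- pair_components(a, b)
  tot <- cmp["s"] + cmp["u_a"] + cmp["u_b"]
  if (tot == 0) {
    warning("Jaccard distance undefined for two empty communities")
    d <- NA_real_
  } else d <- unname((cmp["u_a"] + cmp["u_b"]) / tot)
  attr(d, "components") <- cmp
  d
}

#' Turnover component of the Jaccard dissimilarity
#'
#' Baselga's partition: beta_jtu = 2 min(u_a, u_b) / (s + 2 min(u_a, u_b)),
#' the species-replacement share of the full Jaccard distance; nested pairs
#' have zero turnover.
#'
#' @inheritParams jaccard_distance
#' @return Numeric turnover in `[0, 1]` (`NA` for two empty communities).
#' @export
jaccard_turnover <- function(a, b) {
  cmp <- pair_components(a, b)
  if (sum(cmp) == 0) {
    warning("Jaccard turnover undefined for two empty communities")
    return(NA_real_)
  }
  mu <- min(cmp["u_a"], cmp["u_b"])
  if (cmp["s"] + mu == 0) {
    # disjoint nonempty sets: pure replacement
    if (cmp["u_a"] > 0 && cmp["u_b"] > 0) return(1)
    return(0)
  }
  unname(2 * mu / (cmp["s"] + 2 * mu))
}

pair_components <- function(a, b) {
  if (is.character(a) || is.character(b)) {
    a <- unique(a); b <- unique(b)
    s <- length(intersect(a, b))
    c(s = s, u_a = length(a) - s, u_b = length(b) - s)
  } else {
    a <- as.logical(a); b <- as.logical(b)
    stopifnot(length(a) == length(b))
    c(s = sum(a & b), u_a = sum(a & !b), u_b = sum(!a & b))
  }
}

# all pairwise binary distances among rows of a binary matrix, via crossprod
pairwise_beta <- function(m, metric = c("jaccard", "turnover")) {
  metric <- match.arg(metric)
  sh <- tcrossprod(m)                 # shared counts
  rich <- rowSums(m)
  n <- nrow(m)
  ua <- matrix(rich, n, n) - sh       # unique to row i
  ub <- t(ua)
  if (metric == "jaccard") {
    tot <- sh + ua + ub
    d <- (ua + ub) / tot
    d[tot == 0] <- NA_real_
  } else {
    mu <- pmin(ua, ub)
    den <- sh + 2 * mu
    d <- 2 * mu / den
    d[den == 0 & (ua + ub) > 0 & ua > 0 & ub > 0] <- 1
    d[den == 0 & !(ua > 0 & ub > 0)] <- 0
    d[(sh + ua + ub) == 0] <- NA_real_
  }
  d
}

#' Temporal beta-diversity pairs at one site
#'
#' All unordered pairs of sampled years at a site, with the time lag and
#' the chosen dissimilarity.
#'
#' @param occ an `occ_tensor`.
#' @param site site id.
#' @param metric `"jaccard"` (full distance) or `"turnover"`.
#' @return Data frame with `site`, `year_a`, `year_b`, `lag`, `distance`.
#' @export
temporal_beta_pairs <- function(occ, site, metric = c("jaccard", "turnover")) {
  metric <- match.arg(metric)
  m <- occ$mats[[as.character(site)]]
  if (is.null(m)) stop2("unknown site: ", site)
  yrs <- as.integer(rownames(m))
  if (length(yrs) < 2)
    return(data.frame(site = character(), year_a = integer(), year_b = integer(),
                      lag = integer(), distance = numeric()))
  d <- pairwise_beta(m, metric)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  data.frame(site = as.character(site),
             year_a = yrs[idx[, 1]], year_b = yrs[idx[, 2]],
             lag = abs(yrs[idx[, 2]] - yrs[idx[, 1]]),
             distance = d[idx],
             stringsAsFactors = FALSE)
}

#' Spatial beta-diversity pairs in one year
#'
#' All unordered pairs of sites sampled in the given year.
#'
#' @param occ an `occ_tensor`.
#' @param year calendar year.
#' @inheritParams temporal_beta_pairs
#' @return Data frame with `site_a`, `site_b`, `year`, `distance`.
#' @export
spatial_beta_pairs <- function(occ, year, metric = c("jaccard", "turnover")) {
  metric <- match.arg(metric)
  year <- as.integer(year)
  sites <- occ$scheme$site[occ$scheme$year == year]
  if (length(sites) < 2)
    return(data.frame(site_a = character(), site_b = character(),
                      year = integer(), distance = numeric()))
  m <- do.call(rbind, lapply(sites, function(s)
    occ$mats[[s]][as.character(year), ]))
  d <- pairwise_beta(m, metric)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  data.frame(site_a = sites[idx[, 1]], site_b = sites[idx[, 2]],
             year = year, distance = d[idx], stringsAsFactors = FALSE)
}

#' Bootstrap extrapolation of regional (gamma) richness for one year
#'
#' The bootstrap richness estimator over the sites sampled that year:
#' S_boot = S_obs + sum_k (1 - p_k)^N, where N is the number of sites and
#' p_k the fraction of those sites occupied by OTU k (sum over OTUs
#' observed that year).
#'
#' @param occ an `occ_tensor`.
#' @param year calendar year.
#' @return Numeric estimate, with attribute `n_sites`; when fewer than two
#'   sites were sampled that year the observed richness is returned with a
#'   warning and attribute `unreliable = TRUE`.
#' @export
gamma_bootstrap <- function(occ, year) {
  year <- as.integer(year)
  sites <- occ$scheme$site[occ$scheme$year == year]
  if (!length(sites)) stop2("year ", year, " was not sampled")
  m <- do.call(rbind, lapply(sites, function(s)
    occ$mats[[s]][as.character(year), , drop = FALSE]))
  freq <- colSums(m)
  obs <- freq > 0
  n <- length(sites)
  est <- sum(obs) + sum((1 - freq[obs] / n)^n)
  attr(est, "n_sites") <- n
  if (n < 2) {
    warning("gamma_bootstrap: only ", n, " site sampled in ", year,
            "; extrapolation unreliable")
    attr(est, "unreliable") <- TRUE
  }
  est
}

#' ACE richness estimator from a sample's count vector
#'
#' Classic abundance-based coverage estimator with rare-class threshold 10.
#' With S_rare the number of OTUs of count 1..10, F_k the number of OTUs
#' with count k, N_rare the total rare count and C = 1 - F_1/N_rare the
#' sample coverage:
#' ACE = S_abund + S_rare/C + (F_1/C) * gamma2, where gamma2 is the
#' truncated squared coefficient of variation (floored at 0). When every
#' rare OTU is a singleton (C = 0) the estimator is undefined and the
#' Chao1 estimate S_obs + F_1(F_1 - 1) / (2(F_2 + 1)) is returned instead
#' (logged, attribute `estimator = "chao1"`).
#'
#' @param abundances vector of per-OTU counts (zeros ignored).
#' @param rare_threshold rare-class cutoff (default 10).
#' @return Numeric richness estimate (>= observed richness).
#' @export
ace_richness <- function(abundances, rare_threshold = 10L) {
  x <- abundances[abundances > 0]
  if (!length(x)) stop2("ace_richness: no nonzero counts")
  s_obs <- length(x)
  rare <- x[x <= rare_threshold]
  s_abund <- s_obs - length(rare)
  s_rare <- length(rare)
  if (s_rare == 0) return(as.numeric(s_obs))
  f1 <- sum(rare == 1)
  n_rare <- sum(rare)
  C <- 1 - f1 / n_rare
  if (C <= 0) {
    f2 <- sum(x == 2)
    est <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    ed_log("ace_richness: all rare OTUs are singletons; Chao1 fallback used")
    attr(est, "estimator") <- "chao1"
    return(est)
  }
  k <- seq_len(rare_threshold)
  fk <- vapply(k, function(i) sum(rare == i), numeric(1))
  g2 <- 0
  if (n_rare > 1)
    g2 <- max(s_rare / C * sum(k * (k - 1) * fk) / (n_rare * (n_rare - 1)) - 1, 0)
  est <- s_abund + s_rare / C + f1 / C * g2
  attr(est, "estimator") <- "ace"
  max(est, s_obs)
}

#' Compute the full diversity series of an occurrence tensor
#'
#' Per-cell alpha richness, all temporal beta pairs (within site, across
#' years), all spatial beta pairs (within year, across sites) and the
#' per-year bootstrap gamma estimate. Pairs of two empty communities yield
#' `NA` distances and are dropped (count logged).
#'
#' @param occ an `occ_tensor`.
#' @param metric dissimilarity for the beta components: `"jaccard"` or
#'   `"turnover"`.
#' @return A list of class `diversity_series` with data frames `alpha`
#'   (`site`, `year`, `richness`), `temporal_beta`, `spatial_beta` and
#'   `gamma` (`year`, `gamma`, `n_sites`).
#' @export
compute_diversity <- function(occ, metric = c("jaccard", "turnover")) {
  metric <- match.arg(metric)
  stopifnot(inherits(occ, "occ_tensor"))
  alpha <- do.call(rbind, lapply(names(occ$mats), function(s) {
    m <- occ$mats[[s]]
    data.frame(site = s, year = as.integer(rownames(m)),
               richness = as.integer(rowSums(m)), stringsAsFactors = FALSE)
  }))
  tb <- do.call(rbind, lapply(names(occ$mats), function(s)
    temporal_beta_pairs(occ, s, metric)))
  yrs <- sort(unique(occ$scheme$year))
  sb <- do.call(rbind, lapply(yrs, function(y) spatial_beta_pairs(occ, y, metric)))
  gam <- do.call(rbind, lapply(yrs, function(y) {
    g <- suppressWarnings(gamma_bootstrap(occ, y))
    data.frame(year = y, gamma = as.numeric(g), n_sites = attr(g, "n_sites"))
  }))
  n_na <- sum(is.na(tb$distance)) + sum(is.na(sb$distance))
  if (n_na > 0)
    ed_log("compute_diversity: dropped ", n_na, " empty-vs-empty beta pairs")
  tb <- tb[!is.na(tb$distance), , drop = FALSE]
  sb <- sb[!is.na(sb$distance), , drop = FALSE]
  structure(list(alpha = alpha, temporal_beta = tb, spatial_beta = sb,
                 gamma = gam, metric = metric),
            class = "diversity_series")
}

#' @export
print.diversity_series <- function(x, ...) {
  cat("diversity_series (", x$metric, "): ",
      nrow(x$alpha), " alpha cells, ",
      nrow(x$temporal_beta), " temporal pairs, ",
      nrow(x$spatial_beta), " spatial pairs, ",
      nrow(x$gamma), " gamma years\n", sep = "")
  invisible(x)
}

#' Write a diversity series as tidy TSV tables
#'
#' One file per index: `<prefix>_alpha.tsv`, `<prefix>_temporal_beta.tsv`,
#' `<prefix>_spatial_beta.tsv`, `<prefix>_gamma.tsv`.
#'
#' @param div a `diversity_series`.
#' @param prefix path prefix.
#' @return The written paths, invisibly.
#' @export
write_diversity <- function(div, prefix) {
  stopifnot(inherits(div, "diversity_series"))
  paths <- c(alpha = paste0(prefix, "_alpha.tsv"),
             temporal_beta = paste0(prefix, "_temporal_beta.tsv"),
             spatial_beta = paste0(prefix, "_spatial_beta.tsv"),
             gamma = paste0(prefix, "_gamma.tsv"))
  for (nm in names(paths))
    utils::write.table(div[[nm]], paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(paths)
}
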