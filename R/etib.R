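#' Per-site immigration, extinction and detection rates
#'
#' @param site site id.
#' @param m immigration probability per OTU per year, in (0, 1).
#' @param e extinction probability per OTU per year, in (0, 1).
#' @param rho detection probability per present OTU per sampling event,
#'   in (0, 1].
#' @return A list of class `community_rates`.
#' @export
community_rates <- function(site, m, e, rho = 1) {
  stopifnot(m > 0, m < 1, e > 0, e < 1, rho > 0, rho <= 1)
  structure(list(site = as.character(site), m = m, e = e, rho = rho),
            class = "community_rates")
}

#' Equilibrium local richness of the island-biogeography model
#'
#' The immigration-extinction balance m(S - s) = e s gives the equilibrium
#' richness s = m S / (m + e).
#'
#' @param m,e per-OTU immigration and extinction probabilities.
#' @param S metacommunity size.
#' @return Numeric equilibrium richness.
#' @examples
#' equilibrium_richness(0.1, 0.3, 1000)  # 250
#' @export
equilibrium_richness <- function(m, e, S) {
  stopifnot(S >= 1)
  if (m + e <= 0) stop2("m + e must be positive")
  m * S / (m + e)
}

#' Expected observed richness under detection thinning
#'
#' The detection-thinned equilibrium rho * m S / (m + e): each of the
#' s = mS/(m+e) OTUs present at equilibrium is seen with probability rho.
#'
#' @inheritParams equilibrium_richness
#' @param rho detection probability.
#' @return Numeric expectation.
#' @export
expected_observed_richness <- function(m, e, S, rho = 1) {
  rho * equilibrium_richness(m, e, S)
}

#' Per-OTU rates from shared quantiles through a beta distribution
#'
#' Non-neutrality: per-OTU rates are beta-distributed with shape parameters
#' `alpha` and `alpha * (1 - mean_rate) / mean_rate`, so the mean equals
#' `mean_rate` and the spread shrinks as `alpha` grows (neutral limit
#' `alpha = Inf`). Shared quantiles across sites conserve the OTU rate
#' ranks: `rate_k = qbeta(quantile_k, alpha, alpha (1 - mean)/mean)`.
#'
#' @param mean_rate community-average rate in (0, 1).
#' @param alpha non-neutrality concentration (> 0, `Inf` = neutral).
#' @param quantiles per-OTU quantiles in (0, 1), shared across sites.
#' @return Numeric vector of per-OTU rates.
#' @export
draw_otu_rates <- function(mean_rate, alpha, quantiles) {
  stopifnot(mean_rate > 0, mean_rate < 1, alpha > 0)
  if (any(quantiles <= 0 | quantiles >= 1)) stop2("quantiles must lie in (0, 1)")
  if (!is.finite(alpha)) return(rep(mean_rate, length(quantiles)))
  shape2 <- alpha * (1 - mean_rate) / mean_rate
  r <- stats::qbeta(quantiles, alpha, shape2)
  # guard against numerical 0/1 at extreme quantiles
  pmin(pmax(r, 1e-12), 1 - 1e-12)
}

#' Metacommunity-level parameters of the non-neutral model
#'
#' @param S metacommunity OTU count.
#' @param log_alpha natural log of the non-neutrality concentration;
#'   `Inf` gives the neutral model.
#' @param u_m,u_e optional per-OTU rate quantiles (length `S`); drawn
#'   uniformly (independently for immigration and extinction) when omitted.
#' @param seed RNG seed used when quantiles are drawn here.
#' @return A list of class `metacommunity_params` with elements `S`,
#'   `alpha`, `log_alpha`, `u_m`, `u_e`.
#' @export
metacommunity_params <- function(S, log_alpha = Inf, u_m = NULL, u_e = NULL,
                                 seed = NULL) {
  stopifnot(is_count(S), S >= 1)
  S <- as.integer(S)
  if (is.null(u_m) || is.null(u_e)) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(u_m)) u_m <- stats::runif(S)
    if (is.null(u_e)) u_e <- stats::runif(S)
  }
  stopifnot(length(u_m) == S, length(u_e) == S)
  structure(list(S = S, alpha = exp(log_alpha), log_alpha = log_alpha,
                 u_m = u_m, u_e = u_e),
            class = "metacommunity_params")
}

#' Initial community composition
#'
#' Every OTU enters the initial community independently. Under the
#' `"burnin"` rule the probability is the neutral equilibrium occupancy
#' m/(m+e) (identical for all OTUs); under `"stationary"` each OTU uses its
#' own stationary occupancy m_k/(m_k + e_k), which puts the chain exactly
#' at its stationary law with no burn-in.
#'
#' @param m_k,e_k per-OTU immigration and extinction probabilities.
#' @param mode `"stationary"` or `"burnin"`.
#' @return Logical presence vector.
#' @export
initialize_community <- function(m_k, e_k, mode = c("stationary", "burnin")) {
  mode <- match.arg(mode)
  p <- if (mode == "stationary") m_k / (m_k + e_k)
       else rep(mean(m_k) / (mean(m_k) + mean(e_k)), length(m_k))
  stats::runif(length(m_k)) < p
}

#' Build a ragged (site, year) sampling scheme
#'
#' @param n_sites number of sites (named `site1..siteN`).
#' @param start_year,end_year calendar span.
#' @param cadence `1` for annual, `2` for biannual sampling.
#' @param missing_fraction fraction of (site, year) cells dropped at random.
#' @param seed RNG seed for the missing-cell draw.
#' @return Data frame with columns `site`, `year`.
#' @export
make_scheme <- function(n_sites, start_year, end_year, cadence = 1L,
                        missing_fraction = 0, seed = 1L) {
  stopifnot(n_sites >= 1, end_year >= start_year, cadence >= 1)
  yrs <- seq(as.integer(start_year), as.integer(end_year), by = as.integer(cadence))
  grid <- expand.grid(site = paste0("site", seq_len(n_sites)), year = yrs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$site, grid$year), , drop = FALSE]
  if (missing_fraction > 0) {
    set.seed(seed)
    drop <- stats::runif(nrow(grid)) < missing_fraction
    # never drop a site's first or last year entirely empty scheme guard
    grid <- grid[!drop, , drop = FALSE]
    if (!nrow(grid)) stop2("missing_fraction removed every cell")
  }
  rownames(grid) <- NULL
  grid
}

#' Simulate the (non-)neutral island-biogeography occupancy model
#'
#' Discrete-time Markov chain per OTU and site: an absent OTU k colonizes
#' with probability m_k, a present OTU goes extinct with probability e_k;
#' one step = one calendar year; sites evolve independently but share the
#' per-OTU rate quantiles (rank conservation). Present OTUs are detected
#' independently with probability `rho` at each sampled (site, year) cell;
#' there are no false positives.
#'
#' @param rates list of [community_rates()] (one per site in the scheme),
#'   or a single `community_rates` recycled to all sites.
#' @param meta a [metacommunity_params()].
#' @param scheme data frame of sampled `site`, `year` cells
#'   (see [make_scheme()]).
#' @param seed RNG seed; fixing it fixes latent and observed output exactly.
#' @param init `"stationary"` (default; exact stationarity, no burn-in
#'   needed) or `"burnin"` (mean-rate Bernoulli start at `burn_in_start`).
#' @param burn_in_start first simulated year under `init = "burnin"`
#'   (default 1500).
#' @param record_latent record the latent occupancy for every simulated
#'   year (`"all"`) or only the scheme years (`"scheme"`, default).
#' @return A list of class `sim_run`: `latent` and `observed` are
#'   `occ_tensor`s (observed restricted to the scheme), plus `rates`,
#'   `meta`, `m_k`/`e_k` per site, and `seed`.
#' @export
simulate_etib <- function(rates, meta, scheme, seed = 1L,
                          init = c("stationary", "burnin"),
                          burn_in_start = 1500L,
                          record_latent = c("scheme", "all")) {
  init <- match.arg(init)
  record_latent <- match.arg(record_latent)
  if (inherits(rates, "community_rates")) {
    sites <- unique(scheme$site)
    rates <- lapply(sites, function(s) {
      r <- rates; r$site <- s; r
    })
  }
  names(rates) <- vapply(rates, `[[`, character(1), "site")
  miss <- setdiff(unique(scheme$site), names(rates))
  if (length(miss)) stop2("scheme references unknown site(s): ",
                          paste(miss, collapse = ", "))
  stopifnot(inherits(meta, "metacommunity_params"))
  set.seed(seed)
  S <- meta$S
  otu_ids <- paste0("otu", seq_len(S))

  first_year <- if (init == "burnin") as.integer(burn_in_start) else min(scheme$year)
  if (init == "burnin" && min(scheme$year) < burn_in_start)
    stop2("scheme starts before burn_in_start")
  last_year <- max(scheme$year)
  years <- first_year:last_year

  latent <- list(); observed <- list()
  m_k_site <- list(); e_k_site <- list()
  rate_cache <- new.env(parent = emptyenv())  # sites sharing a mean reuse qbeta
  cached_rates <- function(mean_rate, quantiles, tag) {
    key <- paste0(tag, mean_rate)
    got <- get0(key, envir = rate_cache)
    if (is.null(got)) {
      got <- draw_otu_rates(mean_rate, meta$alpha, quantiles)
      assign(key, got, envir = rate_cache)
    }
    got
  }
  for (s in unique(scheme$site)) {
    r <- rates[[s]]
    m_k <- cached_rates(r$m, meta$u_m, "m")
    e_k <- cached_rates(r$e, meta$u_e, "e")
    m_k_site[[s]] <- m_k; e_k_site[[s]] <- e_k
    sc_years <- sort(scheme$year[scheme$site == s])
    keep_years <- if (record_latent == "all") years else sc_years
    lat <- matrix(0L, length(keep_years), S,
                  dimnames = list(keep_years, otu_ids))
    obs <- matrix(0L, length(sc_years), S, dimnames = list(sc_years, otu_ids))
    state <- initialize_community(m_k, e_k, mode = if (init == "burnin") "burnin"
                                                   else "stationary")
    lat_map <- match(years, keep_years)
    obs_map <- match(years, sc_years)
    lat_map[is.na(lat_map)] <- 0L
    obs_map[is.na(obs_map)] <- 0L
    chain <- .sim_site_chain(m_k, e_k, r$rho, state, lat_map, obs_map,
                             nrow(lat), nrow(obs))
    lat[] <- chain$lat
    obs[] <- chain$obs
    latent[[s]] <- lat; observed[[s]] <- obs
  }
  # matrices are binary by construction; bypass occ_tensor() validation
  mk_occ <- function(mats) {
    scheme_out <- data.frame(
      site = rep(names(mats), vapply(mats, nrow, integer(1))),
      year = unlist(lapply(mats, function(m) as.integer(rownames(m))),
                    use.names = FALSE),
      stringsAsFactors = FALSE)
    structure(list(otu_ids = otu_ids, scheme = scheme_out, mats = mats),
              class = "occ_tensor")
  }
  structure(list(latent = mk_occ(latent), observed = mk_occ(observed),
                 rates = rates, meta = meta, m_k = m_k_site, e_k = e_k_site,
                 seed = seed, init = init, burn_in_start = burn_in_start),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat("sim_run: S =", x$meta$S, ", log(alpha) =", x$meta$log_alpha,
      ",", length(x$latent$mats), "sites, seed", x$seed, "\n")
  invisible(x)
}
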