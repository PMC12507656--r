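# Synthetic natural-sampler datasets with known ground truth: latent
# occupancy from the non-neutral occupancy model, an optional disturbance
# scenario, detection thinning, and read counts drawn by giving each
# detected OTU a lognormal abundance and sampling a fixed number of reads
# multinomially (so the ACE estimator and the relative-abundance presence
# threshold are exercised the way real metabarcoding data exercise them).

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults emulate a desk-scale specimen-bank design: 5 sites sampled
#' annually for 20 years, a metacommunity of 500 OTUs with mean annual
#' immigration 0.05, extinction 0.20 and detection 0.8, moderate
#' non-neutrality (log alpha = 3), 1e5 reads per sample, lognormal(0, 1.5)
#' within-sample abundances. Scenarios: `"equilibrium"` (no disturbance),
#' `"regional_turnover"` (regional extinction of `turnover_fraction` of the
#' regionally present OTUs, replaced by widespread invaders calibrated to
#' leave alpha flat while gamma and spatial beta decline),
#' `"site_differentiation"` (each site receives its own disjoint invader
#' set) and `"alpha_decline"` (extinction rates ramp up after onset).
#'
#' @param name scenario name.
#' @param n_sites,start_year,end_year,cadence,missing_fraction sampling
#'   design, passed to [make_scheme()].
#' @param S metacommunity OTU count.
#' @param m,e,rho community-average immigration, extinction and detection.
#' @param log_alpha non-neutrality concentration (natural log).
#' @param reads_per_sample sequencing depth per sample.
#' @param lognormal_meanlog,lognormal_sdlog abundance-distribution
#'   parameters.
#' @param turnover_fraction fraction of regional OTUs affected at onset.
#' @param onset_year first disturbed year (default: midpoint of the span).
#' @param invader_m,invader_e annual immigration and extinction rates of
#'   invader OTUs: strong colonizers (defaults 0.5 / 0.05, stationary
#'   occupancy ~0.91) so that invaders establish across sites within a few
#'   years, as "widespread" invasion implies.
#' @param decline_factor extinction multiplier reached by the final year
#'   under `"alpha_decline"`.
#' @param detection how imperfect detection is realized: `"reads"`
#'   (default) calibrates each sample's sequencing depth (up to
#'   `reads_per_sample`) so that a present OTU passes the presence
#'   threshold with probability ~`rho`, which is the mechanism the
#'   ACE-based sampling-fraction estimator measures; `"bernoulli"` applies
#'   the literal process-model thinning at fixed depth `reads_per_sample`.
#' @param presence_threshold relative-abundance presence cutoff assumed by
#'   the depth calibration (match the analysis threshold).
#' @param seed RNG seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(name = c("equilibrium", "regional_turnover",
                                     "site_differentiation", "alpha_decline"),
                            n_sites = 5L, start_year = 1999L, end_year = 2018L,
                            cadence = 1L, missing_fraction = 0,
                            S = 500L, m = 0.05, e = 0.2, rho = 0.8,
                            log_alpha = 3,
                            reads_per_sample = 1e5L,
                            lognormal_meanlog = 0, lognormal_sdlog = 1.5,
                            turnover_fraction = 0.1,
                            onset_year = NULL,
                            invader_m = 0.5, invader_e = 0.05,
                            decline_factor = 3,
                            detection = c("reads", "bernoulli"),
                            presence_threshold = 1e-4,
                            seed = 1L) {
  detection <- match.arg(detection)
  name <- match.arg(name)
  if (is.null(onset_year))
    onset_year <- as.integer(floor((start_year + end_year) / 2))
  stopifnot(turnover_fraction >= 0, turnover_fraction < 1,
            onset_year >= start_year, onset_year <= end_year)
  structure(as.list(environment()), class = "scenario_config")
}


#' Generate a synthetic OTU read-count dataset with ground truth
#'
#' Simulates latent occupancy under the occupancy model, applies the
#' configured disturbance at `onset_year`, thins presences with the
#' detection probability, assigns each detected OTU a lognormal abundance
#' and draws `reads_per_sample` reads multinomially per sample.
#'
#' @param cfg a [scenario_config()].
#' @return A list of class `synthetic_dataset`: `table` (an [otu_table()]),
#'   `latent` (`occ_tensor` of the disturbed latent occupancy on the
#'   scheme), `detected` (`occ_tensor` after detection thinning), `scheme`,
#'   `truth` (true parameters and intervention bookkeeping) and `cfg`.
#' @export
generate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  scheme <- make_scheme(cfg$n_sites, cfg$start_year, cfg$end_year,
                        cfg$cadence, cfg$missing_fraction,
                        seed = child_seed(cfg$seed, 11L))
  sites <- unique(scheme$site)
  rates <- lapply(sites, function(s) community_rates(s, cfg$m, cfg$e, cfg$rho))
  meta <- metacommunity_params(cfg$S, cfg$log_alpha,
                               seed = child_seed(cfg$seed, 13L))
  # full-grid latent simulation (every site, every year) so interventions
  # can act on unsampled years too
  grid <- make_scheme(cfg$n_sites, cfg$start_year, cfg$end_year, 1L, 0)
  run <- simulate_etib(rates, meta, grid, seed = child_seed(cfg$seed, 17L),
                       init = "stationary")
  lat <- lapply(run$latent$mats, identity)
  years <- as.integer(rownames(lat[[1]]))
  set.seed(child_seed(cfg$seed, 19L))
  truth <- list(S = cfg$S, log_alpha = cfg$log_alpha, m = cfg$m, e = cfg$e,
                rho = cfg$rho, scenario = cfg$name,
                onset_year = cfg$onset_year)

  if (cfg$name == "regional_turnover" || cfg$name == "site_differentiation") {
    onset_idx <- which(years >= cfg$onset_year)
    pre_idx <- which(years < cfg$onset_year)
    if (!length(pre_idx)) stop2("onset_year leaves no undisturbed years")
    # regional extinction: a uniform draw from the OTUs regionally present
    # just before the disturbance
    last_pre <- max(pre_idx)
    regional <- which(Reduce(`|`, lapply(lat, function(m)
      m[last_pre, ] > 0)))
    n_ext <- max(1L, round(cfg$turnover_fraction * length(regional)))
    extinct <- sample(regional, n_ext)
    for (s in sites) lat[[s]][onset_idx, extinct] <- 0L

    # invader count calibrated so expected local richness stays flat:
    # each site loses ~turnover_fraction of its richness and regains it
    # from invaders at their stationary occupancy
    occ_inv <- cfg$invader_m / (cfg$invader_m + cfg$invader_e)
    mean_alpha <- mean(vapply(lat, function(mm)
      mean(rowSums(mm[pre_idx, , drop = FALSE])), numeric(1)))
    n_inv <- max(1L, round(cfg$turnover_fraction * mean_alpha / occ_inv))
    n_sets <- if (cfg$name == "regional_turnover") 1L else length(sites)
    inv_ids <- paste0("inv", seq_len(n_inv * n_sets))
    truth$extinct <- colnames(lat[[1]])[extinct]
    truth$invaders <- inv_ids
    if (cfg$S < n_inv * n_sets)
      stop2("invader count ", n_inv * n_sets, " exceeds the S budget")
    for (k in seq_along(sites)) {
      s <- sites[k]
      blk <- matrix(0L, length(years), n_inv * n_sets,
                    dimnames = list(years, inv_ids))
      own <- if (n_sets == 1L) seq_len(n_inv)
             else (k - 1L) * n_inv + seq_len(n_inv)
      state <- rep(FALSE, n_inv)
      for (i in onset_idx) {
        u <- stats::runif(n_inv)
        state <- ifelse(state, u >= cfg$invader_e, u < cfg$invader_m)
        blk[i, own] <- as.integer(state)
      }
      lat[[s]] <- cbind(lat[[s]], blk)
    }
  } else if (cfg$name == "alpha_decline") {
    # re-simulate forward from onset with ramped extinction
    onset_idx <- which(years >= cfg$onset_year)
    ramp_years <- years[onset_idx]
    ramp <- 1 + (cfg$decline_factor - 1) *
      (ramp_years - cfg$onset_year) / max(1L, max(years) - cfg$onset_year)
    for (s in sites) {
      e_k0 <- run$e_k[[s]]; m_k <- run$m_k[[s]]
      state <- lat[[s]][onset_idx[1] - 1L, ] == 1L
      if (onset_idx[1] == 1L) state <- lat[[s]][1L, ] == 1L
      for (j in seq_along(onset_idx)) {
        e_k <- pmin(e_k0 * ramp[j], 1 - 1e-12)
        u <- stats::runif(length(state))
        state <- ifelse(state, u >= e_k, u < m_k)
        lat[[s]][onset_idx[j], ] <- as.integer(state)
      }
    }
    truth$decline_factor <- cfg$decline_factor
  }

  # restrict to the sampling scheme, apply detection, draw reads.
  # detection = "reads" (default): the configured detection probability is
  # realized through read subsampling itself - the sequencing depth of each
  # sample is calibrated so that a present OTU passes the relative-abundance
  # presence threshold with probability ~rho on average. This is the
  # mechanism the ACE-based sampling-fraction estimate measures, so the
  # generated data exercise the detection-inference stage coherently.
  # detection = "bernoulli": literal process-model thinning (present OTUs
  # dropped independently with probability 1 - rho) at fixed depth; ACE
  # cannot see such misses, so rho inference is not meaningful there.
  otu_ids <- colnames(lat[[1]])
  thr <- cfg$presence_threshold %||% 1e-4
  lat_scheme <- list(); det_scheme <- list()
  counts <- NULL; md <- NULL
  for (s in sites) {
    sc_years <- sort(scheme$year[scheme$site == s])
    lm_ <- lat[[s]][as.character(sc_years), , drop = FALSE]
    dm <- lm_ * 0L
    lat_scheme[[s]] <- lm_
    for (i in seq_len(nrow(lm_))) {
      present <- which(lm_[i, ] == 1L)
      cnt <- integer(length(otu_ids))
      if (length(present)) {
        w <- stats::rlnorm(length(present), cfg$lognormal_meanlog,
                           cfg$lognormal_sdlog)
        p <- w / sum(w)
        if (identical(cfg$detection, "bernoulli")) {
          keep <- stats::runif(length(present)) < cfg$rho
          if (any(keep)) {
            pk <- p[keep] / sum(p[keep])
            cnt[present[keep]] <- stats::rmultinom(
              1, cfg$reads_per_sample, pk)[, 1]
          }
        } else {
          # expected fraction of present OTUs reaching the threshold at
          # depth R (Poisson approximation to the multinomial counts)
          det_at <- function(R)
            mean(1 - stats::ppois(R * thr, R * p))
          R <- if (det_at(cfg$reads_per_sample) <= cfg$rho) cfg$reads_per_sample
               else round(stats::uniroot(function(R) det_at(R) - cfg$rho,
                                         c(50, cfg$reads_per_sample))$root)
          cnt[present] <- stats::rmultinom(1, R, p)[, 1]
        }
      }
      dm[i, ] <- as.integer(cnt >= sum(cnt) * thr & cnt > 0)
      counts <- rbind(counts, cnt)
      md <- rbind(md, data.frame(
        sample_id = paste0(s, "_", sc_years[i]), site = s,
        year = sc_years[i], stringsAsFactors = FALSE))
    }
    det_scheme[[s]] <- dm
  }
  rownames(counts) <- md$sample_id
  colnames(counts) <- otu_ids
  tbl <- otu_table(counts, md)
  structure(list(table = tbl,
                 latent = occ_tensor(lat_scheme),
                 detected = occ_tensor(det_scheme),
                 scheme = scheme, truth = truth, cfg = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset (", x$cfg$name, "): ", sep = "")
  print(x$table)
  invisible(x)
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Counts + metadata TSV (readable by [read_otu_table()]), latent
#' occurrence as long-format TSV, ground truth as JSON.
#'
#' @param x a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_scenario <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(x$table, file.path(dir, "counts.tsv"),
                  file.path(dir, "metadata.tsv"))
  write_occurrence(x$latent, file.path(dir, "latent_occurrence.tsv"))
  jsonlite::write_json(x$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
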