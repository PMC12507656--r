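# Trend estimation: linear mixed model with a site random intercept and
# AR(1) residual correlation within site, fitted by maximum likelihood with
# the variance-structure parameters profiled out. The marginal covariance of
# one site block is sigma^2 (R(phi) + r J), R_ij = phi^|t_i - t_j|,
# r = tau^2 / sigma^2. For a given (phi, r) the GLS estimate of the slope
# and the profiled sigma^2 are closed-form, leaving a 2-D (or 1-D) search.
# This direct fit matches nlme::lme(..., correlation = corAR1, method = "ML")
# and is fast enough for the ~10^5 fits of a null-ensemble study.

ar1_lmm <- function(y, x, group = NULL, time = NULL, ar1 = TRUE,
                    random = !is.null(group)) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  time <- if (is.null(time)) x else time[ok]
  group <- if (is.null(group)) rep("g", length(y)) else as.character(group)[ok]
  n <- length(y)
  if (length(unique(x)) < 3) stop2("need >= 3 distinct predictor values")

  # aggregate replicated (group, time) cells so the AR(1) matrix stays PD
  key <- paste(group, time, sep = "\r")
  if (anyDuplicated(key)) {
    u <- unique(key)
    f <- factor(key, levels = u)
    y <- as.numeric(tapply(y, f, mean))
    x <- as.numeric(tapply(x, f, mean))
    group <- sub("\r.*$", "", u)
    time <- as.numeric(sub("^.*\r", "", u))
    n <- length(y)
  }

  X <- cbind(`(Intercept)` = 1, slope = x)
  groups <- split(seq_len(n), group)
  # exact-fit guard: zero residual variance makes the ML surface degenerate
  G <- length(groups)
  X0 <- if (G > 1) {
    dum <- matrix(0, n, G - 1)
    for (g in 2:G) dum[groups[[g]], g - 1] <- 1
    cbind(X, dum)
  } else X
  ls0 <- stats::lm.fit(X0, y)
  if (sqrt(mean(ls0$residuals^2)) < 1e-10) {
    return(list(slope = unname(ls0$coefficients[["slope"]]), slope_se = 0,
                intercept = unname(ls0$coefficients[[1]]),
                phi = 0, ratio = 0, sigma2 = 0, loglik = Inf,
                n_obs = n, converged = TRUE, exact = TRUE))
  }

  # per-group precomputation: column layout [y, 1, x]; the ones column is
  # both the intercept and the random-effect loading (Sherman-Morrison)
  pre <- lapply(groups, function(idx) {
    o <- order(time[idx]); idx <- idx[o]
    list(gaps = diff(time[idx]),
         M = cbind(y[idx], 1, x[idx]))
  })

  # R(phi)^{-1} enters through the O(k) conditional whitening
  # z_1 = y_1, z_t = (y_t - phi^g y_{t-1}) / sqrt(1 - phi^{2g});
  # the random intercept r J is folded in by Sherman-Morrison. When every
  # group shares the same gap vector (balanced design) all groups are
  # whitened in one matrix operation.
  G2 <- length(pre)
  balanced <- G2 > 1 &&
    all(vapply(pre, function(p) identical(p$gaps, pre[[1]]$gaps), logical(1)))
  if (balanced) {
    Mall <- do.call(cbind, lapply(pre, `[[`, "M"))
    gaps1 <- pre[[1]]$gaps
    k1 <- nrow(Mall)
  }

  sm_accumulate <- function(CP_blocks, logdet, r) {
    CPT <- matrix(0, 3, 3)
    for (CP in CP_blocks) {
      if (r > 0) {
        c1 <- 1 + r * CP[2, 2]
        CP <- CP - (r / c1) * tcrossprod(CP[, 2])
        logdet <- logdet + log(c1)
      }
      CPT <- CPT + CP
    }
    list(CPT = CPT, logdet = logdet)
  }

  finish_fit <- function(CPT, logdet) {
    ytVy <- CPT[1, 1]; XtVy <- CPT[2:3, 1]; XtVX <- CPT[2:3, 2:3]
    det2 <- XtVX[1, 1] * XtVX[2, 2] - XtVX[1, 2]^2
    if (!is.finite(det2) || det2 <= 0) return(NULL)
    beta <- c(XtVX[2, 2] * XtVy[1] - XtVX[1, 2] * XtVy[2],
              XtVX[1, 1] * XtVy[2] - XtVX[1, 2] * XtVy[1]) / det2
    rss <- ytVy - 2 * sum(beta * XtVy) + sum(beta * (XtVX %*% beta))
    sigma2 <- max(rss / n, 1e-300)
    nll <- 0.5 * (n * log(sigma2) + logdet + n * (1 + log(2 * pi)))
    list(nll = nll, beta = beta, sigma2 = sigma2, XtVX = XtVX)
  }

  profile_fit <- function(phi, r) {
    if (balanced) {
      a <- phi^gaps1
      s2 <- 1 - a * a
      Z <- rbind(Mall[1, ],
                 (Mall[-1, , drop = FALSE] - Mall[-k1, , drop = FALSE] * a) /
                   sqrt(s2))
      CP <- crossprod(Z)
      blocks <- lapply(seq_len(G2), function(g) {
        ix <- 3L * (g - 1L) + 1:3
        CP[ix, ix]
      })
      acc <- sm_accumulate(blocks, G2 * sum(log(s2)), r)
    } else {
      blocks <- list(); logdet <- 0
      for (p in pre) {
        M <- p$M; k <- nrow(M)
        if (k > 1) {
          a <- phi^p$gaps
          s2 <- 1 - a * a
          Z <- rbind(M[1, ],
                     (M[-1, , drop = FALSE] - M[-k, , drop = FALSE] * a) /
                       sqrt(s2))
          logdet <- logdet + sum(log(s2))
        } else Z <- M
        blocks[[length(blocks) + 1L]] <- crossprod(Z)
      }
      acc <- sm_accumulate(blocks, logdet, r)
    }
    finish_fit(acc$CPT, acc$logdet)
  }

  obj <- function(par) {
    phi <- if (ar1) tanh(par[1]) else 0
    r <- if (random) exp(par[2 - !ar1]) else 0
    pf <- tryCatch(profile_fit(phi, r), error = function(err) NULL)
    if (is.null(pf) || !is.finite(pf$nll)) return(1e10)
    pf$nll
  }

  npar <- ar1 + random
  converged <- TRUE
  if (npar == 0) {
    par <- numeric(0)
  } else if (npar == 1) {
    opt <- stats::optimize(function(p) obj(p), c(-5, 5), tol = 1e-6)
    par <- opt$minimum
  } else {
    opt <- stats::optim(rep(0, npar), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-8, maxit = 400))
    par <- opt$par
    converged <- opt$convergence == 0
  }
  phi <- if (ar1) tanh(par[1]) else 0
  r <- if (random) exp(par[2 - !ar1]) else 0
  pf <- tryCatch(profile_fit(phi, r), error = function(err) NULL)
  if (is.null(pf)) {                   # fall back to independence
    ed_log("ar1_lmm: AR(1) fit failed; falling back to phi = 0")
    phi <- 0; r <- 0
    pf <- profile_fit(0, 0)
    converged <- FALSE
  }
  vb <- pf$sigma2 * solve(pf$XtVX)
  list(slope = unname(pf$beta[2]), slope_se = sqrt(vb[2, 2]),
       intercept = unname(pf$beta[1]), phi = phi, ratio = r,
       sigma2 = pf$sigma2, loglik = -obj(par), n_obs = n,
       converged = converged, exact = FALSE)
}

#' Fit the temporal trend of a diversity index
#'
#' Linear mixed model by maximum likelihood: the index value against
#' calendar year (alpha, spatial beta, gamma) or against the time lag
#' between samples (temporal beta), with a site random intercept (omitted
#' for gamma, which is a single regional series) and AR(1) residual
#' correlation within site. Replicated (site, time) observations (beta
#' pairs) are averaged per cell before fitting so the AR(1) correlation is
#' well defined; on balanced designs the slope equals the all-pairs OLS
#' slope. A failed AR(1) fit falls back to phi = 0 with a logged warning.
#'
#' @param div a `diversity_series`.
#' @param index_kind one of `"alpha"`, `"temporal_beta"`, `"spatial_beta"`,
#'   `"gamma"`.
#' @param log_response fit the natural log of the response (used by the
#'   homogenization classification); a `log(x + 1)` guard is applied (and
#'   logged) when zeros are present.
#' @param ar1 estimate the AR(1) coefficient (`FALSE` forces phi = 0).
#' @param random include the site random intercept (`FALSE` with
#'   `ar1 = FALSE` reduces the fit to ordinary least squares).
#' @return A list of class `trend_result`: `index_kind`, `slope`,
#'   `slope_se`, `phi`, `n_obs`, `converged`.
#' @export
fit_trend <- function(div, index_kind = c("alpha", "temporal_beta",
                                          "spatial_beta", "gamma"),
                      log_response = FALSE, ar1 = TRUE, random = NULL) {
  index_kind <- match.arg(index_kind)
  stopifnot(inherits(div, "diversity_series"))
  d <- switch(index_kind,
    alpha = list(y = div$alpha$richness, x = div$alpha$year,
                 group = div$alpha$site),
    temporal_beta = list(y = div$temporal_beta$distance,
                         x = div$temporal_beta$lag,
                         group = div$temporal_beta$site),
    spatial_beta = list(y = div$spatial_beta$distance,
                        x = div$spatial_beta$year, group = NULL),
    gamma = list(y = div$gamma$gamma, x = div$gamma$year, group = NULL))
  use_random <- if (is.null(random)) !is.null(d$group) else random
  y <- d$y
  if (log_response) {
    if (any(y <= 0, na.rm = TRUE)) {
      ed_log("fit_trend(", index_kind, "): zero values; using log(x + 1)")
      y <- log1p(y)
    } else y <- log(y)
  }
  f <- ar1_lmm(y, d$x, group = d$group, ar1 = ar1, random = use_random)
  structure(list(index_kind = index_kind, slope = f$slope,
                 slope_se = f$slope_se, phi = f$phi, n_obs = f$n_obs,
                 converged = f$converged, log_response = log_response),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("trend_result %s: slope %.5g (se %.3g), phi %.3f, n = %d\n",
              x$index_kind, x$slope, x$slope_se, x$phi, x$n_obs))
  invisible(x)
}

# Aggregated diversity summaries straight from the occurrence matrices:
# per-(site, year) alpha, per-(site, lag) mean temporal beta, per-year mean
# spatial beta and per-year bootstrap gamma. Equivalent to running
# compute_diversity() and averaging replicated cells (what fit_trend does
# internally), but without building per-pair data frames - this is the hot
# path of the null-ensemble machinery.
diversity_aggregates <- function(occ, metric = "jaccard") {
  sites <- names(occ$mats)
  a_site <- character(0); a_year <- integer(0); a_rich <- integer(0)
  t_site <- character(0); t_lag <- integer(0); t_dist <- numeric(0)
  for (s in sites) {
    m <- occ$mats[[s]]
    yrs <- as.integer(rownames(m))
    a_site <- c(a_site, rep(s, length(yrs)))
    a_year <- c(a_year, yrs)
    a_rich <- c(a_rich, as.integer(rowSums(m)))
    if (nrow(m) >= 2) {
      d <- pairwise_beta(m, metric)
      lag <- abs(outer(yrs, yrs, `-`))
      ok <- upper.tri(d) & !is.na(d)
      grp <- lag[ok]
      mb_sum <- rowsum(d[ok], grp)        # rows follow factor(grp) ordering
      cnt <- as.vector(table(grp))
      lv <- as.integer(rownames(mb_sum))
      o <- order(lv)
      t_site <- c(t_site, rep(s, length(lv)))
      t_lag <- c(t_lag, lv[o])
      t_dist <- c(t_dist, (mb_sum[, 1] / cnt)[o])
    }
  }
  yrs_all <- sort(unique(occ$scheme$year))
  row_of <- lapply(occ$mats, function(m) match(yrs_all, as.integer(rownames(m))))
  g_val <- numeric(length(yrs_all))
  s_year <- integer(0); s_dist <- numeric(0)
  for (k in seq_along(yrs_all)) {
    keep <- !vapply(row_of, function(ix) is.na(ix[k]), logical(1))
    ss <- sites[keep]
    m <- do.call(rbind, lapply(ss, function(s) occ$mats[[s]][row_of[[s]][k], ]))
    freq <- colSums(m); obs <- freq > 0; nS <- length(ss)
    g_val[k] <- sum(obs) + sum((1 - freq[obs] / nS)^nS)
    if (nS >= 2) {
      d <- pairwise_beta(m, metric)
      v <- d[upper.tri(d)]
      v <- v[!is.na(v)]
      if (length(v)) { s_year <- c(s_year, yrs_all[k]); s_dist <- c(s_dist, mean(v)) }
    }
  }
  list(alpha = list(site = a_site, year = a_year, richness = a_rich),
       tbeta = list(site = t_site, lag = t_lag, distance = t_dist),
       sbeta = list(year = s_year, distance = s_dist),
       gamma = list(year = yrs_all, gamma = g_val))
}

# slope set of one simulated replicate, via the aggregated fast path
aggregate_slopes <- function(occ, metric = "jaccard", compute_log = TRUE) {
  ag <- diversity_aggregates(occ, metric)
  out <- c(
    alpha = ar1_lmm(ag$alpha$richness, ag$alpha$year, ag$alpha$site)$slope,
    temporal_beta = ar1_lmm(ag$tbeta$distance, ag$tbeta$lag, ag$tbeta$site)$slope,
    spatial_beta = ar1_lmm(ag$sbeta$distance, ag$sbeta$year)$slope,
    gamma = ar1_lmm(ag$gamma$gamma, ag$gamma$year)$slope)
  if (compute_log) {
    la <- if (any(ag$alpha$richness <= 0)) log1p(ag$alpha$richness)
          else log(ag$alpha$richness)
    lg <- if (any(ag$gamma$gamma <= 0)) log1p(ag$gamma$gamma)
          else log(ag$gamma$gamma)
    out <- c(out,
             log_alpha = ar1_lmm(la, ag$alpha$year, ag$alpha$site)$slope,
             log_gamma = ar1_lmm(lg, ag$gamma$year)$slope)
  }
  out
}

#' Null ensemble of diversity-trend slopes under the equilibrium model
#'
#' Simulates the fitted non-neutral occupancy model `n` times on the
#' empirical sampling scheme, computes the diversity series of each
#' replicate and fits every index trend, returning one slope vector per
#' index (plus the log-alpha and log-gamma slopes used by the
#' homogenization classification).
#'
#' @param rates list of per-site [community_rates()] (estimated m, e, rho).
#' @param S,log_alpha metacommunity parameters (SBI estimates).
#' @param scheme sampling scheme data frame.
#' @param n ensemble size (default 1000).
#' @param seed RNG seed.
#' @param metric beta metric.
#' @return A list of class `null_ensemble` of numeric slope vectors:
#'   `alpha`, `temporal_beta`, `spatial_beta`, `gamma`, `log_alpha`,
#'   `log_gamma`.
#' @export
simulate_null_ensemble <- function(rates, S, log_alpha, scheme, n = 1000,
                                   seed = 1L, metric = "jaccard",
                                   compute_log = TRUE) {
  kinds <- c("alpha", "temporal_beta", "spatial_beta", "gamma")
  if (compute_log) kinds <- c(kinds, "log_alpha", "log_gamma")
  out <- stats::setNames(rep(list(numeric(n)), length(kinds)), kinds)
  for (i in seq_len(n)) {
    run <- simulate_etib(rates,
                         metacommunity_params(S, log_alpha,
                                              seed = child_seed(seed, 2L * i)),
                         scheme, seed = child_seed(seed, 2L * i + 1L),
                         init = "stationary")
    sl <- suppressMessages(
      aggregate_slopes(run$observed, metric, compute_log = compute_log))
    for (k in kinds) out[[k]][i] <- sl[[k]]
  }
  structure(c(out, list(S = S, log_alpha_param = log_alpha, seed = seed)),
            class = "null_ensemble")
}

#' Compare an empirical trend with its null-ensemble distribution
#'
#' Reports both tail proportions — the fraction of null slopes at or above
#' and at or below the empirical slope (ties count in both) — and flags the
#' trend significant when it falls strictly outside the central 95% of the
#' null distribution (exclusive 2.5th/97.5th percentile boundaries).
#'
#' @param empirical a `trend_result` or a single slope value.
#' @param null_slopes numeric vector of null slopes (>= 100 required).
#' @return A list of class `null_test`: `empirical_slope`, `p_high`,
#'   `p_low`, `significant`, `n_null`.
#' @export
test_trend <- function(empirical, null_slopes) {
  slope <- if (inherits(empirical, "trend_result")) empirical$slope
           else as.numeric(empirical)
  null_slopes <- null_slopes[is.finite(null_slopes)]
  n <- length(null_slopes)
  if (n < 100) stop2("null ensemble too small (", n, " < 100)")
  q <- stats::quantile(null_slopes, c(0.025, 0.975), names = FALSE)
  structure(list(
    empirical_slope = slope,
    p_high = mean(null_slopes >= slope),
    p_low = mean(null_slopes <= slope),
    significant = slope < q[1] || slope > q[2],
    n_null = n,
    null_q = q), class = "null_test")
}

#' @export
print.null_test <- function(x, ...) {
  cat(sprintf("null_test: slope %.5g vs %d nulls [%.5g, %.5g], p_high %.3f p_low %.3f%s\n",
              x$empirical_slope, x$n_null, x$null_q[1], x$null_q[2],
              x$p_high, x$p_low, if (x$significant) " *" else ""))
  invisible(x)
}

#' Homogenization/differentiation classification from log-diversity slopes
#'
#' Fits the slopes of log(alpha richness) and log(bootstrap gamma) against
#' year; delta_alpha > delta_gamma classifies the dataset as spatial
#' homogenization, delta_alpha < delta_gamma as spatial differentiation.
#' Significance of each delta comes from the matching log-slope null
#' ensemble when one is supplied.
#'
#' @param div a `diversity_series`.
#' @param null a `null_ensemble` (optional).
#' @return A list of class `blowes_point`: `delta_alpha`, `delta_gamma`,
#'   `sig_alpha`, `sig_gamma`, `classification`.
#' @export
blowes_classify <- function(div, null = NULL) {
  da <- fit_trend(div, "alpha", log_response = TRUE)$slope
  dg <- fit_trend(div, "gamma", log_response = TRUE)$slope
  sig_a <- sig_g <- NA
  if (!is.null(null)) {
    sig_a <- test_trend(da, null$log_alpha)$significant
    sig_g <- test_trend(dg, null$log_gamma)$significant
  }
  cls <- if (isTRUE(all.equal(da, dg))) "neither"
         else if (da > dg) "homogenization" else "differentiation"
  structure(list(delta_alpha = da, delta_gamma = dg,
                 sig_alpha = sig_a, sig_gamma = sig_g,
                 classification = cls), class = "blowes_point")
}

#' @export
print.blowes_point <- function(x, ...) {
  cat(sprintf("blowes_point: delta_alpha %.5g, delta_gamma %.5g -> %s\n",
              x$delta_alpha, x$delta_gamma, x$classification))
  invisible(x)
}

#' Per-OTU occurrence trends
#'
#' For every OTU present in at least `min_prevalence` of the (site, year)
#' cells and at at least `min_sites` sites, fits a binomial trend of
#' presence on calendar year with site random intercepts (lme4::glmer;
#' engine `"glm"` uses fixed site intercepts instead and is logged as the
#' fallback). Returns the year coefficient (log-odds per year), its Wald p
#' value and Benjamini-Hochberg q values across the tested OTUs. Fits with
#' complete separation or non-finite standard errors are flagged with
#' `p = NA`.
#'
#' @param occ an `occ_tensor`.
#' @param min_prevalence minimum fraction of cells occupied.
#' @param min_sites minimum number of sites with >= 1 occurrence.
#' @param engine `"glmer"` (random site intercepts) or `"glm"` (fixed).
#' @param otus optional subset of OTU ids to test.
#' @return Data frame: `otu`, `slope`, `se`, `p`, `q`, `n_cells`,
#'   `prevalence`, `flagged`.
#' @export
otu_occurrence_trend <- function(occ, min_prevalence = 0.1, min_sites = 2L,
                                 engine = c("glmer", "glm"), otus = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(occ, "occ_tensor"))
  long <- do.call(rbind, lapply(names(occ$mats), function(s) {
    m <- occ$mats[[s]]
    data.frame(site = s, year = rep(as.integer(rownames(m)), ncol(m)),
               otu = rep(colnames(m), each = nrow(m)),
               present = as.integer(m), stringsAsFactors = FALSE)
  }))
  n_cells <- nrow(occ$scheme)
  prev <- tapply(long$present, long$otu, mean)
  sites_per_otu <- tapply(long$present > 0, list(long$otu, long$site), any)
  n_sites_otu <- rowSums(sites_per_otu, na.rm = TRUE)
  eligible <- names(prev)[prev >= min_prevalence &
                            n_sites_otu[names(prev)] >= min_sites]
  if (!is.null(otus)) eligible <- intersect(eligible, otus)
  if (!length(eligible))
    return(data.frame(otu = character(), slope = numeric(), se = numeric(),
                      p = numeric(), q = numeric(), n_cells = integer(),
                      prevalence = numeric(), flagged = logical()))
  if (engine == "glm")
    ed_log("otu_occurrence_trend: fixed-site-intercept fallback engine")
  yr0 <- mean(unique(long$year))
  res <- lapply(eligible, function(o) {
    d <- long[long$otu == o, , drop = FALSE]
    d$yr <- d$year - yr0
    flagged <- FALSE; slope <- NA_real_; se <- NA_real_; p <- NA_real_
    if (all(d$present == 1) || all(d$present == 0)) {
      flagged <- TRUE                 # zero-information fit
    } else {
      fit <- tryCatch({
        if (engine == "glmer") {
          g <- suppressMessages(suppressWarnings(
            lme4::glmer(present ~ yr + (1 | site), data = d,
                        family = stats::binomial)))
          cf <- summary(g)$coefficients
          cf["yr", c("Estimate", "Std. Error", "Pr(>|z|)")]
        } else {
          g <- suppressWarnings(stats::glm(
            present ~ yr + factor(site), data = d, family = stats::binomial))
          cf <- summary(g)$coefficients
          cf["yr", c("Estimate", "Std. Error", "Pr(>|z|)")]
        }
      }, error = function(err) NULL)
      if (is.null(fit) || !all(is.finite(fit)) || fit[2] > 50) {
        flagged <- TRUE               # separation or failed fit
        if (!is.null(fit)) slope <- unname(fit[1])
      } else {
        slope <- unname(fit[1]); se <- unname(fit[2]); p <- unname(fit[3])
      }
    }
    data.frame(otu = o, slope = slope, se = se, p = p,
               n_cells = nrow(d), prevalence = unname(prev[o]),
               flagged = flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("otu", "slope", "se", "p", "q", "n_cells", "prevalence", "flagged")]
}
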