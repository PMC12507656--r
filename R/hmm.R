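# Two-state occupancy HMM: hidden state in {absent, present}, annual
# transition matrix [[1-m, m], [e, 1-e]], emission P(obs=1 | present) = rho,
# P(obs=1 | absent) = 0. Gaps of g years enter through the g-th matrix
# power, which for a two-state chain has the closed form
#   A^g = [[pi_a + pi_p L^g, pi_p (1 - L^g)],
#          [pi_a (1 - L^g), pi_p + pi_a L^g]],
# with pi_a = e/(m+e), pi_p = m/(m+e), L = 1 - m - e.

trans_power <- function(m, e, g) {
  pia <- e / (m + e); pip <- m / (m + e)
  L <- (1 - m - e)^g
  matrix(c(pia + pip * L, pia * (1 - L),
           pip * (1 - L), pip + pia * L), 2, 2)
}

#' Forward log-likelihood of detection histories under the occupancy HMM
#'
#' Computes the exact marginal log-likelihood of one or more binary
#' detection sequences observed at (possibly gapped) sampling years, for a
#' two-state hidden Markov chain with annual immigration probability `m`,
#' extinction probability `e` and detection probability `rho`. The initial
#' state distribution is the stationary one, (e/(m+e), m/(m+e)). Rows of a
#' matrix input are treated as independent OTUs sharing the same years and
#' a vector of per-OTU log-likelihoods is returned.
#'
#' @param obs binary vector, or matrix with one row per OTU and one column
#'   per sampled year.
#' @param years integer sampling years (strictly increasing).
#' @param m,e annual immigration and extinction probabilities in (0, 1).
#' @param rho detection probability in (0, 1].
#' @return Numeric log-likelihood (vector when `obs` is a matrix).
#' @export
hmm_forward_loglik <- function(obs, years, m, e, rho) {
  if (is.vector(obs)) obs <- matrix(obs, nrow = 1)
  if (!all(obs %in% c(0, 1))) stop2("observations must be binary")
  years <- as.integer(years)
  if (ncol(obs) != length(years)) stop2("ncol(obs) must match length(years)")
  if (length(years) > 1 && any(diff(years) <= 0))
    stop2("years must be strictly increasing (positive gaps)")
  stopifnot(m > 0, m < 1, e > 0, e < 1, rho > 0, rho <= 1)
  n <- nrow(obs); TT <- length(years)
  # alpha: n x 2 forward probabilities, rescaled each step
  alpha <- matrix(c(e, m) / (m + e), n, 2, byrow = TRUE)
  ll <- numeric(n)
  for (t in seq_len(TT)) {
    if (t > 1) {
      A <- trans_power(m, e, years[t] - years[t - 1])
      alpha <- alpha %*% A
    }
    o <- obs[, t]
    # emission: obs=1 -> (0, rho); obs=0 -> (1, 1-rho)
    alpha[, 1] <- alpha[, 1] * (1 - o)
    alpha[, 2] <- alpha[, 2] * ifelse(o == 1, rho, 1 - rho)
    sc <- alpha[, 1] + alpha[, 2]
    if (any(sc <= 0)) return(rep(-Inf, n)[seq_len(n)])
    ll <- ll + log(sc)
    alpha <- alpha / sc
  }
  ll
}

#' Detection probability of a site from ACE richness
#'
#' For every sample collected at the site, the sampling fraction is the
#' observed OTU richness divided by the ACE extrapolated richness of the
#' sample's count vector; the site-level detection probability is the mean
#' over samples, clamped to (0, 1].
#'
#' @param x an [otu_table()].
#' @param site site id.
#' @return Numeric detection probability estimate, with attribute
#'   `per_sample` (the per-sample ratios).
#' @export
estimate_rho <- function(x, site) {
  stopifnot(inherits(x, "otu_table"))
  rows <- which(x$samples$site == as.character(site))
  if (!length(rows)) stop2("unknown site: ", site)
  ratios <- vapply(rows, function(i) {
    cnt <- x$counts[i, ]
    cnt <- cnt[cnt > 0]
    if (!length(cnt)) return(NA_real_)
    length(cnt) / as.numeric(ace_richness(cnt))
  }, numeric(1))
  ratios <- ratios[is.finite(ratios)]
  if (!length(ratios)) stop2("ACE undefined for every sample at site ", site)
  rho <- min(max(mean(ratios), 1e-6), 1)
  attr(rho, "per_sample") <- ratios
  rho
}

#' Fit site-level immigration and extinction rates by HMM maximum likelihood
#'
#' Maximizes the summed forward log-likelihood over the OTUs observed at
#' least once at the site, holding the detection probability fixed at the
#' ACE-derived value. By default each OTU's likelihood is conditioned on
#' its having been detected at least once (division by
#' 1 - P(all-zero history)), the standard truncation for occupancy data
#' restricted to ever-observed taxa; `conditional = FALSE` gives the plain
#' joint likelihood. Optimization is quasi-Newton on (logit m, logit e)
#' from three starting points; boundary optima are flagged.
#'
#' @param occ an `occ_tensor` of observed presences.
#' @param site site id.
#' @param rho detection probability held fixed during the fit.
#' @param conditional condition on >= 1 detection per fitted OTU.
#' @param starts matrix of (m, e) starting values, one row each.
#' @return A list of class `hmm_fit`: `site`, `m_hat`, `e_hat`, `rho_used`,
#'   `loglik`, `converged`, `boundary`, `n_otus_fit`.
#' @export
fit_rates <- function(occ, site, rho,
                      conditional = TRUE,
                      starts = rbind(c(0.01, 0.01), c(0.1, 0.1), c(0.5, 0.5))) {
  stopifnot(inherits(occ, "occ_tensor"), rho > 0, rho <= 1)
  m0 <- occ$mats[[as.character(site)]]
  if (is.null(m0)) stop2("unknown site: ", site)
  years <- as.integer(rownames(m0))
  obs <- t(m0)                       # OTUs in rows, years in columns
  obs <- obs[rowSums(obs) > 0, , drop = FALSE]
  n_fit <- nrow(obs)
  if (n_fit == 0) stop2("no OTU observed at site ", site)
  zero_hist <- matrix(0L, 1, length(years))

  nll <- function(par) {
    m <- stats::plogis(par[1]); e <- stats::plogis(par[2])
    if (m <= 1e-9 || m >= 1 - 1e-9 || e <= 1e-9 || e >= 1 - 1e-9) return(1e10)
    ll <- sum(hmm_forward_loglik(obs, years, m, e, rho))
    if (conditional) {
      ll0 <- hmm_forward_loglik(zero_hist, years, m, e, rho)
      p_seen <- 1 - exp(ll0)
      if (p_seen <= 0) return(1e10)
      ll <- ll - n_fit * log(p_seen)
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(stats::qlogis(starts[i, ]), nll, method = "BFGS",
                   control = list(reltol = 1e-10, maxit = 500)),
      error = function(err) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop2("optimizer failed from every start at site ", site)
  m_hat <- stats::plogis(best$par[1]); e_hat <- stats::plogis(best$par[2])
  boundary <- min(m_hat, 1 - m_hat, e_hat, 1 - e_hat) < 1e-4
  if (boundary)
    ed_log("fit_rates(", site, "): boundary estimate m=", signif(m_hat, 4),
           " e=", signif(e_hat, 4))
  structure(list(site = as.character(site), m_hat = m_hat, e_hat = e_hat,
                 rho_used = rho, loglik = -best$value,
                 converged = best$convergence == 0, boundary = boundary,
                 n_otus_fit = n_fit),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("hmm_fit %s: m = %.4f, e = %.4f (rho = %.3f, %d OTUs, logLik %.1f%s)\n",
              x$site, x$m_hat, x$e_hat, x$rho_used, x$n_otus_fit, x$loglik,
              if (x$boundary) ", BOUNDARY" else ""))
  invisible(x)
}

#' Estimate detection and turnover rates for every site of a dataset
#'
#' Convenience wrapper running [estimate_rho()] and [fit_rates()] per site.
#'
#' @param x the filtered [otu_table()] (for ACE detection probabilities).
#' @param occ the matching `occ_tensor` (for the HMM fits).
#' @param conditional passed to [fit_rates()].
#' @return Data frame with one row per site: `site`, `m_hat`, `e_hat`,
#'   `rho`, `loglik`, `converged`, `n_otus_fit`.
#' @export
infer_rates <- function(x, occ, conditional = TRUE) {
  sites <- names(occ$mats)
  out <- lapply(sites, function(s) {
    rho <- estimate_rho(x, s)
    f <- fit_rates(occ, s, as.numeric(rho), conditional = conditional)
    data.frame(site = s, m_hat = f$m_hat, e_hat = f$e_hat,
               rho = as.numeric(rho), loglik = f$loglik,
               converged = f$converged, n_otus_fit = f$n_otus_fit,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
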