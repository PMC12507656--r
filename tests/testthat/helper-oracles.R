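# Independent reference implementations used as oracles. These are kept
# deliberately naive (set arithmetic, exhaustive enumeration, closed forms)
# and never share code with the package internals they check.

options(etibdiv.quiet = TRUE)

# --- set-based beta-diversity references ------------------------------------

bf_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  un <- union(a, b)
  if (!length(un)) return(NA_real_)
  1 - length(intersect(a, b)) / length(un)
}

bf_turnover <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(union(a, b))) return(NA_real_)
  s <- length(intersect(a, b))
  mu <- min(length(setdiff(a, b)), length(setdiff(b, a)))
  if (s + mu == 0) {
    if (length(setdiff(a, b)) > 0 && length(setdiff(b, a)) > 0) return(1)
    return(0)
  }
  2 * mu / (s + 2 * mu)
}

ids_of <- function(v) which(as.logical(v))

# --- bootstrap gamma reference ----------------------------------------------

bf_gamma_boot <- function(site_by_otu) {
  N <- nrow(site_by_otu)
  freq <- colSums(site_by_otu > 0)
  seen <- freq > 0
  sum(seen) + sum((1 - freq[seen] / N)^N)
}

# --- ACE reference (direct transcription of the classic estimator) ----------

bf_ace <- function(x, k = 10) {
  x <- x[x > 0]
  s_ab <- sum(x > k)
  rare <- x[x <= k]
  s_r <- length(rare)
  if (s_r == 0) return(length(x))
  f1 <- sum(rare == 1)
  n_r <- sum(rare)
  C <- 1 - f1 / n_r
  if (C <= 0) {
    f2 <- sum(x == 2)
    return(length(x) + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
  fk <- vapply(1:k, function(i) sum(rare == i), numeric(1))
  g2 <- if (n_r > 1)
    max(s_r / C * sum((1:k) * (0:(k - 1)) * fk) / (n_r * (n_r - 1)) - 1, 0)
  else 0
  max(s_ab + s_r / C + f1 / C * g2, length(x))
}

# --- exhaustive-path HMM likelihood -----------------------------------------

mat_pow <- function(A, g) Reduce(`%*%`, rep(list(A), g))

bf_hmm_loglik <- function(obs, years, m, e, rho) {
  TT <- length(obs)
  A <- matrix(c(1 - m, m, e, 1 - e), 2, 2, byrow = TRUE)  # rows: from
  init <- c(e, m) / (m + e)
  paths <- as.matrix(expand.grid(rep(list(0:1), TT)))
  total <- 0
  for (i in seq_len(nrow(paths))) {
    z <- paths[i, ]
    p <- init[z[1] + 1]
    if (TT > 1)
      for (t in 2:TT) {
        g <- years[t] - years[t - 1]
        p <- p * mat_pow(A, g)[z[t - 1] + 1, z[t] + 1]
      }
    for (t in seq_len(TT)) {
      em <- if (obs[t] == 1) {
        if (z[t] == 1) rho else 0
      } else {
        if (z[t] == 1) 1 - rho else 1
      }
      p <- p * em
    }
    total <- total + p
  }
  log(total)
}

# --- small fixture builders --------------------------------------------------

# an otu_table from explicit counts with one sample per (site, year)
make_table <- function(counts, sites, years) {
  rownames(counts) <- paste0(sites, "_", years)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("o", seq_len(ncol(counts)))
  otu_table(counts,
            data.frame(sample_id = rownames(counts), site = sites,
                       year = years, stringsAsFactors = FALSE))
}

# a well-behaved table: ns sites x ny years, depth reads per sample
make_rich_table <- function(ns = 3, ny = 6, n_otu = 8, depth = 1000, seed = 1) {
  set.seed(seed)
  sites <- rep(paste0("s", seq_len(ns)), each = ny)
  years <- rep(seq(2001, by = 1, length.out = ny), ns)
  counts <- matrix(rpois(ns * ny * n_otu, depth / n_otu), ns * ny, n_otu)
  counts[counts < 0] <- 0
  make_table(counts, sites, years)
}

default_rates <- function(ns = 5, m = 0.05, e = 0.2, rho = 0.8)
  lapply(paste0("site", seq_len(ns)), function(s) community_rates(s, m, e, rho))

# random small occurrence tensor for property tests
random_occ <- function(seed, ns = 3, ny = 4, S = 12, p = 0.4) {
  set.seed(seed)
  mats <- lapply(seq_len(ns), function(i) {
    m <- matrix(as.integer(runif(ny * S) < p), ny, S,
                dimnames = list(2001:(2000 + ny), paste0("o", 1:S)))
    m
  })
  names(mats) <- paste0("s", seq_len(ns))
  occ_tensor(mats)
}
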