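# helper: diversity_series-shaped object built from explicit data frames
fake_div <- function(alpha = NULL, gamma = NULL, tb = NULL, sb = NULL) {
  structure(list(
    alpha = alpha %||% data.frame(site = character(), year = integer(),
                                  richness = integer()),
    temporal_beta = tb %||% data.frame(site = character(), year_a = integer(),
                                       year_b = integer(), lag = integer(),
                                       distance = numeric()),
    spatial_beta = sb %||% data.frame(site_a = character(), site_b = character(),
                                      year = integer(), distance = numeric()),
    gamma = gamma %||% data.frame(year = integer(), gamma = numeric(),
                                  n_sites = integer()),
    metric = "jaccard"), class = "diversity_series")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("noiseless linear data recover the exact slope", {
  d <- expand.grid(site = c("a", "b", "c"), year = 2001:2012)
  d$richness <- 2 * d$year + c(a = 5, b = 0, c = -5)[as.character(d$site)]
  tr <- fit_trend(fake_div(alpha = d), "alpha")
  expect_equal(tr$slope, 2, tolerance = 1e-6)
  expect_equal(tr$phi, 0)
  expect_lt(tr$slope_se, 1e-6)
})

test_that("slopes are invariant to site relabeling", {
  set.seed(12)
  d <- expand.grid(site = paste0("s", 1:4), year = 2001:2015)
  d$richness <- round(50 + 0.7 * (d$year - 2000) + rnorm(nrow(d), 0, 3))
  t1 <- fit_trend(fake_div(alpha = d), "alpha")
  d2 <- d
  d2$site <- c(s1 = "s3", s2 = "s4", s3 = "s1", s4 = "s2")[as.character(d$site)]
  t2 <- fit_trend(fake_div(alpha = d2), "alpha")
  expect_equal(t1$slope, t2$slope, tolerance = 1e-8)
})

test_that("the AR(1) mixed fit matches nlme::lme by maximum likelihood", {
  skip_if_not_installed("nlme")
  set.seed(42)
  for (rep in 1:3) {
    ns <- 5; ny <- 18; phi <- 0.6
    d <- expand.grid(site = paste0("s", 1:ns), year = 1:ny)
    d <- d[order(d$site, d$year), ]
    u <- rnorm(ns)
    eps <- unlist(lapply(1:ns, function(i) {
      e <- rnorm(ny)
      for (t in 2:ny) e[t] <- phi * e[t - 1] + sqrt(1 - phi^2) * rnorm(1)
      e
    }))
    d$y <- 0.5 * d$year + u[as.integer(factor(d$site))] + eps
    ours <- etibdiv:::ar1_lmm(d$y, d$year, d$site)
    ref <- nlme::lme(y ~ year, random = ~ 1 | site,
                     correlation = nlme::corAR1(form = ~ year | site),
                     data = d, method = "ML")
    expect_equal(ours$slope, unname(nlme::fixef(ref)[2]), tolerance = 1e-4)
    expect_equal(ours$phi,
                 unname(coef(ref$modelStruct$corStruct, unconstrained = FALSE)),
                 tolerance = 1e-3)
  }
})

test_that("AR(1) slope estimation is approximately unbiased", {
  set.seed(99)
  ns <- 9; ny <- 20; phi <- 0.6; b <- 0.5
  ests <- replicate(12, {
    d <- expand.grid(site = paste0("s", 1:ns), year = 1:ny)
    d <- d[order(d$site, d$year), ]
    u <- rnorm(ns, 0, 1)
    eps <- unlist(lapply(1:ns, function(i) {
      e <- rnorm(ny)
      for (t in 2:ny) e[t] <- phi * e[t - 1] + sqrt(1 - phi^2) * rnorm(1)
      e
    }))
    d$y <- b * d$year + u[as.integer(factor(d$site))] + eps
    f <- etibdiv:::ar1_lmm(d$y, d$year, d$site)
    c(f$slope, f$slope_se)
  })
  se_mean <- sqrt(mean(ests[2, ]^2) / ncol(ests))
  expect_lt(abs(mean(ests[1, ]) - b), 3 * se_mean)
})

test_that("with phi = 0 and no random effect the fit is ordinary least squares", {
  set.seed(1)
  d <- data.frame(year = rep(2001:2012, 2))
  d$gamma <- 100 + 1.5 * (d$year - 2000) + rnorm(nrow(d), 0, 4)
  f <- etibdiv:::ar1_lmm(d$gamma, d$year, ar1 = FALSE, random = FALSE)
  ols <- lm(gamma ~ year, d)
  expect_equal(f$slope, unname(coef(ols)[2]), tolerance = 1e-8)
})

test_that("null-ensemble comparison reports both tails with exclusive bounds", {
  nulls <- as.numeric(1:1000)
  top <- test_trend(2000, nulls)
  expect_equal(top$p_high, 0)
  expect_equal(top$p_low, 1)
  expect_true(top$significant)

  mid <- test_trend(500.5, nulls)
  expect_equal(mid$p_high, 0.5)
  expect_equal(mid$p_low, 0.5)
  expect_false(mid$significant)

  # exactly at the 97.5th percentile: outside-strictly rule -> not significant
  q975 <- unname(quantile(nulls, 0.975))
  expect_false(test_trend(q975, nulls)$significant)
  expect_true(test_trend(q975 + 1, nulls)$significant)
  expect_error(test_trend(0, nulls[1:50]), "too small")
})

test_that("null ensembles are reproducible and centred at equilibrium", {
  sch <- make_scheme(3, 2001, 2012)
  rts <- default_rates(3)
  n1 <- simulate_null_ensemble(rts, 200, 3, sch, n = 120, seed = 8)
  n2 <- simulate_null_ensemble(rts, 200, 3, sch, n = 120, seed = 8)
  expect_identical(n1$alpha, n2$alpha)
  expect_identical(n1$spatial_beta, n2$spatial_beta)
  # equilibrium: alpha trend centred near zero
  expect_lt(abs(mean(n1$alpha)), 2 * sd(n1$alpha) / sqrt(length(n1$alpha)) + 0.05)
})

test_that("delta-alpha/delta-gamma classification follows the slope order", {
  yrs <- 2001:2012
  # flat alpha, declining gamma -> homogenization
  a <- expand.grid(site = c("x", "y"), year = yrs); a$richness <- 50
  g <- data.frame(year = yrs, gamma = 120 * exp(-0.01 * (yrs - 2000)),
                  n_sites = 2)
  set.seed(2)
  a$richness <- a$richness + rnorm(nrow(a), 0, 0.5)
  b <- blowes_classify(fake_div(alpha = a, gamma = g))
  expect_equal(b$classification, "homogenization")
  expect_gt(b$delta_alpha, b$delta_gamma)

  # all-constant communities: both deltas zero
  a$richness <- 50; g$gamma <- 120
  b0 <- blowes_classify(fake_div(alpha = a, gamma = g))
  expect_equal(b0$delta_alpha, 0, tolerance = 1e-10)
  expect_equal(b0$delta_gamma, 0, tolerance = 1e-10)
})

test_that("per-OTU occurrence trends filter, fit and flag correctly", {
  set.seed(30)
  ny <- 20; yrs <- 2001:2020; S <- 6
  mk <- function(p_by_year) {
    vapply(p_by_year, function(p) rbinom(1, 1, p), integer(1))
  }
  mats <- lapply(1:3, function(s) {
    m <- matrix(0L, ny, S, dimnames = list(yrs, paste0("o", 1:S)))
    m[, 1] <- 1L                                   # ubiquitous OTU
    m[, 2] <- mk(seq(0.05, 0.95, length.out = ny)) # invader ramp
    m[, 3] <- mk(rep(0.5, ny))                     # stable OTU
    m[1, 4] <- 1L                                  # rare OTU (~2% of cells)
    m[, 5] <- mk(seq(0.95, 0.05, length.out = ny)) # decliner
    m
  })
  names(mats) <- paste0("s", 1:3)
  occ <- occ_tensor(mats)
  res <- otu_occurrence_trend(occ, engine = "glm")
  expect_false("o4" %in% res$otu)        # below the 10% prevalence filter
  expect_false("o6" %in% res$otu)        # never present
  expect_true(res$flagged[res$otu == "o1"])   # zero-information fit
  expect_gt(res$slope[res$otu == "o2"], 0)
  expect_lt(res$slope[res$otu == "o5"], 0)
  expect_lt(res$p[res$otu == "o2"], 0.05)
  expect_true(all(res$q >= res$p - 1e-12, na.rm = TRUE))

  # the mixed-model engine agrees on the sign of the ramp effect
  res2 <- otu_occurrence_trend(occ, engine = "glmer", otus = c("o2", "o5"))
  expect_gt(res2$slope[res2$otu == "o2"], 0)
  expect_lt(res2$slope[res2$otu == "o5"], 0)
})
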