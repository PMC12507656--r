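test_that("Jaccard distance and turnover match their defining arithmetic", {
  expect_equal(jaccard_distance(c("A", "B", "C"), c("B", "C", "D")),
               0.5, ignore_attr = TRUE)
  expect_equal(jaccard_distance(c("A", "B"), c("A", "B")), 0, ignore_attr = TRUE)
  expect_equal(jaccard_distance(c("A"), c("B")), 1, ignore_attr = TRUE)
  cmp <- attr(jaccard_distance(c("A", "B", "C"), c("B", "C", "D")), "components")
  expect_equal(unname(cmp), c(2, 1, 1))

  # s = 2, u_a = u_b = 1 -> 2*1 / (2 + 2*1) = 0.5
  expect_equal(jaccard_turnover(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(jaccard_turnover(c("A", "B", "C"), c("A", "B")), 0)  # nested
  expect_equal(jaccard_turnover(c("A", "B"), c("C", "D")), 1)      # disjoint

  expect_warning(d <- jaccard_distance(integer(0), integer(0)), "empty")
  expect_true(is.na(d))
})

test_that("alpha richness counts presences in a sampled cell", {
  occ <- occ_tensor(list(A = matrix(c(1L, 0L, 1L, 1L), 1, 4,
                                    dimnames = list("2001", paste0("o", 1:4)))))
  expect_equal(alpha_richness(occ, "A", 2001), 3)
  occ0 <- occ_tensor(list(A = matrix(0L, 1, 4,
                                     dimnames = list("2001", paste0("o", 1:4)))))
  expect_equal(alpha_richness(occ0, "A", 2001), 0)
  expect_error(alpha_richness(occ, "A", 1999), "not sampled")
})

test_that("temporal and spatial beta pairs enumerate the right cells", {
  occ <- random_occ(2, ns = 4, ny = 3)
  tb <- temporal_beta_pairs(occ, "s1")
  expect_equal(nrow(tb), choose(3, 2))
  sb <- spatial_beta_pairs(occ, 2001)
  expect_equal(nrow(sb), choose(4, 2))

  # identical communities across years -> all temporal distances zero
  m <- matrix(rep(c(1L, 0L, 1L), each = 3), 3, 3,
              dimnames = list(2001:2003, paste0("o", 1:3)))
  expect_true(all(temporal_beta_pairs(occ_tensor(list(A = m)), "A")$distance == 0))

  # a site unsampled in a year is excluded from that year's pairs
  mats <- list(A = matrix(1L, 2, 2, dimnames = list(2001:2002, c("o1", "o2"))),
               B = matrix(1L, 1, 2, dimnames = list("2001", c("o1", "o2"))))
  sb2 <- spatial_beta_pairs(occ_tensor(mats), 2002)
  expect_equal(nrow(sb2), 0)
  # two sites sharing all OTUs -> distance 0
  sb1 <- spatial_beta_pairs(occ_tensor(mats), 2001)
  expect_equal(sb1$distance, 0)
})

test_that("temporal distances grow with lag when one OTU turns over per year", {
  # year t has OTUs {t, t+1, ..., t+4}: each step replaces exactly one OTU
  ny <- 6; S <- ny + 4
  m <- matrix(0L, ny, S, dimnames = list(2000 + 1:ny, paste0("o", 1:S)))
  for (t in seq_len(ny)) m[t, t:(t + 4)] <- 1L
  tb <- temporal_beta_pairs(occ_tensor(list(A = m)), "A")
  avg <- tapply(tb$distance, tb$lag, mean)
  expect_true(all(diff(avg) > 0))
})

test_that("bootstrap gamma follows the closed-form estimator", {
  # 2 sites, OTU A at both, OTU B at one: 2 + 0 + (1 - 1/2)^2 = 2.25
  mats <- list(s1 = matrix(c(1L, 1L), 1, 2, dimnames = list("2001", c("A", "B"))),
               s2 = matrix(c(1L, 0L), 1, 2, dimnames = list("2001", c("A", "B"))))
  expect_equal(as.numeric(gamma_bootstrap(occ_tensor(mats), 2001)), 2.25)

  # every OTU everywhere -> no extrapolation
  mats <- list(s1 = matrix(1L, 1, 3, dimnames = list("2001", paste0("o", 1:3))),
               s2 = matrix(1L, 1, 3, dimnames = list("2001", paste0("o", 1:3))))
  expect_equal(as.numeric(gamma_bootstrap(occ_tensor(mats), 2001)), 3)

  # single OTU at one of N sites -> S_obs + (1 - 1/N)^N
  N <- 4
  mats <- lapply(seq_len(N), function(i)
    matrix(as.integer(i == 1), 1, 1, dimnames = list("2001", "o1")))
  names(mats) <- paste0("s", 1:N)
  expect_equal(as.numeric(gamma_bootstrap(occ_tensor(mats), 2001)),
               1 + (1 - 1 / N)^N)

  # one site only -> flagged unreliable
  occ1 <- occ_tensor(list(s1 = matrix(1L, 1, 2,
                                      dimnames = list("2001", c("a", "b")))))
  expect_warning(g <- gamma_bootstrap(occ1, 2001), "unreliable")
  expect_true(attr(g, "unreliable"))
})

test_that("ACE reproduces the classic estimator and its edge cases", {
  expect_equal(as.numeric(ace_richness(c(12, 30, 100))), 3)  # no rare class
  # hand computation for (1, 1, 2, 15): S_ab=1, S_r=3, F1=2, N_r=4, C=.5,
  # gamma2 = max(6 * 2/12 - 1, 0) = 0 -> ACE = 1 + 6 + 0 = 7
  expect_equal(as.numeric(ace_richness(c(1, 1, 2, 15))), 7)
  # all singletons -> Chao1 fallback: 3 + 3*2/2 = 6
  a <- ace_richness(c(1, 1, 1))
  expect_equal(as.numeric(a), 6)
  expect_equal(attr(a, "estimator"), "chao1")
  expect_error(ace_richness(c(0, 0)), "nonzero")
})

test_that("metrics agree with vegan on random abundance data", {
  skip_if_not_installed("vegan")
  set.seed(31)
  for (i in 1:25) {
    x <- rpois(60, 2)
    if (!any(x > 0)) next
    est <- vegan::estimateR(x)
    expect_equal(as.numeric(ace_richness(x)), unname(est["S.ACE"]),
                 tolerance = 1e-10)
    m <- matrix(as.integer(runif(5 * 30) < 0.4), 5, 30)
    keep <- rowSums(m) > 0
    if (sum(keep) >= 2) {
      m2 <- m[keep, , drop = FALSE]
      ours <- etibdiv:::pairwise_beta(m2, "jaccard")
      ref <- as.matrix(vegan::vegdist(m2, "jaccard", binary = TRUE))
      expect_equal(unname(ours[upper.tri(ours)]), ref[upper.tri(ref)],
                   tolerance = 1e-12)
      pool <- vegan::specpool(m2)
      mats <- lapply(seq_len(nrow(m2)), function(r)
        matrix(m2[r, ], 1, ncol(m2), dimnames = list("2001", paste0("o", 1:ncol(m2)))))
      names(mats) <- paste0("s", seq_len(nrow(m2)))
      expect_equal(as.numeric(gamma_bootstrap(occ_tensor(mats), 2001)),
                   pool$boot, tolerance = 1e-10)
    }
  }
})

test_that("beta metrics are bounded, symmetric and zero on identical sets", {
  set.seed(17)
  pool <- paste0("o", 1:12)
  for (i in 1:200) {
    a <- sample(pool, rbinom(1, 12, 0.5))
    b <- sample(pool, rbinom(1, 12, 0.5))
    if (!length(union(a, b))) next
    jd <- jaccard_distance(a, b); jt <- jaccard_turnover(a, b)
    expect_gte(jd, 0); expect_lte(jd, 1)
    expect_gte(jt, 0); expect_lte(jt, jd + 1e-15)
    expect_equal(jd, jaccard_distance(b, a), ignore_attr = TRUE)
    expect_equal(jt, jaccard_turnover(b, a))
  }
  expect_equal(jaccard_distance(pool, pool), 0, ignore_attr = TRUE)
})

test_that("compute_diversity assembles consistent tidy series", {
  occ <- random_occ(9, ns = 3, ny = 4, S = 15)
  div <- compute_diversity(occ)
  expect_equal(nrow(div$alpha), 12)
  expect_equal(nrow(div$temporal_beta), 3 * choose(4, 2))
  expect_equal(nrow(div$spatial_beta), 4 * choose(3, 2))
  expect_equal(nrow(div$gamma), 4)
  expect_true(all(div$gamma$gamma >=
    vapply(div$gamma$year, function(y) {
      pooled <- Reduce(`|`, lapply(occ$mats, function(m) m[as.character(y), ] > 0))
      sum(pooled)
    }, numeric(1)) - 1e-10))
  # richness values match direct per-cell counts
  expect_equal(div$alpha$richness[div$alpha$site == "s2"],
               as.integer(rowSums(occ$mats$s2)))
})
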