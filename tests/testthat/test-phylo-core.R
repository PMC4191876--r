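test_that("log weight sum matches enumeration on random trees and clamps", {
  set.seed(11)
  for (rep in 1:12) {
    tr <- random_test_tree(sample(3:6, 1))
    s <- runif(1, -1, 1)
    expect_equal(log_weight_sum(tr, NULL, s), enum_logZ(tr, NULL, s),
                 tolerance = 1e-11)
    cl <- setNames(sample(0:1, sum(tr$is_leaf), TRUE), leaves(tr))
    expect_equal(log_weight_sum(tr, cl, s), enum_logZ(tr, cl, s),
                 tolerance = 1e-11)
  }
})

test_that("decoupled zero-field weight sum counts configurations", {
  tr <- phylo_mrf("(a,b);", beta = 0, h = 0, reference = "a")
  expect_equal(log_weight_sum(tr), 3 * log(2), tolerance = 1e-12)
})

test_that("perfect coupling locks the root to clamped leaves", {
  b <- 25
  tr <- phylo_mrf("(a,b);", beta = b, h = 0, reference = "a")
  got <- log_weight_sum(tr, c(a = 1L, b = 1L), 0)
  expect_equal(got, 2 * b, tolerance = 1e-9) # disagreeing root is e^{-2b} down
})

test_that("clamping an unknown node is an input error", {
  tr <- phylo_mrf("(a,b);", beta = 0, h = 0, reference = "a")
  expect_error(log_weight_sum(tr, c(zz = 1L)), "unknown node")
})

test_that("site log-likelihood has the closed form on a decoupled star", {
  h <- 0.3; s <- 0.7
  tr <- phylo_mrf("(r,s1,s2,s3,s4);", beta = 0, h = h, reference = "r")
  pat <- conservation_pattern(c(r = 1, s1 = 1, s2 = 1, s3 = 1, s4 = 0))
  expect_equal(site_loglik(tr, pat, s),
               3 * (h + s) - 4 * log(1 + exp(h + s)), tolerance = 1e-10)
})

test_that("strong coupling makes the all-present pattern certain", {
  tr <- phylo_mrf("((a,b),(c,d));", beta = 40, h = 0, reference = "a")
  pat <- conservation_pattern(setNames(rep(1L, 4), c("a", "b", "c", "d")))
  expect_equal(site_loglik(tr, pat, 0), 0, tolerance = 1e-6)
})

test_that("site likelihood normalizes over all observable patterns", {
  set.seed(21)
  tr <- random_test_tree(5)
  for (s in c(-0.5, 0, 0.8)) {
    tot <- sum(vapply(all_patterns(tr),
                      function(p) exp(site_loglik(tr, p, s)), 0))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("a pattern with reference absent is rejected", {
  tr <- phylo_mrf("(r,s1,s2);", beta = 0, h = 0, reference = "r")
  pat <- conservation_pattern(c(s1 = 1, s2 = 0)) # fine: reference implied
  expect_silent(site_loglik(tr, pat, 0))
  expect_error(
    site_loglik(tr, conservation_pattern(c(r = 0, s1 = 1)), 0),
    "reference")
  # but values must be named and binary
  expect_error(conservation_pattern(c(r = 2)), "0 or 1")
})

test_that("fitted sigma matches logit(k/n) - h on the decoupled star", {
  tr <- phylo_mrf("(r,s1,s2,s3,s4);", beta = 0, h = 0, reference = "r")
  pat <- conservation_pattern(c(r = 1, s1 = 1, s2 = 1, s3 = 1, s4 = 0))
  f <- fit_sigma(tr, pat)
  expect_equal(f$sigma_hat, log(3), tolerance = 1e-4)
  expect_gte(f$D, 0)
  # with a field, the closed form shifts by -h
  h <- 0.9
  trh <- phylo_mrf("(r,s1,s2,s3,s4);", beta = 0, h = h, reference = "r")
  fh <- fit_sigma(trh, pat)
  expect_equal(fh$sigma_hat, log(3) - h, tolerance = 1e-4)
})

test_that("a background-typical pattern yields sigma_hat = 0 and D = 0", {
  # k/n at the background mode: h = logit(1/2) = 0, k = 2 of n = 4
  tr <- phylo_mrf("(r,s1,s2,s3,s4);", beta = 0, h = 0, reference = "r")
  pat <- conservation_pattern(c(r = 1, s1 = 1, s2 = 1, s3 = 0, s4 = 0))
  f <- fit_sigma(tr, pat)
  expect_equal(f$sigma_hat, 0, tolerance = 1e-4)
  expect_equal(f$D, 0, tolerance = 1e-7)
})

test_that("flipping a species to present never decreases sigma_hat", {
  set.seed(31)
  for (rep in 1:6) {
    tr <- random_test_tree(5)
    pat <- random_leaf_pattern(tr)
    f0 <- fit_sigma(tr, pat)
    ref <- tr$labels[tr$reference]
    for (sp in setdiff(leaves(tr), ref)) {
      if (pat$values[[sp]] == 1L) next
      v2 <- pat$values
      v2[sp] <- 1L
      f1 <- fit_sigma(tr, conservation_pattern(v2))
      expect_gte(f1$sigma_hat, f0$sigma_hat - 1e-6)
    }
  }
})

test_that("absent species and explicit zeros give identical likelihoods", {
  tr <- phylo_mrf("((r,a),(b,c));", beta = 0.7, h = -0.2, reference = "r")
  p_explicit <- conservation_pattern(c(r = 1, a = 1, b = 0, c = 0))
  p_partial <- conservation_pattern(c(r = 1, a = 1)) # b, c unalignable
  for (s in c(-1, 0, 1.3)) {
    expect_identical(site_loglik(tr, p_explicit, s),
                     site_loglik(tr, p_partial, s))
  }
  f1 <- fit_sigma(tr, p_explicit)
  f2 <- fit_sigma(tr, p_partial)
  expect_equal(f1$sigma_hat, f2$sigma_hat)
  expect_equal(f1$D, f2$D)
})

test_that("likelihood is invariant to re-rooting the undirected field", {
  # the same undirected field written rooted at n5 and rooted at n7; the
  # coupling of an undirected edge travels with it (keyed by the lower node)
  h <- c(r = 0.1, a = -0.5, b = 0.3, c = 0, d = -0.2, n5 = 0.6, n6 = -0.1,
         n7 = 0.25)
  betaA <- c(n6 = 0.4, r = 0.8, a = -0.3, b = 0.5, n7 = 0.9, c = 1.1,
             d = 0.2)
  trA <- phylo_mrf("((r,a)n6,b,(c,d)n7)n5;", beta = betaA, h = h,
                   reference = "r")
  betaB <- c(c = 1.1, d = 0.2, n5 = 0.9, n6 = 0.4, b = 0.5, r = 0.8,
             a = -0.3)
  trB <- phylo_mrf("(c,d,((r,a)n6,b)n5)n7;", beta = betaB, h = h,
                   reference = "r")
  pat <- conservation_pattern(c(r = 1, a = 0, b = 1, c = 0, d = 1))
  for (s in c(-0.6, 0, 0.4)) {
    expect_equal(log_weight_sum(trA, NULL, s), log_weight_sum(trB, NULL, s),
                 tolerance = 1e-10)
    expect_equal(site_loglik(trA, pat, s), site_loglik(trB, pat, s),
                 tolerance = 1e-10)
  }
})

test_that("pair likelihood factorizes at J = 0 and matches enumeration", {
  set.seed(41)
  for (rep in 1:6) {
    tr <- random_test_tree(4)
    trY <- set_params(tr, beta = runif(tr$n - 1, -1, 1),
                      h = runif(tr$n, -1, 1))
    px <- random_leaf_pattern(tr)
    py <- random_leaf_pattern(tr)
    expect_equal(pair_loglik(tr, trY, px, py, 0.3, -0.4, 0),
                 site_loglik(tr, px, 0.3) + site_loglik(trY, py, -0.4),
                 tolerance = 1e-10)
    got <- pair_loglik(tr, trY, px, py, 0.3, -0.4, 0.7)
    expect_equal(got, enum_pair_loglik(tr, trY, px, py, 0.3, -0.4, 0.7),
                 tolerance = 1e-10)
    # symmetry under swapping the two sites
    expect_equal(got, pair_loglik(trY, tr, py, px, -0.4, 0.3, 0.7),
                 tolerance = 1e-10)
  }
})

test_that("pair likelihood rejects mismatched topologies", {
  trA <- phylo_mrf("((r,a),b);", beta = 0, h = 0, reference = "r")
  trB <- phylo_mrf("((r,b),a);", beta = 0, h = 0, reference = "r")
  p <- conservation_pattern(c(r = 1, a = 1, b = 0))
  expect_error(pair_loglik(trA, trB, p, p, 0, 0, 0), "topology")
})

test_that("identical and complementary patterns couple with the right sign", {
  tr <- random_phylogeny(5, seed = 77)
  same <- conservation_pattern(c(sp1 = 1, sp2 = 1, sp3 = 0, sp4 = 1,
                                 sp5 = 0))
  anti <- conservation_pattern(c(sp1 = 1, sp2 = 0, sp3 = 1, sp4 = 0,
                                 sp5 = 1))
  fs <- fit_pair(tr, tr, same, same)
  expect_gt(fs$J_hat, 0)
  expect_gt(fs$deltaL, 0)
  fa <- fit_pair(tr, tr, same, anti)
  expect_lt(fa$J_hat, 0)
})

test_that("pair fit matches a dense grid search", {
  tr <- random_phylogeny(4, seed = 13)
  px <- conservation_pattern(c(sp1 = 1, sp2 = 1, sp3 = 0, sp4 = 1))
  py <- conservation_pattern(c(sp1 = 1, sp2 = 1, sp3 = 0, sp4 = 0))
  opts <- optimizer_settings(sigma_bounds = c(-3, 3), J_bounds = c(-3, 3))
  fp <- fit_pair(tr, tr, px, py, opts)
  f3 <- function(s1, s2, J) pair_loglik(tr, tr, px, py, s1, s2, J)
  coarse <- seq(-3, 3, by = 0.1)
  best <- c(-Inf, 0, 0, 0)
  for (s1 in coarse) for (s2 in coarse) for (J in coarse) {
    v <- f3(s1, s2, J)
    if (v > best[1]) best <- c(v, s1, s2, J)
  }
  fine <- function(x, lim) seq(max(-lim, x - 0.1), min(lim, x + 0.1),
                               by = 0.01)
  for (s1 in fine(best[2], 3)) for (s2 in fine(best[3], 3))
    for (J in fine(best[4], 3)) {
      v <- f3(s1, s2, J)
      if (v > best[1]) best <- c(v, s1, s2, J)
    }
  fx <- fit_sigma(tr, px, opts)
  fy <- fit_sigma(tr, py, opts)
  grid_deltaL <- best[1] - (fx$loglik_at_hat + fy$loglik_at_hat)
  expect_equal(fp$deltaL, grid_deltaL, tolerance = 1e-3)
})

test_that("deltaL is nested-nonnegative and swap-symmetric", {
  set.seed(51)
  for (rep in 1:20) {
    tr <- random_test_tree(sample(3:5, 1))
    px <- random_leaf_pattern(tr)
    py <- random_leaf_pattern(tr)
    f1 <- fit_pair(tr, tr, px, py)
    expect_gte(f1$deltaL, -1e-6)
    f2 <- fit_pair(tr, tr, py, px)
    expect_equal(f1$deltaL, f2$deltaL, tolerance = 1e-4)
  }
})

test_that("pair classification applies the cutoff and sign rules", {
  mk <- function(dL, J) list(deltaL = dL, J_hat = J)
  expect_identical(classify_pair(mk(5.0, 0.3), 2), "positive")
  expect_identical(classify_pair(mk(1.0, 0.3), 2), "none")
  expect_identical(classify_pair(mk(3.0, -0.2), 2), "negative")
  expect_identical(classify_pair(mk(3.0, 0), 2), "none")
  expect_error(classify_pair(mk(3, 1), cutoff = -1))
})
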