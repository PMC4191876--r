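test_that("Poisson enrichment is the upper tail at the control mean", {
  expect_equal(poisson_enrichment(5, 2), 1 - ppois(4, 2), tolerance = 1e-12)
  expect_equal(poisson_enrichment(5, 2), 0.052653, tolerance = 1e-4)
  expect_equal(poisson_enrichment(0, 3.7), 1)
  expect_equal(poisson_enrichment(0, 0), 1)
  expect_warning(p <- poisson_enrichment(2, 0), "mu->0")
  expect_equal(p, 0)
})

test_that("the Poisson test is super-uniform under its null", {
  set.seed(91)
  mu <- 4
  obs <- rpois(10000, mu)
  pv <- ppois(obs - 1, mu, lower.tail = FALSE)
  for (a in c(0.01, 0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(pv <= a), a + 3 * sqrt(a * (1 - a) / 10000))
})

test_that("the Skellam pmf equals the Poisson convolution", {
  conv <- function(k, m1, m2) {
    j <- 0:200
    sum(dpois(j + k, m1)[j + k >= 0] * dpois(j, m2)[j + k >= 0])
  }
  expect_equal(dskellam(0, 1, 1), exp(-2) * besselI(2, 0), tolerance = 1e-12)
  expect_equal(dskellam(0, 1, 1), 0.3085, tolerance = 1e-4)
  for (k in -6:6) {
    expect_equal(dskellam(k, 3, 2), conv(k, 3, 2), tolerance = 1e-10)
    expect_equal(dskellam(k, 0.3, 7), conv(k, 0.3, 7), tolerance = 1e-10)
  }
  expect_equal(sum(dskellam(-50:50, 3, 2)), 1, tolerance = 1e-10)
  # degenerate cases
  expect_equal(dskellam(0, 0, 0), 1)
  expect_equal(dskellam(2, 0, 0), 0)
  expect_equal(dskellam(3, 2, 0), dpois(3, 2))
  expect_equal(dskellam(-3, 0, 2), dpois(3, 2))
})

test_that("Skellam excess tails are symmetric at equal means", {
  se <- skellam_excess(4, 4, 2.5, 2.5)
  expect_equal(se$p_excess_positive, se$p_excess_negative)
  expect_gt(se$p_excess_positive, 0.5)
  # both-zero control means are handled exactly
  se0 <- skellam_excess(0, 0, 0, 0)
  expect_equal(se0$p_excess_positive, 1)
  se1 <- skellam_excess(3, 0, 0, 0)
  expect_equal(se1$p_excess_positive, 0)
})

test_that("the Skellam excess test is super-uniform under its null", {
  set.seed(92)
  mp <- 3; mn <- 2
  np <- rpois(10000, mp); nn <- rpois(10000, mn)
  pv <- vapply(seq_along(np), function(i)
    skellam_excess(np[i], nn[i], mp, mn)$p_excess_positive, 0)
  for (a in c(0.01, 0.05, 0.1, 0.25))
    expect_lte(mean(pv <= a), a + 3 * sqrt(a * (1 - a) / 10000))
})

.fake_boot <- function(n_ctrl, B = 50, rescale = 1, seed = 1) {
  set.seed(seed)
  structure(list(samples = lapply(seq_len(B), function(b)
    sample.int(n_ctrl, n_ctrl, replace = TRUE)),
    weights = rep(1, n_ctrl), rescale = rescale, breaks = NULL),
    class = "bootstrap_samples")
}

test_that("category summaries count, rescale and test correctly", {
  real <- data.frame(deltaL = c(5, 3, 0.4, 2.5, 1), J_hat = c(1, -1, 2, 2, 0))
  ctrl <- data.frame(deltaL = rep(c(4, 0.1), c(2, 38)),
                     J_hat = rep(c(1, 0.2), c(2, 38)))
  bt <- .fake_boot(nrow(ctrl), rescale = 0.5)
  s <- summarize_category(real, ctrl, bt, pair_cutoff = 2, "demo")
  expect_equal(s$n_corr, 3)
  expect_equal(s$n_pos, 2)
  expect_equal(s$n_neg, 1)
  expect_equal(s$mean_absJ, mean(c(1, 1, 2)))
  # control mean: ~2 significant of 40 per draw, rescaled by 0.5
  expect_equal(s$mu, 1, tolerance = 0.4)
  expect_lt(s$p_enrichment, 0.2)
  # empty category reports ones
  s0 <- summarize_category(real[0, ], ctrl, bt, 2, "empty")
  expect_equal(s0$n_corr, 0)
  expect_equal(s0$p_enrichment, 1)
  # zero observed against a positive control mean is never enriched
  zr <- data.frame(deltaL = c(0.1, 0.2), J_hat = c(1, 1))
  sz <- summarize_category(zr, ctrl, bt, 2, "null")
  expect_equal(sz$p_enrichment, 1)
})

test_that("subsetted categories report median p and mean counts", {
  real <- data.frame(deltaL = c(5, 5, 0.1, 0.1), J_hat = c(1, 1, 1, 1),
                     subset = c(1, 1, 2, 2))
  ctrl <- data.frame(deltaL = c(3, rep(0.1, 29)), J_hat = rep(1, 30))
  bt <- .fake_boot(30)
  s <- summarize_category(real, ctrl, bt, 2, "sub")
  expect_equal(s$n_corr, 1) # mean of (2, 0)
  expect_equal(s$n_pairs, 2)
})

test_that("gene-set strategy tests separate the two strata", {
  pos <- data.frame(deltaL = 5, J_hat = 1)
  mk <- function(n, dl, j, same) if (n == 0) NULL else
    data.frame(deltaL = rep(dl, n), J_hat = rep(j, n),
               same_gene = rep(same, n))
  # complex-like: positive same-gene, negative different-gene couplings
  real <- rbind(mk(6, 5, 1, TRUE), mk(2, 0.3, 1, TRUE),
                mk(6, 5, -1, FALSE), mk(2, 0.2, 1, FALSE))
  ctrl <- data.frame(deltaL = c(3, rep(0.1, 49)),
                     J_hat = c(-1, rep(1, 49)))
  bt <- .fake_boot(50)
  out <- geneset_strategy_test(real, ctrl, bt, 2, "complex")
  same <- out[out$category == "same_gene", ]
  diff <- out[out$category == "different_gene", ]
  expect_lt(same$p_excess_positive, 0.01)
  expect_lt(diff$p_excess_negative, 0.01)
  expect_gt(diff$p_excess_positive, 0.5)
  # pathway-like: positive couplings in both strata
  real2 <- rbind(mk(6, 5, 1, TRUE), mk(6, 5, 1, FALSE))
  out2 <- geneset_strategy_test(real2, ctrl, bt, 2, "pathway")
  expect_true(all(out2$p_excess_positive < 0.01))
  # a single-gene set has an empty different-gene stratum
  out3 <- geneset_strategy_test(mk(3, 5, 1, TRUE), ctrl, bt, 2, "solo")
  expect_equal(out3$p_enrichment[out3$category == "different_gene"], 1)
  # BH adjustment flags the planted sets at 5% FDR
  tab <- adjust_geneset_table(rbind(out, out2, out3))
  expect_true(all(c("q_excess_positive", "significant") %in% names(tab)))
})

test_that("network edges keep the top percentile with deterministic ties", {
  pairs <- data.frame(
    family1 = c("A", "A", "A", "B", "C"),
    family2 = c("B", "B", "B", "C", "A"),
    deltaL = c(5, 4, 3, 5, 0.2), J_hat = c(1, 1, -1, 1, 1))
  net <- build_network(pairs, "count", percentile = 0.5, pair_cutoff = 2)
  e <- net$edges
  expect_equal(e$weight[e$a == "A" & e$b == "B"], 3)
  expect_true(e$kept[e$a == "A" & e$b == "B"])
  expect_false(any(e$kept[e$weight == 0]))
  deg <- network_degree(net)
  expect_equal(sum(deg), 2 * sum(e$kept))
  # fraction-positive statistic
  net2 <- build_network(pairs, "fraction_positive", percentile = 1,
                        pair_cutoff = 2)
  e2 <- net2$edges
  expect_equal(e2$weight[e2$a == "A" & e2$b == "B"], 2 / 3)
  # retention is monotone in the percentile
  n_half <- sum(build_network(pairs, "count", 0.5, 2)$edges$kept)
  n_all <- sum(build_network(pairs, "count", 1, 2)$edges$kept)
  expect_lte(n_half, n_all)
  # no self-edges
  self <- data.frame(family1 = "A", family2 = "A", deltaL = 9, J_hat = 1)
  expect_equal(nrow(build_network(self, "count")$edges), 0)
})

test_that("expression overlap is the normalized dot product", {
  ex <- rbind(a = c(1, 1, 0), b = c(1, 0, 1), c = c(2, 2, 0),
              z = c(0, 0, 0))
  expect_warning(ov <- expression_overlap(ex), "zero-expression")
  expect_equal(ov["a", "b"], 0.5)
  expect_equal(ov["a", "c"], 1)
  expect_equal(ov["a", "a"], 1)
  expect_false("z" %in% rownames(ov))
  # orthogonal rows
  ex2 <- rbind(a = c(1, 0), b = c(0, 2))
  expect_equal(expression_overlap(ex2)["a", "b"], 0)
  net <- network_from_matrix(expression_overlap(ex2), percentile = 1)
  expect_s3_class(net, "mirna_network")
})

test_that("network comparison reduces to the hypergeometric table", {
  mknet <- function(edges, nodes) {
    df <- data.frame(a = edges[, 1], b = edges[, 2],
                     weight = 1, kept = TRUE, stringsAsFactors = FALSE)
    structure(list(nodes = nodes, edges = df, threshold = 1,
                   effective_percentile = 1), class = "mirna_network")
  }
  nodes <- LETTERS[1:6] # 15 possible edges
  eA <- cbind(c("A", "A", "B", "C"), c("B", "C", "C", "D"))
  cmp_same <- compare_networks(mknet(eA, nodes), mknet(eA, nodes))
  expect_lt(cmp_same$p, 0.05)
  # hand-built table: shared 6, A-only 2, B-only 2, neither 10
  tab <- matrix(c(6, 2, 2, 10), 2, 2)
  expect_equal(fisher.test(tab)$p.value,
               compare_networks_p_oracle <- local({
                 # direct two-sided hypergeometric evaluation
                 m <- 8; n <- 12; k <- 8
                 d <- dhyper(0:8, m, n, k)
                 sum(d[d <= dhyper(6, m, n, k) * (1 + 1e-7)])
               }), tolerance = 1e-9)
  expect_error(compare_networks(mknet(eA, c("A", "B")), mknet(eA, "A")),
               "common nodes")
})

test_that("network overlap p is roughly uniform under random rewiring", {
  set.seed(93)
  nodes <- LETTERS[1:10]
  cmb <- t(combn(nodes, 2))
  mknet <- function(idx) {
    df <- data.frame(a = cmb[idx, 1], b = cmb[idx, 2], weight = 1,
                     kept = TRUE, stringsAsFactors = FALSE)
    structure(list(nodes = nodes, edges = df, threshold = 1,
                   effective_percentile = 1), class = "mirna_network")
  }
  netA <- mknet(sample(nrow(cmb), 12))
  pv <- replicate(300, compare_networks(netA,
                                        mknet(sample(nrow(cmb), 12)))$p)
  expect_gt(mean(pv), 0.35)
  expect_lte(mean(pv <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("Mann-Whitney comparisons are two-sided with tie handling", {
  set.seed(94)
  a <- rnorm(60)
  expect_gt(mwu_compare(a, a), 0.9)
  b <- rnorm(50); c <- rnorm(50, mean = 3)
  expect_lt(mwu_compare(c, b), 1e-4)
  expect_equal(mwu_compare(1, 2), 1) # exact two-sided with ranks {1,2}
  expect_equal(mwu_compare(rep(1, 5), rep(1, 7)), 1) # all tied
})
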