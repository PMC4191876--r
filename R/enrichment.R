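# Enrichment statistics over classified site pairs: Poisson test against the
# bootstrap-control mean, Skellam test for positive/negative excess, per-
# gene-set strategy tests, and miRNA-miRNA network construction/comparison.

#' Upper-tail Poisson enrichment p-value
#'
#' `p = P(Poisson(control_mean) >= observed)`; the number of significantly
#' correlated control pairs across bootstrap samples is Poisson-like (its
#' variance scales with its mean), so the enrichment of observed correlated
#' pairs over the bootstrap mean is tested against a Poisson null.
#'
#' @param observed observed count (non-negative integer).
#' @param control_mean mean count over the bootstrap control samples.
#' @return p-value in `[0, 1]`.
#' @export
poisson_enrichment <- function(observed, control_mean) {
  stopifnot(observed >= 0, control_mean >= 0)
  if (control_mean == 0) {
    if (observed == 0) return(1)
    warning("control mean is 0 with observed > 0; p reported as the mu->0 limit")
    return(0)
  }
  stats::ppois(observed - 1L, control_mean, lower.tail = FALSE)
}

#' Skellam probability mass function
#'
#' Distribution of `N1 - N2` for independent Poissons; evaluated through the
#' modified Bessel function of the first kind with a direct Poisson
#' convolution fallback where the Bessel form is not finite.
#'
#' @param k integer quantiles (may be negative).
#' @param mu1,mu2 the two Poisson means (>= 0).
#' @return `P(D = k)`.
#' @export
dskellam <- function(k, mu1, mu2) {
  stopifnot(mu1 >= 0, mu2 >= 0)
  if (mu1 == 0 && mu2 == 0) return(as.numeric(k == 0))
  if (mu2 == 0) return(ifelse(k >= 0, stats::dpois(k, mu1), 0))
  if (mu1 == 0) return(ifelse(k <= 0, stats::dpois(-k, mu2), 0))
  s <- 2 * sqrt(mu1 * mu2)
  lp <- -(mu1 + mu2) + s + 0.5 * k * log(mu1 / mu2) +
    log(besselI(s, abs(k), expon.scaled = TRUE))
  p <- exp(lp)
  bad <- !is.finite(p)
  if (any(bad)) p[bad] <- vapply(k[bad], .dskellam_conv, 0, mu1, mu2)
  p
}

# brute-force convolution of two truncated Poisson pmfs
.dskellam_conv <- function(k, mu1, mu2) {
  top <- ceiling(max(mu1, mu2) + 12 * sqrt(max(mu1, mu2)) + abs(k) + 20)
  j <- 0:top
  i <- j + k
  ok <- i >= 0
  sum(stats::dpois(i[ok], mu1) * stats::dpois(j[ok], mu2))
}

#' Skellam test for an excess of positive or negative correlations
#'
#' The counts of positively and negatively correlated pairs are modeled as
#' independent Poissons with the bootstrap-control means; with
#' `D ~ Skellam(mu_pos, mu_neg)` the one-sided tails at the observed
#' difference `n_pos - n_neg` give the excess p-values.
#'
#' @param n_pos,n_neg observed counts of positively/negatively correlated
#'   pairs.
#' @param mu_pos,mu_neg control means.
#' @return list with `p_excess_positive = P(D >= n_pos - n_neg)` and
#'   `p_excess_negative = P(D <= n_pos - n_neg)`.
#' @export
skellam_excess <- function(n_pos, n_neg, mu_pos, mu_neg) {
  d <- n_pos - n_neg
  if (mu_pos == 0 && mu_neg == 0) {
    return(list(p_excess_positive = as.numeric(d <= 0),
                p_excess_negative = as.numeric(d >= 0)))
  }
  m <- mu_pos - mu_neg
  sd <- sqrt(mu_pos + mu_neg)
  lo <- floor(min(d, m - 12 * sd) - 10)
  hi <- ceiling(max(d, m + 12 * sd) + 10)
  ks <- lo:hi
  pmf <- dskellam(ks, mu_pos, mu_neg)
  list(p_excess_positive = min(1, sum(pmf[ks >= d])),
       p_excess_negative = min(1, sum(pmf[ks <= d])))
}

# significant / positive / negative counts of a pair table
.pair_counts <- function(deltaL, J, cutoff) {
  sig <- deltaL >= cutoff & J != 0
  c(n_corr = sum(sig), n_pos = sum(sig & J > 0), n_neg = sum(sig & J < 0))
}

#' Summarize a category of site pairs against its bootstrap control
#'
#' Counts observed correlated pairs (total/positive/negative) at the
#' log-likelihood cutoff, averages the rescaled counts over the control
#' bootstrap samples, and attaches the Poisson enrichment and Skellam excess
#' p-values plus the mean coupling strength `|J|` over correlated pairs.
#' When the real pairs were drawn in random subsets, counts are averaged and
#' p-values reported as the median over subsets.
#'
#' @param real_pairs data.frame with `deltaL`, `J_hat` and optionally
#'   `subset`.
#' @param control_pairs data.frame with `deltaL`, `J_hat` for all control
#'   pairs.
#' @param boot a [biased_bootstrap()] result over `control_pairs` rows.
#' @param pair_cutoff log-likelihood-ratio cutoff defining correlated pairs.
#' @param category label carried into the output.
#' @return one-row data.frame (`pair_count_summary`): counts, control means,
#'   `mean_absJ`, `p_enrichment`, `p_excess_positive`, `p_excess_negative`.
#' @export
summarize_category <- function(real_pairs, control_pairs, boot,
                               pair_cutoff = 2.0, category = "all") {
  empty <- data.frame(category = category, n_pairs = 0L, n_corr = 0,
                      n_pos = 0, n_neg = 0, mu = 0, mu_pos = 0, mu_neg = 0,
                      mean_absJ = NA_real_, p_enrichment = 1,
                      p_excess_positive = 1, p_excess_negative = 1,
                      stringsAsFactors = FALSE)
  if (is.null(real_pairs) || !nrow(real_pairs)) return(empty)

  ctl <- matrix(0, nrow = length(boot$samples), ncol = 3)
  for (b in seq_along(boot$samples)) {
    idx <- boot$samples[[b]]
    ctl[b, ] <- .pair_counts(control_pairs$deltaL[idx],
                             control_pairs$J_hat[idx], pair_cutoff) *
      boot$rescale
  }
  mu <- colMeans(ctl)

  subsets <- if (is.null(real_pairs$subset)) rep(0L, nrow(real_pairs)) else
    real_pairs$subset
  per <- lapply(unique(subsets), function(s) {
    rp <- real_pairs[subsets == s, , drop = FALSE]
    cnt <- .pair_counts(rp$deltaL, rp$J_hat, pair_cutoff)
    sk <- skellam_excess(cnt["n_pos"], cnt["n_neg"], mu[2], mu[3])
    list(cnt = cnt, n = nrow(rp),
         p_enr = poisson_enrichment(cnt["n_corr"], mu[1]),
         p_pos = sk$p_excess_positive, p_neg = sk$p_excess_negative)
  })
  cnt <- colMeans(do.call(rbind, lapply(per, `[[`, "cnt")))
  sig <- real_pairs$deltaL >= pair_cutoff & real_pairs$J_hat != 0
  data.frame(category = category,
             n_pairs = mean(vapply(per, `[[`, 0, "n")),
             n_corr = cnt[["n_corr"]], n_pos = cnt[["n_pos"]],
             n_neg = cnt[["n_neg"]],
             mu = mu[1], mu_pos = mu[2], mu_neg = mu[3],
             mean_absJ = if (any(sig)) mean(abs(real_pairs$J_hat[sig])) else
               NA_real_,
             p_enrichment = stats::median(vapply(per, `[[`, 0, "p_enr")),
             p_excess_positive = stats::median(vapply(per, `[[`, 0, "p_pos")),
             p_excess_negative = stats::median(vapply(per, `[[`, 0, "p_neg")),
             stringsAsFactors = FALSE)
}

#' Same-gene / different-gene strategy test within a gene set
#'
#' Applies [summarize_category()] separately to pairs whose sites lie in the
#' same gene and in different genes of the set, mirroring the contrast
#' between local (complex-like) and global (pathway-like) regulatory
#' strategies; empty strata report p = 1.
#'
#' @param real_pairs pairs within the gene set (with `same_gene`, `deltaL`,
#'   `J_hat`).
#' @param control_pairs,boot control machinery as in [summarize_category()].
#' @param pair_cutoff correlation cutoff.
#' @param set_id label.
#' @return two-row data.frame (strata `same_gene`, `different_gene`).
#' @export
geneset_strategy_test <- function(real_pairs, control_pairs, boot,
                                  pair_cutoff = 2.0, set_id = "set") {
  strata <- list(same_gene = real_pairs[real_pairs$same_gene, , drop = FALSE],
                 different_gene = real_pairs[!real_pairs$same_gene, ,
                                             drop = FALSE])
  out <- do.call(rbind, lapply(names(strata), function(nm)
    summarize_category(strata[[nm]], control_pairs, boot, pair_cutoff,
                       category = nm)))
  out$set_id <- set_id
  out
}

#' Benjamini-Hochberg adjustment across gene sets
#'
#' @param df stacked [geneset_strategy_test()] rows.
#' @param fdr target false discovery rate.
#' @return `df` with `q_excess_positive`, `q_excess_negative` and
#'   `significant` (either direction below `fdr`), adjusted within stratum.
#' @export
adjust_geneset_table <- function(df, fdr = 0.05) {
  df$q_excess_positive <- NA_real_
  df$q_excess_negative <- NA_real_
  for (st in unique(df$category)) {
    i <- df$category == st
    df$q_excess_positive[i] <- stats::p.adjust(df$p_excess_positive[i], "BH")
    df$q_excess_negative[i] <- stats::p.adjust(df$p_excess_negative[i], "BH")
  }
  df$significant <- pmin(df$q_excess_positive, df$q_excess_negative) < fdr
  df
}

#' miRNA-miRNA network from correlated site pairs
#'
#' Edge weight between two miRNA families is the number of correlated site
#' pairs (`edge_stat = "count"`) or the fraction of co-occurring pairs that
#' are positively correlated (`"fraction_positive"`); binary edges keep the
#' top `percentile` of weights (ties at the boundary are included and the
#' effective percentile recorded).  Self-pairs (same family) are excluded.
#'
#' @param pairs data.frame with `family1`, `family2`, `deltaL`, `J_hat`.
#' @param edge_stat `"count"` or `"fraction_positive"`.
#' @param percentile fraction of edges to keep.
#' @param pair_cutoff correlation cutoff.
#' @return list of class `mirna_network`: `nodes`, `edges` (a, b, weight,
#'   kept), `threshold`, `effective_percentile`.
#' @export
build_network <- function(pairs, edge_stat = c("count", "fraction_positive"),
                          percentile = 0.5, pair_cutoff = 2.0) {
  edge_stat <- match.arg(edge_stat)
  pairs <- pairs[pairs$family1 != pairs$family2, , drop = FALSE]
  if (!nrow(pairs)) {
    edges <- data.frame(a = character(), b = character(),
                        weight = numeric(), kept = logical(),
                        stringsAsFactors = FALSE)
    return(structure(list(nodes = character(), edges = edges,
                          threshold = Inf,
                          effective_percentile = NA_real_),
                     class = "mirna_network"))
  }
  a <- pmin(pairs$family1, pairs$family2)
  b <- pmax(pairs$family1, pairs$family2)
  key <- paste(a, b, sep = "\r")
  sig <- pairs$deltaL >= pair_cutoff & pairs$J_hat != 0
  pos <- sig & pairs$J_hat > 0
  n_tested <- tapply(sig, key, length)
  n_corr <- tapply(sig, key, sum)
  n_pos <- tapply(pos, key, sum)
  w <- if (edge_stat == "count") n_corr else n_pos / pmax(n_tested, 1L)
  ks <- strsplit(names(w), "\r")
  edges <- data.frame(a = vapply(ks, `[`, "", 1), b = vapply(ks, `[`, "", 2),
                      weight = as.numeric(w), stringsAsFactors = FALSE)
  edges <- edges[order(-edges$weight, edges$a, edges$b), , drop = FALSE]
  n_keep <- ceiling(percentile * nrow(edges))
  thr <- if (n_keep > 0) edges$weight[n_keep] else Inf
  edges$kept <- edges$weight >= thr & edges$weight > 0
  structure(list(nodes = sort(unique(c(edges$a, edges$b))), edges = edges,
                 threshold = thr,
                 effective_percentile = if (nrow(edges))
                   sum(edges$kept) / nrow(edges) else NA_real_),
            class = "mirna_network")
}

#' Node connectivity of a network (retained edges per node)
#' @param net a `mirna_network`.
#' @return named integer vector.
#' @export
network_degree <- function(net) {
  kept <- net$edges[net$edges$kept, , drop = FALSE]
  tab <- table(factor(c(kept$a, kept$b), levels = net$nodes))
  stats::setNames(as.integer(tab), names(tab))
}

#' Expression overlap between miRNA families
#'
#' `overlap(a, b) = <e_a, e_b> / (|e_a| |e_b|)` across tissues; families with
#' all-zero expression are excluded with a warning.
#'
#' @param expr nonnegative matrix (families x tissues).
#' @return symmetric overlap matrix over the retained families.
#' @export
expression_overlap <- function(expr) {
  stopifnot(is.matrix(expr), all(expr >= 0))
  nrm <- sqrt(rowSums(expr^2))
  if (any(nrm == 0)) {
    warning("excluding zero-expression families: ",
            paste(rownames(expr)[nrm == 0], collapse = ", "))
    expr <- expr[nrm > 0, , drop = FALSE]
    nrm <- nrm[nrm > 0]
  }
  ov <- (expr %*% t(expr)) / outer(nrm, nrm)
  ov
}

#' Network from a symmetric weight matrix by the percentile rule
#'
#' @param w symmetric matrix with family names.
#' @param percentile fraction of edges to keep.
#' @return a `mirna_network`.
#' @export
network_from_matrix <- function(w, percentile = 0.5) {
  fam <- rownames(w)
  idx <- which(upper.tri(w), arr.ind = TRUE)
  edges <- data.frame(a = pmin(fam[idx[, 1]], fam[idx[, 2]]),
                      b = pmax(fam[idx[, 1]], fam[idx[, 2]]),
                      weight = w[idx], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$weight, edges$a, edges$b), , drop = FALSE]
  n_keep <- ceiling(percentile * nrow(edges))
  thr <- if (n_keep > 0) edges$weight[n_keep] else Inf
  edges$kept <- edges$weight >= thr
  structure(list(nodes = sort(fam), edges = edges, threshold = thr,
                 effective_percentile = sum(edges$kept) / nrow(edges)),
            class = "mirna_network")
}

#' Fisher test on the edge overlap of two networks
#'
#' Builds the 2x2 table of all node pairs over the common node universe
#' (edge in A x edge in B) and applies the two-sided Fisher exact test.
#'
#' @param netA,netB `mirna_network`s.
#' @return list with `p`, `table`, `common_nodes`.
#' @export
compare_networks <- function(netA, netB) {
  common <- intersect(netA$nodes, netB$nodes)
  if (length(common) < 2L) stop("fewer than 2 common nodes")
  edge_set <- function(net) {
    kept <- net$edges[net$edges$kept & net$edges$a %in% common &
                        net$edges$b %in% common, , drop = FALSE]
    paste(kept$a, kept$b, sep = "\r")
  }
  ea <- edge_set(netA); eb <- edge_set(netB)
  cmb <- utils::combn(sort(common), 2L)
  univ <- paste(cmb[1, ], cmb[2, ], sep = "\r")
  tab <- table(factor(univ %in% ea, c(TRUE, FALSE)),
               factor(univ %in% eb, c(TRUE, FALSE)))
  list(p = stats::fisher.test(tab)$p.value, table = tab,
       common_nodes = common)
}

#' Two-sided Mann-Whitney comparison of two score distributions
#'
#' @param valuesA,valuesB numeric vectors (non-empty).
#' @return two-sided p-value with tie correction; 1 when everything is tied.
#' @export
mwu_compare <- function(valuesA, valuesB) {
  stopifnot(length(valuesA) > 0, length(valuesB) > 0)
  if (length(unique(c(valuesA, valuesB))) == 1L) return(1)
  stats::wilcox.test(valuesA, valuesB)$p.value
}
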