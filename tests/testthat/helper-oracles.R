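# Independent brute-force oracles: exhaustive enumeration over all node
# configurations of the tree MRF.  Deliberately naive and shared by the unit
# and acceptance tests; never calls the message-passing engine.

enum_logZ <- function(tree, clamps = NULL, sigma = 0) {
  n <- tree$n
  fixed <- rep(NA_integer_, n)
  if (length(clamps)) fixed[match(names(clamps), tree$labels)] <- clamps
  free <- which(is.na(fixed))
  tot <- -Inf
  lse2 <- function(a, b) {
    m <- max(a, b)
    if (!is.finite(m)) return(m)
    m + log(exp(a - m) + exp(b - m))
  }
  for (m in 0:(2^length(free) - 1)) {
    x <- fixed
    if (length(free)) x[free] <- bitwAnd(m %/% 2^(seq_along(free) - 1), 1)
    w <- sum((tree$h + sigma) * x)
    for (v in seq_len(n)) if (v != tree$root)
      w <- w + tree$beta[v] * (x[v] == x[tree$parent[v]])
    tot <- lse2(tot, w)
  }
  tot
}

enum_site_loglik <- function(tree, pattern, sigma) {
  cl <- coevosite:::.pattern_clamps(tree, pattern)
  ref <- stats::setNames(1L, tree$labels[tree$reference])
  enum_logZ(tree, cl, sigma) - enum_logZ(tree, ref, sigma)
}

enum_pair_logZ <- function(trX, trY, clX, clY, s1, s2, J) {
  n <- trX$n
  fx <- rep(NA_integer_, n); fy <- rep(NA_integer_, n)
  if (length(clX)) fx[match(names(clX), trX$labels)] <- clX
  if (length(clY)) fy[match(names(clY), trX$labels)] <- clY
  freex <- which(is.na(fx)); freey <- which(is.na(fy))
  lse2 <- function(a, b) {
    m <- max(a, b)
    if (!is.finite(m)) return(m)
    m + log(exp(a - m) + exp(b - m))
  }
  tot <- -Inf
  for (mx in 0:(2^length(freex) - 1)) for (my in 0:(2^length(freey) - 1)) {
    x <- fx; y <- fy
    if (length(freex)) x[freex] <- bitwAnd(mx %/% 2^(seq_along(freex) - 1), 1)
    if (length(freey)) y[freey] <- bitwAnd(my %/% 2^(seq_along(freey) - 1), 1)
    w <- sum((trX$h + s1) * x) + sum((trY$h + s2) * y) + J * sum(x * y)
    for (v in seq_len(n)) if (v != trX$root)
      w <- w + trX$beta[v] * (x[v] == x[trX$parent[v]]) +
        trY$beta[v] * (y[v] == y[trX$parent[v]])
    tot <- lse2(tot, w)
  }
  tot
}

enum_pair_loglik <- function(trX, trY, patX, patY, s1, s2, J) {
  clX <- coevosite:::.pattern_clamps(trX, patX)
  clY <- coevosite:::.pattern_clamps(trY, patY)
  ref <- stats::setNames(1L, trX$labels[trX$reference])
  enum_pair_logZ(trX, trY, clX, clY, s1, s2, J) -
    enum_pair_logZ(trX, trY, ref, ref, s1, s2, J)
}

# random tree with parameters drawn in [-1, 1] (harsher than the generator's
# conservation-like defaults: negative couplings and fields included)
random_test_tree <- function(n_leaves, seed = NULL) {
  tr <- random_phylogeny(n_leaves, seed = seed)
  set_params(tr, beta = stats::runif(tr$n - 1, -1, 1),
             h = stats::runif(tr$n, -1, 1))
}

random_leaf_pattern <- function(tree) {
  lv <- leaves(tree)
  v <- stats::setNames(sample(0:1, length(lv), replace = TRUE), lv)
  v[tree$labels[tree$reference]] <- 1L
  conservation_pattern(v, site_id = "t")
}

# enumerate all observable patterns (reference fixed present)
all_patterns <- function(tree) {
  lv <- leaves(tree)
  ref <- tree$labels[tree$reference]
  oth <- setdiff(lv, ref)
  lapply(0:(2^length(oth) - 1), function(m) {
    v <- stats::setNames(c(1L, bitwAnd(m %/% 2^(seq_along(oth) - 1), 1)),
                         c(ref, oth))
    conservation_pattern(v)
  })
}
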