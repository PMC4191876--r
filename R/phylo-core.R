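# Exact likelihood engine on the tree MRF.  The statistical weight of a full
# node configuration x (leaves + hidden ancestors) is
#   exp( sum_edges beta_e * 1[x_u = x_v] + sum_nodes h_v * x_v
#        + sigma * sum_nodes x_v ),
# and observed patterns are scored by integrating out the hidden ancestors
# with sum-product message passing, conditioning on presence in the reference
# species.

.allowed_mat <- function(tree, clamps, k = 2L) {
  al <- matrix(1L, tree$n, k)
  if (length(clamps)) {
    idx <- match(names(clamps), tree$labels)
    if (anyNA(idx))
      stop("clamp on unknown node: ",
           paste(names(clamps)[is.na(idx)], collapse = ", "))
    for (j in seq_along(idx)) {
      al[idx[j], ] <- 0L
      al[idx[j], clamps[j] + 1L] <- 1L
    }
  }
  al
}

#' Log partition function of the clamped tree MRF
#'
#' Log of the sum, over all configurations of the unclamped nodes, of the
#' statistical weight `exp(sum_e beta_e 1[x_u=x_v] + sum_v (h_v + sigma) x_v)`.
#' Computed in the log domain by upward message passing, O(states^2 * nodes);
#' overflow-free and bit-identical across calls.
#'
#' @param tree a [phylo_mrf()].
#' @param clamps named 0/1 vector of observed node states (may be empty).
#' @param sigma site conservation score added to the field of every node.
#' @return the log weight sum (a single number).
#' @export
log_weight_sum <- function(tree, clamps = NULL, sigma = 0) {
  stopifnot(inherits(tree, "phylo_mrf"))
  node_pot <- cbind(0, tree$h + sigma)
  al <- .allowed_mat(tree, clamps, 2L)
  mrf_logZ_cpp(tree$parent, tree$postorder, node_pot, tree$edge_pot2, al)
}

#' Conditional log-likelihood of one conservation pattern
#'
#' `log P_sigma(pattern | reference present)`: the clamped log weight sum over
#' all leaves (species absent from the pattern clamped to 0) minus the log
#' weight sum clamped only at the reference.  Conditioning on the reference
#' accounts for sites present in other species but unobservable in the
#' reference.
#'
#' @param tree a [phylo_mrf()].
#' @param pattern a [conservation_pattern()] over (a subset of) the leaves.
#' @param sigma conservation score.
#' @return log-likelihood (a single number).
#' @export
site_loglik <- function(tree, pattern, sigma = 0) {
  cl <- .pattern_clamps(tree, pattern)
  ref <- stats::setNames(1L, tree$labels[tree$reference])
  log_weight_sum(tree, cl, sigma) - log_weight_sum(tree, ref, sigma)
}

#' Optimizer settings for site and pair fits
#'
#' @param sigma_bounds,J_bounds finite search intervals containing 0.
#' @param loglik_tol convergence tolerance on the log-likelihood.
#' @param max_iter maximum coordinate-ascent sweeps for the pair fit.
#' @param n_grid number of coarse grid points per 1-D maximization.
#' @param n_starts reserved for multi-start refinements.
#' @return a list of class `optimizer_settings`.
#' @export
optimizer_settings <- function(sigma_bounds = c(-15, 15), J_bounds = c(-10, 10),
                               loglik_tol = 1e-6, max_iter = 50L,
                               n_grid = 41L, n_starts = 1L) {
  stopifnot(all(is.finite(sigma_bounds)), all(is.finite(J_bounds)),
            sigma_bounds[1] < 0, sigma_bounds[2] > 0,
            J_bounds[1] < 0, J_bounds[2] > 0, loglik_tol > 0)
  structure(list(sigma_bounds = sigma_bounds, J_bounds = J_bounds,
                 loglik_tol = loglik_tol, max_iter = as.integer(max_iter),
                 n_grid = as.integer(n_grid), n_starts = as.integer(n_starts)),
            class = "optimizer_settings")
}

# 1-D maximization: coarse grid (plus caller-supplied extra points), then
# Brent refinement on the bracketing interval around the best grid point
.max1d <- function(f, bounds, n_grid = 41L, extra = 0, tol = 1e-6) {
  grid <- sort(unique(c(seq(bounds[1], bounds[2], length.out = n_grid), extra)))
  vals <- vapply(grid, f, 0)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  best <- list(maximum = grid[i], objective = vals[i])
  if (hi > lo) {
    op <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
    if (op$objective > best$objective)
      best <- list(maximum = op$maximum, objective = op$objective)
  }
  best
}

#' Fit the per-site conservation score
#'
#' Maximizes [site_loglik()] over `sigma` by a coarse grid followed by Brent
#' refinement, and reports the conservation log-likelihood ratio
#' `D = loglik(sigma_hat) - loglik(0)` of the tilted model against the
#' background.
#'
#' @inheritParams site_loglik
#' @param opts an [optimizer_settings()].
#' @return a list of class `site_score` with `sigma_hat`, `loglik_at_hat`,
#'   `loglik_at_zero`, `D`, plus the site/gene ids of the pattern.
#' @export
fit_sigma <- function(tree, pattern, opts = optimizer_settings()) {
  cl <- .pattern_clamps(tree, pattern)
  ref <- stats::setNames(1L, tree$labels[tree$reference])
  f <- function(s) log_weight_sum(tree, cl, s) - log_weight_sum(tree, ref, s)
  best <- .max1d(f, opts$sigma_bounds, opts$n_grid, extra = 0,
                 tol = opts$loglik_tol)
  ll0 <- f(0)
  if (!is.finite(best$objective) || !is.finite(ll0))
    stop("non-finite likelihood for site ", pattern$site_id %||% "<unnamed>")
  structure(list(site_id = pattern$site_id, gene_id = pattern$gene_id,
                 sigma_hat = best$maximum, loglik_at_hat = best$objective,
                 loglik_at_zero = ll0, D = best$objective - ll0),
            class = "site_score")
}

#' Fit conservation scores for many patterns on one tree
#'
#' Same estimator as [fit_sigma()] but amortizes the sigma-dependent
#' normalizer (which is shared by all patterns on a tree) across sites.
#'
#' @param tree a [phylo_mrf()].
#' @param patterns list of [conservation_pattern()]s.
#' @param opts an [optimizer_settings()].
#' @return data.frame with one row per pattern: `site_id`, `gene_id`,
#'   `sigma_hat`, `loglik_at_hat`, `loglik_at_zero`, `D`.
#' @export
fit_sigma_batch <- function(tree, patterns, opts = optimizer_settings()) {
  ref <- stats::setNames(1L, tree$labels[tree$reference])
  memo <- new.env(parent = emptyenv())
  norm <- function(s) {
    key <- sprintf("%.17g", s)
    v <- memo[[key]]
    if (is.null(v)) {
      v <- log_weight_sum(tree, ref, s)
      memo[[key]] <- v
    }
    v
  }
  rows <- lapply(patterns, function(p) {
    cl <- .pattern_clamps(tree, p)
    f <- function(s) log_weight_sum(tree, cl, s) - norm(s)
    best <- .max1d(f, opts$sigma_bounds, opts$n_grid, tol = opts$loglik_tol)
    ll0 <- f(0)
    data.frame(site_id = p$site_id %||% NA_character_,
               gene_id = p$gene_id %||% NA_character_,
               sigma_hat = best$maximum, loglik_at_hat = best$objective,
               loglik_at_zero = ll0, D = best$objective - ll0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# composite-chain (pair) machinery: state s = x + 2*y in {0,..,3}
.pair_node_pot <- function(treeX, treeY, sigma1, sigma2, J) {
  x <- c(0, 1, 0, 1); y <- c(0, 0, 1, 1)
  hx <- treeX$h + sigma1; hy <- treeY$h + sigma2
  outer(hx, x) + outer(hy, y) + J * outer(rep(1, treeX$n), x * y)
}

.pair_allowed <- function(treeX, clX, clY) {
  al <- matrix(1L, treeX$n, 4L)
  x <- c(0L, 1L, 0L, 1L); y <- c(0L, 0L, 1L, 1L)
  set1 <- function(al, clamps, chain) {
    idx <- match(names(clamps), treeX$labels)
    if (anyNA(idx))
      stop("clamp on unknown node: ",
           paste(names(clamps)[is.na(idx)], collapse = ", "))
    for (j in seq_along(idx)) {
      keep <- if (chain == 1L) x == clamps[j] else y == clamps[j]
      al[idx[j], !keep] <- 0L
    }
    al
  }
  al <- set1(al, clX, 1L)
  set1(al, clY, 2L)
}

.check_same_topology <- function(treeX, treeY) {
  if (treeX$n != treeY$n || !identical(treeX$parent, treeY$parent) ||
      !identical(treeX$labels, treeY$labels) ||
      treeX$reference != treeY$reference)
    stop("the two trees must share topology, labels and reference")
}

#' Joint log-likelihood of two patterns under the coupled pair model
#'
#' The two sites evolve on the same topology (background parameters may differ
#' when the sites lie in different genes) with a composite per-node state
#' `(x_v, y_v)` and an extra coupling term `J * sum_v x_v * y_v` over all
#' nodes including hidden ancestors.  At `J = 0` this equals
#' `site_loglik(X) + site_loglik(Y)` exactly.
#'
#' @param treeX,treeY [phylo_mrf()]s with identical topology and reference.
#' @param patX,patY the two [conservation_pattern()]s.
#' @param sigma1,sigma2 per-site conservation scores.
#' @param J pair coupling; positive favours simultaneous presence.
#' @return joint conditional log-likelihood (a single number).
#' @export
pair_loglik <- function(treeX, treeY, patX, patY, sigma1, sigma2, J) {
  .check_same_topology(treeX, treeY)
  clX <- .pattern_clamps(treeX, patX)
  clY <- .pattern_clamps(treeY, patY)
  ep <- .edge_pot(treeX, k = 4L, beta_y = treeY$beta)
  ref_lab <- treeX$labels[treeX$reference]
  refc <- stats::setNames(1L, ref_lab)
  np <- .pair_node_pot(treeX, treeY, sigma1, sigma2, J)
  num <- mrf_logZ_cpp(treeX$parent, treeX$postorder, np, ep,
                      .pair_allowed(treeX, clX, clY))
  den <- mrf_logZ_cpp(treeX$parent, treeX$postorder, np, ep,
                      .pair_allowed(treeX, refc, refc))
  num - den
}

#' Fit the pair coupling and re-fitted site scores
#'
#' Maximizes the coupled joint likelihood over `(sigma1, sigma2, J)` by
#' coordinate ascent (each 1-D step by grid + Brent refinement), initialized
#' at the independent fits with `J = 0` so that the log-likelihood ratio
#' `deltaL` against the independent model is non-negative up to tolerance.
#' The site scores are re-fitted jointly because the independent estimates may
#' absorb a contribution that belongs to the coupling term.
#'
#' @inheritParams pair_loglik
#' @param opts an [optimizer_settings()].
#' @param pair_cutoff log-likelihood-ratio cutoff used to set the `sign`
#'   classification (natural-log units).
#' @return a list of class `pair_score`: `sigma1_joint`, `sigma2_joint`,
#'   `J_hat`, `deltaL`, `loglik_joint`, `sign`, `converged`.
#' @export
fit_pair <- function(treeX, treeY, patX, patY, opts = optimizer_settings(),
                     pair_cutoff = 2.0) {
  .check_same_topology(treeX, treeY)
  # canonical site order (by clamp string) makes the fit exactly invariant
  # under swapping the two sites
  keyX <- paste(c(.pattern_clamps(treeX, patX), signif(treeX$h, 12)),
                collapse = ",")
  keyY <- paste(c(.pattern_clamps(treeY, patY), signif(treeY$h, 12)),
                collapse = ",")
  if (keyY < keyX) {
    sw <- fit_pair(treeY, treeX, patY, patX, opts, pair_cutoff)
    return(structure(list(site1 = patX$site_id, site2 = patY$site_id,
                          sigma1_joint = sw$sigma2_joint,
                          sigma2_joint = sw$sigma1_joint,
                          J_hat = sw$J_hat, deltaL = sw$deltaL,
                          loglik_joint = sw$loglik_joint,
                          converged = sw$converged, sign = sw$sign),
                     class = "pair_score"))
  }
  fx <- fit_sigma(treeX, patX, opts)
  fy <- fit_sigma(treeY, patY, opts)
  clX <- .pattern_clamps(treeX, patX)
  clY <- .pattern_clamps(treeY, patY)
  ep <- .edge_pot(treeX, k = 4L, beta_y = treeY$beta)
  ref_lab <- treeX$labels[treeX$reference]
  refc <- stats::setNames(1L, ref_lab)
  al_num <- .pair_allowed(treeX, clX, clY)
  al_den <- .pair_allowed(treeX, refc, refc)
  f3 <- function(s1, s2, J) {
    np <- .pair_node_pot(treeX, treeY, s1, s2, J)
    mrf_logZ_cpp(treeX$parent, treeX$postorder, np, ep, al_num) -
      mrf_logZ_cpp(treeX$parent, treeX$postorder, np, ep, al_den)
  }
  th <- c(fx$sigma_hat, fy$sigma_hat, 0)
  ll <- f3(th[1], th[2], th[3])
  ngrid <- max(11L, opts$n_grid %/% 2L)
  converged <- FALSE
  for (sweep in seq_len(opts$max_iter)) {
    ll_prev <- ll
    for (j in 1:3) {
      bounds <- if (j == 3) opts$J_bounds else opts$sigma_bounds
      g <- function(v) {
        t2 <- th; t2[j] <- v
        f3(t2[1], t2[2], t2[3])
      }
      best <- .max1d(g, bounds, ngrid, extra = th[j], tol = opts$loglik_tol)
      # a move must buy a tolerance-sized gain: on a flat profile the nested
      # value (J = 0, independent sigmas) is kept rather than drifting
      if (best$objective > ll + opts$loglik_tol) {
        th[j] <- best$maximum
        ll <- best$objective
      }
    }
    if (ll - ll_prev < opts$loglik_tol) {
      converged <- TRUE
      break
    }
    if (sweep >= 2L) break # hand the ridge over to the quasi-Newton polish
  }
  # coordinate ascent alone creeps along the ridge that opens up when the two
  # patterns (nearly) coincide; a bounded quasi-Newton polish from the ascent
  # point settles it
  if (!converged) {
    op <- try(stats::optim(th, function(t2) f3(t2[1], t2[2], t2[3]),
                           method = "L-BFGS-B",
                           lower = c(opts$sigma_bounds[1], opts$sigma_bounds[1],
                                     opts$J_bounds[1]),
                           upper = c(opts$sigma_bounds[2], opts$sigma_bounds[2],
                                     opts$J_bounds[2]),
                           control = list(fnscale = -1,
                                          maxit = 10L * opts$max_iter)),
              silent = TRUE)
    if (!inherits(op, "try-error") && op$value > ll + opts$loglik_tol) {
      th <- op$par
      ll <- op$value
      converged <- op$convergence == 0
    } else if (!inherits(op, "try-error")) {
      converged <- TRUE # no tolerance-sized gain left anywhere
    }
  }
  if (!converged)
    warning("pair fit did not converge for pair (",
            patX$site_id %||% "?", ", ", patY$site_id %||% "?", ")")
  deltaL <- ll - (fx$loglik_at_hat + fy$loglik_at_hat)
  score <- structure(list(
    site1 = patX$site_id, site2 = patY$site_id,
    sigma1_joint = th[1], sigma2_joint = th[2], J_hat = th[3],
    deltaL = deltaL, loglik_joint = ll, converged = converged,
    sign = NA_character_), class = "pair_score")
  score$sign <- classify_pair(score, pair_cutoff)
  score
}

#' @export
print.site_score <- function(x, ...) {
  cat(sprintf("site_score %s (gene %s): sigma_hat = %.3f, D = %.3f\n",
              x$site_id %||% "?", x$gene_id %||% "?", x$sigma_hat, x$D))
  invisible(x)
}

#' @export
print.pair_score <- function(x, ...) {
  cat(sprintf(
    "pair_score (%s, %s): J_hat = %.3f, deltaL = %.3f, sign = %s%s\n",
    x$site1 %||% "?", x$site2 %||% "?", x$J_hat, x$deltaL, x$sign,
    if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

#' Classify a fitted pair as positively/negatively correlated or neither
#'
#' A pair is correlated when its log-likelihood ratio `deltaL` reaches the
#' cutoff; the direction is the sign of the fitted coupling (an exact tie
#' `J_hat = 0` is classified as none).
#'
#' @param score a `pair_score` (or any list with `deltaL` and `J_hat`).
#' @param cutoff positive log-likelihood-ratio cutoff (natural-log units).
#' @return one of `"positive"`, `"negative"`, `"none"`.
#' @export
classify_pair <- function(score, cutoff = 2.0) {
  stopifnot(cutoff > 0)
  if (score$deltaL >= cutoff && score$J_hat > 0) return("positive")
  if (score$deltaL >= cutoff && score$J_hat < 0) return("negative")
  "none"
}
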