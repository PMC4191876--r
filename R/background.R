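# Species- and gene-class-specific background of K-mer conservation.  The
# empirical inputs are, per gene class, the fraction of reference-UTR K-mers
# present in each other species and simultaneously present in each species
# pair; the tree MRF parameters are fitted to reproduce both sets of moments.

#' Empirical K-mer conservation statistics
#'
#' @param f_s named vector: fraction of reference K-mers present in each
#'   species.
#' @param f_st symmetric matrix of joint presence fractions (same species
#'   order).
#' @param n_kmers number of supporting K-mers.
#' @return an object of class `kmer_stats`.
#' @export
kmer_stats <- function(f_s, f_st, n_kmers) {
  sp <- names(f_s)
  stopifnot(!is.null(sp), is.matrix(f_st),
            identical(rownames(f_st), sp), identical(colnames(f_st), sp))
  if (any(f_s < 0 | f_s > 1)) stop("f_s must lie in [0, 1]")
  lim <- outer(f_s, f_s, pmin)
  bad <- f_st > lim + 1e-12 | f_st < -1e-12
  diag(bad) <- FALSE
  if (any(bad)) stop("f_st must satisfy 0 <= f_st <= min(f_s, f_t)")
  if (n_kmers < 0) stop("n_kmers must be >= 0")
  structure(list(species = sp, f_s = f_s, f_st = f_st,
                 n_kmers = as.integer(n_kmers)), class = "kmer_stats")
}

#' Per-species and per-pair conservation frequencies from patterns
#'
#' @param patterns list of [conservation_pattern()]s over background K-mers.
#' @param species the (non-reference) species to tabulate; patterns lacking a
#'   species count it as absent.
#' @return a [kmer_stats()].
#' @export
compute_kmer_stats <- function(patterns, species) {
  if (!length(patterns)) stop("no patterns supplied")
  m <- vapply(patterns, function(p) {
    v <- stats::setNames(rep(0L, length(species)), species)
    keep <- intersect(names(p$values), species)
    v[keep] <- p$values[keep]
    v
  }, integer(length(species)))
  m <- matrix(m, nrow = length(species),
              dimnames = list(species, NULL)) # species x patterns
  f_s <- rowMeans(m)
  f_st <- (m %*% t(m)) / ncol(m)
  kmer_stats(f_s, f_st, n_kmers = ncol(m))
}

#' Exact single and pair presence marginals of the background model
#'
#' `p_s = P(x_s = 1 | x_ref = 1)` and `p_st = P(x_s = x_t = 1 | x_ref = 1)`
#' at `sigma = 0`, computed by clamped message passing.
#'
#' @param tree a [phylo_mrf()].
#' @return list with `species` (non-reference leaves), `p_s` (named vector)
#'   and `p_st` (symmetric matrix with `p_s` on the diagonal).
#' @export
model_marginals <- function(tree) {
  ref_lab <- tree$labels[tree$reference]
  sp <- setdiff(leaves(tree), ref_lab)
  ref <- stats::setNames(1L, ref_lab)
  lZ0 <- log_weight_sum(tree, ref, 0)
  p_s <- vapply(sp, function(s) {
    exp(log_weight_sum(tree, c(ref, stats::setNames(1L, s)), 0) - lZ0)
  }, 0)
  p_st <- diag(p_s, nrow = length(sp))
  dimnames(p_st) <- list(sp, sp)
  if (length(sp) > 1) {
    for (i in seq_len(length(sp) - 1)) for (j in (i + 1):length(sp)) {
      cl <- c(ref, stats::setNames(c(1L, 1L), sp[c(i, j)]))
      p_st[i, j] <- p_st[j, i] <- exp(log_weight_sum(tree, cl, 0) - lZ0)
    }
  }
  list(species = sp, p_s = p_s, p_st = p_st)
}

#' Assign genes to conservation classes by quantile binning
#'
#' Genes are ranked by the mean of their per-species conservation vector
#' (ties broken by gene id) and split into `n_classes` equipopulated bins.
#' Each class later receives its own background fit, absorbing UTR-level
#' conservation heterogeneity.
#'
#' @param per_gene_stats matrix (genes x species) of per-species conservation
#'   fractions, with gene ids as row names.
#' @param n_classes number of classes (>= 1).
#' @return list of class `gene_class_assignment`: `class` (named integer,
#'   1-based), `profile` (class x species mean conservation).
#' @export
assign_gene_classes <- function(per_gene_stats, n_classes = 20L) {
  stopifnot(is.matrix(per_gene_stats), !is.null(rownames(per_gene_stats)),
            n_classes >= 1)
  genes <- rownames(per_gene_stats)
  if (length(genes) < n_classes)
    stop("need at least as many genes as classes")
  mu <- rowMeans(per_gene_stats)
  ord <- order(mu, genes)
  cls <- integer(length(genes))
  cls[ord] <- as.integer(ceiling(seq_along(ord) * n_classes / length(ord)))
  names(cls) <- genes
  prof <- do.call(rbind, lapply(seq_len(n_classes), function(k) {
    colMeans(per_gene_stats[cls == k, , drop = FALSE])
  }))
  rownames(prof) <- seq_len(n_classes)
  structure(list(class = cls, profile = prof),
            class = "gene_class_assignment")
}

#' Fit background parameters to empirical conservation moments
#'
#' Least-squares moment matching: minimizes
#' `sum_s (p_s - f_s)^2 + sum_{s<t} (p_st - f_st)^2`
#' over the edge couplings and node fields by quasi-Newton descent with
#' numerical gradients and random restarts.  The pair constraints are what
#' force the model to carry genuine phylogenetic correlation, not just the
#' right per-species frequencies.  Only the fitted distribution is meant to be
#' reproducible; individual parameters need not be identified.
#'
#' @param tree a [phylo_mrf()] providing topology and reference; its current
#'   parameters seed the first start.
#' @param stats a [kmer_stats()] covering all non-reference leaves.
#' @param n_starts random restarts (first start at the supplied parameters).
#' @param maxit iteration cap per start.
#' @param seed integer seed for the random restarts.
#' @param fix_beta optional number: pin all edge couplings to this value and
#'   fit only the fields (used for the no-phylogeny variant).
#' @return list of class `background_fit`: `tree` (fitted), `residual`
#'   (root-mean-square moment mismatch), `objective`, `converged`.
#' @export
fit_background <- function(tree, stats, n_starts = 3L, maxit = 500L,
                           seed = 1L, fix_beta = NULL) {
  ref_lab <- tree$labels[tree$reference]
  sp <- setdiff(leaves(tree), ref_lab)
  if (!all(sp %in% stats$species))
    stop("stats must cover all non-reference leaves")
  f_s <- stats$f_s[sp]
  f_st <- stats$f_st[sp, sp, drop = FALSE]
  ut <- upper.tri(f_st)
  nonroot <- setdiff(seq_len(tree$n), tree$root)
  free_h <- setdiff(seq_len(tree$n), tree$reference) # reference field cancels
  nb <- if (is.null(fix_beta)) length(nonroot) else 0L

  unpack <- function(theta) {
    tr <- tree
    beta <- if (nb) theta[seq_len(nb)] else rep(fix_beta, length(nonroot))
    tr$beta[nonroot] <- beta
    tr$h[free_h] <- theta[nb + seq_along(free_h)]
    tr$edge_pot2 <- .edge_pot(tr, k = 2L)
    tr
  }
  objective <- function(theta) {
    mm <- model_marginals(unpack(theta))
    sum((mm$p_s[sp] - f_s)^2) + sum((mm$p_st[sp, sp][ut] - f_st[ut])^2)
  }

  set.seed(seed)
  starts <- vector("list", n_starts)
  starts[[1]] <- c(if (nb) tree$beta[nonroot], tree$h[free_h])
  if (n_starts > 1) for (i in 2:n_starts)
    starts[[i]] <- c(if (nb) stats::runif(nb, 0, 2),
                     stats::runif(length(free_h), -2, 1))
  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, objective, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  n_mom <- length(f_s) + sum(ut)
  residual <- sqrt(best$value / n_mom)
  structure(list(tree = unpack(best$par), residual = residual,
                 objective = best$value,
                 converged = best$convergence == 0 || residual < 1e-3),
            class = "background_fit")
}

#' Species-only (no-phylogeny) background as a degenerate star tree
#'
#' Builds a star phylogeny with zero edge couplings whose leaf fields
#' reproduce the per-species presence frequencies exactly
#' (`h_s = logit(f_s)`).  Serves as the baseline model that ignores shared
#' ancestry.
#'
#' @param stats a [kmer_stats()].
#' @param reference reference leaf label (added to the star).
#' @return a [phylo_mrf()].
#' @export
star_background <- function(stats, reference) {
  sp <- setdiff(stats$species, reference)
  nwk <- paste0("(", paste(c(reference, sp), collapse = ","), ");")
  f <- pmin(pmax(stats$f_s[sp], 1e-6), 1 - 1e-6)
  h <- stats::setNames(logit(f), sp)
  phylo_mrf(nwk, beta = 0, h = h, reference = reference)
}
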