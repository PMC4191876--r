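# Synthetic data: exact samples from the tree MRF with planted sigma and J,
# random phylogenies, and a toy alignment bundle (MAF + BED + seed table +
# GMT + expression) so the whole pipeline runs without any download.

#' Random phylogeny with a conservation-like parameter profile
#'
#' Pure-birth topology; edge couplings drawn log-uniformly; node fields
#' decreasing with topological distance from the reference leaf, emulating the
#' typical decay of background K-mer conservation with phylogenetic distance.
#'
#' @param n_leaves number of species (>= 2); leaves are labelled `sp1..spN`
#'   with `sp1` the reference.
#' @param beta_range range for the log-uniform edge couplings.
#' @param h0 field at the reference; fields decrease from it.
#' @param h_slope decrease of the field per topological step away from the
#'   reference; the default `NULL` scales it so the most distant species
#'   sits at `h_floor`, giving every tree the same conservation span from
#'   near-full (close species) to the floor, as in real alignments where the
#'   profile spans roughly the same range whatever the species count.
#' @param h_floor field of the most distant species: background K-mer
#'   conservation decays to a floor of several percent, not to zero, and
#'   species below that floor would carry no information.
#' @param seed optional integer seed.
#' @return a [phylo_mrf()].
#' @export
random_phylogeny <- function(n_leaves, beta_range = c(0.5, 2), h0 = 2,
                             h_slope = NULL, h_floor = -2, seed = NULL) {
  stopifnot(n_leaves >= 2)
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rphylo(n_leaves, birth = 1, death = 0)
  phy$tip.label <- paste0("sp", seq_len(n_leaves))
  phy$edge.length <- rep(1, nrow(phy$edge))
  d <- ape::dist.nodes(phy)[1, ] # topological distance from sp1
  if (is.null(h_slope)) h_slope <- (h0 - h_floor) / max(d)
  n <- n_leaves + phy$Nnode
  beta <- exp(stats::runif(n - 1, log(beta_range[1]), log(beta_range[2])))
  tr <- phylo_mrf(phy, beta = 0, h = 0, reference = "sp1")
  set_params(tr, beta = beta, h = pmax(h0 - h_slope * d, h_floor))
}

# draw n exact samples of the full node configuration given potentials/clamps
.sample_states <- function(tree, node_pot, edge_pot, allowed, n) {
  k <- ncol(node_pot)
  msg <- mrf_messages_cpp(tree$parent, tree$postorder, node_pot, edge_pot,
                          allowed)
  states <- matrix(0L, tree$n, n)
  states[tree$root, ] <- sample.int(k, n, replace = TRUE,
                                    prob = msg$root_dist) - 1L
  for (v in rev(tree$postorder)) {
    if (v == tree$root) next
    sp_states <- states[tree$parent[v], ]
    for (s in unique(sp_states)) {
      idx <- which(sp_states == s)
      states[v, idx] <- sample.int(k, length(idx), replace = TRUE,
                                   prob = msg$cond[v, s + 1L, ]) - 1L
    }
  }
  states
}

#' Exact samples of conservation patterns from the tree MRF
#'
#' Ancestral sampling: upward messages with the reference clamped to present,
#' a root draw from its posterior, then downward conditional draws.  The
#' sampler is exact; empirical frequencies converge to [model_marginals()].
#'
#' @param tree a [phylo_mrf()].
#' @param sigma planted conservation score.
#' @param n number of patterns.
#' @param condition_reference clamp the reference to present (the observation
#'   process of reference-anchored alignments).
#' @param seed optional integer seed.
#' @return list of [conservation_pattern()]s over all leaves.
#' @export
sample_patterns <- function(tree, sigma = 0, n = 1L,
                            condition_reference = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  node_pot <- cbind(0, tree$h + sigma)
  clamps <- if (condition_reference)
    stats::setNames(1L, tree$labels[tree$reference]) else NULL
  al <- .allowed_mat(tree, clamps, 2L)
  st <- .sample_states(tree, node_pot, tree$edge_pot2, al, n)
  lv <- which(tree$is_leaf)
  lapply(seq_len(n), function(i) {
    conservation_pattern(stats::setNames(st[lv, i], tree$labels[lv]),
                         site_id = paste0("sim", i))
  })
}

#' Exact samples of coupled pattern pairs
#'
#' Samples from the composite 4-state chain with planted `(sigma1, sigma2, J)`,
#' both references clamped to present.  At `J = 0` this reduces to two
#' independent [sample_patterns()] draws.
#'
#' @inheritParams pair_loglik
#' @param n number of pairs.
#' @param seed optional integer seed.
#' @return list of `list(x = , y = )` pattern pairs.
#' @export
sample_pattern_pairs <- function(treeX, treeY, sigma1 = 0, sigma2 = 0, J = 0,
                                 n = 1L, seed = NULL) {
  .check_same_topology(treeX, treeY)
  if (!is.null(seed)) set.seed(seed)
  np <- .pair_node_pot(treeX, treeY, sigma1, sigma2, J)
  ep <- .edge_pot(treeX, k = 4L, beta_y = treeY$beta)
  ref <- stats::setNames(1L, treeX$labels[treeX$reference])
  al <- .pair_allowed(treeX, ref, ref)
  st <- .sample_states(treeX, np, ep, al, n)
  lv <- which(treeX$is_leaf)
  labs <- treeX$labels[lv]
  lapply(seq_len(n), function(i) {
    s <- st[lv, i]
    list(x = conservation_pattern(stats::setNames(s %% 2L, labs),
                                  site_id = paste0("simx", i)),
         y = conservation_pattern(stats::setNames(s %/% 2L, labs),
                                  site_id = paste0("simy", i)))
  })
}

# ---- toy bundle -----------------------------------------------------------

.RC <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")

.revcomp_dna <- function(x) {
  paste(rev(.RC[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

#' Specification of a synthetic alignment bundle
#'
#' @param n_species number of species in the planted phylogeny.
#' @param n_genes number of genes (3'UTRs).
#' @param utr_length reference UTR length in nt.
#' @param sigma_true planted conservation score of independent planted sites.
#' @param J_true planted coupling of planted site pairs.
#' @param sigma_coupled per-site score of the coupled pairs; kept below
#'   `sigma_true` because the coupling itself raises presence, so coupled
#'   sites would otherwise saturate and carry no correlation information.
#' @param n_coupled_genes genes whose first two sites are planted as a
#'   coupled (close) pair; the remaining genes carry independent sites.
#' @param sites_per_gene planted sites per gene; the first two lie 70 nt
#'   apart (a close pair), the rest spread over the UTR.
#' @param footprint_fraction fraction of planted sites covered by a planted
#'   AGO-footprint interval.
#' @param seed integer seed recorded in all outputs.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_species = 10L, n_genes = 12L, utr_length = 600L,
                            sigma_true = 1, J_true = 2.5,
                            sigma_coupled = -1,
                            n_coupled_genes = 10L, sites_per_gene = 3L,
                            footprint_fraction = 0.4, seed = 1L) {
  stopifnot(n_genes >= n_coupled_genes, sites_per_gene >= 1)
  structure(list(n_species = n_species, n_genes = n_genes,
                 utr_length = utr_length, sigma_true = sigma_true,
                 J_true = J_true, sigma_coupled = sigma_coupled,
                 n_coupled_genes = n_coupled_genes,
                 sites_per_gene = sites_per_gene,
                 footprint_fraction = footprint_fraction,
                 seed = as.integer(seed)), class = "simulation_spec")
}

# seeds of well-known deeply conserved miRNA families (positions 2-8)
.DEFAULT_SEEDS <- data.frame(
  family_id = c("let-7", "miR-1", "miR-124"),
  seed7 = c("GAGGUAG", "GGAAUGU", "AAGGCAC"),
  n_members = c(9L, 2L, 3L),
  stringsAsFactors = FALSE
)

# random DNA with roughly uniform composition
.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

#' Write a toy multi-species alignment bundle
#'
#' Generates reference 3'UTRs with planted seed matches whose conservation
#' patterns are exact draws from the planted tree MRF at `sigma_true` (and,
#' for coupled genes, pattern pairs at `J_true`), realizes them in per-species
#' alignment rows (absence rendered as a substitution or an alignment gap with
#' equal probability), mutates non-site background at a per-species divergence
#' rate that grows with distance from the reference, and writes MAF, UTR BED,
#' seed TSV, footprint BED, GMT gene sets, an expression matrix and a manifest
#' of planted truths.  The reference sequence is rejection-sampled so the only
#' seed matches present are the planted ones; scanning the bundle therefore
#' recovers the planted site matrix exactly.
#'
#' @param spec a [simulation_spec()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the planted `tree`, the `manifest`
#'   data.frame of planted sites, the planted pair table, and the file paths.
#' @export
emit_toy_bundle <- function(spec, out_dir) {
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  tree <- random_phylogeny(spec$n_species)
  species <- leaves(tree)
  ref <- tree$labels[tree$reference]
  seeds <- .DEFAULT_SEEDS

  # per-species background divergence grows with distance from the reference
  dd <- ape::dist.nodes(tree$phylo)[tree$reference, seq_len(spec$n_species)]
  div <- pmin(0.5, 0.04 * dd)
  names(div) <- species

  match8 <- function(seed7) paste0(.revcomp_dna(seed7), "A") # 8mer site
  site_len <- 8L

  genes <- sprintf("g%02d", seq_len(spec$n_genes))
  manifest <- NULL
  pair_truth <- NULL
  maf_lines <- character()
  utr_bed <- character()
  fp_bed <- character()

  for (gi in seq_along(genes)) {
    g <- genes[gi]
    gstart <- (gi - 1L) * 10000L
    L <- spec$utr_length
    # planted site layout (0-based offsets), rotating families; the first
    # two sites form a close pair (70 nt apart), the rest spread out
    fam_idx <- 1L + (gi + seq_len(spec$sites_per_gene)) %% nrow(seeds)
    pos <- round(seq(50L, L - 60L, length.out = spec$sites_per_gene))
    if (spec$sites_per_gene >= 2L) pos[2] <- pos[1] + 70L
    # reference sequence: random background, planted matches, rejection-
    # sampled until scanning the analysis types recovers exactly the plant
    repeat {
      refseq <- strsplit(.rand_dna(L), "")[[1]]
      for (j in seq_len(spec$sites_per_gene)) {
        m <- strsplit(match8(seeds$seed7[fam_idx[j]]), "")[[1]]
        refseq[pos[j] + seq_along(m)] <- m
      }
      sq <- paste(refseq, collapse = "")
      ok <- TRUE
      for (si in seq_len(nrow(seeds))) {
        hits <- seed_sites(seeds$seed7[si], sq,
                           types = c("8mer", "7merA1", "7merm8"))
        want <- sort(pos[fam_idx == si])
        if (nrow(hits) != length(want) ||
            !identical(sort(hits$position), as.integer(want)) ||
            !all(hits$type == "8mer")) ok <- FALSE
      }
      if (ok) break
    }

    # conservation patterns: coupled pair for the first genes, independent
    # sites otherwise
    pats <- vector("list", spec$sites_per_gene)
    coupled <- gi <= spec$n_coupled_genes && spec$sites_per_gene >= 2L
    if (coupled) {
      pp <- sample_pattern_pairs(tree, tree, spec$sigma_coupled,
                                 spec$sigma_coupled,
                                 spec$J_true, n = 1L)[[1]]
      pats[[1]] <- pp$x$values
      pats[[2]] <- pp$y$values
      if (spec$sites_per_gene > 2L)
        for (j in 3:spec$sites_per_gene)
          pats[[j]] <- sample_patterns(tree, spec$sigma_true, 1L)[[1]]$values
    } else {
      for (j in seq_len(spec$sites_per_gene))
        pats[[j]] <- sample_patterns(tree, spec$sigma_true, 1L)[[1]]$values
    }

    # species rows: background divergence outside sites, pattern inside
    rows <- stats::setNames(vector("list", length(species)), species)
    rows[[ref]] <- refseq
    for (s in setdiff(species, ref)) {
      row <- refseq
      mut <- stats::runif(L) < div[s]
      row[mut] <- sample(c("A", "C", "G", "T"), sum(mut), TRUE)
      for (j in seq_len(spec$sites_per_gene)) {
        span <- pos[j] + seq_len(site_len)
        m <- strsplit(match8(seeds$seed7[fam_idx[j]]), "")[[1]]
        if (pats[[j]][[s]] == 1L) {
          row[span] <- m
        } else {
          row[span] <- m
          hit <- span[sample.int(site_len, 1L)]
          if (stats::runif(1) < 0.5) {
            row[hit] <- sample(setdiff(c("A", "C", "G", "T"), row[hit]), 1L)
          } else {
            row[hit] <- "-"
          }
        }
      }
      rows[[s]] <- row
    }

    # one MAF block per gene (reference ungapped)
    maf_lines <- c(maf_lines, "a score=0.0", vapply(species, function(s) {
      sprintf("s %s.chr1 %d %d + 1000000 %s",
              s, gstart, L, paste(rows[[s]], collapse = ""))
    }, ""), "")
    utr_bed <- c(utr_bed,
                 sprintf("chr1\t%d\t%d\t%s\t0\t+", gstart, gstart + L, g))

    for (j in seq_len(spec$sites_per_gene)) {
      manifest <- rbind(manifest, data.frame(
        gene_id = g, family_id = seeds$family_id[fam_idx[j]], type = "8mer",
        position = pos[j], genomic_start = gstart + pos[j],
        pattern = paste(pats[[j]][species], collapse = ""),
        coupled = coupled && j <= 2L, stringsAsFactors = FALSE))
    }
    if (coupled)
      pair_truth <- rbind(pair_truth, data.frame(
        gene_id = g, pos1 = pos[1], pos2 = pos[2], J_true = spec$J_true,
        stringsAsFactors = FALSE))
  }

  # planted AGO footprints over a fraction of planted sites (40 nt windows)
  n_fp <- round(spec$footprint_fraction * nrow(manifest))
  if (n_fp > 0) {
    idx <- sample.int(nrow(manifest), n_fp)
    fp_bed <- sprintf("chr1\t%d\t%d\tfp%d\t0\t+",
                      pmax(0L, manifest$genomic_start[idx] - 16L),
                      manifest$genomic_start[idx] + 24L, seq_len(n_fp))
    manifest$in_footprint <- seq_len(nrow(manifest)) %in% idx
  } else {
    manifest$in_footprint <- FALSE
  }

  # gene sets: a "complex-like" set (coupled genes) and a random set
  coupled_genes <- genes[seq_len(spec$n_coupled_genes)]
  other <- setdiff(genes, coupled_genes)
  gmt <- c(paste(c("planted_set", "synthetic", coupled_genes),
                 collapse = "\t"),
           paste(c("random_set", "synthetic",
                   sample(genes, min(4L, length(genes)))), collapse = "\t"))

  # expression matrix: families x tissues, nonnegative
  tissues <- paste0("tissue", 1:6)
  expr <- matrix(stats::rexp(nrow(seeds) * length(tissues)),
                 nrow = nrow(seeds),
                 dimnames = list(seeds$family_id, tissues))

  paths <- list(
    maf = file.path(out_dir, "alignment.maf"),
    utrs = file.path(out_dir, "utrs.bed"),
    seeds = file.path(out_dir, "seeds.tsv"),
    footprints = file.path(out_dir, "footprints.bed"),
    genesets = file.path(out_dir, "genesets.gmt"),
    expression = file.path(out_dir, "expression.tsv"),
    tree = file.path(out_dir, "tree.nwk"),
    params = file.path(out_dir, "tree_params.tsv"),
    manifest = file.path(out_dir, "manifest.tsv"),
    pairs_truth = file.path(out_dir, "planted_pairs.tsv")
  )
  writeLines(c(sprintf("##maf version=1 scoring=none seed=%d", spec$seed),
               "", maf_lines), paths$maf)
  writeLines(utr_bed, paths$utrs)
  utils::write.table(seeds, paths$seeds, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(fp_bed, paths$footprints)
  writeLines(gmt, paths$genesets)
  utils::write.table(data.frame(family_id = rownames(expr), expr,
                                check.names = FALSE),
                     paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ape::write.tree(.as_phylo_labeled(tree), paths$tree)
  write_mrf_params(tree, paths$params)
  manifest$seed <- spec$seed
  utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(pair_truth)) {
    pair_truth$seed <- spec$seed
    utils::write.table(pair_truth, paths$pairs_truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(tree = tree, manifest = manifest, pairs = pair_truth,
                 species = species, paths = paths))
}

# ape phylo with internal labels kept so the parameter sidecar round-trips
.as_phylo_labeled <- function(tree) {
  phy <- tree$phylo
  phy$node.label <- tree$labels[!tree$is_leaf]
  phy
}
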