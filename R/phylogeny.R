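#' Phylogeny with conservation couplings and occupancy fields
#'
#' Builds the tree-structured Markov random field used as the background model
#' of site conservation.  Each node (leaf species or hidden ancestor) carries a
#' binary presence/absence state; each edge carries a coupling `beta` rewarding
#' agreement between parent and child (the branch-length-like parameter), and
#' each node carries a field `h` setting its equilibrium presence probability
#' (the equilibrium-frequency-like parameter, allowed to vary along the tree).
#' One leaf is designated the reference species: all likelihoods in the package
#' are conditioned on site presence in the reference.
#'
#' @param topology an [ape::phylo] object, a newick string, or a path to a
#'   newick file.  Internal nodes without labels are auto-named `anc1`,
#'   `anc2`, ...
#' @param beta edge couplings: a single number recycled to every edge, or a
#'   named vector keyed by child-node label (each edge is identified by the
#'   node below it).  Dimensionless; larger values mean stronger agreement
#'   along the branch.
#' @param h occupancy fields: a single number recycled to every node, or a
#'   named vector keyed by node label.
#' @param reference label of the reference leaf.
#' @return an object of class `phylo_mrf`.
#' @examples
#' tr <- phylo_mrf("((human,chimp),mouse);", beta = 1, h = -0.5,
#'                 reference = "human")
#' @export
phylo_mrf <- function(topology, beta = 0, h = 0, reference) {
  phy <- topology
  if (is.character(phy)) {
    phy <- if (grepl("\\(", phy[1])) ape::read.tree(text = phy) else ape::read.tree(phy)
  }
  if (!inherits(phy, "phylo")) stop("topology must be a phylo object or newick")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  n <- ntip + nnode
  node_lab <- phy$node.label
  if (is.null(node_lab) || !length(node_lab) || any(!nzchar(node_lab)))
    node_lab <- paste0("anc", seq_len(nnode))
  labels <- c(phy$tip.label, node_lab)
  if (anyDuplicated(labels)) stop("duplicate node labels in topology")

  parent <- integer(n)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- which(parent == 0L)
  if (length(root) != 1L) stop("tree must have exactly one root")

  po_edge <- ape::reorder.phylo(phy, "postorder")$edge
  postorder <- c(po_edge[, 2], root)

  is_leaf <- seq_len(n) <= ntip
  if (missing(reference)) stop("a reference leaf must be designated")
  ref <- match(reference, labels)
  if (is.na(ref) || !is_leaf[ref]) stop("reference must name a leaf: ", reference)

  expand <- function(x, ids, what) {
    if (length(x) == 1L && is.null(names(x))) {
      out <- rep(as.numeric(x), length(ids))
    } else {
      if (is.null(names(x))) stop(what, " must be scalar or named by node label")
      out <- rep(0, length(ids))
      idx <- match(names(x), labels[ids])
      if (anyNA(idx)) stop("unknown node in ", what, ": ",
                           paste(names(x)[is.na(idx)], collapse = ", "))
      out[idx] <- as.numeric(x)
    }
    out
  }
  nonroot <- setdiff(seq_len(n), root)
  beta_full <- rep(NA_real_, n)
  beta_full[nonroot] <- expand(beta, nonroot, "beta")
  h_full <- expand(h, seq_len(n), "h")
  if (any(!is.finite(beta_full[nonroot]))) stop("all beta must be finite")
  if (any(!is.finite(h_full))) stop("all h must be finite")

  tr <- structure(list(
    n = n, labels = labels, parent = parent, postorder = as.integer(postorder),
    is_leaf = is_leaf, root = root, reference = ref,
    beta = beta_full, h = h_full, phylo = phy
  ), class = "phylo_mrf")
  tr$edge_pot2 <- .edge_pot(tr, k = 2L)
  tr
}

# k-state agreement edge potentials; for the composite (pair) chain the state
# is s = x + 2*y and both sub-chains contribute their own beta
.edge_pot <- function(tree, k = 2L, beta_y = NULL) {
  n <- tree$n
  ep <- array(0, dim = c(k, k, n))
  for (v in seq_len(n)) {
    if (v == tree$root) next
    b <- tree$beta[v]
    if (k == 2L) {
      ep[, , v] <- matrix(c(b, 0, 0, b), 2, 2)
    } else {
      by <- beta_y[v]
      x <- rep(c(0L, 1L), 2); y <- rep(c(0L, 1L), each = 2)
      for (sp in 1:4) for (sc in 1:4)
        ep[sp, sc, v] <- b * (x[sp] == x[sc]) + by * (y[sp] == y[sc])
    }
  }
  ep
}

#' @export
print.phylo_mrf <- function(x, ...) {
  cat(sprintf("phylo_mrf: %d nodes (%d leaves), reference '%s'\n",
              x$n, sum(x$is_leaf), x$labels[x$reference]))
  cat(sprintf("  beta range [%.3g, %.3g], h range [%.3g, %.3g]\n",
              min(x$beta, na.rm = TRUE), max(x$beta, na.rm = TRUE),
              min(x$h), max(x$h)))
  invisible(x)
}

#' Leaf (species) labels of a phylogeny
#' @param tree a `phylo_mrf`.
#' @return character vector of leaf labels.
#' @export
leaves <- function(tree) tree$labels[tree$is_leaf]

#' Replace the parameters of a phylogeny
#'
#' @param tree a `phylo_mrf`.
#' @param beta,h replacement parameters in the internal node order (`beta`
#'   over non-root nodes, `h` over all nodes), or `NULL` to keep.
#' @return the updated `phylo_mrf`.
#' @export
set_params <- function(tree, beta = NULL, h = NULL) {
  if (!is.null(beta)) {
    nonroot <- setdiff(seq_len(tree$n), tree$root)
    stopifnot(length(beta) == length(nonroot))
    tree$beta[nonroot] <- beta
  }
  if (!is.null(h)) {
    stopifnot(length(h) == tree$n)
    tree$h <- h
  }
  tree$edge_pot2 <- .edge_pot(tree, k = 2L)
  tree
}

#' Write / read phylogeny parameters as a sidecar TSV
#'
#' The topology travels as newick; `beta` and `h` travel in a tab-separated
#' sidecar with columns `id`, `param` (`beta` for the edge between a node and
#' its parent, `h` for a node field) and `value`.
#'
#' @param tree a `phylo_mrf`.
#' @param file path of the TSV.
#' @return `write_mrf_params` returns `file` invisibly.
#' @export
write_mrf_params <- function(tree, file) {
  nonroot <- setdiff(seq_len(tree$n), tree$root)
  df <- rbind(
    data.frame(id = tree$labels[nonroot], param = "beta",
               value = tree$beta[nonroot]),
    data.frame(id = tree$labels, param = "h", value = tree$h)
  )
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_mrf_params
#' @param newick path to the newick topology.
#' @param params path to the parameter sidecar TSV.
#' @param reference reference leaf label.
#' @return `read_phylo_mrf` returns a `phylo_mrf`.
#' @export
read_phylo_mrf <- function(newick, params, reference) {
  df <- utils::read.delim(params, stringsAsFactors = FALSE)
  beta <- df$value[df$param == "beta"]
  names(beta) <- df$id[df$param == "beta"]
  h <- df$value[df$param == "h"]
  names(h) <- df$id[df$param == "h"]
  phylo_mrf(newick, beta = beta, h = h, reference = reference)
}

#' Conservation pattern of one site
#'
#' Binary presence/absence of a site across the aligned species.  Species with
#' no alignable sequence are recorded as absent (0), not missing: alignment
#' gaps are treated as evidence against conservation, and systematic absence
#' is absorbed by the gene-class background.  The reference species is always
#' present by construction (only reference sites are observed).
#'
#' @param values named 0/1 vector over species; the reference entry, if given,
#'   must be 1.
#' @param site_id,gene_id identifiers carried along for reporting.
#' @return an object of class `conservation_pattern`.
#' @export
conservation_pattern <- function(values, site_id = NA_character_,
                                 gene_id = NA_character_) {
  v <- as.integer(values)
  if (any(!v %in% c(0L, 1L))) stop("pattern values must be 0 or 1")
  names(v) <- names(values)
  if (is.null(names(v)) && length(v)) stop("pattern values must be named by species")
  structure(list(site_id = site_id, gene_id = gene_id, values = v),
            class = "conservation_pattern")
}

# full leaf clamps for a pattern: every leaf observed; absent species -> 0;
# reference forced to 1
.pattern_clamps <- function(tree, pattern) {
  lv <- leaves(tree)
  vals <- pattern$values
  unknown <- setdiff(names(vals), lv)
  if (length(unknown))
    stop("pattern species not in tree: ", paste(unknown, collapse = ", "))
  ref_lab <- tree$labels[tree$reference]
  if (ref_lab %in% names(vals) && vals[[ref_lab]] != 1L)
    stop("reference species must be present (1) in pattern ",
         pattern$site_id %||% "")
  cl <- stats::setNames(rep(0L, length(lv)), lv)
  cl[names(vals)] <- vals
  cl[ref_lab] <- 1L
  cl
}
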