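# End-to-end orchestration: stitched alignments -> background fit -> site and
# pair scores -> matched controls -> enrichment summaries, driven by a YAML
# config with one global seed expanded deterministically per stage.

.PIPELINE_STAGES <- c("simulate", "scan", "stats", "fit-bg", "score-sites",
                      "score-pairs", "controls", "enrich")

.DEFAULT_PARAMS <- list(
  K = 7L, n_classes = 2L,
  site_types = c("8mer", "7merA1", "7merm8"),
  pair_cutoff = 2.0, sigma_bounds = c(-15, 15), min_sigma = -4,
  close_distance = 100L, count_tolerance = 0.15, n_bins = 10L,
  B = 100L, n_ctrl = 10L, n_controls = 200L, min_info = 0.4,
  max_sites = 200L, n_subsets = 5L, percentile = 0.5, fdr = 0.05)

#' Read and validate a pipeline configuration
#'
#' The config is YAML with blocks `paths` (tree, maf, utrs, seeds and the
#' optional footprints/genesets/expression/motifs/forbidden_seeds),
#' `reference`, `params` (any of K, n_classes, site_types, pair_cutoff,
#' sigma_bounds, min_sigma, close_distance, count_tolerance, n_bins, B,
#' n_ctrl, n_controls, min_info, max_sites, n_subsets, percentile, fdr),
#' `seed`, `out_dir` and optionally `simulate` (arguments of
#' [simulation_spec()]).  Unknown keys are rejected by name.
#'
#' @param file YAML path, or a list with the same structure.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(file) {
  cfg <- if (is.character(file)) yaml::read_yaml(file) else file
  known <- c("paths", "reference", "params", "seed", "out_dir", "simulate")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  extra_p <- setdiff(names(cfg$params), names(.DEFAULT_PARAMS))
  if (length(extra_p))
    stop("unknown params keys: ", paste(extra_p, collapse = ", "))
  cfg$params <- utils::modifyList(.DEFAULT_PARAMS, cfg$params %||% list())
  if (is.null(cfg$out_dir)) stop("config needs an out_dir")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  p <- cfg$params
  stopifnot(p$pair_cutoff > 0, p$count_tolerance >= 0, p$n_bins >= 2,
            p$percentile > 0, p$percentile <= 1, p$fdr > 0, p$fdr < 1)
  structure(cfg, class = "run_config")
}

.log <- function(state, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  cat(msg, "\n", file = state$logfile, append = TRUE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order.  Every stage writes its
#' TSV artifacts under `config$out_dir` plus a log echoing the seed and
#' parameters; rerunning with an identical config reproduces identical
#' artifacts.  A stage whose upstream artifact is missing stops with an error
#' naming the stage to run first.
#'
#' @param config a [read_run_config()] result (or path to the YAML).
#' @param stages subset of `simulate, scan, stats, fit-bg, score-sites,
#'   score-pairs, controls, enrich` (default: all that apply).
#' @return invisibly, an environment holding the in-memory artifacts.
#' @export
run_pipeline <- function(config, stages = NULL) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  if (is.null(stages))
    stages <- if (is.null(config$simulate)) .PIPELINE_STAGES[-1] else
      .PIPELINE_STAGES
  bad <- setdiff(stages, .PIPELINE_STAGES)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$config <- config
  state$logfile <- file.path(config$out_dir, "pipeline.log")
  cat("", file = state$logfile)
  .log(state, "coevosite ", as.character(utils::packageVersion("coevosite")),
       " | seed ", config$seed)
  .log(state, "params: ", paste(names(config$params),
                                vapply(config$params, function(x)
                                  paste(x, collapse = ","), ""),
                                sep = "=", collapse = " "))
  for (st in stages) {
    .log(state, "stage ", st)
    switch(st,
           "simulate" = .stage_simulate(state),
           "scan" = .stage_scan(state),
           "stats" = .stage_stats(state),
           "fit-bg" = .stage_fitbg(state),
           "score-sites" = .stage_score_sites(state),
           "score-pairs" = .stage_score_pairs(state),
           "controls" = .stage_controls(state),
           "enrich" = .stage_enrich(state))
  }
  invisible(state)
}

.out <- function(state, name) file.path(state$config$out_dir, name)

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage_simulate <- function(state) {
  cfg <- state$config
  if (is.null(cfg$simulate)) stop("config has no simulate block")
  args <- cfg$simulate
  args$seed <- args$seed %||% derive_seed(cfg$seed, "simulate")
  spec <- do.call(simulation_spec, args)
  bundle <- emit_toy_bundle(spec, file.path(cfg$out_dir, "bundle"))
  # the bundle provides every input path the later stages need
  cfg$paths <- utils::modifyList(cfg$paths %||% list(), list(
    tree = bundle$paths$tree, tree_params = bundle$paths$params,
    maf = bundle$paths$maf, utrs = bundle$paths$utrs,
    seeds = bundle$paths$seeds, footprints = bundle$paths$footprints,
    genesets = bundle$paths$genesets, expression = bundle$paths$expression))
  cfg$reference <- "sp1"
  state$config <- cfg
  state$bundle <- bundle
  .log(state, "  bundle: ", nrow(bundle$manifest), " planted sites in ",
       length(unique(bundle$manifest$gene_id)), " genes")
}

.need_path <- function(state, key, stage_hint) {
  p <- state$config$paths[[key]]
  if (is.null(p) || !file.exists(p))
    stop("missing input '", key, "'; run stage '", stage_hint,
         "' first or point paths$", key, " at a file")
  p
}

.ensure_alignments <- function(state) {
  if (!is.null(state$alns)) return(invisible())
  cfg <- state$config
  tree_file <- .need_path(state, "tree", "simulate")
  params <- .need_path(state, "tree_params", "simulate")
  state$tree0 <- read_phylo_mrf(tree_file, params, cfg$reference)
  species <- leaves(state$tree0)
  utrs <- read_bed(.need_path(state, "utrs", "simulate"))
  if (is.null(utrs$name)) stop("UTR BED needs a name column (gene ids)")
  if (anyDuplicated(utrs$name)) stop("duplicate gene ids in UTR BED")
  maf <- read_maf(.need_path(state, "maf", "simulate"))
  state$alns <- lapply(seq_len(nrow(utrs)), function(i) {
    u <- utrs[i, ]
    u$gene_id <- u$name
    stitch_maf(maf, u, species, cfg$reference)
  })
  names(state$alns) <- utrs$name
  state$species <- species
}

.stage_scan <- function(state) {
  cfg <- state$config
  .ensure_alignments(state)
  seeds <- read_seed_table(.need_path(state, "seeds", "simulate"))
  calls <- build_site_matrix(state$alns, seeds,
                             site_types = cfg$params$site_types)
  state$calls <- calls
  state$sites <- site_table(calls)
  .write_tsv(state$sites, .out(state, "sites.tsv"))
  .log(state, "  ", length(calls), " site calls for ", length(seeds),
       " families")
}

#' Per-offset K-mer conservation profile of one alignment
#'
#' For every K-mer of the reference UTR, scores each species 1 iff its row is
#' identical over the K-mer's columns with no gap/absent character; these are
#' the background statistics averaged into [compute_kmer_stats()].
#'
#' @param aln a [stitch_maf()] result.
#' @param K K-mer length.
#' @return 0/1 matrix, offsets x species.
#' @export
kmer_conservation_profile <- function(aln, K = 7L) {
  ref <- aln$reference
  species <- names(aln$rows)
  refrow <- strsplit(aln$rows[[ref]], "")[[1]]
  L <- length(aln$colmap)
  n_off <- L - K + 1L
  if (n_off < 1L)
    return(matrix(0L, 0, length(species),
                  dimnames = list(NULL, species)))
  out <- matrix(0L, n_off, length(species), dimnames = list(NULL, species))
  for (s in species) {
    if (s == ref) {
      out[, s] <- 1L
      next
    }
    row <- strsplit(aln$rows[[s]], "")[[1]]
    ok <- row == refrow & row %in% c("A", "C", "G", "T")
    # a K-mer is conserved iff all K reference columns match and the spanned
    # columns contain no insertion relative to the reference
    cons <- logical(n_off)
    for (i in seq_len(n_off)) {
      cols <- aln$colmap[i]:aln$colmap[i + K - 1L]
      cons[i] <- length(cols) == K && all(ok[cols])
    }
    out[, s] <- as.integer(cons)
  }
  out
}

.stage_stats <- function(state) {
  cfg <- state$config
  .ensure_alignments(state)
  K <- cfg$params$K
  profs <- lapply(state$alns, kmer_conservation_profile, K = K)
  state$kmer_profiles <- profs
  per_gene <- do.call(rbind, lapply(profs, colMeans))
  rownames(per_gene) <- names(profs)
  state$per_gene_cons <- per_gene
  .write_tsv(data.frame(gene_id = rownames(per_gene), per_gene,
                        check.names = FALSE),
             .out(state, "gene_conservation.tsv"))
  .log(state, "  K=", K, " conservation profiles for ",
       length(profs), " genes")
}

.stage_fitbg <- function(state) {
  cfg <- state$config
  if (is.null(state$per_gene_cons)) .stage_stats(state)
  nonref <- setdiff(state$species, cfg$reference)
  gca <- assign_gene_classes(state$per_gene_cons[, nonref, drop = FALSE],
                             n_classes = cfg$params$n_classes)
  state$gene_class <- gca
  .write_tsv(data.frame(gene_id = names(gca$class), class = gca$class),
             .out(state, "gene_classes.tsv"))
  fits <- list()
  for (k in sort(unique(gca$class))) {
    genes_k <- names(gca$class)[gca$class == k]
    mats <- state$kmer_profiles[genes_k]
    pooled <- do.call(rbind, mats)[, nonref, drop = FALSE]
    f_s <- colMeans(pooled)
    f_st <- crossprod(pooled) / nrow(pooled)
    st <- kmer_stats(f_s, f_st, nrow(pooled))
    stm <- rbind(single = f_s, f_st)
    utils::write.table(
      data.frame(species = rownames(stm), stm, check.names = FALSE),
      .out(state, sprintf("background_stats_class%d.tsv", k)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    # neutral initialization: the input tree contributes topology only
    init <- set_params(state$tree0, beta = rep(1, state$tree0$n - 1L),
                       h = rep(0, state$tree0$n))
    fit <- fit_background(init, st, n_starts = 1L, maxit = 300L,
                          seed = derive_seed(cfg$seed, paste0("fit-bg", k)))
    fits[[as.character(k)]] <- fit
    write_mrf_params(fit$tree,
                     .out(state, sprintf("background_class%d.tsv", k)))
    .log(state, "  class ", k, ": ", length(genes_k), " genes, residual ",
         signif(fit$residual, 3), if (fit$converged) "" else " (not converged)")
  }
  state$bg_fits <- fits
}

# background tree for a gene (its class fit)
.gene_tree <- function(state, gene_id) {
  k <- state$gene_class$class[[gene_id]]
  state$bg_fits[[as.character(k)]]$tree
}

.require_scores_input <- function(state) {
  if (is.null(state$calls)) .stage_scan(state)
  if (is.null(state$bg_fits)) stop("no background fits; run 'fit-bg' first")
}

.stage_score_sites <- function(state) {
  cfg <- state$config
  .require_scores_input(state)
  calls <- state$calls
  cls <- vapply(calls, function(cl) state$gene_class$class[[cl$gene_id]], 0L)
  opts <- optimizer_settings(sigma_bounds = cfg$params$sigma_bounds)
  scores <- vector("list", length(calls))
  for (k in sort(unique(cls))) {
    idx <- which(cls == k)
    tree_k <- state$bg_fits[[as.character(k)]]$tree
    df <- fit_sigma_batch(tree_k, lapply(calls[idx], `[[`, "pattern"), opts)
    for (j in seq_along(idx)) scores[[idx[j]]] <- df[j, ]
  }
  sc <- do.call(rbind, scores)
  out <- cbind(state$sites, sc[match(state$sites$site_id, sc$site_id),
                               c("sigma_hat", "loglik_at_hat", "D")])
  state$site_scores <- out
  .write_tsv(out, .out(state, "site_scores.tsv"))
  .log(state, "  scored ", nrow(out), " sites; median sigma ",
       signif(stats::median(out$sigma_hat), 3))
}

# fit all pairs in a pair table; sites indexed by site_id
.fit_pair_table <- function(state, pairs, site_lookup) {
  cfg <- state$config
  opts <- optimizer_settings(sigma_bounds = cfg$params$sigma_bounds)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    c1 <- site_lookup[[pairs$site1[i]]]
    c2 <- site_lookup[[pairs$site2[i]]]
    fp <- fit_pair(.gene_tree(state, c1$gene_id),
                   .gene_tree(state, c2$gene_id),
                   c1$pattern, c2$pattern, opts,
                   pair_cutoff = cfg$params$pair_cutoff)
    data.frame(sigma1 = fp$sigma1_joint, sigma2 = fp$sigma2_joint,
               J_hat = fp$J_hat, deltaL = fp$deltaL, sign = fp$sign,
               converged = fp$converged, stringsAsFactors = FALSE)
  })
  cbind(pairs, do.call(rbind, res))
}

.stage_score_pairs <- function(state) {
  cfg <- state$config
  if (is.null(state$site_scores)) stop("no site scores; run 'score-sites' first")
  sites <- state$site_scores
  keep <- sites$sigma_hat >= cfg$params$min_sigma
  .log(state, "  baseline sigma >= ", cfg$params$min_sigma, ": ",
       sum(keep), "/", nrow(sites), " sites enter pairing")
  sites <- sites[keep, , drop = FALSE]
  lookup <- stats::setNames(state$calls, state$sites$site_id)

  pairs <- enumerate_pairs(sites, scope = "same_utr",
                           max_sites = cfg$params$max_sites,
                           n_subsets = cfg$params$n_subsets,
                           close_distance = cfg$params$close_distance,
                           seed = derive_seed(cfg$seed, "pairs-utr"))
  if (!is.null(cfg$paths$genesets) && file.exists(cfg$paths$genesets)) {
    gs <- read_gmt(cfg$paths$genesets)
    gs <- lapply(gs, intersect, unique(sites$gene_id))
    gs <- gs[lengths(gs) >= 2L]
    if (length(gs)) {
      gp <- enumerate_pairs(sites, scope = "gene_set", gene_sets = gs,
                            max_sites = cfg$params$max_sites,
                            n_subsets = cfg$params$n_subsets,
                            close_distance = cfg$params$close_distance,
                            seed = derive_seed(cfg$seed, "pairs-gs"))
      pairs <- rbind(pairs, gp)
    }
    state$gene_sets <- gs
  }
  dup <- duplicated(paste(pairs$site1, pairs$site2, pairs$set_id, pairs$subset))
  pairs <- pairs[!dup, , drop = FALSE]
  scored <- .fit_pair_table(state, pairs, lookup)
  sg <- stats::setNames(sites$sigma_hat, sites$site_id)
  scored$sbar <- (sg[scored$site1] + sg[scored$site2]) / 2
  state$pair_scores <- scored
  .write_tsv(scored, .out(state, "pair_scores.tsv"))
  .log(state, "  scored ", nrow(scored), " pairs; ",
       sum(scored$sign != "none"), " correlated at cutoff ",
       cfg$params$pair_cutoff)
}

.stage_controls <- function(state) {
  cfg <- state$config
  if (is.null(state$pair_scores)) stop("no pair scores; run 'score-pairs' first")
  p <- cfg$params
  seeds_real <- read_seed_table(.need_path(state, "seeds", "simulate"))
  real7 <- vapply(seeds_real, `[[`, "", "seed7")
  forbidden <- if (!is.null(cfg$paths$forbidden_seeds))
    utils::read.delim(cfg$paths$forbidden_seeds)$seed7 else character()
  motifs <- if (!is.null(cfg$paths$motifs))
    utils::read.delim(cfg$paths$motifs)$motif else character()

  ctrl <- generate_control_seeds(real7, forbidden, motifs,
                                 n = p$n_controls, min_info = p$min_info,
                                 seed = derive_seed(cfg$seed, "controls"))
  ctrl$control_id <- sprintf("ctrl%04d", seq_len(nrow(ctrl)))
  .write_tsv(ctrl, .out(state, "control_seeds.tsv"))

  # scan control seeds like a miRNA family each
  ctrl_defs <- lapply(seq_len(nrow(ctrl)), function(i)
    seed_def(ctrl$control_id[i], ctrl$sequence[i]))
  ctrl_calls <- build_site_matrix(state$alns, ctrl_defs,
                                  site_types = p$site_types)
  # drop control sites overlapping any real site
  real_iv <- do.call(rbind, lapply(state$calls, function(cl)
    data.frame(chrom = cl$genomic$chrom, start = cl$genomic$start,
               end = cl$genomic$end)))
  overlapping <- filter_sites_by_intervals(ctrl_calls, real_iv)
  ov_ids <- vapply(overlapping, `[[`, "", "site_id")
  keep <- !(vapply(ctrl_calls, `[[`, "", "site_id") %in% ov_ids)
  ctrl_calls <- ctrl_calls[keep]
  .log(state, "  ", length(ctrl_calls), " control sites (",
       sum(!keep), " removed as overlapping real sites)")
  if (!length(ctrl_calls)) stop("no usable control sites")

  # score control sites on the same gene-class backgrounds
  ctab <- site_table(ctrl_calls)
  cls <- vapply(ctrl_calls, function(cl) state$gene_class$class[[cl$gene_id]],
                0L)
  opts <- optimizer_settings(sigma_bounds = p$sigma_bounds)
  sig <- numeric(length(ctrl_calls))
  for (k in sort(unique(cls))) {
    idx <- which(cls == k)
    df <- fit_sigma_batch(state$bg_fits[[as.character(k)]]$tree,
                          lapply(ctrl_calls[idx], `[[`, "pattern"), opts)
    sig[idx] <- df$sigma_hat
  }
  ctab$sigma_hat <- sig
  .write_tsv(ctab, .out(state, "control_sites.tsv"))
  # same conservation baseline as the real sites
  base_keep <- ctab$sigma_hat >= p$min_sigma
  ctab <- ctab[base_keep, , drop = FALSE]
  ctrl_calls <- ctrl_calls[base_keep]
  .log(state, "  ", nrow(ctab), " control sites pass the sigma baseline")
  if (!nrow(ctab)) stop("no control sites above the sigma baseline")

  # two-tier matching per real family: site counts, then conservation
  utr_seqs <- vapply(state$alns, reference_sequence, "")
  ctrl_counts <- count_seed_sites(ctrl$sequence, utr_seqs, types = p$site_types)
  rownames(ctrl_counts) <- ctrl$control_id
  ctrl_total <- rowSums(ctrl_counts)
  selected <- character()
  for (fam in unique(state$sites$family_id)) {
    fam_sites <- state$site_scores[state$site_scores$family_id == fam, ]
    if (nrow(fam_sites) < p$n_bins) {
      .log(state, "  family ", fam, ": fewer sites than bins, skipped")
      next
    }
    fam_count <- sum(state$sites$family_id == fam)
    lo <- ceiling((1 - p$count_tolerance) * fam_count)
    hi <- floor((1 + p$count_tolerance) * fam_count)
    pool <- ctrl$control_id[ctrl_total >= lo & ctrl_total <= hi]
    if (!length(pool)) {
      # toy-scale fallback: planted densities exceed any control's chance
      # matches, so relax the count tier rather than losing the family
      .log(state, "  family ", fam,
           ": no count-matched controls, using full pool")
      pool <- ctrl$control_id
    }
    csites <- ctab[ctab$family_id %in% pool, , drop = FALSE]
    if (!nrow(csites)) { # count-matched seeds have no scoreable sites left
      .log(state, "  family ", fam,
           ": count-matched controls have no usable sites, using full pool")
      csites <- ctab
    }
    csites$control_id <- csites$family_id
    mcs <- match_controls_by_conservation(
      fam_sites$sigma_hat, csites, n_ctrl = p$n_ctrl, n_bins = p$n_bins,
      seed = derive_seed(cfg$seed, paste0("match-", fam)))
    selected <- union(selected, mcs$controls$control_id)
  }
  if (!length(selected)) stop("no matched control seeds selected")
  .log(state, "  ", length(selected), " matched control seeds selected")

  # control pairs over the lumped matched sets, same scopes as the real run
  csel <- ctab[ctab$family_id %in% selected, , drop = FALSE]
  cpairs <- enumerate_pairs(csel, scope = "same_utr",
                            max_sites = p$max_sites,
                            n_subsets = p$n_subsets,
                            close_distance = p$close_distance,
                            seed = derive_seed(cfg$seed, "ctrl-pairs"))
  if (!is.null(state$gene_sets) && length(state$gene_sets)) {
    cgp <- enumerate_pairs(csel, scope = "gene_set",
                           gene_sets = state$gene_sets,
                           max_sites = p$max_sites, n_subsets = p$n_subsets,
                           close_distance = p$close_distance,
                           seed = derive_seed(cfg$seed, "ctrl-pairs-gs"))
    cpairs <- rbind(cpairs, cgp)
  }
  dup <- duplicated(paste(cpairs$site1, cpairs$site2, cpairs$set_id,
                          cpairs$subset))
  cpairs <- cpairs[!dup, , drop = FALSE]
  if (!nrow(cpairs)) stop("no control pairs available")
  lookup <- stats::setNames(ctrl_calls, ctab$site_id)
  cscored <- .fit_pair_table(state, cpairs, lookup)
  sgc <- stats::setNames(ctab$sigma_hat, ctab$site_id)
  cscored$sbar <- (sgc[cscored$site1] + sgc[cscored$site2]) / 2
  state$control_pairs <- cscored
  .write_tsv(cscored, .out(state, "control_pairs.tsv"))
  .log(state, "  scored ", nrow(cscored), " control pairs")
}

.stage_enrich <- function(state) {
  cfg <- state$config
  p <- cfg$params
  if (is.null(state$pair_scores) || is.null(state$control_pairs))
    stop("need pair scores and control pairs; run 'score-pairs' and 'controls'")
  real <- state$pair_scores
  ctrl <- state$control_pairs

  boot_for <- function(rp, cp, tag) {
    biased_bootstrap(rp$sbar, cp$sbar, B = p$B, n_bins = p$n_bins,
                     seed = derive_seed(cfg$seed, paste0("boot-", tag)))
  }
  categories <- list(
    all = function(df) df$set_id == "all",
    close = function(df) df$set_id == "all" & df$close,
    distant = function(df) df$set_id == "all" & !df$close,
    same_family = function(df) df$set_id == "all" & df$same_family,
    different_family = function(df) df$set_id == "all" & !df$same_family)
  rows <- list()
  for (nm in names(categories)) {
    rsel <- real[categories[[nm]](real), , drop = FALSE]
    csel <- ctrl[categories[[nm]](ctrl), , drop = FALSE]
    if (!nrow(csel)) csel <- ctrl[ctrl$set_id == "all", , drop = FALSE]
    if (!nrow(rsel) || !nrow(csel)) {
      rows[[nm]] <- summarize_category(rsel[0, ], csel, NULL,
                                       p$pair_cutoff, nm)
      next
    }
    bt <- boot_for(rsel, csel, nm)
    rows[[nm]] <- summarize_category(rsel, csel, bt, p$pair_cutoff, nm)
  }
  summary <- do.call(rbind, rows)
  state$enrichment <- summary
  .write_tsv(summary, .out(state, "enrichment.tsv"))

  if (!is.null(state$gene_sets) && length(state$gene_sets)) {
    gs_rows <- list()
    for (sid in names(state$gene_sets)) {
      rsel <- real[real$set_id == sid, , drop = FALSE]
      csel <- ctrl[ctrl$set_id == sid, , drop = FALSE]
      if (!nrow(csel)) csel <- ctrl
      if (!nrow(rsel)) next
      bt <- boot_for(rsel, csel, paste0("gs-", sid))
      gs_rows[[sid]] <- geneset_strategy_test(rsel, csel, bt, p$pair_cutoff,
                                              set_id = sid)
    }
    if (length(gs_rows)) {
      gs_tab <- adjust_geneset_table(do.call(rbind, gs_rows), fdr = p$fdr)
      state$geneset_tests <- gs_tab
      .write_tsv(gs_tab, .out(state, "geneset_tests.tsv"))
    }
  }

  net <- build_network(real[real$set_id == "all", , drop = FALSE],
                       edge_stat = "count", percentile = p$percentile,
                       pair_cutoff = p$pair_cutoff)
  state$network <- net
  .write_tsv(net$edges, .out(state, "network_edges.tsv"))
  if (!is.null(cfg$paths$expression) && file.exists(cfg$paths$expression)) {
    ex <- utils::read.delim(cfg$paths$expression, check.names = FALSE)
    em <- as.matrix(ex[, -1, drop = FALSE])
    rownames(em) <- ex[[1]]
    ov <- expression_overlap(em)
    enet <- network_from_matrix(ov, percentile = p$percentile)
    cmp <- try(compare_networks(net, enet), silent = TRUE)
    if (!inherits(cmp, "try-error")) {
      state$network_comparison <- cmp
      .log(state, "  correlation vs co-expression network: Fisher p = ",
           signif(cmp$p, 3))
    }
  }
  .log(state, "  enrichment summary written (",
       nrow(summary), " categories)")
}
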