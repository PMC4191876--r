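# Control-seed machinery: a dinucleotide-matched universe of synthetic 7-mer
# seeds, two-tier matching (site counts, then conservation histograms) and
# the conservation-biased bootstrap over control site pairs.

#' Information content of a 7-mer seed
#'
#' `I = 2 + sum_n f_n log2 f_n` with `f_n` the nucleotide frequencies within
#' the seed; 2 bits for a single-letter seed, near 0 for maximally mixed
#' composition.
#'
#' @param seed 7-letter seed over `{A,C,G,U}` (T accepted as U).
#' @return information content in bits, in `[0, 2]`.
#' @export
info_content <- function(seed) {
  s <- strsplit(toupper(chartr("T", "U", seed)), "")[[1]]
  if (any(!s %in% c("A", "C", "G", "U")))
    stop("seed must be over {A,C,G,U}: ", seed)
  f <- table(s) / length(s)
  2 + sum(f * log2(f))
}

#' Generate dinucleotide- and information-content-matched control seeds
#'
#' Candidates are drawn from a stationary first-order chain fitted to the
#' dinucleotide frequencies of the real seeds and kept if (1) not in the
#' forbidden miRNA-seed set, (2) their reverse complement is not an RNA
#' binding protein motif, and (3) their information content exceeds
#' `min_info`; surviving candidates enter the list with probability
#' proportional to the empirical density of real-seed information content at
#' their own value.
#'
#' @param real_seeds character vector of 7-letter seeds or list of
#'   [seed_def()]s.
#' @param forbidden_seeds seeds no control may equal (the real seeds are
#'   always included).
#' @param rbp_motifs 7-mers whose reverse complement is excluded.
#' @param n number of control seeds to return.
#' @param min_info information-content acceptance threshold in bits.
#' @param unique_seeds keep each accepted sequence at most once.
#' @param seed integer RNG seed (full determinism).
#' @param max_tries candidate cap before giving up.
#' @return data.frame with `sequence` and `info_content`.
#' @export
generate_control_seeds <- function(real_seeds, forbidden_seeds = character(),
                                   rbp_motifs = character(), n = 5000L,
                                   min_info = 0.4, unique_seeds = TRUE,
                                   seed = 1L, max_tries = 500L * n) {
  if (is.list(real_seeds))
    real_seeds <- vapply(real_seeds, `[[`, "", "seed7")
  real_seeds <- toupper(chartr("T", "U", real_seeds))
  forbidden <- unique(c(real_seeds,
                        toupper(chartr("T", "U", forbidden_seeds))))
  motif_rc <- toupper(chartr("T", "U", rbp_motifs))
  set.seed(seed)

  nts <- c("A", "C", "G", "U")
  chars <- lapply(strsplit(real_seeds, ""), factor, levels = nts)
  init <- table(factor(unlist(chars), levels = nts)) + 0.5
  init <- as.numeric(init / sum(init))
  trans <- matrix(0.5, 4, 4, dimnames = list(nts, nts))
  for (cs in chars)
    for (i in 1:6) trans[cs[i], cs[i + 1]] <- trans[cs[i], cs[i + 1]] + 1
  trans <- trans / rowSums(trans)

  ic_real <- vapply(real_seeds, info_content, 0)
  brk <- seq(0, 2, length.out = 11L)
  dens <- tabulate(findInterval(ic_real, brk, rightmost.closed = TRUE),
                   nbins = 10L)
  accept_p <- dens / max(dens)

  rc_rna <- function(x)
    chartr("ACGU", "UGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))

  out <- character(0)
  ic_out <- numeric(0)
  tries <- 0L
  while (length(out) < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- character(7)
    cand[1] <- sample(nts, 1L, prob = init)
    for (i in 2:7) cand[i] <- sample(nts, 1L, prob = trans[cand[i - 1L], ])
    cand <- paste(cand, collapse = "")
    if (cand %in% forbidden) next
    if (rc_rna(cand) %in% motif_rc) next
    ic <- info_content(cand)
    if (ic <= min_info) next
    if (unique_seeds && cand %in% out) next
    bin <- min(10L, max(1L, findInterval(ic, brk, rightmost.closed = TRUE)))
    if (stats::runif(1) > accept_p[bin]) next
    out <- c(out, cand)
    ic_out <- c(ic_out, ic)
  }
  if (length(out) < n)
    stop("control-seed generation exhausted after ", tries,
         " candidates; achieved ", length(out), " of ", n)
  data.frame(sequence = out, info_content = ic_out,
             stringsAsFactors = FALSE)
}

#' Select control seeds with matched site counts
#'
#' Keeps, separately for each site type, the controls whose site count lies
#' within a +/- `tolerance` band of the real family's count (rounded inward:
#' `[ceiling((1-t)c), floor((1+t)c)]`).
#'
#' @param family_counts named integer vector: real site count per type.
#' @param control_counts matrix controls x types (rownames = control ids).
#' @param tolerance fractional matching band (default 15 percent).
#' @return named list per type of matching control ids; empty matches warn.
#' @export
match_controls_by_count <- function(family_counts, control_counts,
                                    tolerance = 0.15) {
  stopifnot(nrow(control_counts) > 0)
  out <- list()
  for (ty in names(family_counts)) {
    cc <- family_counts[[ty]]
    lo <- ceiling((1 - tolerance) * cc)
    hi <- floor((1 + tolerance) * cc)
    hit <- control_counts[, ty] >= lo & control_counts[, ty] <= hi
    ids <- rownames(control_counts)[hit]
    if (!length(ids))
      warning("no count-matched controls for type ", ty, " (count ", cc, ")")
    out[[ty]] <- ids
  }
  out
}

# equipopulated bin breaks on a reference sample, open at both ends
.equi_breaks <- function(x, n_bins) {
  q <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                       names = FALSE, type = 7)
  q[1] <- -Inf
  q[n_bins + 1L] <- Inf
  # guard against ties collapsing bins
  for (i in 2:n_bins) if (q[i] <= q[i - 1L]) q[i] <- q[i - 1L] + 1e-9
  q
}

#' Select control seeds whose site conservation matches a real family
#'
#' The real family's sigma values define 10 equipopulated bins; each control
#' seed is scored by the relative squared difference of its binned site
#' counts against the real counts, after removing control sites that overlap
#' any real site; the `n_ctrl` best controls are returned in randomized
#' order (recorded seed) to avoid creating a hierarchy among control sets.
#'
#' @param real_sigma sigma values of the family's (7mer/8mer) sites; length
#'   must reach `n_bins`.
#' @param control_sites data.frame with `control_id`, `sigma_hat` and
#'   optionally a logical `overlaps_real` column (such sites are dropped).
#' @param n_ctrl number of control seeds to select.
#' @param n_bins number of equipopulated bins.
#' @param seed RNG seed for the order randomization.
#' @return list of class `matched_control_set`: `controls` (data.frame
#'   `control_id`, `metric` in randomized order), `breaks`, `seed`.
#' @export
match_controls_by_conservation <- function(real_sigma, control_sites,
                                           n_ctrl = 50L, n_bins = 10L,
                                           seed = 1L) {
  if (length(real_sigma) < n_bins)
    stop("need at least n_bins real sites to build the histogram")
  if (!is.null(control_sites$overlaps_real))
    control_sites <- control_sites[!control_sites$overlaps_real, , drop = FALSE]
  if (!nrow(control_sites))
    stop("no control sites left after overlap filtering")
  brk <- .equi_breaks(real_sigma, n_bins)
  r_b <- tabulate(findInterval(real_sigma, brk), nbins = n_bins)
  ids <- unique(control_sites$control_id)
  metric <- vapply(ids, function(id) {
    sg <- control_sites$sigma_hat[control_sites$control_id == id]
    c_b <- tabulate(findInterval(sg, brk), nbins = n_bins)
    sum((c_b - r_b)^2 / r_b)
  }, 0)
  ord <- order(metric, ids)
  best <- ids[ord][seq_len(min(n_ctrl, length(ids)))]
  met <- metric[ord][seq_len(min(n_ctrl, length(ids)))]
  set.seed(seed)
  perm <- sample.int(length(best))
  structure(list(controls = data.frame(control_id = best[perm],
                                       metric = met[perm],
                                       stringsAsFactors = FALSE),
                 breaks = brk, seed = seed),
            class = "matched_control_set")
}

#' Conservation-biased bootstrap of control site pairs
#'
#' Mean pair conservation values are histogrammed on 10 bins equipopulated on
#' the real pairs; each control pair is resampled with probability
#' proportional to the real/control ratio of its bin's counts, shifting the
#' control ensemble toward the real conservation profile.  Each of the `B`
#' samples draws `length(control_sbar)` pairs with replacement and carries
#' the rescaling factor `n_real / n_sample` used to put significant-pair
#' counts on the real scale.  With identical histograms all weights are equal
#' and the procedure reduces to an ordinary bootstrap.
#'
#' @param real_sbar mean conservation (`(sigma1 + sigma2)/2`) of the real
#'   pairs.
#' @param control_sbar same for the control pairs.
#' @param B number of bootstrap samples.
#' @param n_bins number of equipopulated bins (defined on the real pairs).
#' @param seed RNG seed.
#' @return list of class `bootstrap_samples`: `samples` (list of index
#'   vectors into the control pairs), `weights`, `rescale`, `breaks`.
#' @export
biased_bootstrap <- function(real_sbar, control_sbar, B = 100L,
                             n_bins = 10L, seed = 1L) {
  stopifnot(length(real_sbar) > 0, length(control_sbar) > 0)
  brk <- .equi_breaks(real_sbar, n_bins)
  r_b <- tabulate(findInterval(real_sbar, brk), nbins = n_bins)
  c_b <- tabulate(findInterval(control_sbar, brk), nbins = n_bins)
  if (any(c_b == 0 & r_b > 0))
    warning("empty control bin with nonzero real count; ",
            "weights capped for that bin")
  bin <- findInterval(control_sbar, brk)
  w <- r_b[bin] / pmax(c_b[bin], 1L)
  if (all(w == 0)) w <- rep(1, length(w))
  n_ctrl <- length(control_sbar)
  set.seed(seed)
  samples <- lapply(seq_len(B), function(b)
    sample.int(n_ctrl, n_ctrl, replace = TRUE, prob = w))
  structure(list(samples = samples, weights = w,
                 rescale = length(real_sbar) / n_ctrl, breaks = brk,
                 seed = seed), class = "bootstrap_samples")
}

#' Per-type site counts for a set of seeds over reference UTR sequences
#'
#' @param seed7s character vector of 7-letter seeds.
#' @param utr_seqs character vector of reference UTR sequences.
#' @param types site types to count.
#' @return matrix seeds x types.
#' @export
count_seed_sites <- function(seed7s, utr_seqs,
                             types = c("8mer", "7merA1", "7merm8")) {
  counts <- matrix(0L, length(seed7s), length(types),
                   dimnames = list(seed7s, types))
  for (i in seq_along(seed7s)) {
    for (sq in utr_seqs) {
      hits <- seed_sites(seed7s[i], sq, types = types)
      if (nrow(hits)) {
        tb <- table(factor(hits$type, levels = types))
        counts[i, ] <- counts[i, ] + as.integer(tb)
      }
    }
  }
  counts
}
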