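# Seed-match scanning over stitched multi-species alignments.  Reference
# 3'UTR intervals select and concatenate reference-anchored MAF blocks; the
# reference transcript is scanned for the five TargetScan-style site types;
# per-species conservation is called at orthologous alignment columns.

#' miRNA seed definition (mature positions 2-8)
#'
#' @param family_id miRNA family identifier.
#' @param seed7 7-letter RNA string over `{A,C,G,U}`.
#' @param n_members number of family members (metadata).
#' @return a list of class `seed_def`.
#' @export
seed_def <- function(family_id, seed7, n_members = NA_integer_) {
  seed7 <- toupper(chartr("T", "U", seed7))
  if (nchar(seed7) != 7L || grepl("[^ACGU]", seed7))
    stop("seed7 must be 7 letters over {A,C,G,U}: ", seed7)
  structure(list(family_id = family_id, seed7 = seed7,
                 n_members = as.integer(n_members)), class = "seed_def")
}

#' Read a seed family table (TSV: family_id, seed7[, n_members])
#' @param file path.
#' @return list of [seed_def()]s.
#' @export
read_seed_table <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("family_id", "seed7") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i)
    seed_def(df$family_id[i], df$seed7[i],
             if ("n_members" %in% names(df)) df$n_members[i] else NA))
}

#' Target-strand match strings of the five site types
#'
#' Site types on the mRNA are reverse complements of miRNA seed positions:
#' `7merm8 = rc(2-8)`, `7merA1 = rc(2-7) + A`, `8mer = rc(2-8) + A`,
#' `6mer = rc(2-7)`, `offset6mer = rc(3-8)` (DNA alphabet).
#'
#' @param seed7 7-letter seed (positions 2-8) as RNA or DNA.
#' @return named character vector of match strings.
#' @export
seed_match_strings <- function(seed7) {
  if (inherits(seed7, "seed_def")) seed7 <- seed7$seed7
  s <- toupper(chartr("T", "U", seed7))
  if (nchar(s) != 7L || grepl("[^ACGU]", s)) stop("malformed seed: ", seed7)
  rc28 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", s))))
  c(`8mer` = paste0(rc28, "A"),
    `7merA1` = paste0(substr(rc28, 2, 7), "A"),
    `7merm8` = rc28,
    `6mer` = substr(rc28, 2, 7),
    offset6mer = substr(rc28, 1, 6))
}

# precedence used to assign a single best type to each occurrence
.SITE_TYPES <- c("8mer", "7merA1", "7merm8", "6mer", "offset6mer")

#' Scan a reference UTR sequence for seed-match sites
#'
#' Finds all occurrences of the five site types and assigns each genomic
#' occurrence the single best type in the order 8mer, 7merA1, 7merm8, 6mer,
#' offset 6mer: a lower-precedence candidate overlapping an already assigned
#' span is dropped, so no reference position is reported under two types.
#' `N` never matches.
#'
#' @param seed a [seed_def()] or 7-letter seed string.
#' @param utr_sequence reference transcript sequence over `{A,C,G,T/U,N}`.
#' @param types site types to report (the scan always resolves precedence
#'   against all five).
#' @return data.frame with `position` (0-based offset of the match start
#'   relative to the UTR start), `type`, `match`.
#' @export
seed_sites <- function(seed, utr_sequence, types = .SITE_TYPES) {
  ms <- seed_match_strings(seed)
  seqd <- Biostrings::DNAString(chartr("U", "T", toupper(utr_sequence)))
  claimed <- rep(FALSE, length(seqd))
  out <- list()
  for (ty in .SITE_TYPES) {
    m <- Biostrings::matchPattern(ms[[ty]], seqd, fixed = TRUE)
    for (i in seq_along(m)) {
      span <- IRanges::start(m)[i]:IRanges::end(m)[i]
      if (any(claimed[span])) next
      claimed[span] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        position = IRanges::start(m)[i] - 1L, type = ty, match = ms[[ty]],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(position = integer(), type = character(),
               match = character(), stringsAsFactors = FALSE)
  res <- res[res$type %in% types, , drop = FALSE]
  res[order(res$position), , drop = FALSE]
}

# ---- MAF parsing and stitching --------------------------------------------

#' Parse a (reference-anchored) MAF file
#'
#' @param file path to an uncompressed MAF file.
#' @return list of blocks; each block is a data.frame with `species`,
#'   `chrom`, `start`, `size`, `strand`, `src_size`, `text`.
#' @export
read_maf <- function(file) {
  lines <- readLines(file)
  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && nrow(cur)) blocks[[length(blocks) + 1L]] <<- cur
    cur <<- NULL
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      flush()
      cur <- data.frame(species = character(), chrom = character(),
                        start = integer(), size = integer(),
                        strand = character(), src_size = integer(),
                        text = character(), stringsAsFactors = FALSE)
    } else if (startsWith(ln, "s ")) {
      if (is.null(cur)) stop("MAF 's' line outside a block")
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) < 7L) stop("malformed MAF s line: ", ln)
      cur <- rbind(cur, data.frame(
        species = sub("\\..*$", "", f[2]), chrom = sub("^[^.]*\\.", "", f[2]),
        start = as.integer(f[3]), size = as.integer(f[4]), strand = f[5],
        src_size = as.integer(f[6]), text = toupper(f[7]),
        stringsAsFactors = FALSE))
    }
  }
  flush()
  blocks
}

.ABSENT <- "*" # unalignable/absent stretch marker (scores 0 downstream)

#' Stitch MAF blocks over a reference UTR interval
#'
#' Blocks overlapping the interval are trimmed to it and concatenated in
#' reference order; stretches of the reference not covered by any block are
#' filled with `N` (or the supplied reference sequence) in the reference row
#' and with the absent marker `*` in every other row; species missing from a
#' block get the absent marker across that block.  Minus-strand UTRs are
#' reverse-complemented into transcript orientation.
#'
#' @param maf path to a MAF file or the result of [read_maf()].
#' @param utr list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `gene_id`.
#' @param species species to keep (rows are emitted in this order).
#' @param reference reference species (must be present in every used block).
#' @param ref_seq optional genomic (+ strand) reference sequence of the UTR,
#'   used to fill uncovered reference stretches.
#' @return an object of class `stitched_alignment` with `gene_id`, `interval`,
#'   `rows` (named character vector, equal lengths) and `colmap` (transcript
#'   position, 1-based, to alignment column).
#' @export
stitch_maf <- function(maf, utr, species, reference, ref_seq = NULL) {
  blocks <- if (is.character(maf)) read_maf(maf) else maf
  stopifnot(reference %in% species)
  u_start <- as.integer(utr$start); u_end <- as.integer(utr$end)
  keep <- Filter(function(b) {
    r <- b[b$species == reference, ]
    nrow(r) == 1L && r$chrom == utr$chrom && r$strand == "+" &&
      r$start < u_end && (r$start + r$size) > u_start
  }, blocks)
  if (length(keep) > 1L) {
    starts <- vapply(keep, function(b) b$start[b$species == reference], 0L)
    keep <- keep[order(starts)]
    ends <- vapply(keep, function(b) {
      r <- b[b$species == reference, ]
      r$start + r$size
    }, 0L)
    starts <- sort(starts)
    if (any(starts[-1] < ends[-length(ends)]))
      stop(sprintf("overlapping MAF blocks on the reference near %s:%d",
                   utr$chrom, starts[which(starts[-1] < ends[-length(ends)])[1] + 1L]))
  }

  pieces <- list() # each: list(rows = named char vec, ref_cols = logical)
  cursor <- u_start
  add_gap <- function(from, to) {
    len <- to - from
    if (len <= 0L) return()
    ref_row <- if (!is.null(ref_seq))
      substr(ref_seq, from - u_start + 1L, to - u_start) else
      strrep("N", len)
    rows <- stats::setNames(rep(strrep(.ABSENT, len), length(species)),
                            species)
    rows[reference] <- ref_row
    pieces[[length(pieces) + 1L]] <<- rows
  }
  for (b in keep) {
    r <- b[b$species == reference, ]
    # columns of the reference bases inside the UTR
    chars <- strsplit(r$text, "")[[1]]
    is_base <- chars != "-"
    gpos <- integer(length(chars)) # genomic position per ref base column
    gpos[is_base] <- r$start + seq_len(sum(is_base)) - 1L
    sel_base <- is_base & gpos >= max(u_start, r$start) & gpos < min(u_end, r$start + r$size)
    if (!any(sel_base)) next
    first_col <- which(sel_base)[1]
    last_col <- max(which(sel_base))
    cols <- first_col:last_col
    blk_from <- gpos[first_col]
    add_gap(cursor, blk_from)
    rows <- stats::setNames(rep(NA_character_, length(species)), species)
    for (s in species) {
      rr <- b[b$species == s, ]
      rows[s] <- if (nrow(rr) == 1L)
        paste(strsplit(rr$text, "")[[1]][cols], collapse = "") else
        strrep(.ABSENT, length(cols))
    }
    pieces[[length(pieces) + 1L]] <- rows
    cursor <- gpos[last_col] + 1L
  }
  add_gap(cursor, u_end)

  rows <- stats::setNames(vapply(species, function(s)
    paste(vapply(pieces, `[[`, "", s), collapse = ""), ""), species)

  if (identical(utr$strand, "-")) {
    rows <- vapply(rows, function(x) {
      x <- chartr("ACGTN", "TGCAN", x)
      paste(rev(strsplit(x, "")[[1]]), collapse = "")
    }, "")
  }
  ref_chars <- strsplit(rows[[reference]], "")[[1]]
  colmap <- which(ref_chars != "-" & ref_chars != .ABSENT)
  if (length(colmap) != u_end - u_start)
    stop("stitched reference does not cover the UTR interval")
  structure(list(gene_id = utr$gene_id, interval = utr, rows = rows,
                 reference = reference, colmap = colmap),
            class = "stitched_alignment")
}

#' Reference transcript sequence of a stitched alignment
#' @param aln a `stitched_alignment`.
#' @return the ungapped reference row.
#' @export
reference_sequence <- function(aln) {
  gsub("[-*]", "", aln$rows[[aln$reference]])
}

#' Per-species conservation call at one site
#'
#' A species is scored present (1) iff its row carries the identical match
#' string, with no gap or absent characters, across the alignment columns
#' spanned by the reference match; substitutions, gaps and unalignable
#' stretches all score 0 (gaps count as evidence of absence).  The reference
#' is always 1.
#'
#' @param aln a [stitch_maf()] result.
#' @param position 0-based match start relative to the UTR start (transcript
#'   orientation).
#' @param match the match string.
#' @param site_id,gene_id identifiers for the resulting pattern.
#' @return a [conservation_pattern()] over the alignment's species.
#' @export
site_conservation <- function(aln, position, match,
                              site_id = NA_character_,
                              gene_id = aln$gene_id) {
  len <- nchar(match)
  idx <- aln$colmap[position + seq_len(len)]
  if (anyNA(idx)) stop("site extends beyond the alignment")
  cols <- idx[1]:idx[len]
  vals <- vapply(names(aln$rows), function(s) {
    sub <- substr(aln$rows[[s]], cols[1], cols[length(cols)])
    as.integer(identical(sub, match))
  }, 0L)
  vals[aln$reference] <- 1L
  conservation_pattern(vals, site_id = site_id, gene_id = gene_id)
}

#' Scan a set of gene alignments and build the binary site matrix
#'
#' @param alns list of [stitch_maf()] results (one per gene).
#' @param seeds list of [seed_def()]s.
#' @param site_types types to keep; the default restricts the analysis to
#'   7mer and 8mer sites, whose conservation signal-to-noise is highest.
#' @return list of `site_call` objects, ordered by (gene, position, seed);
#'   each carries `site_id`, `gene_id`, `family_id`, `type`, `position`,
#'   `match`, `genomic` (chrom/start/end) and `pattern`.
#' @export
build_site_matrix <- function(alns, seeds,
                              site_types = c("8mer", "7merA1", "7merm8")) {
  gene_ids <- vapply(alns, `[[`, "", "gene_id")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in alignments")
  calls <- list()
  for (aln in alns) {
    utr_seq <- reference_sequence(aln)
    for (sd in seeds) {
      hits <- seed_sites(sd, utr_seq, types = site_types)
      for (i in seq_len(nrow(hits))) {
        pos <- hits$position[i]; mt <- hits$match[i]
        g <- .site_genomic(aln$interval, pos, nchar(mt))
        sid <- sprintf("%s:%s:%d:%s", aln$gene_id, sd$family_id, pos,
                       hits$type[i])
        calls[[length(calls) + 1L]] <- structure(list(
          site_id = sid, gene_id = aln$gene_id, family_id = sd$family_id,
          type = hits$type[i], position = pos, match = mt, genomic = g,
          pattern = site_conservation(aln, pos, mt, site_id = sid)),
          class = "site_call")
      }
    }
  }
  ord <- order(vapply(calls, `[[`, "", "gene_id"),
               vapply(calls, `[[`, 0L, "position"),
               vapply(calls, `[[`, "", "family_id"))
  calls[ord]
}

# genomic (0-based half-open, + strand) interval of a site
.site_genomic <- function(utr, position, len) {
  if (identical(utr$strand, "-")) {
    list(chrom = utr$chrom, start = as.integer(utr$end) - position - len,
         end = as.integer(utr$end) - position)
  } else {
    list(chrom = utr$chrom, start = as.integer(utr$start) + position,
         end = as.integer(utr$start) + position + len)
  }
}

#' Read a BED file (3-6 columns, 0-based half-open)
#' @param file path.
#' @return data.frame with `chrom`, `start`, `end` and any of `name`,
#'   `score`, `strand` present.
#' @export
read_bed <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t")
  n <- lengths(parts)
  bad <- which(n < 3L)
  if (length(bad)) stop("malformed BED line ", bad[1], ": ", lines[bad[1]])
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    start = suppressWarnings(as.integer(vapply(parts, `[`, "", 2))),
    end = suppressWarnings(as.integer(vapply(parts, `[`, "", 3))),
    stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end)) {
    bad <- which(is.na(df$start) | is.na(df$end))[1]
    stop("malformed BED line ", bad, ": ", lines[bad])
  }
  if (any(n >= 4L)) df$name <- vapply(parts, function(p) p[4] %||% NA_character_, "")
  if (any(n >= 6L)) df$strand <- vapply(parts, function(p) p[6] %||% NA_character_, "")
  df
}

#' Keep sites overlapping genomic intervals
#'
#' A site is kept when its reference genomic span overlaps at least one
#' interval by at least one base (half-open coordinates).
#'
#' @param calls list of `site_call`s from [build_site_matrix()].
#' @param intervals BED path or data.frame with `chrom`, `start`, `end`.
#' @return the overlapping subset of `calls`.
#' @export
filter_sites_by_intervals <- function(calls, intervals) {
  bed <- if (is.character(intervals)) read_bed(intervals) else intervals
  if (!nrow(bed)) return(calls[integer()])
  keep <- vapply(calls, function(cl) {
    g <- cl$genomic
    hit <- bed$chrom == g$chrom
    if (!any(hit)) return(FALSE)
    ir <- IRanges::IRanges(bed$start[hit] + 1L, bed$end[hit])
    length(IRanges::findOverlaps(
      IRanges::IRanges(g$start + 1L, g$end), ir)) > 0
  }, TRUE)
  calls[keep]
}

#' Tabulate site calls (one row per site)
#' @param calls list of `site_call`s.
#' @return data.frame with ids, family, type, position, genomic span and the
#'   pattern as a compact string.
#' @export
site_table <- function(calls) {
  if (!length(calls))
    return(data.frame(site_id = character(), gene_id = character(),
                      family_id = character(), type = character(),
                      position = integer(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(calls, function(cl) data.frame(
    site_id = cl$site_id, gene_id = cl$gene_id, family_id = cl$family_id,
    type = cl$type, position = cl$position, chrom = cl$genomic$chrom,
    genomic_start = cl$genomic$start, genomic_end = cl$genomic$end,
    pattern = paste(cl$pattern$values, collapse = ""),
    stringsAsFactors = FALSE)))
}

#' Enumerate site pairs within a regulatory scope
#'
#' Pairs are drawn within the same 3'UTR (`scope = "same_utr"`) or within
#' each gene set (`scope = "gene_set"`, same or different genes).  When a
#' scope unit holds more than `max_sites` sites, `n_subsets` random subsets
#' of `max_sites` sites are drawn and every pair is tagged with its subset;
#' downstream p-values are then reported as the median over subsets.  Pairs
#' closer than 100 nt in the reference are flagged `close`.
#'
#' @param sites data.frame from [site_table()] (optionally with `sigma_hat`
#'   merged in).
#' @param scope `"same_utr"` or `"gene_set"`.
#' @param gene_sets named list of gene-id vectors (required for
#'   `"gene_set"`).
#' @param max_sites,n_subsets subset size and count for large scopes.
#' @param close_distance distance cutoff (nt) between reference positions
#'   below which a same-gene pair counts as close.
#' @param seed integer seed for subset draws.
#' @return data.frame of annotated pairs: ids, genes, families, `distance`,
#'   `close`, `same_gene`, `same_family`, `set_id`, `subset` (0 = full set).
#' @export
enumerate_pairs <- function(sites, scope = c("same_utr", "gene_set"),
                            gene_sets = NULL, max_sites = 200L,
                            n_subsets = 5L, close_distance = 100L,
                            seed = 1L) {
  scope <- match.arg(scope)
  set.seed(seed)
  units <- if (scope == "same_utr") {
    list(all = sites)
  } else {
    if (is.null(gene_sets)) stop("gene_sets required for gene_set scope")
    lapply(gene_sets, function(gs)
      sites[sites$gene_id %in% gs, , drop = FALSE])
  }
  out <- list()
  pairs_of <- function(df, set_id, subset) {
    n <- nrow(df)
    if (n < 2L) return(NULL)
    idx <- utils::combn(n, 2L)
    i <- idx[1, ]; j <- idx[2, ]
    same_gene <- df$gene_id[i] == df$gene_id[j]
    if (scope == "same_utr") {
      sel <- same_gene
      i <- i[sel]; j <- j[sel]; same_gene <- same_gene[sel]
      if (!length(i)) return(NULL)
    }
    dist <- ifelse(same_gene, abs(df$position[i] - df$position[j]), NA)
    data.frame(site1 = df$site_id[i], site2 = df$site_id[j],
               gene1 = df$gene_id[i], gene2 = df$gene_id[j],
               family1 = df$family_id[i], family2 = df$family_id[j],
               distance = dist,
               close = !is.na(dist) & dist < close_distance,
               same_gene = same_gene,
               same_family = df$family_id[i] == df$family_id[j],
               set_id = set_id, subset = subset, stringsAsFactors = FALSE)
  }
  for (nm in names(units)) {
    df <- units[[nm]]
    if (nrow(df) > max_sites) {
      for (k in seq_len(n_subsets)) {
        sub <- df[sort(sample.int(nrow(df), max_sites)), , drop = FALSE]
        out[[length(out) + 1L]] <- pairs_of(sub, nm, k)
      }
    } else {
      out[[length(out) + 1L]] <- pairs_of(df, nm, 0L)
    }
  }
  out <- Filter(Negate(is.null), out)
  if (!length(out))
    return(data.frame(site1 = character(), site2 = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Read a GMT gene-set file
#' @param file path; each line `set_id<TAB>source<TAB>gene1<TAB>...`.
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[`, "", 1))
}
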