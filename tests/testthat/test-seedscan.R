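test_that("seed match strings are the reverse complements of the seed", {
  ms <- seed_match_strings("GAGGUAG") # let-7 family, positions 2-8
  expect_identical(ms[["7merm8"]], "CTACCTC")
  expect_identical(ms[["8mer"]], "CTACCTCA")
  expect_identical(ms[["7merA1"]], "TACCTCA")
  expect_identical(ms[["6mer"]], "TACCTC")
  expect_identical(ms[["offset6mer"]], "CTACCT")
  expect_error(seed_match_strings("GAGG"), "malformed")
  expect_error(seed_def("f", "GAGGXAG"), "7 letters")
})

test_that("scanning calls the single best type per occurrence", {
  utr8 <- "GGGGCTACCTCAGGGG"
  hits <- seed_sites("GAGGUAG", utr8)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$type, "8mer")
  expect_equal(hits$position, 4L)
  # terminal A -> G downgrades the call to 7merm8
  utr7 <- "GGGGCTACCTCGGGGG"
  hits7 <- seed_sites("GAGGUAG", utr7)
  expect_equal(nrow(hits7), 1L)
  expect_identical(hits7$type, "7merm8")
  expect_equal(hits7$position, 4L)
  # no complementary substring -> empty
  expect_equal(nrow(seed_sites("GAGGUAG", "AAAAAAAAAAAA")), 0L)
  # N never matches
  expect_equal(nrow(seed_sites("GAGGUAG", "GGGGCTACCNCAGGGG")), 0L)
})

test_that("type precedence is exclusive over reference positions", {
  check <- function(utr) {
    hits <- seed_sites("GAGGUAG", utr)
    len <- nchar(hits$match)
    spans <- unlist(lapply(seq_len(nrow(hits)), function(i)
      hits$position[i] + seq_len(len[i]) - 1L))
    expect_false(anyDuplicated(spans) > 0)
    hits
  }
  # overlapping candidate matches resolve to non-overlapping calls
  hits <- check("GGCTACCTCTACCTCAGG")
  expect_gte(nrow(hits), 2L)
  set.seed(81)
  for (rep in 1:5)
    check(paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""))
})

.mk_maf <- function(blocks) {
  lines <- "##maf version=1"
  for (b in blocks) {
    lines <- c(lines, "", "a score=0")
    for (r in b)
      lines <- c(lines, sprintf("s %s %d %d %s %d %s",
                                r[1], as.integer(r[2]), as.integer(r[3]),
                                r[4], 1000L, r[5]))
  }
  f <- tempfile(fileext = ".maf")
  writeLines(lines, f)
  f
}

test_that("a single covering block stitches to its own rows", {
  f <- .mk_maf(list(list(c("hg.chr1", 100, 8, "+", "ACGTACGT"),
                         c("mm.chr1", 5, 8, "+", "ACGAACGT"))))
  utr <- list(chrom = "chr1", start = 100, end = 108, strand = "+",
              gene_id = "g1")
  aln <- stitch_maf(f, utr, c("hg", "mm"), "hg")
  expect_identical(unname(aln$rows["hg"]), "ACGTACGT")
  expect_identical(unname(aln$rows["mm"]), "ACGAACGT")
  expect_identical(reference_sequence(aln), "ACGTACGT")
})

test_that("a reference gap between blocks is filled with absent markers", {
  f <- .mk_maf(list(
    list(c("hg.chr1", 100, 4, "+", "ACGT"), c("mm.chr1", 0, 4, "+", "AGGT")),
    list(c("hg.chr1", 109, 4, "+", "TTTT"), c("mm.chr1", 9, 4, "+", "TATT"))))
  utr <- list(chrom = "chr1", start = 100, end = 113, strand = "+",
              gene_id = "g1")
  aln <- stitch_maf(f, utr, c("hg", "mm"), "hg",
                    ref_seq = "ACGTGGGGGTTTT")
  expect_equal(nchar(aln$rows[["hg"]]), 4 + 5 + 4)
  expect_identical(unname(aln$rows["mm"]), paste0("AGGT", "*****", "TATT"))
  expect_identical(reference_sequence(aln), "ACGTGGGGGTTTT")
})

test_that("species missing from a block get the absent marker", {
  f <- .mk_maf(list(list(c("hg.chr1", 0, 6, "+", "ACGTAC"))))
  utr <- list(chrom = "chr1", start = 0, end = 6, strand = "+",
              gene_id = "g1")
  aln <- stitch_maf(f, utr, c("hg", "mm"), "hg")
  expect_identical(unname(aln$rows["mm"]), "******")
})

test_that("overlapping reference blocks are an input error", {
  f <- .mk_maf(list(
    list(c("hg.chr1", 100, 6, "+", "ACGTAC")),
    list(c("hg.chr1", 104, 6, "+", "ACTTTT"))))
  utr <- list(chrom = "chr1", start = 100, end = 110, strand = "+",
              gene_id = "g1")
  expect_error(stitch_maf(f, utr, "hg", "hg"), "overlapping")
})

test_that("minus-strand UTRs come out in transcript orientation", {
  # genomic + strand holds the reverse complement of the transcript
  f <- .mk_maf(list(list(c("hg.chr1", 10, 8, "+", "TGAGGTAG"),
                         c("mm.chr1", 0, 8, "+", "TGAGGTAG"))))
  utr <- list(chrom = "chr1", start = 10, end = 18, strand = "-",
              gene_id = "g1")
  aln <- stitch_maf(f, utr, c("hg", "mm"), "hg")
  expect_identical(reference_sequence(aln), "CTACCTCA")
  hits <- seed_sites("GAGGUAG", reference_sequence(aln))
  expect_identical(hits$type, "8mer")
})

test_that("conservation calls require identical gap-free spans", {
  f <- .mk_maf(list(list(
    c("hg.chr1", 0, 12, "+", "GGCTACCTCAGG"),
    c("sp2.chr1", 0, 12, "+", "GGCTACCTCAGG"),   # identical -> 1
    c("sp3.chr1", 0, 12, "+", "GGCTACATCAGG"),   # substitution -> 0
    c("sp4.chr1", 0, 11, "+", "GGCTAC-TCAGG")))) # gap in span -> 0
  utr <- list(chrom = "chr1", start = 0, end = 12, strand = "+",
              gene_id = "g1")
  aln <- stitch_maf(f, utr, c("hg", "sp2", "sp3", "sp4"), "hg")
  pat <- site_conservation(aln, 2L, "CTACCTCA")
  expect_equal(unname(pat$values[c("hg", "sp2", "sp3", "sp4")]),
               c(1L, 1L, 0L, 0L))
})

test_that("site matrix enumeration is deterministic and typed", {
  f <- .mk_maf(list(list(c("hg.chr1", 0, 20, "+", "GGCTACCTCAGGTACCTCAG"),
                         c("mm.chr1", 0, 20, "+", "GGCTACCTCAGGTACCTCAG"))))
  utr <- list(chrom = "chr1", start = 0, end = 20, strand = "+",
              gene_id = "g1")
  aln <- stitch_maf(f, utr, c("hg", "mm"), "hg")
  seeds <- list(seed_def("let-7", "GAGGUAG"))
  calls <- build_site_matrix(list(aln), seeds)
  expect_equal(length(calls), 2L)
  expect_identical(vapply(calls, `[[`, "", "type"), c("8mer", "7merA1"))
  expect_error(build_site_matrix(list(aln, aln), seeds), "duplicate")
  # scanning a non-matching control seed yields nothing
  none <- build_site_matrix(list(aln), list(seed_def("ccc", "CCCCCCC")))
  expect_length(none, 0L)
})

test_that("interval filtering uses half-open overlap", {
  f <- .mk_maf(list(list(c("hg.chr1", 100, 20, "+",
                           "GGCTACCTCAGGGGGGGGGG"))))
  utr <- list(chrom = "chr1", start = 100, end = 120, strand = "+",
              gene_id = "g1")
  aln <- stitch_maf(f, utr, "hg", "hg")
  calls <- build_site_matrix(list(aln), list(seed_def("let-7", "GAGGUAG")))
  expect_equal(length(calls), 1L) # site at genomic [102, 110)
  keep <- filter_sites_by_intervals(calls, data.frame(
    chrom = "chr1", start = 90, end = 110))
  expect_length(keep, 1L)
  drop <- filter_sites_by_intervals(calls, data.frame(
    chrom = "chr1", start = 110, end = 150))
  expect_length(drop, 0L)
  bedf <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t90\t110\tfp1", "chr1\txx\t10"), bedf)
  expect_error(read_bed(bedf), "line 2")
})

test_that("pair enumeration respects scope, distance and subsets", {
  sites <- data.frame(
    site_id = paste0("s", 1:3), gene_id = "g1",
    family_id = c("f1", "f2", "f1"), position = c(100, 150, 300),
    stringsAsFactors = FALSE)
  pr <- enumerate_pairs(sites, "same_utr")
  expect_equal(nrow(pr), 3L) # C(3,2)
  d <- pr[pr$site1 == "s1" & pr$site2 == "s2", ]
  expect_true(d$close) # 50 nt apart
  expect_false(pr[pr$site1 == "s1" & pr$site2 == "s3", "close"]) # 200 nt
  expect_true(pr[pr$site1 == "s1" & pr$site2 == "s3", "same_family"])
  # subsets are reproducible under a fixed seed
  big <- data.frame(site_id = paste0("s", 1:250),
                    gene_id = rep(paste0("g", 1:25), each = 10),
                    family_id = "f1",
                    position = rep(seq(0, 900, by = 100), 25),
                    stringsAsFactors = FALSE)
  p1 <- enumerate_pairs(big, "same_utr", max_sites = 200, n_subsets = 5,
                        seed = 99)
  p2 <- enumerate_pairs(big, "same_utr", max_sites = 200, n_subsets = 5,
                        seed = 99)
  expect_identical(p1, p2)
  expect_setequal(unique(p1$subset), 1:5)
  # gene-set scope spans genes
  gs <- list(setA = c("g1", "g2"))
  pg <- enumerate_pairs(sites, "gene_set", gene_sets = gs)
  expect_equal(nrow(pg), 3L)
})

test_that("toy bundles round-trip through stitching and scanning", {
  spec <- simulation_spec(n_species = 6, n_genes = 4, sites_per_gene = 2,
                          n_coupled_genes = 2, seed = 33)
  out <- tempfile("bundle")
  bundle <- emit_toy_bundle(spec, out)
  utrs <- read_bed(bundle$paths$utrs)
  seeds <- read_seed_table(bundle$paths$seeds)
  maf <- read_maf(bundle$paths$maf)
  alns <- lapply(seq_len(nrow(utrs)), function(i) {
    u <- utrs[i, ]; u$gene_id <- u$name
    stitch_maf(maf, u, bundle$species, "sp1")
  })
  calls <- build_site_matrix(alns, seeds)
  tab <- site_table(calls)
  m <- bundle$manifest
  expect_equal(nrow(tab), nrow(m))
  key <- function(df) sort(paste(df$gene_id, df$family_id, df$position))
  expect_identical(key(tab), key(m))
  mm <- m[match(paste(tab$gene_id, tab$family_id, tab$position),
                paste(m$gene_id, m$family_id, m$position)), ]
  expect_identical(tab$pattern, mm$pattern)
  # footprint bookkeeping: exactly the covered planted sites survive
  fcalls <- filter_sites_by_intervals(calls, bundle$paths$footprints)
  expect_equal(length(fcalls), sum(m$in_footprint))
})
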