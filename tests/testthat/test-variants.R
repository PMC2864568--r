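test_that("indels are left-aligned against the anchor", {
  ##              01234567
  seq <- "ACGTTTTG"
  ## deleting one T of the run, described at position 4, shifts to the
  ## base before the run
  nv <- normalize_variant(seq, 4L, "TT", "T")
  expect_equal(nv, list(pos = 2L, ref = "GT", alt = "G"))
  ## insertion of a T inside the run likewise
  nv <- normalize_variant(seq, 4L, "T", "TT")
  expect_equal(nv, list(pos = 2L, ref = "G", alt = "GT"))
  ## a non-repetitive indel stays put (shared suffix trimmed only)
  nv <- normalize_variant("ACGTACGT", 3L, "TAC", "T")
  expect_equal(nv$pos, 3L)
  expect_equal(nv$ref, "TAC")
  expect_equal(nv$alt, "T")
})

## a synthetic pair of haplotype contigs with known planted variants
variant_scenario <- function(depth_moved = 4) {
  anchor <- rand_seq(3000, seed = 71)
  ach <- strsplit(anchor, "")[[1]]
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  ## planted edits in anchor coordinates (applied to the moved copy)
  snp_pos <- c(700L, 1000L, 1300L, 1600L)
  close_pos <- c(2000L, 2003L)      # a pair the quality filter must drop
  del_pos <- 1900L; del_len <- 3L   # run of 3 deleted anchor bases
  ins_pos <- 2200L; ins_seq <- "AG" # inserted after anchor base 2200
  ## the moved contig copies anchor positions [500, 2500) (0-based); a
  ## 0-based anchor position p sits at 1-based moved index p - 500 + 1
  mch <- ach[501:2500]
  local <- function(p) p - 500L
  for (p in c(snp_pos, close_pos)) {
    mch[local(p) + 1L] <- other(ach[p + 1L])
  }
  m <- paste(mch, collapse = "")
  ## apply indels right to left in moved-local coordinates
  m <- paste0(substr(m, 1, local(ins_pos) + 1L), ins_seq,
              substr(m, local(ins_pos) + 2L, nchar(m)))
  m <- paste0(substr(m, 1, local(del_pos)),
              substr(m, local(del_pos) + del_len + 1L, nchar(m)))
  pl <- toy_agp(data.table::data.table(
    contig_id = c("B", "M"), chrom = "chr1",
    start = c(0L, 3100L), end = c(3000L, 3100L + nchar(m)),
    orientation = "forward"))$placements
  rows <- list()
  for (s in seq(0, 2600, by = 100)) {
    rows[[length(rows) + 1]] <- list(paste0("a", s), "B", s,
                                     min(s + 400, 3000), "forward", "libA",
                                     NA)
  }
  for (s in seq(0, nchar(m) - 400, by = 100)) {
    rows[[length(rows) + 1]] <- list(paste0("m", s), "M", s, s + 400,
                                     "forward", "libA", NA)
  }
  lay <- do.call(toy_layout, rows)
  hit <- align_pair(m, anchor, query_id = "M", target_id = "B")[[1]]
  cand <- falsedup:::new_candidate("DCC", "M", "B", hit, pl)
  contigs <- c(B = anchor, M = m)
  list(cand = cand, lay = lay, contigs = contigs, pl = pl, anchor = anchor,
       snp_pos = snp_pos, close_pos = close_pos, del_pos = del_pos,
       del_len = del_len, ins_pos = ins_pos, ins_seq = ins_seq,
       ach = ach, other = other)
}

test_that("planted SNPs and indels are recovered exactly", {
  sc <- variant_scenario()
  pileup <- merge_and_realign(sc$cand, sc$lay, sc$contigs, sc$pl)
  v <- call_variants(pileup, sc$anchor, min_allele_depth = 2L)
  ## before the quality filter: all six SNPs and both indels
  snps <- v[var_type == "SNP"]
  expect_setequal(snps$position, c(sc$snp_pos, sc$close_pos))
  for (p in sc$snp_pos) {
    row <- snps[position == p]
    expect_equal(row$ref_allele, sc$ach[p + 1L])
    expect_equal(row$alt_allele, sc$other(sc$ach[p + 1L]))
  }
  indels <- v[var_type == "indel"]
  expect_equal(nrow(indels), 2L)
  ## the 3 bp deletion merges into one left-aligned record
  exp_del <- normalize_variant(
    sc$anchor, sc$del_pos - 1L,
    paste(sc$ach[sc$del_pos:(sc$del_pos + sc$del_len)], collapse = ""),
    sc$ach[sc$del_pos])
  del_row <- indels[nchar(ref_allele) > nchar(alt_allele)]
  expect_equal(del_row$position, exp_del$pos)
  expect_equal(del_row$ref_allele, exp_del$ref)
  expect_equal(del_row$alt_allele, exp_del$alt)
  exp_ins <- normalize_variant(sc$anchor, sc$ins_pos,
                               sc$ach[sc$ins_pos + 1L],
                               paste0(sc$ach[sc$ins_pos + 1L], sc$ins_seq))
  ins_row <- indels[nchar(alt_allele) > nchar(ref_allele)]
  expect_equal(ins_row$position, exp_ins$pos)
  expect_equal(ins_row$alt_allele, exp_ins$alt)

  ## depths are reproducible by independent interval counting
  for (p in sc$snp_pos) {
    row <- snps[position == p]
    a_depth <- sum(vapply(seq(0, 2600, by = 100), function(s) {
      s <= p && p < min(s + 400, 3000)
    }, NA))
    expect_equal(row$depth_ref, a_depth)
  }

  ## the quality filter drops the close pair and nothing else
  vq <- quality_filter(v, pileup, flank = 5L)
  expect_setequal(vq[var_type == "SNP", position], sc$snp_pos)
  ## no emitted variant lies within the flank of another
  pos <- sort(vq$position)
  expect_true(all(diff(pos) > 5L))
})

test_that("alleles below the depth threshold are not called", {
  sc <- variant_scenario()
  ## strip the moved contig down to a single read over each variant
  lay1 <- sc$lay[!startsWith(read_id, "m") |
                 read_id %in% paste0("m", seq(0, 2000, by = 400))]
  pileup <- merge_and_realign(sc$cand, lay1, sc$contigs, sc$pl)
  v <- call_variants(pileup, sc$anchor, min_allele_depth = 2L)
  expect_equal(nrow(v), 0L)
})

test_that("the coverage filter keeps only single-copy calls", {
  variants <- data.table::data.table(
    chrom = "chr1", position = c(10L, 20L, 30L),
    ref_allele = "A", alt_allele = "G", var_type = "SNP",
    depth_ref = 3L, depth_alt = 3L, call_id = c(1L, 1L, 2L))
  calls <- data.table::data.table(call_id = c(1L, 2L),
                                  a_stat = c(6.137, -7.726))
  out <- coverage_filter(variants, calls)
  expect_equal(out$call_id, c(1L, 1L))
  expect_equal(nrow(coverage_filter(variants[0], calls)), 0L)
})

test_that("pipeline variants match the simulator's planted variants", {
  b <- tiny_bundle()
  res <- tiny_result()
  tv <- merge(b$truth$variants,
              b$truth$features[, .(feature_id, moved_contig)],
              by = "feature_id")
  calls <- res$detect$calls
  passed <- unique(calls[verdict == "mis_assembled" & a_stat > 0,
                         moved_contig_id])
  expected <- tv[callable == TRUE & moved_contig %in% passed]
  pv <- res$variants
  key <- function(d) paste(d$chrom, d$position, d$ref_allele, d$alt_allele)
  expect_gte(mean(key(expected) %in% key(pv)), 0.95)
  ## precision: nearly everything called was planted
  expect_gte(mean(key(pv) %in% key(tv)), 0.95)
})
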