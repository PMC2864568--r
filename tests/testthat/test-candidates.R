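mk_hit <- function(q_start, q_end, t_start, t_end, identity,
                   strand = "same") {
  falsedup:::linear_hit("moved", "anchor", q_start, q_end, t_start, t_end,
                        strand = strand, identity = identity)
}

test_that("neighbor pairing uses the gap between nearest ends", {
  pl <- data.table::data.table(
    contig_id = c("a", "b", "c"), chrom = "chr1",
    start = c(0L, 55000L, 140000L),
    end = c(10000L, 80000L, 150000L),
    orientation = "forward", placed = TRUE)
  pairs <- neighbor_pairs(pl, window = 50000L)
  ## a-b gap 45,000 <= 50,000 -> paired; b-c gap 60,000 -> excluded
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$left_id, "a")
  expect_equal(pairs$right_id, "b")
  ## adjacent contigs (gap 0) pair, and each unordered pair appears once
  pl2 <- data.table::data.table(
    contig_id = c("a", "b"), chrom = "chr1", start = c(0L, 10000L),
    end = c(10000L, 20000L), orientation = "forward", placed = TRUE)
  pairs2 <- neighbor_pairs(pl2, window = 50000L)
  expect_equal(nrow(pairs2), 1L)
  ## boundary: gap exactly window pairs, window+1 does not
  pl3 <- data.table::copy(pl2)[contig_id == "b",
                               `:=`(start = 60000L, end = 70000L)]
  expect_equal(nrow(neighbor_pairs(pl3, 50000L)), 1L)
  pl3[contig_id == "b", `:=`(start = 60001L, end = 70001L)]
  expect_equal(nrow(neighbor_pairs(pl3, 50000L)), 0L)
})

test_that("DCC rule: coverage > 93% of the moved contig at > 95% identity", {
  ## a 1,537 bp contig aligning in its entirety at 98.9%
  expect_true(classify_dcc(mk_hit(0L, 1537L, 100L, 1637L, 0.989), 1537L))
  expect_false(classify_dcc(mk_hit(0L, 900L, 0L, 900L, 0.96), 1000L))
  expect_true(classify_dcc(mk_hit(0L, 1000L, 0L, 1000L, 1.0), 1000L))
})

test_that("DOC rule: >300 bp, >95% identity, hit at the facing ends", {
  ## hit touching the right end of the left contig (len 5000) and the left
  ## end of the right contig (len 4000)
  expect_true(classify_doc(mk_hit(0L, 400L, 4600L, 5000L, 0.97),
                           5000L, 4000L))
  ## same alignment located mid-contig
  expect_false(classify_doc(mk_hit(1000L, 1400L, 2000L, 2400L, 0.97),
                            5000L, 4000L))
  ## within 10 bp of both ends (the common case)
  expect_true(classify_doc(mk_hit(10L, 410L, 4590L, 4990L, 0.97),
                           5000L, 4000L))
  ## too short / low identity / wrong strand
  expect_false(classify_doc(mk_hit(0L, 250L, 4750L, 5000L, 0.97),
                            5000L, 4000L))
  expect_false(classify_doc(mk_hit(0L, 400L, 4600L, 5000L, 0.94),
                            5000L, 4000L))
  expect_false(classify_doc(mk_hit(0L, 400L, 4600L, 5000L, 0.97,
                                   strand = "opposite"), 5000L, 4000L))
})

test_that("classification rules are monotone in identity and coverage", {
  set.seed(4)
  for (i in 1:200) {
    id1 <- runif(1, 0.9, 1); id2 <- runif(1, id1, 1)
    cov1 <- runif(1, 0.85, 1); cov2 <- runif(1, cov1, 1)
    L <- 1000L
    h_lo <- mk_hit(0L, as.integer(cov1 * L), 0L, as.integer(cov1 * L), id1)
    h_hi <- mk_hit(0L, as.integer(cov2 * L), 0L, as.integer(cov2 * L), id2)
    if (classify_dcc(h_lo, L)) expect_true(classify_dcc(h_hi, L))
    d_lo <- mk_hit(0L, 400L, 4600L, 5000L, id1)
    d_hi <- mk_hit(0L, 400L, 4600L, 5000L, id2)
    if (classify_doc(d_lo, 5000L, 4000L)) {
      expect_true(classify_doc(d_hi, 5000L, 4000L))
    }
  }
})

test_that("DOC adjacency filter keeps only adjacent or DCC-bridged pairs", {
  pl <- toy_agp(data.table::data.table(
    contig_id = c("L", "m1", "m2", "R"), chrom = "chr1",
    start = c(0L, 1100L, 2100L, 3100L),
    end = c(1000L, 2000L, 3000L, 4000L),
    orientation = "forward"))$placements
  mk_doc <- function(left, right) {
    cand <- falsedup:::new_candidate(
      "DOC", right, left,
      falsedup:::linear_hit(right, left, 0L, 400L, 600L, 1000L,
                            identity = 0.99), pl)
    cand
  }
  adjacent <- mk_doc("m2", "R")
  bridged <- mk_doc("m1", "R")      # m2 in between
  blocked <- mk_doc("L", "R")       # m1 and m2 in between
  out <- doc_adjacency_filter(list(adjacent, bridged, blocked), pl,
                              dcc_mis_ids = "m2")
  ids <- vapply(out, function(c) c$anchor_contig_id, "")
  expect_setequal(ids, c("m2", "m1"))
  out2 <- doc_adjacency_filter(list(bridged), pl, dcc_mis_ids = character(0))
  expect_length(out2, 0)
})

test_that("every planted duplication pattern appears in the candidates", {
  b <- tiny_bundle()
  res <- tiny_result()
  cand_ids <- vapply(res$detect$candidates, `[[`, "", "moved_contig_id")
  f <- b$truth$features
  placed_pat <- f[pattern %in% c("DCC_misassembly", "DOC_misassembly",
                                 "true_duplication")]
  expect_true(all(placed_pat$moved_contig %in% cand_ids))
})

test_that("a DOC merged layout shrinks the chromosome by overlap + gap", {
  b <- tiny_bundle()
  res <- tiny_result()
  calls <- res$detect$calls
  doc_calls <- calls[kind == "DOC" & verdict == "mis_assembled"]
  expect_gt(nrow(doc_calls), 0)
  for (i in seq_len(nrow(doc_calls))) {
    cand <- res$detect$candidates[[doc_calls$cand_idx[i]]]
    ml <- merged_layout(cand, b$agp$placements, b$agp$gaps)
    ## delta is the overlap prefix of the moved contig plus the removed gap
    expect_equal(ml$delta, cand$hit$q_end + ml$removed_gap)
  }
})
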