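## candidates: find apparent nearby duplications and classify them as DCC
## (duplicated contained contig) or DOC (duplicated overlapping contigs).
## All geometry is computed in each contig's chromosomally oriented frame
## (sequence reverse-complemented when the contig is placed on the minus
## strand), so a genuine haplotype duplication always appears as a
## same-strand hit and end proximity can be read off directly.

#' Enumerate nearby contig pairs
#'
#' All unordered pairs of placed contigs on one chromosome whose spans are
#' separated by at most \code{window} bp (gap between nearest ends;
#' adjacent and overlapping spans count as gap 0).
#'
#' @param placements Contig placements (one chromosome or several; pairs are
#'   formed within chromosomes).
#' @param window Maximum gap in bp.
#' @return data.table: chrom, left_id, right_id (left has the smaller start).
#' @export
neighbor_pairs <- function(placements, window = 50000L) {
  out <- list()
  for (ch in unique(placements$chrom)) {
    p <- placements[chrom == ch][order(start)]
    n <- nrow(p)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      j <- i + 1L
      while (j <= n && p$start[j] - p$end[i] <= window) {
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = ch, left_id = p$contig_id[i], right_id = p$contig_id[j])
        j <- j + 1L
      }
    }
  }
  if (!length(out)) {
    return(data.table::data.table(chrom = character(), left_id = character(),
                                  right_id = character()))
  }
  data.table::rbindlist(out)
}

## chromosomally oriented sequence of a contig (with memoising cache)
oriented_seq <- function(contigs, contig_id, orientation, cache = NULL) {
  if (!is.null(cache) && !is.null(cache[[contig_id]])) {
    return(cache[[contig_id]])
  }
  s <- contigs[[contig_id]]
  if (identical(orientation, "reverse")) s <- revcomp(s)
  if (!is.null(cache)) cache[[contig_id]] <- s
  s
}

#' DCC classification rule
#'
#' A hit marks a duplicated contained contig when it covers more than
#' \code{cov_min} of the moved (shorter) contig's length at more than
#' \code{id_min} identity.  Monotone in both coverage and identity.
#'
#' @param hit Alignment hit whose query is the moved contig.
#' @param moved_contig_length Length of the moved contig.
#' @param cov_min,id_min Thresholds (defaults for placed contigs).
#' @return TRUE/FALSE.
#' @export
classify_dcc <- function(hit, moved_contig_length, cov_min = 0.93,
                         id_min = 0.95) {
  hit$length / moved_contig_length > cov_min && hit$identity > id_min
}

#' DOC classification rule
#'
#' A hit marks duplicated overlapping contigs when it is longer than
#' \code{min_len}, above \code{id_min} identity, reaches within
#' \code{end_slack} of the right end of the left contig and of the left end
#' of the right contig (in chromosomal orientation), and its strand is
#' consistent with a head-to-tail join (same strand in oriented frames).
#'
#' @param hit Hit with query = right contig, target = left contig, both in
#'   oriented frames.
#' @param left_len,right_len Contig lengths.
#' @param end_slack Maximum distance from the facing ends, bp.
#' @param min_len Minimum alignment length, bp.
#' @param id_min Identity threshold.
#' @return TRUE/FALSE.
#' @export
classify_doc <- function(hit, left_len, right_len, end_slack = 300L,
                         min_len = 300L, id_min = 0.95) {
  hit$strand == "same" &&
    hit$length > min_len &&
    hit$identity > id_min &&
    hit$t_end >= left_len - end_slack &&
    hit$q_start <= end_slack
}

new_candidate <- function(kind, moved_contig_id, anchor_contig_id, hit,
                          placements) {
  anchor <- placements[contig_id == anchor_contig_id]
  moved <- placements[contig_id == moved_contig_id]
  cand <- list(kind = kind, moved_contig_id = moved_contig_id,
               anchor_contig_id = anchor_contig_id, hit = hit,
               chrom = anchor$chrom,
               span_start = anchor$start + hit$t_start,
               span_end = anchor$start + hit$t_end,
               junction = NA_integer_, delta = NA_integer_,
               removed_contigs = character(0))
  if (kind == "DOC" && nrow(moved)) {
    cand$junction <- moved$start
    cand$delta <- (moved$start + hit$q_end) - (anchor$start + hit$t_end)
  }
  class(cand) <- "dup_candidate"
  cand
}

#' Find DCC/DOC candidates among placed contigs
#'
#' Aligns every nearby contig pair (gap <= \code{window}) with the internal
#' aligner, or matches externally supplied hits, and applies the DCC and DOC
#' classification rules.  Within-contig duplications are not considered.
#'
#' @param contigs Named character vector of contig sequences.
#' @param placements Contig placements.
#' @param window Neighborhood window, bp.
#' @param hits Optional externally supplied hits (from
#'   [ingest_alignments()]); hit query/target ids must be contig ids and
#'   coordinates must be in chromosomally oriented frames.
#' @param dcc_cov_min,dcc_id_min,doc_min_len,doc_id_min,end_slack
#'   Classification thresholds.
#' @param verbose Log per-stage counts to stderr.
#' @return List of \code{dup_candidate} objects.
#' @export
find_candidates <- function(contigs, placements, window = 50000L,
                            hits = NULL, dcc_cov_min = 0.93,
                            dcc_id_min = 0.95, doc_min_len = 300L,
                            doc_id_min = 0.95, end_slack = 300L,
                            verbose = FALSE) {
  pairs <- neighbor_pairs(placements[placed == TRUE], window)
  if (verbose) message("candidates: ", nrow(pairs), " neighbor pairs")
  cache <- new.env(parent = emptyenv())
  cands <- list()
  pair_hits <- function(lid, rid) {
    if (!is.null(hits)) {
      sel <- vapply(hits, function(h) {
        (h$query_id == rid && h$target_id == lid) ||
          (h$query_id == lid && h$target_id == rid)
      }, logical(1L))
      lapply(hits[sel], function(h) {
        if (h$query_id == rid) h else invert_hit(h)
      })
    } else {
      lp <- placements[contig_id == lid]
      rp <- placements[contig_id == rid]
      align_pair(oriented_seq(contigs, rid, rp$orientation, cache),
                 oriented_seq(contigs, lid, lp$orientation, cache),
                 query_id = rid, target_id = lid)
    }
  }
  for (i in seq_len(nrow(pairs))) {
    lid <- pairs$left_id[i]; rid <- pairs$right_id[i]
    llen <- nchar(contigs[[lid]]); rlen <- nchar(contigs[[rid]])
    for (h in pair_hits(lid, rid)) {
      ## DCC: the shorter contig is the candidate moved contig
      if (rlen <= llen) {
        moved <- rid; anchor <- lid; hm <- h
      } else {
        moved <- lid; anchor <- rid; hm <- invert_hit(h)
      }
      mlen <- nchar(contigs[[moved]])
      if (classify_dcc(hm, mlen, dcc_cov_min, dcc_id_min)) {
        cands[[length(cands) + 1L]] <-
          new_candidate("DCC", moved, anchor, hm, placements)
      } else if (classify_doc(h, llen, rlen, end_slack, doc_min_len,
                              doc_id_min)) {
        ## DOC: left contig is the anchor, right contig joins onto it
        cands[[length(cands) + 1L]] <-
          new_candidate("DOC", rid, lid, h, placements)
      }
    }
  }
  if (verbose) {
    message("candidates: ", sum(vapply(cands, `[[`, "", "kind") == "DCC"),
            " DCC, ", sum(vapply(cands, `[[`, "", "kind") == "DOC"), " DOC")
  }
  cands
}

#' DOC adjacency filter
#'
#' A DOC candidate is retained only when its two contigs are adjacent on
#' the chromosome (no placed contig in between) or when exactly one contig
#' lies between them and that contig has already been classified as a
#' mis-assembled DCC.
#'
#' @param candidates Candidate list.
#' @param placements Contig placements.
#' @param dcc_mis_ids Contig ids called mis-assembled DCCs.
#' @return Filtered candidate list (DCCs pass through unchanged); retained
#'   DOCs with one intervening mis-assembled DCC record it in
#'   \code{removed_contigs}.
#' @export
doc_adjacency_filter <- function(candidates, placements,
                                 dcc_mis_ids = character(0)) {
  keep <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    if (cand$kind != "DOC") { keep[i] <- TRUE; next }
    left <- placements[contig_id == cand$anchor_contig_id]
    right <- placements[contig_id == cand$moved_contig_id]
    between <- placements[placed == TRUE & chrom == left$chrom &
                          start >= left$end & end <= right$start &
                          !contig_id %in% c(cand$anchor_contig_id,
                                            cand$moved_contig_id)]
    if (nrow(between) == 0L) {
      keep[i] <- TRUE
    } else if (nrow(between) == 1L && between$contig_id %in% dcc_mis_ids) {
      candidates[[i]]$removed_contigs <- between$contig_id
      keep[i] <- TRUE
    }
  }
  candidates[keep]
}

#' Describe the merged layout of a candidate
#'
#' For a DCC the moved contig's reads are re-projected onto the anchor's
#' chromosomal span at the alignment offset (gap-aware through the
#' alignment path).  For a DOC the right contig is joined onto the left by
#' superimposing the overlap; the intervening gap (and any single
#' mis-assembled DCC contig in between) is removed and downstream
#' coordinates shift left by \code{delta}.
#'
#' @param candidate A \code{dup_candidate}.
#' @param placements Contig placements.
#' @param gaps Gap records from the AGP (used to report removed gap length).
#' @return List: kind, chrom, span_start, span_end, and for DOCs the
#'   junction, total length change \code{delta} (overlap + removed gap +
#'   removed contigs), and removed gap length.
#' @export
merged_layout <- function(candidate, placements, gaps = NULL) {
  out <- list(kind = candidate$kind, chrom = candidate$chrom,
              span_start = candidate$span_start,
              span_end = candidate$span_end)
  if (candidate$kind == "DOC") {
    out$junction <- candidate$junction
    out$delta <- candidate$delta
    if (!is.null(gaps)) {
      left <- placements[contig_id == candidate$anchor_contig_id]
      right <- placements[contig_id == candidate$moved_contig_id]
      out$removed_gap <- gaps[chrom == left$chrom & start >= left$end &
                              end <= right$start, sum(length)]
    }
  } else {
    moved <- placements[contig_id == candidate$moved_contig_id]
    if (nrow(moved)) out$removed_length <- moved$end - moved$start
  }
  out
}

#' Project moved-contig reads into the merged location
#'
#' Re-computes each read's chromosomal interval, 5' end and orientation as
#' if the moved contig were superimposed on (DCC) or joined with (DOC) its
#' anchor, mapping positions through the anchoring alignment's gapped path.
#'
#' @param cand A \code{dup_candidate}.
#' @param layout_rows Layout rows of the moved contig.
#' @param placements Contig placements.
#' @return data.table: read_id, g_start, g_end, pos5, chrom_orient.
#' @export
project_merged <- function(cand, layout_rows, placements) {
  hit <- cand$hit
  anchor <- placements[contig_id == cand$anchor_contig_id]
  moved <- placements[contig_id == cand$moved_contig_id]
  ## read intervals in the moved contig's chromosomally oriented frame
  if (nrow(moved) && moved$orientation == "reverse") {
    Lm <- moved$end - moved$start
    o_s <- Lm - layout_rows$end
    o_e <- Lm - layout_rows$start
    o_orient <- ifelse(layout_rows$orientation == "forward",
                       "reverse", "forward")
  } else {
    o_s <- layout_rows$start
    o_e <- layout_rows$end
    o_orient <- layout_rows$orientation
  }
  t1 <- map_through_hit(hit, o_s)
  t2 <- map_through_hit(hit, o_e - 1L)
  if (hit$strand == "same") {
    g_start <- anchor$start + t1
    g_end <- anchor$start + t2 + 1L
    orient <- o_orient
  } else {
    g_start <- anchor$start + t2
    g_end <- anchor$start + t1 + 1L
    orient <- ifelse(o_orient == "forward", "reverse", "forward")
  }
  data.table::data.table(
    read_id = layout_rows$read_id,
    g_start = g_start, g_end = g_end,
    pos5 = ifelse(orient == "forward", g_start, g_end - 1L),
    chrom_orient = orient)
}
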