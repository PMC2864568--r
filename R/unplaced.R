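## unplaced: screen contigs not assigned to a chromosome as haplotype
## variants of placed sequence.  Criteria are stricter than for placed
## contigs because unplaced contigs cannot be localized: higher alignment
## thresholds, and mate support must clear a wider probability floor
## (0.05 cumulative tail, roughly two standard deviations for a normal).

#' Find DCC/DOC candidates for unplaced contigs
#'
#' Aligns each unplaced contig against all placed contigs (no distance
#' window applies).  A DCC requires identity >= \code{dcc_id_min} over at
#' least \code{dcc_cov_min} of the unplaced contig's length; a DOC requires
#' identity >= \code{doc_id_min} over at least \code{doc_min_len} bp with
#' the hit reaching an end of the unplaced contig.
#'
#' @param unplaced_seqs Named character vector of unplaced contig sequences.
#' @param contigs Placed contig sequences.
#' @param placements Contig placements (placed contigs).
#' @param hits Optional externally supplied hits (query = unplaced contig).
#' @param dcc_id_min,dcc_cov_min,doc_id_min,doc_min_len,end_slack Thresholds.
#' @param verbose Log progress.
#' @return List of \code{dup_candidate}s (query frame = unplaced contig
#'   forward strand).
#' @export
unplaced_candidates <- function(unplaced_seqs, contigs, placements,
                                hits = NULL, dcc_id_min = 0.96,
                                dcc_cov_min = 0.94, doc_id_min = 0.96,
                                doc_min_len = 400L, end_slack = 300L,
                                verbose = FALSE) {
  placed <- placements[placed == TRUE]
  cache <- new.env(parent = emptyenv())
  ## precompute oriented target k-mer codes for the seed prefilter
  tcodes <- new.env(parent = emptyenv())
  target_codes <- function(cid) {
    if (is.null(tcodes[[cid]])) {
      orient <- placed[contig_id == cid, orientation]
      tcodes[[cid]] <- kmer_codes(oriented_seq(contigs, cid, orient, cache),
                                  sentinel = -2)
    }
    tcodes[[cid]]
  }
  cands <- list()
  for (uid in names(unplaced_seqs)) {
    useq <- unplaced_seqs[[uid]]
    ulen <- nchar(useq)
    qf <- kmer_codes(useq, sentinel = -1)
    qr <- kmer_codes(revcomp(useq), sentinel = -1)
    uhits <- if (!is.null(hits)) {
      Filter(function(h) h$query_id == uid, hits)
    } else {
      found <- list()
      for (cid in placed$contig_id) {
        tc <- target_codes(cid)
        seeded <- any(!is.na(match(qf, tc))) || any(!is.na(match(qr, tc)))
        if (!seeded) next
        orient <- placed[contig_id == cid, orientation]
        hs <- align_pair(useq, oriented_seq(contigs, cid, orient, cache),
                         query_id = uid, target_id = cid)
        found <- c(found, hs)
      }
      found
    }
    for (h in uhits) {
      anchor <- h$target_id
      is_dcc <- h$identity >= dcc_id_min && h$length / ulen >= dcc_cov_min
      is_doc <- !is_dcc && h$identity >= doc_id_min &&
        h$length >= doc_min_len &&
        (h$q_start <= end_slack || h$q_end >= ulen - end_slack)
      if (is_dcc || is_doc) {
        cand <- new_candidate(if (is_dcc) "DCC" else "DOC", uid, anchor, h,
                              placements)
        cand$unplaced <- TRUE
        cands[[length(cands) + 1L]] <- cand
      }
    }
  }
  if (verbose) message("unplaced: ", length(cands), " candidates")
  cands
}

#' Mate consistency under the implied placement
#'
#' A mate pair is consistent when it is properly oriented and the implied
#' fragment size has probability strictly greater than the library's
#' 0.05-tail probability floor (roughly within two standard deviations for
#' a normal model).
#'
#' @param model Library model.
#' @param size Implied fragment size(s).
#' @param oriented_properly Logical vector.
#' @param tail Floor tail (0.05 for the unplaced analysis).
#' @return Logical vector.
#' @export
mate_consistency <- function(model, size, oriented_properly, tail = 0.05) {
  fl <- compute_floor(model, tail)
  p <- if (model$kind == "normal") {
    stats::dnorm(size, model$mu, model$sigma)
  } else {
    idx <- match(as.integer(round(size)), model$grid)
    d <- model$density[idx]
    d[is.na(d)] <- 0
    d
  }
  oriented_properly & p > fl
}

#' Classify one unplaced candidate
#'
#' Counts the contig's mate pairs with a placed mate outside the contig and
#' how many are consistent in the implied location; the contig is a
#' haplotype variant iff at least \code{min_consistent} pairs are
#' consistent and the consistent fraction is at least \code{min_fraction}.
#'
#' @param cand Candidate from [unplaced_candidates()].
#' @param layout Read layout.
#' @param placements Contig placements.
#' @param models Library models.
#' @param proj Optional precomputed projection table.
#' @param tail Floor tail.
#' @param min_consistent,min_fraction Verdict thresholds.
#' @return One-row data.table: contig_id, anchor_contig_id, kind,
#'   n_consistent, n_outside_mates, verdict.
#' @export
classify_unplaced <- function(cand, layout, placements, models, proj = NULL,
                              tail = 0.05, min_consistent = 2L,
                              min_fraction = 0.30) {
  if (is.null(proj)) proj <- project_reads(layout, placements)
  rel <- relevant_reads_dcc(cand$moved_contig_id, layout)
  if (nrow(rel)) {
    mate_placed <- proj$placed[match(rel$mate_id, proj$read_id)]
    rel <- rel[mate_placed %in% TRUE]
  }
  n_out <- nrow(rel)
  n_cons <- 0L
  if (n_out) {
    mp <- project_merged(cand, rel, placements)
    pm <- proj[match(rel$mate_id, proj$read_id)]
    frag <- implied_fragment(mp$pos5, mp$chrom_orient, pm$pos5,
                             pm$chrom_orient)
    cons <- logical(n_out)
    for (lib in unique(rel$library_id)) {
      sel <- rel$library_id == lib
      cons[sel] <- mate_consistency(models[[lib]], frag$size[sel],
                                    frag$oriented_properly[sel], tail)
    }
    n_cons <- sum(cons)
  }
  verdict <- if (n_cons >= min_consistent &&
                 n_out > 0L && n_cons / n_out >= min_fraction) {
    "haplotype_variant"
  } else "kept"
  data.table::data.table(
    contig_id = cand$moved_contig_id,
    anchor_contig_id = cand$anchor_contig_id, kind = cand$kind,
    n_consistent = as.integer(n_cons), n_outside_mates = as.integer(n_out),
    verdict = verdict)
}

#' Classify all unplaced candidates
#'
#' Candidates are evaluated independently; when an unplaced contig
#' qualifies through several placed anchors, the anchor with the best
#' consistent fraction wins.
#'
#' @inheritParams classify_unplaced
#' @param cands Candidate list.
#' @return data.table of verdicts, one row per unplaced contig with at
#'   least one candidate.
#' @export
classify_unplaced_all <- function(cands, layout, placements, models,
                                  tail = 0.05, min_consistent = 2L,
                                  min_fraction = 0.30) {
  if (!length(cands)) {
    return(data.table::data.table(
      contig_id = character(), anchor_contig_id = character(),
      kind = character(), n_consistent = integer(),
      n_outside_mates = integer(), verdict = character()))
  }
  proj <- project_reads(layout, placements)
  rows <- data.table::rbindlist(lapply(cands, classify_unplaced, layout,
                                       placements, models, proj, tail,
                                       min_consistent, min_fraction))
  rows[, frac := ifelse(n_outside_mates > 0, n_consistent / n_outside_mates, 0)]
  data.table::setorder(rows, contig_id, -frac, -n_consistent)
  best <- rows[, .SD[1L], by = contig_id]
  best[, frac := NULL]
  best[]
}
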