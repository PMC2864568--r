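## likelihood: evaluate the mate-pair placement likelihood of each candidate
## at its original and merged locations and call mis-assemblies.
## All computation is in log space; the per-library probability floor keeps
## every term finite, so the comparison is never dominated by a single
## extreme fragment.

#' Relevant reads for a DCC candidate
#'
#' All reads in the moved contig whose mate is placed in a different
#' contig; unmated reads and reads with within-contig mates are excluded.
#'
#' @param contig Moved contig id.
#' @param layout Read layout.
#' @return Layout rows of the relevant reads.
#' @export
relevant_reads_dcc <- function(contig, layout) {
  inside <- layout[contig_id == contig & !is.na(mate_id)]
  mate_contig <- layout$contig_id[match(inside$mate_id, layout$read_id)]
  inside[!is.na(mate_contig) & mate_contig != contig]
}

#' Relevant reads for a DOC candidate
#'
#' Reads in either contig of the pair whose mate link crosses the overlap
#' junction: reads pointing right from the left contig with the mate's 5'
#' end at or beyond the junction, and reads pointing left from the right
#' contig with the mate's 5' end before it.  Pairs pointing away from the
#' overlap are assumed to have fixed the adjacent gap sizes and are
#' excluded.
#'
#' @param cand DOC candidate.
#' @param layout Read layout.
#' @param proj Projection table from \code{project_reads()}.
#' @return Layout rows of the relevant reads (one row per read; a crossing
#'   pair can contribute rows for both of its reads).
#' @export
relevant_reads_doc <- function(cand, layout, proj) {
  junction <- cand$junction
  ids <- c(cand$anchor_contig_id, cand$moved_contig_id)
  inside <- layout[contig_id %in% ids & !is.na(mate_id)]
  if (!nrow(inside)) return(inside)
  p <- proj[match(inside$read_id, read_id)]
  pm <- proj[match(inside$mate_id, read_id)]
  ok <- !is.na(pm$pos5) & pm$placed &
    ((inside$contig_id == cand$anchor_contig_id &
        p$chrom_orient == "forward" & pm$pos5 >= junction) |
     (inside$contig_id == cand$moved_contig_id &
        p$chrom_orient == "reverse" & pm$pos5 < junction))
  inside[ok]
}

#' Fragment implied by a mate pair in a layout variant
#'
#' The 5'-to-5' distance between the two projected reads and whether they
#' face each other, both recomputed in the given layout.
#'
#' @param pos5_r,orient_r Projected 5' position/orientation of the read.
#' @param pos5_m,orient_m Same for the mate.
#' @return data.table: size, oriented_properly (vectorized).
#' @export
implied_fragment <- function(pos5_r, orient_r, pos5_m, orient_m) {
  data.table::data.table(
    size = abs(pos5_m - pos5_r),
    oriented_properly = fragment_proper(pos5_r, orient_r, pos5_m, orient_m))
}

#' Placement log-likelihood of a set of fragments
#'
#' Mate pairs are independent, so the log-likelihood of a location is the
#' sum over relevant pairs of the log probability of the implied fragment
#' size under the pair's library model (floored, so always finite).
#'
#' @param fragments data.table: library_id, size, oriented_properly.
#' @param models Named list of \code{library_model}s.
#' @return Log-likelihood (natural log).
#' @export
location_likelihood <- function(fragments, models) {
  if (!nrow(fragments)) return(0)
  missing <- setdiff(unique(fragments$library_id), names(models))
  if (length(missing)) {
    stop("no library model for: ", paste(missing, collapse = ", "))
  }
  total <- 0
  for (lib in unique(fragments$library_id)) {
    f <- fragments[library_id == lib]
    total <- total +
      sum(log(model_prob(models[[lib]], f$size, f$oriented_properly)))
  }
  total
}

## merged-location 5' position/orientation for an arbitrary projected read
## in the context of a candidate: moved-contig reads go through the
## alignment path; for DOCs, reads at or beyond the junction shift left by
## delta; everything else is fixed.
merged_position <- function(cand, read_ids, layout, proj, placements) {
  p <- proj[match(read_ids, read_id)]
  out <- data.table::data.table(read_id = read_ids, pos5 = p$pos5,
                                chrom_orient = p$chrom_orient)
  in_moved <- p$contig_id == cand$moved_contig_id
  if (any(in_moved)) {
    rows <- layout[match(read_ids[in_moved], read_id)]
    mp <- project_merged(cand, rows, placements)
    out[in_moved, `:=`(pos5 = mp$pos5, chrom_orient = mp$chrom_orient)]
  }
  if (cand$kind == "DOC") {
    shift <- !in_moved & p$placed & p$chrom == cand$chrom &
      p$pos5 >= cand$junction
    out[shift, pos5 := pos5 - cand$delta]
  }
  out
}

#' Evaluate one candidate and call the verdict
#'
#' Computes the placement likelihood of the candidate's relevant mate pairs
#' at the original location and at the merged location implied by the
#' alignment.  The verdict is \code{mis_assembled} iff the merged-location
#' likelihood is strictly greater; ties and candidates without relevant
#' pairs are \code{kept}.
#'
#' @param cand A \code{dup_candidate}.
#' @param layout Read layout.
#' @param placements Contig placements.
#' @param models Library models.
#' @param proj Optional precomputed projection table.
#' @return One-row data.table: ids, kind, n_relevant, loglik_original,
#'   loglik_merged, verdict, flag.
#' @export
classify_candidate <- function(cand, layout, placements, models,
                               proj = NULL) {
  if (is.null(proj)) proj <- project_reads(layout, placements)
  rel <- if (cand$kind == "DCC") {
    relevant_reads_dcc(cand$moved_contig_id, layout)
  } else {
    relevant_reads_doc(cand, layout, proj)
  }
  ## one row per pair
  if (nrow(rel)) {
    key <- ifelse(rel$read_id < rel$mate_id,
                  paste(rel$read_id, rel$mate_id),
                  paste(rel$mate_id, rel$read_id))
    rel <- rel[!duplicated(key)]
    ## exclude pairs touching contigs removed by the merge (intervening
    ## mis-assembled DCCs of a DOC join)
    if (length(cand$removed_contigs)) {
      mate_contig <- layout$contig_id[match(rel$mate_id, layout$read_id)]
      rel <- rel[!(mate_contig %in% cand$removed_contigs)]
    }
    ## exclude pairs whose mate is unplaced
    mate_placed <- proj$placed[match(rel$mate_id, proj$read_id)]
    rel <- rel[mate_placed %in% TRUE]
  }
  n_rel <- nrow(rel)
  if (n_rel == 0L) {
    return(data.table::data.table(
      moved_contig_id = cand$moved_contig_id,
      anchor_contig_id = cand$anchor_contig_id, kind = cand$kind,
      n_relevant = 0L, loglik_original = NA_real_, loglik_merged = NA_real_,
      verdict = "kept", flag = "no_evidence",
      chrom = cand$chrom, span_start = cand$span_start,
      span_end = cand$span_end,
      overlap_len = if (cand$kind == "DOC") cand$hit$length else NA_integer_))
  }
  p_r <- proj[match(rel$read_id, proj$read_id)]
  p_m <- proj[match(rel$mate_id, proj$read_id)]
  same_chrom <- !is.na(p_m$chrom) & p_r$chrom == p_m$chrom
  orig <- implied_fragment(p_r$pos5, p_r$chrom_orient,
                           p_m$pos5, p_m$chrom_orient)
  orig[!same_chrom, `:=`(size = 0, oriented_properly = FALSE)]
  m_r <- merged_position(cand, rel$read_id, layout, proj, placements)
  m_m <- merged_position(cand, rel$mate_id, layout, proj, placements)
  merg <- implied_fragment(m_r$pos5, m_r$chrom_orient,
                           m_m$pos5, m_m$chrom_orient)
  merg[!same_chrom, `:=`(size = 0, oriented_properly = FALSE)]
  orig[, library_id := rel$library_id]
  merg[, library_id := rel$library_id]
  ll_o <- location_likelihood(orig, models)
  ll_m <- location_likelihood(merg, models)
  data.table::data.table(
    moved_contig_id = cand$moved_contig_id,
    anchor_contig_id = cand$anchor_contig_id, kind = cand$kind,
    n_relevant = n_rel, loglik_original = ll_o, loglik_merged = ll_m,
    verdict = if (ll_m > ll_o) "mis_assembled" else "kept",
    flag = NA_character_,
    chrom = cand$chrom, span_start = cand$span_start,
    span_end = cand$span_end,
    overlap_len = if (cand$kind == "DOC") cand$hit$length else NA_integer_)
}

#' Evaluate a candidate list and resolve multi-anchor ties
#'
#' Each candidate is evaluated independently; when a moved contig has
#' several anchors whose merged location wins, only the relocation with the
#' highest merged-location likelihood is accepted and the others are
#' demoted to \code{kept} with flag \code{lower_likelihood_anchor}.
#'
#' @param candidates Candidate list.
#' @param layout Read layout.
#' @param placements Contig placements.
#' @param models Library models.
#' @param verbose Log progress.
#' @return data.table of calls with a \code{cand_idx} column indexing
#'   \code{candidates}.
#' @export
classify_all <- function(candidates, layout, placements, models,
                         verbose = FALSE) {
  if (!length(candidates)) {
    return(data.table::data.table(
      moved_contig_id = character(), anchor_contig_id = character(),
      kind = character(), n_relevant = integer(),
      loglik_original = numeric(), loglik_merged = numeric(),
      verdict = character(), flag = character(), chrom = character(),
      span_start = integer(), span_end = integer(),
      overlap_len = integer(), cand_idx = integer()))
  }
  proj <- project_reads(layout, placements)
  calls <- data.table::rbindlist(lapply(seq_along(candidates), function(i) {
    r <- classify_candidate(candidates[[i]], layout, placements, models, proj)
    r[, cand_idx := i]
    r
  }))
  ## multi-anchor resolution
  mis <- calls[verdict == "mis_assembled"]
  if (nrow(mis)) {
    best <- mis[order(-loglik_merged), .SD[1L], by = moved_contig_id]
    demote <- setdiff(mis$cand_idx, best$cand_idx)
    calls[cand_idx %in% demote,
          `:=`(verdict = "kept", flag = "lower_likelihood_anchor")]
  }
  if (verbose) {
    message("likelihood: ", sum(calls$verdict == "mis_assembled"), " of ",
            nrow(calls), " candidates called mis-assembled")
  }
  calls
}
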