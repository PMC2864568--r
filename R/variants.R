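## variants: merge the reads of a confirmed false duplication, re-compute
## the column pileup of both haplotype contigs over the anchoring alignment,
## and emit the SNPs/indels the split haplotypes concealed.
## Read bases are taken from each contig's consensus at the read's interval
## (the layout carries intervals, not sequences), so a column's observation
## multiset is the contig base repeated once per covering read.

## per-position read-coverage vector over a contig's oriented frame
coverage_vector <- function(o_start, o_end, L) {
  d <- integer(L + 1L)
  if (length(o_start)) {
    add <- tabulate(o_start + 1L, nbins = L + 1L)
    rem <- tabulate(o_end + 1L, nbins = L + 1L)
    d <- add - rem
  }
  cumsum(d)[seq_len(L)]
}

## oriented-frame intervals of layout rows within a contig
oriented_intervals <- function(rows, L, orientation) {
  if (identical(orientation, "reverse")) {
    list(start = L - rows$end, end = L - rows$start)
  } else {
    list(start = rows$start, end = rows$end)
  }
}

#' Recompute the merged read pileup of a mis-assembly call
#'
#' Aligns the moved contig onto the anchor through the candidate's
#' alignment path and builds per-column pileups across the merged span:
#' each column carries the anchor-frame position, both contig bases (gap
#' for indel columns) and the number of reads from each contig covering it.
#'
#' @param cand The call's \code{dup_candidate}.
#' @param layout Read layout.
#' @param contigs Contig sequences (placed and, for unplaced calls, the
#'   moved contig).
#' @param placements Contig placements.
#' @return data.table: col, t_pos, q_pos, base_anchor, base_moved,
#'   depth_anchor, depth_moved (positions in the anchor/moved oriented
#'   frames; NA at gap columns).
#' @export
merge_and_realign <- function(cand, layout, contigs, placements) {
  hit <- cand$hit
  anchor_pl <- placements[contig_id == cand$anchor_contig_id]
  moved_pl <- placements[contig_id == cand$moved_contig_id]
  a_orient <- if (nrow(anchor_pl)) anchor_pl$orientation else "forward"
  m_orient <- if (nrow(moved_pl)) moved_pl$orientation else "forward"
  aseq <- oriented_seq(contigs, cand$anchor_contig_id, a_orient)
  mseq_fwd <- oriented_seq(contigs, cand$moved_contig_id, m_orient)
  Lm <- nchar(mseq_fwd)
  La <- nchar(aseq)
  ## aligned strings; linear (ingested) hits are re-extended here
  if (is.null(hit$aligned_query)) {
    qa <- if (hit$strand == "same") {
      substr(mseq_fwd, hit$q_start + 1L, hit$q_end)
    } else {
      revcomp(substr(mseq_fwd, hit$q_start + 1L, hit$q_end))
    }
    ta <- substr(aseq, hit$t_start + 1L, hit$t_end)
    aln <- Biostrings::pairwiseAlignment(
      qa, ta, type = "global", substitutionMatrix = fd_submat(),
      gapOpening = 5, gapExtension = 2)
    pa <- as.character(Biostrings::pattern(aln))
    sa <- as.character(Biostrings::subject(aln))
  } else {
    pa <- hit$aligned_query
    sa <- hit$aligned_target
  }
  pc <- strsplit(pa, "", fixed = TRUE)[[1L]]
  sc <- strsplit(sa, "", fixed = TRUE)[[1L]]
  ## alignment-frame query coordinates: ascend in the strand the alignment
  ## was computed on (reverse complement of the moved frame for opposite)
  aln_q_start <- if (hit$strand == "same") hit$q_start else Lm - hit$q_end
  qi <- cumsum(pc != "-")
  ti <- cumsum(sc != "-")
  q_pos_aln <- ifelse(pc != "-", aln_q_start + qi - 1L, NA_integer_)
  t_pos <- ifelse(sc != "-", hit$t_start + ti - 1L, NA_integer_)
  q_pos <- if (hit$strand == "same") q_pos_aln else (Lm - 1L) - q_pos_aln
  ## depth vectors; for opposite-strand hits work in the alignment frame
  m_rows <- layout[contig_id == cand$moved_contig_id]
  a_rows <- layout[contig_id == cand$anchor_contig_id]
  mi <- oriented_intervals(m_rows, Lm, m_orient)
  if (hit$strand == "opposite") {
    mi <- list(start = Lm - mi$end, end = Lm - mi$start)
  }
  ai <- oriented_intervals(a_rows, La, a_orient)
  cov_m <- coverage_vector(mi$start, mi$end, Lm)
  cov_a <- coverage_vector(ai$start, ai$end, La)
  at_q <- function(pos) ifelse(is.na(pos) | pos < 0L | pos >= Lm,
                               0L, cov_m[pos + 1L])
  at_t <- function(pos) ifelse(is.na(pos) | pos < 0L | pos >= La,
                               0L, cov_a[pos + 1L])
  ## gap columns take the spanning depth: min of the flanking positions
  fill_fwd <- function(x) { # last non-NA carried forward
    idx <- cumsum(!is.na(x))
    vals <- x[!is.na(x)]
    ifelse(idx == 0L, NA_integer_, vals[pmax(idx, 1L)])
  }
  q_prev <- fill_fwd(q_pos_aln)
  t_prev <- fill_fwd(t_pos)
  depth_m <- ifelse(!is.na(q_pos_aln), at_q(q_pos_aln),
                    pmin(at_q(q_prev), at_q(q_prev + 1L)))
  depth_a <- ifelse(!is.na(t_pos), at_t(t_pos),
                    pmin(at_t(t_prev), at_t(t_prev + 1L)))
  data.table::data.table(
    col = seq_along(pc),
    t_pos = as.integer(t_pos), q_pos = as.integer(q_pos),
    base_anchor = sc, base_moved = pc,
    depth_anchor = as.integer(depth_a), depth_moved = as.integer(depth_m))
}

#' Left-align and trim an indel against the anchor sequence
#'
#' @param seq Anchor (oriented) sequence.
#' @param pos 0-based position of the first REF base.
#' @param ref,alt Alleles.
#' @return list(pos, ref, alt), left-aligned with shared suffix removed.
#' @export
normalize_variant <- function(seq, pos, ref, alt) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        (nr > 1L || na > 1L)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 0L) { # cannot extend left of the sequence
          base <- substr(seq, pos + 1L, pos + 1L)
          ref <- paste0(ref, base); alt <- paste0(alt, base)
          break
        }
        pos <- pos - 1L
        base <- substr(seq, pos + 1L, pos + 1L)
        ref <- paste0(base, ref)
        alt <- paste0(base, alt)
      }
      next
    }
    break
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Call SNPs and indels from a merged pileup
#'
#' A column yields a SNP when the two contig bases disagree and each allele
#' is supported by at least \code{min_allele_depth} reads.  Runs of
#' consecutive gap-on-one-side columns merge into a single indel record,
#' left-aligned against the anchor sequence with a preceding anchor base
#' (VCF convention).
#'
#' @param pileup Pileup from [merge_and_realign()].
#' @param anchor_seq Anchor contig sequence in its oriented frame.
#' @param min_allele_depth Minimum reads per allele.
#' @return data.table of variant records with anchor-frame positions
#'   (\code{position}) and the pileup column span (\code{col_start},
#'   \code{col_end}) used by [quality_filter()].
#' @export
call_variants <- function(pileup, anchor_seq, min_allele_depth = 2L) {
  recs <- list()
  bases <- c("A", "C", "G", "T")
  snp <- pileup[base_anchor %in% bases & base_moved %in% bases &
                base_anchor != base_moved &
                depth_anchor >= min_allele_depth &
                depth_moved >= min_allele_depth]
  if (nrow(snp)) {
    recs[[length(recs) + 1L]] <- data.table::data.table(
      position = snp$t_pos, ref_allele = snp$base_anchor,
      alt_allele = snp$base_moved, var_type = "SNP",
      depth_ref = snp$depth_anchor, depth_alt = snp$depth_moved,
      col_start = snp$col, col_end = snp$col)
  }
  ## indel runs
  gap_side <- ifelse(pileup$base_anchor == "-", "ins",
                     ifelse(pileup$base_moved == "-", "del", "none"))
  r <- rle(gap_side)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values != "none")) {
    i1 <- starts[k]; i2 <- ends[k]
    side <- r$values[k]
    run <- pileup[i1:i2]
    d_m <- min(run$depth_moved)
    d_a <- min(run$depth_anchor)
    if (d_m < min_allele_depth || d_a < min_allele_depth) next
    if (side == "ins") {
      ## anchor gap: bases present only in the moved contig
      t_prev <- pileup[seq_len(i1 - 1L)][!is.na(t_pos)][.N, t_pos]
      if (!length(t_prev) || is.na(t_prev)) next
      ref <- substr(anchor_seq, t_prev + 1L, t_prev + 1L)
      alt <- paste0(ref, paste(run$base_moved, collapse = ""))
      pos <- t_prev
    } else {
      ## moved gap: anchor bases absent from the moved contig
      t1 <- run$t_pos[1L]; t2 <- run$t_pos[nrow(run)]
      if (t1 == 0L) next  # no preceding anchor base
      pos <- t1 - 1L
      ref <- substr(anchor_seq, pos + 1L, t2 + 1L)
      alt <- substr(anchor_seq, pos + 1L, pos + 1L)
    }
    nv <- normalize_variant(anchor_seq, pos, ref, alt)
    recs[[length(recs) + 1L]] <- data.table::data.table(
      position = nv$pos, ref_allele = nv$ref, alt_allele = nv$alt,
      var_type = "indel", depth_ref = d_a, depth_alt = d_m,
      col_start = i1, col_end = i2)
  }
  if (!length(recs)) {
    return(data.table::data.table(
      position = integer(), ref_allele = character(),
      alt_allele = character(), var_type = character(),
      depth_ref = integer(), depth_alt = integer(),
      col_start = integer(), col_end = integer()))
  }
  out <- data.table::rbindlist(recs)
  data.table::setorder(out, position)
  out
}

#' Filter variants by neighborhood quality
#'
#' A variant is kept only when no other discordant pileup column (any
#' column where the two contigs disagree, including sub-threshold ones)
#' lies within \code{flank} bp of it on the anchor.  Because pileup
#' observations derive from each contig's consensus, unanimity of the
#' flanking columns reduces to their concordance.
#'
#' @param variants Output of [call_variants()].
#' @param pileup The matching pileup.
#' @param flank Flank width, bp.
#' @return Filtered variant table.
#' @export
quality_filter <- function(variants, pileup, flank = 5L) {
  if (!nrow(variants)) return(variants)
  ## anchor position per column, gap columns taking the nearest non-gap
  ## position at or before them
  tp <- pileup$t_pos
  nn <- which(!is.na(tp))
  filled <- if (length(nn)) tp[nn][pmax(cumsum(!is.na(tp)), 1L)] else tp
  disc <- which(pileup$base_anchor != pileup$base_moved)
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i]
    vt1 <- filled[v$col_start]
    vt2 <- filled[v$col_end]
    other <- disc[disc < v$col_start | disc > v$col_end]
    if (!length(other)) { keep[i] <- TRUE; next }
    ot <- filled[other]
    dist <- pmin(abs(ot - vt1), abs(ot - vt2))
    keep[i] <- all(dist > flank, na.rm = TRUE)
  }
  variants[keep]
}

#' Filter variants by the coverage check
#'
#' Variants are retained only for calls whose A-statistic indicates a
#' single-copy region (A > 0), filtering out mis-assembled repetitive
#' sequence.
#'
#' @param variants Combined variant table with a \code{call_id} column.
#' @param calls Call table with \code{call_id} and \code{a_stat}.
#' @return Filtered variant table.
#' @export
coverage_filter <- function(variants, calls) {
  if (!nrow(variants)) return(variants)
  ok <- calls[!is.na(a_stat) & a_stat > 0, call_id]
  variants[call_id %in% ok]
}

#' Call variants for all confirmed mis-assemblies
#'
#' Runs [merge_and_realign()], [call_variants()] and [quality_filter()] per
#' mis-assembled call, converts positions to chromosome coordinates via the
#' anchor placement, and applies [coverage_filter()].
#'
#' @param calls Call table (with \code{a_stat} attached).
#' @param candidates Candidate list indexed by \code{calls$cand_idx}.
#' @param layout Read layout.
#' @param contigs Contig sequences.
#' @param placements Contig placements.
#' @param min_allele_depth,flank Calling/filter parameters.
#' @param apply_coverage_filter Apply the A > 0 filter (default TRUE).
#' @return data.table: chrom, position (0-based), ref_allele, alt_allele,
#'   var_type, depth_ref, depth_alt, call_id, moved_contig_id,
#'   anchor_contig_id.
#' @export
call_variants_all <- function(calls, candidates, layout, contigs, placements,
                              min_allele_depth = 2L, flank = 5L,
                              apply_coverage_filter = TRUE) {
  mis <- which(calls$verdict == "mis_assembled")
  out <- list()
  for (i in mis) {
    cand <- candidates[[calls$cand_idx[i]]]
    anchor_pl <- placements[contig_id == cand$anchor_contig_id]
    aseq <- oriented_seq(contigs, cand$anchor_contig_id,
                         if (nrow(anchor_pl)) anchor_pl$orientation
                         else "forward")
    pileup <- merge_and_realign(cand, layout, contigs, placements)
    v <- call_variants(pileup, aseq, min_allele_depth)
    v <- quality_filter(v, pileup, flank)
    if (!nrow(v)) next
    v[, `:=`(col_start = NULL, col_end = NULL)]
    v[, `:=`(chrom = cand$chrom,
             position = position + (if (nrow(anchor_pl)) anchor_pl$start
                                    else 0L),
             call_id = i,
             moved_contig_id = cand$moved_contig_id,
             anchor_contig_id = cand$anchor_contig_id)]
    out[[length(out) + 1L]] <- v
  }
  variants <- if (length(out)) data.table::rbindlist(out) else {
    data.table::data.table(
      position = integer(), ref_allele = character(),
      alt_allele = character(), var_type = character(),
      depth_ref = integer(), depth_alt = integer(), chrom = character(),
      call_id = integer(), moved_contig_id = character(),
      anchor_contig_id = character())
  }
  if (apply_coverage_filter && nrow(variants)) {
    calls2 <- data.table::copy(calls)[, call_id := .I]
    variants <- coverage_filter(variants, calls2)
  }
  data.table::setcolorder(
    variants, intersect(c("chrom", "position", "ref_allele", "alt_allele",
                          "var_type", "depth_ref", "depth_alt", "call_id",
                          "moved_contig_id", "anchor_contig_id"),
                        names(variants)))
  variants[]
}
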