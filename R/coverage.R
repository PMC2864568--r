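## coverage: the A-statistic, a Poisson read-arrival log-odds of single-copy
## versus two-copy sequence over the alignment span of a duplication call.

#' The A-statistic
#'
#' Log likelihood ratio of observing \code{k} read arrivals in a span of
#' length \code{L} under a Poisson arrival process at the genome-average
#' rate rho = R/G (single copy) versus rate 2 rho (duplicated):
#' \deqn{A = L R / G - k \ln 2.}
#' Positive values favor single copy.
#'
#' @param total_reads Total placed reads R.
#' @param genome_length Total placed sequence length G (bp).
#' @param span_length Span length L (bp).
#' @param span_read_count Reads whose 5' ends fall in the span, counting
#'   reads from both contigs of the duplication, k.
#' @return The A-statistic (natural log units).
#' @export
a_statistic <- function(total_reads, genome_length, span_length,
                        span_read_count) {
  if (genome_length <= 0) stop("genome_length must be positive")
  stopifnot(total_reads > 0, span_length > 0, span_read_count >= 0)
  span_length * total_reads / genome_length - span_read_count * log(2)
}

#' Annotate calls with the A-statistic
#'
#' For each call the span is the chromosomal extent of the anchoring
#' alignment; reads are counted from both contigs: anchor-contig reads whose
#' 5' end lies in the span plus moved-contig reads whose merged-location 5'
#' end lies in the span.  Counting by 5'-end containment avoids
#' double-counting straddlers.
#'
#' @param calls Call table from [classify_all()].
#' @param candidates The candidate list matching \code{calls} rows.
#' @param layout Read layout.
#' @param placements Contig placements.
#' @return \code{calls} with columns \code{a_stat} and \code{single_copy}
#'   added.
#' @export
attach_coverage <- function(calls, candidates, layout, placements) {
  proj <- project_reads(layout, placements)
  placed <- proj[placed == TRUE]
  R <- nrow(placed)
  G <- sum(placements$end - placements$start)
  calls[, `:=`(a_stat = NA_real_, single_copy = NA)]
  for (i in seq_len(nrow(calls))) {
    cand <- candidates[[calls$cand_idx[i]]]
    span <- c(calls$span_start[i], calls$span_end[i])
    anchor_in <- placed[contig_id == cand$anchor_contig_id &
                        pos5 >= span[1] & pos5 < span[2], .N]
    moved_rows <- layout[contig_id == cand$moved_contig_id]
    k_moved <- 0L
    if (nrow(moved_rows)) {
      mp <- project_merged(cand, moved_rows, placements)
      k_moved <- sum(mp$pos5 >= span[1] & mp$pos5 < span[2])
    }
    a <- a_statistic(R, G, span[2] - span[1], anchor_in + k_moved)
    data.table::set(calls, i, "a_stat", a)
    data.table::set(calls, i, "single_copy", a > 0)
  }
  calls[]
}
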