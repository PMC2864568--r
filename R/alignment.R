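## Internal seed-and-extend pairwise aligner.
## Exact k-mer seeds (2-bit packed, rolling code) locate candidate regions;
## Biostrings::pairwiseAlignment performs the local extension inside a
## windowed sub-problem, which keeps the dynamic program small.  Sufficient
## for assembly-scale fixtures; real-genome users can ingest external
## aligner output with ingest_alignments().

## numeric rolling codes for all k-mers of a sequence; non-ACGT -> sentinel
kmer_codes <- function(seq, k = 15L, sentinel = -1) {
  n <- nchar(seq)
  if (n < k) return(numeric(0))
  v <- utf8ToInt(seq)
  x <- rep(NA_real_, n)
  x[v == 65L] <- 0  # A
  x[v == 67L] <- 1  # C
  x[v == 71L] <- 2  # G
  x[v == 84L] <- 3  # T
  m <- n - k + 1L
  out <- numeric(m)
  for (i in 0:(k - 1L)) out <- out * 4 + x[(1L + i):(m + i)]
  out[is.na(out)] <- sentinel
  out
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## cluster seed matches by diagonal, returning candidate windows
seed_clusters <- function(qpos, tpos, k, diag_gap = 100L, min_seeds = 2L) {
  if (!length(qpos)) return(list())
  d <- qpos - tpos
  o <- order(d, qpos)
  d <- d[o]; qp <- qpos[o]; tp <- tpos[o]
  brk <- c(0L, which(diff(d) > diag_gap), length(d))
  out <- list()
  for (i in seq_len(length(brk) - 1L)) {
    idx <- (brk[i] + 1L):brk[i + 1L]
    if (length(idx) < min_seeds) next
    out[[length(out) + 1L]] <- list(
      q_lo = min(qp[idx]), q_hi = max(qp[idx]) + k - 1L,
      t_lo = min(tp[idx]), t_hi = max(tp[idx]) + k - 1L,
      n_seeds = length(idx))
  }
  ## merge clusters whose windows overlap on both axes
  if (length(out) > 1L) {
    merged <- TRUE
    while (merged) {
      merged <- FALSE
      for (i in seq_along(out)) {
        for (j in seq_along(out)) {
          if (j <= i || i > length(out) || j > length(out)) next
          a <- out[[i]]; b <- out[[j]]
          if (a$q_lo <= b$q_hi + 200L && b$q_lo <= a$q_hi + 200L &&
              a$t_lo <= b$t_hi + 200L && b$t_lo <= a$t_hi + 200L) {
            out[[i]] <- list(q_lo = min(a$q_lo, b$q_lo),
                             q_hi = max(a$q_hi, b$q_hi),
                             t_lo = min(a$t_lo, b$t_lo),
                             t_hi = max(a$t_hi, b$t_hi),
                             n_seeds = a$n_seeds + b$n_seeds)
            out[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
  }
  out
}

fd_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3,
                                                     baseOnly = TRUE)
    }
    m
  }
})

## build an alignment_hit from aligned strings (no gaps at either end)
## q_start/t_start: absolute 0-based starts of the aligned region
build_hit <- function(query_id, target_id, pa, sa, q_start, t_start,
                      strand = "same", q_len = NA_integer_) {
  pc <- strsplit(pa, "", fixed = TRUE)[[1L]]
  sc <- strsplit(sa, "", fixed = TRUE)[[1L]]
  qi <- cumsum(pc != "-")
  ti <- cumsum(sc != "-")
  matches <- sum(pc == sc & pc != "-")
  n_q <- qi[length(qi)]
  n_t <- ti[length(ti)]
  ## map each query offset (1..n_q) to a target coordinate
  qcols <- which(pc != "-")
  map_qt <- t_start + pmax(ti[qcols] - 1L, 0L)
  tcols <- which(sc != "-")
  map_tq <- q_start + pmax(qi[tcols] - 1L, 0L)
  hit <- list(query_id = query_id, target_id = target_id,
              q_start = q_start, q_end = q_start + n_q,
              t_start = t_start, t_end = t_start + n_t,
              strand = strand,
              identity = matches / length(pc),
              length = n_q,
              n_cols = length(pc),
              map_qt = as.integer(map_qt),
              map_tq = as.integer(map_tq),
              aligned_query = pa, aligned_target = sa)
  class(hit) <- "alignment_hit"
  hit
}

## flip query coordinates of an opposite-strand hit computed on revcomp(query)
## back into forward-query coordinates. n = length of the original query.
flip_hit_query <- function(hit, n) {
  q_start <- n - hit$q_end
  q_end <- n - hit$q_start
  hit$map_qt <- rev(hit$map_qt)
  hit$map_tq <- (n - 1L) - hit$map_tq
  hit$q_start <- q_start
  hit$q_end <- q_end
  hit$strand <- "opposite"
  hit
}

#' Align two sequences with the internal seed-and-extend aligner
#'
#' Finds local alignments between \code{seq_a} (query) and \code{seq_b}
#' (target) on both strands.  Guaranteed (by construction of the seeding) to
#' find any shared region of at least \code{min_len} bp at >= 95\% identity
#' in synthetic fixtures.  Query coordinates are always reported on the
#' forward strand of the query.
#'
#' @param seq_a,seq_b Uppercase DNA strings.
#' @param query_id,target_id Identifiers recorded in the hits.
#' @param k Seed k-mer size.
#' @param min_len Minimum alignment length to report.
#' @param both_strands Search the reverse complement of the query too.
#' @return List of \code{alignment_hit} objects (possibly empty), each with
#'   fields query_id, target_id, q_start, q_end, t_start, t_end, strand
#'   (\code{same}/\code{opposite}), identity (matches / alignment columns),
#'   length, and gapped coordinate maps.
#' @export
align_pair <- function(seq_a, seq_b, query_id = "query", target_id = "target",
                       k = 15L, min_len = 100L, both_strands = TRUE) {
  stopifnot(nchar(seq_a) > 0L, nchar(seq_b) > 0L)
  cb <- kmer_codes(seq_b, k, sentinel = -2)
  hits <- list()
  strands <- if (both_strands) c("same", "opposite") else "same"
  for (strand in strands) {
    ## a direct-strand hit makes an additional inverted search redundant for
    ## the duplication geometries considered here
    if (strand == "opposite" && length(hits)) break
    qs <- if (strand == "same") seq_a else revcomp(seq_a)
    ca <- kmer_codes(qs, k, sentinel = -1)
    if (!length(ca) || !length(cb)) next
    mm <- match(ca, cb)
    sel <- !is.na(mm)
    if (!any(sel)) next
    cl <- seed_clusters(which(sel), mm[sel], k)
    for (win in cl) {
      margin <- 400L
      q_lo <- max(1L, win$q_lo - margin); q_hi <- min(nchar(qs), win$q_hi + margin)
      t_lo <- max(1L, win$t_lo - margin); t_hi <- min(nchar(seq_b), win$t_hi + margin)
      aln <- Biostrings::pairwiseAlignment(
        substr(qs, q_lo, q_hi), substr(seq_b, t_lo, t_hi),
        type = "local", substitutionMatrix = fd_submat(),
        gapOpening = 5, gapExtension = 2)
      pv <- Biostrings::pattern(aln)
      sv <- Biostrings::subject(aln)
      pa <- as.character(pv)
      sa <- as.character(sv)
      if (nchar(pa) == 0L) next
      hit <- build_hit(query_id, target_id, pa, sa,
                       q_start = (q_lo - 1L) + (BiocGenerics::start(pv) - 1L),
                       t_start = (t_lo - 1L) + (BiocGenerics::start(sv) - 1L),
                       strand = "same")
      if (strand == "opposite") hit <- flip_hit_query(hit, nchar(seq_a))
      if (hit$length >= min_len) hits[[length(hits) + 1L]] <- hit
    }
  }
  ## deduplicate near-identical hits from the two strand searches
  if (length(hits) > 1L) {
    key <- vapply(hits, function(h) paste(h$q_start, h$q_end, h$t_start,
                                          h$t_end, h$strand), "")
    hits <- hits[!duplicated(key)]
  }
  hits
}

#' Project query positions through an alignment hit
#'
#' Maps absolute (0-based) query coordinates to target coordinates through
#' the hit's gapped alignment path; positions outside the aligned interval
#' are extrapolated linearly.
#'
#' @param hit An \code{alignment_hit}.
#' @param qpos Integer vector of query positions.
#' @return Integer vector of target positions.
#' @export
map_through_hit <- function(hit, qpos) {
  inside <- qpos >= hit$q_start & qpos < hit$q_end
  out <- integer(length(qpos))
  out[inside] <- hit$map_qt[qpos[inside] - hit$q_start + 1L]
  if (hit$strand == "same") {
    lo <- qpos < hit$q_start
    hi <- qpos >= hit$q_end
    out[lo] <- hit$map_qt[1L] - (hit$q_start - qpos[lo])
    out[hi] <- hit$map_qt[length(hit$map_qt)] + (qpos[hi] - (hit$q_end - 1L))
  } else {
    lo <- qpos < hit$q_start
    hi <- qpos >= hit$q_end
    out[lo] <- hit$map_qt[1L] + (hit$q_start - qpos[lo])
    out[hi] <- hit$map_qt[length(hit$map_qt)] - (qpos[hi] - (hit$q_end - 1L))
  }
  out
}

## swap query and target of a hit
invert_hit <- function(hit) {
  structure(list(query_id = hit$target_id, target_id = hit$query_id,
                 q_start = hit$t_start, q_end = hit$t_end,
                 t_start = hit$q_start, t_end = hit$q_end,
                 strand = hit$strand, identity = hit$identity,
                 length = hit$t_end - hit$t_start, n_cols = hit$n_cols,
                 map_qt = hit$map_tq, map_tq = hit$map_qt,
                 aligned_query = hit$aligned_target,
                 aligned_target = hit$aligned_query),
            class = "alignment_hit")
}

#' Ingest alignments from an external aligner
#'
#' Accepts minimal PAF (\code{format = "paf"}) or MUMmer
#' \code{show-coords -T} style TSV (\code{format = "coords"}: S1 E1 S2 E2
#' LEN1 LEN2 \%IDY REF QRY, 1-based inclusive, reference first).  Coordinate
#' maps are linear interpolations of the reported interval, which keeps the
#' semantics identical to [align_pair()] output at up to a few bp of offset
#' error inside gapped regions.
#'
#' @param path Path to the alignment file.
#' @param format \code{"paf"} or \code{"coords"}.
#' @return List of \code{alignment_hit} objects.
#' @export
ingest_alignments <- function(path, format = c("paf", "coords")) {
  format <- match.arg(format)
  if (format == "paf") {
    dt <- fd_read_tsv(path, c("qname", "qlen", "qstart", "qend", "strand",
                              "tname", "tlen", "tstart", "tend", "nmatch",
                              "alnlen", "mapq"))
    hits <- lapply(seq_len(nrow(dt)), function(i) {
      r <- dt[i]
      linear_hit(r$qname, r$tname, as.integer(r$qstart), as.integer(r$qend),
                 as.integer(r$tstart), as.integer(r$tend),
                 strand = if (r$strand == "-") "opposite" else "same",
                 identity = as.numeric(r$nmatch) / as.numeric(r$alnlen))
    })
  } else {
    dt <- fd_read_tsv(path, c("s1", "e1", "s2", "e2", "len1", "len2",
                              "idy", "ref", "qry"))
    hits <- lapply(seq_len(nrow(dt)), function(i) {
      r <- dt[i]
      s2 <- as.integer(r$s2); e2 <- as.integer(r$e2)
      opp <- s2 > e2
      if (opp) { tmp <- s2; s2 <- e2; e2 <- tmp }
      linear_hit(r$qry, r$ref, s2 - 1L, e2, as.integer(r$s1) - 1L,
                 as.integer(r$e1),
                 strand = if (opp) "opposite" else "same",
                 identity = as.numeric(r$idy) / 100)
    })
  }
  hits
}

## hit with linearly interpolated coordinate maps (no gapped path available)
linear_hit <- function(query_id, target_id, q_start, q_end, t_start, t_end,
                       strand = "same", identity = NA_real_) {
  nq <- q_end - q_start
  nt <- t_end - t_start
  tq_seq <- if (strand == "same") {
    as.integer(round(seq(t_start, t_end - 1L, length.out = nq)))
  } else {
    as.integer(round(seq(t_end - 1L, t_start, length.out = nq)))
  }
  qt_seq <- if (strand == "same") {
    as.integer(round(seq(q_start, q_end - 1L, length.out = nt)))
  } else {
    as.integer(round(seq(q_end - 1L, q_start, length.out = nt)))
  }
  structure(list(query_id = query_id, target_id = target_id,
                 q_start = q_start, q_end = q_end,
                 t_start = t_start, t_end = t_end,
                 strand = strand, identity = identity,
                 length = nq, n_cols = max(nq, nt),
                 map_qt = tq_seq, map_tq = qt_seq,
                 aligned_query = NULL, aligned_target = NULL),
            class = "alignment_hit")
}
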