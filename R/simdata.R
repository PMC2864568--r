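## simdata: generate fully labeled synthetic assemblies exhibiting the
## haplotype mis-assembly patterns the pipeline detects.
##
## The generative picture: a haploid reference with localized heterozygous
## tracts mutated on the second haplotype.  An "assembler" that separated
## the haplotypes emits, per tract, either
##   DCC:  the host contig carries haplotype 1 across the whole region and a
##         short extra contig carries haplotype 2's tract (with one read
##         length of homozygous overhang on each side, as real haplotype
##         contigs break roughly a read length beyond the divergence),
##         placed right after the host with a gap;
##   DOC:  a left contig ending with haplotype 1's copy of the tract (plus
##         overhang) and a right contig beginning with haplotype 2's copy,
##         placed adjacently -- the tract appears twice;
##   unplaced variant: like a DCC but the haplotype-2 contig is left off
##         the chromosome.
## True duplications are planted as two diverged copies in the reference
## itself, the second copy assembled as its own contig whose mates anchor
## it at its true location.  Paired reads are drawn from both haplotypes
## with normal fragment sizes per library; reads are partitioned totally by
## haplotype inside mis-assembled regions and dropped when they straddle a
## contig boundary (their mate is kept, unmated).

#' Default simulation configuration
#'
#' Sanger-era defaults: 700 bp reads, a 4 kb +/- 400 and a 10 kb +/- 1 kb
#' library totalling 7x coverage, heterozygous tracts of 1-2 kb at 1\% SNP
#' and 0.1\% indel divergence (alignment identity around 98-99\%, matching
#' the range reported for real false duplications).
#'
#' @param seed Mandatory integer seed; every random draw flows from it.
#' @param genome_length Haploid genome length, bp.
#' @param n_het_tracts Number of heterozygous tracts (split among patterns
#'   by \code{misassembly_mix}).
#' @param het_tract_length Range (min, max) of tract lengths, bp.
#' @param snp_rate,indel_rate Per-bp mutation rates inside het tracts.
#' @param libraries List of library specs: library_id, mean, sd,
#'   read_length, coverage.
#' @param true_dup_count Number of planted true segmental duplications.
#' @param misassembly_mix Named fractions (dcc, doc, unplaced) of
#'   \code{n_het_tracts}.
#' @param dup_length Range of true-duplication copy lengths, bp.
#' @param dup_offset Range of distances between the two true copies, bp.
#' @param dup_divergence Per-bp substitution rate between true copies.
#' @param flank_range Range of homozygous spacing between planted features.
#' @param gap_len AGP gap length between consecutive contigs, bp.
#' @param overhang Homozygous overhang carried by haplotype contigs, bp.
#' @param rev_fraction Fraction of DCC haplotype contigs placed on the
#'   minus strand.
#' @param n_clean_unplaced Unrelated unplaced contigs (negatives).
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed,
                       genome_length = 5e6,
                       n_het_tracts = 220L,
                       het_tract_length = c(1000L, 2000L),
                       snp_rate = 0.01,
                       indel_rate = 0.001,
                       libraries = list(
                         list(library_id = "lib4k", mean = 4000, sd = 400,
                              read_length = 700L, coverage = 4),
                         list(library_id = "lib10k", mean = 10000, sd = 1000,
                              read_length = 700L, coverage = 3)),
                       true_dup_count = 200L,
                       misassembly_mix = c(dcc = 5 / 11, doc = 5 / 11,
                                           unplaced = 1 / 11),
                       dup_length = c(1500L, 2500L),
                       dup_offset = c(2000L, 8000L),
                       dup_divergence = 0.01,
                       flank_range = c(3500L, 6500L),
                       gap_len = 100L,
                       overhang = 700L,
                       rev_fraction = 0.25,
                       n_clean_unplaced = 5L) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(snp_rate >= 0, snp_rate <= 0.05, indel_rate >= 0,
            indel_rate <= 0.05, all(vapply(libraries, `[[`, 1, "coverage") > 0))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## point-mutate a sequence at the given per-bp rate (substitutions only)
mutate_snps <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

## mutate a het tract onto haplotype 2: SNPs plus 1-3 bp indels.
## Returns the hap2 sequence, a monotone map from each 1-based ref index to
## the 0-based hap2 offset of that base (or of the position it would occupy
## if deleted), and the planted variants in 0-based tract coordinates.
mutate_tract <- function(seq, snp_rate, indel_rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  bases <- c("A", "C", "G", "T")
  u1 <- stats::runif(L); u2 <- stats::runif(L)
  is_snp <- u1 < snp_rate
  is_ind <- !is_snp & u2 < indel_rate
  is_ind[c(1L, seq.int(max(1L, L - 4L), L))] <- FALSE
  ev <- which(is_snp | is_ind)
  pieces <- character(0)
  map <- integer(L)
  vars <- list()
  cur <- 1L; out_len <- 0L
  for (i in ev) {
    if (i < cur) next
    if (i > cur) {
      pieces <- c(pieces, substr(seq, cur, i - 1L))
      map[cur:(i - 1L)] <- out_len + 0L:(i - 1L - cur)
      out_len <- out_len + (i - cur)
    }
    if (is_snp[i]) {
      alt <- sample(setdiff(bases, ch[i]), 1L)
      pieces <- c(pieces, alt)
      map[i] <- out_len
      out_len <- out_len + 1L
      cur <- i + 1L
      vars[[length(vars) + 1L]] <- list(type = "SNP", pos0 = i - 1L,
                                        ref = ch[i], alt = alt)
    } else if (stats::runif(1L) < 0.5) {
      k <- sample(1:3, 1L)
      k <- min(k, L - i - 1L)
      map[i:(i + k - 1L)] <- out_len
      cur <- i + k
      vars[[length(vars) + 1L]] <- list(
        type = "del", pos0 = i - 2L,
        ref = paste(ch[(i - 1L):(i + k - 1L)], collapse = ""),
        alt = ch[i - 1L])
    } else {
      k <- sample(1:3, 1L)
      ins <- paste(sample(bases, k, replace = TRUE), collapse = "")
      pieces <- c(pieces, ins)
      out_len <- out_len + k
      cur <- i  # ref base i not consumed; copied by the next segment
      vars[[length(vars) + 1L]] <- list(
        type = "ins", pos0 = i - 2L, ref = ch[i - 1L],
        alt = paste0(ch[i - 1L], ins))
      ## avoid re-processing event i
      is_snp[i] <- FALSE
    }
  }
  if (cur <= L) {
    pieces <- c(pieces, substr(seq, cur, L))
    map[cur:L] <- out_len + 0L:(L - cur)
    out_len <- out_len + (L - cur + 1L)
  }
  list(seq = paste(pieces, collapse = ""), map = map,
       hap2_len = out_len, variants = vars)
}

#' Simulate a labeled synthetic assembly
#'
#' Deterministic given \code{config$seed}.  See the package vignette for
#' the generative model.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, the bundle is written
#'   as contigs.fasta, assembly.agp, layout.tsv, libraries.tsv,
#'   truth_features.tsv, truth_variants.tsv and truth.json.
#' @return List: contigs (named character vector, placed + unplaced), agp
#'   (\code{"agp"} object), layout (data.table), libraries (data.table),
#'   truth (list: features, variants data.tables), config.
#' @export
simulate_assembly <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- as.integer(config$genome_length)
  ov <- as.integer(config$overhang)
  mix <- config$misassembly_mix
  n_dcc <- round(config$n_het_tracts * mix[["dcc"]])
  n_doc <- round(config$n_het_tracts * mix[["doc"]])
  n_unp <- config$n_het_tracts - n_dcc - n_doc

  ## ---- plant feature coordinates along the reference ----
  types <- sample(c(rep("dcc", n_dcc), rep("doc", n_doc),
                    rep("unplaced", n_unp),
                    rep("dup", config$true_dup_count)))
  nf <- length(types)
  feat <- data.table::data.table(
    feature_id = sprintf("feat%04d", seq_len(nf)), type = types,
    tract_start = NA_integer_, tract_end = NA_integer_,
    dup_start2 = NA_integer_, dup_end2 = NA_integer_)
  cursor <- 0L
  for (i in seq_len(nf)) {
    flank <- sample(config$flank_range[1L]:config$flank_range[2L], 1L)
    fs <- cursor + flank
    if (types[i] == "dup") {
      D <- sample(config$dup_length[1L]:config$dup_length[2L], 1L)
      off <- sample(config$dup_offset[1L]:config$dup_offset[2L], 1L)
      data.table::set(feat, i, "tract_start", fs)
      data.table::set(feat, i, "tract_end", fs + D)
      data.table::set(feat, i, "dup_start2", fs + D + off)
      data.table::set(feat, i, "dup_end2", fs + D + off + D)
      cursor <- fs + D + off + D
    } else {
      TL <- sample(config$het_tract_length[1L]:config$het_tract_length[2L], 1L)
      data.table::set(feat, i, "tract_start", fs)
      data.table::set(feat, i, "tract_end", fs + TL)
      cursor <- fs + TL
    }
  }
  if (cursor + config$flank_range[2L] > G) {
    stop("config implies overlapping planted features: need ",
         cursor + config$flank_range[2L], " bp, have ", G)
  }

  ## ---- reference sequence; write true-duplication second copies ----
  ref <- rand_dna(G)
  for (i in which(feat$type == "dup")) {
    copy <- substr(ref, feat$tract_start[i] + 1L, feat$tract_end[i])
    copy2 <- mutate_snps(copy, config$dup_divergence)
    ref <- paste0(substr(ref, 1L, feat$dup_start2[i]), copy2,
                  substr(ref, feat$dup_end2[i] + 1L, G))
  }

  ## ---- haplotype-2 tracts ----
  het_idx <- which(feat$type %in% c("dcc", "doc", "unplaced"))
  tracts <- vector("list", nf)
  for (i in het_idx) {
    tr <- substr(ref, feat$tract_start[i] + 1L, feat$tract_end[i])
    tracts[[i]] <- mutate_tract(tr, config$snp_rate, config$indel_rate)
  }

  ## ---- contig tiling ----
  ## canonical tiles cover [0, G); DOC and dup features break the tiling,
  ## DCC/unplaced tracts live inside a host tile.
  dup_slack <- 50L
  tiles <- list()   # list of (ref_s, ref_e, role, feature)
  seg_start <- 0L
  ord <- order(feat$tract_start)
  for (i in ord) {
    if (feat$type[i] == "doc") {
      last <- length(tiles)
      if (last && is.na(tiles[[last]]$e)) {
        ## close an open docD tile in the flank before this tract, far
        ## enough from both tracts that no tract-overlapping read straddles
        ## the boundary
        brk <- feat$tract_start[i] - 1750L
        tiles[[last]]$e <- brk
        seg_start <- brk
      }
      tiles[[length(tiles) + 1L]] <- list(s = seg_start,
                                          e = feat$tract_end[i],
                                          role = "docC", fi = i)
      seg_start <- feat$tract_end[i]
      ## the docD tile is closed by the next break (or the genome end)
      tiles[[length(tiles) + 1L]] <- list(s = seg_start, e = NA_integer_,
                                          role = "docD", fi = i)
      seg_start <- NA_integer_  # docD absorbs until the next break
    } else if (feat$type[i] == "dup") {
      e_s <- feat$dup_start2[i] - dup_slack
      e_e <- feat$dup_end2[i] + dup_slack
      last <- length(tiles)
      if (last && is.na(tiles[[last]]$e)) {
        tiles[[last]]$e <- e_s  # close an open docD tile
      } else {
        tiles[[length(tiles) + 1L]] <- list(s = seg_start, e = e_s,
                                            role = "plain", fi = NA_integer_)
      }
      tiles[[length(tiles) + 1L]] <- list(s = e_s, e = e_e, role = "dupE",
                                          fi = i)
      seg_start <- e_e
    }
  }
  last <- length(tiles)
  if (last && is.na(tiles[[last]]$e)) {
    tiles[[last]]$e <- G
  } else {
    tiles[[length(tiles) + 1L]] <- list(s = seg_start, e = G, role = "plain",
                                        fi = NA_integer_)
  }
  tile_dt <- data.table::rbindlist(lapply(tiles, function(t) {
    data.table::data.table(ref_s = t$s, ref_e = t$e, role = t$role,
                           fi = t$fi)
  }))
  data.table::setorder(tile_dt, ref_s)
  tile_dt[, tile_id := sprintf("ctg%05d", .I)]
  ## body offset of a ref position within the tile's contig: docD bodies
  ## carry an overhang plus the haplotype-2 tract before their ref part
  tile_dt[, body_add := 0L]
  for (k in which(tile_dt$role == "docD")) {
    tile_dt[k, body_add := ov + tracts[[tile_dt$fi[k]]]$hap2_len]
  }

  ## host tile of each tract: the canonical tile containing tract_start
  ## (for a DOC that is the docC tile, whose tile ends at tract_end)
  ti <- findInterval(feat$tract_start, tile_dt$ref_s)
  feat[, host_tile := tile_dt$tile_id[ti]]

  ## ---- contig sequences ----
  body_of <- function(row) {
    fi <- row$fi
    switch(row$role,
      plain = substr(ref, row$ref_s + 1L, row$ref_e),
      dupE = substr(ref, row$ref_s + 1L, row$ref_e),
      docC = substr(ref, row$ref_s + 1L, row$ref_e + ov),
      docD = {
        tr <- tracts[[fi]]
        paste0(substr(ref, feat$tract_start[fi] - ov + 1L,
                      feat$tract_start[fi]),
               tr$seq,
               substr(ref, feat$tract_end[fi] + 1L, row$ref_e))
      })
  }
  contigs <- character(0)
  for (i in seq_len(nrow(tile_dt))) {
    contigs[[tile_dt$tile_id[i]]] <- body_of(tile_dt[i])
  }
  ## haplotype-2 contigs for dcc and unplaced tracts
  feat[, var_contig := NA_character_]
  feat[, var_rev := FALSE]
  vn <- 0L
  for (i in which(feat$type %in% c("dcc", "unplaced"))) {
    vn <- vn + 1L
    vid <- sprintf("hap%04d", vn)
    tr <- tracts[[i]]
    body <- paste0(substr(ref, feat$tract_start[i] - ov + 1L,
                          feat$tract_start[i]),
                   tr$seq,
                   substr(ref, feat$tract_end[i] + 1L,
                          feat$tract_end[i] + ov))
    rev <- feat$type[i] == "dcc" && stats::runif(1L) < config$rev_fraction
    contigs[[vid]] <- if (rev) revcomp(body) else body
    data.table::set(feat, i, "var_contig", vid)
    data.table::set(feat, i, "var_rev", rev)
  }
  for (i in which(feat$type == "doc")) {
    data.table::set(feat, i, "var_contig",
                    tile_dt[role == "docD" & fi == i, tile_id])
  }
  ## clean unplaced negatives
  clean_unplaced <- character(0)
  for (i in seq_len(config$n_clean_unplaced)) {
    cid <- sprintf("unp%03d", i)
    contigs[[cid]] <- rand_dna(1500L)
    clean_unplaced <- c(clean_unplaced, cid)
  }

  ## ---- AGP: tiles in order, DCC haplotype contigs inserted after their
  ## host tile ----
  comp_order <- list()
  for (i in seq_len(nrow(tile_dt))) {
    tid <- tile_dt$tile_id[i]
    comp_order[[length(comp_order) + 1L]] <-
      list(id = tid, orient = "forward")
    ins <- feat[type == "dcc" & host_tile == tid][order(tract_start)]
    for (j in seq_len(nrow(ins))) {
      comp_order[[length(comp_order) + 1L]] <-
        list(id = ins$var_contig[j],
             orient = if (ins$var_rev[j]) "reverse" else "forward")
    }
  }
  chrom <- "chr1"
  pl <- list(); gp <- list()
  pos <- 0L
  for (k in seq_along(comp_order)) {
    cid <- comp_order[[k]]$id
    len <- nchar(contigs[[cid]])
    pl[[k]] <- data.table::data.table(
      contig_id = cid, chrom = chrom, start = pos, end = pos + len,
      orientation = comp_order[[k]]$orient, placed = TRUE,
      component_type = "W", component_beg = 1L, component_end = len)
    pos <- pos + len
    if (k < length(comp_order)) {
      gp[[k]] <- data.table::data.table(
        chrom = chrom, start = pos, end = pos + config$gap_len,
        length = config$gap_len, gap_type = "scaffold", linkage = "yes",
        evidence = "paired-ends")
      pos <- pos + config$gap_len
    }
  }
  placements <- data.table::rbindlist(pl)
  gaps <- data.table::rbindlist(gp)
  agp <- structure(list(placements = placements, gaps = gaps),
                   class = "agp")

  ## ---- reads ----
  layout <- simulate_reads(config, G, ref, feat, tracts, tile_dt, contigs,
                           placements, ov)

  ## ---- truth labels ----
  truth <- build_truth(config, feat, tracts, tile_dt, contigs, placements,
                       layout, ov)

  libraries <- data.table::rbindlist(lapply(config$libraries, function(l) {
    data.table::data.table(
      library_id = l$library_id, ta_mean = l$mean, ta_sd = l$sd,
      read_count = sum(layout$library_id == l$library_id))
  }))

  bundle <- list(contigs = contigs, agp = agp, layout = layout,
                 libraries = libraries, truth = truth, config = config,
                 clean_unplaced = clean_unplaced)
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

## draw paired reads and assign them to contigs
simulate_reads <- function(config, G, ref, feat, tracts, tile_dt, contigs,
                           placements, ov) {
  het <- feat[type %in% c("dcc", "doc", "unplaced")][order(tract_start)]
  het_n <- nrow(het)
  ## concatenated hap2 maps for vectorized lookup
  map_all <- unlist(lapply(het$feature_id, function(fid) {
    tracts[[which(feat$feature_id == fid)]]$map
  }))
  map_off <- c(0L, cumsum(het$tract_end - het$tract_start))[seq_len(het_n)]
  hap2_lens <- vapply(het$feature_id, function(fid) {
    tracts[[which(feat$feature_id == fid)]]$hap2_len
  }, 0L)
  het_host_idx <- match(het$host_tile, tile_dt$tile_id)

  rows <- list()
  for (lib in config$libraries) {
    rl <- as.integer(lib$read_length)
    n_pairs <- round(lib$coverage * G / (2 * rl))
    d <- pmax(as.integer(round(stats::rnorm(n_pairs, lib$mean, lib$sd))),
              rl + 1L)
    s <- floor(stats::runif(n_pairs) * (G - d - 1))
    hap <- sample(1:2, n_pairs, replace = TRUE)
    reads <- data.table::data.table(
      pair = rep(seq_len(n_pairs), each = 2L),
      mate_no = rep(c(1L, 2L), n_pairs),
      s = as.integer(rbind(s, s + d - rl + 1L)),
      e = as.integer(rbind(s + rl, s + d + 1L)),
      orient = rep(c("forward", "reverse"), n_pairs),
      hap = rep(hap, each = 2L))
    reads[, read_id := paste0(lib$library_id, "_", pair,
                              ifelse(mate_no == 1L, "a", "b"))]
    reads[, mate_id := paste0(lib$library_id, "_", pair,
                              ifelse(mate_no == 1L, "b", "a"))]
    ## which het tract (if any) does the read overlap?
    hi <- findInterval(reads$e - 1L, het$tract_start)
    hi[hi < 1L] <- NA_integer_
    ov_tract <- !is.na(hi) & het$tract_end[pmax(hi, 1L)] > reads$s
    hi[!ov_tract] <- NA_integer_
    ## canonical tile of the read start
    tix <- findInterval(reads$s, tile_dt$ref_s)
    reads[, `:=`(contig_id = NA_character_, cs = NA_integer_,
                 ce = NA_integer_, keep = TRUE)]
    ## --- case 1: no tract overlap -> canonical tile ---
    c1 <- is.na(hi)
    if (any(c1)) {
      t_idx <- tix[c1]
      body_end <- tile_dt$ref_e[t_idx] +
        ifelse(tile_dt$role[t_idx] == "docC", ov, 0L)
      contained <- reads$e[c1] <= body_end
      off <- reads$s[c1] - tile_dt$ref_s[t_idx] + tile_dt$body_add[t_idx]
      reads[c1, `:=`(contig_id = tile_dt$tile_id[t_idx],
                     cs = off, ce = off + (e - s),
                     keep = contained)]
    }
    ## --- case 2: overlaps a het tract ---
    c2 <- !is.na(hi)
    if (any(c2)) {
      h <- hi[c2]
      ht <- het[h]
      hap_r <- reads$hap[c2]
      stype <- ht$type
      ## haplotype 1 (or hap2 outside a doc): host contig
      to_host <- hap_r == 1L
      ## haplotype 2: variant contig (dcc/unplaced) or docD
      host_idx <- het_host_idx[h]
      host_tile_s <- tile_dt$ref_s[host_idx]
      host_body_end <- tile_dt$ref_e[host_idx] +
        ifelse(tile_dt$role[host_idx] == "docC", ov, 0L)
      s2 <- reads$s[c2]; e2 <- reads$e[c2]
      v_cs <- integer(sum(c2)); v_ce <- integer(sum(c2))
      v_cid <- character(sum(c2)); v_keep <- logical(sum(c2))
      ## hap1 -> host
      w <- which(to_host)
      if (length(w)) {
        add <- tile_dt$body_add[host_idx[w]]
        v_keep[w] <- s2[w] >= host_tile_s[w] & e2[w] <= host_body_end[w]
        v_cid[w] <- tile_dt$tile_id[host_idx[w]]
        v_cs[w] <- s2[w] - host_tile_s[w] + add
        v_ce[w] <- e2[w] - host_tile_s[w] + add
      }
      ## hap2 -> variant contig
      w <- which(!to_host)
      if (length(w)) {
        hw <- h[w]
        body_s <- het$tract_start[hw] - ov
        body_e_ref <- ifelse(het$type[hw] == "doc",
                             tile_dt$ref_e[match(het$var_contig[hw],
                                                 tile_dt$tile_id)],
                             het$tract_end[hw] + ov)
        v_keep[w] <- s2[w] >= body_s & e2[w] <= body_e_ref
        v_cid[w] <- het$var_contig[hw]
        o1 <- hap2_offset_vec(s2[w], hw, het, ov, map_all, map_off,
                              hap2_lens)
        o2 <- hap2_offset_vec(e2[w] - 1L, hw, het, ov, map_all, map_off,
                              hap2_lens)
        v_cs[w] <- o1
        v_ce[w] <- o2 + 1L
      }
      reads[c2, `:=`(contig_id = v_cid, cs = v_cs, ce = v_ce,
                     keep = v_keep)]
    }
    ## flip coordinates in reverse-placed variant contigs
    revs <- het[var_rev == TRUE, var_contig]
    if (length(revs)) {
      sel <- reads$contig_id %in% revs
      if (any(sel)) {
        Ls <- nchar(unlist(contigs[reads$contig_id[sel]]))
        new_s <- Ls - reads$ce[sel]
        new_e <- Ls - reads$cs[sel]
        reads[sel, `:=`(cs = new_s, ce = new_e,
                        orient = ifelse(orient == "forward",
                                        "reverse", "forward"))]
      }
    }
    ## degenerate intervals (fully inside a deletion) are dropped
    reads[ce <= cs, keep := FALSE]
    reads <- reads[keep == TRUE]
    ## unmate pairs with a dropped partner
    reads[, mate_here := mate_id %in% read_id]
    reads[mate_here == FALSE, mate_id := NA_character_]
    rows[[length(rows) + 1L]] <- reads[, .(
      read_id, contig_id, start = cs, end = ce, orientation = orient,
      library_id = lib$library_id, mate_id)]
  }
  data.table::rbindlist(rows)
}

hap2_offset_vec <- function(pos, h, het, ov, map_all, map_off, hap2_lens) {
  ts <- het$tract_start[h]; te <- het$tract_end[h]
  off <- integer(length(pos))
  left <- pos < ts
  mid <- pos >= ts & pos < te
  right <- pos >= te
  off[left] <- ov - (ts[left] - pos[left])
  off[mid] <- ov + map_all[map_off[h[mid]] + (pos[mid] - ts[mid]) + 1L]
  off[right] <- ov + hap2_lens[h[right]] + (pos[right] - te[right])
  off
}

## truth labels: per-feature pattern/contigs/spans and planted variants in
## anchor (chromosome) coordinates, with independently computed callable
## depths from the read layout.
build_truth <- function(config, feat, tracts, tile_dt, contigs, placements,
                        layout, ov) {
  chrom_start <- stats::setNames(placements$start, placements$contig_id)
  features <- data.table::data.table(
    feature_id = feat$feature_id,
    pattern = c(dcc = "DCC_misassembly", doc = "DOC_misassembly",
                unplaced = "unplaced_variant",
                dup = "true_duplication")[feat$type],
    moved_contig = feat$var_contig,
    anchor_contig = feat$host_tile,
    tract_start = feat$tract_start, tract_end = feat$tract_end)
  ## true duplications: the moved contig is the dupE tile, the anchor is
  ## the tile containing copy 1
  dup_i <- which(feat$type == "dup")
  for (i in dup_i) {
    data.table::set(features, i, "moved_contig",
                    tile_dt[role == "dupE" & fi == i, tile_id])
  }
  ## anchor-frame/chromosome coordinates of the het tract
  host_idx <- match(features$anchor_contig, tile_dt$tile_id)
  features[, anchor_offset := tract_start - tile_dt$ref_s[host_idx] +
             tile_dt$body_add[host_idx]]
  features[, chrom := "chr1"]
  features[, chrom_tract_start := chrom_start[anchor_contig] + anchor_offset]
  features[, chrom_tract_end := chrom_tract_start + (tract_end - tract_start)]

  ## planted variants
  vrows <- list()
  proj_cov <- layout_coverage_index(layout)
  for (i in which(feat$type %in% c("dcc", "doc", "unplaced"))) {
    tr <- tracts[[i]]
    if (!length(tr$variants)) next
    f <- features[i]
    anchor_seq <- contigs[[f$anchor_contig]]
    a_off <- f$anchor_offset
    het_contig <- feat$var_contig[i]
    var_rev <- feat$var_rev[i]
    Lv <- nchar(contigs[[het_contig]])
    for (v in tr$variants) {
      apos <- a_off + v$pos0
      nv <- normalize_variant(anchor_seq, apos, v$ref, v$alt)
      ## hap2-frame interval whose spanning reads support the alt allele
      t0 <- v$pos0
      if (v$type == "SNP") {
        q1 <- ov + tr$map[t0 + 1L]; q2 <- q1
        a1 <- t0; a2 <- t0
      } else if (v$type == "del") {
        a1 <- t0; a2 <- t0 + nchar(v$ref)
        q1 <- ov + tr$map[min(t0 + 1L, length(tr$map))]
        q2 <- ov + tr$map[min(a2 + 1L, length(tr$map))]
      } else {
        a1 <- t0; a2 <- t0 + 1L
        q1 <- ov + tr$map[t0 + 1L]
        q2 <- ov + tr$map[min(t0 + 2L, length(tr$map))]
      }
      if (var_rev) {
        tmp <- Lv - 1L - q2
        q2 <- Lv - 1L - q1
        q1 <- tmp
      }
      depth_alt <- spanning_depth(proj_cov, het_contig, q1, q2)
      depth_ref <- spanning_depth(proj_cov, f$anchor_contig,
                                  a_off + a1, a_off + a2)
      vrows[[length(vrows) + 1L]] <- data.table::data.table(
        feature_id = feat$feature_id[i], chrom = "chr1",
        position = chrom_start[f$anchor_contig] + nv$pos,
        anchor_pos = nv$pos,
        ref_allele = nv$ref, alt_allele = nv$alt,
        var_type = if (v$type == "SNP") "SNP" else "indel",
        depth_alt = depth_alt, depth_ref = depth_ref)
    }
  }
  variants <- if (length(vrows)) data.table::rbindlist(vrows) else {
    data.table::data.table(feature_id = character(), chrom = character(),
                           position = integer(), anchor_pos = integer(),
                           ref_allele = character(), alt_allele = character(),
                           var_type = character(), depth_alt = integer(),
                           depth_ref = integer())
  }
  ## callable: both alleles at min depth and no other planted variant
  ## within the quality-filter flank
  if (nrow(variants)) {
    data.table::setorder(variants, feature_id, position)
    variants[, iso := {
      d_prev <- c(Inf, diff(position))
      d_next <- c(diff(position), Inf)
      d_prev > 5L + nchar(ref_allele) & d_next > 5L + nchar(ref_allele)
    }, by = feature_id]
    variants[, callable := depth_alt >= 2L & depth_ref >= 2L & iso]
    variants[, iso := NULL]
  } else {
    variants[, callable := logical(0)]
  }
  list(features = features[], variants = variants[])
}

## per-contig sorted read intervals for independent depth counting
layout_coverage_index <- function(layout) {
  split(layout[, .(start, end)], layout$contig_id)
}

## number of reads whose interval covers [p1, p2] (0-based, inclusive)
spanning_depth <- function(idx, contig_id, p1, p2) {
  iv <- idx[[contig_id]]
  if (is.null(iv)) return(0L)
  sum(iv$start <= p1 & iv$end >= p2 + 1L)
}

#' Write a simulated bundle to disk
#' @param bundle Output of [simulate_assembly()].
#' @param dir Output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_contigs(bundle$contigs, file.path(dir, "contigs.fasta"))
  write_agp(bundle$agp, file.path(dir, "assembly.agp"))
  write_layout(bundle$layout, file.path(dir, "layout.tsv"))
  write_libraries(bundle$libraries, file.path(dir, "libraries.tsv"))
  utils::write.table(bundle$truth$features,
                     file.path(dir, "truth_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$variants,
                     file.path(dir, "truth_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- bundle$config
  cfg$libraries <- lapply(cfg$libraries, as.list)
  jsonlite::write_json(
    list(config = unclass(cfg),
         n_features = nrow(bundle$truth$features),
         n_planted_variants = nrow(bundle$truth$variants)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
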