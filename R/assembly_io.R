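## assembly_io: readers/writers for FASTA, AGP, read layout, library metadata,
## plus coordinate projection between contig and chromosome frames.
## Internal convention: 0-based half-open; AGP/VCF converted at the boundary.

#' Read contig sequences from a FASTA file
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @return Named character vector of uppercased sequences, keyed by the first
#'   whitespace-delimited token of each header.
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate contig ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for contig(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write contig sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width.
#' @export
write_contigs <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    cat(">", id, "\n", sep = "", file = con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

## read a (possibly gzipped) TSV without headers into a data.table
fd_read_tsv <- function(path, col.names) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  df <- utils::read.table(con, sep = "\t", header = FALSE,
                          col.names = col.names, comment.char = "#",
                          colClasses = "character", quote = "",
                          blank.lines.skip = TRUE, fill = TRUE)
  data.table::as.data.table(df)
}

#' Read an AGP v2.0 file
#'
#' AGP rows are 1-based inclusive; they are converted to the internal 0-based
#' half-open convention.  Gap rows (component type \code{N}/\code{U}) are kept
#' as explicit records because DOC joins need them.
#'
#' @param path Path to an AGP file (plain or gzip).
#' @return An object of class \code{"agp"}: a list with \code{$placements}
#'   (data.table: contig_id, chrom, start, end, orientation, placed,
#'   component_type, component_beg, component_end) and \code{$gaps}
#'   (data.table: chrom, start, end, length, gap_type, linkage, evidence).
#' @export
read_agp <- function(path) {
  cn <- c("object", "object_beg", "object_end", "part_number",
          "component_type", "f6", "f7", "f8", "f9")
  dt <- fd_read_tsv(path, cn)
  dt[, `:=`(object_beg = as.integer(object_beg),
            object_end = as.integer(object_end),
            part_number = as.integer(part_number))]
  is_gap <- dt$component_type %in% c("N", "U")
  comp <- dt[!is_gap]
  gaps <- dt[is_gap]
  placements <- data.table::data.table(
    contig_id = comp$f6,
    chrom = comp$object,
    start = comp$object_beg - 1L,
    end = comp$object_end,
    orientation = ifelse(comp$f9 %in% c("-", "minus"), "reverse", "forward"),
    placed = TRUE,
    component_type = comp$component_type,
    component_beg = as.integer(comp$f7),
    component_end = as.integer(comp$f8)
  )
  gap_records <- data.table::data.table(
    chrom = gaps$object,
    start = gaps$object_beg - 1L,
    end = gaps$object_end,
    length = as.integer(gaps$f6),
    gap_type_code = gaps$component_type,
    gap_type = gaps$f7,
    linkage = gaps$f8,
    evidence = gaps$f9
  )
  if (nrow(gap_records) && any(gap_records$length < 0L)) {
    stop("negative gap length in AGP")
  }
  ## components on one chromosome must not overlap
  for (ch in unique(placements$chrom)) {
    p <- placements[chrom == ch][order(start)]
    if (nrow(p) > 1L && any(p$start[-1L] < p$end[-nrow(p)])) {
      stop("overlapping components on chromosome ", ch)
    }
  }
  validate_placements(placements)
  structure(list(placements = placements, gaps = gap_records), class = "agp")
}

validate_placements <- function(placements) {
  if (any(placements$end <= placements$start)) {
    stop("placement with end <= start")
  }
  invisible(TRUE)
}

#' Write an AGP v2.0 file
#'
#' Component rows round-trip byte-identically through [read_agp()].
#'
#' @param agp An \code{"agp"} object.
#' @param path Output path.
#' @export
write_agp <- function(agp, path) {
  p <- data.table::copy(agp$placements)
  g <- data.table::copy(agp$gaps)
  rows <- data.table::rbindlist(list(
    data.table::data.table(
      object = p$chrom, object_beg = p$start + 1L, object_end = p$end,
      component_type = p$component_type,
      f6 = p$contig_id, f7 = as.character(p$component_beg),
      f8 = as.character(p$component_end),
      f9 = ifelse(p$orientation == "reverse", "-", "+")),
    if (nrow(g)) data.table::data.table(
      object = g$chrom, object_beg = g$start + 1L, object_end = g$end,
      component_type = if (is.null(g$gap_type_code)) "N" else g$gap_type_code,
      f6 = as.character(g$length), f7 = g$gap_type,
      f8 = g$linkage, f9 = g$evidence)
  ), fill = TRUE)
  data.table::setorder(rows, object, object_beg)
  rows[, part_number := seq_len(.N), by = object]
  out <- rows[, paste(object, object_beg, object_end, part_number,
                      component_type, f6, f7, f8, f9, sep = "\t")]
  writeLines(out, path)
  invisible(path)
}

#' Read a read-in-contig layout file
#'
#' Tab-separated, seven columns: read_id, contig_id, start, end, orientation
#' (\code{+}/\code{-} or \code{forward}/\code{reverse}), library_id, mate_id
#' (empty or \code{.} when the mate is absent).  Coordinates are 0-based
#' half-open intervals within the contig.
#'
#' Mate symmetry is verified: reads whose mate reference is asymmetric (mate
#' missing from the file, or the mate names a different read) are dropped
#' with a warning.
#'
#' @param path Path to the layout file (plain or gzip).
#' @param libraries Optional library metadata (see [read_libraries()]); if
#'   supplied, an unknown \code{library_id} is an error.
#' @return data.table: read_id, contig_id, start, end, orientation,
#'   library_id, mate_id (NA when unmated).
#' @export
read_layout <- function(path, libraries = NULL) {
  cn <- c("read_id", "contig_id", "start", "end", "orientation",
          "library_id", "mate_id")
  dt <- fd_read_tsv(path, cn)
  dt[, `:=`(start = as.integer(start), end = as.integer(end))]
  dt[, orientation := ifelse(orientation %in% c("-", "reverse"),
                             "reverse", "forward")]
  dt[mate_id %in% c("", ".", "NA"), mate_id := NA_character_]
  if (any(dt$end <= dt$start)) stop("read placement with end <= start")
  if (anyDuplicated(dt$read_id)) stop("duplicate read ids in layout")
  if (!is.null(libraries)) {
    unknown <- setdiff(dt$library_id, libraries$library_id)
    if (length(unknown)) {
      stop("unknown library id(s) in layout: ", paste(unknown, collapse = ", "))
    }
  }
  ## verify mate symmetry
  mated <- dt[!is.na(mate_id)]
  if (nrow(mated)) {
    ## a pair is symmetric iff mate(mate(r)) == r
    mate_of <- stats::setNames(mated$mate_id, mated$read_id)
    ok <- !is.na(mate_of[mated$mate_id]) & mate_of[mated$mate_id] == mated$read_id
    if (any(!ok)) {
      warning(sum(!ok), " read(s) with asymmetric mate references dropped")
      drop_ids <- unique(c(mated$read_id[!ok], mated$mate_id[!ok]))
      dt <- dt[!read_id %in% drop_ids]
    }
  }
  dt[]
}

#' Write a read layout file
#' @param layout Layout data.table (see [read_layout()]).
#' @param path Output path.
#' @export
write_layout <- function(layout, path) {
  out <- layout[, paste(read_id, contig_id, start, end,
                        ifelse(orientation == "reverse", "-", "+"),
                        library_id,
                        ifelse(is.na(mate_id), ".", mate_id), sep = "\t")]
  writeLines(out, path)
  invisible(path)
}

#' Read library metadata (Trace-Archive style)
#'
#' Tab-separated: library_id, ta_mean, ta_sd, read_count.
#'
#' @param path Path to the library file (plain or gzip).
#' @return data.table with those columns (numeric mean/sd).
#' @export
read_libraries <- function(path) {
  dt <- fd_read_tsv(path, c("library_id", "ta_mean", "ta_sd", "read_count"))
  dt[, `:=`(ta_mean = as.numeric(ta_mean), ta_sd = as.numeric(ta_sd),
            read_count = as.integer(read_count))]
  if (any(dt$ta_sd <= 0) || any(dt$ta_mean <= 0)) {
    stop("library metadata requires ta_mean > 0 and ta_sd > 0")
  }
  dt[]
}

#' Write library metadata
#' @param libraries Library data.table.
#' @param path Output path.
#' @export
write_libraries <- function(libraries, path) {
  out <- libraries[, paste(library_id, ta_mean, ta_sd, read_count, sep = "\t")]
  writeLines(out, path)
  invisible(path)
}

#' Project a read placement onto the chromosome
#'
#' Returns the chromosomal position of the read's 5' end and its chromosomal
#' orientation.  For a reverse-placed contig the read orientation flips and
#' coordinates mirror within the contig span; the 5' end of a chromosomally
#' reverse read is the rightmost base of its interval.
#'
#' @param rp A one-row read placement (list/data.frame with contig_id, start,
#'   end, orientation).
#' @param cp The contig placement (contig_id, start, end, orientation).
#' @return list(pos5 = chromosomal 5' position, orientation).
#' @export
project_to_chromosome <- function(rp, cp) {
  if (rp$contig_id != cp$contig_id) stop("contig_id mismatch")
  L <- cp$end - cp$start
  if (rp$end > L || rp$start < 0L) stop("read interval exceeds contig span")
  if (cp$orientation == "forward") {
    ori <- rp$orientation
    pos5 <- if (ori == "forward") cp$start + rp$start else cp$start + rp$end - 1L
  } else {
    ori <- if (rp$orientation == "forward") "reverse" else "forward"
    ## interval mirrors to [L - end, L - start)
    pos5 <- if (ori == "forward") cp$start + (L - rp$end)
            else cp$start + (L - rp$start) - 1L
  }
  list(pos5 = pos5, orientation = ori)
}

## Vectorized projection of a whole layout through contig placements.
## Returns a data.table keyed by read_id with chromosomal interval, 5' end
## and orientation; reads in unplaced contigs get placed = FALSE.
project_reads <- function(layout, placements) {
  pl <- placements[, .(contig_id, c_chrom = chrom, c_start = start,
                       c_end = end, c_orient = orientation)]
  dt <- merge(layout, pl, by = "contig_id", all.x = TRUE, sort = FALSE)
  dt[, placed := !is.na(c_start)]
  dt[, L := c_end - c_start]
  if (any(dt$placed & (dt$end > dt$L | dt$start < 0L))) {
    stop("read interval exceeds contig span")
  }
  fwd <- dt$c_orient == "forward"
  dt[, chrom_orient := orientation]
  dt[placed & !fwd, chrom_orient := ifelse(orientation == "forward",
                                           "reverse", "forward")]
  dt[, `:=`(g_start = NA_integer_, g_end = NA_integer_)]
  dt[placed & fwd, `:=`(g_start = c_start + start, g_end = c_start + end)]
  dt[placed & !fwd, `:=`(g_start = c_start + (L - end),
                         g_end = c_start + (L - start))]
  dt[, pos5 := ifelse(chrom_orient == "forward", g_start, g_end - 1L)]
  dt[, .(read_id, contig_id, library_id, mate_id, placed,
         chrom = c_chrom, g_start, g_end, pos5, chrom_orient,
         start, end, orientation)]
}

#' Project a chromosomal interval back into contig coordinates
#'
#' Inverse of the chromosome projection; used for round-trip checks.
#'
#' @param g_start,g_end Chromosomal interval (0-based half-open).
#' @param chrom_orient Chromosomal orientation of the read.
#' @param cp Contig placement row.
#' @return list(start, end, orientation) in contig coordinates.
#' @export
project_to_contig <- function(g_start, g_end, chrom_orient, cp) {
  L <- cp$end - cp$start
  if (cp$orientation == "forward") {
    list(start = g_start - cp$start, end = g_end - cp$start,
         orientation = chrom_orient)
  } else {
    list(start = L - (g_end - cp$start), end = L - (g_start - cp$start),
         orientation = if (chrom_orient == "forward") "reverse" else "forward")
  }
}

#' Write mis-assembly calls as TSV and BED
#'
#' The BED file (0-based half-open) contains the chromosomal alignment span
#' of each call whose verdict is \code{mis_assembled}.
#'
#' @param calls Call table from [classify_all()]/[run_detect()].
#' @param path Output TSV path; the BED is written next to it with extension
#'   \code{.bed}.
#' @param placements Contig placements (for validating contig references).
#' @export
write_calls <- function(calls, path, placements = NULL) {
  if (!is.null(placements)) {
    ids <- unique(c(calls$moved_contig_id, calls$anchor_contig_id))
    unknown <- setdiff(ids, placements$contig_id)
    if (length(unknown)) {
      stop("call references unknown contig(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  cols <- intersect(
    c("moved_contig_id", "anchor_contig_id", "kind", "n_relevant",
      "loglik_original", "loglik_merged", "verdict", "flag", "a_stat",
      "single_copy", "chrom", "span_start", "span_end"),
    names(calls))
  dt <- calls[, cols, with = FALSE]
  num <- vapply(dt, is.double, logical(1L))
  for (cc in names(dt)[num]) data.table::set(dt, j = cc,
                                             value = formatC(dt[[cc]], digits = 6, format = "g"))
  utils::write.table(dt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- calls[verdict == "mis_assembled" & !is.na(chrom),
               .(chrom, span_start, span_end,
                 name = paste0(moved_contig_id, "_", kind))]
  writeLines(bed[, paste(chrom, span_start, span_end, name, sep = "\t")],
             sub("\\.[^.]*$", ".bed", path))
  invisible(path)
}

#' Write a corrected AGP
#'
#' Components confirmed as mis-assembled erroneous duplications are removed:
#' a DCC's moved contig row (and its preceding gap) is deleted, and a DOC's
#' right contig is trimmed at its component start so the duplicated overlap
#' appears only once.  Object coordinates are recomputed so each chromosome
#' remains a contiguous 1-based tiling.
#'
#' @param agp Original \code{"agp"} object.
#' @param calls Call table; only rows with verdict \code{mis_assembled} are
#'   applied.
#' @param path Output path.
#' @return Invisibly, the corrected \code{"agp"} object.
#' @export
write_corrected_agp <- function(agp, calls, path) {
  p <- data.table::copy(agp$placements)
  g <- data.table::copy(agp$gaps)
  mis <- calls[verdict == "mis_assembled"]
  unknown <- setdiff(mis$moved_contig_id, p$contig_id)
  if (length(unknown)) {
    stop("call references unknown contig(s): ", paste(unknown, collapse = ", "))
  }
  drop_dcc <- mis[kind == "DCC", moved_contig_id]
  ## remove DCC rows and the gap immediately preceding each
  for (cid in drop_dcc) {
    row <- p[contig_id == cid]
    g <- g[!(chrom == row$chrom & end == row$start)]
    p <- p[contig_id != cid]
  }
  for (i in seq_len(nrow(mis[kind == "DOC"]))) {
    row <- mis[kind == "DOC"][i]
    if (!row$moved_contig_id %in% p$contig_id) next
    trim <- row$overlap_len
    idx <- which(p$contig_id == row$moved_contig_id)
    ## trim the duplicated overlap off the component start, drop the gap
    left <- p$contig_id == row$anchor_contig_id
    g <- g[!(chrom == p$chrom[idx] & end == p$start[idx])]
    if (p$orientation[idx] == "forward") {
      p$component_beg[idx] <- p$component_beg[idx] + trim
    } else {
      p$component_end[idx] <- p$component_end[idx] - trim
    }
    p$start[idx] <- p$start[idx] + trim
  }
  ## recompute object coordinates per chromosome: contiguous tiling
  events <- data.table::rbindlist(list(
    p[, .(chrom, start, len = (component_end - component_beg + 1L),
          type = "W", id = contig_id)],
    if (nrow(g)) g[, .(chrom, start, len = length, type = "N",
                       id = NA_character_)]), fill = TRUE)
  data.table::setorder(events, chrom, start)
  events[, new_start := cumsum(data.table::shift(len, fill = 0L)), by = chrom]
  newp <- merge(p, events[type == "W", .(chrom, id, new_start)],
                by.x = c("chrom", "contig_id"), by.y = c("chrom", "id"))
  newp[, `:=`(start = new_start, end = new_start + component_end - component_beg + 1L)]
  newp[, new_start := NULL]
  newg <- if (nrow(g)) {
    m <- merge(g, events[type == "N", .(chrom, start, new_start)],
               by = c("chrom", "start"))
    m[, `:=`(start = new_start, end = new_start + length)][, new_start := NULL]
  } else g
  out <- structure(list(placements = newp, gaps = newg), class = "agp")
  write_agp(out, path)
  invisible(out)
}

#' Write variants as VCF 4.2
#'
#' Positions are converted from the internal 0-based convention to VCF's
#' 1-based coordinates; indels follow the left-aligned anchored-base
#' convention (normalization is done at call time).
#'
#' @param variants data.table with chrom, position (0-based), ref_allele,
#'   alt_allele, var_type, depth_ref, depth_alt.
#' @param path Output path.
#' @export
write_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
           "##INFO=<ID=DPR,Number=1,Type=Integer,Description=\"Reference allele depth\">",
           "##INFO=<ID=DPA,Number=1,Type=Integer,Description=\"Alternate allele depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants)) {
    variants[, paste(chrom, position + 1L, ".", ref_allele, alt_allele, ".",
                     "PASS",
                     paste0("TYPE=", var_type, ";DPR=", depth_ref,
                            ";DPA=", depth_alt),
                     sep = "\t")]
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#' @param path VCF path.
#' @return data.table with internal 0-based positions.
#' @export
read_vcf <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln)) {
    return(data.table::data.table(chrom = character(), position = integer(),
                                  ref_allele = character(),
                                  alt_allele = character(),
                                  var_type = character(),
                                  depth_ref = integer(), depth_alt = integer()))
  }
  f <- data.table::tstrsplit(ln, "\t")
  info <- f[[8]]
  grab <- function(key) sub(paste0(".*", key, "="), "",
                            sub(";.*", "", sub(paste0(".*(", key, "=[^;]*).*"),
                                               "\\1", info)))
  data.table::data.table(
    chrom = f[[1]], position = as.integer(f[[2]]) - 1L,
    ref_allele = f[[4]], alt_allele = f[[5]],
    var_type = grab("TYPE"),
    depth_ref = as.integer(grab("DPR")),
    depth_alt = as.integer(grab("DPA")))
}
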