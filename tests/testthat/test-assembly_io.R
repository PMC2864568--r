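test_that("FASTA reading normalizes and validates records", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">ctgA extra description", rand_seq(1000, seed = 1),
               ">ctgB", tolower(rand_seq(500))), fa)
  seqs <- read_contigs(fa)
  expect_named(seqs, c("ctgA", "ctgB"))
  expect_equal(unname(nchar(seqs)), c(1000L, 500L))
  expect_false(grepl("[acgt]", seqs[["ctgB"]]))

  writeLines(c(">x", "ACGT", ">x", "ACGT"), fa)
  expect_error(read_contigs(fa), "duplicate")
})

test_that("AGP coordinates convert to 0-based half-open and round-trip", {
  agp_file <- tempfile(fileext = ".agp")
  rows <- c("chr1\t1\t1000\t1\tW\tctgA\t1\t1000\t+",
            "chr1\t1001\t1500\t2\tN\t500\tscaffold\tyes\tpaired-ends",
            "chr1\t1501\t2300\t3\tW\tctgB\t1\t800\t-")
  writeLines(rows, agp_file)
  agp <- read_agp(agp_file)
  expect_equal(agp$placements$start, c(0L, 1500L))
  expect_equal(agp$placements$end, c(1000L, 2300L))
  expect_equal(agp$placements$orientation, c("forward", "reverse"))
  expect_equal(agp$gaps$length, 500L)
  out <- tempfile(fileext = ".agp")
  write_agp(agp, out)
  back <- readLines(out)
  expect_identical(back[c(1, 3)], rows[c(1, 3)])

  writeLines(c("chr1\t1\t1000\t1\tW\tctgA\t1\t1000\t+",
               "chr1\t900\t1500\t2\tW\tctgB\t1\t601\t+"), agp_file)
  expect_error(read_agp(agp_file), "overlap")
})

test_that("layout loading enforces mate symmetry and known libraries", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("r1\tctgA\t0\t100\t+\tlibA\tr2",
               "r2\tctgA\t500\t600\t-\tlibA\tr1",
               "r3\tctgA\t800\t900\t+\tlibA\tr9",
               "r4\tctgA\t100\t200\t+\tlibA\t."), f)
  libs <- data.table::data.table(library_id = "libA", ta_mean = 4000,
                                 ta_sd = 400, read_count = 4L)
  expect_warning(lay <- read_layout(f, libs), "asymmetric")
  expect_setequal(lay$read_id, c("r1", "r2", "r4"))
  expect_true(is.na(lay[read_id == "r4", mate_id]))

  writeLines("r1\tctgA\t0\t100\t+\tlibX\t.", f)
  expect_error(read_layout(f, libs), "unknown library")
})

test_that("chromosome projection handles both contig orientations", {
  fwd <- list(contig_id = "c", start = 5000L, end = 6000L,
              orientation = "forward")
  rev <- list(contig_id = "c", start = 5000L, end = 6000L,
              orientation = "reverse")
  rp <- list(contig_id = "c", start = 100L, end = 200L,
             orientation = "forward")
  p <- project_to_chromosome(rp, fwd)
  expect_equal(p$pos5, 5100L)
  expect_equal(p$orientation, "forward")
  p <- project_to_chromosome(rp, rev)
  expect_equal(p$pos5, 5899L)  # 5000 + (1000 - 100) - 1
  expect_equal(p$orientation, "reverse")
  p <- project_to_chromosome(list(contig_id = "c", start = 0L, end = 100L,
                                  orientation = "forward"),
                             list(contig_id = "c", start = 0L, end = 1000L,
                                  orientation = "forward"))
  expect_equal(p$pos5, 0L)
  expect_error(project_to_chromosome(
    list(contig_id = "c", start = 900L, end = 1100L,
         orientation = "forward"), fwd), "exceeds")
})

test_that("projection to chromosome and back is the identity", {
  set.seed(42)
  for (i in 1:50) {
    L <- sample(500:5000, 1)
    cp <- list(contig_id = "c", start = sample(0:10000, 1), end = NA,
               orientation = sample(c("forward", "reverse"), 1))
    cp$end <- cp$start + L
    s <- sample(0:(L - 100), 1)
    e <- s + sample(50:100, 1)
    ori <- sample(c("forward", "reverse"), 1)
    lay <- toy_layout(list("r", "c", s, e, ori, "libA", NA))
    pl <- data.table::data.table(contig_id = "c", chrom = "chr1",
                                 start = cp$start, end = cp$end,
                                 orientation = cp$orientation)
    pr <- falsedup:::project_reads(lay, pl)
    back <- project_to_contig(pr$g_start, pr$g_end, pr$chrom_orient, cp)
    expect_equal(back$start, s)
    expect_equal(back$end, e)
    expect_equal(back$orientation, ori)
    ## 5' is interval start for forward reads, last base for reverse
    expect_equal(pr$pos5,
                 if (pr$chrom_orient == "forward") pr$g_start
                 else pr$g_end - 1L)
  }
})

test_that("mate symmetry holds for all retained pairs after loading", {
  b <- tiny_bundle()
  f <- tempfile(fileext = ".tsv")
  write_layout(b$layout, f)
  lay <- read_layout(f, b$libraries)
  mated <- lay[!is.na(mate_id)]
  mate_of <- stats::setNames(mated$mate_id, mated$read_id)
  expect_true(all(mate_of[mated$mate_id] == mated$read_id))
})

test_that("VCF writing round-trips and uses 1-based coordinates", {
  v <- data.table::data.table(
    chrom = c("chr1", "chr1"), position = c(99L, 200L),
    ref_allele = c("A", "CTG"), alt_allele = c("G", "C"),
    var_type = c("SNP", "indel"), depth_ref = c(5L, 4L),
    depth_alt = c(3L, 2L))
  f <- tempfile(fileext = ".vcf")
  write_vcf(v, f)
  lines <- readLines(f)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  expect_true(any(grepl("^chr1\t100\t", lines)))  # 0-based 99 -> POS 100
  back <- read_vcf(f)
  expect_equal(back$position, v$position)
  expect_equal(back$ref_allele, v$ref_allele)
  expect_equal(back$depth_alt, v$depth_alt)
})

test_that("call tables validate contig references", {
  calls <- data.table::data.table(
    moved_contig_id = "ghost", anchor_contig_id = "ctgA", kind = "DCC",
    n_relevant = 1L, loglik_original = -10, loglik_merged = -5,
    verdict = "mis_assembled", flag = NA_character_, chrom = "chr1",
    span_start = 0L, span_end = 100L)
  pl <- data.table::data.table(contig_id = "ctgA", chrom = "chr1",
                               start = 0L, end = 1000L,
                               orientation = "forward", placed = TRUE)
  expect_error(write_calls(calls, tempfile(), pl), "unknown contig")
})
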