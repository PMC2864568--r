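test_that("DCC relevance: reads with a mate in another contig", {
  rows <- list()
  ## 4 externally mated, 3 internally mated (incl. both ends), 3 unmated
  for (i in 1:4) {
    rows[[length(rows) + 1]] <- list(paste0("e", i), "M", i * 100, i * 100 + 50,
                                     "forward", "libA", paste0("x", i))
    rows[[length(rows) + 1]] <- list(paste0("x", i), "B", i * 100, i * 100 + 50,
                                     "reverse", "libA", paste0("e", i))
  }
  rows[[length(rows) + 1]] <- list("i1", "M", 500, 550, "forward", "libA", "i2")
  rows[[length(rows) + 1]] <- list("i2", "M", 700, 750, "reverse", "libA", "i1")
  rows[[length(rows) + 1]] <- list("i3", "M", 800, 850, "forward", "libA", NA)
  for (i in 1:2) {
    rows[[length(rows) + 1]] <- list(paste0("u", i), "M", 900 + i * 10,
                                     910 + i * 10, "forward", "libA", NA)
  }
  lay <- do.call(toy_layout, rows)
  rel <- relevant_reads_dcc("M", lay)
  expect_setequal(rel$read_id, paste0("e", 1:4))
})

test_that("implied fragments follow the 5' geometry", {
  f <- implied_fragment(2000L, "forward", 5000L, "reverse")
  expect_equal(f$size, 3000L)
  expect_true(f$oriented_properly)
  f <- implied_fragment(5000L, "forward", 2000L, "reverse")
  expect_false(f$oriented_properly)  # pointing away
  f <- implied_fragment(3000L, "forward", 3000L, "reverse")
  expect_equal(f$size, 0L)
  expect_true(f$oriented_properly)
})

test_that("location likelihood equals the independent product oracle", {
  set.seed(41)
  models <- list(
    libA = normal_model(data.frame(library_id = "libA", ta_mean = 4000,
                                   ta_sd = 400)),
    libB = fit_empirical(rnorm(2000, 9000, 800), "libB"))
  for (rep in 1:20) {
    n <- sample(1:10, 1)
    fr <- data.table::data.table(
      library_id = sample(c("libA", "libB"), n, replace = TRUE),
      size = sample(c(4000, 9000, 2500, 60000), n, replace = TRUE) +
        rnorm(n, 0, 300),
      oriented_properly = runif(n) > 0.2)
    ## oracle: direct product of per-pair probabilities, taken to log at
    ## the end
    prod_p <- 1
    for (i in seq_len(n)) {
      m <- models[[fr$library_id[i]]]
      p <- if (!fr$oriented_properly[i]) {
        m$floor
      } else if (m$kind == "normal") {
        max(dnorm(fr$size[i], m$mu, m$sigma), m$floor)
      } else {
        idx <- match(as.integer(round(fr$size[i])), m$grid)
        max(if (is.na(idx)) 0 else m$density[idx], m$floor)
      }
      prod_p <- prod_p * p
    }
    ll <- location_likelihood(fr, models)
    expect_equal(ll, log(prod_p), tolerance = 1e-9)
  }
})

test_that("likelihood extremes: all at the mode and all at the floor", {
  models <- toy_models()
  n <- 7
  at_mode <- data.table::data.table(library_id = "libA",
                                    size = rep(4000, n),
                                    oriented_properly = TRUE)
  expect_equal(location_likelihood(at_mode, models),
               n * log(dnorm(4000, 4000, 400)))
  floored <- data.table::data.table(library_id = "libA",
                                    size = rep(40000, n),
                                    oriented_properly = TRUE)
  expect_equal(location_likelihood(floored, models),
               n * log(models$libA$floor))
  ## a fragment with equal probability in two layouts never changes the
  ## comparison
  extra <- data.table::data.table(library_id = "libA", size = 4100,
                                  oriented_properly = TRUE)
  d <- location_likelihood(rbind(at_mode, extra), models) -
    location_likelihood(rbind(floored, extra), models)
  expect_equal(d, location_likelihood(at_mode, models) -
                 location_likelihood(floored, models))
  expect_error(location_likelihood(
    data.table::data.table(library_id = "nope", size = 1,
                           oriented_properly = TRUE), models),
    "no library model")
})

test_that("candidates without relevant pairs are kept with a flag", {
  pl <- toy_agp(data.table::data.table(
    contig_id = c("B", "M"), chrom = "chr1",
    start = c(0L, 10100L), end = c(10000L, 11100L),
    orientation = "forward"))$placements
  cand <- falsedup:::new_candidate(
    "DCC", "M", "B",
    falsedup:::linear_hit("M", "B", 0L, 1000L, 4000L, 5000L,
                          identity = 0.99), pl)
  lay <- toy_layout(list("r1", "M", 100, 200, "forward", "libA", NA))
  call <- classify_candidate(cand, lay, pl, toy_models())
  expect_equal(call$verdict, "kept")
  expect_equal(call$flag, "no_evidence")
  expect_equal(call$n_relevant, 0L)
})

test_that("planted mis-assemblies are called and true duplications kept", {
  b <- tiny_bundle()
  res <- tiny_result()
  calls <- res$detect$calls
  f <- b$truth$features
  mis <- unique(calls[verdict == "mis_assembled", moved_contig_id])
  dcc <- f[pattern == "DCC_misassembly", moved_contig]
  doc <- f[pattern == "DOC_misassembly", moved_contig]
  dup <- f[pattern == "true_duplication", moved_contig]
  expect_gte(mean(dcc %in% mis), 0.8)
  expect_gte(mean(doc %in% mis), 0.8)
  expect_equal(sum(dup %in% mis), 0)
})

test_that("verdicts are invariant to translation and strand flip", {
  b <- tiny_bundle()
  res <- tiny_result()
  calls <- res$detect$calls
  pick <- calls[verdict == "mis_assembled" & kind == "DCC"][1]
  cand <- res$detect$candidates[[pick$cand_idx]]
  pl <- b$agp$placements
  models <- res$detect$models
  base <- classify_candidate(cand, b$layout, pl, models)

  ## translation: shift the whole chromosome right by 10 kb
  pl_t <- data.table::copy(pl)[, `:=`(start = start + 10000L,
                                      end = end + 10000L)]
  cand_t <- falsedup:::new_candidate(cand$kind, cand$moved_contig_id,
                                     cand$anchor_contig_id, cand$hit, pl_t)
  shifted <- classify_candidate(cand_t, b$layout, pl_t, models)
  expect_equal(shifted$verdict, base$verdict)
  expect_equal(shifted$loglik_merged - shifted$loglik_original,
               base$loglik_merged - base$loglik_original, tolerance = 1e-9)

  ## strand flip: mirror every placement within the chromosome span and
  ## toggle orientations; read layouts are untouched
  span <- max(pl$end)
  pl_f <- data.table::copy(pl)[, `:=`(
    start = span - end, end = span - start,
    orientation = ifelse(orientation == "forward", "reverse", "forward"))]
  ## the hit lives in oriented frames, which also flip: rebuild from the
  ## flipped oriented sequences
  a_pl <- pl_f[contig_id == cand$anchor_contig_id]
  m_pl <- pl_f[contig_id == cand$moved_contig_id]
  hit_f <- align_pair(
    falsedup:::oriented_seq(b$contigs, cand$moved_contig_id,
                            m_pl$orientation),
    falsedup:::oriented_seq(b$contigs, cand$anchor_contig_id,
                            a_pl$orientation),
    query_id = cand$moved_contig_id,
    target_id = cand$anchor_contig_id)[[1]]
  cand_f <- falsedup:::new_candidate(cand$kind, cand$moved_contig_id,
                                     cand$anchor_contig_id, hit_f, pl_f)
  flipped <- classify_candidate(cand_f, b$layout, pl_f, models)
  expect_equal(flipped$verdict, base$verdict)
})
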