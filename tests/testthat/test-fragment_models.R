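test_that("fragment observations measure 5'-to-5' distances per library", {
  pl <- data.table::data.table(
    contig_id = c("A", "B"), chrom = c("chr1", "chr2"),
    start = c(0L, 0L), end = c(100000L, 100000L),
    orientation = "forward", placed = TRUE)
  lay <- toy_layout(
    list("r1", "A", 1000, 1100, "forward", "libA", "r2"),
    list("r2", "A", 3900, 4000, "reverse", "libA", "r1"),
    list("r3", "A", 6000, 6100, "forward", "libA", "r4"),
    list("r4", "A", 9000, 9100, "forward", "libA", "r3"),  # same direction
    list("r5", "A", 0, 100, "forward", "libA", "r6"),
    list("r6", "B", 5000, 5100, "reverse", "libA", "r5"))  # other chrom
  fr <- collect_fragments(lay, pl)
  expect_equal(nrow(fr), 2L)
  f12 <- fr[read_id == "r1"]
  expect_equal(f12$size, 2999)  # 5' ends at 1000 and 3999
  expect_true(f12$oriented_properly)
  expect_false(fr[read_id == "r3", oriented_properly])
})

test_that("the KS decision keeps the nominal model unless it is rejected", {
  meta <- data.frame(library_id = "l", ta_mean = 5000, ta_sd = 1000)
  expect_equal(ks_decision(c(5000), meta), "keep_normal")
  set.seed(21)
  ## a shifted, tighter library is detected
  expect_equal(ks_decision(rnorm(10000, 4500, 400), meta), "re_estimate")
  ## under the null the decision is mostly keep (a fuller calibration is in
  ## the acceptance suite)
  keeps <- mean(replicate(100, {
    ks_decision(rnorm(1000, 5000, 1000), meta) == "keep_normal"
  }))
  expect_gt(keeps, 0.9)
})

test_that("spline re-estimation recovers the library parameters", {
  set.seed(31)
  m <- fit_empirical(rnorm(10000, 3000, 300), "x")
  expect_equal(m$kind, "empirical")
  expect_lt(abs(m$mu - 3000) / 3000, 0.01)
  expect_lt(abs(m$sigma - 300) / 300, 0.05)
  expect_equal(sum(m$density), 1, tolerance = 1e-6)
  expect_true(all(m$density >= 0))
})

test_that("smoothing preserves well-separated modes of a mixed library", {
  set.seed(32)
  m <- fit_empirical(c(rnorm(5000, 3000, 300), rnorm(5000, 9000, 300)), "b")
  d <- m$density
  locmax <- which(diff(sign(diff(d))) == -2) + 1L
  modes <- m$grid[locmax[d[locmax] > 0.2 * max(d)]]
  expect_true(any(abs(modes - 3000) < 300))
  expect_true(any(abs(modes - 9000) < 300))
})

test_that("identical observations give a degenerate spike model", {
  m <- fit_empirical(rep(500, 50), "s")
  expect_equal(m$grid, 500L)
  expect_equal(m$density, 1)
  expect_lt(m$floor, 1)
  expect_gt(m$floor, 0)
})

## independent brute-force floor oracle: search over candidate floors on a
## discretized pmf
brute_floor <- function(p, tail) {
  cand <- sort(unique(p))
  best <- cand[1]
  for (m in cand) {
    if (sum(p[p < m]) <= tail) best <- m else break
  }
  best
}

test_that("the probability floor excludes exactly the prescribed tail", {
  for (tail in c(1e-4, 0.05)) {
    for (sigma in c(100, 400, 1000)) {
      model <- normal_model(data.frame(library_id = "l", ta_mean = 10 * sigma,
                                       ta_sd = sigma), floor_tail = tail)
      grid <- seq(floor(10 * sigma - 8 * sigma), ceiling(10 * sigma + 8 * sigma))
      p <- dnorm(grid, 10 * sigma, sigma)
      expect_equal(model$floor, brute_floor(p, tail), tolerance = 1e-12)
      ## tight maximality: mass below the floor within the tail, and the
      ## next larger candidate floor violates it
      expect_lte(sum(p[p < model$floor]), tail)
      nxt <- min(p[p > model$floor])
      expect_gt(sum(p[p < nxt]), tail)
      ## the floor corresponds to ~3.89 SD (1e-4) or ~1.96 SD (0.05)
      z <- sqrt(-2 * log(model$floor * sigma * sqrt(2 * pi)))
      expect_equal(z, qnorm(1 - tail / 2), tolerance = 0.02)
    }
  }
})

test_that("fragment probabilities are floored and keep logs finite", {
  m <- toy_models()[["libA"]]
  expect_gt(model_prob(m, 4000, TRUE), m$floor)
  expect_equal(model_prob(m, 4000 + 10 * 400, TRUE), m$floor)  # 10 SD away
  expect_equal(model_prob(m, 4000, FALSE), m$floor)  # disoriented
  sizes <- seq(-1000, 50000, by = 117)
  p <- model_prob(m, sizes, rep(c(TRUE, FALSE), length.out = length(sizes)))
  expect_true(all(p >= m$floor))
  expect_true(all(is.finite(log(p))))

  ## empirical model: outside-grid sizes fall to the floor
  set.seed(33)
  me <- fit_empirical(rnorm(5000, 3000, 300), "x")
  expect_equal(model_prob(me, 100, TRUE), me$floor)
  expect_gt(model_prob(me, 3000, TRUE), me$floor)
})

test_that("model selection applies the re-estimation rule per library", {
  set.seed(34)
  libs <- data.table::data.table(
    library_id = c("good", "shifted", "sparse"),
    ta_mean = c(4000, 4000, 4000), ta_sd = c(400, 400, 400),
    read_count = c(2000L, 2000L, 40L))
  fr <- data.table::rbindlist(list(
    data.table::data.table(library_id = "good", read_id = "x", mate_id = "y",
                           size = rnorm(2000, 4000, 400),
                           oriented_properly = TRUE),
    data.table::data.table(library_id = "shifted", read_id = "x",
                           mate_id = "y", size = rnorm(2000, 3500, 200),
                           oriented_properly = TRUE),
    data.table::data.table(library_id = "sparse", read_id = "x",
                           mate_id = "y", size = rnorm(40, 3000, 100),
                           oriented_properly = TRUE)))
  models <- build_library_models(fr, libs)
  expect_equal(models$good$kind, "normal")
  expect_equal(models$shifted$kind, "empirical")
  ## too few observations for a spline even though the KS test rejects
  expect_equal(models$sparse$kind, "normal")
})

test_that("library models round-trip through JSON", {
  set.seed(35)
  models <- list(
    n = normal_model(data.frame(library_id = "n", ta_mean = 4000,
                                ta_sd = 400)),
    e = fit_empirical(rnorm(2000, 3000, 300), "e"))
  f <- tempfile(fileext = ".json")
  write_library_models(models, f)
  back <- read_library_models(f)
  expect_equal(back$n$mu, 4000)
  expect_equal(back$n$floor, models$n$floor)
  expect_equal(back$e$density, models$e$density, tolerance = 1e-12)
  expect_equal(model_prob(back$e, 3000, TRUE),
               model_prob(models$e, 3000, TRUE))
})
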