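## fragment_models: per-library fragment-size probability models.
## Default is the nominal (Trace-Archive) normal; when a one-sample KS test
## rejects it at alpha = 0.01 and enough observations exist, an empirical
## density is re-estimated as a cubic smoothing spline over a 1-bp histogram.
## Every model carries a probability floor: the largest value m such that
## the total mass of fragment sizes with probability below m is at most the
## chosen tail (1e-4 for placed-contig analysis, 0.05 for unplaced contigs).

#' Collect fragment-size observations per library
#'
#' One observation per mate pair whose two reads are both placed on the same
#' chromosome: the distance between the projected 5' ends, and whether the
#' reads point toward each other.
#'
#' @param layout Read layout (see [read_layout()]).
#' @param placements Contig placements.
#' @return data.table: library_id, read_id, mate_id, size, oriented_properly.
#' @export
collect_fragments <- function(layout, placements) {
  proj <- project_reads(layout, placements)
  pr <- proj[placed & !is.na(mate_id)]
  m <- merge(pr, proj[, .(mate_id_key = read_id, m_placed = placed,
                          m_chrom = chrom, m_pos5 = pos5,
                          m_orient = chrom_orient)],
             by.x = "mate_id", by.y = "mate_id_key")
  m <- m[m_placed & chrom == m_chrom & read_id < mate_id]
  m[, size := abs(m_pos5 - pos5)]
  m[, oriented_properly := fragment_proper(pos5, chrom_orient,
                                           m_pos5, m_orient)]
  m[, .(library_id, read_id, mate_id, size, oriented_properly)]
}

## a pair is properly oriented iff the reads face each other
fragment_proper <- function(p1, o1, p2, o2) {
  (p1 < p2 & o1 == "forward" & o2 == "reverse") |
  (p2 < p1 & o2 == "forward" & o1 == "reverse") |
  (p1 == p2 & o1 != o2)
}

#' Decide whether a library's fragment distribution needs re-estimation
#'
#' One-sample Kolmogorov-Smirnov test of the properly oriented fragment
#' sizes against Normal(ta_mean, ta_sd).  The nominal model is kept unless
#' the test rejects at \code{alpha}.
#'
#' @param sizes Numeric vector of fragment sizes (properly oriented pairs).
#' @param meta One-row library metadata (ta_mean, ta_sd).
#' @param alpha Rejection level.
#' @return \code{"re_estimate"} or \code{"keep_normal"}.
#' @export
ks_decision <- function(sizes, meta, alpha = 0.01) {
  if (length(sizes) < 2L) return("keep_normal")
  p <- suppressWarnings(
    stats::ks.test(sizes, "pnorm", mean = meta$ta_mean, sd = meta$ta_sd)$p.value)
  if (is.na(p)) return("keep_normal")
  if (p < alpha) "re_estimate" else "keep_normal"
}

#' Fit an empirical fragment-size density by spline smoothing
#'
#' Two-pass outlier trimming (estimate mean/SD, drop sizes more than
#' \code{trim_sd} standard deviations away, re-estimate), then a cubic
#' smoothing spline (generalized cross-validation, the
#' \code{stats::smooth.spline} default) fit to the relative frequencies of a
#' 1-bp histogram; negative smoothed values are clamped to zero and the
#' density renormalized to sum to one over its integer grid.
#'
#' @param sizes Properly oriented fragment sizes.
#' @param library_id Identifier recorded in the model.
#' @param grid_step Histogram bin width in bp.
#' @param trim_sd Outlier trim threshold in SD units.
#' @param floor_tail Cumulative-mass tail defining the probability floor.
#' @return A \code{library_model} of kind \code{"empirical"}.
#' @export
fit_empirical <- function(sizes, library_id = "lib", grid_step = 1L,
                          trim_sd = 4, floor_tail = 1e-4) {
  stopifnot(length(sizes) >= 1L)
  sizes <- as.numeric(sizes)
  mu1 <- mean(sizes); sd1 <- stats::sd(sizes)
  if (is.na(sd1) || sd1 == 0) {
    ## all observations identical: degenerate spike model
    grid <- as.integer(round(mu1))
    model <- new_library_model(library_id, "empirical", mu = mu1, sigma = 0,
                               grid = grid, density = 1)
    model$floor <- floor_tail * 1
    model$floor_tail <- floor_tail
    return(model)
  }
  keep <- abs(sizes - mu1) <= trim_sd * sd1
  s <- sizes[keep]
  mu2 <- mean(s); sd2 <- stats::sd(s)
  grid <- seq(floor(min(s)), ceiling(max(s)), by = grid_step)
  counts <- tabulate(findInterval(s, grid), nbins = length(grid))
  freq <- counts / sum(counts)
  fit <- stats::smooth.spline(grid, freq)
  dens <- stats::predict(fit, grid)$y
  dens[dens < 0] <- 0
  if (sum(dens) == 0) dens <- freq  # pathological fit: fall back to histogram
  dens <- dens / sum(dens)
  model <- new_library_model(library_id, "empirical",
                             mu = sum(grid * dens), sigma = sqrt(
                               pmax(sum(grid^2 * dens) - sum(grid * dens)^2, 0)),
                             grid = as.integer(grid), density = dens)
  model$floor <- compute_floor(model, floor_tail)
  model$floor_tail <- floor_tail
  model
}

#' Construct a normal (Trace-Archive) library model
#'
#' @param meta One-row library metadata (library_id, ta_mean, ta_sd).
#' @param floor_tail Cumulative-mass tail for the floor.
#' @return A \code{library_model} of kind \code{"normal"}.
#' @export
normal_model <- function(meta, floor_tail = 1e-4) {
  model <- new_library_model(meta$library_id, "normal",
                             mu = meta$ta_mean, sigma = meta$ta_sd,
                             grid = NULL, density = NULL)
  model$floor <- compute_floor(model, floor_tail)
  model$floor_tail <- floor_tail
  model
}

new_library_model <- function(library_id, kind, mu, sigma, grid, density) {
  structure(list(library_id = library_id, kind = kind, mu = mu, sigma = sigma,
                 grid = grid, density = density, floor = NA_real_,
                 floor_tail = NA_real_),
            class = "library_model")
}

#' Compute a model's probability floor
#'
#' The largest value m such that the total probability mass of fragment
#' sizes with probability below m is at most \code{tail}.  Far-distant
#' outliers are not counted: the support considered is the (already
#' 4-SD-trimmed) grid for empirical models, and roughly +/- 8 SD for the
#' discretized normal.
#'
#' @param model A \code{library_model}.
#' @param tail Cumulative-mass tail (1e-4 placed, 0.05 unplaced).
#' @return The floor probability (> 0).
#' @export
compute_floor <- function(model, tail = 1e-4) {
  p <- if (model$kind == "normal") {
    grid <- seq(floor(model$mu - 8 * model$sigma),
                ceiling(model$mu + 8 * model$sigma))
    stats::dnorm(grid, model$mu, model$sigma)
  } else {
    model$density
  }
  p <- p[p > 0]
  sp <- sort(p)
  cum <- cumsum(sp)
  k <- sum(cum <= tail)
  if (k >= length(sp)) k <- length(sp) - 1L
  if (k < length(sp) && k >= 0L && (k + 1L) <= length(sp)) {
    m <- sp[k + 1L]
  } else {
    m <- sp[1L]
  }
  if (m >= max(sp)) {
    ## degenerate (e.g. single-atom) model: a small fraction of the top mass
    m <- tail * max(sp)
  }
  m
}

#' Fragment-size probability under a library model
#'
#' Disoriented pairs (not pointing toward each other) receive the floor;
#' properly oriented pairs receive the model density at their size, but
#' never less than the floor.  This keeps every log-likelihood finite and
#' prevents extreme distances from dominating likelihood comparisons.
#'
#' @param model A \code{library_model}.
#' @param size Fragment size(s), bp.
#' @param oriented_properly Logical vector.
#' @param floor Optional floor override (e.g. the 0.05-tail floor for the
#'   unplaced-contig analysis).
#' @return Numeric vector of probabilities, all >= the floor.
#' @export
model_prob <- function(model, size, oriented_properly = TRUE, floor = NULL) {
  fl <- if (is.null(floor)) model$floor else floor
  p <- if (model$kind == "normal") {
    stats::dnorm(size, model$mu, model$sigma)
  } else {
    idx <- match(as.integer(round(size)), model$grid)
    d <- model$density[idx]
    d[is.na(d)] <- 0
    d
  }
  p <- pmax(p, fl)
  p[!oriented_properly] <- fl
  p
}

#' Build fragment-size models for every library
#'
#' Applies the decision rule per library: keep the nominal normal model
#' unless the KS test rejects it at \code{alpha} and at least
#' \code{min_obs} properly oriented observations are available for spline
#' re-estimation.
#'
#' @param fragments Observations from [collect_fragments()].
#' @param libraries Library metadata table.
#' @param alpha KS rejection level.
#' @param min_obs Minimum observations for spline fitting.
#' @param floor_tail Floor tail (1e-4 placed analysis).
#' @return Named list of \code{library_model} objects.
#' @export
build_library_models <- function(fragments, libraries, alpha = 0.01,
                                 min_obs = 500L, floor_tail = 1e-4) {
  models <- list()
  for (i in seq_len(nrow(libraries))) {
    meta <- libraries[i]
    sizes <- fragments[library_id == meta$library_id &
                       oriented_properly == TRUE, size]
    decision <- ks_decision(sizes, meta, alpha)
    models[[meta$library_id]] <-
      if (decision == "re_estimate" && length(sizes) >= min_obs) {
        fit_empirical(sizes, meta$library_id, floor_tail = floor_tail)
      } else {
        normal_model(meta, floor_tail = floor_tail)
      }
  }
  models
}

#' Dump library models to JSON
#' @param models Named list of \code{library_model}s.
#' @param path Output path.
#' @export
write_library_models <- function(models, path) {
  obj <- lapply(models, function(m) {
    list(library_id = m$library_id, kind = m$kind, mu = m$mu, sigma = m$sigma,
         grid = m$grid, density = m$density, floor = m$floor,
         floor_tail = m$floor_tail)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load library models from JSON
#' @param path JSON path written by [write_library_models()].
#' @return Named list of \code{library_model}s.
#' @export
read_library_models <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(obj, function(m) {
    mod <- new_library_model(m$library_id, m$kind, m$mu, m$sigma,
                             if (is.null(m$grid)) NULL else as.integer(m$grid),
                             m$density)
    mod$floor <- m$floor
    mod$floor_tail <- m$floor_tail
    mod
  })
  stats::setNames(models, vapply(models, `[[`, "", "library_id"))
}

#' Diagnostic density plot for a library model
#' @param model A \code{library_model}.
#' @param observations Optional raw sizes to overlay as a histogram.
#' @export
plot_library_model <- function(model, observations = NULL) {
  if (model$kind == "normal") {
    x <- seq(model$mu - 5 * model$sigma, model$mu + 5 * model$sigma,
             length.out = 500)
    y <- stats::dnorm(x, model$mu, model$sigma)
  } else {
    x <- model$grid; y <- model$density
  }
  graphics::plot(x, y, type = "l", xlab = "fragment size (bp)",
                 ylab = "probability",
                 main = paste0(model$library_id, " (", model$kind, ")"))
  if (!is.null(observations)) {
    h <- graphics::hist(observations, breaks = 100, plot = FALSE)
    graphics::lines(h$mids, h$density * mean(diff(x)), col = "grey50")
  }
  graphics::abline(h = model$floor, lty = 2, col = "red")
  invisible(NULL)
}
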