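# Seed-deterministic synthetic-data generators. Every generator returns the
# data alongside machine-readable planted ground truth so each pipeline
# stage has an end-to-end recovery test without any external downloads.
#
# Defaults encode the study conditions being emulated: 8 bi-daily frames for
# the 14-day Matrigel growth phase, 48 hourly steps for the 48-h eversion
# window, a 26-small / 10-large degradation cohort, and negative-binomial
# counts with lognormal baselines and planted log2 effects.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  expr
}

#' Simulate the Matrigel growth phase of one bot
#'
#' Three archetypes: \code{dormant} (one particle, constant area plus
#' noise), \code{monoclonal} (one particle, exponential area growth) and
#' \code{merger} (\code{founders} spheroids growing while approaching a
#' common point; whenever two particles come within the sum of their
#' equivalent radii they are replaced by one particle with the summed area
#' at the area-weighted centroid).
#'
#' @param archetype \code{"dormant"}, \code{"monoclonal"} or
#'   \code{"merger"}.
#' @param n_frames number of frames (default 8: bi-daily imaging, 14 days).
#' @param founders founder count for \code{merger} (>= 2); 1 otherwise.
#' @param growth_rate per-frame multiplicative area growth (default 1.35
#'   for the expanding archetypes; dormant uses 1).
#' @param init_area founder area, pixel^2 (default 120, single-cell scale).
#' @param noise_sd additive area noise SD, pixel^2 (default 0).
#' @param approach_speed centroid approach speed toward the cohort center,
#'   pixels/frame (merger only; default set so founders meet by ~60\% of
#'   the time course).
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @return list with \code{particles} (a particle table) and \code{truth}
#'   (list: \code{archetype}, \code{merge_events}, \code{fin_area}).
#' @export
gen_growth <- function(archetype = c("dormant", "monoclonal", "merger"),
                       n_frames = 8, founders = 2, growth_rate = 1.35,
                       init_area = 120, noise_sd = 0,
                       approach_speed = NULL, seed = NULL) {
  archetype <- match.arg(archetype)
  stopifnot(n_frames >= 2, init_area > 0, is.finite(growth_rate))
  if (archetype != "merger") founders <- 1L
  if (archetype == "merger" && founders < 2L)
    stop("gen_growth: merger needs >= 2 founders")
  with_seed(seed, {
    if (archetype != "merger") {
      rate <- if (archetype == "dormant") 1 else growth_rate
      area <- init_area * rate^(0:(n_frames - 1)) +
        rnorm(n_frames, 0, noise_sd)
      area <- pmax(area, 1)
      tab <- data.frame(frame = 0:(n_frames - 1), label = "F1",
                        x = 0, y = 0, area = area)
      return(list(particles = validate_particle_table(tab),
                  truth = list(archetype = archetype, merge_events = 1L,
                               fin_area = area[n_frames])))
    }
    # merger: founders on a circle, drifting to the origin while growing
    r0 <- 35 * founders
    if (is.null(approach_speed)) approach_speed <- r0 / (0.6 * n_frames)
    ang <- 2 * pi * (seq_len(founders) - 1) / founders
    parts <- data.frame(label = paste0("F", seq_len(founders)),
                        x = r0 * cos(ang), y = r0 * sin(ang),
                        area = init_area * (1 + runif(founders, -0.1, 0.1)))
    parts$members <- as.list(seq_len(founders))  # founder indices per particle
    rows <- list()
    merge_counter <- 0L
    for (f in 0:(n_frames - 1)) {
      if (f > 0) {
        # grow and approach
        parts$area <- parts$area * growth_rate
        d <- sqrt(parts$x^2 + parts$y^2)
        step <- pmin(approach_speed, d)
        shrink <- ifelse(d > 0, (d - step) / d, 0)
        parts$x <- parts$x * shrink
        parts$y <- parts$y * shrink
        # fuse any particles whose disks touch (connected components)
        repeat {
          n <- nrow(parts)
          if (n < 2) break
          req <- sqrt(parts$area / pi)
          fused <- FALSE
          for (i in seq_len(n - 1)) {
            for (j in (i + 1):n) {
              dij <- sqrt((parts$x[i] - parts$x[j])^2 +
                          (parts$y[i] - parts$y[j])^2)
              if (dij <= req[i] + req[j]) {
                merge_counter <- merge_counter + 1L
                wa <- parts$area[c(i, j)]
                newrow <- data.frame(
                  label = paste0("M", f, "_", merge_counter),
                  x = sum(parts$x[c(i, j)] * wa) / sum(wa),
                  y = sum(parts$y[c(i, j)] * wa) / sum(wa),
                  area = sum(wa))
                newrow$members <- list(sort(unlist(parts$members[c(i, j)])))
                parts <- rbind(parts[-c(i, j), , drop = FALSE], newrow)
                fused <- TRUE
                break
              }
            }
            if (fused) break
          }
          if (!fused) break
        }
      }
      obs_area <- pmax(parts$area + rnorm(nrow(parts), 0, noise_sd), 1)
      rows[[length(rows) + 1L]] <-
        data.frame(frame = f, label = parts$label,
                   x = parts$x, y = parts$y, area = obs_area)
    }
    tab <- do.call(rbind, rows)
    # final spheroid = largest particle in the last frame
    lastf <- tab[tab$frame == n_frames - 1, ]
    fin <- lastf[which.max(lastf$area), ]
    fin_members <- parts$members[[which(parts$label == fin$label)]]
    list(particles = validate_particle_table(tab),
         truth = list(archetype = archetype,
                      merge_events = length(fin_members),
                      fin_area = fin$area))
  })
}

#' Simulate a cohort of growth time courses
#'
#' Defaults mirror the observed archetype mix (16 dormant, 9 merger,
#' 5 monoclonal). Cohort mergers fuse a single pair of precursors
#' (\code{founders = 2}, the typical observed merge); other founder counts
#' are available through \code{\link{gen_growth}} directly.
#'
#' @param n named integer vector with archetype counts.
#' @param n_frames,growth_rate,noise_sd passed to \code{\link{gen_growth}}.
#' @param seed RNG seed.
#' @return list with \code{tables} (named list of particle tables) and
#'   \code{archetype} (named character vector of planted labels).
#' @export
gen_growth_cohort <- function(n = c(dormant = 16, merger = 9, monoclonal = 5),
                              n_frames = 8, growth_rate = 1.35,
                              noise_sd = 2, seed = NULL) {
  with_seed(seed, {
    labels <- rep(names(n), n)
    tables <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      sim <- gen_growth(labels[i], n_frames = n_frames, founders = 2L,
                        growth_rate = growth_rate * exp(rnorm(1, 0, 0.015)),
                        init_area = 120 * exp(rnorm(1, 0, 0.1)),
                        noise_sd = noise_sd, seed = NULL)
      tables[[i]] <- sim$particles
    }
    names(tables) <- sprintf("bot%02d", seq_along(labels))
    list(tables = tables,
         archetype = stats::setNames(labels, names(tables)))
  })
}

#' Simulate an eversion trajectory
#'
#' \code{displacer}: correlated random walk (lognormal step lengths,
#' wrapped-normal heading increments). \code{static}: independent isotropic
#' jitter around the origin (no net displacement). \code{circle} and
#' \code{line} are exact geometric presets for analytic checks: the
#' vertices of a regular polygon traversed in order, and uniform steps
#' along +x.
#'
#' @param mode one of \code{"displacer"}, \code{"static"}, \code{"circle"},
#'   \code{"line"}.
#' @param n_steps number of steps (default 48: hourly frames, 48 h).
#' @param step_meanlog,step_sdlog lognormal step-length parameters for the
#'   displacer (defaults log(8), 0.35 pixels).
#' @param heading_sd wrapped-normal SD of heading increments, radians
#'   (default 0.5).
#' @param jitter_sd static-mode jitter SD, pixels (default 0.8).
#' @param n_sides polygon sides for the circle preset (default 24).
#' @param radius circle radius / line step scale, pixels (default 50 / 5).
#' @param seed RNG seed.
#' @return list with \code{trajectory} (data frame frame/x/y of
#'   \code{n_steps + 1} points) and \code{mode}.
#' @export
gen_trajectory <- function(mode = c("displacer", "static", "circle", "line"),
                           n_steps = 48, step_meanlog = log(8),
                           step_sdlog = 0.35, heading_sd = 0.5,
                           jitter_sd = 0.8, n_sides = 24, radius = 50,
                           seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_steps >= 3)
  with_seed(seed, {
    tt <- 0:n_steps
    xy <- switch(mode,
      line = cbind(x = 5 * tt, y = 0 * tt),
      circle = {
        a <- 2 * pi * tt / n_sides
        cbind(x = radius * cos(a), y = radius * sin(a))
      },
      static = cbind(x = rnorm(n_steps + 1, 0, jitter_sd),
                     y = rnorm(n_steps + 1, 0, jitter_sd)),
      displacer = {
        steps <- rlnorm(n_steps, step_meanlog, step_sdlog)
        h <- cumsum(c(runif(1, -pi, pi), rnorm(n_steps - 1, 0, heading_sd)))
        cbind(x = cumsum(c(0, steps * cos(h))),
              y = cumsum(c(0, steps * sin(h))))
      })
    list(trajectory = data.frame(frame = tt, x = xy[, "x"], y = xy[, "y"]),
         mode = mode)
  })
}

#' Simulate a cohort of eversion trajectories
#'
#' @param n named counts per mode (default 40 displacers, 40 statics).
#' @param n_steps steps per trajectory.
#' @param seed RNG seed.
#' @param ... passed to \code{\link{gen_trajectory}}.
#' @return list with \code{trajectories} (named list) and \code{mode}
#'   (named character vector of planted labels).
#' @export
gen_trajectory_cohort <- function(n = c(displacer = 40, static = 40),
                                  n_steps = 48, seed = NULL, ...) {
  with_seed(seed, {
    labels <- rep(names(n), n)
    trajs <- lapply(labels, function(m)
      gen_trajectory(m, n_steps = n_steps, seed = NULL, ...)$trajectory)
    names(trajs) <- sprintf("bot%02d", seq_along(labels))
    list(trajectories = trajs, mode = stats::setNames(labels, names(trajs)))
  })
}

#' Simulate size-dependent degradation of one bot
#'
#' Linear decay with additive noise:
#' \code{area(t) = max(0, A0 - rate * t + eps_t)}, \code{t = 0, 1, ...}.
#' The planted lifespan is the number of frames before the area first drops
#' below \code{threshold} (the same truncation rule
#' \code{\link{degradation_features}} applies).
#'
#' @param A0 initial area, pixel^2.
#' @param rate decay rate, pixel^2/frame (shared across bots in the source
#'   observation: similar degradation rate regardless of size).
#' @param noise_sd additive noise SD (default 0).
#' @param threshold untrackability threshold (default 1 pixel^2).
#' @param n_frames series length (default long enough to reach zero).
#' @param seed RNG seed.
#' @return list with \code{areas} and \code{truth} (list with
#'   \code{lifespan}).
#' @export
gen_decay <- function(A0, rate, noise_sd = 0, threshold = 1,
                      n_frames = NULL, seed = NULL) {
  stopifnot(A0 > 0, rate > 0, noise_sd >= 0)
  if (is.null(n_frames)) n_frames <- ceiling(A0 / rate) + 3L
  with_seed(seed, {
    tt <- 0:(n_frames - 1)
    areas <- pmax(0, A0 - rate * tt + rnorm(n_frames, 0, noise_sd))
    below <- which(areas < threshold)
    lifespan <- if (length(below)) below[1L] - 1L else length(areas)
    list(areas = areas, truth = list(lifespan = lifespan))
  })
}

#' Simulate a degradation cohort of small and large bots
#'
#' Defaults mirror the observed group sizes (26 small, 10 large) with a
#' shared decay rate, so larger initial areas live longer.
#'
#' @param n named counts, \code{c(small = ..., large = ...)}.
#' @param A0_small,A0_large uniform ranges of initial areas.
#' @param rate shared decay rate (pixel^2/frame).
#' @param noise_sd additive area noise SD.
#' @param threshold untrackability threshold.
#' @param seed RNG seed.
#' @return list with \code{series} (named list of area vectors) and
#'   \code{size_class} (named planted labels).
#' @export
gen_decay_cohort <- function(n = c(small = 26, large = 10),
                             A0_small = c(800, 1500),
                             A0_large = c(4000, 6500),
                             rate = 60, noise_sd = 10, threshold = 40,
                             seed = NULL) {
  with_seed(seed, {
    labels <- rep(names(n), n)
    series <- lapply(labels, function(cl) {
      rng <- if (cl == "small") A0_small else A0_large
      gen_decay(runif(1, rng[1], rng[2]), rate = rate, noise_sd = noise_sd,
                threshold = threshold, seed = NULL)$areas
    })
    names(series) <- sprintf("bot%02d", seq_along(labels))
    list(series = series, size_class = stats::setNames(labels, names(series)))
  })
}

#' Simulate a counts matrix with planted structure
#'
#' Negative-binomial counts with lognormal gene baselines, a planted set of
#' silent genes (identically zero), planted upregulated genes in one
#' condition with a fixed log2 effect, per-gene lengths and phylostratum
#' assignments, a morula table whose overlap with the planted DEG set is a
#' stated fraction, and per-sample depth variation.
#'
#' @param n_genes total genes (default 2000).
#' @param n_silent genes with zero counts everywhere (default 10\%).
#' @param conditions named integer vector: samples per condition (default
#'   \code{c(Progenitor = 4, Day0 = 4)}); planted DE upregulates the second
#'   condition relative to the first.
#' @param n_de planted upregulated genes (default 200).
#' @param de_effect planted log2 effect size (default 3).
#' @param dispersion NB dispersion (default 0.05).
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of expressed
#'   baseline mean counts (defaults log(200), 1).
#' @param depth_sdlog lognormal SD of per-sample depth factors (default
#'   0.15).
#' @param stratum_probs probabilities over \code{\link{phylostrata}()} for
#'   gene-age assignment (default weighted toward the ancient strata).
#' @param morula_de_overlap fraction of planted DEGs also in the morula set
#'   (default 0.134).
#' @param morula_background_frac fraction of non-DE genes in the morula set
#'   (default 0.2).
#' @param seed RNG seed.
#' @return list with \code{counts}, \code{condition}, \code{annotation}
#'   (gene_id, length_bp, phylostratum), \code{morula} (named RPKM-scale
#'   values) and \code{truth} (planted gene sets and per-stratum counts).
#' @export
gen_counts <- function(n_genes = 2000, n_silent = round(0.1 * n_genes),
                       conditions = c(Progenitor = 4, Day0 = 4),
                       n_de = 200, de_effect = 3, dispersion = 0.05,
                       baseline_meanlog = log(200), baseline_sdlog = 1,
                       depth_sdlog = 0.15,
                       stratum_probs = NULL,
                       morula_de_overlap = 0.134,
                       morula_background_frac = 0.2,
                       seed = NULL) {
  stopifnot(length(conditions) >= 2, n_silent < n_genes,
            n_de <= n_genes - n_silent, dispersion > 0)
  if (is.null(stratum_probs)) {
    stratum_probs <- c(0.22, 0.18, rep(0.6 / 17, 17))
  }
  stopifnot(length(stratum_probs) == 19)
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    samples <- unlist(lapply(names(conditions), function(cn)
      paste0(cn, "_", seq_len(conditions[[cn]]))))
    cond <- stats::setNames(rep(names(conditions), conditions), samples)

    silent <- sort(sample(n_genes, n_silent))
    expressed <- setdiff(seq_len(n_genes), silent)
    de <- sort(sample(expressed, n_de))

    base <- numeric(n_genes)
    base[expressed] <- rlnorm(length(expressed), baseline_meanlog,
                              baseline_sdlog)
    # per-condition means; DE genes upregulated in the 2nd condition
    mu <- matrix(base, n_genes, length(conditions),
                 dimnames = list(genes, names(conditions)))
    mu[de, 2L] <- mu[de, 2L] * 2^de_effect

    depth <- rlnorm(length(samples), 0, depth_sdlog)
    counts <- matrix(0L, n_genes, length(samples),
                     dimnames = list(genes, samples))
    for (s in seq_along(samples)) {
      m <- mu[, cond[s]] * depth[s]
      pos <- m > 0
      counts[pos, s] <- rnbinom(sum(pos), mu = m[pos], size = 1 / dispersion)
    }

    strata <- sample(phylostrata(), n_genes, replace = TRUE,
                     prob = stratum_probs)
    annotation <- data.frame(gene_id = genes,
                             length_bp = pmax(200L, round(rlnorm(
                               n_genes, log(1500), 0.5))),
                             phylostratum = strata)

    n_overlap <- round(morula_de_overlap * n_de)
    morula_from_de <- sample(de, n_overlap)
    nonde <- setdiff(expressed, de)
    morula_bg <- sample(nonde, round(morula_background_frac * length(nonde)))
    morula_members <- genes[sort(c(morula_from_de, morula_bg))]
    morula <- stats::setNames(runif(n_genes, 0, 1.5), genes)
    morula[morula_members] <- runif(length(morula_members), 5, 50)

    expressed_per_stratum <- table(factor(strata[expressed],
                                          levels = phylostrata()))
    de_per_stratum <- table(factor(strata[de], levels = phylostrata()))
    list(counts = counts, condition = cond, annotation = annotation,
         morula = morula,
         truth = list(
           expressed_genes = genes[expressed],
           silent_genes = genes[silent],
           de_genes = genes[de],
           de_effect = de_effect,
           expressed_per_stratum = expressed_per_stratum,
           de_per_stratum = de_per_stratum,
           morula_de_overlap = n_overlap / n_de,
           morula_members = morula_members))
  })
}
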