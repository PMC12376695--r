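# Independent oracles used to cross-check the package implementations.
# Each is written as a direct, transparent computation (loops, explicit
# intermediates) deliberately avoiding the code paths it checks.

# mean resultant length by explicit vector summation
oracle_resultant <- function(angles) {
  sx <- 0; sy <- 0
  for (a in angles) { sx <- sx + cos(a); sy <- sy + sin(a) }
  sqrt(sx^2 + sy^2) / length(angles)
}

# 14 eversion features recomputed in a single pass from raw coordinates
oracle_eversion <- function(xy) {
  dx <- diff(xy$x); dy <- diff(xy$y)
  d <- sqrt(dx^2 + dy^2)
  stopifnot(all(d > 0))  # oracle only for always-moving trajectories
  h <- atan2(dy, dx)
  w <- diff(h)
  w <- ((w + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  rbar <- function(a) oracle_resultant(a)
  cmean <- atan2(mean(sin(h)), mean(cos(h)))
  cand <- sort(unique(h))
  dev <- sapply(cand, function(a) {
    dd <- abs(h - a) %% (2 * pi); mean(pmin(dd, 2 * pi - dd))
  })
  cmed <- cand[which.min(dev)]
  csd <- sqrt(-2 * log(min(rbar(h), 1)))
  cv <- function(a) 1 - rbar(a)
  gyr <- if (cv(c(w, -w)) < 1e-9) 0 else 1 - cv(w) / cv(c(w, -w))
  c(mean_angular_speed = mean(w), median_angular_speed = median(w),
    sd_angular_speed = sd(w),
    mean_linear_distance = mean(d), median_linear_distance = median(d),
    sd_linear_distance = sd(d),
    mean_heading = cmean, median_heading = cmed, sd_heading = csd,
    mean_linear_speed = mean(d), median_linear_speed = median(d),
    sd_linear_speed = sd(d),
    straightness = rbar(h), gyration = min(max(gyr, 0), 1))
}

# exhaustive greedy-merge Ward clustering: at every step scan all cluster
# pairs, computing the Ward cost from first principles (increase in total
# within-cluster sum of squares; height = sqrt(2 * increase), matching
# unsquared-input Ward.D2 heights)
oracle_ward <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  heights <- numeric(0)
  partitions <- list()
  ess <- function(idx) {
    pts <- m[idx, , drop = FALSE]
    mu <- colMeans(pts)
    sum(sweep(pts, 2L, mu)^2)
  }
  while (length(clusters) > 1L) {
    best <- NULL; bestc <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        inc <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        cost <- sqrt(2 * inc)
        if (cost < bestc) { bestc <- cost; best <- c(j, i) }
      }
    }
    heights <- c(heights, bestc)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- clusters[-best[2L]]
    lab <- integer(nrow(m))
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1L]] <- lab
  }
  # partitions[[i]] is the partition into n - i clusters
  list(heights = heights, partitions = partitions)
}

# naive TMM materializing every intermediate (M, A, weights, trim masks)
oracle_naive_rank <- function(v) {
  r <- numeric(length(v))
  for (i in seq_along(v))
    r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  r
}

oracle_tmm <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  lib <- colSums(counts)
  uq <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts)))
    uq[s] <- quantile(1e6 * counts[, s] / lib[s], 0.75, names = FALSE)
  cand <- which(abs(uq - mean(uq)) == min(abs(uq - mean(uq))))
  ref <- cand[order(colnames(counts)[cand])][1L]
  f <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    if (s == ref) { f[s] <- 1; next }
    M <- A <- w <- numeric(0)
    for (g in seq_len(nrow(counts))) {
      y <- counts[g, s]; r <- counts[g, ref]
      if (y > 0 && r > 0) {
        py <- y / lib[s]; pr <- r / lib[ref]
        M <- c(M, log2(py / pr))
        A <- c(A, (log2(py) + log2(pr)) / 2)
        w <- c(w, 1 / ((lib[s] - y) / (lib[s] * y) +
                         (lib[ref] - r) / (lib[ref] * r)))
      }
    }
    if (!length(M) || max(abs(M)) < 1e-6) { f[s] <- 1; next }
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    rM <- oracle_naive_rank(M); rA <- oracle_naive_rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    f[s] <- if (any(keep)) 2^(sum(w[keep] * M[keep]) / sum(w[keep])) else 1
  }
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# distinct founding roots of a lineage segment by recursive traversal
oracle_root_ids <- function(g, seg) {
  pars <- g$parents[[seg]]
  if (!length(pars)) return(seg)
  sort(unique(unlist(lapply(pars, function(p) oracle_root_ids(g, p)))))
}

# adjusted Rand index between two labelings (via mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# random counts matrix for TMM checks
random_counts <- function(ng, ns, seed) {
  set.seed(seed)
  m <- matrix(rnbinom(ng * ns, mu = exp(runif(ng, 1, 6)), size = 5), ng, ns,
              dimnames = list(sprintf("g%04d", seq_len(ng)),
                              paste0("S", seq_len(ns))))
  m
}

# hand-built three-founder merge fixture: A and B merge at frame 2, the
# product merges with C at frame 3
merge_fixture <- function() {
  data.frame(
    frame = c(0, 0, 0, 1, 1, 1, 2, 2, 3),
    label = c("A", "B", "C", "A", "B", "C", "M", "C", "Z"),
    x = c(0, 40, 200, 10, 30, 160, 20, 110, 60),
    y = 0,
    area = c(100, 100, 100, 110, 110, 110, 230, 120, 360))
}
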