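# Shared phenotype-clustering stage: z-score standardization, PCA with a
# deterministic sign convention, Ward.D2 hierarchical clustering cut to k
# groups, and per-feature two-sided Wilcoxon rank-sum comparisons with the
# significance-star convention. Used identically for the growth (k = 3),
# eversion (k = 2) and degradation (k = 2) feature matrices.

#' Column-wise z-score standardization
#'
#' Centers each feature to mean 0 and scales to SD 1 (n-1 denominator).
#' Constant columns carry no contrast and are dropped with a warning.
#'
#' @param m numeric matrix (bots x features) with unique column names, no
#'   missing values, at least 2 rows.
#' @return standardized matrix (possibly with fewer columns).
#' @export
standardize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("standardize: need at least 2 rows")
  if (anyNA(m)) stop("standardize: missing values not allowed")
  if (anyDuplicated(colnames(m))) stop("standardize: duplicate feature names")
  sds <- apply(m, 2L, sd)
  const <- sds == 0
  if (all(const)) stop("standardize: all columns are constant")
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Principal component analysis with deterministic sign convention
#'
#' Eigendecomposition of the covariance of the (already standardized)
#' matrix; components ordered by decreasing eigenvalue. For each component
#' the loading of largest magnitude is made positive, so scores are
#' bit-stable across runs and platforms.
#'
#' @param m standardized feature matrix, at least 2 rows.
#' @return list with \code{scores} (bots x components), \code{loadings}
#'   (features x components) and \code{var_ratio} (explained-variance
#'   ratios, summing to 1).
#' @export
pca_features <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("pca_features: need at least 2 rows")
  p <- prcomp(m, center = FALSE, scale. = FALSE)
  flip <- apply(p$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2L, flip, `*`)
  loadings <- sweep(p$rotation, 2L, flip, `*`)
  list(scores = scores, loadings = loadings,
       var_ratio = p$sdev^2 / sum(p$sdev^2))
}

#' Ward.D2 hierarchical clustering cut to k groups
#'
#' Agglomerative clustering with the Ward.D2 criterion (merge cost = the
#' increase in total within-cluster sum of squared Euclidean distances;
#' input distances are \emph{not} pre-squared). Labels are renumbered by
#' decreasing cluster size, ties broken by smallest member index.
#'
#' @param m numeric matrix (rows clustered on Euclidean distances).
#' @param k number of clusters, \code{k <= nrow(m)}.
#' @return list with \code{labels} (integer vector in 1..k), \code{hclust}
#'   (the full linkage tree), \code{merge}, \code{height}.
#' @export
ward_d2 <- function(m, k) {
  m <- as.matrix(m)
  if (k > nrow(m)) stop("ward_d2: k exceeds number of rows")
  hc <- hclust(dist(m), method = "ward.D2")
  raw <- cutree(hc, k = k)
  list(labels = relabel_by_size(raw), hclust = hc,
       merge = hc$merge, height = hc$height)
}

relabel_by_size <- function(labels) {
  ids <- sort(unique(labels))
  size <- vapply(ids, function(g) sum(labels == g), integer(1))
  first <- vapply(ids, function(g) which(labels == g)[1L], integer(1))
  ord <- ids[order(-size, first)]
  match(labels, ord)
}

#' Significance stars for a p-value
#'
#' Caption convention with half-open intervals and a strict upper bound:
#' p < 0.0001 \code{****}, < 0.001 \code{***}, < 0.01 \code{**},
#' < 0.05 \code{*}, otherwise \code{ns} (so p = 0.05 is \code{ns}).
#'
#' @param p p-value in \[0, 1\].
#' @return one of \code{"****"}, \code{"***"}, \code{"**"}, \code{"*"},
#'   \code{"ns"}.
#' @export
p_stars <- function(p) {
  stopifnot(is.finite(p), p >= 0, p <= 1)
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Two-group Wilcoxon rank-sum comparison of one feature
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test between exactly two
#' clusters: the exact null distribution when both groups have at most 8
#' observations and there are no ties, otherwise the normal approximation
#' with tie correction and continuity correction.
#'
#' @param values numeric vector, one value per bot.
#' @param labels group labels (exactly 2 distinct values), same length.
#' @param feature optional feature name carried into the result.
#' @return list with \code{feature}, \code{statistic} (rank-sum W),
#'   \code{p_value}, \code{stars}.
#' @export
compare_groups <- function(values, labels, feature = NA_character_) {
  groups <- sort(unique(labels))
  if (length(groups) != 2L)
    stop("compare_groups: exactly 2 groups required (got ", length(groups),
         "); run pairwise for more")
  x <- values[labels == groups[1L]]
  y <- values[labels == groups[2L]]
  if (!length(x) || !length(y)) stop("compare_groups: empty group")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8L && length(y) <= 8L && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  p <- wt$p.value
  # all observations tied across groups: no rank signal, p = 1
  if (!is.finite(p)) p <- 1
  list(feature = feature, statistic = unname(wt$statistic),
       p_value = p, stars = p_stars(p))
}

#' Full phenotype-clustering pipeline
#'
#' Standardize, run PCA (for reporting/visualization), cluster with Ward.D2
#' in the chosen space, and compare every feature between clusters with
#' two-sided Wilcoxon rank-sum tests (pairwise when k > 2).
#'
#' Clustering defaults to the standardized feature space; PCA scores are an
#' alternative via \code{cluster_space = "pca"}.
#'
#' @param m feature matrix (bots x features).
#' @param k number of clusters (3 for growth, 2 for eversion and
#'   degradation in the source analyses).
#' @param cluster_space \code{"features"} (default) or \code{"pca"}.
#' @return object of class \code{bot_clusters}: list with
#'   \code{standardized}, \code{pca}, \code{labels}, \code{linkage},
#'   \code{comparisons}, \code{k}, \code{cluster_space}.
#' @export
phenocluster <- function(m, k, cluster_space = c("features", "pca")) {
  cluster_space <- match.arg(cluster_space)
  z <- standardize(m)
  pc <- pca_features(z)
  space <- if (cluster_space == "pca") pc$scores else z
  wd <- ward_d2(space, k)
  labels <- wd$labels
  comparisons <- list()
  pairs <- utils::combn(sort(unique(labels)), 2L, simplify = FALSE)
  for (pr in pairs) {
    sel <- labels %in% pr
    cmp <- lapply(colnames(z), function(f)
      compare_groups(z[sel, f], labels[sel], feature = f))
    names(cmp) <- colnames(z)
    comparisons[[paste(pr, collapse = "v")]] <- cmp
  }
  structure(list(standardized = z, pca = pc, labels = labels,
                 linkage = wd$hclust, comparisons = comparisons,
                 k = k, cluster_space = cluster_space),
            class = "bot_clusters")
}

#' @export
print.bot_clusters <- function(x, ...) {
  cat("bot_clusters: n =", nrow(x$standardized), "bots,",
      ncol(x$standardized), "features, k =", x$k,
      paste0("(", x$cluster_space, " space)\n"))
  cat("cluster sizes:", paste(tabulate(x$labels, x$k), collapse = "/"), "\n")
  cat("variance explained by PC1-2:",
      sprintf("%.1f%%", 100 * sum(x$pca$var_ratio[1:min(2, length(x$pca$var_ratio))])),
      "\n")
  for (pair in names(x$comparisons)) {
    cat("comparisons", pair, ":\n")
    for (cmp in x$comparisons[[pair]]) {
      cat(sprintf("  %-24s W = %6.1f  p = %.3g %s\n",
                  cmp$feature, cmp$statistic, cmp$p_value, cmp$stars))
    }
  }
  invisible(x)
}
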