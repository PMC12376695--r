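# Bulk transcriptome staging: CPM, low-expression filtering, TMM
# normalization, logCPM, log fold changes, phylostratigraphic gene-age
# counting, and overlap with morula-stage genes.
#
# The normalization and filtering steps are implemented here in full (CPM,
# the CPM > 0.29 in >= 3 samples rule, weighted trimmed mean of M-values)
# rather than delegated, because the exact arithmetic of these steps is the
# point of this module; moderated differential-expression statistics are
# deliberately out of scope (see de_ttest).

#' The 19 phylostrata (gene evolutionary-age classes)
#'
#' From oldest ("All living organisms": Eubacteria, bacteria and their
#' descendants) to youngest (Primates). Phylostratum assignment gives each
#' protein-coding gene the oldest clade in which homologs are detectable.
#'
#' @return character vector of the 19 admissible phylostratum names.
#' @export
phylostrata <- function() {
  c("All living organisms", "Eukaryota", "Opisthokonta", "Holozoa",
    "Metazoa", "Eumetazoa", "Bilateria", "Deuterostomia", "Chordata",
    "Olfactores", "Craniata", "Euteleostomi", "Tetrapoda", "Amniota",
    "Mammalia", "Eutheria", "Boreoeutheria", "Euarchontoglires", "Primates")
}

#' Counts per million mapped reads
#'
#' \code{cpm[g,s] = 1e6 * count[g,s] / (libsize[s] * factor[s])}, with
#' library sizes the column sums of \code{counts}.
#'
#' @param counts genes x samples nonnegative matrix.
#' @param factors per-sample normalization factors (default all 1).
#' @return matrix of the same shape.
#' @export
cpm <- function(counts, factors = rep(1, ncol(counts))) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("cpm: zero library size")
  if (any(factors <= 0) || any(!is.finite(factors)))
    stop("cpm: factors must be finite and positive")
  sweep(counts, 2L, lib * factors, `/`) * 1e6
}

#' Reads per kilobase per million mapped reads
#'
#' @param counts genes x samples matrix.
#' @param length_bp per-gene transcript length in bp (named or in row order).
#' @return matrix of RPKM values.
#' @export
rpkm <- function(counts, length_bp) {
  counts <- as.matrix(counts)
  if (!is.null(names(length_bp)) && !is.null(rownames(counts)))
    length_bp <- length_bp[rownames(counts)]
  if (length(length_bp) != nrow(counts) || anyNA(length_bp))
    stop("rpkm: lengths must cover every gene")
  cpm(counts) / (length_bp / 1e3)
}

#' Low-expression gene filter
#'
#' A gene is kept iff its CPM (computed with unit factors, i.e. raw library
#' sizes) is strictly greater than \code{cpm_threshold} in at least
#' \code{min_samples} samples. The default threshold 0.29 corresponds to
#' roughly 10 reads at the source study's depth.
#'
#' @param counts genes x samples matrix with rownames.
#' @param cpm_threshold strict CPM cutoff (default 0.29).
#' @param min_samples minimum number of qualifying samples (default 3).
#' @return character vector of kept gene ids.
#' @export
filter_genes <- function(counts, cpm_threshold = 0.29, min_samples = 3) {
  counts <- as.matrix(counts)
  stopifnot(cpm_threshold > 0, min_samples > 0)
  if (min_samples > ncol(counts))
    stop("filter_genes: min_samples exceeds sample count")
  keep <- rowSums(cpm(counts) > cpm_threshold) >= min_samples
  rownames(counts)[keep]
}

# TMM factor of one sample against the reference column.
tmm_one <- function(y, ref, lib_y, lib_ref, trim_M, trim_A) {
  pos <- y > 0 & ref > 0
  y <- y[pos]; ref <- ref[pos]
  if (!length(y)) {
    warning("tmm_factors: no genes shared with reference; factor set to 1")
    return(1)
  }
  M <- log2((y / lib_y) / (ref / lib_ref))
  A <- (log2(y / lib_y) + log2(ref / lib_ref)) / 2
  # identical composition: nothing to estimate
  if (max(abs(M)) < 1e-6) return(1)
  v <- (lib_y - y) / (lib_y * y) + (lib_ref - ref) / (lib_ref * ref)
  n <- length(M)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) {
    warning("tmm_factors: no genes survive trimming; factor set to 1")
    return(1)
  }
  f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
  2^f
}

#' Weighted trimmed mean of M-values (TMM) normalization factors
#'
#' The reference sample is the one whose upper-quartile CPM is closest to
#' the mean upper quartile (ties toward the smaller sample id). For every
#' sample, gene-wise M (log2 ratio of count proportions against the
#' reference) and A (average log2 abundance) are computed over genes with
#' positive counts in both; both tails are trimmed (\code{trim_M} fraction
#' on M, \code{trim_A} on A); the factor is \code{2^(sum(w*M)/sum(w))} with
#' inverse asymptotic-variance (delta-method binomial) weights. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param counts filtered genes x samples matrix, at least 2 samples.
#' @param trim_M two-sided trim fraction on M-values (default 0.30).
#' @param trim_A two-sided trim fraction on A-values (default 0.05).
#' @return named numeric vector of per-sample factors, geometric mean 1.
#'   All factors are 1 when no normalization is needed (identical
#'   compositions).
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("tmm_factors: need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("tmm_factors: zero library size")
  uq <- apply(cpm(counts), 2L, quantile, probs = 0.75, names = FALSE)
  cand <- which(abs(uq - mean(uq)) == min(abs(uq - mean(uq))))
  ids <- colnames(counts)
  ref <- if (!is.null(ids)) cand[order(ids[cand])][1L] else cand[1L]
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    tmm_one(counts[, s], counts[, ref], lib[s], lib[ref], trim_M, trim_A)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- ids
  f
}

#' log2 counts per million
#'
#' \code{log2(1e6 * (count + prior) / (libsize * factor + 2 * prior))}.
#' The prior count (default 0.5) keeps zero counts finite; with
#' \code{prior = 0} this is exactly
#' \code{log2(1e6 * count / (libsize * factor))} on positive counts.
#'
#' @param counts genes x samples matrix.
#' @param factors per-sample normalization factors (default all 1; use
#'   \code{\link{tmm_factors}}).
#' @param prior pseudocount, >= 0 (default 0.5).
#' @return matrix of logCPM values.
#' @export
log_cpm <- function(counts, factors = rep(1, ncol(counts)), prior = 0.5) {
  counts <- as.matrix(counts)
  if (prior < 0) stop("log_cpm: negative prior count")
  lib <- colSums(counts)
  if (any(lib * factors <= 0)) stop("log_cpm: nonpositive effective library size")
  log2(sweep(counts + prior, 2L, lib * factors + 2 * prior, `/`) * 1e6)
}

condition_means <- function(logcpm, condition) {
  condition <- check_condition(logcpm, condition)
  grps <- unique(unname(condition))
  out <- vapply(grps, function(g)
    rowMeans(logcpm[, condition == g, drop = FALSE]),
    numeric(nrow(logcpm)))
  colnames(out) <- grps
  out
}

check_condition <- function(mat, condition) {
  if (is.null(names(condition))) {
    if (length(condition) != ncol(mat))
      stop("condition must be named by sample or match column count")
    names(condition) <- colnames(mat)
  }
  missing <- setdiff(colnames(mat), names(condition))
  if (length(missing))
    stop("samples without condition: ", paste(missing, collapse = ", "))
  condition[colnames(mat)]
}

#' Per-gene log fold change between two conditions
#'
#' Difference of per-condition mean logCPM: \code{mean(A) - mean(B)}.
#'
#' @param logcpm genes x samples logCPM matrix (see \code{\link{log_cpm}}).
#' @param condition per-sample condition labels (named by sample id, or in
#'   column order).
#' @param contrast length-2 character vector \code{c(A, B)}.
#' @return named numeric vector of per-gene logFC.
#' @export
log_fold_change <- function(logcpm, condition, contrast) {
  stopifnot(length(contrast) == 2L)
  condition <- check_condition(logcpm, condition)
  if (!all(contrast %in% condition))
    stop("unknown condition in contrast: ",
         paste(setdiff(contrast, condition), collapse = ", "))
  a <- rowMeans(logcpm[, condition == contrast[1L], drop = FALSE])
  b <- rowMeans(logcpm[, condition == contrast[2L], drop = FALSE])
  a - b
}

check_annotation <- function(annotation) {
  stopifnot(all(c("gene_id", "phylostratum") %in% names(annotation)))
  bad <- setdiff(unique(annotation$phylostratum), phylostrata())
  if (length(bad))
    stop("unknown phylostratum name(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(annotation$gene_id))
    stop("duplicate gene ids in annotation")
  annotation
}

count_by_stratum <- function(genes, annotation, strata) {
  ps <- annotation$phylostratum[match(genes, annotation$gene_id)]
  table(factor(ps[!is.na(ps)], levels = strata))
}

#' Per-condition expressed-gene counts by phylostratum
#'
#' For each condition, a gene counts toward its phylostratum iff its mean
#' logCPM in that condition exceeds \code{threshold} (default 1; set
#' \code{measure = "cpm"} to threshold mean CPM instead). Unannotated genes
#' are excluded (their number is reported via a message).
#'
#' @param logcpm genes x samples logCPM matrix (or CPM matrix when
#'   \code{measure = "cpm"}).
#' @param annotation data frame with \code{gene_id}, \code{phylostratum}
#'   (one of \code{\link{phylostrata}()}).
#' @param condition per-sample condition labels.
#' @param threshold strict expression cutoff (default 1).
#' @param strata strata to report (default the two most ancient, as in the
#'   source analysis: "All living organisms" and "Eukaryota"; use
#'   \code{phylostrata()} for all 19).
#' @param measure label for what \code{logcpm} holds; affects nothing but
#'   documentation of intent (the threshold is applied to the given matrix).
#' @return integer matrix, strata x conditions.
#' @export
phylostratum_expressed_counts <- function(logcpm, annotation, condition,
                                          threshold = 1,
                                          strata = c("All living organisms",
                                                     "Eukaryota"),
                                          measure = c("logcpm", "cpm")) {
  measure <- match.arg(measure)
  annotation <- check_annotation(annotation)
  if (!all(strata %in% phylostrata()))
    stop("unknown stratum name(s): ",
         paste(setdiff(strata, phylostrata()), collapse = ", "))
  means <- condition_means(logcpm, condition)
  annotated <- rownames(logcpm) %in% annotation$gene_id
  if (any(!annotated))
    message(sum(!annotated), " unannotated gene(s) excluded from stratum counts")
  out <- vapply(colnames(means), function(g) {
    qualifying <- rownames(logcpm)[annotated & means[, g] > threshold]
    as.integer(count_by_stratum(qualifying, annotation, strata))
  }, integer(length(strata)))
  out <- matrix(out, nrow = length(strata),
                dimnames = list(strata, colnames(means)))
  out
}

#' Overexpressed-DEG counts by phylostratum
#'
#' Counts, per phylostratum, the genes whose log fold change exceeds
#' \code{threshold} (one-sided: overexpression only; downregulated genes
#' are never counted).
#'
#' @param logfc named per-gene logFC vector (see
#'   \code{\link{log_fold_change}}).
#' @param annotation data frame with \code{gene_id}, \code{phylostratum}.
#' @param threshold strict logFC cutoff (default 2).
#' @param strata strata to report (default "All living organisms" and
#'   "Eukaryota").
#' @return named integer vector of counts per stratum.
#' @export
phylostratum_deg_counts <- function(logfc, annotation, threshold = 2,
                                    strata = c("All living organisms",
                                               "Eukaryota")) {
  annotation <- check_annotation(annotation)
  if (!all(strata %in% phylostrata()))
    stop("unknown stratum name(s): ",
         paste(setdiff(strata, phylostrata()), collapse = ", "))
  up <- names(logfc)[logfc > threshold]
  out <- count_by_stratum(up, annotation, strata)
  stats::setNames(as.integer(out), strata)
}

#' Overlap of a DEG set with morula-stage genes
#'
#' The morula gene set is the genes whose (cell-averaged) expression value
#' exceeds \code{rpkm_threshold} (default RPKM > 2); the statistic is
#' \code{|DEG intersect morula| / |DEG|}.
#'
#' @param deg_genes character vector of DEG ids (nonempty).
#' @param morula_expression named numeric vector, gene id -> mean
#'   expression (RPKM) at the morula stage.
#' @param rpkm_threshold strict membership cutoff (default 2).
#' @return list with \code{fraction} and \code{genes} (the intersection).
#' @export
morula_overlap <- function(deg_genes, morula_expression, rpkm_threshold = 2) {
  if (length(deg_genes) == 0L) stop("morula_overlap: empty DEG set")
  if (is.null(names(morula_expression)))
    stop("morula_overlap: morula expression must be named by gene id")
  morula_set <- names(morula_expression)[morula_expression > rpkm_threshold]
  inter <- intersect(deg_genes, morula_set)
  list(fraction = length(inter) / length(deg_genes), genes = inter)
}

#' Plain per-gene two-sample t-test (optional plumbing)
#'
#' Ordinary Welch t-tests on logCPM with Benjamini-Hochberg adjustment.
#' This is intentionally simple plumbing and is \emph{not} equivalent to
#' moderated (empirical-Bayes, precision-weighted) differential-expression
#' pipelines; use it only for rough screening of synthetic data.
#'
#' @inheritParams log_fold_change
#' @return data frame with \code{gene}, \code{logFC}, \code{p}, \code{padj}.
#' @export
de_ttest <- function(logcpm, condition, contrast) {
  condition <- check_condition(logcpm, condition)
  a <- logcpm[, condition == contrast[1L], drop = FALSE]
  b <- logcpm[, condition == contrast[2L], drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("de_ttest: need >= 2 samples per condition")
  p <- vapply(seq_len(nrow(logcpm)), function(i)
    stats::t.test(a[i, ], b[i, ])$p.value, numeric(1))
  data.frame(gene = rownames(logcpm),
             logFC = rowMeans(a) - rowMeans(b),
             p = p, padj = stats::p.adjust(p, "BH"),
             row.names = NULL)
}
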