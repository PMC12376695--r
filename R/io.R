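# Readers and writers for every file format the pipeline touches:
# CSV particle tables (including the Fiji AnalyzeParticles header dialect),
# TSV counts/annotation/morula tables, CSV feature matrices, JSON cluster
# reports. All readers validate invariants on ingestion.

validate_particle_table <- function(tab) {
  req <- c("frame", "label", "x", "y", "area")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    stop("particle table missing column(s): ", paste(missing, collapse = ", "))
  if (anyNA(tab$frame) || any(tab$frame < 0) || any(tab$frame != floor(tab$frame)))
    stop("particle table: frame must be a nonnegative integer index")
  if (anyDuplicated(paste(tab$frame, tab$label, sep = "\r")))
    stop("particle table: duplicate (frame, label) pair")
  if (anyNA(tab$area) || any(tab$area <= 0))
    stop("particle table: area must be strictly positive")
  tab <- tab[order(tab$frame, tab$label), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Column-name dialect for Fiji AnalyzeParticles output
#'
#' Maps the canonical names (\code{frame}, \code{x}, \code{y}, \code{area},
#' \code{perimeter}) to Fiji's \code{Slice}/\code{X}/\code{Y}/\code{Area}/
#' \code{Perim.} headers; \code{Slice} is 1-based and converted to a
#' 0-based frame index (\code{frame_base = 1}).
#'
#' @return list with \code{cols} (canonical -> file column name) and
#'   \code{frame_base}.
#' @export
dialect_fiji <- function() {
  list(cols = c(frame = "Slice", x = "X", y = "Y", area = "Area",
                perimeter = "Perim."),
       frame_base = 1)
}

#' Read a per-frame particle table
#'
#' Canonical columns are \code{frame}, \code{label}, \code{x}, \code{y},
#' \code{area} and optionally \code{perimeter}; a dialect maps other
#' headers onto them (see \code{\link{dialect_fiji}}). When no label column
#' is present, labels are assigned by within-frame row order. Coordinates
#' are pixels with y increasing downward (image convention); they pass
#' through unchanged. The result is validated ((frame, label) unique,
#' areas strictly positive) and sorted by (frame, label).
#'
#' @param path CSV file path.
#' @param dialect optional list with \code{cols} (named character vector,
#'   canonical name -> file column name) and \code{frame_base} (subtracted
#'   from the frame column; default 0).
#' @return validated particle table (data frame).
#' @export
read_particle_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, check.names = FALSE)
  cols <- c(frame = "frame", label = "label", x = "x", y = "y",
            area = "area", perimeter = "perimeter")
  frame_base <- 0
  if (!is.null(dialect)) {
    cols[names(dialect$cols)] <- dialect$cols
    if (!is.null(dialect$frame_base)) frame_base <- dialect$frame_base
  }
  for (canon in c("frame", "x", "y", "area")) {
    if (!cols[[canon]] %in% names(raw))
      stop("particle table missing column(s): ", canon,
           " (looked for '", cols[[canon]], "')")
  }
  tab <- data.frame(frame = raw[[cols[["frame"]]]] - frame_base,
                    x = raw[[cols[["x"]]]],
                    y = raw[[cols[["y"]]]],
                    area = raw[[cols[["area"]]]])
  tab$label <- if (cols[["label"]] %in% names(raw)) {
    as.character(raw[[cols[["label"]]]])
  } else {
    stats::ave(seq_len(nrow(tab)), tab$frame,
               FUN = function(i) seq_along(i))
  }
  if (cols[["perimeter"]] %in% names(raw))
    tab$perimeter <- raw[[cols[["perimeter"]]]]
  validate_particle_table(tab)
}

#' Write a particle table to CSV (canonical headers)
#' @param table particle table.
#' @param path output CSV path.
#' @export
write_particle_table <- function(table, path) {
  write.csv(validate_particle_table(table), path, row.names = FALSE)
}

#' Read a counts matrix and its sample-condition map
#'
#' The counts file is TSV with the gene id in the first column and one
#' integer column per sample; the condition file is TSV with columns
#' \code{sample} and \code{condition}. Every sample must have a condition;
#' sample order is preserved.
#'
#' @param path counts TSV path.
#' @param condition_path condition-map TSV path.
#' @return list with \code{counts} (integer matrix, genes x samples) and
#'   \code{condition} (named character vector).
#' @export
read_counts <- function(path, condition_path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, check.names = FALSE)
  if (ncol(raw) < 3L) stop("counts table needs a gene column and >= 2 samples")
  genes <- as.character(raw[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in counts table")
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != floor(m)))
    stop("counts must be nonnegative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  cmap <- read.delim(condition_path, check.names = FALSE)
  if (!all(c("sample", "condition") %in% names(cmap)))
    stop("condition map needs columns 'sample' and 'condition'")
  missing <- setdiff(colnames(m), cmap$sample)
  if (length(missing))
    stop("samples without condition: ", paste(missing, collapse = ", "))
  cond <- stats::setNames(as.character(cmap$condition),
                          as.character(cmap$sample))[colnames(m)]
  list(counts = m, condition = cond)
}

#' Write a counts matrix and condition map to TSV
#' @param counts genes x samples integer matrix.
#' @param condition named condition vector.
#' @param path counts TSV path.
#' @param condition_path condition TSV path.
#' @export
write_counts <- function(counts, condition, path, condition_path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  cdf <- data.frame(sample = colnames(counts),
                    condition = unname(condition[colnames(counts)]))
  utils::write.table(cdf, condition_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' Read a gene annotation table (id, length, phylostratum)
#'
#' TSV with columns \code{gene_id}, \code{length_bp} (integer > 0) and
#' \code{phylostratum} (one of the 19 names from
#' \code{\link{phylostrata}()}); each gene maps to exactly one stratum.
#'
#' @param path TSV path.
#' @return validated data frame.
#' @export
read_gene_annotation <- function(path) {
  ann <- read.delim(path, check.names = FALSE)
  req <- c("gene_id", "length_bp", "phylostratum")
  missing <- setdiff(req, names(ann))
  if (length(missing))
    stop("annotation missing column(s): ", paste(missing, collapse = ", "))
  if (any(ann$length_bp <= 0) || any(ann$length_bp != floor(ann$length_bp)))
    stop("annotation: length_bp must be a positive integer")
  check_annotation(ann)
}

#' Write a gene annotation table to TSV
#' @param annotation data frame (gene_id, length_bp, phylostratum).
#' @param path TSV path.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(check_annotation(annotation), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' Read a morula expression table (gene id, mean expression)
#' @param path TSV path with columns \code{gene_id} and \code{expression}.
#' @return named numeric vector, gene id -> mean expression.
#' @export
read_morula_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  if (!all(c("gene_id", "expression") %in% names(tab)))
    stop("morula table needs columns 'gene_id' and 'expression'")
  stats::setNames(as.numeric(tab$expression), as.character(tab$gene_id))
}

#' Write a morula expression table to TSV
#' @param morula named numeric vector.
#' @param path TSV path.
#' @export
write_morula_table <- function(morula, path) {
  utils::write.table(data.frame(gene_id = names(morula),
                                expression = unname(morula)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Write / read a bot-by-feature matrix as CSV
#'
#' Values round-trip at full double precision (>= 12 significant digits);
#' an empty matrix yields a header-only file.
#'
#' @param m numeric matrix with row (bot) and column (feature) names.
#' @param path CSV path.
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(bot = if (is.null(rownames(m))) character(nrow(m))
                         else rownames(m),
                   as.data.frame(m), check.names = FALSE)
  # write.csv prints doubles at 15 significant digits
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_feature_matrix
#' @return \code{read_feature_matrix}: numeric matrix with bot rownames.
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"bot" %in% names(df)) stop("feature matrix CSV needs a 'bot' column")
  m <- as.matrix(df[, setdiff(names(df), "bot"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$bot
  m
}

#' Write / read a cluster report as JSON
#'
#' Serializes the labels, PCA explained-variance ratios and group
#' comparisons of a \code{\link{phenocluster}} result; numbers are written
#' at full precision so the report round-trips losslessly beyond 12
#' significant digits.
#'
#' @param result a \code{bot_clusters} object.
#' @param path JSON path.
#' @export
write_cluster_report <- function(result, path) {
  stopifnot(inherits(result, "bot_clusters"))
  report <- list(
    k = result$k,
    cluster_space = result$cluster_space,
    bots = rownames(result$standardized),
    labels = as.integer(result$labels),
    explained_variance = as.numeric(result$pca$var_ratio),
    comparisons = lapply(result$comparisons, function(pair)
      lapply(pair, function(cmp)
        list(feature = cmp$feature, statistic = cmp$statistic,
             p_value = cmp$p_value, stars = cmp$stars)))
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_cluster_report
#' @return \code{read_cluster_report}: the report as a list.
#' @export
read_cluster_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}
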