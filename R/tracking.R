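# Lineage tracking of growing spheroids from per-frame particle tables.
#
# The source imaging is bi-daily wide-field microscopy of spheroids embedded
# in Matrigel; segmentation (Fiji AnalyzeParticles) yields one centroid+area
# record per object per frame. Linking uses greedy mutual-nearest-neighbour
# assignment between consecutive observed frames, with a merge rule: when
# several live tracks point at the same particle in the next frame and that
# particle's area is consistent with the sum of its parents' areas, the
# tracks fuse into a new segment with a multi-parent merge edge.

#' Link per-frame particles into a spheroid lineage graph
#'
#' Greedy mutual-nearest-neighbour linking between consecutive observed
#' frames. A particle at frame t+1 targeted by two or more live tracks whose
#' summed area matches the particle's area within \code{area_ratio_tol}
#' (relative to the larger of the two quantities, since the fused spheroid
#' keeps growing between observations) produces a merge node with those
#' tracks as parents. Particles
#' with no assignment start new root segments; tracks with no successor
#' terminate. Ties in nearest-neighbour choice are broken toward the
#' smaller particle label.
#'
#' @param table a particle table (see \code{\link{read_particle_table}}):
#'   data frame with columns \code{frame}, \code{label}, \code{x}, \code{y},
#'   \code{area}.
#' @param max_disp maximum centroid displacement (pixels) for a link;
#'   default 50 (bi-daily imaging implies generous tolerances).
#' @param area_ratio_tol relative tolerance for the merged-area check;
#'   default 0.3.
#' @return an object of class \code{lineage_graph}: list with
#'   \code{segments} (list of data frames, one per track segment, rows
#'   ordered by frame), \code{parents} (list of integer vectors of parent
#'   segment ids), \code{events} (per segment, \code{"root"},
#'   \code{"merge"}), and the input \code{table}.
#' @export
link_frames <- function(table, max_disp = 50, area_ratio_tol = 0.3) {
  table <- validate_particle_table(table)
  if (nrow(table) == 0L) stop("link_frames: empty particle table")
  if (!all(is.finite(table$x)) || !all(is.finite(table$y)))
    stop("link_frames: non-finite coordinates")
  stopifnot(max_disp > 0)

  frames <- sort(unique(table$frame))
  by_frame <- split(table, table$frame)
  # order rows within frame by label for deterministic tie-breaks
  by_frame <- lapply(by_frame, function(d) d[order(d$label), , drop = FALSE])

  segments <- list()   # each: data.frame rows of the table
  parents <- list()
  events <- character(0)
  new_segment <- function(row, pars, ev) {
    segments[[length(segments) + 1L]] <<- row
    parents[[length(parents) + 1L]] <<- pars
    events <<- c(events, ev)
    length(segments)
  }

  f1 <- by_frame[[as.character(frames[1])]]
  live <- integer(0)  # segment ids whose last row is at the current frame
  for (i in seq_len(nrow(f1))) live <- c(live, new_segment(f1[i, ], integer(0), "root"))

  for (fi in seq_along(frames)[-1]) {
    A <- do.call(rbind, lapply(live, function(s) tail(segments[[s]], 1L)))
    B <- by_frame[[as.character(frames[fi])]]
    segA <- live
    nextlive <- integer(0)

    if (length(live) == 0L) {
      for (j in seq_len(nrow(B)))
        nextlive <- c(nextlive, new_segment(B[j, ], integer(0), "root"))
      live <- nextlive
      next
    }

    D <- outer(seq_len(nrow(A)), seq_len(nrow(B)), function(ia, jb) {
      sqrt((A$x[ia] - B$x[jb])^2 + (A$y[ia] - B$y[jb])^2)
    })
    # nearest candidate (within max_disp) for each side; rows/cols are
    # label-ordered so which.min breaks ties toward the smaller label
    nn_b <- apply(D, 1L, function(r) {
      j <- which.min(r)
      if (r[j] <= max_disp) j else NA_integer_
    })
    nn_a <- apply(D, 2L, function(cc) {
      i <- which.min(cc)
      if (cc[i] <= max_disp) i else NA_integer_
    })

    assigned_a <- rep(FALSE, nrow(A))
    for (j in seq_len(nrow(B))) {
      P <- which(!is.na(nn_b) & nn_b == j)
      if (length(P) >= 2L) {
        asum <- sum(A$area[P])
        # normalize by the larger quantity: the fused spheroid keeps growing
        # between observations, so the parent sum underestimates its area
        if (abs(B$area[j] - asum) <= area_ratio_tol * max(B$area[j], asum)) {
          nextlive <- c(nextlive, new_segment(B[j, ], segA[P], "merge"))
          assigned_a[P] <- TRUE
          next
        }
        # area inconsistent with a merge: keep only the mutual link
        P <- if (!is.na(nn_a[j]) && nn_a[j] %in% P) nn_a[j] else integer(0)
      }
      if (length(P) == 1L && !is.na(nn_a[j]) && nn_a[j] == P) {
        s <- segA[P]
        segments[[s]] <- rbind(segments[[s]], B[j, ])
        assigned_a[P] <- TRUE
        nextlive <- c(nextlive, s)
      } else {
        nextlive <- c(nextlive, new_segment(B[j, ], integer(0), "root"))
      }
    }
    live <- nextlive
  }

  structure(list(segments = segments, parents = parents, events = events,
                 table = table),
            class = "lineage_graph")
}

#' @export
print.lineage_graph <- function(x, ...) {
  nmerge <- sum(x$events == "merge")
  cat("lineage_graph:", length(x$segments), "segments,",
      sum(x$events == "root"), "roots,", nmerge, "merge events,",
      nrow(x$table), "particles\n")
  invisible(x)
}

# terminal segment with the latest last frame; ties -> largest final area,
# then smallest segment id
final_segment_id <- function(g) {
  lastf <- vapply(g$segments, function(s) max(s$frame), numeric(1))
  lasta <- vapply(g$segments, function(s) s$area[which.max(s$frame)], numeric(1))
  children <- unlist(g$parents)
  is_parent <- seq_along(g$segments) %in% unlist(g$parents)
  # a segment that was absorbed into a merge is not terminal
  cand <- which(!is_parent)
  cand[order(-lastf[cand], -lasta[cand], cand)][1L]
}

ancestry_ids <- function(g, seg) {
  if (seg < 1L || seg > length(g$segments))
    stop("segment not in graph")
  seen <- logical(length(g$segments))
  stack <- seg
  while (length(stack)) {
    s <- stack[[1L]]; stack <- stack[-1L]
    if (seen[s]) next
    seen[s] <- TRUE
    stack <- c(stack, g$parents[[s]])
  }
  which(seen)
}

#' Count founding components in a spheroid's ancestry
#'
#' The number of root segments reachable backward from the final segment:
#' 1 for monoclonal expansion (a single chain), k when k founding precursor
#' spheroids were absorbed through merge events.
#'
#' @param g a \code{lineage_graph}.
#' @param final_segment segment id; default the terminal segment with the
#'   latest frame (largest final area on ties).
#' @return integer >= 1.
#' @export
merge_event_count <- function(g, final_segment = NULL) {
  if (is.null(final_segment)) final_segment <- final_segment_id(g)
  anc <- ancestry_ids(g, final_segment)
  sum(g$events[anc] == "root")
}

#' The three growth features of a tracked spheroid
#'
#' \code{merge_events}: number of founding components
#' (\code{\link{merge_event_count}}); \code{fin_area}: area at the last
#' frame of the final segment; \code{sd_area}: standard deviation (n-1
#' denominator) of consecutive frame-to-frame differences of the total
#' ancestral area series (the per-frame sum of areas over all ancestor
#' particles alive at that frame, so pre-merge growth contributes).
#'
#' @inheritParams merge_event_count
#' @return named numeric vector \code{c(merge_events, fin_area, sd_area)}.
#' @export
growth_features <- function(g, final_segment = NULL) {
  if (is.null(final_segment)) final_segment <- final_segment_id(g)
  anc <- ancestry_ids(g, final_segment)
  rows <- do.call(rbind, g$segments[anc])
  series <- tapply(rows$area, rows$frame, sum)
  series <- series[order(as.numeric(names(series)))]
  d <- diff(as.numeric(series))
  fin <- g$segments[[final_segment]]
  c(merge_events = merge_event_count(g, final_segment),
    fin_area = fin$area[which.max(fin$frame)],
    sd_area = if (length(d) >= 2L) sd(d) else 0)
}

#' Growth features for every bot in a list of particle tables
#'
#' Convenience wrapper running \code{\link{link_frames}} and
#' \code{\link{growth_features}} per bot and assembling the 3-column
#' feature matrix consumed by \code{\link{phenocluster}}.
#'
#' @param tables named list of particle tables (one per bot).
#' @param ... passed to \code{\link{link_frames}}.
#' @return numeric matrix, bots x c(merge_events, fin_area, sd_area).
#' @export
growth_feature_matrix <- function(tables, ...) {
  feats <- t(vapply(tables, function(tb) growth_features(link_frames(tb, ...)),
                    numeric(3)))
  rownames(feats) <- names(tables)
  feats
}
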