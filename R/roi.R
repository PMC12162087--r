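# ROI delineation: the manual drawing procedure of the study encoded as a
# deterministic heuristic — percentile thresholding of the 2D- and 3D-motion
# contrast maps (95th, relaxed stepwise to the 90th), 4-connected cluster
# extraction, hMT/MST = largest 2D cluster, pFST = the 3D-not-2D cluster
# adjacent and anterior/inferior to it — plus the overlap metrics (DICE,
# centroid distance, surface area).

#' Percentile-threshold a contrast map
#'
#' Keeps vertices at or above the q-th percentile of the whole hemisphere
#' (linear-interpolation percentile). Thresholds are restricted to the
#' 90-95 band used for delineation. On a constant map every vertex equals
#' its own percentile and all vertices pass.
#'
#' @param map Numeric matrix (grid shape) or vector of contrast values.
#' @param q Percentile in `[90, 95]`.
#' @return Logical mask, same shape as `map`.
#' @export
percentile_threshold <- function(map, q) {
  if (q < 90 || q > 95) stop("q must lie in [90, 95]")
  thr <- stats::quantile(map, q / 100, type = 7, names = FALSE)
  mask <- map >= thr
  mask
}

#' Extract 4-connected clusters from a binary mask
#'
#' @param mask Logical matrix (grid shape).
#' @return List of integer vectors (vertex indices into the matrix), ordered
#'   by decreasing size, ties broken by smallest vertex index.
#' @export
connected_clusters <- function(mask) {
  mask <- as.matrix(mask)
  dims <- dim(mask)
  lab <- matrix(0L, dims[1], dims[2])
  nxt <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((cur - 1L) %% dims[1]) + 1L
      c <- ((cur - 1L) %/% dims[1]) + 1L
      nb <- c(if (r > 1) cur - 1L, if (r < dims[1]) cur + 1L,
              if (c > 1) cur - dims[1], if (c < dims[2]) cur + dims[1])
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      stack <- c(stack, nb)
    }
  }
  if (nxt == 0L) return(list())
  clusters <- split(which(lab != 0L), lab[lab != 0L])
  ord <- order(-vapply(clusters, length, 0L),
               vapply(clusters, min, 0L))
  unname(clusters[ord])
}

#' Classify the activation-overlap scenario of the two localizers
#'
#' `disjoint` when the masks do not intersect; otherwise
#' `overlap_3d_superset` when the 3D-only remainder is at least as large as
#' the 2D-only remainder (the 2D localizer activates a subset of the 3D
#' activation, the majority pattern), else `overlap_2d_superset`.
#'
#' @param mask2d,mask3d Logical masks of identical shape.
#' @return One of `"disjoint"`, `"overlap_3d_superset"`,
#'   `"overlap_2d_superset"`.
#' @export
classify_scenario <- function(mask2d, mask3d) {
  if (!identical(dim(as.matrix(mask2d)), dim(as.matrix(mask3d))))
    stop("masks must share a shape")
  inter <- sum(mask2d & mask3d)
  if (inter == 0) return("disjoint")
  only3 <- sum(mask3d & !mask2d)
  only2 <- sum(mask2d & !mask3d)
  if (only3 >= only2) "overlap_3d_superset" else "overlap_2d_superset"
}

cluster_centroid <- function(idx, dims) {
  r <- ((idx - 1L) %% dims[1]) + 1L
  c <- ((idx - 1L) %/% dims[1]) + 1L
  c(row = mean(r), col = mean(c))
}

# minimum Euclidean vertex distance between two clusters
cluster_distance <- function(a, b, dims) {
  ra <- ((a - 1L) %% dims[1]) + 1L; ca <- ((a - 1L) %/% dims[1]) + 1L
  rb <- ((b - 1L) %% dims[1]) + 1L; cb <- ((b - 1L) %/% dims[1]) + 1L
  min(sqrt(outer(ra, rb, "-")^2 + outer(ca, cb, "-")^2))
}

#' Delineate hMT/MST and pFST from the two motion contrast maps
#'
#' Encodes the drawing procedure: (1) hMT/MST is the largest 4-connected
#' cluster of the thresholded 2D-motion map; (2) candidate pFST clusters are
#' the clusters of the thresholded 3D-motion map after removing hMT/MST;
#' (3) among candidates adjacent to hMT/MST (or within `adjacency` vertices),
#' the one whose centroid scores highest on the anterior/inferior criterion
#' (delta-col + delta-row > 0; ties to the larger cluster) becomes pFST;
#' (4) if no candidate qualifies, both thresholds are lowered in steps of
#' `q_step` from `q_start` toward `q_floor` and the procedure retried. If no
#' candidate qualifies at the floor, pFST is returned empty and flagged.
#'
#' @param map2d,map3d Contrast maps (numeric matrices, grid shape).
#' @param q_start Starting percentile (default 95).
#' @param q_floor Lowest allowed percentile (default 90).
#' @param q_step Lowering step in percentile points.
#' @param adjacency Maximum vertex distance for a candidate to count as
#'   adjacent to hMT/MST (1 = sharing a 4-neighbor boundary).
#' @param min_size Minimum candidate cluster size (vertices). Percentile
#'   masks always cover 5-10% of the hemisphere, so isolated noise specks
#'   survive thresholding; the drawing procedure targets contiguous
#'   activation peaks, not single vertices.
#' @param search_mask Optional logical matrix restricting the search (the
#'   anatomical lateral-occipital / inferior-temporal window of the manual
#'   procedure).
#' @return An `roi_set`: list with `labels` (character matrix: `none`,
#'   `hMTMST`, `pFST`), masks `hMTMST`/`pFST`, `threshold_2d`,
#'   `threshold_3d`, `scenario`, `pfst_found`.
#' @export
delineate <- function(map2d, map3d, q_start = 95, q_floor = 90, q_step = 1,
                      adjacency = 3, min_size = 5, search_mask = NULL) {
  map2d <- as.matrix(map2d); map3d <- as.matrix(map3d)
  dims <- dim(map2d)
  if (!identical(dims, dim(map3d))) stop("contrast maps must share a shape")
  qs <- seq(q_start, q_floor, by = -abs(q_step))
  if (qs[length(qs)] != q_floor) qs <- c(qs, q_floor)
  hmt <- NULL; pfst <- NULL; used_q <- NA_real_; scen <- NA_character_
  for (q in qs) {
    m2 <- percentile_threshold(map2d, q)
    m3 <- percentile_threshold(map3d, q)
    if (!is.null(search_mask)) {
      m2 <- m2 & search_mask
      m3 <- m3 & search_mask
    }
    cl2 <- connected_clusters(m2)
    if (length(cl2) == 0) next
    hmt_q <- cl2[[1]]
    hmask <- matrix(FALSE, dims[1], dims[2]); hmask[hmt_q] <- TRUE
    cand_mask <- m3 & !hmask
    cands <- connected_clusters(cand_mask)
    cands <- cands[vapply(cands, length, 0L) >= min_size]
    if (length(cands) > 0) {
      hc <- cluster_centroid(hmt_q, dims)
      keep <- vapply(cands, function(cc)
        cluster_distance(cc, hmt_q, dims) <= adjacency, logical(1))
      cands <- cands[keep]
      if (length(cands) > 0) {
        score <- vapply(cands, function(cc) {
          cc_c <- cluster_centroid(cc, dims)
          (cc_c["col"] - hc["col"]) + (cc_c["row"] - hc["row"])
        }, numeric(1))
        sizes <- vapply(cands, length, 0L)
        elig <- which(score > 0)
        if (length(elig) > 0) {
          best <- elig[order(-score[elig], -sizes[elig])][1]
          hmt <- hmt_q; pfst <- cands[[best]]
          used_q <- q; scen <- classify_scenario(m2, m3)
          break
        }
      }
    }
    if (is.null(hmt)) { hmt <- hmt_q; used_q <- q; scen <- classify_scenario(m2, m3) }
  }
  if (is.null(hmt))
    stop("delineation failed: no hMT/MST cluster at any threshold in [",
         q_floor, ", ", q_start, "]")
  labels <- matrix("none", dims[1], dims[2])
  labels[hmt] <- "hMTMST"
  hmask <- matrix(FALSE, dims[1], dims[2]); hmask[hmt] <- TRUE
  pmask <- matrix(FALSE, dims[1], dims[2])
  if (!is.null(pfst)) { labels[pfst] <- "pFST"; pmask[pfst] <- TRUE }
  structure(list(labels = labels, hMTMST = hmask, pFST = pmask,
                 threshold_2d = used_q, threshold_3d = used_q,
                 scenario = scen, pfst_found = !is.null(pfst)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> hMT/MST %d vertices, pFST %d vertices (q = %g, %s)\n",
              sum(x$hMTMST), sum(x$pFST), x$threshold_2d, x$scenario))
  invisible(x)
}

#' DICE overlap coefficient
#'
#' `2 |A n B| / (|A| + |B|)`; 0 when both sets are empty (documented
#' convention).
#'
#' @param a,b Logical masks (or index vectors with `shape` ignored).
#' @return Fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(0)
  2 * sum(a & b) / (na + nb)
}

#' Euclidean distance between ROI centroids
#'
#' Unweighted vertex centroids; multiply grid units into mm via `spacing`.
#'
#' @param a,b Non-empty logical masks of identical shape.
#' @param spacing Physical size of one vertex step (default 1, grid units).
#' @return Distance.
#' @export
centroid_distance <- function(a, b, spacing = 1) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (sum(a) == 0 || sum(b) == 0) stop("centroid of an empty ROI is undefined")
  dims <- dim(a)
  ca <- cluster_centroid(which(a), dims)
  cb <- cluster_centroid(which(b), dims)
  spacing * sqrt(sum((ca - cb)^2))
}

#' ROI surface area
#' @param roi Logical mask.
#' @param vertex_area Area per vertex in mm^2 (> 0).
#' @return Area in mm^2.
#' @export
surface_area <- function(roi, vertex_area = 1) {
  if (vertex_area <= 0) stop("vertex_area must be positive")
  sum(roi) * vertex_area
}

#' Export an ROI set as a CSV label table
#' @param roi An `roi_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_csv <- function(roi, path) {
  dims <- dim(roi$labels)
  d <- data.frame(vertex = seq_len(prod(dims)),
                  row = rep(seq_len(dims[1]), times = dims[2]),
                  col = rep(seq_len(dims[2]), each = dims[1]),
                  label = as.vector(roi$labels))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
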