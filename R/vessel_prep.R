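#' Skeletonize a binary mask
#'
#' Topology-preserving iterative thinning to a one-pixel-wide, 8-connected
#' skeleton, followed by endpoint re-extension inside the source mask so
#' that blunt tube ends are not shortened. The skeleton is always a subset
#' of the mask and has the same number of connected components.
#'
#' @param mask binary integer matrix.
#' @param prune_spurs_px prune side branches shorter than this many pixels
#'   that end in a branch point (0 disables). Thinning tubes with bumpy
#'   boundaries sprouts short spurs whose branch points would otherwise
#'   fragment the vessel into spurious segments.
#' @return an object of class `skeleton`: list with `skeleton_mask` (binary
#'   matrix) and `branch_degree` (integer matrix counting the 8-neighbour
#'   skeleton pixels of every skeleton pixel; 0 elsewhere).
#' @export
skeletonize <- function(mask, prune_spurs_px = 0) {
  if (!is_binary_mask(mask)) stop("mask must be a binary matrix")
  sk <- cpp_thin(as_mask(mask), TRUE)
  if (prune_spurs_px > 0) sk <- prune_spurs(sk, prune_spurs_px)
  deg <- cpp_neighbor_count(sk)
  deg[sk == 0L] <- 0L
  structure(list(skeleton_mask = sk, branch_degree = deg), class = "skeleton")
}

# delete skeleton side branches shorter than min_len that terminate in a
# branch point; whole components (no branch point reached) are never removed
prune_spurs <- function(sk, min_len, passes = 2L) {
  offs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  H <- nrow(sk); W <- ncol(sk)
  for (p in seq_len(passes)) {
    deg <- cpp_neighbor_count(sk)
    ends <- which(sk == 1L & deg == 1L, arr.ind = TRUE)
    if (nrow(ends) == 0L) break
    removed <- FALSE
    for (e in seq_len(nrow(ends))) {
      path <- matrix(ends[e, ], 1, 2)
      cur <- ends[e, ]
      prev <- c(NA_integer_, NA_integer_)
      hit_branch <- FALSE
      while (nrow(path) <= min_len) {
        nb <- sweep(offs, 2, cur, "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= H & nb[, 2] >= 1 & nb[, 2] <= W
        nb <- nb[ok, , drop = FALSE]
        nb <- nb[sk[nb] == 1L, , drop = FALSE]
        if (!is.na(prev[1])) {
          nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
        }
        if (nrow(nb) == 0L) break          # isolated short line: keep
        if (nrow(nb) > 1L || deg[nb[1, 1], nb[1, 2]] >= 3L) {
          hit_branch <- TRUE
          break
        }
        prev <- cur
        cur <- nb[1, ]
        path <- rbind(path, cur)
      }
      if (hit_branch && nrow(path) <= min_len) {
        sk[path] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  sk
}

# vessel-segment partition: connected components of the skeleton after
# removing branch points (degree >= 3) together with a small ball around
# them (crossing zones thin to a mesh of close-by junctions; removing the
# ball leaves exactly the vessel arms), propagated to every mask pixel by
# geodesic nearest-seed BFS
segment_labels <- function(mask, skel = NULL, branch_ball_px = 3) {
  if (is.null(skel)) skel <- skeletonize(mask, prune_spurs_px = 10)
  core <- skel$skeleton_mask
  bp <- which(skel$branch_degree >= 3L, arr.ind = TRUE)
  if (nrow(bp) > 0) {
    ball <- cpp_stamp_tube(matrix(0L, nrow(core), ncol(core)),
                           bp[, 1] - 1, bp[, 2] - 1,
                           rep(branch_ball_px, nrow(bp)), 1L)
    core[ball == 1L] <- 0L
  }
  seg <- cpp_label8(core)
  cpp_nearest_label_bfs(as_mask(mask), seg)
}

#' Refine artery/vein labels against the vessel mask
#'
#' The artery/vein pixel classification is noisier than the vessel
#' segmentation, so labels are cleaned in two steps: (i) clip the
#' artery/vein map to the vessel mask, and (ii) homogenize labels per
#' vessel segment. Segments are obtained by removing branch points (plus a
#' small ball around them) from the vessel skeleton, taking 8-connected
#' components and propagating them to every mask pixel by geodesic
#' nearest-seed assignment; every segment pixel receives the majority label
#' among the segment's original non-background labels. Ties and segments
#' without any label become 0 (unknown).
#'
#' Pixels within `junction_radius_px` of a skeleton branch point are left
#' with their clipped original labels: inside a junction or crossing zone
#' the notion of a single-vessel segment breaks down, and it is exactly
#' there that the artery/vein overwrite pattern of a crossing carries the
#' diagnostic signal. The operation is idempotent and never alters the
#' vessel mask.
#'
#' @param scene a [vessel_scene()].
#' @param junction_radius_px radius of the protected zone around skeleton
#'   branch points.
#' @return the scene with a refined `av_map`.
#' @export
refine_av_labels <- function(scene, junction_radius_px = 15) {
  stopifnot(inherits(scene, "vessel_scene"))
  if (sum(scene$vessel_mask) == 0L) {
    stop("vessel_mask is empty; nothing to refine")
  }
  av <- scene$av_map
  av[scene$vessel_mask == 0L] <- 0L
  skel <- skeletonize(scene$vessel_mask, prune_spurs_px = 10)
  seg <- segment_labels(scene$vessel_mask, skel)
  nseg <- max(seg)
  if (nseg > 0L) {
    protected <- matrix(0L, nrow(av), ncol(av))
    bp <- which(skel$branch_degree >= 3L, arr.ind = TRUE)
    if (nrow(bp) > 0) {
      protected <- cpp_stamp_tube(protected, bp[, 1] - 1, bp[, 2] - 1,
                                  rep(junction_radius_px, nrow(bp)), 1L)
    }
    sel <- seg > 0L
    seg_id <- seg[sel]
    lab <- av[sel]
    n_art <- tabulate(seg_id[lab == 1L], nbins = nseg)
    n_vei <- tabulate(seg_id[lab == 2L], nbins = nseg)
    major <- integer(nseg)
    major[n_art > n_vei] <- 1L
    major[n_vei > n_art] <- 2L   # ties (incl. 0/0) stay 0 = unknown
    new_lab <- major[seg_id]
    keep <- protected[sel] == 1L
    new_lab[keep] <- lab[keep]
    av[sel] <- new_lab
  }
  scene$av_map <- av
  scene
}
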