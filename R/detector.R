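#' Detect arterio-venous crossing candidates
#'
#' Finds candidate crossing points on a refined scene in four steps:
#' (1) contact pixels are artery pixels with at least one vein pixel among
#' their 8-neighbours; (2) contact pixels are clustered by 8-connectivity
#' and each cluster yields a raw candidate at its centroid with the cluster
#' size as score; (3) a skeleton traversal check keeps a candidate only if,
#' within a disc of radius `check_radius_px` around it, both the artery and
#' the vein skeleton actually traverse the disc (each hits the disc
#' boundary band in at least two separate places) -- this rejects
#' T-junctions where one vessel merely terminates on the other;
#' (4) candidates closer than `merge_radius_px` are merged at their
#' score-weighted centroid. Candidates whose centroid falls inside the
#' optic-cup mask are dropped (vessel geometry there is too unreliable for
#' grading).
#'
#' @param scene a refined [vessel_scene()] (see [refine_av_labels()]); an
#'   error is raised if artery/vein labels exist outside the vessel mask.
#' @param merge_radius_px merge radius for nearby candidates (pixels).
#' @param check_radius_px radius of the skeleton-traversal disc (pixels).
#' @return data frame of candidates: `subject_id`, `image_id`, `row`,
#'   `col` (0-based, score-weighted centroids), `score`, `in_cup`. Only
#'   candidates outside the cup are returned.
#' @export
detect_candidates <- function(scene, merge_radius_px = 20,
                              check_radius_px = 15) {
  stopifnot(inherits(scene, "vessel_scene"))
  if (any(scene$av_map != 0L & scene$vessel_mask == 0L)) {
    stop("scene is not refined: artery/vein labels outside the vessel mask; ",
         "run refine_av_labels() first")
  }
  contact <- cpp_contact_pixels(scene$av_map)
  if (sum(contact) == 0L) return(empty_candidates(scene))
  lab <- cpp_label8(contact)
  k <- max(lab)
  sel <- which(lab > 0L, arr.ind = TRUE)
  ids <- factor(lab[sel], levels = seq_len(k))
  # 0-based centroids
  cent_r <- as.numeric(tapply(sel[, 1] - 1, ids, mean))
  cent_c <- as.numeric(tapply(sel[, 2] - 1, ids, mean))
  score <- as.numeric(table(ids))
  cand <- data.frame(row = cent_r, col = cent_c, score = score)

  # merge before the traversal check: the two contact arcs flanking the
  # occluded vessel then collapse onto the true crossing center, where the
  # disc test is meaningful
  cand <- merge_candidates(cand, merge_radius_px)

  skel_a <- skeletonize(as_mask(scene$av_map == 1L))$skeleton_mask
  skel_v <- skeletonize(as_mask(scene$av_map == 2L))$skeleton_mask

  # recentre each candidate on the intersection of the local artery and
  # vein centerlines (total-least-squares line fits to the label masks
  # inside a small window): contact-arc centroids are biased sideways when
  # the arcs flanking the occluded vessel are asymmetric. Fitting the
  # masks (not the skeletons) keeps the estimate exactly flip-symmetric.
  mask_a <- as_mask(scene$av_map == 1L)
  mask_v <- as_mask(scene$av_map == 2L)
  for (i in seq_len(nrow(cand))) {
    xy <- snap_to_intersection(mask_a, mask_v,
                               c(cand$row[i], cand$col[i]),
                               window = check_radius_px + 5)
    if (!is.null(xy)) {
      cand$row[i] <- xy[1]
      cand$col[i] <- xy[2]
    }
  }
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    traverses_disc(skel_a, c(cand$row[i], cand$col[i]), check_radius_px) &&
      traverses_disc(skel_v, c(cand$row[i], cand$col[i]), check_radius_px)
  }, logical(1))
  if (!any(keep)) return(empty_candidates(scene))
  cand <- cand[keep, , drop = FALSE]
  in_cup <- rep(FALSE, nrow(cand))
  if (!is.null(scene$cup_mask)) {
    rr <- pmin(pmax(round(cand$row) + 1L, 1L), nrow(scene$cup_mask))
    cc <- pmin(pmax(round(cand$col) + 1L, 1L), ncol(scene$cup_mask))
    in_cup <- scene$cup_mask[cbind(rr, cc)] > 0L
  }
  out <- data.frame(subject_id = scene$subject_id, image_id = scene$image_id,
                    row = cand$row, col = cand$col, score = cand$score,
                    in_cup = in_cup, stringsAsFactors = FALSE)
  out[!out$in_cup, , drop = FALSE]
}

empty_candidates <- function(scene) {
  data.frame(subject_id = character(), image_id = character(),
             row = numeric(), col = numeric(), score = numeric(),
             in_cup = logical(), stringsAsFactors = FALSE)
}

# intersection of the principal-axis line fits of two pixel masks inside a
# window around xy (all 0-based); NULL when either fit is unsupported or
# the lines are too parallel / the intersection too far to be trustworthy
snap_to_intersection <- function(mask_a, mask_v, xy, window = 20,
                                 min_px = 5, max_shift = 12) {
  pa <- skeleton_points_near(mask_a, xy, window)
  pv <- skeleton_points_near(mask_v, xy, window)
  if (nrow(pa) < min_px || nrow(pv) < min_px) return(NULL)
  fit <- function(p) {
    ctr <- colMeans(p)
    sv <- La.svd(sweep(p, 2, ctr), nu = 0)
    list(ctr = ctr, dir = sv$vt[1, ])
  }
  fa <- fit(pa); fv <- fit(pv)
  # solve ctr_a + s*dir_a = ctr_v + t*dir_v
  A <- cbind(fa$dir, -fv$dir)
  if (abs(det(A)) < 0.17) return(NULL)   # crossing angle below ~10 degrees
  st <- solve(A, fv$ctr - fa$ctr)
  pt <- fa$ctr + st[1] * fa$dir
  if (sqrt(sum((pt - xy)^2)) > max_shift) return(NULL)
  pt
}

skeleton_points_near <- function(skel, xy, window) {
  H <- nrow(skel); W <- ncol(skel)
  r0 <- max(1L, floor(xy[1] - window) + 1L)
  r1 <- min(H, ceiling(xy[1] + window) + 1L)
  c0 <- max(1L, floor(xy[2] - window) + 1L)
  c1 <- min(W, ceiling(xy[2] + window) + 1L)
  sub <- skel[r0:r1, c0:c1, drop = FALSE]
  p <- which(sub == 1L, arr.ind = TRUE)
  cbind(p[, 1] + r0 - 2L, p[, 2] + c0 - 2L)  # back to 0-based full coords
}

# does the skeleton traverse the disc of radius R at xy (0-based)?
# Skeleton pixels inside the disc (with a small outer margin absorbing the
# occlusion gap of the vessel drawn underneath) are clustered; each cluster
# reaching the boundary zone (distance >= R - 1) counts as one boundary
# hit, or two when it reaches it on roughly opposite sides (angular
# separation > 120 degrees). Traversal requires >= 2 boundary hits; a
# branch merely terminating at the crossing yields 1.
traverses_disc <- function(skel, xy, radius, outer_margin = 4) {
  H <- nrow(skel); W <- ncol(skel)
  rout <- radius + outer_margin
  r0 <- max(1L, floor(xy[1] - rout) + 1L)
  r1 <- min(H, ceiling(xy[1] + rout) + 1L)
  c0 <- max(1L, floor(xy[2] - rout) + 1L)
  c1 <- min(W, ceiling(xy[2] + rout) + 1L)
  if (r0 > r1 || c0 > c1) return(FALSE)
  sub <- skel[r0:r1, c0:c1, drop = FALSE]
  rr <- matrix(seq(r0, r1) - 1, nrow(sub), ncol(sub))
  cc <- matrix(seq(c0, c1) - 1, nrow(sub), ncol(sub), byrow = TRUE)
  d2 <- (rr - xy[1])^2 + (cc - xy[2])^2
  disc <- sub == 1L & d2 <= rout^2
  if (sum(disc) == 0L) return(FALSE)
  lab <- cpp_label8(as_mask(disc * 1L))
  hits <- 0L
  for (g in seq_len(max(lab))) {
    selg <- lab == g & d2 >= (radius - 1)^2
    ng <- sum(selg)
    if (ng == 0L) next
    ang <- atan2(cc[selg] - xy[2], rr[selg] - xy[1])
    if (ng > 1L) {
      dd <- abs(outer(ang, ang, "-"))
      maxsep <- max(pmin(dd, 2 * pi - dd))
    } else maxsep <- 0
    hits <- hits + if (maxsep > 2 * pi / 3) 2L else 1L
    if (hits >= 2L) return(TRUE)
  }
  FALSE
}

# single-linkage merge of candidates closer than `radius`; score-weighted
# centroids, total score conserved
merge_candidates <- function(cand, radius) {
  n <- nrow(cand)
  if (n <= 1L) return(cand)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- sqrt((cand$row[i] - cand$row[j])^2 + (cand$col[i] - cand$col[j])^2)
      if (d < radius) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  out <- lapply(groups, function(ix) {
    w <- cand$score[ix]
    data.frame(row = sum(cand$row[ix] * w) / sum(w),
               col = sum(cand$col[ix] * w) / sum(w),
               score = sum(w))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract a patch centered at a crossing point
#'
#' Cuts a `size_px` x `size_px` crop of the fundus centered at `xy`
#' (0-based row/col). For even sizes the crop covers rows
#' `[row - size/2, row + size/2)` (half-open). When the window exceeds the
#' image, the fundus is reflect-padded first, so the output always has the
#' requested size.
#'
#' @param scene a [vessel_scene()].
#' @param xy 0-based integer (row, col) center.
#' @param size_px patch side length (default 150).
#' @return an object of class `labeled_patch`: list with `pixels`
#'   (size x size x 3 array), `center_xy`, and optional `is_valid` /
#'   `grade` fields (both `NA` here; filled by manifests or classifiers).
#' @export
extract_patch <- function(scene, xy, size_px = 150L) {
  stopifnot(inherits(scene, "vessel_scene"))
  if (size_px < 1L) stop("size_px must be at least 1")
  H <- dim(scene$fundus)[1]; W <- dim(scene$fundus)[2]
  r <- round(xy[1]); c <- round(xy[2])
  if (r < 0 || c < 0 || r >= H || c >= W) stop("xy out of image bounds")
  off <- size_px %/% 2L
  rows <- reflect_index(seq(r - off + 1L, length.out = size_px), H)
  cols <- reflect_index(seq(c - off + 1L, length.out = size_px), W)
  structure(list(pixels = scene$fundus[rows, cols, , drop = FALSE],
                 center_xy = c(r, c), is_valid = NA, grade = NA_character_),
            class = "labeled_patch")
}

#' Match detected candidates against planted ground truth
#'
#' Greedy one-to-one matching by ascending distance: the closest
#' (candidate, truth) pair within `tol_px` is matched first, both are
#' removed, and so on. Matched pairs are true positives, unmatched
#' candidates false positives, unmatched truths false negatives.
#'
#' @param candidates data frame with `row`, `col` (as from
#'   [detect_candidates()]).
#' @param truth data frame with `row`, `col` (as from [generate_scene()]).
#' @param tol_px matching tolerance in pixels (> 0).
#' @return list with counts `tp`, `fp`, `fn` and the matched index pairs.
#' @export
match_candidates <- function(candidates, truth, tol_px = 5) {
  stopifnot(tol_px > 0)
  nc <- nrow(candidates); nt <- nrow(truth)
  if (nc == 0L || nt == 0L) {
    return(list(tp = 0L, fp = nc, fn = nt,
                pairs = matrix(integer(0), 0, 2)))
  }
  d <- outer(candidates$row, truth$row, "-")^2 +
    outer(candidates$col, truth$col, "-")^2
  d <- sqrt(d)
  pairs <- NULL
  free_c <- rep(TRUE, nc); free_t <- rep(TRUE, nt)
  repeat {
    d_act <- d
    d_act[!free_c, ] <- Inf
    d_act[, !free_t] <- Inf
    m <- which.min(d_act)
    if (length(m) == 0L || d_act[m] > tol_px) break
    i <- (m - 1L) %% nc + 1L
    j <- (m - 1L) %/% nc + 1L
    pairs <- rbind(pairs, c(i, j))
    free_c[i] <- FALSE; free_t[j] <- FALSE
    if (!any(free_c) || !any(free_t)) break
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  list(tp = tp, fp = nc - tp, fn = nt - tp,
       pairs = if (is.null(pairs)) matrix(integer(0), 0, 2) else pairs)
}
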