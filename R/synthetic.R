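#' Specification of a synthetic retinal scene
#'
#' Describes a seeded synthetic fundus scene with planted arterio-venous
#' crossings. Each crossing consists of one artery and one vein tube
#' (smooth spline-jittered centerlines) intersecting transversally at a
#' known point. The z-order at the overlap is drawn per crossing: with
#' probability `z_order_artery_over_prob` the artery runs over the vein
#' (a *valid*, diagnostically usable crossing, which then receives a
#' severity grade); otherwise the vein covers the artery (invalid). Grade
#' morphology follows the four-level severity scale based on venular
#' caliber narrowing at the crossing edges: the vein caliber on each side
#' of the crossing is scaled by the grade's two narrowing factors.
#'
#' Defaults mirror the label frequencies of the motivating grading study:
#' grade proportions `(1177, 816, 457, 57) / 2507` over
#' none/mild/moderate/severe and a valid-crossing probability of
#' `2507 / 4240`.
#'
#' @param image_size integer (H, W) in pixels.
#' @param n_crossings number of planted crossings.
#' @param artery_caliber_px,vein_caliber_px nominal tube calibers
#'   (diameters) in pixels, at least 2.
#' @param z_order_artery_over_prob probability that the artery is drawn on
#'   top (the crossing is valid).
#' @param grade_distribution probabilities over
#'   `c("none", "mild", "moderate", "severe")`; must sum to 1.
#' @param narrowing_profile named list mapping each grade to its two edge
#'   factors in (0, 1]; factor 1 means no narrowing.
#' @param cup_center,cup_radius optional optic-cup disc (pixels); `NULL`
#'   for no cup zone.
#' @param noise_level standard deviation of additive Gaussian pixel noise
#'   on the fundus (0 disables).
#' @param seed integer seed; identical specs produce byte-identical scenes.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(512L, 512L),
                       n_crossings = 4L,
                       artery_caliber_px = 6,
                       vein_caliber_px = 10,
                       z_order_artery_over_prob = 2507 / 4240,
                       grade_distribution = c(1177, 816, 457, 57) / 2507,
                       narrowing_profile = list(
                         none = c(1, 1), mild = c(0.85, 0.85),
                         moderate = c(0.6, 1), severe = c(0.6, 0.6)),
                       cup_center = NULL, cup_radius = NULL,
                       noise_level = 0.02, seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 150),
            n_crossings >= 0, length(grade_distribution) == 4L)
  if (artery_caliber_px < 2 || vein_caliber_px < 2) {
    stop("calibers must be at least 2 px")
  }
  if (abs(sum(grade_distribution) - 1) > 1e-9) {
    stop("grade_distribution must sum to 1 (within 1e-9)")
  }
  if (z_order_artery_over_prob < 0 || z_order_artery_over_prob > 1) {
    stop("z_order_artery_over_prob must lie in [0, 1]")
  }
  fac <- unlist(narrowing_profile)
  if (any(fac <= 0) || any(fac > 1)) {
    stop("narrowing factors must lie in (0, 1]")
  }
  stopifnot(all(GRADE_LEVELS %in% names(narrowing_profile)))
  if (is.null(cup_center) != is.null(cup_radius)) {
    stop("cup_center and cup_radius must be given together")
  }
  if (noise_level < 0) stop("noise_level must be non-negative")
  structure(list(
    image_size = as.integer(image_size), n_crossings = as.integer(n_crossings),
    artery_caliber_px = artery_caliber_px, vein_caliber_px = vein_caliber_px,
    z_order_artery_over_prob = z_order_artery_over_prob,
    grade_distribution = grade_distribution,
    narrowing_profile = narrowing_profile,
    cup_center = cup_center, cup_radius = cup_radius,
    noise_level = noise_level, seed = as.integer(seed)),
    class = "scene_spec")
}

GRADE_LEVELS <- c("none", "mild", "moderate", "severe")

#' Co-registered retinal scene rasters
#'
#' Container for one fundus scene: the RGB image, its binary vessel mask,
#' the artery/vein code map (0 background, 1 artery, 2 vein) and an
#' optional optic-cup mask, all sharing the same height and width.
#'
#' @param fundus H x W x 3 numeric array in \[0, 1\].
#' @param vessel_mask H x W integer matrix in \{0, 1\}.
#' @param av_map H x W integer matrix with codes \{0, 1, 2\}.
#' @param cup_mask optional H x W integer matrix in \{0, 1\}.
#' @param subject_id,image_id identifiers carried through manifests.
#' @return an object of class `vessel_scene`.
#' @export
vessel_scene <- function(fundus, vessel_mask, av_map, cup_mask = NULL,
                         subject_id = NA_character_, image_id = NA_character_) {
  d <- dim(fundus)
  stopifnot(length(d) == 3L, d[3] == 3L)
  stopifnot(identical(dim(vessel_mask), d[1:2]),
            identical(dim(av_map), d[1:2]))
  if (!is.null(cup_mask)) stopifnot(identical(dim(cup_mask), d[1:2]))
  structure(list(fundus = fundus, vessel_mask = as_mask(vessel_mask),
                 av_map = as_mask(av_map),
                 cup_mask = if (is.null(cup_mask)) NULL else as_mask(cup_mask),
                 subject_id = subject_id, image_id = image_id),
            class = "vessel_scene")
}

#' @export
print.vessel_scene <- function(x, ...) {
  d <- dim(x$fundus)
  cat("vessel_scene", if (!is.na(x$image_id)) x$image_id else "",
      sprintf("(%d x %d)", d[1], d[2]), "\n")
  cat(" vessel px:", sum(x$vessel_mask), " artery px:", sum(x$av_map == 1L),
      " vein px:", sum(x$av_map == 2L),
      if (!is.null(x$cup_mask)) paste(" cup px:", sum(x$cup_mask)) else "", "\n")
  invisible(x)
}

# smooth jittered centerline through `center` with direction theta;
# returns rows/cols/t sampled every 0.5 px, t in [-half_len, half_len]
vessel_centerline <- function(center, theta, half_len, wiggle = 5) {
  tt <- seq(-half_len, half_len, by = 0.5)
  u <- c(cos(theta), sin(theta))          # along-vessel unit (row, col)
  nv <- c(-sin(theta), cos(theta))        # perpendicular unit
  a <- runif(1, -wiggle, wiggle)
  b <- runif(1, -wiggle, wiggle)
  s <- tt / half_len
  disp <- a * s^2 + b * s^3               # zero displacement at the crossing
  list(rows = center[1] + tt * u[1] + disp * nv[1],
       cols = center[2] + tt * u[2] + disp * nv[2],
       t = tt, theta = theta)
}

# per-point vein radii implementing grade narrowing: full factor within
# `flat` px of the crossing, linear taper back to nominal by `taper` px
vein_radii <- function(tt, nominal_radius, factors, flat = 35, taper = 50) {
  fac <- ifelse(tt < 0, factors[1], factors[2])
  at <- pmin(pmax((abs(tt) - flat) / (taper - flat), 0), 1)
  nominal_radius * (fac + (1 - fac) * at)
}

# render one crossing's two tubes onto the running rasters; z-order encoded
# both in the av map and in the fundus paint order
render_crossing <- function(canvas, center, is_valid, factors, spec) {
  H <- nrow(canvas$vessel); W <- ncol(canvas$vessel)
  theta_a <- runif(1, 0, pi)
  sgn <- sample(c(-1, 1), 1)
  theta_v <- (theta_a + sgn * runif(1, pi / 4, pi / 2)) %% pi
  half_len <- 60
  cl_a <- vessel_centerline(center, theta_a, half_len)
  cl_v <- vessel_centerline(center, theta_v, half_len)
  r_a <- rep(spec$artery_caliber_px / 2, length(cl_a$t))
  r_v <- vein_radii(cl_v$t, spec$vein_caliber_px / 2, factors)

  blank <- matrix(0L, H, W)
  m_a <- cpp_stamp_tube(blank, cl_a$rows, cl_a$cols, r_a, 1L)
  m_v <- cpp_stamp_tube(blank, cl_v$rows, cl_v$cols, r_v, 1L)

  canvas$vessel[m_a == 1L | m_v == 1L] <- 1L
  local_av <- matrix(0L, H, W)
  if (is_valid) {             # artery on top
    local_av[m_v == 1L] <- 2L
    local_av[m_a == 1L] <- 1L
  } else {                    # vein on top
    local_av[m_a == 1L] <- 1L
    local_av[m_v == 1L] <- 2L
  }
  canvas$av[local_av != 0L] <- local_av[local_av != 0L]

  shade_a <- 0.75 + runif(1, -0.03, 0.03)
  col_a <- c(shade_a, 0.32, 0.22)
  shade_v <- 0.38 + runif(1, -0.03, 0.03)
  col_v <- c(shade_v, 0.14, 0.16)
  paint <- function(fund, m, col) {
    sel <- m == 1L
    for (ch in 1:3) {
      plane <- fund[, , ch]
      plane[sel] <- col[ch]
      fund[, , ch] <- plane
    }
    fund
  }
  if (is_valid) {
    canvas$fundus <- paint(canvas$fundus, m_v, col_v)
    canvas$fundus <- paint(canvas$fundus, m_a, col_a)
  } else {
    canvas$fundus <- paint(canvas$fundus, m_a, col_a)
    canvas$fundus <- paint(canvas$fundus, m_v, col_v)
  }
  canvas$theta <- c(artery = theta_a, vein = theta_v)
  canvas
}

#' Generate one synthetic retinal scene
#'
#' Draws `spec$n_crossings` well-separated crossing sites, renders the two
#' vessel tubes of each with the drawn z-order and grade morphology, and
#' returns the rasters together with the planted ground truth. Where the
#' crossing is valid, artery pixels overwrite vein pixels at the overlap
#' (and conversely when invalid), both in the artery/vein map and in the
#' painted fundus appearance. Identical specs (including seed) produce
#' byte-identical output.
#'
#' @param spec a [scene_spec()].
#' @param subject_id,image_id identifiers stored in the scene and records.
#' @return list with elements `scene` (a [vessel_scene()]) and `truth`, a
#'   data frame of ground-truth records with 0-based pixel coordinates
#'   (`row`, `col`), `is_valid`, `grade` (`NA` when invalid), the tube
#'   angles, and the identifiers.
#' @export
generate_scene <- function(spec, subject_id = "s1", image_id = "img1") {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, generate_scene_impl(spec, subject_id, image_id))
}

# unseeded core so that dataset generation can stream scenes from one RNG
generate_scene_impl <- function(spec, subject_id, image_id) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  margin <- 70
  min_sep <- 140
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  max_tries <- 200L * max(1L, spec$n_crossings)
  while (nrow(centers) < spec$n_crossings) {
    if (tries >= max_tries) {
      stop(sprintf(paste0("could not place %d crossings in a %d x %d image ",
                          "after %d tries; reduce n_crossings or enlarge ",
                          "the image"),
                   spec$n_crossings, H, W, tries))
    }
    tries <- tries + 1L
    cand <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                           byrow = TRUE))^2)) >= min_sep)) {
      centers <- rbind(centers, cand)
    }
  }

  fundus <- array(0, dim = c(H, W, 3))
  bg <- c(0.87, 0.55, 0.30)
  for (ch in 1:3) fundus[, , ch] <- bg[ch]

  cup_mask <- NULL
  if (!is.null(spec$cup_center)) {
    rr <- matrix(seq_len(H) - 1, H, W)
    cc <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
    inside <- (rr - spec$cup_center[1])^2 + (cc - spec$cup_center[2])^2 <=
      spec$cup_radius^2
    cup_mask <- matrix(0L, H, W)
    cup_mask[inside] <- 1L
    for (ch in 1:3) {
      plane <- fundus[, , ch]
      plane[inside] <- pmin(plane[inside] + 0.12, 1)
      fundus[, , ch] <- plane
    }
  }

  canvas <- list(vessel = matrix(0L, H, W), av = matrix(0L, H, W),
                 fundus = fundus)
  records <- NULL
  for (k in seq_len(spec$n_crossings)) {
    is_valid <- runif(1) < spec$z_order_artery_over_prob
    grade <- NA_character_
    factors <- c(1, 1)
    if (is_valid) {
      gi <- sample.int(4L, 1L, prob = spec$grade_distribution)
      grade <- GRADE_LEVELS[gi]
      factors <- spec$narrowing_profile[[grade]]
      if (runif(1) < 0.5) factors <- rev(factors)  # random edge orientation
    }
    canvas <- render_crossing(canvas, centers[k, ], is_valid, factors, spec)
    records <- rbind(records, data.frame(
      subject_id = subject_id, image_id = image_id,
      row = as.integer(round(centers[k, 1])),
      col = as.integer(round(centers[k, 2])),
      is_valid = is_valid, grade = grade,
      artery_theta = unname(canvas$theta["artery"]),
      vein_theta = unname(canvas$theta["vein"]),
      stringsAsFactors = FALSE))
  }
  if (is.null(records)) {
    records <- data.frame(subject_id = character(), image_id = character(),
                          row = integer(), col = integer(),
                          is_valid = logical(), grade = character(),
                          artery_theta = numeric(), vein_theta = numeric(),
                          stringsAsFactors = FALSE)
  }

  if (spec$noise_level > 0) {
    canvas$fundus <- canvas$fundus +
      array(rnorm(H * W * 3, 0, spec$noise_level), dim = c(H, W, 3))
  }
  canvas$fundus <- pmin(pmax(canvas$fundus, 0), 1)
  # quantize to 8 bits so in-memory scenes match their PNG round-trip
  canvas$fundus <- round(canvas$fundus * 255) / 255

  list(scene = vessel_scene(canvas$fundus, canvas$vessel, canvas$av,
                            cup_mask, subject_id, image_id),
       truth = records)
}

#' Generate a labelled synthetic patch dataset
#'
#' Renders `n_scenes` scenes (assigned round-robin to `subjects` synthetic
#' examinees), cuts a 150 x 150 patch at every planted crossing and returns
#' the patch stack with its manifest. Per-scene seeds are derived from
#' `spec$seed`, so the whole dataset is reproducible.
#'
#' @param spec a [scene_spec()]; its `seed` seeds the dataset.
#' @param n_scenes number of scenes to render (at least `subjects`).
#' @param subjects number of synthetic subjects.
#' @param patch_px patch side length in pixels.
#' @param render_patches if `FALSE`, only the manifest is returned (faster
#'   and lighter when just the label bookkeeping is needed).
#' @param out_dir optional directory; when given, patches are written as
#'   PNG files named `{image_id}_{row}_{col}.png` plus a `manifest.csv`
#'   with columns `subject_id, image_id, patch_path, row, col, is_valid,
#'   grade`.
#' @return list with `manifest` (data frame) and `patches`
#'   (150 x 150 x 3 x N array, or `NULL` when `render_patches = FALSE`).
#' @export
generate_dataset <- function(spec, n_scenes, subjects, patch_px = 150L,
                             render_patches = TRUE, out_dir = NULL) {
  stopifnot(inherits(spec, "scene_spec"), subjects >= 1,
            n_scenes >= subjects)
  scene_seeds <- with_seed(spec$seed,
                           sample.int(.Machine$integer.max - 1L, n_scenes))
  manifest <- vector("list", n_scenes)
  patch_list <- if (render_patches) vector("list", n_scenes) else NULL
  for (i in seq_len(n_scenes)) {
    sid <- sprintf("subj%03d", ((i - 1L) %% subjects) + 1L)
    iid <- sprintf("scene%04d", i)
    out <- with_seed(scene_seeds[i], generate_scene_impl(spec, sid, iid))
    tr <- out$truth
    tr$patch_path <- NA_character_
    if (render_patches && nrow(tr) > 0) {
      arr <- array(0, dim = c(patch_px, patch_px, 3, nrow(tr)))
      for (j in seq_len(nrow(tr))) {
        p <- extract_patch(out$scene, c(tr$row[j], tr$col[j]), patch_px)
        arr[, , , j] <- p$pixels
        if (!is.null(out_dir)) {
          fn <- file.path(out_dir, sprintf("%s_%d_%d.png", iid, tr$row[j],
                                           tr$col[j]))
          write_fundus_png(p$pixels, fn)
          tr$patch_path[j] <- fn
        }
      }
      patch_list[[i]] <- arr
    }
    manifest[[i]] <- tr
  }
  manifest <- do.call(rbind, manifest)
  cols <- c("subject_id", "image_id", "patch_path", "row", "col",
            "is_valid", "grade")
  manifest <- manifest[, c(cols, setdiff(names(manifest), cols))]
  patches <- NULL
  if (render_patches) {
    n <- nrow(manifest)
    patches <- array(0, dim = c(patch_px, patch_px, 3, n))
    at <- 1L
    for (arr in patch_list) {
      if (is.null(arr)) next
      k <- dim(arr)[4]
      patches[, , , at:(at + k - 1L)] <- arr
      at <- at + k
    }
  }
  if (!is.null(out_dir)) {
    write.csv(manifest[, cols], file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  list(manifest = manifest, patches = patches)
}

#' Measure a vessel caliber by perpendicular profile
#'
#' Samples the mask along the perpendicular of the vessel direction at a
#' point `offset_px` along the vessel from `xy` and returns the width of
#' the contiguous run of vessel pixels covering that point (in pixels).
#' Used to verify planted narrowing morphology.
#'
#' @param mask binary matrix (e.g. `av_map == 2` for the vein).
#' @param xy 0-based (row, col) of the crossing.
#' @param theta vessel direction in radians (as recorded in the ground
#'   truth).
#' @param offset_px signed distance along the vessel from `xy`.
#' @param max_halfwidth maximum half-width scanned, in pixels.
#' @return width in pixels (0 when the profile centre is off the vessel).
#' @export
measure_caliber <- function(mask, xy, theta, offset_px, max_halfwidth = 20) {
  u <- c(cos(theta), sin(theta))
  nv <- c(-sin(theta), cos(theta))
  p <- xy + offset_px * u
  step <- 0.2
  s <- seq(-max_halfwidth, max_halfwidth, by = step)
  rr <- round(p[1] + s * nv[1]) + 1L
  cc <- round(p[2] + s * nv[2]) + 1L
  ok <- rr >= 1L & rr <= nrow(mask) & cc >= 1L & cc <= ncol(mask)
  hit <- logical(length(s))
  hit[ok] <- mask[cbind(rr[ok], cc[ok])] > 0
  mid <- which.min(abs(s))
  if (!hit[mid]) return(0)
  i0 <- mid
  while (i0 > 1L && hit[i0 - 1L]) i0 <- i0 - 1L
  i1 <- mid
  while (i1 < length(hit) && hit[i1 + 1L]) i1 <- i1 + 1L
  (i1 - i0 + 1L) * step
}
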