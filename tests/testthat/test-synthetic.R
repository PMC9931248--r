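test_that("scene specs enforce their invariants", {
  expect_error(scene_spec(artery_caliber_px = 1), "calibers")
  expect_error(scene_spec(grade_distribution = c(0.5, 0.5, 0.1, 0)),
               "sum to 1")
  expect_error(scene_spec(z_order_artery_over_prob = 1.2), "0, 1")
  expect_error(scene_spec(narrowing_profile = list(
    none = c(1, 1), mild = c(0, 1), moderate = c(1, 1), severe = c(1, 1))),
    "narrowing factors")
  expect_error(scene_spec(cup_center = c(10, 10)), "together")
  expect_error(scene_spec(noise_level = -0.1), "non-negative")
})

test_that("generation is deterministic and plants the requested crossings", {
  spec <- scene_spec(n_crossings = 3, seed = 123)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a, b)
  expect_equal(nrow(a$truth), 3)
  expect_true(all(a$truth$row >= 0 & a$truth$row < 512))
  expect_true(all(a$truth$col >= 0 & a$truth$col < 512))
  # grade present iff valid
  expect_equal(is.na(a$truth$grade), !a$truth$is_valid)
})

test_that("artery/vein labels are conserved within the vessel mask", {
  for (seed in c(4, 9)) {
    o <- generate_scene(scene_spec(seed = seed))
    expect_equal(sum(o$scene$av_map != 0L & o$scene$vessel_mask == 0L), 0)
    # planted crossings recoverable: both vessels present within half the
    # occluding tube's caliber plus 2 px of the crossing point (the vessel
    # drawn underneath is covered by the other tube's half-width at the
    # center itself)
    av <- o$scene$av_map
    w <- ceiling(max(6, 10) / 2) + 2L
    for (j in seq_len(nrow(o$truth))) {
      r <- o$truth$row[j] + 1L; c <- o$truth$col[j] + 1L
      win <- av[max(1, r - w):min(nrow(av), r + w),
                max(1, c - w):min(ncol(av), c + w)]
      expect_true(any(win == 1L))
      expect_true(any(win == 2L))
    }
  }
})

test_that("overcrowded specs fail with an informative error", {
  expect_error(generate_scene(scene_spec(image_size = c(200, 200),
                                         n_crossings = 30, seed = 1)),
               "30 crossings in a 200 x 200")
})

test_that("z-order probability controls validity labels", {
  o0 <- generate_scene(scene_spec(n_crossings = 4,
                                  z_order_artery_over_prob = 0, seed = 2))
  expect_true(all(!o0$truth$is_valid))
  o1 <- generate_scene(scene_spec(n_crossings = 4,
                                  z_order_artery_over_prob = 1, seed = 2))
  expect_true(all(o1$truth$is_valid))
})

test_that("vein caliber reflects the planted narrowing factors", {
  # grade none: nominal caliber either side of the crossing
  spec <- scene_spec(noise_level = 0, n_crossings = 2,
                     z_order_artery_over_prob = 1,
                     grade_distribution = c(1, 0, 0, 0), seed = 7)
  o <- generate_scene(spec)
  vm <- o$scene$av_map == 2L
  storage.mode(vm) <- "integer"
  for (k in seq_len(nrow(o$truth))) {
    for (off in c(-20, 20)) {
      w <- measure_caliber(vm, c(o$truth$row[k], o$truth$col[k]),
                           o$truth$vein_theta[k], off)
      expect_lt(abs(w - 10), 1.01)
    }
  }
  # severe with factors (0.5, 0.5): half caliber on both sides
  spec2 <- scene_spec(noise_level = 0, n_crossings = 2,
                      z_order_artery_over_prob = 1,
                      grade_distribution = c(0, 0, 0, 1),
                      narrowing_profile = list(
                        none = c(1, 1), mild = c(0.85, 0.85),
                        moderate = c(0.6, 1), severe = c(0.5, 0.5)),
                      seed = 11)
  o2 <- generate_scene(spec2)
  vm2 <- o2$scene$av_map == 2L
  storage.mode(vm2) <- "integer"
  for (k in seq_len(nrow(o2$truth))) {
    for (off in c(-20, 20)) {
      w <- measure_caliber(vm2, c(o2$truth$row[k], o2$truth$col[k]),
                           o2$truth$vein_theta[k], off)
      expect_lt(abs(w - 5), 1.01)
    }
  }
})

test_that("datasets assign scenes to subjects round-robin", {
  ds <- generate_dataset(scene_spec(n_crossings = 2, seed = 31),
                         n_scenes = 10, subjects = 5,
                         render_patches = FALSE)
  map <- unique(ds$manifest[, c("subject_id", "image_id")])
  expect_equal(nrow(map), 10)
  expect_true(all(table(map$subject_id) == 2))
  # every image belongs to exactly one subject
  expect_equal(length(unique(map$image_id)), 10)
})

test_that("dataset patches are crossing-centered 150x150 crops", {
  ds <- generate_dataset(scene_spec(n_crossings = 2, seed = 32),
                         n_scenes = 2, subjects = 1)
  expect_equal(dim(ds$patches)[1:3], c(150, 150, 3))
  expect_equal(dim(ds$patches)[4], nrow(ds$manifest))
  expect_true(all(c("subject_id", "image_id", "patch_path", "row", "col",
                    "is_valid", "grade") %in% names(ds$manifest)))
})

test_that("empirical grade frequencies follow the requested distribution", {
  p <- c(1177, 816, 457, 57) / 2507
  ds <- generate_dataset(scene_spec(n_crossings = 4,
                                    z_order_artery_over_prob = 1, seed = 33),
                         n_scenes = 100, subjects = 10,
                         render_patches = FALSE)
  counts <- table(factor(ds$manifest$grade,
                         c("none", "mild", "moderate", "severe")))
  n <- sum(counts)
  # within 3 standard deviations of the multinomial expectation
  expect_true(all(abs(counts - n * p) <= 3 * sqrt(n * p * (1 - p)) + 1))
})
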