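# Shared fixtures, built in code and memoized across test files.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, force(expr), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

# strong-signal regime: clean rasters, wide vein, narrowing factors far
# apart -- the separability condition under which the learning-based
# stages are exercised
strong_grading_spec <- function(seed = 1L, ...) {
  scene_spec(noise_level = 0, z_order_artery_over_prob = 1,
             vein_caliber_px = 12, artery_caliber_px = 6,
             narrowing_profile = list(none = c(1, 1), mild = c(0.65, 0.65),
                                      moderate = c(0.35, 1),
                                      severe = c(0.35, 0.35)),
             seed = seed, ...)
}

strong_validity_spec <- function(seed = 1L, ...) {
  scene_spec(noise_level = 0, vein_caliber_px = 12, artery_caliber_px = 6,
             seed = seed, ...)
}

# small labelled datasets (train/val/test by grouped subject split)
split_patch_data <- function(ds, labels, split_seed = 3L) {
  sp <- group_split(ds$manifest, seed = split_seed)
  ix <- split(seq_len(nrow(ds$manifest)), sp$manifest$split)
  lapply(ix, function(i)
    patch_dataset(ds$patches[, , , i, drop = FALSE], labels[i]))
}

small_grading_data <- function() {
  cached("small_grading_data", {
    ds <- generate_dataset(strong_grading_spec(77), n_scenes = 40,
                           subjects = 10)
    split_patch_data(ds, grade_to_int(ds$manifest$grade))
  })
}

small_validity_data <- function() {
  cached("small_validity_data", {
    ds <- generate_dataset(strong_validity_spec(88), n_scenes = 40,
                           subjects = 10)
    split_patch_data(ds, as.integer(ds$manifest$is_valid))
  })
}

# quickly trained models for mechanics tests (not accuracy checks)
quick_grading_submodel <- function() {
  cached("quick_grading_submodel", {
    d <- small_grading_data()
    train_submodel(submodel_spec("tiny"), d$train, d$val, 4L, epochs = 4L,
                   lr = 1e-3, seed = 5)
  })
}

quick_validity_submodel <- function() {
  cached("quick_validity_submodel", {
    d <- small_validity_data()
    train_submodel(submodel_spec("tiny"), d$train, d$val, 2L, epochs = 4L,
                   lr = 1e-3, seed = 6)
  })
}

# quick models + a small scene directory for pipeline-level tests
pipeline_fixture <- function() {
  cached("pipeline_fixture", {
    vm <- quick_validity_submodel()
    gm <- quick_grading_submodel()
    sdir <- tempfile("scenes_")
    dir.create(sdir)
    truth <- NULL
    for (i in 1:3) {
      sp <- strong_validity_spec(seed = 600 + i)
      o <- generate_scene(sp, subject_id = paste0("s", i),
                          image_id = paste0("img", i))
      write_scene(o$scene, sdir)
      truth <- rbind(truth, o$truth)
    }
    list(vm = vm, gm = gm, sdir = sdir, truth = truth)
  })
}

# plus-sign scene: horizontal artery over vertical vein, crossing at
# (center, center), calibers 10
plus_scene <- function(H = 200, W = 200, cup = FALSE) {
  av <- matrix(0L, H, W)
  r0 <- H %/% 2 - 4; c0 <- W %/% 2 - 4
  av[r0:(r0 + 9), 20:(W - 20)] <- 1L
  vein <- matrix(0L, H, W)
  vein[20:(H - 20), c0:(c0 + 9)] <- 1L
  av[vein == 1L & av == 0L] <- 2L
  vessel <- (av > 0) * 1L
  storage.mode(vessel) <- "integer"
  cup_mask <- NULL
  if (cup) {
    rr <- matrix(seq_len(H) - 1, H, W)
    cc <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
    cup_mask <- matrix(0L, H, W)
    cup_mask[(rr - H / 2)^2 + (cc - W / 2)^2 <= 40^2] <- 1L
  }
  vessel_scene(array(0.5, c(H, W, 3)), vessel, av, cup_mask,
               subject_id = "s1", image_id = "plus")
}
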