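test_that("a planted plus-sign crossing yields one centered candidate", {
  sc <- plus_scene()
  cand <- detect_candidates(sc)
  expect_equal(nrow(cand), 1)
  expect_lt(sqrt((cand$row - 99.5)^2 + (cand$col - 99.5)^2), 5)
  expect_true(cand$score >= 1)
})

test_that("parallel tubes and T-junctions yield no candidates", {
  H <- 200; W <- 200
  av <- matrix(0L, H, W)
  av[50:59, 20:180] <- 1L
  av[70:79, 20:180] <- 2L   # parallel, 10 px apart
  sc <- vessel_scene(array(0.5, c(H, W, 3)),
                     mdtnet:::as_mask((av > 0) * 1L), av)
  expect_equal(nrow(detect_candidates(sc)), 0)

  av2 <- matrix(0L, H, W)
  av2[20:180, 96:105] <- 2L
  av2[96:105, 20:95] <- 1L  # artery terminates on the vein
  sc2 <- vessel_scene(array(0.5, c(H, W, 3)),
                      mdtnet:::as_mask((av2 > 0) * 1L), av2)
  expect_equal(nrow(detect_candidates(sc2)), 0)
})

test_that("candidates inside the cup zone are excluded", {
  sc <- plus_scene(cup = TRUE)   # crossing dead-center in the cup
  expect_equal(nrow(detect_candidates(sc)), 0)
  # same geometry without cup finds it
  expect_equal(nrow(detect_candidates(plus_scene())), 1)
})

test_that("unrefined scenes are rejected", {
  sc <- plus_scene()
  sc$av_map[1, 1] <- 1L   # label off the vessel mask
  expect_error(detect_candidates(sc), "not refined")
})

test_that("detector is flip-equivariant", {
  for (seed in c(51, 52)) {
    o <- generate_scene(scene_spec(noise_level = 0, seed = seed))
    sc <- o$scene
    cand <- detect_candidates(sc)
    H <- nrow(sc$vessel_mask)
    fl <- vessel_scene(sc$fundus[H:1, , , drop = FALSE],
                       sc$vessel_mask[H:1, ], sc$av_map[H:1, ])
    cand_f <- detect_candidates(fl)
    expect_equal(nrow(cand), nrow(cand_f))
    if (nrow(cand) > 0) {
      m <- match_candidates(
        data.frame(row = H - 1 - cand_f$row, col = cand_f$col),
        cand, tol_px = 1)
      expect_equal(m$tp, nrow(cand))
    }
  }
})

test_that("merging conserves score", {
  cand <- data.frame(row = c(10, 14, 80), col = c(10, 12, 80),
                     score = c(5, 3, 7))
  merged <- mdtnet:::merge_candidates(cand, 20)
  expect_equal(nrow(merged), 2)
  expect_equal(sum(merged$score), 15)
  i <- which(merged$score == 8)
  expect_equal(merged$row[i], (10 * 5 + 14 * 3) / 8)
})

test_that("patch extraction uses the floor-offset centered crop", {
  o <- generate_scene(scene_spec(seed = 15))
  sc <- o$scene
  p <- extract_patch(sc, c(300, 300), 150)
  expect_equal(dim(p$pixels), c(150, 150, 3))
  # rows/cols 225..374 (0-based)
  expect_identical(p$pixels, sc$fundus[226:375, 226:375, , drop = FALSE])
  # near-border crop is reflect-padded to full size
  p2 <- extract_patch(sc, c(10, 10), 150)
  expect_equal(dim(p2$pixels), c(150, 150, 3))
  # reflection: row index -1 (0-based 9 - 75 + 65 = off-image) mirrors back
  expect_error(extract_patch(sc, c(-1, 10)), "bounds")
  expect_error(extract_patch(sc, c(10, 10), 0), "size_px")
})

test_that("patch of a 150x150 scene centered at (75,75) is the whole image", {
  f <- array(runif(150 * 150 * 3), c(150, 150, 3))
  sc <- vessel_scene(f, matrix(0L, 150, 150), matrix(0L, 150, 150))
  p <- extract_patch(sc, c(75, 75), 150)
  expect_identical(p$pixels, f)
})

test_that("greedy matching is one-to-one by ascending distance", {
  truth <- data.frame(row = c(10, 50, 90), col = c(10, 50, 90))
  m <- match_candidates(truth, truth, 5)
  expect_equal(c(m$tp, m$fp, m$fn), c(3, 0, 0))
  m2 <- match_candidates(truth[0, ], truth, 5)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 0, 3))
  # two candidates near one truth: one TP, one FP
  cand <- data.frame(row = c(10, 12), col = c(10, 10))
  m3 <- match_candidates(cand, truth[1, ], 5)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(1, 1, 0))
  # closest pair matched first
  expect_equal(m3$pairs[1, 1], 1)
})
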