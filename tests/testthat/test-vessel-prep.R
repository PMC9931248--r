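test_that("a wide bar thins to its full-length centerline", {
  m <- matrix(0L, 20, 120)
  m[9:13, 11:110] <- 1L   # 5 px wide, length 100
  sk <- skeletonize(m)
  expect_true(all(sk$skeleton_mask[m == 0L] == 0L))  # skeleton within mask
  n <- sum(sk$skeleton_mask)
  expect_gte(n, 98)
  expect_lte(n, 102)
  deg <- sk$branch_degree[sk$skeleton_mask == 1L]
  expect_true(all(deg <= 2))          # pure line: no branch points
  expect_equal(sum(deg == 1), 2)      # exactly two endpoints
})

test_that("thinning is idempotent on 1-px lines and preserves topology", {
  l <- matrix(0L, 10, 50)
  l[5, 5:45] <- 1L
  expect_identical(skeletonize(l)$skeleton_mask, l)
  d <- matrix(0L, 40, 40)
  for (i in 5:35) d[i, i] <- 1L       # diagonal line
  expect_identical(skeletonize(d)$skeleton_mask, d)

  # annulus: skeleton keeps one component and one cycle
  rr <- matrix(seq_len(60), 60, 60)
  cc <- t(rr)
  ring <- matrix(0L, 60, 60)
  d2 <- (rr - 30)^2 + (cc - 30)^2
  ring[d2 <= 25^2 & d2 >= 15^2] <- 1L
  sk <- skeletonize(ring)$skeleton_mask
  expect_equal(max(mdtnet:::cpp_label8(sk)), 1)
  # a cycle has no endpoints
  deg <- mdtnet:::cpp_neighbor_count(sk)
  expect_equal(sum(sk == 1L & deg == 1L), 0)
  expect_identical(skeletonize(matrix(0L, 5, 5))$skeleton_mask,
                   matrix(0L, 5, 5))
})

test_that("skeleton component count equals mask component count", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(0L, 80, 80)
    for (b in 1:3) {
      r <- sample(10:70, 1); c <- sample(10:70, 1)
      m <- mdtnet:::cpp_stamp_tube(m, r + seq(-10, 10) * runif(1, -1, 1),
                                   c + seq(-10, 10), rep(3, 21), 1L)
    }
    sk <- skeletonize(m)$skeleton_mask
    expect_equal(max(mdtnet:::cpp_label8(sk)), max(mdtnet:::cpp_label8(m)))
    expect_true(all(sk[m == 0L] == 0L))
  }
})

test_that("label refinement homogenizes segments by majority", {
  # one straight tube, 90% artery / 10% vein labels -> all artery
  m <- matrix(0L, 40, 120)
  m[18:22, 11:110] <- 1L
  av <- m * 1L
  av[18:22, 96:105] <- 2L   # 10% vein stripe
  sc <- vessel_scene(array(0.5, c(40, 120, 3)), m, av)
  ref <- refine_av_labels(sc)
  expect_true(all(ref$av_map[m == 1L] == 1L))
  expect_identical(ref$vessel_mask, m)

  # exact 50/50 labels -> unknown (0)
  av2 <- m * 1L
  av2[18:22, 61:110] <- 2L
  ref2 <- refine_av_labels(vessel_scene(array(0.5, c(40, 120, 3)), m, av2))
  expect_true(all(ref2$av_map[m == 1L] == 0L))

  # small vein island inside a large artery segment is flipped
  av3 <- m * 1L
  av3[20, 50:52] <- 2L
  ref3 <- refine_av_labels(vessel_scene(array(0.5, c(40, 120, 3)), m, av3))
  expect_equal(sum(ref3$av_map == 2L), 0)
  expect_true(all(ref3$av_map[m == 1L] == 1L))
})

test_that("refinement clips to the mask, is idempotent, keeps the mask", {
  o <- generate_scene(scene_spec(seed = 14))
  sc <- o$scene
  av_spill <- sc$av_map
  av_spill[1:5, 1:5] <- 1L   # labels off the vessel mask
  sc$av_map <- av_spill
  r1 <- refine_av_labels(sc)
  expect_equal(sum(r1$av_map != 0L & r1$vessel_mask == 0L), 0)
  r2 <- refine_av_labels(r1)
  expect_identical(r1$av_map, r2$av_map)
  expect_identical(r1$vessel_mask, o$scene$vessel_mask)
  expect_error(refine_av_labels(
    vessel_scene(array(0, c(10, 10, 3)), matrix(0L, 10, 10),
                 matrix(0L, 10, 10))), "empty")
})
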