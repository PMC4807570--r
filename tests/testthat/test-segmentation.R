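test_that("threshold semantics are inclusive", {
  v <- array(c(2.5, 3.5, 4.5, 3.8, 0, 12), c(1, 2, 3))
  # boundary value included ("no less than")
  expect_equal(sum(threshold_mask(v, 3.8)), 3)   # 4.5, 3.8, 12
  # Threshold E band [3, 4]: only 3.5 and 3.8 of these values
  e <- threshold_mask(v, 3, 4)
  expect_equal(sort(v[e == 1]), c(3.5, 3.8))
  expect_true(all(threshold_mask(array(0, c(2, 2, 2)), 3.8) == 0))
  expect_error(threshold_mask(v, 4, 3), "lower")
  expect_true(all(threshold_mask(v, 3) %in% c(0L, 1L)))
})

test_that("dilate26 uses the full 3x3x3 structuring element", {
  m <- array(0L, c(5, 5, 5)); m[3, 3, 3] <- 1L
  d1 <- dilate26(m, 1)
  expect_equal(sum(d1), 27)
  expect_true(all(d1[2:4, 2:4, 2:4] == 1))
  corner <- array(0L, c(5, 5, 5)); corner[1, 1, 1] <- 1L
  expect_equal(sum(dilate26(corner, 1)), 8)   # clipped at the boundary
  expect_identical(sum(dilate26(m, 0)), sum(m))
  expect_equal(sum(dilate26(array(0L, c(4, 4, 4)), 1)), 0)
  # against the brute-force neighbourhood oracle on random masks
  for (seed in 1:3) {
    set.seed(seed)
    r <- array(rbinom(6^3, 1, 0.15), c(6, 6, 6))
    expect_equal(as.vector(dilate26(r, 1)),
                 as.vector(brute_force_dilate(r)))
  }
})

test_that("shift artifact mask selects and dilates negative voxels", {
  pos <- array(abs(rnorm(5^3)) + 0.1, c(5, 5, 5))
  expect_equal(sum(shift_artifact_mask(pos)), 0)
  one <- array(1, c(5, 5, 5)); one[3, 3, 3] <- -0.5
  expect_equal(sum(shift_artifact_mask(one)), 27)
})

test_that("segment_yttria equals the brute-force protocol evaluation", {
  for (seed in 1:50) {
    vols <- random_protocol_volumes(seed)
    got <- segment_yttria(vols$above, vols$below, vols$sub)
    want <- brute_force_segment(vols$above, vols$below, vols$sub)
    expect_identical(as.vector(got), as.vector(want))
    # and with the optional E exclusion enabled
    gotE <- segment_yttria(vols$above, vols$below, vols$sub,
                           segmentation_params(use_threshold_E = TRUE))
    wantE <- brute_force_segment(vols$above, vols$below, vols$sub,
                                 use_E = TRUE)
    expect_identical(as.vector(gotE), as.vector(wantE))
  }
})

test_that("all stages are strict binary volumes and i is inside C", {
  for (seed in 51:60) {
    vols <- random_protocol_volumes(seed)
    seg <- segment_yttria(vols$above, vols$below, vols$sub,
                          return_stages = TRUE)
    for (m in seg$masks) expect_true(all(m %in% c(0L, 1L)))
    expect_equal(sum(seg$final == 1 & seg$masks$C == 0), 0)
  }
})

test_that("protocol monotonicity properties hold", {
  vols <- random_protocol_volumes(99)
  base <- segment_yttria(vols$above, vols$below, vols$sub,
                         segmentation_params(threshold_C = 3))
  raised <- segment_yttria(vols$above, vols$below, vols$sub,
                           segmentation_params(threshold_C = 4))
  expect_equal(sum(raised == 1 & base == 0), 0)  # raising C never grows i
  g1 <- segment_yttria(vols$above, vols$below, vols$sub,
                       segmentation_params(dilation_iterations = 1),
                       return_stages = TRUE)$masks$g
  g2 <- segment_yttria(vols$above, vols$below, vols$sub,
                       segmentation_params(dilation_iterations = 2),
                       return_stages = TRUE)$masks$g
  expect_equal(sum(g1 == 1 & g2 == 0), 0)        # dilation never shrinks g
})

test_that("the alternative text reading of stage h is exposed", {
  vols <- random_protocol_volumes(7)
  seg <- segment_yttria(vols$above, vols$below, vols$sub,
                        segmentation_params(h_rule = "text"),
                        return_stages = TRUE)
  # text rule: h = g AND NOT C, so h and C are disjoint
  expect_equal(sum(seg$masks$h == 1 & seg$masks$C == 1), 0)
})

test_that("segment_yttria trivial and error cases", {
  air <- array(0, c(4, 6, 6))
  expect_equal(sum(segment_yttria(air, air, kes_subtract(air, air))), 0)
  v <- array(1, c(4, 6, 6))
  expect_error(segment_yttria(v, v[1:2, , ], kes_subtract(v, v)), "shape")
})

test_that("label_regions matches a flood-fill oracle", {
  empty <- label_regions(array(0L, c(4, 4, 4)))
  expect_equal(nrow(empty$summary), 0)
  two <- array(0L, c(10, 10, 10))
  two[2:4, 2:4, 2:4] <- 1L
  two[7:9, 7:9, 7:9] <- 1L
  res <- label_regions(two)
  expect_equal(sort(res$summary$voxels), c(27, 27))
  expect_equal(nrow(res$summary), 2)
  for (seed in 1:3) {
    set.seed(seed)
    r <- array(rbinom(20^3, 1, 0.3), c(20, 20, 20))
    res <- label_regions(r)
    expect_equal(sum(res$summary$voxels), sum(r))    # conservation
    expect_equal(sort(res$summary$voxels), flood_fill_sizes(r))
  }
  # bounding boxes cover their components
  expect_true(all(res$summary$z0 <= res$summary$z1))
})
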