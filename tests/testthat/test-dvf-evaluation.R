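test_that("error map follows the vector-difference definition", {
  d <- c(6L, 5L, 4L)
  gt <- const_field(d, c(0, 0, 0), direction = "SOT->EOT")
  same <- const_field(d, c(0, 0, 0), direction = "dEOT->EOT")
  expect_true(all(dvf_error_map(dvf_comparison(gt, same)) == 0))
  # constant (1, 2, 2) mm difference: 3-4-5 arithmetic gives 3 mm everywhere
  test <- const_field(d, c(1, 2, 2), direction = "dEOT->EOT")
  expect_true(all(abs(dvf_error_map(dvf_comparison(gt, test)) - 3) < 1e-12))
})

test_that("error map matches an elementwise brute-force recomputation", {
  set.seed(30)
  d <- c(8L, 8L, 8L)
  gt_v <- array(rnorm(prod(d) * 3), c(d, 3))
  te_v <- array(rnorm(prod(d) * 3), c(d, 3))
  gt <- vector_field(gt_v, direction = "SOT->EOT")
  te <- vector_field(te_v, direction = "dEOT->EOT")
  got <- dvf_error_map(dvf_comparison(gt, te))
  expect_equal(got, oracle_error_map(gt_v, te_v), tolerance = 1e-12)
})

test_that("error map is invariant to adding a common field to both sides", {
  set.seed(31)
  d <- c(6L, 6L, 6L)
  gt_v <- array(rnorm(prod(d) * 3), c(d, 3))
  te_v <- array(rnorm(prod(d) * 3), c(d, 3))
  common <- array(rnorm(prod(d) * 3, 0, 5), c(d, 3))
  e1 <- dvf_error_map(dvf_comparison(vector_field(gt_v),
                                     vector_field(te_v)))
  e2 <- dvf_error_map(dvf_comparison(vector_field(gt_v + common),
                                     vector_field(te_v + common)))
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("grid and direction mismatches are refused", {
  a <- const_field(c(4L, 4L, 4L), c(1, 0, 0))
  b <- const_field(c(4L, 4L, 5L), c(1, 0, 0))
  expect_error(dvf_comparison(a, b), "same grid")
  g <- const_field(c(4L, 4L, 4L), c(1, 0, 0), direction = "SOT->EOT")
  t_bad <- const_field(c(4L, 4L, 4L), c(1, 0, 0), direction = "dEOT->SOT")
  expect_error(dvf_comparison(g, t_bad), "different targets")
})

test_that("error statistics follow the stated conventions", {
  st <- error_statistics(c(1, 1, 4))
  expect_equal(st$mean_mm, 2)
  expect_equal(st$median_mm, 1)
  expect_equal(st$max_mm, 4)
  expect_equal(st$pct_lt_2mm, 100 * 2 / 3)
  # all-zero map
  z <- error_statistics(array(0, c(3, 3, 3)))
  expect_equal(z$mean_mm, 0); expect_equal(z$pct_lt_2mm, 100)
  # strict inequality at exactly 2 mm
  expect_equal(error_statistics(c(2, 2))$pct_lt_2mm, 0)
  # lower-central-order-statistic median for even n, midpoint as option
  expect_equal(error_statistics(c(1, 2, 3, 10))$median_mm, 2)
  expect_equal(error_statistics(c(1, 2, 3, 10),
                                median_convention = "midpoint")$median_mm,
               2.5)
  expect_error(error_statistics(numeric(0)), "no voxels")
})

test_that("statistics agree with half-normal closed forms at large n", {
  set.seed(32)
  sigma <- 1.3
  e <- abs(rnorm(1e5, 0, sigma))
  st <- error_statistics(e, threshold = 2)
  expect_lt(abs(st$mean_mm - sigma * sqrt(2 / pi)) / (sigma * sqrt(2 / pi)),
            0.01)
  med_true <- sigma * qnorm(0.75)
  expect_lt(abs(st$median_mm - med_true) / med_true, 0.01)
  pct_true <- 100 * (2 * pnorm(2 / sigma) - 1)
  expect_lt(abs(st$pct_lt_2mm - pct_true), 1)
})

test_that("masking restricts the statistics to selected voxels", {
  d <- c(4L, 4L, 2L)
  err <- array(1, d); err[1:2, , ] <- 3
  m1 <- structure_mask(array(as.integer(slice.index(err, 1) <= 2), d), "left")
  m2 <- structure_mask(array(as.integer(slice.index(err, 1) > 2), d), "right")
  expect_equal(error_statistics(err, mask = m1)$mean_mm, 3)
  expect_equal(error_statistics(err, mask = m2)$mean_mm, 1)
})

test_that("landmark propagation is exact for constant and affine fields", {
  d <- c(10L, 10L, 10L)
  pts <- landmark_set(matrix(c(2, 3, 4, 5.5, 6.25, 7.0), 2, 3, byrow = TRUE))
  zero <- const_field(d, c(0, 0, 0))
  expect_equal(propagate_landmarks(pts, zero)$points, pts$points)
  shift <- const_field(d, c(5, 0, 0))
  moved <- propagate_landmarks(pts, shift)
  expect_equal(moved$points[, 1], pts$points[, 1] + 5)
  expect_equal(moved$points[, 2:3], pts$points[, 2:3])
  # affine field: trilinear interpolation reproduces linear functions exactly
  A <- matrix(c(0.03, 0.01, 0, -0.02, 0.05, 0.01, 0, 0.02, 0.04), 3, 3)
  spec <- dvf_spec(c(12L, 12L, 12L), spacing = c(1.25, 1, 2),
                   origin = c(-2, 0, 3),
                   components = list(list(type = "affine", matrix = A,
                                          offset = c(1, -0.5, 2))))
  fld <- generate_dvf(spec)
  set.seed(33)
  rnd <- cbind(runif(1000, -1, 11), runif(1000, 0.5, 10.5),
               runif(1000, 3.5, 24))
  prop <- propagate_landmarks(landmark_set(rnd), fld)
  truth <- rnd + evaluate_dvf_spec(spec, rnd)
  expect_lt(max(abs(prop$points - truth)), 1e-9)
  # points outside the grid are refused
  outside <- landmark_set(matrix(c(-50, 0, 0), 1))
  expect_error(propagate_landmarks(outside, fld), "outside")
})

test_that("landmark TRE summarises per-point distances", {
  a <- landmark_set(matrix(rnorm(30), 10, 3))
  expect_equal(landmark_tre(a, a)$mean_mm, 0)
  expect_equal(landmark_tre(a, a)$pct_lt_2mm, 100)
  # a single point offset exactly 2 mm is NOT counted below 2 mm
  b <- a; b$points[1, 1] <- b$points[1, 1] + 2
  expect_equal(landmark_tre(landmark_set(b$points), a)$pct_lt_2mm, 90)
  # enumeration oracle: distances 0.1 * (1..100)
  base <- matrix(0, 100, 3)
  off <- base; off[, 1] <- 0.1 * (1:100)
  st <- landmark_tre(landmark_set(off + 5), landmark_set(base + 5))
  expect_equal(st$mean_mm, mean(0.1 * (1:100)))
  expect_equal(st$median_mm, 5.0)          # lower central of 5.0, 5.1
  expect_equal(st$max_mm, 10.0)
  expect_equal(st$pct_lt_2mm, 19)          # 0.1..1.9 strictly below 2
  expect_error(landmark_tre(a, landmark_set(matrix(0, 3, 3))), "counts")
})

test_that("per-structure reports match brute-force masked recomputation", {
  set.seed(34)
  d <- c(8L, 8L, 8L)
  gt <- vector_field(array(rnorm(prod(d) * 3), c(d, 3)),
                     direction = "SOT->EOT")
  te <- vector_field(gt$vectors + array(rnorm(prod(d) * 3, 0, 0.5),
                                        c(d, 3)),
                     direction = "dEOT->EOT")
  cmp <- dvf_comparison(gt, te)
  m1 <- structure_mask(array(as.integer(runif(prod(d)) < 0.3), d), "s1")
  m2 <- structure_mask(array(as.integer(runif(prod(d)) < 0.3), d), "s2")
  rep <- per_structure_report(cmp, list(m1, m2))
  expect_equal(rep$structure, c("s1", "s2", "all"))
  err <- oracle_error_map(gt$vectors, te$vectors)
  for (i in 1:2) {
    m <- list(m1, m2)[[i]]
    sel <- err[m$voxels == 1]
    expect_equal(rep$mean_mm[i], mean(sel))
    expect_equal(rep$max_mm[i], max(sel))
    expect_equal(rep$pct_lt_2mm[i], 100 * mean(sel < 2))
  }
  expect_equal(rep$mean_mm[3], mean(err))
  expect_equal(rep$n[3], prod(d))
  # disjoint constant-error masks report their own levels
  gt0 <- const_field(d, c(0, 0, 0), direction = "SOT->EOT")
  vv <- array(0, c(d, 3))
  vv[1:4, , , 1] <- 1   # 1 mm error left half
  vv[5:8, , , 1] <- 3   # 3 mm error right half
  te2 <- vector_field(vv, direction = "dEOT->EOT")
  left <- structure_mask(array(as.integer(slice.index(array(0, d), 1) <= 4),
                               d), "left")
  right <- structure_mask(array(as.integer(slice.index(array(0, d), 1) > 4),
                                d), "right")
  r2 <- per_structure_report(dvf_comparison(gt0, te2), list(left, right))
  expect_equal(r2$mean_mm[1:2], c(1, 3))
  # a mask covering everything equals the whole-grid row
  allm <- structure_mask(array(1L, d), "everything")
  r3 <- per_structure_report(dvf_comparison(gt0, te2), list(allm))
  expect_equal(r3$mean_mm[1], r3$mean_mm[2])
  expect_error(per_structure_report(
    dvf_comparison(gt0, te2),
    list(structure_mask(array(0L, d), "empty"))), "no voxels")
})

test_that("pct below threshold is monotone in the threshold", {
  set.seed(35)
  e <- abs(rnorm(2000, 0, 2))
  pcts <- vapply(seq(0.5, 6, 0.5), function(th)
    error_statistics(e, threshold = th)$pct_lt_2mm, 0)
  expect_true(all(diff(pcts) >= 0))
})

test_that("propagation through a field and its negation restores constants", {
  d <- c(10L, 10L, 10L)
  f <- const_field(d, c(2, -1, 3))
  g <- const_field(d, c(-2, 1, -3))
  pts <- landmark_set(matrix(c(4, 4, 4, 5, 6, 3), 2, 3, byrow = TRUE))
  back <- propagate_landmarks(propagate_landmarks(pts, f), g)
  expect_equal(back$points, pts$points, tolerance = 1e-12)
})
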