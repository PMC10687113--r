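test_that("load_rigid_body parses, centres and validates rigid ranges", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(tiny_pdb_lines(), f)

  b <- load_rigid_body(f, chain = "A", rigid_ranges = list(c(1, 3)))
  expect_s3_class(b, "rigid_body")
  expect_equal(nrow(b$atoms), 5)
  # rigid-range geometric centre at the origin
  expect_equal(colMeans(b$atoms[, c("x", "y", "z")]), c(x = 0, y = 0, z = 0),
               tolerance = 1e-9)
  # idempotent parse
  b2 <- load_rigid_body(f, chain = "A", rigid_ranges = list(c(1, 3)))
  expect_identical(b$atoms, b2$atoms)
  # missing residue named in the error
  expect_error(load_rigid_body(f, chain = "A", rigid_ranges = list(c(1, 5))),
               "4")
})

test_that("place_conformer applies the pose and leaves the stationary body alone", {
  ts <- tiny_system()
  sys <- ts$system

  # identity pose: moving atoms at template positions
  cf0 <- pose_conformer(sys, c(1, 0, 0, 0), c(0, 0, 0))
  co <- place_conformer(sys, cf0)
  expect_equal(co$moving, confspace:::body_xyz(sys$moving), tolerance = 1e-12,
               ignore_attr = TRUE)

  # 180 degree rotation about z flips x and y
  cfz <- pose_conformer(sys, c(0, 0, 0, 1), c(0, 0, 0))
  coz <- place_conformer(sys, cfz)
  tpl <- confspace:::body_xyz(sys$moving)
  expect_equal(coz$moving[, 1], -tpl[, 1], tolerance = 1e-9)
  expect_equal(coz$moving[, 2], -tpl[, 2], tolerance = 1e-9)
  expect_equal(coz$moving[, 3], tpl[, 3], tolerance = 1e-9)

  # stationary coordinates bitwise unchanged under a random pose
  cfr <- make_conformer(sys, rnorm(4), list(alpha = 1, beta = 0.5,
                                            delta = rep(0.4, 4), phi = rep(1, 4)))
  expect_identical(place_conformer(sys, cfr)$stationary,
                   confspace:::body_xyz(sys$stationary))
})

test_that("rigid-body contract: internal distances invariant under any pose", {
  ts <- tiny_system()
  sys <- ts$system
  tpl <- dist(confspace:::body_xyz(sys$moving))
  set.seed(11)
  for (i in 1:5) {
    cf <- make_conformer(sys, rnorm(4),
                         list(alpha = runif(1, 0, pi), beta = runif(1, -pi, pi),
                              delta = runif(4, 0, sys$linker$delta_max),
                              phi = runif(4, -pi, pi)))
    expect_lt(max(abs(dist(place_conformer(sys, cf)$moving) - tpl)), 1e-6)
  }
})

test_that("pseudo-chain closure: bonds have fixed length and join the anchors", {
  ts <- tiny_system()
  sys <- ts$system
  cf <- make_conformer(sys, c(0.2, 0.4, -0.1, 0.8),
                       list(alpha = 0.9, beta = -2, delta = rep(0.8, 4),
                            phi = c(0.1, -2, 2.5, 0)))
  co <- place_conformer(sys, cf)
  anchor_s <- sys$anchor_stationary
  anchor_m_world <- as.numeric(confspace:::quat_to_mat(cf$quat) %*% sys$anchor_moving) +
    cf$translation
  nodes <- rbind(anchor_s, co$linker, anchor_m_world)
  steps <- sqrt(rowSums(diff(nodes)^2))
  expect_equal(steps, rep(sys$linker$bond_length, nrow(nodes) - 1),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("label_distance uses virtual points and collapses clouds to their mean", {
  stat <- rigid_body(data.frame(name = "CA", resi = 1:2, element = "C",
                                x = c(-1, 1), y = 0, z = 0), role = "stationary")
  mov <- rigid_body(data.frame(name = "CA", resi = 1:2, element = "C",
                               x = c(-1, 1), y = 0, z = 0), role = "moving")
  lk <- linker_spec(2, anchor_stationary = 2, anchor_moving = 1)
  labels <- list(
    A1 = label_site("stationary", 1, position = c(0, 0, 0)),
    A2 = label_site("stationary", 2, position = c(30, 0, 0)),
    B1 = label_site("moving", 1, position = c(10, 0, 0)),
    B2 = label_site("moving", 1, cloud = list(list(xyz = c(0, 0, 0), weight = 0.5),
                                              list(xyz = c(2, 0, 0), weight = 0.5)))
  )
  pairs <- data.frame(label = c("pA", "pB"), a = c("A1", "A2"), b = c("B1", "B2"))
  sys <- conf_system(stat, mov, lk, labels, pairs)
  cf <- pose_conformer(sys, c(1, 0, 0, 0), c(0, 0, 0))

  expect_equal(label_distance(sys, cf, "A1", "A2"), 30)
  expect_equal(label_distance(sys, cf, "A1", "A1"), 0)
  # cloud {0,2} w=0.5 -> mean (1,0,0); distance to (10,0,0) under the pose...
  expect_equal(label_distance(sys, cf, "B2", "B1"), 9)

  # cloud weights must sum to one
  expect_error(label_site("moving", 1,
                          cloud = list(list(xyz = c(0, 0, 0), weight = 0.7))),
               "sum to 1")
})

test_that("label distances are invariant under a global rigid transform", {
  ts <- tiny_system()
  sys <- ts$system
  cf <- ts$truth$states[[1]]
  lp <- label_positions(sys, cf)
  d0 <- sqrt(sum((lp[1, ] - lp[3, ])^2))
  R <- confspace:::quat_to_mat(confspace:::quat_normalize(c(0.3, 1, -2, 0.5)))
  t <- c(5, -3, 11)
  lp2 <- sweep(lp %*% t(R), 2, t, `+`)
  expect_equal(sqrt(sum((lp2[1, ] - lp2[3, ])^2)), d0, tolerance = 1e-9)
})

test_that("steric_score is a soft-sphere quadratic overlap penalty", {
  a <- matrix(c(0, 0, 0), 1, 3)
  b_far <- matrix(c(100, 0, 0), 1, 3)
  expect_equal(steric_score(a, b_far, 3, 3), 0)

  # two carbon-like atoms at half their contact distance
  dmin <- 2 * 1.7
  b_close <- matrix(c(dmin / 2, 0, 0), 1, 3)
  expect_equal(steric_score(a, b_close, 1.7, 1.7, k = 1), (dmin / 2)^2)

  # monotone non-increasing as bodies separate along an axis
  sep <- seq(0, 8, by = 0.5)
  sc <- vapply(sep, function(s) steric_score(a, matrix(c(s, 0, 0), 1, 3), 3, 3), 0)
  expect_true(all(diff(sc) <= 1e-12))
})
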