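triangle <- function() rbind(c(0, 0), c(1, 0), c(0.3, 0.8))

rigid_copy <- function(m, theta, shift, s = 1) {
  R <- rbind(c(cos(theta), sin(theta)), c(-sin(theta), cos(theta)))
  sweep(m %*% R * s, 2, shift, "+")
}

test_that("gpa aligns identical and rigidly transformed configurations", {
  tri <- triangle()
  lms <- landmark_set(list(tri, tri), c("a", "b"), c("sp1", "sp1"))
  fit <- gpa(lms)
  expect_equal(fit$coords[, , 1], fit$coords[, , 2], tolerance = 1e-12)
  expect_equal(unname(fit$coords[, , 1]), unname(fit$consensus), tolerance = 1e-10)

  moved <- rigid_copy(tri, 0.7, c(3, -2), s = 2.5)
  fit2 <- gpa(landmark_set(list(tri, moved), c("a", "b"), c("sp1", "sp1")))
  expect_lt(max(abs(fit2$coords[, , 1] - fit2$coords[, , 2])), 1e-8)
})

test_that("gpa residual of two triangles matches a rotation-grid search", {
  set.seed(2)
  a <- matrix(rnorm(6), 3, 2)
  b <- matrix(rnorm(6), 3, 2)
  fit <- gpa(landmark_set(list(a, b), c("a", "b"), c("s", "s")), scale = FALSE)
  resid <- sum(sweep(fit$coords, c(1, 2), fit$consensus)^2)
  # for two centered configurations the GPA optimum equals half the squared
  # minimal pairwise deviation over relative rotations
  oracle <- grid_procrustes_min(a, b, scale = FALSE)^2 / 2
  expect_equal(resid, oracle, tolerance = 1e-5)
})

test_that("gpa output is invariant under a common rigid motion plus scale", {
  set.seed(9)
  configs <- lapply(1:6, function(i) triangle() + matrix(rnorm(6, sd = 0.05), 3, 2))
  base <- gpa(landmark_set(configs, paste0("s", 1:6), rep("sp", 6)))
  moved <- lapply(configs, rigid_copy, theta = 1.1, shift = c(5, 7), s = 0.3)
  alt <- gpa(landmark_set(moved, paste0("s", 1:6), rep("sp", 6)))
  expect_lt(max(abs(base$coords - alt$coords)), 1e-8)
})

test_that("gpa rejects bad input", {
  expect_error(landmark_set(list(triangle(), triangle()[1:2, ]), c("a", "b"),
                            c("s", "s")), "differ")
  zero <- matrix(1, 4, 2)
  expect_error(gpa(landmark_set(list(zero, triangle()[c(1, 1:3), ]),
                                c("bad", "ok"), c("s", "s"))), "bad")
})

test_that("mirroring produces 42 landmarks from 27 and reflects exactly", {
  # 12 midline landmarks spread in the x = 0 plane, 15 paired to one side
  set.seed(5)
  midline <- cbind(0, rnorm(12), rnorm(12))
  paired <- cbind(abs(rnorm(15)) + 0.5, rnorm(15), rnorm(15))
  cfg <- rbind(midline, paired)
  full <- mirror_landmarks(cfg, 1:12, 13:27)
  expect_equal(nrow(full), 42)
  # reflection across x = 0: mirrored copies negate x, keep y and z
  expect_equal(full[28:42, 1], -paired[, 1], tolerance = 1e-12)
  expect_equal(full[28:42, 2:3], paired[, 2:3], tolerance = 1e-12)
  # a specific point: (-2, 1, 3) across x = 0 lands on (2, 1, 3)
  cfg2 <- rbind(midline, c(-2, 1, 3))
  m2 <- mirror_landmarks(cfg2, 1:12, 13)
  expect_equal(unname(m2[14, ]), c(2, 1, 3), tolerance = 1e-12)
})

test_that("a mirrored symmetric half-shape has vanishing asymmetry", {
  tpl <- default_lpj_template()
  full <- mirror_landmarks(tpl$coords, tpl$midline_ids, tpl$paired_ids)
  expect_equal(nrow(full), 9 + 2 * 12)
  # reflect the full configuration across its own symmetry plane: the
  # result must equal the original with paired/mirrored blocks swapped
  c0 <- full[1, 2]
  refl <- full
  refl[, 2] <- 2 * c0 - refl[, 2]
  reordered <- refl[c(1:9, 22:33, 10:21), ]
  expect_lt(max(abs(full - reordered)), 1e-9)
})

test_that("mirroring twice returns the original paired landmarks", {
  set.seed(6)
  midline <- cbind(rnorm(5), 0, rnorm(5) + 0.2 * rnorm(5))
  paired <- cbind(rnorm(7), abs(rnorm(7)) + 0.3, rnorm(7))
  full <- mirror_landmarks(rbind(midline, paired), 1:5, 6:12)
  again <- mirror_landmarks(full[c(1:5, 13:19), ], 1:5, 6:12)
  expect_lt(max(abs(again[6:12 + 7, ] - paired)), 1e-9)
})

test_that("mirroring errors on collinear midline landmarks", {
  midline <- cbind(1:4, 0, 0)  # a straight line: no unique plane
  paired <- cbind(rnorm(3), 1, rnorm(3))
  expect_error(mirror_landmarks(rbind(midline, paired), 1:4, 5:7), "collinear")
})

test_that("subset extraction re-centers without re-rotating or re-scaling", {
  set.seed(11)
  base <- matrix(rnorm(42), 21, 2)
  # second specimen: premaxilla landmarks (1:4) enlarged about own centroid
  big <- base
  sub_ctr <- colMeans(base[1:4, ])
  big[1:4, ] <- sweep(sweep(base[1:4, ], 2, sub_ctr), 1:2, 1.8, "*") +
    rep(sub_ctr, each = 4)
  fit <- gpa(landmark_set(list(base, big), c("a", "b"), c("s1", "s2")))
  sub <- extract_recentered_subset(fit, 1:4)
  expect_lt(max(abs(apply(sub$coords, 3, colMeans))), 1e-12)
  # relative size difference survives extraction
  cs <- apply(sub$coords, 3, centroid_size)
  expect_gt(cs[2] / cs[1], 1.2)
  # inter-landmark angles unchanged by the translation-only extraction
  ang <- function(m) {
    v1 <- m[2, ] - m[1, ]; v2 <- m[3, ] - m[1, ]
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
  }
  expect_equal(ang(fit$coords[1:4, , 1]), ang(sub$coords[, , 1]),
               tolerance = 1e-12)
  expect_error(extract_recentered_subset(fit, 1:3), "expected 4")
  expect_error(extract_recentered_subset(fit, c(1, 2, 3, 99)), "range")
})

test_that("species mean shapes average aligned specimens", {
  tri <- triangle()
  up <- tri + rbind(c(0, 0.1), 0, 0)
  dn <- tri - rbind(c(0, 0.1), 0, 0)
  lms <- landmark_set(list(tri, up, dn), c("a", "b", "c"),
                      c("sp1", "sp2", "sp2"))
  lms_means <- species_mean_shapes(lms)
  expect_equal(lms_means[, , "sp1"], tri, tolerance = 1e-12)
  expect_equal(lms_means[, , "sp2"], tri, tolerance = 1e-12)
})

test_that("procrustes distance is zero under identity/rotation, matches grid", {
  tri <- triangle()
  expect_equal(procrustes_distance(tri, tri), 0)
  expect_lt(procrustes_distance(tri, rigid_copy(tri, 1.2, c(4, 4), 3)), 1e-10)
  set.seed(3)
  a <- matrix(rnorm(8), 4, 2)
  b <- matrix(rnorm(8), 4, 2)
  expect_equal(procrustes_distance(a, b), grid_procrustes_min(a, b),
               tolerance = 1e-6)
  expect_error(procrustes_distance(a, b[1:3, ]), "differ")
})

test_that("procrustes distance on unit-size shapes obeys the triangle inequality", {
  set.seed(14)
  for (i in 1:100) {
    shapes <- replicate(3, matrix(rnorm(10), 5, 2), simplify = FALSE)
    dab <- procrustes_distance(shapes[[1]], shapes[[2]])
    dbc <- procrustes_distance(shapes[[2]], shapes[[3]])
    dac <- procrustes_distance(shapes[[1]], shapes[[3]])
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("shape PCA finds rank-1 structure and preserves distances", {
  set.seed(7)
  tpl <- default_premaxilla_template()
  basis <- make_deformation_basis(tpl, 2)
  scores <- cbind(seq(-0.1, 0.1, length.out = 8), 0)
  rownames(scores) <- paste0("sp", 1:8)
  means <- array(NA_real_, c(4, 2, 8), dimnames = list(NULL, NULL, rownames(scores)))
  for (i in 1:8) means[, , i] <- tpl + matrix(basis %*% scores[i, ], 4, 2)
  p <- shape_pca(means)
  expect_gt(p$percent_variance[1], 99.999)
  expect_equal(sum(p$percent_variance), 100, tolerance = 1e-6)
  expect_lt(max(abs(colMeans(p$scores))), 1e-12)

  # with all axes retained, score distances equal flattened-shape distances
  noisy <- means + array(rnorm(length(means), sd = 0.01), dim(means))
  dimnames(noisy) <- dimnames(means)
  p2 <- shape_pca(noisy)
  flat <- t(apply(noisy, 3, as.numeric))
  expect_equal(unname(as.matrix(dist(p2$scores))),
               unname(as.matrix(dist(scale(flat, scale = FALSE)))),
               tolerance = 1e-8)
  expect_error(shape_pca(means[, , 1:2]), "at least 3")
})

test_that("metric traits compute angles, ratios, and areas with invariances", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  inner <- sweep(sweep(sq, 2, c(0.5, 0.5)), 1:2, 0.5, "*") + rep(c(0.5, 0.5), each = 4)
  cfg <- rbind(sq, inner)
  defs <- list(
    corner = list(type = "angle", from1 = 1, to1 = 2, from2 = 1, to2 = 4),
    side_ratio = list(type = "distance_ratio", a1 = 1, a2 = 2, b1 = 2, b2 = 3),
    rel_len = list(type = "relative_length", a1 = 1, a2 = 3),
    cover = list(type = "area_ratio", inner = 5:8, outer = 1:4))
  tv <- metric_traits(cfg, defs)
  expect_equal(unname(tv["corner"]), 90)
  expect_equal(unname(tv["side_ratio"]), 1)
  expect_equal(unname(tv["cover"]), 0.25)

  moved <- rigid_copy(cfg, 0.9, c(10, -3))
  expect_equal(metric_traits(moved, defs), tv, tolerance = 1e-10)
  scaled <- cfg * 7
  tv_scaled <- metric_traits(scaled, defs)
  expect_equal(tv_scaled[c("corner", "side_ratio", "rel_len", "cover")],
               tv[c("corner", "side_ratio", "rel_len", "cover")],
               tolerance = 1e-10)

  bad <- list(z = list(type = "angle", from1 = 1, to1 = 1, from2 = 1, to2 = 2))
  expect_error(metric_traits(cfg, bad), "coincident")
})

test_that("TPS and CSV landmark files round-trip", {
  scn <- scenario("decoupled", n_tips = 4, root_age = 5,
                  n_specimens = c(2, 2), seed = 3)
  sim <- simulate_dataset(scn)
  tps <- tempfile(fileext = ".tps")
  write_tps(sim$lpj_half, tps)
  back <- read_tps(tps, structure = "lpj_half")
  expect_equal(back$coords, sim$lpj_half$coords, tolerance = 1e-9)
  expect_identical(back$specimens$species_id, sim$lpj_half$specimens$species_id)

  csv <- tempfile(fileext = ".csv")
  write_landmarks_csv(sim$oral, csv)
  back2 <- read_landmarks_csv(csv, structure = "oral_premaxilla")
  expect_equal(back2$coords, sim$oral$coords, tolerance = 1e-12)
})
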