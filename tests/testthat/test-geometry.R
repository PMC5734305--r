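test_that("default super-helical rotation follows the symmetric formula", {
  expect_equal(default_shr(1, 4), 0)
  expect_equal(default_shr(3, 4), 180)
  expect_equal(default_shr(2, 3), 120)
  for (k in 2:9) expect_equal(default_shr(1, k), 0)
  # evenly spaced around the bundle
  expect_equal(diff(sapply(1:5, default_shr, n = 5)), rep(72, 4))
  expect_error(default_shr(0, 4), class = "coilr_domain_error")
  expect_error(default_shr(5, 4), "\\[1, 4\\]")
  expect_error(default_shr(1, 1), class = "coilr_domain_error")
})

test_that("pitch angle matches the closed form and keeps the pitch sign", {
  expect_equal(pitch_angle(5, 2 * pi * 5), 45)
  expect_equal(pitch_angle(7, 200), atan(2 * pi * 7 / 200) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(pitch_angle(7, 200), 12.4026, tolerance = 1e-4)
  expect_lt(pitch_angle(5, 1e9), 1e-5)             # straight-helix limit
  expect_equal(pitch_angle(5, -140), -pitch_angle(5, 140))
  expect_error(pitch_angle(5, 0), class = "coilr_domain_error")
  expect_error(pitch_angle(-1, 100), class = "coilr_domain_error")
})

test_that("superhelix points lie on the parametric path", {
  p <- helix_params(radius = 5, pitch = 140)
  expect_equal(unlist(superhelix_point(0, p)), c(x = 5, y = 0, z = 0))
  expect_equal(unlist(superhelix_point(140, p)),
               c(x = 5, y = 0, z = 140), tolerance = 1e-12)
  quarter <- superhelix_point(35, p)
  expect_equal(quarter$x, 0, tolerance = 1e-12)
  expect_equal(abs(quarter$y), 5)
  expect_gt(quarter$y, 0)                          # right-handed: +y
  left <- superhelix_point(35, helix_params(radius = 5, pitch = -140))
  expect_lt(left$y, 0)                             # left-handed: -y
  # all points exactly at distance radius from the axis
  zs <- seq(-50, 50, length.out = 31)
  pt <- superhelix_point(zs, p)
  expect_equal(sqrt(pt$x^2 + pt$y^2), rep(5, 31))
})

test_that("built helices respect minor-helix geometry bounds", {
  p <- helix_params(radius = 5, pitch = -200, interface_angle = 26,
                    sequence = strrep("IAALKQE", 4),
                    register = strrep("abcdefg", 4))
  m <- build_helix_backbone(p)
  expect_s3_class(m, "coilr_model")
  expect_true(all(c("N", "CA", "C", "O") %in% m$atom))
  ca <- as.matrix(m[m$atom == "CA", c("x", "y", "z")])
  expect_equal(nrow(ca), 28)
  # CA atoms stay within the minor-radius band around the superhelix
  axdist <- sqrt(ca[, 1]^2 + ca[, 2]^2)
  expect_true(all(axdist > 5 - 2.6 & axdist < 5 + 2.6))
  # virtual CA-CA bond of an alpha helix
  dca <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(dca - 3.8) < 0.2))
  expect_error(build_helix_backbone(p, 3), class = "coilr_domain_error")
})

test_that("straight-helix limit recovers the module constants", {
  p <- helix_params(radius = 5, pitch = -1e7, sequence = strrep("A", 24))
  ca <- as.matrix(build_helix_backbone(p)[
    build_helix_backbone(p)$atom == "CA", c("x", "y", "z")])
  fit <- oracle_helix_fit(ca)
  expect_equal(fit$rise, 1.495, tolerance = 1e-3)
  expect_equal(fit$radius, 2.26, tolerance = 1e-2)
  # heptad-averaged convention: two minor-helix turns per 7 residues
  expect_equal(fit$res_per_turn, 3.5, tolerance = 5e-3)
})

test_that("z-shift translates a chain exactly along the axis", {
  base <- helix_params(radius = 5, pitch = -200, sequence = strrep("A", 8))
  shifted <- base
  shifted$z_shift <- 2.9
  m0 <- build_helix_backbone(base, 8)
  m1 <- build_helix_backbone(shifted, 8)
  delta <- as.matrix(m1[, c("x", "y", "z")]) - as.matrix(m0[, c("x", "y", "z")])
  expect_equal(max(abs(delta[, 1:2])), 0)
  expect_equal(unname(range(delta[, 3])), c(2.9, 2.9))
})

test_that("antiparallel chains run top-down with residue 1 at high z", {
  p <- helix_params(radius = 5, pitch = -200, orientation = "antiparallel",
                    sequence = strrep("A", 14))
  m <- build_helix_backbone(p, 14)
  ca <- m[m$atom == "CA", ]
  expect_gt(ca$z[ca$res_num == 1], ca$z[ca$res_num == 14])
  # axial direction opposite to a parallel chain
  pp <- p
  pp$orientation <- "parallel"
  mp <- build_helix_backbone(pp, 14)
  vz_anti <- diff(ca$z)
  vz_par <- diff(mp[mp$atom == "CA", ]$z)
  expect_true(all(vz_anti < 0) && all(vz_par > 0))
})

test_that("collagen strands are PPII-like and triple helices do not clash", {
  p <- helix_params(radius = 3.0, pitch = 85, interface_angle = -90,
                    sequence = strrep("GPO", 7))
  m <- build_collagen_strand(p)
  ca <- as.matrix(m[m$atom == "CA", c("x", "y", "z")])
  dca <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(dca - 3.8) < 0.3))
  expect_true(all(c("GLY", "PRO", "HYP") %in% m$res_name))
  # left-handed minor helix on a right-handed path
  straight <- build_collagen_strand(
    helix_params(radius = 3.0, pitch = 1e7, sequence = strrep("GPO", 7)))
  fit <- oracle_helix_fit(
    as.matrix(straight[straight$atom == "CA", c("x", "y", "z")]))
  expect_equal(fit$rise, 2.86, tolerance = 1e-3)
  # 3 symmetric strands: no steric overlap between chains
  spec <- example_specs("collagen-homotrimer")
  model <- build_assembly(spec)$model
  xyz <- as.matrix(model[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  inter <- outer(model$chain, model$chain, "!=")
  expect_gt(min(d[inter]), 2.0)
  # z-shift equivariance for strands
  sh <- p
  sh$z_shift <- 2.9
  delta <- as.matrix(build_collagen_strand(sh)[, c("x", "y", "z")]) -
    as.matrix(m[, c("x", "y", "z")])
  expect_equal(max(abs(sweep(delta, 2, c(0, 0, 2.9)))), 0, tolerance = 1e-12)
})

test_that("basic-mode n-mers have exact cyclic symmetry", {
  for (n in c(2, 3, 5, 7)) {
    p <- helix_params(radius = 6 + n / 3, pitch = -200,
                      sequence = strrep("IAALKQE", 2),
                      register = strrep("abcdefg", 2))
    m <- build_assembly(assembly_spec("basic", "coiled_coil", n, list(p)))$model
    rot <- rotation_about_z(360 / n)
    rotated <- transform_model(m, rot)
    # rotating by 360/n and relabeling chains cyclically reproduces the model
    ids <- unique(m$chain)
    relabel <- stats::setNames(c(ids[-1], ids[1]), ids)
    rotated$chain <- unname(relabel[rotated$chain])
    rotated <- rotated[order(match(rotated$chain, ids), rotated$res_num), ]
    m2 <- m[order(match(m$chain, ids), m$res_num), ]
    rmsd <- sqrt(mean(rowSums((as.matrix(rotated[, c("x", "y", "z")]) -
                                 as.matrix(m2[, c("x", "y", "z")]))^2)))
    expect_lt(rmsd, 1e-6)
  }
})
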