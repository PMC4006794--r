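# build a minimal landmark table directly (independent of synth_embryos)
make_landmarks <- function(positions, anterior = c(0, 0), axis = c(1, 0),
                           length = 100, perp = 0) {
  bn <- boundary_names()
  u <- axis / sqrt(sum(axis^2))
  v <- c(-u[2], u[1])
  rec <- data.frame(anterior_x = anterior[1], anterior_y = anterior[2],
                    posterior_x = anterior[1] + length * u[1],
                    posterior_y = anterior[2] + length * u[2])
  for (b in seq_along(bn)) {
    pt <- anterior + positions[b] * length * u + perp * v
    rec[[paste0(bn[b], "_x")]] <- pt[1]
    rec[[paste0(bn[b], "_y")]] <- pt[2]
  }
  rec
}

test_that("relative positions are projections with exact identities", {
  tpl <- default_stripe_template()
  # landmark at the anterior tip -> 0; at the midpoint -> 0.5
  pos0 <- tpl; pos0[1] <- 0; pos0[2] <- 0.5
  rp <- relative_positions(make_landmarks(pos0))
  expect_equal(rp$S1A, 0)
  expect_equal(rp$S1P, 0.5)
  expect_equal(rp$length, 100)
  # off-axis landmark: only the axial component counts
  rp_perp <- relative_positions(make_landmarks(tpl, perp = 30))
  expect_equal(unlist(rp_perp[boundary_names()]), tpl, tolerance = 1e-9,
               ignore_attr = TRUE)
  # raw-distance mode differs for off-axis landmarks
  rp_dist <- relative_positions(make_landmarks(tpl, perp = 30),
                                mode = "distance")
  expect_true(all(unlist(rp_dist[boundary_names()]) >
                    unlist(rp_perp[boundary_names()])))
  expect_error(relative_positions(make_landmarks(tpl, length = 0)),
               "degenerate-axis")
})

test_that("relative positions are isometry- and scale-invariant", {
  tpl <- default_stripe_template()
  base <- relative_positions(make_landmarks(tpl, perp = 12))
  rot <- relative_positions(make_landmarks(tpl, anterior = c(57, -31),
                                           axis = c(-3, 4), length = 100,
                                           perp = 12))
  expect_equal(unlist(rot[boundary_names()]), unlist(base[boundary_names()]),
               tolerance = 1e-9)
  scaled <- relative_positions(make_landmarks(tpl, length = 417, perp = 50.04))
  expect_equal(unlist(scaled[boundary_names()]),
               unlist(relative_positions(
                 make_landmarks(tpl, length = 100, perp = 12))[boundary_names()]),
               tolerance = 1e-9)
})

test_that("residualize removes the nuisance and centres each boundary", {
  e <- synth_embryos(n_per_class = 20, orientation_effect = 0.02, seed = 5)
  rp <- relative_positions(e$landmarks)
  res <- residualize(rp, rp$orientation)
  for (b in boundary_names()) {
    expect_lt(abs(mean(res[[b]])), 1e-10)
    expect_lt(abs(cor(res[[b]], rp$orientation)), 1e-10)
  }
  # positions exactly linear in the nuisance leave ~zero residuals
  lin <- rp
  for (b in boundary_names()) lin[[b]] <- 0.1 + 0.01 * rp$orientation
  res_lin <- residualize(lin, rp$orientation)
  expect_lt(max(abs(unlist(res_lin[boundary_names()]))), 1e-10)
  # constant nuisance degrades to centred positions with a warning
  expect_warning(res_c <- residualize(rp, rep(1, nrow(rp))), "constant")
  expect_equal(res_c$S3A, rp$S3A - mean(rp$S3A), tolerance = 1e-12)
})

test_that("genotype tests use line means, flag planted shifts only", {
  # identical tables per class: no signal anywhere
  e <- synth_embryos(n_per_class = 24, noise_sd = 0, line_sd = 0,
                     orientation_effect = 0, stage_effect = 0, seed = 2)
  rp <- relative_positions(e$landmarks)
  res <- suppressWarnings(residualize(rp, rp$orientation))
  bt <- suppressWarnings(
    boundary_genotype_tests(res, rp$genotype, rp$stage, rp$line))
  expect_true(all(abs(bt$estimate) < 1e-9, na.rm = TRUE))

  # planted shift at S3A is detected there and only there
  e2 <- synth_embryos(n_per_class = 30,
                      shift = list(boundary = "S3A", magnitude = 0.03),
                      seed = 31)
  rp2 <- relative_positions(e2$landmarks)
  res2 <- residualize(rp2, rp2$orientation)
  bt2 <- boundary_genotype_tests(res2, rp2$genotype, rp2$stage, rp2$line)
  expect_equal(attr(bt2, "cutoff"), 0.05 / 14, tolerance = 1e-12)
  expect_true(bt2$significant[bt2$boundary == "S3A"])
  s3a <- bt2[bt2$boundary == "S3A", ]
  expect_lt(abs(abs(s3a$estimate) - 0.03), 3 * s3a$se)
  expect_error(boundary_genotype_tests(res2, rep("wt", nrow(res2)),
                                       rp2$stage, rp2$line),
               "no-contrast")
})

test_that("synthetic embryo recovery matches the generating truth", {
  # noiseless generator returns the template exactly
  e <- synth_embryos(n_per_class = 4, noise_sd = 0, line_sd = 0,
                     orientation_effect = 0, stage_effect = 0, seed = 9)
  rp <- relative_positions(e$landmarks)
  tpl <- default_stripe_template()
  for (b in boundary_names()) {
    expect_equal(rp[[b]], rep(tpl[[b]], 8), tolerance = 1e-9)
  }
  # generators are pure functions of (parameters, seed)
  e2 <- synth_embryos(n_per_class = 4, noise_sd = 0, line_sd = 0,
                      orientation_effect = 0, stage_effect = 0, seed = 9)
  expect_identical(e$landmarks, e2$landmarks)
  # planted orientation effect is recovered by per-boundary OLS
  e3 <- synth_embryos(n_per_class = 60, orientation_effect = 0.012,
                      noise_sd = 0.004, line_sd = 0, stage_effect = 0,
                      seed = 13)
  rp3 <- relative_positions(e3$landmarks)
  fit <- lm(rp3$S5P ~ rp3$orientation)
  est <- coef(summary(fit))["rp3$orientation", ]
  expect_lt(abs(est["Estimate"] - 0.012), 3 * est["Std. Error"])
})
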