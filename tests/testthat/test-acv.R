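test_that("a free attachment point yields a symmetric linker ball", {
  atoms <- tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          vdw = numeric(0))
  cl <- compute_acv(atoms, c(1, 2, 3), dye_spec_alexa488())
  mp <- attr(cl, "mean_position")
  expect_equal(mp, c(1, 2, 3), tolerance = 1e-6)
  # all points within linker length + max radius of the attachment
  d <- sqrt((cl$x - 1)^2 + (cl$y - 2)^2 + (cl$z - 3)^2)
  expect_lte(max(d), 20 + 5 + 1)
  expect_equal(sum(cl$weight), 1, tolerance = 1e-12)
})

test_that("x_trapped redistributes weight into the contact shell", {
  # one obstacle wall near the attachment creates a contact shell
  wall <- expand.grid(x = seq(-12, 12, by = 1.5), y = seq(-12, 12, by = 1.5),
                      z = -6)
  atoms <- tibble::tibble(x = wall$x, y = wall$y, z = wall$z, vdw = 1.7)
  spec0 <- dye_spec_alexa488(x_trapped = 0)
  spec5 <- dye_spec_alexa488(x_trapped = 0.5)
  cl0 <- compute_acv(atoms, c(0, 0, 0), spec0)
  cl5 <- compute_acv(atoms, c(0, 0, 0), spec5)
  expect_gt(sum(cl0$contact), 0)
  # trapped fraction 0: all weight uniform over the free volume
  expect_equal(sum(cl0$weight[cl0$contact]), 0, tolerance = 1e-12)
  expect_equal(length(unique(round(cl0$weight[!cl0$contact], 15))), 1)
  # trapped fraction 0.5: contact shell carries half the weight
  expect_equal(sum(cl5$weight[cl5$contact]), 0.5, tolerance = 1e-12)
})

test_that("inter-dye metrics match hand enumeration", {
  mk <- function(xyz) {
    cl <- tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         contact = FALSE, weight = rep(1 / nrow(xyz), nrow(xyz)))
    class(cl) <- c("acv_cloud", class(cl))
    cl
  }
  D <- mk(rbind(c(0, 0, 0), c(2, 0, 0)))
  A <- mk(rbind(c(10, 0, 0), c(12, 0, 0)))
  m <- interdye_metrics(D, A)
  # 4 pairs: 10, 12, 8, 10 -> mean 10; mean positions (1,0,0), (11,0,0)
  expect_equal(m$R_mp, 10)
  expect_equal(m$R_da_mean, 10)
  # congruent translated clouds: R_mp equals the translation distance
  A2 <- mk(rbind(c(0, 7, 0), c(2, 7, 0)))
  expect_equal(interdye_metrics(D, A2)$R_mp, 7)
  # Jensen: mean pairwise distance never below the mean-position distance
  set.seed(3)
  for (i in 1:20) {
    C1 <- mk(matrix(stats::rnorm(30, sd = 4), ncol = 3))
    C2 <- mk(sweep(matrix(stats::rnorm(30, sd = 4), ncol = 3), 2,
                   c(25, 0, 0), "+"))
    mm <- interdye_metrics(C1, C2, R0 = 52)
    expect_gte(mm$R_da_mean, mm$R_mp - 1e-9)
    # distance-averaged efficiency stays in [0, 1]
    expect_gte(mm$E_mean, 0); expect_lte(mm$E_mean, 1)
  }
})

test_that("cloud metrics converge under grid refinement", {
  fx <- toy_screen_fixture()
  atoms <- fx$structures$open
  m_coarse <- interdye_metrics(
    fretdyn:::position_cloud(atoms, 5, dye_spec_alexa488(), spacing_A = 1.8),
    fretdyn:::position_cloud(atoms, 30, dye_spec_alexa647(), spacing_A = 1.8))
  m_fine <- interdye_metrics(
    fretdyn:::position_cloud(atoms, 5, dye_spec_alexa488(), spacing_A = 0.9),
    fretdyn:::position_cloud(atoms, 30, dye_spec_alexa647(), spacing_A = 0.9))
  expect_lt(abs(m_fine$R_da_mean - m_coarse$R_da_mean), 0.5)
})

test_that("R_mp to mean-distance calibration is monotone and close", {
  atoms <- tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          vdw = numeric(0))
  cd <- compute_acv(atoms, c(0, 0, 0), dye_spec_alexa488(), spacing_A = 1.5)
  ca <- compute_acv(atoms, c(0, 0, 0), dye_spec_alexa647(), spacing_A = 1.5)
  cal <- calibrate_rmp_rda(cd, ca, separations_A = seq(20, 80, by = 15))
  expect_true(all(diff(cal$data$R_da_mean) > 0))
  # mean distance exceeds R_mp, converging at large separation
  expect_true(all(cal$data$R_da_mean >= cal$data$R_mp - 1e-6))
  pred <- predict_rda_from_rmp(cal, cal$data$R_mp)
  expect_equal(pred, cal$data$R_da_mean, tolerance = 0.02)
})

test_that("Kabsch superposition agrees with the quaternion oracle", {
  # quaternion method: largest eigenvector of the Horn K matrix
  quat_rmsd <- function(X, Y) {
    Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
    S <- crossprod(Yc, Xc)
    K <- matrix(0, 4, 4)
    K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
    K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
    K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
    K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
    K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
    K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
    K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
    K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
    K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
    K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
    lam <- max(eigen(K, symmetric = TRUE)$values)
    msd <- (sum(Xc^2) + sum(Yc^2) - 2 * lam) / nrow(X)
    sqrt(max(msd, 0))
  }
  set.seed(11)
  for (i in 1:25) {
    X <- matrix(stats::rnorm(60), ncol = 3)
    Y <- X + matrix(stats::rnorm(60, sd = 0.3), ncol = 3)
    expect_equal(fretdyn:::kabsch_rmsd(X, Y), quat_rmsd(X, Y),
                 tolerance = 1e-8)
  }
})

test_that("clustering separates rigid conformer groups at the cutoff", {
  set.seed(4)
  base <- matrix(stats::rnorm(90, sd = 6), ncol = 3)
  jitter <- function(m, sd = 0.2) m + matrix(stats::rnorm(length(m), sd = sd),
                                             ncol = 3)
  # group 2: rigid displacement of half the atoms -> RMSD ~5 A
  shifted <- base
  shifted[1:15, 1] <- shifted[1:15, 1] + 10
  as_atoms <- function(m) tibble::tibble(
    eleno = seq_len(nrow(m)), elety = "CA", resid = "ALA",
    resno = seq_len(nrow(m)), chain = "A",
    x = m[, 1], y = m[, 2], z = m[, 3], elesy = "C")
  structs <- list(a1 = as_atoms(jitter(base)), a2 = as_atoms(jitter(base)),
                  b1 = as_atoms(jitter(shifted)), b2 = as_atoms(jitter(shifted)))
  cl <- cluster_structures(structs, cutoff_A = 1.8)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_equal(cl$cluster[3], cl$cluster[4])
  # identical copies collapse to one cluster with zero RMSD
  cl_same <- cluster_structures(list(s1 = as_atoms(base), s2 = as_atoms(base)),
                                cutoff_A = 1.8)
  expect_equal(length(unique(cl_same$cluster)), 1)
  expect_equal(max(attr(cl_same, "rmsd")), 0, tolerance = 1e-10)
  # invariance under global rotation + translation
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- as_atoms(sweep(base %*% Rm, 2, c(5, -3, 8), "+"))
  cl_rot <- cluster_structures(list(orig = as_atoms(base), moved = rot),
                               cutoff_A = 1.8)
  expect_equal(length(unique(cl_rot$cluster)), 1)
})

test_that("screening matches its hand-computable limits", {
  fx <- toy_screen_fixture()
  scr <- fx$screen
  # each state's distance set ranks its generating structure first
  rk <- scr$ranking
  expect_equal(rk$structure[rk$state == "C1"], "open")
  expect_equal(rk$structure[rk$state == "C2"], "ajar")
  expect_equal(rk$structure[rk$state == "C3"], "closed")
  expect_true(all(rk$chi2r_fps < 1))
  # self-match: chi2 = 0 when model distances equal experimental ones
  det <- dplyr::filter(scr$details, .data$structure == "open",
                       .data$state == "C1")
  ds_self <- dplyr::mutate(
    dplyr::select(det, -dplyr::all_of(c("structure", "resid_A", "dR_used_A"))),
    R_exp_A = .data$R_model_A, dR_minus_A = 2.5, dR_plus_A = 2.5)
  scr_self <- screen_structures(fx$structures["open"], ds_self,
                                spacing_A = 1.2)
  expect_equal(scr_self$chi2$chi2r_fps, 0, tolerance = 1e-12)
  # one pair off by exactly its own uncertainty: chi2 = 1/33
  ds_off <- ds_self
  ds_off$R_exp_A[1] <- ds_off$R_exp_A[1] + 2.5
  scr_off <- screen_structures(fx$structures["open"], ds_off, spacing_A = 1.2)
  expect_equal(scr_off$chi2$chi2r_fps, 1 / 33, tolerance = 1e-12)
})
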