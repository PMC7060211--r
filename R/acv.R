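#' Dye specification for accessible-contact-volume modelling
#'
#' Geometry of a dye coupled via a flexible linker, as used by accessible
#' volume (AV) calculations: the linker is a flexible pipe of given length
#' and width, the dye a three-radius ellipsoid-like hard body approximated by
#' the union of three spheres. The contact volume is the part of the AV
#' within `contact_thickness` of the macromolecular surface, where dye
#' density is enhanced; the trapped fraction is estimated from residual vs
#' fundamental anisotropy of the dye, `x_trapped = r_inf / r_0`.
#'
#' Presets: Alexa488 hydroxylamine (linker 20 A, width 4.5 A, radii
#' 5/4.5/1.5 A) and Alexa647 maleimide (22 A, 4.5 A, 11/3/3.5 A).
#'
#' @param linker_length_A,linker_width_A linker pipe dimensions (Angstrom).
#' @param dye_radii_A three dye-sphere radii (Angstrom).
#' @param x_trapped trapped-dye fraction in `[0, 1]`.
#' @param contact_thickness_A contact-shell thickness, default 3.
#' @return object of class `dye_spec`.
#' @export
dye_spec <- function(linker_length_A, linker_width_A = 4.5,
                     dye_radii_A, x_trapped = 0,
                     contact_thickness_A = 3) {
  stopifnot(linker_length_A > 0, linker_width_A > 0,
            all(dye_radii_A > 0), length(dye_radii_A) == 3,
            x_trapped >= 0, x_trapped <= 1)
  structure(list(linker_length_A = linker_length_A,
                 linker_width_A = linker_width_A,
                 dye_radii_A = dye_radii_A, x_trapped = x_trapped,
                 contact_thickness_A = contact_thickness_A),
            class = "dye_spec")
}

#' @rdname dye_spec
#' @param x_trapped trapped fraction passed through to the preset.
#' @export
dye_spec_alexa488 <- function(x_trapped = 0) {
  dye_spec(20, 4.5, c(5, 4.5, 1.5), x_trapped)
}

#' @rdname dye_spec
#' @export
dye_spec_alexa647 <- function(x_trapped = 0) {
  dye_spec(22, 4.5, c(11, 3, 3.5), x_trapped)
}

# default van-der-Waals radii by element (Angstrom); heavy atoms only
vdw_radius <- function(elements) {
  tab <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8, SE = 1.9,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
  r <- tab[toupper(elements)]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Compute an accessible-contact-volume dye cloud
#'
#' Grid search around the attachment atom: a voxel belongs to the accessible
#' volume when a geodesic linker path of length at most the linker length
#' connects it to the attachment point without clashing with protein heavy
#' atoms (path clearance at least half the linker width, via Dijkstra over
#' the 26-neighbourhood), and the voxel itself can host at least one of the
#' three dye spheres. Voxels within the contact thickness of the molecular
#' surface form the contact volume and are re-weighted so that their summed
#' weight equals the trapped fraction `x_trapped`.
#'
#' @param atoms tibble with columns `x`, `y`, `z` (Angstrom) and either
#'   `elety`/`elesy` element symbols or a `vdw` column; typically from
#'   [read_structure()].
#' @param attach_xyz length-3 attachment-atom coordinates; clashes with the
#'   attachment atom itself should be avoided by excluding it from `atoms`.
#' @param spec a [dye_spec()].
#' @param spacing_A grid spacing, default 0.9.
#' @return `acv_cloud`: tibble of weighted dye positions (`x`, `y`, `z`,
#'   `weight`, `contact`) with attributes `mean_position`, `spec`.
#' @export
compute_acv <- function(atoms, attach_xyz, spec, spacing_A = 0.9) {
  stopifnot(inherits(spec, "dye_spec"), length(attach_xyz) == 3)
  atoms <- tibble::as_tibble(atoms)
  if (!"vdw" %in% names(atoms)) {
    el <- atoms$elesy %||% substr(atoms$elety %||% "C", 1, 1)
    atoms$vdw <- vdw_radius(el)
  }
  res <- cpp_acv_grid(
    atoms = as.matrix(atoms[, c("x", "y", "z")]),
    vdw = atoms$vdw,
    attach = as.numeric(attach_xyz),
    linker_length = spec$linker_length_A,
    linker_radius = spec$linker_width_A / 2,
    dye_radii = spec$dye_radii_A,
    contact_thickness = spec$contact_thickness_A,
    spacing = spacing_A)
  if (length(res$x) == 0) {
    stop("empty accessible volume: attachment site appears fully buried")
  }
  cloud <- tibble::tibble(x = res$x, y = res$y, z = res$z,
                          contact = res$contact == 1L)
  n_c <- sum(cloud$contact); n_f <- sum(!cloud$contact)
  xt <- spec$x_trapped
  w <- numeric(nrow(cloud))
  if (n_c == 0 || xt == 0) {
    w[] <- 0
    w[!cloud$contact] <- 1 / max(n_f, 1)
    if (n_f == 0) w[cloud$contact] <- 1 / n_c
  } else if (n_f == 0) {
    w[cloud$contact] <- 1 / n_c
  } else {
    w[cloud$contact] <- xt / n_c
    w[!cloud$contact] <- (1 - xt) / n_f
  }
  cloud$weight <- w
  class(cloud) <- c("acv_cloud", class(cloud))
  attr(cloud, "mean_position") <-
    c(sum(cloud$x * w), sum(cloud$y * w), sum(cloud$z * w))
  attr(cloud, "spec") <- spec
  attr(cloud, "spacing_A") <- spacing_A
  cloud
}

#' @export
print.acv_cloud <- function(x, ...) {
  mp <- attr(x, "mean_position")
  cat("<acv_cloud> ", nrow(x), " grid points (",
      sum(x$contact), " contact); mean position (",
      paste(signif(mp, 4), collapse = ", "), ") A\n", sep = "")
  invisible(x)
}

#' Inter-dye distance metrics between two dye clouds
#'
#' Computes the distance between the dye mean positions,
#' `R_mp = |<R_D> - <R_A>|`, the mean inter-dye distance observed by
#' ensemble TCSPC, `<R_DA> = <|R_D(i) - R_A(j)|>` (weighted over all cloud
#' point pairs), and, given a Foerster radius, the distance-averaged mean
#' FRET efficiency `<E> = <1/(1 + (R/R0)^6)>`. Clouds larger than
#' `max_points` are deterministically subsampled (weight-proportional,
#' fixed seed) before the pairwise sums.
#'
#' @param cloud_d,cloud_a `acv_cloud`s of donor and acceptor.
#' @param R0 Foerster radius (Angstrom), `NULL` to skip `<E>`.
#' @param max_points subsampling bound per cloud.
#' @return tibble with `R_mp`, `R_da_mean`, `E_mean`.
#' @export
interdye_metrics <- function(cloud_d, cloud_a, R0 = NULL, max_points = 4000L) {
  stopifnot(nrow(cloud_d) > 0, nrow(cloud_a) > 0)
  if (!is.null(R0) && R0 <= 0) stop("R0 must be > 0")
  mp_d <- attr(cloud_d, "mean_position") %||%
    colSums(as.matrix(cloud_d[, c("x", "y", "z")]) * cloud_d$weight)
  mp_a <- attr(cloud_a, "mean_position") %||%
    colSums(as.matrix(cloud_a[, c("x", "y", "z")]) * cloud_a$weight)
  R_mp <- sqrt(sum((mp_d - mp_a)^2))
  sub <- function(cl) {
    if (nrow(cl) <= max_points) return(cl)
    set.seed(20260401L)
    idx <- sample.int(nrow(cl), max_points, prob = cl$weight)
    out <- cl[idx, ]
    out$weight <- rep(1 / max_points, max_points)
    out
  }
  cd <- sub(cloud_d); ca <- sub(cloud_a)
  m <- cpp_cloud_metrics(as.matrix(cd[, c("x", "y", "z")]), cd$weight,
                         as.matrix(ca[, c("x", "y", "z")]), ca$weight,
                         if (is.null(R0)) -1 else R0)
  tibble::tibble(R_mp = R_mp, R_da_mean = m[1],
                 E_mean = if (is.null(R0)) NA_real_ else m[2])
}

#' Calibrate the polynomial mapping between R_mp and mean inter-dye distance
#'
#' The mean position distance `R_mp` and the TCSPC-observed mean distance
#' `<R_DA>` differ systematically for extended dye clouds; their empirical
#' relationship is well described by a third-order polynomial. This fits that
#' polynomial from simulated cloud pairs at a range of separations.
#'
#' @param cloud_d,cloud_a template clouds (translated apart to sample
#'   separations).
#' @param separations_A separations at which to evaluate (Angstrom).
#' @return list with `coef` (polynomial coefficients, ascending powers) and
#'   `data` (the calibration table); use [predict_rda_from_rmp()].
#' @export
calibrate_rmp_rda <- function(cloud_d, cloud_a,
                              separations_A = seq(20, 100, by = 10)) {
  tab <- purrr::map_dfr(separations_A, function(d) {
    ca <- cloud_a
    ca$x <- ca$x - mean(range(ca$x)) + mean(range(cloud_d$x)) + d
    attr(ca, "mean_position") <- NULL
    m <- interdye_metrics(cloud_d, ca)
    m
  })
  fit <- stats::lm(R_da_mean ~ poly(R_mp, 3, raw = TRUE), data = tab)
  list(coef = unname(stats::coef(fit)), data = tab)
}

#' @rdname calibrate_rmp_rda
#' @param calibration result of [calibrate_rmp_rda()].
#' @param R_mp distances to convert.
#' @export
predict_rda_from_rmp <- function(calibration, R_mp) {
  drop(cbind(1, R_mp, R_mp^2, R_mp^3) %*% calibration$coef)
}
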