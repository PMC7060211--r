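#' Define a donor-acceptor distance-distribution decay model
#'
#' The ensemble TCSPC analysis treats each conformational state as a normal
#' distribution of donor-acceptor distances (dye linkers broaden even a rigid
#' conformation into a distance distribution). A model is a superposition of
#' such components plus a donor-only fraction.
#'
#' @param components tibble with columns `fraction`, `mean_R` (Angstrom) and
#'   `width` (Angstrom, standard deviation). Fractions are over the FRET
#'   species only and must sum to 1.
#' @param x_donly donor-only fraction of the total signal, in `[0, 1]`.
#' @param donor_lifetimes tibble with columns `amplitude` and `tau_ns`
#'   describing the unquenched donor fluorescence lifetime spectrum.
#' @param R0 Foerster radius (Angstrom) under the kappa^2 = 2/3 assumption.
#' @return object of class `distance_model`.
#' @examples
#' m <- distance_model(
#'   components = tibble::tibble(fraction = 1, mean_R = 45, width = 8),
#'   donor_lifetimes = tibble::tibble(amplitude = 1, tau_ns = 4), R0 = 52)
#' @export
distance_model <- function(components, x_donly = 0,
                           donor_lifetimes, R0) {
  components <- tibble::as_tibble(components)
  donor_lifetimes <- tibble::as_tibble(donor_lifetimes)
  stopifnot(all(c("fraction", "mean_R", "width") %in% names(components)),
            all(c("amplitude", "tau_ns") %in% names(donor_lifetimes)))
  if (R0 <= 0) stop("R0 must be > 0")
  if (nrow(donor_lifetimes) < 1) stop("donor lifetime spectrum is empty")
  if (any(components$mean_R <= 0)) stop("mean distances must be > 0")
  if (any(components$width <= 0)) stop("widths must be > 0")
  if (x_donly < 0 || x_donly > 1) stop("x_donly must lie in [0, 1]")
  if (abs(sum(components$fraction) - 1) > 1e-8) {
    stop("component fractions must sum to 1")
  }
  a <- donor_lifetimes$amplitude
  donor_lifetimes$amplitude <- a / sum(a)
  structure(
    list(components = components, x_donly = x_donly,
         donor_lifetimes = donor_lifetimes, R0 = R0),
    class = "distance_model"
  )
}

#' @export
print.distance_model <- function(x, ...) {
  cat("<distance_model> ", nrow(x$components), " component(s), R0 = ",
      x$R0, " A, x_DOnly = ", x$x_donly, "\n", sep = "")
  print(x$components)
  invisible(x)
}

# amplitude-averaged donor-only lifetime (ns); sets the FRET rate scale
species_avg_donor_lifetime <- function(model) {
  with(model$donor_lifetimes, sum(amplitude * tau_ns) / sum(amplitude))
}

# quadrature nodes/weights for one Gaussian distance component: equidistant
# grid over mean +/- 5 width, truncated at R >= 1 A, weights renormalized
distance_quadrature <- function(mean_R, width, n = 441L) {
  R <- seq(mean_R - 5 * width, mean_R + 5 * width, length.out = n)
  keep <- R >= 1
  R <- R[keep]
  if (length(R) < 2) stop("distance quadrature grid collapsed (mean_R too small?)")
  w <- stats::dnorm(R, mean_R, width)
  w <- w / sum(w)
  list(R = R, w = w)
}

#' FRET-induced donor decay of a distance-distribution model
#'
#' Evaluates the donor fluorescence decay
#' \deqn{F(t) = x_{D0} f_D(t) + (1 - x_{D0}) \sum_i x_i \int p_i(R)\,
#'   f_D(t)\, e^{-t\,k_{FRET}(R)}\, dR}
#' with \eqn{f_D(t) = \sum_m a_m e^{-t/\tau_{Dm}}} the unquenched donor decay
#' and \eqn{k_{FRET}(R) = (1/\tau_{D0}) (R_0/R)^6}, where \eqn{\tau_{D0}} is
#' the amplitude-averaged donor-only lifetime. Each \eqn{p_i} is a normal
#' distribution truncated to R >= 1 Angstrom and renormalized; the integral
#' uses an equidistant 441-point grid over mean +/- 5 widths.
#'
#' @param model a [distance_model()].
#' @param t_grid time grid (ns, `t >= 0`).
#' @param n_quad number of quadrature nodes per component.
#' @return tibble with columns `time_ns`, `intensity` (F(0) = 1).
#' @export
fret_induced_donor_decay <- function(model, t_grid, n_quad = 441L) {
  stopifnot(inherits(model, "distance_model"), all(t_grid >= 0))
  int <- decay_intensity(model, t_grid, n_quad)
  tibble::tibble(time_ns = t_grid, intensity = int)
}

# bare numeric version used by the fitting code (avoids tibble overhead)
decay_intensity <- function(model, t_grid, n_quad = 441L) {
  dl <- model$donor_lifetimes
  fD <- drop(exp(-outer(t_grid, 1 / dl$tau_ns)) %*% dl$amplitude)
  tau_D0 <- species_avg_donor_lifetime(model)
  comp <- model$components
  fret_sum <- numeric(length(t_grid))
  for (i in seq_len(nrow(comp))) {
    q <- distance_quadrature(comp$mean_R[i], comp$width[i], n_quad)
    kf <- (1 / tau_D0) * (model$R0 / q$R)^6
    # quench factor integrated over the distance distribution
    quench <- drop(exp(-outer(t_grid, kf)) %*% q$w)
    fret_sum <- fret_sum + comp$fraction[i] * quench
  }
  fD * (model$x_donly + (1 - model$x_donly) * fret_sum)
}

# steady-state FRET efficiency of the model's FRET species (no DOnly)
model_mean_efficiency <- function(model, n_quad = 441L) {
  tau_D0 <- species_avg_donor_lifetime(model)
  comp <- model$components
  E <- 0
  for (i in seq_len(nrow(comp))) {
    q <- distance_quadrature(comp$mean_R[i], comp$width[i], n_quad)
    Ei <- sum(q$w / (1 + (q$R / model$R0)^6))
    E <- E + comp$fraction[i] * Ei
  }
  E
}
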