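#' Select single-molecule bursts from a photon stream
#'
#' Sliding-window burst search: a photon is a burst photon when at least `L`
#' photons (including itself) fall inside a window of length `T_us`
#' centred on it; maximal runs of consecutive burst photons form candidate
#' bursts, and candidates with fewer than `min_photons` photons are dropped.
#' The procedure is deterministic and local: concatenating streams changes
#' nothing beyond one window length at the joint.
#'
#' @param stream `photon_stream` tibble sorted by macro-time.
#' @param T_us sliding window length (microseconds).
#' @param L minimum photons inside the window.
#' @param min_photons minimum photons per burst.
#' @return tibble with one row per burst: `burst_id`, `first`, `last`
#'   (photon indices), `t_start_ms`, `duration_ms`, `n_photons`.
#' @export
select_bursts <- function(stream, T_us = 120, L = 10L, min_photons = 60L) {
  if (nrow(stream) == 0) {
    return(tibble::tibble(burst_id = integer(), first = integer(),
                          last = integer(), t_start_ms = numeric(),
                          duration_ms = numeric(), n_photons = integer()))
  }
  t <- photon_times_ms(stream)
  if (is.unsorted(t)) stop("stream must be sorted by macro-time")
  half <- T_us * 1e-3 / 2
  # neighbours within [t - T/2, t + T/2]
  n_nb <- findInterval(t + half, t) - findInterval(t - half, t, left.open = TRUE)
  in_burst <- n_nb >= L
  r <- rle(in_burst)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_photons
  first <- starts[keep]; last <- ends[keep]
  tibble::tibble(
    burst_id = seq_along(first), first = first, last = last,
    t_start_ms = t[first],
    duration_ms = t[last] - t[first],
    n_photons = last - first + 1L)
}

# vectorized MLE of a single-exponential lifetime from micro-times observed
# inside a truncated window of length span_ns: solves
#   mean(t) = tau - span * exp(-span/tau) / (1 - exp(-span/tau))
# by Newton iterations on all bursts at once
exp_mle_truncated <- function(mean_t, span_ns, n_iter = 30L) {
  tau <- pmin(pmax(mean_t, 1e-3), span_ns)
  trunc_mean <- function(tau) {
    ez <- exp(-pmin(span_ns / tau, 500))
    tau - span_ns * ez / (1 - ez)
  }
  for (i in seq_len(n_iter)) {
    f <- trunc_mean(tau) - mean_t
    h <- pmax(tau * 1e-4, 1e-6)   # secant derivative, robust across z
    d <- (trunc_mean(tau + h) - trunc_mean(tau)) / h
    step <- f / d
    step[!is.finite(step)] <- 0
    tau <- pmin(pmax(tau - step, 1e-3), span_ns * 20)
  }
  tau
}

#' FRET indicators for selected bursts
#'
#' For each burst, the intensity-based FRET efficiency
#' `E = F_A / (F_A + gamma * F_D)` after background subtraction and spectral
#' crosstalk correction (`F_A = R - alpha * G - B_R`, `F_D = G - B_G`), and
#' the fluorescence-averaged donor lifetime from a maximum-likelihood fit of
#' a single exponential to the green micro-times inside `fit_range_ns`
#' (excluding the IRF rise).
#'
#' @param stream `photon_stream`.
#' @param bursts result of [select_bursts()].
#' @param gamma detection-efficiency ratio, default 1.
#' @param alpha spectral crosstalk of donor signal into the red channel.
#' @param background_kHz green/red background rates.
#' @param fit_range_ns micro-time window (ns) used for the lifetime MLE;
#'   defaults to `irf_peak_ns - 3 irf_sigma_ns` up to the end of the period,
#'   so that the symmetric IRF spread averages out of the arrival-time mean.
#' @param irf_peak_ns position of the IRF maximum (ns); decay times are
#'   measured from here.
#' @param irf_sigma_ns IRF width (ns).
#' @return bursts tibble extended with `F_D`, `F_A`, `E`, `tau_ns`, `valid`.
#' @export
burst_indicators <- function(stream, bursts, gamma = 1, alpha = 0,
                             background_kHz = c(0, 0),
                             fit_range_ns = NULL, irf_peak_ns = 2,
                             irf_sigma_ns = 0.25) {
  if (nrow(bursts) == 0) {
    return(dplyr::mutate(bursts, F_D = numeric(), F_A = numeric(),
                         E = numeric(), tau_ns = numeric(), valid = logical()))
  }
  chan_w <- attr(stream, "micro_channel_width_ns")
  sync <- attr(stream, "sync_period_ns")
  if (is.null(fit_range_ns)) {
    fit_range_ns <- c(max(irf_peak_ns - 3 * irf_sigma_ns, 0), sync)
  }
  det <- stream$detector
  mic_ns <- (stream$microtime_channel + 0.5) * chan_w
  res <- purrr::map_dfr(seq_len(nrow(bursts)), function(b) {
    idx <- bursts$first[b]:bursts$last[b]
    g_raw <- sum(det[idx] == 0L)
    r_raw <- sum(det[idx] == 1L)
    dur <- bursts$duration_ms[b]
    F_D <- g_raw - background_kHz[1] * dur
    F_A <- (r_raw - background_kHz[2] * dur) - alpha * F_D
    tot <- F_A + gamma * F_D
    E <- if (tot > 0) F_A / tot else NA_real_
    mg <- mic_ns[idx][det[idx] == 0L]
    mg <- mg[mg >= fit_range_ns[1] & mg <= fit_range_ns[2]]
    tau <- if (length(mg) >= 10) {
      # decay times measured from the IRF peak; the symmetric IRF spread
      # cancels in the mean, the period truncation is corrected by the MLE
      exp_mle_truncated(max(mean(mg) - irf_peak_ns, 1e-3),
                        fit_range_ns[2] - irf_peak_ns)
    } else NA_real_
    tibble::tibble(F_D = F_D, F_A = F_A, E = E, tau_ns = tau,
                   valid = tot > 0)
  })
  out <- dplyr::bind_cols(bursts, res)
  out$flag_E <- !is.na(out$E) & (out$E < -0.1 | out$E > 1.1)
  out
}

#' Static and dynamic FRET-lines
#'
#' FRET-lines are loci in the (fluorescence-averaged donor lifetime,
#' intensity-averaged FRET efficiency) plane. The static line is the locus of
#' molecules in a single conformational state: parametric in the inter-dye
#' distance, with the dye-linker flexibility broadening each distance into a
#' Gaussian of width `sigma_link`, so that
#' `tau_F = E[tau^2]/E[tau]`, `E = 1 - E[tau]/tau_D0` over that distribution.
#' The dynamic line connects two exchanging states: mixtures of two species
#' with lifetimes tau1', tau2' trace
#' `E = 1 - tau_x/tau_D0` with `tau_x = tau1' tau2' / (tau1' + tau2' - tau_F)`
#' (elimination of the species fraction from the first two lifetime moments).
#' Populations falling on the dynamic line, right-shifted from the static
#' line, are the model-free signature of sub-millisecond exchange.
#'
#' @param tau_D0 donor-only lifetime (ns).
#' @param kind `"static"` or `"dynamic"`.
#' @param R0 Foerster radius (Angstrom), static line.
#' @param sigma_link Gaussian linker width (Angstrom), static line.
#' @param endpoints length-2 species lifetimes tau' (ns), dynamic line.
#' @param n points on the line.
#' @return `fret_line` tibble with columns `tau_F_ns`, `E` (and `R` for the
#'   static line).
#' @export
fret_lines <- function(tau_D0, kind = c("static", "dynamic"),
                       R0 = 52, sigma_link = 6, endpoints = NULL, n = 201L) {
  kind <- match.arg(kind)
  stopifnot(tau_D0 > 0)
  if (kind == "static") {
    if (sigma_link < 0) stop("sigma_link must be >= 0")
    Rgrid <- seq(0.3 * R0, 2.5 * R0, length.out = n)
    pts <- purrr::map_dfr(Rgrid, function(Rc) {
      if (sigma_link == 0) {
        tau <- tau_D0 / (1 + (R0 / Rc)^6)
        tibble::tibble(R = Rc, tau_F_ns = tau, E = 1 - tau / tau_D0)
      } else {
        q <- distance_quadrature(Rc, sigma_link, 201L)
        tau <- tau_D0 / (1 + (R0 / q$R)^6)
        m1 <- sum(q$w * tau)
        m2 <- sum(q$w * tau^2)
        tibble::tibble(R = Rc, tau_F_ns = m2 / m1, E = 1 - m1 / tau_D0)
      }
    })
  } else {
    stopifnot(length(endpoints) == 2, all(endpoints > 0),
              all(endpoints < tau_D0))
    t1 <- endpoints[1]; t2 <- endpoints[2]
    tau_F <- seq(min(t1, t2), max(t1, t2), length.out = n)
    tau_x <- t1 * t2 / (t1 + t2 - tau_F)
    pts <- tibble::tibble(tau_F_ns = tau_F, E = 1 - tau_x / tau_D0)
  }
  class(pts) <- c("fret_line", class(pts))
  attr(pts, "kind") <- kind
  attr(pts, "tau_D0") <- tau_D0
  attr(pts, "endpoints") <- endpoints
  attr(pts, "sigma_link") <- if (kind == "static") sigma_link else NULL
  pts
}

# interpolate the E value of a line at given tau_F
fret_line_E_at <- function(line, tau_F) {
  stats::approx(line$tau_F_ns, line$E, xout = tau_F, rule = 2)$y
}

#' Compare experimental and simulated burst histograms
#'
#' Chi-square distance between normalized burst histograms (1D in E, 1D in
#' lifetime, and 2D), with the null distribution obtained by bootstrap
#' resampling of the simulated set against itself: `p` is the fraction of
#' bootstrap distances at least as large as the observed one. Used to decide
#' which of two competing kinetic solutions reproduces the measured MFD
#' histograms.
#'
#' @param exp_bursts,sim_bursts burst tibbles from [burst_indicators()].
#' @param tau_D0 donor-only lifetime; sets the lifetime axis range.
#' @param n_bins bins per axis (default 61 over E in [-0.1, 1.1] and
#'   lifetime in [0, tau_D0 + 0.5]).
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @return tibble with `axis` (`"E"`, `"tau"`, `"2D"`), `distance`, `p`.
#' @export
compare_histograms <- function(exp_bursts, sim_bursts, tau_D0 = 4,
                               n_bins = 61L, n_boot = 1000L, seed = 1L) {
  eb <- dplyr::filter(exp_bursts, .data$valid, is.finite(.data$E),
                      is.finite(.data$tau_ns))
  sb <- dplyr::filter(sim_bursts, .data$valid, is.finite(.data$E),
                      is.finite(.data$tau_ns))
  if (nrow(eb) < 50 || nrow(sb) < 50) {
    warning("fewer than 50 valid bursts; p-values undefined")
    return(tibble::tibble(axis = c("E", "tau", "2D"), distance = NA_real_,
                          p = NA_real_, flagged = TRUE))
  }
  e_breaks <- seq(-0.1, 1.1, length.out = n_bins + 1)
  t_breaks <- seq(0, tau_D0 + 0.5, length.out = n_bins + 1)
  clampcut <- function(x, breaks) {
    x <- pmin(pmax(x, breaks[1]), breaks[length(breaks)])
    findInterval(x, breaks, rightmost.closed = TRUE)
  }
  bin2d <- function(b) {
    i <- clampcut(b$E, e_breaks)
    j <- clampcut(b$tau_ns, t_breaks)
    list(e = tabulate(i, n_bins), t = tabulate(j, n_bins),
         b2 = tabulate((i - 1L) * n_bins + j, n_bins * n_bins))
  }
  chi2_dist <- function(h1, h2) {
    p1 <- h1 / sum(h1); p2 <- h2 / sum(h2)
    s <- p1 + p2
    ok <- s > 0
    sum((p1[ok] - p2[ok])^2 / s[ok])
  }
  he <- bin2d(eb); hs <- bin2d(sb)
  obs <- c(E = chi2_dist(he$e, hs$e), tau = chi2_dist(he$t, hs$t),
           `2D` = chi2_dist(he$b2, hs$b2))
  set.seed(seed)
  n_e <- nrow(eb)
  null_d <- matrix(NA_real_, n_boot, 3)
  for (b in seq_len(n_boot)) {
    i1 <- sample.int(nrow(sb), n_e, replace = TRUE)
    i2 <- sample.int(nrow(sb), nrow(sb), replace = TRUE)
    h1 <- bin2d(sb[i1, ]); h2 <- bin2d(sb[i2, ])
    null_d[b, ] <- c(chi2_dist(h1$e, h2$e), chi2_dist(h1$t, h2$t),
                     chi2_dist(h1$b2, h2$b2))
  }
  p <- vapply(1:3, function(k) mean(null_d[, k] >= obs[k]), numeric(1))
  tibble::tibble(axis = c("E", "tau", "2D"), distance = unname(obs),
                 p = p, flagged = FALSE)
}
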