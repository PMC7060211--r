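#' Build species-selective micro-time filters
#'
#' Filtered FCS separates species that differ in their fluorescence decay
#' pattern. Given the expected normalized micro-time pattern of each species
#' (stacked over detectors) and the measured total histogram, the
#' weighted-least-squares filters
#' \deqn{W = (M^T D M)^{-1} M^T D, \quad D = diag(1/\mathrm{total})}
#' are unbiased: applying the species-i filter to the expected pure-species-j
#' histogram returns the species-j photon number times delta_ij.
#'
#' @param patterns matrix (channels x species) of normalized decay patterns;
#'   channels index the stacked (detector, micro-time) bins. Columns may be
#'   named.
#' @param total measured total histogram over the same channels (counts).
#' @return `filter_set`: list with `weights` (channels x species matrix),
#'   `patterns`, `total`, `keep` (channels retained).
#' @export
build_filters <- function(patterns, total) {
  patterns <- as.matrix(patterns)
  ns <- ncol(patterns)
  stopifnot(length(total) == nrow(patterns))
  keep <- total > 0 & rowSums(patterns) > 0
  M <- patterns[keep, , drop = FALSE]
  M <- sweep(M, 2, colSums(M), "/")
  D <- 1 / total[keep]
  MtD <- t(M * D)
  A <- MtD %*% M
  # diagnose rank deficiency with the offending pair
  if (ns > 1) {
    qrA <- qr(A)
    if (qrA$rank < ns) {
      cors <- stats::cor(M)
      diag(cors) <- 0
      worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
      nms <- colnames(patterns) %||% paste0("species", seq_len(ns))
      stop("patterns are linearly dependent (singular filter matrix); ",
           "most collinear pair: ", nms[worst[1]], " / ", nms[worst[2]])
    }
  }
  W_keep <- solve(A, MtD)           # species x kept-channels
  W <- matrix(0, nrow(patterns), ns)
  W[keep, ] <- t(W_keep)
  colnames(W) <- colnames(patterns)
  structure(list(weights = W, patterns = patterns, total = total,
                 keep = keep),
            class = "filter_set")
}

#' @export
print.filter_set <- function(x, ...) {
  cat("<filter_set> ", ncol(x$weights), " species over ",
      nrow(x$weights), " (detector x micro-time) channels\n", sep = "")
  invisible(x)
}

#' Stacked (detector, micro-time) filter channel per photon
#'
#' Maps every photon onto the stacked channel index used by
#' [build_filters()]: micro-times rebinned to `n_micro_bins` per detector,
#' detectors concatenated.
#'
#' @param stream a `photon_stream`.
#' @param n_micro_bins micro-time bins per detector.
#' @return integer vector of 1-based channel indices.
#' @export
photon_filter_channel <- function(stream, n_micro_bins) {
  n_chan <- round(attr(stream, "sync_period_ns") /
                    attr(stream, "micro_channel_width_ns"))
  fold <- n_chan / n_micro_bins
  mb <- pmin(floor(stream$microtime_channel / fold), n_micro_bins - 1L)
  stream$detector * n_micro_bins + mb + 1L
}

#' Expected micro-time pattern of a simulated state
#'
#' Closed-form normalized decay pattern of a conformational state over the
#' stacked (detector, micro-time) channels of a [sim_config()]: the
#' quenched donor decay in the green channel and the transfer-plus-acceptor
#' cascade in the red channel, convolved with the Gaussian IRF. Used to
#' construct species filters for synthetic photon streams; for measured
#' data the patterns come from sub-ensemble decays of the limiting burst
#' populations instead.
#'
#' @param config a [sim_config()].
#' @param efficiency the state's FRET efficiency.
#' @param n_micro_bins micro-time bins per detector.
#' @return numeric pattern vector (sums to 1) over `2 * n_micro_bins`
#'   channels.
#' @export
state_pattern <- function(config, efficiency, n_micro_bins = 64L) {
  tau_D0 <- with(config$donor_lifetimes, sum(amplitude * tau_ns) / sum(amplitude))
  E <- min(efficiency, 0.999)
  kf <- (1 / tau_D0) * E / (1 - E)
  dtb <- config$sync_period_ns / n_micro_bins
  tg <- (seq_len(n_micro_bins) - 0.5) * dtb
  amp <- config$donor_lifetimes$amplitude / sum(config$donor_lifetimes$amplitude)
  taus <- config$donor_lifetimes$tau_ns
  # donor-quenched decay per donor component
  green <- rowSums(vapply(seq_along(taus), function(m) {
    k <- 1 / taus[m] + kf
    amp[m] * exp(-tg * k) * k
  }, numeric(n_micro_bins)))
  # sensitised acceptor: convolution of quench and acceptor decay
  red <- rowSums(vapply(seq_along(taus), function(m) {
    kq <- 1 / taus[m] + kf
    ka <- 1 / config$tau_acceptor_ns
    amp[m] * kq * ka / (kq - ka) * (exp(-tg * ka) - exp(-tg * kq))
  }, numeric(n_micro_bins)))
  # fold in the Gaussian IRF by discrete convolution on the bin grid
  irf <- stats::dnorm(tg, config$irf_mean_ns, max(config$irf_sigma_ns, dtb / 4))
  irf <- irf / sum(irf)
  conv <- function(v) Re(stats::fft(stats::fft(irf) * stats::fft(v),
                                    inverse = TRUE)) / length(v)
  rate <- state_channel_rates(
    tibble::tibble(efficiency = efficiency, brightness_kHz = 1),
    config$crosstalk, config$direct_excitation)
  g <- conv(green); r <- conv(red)
  pat <- c(rate[1, "green"] * g / sum(g),
           (rate[1, "red_fret"] * r / sum(r) + rate[1, "red_ct"] * g / sum(g)))
  pat / sum(pat)
}

#' Species-selective correlation functions of a filtered photon stream
#'
#' Computes species auto- (sACF) and cross-correlation functions (sCCF)
#' \deqn{G_{ij}(t_c) = \frac{\langle \sum w_i(t) \sum w_j(t+t_c)\rangle}
#'   {\langle \sum w_i\rangle \langle \sum w_j\rangle} - 1}
#' from per-photon filter weights on a quasi-logarithmic lag grid (16 lags
#' per cascade, doubling bin width, first lag 4 sync periods), using an exact
#' photon-pair accumulator. Uncertainties are standard deviations over
#' `n_segments` equal stream segments.
#'
#' @param stream `photon_stream`.
#' @param filters `filter_set` from [build_filters()] whose channels match
#'   `n_micro_bins` stacked over the stream's detectors, or `NULL` for plain
#'   (unfiltered) correlation.
#' @param n_micro_bins micro-time bins per detector used by the filters.
#' @param max_lag_ms largest lag.
#' @param n_segments segments for the noise estimate.
#' @return tibble with `kind` ("sACF"/"sCCF"), `species_i`, `species_j`,
#'   `lag_ms`, `G`, `sd`.
#' @export
correlate_filtered <- function(stream, filters = NULL, n_micro_bins = 64L,
                               max_lag_ms = 100, n_segments = 8L) {
  t <- photon_times_ms(stream)
  T_total <- attr(stream, "duration_s") * 1e3
  if (is.null(T_total) || !is.finite(T_total)) T_total <- max(t)
  sync_ms <- attr(stream, "sync_period_ns") * 1e-6
  if (!is.null(filters)) {
    ch <- photon_filter_channel(stream, n_micro_bins)
    W <- filters$weights
    ns <- ncol(W)
    wmat <- W[ch, , drop = FALSE]
    species <- colnames(W) %||% paste0("S", seq_len(ns))
  } else {
    wmat <- matrix(1, length(t), 1)
    species <- "all"
    ns <- 1L
  }
  if (any(colSums(wmat) <= 0)) stop("total filtered intensity <= 0")
  cascades <- multi_tau_cascades(first_lag_ms = 4 * sync_ms,
                                 max_lag_ms = max_lag_ms)
  pairs <- expand.grid(i = seq_len(ns), j = seq_len(ns))
  seg_breaks <- seq(0, T_total, length.out = n_segments + 1)
  out_pairs <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    out_pairs[[k]] <- list(lag = numeric(0), lo = numeric(0), hi = numeric(0),
                           G = numeric(0), sd = numeric(0))
  }
  for (casc in cascades) {
    # multiple-tau coarsening: aggregate photon weights on a grid of half
    # the cascade's bin width before pair counting
    b <- casc$width / 2
    key <- floor(t / b)
    first <- !duplicated(key)
    grp <- cumsum(first)
    W <- rowsum(wmat, grp, reorder = FALSE)
    ta <- (key[first] + 0.5) * b
    seg_id <- pmin(findInterval(ta, seg_breaks, rightmost.closed = TRUE),
                   n_segments)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      full <- cpp_pair_correlate(ta, W[, i], W[, j], casc$edges, T_total)
      G <- full$S / pmax(full$D, .Machine$double.xmin) - 1
      Gseg <- vapply(seq_len(n_segments), function(s) {
        sel <- seg_id == s
        if (sum(sel) < 10) return(rep(NA_real_, length(G)))
        seg <- cpp_pair_correlate(ta[sel] - seg_breaks[s], W[sel, i],
                                  W[sel, j], casc$edges,
                                  seg_breaks[s + 1] - seg_breaks[s])
        seg$S / pmax(seg$D, .Machine$double.xmin) - 1
      }, numeric(length(G)))
      n_ok <- rowSums(!is.na(Gseg))
      sdv <- apply(Gseg, 1, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1))
      op <- out_pairs[[k]]
      out_pairs[[k]] <- list(
        lag = c(op$lag, (casc$edges[-length(casc$edges)] + casc$edges[-1]) / 2),
        lo = c(op$lo, casc$edges[-length(casc$edges)]),
        hi = c(op$hi, casc$edges[-1]),
        G = c(op$G, G), sd = c(op$sd, sdv))
    }
  }
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    i <- pairs$i[k]; j <- pairs$j[k]
    tibble::tibble(
      kind = if (i == j) "sACF" else "sCCF",
      species_i = species[i], species_j = species[j],
      lag_ms = out_pairs[[k]]$lag,
      lag_lo_ms = out_pairs[[k]]$lo, lag_hi_ms = out_pairs[[k]]$hi,
      G = out_pairs[[k]]$G, sd = out_pairs[[k]]$sd)
  })
  class(out) <- c("corr_curves", class(out))
  out
}

# quasi-logarithmic lag cascades: 16 lags per cascade, bin width doubling,
# first lag 4 sync periods; each cascade carries its own edge vector
multi_tau_cascades <- function(first_lag_ms, max_lag_ms, per_cascade = 16L) {
  cascades <- list()
  width <- first_lag_ms
  lo <- first_lag_ms
  while (lo < max_lag_ms) {
    hi <- min(lo + per_cascade * width, max_lag_ms * 1.0001)
    edges <- seq(lo, lo + per_cascade * width, by = width)
    edges <- edges[edges <= hi]
    if (length(edges) >= 2) {
      cascades[[length(cascades) + 1]] <- list(width = width, edges = edges)
    }
    lo <- lo + per_cascade * width
    width <- width * 2
  }
  cascades
}

#' Fit diffusion-plus-kinetics models to correlation curves
#'
#' Global weighted least-squares fit of
#' \deqn{G(t_c) = \frac{1}{N}\,(1 + t_c/t_d)^{-1} (1 + t_c/(s^2 t_d))^{-1/2}
#'   \big(1 + \sum_i A_i e^{-t_c/t_{Ri}}\big) + G_\infty}
#' to a set of sACF/sCCF curves. The diffusion time and the relaxation times
#' are shared across curves when `global = TRUE`; amplitudes `N`, `A_i` and
#' offset are per curve. Anti-correlated cross-correlation terms have
#' `A_i < 0`. Relaxation times closer than 10% are flagged as unresolvable.
#'
#' @param curves tibble from [correlate_filtered()] (columns `lag_ms`, `G`,
#'   `sd`, one group per `(kind, species_i, species_j)`).
#' @param n_relax number of exponential relaxation terms.
#' @param global share `t_diff` and `t_R` across curves; with
#'   `global = FALSE` each curve is fitted independently and a named list of
#'   fits is returned.
#' @param axial_ratio structure parameter `s = w_z/w_xy`.
#' @param fit_axial_ratio fit `s` (shared across curves) instead of fixing
#'   it; standard when the detection profile is imperfectly known.
#' @param t_diff_fixed freeze the diffusion time at this value (ms), e.g.
#'   from a separate full-lag-range fit, so that nested comparisons of
#'   kinetic terms are confined to the kinetic lag window.
#' @param t_diff_init,t_R_init optional starting values (ms).
#' @param lag_range_ms fit range in lag.
#' @return object of class `ffcs_fit` with `par` tibble and per-curve
#'   amplitudes; see `tidy()`/`glance()`.
#' @export
fit_correlations <- function(curves, n_relax = 1L, global = TRUE,
                             axial_ratio = 4, fit_axial_ratio = FALSE,
                             t_diff_init = NULL, t_diff_fixed = NULL,
                             t_R_init = NULL, lag_range_ms = NULL) {
  stopifnot(n_relax >= 0)
  curves <- dplyr::mutate(curves,
                          curve = paste(.data$kind, .data$species_i,
                                        .data$species_j, sep = ":"))
  if (!global) {
    # independent fits: every curve keeps its own diffusion and relaxation
    # times; returned as a named list of single-curve fits
    split_curves <- split(curves, curves$curve)
    return(lapply(split_curves, fit_correlations, n_relax = n_relax,
                  global = TRUE, axial_ratio = axial_ratio,
                  fit_axial_ratio = fit_axial_ratio,
                  t_diff_init = t_diff_init, t_diff_fixed = t_diff_fixed,
                  t_R_init = t_R_init, lag_range_ms = lag_range_ms))
  }
  if (!is.null(lag_range_ms)) {
    curves <- dplyr::filter(curves, .data$lag_ms >= lag_range_ms[1],
                            .data$lag_ms <= lag_range_ms[2])
  }
  ids <- unique(curves$curve)
  K <- length(ids)
  dat <- split(curves, curves$curve)[ids]
  if (is.null(t_diff_init)) t_diff_init <- 0.5
  if (is.null(t_R_init)) {
    t_R_init <- 10^seq(log10(2e-3), log10(0.2), length.out = max(n_relax, 1))
  }
  # parameters: log t_diff, log t_R (shared), per curve: log N, A_i, offset
  if (!is.null(t_diff_fixed)) t_diff_init <- t_diff_fixed
  p0 <- c(ltd = log(t_diff_init))
  if (fit_axial_ratio) p0 <- c(p0, ls = log(axial_ratio))
  if (n_relax > 0) p0 <- c(p0, stats::setNames(log(t_R_init[seq_len(n_relax)]),
                                               paste0("ltr", seq_len(n_relax))))
  for (k in seq_len(K)) {
    G0 <- max(abs(dat[[k]]$G[1]), 1e-3)
    p0 <- c(p0, stats::setNames(c(log(1 / G0),
                                  rep(sign(dat[[k]]$G[1]) * 0.3, n_relax), 0),
                                c(paste0("lN.", k),
                                  if (n_relax > 0) paste0("A", seq_len(n_relax), ".", k),
                                  paste0("off.", k))))
  }
  model_point <- function(p, k, lag) {
    td <- if (!is.null(t_diff_fixed)) t_diff_fixed else exp(p[["ltd"]])
    s_ax <- if (fit_axial_ratio) exp(p[["ls"]]) else axial_ratio
    tr <- if (n_relax > 0) exp(vapply(paste0("ltr", seq_len(n_relax)),
                                      function(nm) p[[nm]], numeric(1)))
    N <- exp(p[[paste0("lN.", k)]])
    A <- if (n_relax > 0) vapply(paste0("A", seq_len(n_relax), ".", k),
                                 function(nm) p[[nm]], numeric(1))
    off <- p[[paste0("off.", k)]]
    diff_term <- 1 / (1 + lag / td) / sqrt(1 + lag / (s_ax^2 * td))
    kin <- if (n_relax > 0) 1 + drop(exp(-outer(lag, 1 / tr)) %*% A) else 1
    (1 / N) * diff_term * kin + off
  }
  # the aggregated pair estimator samples G through the multiple-tau
  # kernel: per bin [lo, hi) of width 2b, pairs sit at centre differences
  # lo and lo+b, each spread by a triangular kernel of half-width b (the
  # aggregation bin). Model the expectation as the average of the two
  # triangle-smoothed evaluations (second-order accurate).
  model_curve <- function(p, k, lag, lo = NULL, hi = NULL) {
    if (is.null(lo) || is.null(hi)) return(model_point(p, k, lag))
    b <- (hi - lo) / 2
    tri <- function(c0) {
      cm <- pmax(c0 - b, 1e-9)
      model_point(p, k, c0) +
        (model_point(p, k, c0 + b) - 2 * model_point(p, k, c0) +
           model_point(p, k, cm)) / 12
    }
    (tri(lo) + tri(lo + b)) / 2
  }
  resid_fn <- function(p) {
    unlist(lapply(seq_len(K), function(k) {
      d <- dat[[k]]
      w <- 1 / pmax(d$sd, 1e-3 * max(abs(d$G), 1e-12))
      (d$G - model_curve(p, k, d$lag_ms, d$lag_lo_ms, d$lag_hi_ms)) * w
    }))
  }
  # relaxation times are only meaningful inside the measured lag window;
  # unbounded they degenerate into baseline terms
  lag_rng <- range(curves$lag_ms)
  lower <- rep(-Inf, length(p0)); upper <- rep(Inf, length(p0))
  is_tr <- grepl("^ltr", names(p0))
  lower[is_tr] <- log(lag_rng[1])
  upper[is_tr] <- log(lag_rng[2])
  is_td <- names(p0) == "ltd"
  lower[is_td] <- log(lag_rng[1])
  upper[is_td] <- log(lag_rng[2] * 50)
  if (!is.null(t_diff_fixed)) {
    lower[is_td] <- log(t_diff_fixed) - 1e-12
    upper[is_td] <- log(t_diff_fixed) + 1e-12
  }
  fit <- minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  t_R <- if (n_relax > 0) sort(exp(vapply(paste0("ltr", seq_len(n_relax)),
                                          function(nm) p[[nm]], numeric(1))))
  unresolved <- n_relax > 1 &&
    any(diff(t_R) / t_R[-length(t_R)] < 0.1)
  if (unresolved) warning("relaxation times within 10%: n_relax too large")
  n_obs <- sum(vapply(dat, nrow, integer(1)))
  n_par <- length(p0)
  rss <- sum(fit$fvec^2)
  per_curve <- purrr::map_dfr(seq_len(K), function(k) {
    tibble::tibble(curve = ids[k], N = exp(p[[paste0("lN.", k)]]),
                   offset = p[[paste0("off.", k)]],
                   !!!stats::setNames(
                     as.list(if (n_relax > 0)
                       vapply(paste0("A", seq_len(n_relax), ".", k),
                              function(nm) p[[nm]], numeric(1)) else numeric(0)),
                     if (n_relax > 0) paste0("A", seq_len(n_relax)) else character(0)))
  })
  structure(list(par = p,
                 t_diff_ms = if (!is.null(t_diff_fixed)) t_diff_fixed else exp(p[["ltd"]]),
                 axial_ratio_fit = if (fit_axial_ratio) exp(p[["ls"]]) else axial_ratio,
                 t_R_ms = t_R,
                 per_curve = per_curve, n_relax = n_relax,
                 rss = rss, n_obs = n_obs, n_par = n_par,
                 chi2r = rss / (n_obs - n_par), unresolved = unresolved,
                 axial_ratio = axial_ratio, curves = curves,
                 model = model_curve, ids = ids,
                 converged = fit$info %in% 1:4),
            class = "ffcs_fit")
}

#' @export
print.ffcs_fit <- function(x, ...) {
  cat("<ffcs_fit> t_diff = ", signif(x$t_diff_ms, 4), " ms", sep = "")
  if (x$n_relax > 0) {
    cat("; t_R = ", paste(signif(x$t_R_ms * 1e3, 4), collapse = ", "),
        " us", sep = "")
  }
  cat("; chi2_r = ", signif(x$chi2r, 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ffcs_fit <- function(x, ...) {
  out <- tibble::tibble(term = "t_diff_ms", estimate = x$t_diff_ms)
  if (x$n_relax > 0) {
    out <- dplyr::bind_rows(out,
      tibble::tibble(term = paste0("t_R", seq_len(x$n_relax), "_ms"),
                     estimate = x$t_R_ms))
  }
  out
}

#' @export
glance.ffcs_fit <- function(x, ...) {
  tibble::tibble(n_relax = x$n_relax, chi2r = x$chi2r, rss = x$rss,
                 n_obs = x$n_obs, n_par = x$n_par,
                 converged = x$converged, unresolved = x$unresolved)
}

#' F-test between nested correlation fits
#'
#' Tests whether the richer model (more relaxation terms) significantly
#' improves the fit: `F = ((RSS0-RSS1)/(p1-p0)) / (RSS1/(n-p1))`.
#'
#' @param fit0,fit1 nested [fit_correlations()] results (fit1 richer).
#' @return tibble with `F`, `df1`, `df2`, `p_value`.
#' @export
ftest_correlation_models <- function(fit0, fit1) {
  stopifnot(fit1$n_par > fit0$n_par, fit0$n_obs == fit1$n_obs)
  df1 <- fit1$n_par - fit0$n_par
  df2 <- fit1$n_obs - fit1$n_par
  Fv <- ((fit0$rss - fit1$rss) / df1) / (fit1$rss / df2)
  tibble::tibble(F = Fv, df1 = df1, df2 = df2,
                 p_value = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}
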