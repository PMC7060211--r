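# ---- parameterization ------------------------------------------------------
# The global fit works on a flat named parameter vector:
#   q.<i>      logit of shared species fraction i relative to the pivot
#   R.<d>.<i>  mean distance (A), dataset d, component i
#   lw.<d>.<i> log width (A)
#   ltau.<d>.<m> log donor lifetime (ns), shared between DA and DOnly
#   qa.<d>.<m>   logit of donor amplitude m relative to amplitude 1
#   shift.<d>    IRF time shift (channels), optional
#   qd0.<d>      logit of the DOnly fraction, optional
# Any entry can be removed from the free vector and pinned via `fixed`;
# fixing a shared fraction uses the special entry xfix = c(i, value).

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(pmin(z, 50))
  e / sum(e)
}

fit_config <- function(n_comp, n_datasets, n_donor = 1L, free_shift = FALSE,
                       fit_donly_fraction = FALSE, n_quad = 441L,
                       x_donly = 0) {
  list(n_comp = as.integer(n_comp), K = as.integer(n_datasets),
       n_donor = as.integer(n_donor), free_shift = free_shift,
       fit_donly_fraction = fit_donly_fraction, n_quad = as.integer(n_quad),
       x_donly = x_donly)
}

par_names <- function(cfg, fixed_frac = NULL) {
  nm <- character(0)
  if (cfg$n_comp > 1) {
    comps <- seq_len(cfg$n_comp)
    if (!is.null(fixed_frac)) comps <- setdiff(comps, fixed_frac[1])
    # first remaining component is the pivot (logit 0)
    if (length(comps) > 1) nm <- c(nm, paste0("q.", comps[-1]))
  }
  for (d in seq_len(cfg$K)) {
    nm <- c(nm,
            paste0("R.", d, ".", seq_len(cfg$n_comp)),
            paste0("lw.", d, ".", seq_len(cfg$n_comp)),
            paste0("ltau.", d, ".", seq_len(cfg$n_donor)))
    if (cfg$n_donor > 1) nm <- c(nm, paste0("qa.", d, ".", 2:cfg$n_donor))
    if (cfg$free_shift) nm <- c(nm, paste0("shift.", d))
    if (cfg$fit_donly_fraction) nm <- c(nm, paste0("qd0.", d))
  }
  nm
}

unpack_pars <- function(p, cfg, fixed = NULL, fixed_frac = NULL) {
  full <- c(p, fixed)
  g <- function(nm, default = NULL) {
    if (nm %in% names(full)) unname(full[nm]) else default
  }
  if (cfg$n_comp == 1) {
    fracs <- 1
  } else {
    comps <- seq_len(cfg$n_comp)
    if (is.null(fixed_frac)) {
      z <- c(0, vapply(paste0("q.", comps[-1]), g, numeric(1),
                       USE.NAMES = FALSE))
      fracs <- softmax(z)
    } else {
      free_comps <- setdiff(comps, fixed_frac[1])
      z <- c(0, vapply(paste0("q.", free_comps[-1]), g, numeric(1),
                       USE.NAMES = FALSE))
      fracs <- numeric(cfg$n_comp)
      fracs[fixed_frac[1]] <- fixed_frac[2]
      fracs[free_comps] <- (1 - fixed_frac[2]) * softmax(z)
    }
  }
  per <- lapply(seq_len(cfg$K), function(d) {
    mean_R <- vapply(paste0("R.", d, ".", seq_len(cfg$n_comp)), g,
                     numeric(1), USE.NAMES = FALSE)
    width <- exp(vapply(paste0("lw.", d, ".", seq_len(cfg$n_comp)), g,
                        numeric(1), USE.NAMES = FALSE))
    tau <- exp(vapply(paste0("ltau.", d, ".", seq_len(cfg$n_donor)), g,
                      numeric(1), USE.NAMES = FALSE))
    amp <- if (cfg$n_donor > 1) {
      softmax(c(0, vapply(paste0("qa.", d, ".", 2:cfg$n_donor), g, numeric(1),
                          USE.NAMES = FALSE)))
    } else 1
    shift <- if (cfg$free_shift) g(paste0("shift.", d)) else 0
    xd0 <- if (cfg$fit_donly_fraction) stats::plogis(g(paste0("qd0.", d))) else cfg$x_donly
    list(mean_R = mean_R, width = width, tau = tau, amp = amp,
         shift = shift, x_donly = xd0)
  })
  list(fracs = fracs, per = per)
}

# weighted linear solve for (amplitude, scatter, background) of one curve;
# returns the orthonormal basis Q of the active weighted design columns so
# the Jacobian can be projected out of the profiled linear space (Kaufman)
solve_linear <- function(counts, conv, irf_n, idx) {
  sig <- sqrt(pmax(counts[idx], 1))
  X <- cbind(conv[idx], irf_n[idx], 1) / sig
  y <- counts[idx] / sig
  coef <- tryCatch(qr.coef(qr(X), y), error = function(e) c(NA, NA, NA))
  coef[is.na(coef)] <- 0
  active <- coef > 0
  if (any(coef < 0)) {
    coef <- pmax(coef, 0)
    if (any(active)) {
      Xa <- X[, active, drop = FALSE]
      ca <- tryCatch(qr.coef(qr(Xa), y), error = function(e) coef[active])
      ca[is.na(ca) | ca < 0] <- 0
      coef[active] <- ca
    }
  }
  active <- coef > 0
  Q <- if (any(active)) qr.Q(qr(X[, active, drop = FALSE])) else NULL
  model <- conv * coef[1] + irf_n * coef[2] + coef[3]
  list(coef = coef, model = model, Q = Q)
}

# full per-dataset model state: residuals, linear coefficients, and the
# intermediates reused by the analytic Jacobian
dataset_internals <- function(ds, pieces, fracs, R0, n_quad) {
  t <- ds$time_ns
  idx <- ds$fit_range[1]:ds$fit_range[2]
  irf_n <- ds$irf / sum(ds$irf)
  if (pieces$shift != 0) irf_n <- shift_channels(irf_n, pieces$shift)
  amp <- pieces$amp / sum(pieces$amp)
  tau <- pmax(pieces$tau, 1e-3)
  tau_D0 <- sum(amp * tau)
  fD_m <- exp(-outer(t, 1 / tau))              # per donor component
  fD <- drop(fD_m %*% amp)
  n_comp <- length(fracs)
  comps <- vector("list", n_comp)
  G <- rep(pieces$x_donly, length(t))
  for (i in seq_len(n_comp)) {
    q <- distance_quadrature(pieces$mean_R[i], max(pieces$width[i], 1e-3), n_quad)
    k <- (1 / tau_D0) * (R0 / q$R)^6
    E <- exp(-outer(t, k))
    g <- drop(E %*% q$w)
    comps[[i]] <- list(R = q$R, w = q$w, k = k, E = E, g = g,
                       mean_R = pieces$mean_R[i], width = pieces$width[i])
    G <- G + (1 - pieces$x_donly) * fracs[i] * g
  }
  Fda <- fD * G
  Fd0 <- fD
  conv_da <- circular_convolve(irf_n, Fda)
  conv_d0 <- circular_convolve(irf_n, Fd0)
  fit_da <- solve_linear(ds$da, conv_da, irf_n, idx)
  fit_d0 <- solve_linear(ds$donly, conv_d0, irf_n, idx)
  sig_da <- sqrt(pmax(ds$da[idx], 1))
  sig_d0 <- sqrt(pmax(ds$donly[idx], 1))
  res <- c((ds$da[idx] - fit_da$model[idx]) / sig_da,
           (ds$donly[idx] - fit_d0$model[idx]) / sig_d0)
  list(res = res, model_da = fit_da$model, model_d0 = fit_d0$model,
       lin_da = fit_da$coef, lin_d0 = fit_d0$coef,
       Q_da = fit_da$Q, Q_d0 = fit_d0$Q, n = 2 * length(idx),
       t = t, idx = idx, irf_n = irf_n, fD = fD, fD_m = fD_m, amp = amp,
       tau = tau, tau_D0 = tau_D0, G = G, comps = comps,
       sig_da = sig_da, sig_d0 = sig_d0,
       x_donly = pieces$x_donly)
}

# backwards-compatible wrapper (used by reporting/plotting)
dataset_residuals <- function(ds, pieces, fracs, R0, n_quad) {
  dataset_internals(ds, pieces, fracs, R0, n_quad)
}

# memoised joint state across datasets (fn and jac are called with the same
# parameter vector in sequence; avoid recomputing the expensive kernels)
global_state <- function(p, datasets, cfg, R0, fixed, fixed_frac, cache) {
  # minpack.lm mutates `par` in place between calls: key the cache on a
  # forced value copy, never on the SEXP itself
  key <- unname(as.numeric(p)) + 0
  if (!is.null(cache$p) && identical(cache$p, key)) return(cache$val)
  up <- unpack_pars(p, cfg, fixed, fixed_frac)
  val <- list(up = up,
              per = lapply(seq_along(datasets), function(d) {
                dataset_internals(datasets[[d]], up$per[[d]], up$fracs, R0,
                                  cfg$n_quad)
              }))
  cache$p <- key
  cache$val <- val
  val
}

global_residuals <- function(p, datasets, cfg, R0, fixed = NULL,
                             fixed_frac = NULL, cache = NULL) {
  if (is.null(cache)) cache <- new.env()
  st <- global_state(p, datasets, cfg, R0, fixed, fixed_frac, cache)
  unlist(lapply(st$per, `[[`, "res"))
}

# analytic Jacobian of the weighted residuals (Kaufman variable-projection
# approximation: the analytically profiled amplitude/scatter/background are
# held at their current values). Covers the standard parameterization
# (single-donor-lifetime fits without free shift); richer configurations
# fall back to nls.lm's numeric differences.
global_jacobian <- function(p, datasets, cfg, R0, fixed = NULL,
                            fixed_frac = NULL, cache = NULL) {
  if (is.null(cache)) cache <- new.env()
  st <- global_state(p, datasets, cfg, R0, fixed, fixed_frac, cache)
  up <- st$up
  fracs <- up$fracs
  n_comp <- cfg$n_comp
  # softmax state for fraction derivatives
  if (n_comp > 1) {
    if (is.null(fixed_frac)) {
      s_soft <- fracs
      free_comps <- seq_len(n_comp)[-1]
      scale_frac <- 1
    } else {
      fc <- fixed_frac[1]
      free_all <- setdiff(seq_len(n_comp), fc)
      s_soft <- fracs
      s_soft[free_all] <- fracs[free_all] / max(1 - fixed_frac[2], 1e-12)
      free_comps <- free_all[-1]
      scale_frac <- 1 - fixed_frac[2]
    }
  }
  rows_per <- vapply(st$per, function(z) as.integer(z$n), integer(1))
  n_res <- sum(rows_per)
  J <- matrix(0, n_res, length(p))
  colnames(J) <- names(p)
  row0 <- c(0, cumsum(rows_per))
  for (d in seq_along(datasets)) {
    it <- st$per[[d]]
    nidx <- length(it$idx)
    A_da <- it$lin_da[1]
    A_d0 <- it$lin_d0[1]
    xd0 <- it$x_donly
    put <- function(nm, dF_da, dF_d0 = NULL) {
      col <- numeric(n_res)
      cda <- circular_convolve(it$irf_n, dF_da)
      v <- A_da * cda[it$idx] / it$sig_da
      if (!is.null(it$Q_da)) v <- v - it$Q_da %*% crossprod(it$Q_da, v)
      col[(row0[d] + 1):(row0[d] + nidx)] <- -v
      if (!is.null(dF_d0)) {
        cd0 <- circular_convolve(it$irf_n, dF_d0)
        v0 <- A_d0 * cd0[it$idx] / it$sig_d0
        if (!is.null(it$Q_d0)) v0 <- v0 - it$Q_d0 %*% crossprod(it$Q_d0, v0)
        col[(row0[d] + nidx + 1):(row0[d] + 2 * nidx)] <- -v0
      }
      J[, nm] <<- J[, nm] + col
    }
    # shared fraction logits
    if (n_comp > 1) {
      for (b in free_comps) {
        nm <- paste0("q.", b)
        if (!nm %in% names(p)) next
        dG <- numeric(length(it$t))
        for (a in if (is.null(fixed_frac)) seq_len(n_comp)
             else setdiff(seq_len(n_comp), fixed_frac[1])) {
          dx_ab <- scale_frac * s_soft[a] * ((a == b) - s_soft[b])
          dG <- dG + dx_ab * it$comps[[a]]$g
        }
        put(nm, it$fD * (1 - xd0) * dG)
      }
    }
    # per-dataset distances and widths
    for (i in seq_len(n_comp)) {
      cmp <- it$comps[[i]]
      mu <- cmp$mean_R; sw <- max(cmp$width, 1e-3)
      zc <- (cmp$R - mu) / sw
      nmR <- paste0("R.", d, ".", i)
      if (nmR %in% names(p)) {
        dw <- cmp$w * (zc / sw - sum(cmp$w * zc / sw))
        dF <- it$fD * (1 - xd0) * fracs[i] * drop(cmp$E %*% dw)
        put(nmR, dF)
      }
      nmW <- paste0("lw.", d, ".", i)
      if (nmW %in% names(p)) {
        dlog <- (zc^2 - 1) / sw
        dw <- cmp$w * (dlog - sum(cmp$w * dlog))
        dF <- it$fD * (1 - xd0) * fracs[i] * drop(cmp$E %*% dw) * sw
        put(nmW, dF)
      }
    }
    # donor lifetime (single-component spectrum)
    nmT <- paste0("ltau.", d, ".1")
    if (cfg$n_donor == 1 && nmT %in% names(p)) {
      tau <- it$tau[1]
      dfD <- it$fD * it$t / tau^2
      dsum <- numeric(length(it$t))
      for (i in seq_len(n_comp)) {
        cmp <- it$comps[[i]]
        H <- drop((cmp$E * outer(it$t, cmp$k)) %*% cmp$w)
        dsum <- dsum + fracs[i] * H / tau
      }
      dF_da <- (dfD * it$G + it$fD * (1 - xd0) * dsum) * tau
      dF_d0 <- dfD * tau
      put(nmT, dF_da, dF_d0)
    }
  }
  J
}

jac_supported <- function(cfg) {
  cfg$n_donor == 1L && !cfg$free_shift && !cfg$fit_donly_fraction
}

init_guess <- function(datasets, cfg, R0) {
  p <- numeric(0)
  if (cfg$n_comp > 1) {
    p <- c(p, stats::setNames(rep(0, cfg$n_comp - 1),
                              paste0("q.", 2:cfg$n_comp)))
  }
  spread <- seq(0.75, 1.25, length.out = max(cfg$n_comp, 2))[seq_len(cfg$n_comp)]
  if (cfg$n_comp == 1) spread <- 1
  for (d in seq_len(cfg$K)) {
    ds <- datasets[[d]]
    # crude DOnly lifetime moment: mean arrival minus IRF mean (periodic-safe
    # enough for initialization)
    m_irf <- sum(ds$time_ns * ds$irf) / sum(ds$irf)
    m_d0 <- sum(ds$time_ns * ds$donly) / sum(ds$donly)
    tau0 <- max(m_d0 - m_irf, 0.5)
    p <- c(p,
           stats::setNames(R0 * spread, paste0("R.", d, ".", seq_len(cfg$n_comp))),
           stats::setNames(rep(log(6), cfg$n_comp),
                           paste0("lw.", d, ".", seq_len(cfg$n_comp))),
           stats::setNames(rep(log(tau0), cfg$n_donor) +
                             log(seq(1, 0.5, length.out = cfg$n_donor)),
                           paste0("ltau.", d, ".", seq_len(cfg$n_donor))))
    if (cfg$n_donor > 1) {
      p <- c(p, stats::setNames(rep(0, cfg$n_donor - 1),
                                paste0("qa.", d, ".", 2:cfg$n_donor)))
    }
    if (cfg$free_shift) p <- c(p, stats::setNames(0, paste0("shift.", d)))
    if (cfg$fit_donly_fraction) {
      p <- c(p, stats::setNames(stats::qlogis(0.05), paste0("qd0.", d)))
    }
  }
  p
}

run_lm <- function(p0, datasets, cfg, R0, fixed, fixed_frac, maxiter = 120) {
  lower <- rep(-Inf, length(p0))
  upper <- rep(Inf, length(p0))
  isR <- startsWith(names(p0), "R.")
  lower[isR] <- 5; upper[isR] <- 500         # physical distance range (A)
  isW <- startsWith(names(p0), "lw.")
  lower[isW] <- log(0.3); upper[isW] <- log(60)
  cache <- new.env()
  # iteration-capped refits are routine during profile scans: the cap is
  # reported via the convergence flag, not as a warning
  withCallingHandlers(
    minpack.lm::nls.lm(
      par = p0,
      fn = global_residuals,
      jac = if (jac_supported(cfg)) global_jacobian,
      datasets = datasets, cfg = cfg, R0 = R0,
      fixed = fixed, fixed_frac = fixed_frac, cache = cache,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = maxiter, ptol = 1e-10,
                                           ftol = 1e-10)),
    warning = function(w) {
      if (grepl("maxiter", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

count_linear_pars <- function(datasets) 6L * length(datasets)

#' Global fit of TCSPC decays with Gaussian distance distributions
#'
#' Jointly fits one or more [decay_dataset()]s with the distance-distribution
#' decay model of [fret_induced_donor_decay()]: for every dataset the model is
#' the donor decay convolved with the measured IRF plus a scattered-light term
#' and a flat background, weighted by Poisson counting noise
#' (sigma = sqrt(max(counts, 1))). The donor lifetime spectrum is shared
#' between the DA and DOnly curves of each dataset; the species fractions of
#' the conformational states are shared across all datasets, while the mean
#' distances and widths are dataset-specific. Amplitude, scatter and
#' background are profiled analytically per curve.
#'
#' Multi-component surfaces are multi-modal; after the deterministic first
#' start the fit restarts from latin-hypercube draws until the global reduced
#' chi-square is statistically acceptable or `n_restarts` is exhausted.
#' Components are reported sorted by ascending mean distance of the first
#' dataset (label-switching convention).
#'
#' @param datasets a [decay_dataset()] or list of them.
#' @param n_components number of Gaussian distance components.
#' @param R0 Foerster radius (Angstrom).
#' @param n_donor number of donor lifetime components.
#' @param free_shift fit a sub-channel IRF time shift per dataset.
#' @param fit_donly_fraction fit a per-dataset donor-only fraction
#'   (otherwise fixed at `x_donly`).
#' @param x_donly fixed donor-only fraction when not fitted.
#' @param n_quad distance quadrature nodes per component.
#' @param n_restarts maximum latin-hypercube restarts.
#' @param init optional named starting vector (internal coordinates).
#' @param seed seed for the restart draws.
#' @return object of class `decay_fit`; see [tidy.decay_fit()] /
#'   [glance.decay_fit()].
#' @export
fit_decays_global <- function(datasets, n_components, R0,
                              n_donor = 1L, free_shift = FALSE,
                              fit_donly_fraction = FALSE, x_donly = 0,
                              n_quad = 441L, n_restarts = 8L,
                              init = NULL, seed = 1L, maxiter = 150) {
  if (inherits(datasets, "decay_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, logical(1), "decay_dataset")))
  if (n_components < 1) stop("n_components must be >= 1")
  cfg <- fit_config(n_components, length(datasets), n_donor, free_shift,
                    fit_donly_fraction, n_quad, x_donly)
  p0 <- init_guess(datasets, cfg, R0)
  if (!is.null(init)) p0[names(init)] <- init
  n_tot <- sum(vapply(datasets, function(d) 2L * diff(d$fit_range) + 2L,
                      integer(1)))
  n_free <- length(p0) + count_linear_pars(datasets)
  accept <- 1 + 4 * sqrt(2 / n_tot)  # ~4 sigma above the Poisson expectation

  best <- run_lm(p0, datasets, cfg, R0, NULL, NULL, maxiter = maxiter)
  chi2r <- function(f) sum(f$fvec^2) / (n_tot - n_free)
  tried <- 0L
  if (n_restarts > 0 && chi2r(best) > accept && is.null(init)) {
    set.seed(seed)
    while (tried < n_restarts && chi2r(best) > accept) {
      tried <- tried + 1L
      p1 <- p0
      for (d in seq_len(cfg$K)) {
        rn <- paste0("R.", d, ".", seq_len(cfg$n_comp))
        p1[rn] <- sort(stats::runif(cfg$n_comp, 0.6 * R0, 1.5 * R0))
        wn <- paste0("lw.", d, ".", seq_len(cfg$n_comp))
        p1[wn] <- log(stats::runif(cfg$n_comp, 3, 12))
      }
      cand <- run_lm(p1, datasets, cfg, R0, NULL, NULL, maxiter = maxiter)
      if (chi2r(cand) < chi2r(best)) best <- cand
    }
  }

  build_fit_result(best, datasets, cfg, R0, n_tot, n_free,
                   converged = best$info %in% 1:4, restarts = tried)
}

order_components <- function(up, cfg) {
  # sort by mean distance of dataset 1 to break label switching
  order(up$per[[1]]$mean_R)
}

build_fit_result <- function(lmfit, datasets, cfg, R0, n_tot, n_free,
                             converged, restarts = 0L,
                             fixed = NULL, fixed_frac = NULL) {
  p <- lmfit$par
  up <- unpack_pars(p, cfg, fixed, fixed_frac)
  ord <- order_components(up, cfg)
  per_rows <- list()
  chi2_ds <- numeric(cfg$K)
  lin <- list()
  rss <- 0
  for (d in seq_len(cfg$K)) {
    dr <- dataset_residuals(datasets[[d]], up$per[[d]], up$fracs, R0, cfg$n_quad)
    p_local <- 2 * cfg$n_comp + cfg$n_donor + 6 +
      (cfg$n_comp - 1) / cfg$K
    chi2_ds[d] <- sum(dr$res^2) / (dr$n - p_local)
    rss <- rss + sum(dr$res^2)
    lin[[d]] <- list(da = dr$lin_da, d0 = dr$lin_d0)
    per_rows[[d]] <- tibble::tibble(
      dataset = datasets[[d]]$name, dataset_id = d,
      component = seq_len(cfg$n_comp),
      fraction = up$fracs[ord], mean_R = up$per[[d]]$mean_R[ord],
      width = up$per[[d]]$width[ord])
  }
  structure(
    list(par = p, fixed = fixed, fixed_frac = fixed_frac, cfg = cfg, R0 = R0,
         datasets = datasets, fractions = up$fracs[ord], unpacked = up,
         component_order = ord,
         estimates = dplyr::bind_rows(per_rows),
         donor = lapply(up$per, function(z)
           tibble::tibble(amplitude = z$amp / sum(z$amp), tau_ns = z$tau)),
         linear = lin,
         chi2r_datasets = chi2_ds,
         chi2r_global = rss / (n_tot - n_free),
         n_points = n_tot, n_free = n_free,
         converged = converged, restarts = restarts),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> ", x$cfg$n_comp, " component(s), ", x$cfg$K,
      " dataset(s); global chi2_r = ", signif(x$chi2r_global, 5),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(x$estimates)
  invisible(x)
}

#' Tidy methods for decay fits
#'
#' `tidy()` returns the per-dataset component table (shared fraction, mean
#' distance, width); `glance()` a one-row fit summary.
#'
#' @param x a `decay_fit`.
#' @param ... unused.
#' @export
tidy.decay_fit <- function(x, ...) x$estimates

#' @rdname tidy.decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    n_components = x$cfg$n_comp, n_datasets = x$cfg$K,
    chi2r_global = x$chi2r_global, n_points = x$n_points,
    n_free = x$n_free, converged = x$converged, restarts = x$restarts)
}

# internal refit with pinned quantities, warm-started from `fit`
refit_fixed <- function(fit, fixed = NULL, fixed_frac = NULL, init = NULL,
                        maxiter = 40) {
  cfg <- fit$cfg
  nm <- par_names(cfg, fixed_frac)
  p0 <- if (is.null(init)) fit$par[intersect(names(fit$par), nm)] else init
  missing <- setdiff(nm, names(p0))
  if (length(missing)) {
    full0 <- init_guess(fit$datasets, cfg, fit$R0)
    p0 <- c(p0, full0[missing])
  }
  p0 <- p0[setdiff(names(p0), names(fixed))]
  lmfit <- run_lm(p0, fit$datasets, cfg, fit$R0, fixed, fixed_frac, maxiter)
  n_free <- length(p0) + count_linear_pars(fit$datasets)
  build_fit_result(lmfit, fit$datasets, cfg, fit$R0, fit$n_points, n_free,
                   converged = lmfit$info %in% 1:4,
                   fixed = fixed, fixed_frac = fixed_frac)
}

# translate a user-facing parameter spec to the internal fixing mechanism
fixed_spec <- function(fit, parameter, dataset, component, value) {
  switch(parameter,
    fraction = list(fixed = NULL,
                    fixed_frac = c(internal_component(fit, component), value)),
    mean_R = list(
      fixed = stats::setNames(value, paste0("R.", dataset, ".",
                                            internal_component(fit, component))),
      fixed_frac = NULL),
    width = list(
      fixed = stats::setNames(log(value), paste0("lw.", dataset, ".",
                                                 internal_component(fit, component))),
      fixed_frac = NULL),
    stop("unknown parameter: ", parameter)
  )
}

# map reported (distance-ordered) component index to internal index
internal_component <- function(fit, component) {
  fit$component_order[component]
}

#' Support-plane (profile chi-square) scan of a fit parameter
#'
#' Pins one model parameter at each grid value and re-optimizes all other
#' parameters, tracing the profile of the global reduced chi-square. The
#' confidence interval collects the grid values whose chi-square stays below
#' the F-test threshold
#' `chi2r_min * (1 + p/(n-p) * qf(conf, p, n-p))`
#' with `p` free parameters and `n` fitted channels. For distance parameters
#' the asymmetric statistical distance uncertainties are reported as the
#' shortest and longest distance below the threshold.
#'
#' @param fit a converged [fit_decays_global()] result.
#' @param parameter one of `"fraction"`, `"mean_R"`, `"width"`.
#' @param grid numeric grid of parameter values to profile.
#' @param component component index (in the reported, distance-sorted order).
#' @param dataset dataset index (ignored for shared fractions).
#' @param conf confidence level of the F-test threshold.
#' @return object of class `support_plane`: tibble `(value, chi2r_global)`
#'   with attributes `threshold`, `ci`, `dR_minus`, `dR_plus`, `center`.
#' @export
support_plane_scan <- function(fit, parameter, grid, component = 1L,
                               dataset = 1L, conf = 0.68, maxiter = 40) {
  stopifnot(inherits(fit, "decay_fit"), length(grid) >= 3)
  # keep the scan inside the physically meaningful parameter range
  grid <- switch(parameter,
    mean_R = grid[grid >= 6],
    width = grid[grid >= 0.35],
    fraction = grid[grid > 1e-3 & grid < 0.999],
    grid)
  if (length(grid) < 3) stop("grid has fewer than 3 feasible values")
  grid <- sort(grid)
  center <- switch(parameter,
    fraction = fit$fractions[component],
    mean_R = fit$estimates$mean_R[fit$estimates$dataset_id == dataset &
                                    fit$estimates$component == component],
    width = fit$estimates$width[fit$estimates$dataset_id == dataset &
                                  fit$estimates$component == component])
  covered <- center >= min(grid) && center <= max(grid)
  if (!covered) warning("scan grid does not cover the fitted optimum")
  # scan outward from the nearest grid point, warm-starting sequentially
  i0 <- which.min(abs(grid - center))
  order_idx <- c(rev(seq_len(i0)), if (i0 < length(grid)) (i0 + 1):length(grid))
  chi2 <- numeric(length(grid))
  warm_up <- fit$par
  warm <- warm_up
  for (pos in seq_along(order_idx)) {
    i <- order_idx[pos]
    if (i == i0 + 1) warm <- warm_up  # restart warm chain for the upper branch
    spec <- fixed_spec(fit, parameter, dataset, component, grid[i])
    ref <- refit_fixed(fit, spec$fixed, spec$fixed_frac,
                       init = warm[setdiff(names(warm), names(spec$fixed))],
                       maxiter = maxiter)
    chi2[i] <- ref$chi2r_global
    warm <- ref$par
  }
  chi2min <- min(c(chi2, fit$chi2r_global))
  p_free <- fit$n_free
  n <- fit$n_points
  thresh <- chi2min * (1 + p_free / (n - p_free) *
                         stats::qf(conf, p_free, n - p_free))
  below <- chi2 <= thresh
  ci <- if (!any(below)) c(NA_real_, NA_real_) else {
    lo <- grid[which(below)[1]]
    hi <- grid[rev(which(below))[1]]
    # refine by linear interpolation at the crossings
    i_lo <- which(below)[1]
    if (i_lo > 1) {
      lo <- stats::approx(chi2[(i_lo - 1):i_lo], grid[(i_lo - 1):i_lo],
                          xout = thresh)$y
    }
    i_hi <- rev(which(below))[1]
    if (i_hi < length(grid)) {
      hi <- stats::approx(chi2[i_hi:(i_hi + 1)], grid[i_hi:(i_hi + 1)],
                          xout = thresh)$y
    }
    c(lo, hi)
  }
  out <- tibble::tibble(value = grid, chi2r_global = chi2)
  class(out) <- c("support_plane", class(out))
  attr(out, "parameter") <- parameter
  attr(out, "threshold") <- thresh
  attr(out, "conf") <- conf
  attr(out, "ci") <- ci
  attr(out, "center") <- center
  attr(out, "covered") <- covered
  if (parameter == "mean_R" && all(is.finite(ci))) {
    attr(out, "dR_minus") <- max(center - ci[1], 0)
    attr(out, "dR_plus") <- max(ci[2] - center, 0)
  }
  out
}

# ---- MCMC ------------------------------------------------------------------

# adaptive random-walk Metropolis; proposal covariance adapted during the
# first `burn` samples (Haario-style), then frozen
adaptive_metropolis <- function(logpost, init, n_samples, seed,
                                burn = max(400L, n_samples %/% 2L),
                                scale0 = 0.02) {
  set.seed(seed)
  d <- length(init)
  cur <- init
  lp <- logpost(cur)
  if (!is.finite(lp)) stop("initial point has non-finite posterior")
  cov <- diag(pmax(abs(init) * scale0, 1e-4)^2 / d, d)
  chol_c <- chol(cov)
  sfac <- 1            # global step-size factor, tuned to ~30% acceptance
  out <- matrix(NA_real_, n_samples, d)
  lps <- numeric(n_samples)
  acc <- 0L
  total <- burn + n_samples
  run_mean <- cur
  run_cov <- cov
  win_acc <- 0L
  for (i in seq_len(total)) {
    prop <- cur + sfac * drop(crossprod(chol_c, stats::rnorm(d)))
    lp_p <- logpost(prop)
    if (is.finite(lp_p) && log(stats::runif(1)) < lp_p - lp) {
      cur <- prop; lp <- lp_p
      if (i > burn) acc <- acc + 1L else win_acc <- win_acc + 1L
    }
    if (i <= burn) {
      w <- 1 / (i + 1)
      delta <- cur - run_mean
      run_mean <- run_mean + w * delta
      run_cov <- (1 - w) * (run_cov + w * tcrossprod(delta))
      if (i %% 50 == 0) {
        # step-size tuning toward the multivariate optimum (~0.3)
        rate <- win_acc / 50
        if (rate < 0.15) sfac <- sfac / 2
        else if (rate > 0.5) sfac <- sfac * 1.6
        win_acc <- 0L
        if (i >= 100) {
          cand <- run_cov * 2.38^2 / d + diag(mean(diag(run_cov)) * 1e-6 + 1e-12, d)
          ch <- tryCatch(chol(cand), error = function(e) NULL)
          if (!is.null(ch)) { chol_c <- ch; sfac <- max(sfac, 0.5) }
        }
      }
    } else {
      out[i - burn, ] <- cur
      lps[i - burn] <- lp
    }
  }
  colnames(out) <- names(init)
  list(samples = out, logpost = lps, acceptance = acc / n_samples)
}

#' Posterior sampling of decay-model parameters
#'
#' Samples the Poisson likelihood of a single dataset's DA and DOnly decay
#' histograms around a converged fit by adaptive random-walk Metropolis. The
#' free parameters are the fit's nonlinear parameters plus log amplitudes of
#' both curves; scatter and background stay at their fitted values. Marginal
#' histograms of the sampled distances and fractions visualize the statistical
#' parameter uncertainty.
#'
#' @param fit a single-dataset [fit_decays_global()] result.
#' @param n_samples retained samples (after burn-in of `n_samples/4`).
#' @param seed integer seed (chains are reproducible).
#' @return object of class `decay_mcmc` with `samples` (tibble in natural
#'   units), `acceptance`, and `flagged` (acceptance outside `[0.05, 0.9]`).
#' @export
mcmc_uncertainty <- function(fit, n_samples = 2000L, seed = 1L) {
  stopifnot(inherits(fit, "decay_fit"))
  if (fit$cfg$K != 1L) stop("mcmc_uncertainty expects a single-dataset fit")
  ds <- fit$datasets[[1]]
  idx <- ds$fit_range[1]:ds$fit_range[2]
  cfg <- fit$cfg
  lin <- fit$linear[[1]]
  base_names <- names(fit$par)
  init <- c(fit$par,
            lA_da = log(max(lin$da[1], 1e-12)),
            lA_d0 = log(max(lin$d0[1], 1e-12)))
  logpost <- function(p) {
    up <- tryCatch(unpack_pars(p[base_names], cfg, fit$fixed, fit$fixed_frac),
                   error = function(e) NULL)
    if (is.null(up)) return(-Inf)
    pc <- up$per[[1]]
    if (any(pc$mean_R < 5) || any(pc$width > 50)) return(-Inf)
    t <- ds$time_ns
    irf_n <- ds$irf / sum(ds$irf)
    if (pc$shift != 0) irf_n <- shift_channels(irf_n, pc$shift)
    dl <- tibble::tibble(amplitude = pc$amp, tau_ns = pc$tau)
    model_da <- tryCatch(distance_model(
      components = tibble::tibble(fraction = up$fracs, mean_R = pc$mean_R,
                                  width = pc$width),
      x_donly = pc$x_donly, donor_lifetimes = dl, R0 = fit$R0),
      error = function(e) NULL)
    if (is.null(model_da)) return(-Inf)
    conv_da <- circular_convolve(irf_n, decay_intensity(model_da, t, cfg$n_quad))
    Fd0 <- drop(exp(-outer(t, 1 / pc$tau)) %*% (pc$amp / sum(pc$amp)))
    conv_d0 <- circular_convolve(irf_n, Fd0)
    m_da <- exp(p[["lA_da"]]) * conv_da + lin$da[2] * irf_n + lin$da[3]
    m_d0 <- exp(p[["lA_d0"]]) * conv_d0 + lin$d0[2] * irf_n + lin$d0[3]
    m_da <- pmax(m_da[idx], 1e-12)
    m_d0 <- pmax(m_d0[idx], 1e-12)
    sum(ds$da[idx] * log(m_da) - m_da) + sum(ds$donly[idx] * log(m_d0) - m_d0)
  }
  mh <- adaptive_metropolis(logpost, init, n_samples, seed)
  ord <- fit$component_order
  nat <- purrr::map_dfr(seq_len(nrow(mh$samples)), function(i) {
    up <- unpack_pars(mh$samples[i, base_names], cfg, fit$fixed, fit$fixed_frac)
    row <- list(sample = i)
    for (k in seq_len(cfg$n_comp)) {
      row[[paste0("mean_R_", k)]] <- up$per[[1]]$mean_R[ord[k]]
      row[[paste0("width_", k)]] <- up$per[[1]]$width[ord[k]]
      row[[paste0("x_", k)]] <- up$fracs[ord[k]]
    }
    tibble::as_tibble(row)
  })
  flagged <- mh$acceptance < 0.05 || mh$acceptance > 0.9
  if (flagged) warning(sprintf("MCMC acceptance rate %.3f outside [0.05, 0.9]",
                               mh$acceptance))
  structure(list(samples = nat, raw = mh$samples, logpost = mh$logpost,
                 acceptance = mh$acceptance, flagged = flagged),
            class = "decay_mcmc")
}

#' @export
print.decay_mcmc <- function(x, ...) {
  cat("<decay_mcmc> ", nrow(x$samples), " samples, acceptance ",
      signif(x$acceptance, 3), if (x$flagged) "  [FLAGGED]", "\n", sep = "")
  print(utils::head(x$samples, 5))
  invisible(x)
}

#' @export
tidy.decay_mcmc <- function(x, ...) {
  x$samples |>
    tidyr::pivot_longer(-dplyr::all_of("sample"),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(estimate = stats::median(.data$value),
                     sd = stats::sd(.data$value),
                     q16 = stats::quantile(.data$value, 0.16),
                     q84 = stats::quantile(.data$value, 0.84),
                     .groups = "drop")
}
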