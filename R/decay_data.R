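#' Bundle a TCSPC measurement for fitting
#'
#' A decay dataset holds the FRET-labelled (DA) decay histogram, the
#' donor-only (DOnly) reference decay, and the instrument response function
#' (IRF) on a common uniform channel grid, together with the fit range.
#'
#' @param da,donly,irf tibbles with columns `time_ns`, `counts` on identical
#'   uniform grids. Counts are non-negative (integers for measured data).
#' @param fit_range integer channel range `c(first, last)` used in fitting;
#'   defaults to all channels.
#' @param name optional label used in reports.
#' @return object of class `decay_dataset`.
#' @export
decay_dataset <- function(da, donly, irf, fit_range = NULL, name = NULL) {
  curves <- lapply(list(da = da, donly = donly, irf = irf), tibble::as_tibble)
  for (nm in names(curves)) {
    cv <- curves[[nm]]
    stopifnot(all(c("time_ns", "counts") %in% names(cv)))
    if (any(cv$counts < 0)) stop(nm, ": counts must be >= 0")
    dt <- diff(cv$time_ns)
    if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) stop(nm, ": non-uniform grid")
  }
  t0 <- curves$da$time_ns
  if (!all(vapply(curves, function(cv) isTRUE(all.equal(cv$time_ns, t0)),
                  logical(1)))) {
    stop("all curves must share one channel grid")
  }
  if (sum(curves$irf$counts) <= 0) stop("IRF has zero mass")
  n <- length(t0)
  if (is.null(fit_range)) fit_range <- c(1L, n)
  fit_range <- as.integer(fit_range)
  if (fit_range[1] < 1 || fit_range[2] > n || fit_range[1] >= fit_range[2]) {
    stop("fit_range outside the channel grid")
  }
  structure(
    list(time_ns = t0, channel_width_ns = t0[2] - t0[1],
         da = curves$da$counts, donly = curves$donly$counts,
         irf = curves$irf$counts, fit_range = fit_range,
         name = name %||% "dataset"),
    class = "decay_dataset"
  )
}

#' @export
print.decay_dataset <- function(x, ...) {
  cat("<decay_dataset> ", x$name, ": ", length(x$time_ns), " channels of ",
      signif(x$channel_width_ns, 4), " ns; DA ", sum(x$da), " / DOnly ",
      sum(x$donly), " counts\n", sep = "")
  invisible(x)
}

#' Read / write decay curves as two-column text
#'
#' The interchange format is whitespace-separated `time_ns counts` with an
#' optional JSON sidecar (same path + `.json`) holding metadata such as the
#' channel width and detection polarization.
#'
#' @param path file path.
#' @param meta named list written to the JSON sidecar (`write_decay` only).
#' @return `read_decay`: tibble with `time_ns`, `counts` and attribute
#'   `"meta"`; `write_decay`: the path, invisibly.
#' @export
read_decay <- function(path) {
  d <- utils::read.table(path, col.names = c("time_ns", "counts"))
  out <- tibble::as_tibble(d)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    attr(out, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  out
}

#' @rdname read_decay
#' @param curve tibble with `time_ns`, `counts`.
#' @export
write_decay <- function(curve, path, meta = NULL) {
  utils::write.table(curve[, c("time_ns", "counts")], path,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Poisson-sample a synthetic TCSPC decay histogram
#'
#' Builds the expected-counts curve of a [distance_model()] (donor decay
#' convolved with the IRF, plus scatter and flat background), scales it to
#' `total_counts`, and draws the channel counts. Multinomial sampling
#' conserves the total exactly; Poisson sampling reproduces independent
#' channel noise.
#'
#' @param model a [distance_model()]; ground truth stored in the result.
#' @param irf tibble `time_ns`, `counts`; the instrument response.
#' @param total_counts expected (Poisson) or exact (multinomial) total.
#' @param scatter_fraction fraction of counts from scattered excitation
#'   light, following the IRF shape.
#' @param background_fraction fraction of counts in a flat background.
#' @param sampling `"poisson"` or `"multinomial"`.
#' @param seed integer RNG seed.
#' @return tibble `time_ns`, `counts` with attributes `"truth"` (the model)
#'   and `"expected"` (expected counts).
#' @export
simulate_decay_histogram <- function(model, irf, total_counts,
                                     scatter_fraction = 0,
                                     background_fraction = 0,
                                     sampling = c("poisson", "multinomial"),
                                     seed = NULL) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(model, "distance_model"), total_counts >= 1)
  irf <- tibble::as_tibble(irf)
  if (sum(irf$counts) <= 0) stop("IRF has zero mass")
  t <- irf$time_ns
  f <- decay_intensity(model, t)
  conv <- circular_convolve(irf$counts / sum(irf$counts), f)
  conv <- conv / sum(conv)
  p <- (1 - scatter_fraction - background_fraction) * conv +
    scatter_fraction * irf$counts / sum(irf$counts) +
    background_fraction / length(t)
  expected <- total_counts * p
  if (!is.null(seed)) set.seed(seed)
  counts <- if (sampling == "poisson") {
    stats::rpois(length(p), expected)
  } else {
    drop(stats::rmultinom(1, size = round(total_counts), prob = p))
  }
  out <- tibble::tibble(time_ns = t, counts = as.numeric(counts))
  attr(out, "truth") <- model
  attr(out, "expected") <- expected
  out
}

# periodic (circular) convolution matching pulsed excitation: the tail of the
# previous excitation period folds into the observation window
circular_convolve <- function(kernel, signal) {
  n <- length(signal)
  stopifnot(length(kernel) == n)
  Re(stats::fft(stats::fft(kernel) * stats::fft(signal), inverse = TRUE)) / n
}

# shift a curve by a (possibly fractional) number of channels, periodically
shift_channels <- function(x, shift) {
  if (shift == 0) return(x)
  n <- length(x)
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  Re(stats::fft(stats::fft(x) * exp(-2i * pi * k * shift / n), inverse = TRUE)) / n
}

#' Synthetic Gaussian instrument response function
#'
#' @param n_channels number of TCSPC channels.
#' @param period_ns excitation repetition period (ns).
#' @param center_ns,width_ns IRF peak position and standard deviation (ns).
#' @param counts total counts in the curve.
#' @return tibble `time_ns`, `counts`.
#' @export
gaussian_irf <- function(n_channels = 1024L, period_ns = 32,
                         center_ns = 2, width_ns = 0.25, counts = 1e6) {
  dt <- period_ns / n_channels
  t <- (seq_len(n_channels) - 0.5) * dt
  d <- stats::dnorm(t, center_ns, width_ns)
  tibble::tibble(time_ns = t, counts = counts * d / sum(d))
}
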