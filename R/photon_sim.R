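#' Configure a single-molecule FRET simulation
#'
#' Describes the study conditions of a confocal diffusion experiment:
#' molecules diffusing freely through a 3D-Gaussian detection volume inside a
#' periodic box much larger than the focus (an "open" volume at constant
#' concentration), switching conformational state as a continuous-time Markov
#' process, and emitting photons whose colour and micro-time reflect the
#' state's FRET efficiency.
#'
#' Defaults emulate a pulsed-excitation MFD experiment on a mid-size protein:
#' diffusion time `w_xy^2 / (4 D)` of 0.54 ms, 3D-Gaussian radii 0.5/2.0 um,
#' 4096 TCSPC channels over a 32 ns repetition period, 4 ns donor lifetime,
#' 1.7 ns acceptor lifetime and a 0.25 ns-wide Gaussian IRF.
#'
#' @param states tibble with columns `efficiency` (FRET efficiency in [0,1])
#'   and `brightness_kHz` (total detected count rate at the focus centre).
#' @param duration_s simulated measurement time (s).
#' @param n_molecules molecules kept in the box (constant number).
#' @param box_half_um half-lengths of the periodic box (um, length 3);
#'   default at least 10x the focal radii.
#' @param w_xy_um,w_z_um lateral/axial 1/e^2 radii of the detection profile.
#' @param diff_um2_ms diffusion coefficient (um^2/ms).
#' @param donor_lifetimes donor-only lifetime spectrum (`amplitude`,`tau_ns`).
#' @param tau_acceptor_ns acceptor fluorescence lifetime.
#' @param crosstalk donor signal fraction leaking into the red channel.
#' @param direct_excitation acceptor count rate at focus relative to state
#'   brightness (directly excited acceptor).
#' @param background_kHz length-2 green/red background rates.
#' @param donly_fraction fraction of molecules carrying no acceptor.
#' @param sync_period_ns excitation repetition period.
#' @param n_microchannels TCSPC channels over one period.
#' @param irf_mean_ns,irf_sigma_ns Gaussian IRF position and width.
#' @param dt_ms diffusion time step; default satisfies
#'   `sqrt(2 D dt) <= w_xy / 20`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(states,
                       duration_s = 10,
                       n_molecules = 25L,
                       box_half_um = NULL,
                       w_xy_um = 0.5, w_z_um = 2.0,
                       diff_um2_ms = 0.116,
                       donor_lifetimes = tibble::tibble(amplitude = 1, tau_ns = 4),
                       tau_acceptor_ns = 1.7,
                       crosstalk = 0, direct_excitation = 0,
                       background_kHz = c(0, 0),
                       donly_fraction = 0,
                       sync_period_ns = 32, n_microchannels = 4096L,
                       irf_mean_ns = 2, irf_sigma_ns = 0.25,
                       dt_ms = NULL) {
  states <- tibble::as_tibble(states)
  stopifnot(all(c("efficiency", "brightness_kHz") %in% names(states)))
  if (any(states$efficiency < 0 | states$efficiency > 1)) {
    stop("state FRET efficiencies must lie in [0, 1]")
  }
  if (any(states$brightness_kHz < 0)) stop("brightness must be >= 0")
  if (w_xy_um <= 0 || w_z_um <= 0) stop("detection radii must be > 0")
  if (sync_period_ns <= 0) stop("repetition period must be > 0")
  if (donly_fraction < 0 || donly_fraction > 1) stop("donly_fraction in [0,1]")
  if (is.null(box_half_um)) box_half_um <- c(5 * w_xy_um, 5 * w_xy_um, 5 * w_z_um)
  if (is.null(dt_ms)) dt_ms <- (w_xy_um / 20)^2 / (2 * max(diff_um2_ms, 1e-12))
  dt_ms <- min(dt_ms, 0.05)
  donor_lifetimes <- tibble::as_tibble(donor_lifetimes)
  # the repetition period must cover essentially all emission
  span <- irf_mean_ns + 3 * irf_sigma_ns +
    log(1000) * max(donor_lifetimes$tau_ns, tau_acceptor_ns)
  if (sync_period_ns < span) {
    warning("repetition period shorter than the 99.9% emission span; ",
            "micro-times will wrap")
  }
  structure(
    list(states = states, duration_s = duration_s,
         n_molecules = as.integer(n_molecules), box_half_um = box_half_um,
         w_xy_um = w_xy_um, w_z_um = w_z_um, diff_um2_ms = diff_um2_ms,
         donor_lifetimes = donor_lifetimes, tau_acceptor_ns = tau_acceptor_ns,
         crosstalk = crosstalk, direct_excitation = direct_excitation,
         background_kHz = background_kHz, donly_fraction = donly_fraction,
         sync_period_ns = sync_period_ns,
         n_microchannels = as.integer(n_microchannels),
         irf_mean_ns = irf_mean_ns, irf_sigma_ns = irf_sigma_ns,
         dt_ms = dt_ms),
    class = "sim_config")
}

#' Simulate a state trajectory of a kinetic network
#'
#' Gillespie simulation: the dwell time in state i is exponential with mean
#' 1/k_i, where k_i is the total exit rate of state i, and the successor is
#' drawn proportionally to the outgoing rate constants. An absorbing state
#' ends the trajectory (its final dwell extends to the end of `duration_s`).
#'
#' @param network a [rate_network()].
#' @param duration_s trajectory length in seconds.
#' @param seed integer seed.
#' @return tibble with `state`, `entry_ms`, `dwell_ms`.
#' @export
simulate_state_trajectory <- function(network, duration_s, seed = NULL) {
  stopifnot(inherits(network, "rate_network"), duration_s > 0)
  if (!is.null(seed)) set.seed(seed)
  dur_ms <- duration_s * 1e3
  K <- network$K
  states <- network$states
  exit <- -diag(K)
  sp <- tryCatch(relaxation_spectrum(network)$fractions,
                 error = function(e) NULL)
  s <- if (is.null(sp)) 1L else sample.int(length(states), 1, prob = sp)
  t <- 0
  cap <- 1024L; n_seg <- 0L
  out_state <- integer(cap); out_entry <- numeric(cap); out_dwell <- numeric(cap)
  push <- function(st, en, dw) {
    if (n_seg == cap) {
      cap <<- cap * 2L
      length(out_state) <<- cap; length(out_entry) <<- cap
      length(out_dwell) <<- cap
    }
    n_seg <<- n_seg + 1L
    out_state[n_seg] <<- st; out_entry[n_seg] <<- en; out_dwell[n_seg] <<- dw
  }
  repeat {
    if (exit[s] <= 0) {  # absorbing state: dwell extends to the end
      push(s, t, dur_ms - t)
      break
    }
    dwell <- stats::rexp(1, exit[s])
    if (t + dwell >= dur_ms) {
      push(s, t, dur_ms - t)
      break
    }
    push(s, t, dwell)
    t <- t + dwell
    rates_out <- K[, s]; rates_out[s] <- 0
    s <- sample.int(length(states), 1, prob = rates_out)
  }
  idx <- seq_len(n_seg)
  tibble::tibble(state = states[out_state[idx]], entry_ms = out_entry[idx],
                 dwell_ms = out_dwell[idx])
}

# per-state detection-channel rates (kHz at focus centre):
# green, red via FRET, red via crosstalk, red via direct excitation
state_channel_rates <- function(states, crosstalk, direct_excitation) {
  Q <- states$brightness_kHz
  E <- states$efficiency
  cbind(green = Q * (1 - E) * (1 - crosstalk),
        red_fret = Q * E,
        red_ct = Q * (1 - E) * crosstalk,
        red_dir = Q * direct_excitation)
}

#' Simulate a time-tagged photon stream
#'
#' Runs the Brownian-dynamics simulation defined by a [sim_config()] and an
#' optional [rate_network()] describing conformational exchange (states of
#' the network map onto rows of `config$states` in order). Every detected
#' photon carries a macro-time (sync ticks), a TCSPC micro-time channel and a
#' detector id (0 green, 1 red). Identical seeds reproduce identical streams.
#'
#' @param config a [sim_config()].
#' @param network optional [rate_network()]; omit for static molecules (each
#'   molecule stays in state 1, or in its assigned initial state).
#' @param seed integer master seed; per-molecule child seeds are derived
#'   deterministically.
#' @param init_positions optional matrix (n_molecules x 3, um) clamping the
#'   starting positions (useful with `diff_um2_ms = 0`).
#' @param init_states optional integer vector of initial states per molecule.
#' @return `photon_stream` tibble with columns `macrotime` (ticks),
#'   `microtime_channel`, `detector`; metadata in attributes
#'   (`sync_period_ns`, `micro_channel_width_ns`, `duration_s`).
#' @export
simulate_photon_stream <- function(config, network = NULL, seed = 1L,
                                   init_positions = NULL, init_states = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_states <- nrow(config$states)
  K <- matrix(0, n_states, n_states)
  Pstep <- diag(n_states)
  if (!is.null(network)) {
    stopifnot(inherits(network, "rate_network"))
    if (length(network$states) != n_states) {
      stop("network states must match config$states rows")
    }
    G <- t(network$K)        # generator, row = from
    # exact state propagation over one diffusion step
    Pstep <- as.matrix(Matrix::expm(G * config$dt_ms))
    Pstep[Pstep < 0] <- 0
    Pstep <- Pstep / rowSums(Pstep)
    K <- G
    diag(K) <- 0
  }
  tau_D0 <- with(config$donor_lifetimes, sum(amplitude * tau_ns) / sum(amplitude))
  E <- pmin(config$states$efficiency, 0.999)
  kfret <- (1 / tau_D0) * E / (1 - E)      # 1/ns
  rates <- state_channel_rates(config$states, config$crosstalk,
                               config$direct_excitation)
  dur_ms <- config$duration_s * 1e3

  if (is.null(init_states)) {
    if (!is.null(network)) {
      frac <- relaxation_spectrum(network)$fractions
      set.seed(seed)
      init_states <- sample.int(n_states, config$n_molecules,
                                replace = TRUE, prob = frac)
    } else {
      init_states <- rep(1L, config$n_molecules)
    }
  }
  n_donly <- round(config$donly_fraction * config$n_molecules)

  run <- function(n_mol, Kmat, rt, kf, mol_offset, states0, pos,
                  Ptrans = diag(nrow(Kmat))) {
    if (n_mol == 0) return(NULL)
    cpp_simulate_photons(
      n_mol = n_mol, box_half = config$box_half_um,
      w_xy = config$w_xy_um, w_z = config$w_z_um,
      diff_coef = config$diff_um2_ms, dt = config$dt_ms, duration = dur_ms,
      K = Kmat, trans_prob = Ptrans, chan_rates = rt, state_kfret = kf,
      donor_amp = config$donor_lifetimes$amplitude,
      donor_tau = config$donor_lifetimes$tau_ns,
      tau_acceptor = config$tau_acceptor_ns,
      irf_mean = config$irf_mean_ns, irf_sigma = config$irf_sigma_ns,
      init_state = as.integer(states0) - 1L,
      init_pos = if (is.null(pos)) matrix(0, 1, 3) else pos,
      use_init_pos = !is.null(pos),
      intensity_cutoff = 1e-5,
      seed = as.double(seed) + mol_offset)
  }

  n_fret <- config$n_molecules - n_donly
  ph <- run(n_fret, K, rates, kfret, 0,
            init_states[seq_len(n_fret)],
            if (!is.null(init_positions)) init_positions[seq_len(n_fret), , drop = FALSE] else NULL,
            Ptrans = Pstep)
  ph0 <- NULL
  if (n_donly > 0) {
    # donor-only molecules: one state, E = 0, mean FRET-species brightness
    Q0 <- mean(config$states$brightness_kHz)
    rt0 <- state_channel_rates(
      tibble::tibble(efficiency = 0, brightness_kHz = Q0),
      config$crosstalk, config$direct_excitation)
    ph0 <- run(n_donly, matrix(0, 1, 1), rt0, 0, 1e6, rep(1L, n_donly), NULL)
  }
  time_ms <- c(ph$time_ms, ph0$time_ms)
  det <- c(ph$detector, ph0$detector)
  mic <- c(ph$micro_ns, ph0$micro_ns)

  # background: homogeneous Poisson per channel, flat micro-time
  set.seed(seed + 7L)
  for (ch in 1:2) {
    rate <- config$background_kHz[ch]
    if (rate > 0) {
      nb <- stats::rpois(1, rate * dur_ms)
      time_ms <- c(time_ms, stats::runif(nb, 0, dur_ms))
      det <- c(det, rep(ch - 1L, nb))
      mic <- c(mic, stats::runif(nb, 0, config$sync_period_ns))
    }
  }

  ord <- order(time_ms)
  time_ms <- time_ms[ord]; det <- det[ord]; mic <- mic[ord]
  sync_ns <- config$sync_period_ns
  mic <- mic %% sync_ns
  chan_w <- sync_ns / config$n_microchannels
  out <- tibble::tibble(
    macrotime = floor(time_ms * 1e6 / sync_ns),
    microtime_channel = pmin(as.integer(floor(mic / chan_w)),
                             config$n_microchannels - 1L),
    detector = as.integer(det))
  class(out) <- c("photon_stream", class(out))
  attr(out, "sync_period_ns") <- sync_ns
  attr(out, "micro_channel_width_ns") <- chan_w
  attr(out, "duration_s") <- config$duration_s
  attr(out, "n_detectors") <- 2L
  out
}

#' Read / write photon streams as portable CSV
#'
#' Columns `macrotime_ticks`, `microtime_channel`, `detector`; stream
#' metadata (sync period in seconds, micro-channel width in ns, duration) in
#' a JSON sidecar `path.json`.
#'
#' @param stream a `photon_stream` tibble.
#' @param path file path (`.csv`).
#' @return `read_photon_csv`: the stream; `write_photon_csv`: the path.
#' @export
write_photon_csv <- function(stream, path) {
  utils::write.csv(
    data.frame(macrotime_ticks = stream$macrotime,
               microtime_channel = stream$microtime_channel,
               detector = stream$detector),
    path, row.names = FALSE)
  meta <- list(sync_period_s = attr(stream, "sync_period_ns") * 1e-9,
               micro_channel_width_ns = attr(stream, "micro_channel_width_ns"),
               duration_s = attr(stream, "duration_s"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_photon_csv
#' @export
read_photon_csv <- function(path) {
  d <- utils::read.csv(path)
  out <- tibble::tibble(macrotime = d$macrotime_ticks,
                        microtime_channel = as.integer(d$microtime_channel),
                        detector = as.integer(d$detector))
  class(out) <- c("photon_stream", class(out))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "sync_period_ns") <- meta$sync_period_s * 1e9
    attr(out, "micro_channel_width_ns") <- meta$micro_channel_width_ns
    attr(out, "duration_s") <- meta$duration_s
  }
  out
}

# absolute photon times in ms from macro ticks
photon_times_ms <- function(stream) {
  stream$macrotime * attr(stream, "sync_period_ns") * 1e-6
}
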