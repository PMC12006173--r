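## Synthetic two-epoch presynaptic drive: a deterministic AP grid, stochastic
## vesicle release with facilitation and docked-site depletion, and a reduced
## coincidence-gated NMDAR Ca2+ influx schedule. This replaces the upstream
## spatial glutamate-diffusion / membrane-voltage machinery with its two
## load-bearing features: which APs release, and whether a bAP follows in
## time to relieve the Mg2+ block.

#' Build the deterministic action-potential train
#'
#' Nested grid: `epochs` epochs, each of `bursts_per_epoch` bursts at
#' `burst_rate_hz`, each burst `aps_per_burst` APs at `ap_rate_hz`. Epoch 1
#' starts at `t_start`; epoch 2 at `epoch2_onset`. Defaults give the
#' two-epoch, 50-AP train (epoch-1 APs at 1.0 + 0.2 b + 0.02 a s).
#'
#' @param epochs,bursts_per_epoch,aps_per_burst counts (>= 0)
#' @param burst_rate_hz,ap_rate_hz rates, Hz (> 0)
#' @param t_start epoch-1 onset, s
#' @param epoch2_onset epoch-2 onset, s
#' @return numeric vector of class `ap_train`, strictly increasing AP times
#' @export
build_ap_train <- function(epochs = 2, bursts_per_epoch = 5,
                           aps_per_burst = 5, burst_rate_hz = 5,
                           ap_rate_hz = 50, t_start = 1, epoch2_onset = 5) {
  stopifnot(epochs >= 0, bursts_per_epoch >= 0, aps_per_burst >= 0,
            burst_rate_hz > 0, ap_rate_hz > 0)
  if (epochs == 0 || bursts_per_epoch == 0 || aps_per_burst == 0)
    return(structure(numeric(0), class = "ap_train"))
  epoch_times <- function(t0)
    t0 + rep((seq_len(bursts_per_epoch) - 1) / burst_rate_hz,
             each = aps_per_burst) +
      rep((seq_len(aps_per_burst) - 1) / ap_rate_hz,
          times = bursts_per_epoch)
  onsets <- c(t_start, epoch2_onset)[seq_len(min(epochs, 2))]
  if (epochs > 2)
    onsets <- c(onsets, epoch2_onset +
                  (epoch2_onset - t_start) * seq_len(epochs - 2))
  times <- unlist(lapply(onsets, epoch_times))
  if (is.unsorted(times, strictly = TRUE))
    stop("overlapping epochs: AP times are not strictly increasing")
  structure(times, class = "ap_train")
}

#' Simulate stochastic vesicle release over an AP train
#'
#' Each of `n_sites` docked sites releases independently at each AP with
#' per-site probability p_site = 1 - (1 - p_init)^(1/n_sites) (so the chance
#' of at least one release at a naive AP is `p_init`), scaled by a
#' facilitation factor that is incremented by `fac_step` after every AP and
#' relaxes to 1 with time constant `fac_tau`. A released site is empty until
#' it redocks (exponential, `redock_rate`), producing depression under
#' sustained drive.
#'
#' @param ap_train from [build_ap_train()]
#' @param n_sites docked sites (default 7)
#' @param p_init initial release probability in [0, 1]
#' @param redock_rate per-site redocking rate, s^-1
#' @param fac_step,fac_tau facilitation stand-in; `fac_step = 0` disables it
#' @param seed integer RNG seed (fully reproducible)
#' @return list of class `release_schedule`: `releases` tibble
#'   (`time`, `site`), `ap_train`, and the per-AP docked counts `n_docked`
#' @export
simulate_release <- function(ap_train, n_sites = 7, p_init = 0.2,
                             redock_rate = 0.2, fac_step = 0.35,
                             fac_tau = 0.12, seed = 1) {
  if (p_init < 0 || p_init > 1) stop("p_init must lie in [0, 1]")
  stopifnot(n_sites >= 1, redock_rate >= 0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  p_site <- 1 - (1 - p_init)^(1 / n_sites)
  docked <- rep(TRUE, n_sites)
  redock_at <- rep(Inf, n_sites)
  fac <- 1
  t_prev <- if (length(ap_train)) ap_train[1] else 0
  rel_t <- numeric(0); rel_s <- integer(0); n_docked <- integer(0)
  for (t in as.numeric(ap_train)) {
    newly <- which(!docked & redock_at <= t)
    docked[newly] <- TRUE; redock_at[newly] <- Inf
    fac <- 1 + (fac - 1) * exp(-(t - t_prev) / fac_tau)
    n_docked <- c(n_docked, sum(docked))
    pr <- min(1, p_site * fac)
    for (s in which(docked)) {
      if (stats::runif(1) < pr) {
        rel_t <- c(rel_t, t); rel_s <- c(rel_s, s)
        docked[s] <- FALSE
        if (redock_rate > 0)
          redock_at[s] <- t + stats::rexp(1, rate = redock_rate)
      }
    }
    if (fac_step > 0) fac <- fac + fac_step
    t_prev <- t
  }
  structure(list(
    releases = tibble::tibble(time = rel_t, site = rel_s),
    ap_train = as.numeric(ap_train),
    n_docked = n_docked,
    seed = as.integer(seed)
  ), class = "release_schedule")
}

#' Schedule Ca2+ influx events from releases and bAP coincidence
#'
#' For each glutamate release, the `n_nmdar` receptors become bound; if a
#' back-propagating AP (each AP time + `bap_delay`) falls within `window`
#' after the release, each bound receptor opens independently with
#' probability `p_open` and contributes one influx event of
#' `n_ca_per_opening` ions at the bAP time with pulse decay `pulse_tau`.
#' A release with no bAP in the window contributes nothing (no Mg2+-block
#' relief). Optional per-receptor desensitization (`refractory`) suppresses
#' openings closer than that interval on the same receptor.
#'
#' @param releases a `release_schedule`
#' @param ap_train AP times (bAPs follow each by `bap_delay`)
#' @param bap_delay s
#' @param window coincidence window, s (> 0)
#' @param n_nmdar receptor count
#' @param p_open opening probability in [0, 1]
#' @param n_ca_per_opening ions per opening
#' @param pulse_tau influx pulse decay constant, s
#' @param refractory per-receptor dead time, s (0 = off)
#' @param seed integer RNG seed
#' @return tibble of class `ca_influx_schedule`: `time`, `n_ions`,
#'   `pulse_tau`
#' @export
schedule_ca_influx <- function(releases, ap_train, bap_delay = 0.01,
                               window = 0.02, n_nmdar = 15, p_open = 0.6,
                               n_ca_per_opening = 90, pulse_tau = 0.005,
                               refractory = 0, seed = 1) {
  if (window <= 0) stop("window must be > 0")
  if (p_open < 0 || p_open > 1) stop("p_open must lie in [0, 1]")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  rel_times <- if (inherits(releases, "release_schedule"))
    releases$releases$time else as.numeric(releases)
  bap_times <- as.numeric(ap_train) + bap_delay
  last_open <- rep(-Inf, n_nmdar)
  ev_t <- numeric(0); ev_n <- integer(0)
  for (tr in sort(rel_times)) {
    k <- which(bap_times >= tr & bap_times <= tr + window)
    if (!length(k)) next
    tb <- bap_times[k[1]]
    eligible <- which(tb - last_open >= refractory)
    opened <- eligible[stats::runif(length(eligible)) < p_open]
    if (length(opened)) {
      last_open[opened] <- tb
      ev_t <- c(ev_t, rep(tb, length(opened)))
      ev_n <- c(ev_n, rep(as.integer(n_ca_per_opening), length(opened)))
    }
  }
  out <- tibble::tibble(time = ev_t, n_ions = ev_n,
                        pulse_tau = rep(pulse_tau, length(ev_t)))
  class(out) <- c("ca_influx_schedule", class(out))
  out
}

#' Build the full default stimulus for one seed
#'
#' Convenience wrapper chaining [build_ap_train()], [simulate_release()] and
#' [schedule_ca_influx()] with the parameter-set values. Release and influx
#' randomness use seeds derived deterministically from `seed`.
#'
#' @param p `spinekin_params`
#' @param seed integer seed
#' @return list: `ap_train`, `releases`, `influx`
#' @export
build_stimulus <- function(p, seed = 1) {
  ap <- build_ap_train(p$epochs, p$bursts_per_epoch, p$aps_per_burst,
                       p$burst_rate_hz, p$ap_rate_hz, p$t_start,
                       p$epoch2_onset)
  rel <- simulate_release(ap, p$n_docked_init, p$p_release_init,
                          p$redock_rate, p$fac_step, p$fac_tau,
                          seed = seed)
  infl <- schedule_ca_influx(rel, ap, p$bap_delay, p$coincidence_window,
                             p$n_nmdar, p$p_open, p$n_ca_per_opening,
                             p$pulse_tau, p$nmdar_refractory,
                             seed = seed + 1000003L)
  list(ap_train = ap, releases = rel, influx = infl)
}

#' Tabulate a stimulus as a tidy event table
#'
#' @param stim result of [build_stimulus()]
#' @return tibble with columns `time_s`, `event_type`, `count`
#' @export
stimulus_table <- function(stim) {
  rbind(
    tibble::tibble(time_s = as.numeric(stim$ap_train), event_type = "ap",
                   count = 1L),
    tibble::tibble(time_s = stim$releases$releases$time,
                   event_type = "release", count = 1L),
    tibble::tibble(time_s = stim$influx$time, event_type = "ca_influx",
                   count = stim$influx$n_ions)
  )[order(c(as.numeric(stim$ap_train), stim$releases$releases$time,
            stim$influx$time)), ]
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
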