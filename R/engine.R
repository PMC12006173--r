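## R-side driver for the compiled stochastic engine.

#' Simulation run configuration
#'
#' @param seed integer RNG seed; every stochastic element of the run
#'   (stimulus expansion and chemistry) is reproducible from it.
#' @param t_end simulated time, s (default 11; use 21 for extended
#'   post-stimulus decay measurements)
#' @param record_dt observable recording interval, s
#' @param engine `"exact"` (Gillespie direct method) or `"hybrid"`
#'   (tau-leaped Ca2+/free-CaM/exchange pools, exact molecule events)
#' @param clamp_ca if not `NA`, free Ca2+ is clamped at this concentration
#'   (uM) and clearance/influx are disabled (equilibrium checks)
#' @param init_pT286_frac fraction of subunits initialized phosphorylated
#'   (substrate-clamp experiments; default 0)
#' @param init_cam_count initial free-CaM count override (`NA` = from
#'   `conc_CaM_total`); species split follows the baseline-Ca equilibrium
#' @param hybrid_n_target expected fast-channel events per leap
#' @param hybrid_dt_max,hybrid_dt_min leap bounds, s
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1, t_end = 11, record_dt = 0.01,
                       engine = c("exact", "hybrid"), clamp_ca = NA,
                       init_pT286_frac = 0, init_cam_count = NA,
                       hybrid_n_target = 25, hybrid_dt_max = 2e-3,
                       hybrid_dt_min = 2e-6) {
  engine <- match.arg(engine)
  stopifnot(t_end > 0, record_dt > 0, init_pT286_frac >= 0,
            init_pT286_frac <= 1)
  structure(list(seed = as.integer(seed), t_end = t_end,
                 record_dt = record_dt, engine = engine,
                 clamp_ca = clamp_ca, init_pT286_frac = init_pT286_frac,
                 init_cam_count = init_cam_count,
                 hybrid_n_target = hybrid_n_target,
                 hybrid_dt_max = hybrid_dt_max,
                 hybrid_dt_min = hybrid_dt_min),
            class = "sim_config")
}

## saturable-pump constants. Vmax is set so the pump linearizes to the
## near-baseline relaxation time tau_ca_clear; the constant influx is then
## solved so the stationary MEAN of the birth-death process equals the
## baseline count (a saturating death rate otherwise biases the mean upward).
.ca_vmax <- function(p, base_cnt) {
  K_cnt <- p$ca_clear_KM * p$V_spine * AVOGADRO * 1e-21
  (base_cnt + K_cnt)^2 / (p$tau_ca_clear * K_cnt)
}

.ca_birth_rate <- function(p, base_cnt, n_max = 400L) {
  K_cnt <- p$ca_clear_KM * p$V_spine * AVOGADRO * 1e-21
  vmax <- .ca_vmax(p, base_cnt)
  mu <- vmax * (1:n_max) / ((1:n_max) + K_cnt)
  mean_for <- function(lambda) {
    logp <- c(0, cumsum(log(lambda) - log(mu)))
    w <- exp(logp - max(logp))
    sum((0:n_max) * w) / sum(w)
  }
  lam0 <- vmax * base_cnt / (base_cnt + K_cnt)
  stats::uniroot(function(l) mean_for(l) - base_cnt,
                 lower = lam0 / 10, upper = lam0 * 2, tol = 1e-10)$root
}

## deterministic largest-remainder allocation of n across probabilities
.allocate_counts <- function(n, probs) {
  x <- n * probs / sum(probs)
  base <- floor(x)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(x - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

.build_model_list <- function(p, config, stimulus) {
  rates <- cam_rate_table(p)
  b_la <- rates$binding[rates$binding$mode == "la", ]
  b_ha <- rates$binding[rates$binding$mode == "ha", ]
  ord <- match(CAM_SPECIES_NAMES, b_la$species)
  ca <- rates$ca
  site_ord <- c("C1", "C2", "N1", "N2")
  ca_ctx <- function(ctx) {
    tab <- ca[ca$context == ctx, ]
    tab$koff[match(site_ord, tab$site)]
  }
  ca_kon_ctx <- function(ctx) {
    tab <- ca[ca$context == ctx, ]
    tab$kon[match(site_ord, tab$site)]
  }
  micro <- pp1_micro_rates(p)

  eq <- equilibrium_cam_distribution(p$ca_baseline, p)
  n_cam_cont <- p$conc_CaM_total * p$V_spine * AVOGADRO * 1e-21
  n_cam0 <- if (is.na(config$init_cam_count)) round(n_cam_cont) else
    as.integer(config$init_cam_count)
  cam_init <- .allocate_counts(n_cam0, eq)

  psd_mode <- match(p$psd_localization,
                    c("off", "camkii_only", "camkii_and_pp1")) - 1L
  n_holo_psd <- if (psd_mode > 0) as.integer(round(p$n_holoenzymes / 2)) else 0L
  pp1_total <- count_from_concentration(p$conc_PP1, p$V_spine)
  pp1_psd <- if (psd_mode == 2) as.integer(round(pp1_total / 2)) else 0L

  clamp_cnt <- if (is.na(config$clamp_ca)) -1 else
    round(config$clamp_ca * p$V_spine * AVOGADRO * 1e-21)
  base_cnt <- p$ca_baseline * p$V_spine * AVOGADRO * 1e-21

  if (is.null(stimulus)) {
    stim <- tibble::tibble(time = numeric(0), n_ions = integer(0),
                           pulse_tau = numeric(0))
  } else stim <- stimulus

  list(
    V_spine_L = p$V_spine * 1e-15,
    V_psd_L = p$V_psd * 1e-15,
    psd_mode = psd_mode,
    trapping = isTRUE(p$trapping),
    competition = isTRUE(p$competition),
    kon_bind = b_la$kon[ord],
    koff_la = b_la$koff[ord],
    koff_ha = b_ha$koff[match(CAM_SPECIES_NAMES, b_ha$species)],
    ca_kon_free = ca_kon_ctx("free"),
    ca_kon_la = ca_kon_ctx("camkii_la"),
    ca_kon_ha = ca_kon_ctx("camkii_ha"),
    ca_koff_free = ca_ctx("free"),
    ca_koff_la = ca_ctx("camkii_la"),
    ca_koff_ha = ca_ctx("camkii_ha"),
    k_pCaM4 = p$k_pCaM4,
    k_pCaMpartial = p$k_pCaMpartial,
    pp1_kon = micro$kon_pp1,
    pp1_koff = micro$koff_pp1,
    pp1_kcat = micro$kcat_pp1,
    ca_clear_vmax = .ca_vmax(p, base_cnt),
    ca_clear_K = p$ca_clear_KM * p$V_spine * AVOGADRO * 1e-21,
    ca_birth_rate = .ca_birth_rate(p, base_cnt),
    ca_baseline_count = base_cnt,
    k_cam_exchange = p$k_cam_exchange,
    nres = as.numeric(n_cam_cont * eq),
    clamp_ca_count = clamp_cnt,
    t_end = config$t_end,
    record_dt = config$record_dt,
    cam_init_counts = cam_init,
    ca_init_count = round(base_cnt),
    n_holo = as.integer(p$n_holoenzymes),
    n_holo_psd = n_holo_psd,
    init_pT286_frac = config$init_pT286_frac,
    pp1_total = as.numeric(pp1_total),
    pp1_psd = as.numeric(pp1_psd),
    stim_time = as.numeric(stim$time),
    stim_n = as.numeric(stim$n_ions),
    stim_tau = as.numeric(stim$pulse_tau),
    engine_mode = if (config$engine == "hybrid") 1L else 0L,
    hybrid_n_target = config$hybrid_n_target,
    hybrid_dt_max = config$hybrid_dt_max,
    hybrid_dt_min = config$hybrid_dt_min
  )
}

#' Run one stochastic trajectory
#'
#' Advances the coupled system (free Ca2+ pool, nine free-CaM species,
#' CaMKII holoenzymes, PP1) from rest through the supplied Ca2+ influx
#' schedule, recording time-binned observables. Trajectories are
#' bit-reproducible for a given seed, engine mode and configuration.
#'
#' @param p `spinekin_params`
#' @param config [sim_config()]
#' @param stimulus a `ca_influx_schedule` (or `NULL` for no stimulus)
#' @return tibble of observables per record bin: free Ca2+ count, free CaM
#'   counts per species, CaM species bound to phosphorylated
#'   (`pbound_*`) and unphosphorylated (`npbound_*`) subunits, `pT286`
#'   totals per compartment, bound PP1 per compartment, cumulative CaM
#'   exchange, total spine CaM, and trapped-site count.
#' @export
run_simulation <- function(p, config = sim_config(), stimulus = NULL) {
  stopifnot(inherits(p, "spinekin_params"), inherits(config, "sim_config"))
  model <- .build_model_list(p, config, stimulus)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  m <- .run_engine(model)
  out <- tibble::as_tibble(as.data.frame(m))
  attr(out, "config") <- config
  attr(out, "params") <- p
  out
}

#' Simulate one condition end-to-end for a single seed
#'
#' Builds the synthetic stimulus for the seed and runs the chemistry.
#'
#' @param p `spinekin_params`
#' @param seed integer seed (drives both stimulus and chemistry)
#' @param t_end simulated time, s
#' @param engine `"hybrid"` (default for production ensembles) or `"exact"`
#' @param ... further arguments to [sim_config()]
#' @return trajectory tibble (see [run_simulation()])
#' @export
simulate_condition <- function(p, seed = 1, t_end = 11,
                               engine = "hybrid", ...) {
  stim <- build_stimulus(p, seed = seed)
  cfg <- sim_config(seed = seed, t_end = t_end, engine = engine, ...)
  run_simulation(p, cfg, stim$influx)
}

#' Run an ensemble of seeds and summarize across them
#'
#' One trajectory per seed (each with its own stochastic stimulus), plus
#' per-bin mean, standard deviation and standard error for every observable.
#'
#' @param p `spinekin_params`
#' @param seeds integer vector of seeds (>= 2)
#' @param t_end simulated time, s
#' @param engine engine mode
#' @param keep_trajectories retain per-seed trajectories (default TRUE)
#' @param ... further [sim_config()] arguments
#' @return object of class `spinekin_ensemble`: `time`, matrices `mean`,
#'   `sd`, `sem` (bins x observables), `n_seeds`, and `trajectories`
#' @export
run_ensemble <- function(p, seeds = 1:10, t_end = 11, engine = "hybrid",
                         keep_trajectories = TRUE, ...) {
  if (length(seeds) < 2) stop("an ensemble needs at least 2 seeds")
  trajs <- lapply(seeds, function(s)
    simulate_condition(p, seed = s, t_end = t_end, engine = engine, ...))
  summarize_ensemble(trajs, seeds = seeds,
                     keep_trajectories = keep_trajectories)
}

#' Summarize a list of trajectories into an ensemble
#'
#' @param trajs list of trajectory tibbles on identical record grids
#' @param seeds optional seed labels
#' @param keep_trajectories retain the raw list
#' @return `spinekin_ensemble`
#' @export
summarize_ensemble <- function(trajs, seeds = seq_along(trajs),
                               keep_trajectories = TRUE) {
  times <- trajs[[1]]$time
  for (tr in trajs)
    if (!isTRUE(all.equal(tr$time, times)))
      stop("trajectories are on mismatched record grids")
  obs <- setdiff(names(trajs[[1]]), "time")
  n <- length(trajs)
  arr <- vapply(trajs, function(tr) as.matrix(tr[, obs]),
                matrix(0, length(times), length(obs)))
  mean_m <- apply(arr, c(1, 2), mean)
  sd_m <- apply(arr, c(1, 2), stats::sd)
  colnames(mean_m) <- colnames(sd_m) <- obs
  structure(list(time = times, mean = mean_m, sd = sd_m,
                 sem = sd_m / sqrt(n), n_seeds = n, seeds = seeds,
                 trajectories = if (keep_trajectories) trajs else NULL),
            class = "spinekin_ensemble")
}

#' @export
print.spinekin_ensemble <- function(x, ...) {
  cat(sprintf("<spinekin_ensemble> %d seeds, %d bins (t = %g..%g s)\n",
              x$n_seeds, length(x$time), min(x$time), max(x$time)))
  pk <- max(x$mean[, "pT286"])
  cat(sprintf("  peak mean pCaMKII: %.1f subunits\n", pk))
  invisible(x)
}

#' Extract the ensemble-mean trace of one observable
#'
#' @param ens `spinekin_ensemble`
#' @param observable column name (default total `pT286`)
#' @return tibble with `time`, `mean`, `sd`, `sem`
#' @export
ensemble_trace <- function(ens, observable = "pT286") {
  stopifnot(inherits(ens, "spinekin_ensemble"))
  if (!observable %in% colnames(ens$mean))
    stop("unknown observable: ", observable)
  tibble::tibble(time = ens$time, mean = ens$mean[, observable],
                 sd = ens$sd[, observable], sem = ens$sem[, observable])
}

#' Tidy long-format view of a trajectory
#'
#' @param traj trajectory tibble from [run_simulation()]
#' @return tibble with columns `time_s`, `observable`, `count`
#' @export
tidy_trajectory <- function(traj) {
  obs <- setdiff(names(traj), "time")
  tibble::tibble(
    time_s = rep(traj$time, times = length(obs)),
    observable = rep(obs, each = nrow(traj)),
    count = unlist(lapply(obs, function(o) traj[[o]]), use.names = FALSE)
  )
}
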