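## Post-processing: exponential decay constants, peaks, the ring-occupancy
## heuristic, and the PP1-sweep tau table.

#' Fit a single-exponential decay constant
#'
#' Fits y(t) = A exp(-(t - t1)/tau) (+ optional floor C) to a mean trace on
#' a window, or uses the two-point closed form
#' tau = (t2 - t1)/log(y1/y2).
#'
#' A non-decaying window (y2 >= y1 at the endpoints for `two_point`, or a
#' non-positive fitted tau) yields a fit-failure result (`ok = FALSE`,
#' `tau = NA`) rather than an error.
#'
#' @param time,value trace vectors (equal length)
#' @param window `c(t1, t2)` fit window, s
#' @param method `"least_squares"` (default) or `"two_point"`
#' @param floor allow an additive floor term in the least-squares fit
#'   (pCaMKII does not decay to zero between epochs in all conditions)
#' @return list of class `tau_fit`: `tau` (s), `amplitude`, `floor`,
#'   `window`, `method`, `rss`, `ok`
#' @examples
#' t <- seq(0, 10, 0.01)
#' fit_exponential_tau(t, 200 * exp(-t / 2), c(0, 5))$tau  # 2
#' @export
fit_exponential_tau <- function(time, value, window,
                                method = c("least_squares", "two_point"),
                                floor = TRUE) {
  method <- match.arg(method)
  stopifnot(length(time) == length(value), length(window) == 2,
            window[1] < window[2])
  if (window[1] < min(time) - 1e-9 || window[2] > max(time) + 1e-9)
    stop("fit window lies outside the trace span")
  fail <- structure(list(tau = NA_real_, amplitude = NA_real_,
                         floor = NA_real_, window = window, method = method,
                         rss = NA_real_, ok = FALSE), class = "tau_fit")
  if (method == "two_point") {
    y1 <- value[which.min(abs(time - window[1]))]
    y2 <- value[which.min(abs(time - window[2]))]
    if (!(y1 > y2 && y2 > 0)) return(fail)
    tau <- (window[2] - window[1]) / log(y1 / y2)
    return(structure(list(tau = tau, amplitude = y1, floor = 0,
                          window = window, method = method, rss = 0,
                          ok = TRUE), class = "tau_fit"))
  }
  sel <- time >= window[1] - 1e-9 & time <= window[2] + 1e-9
  tt <- time[sel] - window[1]
  yy <- value[sel]
  if (length(tt) < 10) stop("least-squares window needs >= 10 samples")
  ## non-decaying window: no positive drop from the first to the last quarter
  q1 <- stats::median(yy[tt <= diff(window) / 4])
  q4 <- stats::median(yy[tt >= 3 * diff(window) / 4])
  if (q1 <= 0 || q1 <= q4) return(fail)
  c0 <- if (floor) max(0, min(yy) - 0.05 * (max(yy) - min(yy))) else 0
  a0 <- max(yy[1] - c0, 1e-8)
  yref <- max(yy[length(yy)] - c0, a0 * 1e-3)
  tau0 <- if (a0 > yref) diff(window) / log(a0 / yref) else diff(window)
  ## parameterized in logs (A, tau > 0) with a non-negative floor
  obj <- function(par) {
    A <- exp(par[1]); tau <- exp(par[2])
    C <- if (floor) par[3]^2 else 0
    sum((yy - (A * exp(-tt / tau) + C))^2)
  }
  best <- NULL
  for (tau_try in unique(c(max(tau0, 1e-3), diff(window) / 2,
                           2 * diff(window), 10 * diff(window)))) {
    par0 <- c(log(a0), log(tau_try), if (floor) sqrt(c0))
    opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  opt <- best
  A <- exp(opt$par[1]); tau <- exp(opt$par[2])
  C <- if (floor) opt$par[3]^2 else 0
  if (!is.finite(tau) || tau <= 0 || A <= 0) return(fail)
  ## reject fits where the window contains no real decay signal
  if (A < 0.02 * max(abs(yy))) return(fail)
  structure(list(tau = tau, amplitude = A, floor = C, window = window,
                 method = method, rss = opt$value, ok = TRUE),
            class = "tau_fit")
}

#' @export
print.tau_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("<tau_fit> tau = %.4g s (A = %.3g, floor = %.3g, %s on [%g, %g] s)\n",
                x$tau, x$amplitude, x$floor, x$method, x$window[1],
                x$window[2]))
  else
    cat("<tau_fit> fit failed (non-decaying window)\n")
  invisible(x)
}

#' Locate the peak of a (smoothed) mean trace
#'
#' Boxcar-smooths the trace (default 50 ms window) and returns the argmax on
#' an interval. Ties report the earliest time.
#'
#' @param time,value trace vectors
#' @param interval `c(t1, t2)` search interval, s
#' @param smooth boxcar width, s (0 disables smoothing)
#' @return list: `t_peak`, `value` (smoothed peak height)
#' @export
find_peak <- function(time, value, interval = range(time), smooth = 0.05) {
  stopifnot(length(time) == length(value), length(interval) == 2)
  sel <- time >= interval[1] - 1e-9 & time <= interval[2] + 1e-9
  if (!any(sel)) stop("empty search interval")
  y <- value
  if (smooth > 0 && length(time) > 2) {
    dt <- stats::median(diff(time))
    k <- max(1L, round(smooth / dt))
    if (k > 1) {
      kern <- rep(1, k)
      num <- stats::filter(y, kern, sides = 2)
      den <- stats::filter(rep(1, length(y)), kern, sides = 2)
      sm <- as.numeric(num / den)
      y <- ifelse(is.na(sm), y, sm)
    }
  }
  ts <- time[sel]; ys <- y[sel]
  i <- which.max(ys)       # first maximum on ties
  list(t_peak = ts[i], value = ys[i])
}

#' Ring-occupancy heuristic for autophosphorylation opportunity
#'
#' Probability that a subunit with newly bound CaM sits immediately
#' clockwise of an active (phosphorylated) subunit in its six-membered ring,
#' given a mean of `m` phosphorylated subunits per ring: m/(6 - m), capped
#' at 1.
#'
#' @param m mean phosphorylated subunits per ring, in [0, 6)
#' @return probability
#' @examples
#' neighbor_probability(1.5)   # 1/3
#' neighbor_probability(0.75)  # ~0.143
#' @export
neighbor_probability <- function(m) {
  if (any(!is.finite(m)) || any(m < 0) || any(m >= 6))
    stop("m must lie in [0, 6)")
  pmin(1, m / (6 - m))
}

#' Tau table across PP1 concentrations and model variants
#'
#' Fits the post-epoch decay constants of ensemble-mean pCaMKII for each
#' supplied condition cell. Epoch-1 decays are fit on `epoch1_window`
#' (default 4-5 s); epoch-2 decays on `epoch2_window` (default 7.7-8.7 s),
#' except for the slow trapping-plus-competition condition which uses the
#' extended window (default 8.7-21 s) when the trace reaches it.
#'
#' @param cells list of cells, each a list with `pp1_uM`, `trapping`,
#'   `competition`, and `ensemble` (a `spinekin_ensemble`); absent/failed
#'   fits are reported as `NA`, never fabricated
#' @param observable trace column to fit (default total `pT286`)
#' @param epoch1_window,epoch2_window,epoch2_window_slow fit windows, s
#' @param method fit method passed to [fit_exponential_tau()]
#' @return tibble with columns `pp1_uM`, `trapping`, `competition`,
#'   `epoch`, `tau_s`, `fit_method`, `window_lo`, `window_hi`
#' @export
make_table1 <- function(cells, observable = "pT286",
                        epoch1_window = c(4, 5),
                        epoch2_window = c(7.7, 8.7),
                        epoch2_window_slow = c(8.7, 21),
                        method = "least_squares") {
  rows <- list()
  for (cell in cells) {
    stopifnot(!is.null(cell$pp1_uM))
    ens <- cell$ensemble
    for (epoch in 1:2) {
      win <- if (epoch == 1) epoch1_window else {
        slow <- isTRUE(cell$trapping) && isTRUE(cell$competition)
        if (slow && !is.null(ens) && max(ens$time) >= epoch2_window_slow[2])
          epoch2_window_slow else epoch2_window
      }
      tau <- NA_real_
      if (!is.null(ens) && max(ens$time) >= win[2]) {
        tr <- ensemble_trace(ens, observable)
        ft <- fit_exponential_tau(tr$time, tr$mean, win, method = method)
        if (ft$ok) tau <- ft$tau
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        pp1_uM = cell$pp1_uM,
        trapping = isTRUE(cell$trapping),
        competition = isTRUE(cell$competition),
        epoch = epoch, tau_s = tau, fit_method = method,
        window_lo = win[1], window_hi = win[2])
    }
  }
  do.call(rbind, rows)
}
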