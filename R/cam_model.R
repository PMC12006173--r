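## Nine-species calmodulin scheme: two sequential Ca2+ sites on each lobe
## (C-terminal sites C1, C2; N-terminal sites N1, N2), giving occupancy
## states (nC, nN) with nC, nN in 0..2. Species order is fixed package-wide.

CAM_SPECIES_NAMES <- c("CaM0", "CaM1C", "CaM2C", "CaM1N", "CaM1C1N",
                       "CaM2C1N", "CaM2N", "CaM1C2N", "CaM4")

#' Enumerate the nine calmodulin Ca2+-occupancy species
#'
#' @return tibble with columns `species`, `nC`, `nN`, `n_ca` in the canonical
#'   package order (index = nC + 3 nN + 1).
#' @export
cam_species <- function() {
  nN <- rep(0:2, each = 3)
  nC <- rep(0:2, times = 3)
  tibble::tibble(species = CAM_SPECIES_NAMES, nC = nC, nN = nN,
                 n_ca = nC + nN)
}

cam_species_index <- function(species) {
  i <- match(species, CAM_SPECIES_NAMES)
  if (any(is.na(i))) stop("unknown CaM species: ",
                          paste(species[is.na(i)], collapse = ", "))
  i
}

CAM_CONTEXTS <- c("free", "camkii_la", "camkii_ha")

#' Derive the full context-dependent rate table
#'
#' Expands the parameter anchors into every rate the simulator uses, in all
#' three binding contexts (free CaM; CaM on an unphosphorylated, low-affinity
#' "la" CaMKII site; CaM on a trapped, high-affinity "ha" site of a
#' pThr286 subunit).
#'
#' The construction has three ingredients, each enforcing detailed balance
#' (zero net free energy around every Ca2+-then-bind vs bind-then-Ca2+ cycle):
#' \itemize{
#'   \item a uniform per-site coupling factor
#'     \eqn{g = (K_D(CaM0,la)/K_D(CaM4,la))^{1/4}} by which CaMKII binding
#'     increases the Ca2+ affinity of every site in the la context
#'     (realized in the Ca2+ off-rates);
#'   \item a second factor \eqn{h} (`ha_ca_lock_factor`, default 1000) for
#'     the trapped (ha) context: the trapped conformation effectively locks
#'     the Ca2+ sites (off-rates reduced 1000-fold). Detailed balance then
#'     forces partially loaded species to dissociate from the trapped site
#'     faster the more Ca2+ they are missing, with apo-CaM released
#'     essentially instantly — trapping requires Ca2+. In this strongly
#'     coupled regime the escape rate of a trapped subunit at resting Ca2+
#'     is set by the thermodynamic cycle, not by `h` itself;
#'   \item geometric interpolation of the CaM-CaMKII association rate with
#'     the number of bound Ca2+ ions between the measured CaM0 and CaM4
#'     values, with species off-rates set by koff = kon * KD.
#' }
#'
#' @param p `spinekin_params`
#' @return list of class `cam_rate_table` with elements `binding`
#'   (species x mode kon/koff/KD) and `ca` (context x site kon/koff), plus
#'   the coupling factors `g` and `h` as attributes.
#' @export
cam_rate_table <- function(p) {
  stopifnot(inherits(p, "spinekin_params"))
  sp <- cam_species()

  KD0_la <- p$KD_CaM0_la * 1e-6           # M
  KD4_la <- p$KD_CaM4_la * 1e-6
  g <- (KD0_la / KD4_la)^(1 / 4)
  KD4_ha <- p$koff_CaM4_ha / p$kon_CaM4   # M
  h <- p$ha_ca_lock_factor

  rho <- (p$kon_CaM4 / p$kon_CaM0)^(1 / 4)
  kon_bind <- p$kon_CaM0 * rho^sp$n_ca
  KD_la <- KD0_la / g^sp$n_ca
  KD_ha <- KD4_ha * h^(4 - sp$n_ca)       # detailed balance from the anchors

  binding <- rbind(
    data.frame(species = sp$species, mode = "la", kon = kon_bind,
               KD = KD_la, koff = kon_bind * KD_la,
               stringsAsFactors = FALSE),
    data.frame(species = sp$species, mode = "ha", kon = kon_bind,
               KD = KD_ha, koff = kon_bind * KD_ha,
               stringsAsFactors = FALSE)
  )

  tab <- p$cam_ca_rate_table
  tab <- tab[match(c("C1", "C2", "N1", "N2"), tab$site), ]
  ca <- do.call(rbind, lapply(CAM_CONTEXTS, function(ctx) {
    fac <- switch(ctx, free = 1, camkii_la = g, camkii_ha = h)
    data.frame(context = ctx, site = tab$site, kon = tab$kon,
               koff = tab$koff_free / fac, stringsAsFactors = FALSE)
  }))

  out <- list(binding = binding, ca = ca)
  attr(out, "g") <- g
  attr(out, "h") <- h
  class(out) <- "cam_rate_table"
  out
}

## site used by a lobe transition: count 0->1 uses site 1, 1->2 site 2
.lobe_site <- function(lobe, from_count, up) {
  k <- if (up) from_count + 1 else from_count
  paste0(lobe, k)
}

#' Ca2+ transition propensity rates for one CaM molecule
#'
#' Returns the (up to four) legal one-ion moves on the (nC, nN) lattice for a
#' species in a given binding context, with association rates proportional to
#' the free Ca2+ concentration.
#'
#' @param species CaM species name (see [cam_species()])
#' @param context one of `"free"`, `"camkii_la"`, `"camkii_ha"`
#' @param ca_uM free Ca2+ concentration, uM (>= 0)
#' @param p `spinekin_params`
#' @param rates optional precomputed [cam_rate_table()]
#' @return tibble with columns `target`, `site`, `direction` (`on`/`off`) and
#'   `rate` (s^-1 per molecule)
#' @export
ca_transition_rates <- function(species, context, ca_uM, p,
                                rates = cam_rate_table(p)) {
  if (!context %in% CAM_CONTEXTS)
    stop("unknown binding context: ", context)
  if (!is.finite(ca_uM) || ca_uM < 0) stop("ca_uM must be >= 0")
  i <- cam_species_index(species)
  sp <- cam_species()
  nC <- sp$nC[i]; nN <- sp$nN[i]
  ca_M <- ca_uM * 1e-6
  ctab <- rates$ca[rates$ca$context == context, ]
  row <- function(lobe, from, up) {
    site <- .lobe_site(lobe, from, up)
    r <- ctab[ctab$site == site, ]
    if (nrow(r) != 1) stop("missing Ca rate entry for site ", site,
                           " in context ", context)
    dC <- if (lobe == "C") (if (up) 1 else -1) else 0
    dN <- if (lobe == "N") (if (up) 1 else -1) else 0
    tgt <- CAM_SPECIES_NAMES[(nC + dC) + 3 * (nN + dN) + 1]
    data.frame(target = tgt, site = site,
               direction = if (up) "on" else "off",
               rate = if (up) r$kon * ca_M else r$koff,
               stringsAsFactors = FALSE)
  }
  out <- list()
  if (nC < 2) out <- c(out, list(row("C", nC, TRUE)))
  if (nC > 0) out <- c(out, list(row("C", nC, FALSE)))
  if (nN < 2) out <- c(out, list(row("N", nN, TRUE)))
  if (nN > 0) out <- c(out, list(row("N", nN, FALSE)))
  tibble::as_tibble(do.call(rbind, out))
}

#' Trapped-state CaM off-rates for every species
#'
#' The measured anchor is the trapped CaM4 off-rate (9e-5 s^-1); every other
#' species' off-rate from the high-affinity site follows from zero net
#' free-energy change around the cycle (bind CaM then load Ca2+ on the
#' subunit) vs (load Ca2+ free then bind CaM4).
#'
#' @param p `spinekin_params`
#' @param rates optional precomputed [cam_rate_table()]
#' @return tibble with columns `species`, `koff_ha`, `KD_ha_M`
#' @export
derive_ha_offrates <- function(p, rates = cam_rate_table(p)) {
  b <- rates$binding[rates$binding$mode == "ha", ]
  if (nrow(b) != 9) stop("ha binding table incomplete")
  tibble::tibble(species = b$species, koff_ha = b$koff, KD_ha_M = b$KD)
}

#' Thermodynamic consistency report for the rate table
#'
#' For every square cycle (Ca2+ binding on CaMKII-bound CaM vs CaM unbinding,
#' Ca2+ binding on free CaM, rebinding) in both bound contexts, reports the
#' absolute log-ratio of clockwise to counter-clockwise equilibrium-constant
#' products. A residual above `tol` flags a detailed-balance violation.
#'
#' @param p `spinekin_params` (ignored when `rates` is supplied)
#' @param rates a [cam_rate_table()]; defaults to the table derived from `p`
#' @param tol flag threshold on |log K ratio|
#' @return tibble with one row per cycle: `mode`, `from`, `to`, `site`,
#'   `residual`, `flagged`
#' @export
validate_thermodynamics <- function(p = NULL, rates = NULL, tol = 1e-6) {
  if (is.null(rates)) {
    if (is.null(p)) stop("missing parameter set or rate table")
    rates <- cam_rate_table(p)
  }
  if (is.null(rates$binding) || is.null(rates$ca) ||
      nrow(rates$binding) == 0 || nrow(rates$ca) == 0)
    stop("missing rate table entries: need 'binding' and 'ca' tables")
  sp <- cam_species()
  need_sites <- c("C1", "C2", "N1", "N2")
  out <- list()
  for (mode in c("la", "ha")) {
    ctx <- paste0("camkii_", mode)
    b <- rates$binding[rates$binding$mode == mode, ]
    if (!setequal(b$species, CAM_SPECIES_NAMES))
      stop("missing binding entries for mode ", mode)
    ca_b <- rates$ca[rates$ca$context == ctx, ]
    ca_f <- rates$ca[rates$ca$context == "free", ]
    if (!all(need_sites %in% ca_b$site) || !all(need_sites %in% ca_f$site))
      stop("missing Ca rate entries for context ", ctx, " or free")
    KD <- function(s) b$KD[match(s, b$species)]
    for (k in seq_len(nrow(sp))) {
      for (lobe in c("C", "N")) {
        cnt <- if (lobe == "C") sp$nC[k] else sp$nN[k]
        if (cnt >= 2) next
        site <- .lobe_site(lobe, cnt, TRUE)
        dC <- if (lobe == "C") 1 else 0
        dN <- if (lobe == "N") 1 else 0
        to <- CAM_SPECIES_NAMES[(sp$nC[k] + dC) + 3 * (sp$nN[k] + dN) + 1]
        Kb <- ca_b[ca_b$site == site, ]
        Kf <- ca_f[ca_f$site == site, ]
        ## clockwise: Ca on bound CaM then CaM(to) unbinds;
        ## counter-clockwise: CaM(from) unbinds then Ca on free CaM
        resid <- abs(log((Kb$kon / Kb$koff) * KD(to)) -
                     log((Kf$kon / Kf$koff) * KD(sp$species[k])))
        out[[length(out) + 1]] <- data.frame(
          mode = mode, from = sp$species[k], to = to, site = site,
          residual = resid, flagged = resid > tol,
          stringsAsFactors = FALSE)
      }
    }
  }
  tibble::as_tibble(do.call(rbind, out))
}

#' Equilibrium distribution of the nine CaM species at clamped Ca2+
#'
#' Analytic solution of the detailed-balance stationary state of the 3x3
#' occupancy lattice at a fixed free Ca2+ concentration. The two lobes are
#' independent at equilibrium, so the joint distribution is the product of
#' two three-state lobe distributions.
#'
#' @param ca_uM clamped free Ca2+, uM (>= 0; may be `Inf`)
#' @param p `spinekin_params`
#' @param context binding context for the rate set (default free CaM)
#' @return named numeric vector of length 9 summing to 1
#' @export
equilibrium_cam_distribution <- function(ca_uM, p, context = "free") {
  if (!context %in% CAM_CONTEXTS) stop("unknown binding context: ", context)
  if (is.na(ca_uM) || ca_uM < 0) stop("ca_uM must be >= 0")
  rates <- cam_rate_table(p)
  ctab <- rates$ca[rates$ca$context == context, ]
  x <- ca_uM * 1e-6
  lobe_weights <- function(lobe) {
    K1 <- with(ctab[ctab$site == paste0(lobe, "1"), ], koff / kon)
    K2 <- with(ctab[ctab$site == paste0(lobe, "2"), ], koff / kon)
    if (is.infinite(x)) return(c(0, 0, 1))
    w <- c(1, x / K1, x^2 / (K1 * K2))
    w / sum(w)
  }
  wC <- lobe_weights("C")
  wN <- lobe_weights("N")
  sp <- cam_species()
  pr <- wC[sp$nC + 1] * wN[sp$nN + 1]
  stats::setNames(pr, sp$species)
}
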