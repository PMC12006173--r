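## Dodecameric CaMKII holoenzyme: two stacked rings of six subunits.
## Autophosphorylation is directional within a ring: the right-hand
## (clockwise) neighbor acts as the kinase, the left-hand subunit is the
## substrate. Positions are 0..5 within a ring; "right neighbor" of position
## i is (i + 1) mod 6. The orientation is an arbitrary but fixed convention.

#' Build an unactivated CaMKII holoenzyme
#'
#' Twelve subunits in two six-membered rings, no CaM bound, all CaM sites in
#' the low-affinity (la) state, Thr286 and Thr306 unphosphorylated, no PP1
#' bound.
#'
#' @param id holoenzyme identifier (integer)
#' @param compartment `"spine"` or `"psd"`
#' @return tibble of 12 subunit rows: `holo`, `ring` (1:2), `pos` (0:5),
#'   `cam_species` (NA = empty site), `mode` (`"la"`/`"ha"`), `pT286`,
#'   `pp1_bound`, `pT306`, `compartment`
#' @export
build_holoenzyme <- function(id = 1L, compartment = c("spine", "psd")) {
  compartment <- match.arg(compartment)
  tibble::tibble(
    holo = as.integer(id),
    ring = rep(1:2, each = 6L),
    pos = rep(0:5, times = 2L),
    cam_species = NA_character_,
    mode = "la",
    pT286 = FALSE,
    pp1_bound = FALSE,
    pT306 = FALSE,
    compartment = compartment
  )
}

#' Ring neighbor of a subunit position
#'
#' @param pos position 0..5 within a ring
#' @param side `"right"` (kinase side, clockwise) or `"left"`
#' @return neighboring position
#' @export
ring_neighbor <- function(pos, side = c("right", "left")) {
  side <- match.arg(side)
  if (any(pos < 0 | pos > 5 | pos != round(pos)))
    stop("pos must be an integer in 0..5")
  if (side == "right") (pos + 1L) %% 6L else (pos - 1L) %% 6L
}

.subunit_fields <- function(s) {
  stopifnot(is.list(s))
  need <- c("cam_species", "mode", "pT286")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("subunit state missing fields: ",
                         paste(miss, collapse = ", "))
  s
}

#' CaM binding / unbinding propensity at one subunit
#'
#' Association propensity for one CaM molecule species given the free count
#' in the shared spine pool; dissociation propensity for the currently bound
#' species given the site's affinity mode. Binding propensity is zero when
#' the site is occupied; unbinding propensity is zero when it is empty.
#'
#' @param subunit list with fields `cam_species`, `mode`, `pT286`
#' @param species CaM species name
#' @param free_count free molecules of `species` in the pool
#' @param volume_fL pool volume, fL
#' @param p `spinekin_params`
#' @param rates optional [cam_rate_table()]
#' @return list with `binding` and `unbinding` propensities (s^-1)
#' @export
cam_binding_propensity <- function(subunit, species, free_count, volume_fL,
                                   p, rates = cam_rate_table(p)) {
  s <- .subunit_fields(subunit)
  b <- rates$binding
  occupied <- !is.na(s$cam_species)
  bind <- if (occupied) 0 else {
    kon <- b$kon[b$species == species & b$mode == "la"][1]
    kon * free_count * .kon_count(1, volume_fL)
  }
  unbind <- if (!occupied) 0 else {
    if (s$cam_species != species) 0 else
      b$koff[b$species == species & b$mode == s$mode][1]
  }
  list(binding = bind, unbinding = unbind)
}

#' Autophosphorylation rate for an adjacent subunit pair
#'
#' The right-hand subunit is the kinase, the left-hand the substrate.
#' Returns 0 when the substrate is already phosphorylated, has no bound CaM,
#' or the kinase is inactive (no bound CaM and not pThr286). Returns
#' `k_pCaM4` when the substrate holds CaM4 and the kinase is active;
#' `k_pCaMpartial` for every other active permutation.
#'
#' @param left substrate subunit (list with `cam_species`, `pT286`)
#' @param right kinase-side subunit
#' @param p `spinekin_params`
#' @return rate, s^-1
#' @export
autophosphorylation_rate <- function(left, right, p) {
  l <- .subunit_fields(left); r <- .subunit_fields(right)
  if (!is.null(l$pos) && !is.null(r$pos)) {
    same_ring <- is.null(l$ring) || is.null(r$ring) || l$ring == r$ring
    if (!same_ring || ring_neighbor(l$pos, "right") != r$pos)
      stop("subunits are not ring-adjacent with `right` on the kinase side")
  }
  if (isTRUE(l$pT286)) return(0)
  if (is.na(l$cam_species)) return(0)
  right_active <- isTRUE(r$pT286) || !is.na(r$cam_species)
  if (!right_active) return(0)
  if (l$cam_species == "CaM4") p$k_pCaM4 else p$k_pCaMpartial
}

#' Apply a Thr286 autophosphorylation event to a holoenzyme
#'
#' Sets `pT286` on the target subunit. With trapping enabled: if CaM is
#' bound, a first-order la -> ha conversion is scheduled at the rate equal to
#' the la off-rate of the bound species; if the site is empty, it switches to
#' ha immediately (rebinding then occurs with trapped off-rates). With
#' trapping disabled the affinity mode never leaves la.
#'
#' @param holo tibble from [build_holoenzyme()]
#' @param subunit_index row index of the substrate subunit
#' @param trapping logical flag
#' @param p `spinekin_params`
#' @param rates optional [cam_rate_table()]
#' @return list: `holo` (updated tibble), `la_to_ha_rate` (s^-1; 0 when no
#'   conversion is scheduled)
#' @export
apply_phosphorylation <- function(holo, subunit_index, trapping, p,
                                  rates = cam_rate_table(p)) {
  i <- subunit_index
  sub <- as.list(holo[i, ])
  pos_r <- ring_neighbor(sub$pos, "right")
  right <- as.list(holo[holo$holo == sub$holo & holo$ring == sub$ring &
                          holo$pos == pos_r, ])
  if (autophosphorylation_rate(sub, right, p) <= 0)
    stop("autophosphorylation fired on an ineligible subunit")
  holo$pT286[i] <- TRUE
  rate <- 0
  if (isTRUE(trapping)) {
    if (is.na(sub$cam_species)) {
      holo$mode[i] <- "ha"
    } else {
      b <- rates$binding
      rate <- b$koff[b$species == sub$cam_species & b$mode == "la"]
    }
  }
  list(holo = holo, la_to_ha_rate = rate)
}
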