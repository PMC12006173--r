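## PP1 dephosphorylation of pThr286, modeled as explicit stochastic
## binding/catalysis whose ensemble behavior is Michaelis-Menten:
## E + S <-> ES (kon, koff), ES -> E + P (kcat), KM = (koff + kcat)/kon.

#' Split PP1 Michaelis-Menten constants into microscopic rates
#'
#' The literature gives only kcat and KM; the kon/koff split is a modeling
#' degree of freedom. The default policy sets koff = kcat (a bound complex is
#' equally likely to catalyze or dissociate); `"zero"` gives the
#' diffusion-limited kcat/KM bound; `"factor"` sets koff = factor * kcat.
#'
#' @param KM_uM Michaelis constant, uM (> 0)
#' @param kcat turnover, s^-1 (> 0)
#' @param koff_policy `"equal_kcat"`, `"zero"` or `"factor"`
#' @param koff_factor multiplier on kcat when policy is `"factor"`
#' @return list of class `pp1_micro_rates`: `kon_pp1` (M^-1 s^-1),
#'   `koff_pp1`, `kcat_pp1` (s^-1)
#' @examples
#' derive_pp1_micro_rates(11, 11.5)  # kon ~ 2.09e6 M^-1 s^-1
#' @export
derive_pp1_micro_rates <- function(KM_uM, kcat,
                                   koff_policy = c("equal_kcat", "zero",
                                                   "factor"),
                                   koff_factor = 1) {
  koff_policy <- match.arg(koff_policy)
  if (!is.finite(KM_uM) || KM_uM <= 0) stop("KM must be > 0")
  if (!is.finite(kcat) || kcat <= 0) stop("kcat must be > 0")
  koff <- switch(koff_policy,
                 equal_kcat = kcat,
                 zero = 0,
                 factor = koff_factor * kcat)
  if (koff < 0) stop("koff must be >= 0")
  out <- list(kon_pp1 = (koff + kcat) / (KM_uM * 1e-6),
              koff_pp1 = koff, kcat_pp1 = kcat)
  class(out) <- "pp1_micro_rates"
  out
}

pp1_micro_rates <- function(p) {
  derive_pp1_micro_rates(p$KM_pp1, p$kcat_pp1, p$pp1_koff_policy,
                         p$pp1_koff_factor)
}

#' PP1 binding propensity at one subunit
#'
#' Zero unless the subunit is pThr286 with a free pp1 site. With the
#' competition (CaM-block) rule enabled, additionally zero unless the CaM
#' site is empty: bound CaM sterically occludes the phosphatase.
#'
#' @param subunit list with fields `pT286`, `pp1_bound`, `cam_species`
#' @param pp1_free free PP1 count in the subunit's compartment
#' @param volume_fL compartment volume, fL
#' @param competition logical: CaM-block rule
#' @param p `spinekin_params`
#' @return propensity, s^-1
#' @export
pp1_binding_propensity <- function(subunit, pp1_free, volume_fL, competition,
                                   p) {
  s <- subunit
  if (!isTRUE(s$pT286) || isTRUE(s$pp1_bound)) return(0)
  if (isTRUE(competition) && !is.na(s$cam_species)) return(0)
  micro <- pp1_micro_rates(p)
  micro$kon_pp1 * pp1_free * .kon_count(1, volume_fL)
}

#' Outcome statistics of a bound PP1-pCaMKII complex
#'
#' A bound complex resolves by an exponential race between catalysis (kcat:
#' Thr286 dephosphorylated, PP1 released) and unbinding (koff: PP1 released,
#' state unchanged).
#'
#' @param p `spinekin_params`
#' @return list: `p_catalysis` = kcat/(kcat+koff), `mean_dwell` =
#'   1/(kcat+koff) s
#' @export
pp1_catalysis_outcome <- function(p) {
  m <- pp1_micro_rates(p)
  tot <- m$kcat_pp1 + m$koff_pp1
  list(p_catalysis = m$kcat_pp1 / tot, mean_dwell = 1 / tot)
}

#' Sample fates of bound PP1 complexes
#'
#' Monte-Carlo draws of (dwell time, catalyzed?) pairs for `n` independent
#' bound complexes; used to check the exponential-race statistics.
#'
#' @param n number of complexes
#' @param p `spinekin_params`
#' @return tibble with columns `dwell` (s) and `catalyzed` (logical)
#' @export
sample_pp1_complex_fates <- function(n, p) {
  m <- pp1_micro_rates(p)
  tot <- m$kcat_pp1 + m$koff_pp1
  tibble::tibble(
    dwell = stats::rexp(n, rate = tot),
    catalyzed = stats::runif(n) < m$kcat_pp1 / tot
  )
}
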