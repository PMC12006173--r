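#' Avogadro constant
#'
#' CODATA value, mol^-1. Exported because copy-number arithmetic in tiny
#' compartments is central to the package and users may want the exact
#' constant used internally.
#' @export
AVOGADRO <- 6.02214076e23

# molecules per (uM * fL): 1e-6 mol/L * 1e-15 L * N_A
.molec_per_uM_fL <- AVOGADRO * 1e-21

#' Convert a concentration to a molecule count
#'
#' Concentrations in the package are micromolar and volumes femtoliters,
#' the natural units for a ~0.016 fL spine head.
#'
#' @param conc_uM concentration, uM (>= 0)
#' @param volume_fL compartment volume, fL (> 0)
#' @param rounding `"nearest"` or `"floor"`
#' @return integer molecule count
#' @examples
#' count_from_concentration(1.25, 0.016)  # 12 PP1 molecules
#' count_from_concentration(30, 0.016)    # 289 CaM molecules
#' @export
count_from_concentration <- function(conc_uM, volume_fL,
                                     rounding = c("nearest", "floor")) {
  rounding <- match.arg(rounding)
  if (any(!is.finite(conc_uM)) || any(conc_uM < 0))
    stop("concentration must be finite and >= 0")
  if (any(!is.finite(volume_fL)) || any(volume_fL <= 0))
    stop("volume must be finite and > 0")
  x <- conc_uM * volume_fL * .molec_per_uM_fL
  n <- if (rounding == "nearest") round(x) else floor(x)
  as.integer(n)
}

#' Convert a molecule count to a concentration
#'
#' Exact inverse of [count_from_concentration()] before rounding.
#'
#' @param count molecule count (>= 0)
#' @param volume_fL compartment volume, fL (> 0)
#' @return concentration, uM
#' @export
concentration_from_count <- function(count, volume_fL) {
  if (any(!is.finite(count)) || any(count < 0))
    stop("count must be finite and >= 0")
  if (any(!is.finite(volume_fL)) || any(volume_fL <= 0))
    stop("volume must be finite and > 0")
  count / (volume_fL * .molec_per_uM_fL)
}

# pseudo-first-order propensity factor: kon [M^-1 s^-1] acting on counts in
# a volume [fL] -> per-pair rate [s^-1]
.kon_count <- function(kon_Msec, volume_fL) {
  kon_Msec / (AVOGADRO * volume_fL * 1e-15)
}
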