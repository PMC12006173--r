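# Shared oracles and fixtures, built in code.

# Brute-force cycle-product solver for trapped-state off-rates: walks an
# explicit lattice path from species X to CaM4, multiplying the equilibrium
# constants of (Ca step on bound CaM) / (Ca step on free CaM), and anchors at
# the trapped CaM4 dissociation constant. Independent of cam_rate_table's
# closed-form construction.
oracle_ha_offrates <- function(rates, mode_ctx = "camkii_ha") {
  sp <- cam_species()
  ca_b <- rates$ca[rates$ca$context == mode_ctx, ]
  ca_f <- rates$ca[rates$ca$context == "free", ]
  keq <- function(tab, site) {
    r <- tab[tab$site == site, ]
    r$kon / r$koff   # association constant, 1/M
  }
  b <- rates$binding[rates$binding$mode == if (mode_ctx == "camkii_ha")
    "ha" else "la", ]
  KD4 <- b$KD[b$species == "CaM4"]
  kon <- rates$binding[rates$binding$mode == "la", ]
  out <- numeric(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    # path: load C sites nC+1..2, then N sites nN+1..2
    ratio <- 1
    for (k in (sp$nC[i] + 1):2) {
      if (sp$nC[i] >= 2) break
      site <- paste0("C", k)
      ratio <- ratio * keq(ca_b, site) / keq(ca_f, site)
    }
    for (k in (sp$nN[i] + 1):2) {
      if (sp$nN[i] >= 2) break
      site <- paste0("N", k)
      ratio <- ratio * keq(ca_b, site) / keq(ca_f, site)
    }
    KD_X <- KD4 * ratio    # weaker binding when trapped Ca gain is forfeited
    out[i] <- kon$kon[kon$species == sp$species[i]] * KD_X
  }
  stats::setNames(out, sp$species)
}

# quick param builders
params_default <- function(...) spinekin_params(...)

# small reduced system for engine cross-checks (6 holoenzymes, ~29 CaM, 2 PP1)
params_reduced <- function(...) {
  spinekin_params(n_holoenzymes = 6L, conc_CaM_total = 3,
                  conc_PP1 = 0.21, ...)
}

# standard-error from block means of a (possibly autocorrelated) trace
block_se <- function(x, nblocks = 10) {
  n <- length(x)
  bs <- floor(n / nblocks)
  m <- vapply(seq_len(nblocks),
              function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  stats::sd(m) / sqrt(nblocks)
}
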