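test_that("a fresh holoenzyme is two unphosphorylated six-rings", {
  h <- build_holoenzyme(3, "psd")
  expect_equal(nrow(h), 12)
  expect_equal(as.integer(table(h$ring)), c(6L, 6L))
  expect_setequal(h$pos[h$ring == 1], 0:5)
  expect_true(all(is.na(h$cam_species)))
  expect_true(all(h$mode == "la"))
  expect_true(all(!h$pT286 & !h$pp1_bound & !h$pT306))
  expect_equal(sum(h$pT286), 0)
  expect_true(all(h$compartment == "psd"))
})

test_that("ring neighbors form inverse six-cycles", {
  for (pos in 0:5) {
    expect_equal(ring_neighbor(ring_neighbor(pos, "right"), "left"), pos)
    expect_equal(ring_neighbor(ring_neighbor(pos, "left"), "right"), pos)
  }
  expect_error(ring_neighbor(6), "0..5")
})

sub <- function(cam = NA_character_, mode = "la", pT = FALSE, pos = NULL,
                ring = 1L) {
  s <- list(cam_species = cam, mode = mode, pT286 = pT)
  if (!is.null(pos)) { s$pos <- pos; s$ring <- ring }
  s
}

test_that("autophosphorylation follows the two-rate permutation rule", {
  p <- spinekin_params()
  # both neighbors CaM4-bound: fast rate
  expect_equal(autophosphorylation_rate(sub("CaM4"), sub("CaM4"), p), 0.96)
  # partially loaded substrate: slow rate regardless of kinase CaM state
  expect_equal(autophosphorylation_rate(sub("CaM2C"), sub("CaM4"), p), 0.1)
  expect_equal(autophosphorylation_rate(sub("CaM2C1N"), sub("CaM2C"), p), 0.1)
  expect_equal(autophosphorylation_rate(sub("CaM0"), sub("CaM4"), p), 0.1)
  # an autophosphorylated kinase needs no CaM
  expect_equal(autophosphorylation_rate(sub("CaM4"), sub(NA, pT = TRUE), p),
               0.96)
  expect_equal(autophosphorylation_rate(sub("CaM1C"), sub(NA, pT = TRUE), p),
               0.1)
  # ineligible cases
  expect_equal(autophosphorylation_rate(sub(NA), sub("CaM4"), p), 0)
  expect_equal(autophosphorylation_rate(sub("CaM4", pT = TRUE), sub("CaM4"),
                                        p), 0)
  expect_equal(autophosphorylation_rate(sub("CaM4"), sub(NA, pT = FALSE), p),
               0)
  # adjacency check when positions are supplied
  expect_error(
    autophosphorylation_rate(sub("CaM4", pos = 0L), sub("CaM4", pos = 2L), p),
    "adjacent")
  expect_equal(
    autophosphorylation_rate(sub("CaM4", pos = 5L), sub("CaM4", pos = 0L), p),
    0.96)  # ring wrap-around
})

test_that("CaM binding propensities respect occupancy and affinity mode", {
  p <- spinekin_params()
  rates <- cam_rate_table(p)
  occupied <- sub("CaM4")
  pr <- cam_binding_propensity(occupied, "CaM4", 100, 0.016, p, rates)
  expect_equal(pr$binding, 0)
  expect_equal(pr$unbinding, 6.6)
  # trapped CaM4 unbinds at the measured trapped off-rate
  trapped <- sub("CaM4", mode = "ha", pT = TRUE)
  expect_equal(cam_binding_propensity(trapped, "CaM4", 0, 0.016, p,
                                      rates)$unbinding, 9e-5)
  # at free CaM4 = KD the association and dissociation propensities balance
  v <- 1.6
  n65 <- 0.065 * v * AVOGADRO * 1e-21   # 65 nM as a (fractional) count
  empty <- sub(NA)
  pr2 <- cam_binding_propensity(empty, "CaM4", n65, v, p, rates)
  expect_equal(pr2$binding, 6.6, tolerance = 1e-6)
  expect_equal(pr2$unbinding, 0)
})

test_that("phosphorylation schedules trapping per the la off-rate rule", {
  p <- spinekin_params()
  h <- build_holoenzyme()
  h$cam_species[1] <- "CaM4"; h$cam_species[2] <- "CaM4"
  # subunit 1 (pos 0) has its kinase at pos 1
  res_off <- apply_phosphorylation(h, 1, trapping = FALSE, p)
  expect_true(res_off$holo$pT286[1])
  expect_equal(res_off$holo$mode[1], "la")
  expect_equal(res_off$la_to_ha_rate, 0)
  res_on <- apply_phosphorylation(h, 1, trapping = TRUE, p)
  expect_equal(res_on$la_to_ha_rate, 6.6)
  expect_equal(res_on$holo$mode[1], "la")  # conversion is scheduled, not instant
  h2 <- h; h2$cam_species[1] <- "CaM2C"
  res2 <- apply_phosphorylation(h2, 1, trapping = TRUE, p)
  rt <- cam_rate_table(p)$binding
  expect_equal(res2$la_to_ha_rate,
               rt$koff[rt$species == "CaM2C" & rt$mode == "la"])
  # firing on an ineligible subunit is an internal consistency error
  h3 <- build_holoenzyme()
  expect_error(apply_phosphorylation(h3, 1, TRUE, p), "ineligible")
})
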