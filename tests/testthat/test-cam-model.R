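test_that("the occupancy scheme enumerates nine species on a 3x3 lattice", {
  sp <- cam_species()
  expect_equal(nrow(sp), 9)
  expect_setequal(sp$species,
                  c("CaM0", "CaM1C", "CaM2C", "CaM1N", "CaM1C1N", "CaM2C1N",
                    "CaM2N", "CaM1C2N", "CaM4"))
  expect_equal(sp$nC[sp$species == "CaM4"], 2)
  expect_equal(sp$nN[sp$species == "CaM4"], 2)
  expect_equal(sp$n_ca[sp$species == "CaM0"], 0)

  # transitions move exactly one ion on one lobe (no diagonal moves)
  p <- spinekin_params()
  for (i in seq_len(9)) {
    tr <- ca_transition_rates(sp$species[i], "free", 1, p)
    for (k in seq_len(nrow(tr))) {
      j <- match(tr$target[k], sp$species)
      dC <- abs(sp$nC[j] - sp$nC[i]); dN <- abs(sp$nN[j] - sp$nN[i])
      expect_equal(dC + dN, 1)
    }
  }
})

test_that("saturation and zero-calcium limits have no illegal transitions", {
  p <- spinekin_params()
  for (ctx in c("free", "camkii_la", "camkii_ha")) {
    tr <- ca_transition_rates("CaM4", ctx, 10, p)
    expect_true(all(tr$direction == "off"))
  }
  tr0 <- ca_transition_rates("CaM0", "free", 0, p)
  expect_true(all(tr0$direction == "on"))
  expect_true(all(tr0$rate == 0))
  expect_error(ca_transition_rates("CaM0", "bogus", 1, p), "context")
})

test_that("bound-context rates follow the detailed-balance coupling factors", {
  p <- spinekin_params()
  rates <- cam_rate_table(p)
  # independent recomputation of the coupling factors from the anchors
  g <- ((p$KD_CaM0_la * 1e-6) / (p$KD_CaM4_la * 1e-6))^(1 / 4)
  h <- p$ha_ca_lock_factor
  tr <- ca_transition_rates("CaM2C", "camkii_la", 1, p)
  off_C2 <- tr$rate[tr$site == "C2" & tr$direction == "off"]
  on_N1 <- tr$rate[tr$site == "N1" & tr$direction == "on"]
  expect_equal(off_C2, 10 / g, tolerance = 1e-12)
  expect_equal(on_N1, 1.08e8 * 1e-6, tolerance = 1e-12)
  # CaMKII binding increases Ca2+ affinity at every site, more so when trapped
  ca <- rates$ca
  for (site in c("C1", "C2", "N1", "N2")) {
    kd <- function(ctx) with(ca[ca$context == ctx & ca$site == site, ],
                             koff / kon)
    expect_lt(kd("camkii_la"), kd("free"))
    expect_lt(kd("camkii_ha"), kd("camkii_la"))
  }
  expect_gt(h, g)
})

test_that("trapped off-rates match the brute-force cycle-product oracle", {
  p <- spinekin_params()
  rates <- cam_rate_table(p)
  ha <- derive_ha_offrates(p)
  expect_equal(ha$koff_ha[ha$species == "CaM4"], 9e-5, tolerance = 1e-12)
  oracle <- oracle_ha_offrates(rates)
  expect_equal(ha$koff_ha, unname(oracle[ha$species]), tolerance = 1e-9)
})

test_that("identical trapped and bound Ca tables give uniform off-rate scaling", {
  p <- spinekin_params()
  rates <- cam_rate_table(p)
  # force the trapped-context Ca kinetics to equal the bound-context ones
  la_rows <- rates$ca$context == "camkii_la"
  ha_rows <- rates$ca$context == "camkii_ha"
  rates$ca$koff[ha_rows] <- rates$ca$koff[la_rows]
  rates$ca$kon[ha_rows] <- rates$ca$kon[la_rows]
  oracle <- oracle_ha_offrates(rates)
  la <- rates$binding[rates$binding$mode == "la", ]
  ratio <- unname(oracle[la$species]) / la$koff
  expect_equal(ratio, rep(9e-5 / 6.6, 9), tolerance = 1e-9)
})

test_that("equilibrium distribution hits the limits and detailed balance", {
  p <- spinekin_params()
  eq0 <- equilibrium_cam_distribution(0, p)
  expect_equal(unname(eq0["CaM0"]), 1)
  eqInf <- equilibrium_cam_distribution(Inf, p)
  expect_equal(unname(eqInf["CaM4"]), 1)
  for (ca in c(0.05, 0.1, 1, 10, 100)) {
    eq <- equilibrium_cam_distribution(ca, p)
    expect_equal(sum(eq), 1, tolerance = 1e-12)
    # flux balance on every lattice edge
    for (s in cam_species()$species) {
      tr <- ca_transition_rates(s, "free", ca, p)
      for (k in seq_len(nrow(tr))) {
        fwd <- eq[s] * tr$rate[k]
        back_tr <- ca_transition_rates(tr$target[k], "free", ca, p)
        back <- eq[tr$target[k]] *
          back_tr$rate[back_tr$target == s]
        if (fwd > 0 || back > 0)
          expect_lt(abs(fwd - back) / max(fwd, back), 1e-9)
      }
    }
  }
  expect_error(equilibrium_cam_distribution(-1, p), ">= 0")
})
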