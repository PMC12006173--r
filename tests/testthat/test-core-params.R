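test_that("copy-number conversions reproduce the printed spine counts", {
  expect_identical(count_from_concentration(1.25, 0.016), 12L)
  expect_identical(count_from_concentration(30, 0.016), 289L)
  expect_identical(count_from_concentration(0, 5), 0L)

  expect_equal(concentration_from_count(12, 0.016), 1.2454, tolerance = 1e-4)
  # 360 subunits in the PSD capsule ~ 200 uM to one significant figure
  expect_equal(signif(concentration_from_count(360, 0.002915), 1), 200)
  expect_identical(concentration_from_count(0, 3), 0)

  expect_error(count_from_concentration(-1, 0.016), "concentration")
  expect_error(count_from_concentration(1, 0), "volume")
  expect_error(concentration_from_count(-5, 1), "count")
  expect_error(concentration_from_count(5, -1), "volume")
})

test_that("floor-mode round trip never overshoots the concentration", {
  for (conc in c(0, 0.01, 0.65, 1.25, 6.67, 30, 200)) {
    for (v in c(0.002915, 0.016, 0.577, 1.6)) {
      n <- count_from_concentration(conc, v, rounding = "floor")
      expect_lte(concentration_from_count(n, v), conc + 1e-12)
    }
  }
})

test_that("parameter invariants are enforced", {
  p <- spinekin_params()
  expect_s3_class(p, "spinekin_params")
  expect_lt(p$koff_CaM4_ha, p$koff_CaM4_la)
  expect_equal(p$kon_CaM4 * p$KD_CaM4_la * 1e-6, p$koff_CaM4_la,
               tolerance = 1e-9)
  expect_lt(p$V_psd, p$V_spine)
  expect_error(spinekin_params(KM_pp1 = -1), "positive")
  expect_error(spinekin_params(koff_CaM4_ha = 10), "trapping")
  expect_error(spinekin_params(p_release_init = 1.5), "0, 1")
  expect_error(spinekin_params(nonsense = 1), "unknown parameter")
  expect_error(spinekin_params(V_psd = 0.02), "V_psd")
})

test_that("shipped config file reproduces the default parameter set", {
  path <- system.file("extdata", "default_params.yaml", package = "spinekin")
  expect_true(nzchar(path))
  p <- load_params(path)
  d <- spinekin_params()
  for (nm in setdiff(names(d), "cam_ca_rate_table"))
    expect_equal(p[[nm]], d[[nm]], info = nm)
  expect_equal(p$cam_ca_rate_table$kon, d$cam_ca_rate_table$kon)
  expect_equal(p$cam_ca_rate_table$koff_free, d$cam_ca_rate_table$koff_free)

  # headline values as printed in the source study
  expect_identical(p$k_pCaM4, 0.96)
  expect_identical(p$k_pCaMpartial, 0.1)
  expect_identical(p$kcat_pp1, 11.5)
  expect_identical(p$KM_pp1, 11)
  expect_identical(p$koff_CaM4_la, 6.6)
  expect_identical(p$koff_CaM4_ha, 9e-5)
  expect_identical(p$KD_CaM4_la, 0.065)
  expect_identical(p$conc_CaM_total, 30)
  expect_identical(p$n_holoenzymes, 60L)
  expect_identical(p$conc_PP1, 1.25)
  expect_identical(p$V_spine, 0.016)
  expect_identical(p$V_psd, 0.002915)
  expect_identical(p$n_docked_init, 7L)
  expect_identical(p$p_release_init, 0.2)
  expect_identical(p$redock_rate, 0.2)
  expect_identical(p$n_nmdar, 15L)
  expect_identical(p$bap_delay, 0.01)
  expect_identical(p$ca_baseline, 0.1)
})

test_that("resolved parameters export to JSON and back", {
  p <- spinekin_params(conc_PP1 = 2.5)
  f <- tempfile(fileext = ".json")
  export_params_json(p, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$conc_PP1, 2.5)
  expect_equal(j$kon_CaM4, p$kon_CaM4)
  unlink(f)
})

test_that("thermodynamic validation passes on the shipped table", {
  v <- validate_thermodynamics(spinekin_params())
  expect_equal(nrow(v), 24)  # 12 lattice up-edges x two bound contexts
  expect_lt(max(v$residual), 1e-9)
  expect_false(any(v$flagged))
})

test_that("a perturbed off-rate flags exactly the cycles touching that edge", {
  p <- spinekin_params()
  rates <- cam_rate_table(p)
  i <- with(rates$binding, which(species == "CaM2C" & mode == "la"))
  rates$binding$koff[i] <- rates$binding$koff[i] * 2
  rates$binding$KD[i] <- rates$binding$koff[i] / rates$binding$kon[i]
  v <- validate_thermodynamics(rates = rates)
  bad <- v[v$flagged, ]
  expect_setequal(paste(bad$mode, bad$from, bad$to),
                  c("la CaM1C CaM2C", "la CaM2C CaM2C1N"))
  expect_true(all(abs(bad$residual - log(2)) < 1e-9))
})

test_that("an empty rate table is a missing-parameter error", {
  expect_error(validate_thermodynamics(rates = list()), "missing")
  expect_error(validate_thermodynamics(), "missing")
})
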