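test_that("trajectories are bit-reproducible per seed in both engine modes", {
  p <- params_reduced()
  for (eng in c("exact", "hybrid")) {
    a <- simulate_condition(p, seed = 4, t_end = 2.5, engine = eng)
    b <- simulate_condition(p, seed = 4, t_end = 2.5, engine = eng)
    expect_identical(as.data.frame(a), as.data.frame(b))
  }
})

test_that("without a stimulus nothing phosphorylates and Ca2+ sits at baseline", {
  p <- spinekin_params()
  tr <- run_simulation(p, sim_config(seed = 2, t_end = 5))
  expect_true(all(tr$pT286 == 0))
  expect_true(all(tr$trapped == 0))
  # 100 nM in 0.016 fL is ~0.96 ions on average
  expect_lt(abs(mean(tr$ca_free[tr$time > 0.5]) - 0.963), 0.25)
  expect_true(all(tr$ca_free >= 0))
})

test_that("conservation: CaM changes only through reservoir exchange", {
  p <- params_reduced()
  tr <- simulate_condition(p, seed = 9, t_end = 3, engine = "exact")
  expect_true(all(abs(tr$cam_total - (tr$cam_total[1] + tr$cam_exchange_net))
                  < 1e-9))
  # subunit bookkeeping stays within the fixed total
  bound <- rowSums(tr[, grep("^pbound_|^npbound_", names(tr))])
  expect_true(all(bound <= 12 * p$n_holoenzymes))
  expect_true(all(tr$pT286 <= 12 * p$n_holoenzymes))
  expect_true(all(tr$pT286 == tr$pT286_psd + tr$pT286_out))
})

test_that("trapping off means no subunit ever reaches the high-affinity state", {
  p <- spinekin_params(trapping = FALSE)
  tr <- simulate_condition(p, seed = 3, t_end = 4, engine = "hybrid")
  expect_true(all(tr$trapped == 0))
  p2 <- spinekin_params(trapping = TRUE)
  tr2 <- simulate_condition(p2, seed = 3, t_end = 4, engine = "hybrid")
  expect_gt(max(tr2$trapped), 0)
})

test_that("clamped-Ca equilibrium occupancy matches the analytic fixed point", {
  # 1 holoenzyme + small CaM pool in a larger volume at clamped 50 uM Ca:
  # free species sit at the free-CaM equilibrium and subunit occupancy
  # follows the multi-species binding isotherm with depletion
  v <- 1.6
  p <- spinekin_params(V_spine = v, n_holoenzymes = 1L,
                       conc_CaM_total = 0.0208, k_cam_exchange = 0)
  ca <- 50
  cfg <- sim_config(seed = 21, t_end = 25, record_dt = 0.05, clamp_ca = ca,
                    init_cam_count = 20)
  tr <- run_simulation(p, cfg)
  eq <- equilibrium_cam_distribution(ca, p)
  rates <- cam_rate_table(p)
  b <- rates$binding[rates$binding$mode == "la", ]
  KD_cnt <- b$KD[match(names(eq), b$species)] * 1e6 * v * AVOGADRO * 1e-21
  # fixed point: B = 12 * sum_s(F_s/KD_s) / (1 + sum_s(F_s/KD_s)), F = 20 - B
  Free <- 20
  for (i in 1:200) {
    load <- sum(Free * eq / KD_cnt)
    B <- 12 * load / (1 + load)
    Free <- 20 - B
  }
  sel <- tr$time > 3
  bound <- rowSums(tr[sel, grep("^pbound_|^npbound_", names(tr))])
  se <- block_se(bound)
  expect_lt(abs(mean(bound) - B), 3 * se + 0.35)
})

test_that("clamped-Ca free-CaM species distribution matches the analytic solver", {
  p <- spinekin_params(n_holoenzymes = 0L, k_cam_exchange = 0)
  ca <- 1
  tr <- run_simulation(p, sim_config(seed = 31, t_end = 25, record_dt = 0.05,
                                     clamp_ca = ca))
  eq <- equilibrium_cam_distribution(ca, p)
  sel <- tr$time > 3
  for (s in c("CaM0", "CaM1C", "CaM2C", "CaM1N", "CaM2N")) {
    x <- tr[[paste0("free_", s)]][sel]
    se <- block_se(x)
    expect_lt(abs(mean(x) - 289 * eq[s]), 3 * se + 0.6)
  }
})

test_that("the spine CaM pool relaxes to the reservoir composition", {
  p <- spinekin_params(n_holoenzymes = 0L)
  cfg <- sim_config(seed = 5, t_end = 1.5, record_dt = 0.01,
                    init_cam_count = 0)
  tr <- run_simulation(p, cfg)
  expect_equal(tr$cam_total[1], 0)
  k <- p$k_cam_exchange
  # linear relaxation: N(t) = 289 (1 - exp(-k t)); check at 1/k and at the end
  n_at_tau <- tr$cam_total[which.min(abs(tr$time - 1 / k))]
  expect_lt(abs(n_at_tau - 289 * (1 - exp(-1))) / (289 * (1 - exp(-1))), 0.15)
  expect_gt(tr$cam_total[nrow(tr)], 0.95 * 289 * (1 - exp(-k * 1.5)))
  # confined species untouched by exchange
  expect_true(all(tr$pT286 == 0))
})

test_that("hybrid and exact engines agree on a reduced system", {
  p <- params_reduced()
  peaks <- function(eng) vapply(1:10, function(s)
    max(simulate_condition(p, seed = s, t_end = 4, engine = eng)$pT286), 0)
  pe <- peaks("exact"); ph <- peaks("hybrid")
  pooled_se <- sqrt(stats::var(pe) / 10 + stats::var(ph) / 10)
  expect_lt(abs(mean(pe) - mean(ph)), 3 * pooled_se + 1e-9)
})

test_that("PSD localization partitions CaMKII and PP1 and conserves them", {
  p <- spinekin_params(trapping = TRUE, competition = TRUE,
                       psd_localization = "camkii_and_pp1")
  tr <- simulate_condition(p, seed = 6, t_end = 3, engine = "hybrid")
  expect_true(all(tr$pp1_bound_psd <= 6))
  expect_true(all(tr$pp1_bound_out <= 6))
  # capsule holds half the holoenzymes: its pT286 can exceed zero and is
  # bounded by its 360 subunits
  expect_true(all(tr$pT286_psd <= 360))
  expect_gt(max(tr$pT286_psd), 0)
})

test_that("an eligible pair table drives phosphorylation at the stated rates", {
  # one ring with two adjacent CaM4 subunits: exactly one ordered pair is
  # eligible, with its kinase clockwise of the substrate, at k_pCaM4
  p <- spinekin_params()
  h <- build_holoenzyme()
  h$cam_species[h$ring == 1 & h$pos == 2] <- "CaM4"
  h$cam_species[h$ring == 1 & h$pos == 3] <- "CaM4"
  rates <- vapply(seq_len(12), function(i) {
    s <- as.list(h[i, ])
    r <- as.list(h[h$ring == s$ring & h$pos == ring_neighbor(s$pos, "right"), ])
    autophosphorylation_rate(s, r, p)
  }, 0)
  expect_equal(sum(rates > 0), 1)
  expect_equal(max(rates), 0.96)
  expect_equal(which(rates > 0), which(h$ring == 1 & h$pos == 2))
})
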