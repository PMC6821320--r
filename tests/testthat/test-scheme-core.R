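test_that("rate_set validates its fields", {
  r <- rate_set(1, 0.1, 1, 70, 55, 200, 0.1)
  expect_s3_class(r, "rate_set")
  expect_error(rate_set(-1, 0.1, 1, 70, 55, 200, 0.1), "finite and >= 0")
  expect_error(rate_set(1, 0.1, 1, 70, 55, 200, 1.2), "f_inactive0")
  expect_error(rate_set(Inf, 0.1, 1, 70, 55, 200, 0), "finite")
})

test_that("initial occupancy splits the population by the inactive fraction", {
  r0 <- rate_set(1, 0.1, 1, 70, 55, 200, f_inactive0 = 0)
  expect_equal(unname(equilibrium_initial(r0)), c(0, 1, 0, 0, 0))
  r10 <- rate_set(1, 0.1, 1, 70, 55, 200, f_inactive0 = 0.10)
  expect_equal(unname(equilibrium_initial(r10)), c(0.10, 0.90, 0, 0, 0))
  r1 <- rate_set(1, 0.1, 1, 70, 55, 200, f_inactive0 = 1)
  expect_equal(unname(equilibrium_initial(r1)), c(1, 0, 0, 0, 0))
})

test_that("occupancies are conserved and valid along trajectories", {
  rates_list <- list(
    reference_rates("UTP"), reference_rates("PsiTP"),
    rate_set(0.3, 0.05, 0.2, 5, 5, 20, 0.25))
  for (r in rates_list) {
    tr <- propagate(r, 50, exp(seq(log(1e-4), log(60), length.out = 60)))
    expect_true(all(abs(rowSums(tr$occupancies) - 1) < 1e-9))
    expect_true(all(tr$occupancies > -1e-9 & tr$occupancies < 1 + 1e-9))
    expect_true(all(diff(signal_hcl(tr)) > -1e-9))
    expect_true(all(diff(tr$occupancies[, "POST"]) > -1e-9))
  }
})

test_that("without substrate the isomerization relaxes to its equilibrium", {
  r <- rate_set(2, 0.5, 1, 70, 55, 200, f_inactive0 = 0.4)
  tr <- propagate(r, 0, c(0.1, 1, 20))
  expect_true(all(signal_hcl(tr) == 0))
  expect_equal(unname(tr$occupancies[3, "I"]), 0.5 / 2.5, tolerance = 1e-7)
  expect_equal(unname(tr$occupancies[3, "A"]), 2 / 2.5, tolerance = 1e-7)
})

test_that("the irreversible chain exhausts into the post-translocated state", {
  tr <- propagate(chain_rates(), 10, c(1, 60))
  expect_equal(unname(tr$occupancies[2, "POST"]), 1, tolerance = 1e-8)
})

test_that("propagation matches the sequential-decay closed form to 1e-6", {
  r <- chain_rates(k_on = 1, k_inc = 50, k_tra = 100)  # k1 = 10 at 10 uM
  t <- exp(seq(log(1e-3), log(1), length.out = 40))
  tr <- propagate(r, 10, t)
  expect_true(max(abs(tr$occupancies[, "POST"] -
                        bateman_post(t, 10, 50, 100))) < 1e-6)
})

test_that("propagation rejects invalid inputs", {
  r <- reference_rates("UTP")
  expect_error(propagate(r, -1, c(0.1, 1)), "non-negative")
  expect_error(propagate(r, 10, c(1, 0.5)), "increasing")
})

test_that("deterministic propagation agrees with the stochastic oracle", {
  # documented example rates plus random sets, all within 3 binomial SE
  cases <- list(
    list(rates = chain_rates(k_on = 1, k_inc = 50, k_tra = 100),
         ntp = 10, times = c(0.05, 0.1, 0.3)),
    list(rates = rate_set(0, 0, 1, 10, 50, 100, 0), ntp = 10,
         times = c(0.1)),
    list(rates = reference_rates("UTP"), ntp = 200,
         times = c(0.01, 0.05, 0.5)),
    list(rates = rate_set(0.5, 0.2, 0.3, 20, 10, 30, 0.3), ntp = 25,
         times = c(0.05, 0.5, 2)))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    n <- 100000L
    g <- gillespie_oracle(cs$rates, cs$ntp, n, seed = 100 + i,
                          times = cs$times)
    tr <- propagate(cs$rates, cs$ntp, cs$times)
    se <- pmax(g$se, sqrt(1 / n))  # floor for fractions near 0/1
    expect_true(all(abs(tr$occupancies - g$fractions) <= 3 * se),
                label = paste("case", i, "within 3 SE"))
  }
})

test_that("the stochastic oracle is seed-deterministic and bounded", {
  r <- reference_rates("UTP")
  g1 <- gillespie_oracle(r, 50, 5000, seed = 9, times = c(0.02, 0.2))
  g2 <- gillespie_oracle(r, 50, 5000, seed = 9, times = c(0.02, 0.2))
  expect_identical(g1$fractions, g2$fractions)
  expect_true(all(g1$se <= sqrt(0.25 / 5000)))
  g0 <- gillespie_oracle(r, 0, 2000, seed = 9, times = c(0.5, 5))
  expect_true(all(g0$fractions[, c("PRE", "POST")] == 0))
})

test_that("HCl signal is the extended-RNA fraction PRE + POST", {
  traj <- structure(list(
    times = 1, ntp_conc = 10,
    occupancies = matrix(c(0.2, 0.2, 0.3, 0.2, 0.1), 1, 5,
                         dimnames = list(NULL,
                                         c("I", "A", "AN", "PRE", "POST")))),
    class = "trajectory")
  expect_equal(signal_hcl(traj), 0.3)
  r <- reference_rates("UTP")
  tr0 <- propagate(r, 100, c(1e-9))
  expect_equal(signal_hcl(tr0), 0, tolerance = 1e-6)
})

test_that("EDTA pulse-chase partitions the bound complex by k_inc/(k_inc+k_off)", {
  mk <- function(k_inc, k_off)
    rate_set(0, 0, 1, k_off, k_inc, 100, 0)
  traj <- structure(list(
    times = 1, ntp_conc = 10,
    occupancies = matrix(c(0, 0.2, 0.3, 0.3, 0.2), 1, 5,
                         dimnames = list(NULL,
                                         c("I", "A", "AN", "PRE", "POST")))),
    class = "trajectory")
  expect_equal(signal_edta(traj, mk(50, 0)), 0.5 + 0.3)       # p = 1
  expect_equal(signal_edta(traj, mk(20, 20)), 0.5 + 0.15)     # p = 0.5
  expect_equal(signal_edta(traj, mk(50, 10)), 0.5 + 0.3 * 5 / 6)
})

test_that("EDTA partition equals the quencher-removal limit of the scheme", {
  # independent route: quench at time t = drop free NTP, integrate the
  # bound complex to completion; extended fraction at infinity must equal
  # PRE + POST + p * AN at the quench time
  r <- rate_set(0.8, 0.1, 1, 10, 50, 100, 0.1)
  for (t_q in c(0.02, 0.1, 0.5)) {
    tr <- propagate(r, 20, t_q)
    quenched <- propagate(r, 0, c(200), initial = tr$occupancies[1, ])
    expect_equal(signal_edta(tr, r)[1],
                 unname(quenched$occupancies[1, "PRE"] +
                          quenched$occupancies[1, "POST"]),
                 tolerance = 1e-7)
  }
})

test_that("EDTA signal dominates HCl signal with equality when AN drains", {
  r <- reference_rates("UTP")
  t <- exp(seq(log(1e-3), log(30), length.out = 50))
  tr <- propagate(r, 100, t)
  expect_true(all(signal_edta(tr, r) >= signal_hcl(tr) - 1e-12))
  r_noinc <- rate_set(1, 0.1, 1, 70, 0, 200, 0.1)  # k_inc = 0 => p = 0
  tr2 <- propagate(r_noinc, 100, t)
  expect_equal(signal_edta(tr2, r_noinc), signal_hcl(tr2))
})

test_that("fluorescence projects POST through scale and offset", {
  r <- reference_rates("UTP")
  t <- exp(seq(log(1e-3), log(10), length.out = 30))
  tr <- propagate(r, 100, t)
  obs <- observation_model("fluorescence", scale = 2, offset = 1)
  f <- signal_fluorescence(tr, obs)
  expect_true(all(diff(f) > -1e-12))
  # complete translocation gives the 3-fold enhancement over baseline
  expect_equal(1 + 2 * 1, 3)
  expect_equal(max(f) / f[1], 3, tolerance = 0.05)
  ident <- signal_fluorescence(tr, observation_model("fluorescence", 1, 0))
  expect_equal(ident, unname(tr$occupancies[, "POST"]))
  tr0 <- propagate(r, 0, t)  # POST stays 0 without substrate
  expect_equal(signal_fluorescence(tr0, obs), rep(1, length(t)))
  expect_error(signal_fluorescence(tr, observation_model("hcl_quench")),
               "fluorescence")
})

test_that("translocation adds a mean delay of exactly 1/k_tra", {
  r <- chain_rates(k_on = 1, k_inc = 50, k_tra = 120)
  t <- exp(seq(log(1e-6), log(50), length.out = 6000))
  tr <- propagate(r, 12.5, t)
  lag <- mean_completion_time(t, unname(tr$occupancies[, "POST"])) -
    mean_completion_time(t, signal_hcl(tr))
  expect_within_rel(lag, 1 / 120, 0.01)
})

test_that("amplitude ratios estimate the post-translocated fraction", {
  expect_equal(post_fraction_from_amplitudes(0.7, 1.0)$fraction, 0.7)
  expect_equal(post_fraction_from_amplitudes(1, 1)$fraction, 1)
  expect_equal(post_fraction_from_amplitudes(0, 1)$fraction, 0)
  expect_true(post_fraction_from_amplitudes(1.2, 1)$clipped)
  expect_false(post_fraction_from_amplitudes(0.7, 1)$clipped)
  expect_error(post_fraction_from_amplitudes(0.5, 0), "positive")
})
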