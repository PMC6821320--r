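noiseless_dataset <- function(rates, design = small_design(40L, 20L)) {
  gen_ntp_dataset(rates, design, noise_spec("relative", 0, 1),
                  label = "U")
}

test_that("chi-square is zero at the generating rates and positive elsewhere", {
  truth <- reference_rates("UTP")
  ds <- noiseless_dataset(truth)
  expect_lt(chi_square(truth, ds), 1e-10)
  # local optimality: +10% on any single rate strictly increases chi2
  for (nm in c("k_act", "k_on", "k_off", "k_inc", "k_tra", "f_inactive0")) {
    pars <- as.list(unclass(truth))
    pars[[nm]] <- pars[[nm]] * 1.1
    expect_gt(chi_square(do.call(rate_set, pars), ds), 1e-4)
  }
})

test_that("chi-square matches its weighted-residual definition", {
  truth <- reference_rates("UTP")
  tr <- propagate(truth, 200, c(0.01, 0.1))
  model <- signal_hcl(tr)
  tc <- time_course("one", "hcl_quench", 200, c(0.01, 0.1),
                    model + c(2 * 0.05, 0), sigma = 0.05)
  expect_equal(chi_square(truth, kinetic_dataset(list(tc))), 4,
               tolerance = 1e-6)
})

test_that("uniform sigma rescaling rescales chi-square by the inverse square", {
  truth <- reference_rates("UTP")
  design <- small_design(30L, 15L)
  ds1 <- gen_ntp_dataset(truth, design, noise_spec("relative", 0.02, 3))
  ds2 <- kinetic_dataset(lapply(unname(ds1), function(tc)
    time_course(tc$trace_id, tc$modality, tc$ntp_conc, tc$times,
                tc$values, sigma = 2 * tc$sigma)))
  probe <- rate_set(1, 0.1, 0.8, 50, 40, 150, 0.12)
  expect_equal(chi_square(probe, ds2), chi_square(probe, ds1) / 4,
               tolerance = 1e-9)
})

test_that("a noiseless concentration-series design is recovered to 0.1%", {
  truth <- reference_rates("UTP")
  ds <- noiseless_dataset(truth, small_design(60L, 25L))
  fit <- fit_global(ds, fit_spec(restarts = 3L, seed = 11L))
  expect_true(fit$converged)
  for (nm in names(unclass(truth)))
    expect_within_rel(fit$rates[[nm]], truth[[nm]], 1e-3)
  # profiled fluorescence nuisances recover the generating optics
  nu <- fit$nuisances[[1L]]
  expect_equal(unname(nu[["scale"]]), 2, tolerance = 1e-3)
  expect_equal(unname(nu[["offset"]]), 1, tolerance = 1e-3)
})

test_that("the global fit is invariant to trace ordering", {
  truth <- reference_rates("UTP")
  ds <- gen_ntp_dataset(truth, small_design(30L, 15L),
                        noise_spec("relative", 0.02, 21))
  spec <- fit_spec(restarts = 2L, seed = 5L)
  fit1 <- fit_global(ds, spec)
  fit2 <- fit_global(kinetic_dataset(rev(unname(ds))), spec)
  # identical up to optimizer arithmetic (residual summation order)
  expect_equal(unclass(fit1$rates), unclass(fit2$rates), tolerance = 1e-4)
  expect_equal(fit1$chisq, fit2$chisq, tolerance = 1e-6)
})

test_that("noisy data are recovered within the 10%-chi-square bounds", {
  truth <- reference_rates("UTP")
  ds <- gen_ntp_dataset(truth, small_design(50L, 25L,
                                            concs = c(1.25, 5, 25, 250)),
                        noise_spec("relative", 0.02, 42))
  fit <- fit_global(ds, fit_spec(restarts = 3L, seed = 7L))
  pb <- profile_bounds(fit, ds)
  for (i in seq_len(nrow(pb))) {
    nm <- pb$parameter[i]
    expect_true(truth[[nm]] >= pb$lower[i] - 1e-12 &&
                  truth[[nm]] <= pb$upper[i] + 1e-12,
                label = paste(nm, "bound brackets the generating value"))
  }
  # non-clipped bounds sit at the 10% chi-square increase within 1%
  target <- 1.10 * fit$chisq
  chis <- c(pb$chisq_lower[!pb$clipped_lower],
            pb$chisq_upper[!pb$clipped_upper])
  expect_true(all(abs(chis - target) <= 0.01 * target))
})

test_that("an unidentifiable single-trace design raises a warning", {
  truth <- reference_rates("UTP")
  tc <- gen_timecourse(truth, "fluorescence", 25,
                       exp(seq(log(0.01), log(5), length.out = 40)),
                       noise_spec("relative", 0.02, 2),
                       obs = reference_fluor_obs(), trace_id = "only")
  expect_warning(fit_global(kinetic_dataset(list(tc)),
                            fit_spec(float = c("k_on", "k_off"),
                                     restarts = 1L, seed = 1L),
                            start = truth),
                 "identifiable")
})

test_that("profile bounds follow the chi-square threshold definition", {
  truth <- reference_rates("UTP")
  ds <- gen_ntp_dataset(truth, small_design(30L, 15L),
                        noise_spec("relative", 0.02, 8))
  fit <- suppressWarnings(
    fit_global(ds, fit_spec(float = "k_inc", restarts = 1L, seed = 1L),
               start = truth))
  expect_error(profile_bounds(fit, ds, threshold_factor = 0.9), ">= 1")
  pb1 <- profile_bounds(fit, ds, threshold_factor = 1)
  expect_equal(pb1$lower, pb1$best)
  expect_equal(pb1$upper, pb1$best)
  # single floated parameter: no re-optimization, so the bound must agree
  # with an independent root of chi_square(k) = 1.1 * chi2_min
  pb <- profile_bounds(fit, ds)
  target <- 1.10 * fit$chisq
  chi_of <- function(k) {
    pars <- as.list(unclass(fit$rates)); pars$k_inc <- k
    chi_square(do.call(rate_set, pars), ds)
  }
  root_hi <- stats::uniroot(function(k) chi_of(k) - target,
                            c(fit$rates[["k_inc"]],
                              2 * fit$rates[["k_inc"]]), tol = 1e-10)$root
  root_lo <- stats::uniroot(function(k) chi_of(k) - target,
                            c(fit$rates[["k_inc"]] / 2,
                              fit$rates[["k_inc"]]), tol = 1e-10)$root
  expect_within_rel(pb$upper, root_hi, 0.01)
  expect_within_rel(pb$lower, root_lo, 0.01)
})
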