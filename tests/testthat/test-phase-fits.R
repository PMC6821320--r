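test_that("the two-phase form has the documented limits", {
  f <- list(A_fast = 0.6, k_fast = 14, A_slow = 0.4, tau_slow = 2,
            beta_slow = 0.7)
  expect_equal(eval_two_phase(f, 0), 0)
  expect_true(all(diff(eval_two_phase(f, seq(0, 50, 0.1))) >= 0))
  expect_equal(eval_two_phase(f, 1e6), 1, tolerance = 1e-12)
  # a pure exponential phase is half complete at ln2 / k
  f1 <- list(A_fast = 1, k_fast = 14, A_slow = 0, tau_slow = 1,
             beta_slow = 1)
  expect_equal(eval_two_phase(f1, log(2) / 14), 0.5)
  # beta = 1 collapses the slow phase to a plain exponential of rate 1/tau
  fb <- list(A_fast = 0, k_fast = 100, A_slow = 1, tau_slow = 2,
             beta_slow = 1)
  t <- c(0.5, 1, 4)
  expect_equal(eval_two_phase(fb, t), 1 - exp(-t / 2))
  expect_error(eval_two_phase(f, -1), "non-negative")
})

test_that("median reaction times follow tau * log(2)^(1/beta)", {
  expect_equal(median_time(2, 1), 2 * log(2))
  expect_equal(median_time(1, 0.5), log(2)^2)
  # agreement with the numeric half-completion root over a (tau, beta) grid
  for (tau in c(0.3, 3, 40)) for (beta in c(0.25, 0.6, 1)) {
    root <- stats::uniroot(function(t) (t / tau)^beta - log(2),
                           c(1e-9, 1e6), tol = 1e-13)$root
    expect_equal(median_time(tau, beta), root, tolerance = 1e-9)
  }
  expect_error(median_time(-1, 0.5), "tau")
  expect_error(median_time(1, 1.5), "beta")
})

phase_grid <- function(n = 40L) exp(seq(log(0.01), log(30),
                                        length.out = n))

test_that("two-phase fits recover generating parameters from clean data", {
  truth <- reference_two_phase("TEC-U")
  tc <- gen_phase_course(truth, phase_grid(),
                         noise_spec("relative", 0, 1))
  fit <- fit_two_phase(tc)
  for (nm in names(truth))
    expect_within_rel(fit[[nm]], truth[[nm]], 1e-3)
  expect_true(fit$k_fast >= 1 / fit$tau_slow)
})

test_that("pure single-exponential data collapse the slow phase", {
  truth <- list(A_fast = 0.9, k_fast = 8, A_slow = 0, tau_slow = 1,
                beta_slow = 1)
  tc <- gen_phase_course(truth, phase_grid(),
                         noise_spec("relative", 0, 4))
  fit <- fit_two_phase(tc)
  expect_lt(fit$A_slow, 0.02)
  expect_within_rel(fit$k_fast, 8, 0.02)
  # nested-model consistency: the two-phase fit is never worse than the
  # best single-exponential fit of the same data
  sse_single <- stats::optim(c(0.9, 8), function(p)
    sum((tc$values - p[1] * (1 - exp(-p[2] * tc$times)))^2))$value
  expect_lte(fit$rss, sse_single + 1e-6)
})

test_that("noisy fast-phase rates are recovered within 10% in the median", {
  truth <- reference_two_phase("TEC-U")
  k_hat <- vapply(1:5, function(s) {
    tc <- gen_phase_course(truth, phase_grid(),
                           noise_spec("relative", 0.02, 100 + s))
    fit_two_phase(tc)$k_fast
  }, numeric(1))
  expect_within_rel(stats::median(k_hat), truth$k_fast, 0.10)
})

test_that("phase fits are scale-equivariant", {
  truth <- reference_two_phase("TEC-U")
  tc <- gen_phase_course(truth, phase_grid(),
                         noise_spec("relative", 0.01, 33))
  tc3 <- time_course(tc$trace_id, tc$modality, tc$ntp_conc, tc$times,
                     3 * tc$values, sigma = 3 * tc$sigma)
  f1 <- fit_two_phase(tc)
  f3 <- fit_two_phase(tc3)
  expect_equal(f3$A_fast, 3 * f1$A_fast, tolerance = 1e-4)
  expect_equal(f3$A_slow, 3 * f1$A_slow, tolerance = 1e-4)
  expect_equal(f3$k_fast, f1$k_fast, tolerance = 1e-5)
  expect_equal(f3$tau_slow, f1$tau_slow, tolerance = 1e-5)
  expect_equal(f3$beta_slow, f1$beta_slow, tolerance = 1e-5)
})

cleavage_grid <- function(n = 15L) exp(seq(log(0.5), log(600),
                                           length.out = n))

test_that("cleavage fits recover the resistant fraction from clean data", {
  truth <- reference_cleavage("TEC-U-G")
  tc <- gen_phase_course(truth, cleavage_grid(),
                         noise_spec("relative", 0, 7))
  fit <- fit_cleavage(tc)
  expect_within_rel(fit$cleavable, truth$cleavable, 1e-3)
  expect_within_rel(fit$tau, truth$tau, 1e-3)
  expect_within_rel(fit$beta, truth$beta, 1e-3)
  expect_equal(fit$resistant_fraction, 1 - fit$cleavable)
  expect_equal(fit$resistant_fraction, 0.4, tolerance = 1e-3)
})

test_that("a fully cleavable exponential course is a special case", {
  truth <- list(cleavable = 1, tau = 5, beta = 1)
  tc <- gen_phase_course(truth, cleavage_grid(),
                         noise_spec("relative", 0, 12))
  fit <- fit_cleavage(tc)
  expect_within_rel(fit$cleavable, 1, 1e-3)
  expect_within_rel(fit$tau, 5, 1e-3)
  expect_equal(fit$beta, 1, tolerance = 1e-3)
})

test_that("degenerate cleavage inputs are flagged, not fitted", {
  tc0 <- time_course("none", "hcl_quench", 200, cleavage_grid(8L),
                     rep(0, 8))
  fit <- fit_cleavage(tc0)
  expect_true(fit$degenerate)
  expect_equal(fit$cleavable, 0)
  expect_equal(fit$resistant_fraction, 1)
  expect_error(fit_two_phase(time_course("flat", "hcl_quench", 200,
                                         phase_grid(10L), rep(0.5, 10))),
               "degenerate|constant")
})

test_that("phase fit tables carry one labeled row per trace", {
  ds <- kinetic_dataset(list(
    gen_phase_course(reference_cleavage("TEC-U-G"), cleavage_grid(),
                     noise_spec("relative", 0.01, 1), trace_id = "u"),
    gen_phase_course(reference_cleavage("TEC-OZM-G"), cleavage_grid(),
                     noise_spec("relative", 0.01, 2), trace_id = "ozm")))
  tab <- phase_fit_table(ds, "cleavage")
  expect_equal(tab$trace_id, c("u", "ozm"))
  expect_true(all(tab$t_median > 0))
  expect_gt(tab$t_median[1], tab$t_median[2])  # analog cleaves faster
})
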