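#' Noise specification for synthetic data generators
#'
#' Gaussian, homoscedastic per trace. `"absolute"` uses `sd` in signal
#' units; `"relative"` uses `sd` as a fraction of the noiseless trace's
#' signal range (the default convention, 2\% of range, mimics typical
#' stopped-flow / quench-flow scatter).
#'
#' @param kind `"relative"` or `"absolute"`.
#' @param sd standard deviation (>= 0).
#' @param seed mandatory integer seed; generators are pure functions of
#'   (parameters, seed).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("relative", "absolute"), sd = 0.02,
                       seed) {
  kind <- match.arg(kind)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (missing(seed) || !is.finite(seed))
    stop("an integer seed is required", call. = FALSE)
  structure(list(kind = kind, sd = sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Experiment design of the single-nucleotide addition assay
#'
#' Defaults describe the assay conditions: stopped-flow 6-MI
#' fluorescence concentration series at eight final NTP concentrations
#' spanning 1.25-250 uM (TEC and NTP mixed 1:1, final TEC 0.1 uM),
#' and quench-flow RNA-extension courses at a final 200 uM NTP sampled
#' over 0.004-60 s. Time grids are log-spaced: 50 points for quench-flow,
#' 500 for stopped-flow.
#'
#' @param fluor_conc fluorescence NTP concentrations (uM).
#' @param quench_conc quench-flow NTP concentration (uM).
#' @param fluor_times stopped-flow time grid (s).
#' @param quench_times quench-flow time grid (s).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(
    fluor_conc = signif(1.25 * (250 / 1.25)^((0:7) / 7), 4),
    quench_conc = 200,
    fluor_times = exp(seq(log(0.002), log(10), length.out = 500L)),
    quench_times = exp(seq(log(0.004), log(60), length.out = 50L))) {
  if (any(fluor_conc <= 0) || quench_conc <= 0)
    stop("concentrations must be > 0", call. = FALSE)
  check_times(fluor_times)
  check_times(quench_times)
  structure(list(fluor_conc = fluor_conc, quench_conc = quench_conc,
                 fluor_times = fluor_times, quench_times = quench_times),
            class = "experiment_design")
}

with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv())
    else rm(".Random.seed", envir = globalenv()))
  expr
}

add_noise <- function(values, noise) {
  rng <- diff(range(values))
  sd_abs <- switch(noise$kind, absolute = noise$sd,
                   relative = noise$sd * rng)
  noisy <- with_seed(noise$seed,
                     values + stats::rnorm(length(values), 0, sd_abs))
  list(values = noisy, sd = sd_abs)
}

#' Simulate one time course from the four-step scheme
#'
#' Forward model: [propagate()] projected through the requested modality,
#' plus seeded Gaussian noise. The generating standard deviation is
#' recorded in the trace's `sigma` field (omitted when zero).
#'
#' @param rates a [rate_set()].
#' @param modality `"hcl_quench"`, `"edta_quench"` or `"fluorescence"`.
#' @param ntp_conc NTP concentration (uM).
#' @param times time grid (s).
#' @param noise a [noise_spec()].
#' @param obs an [observation_model()] (fluorescence only).
#' @param trace_id trace label.
#' @return A [time_course()].
#' @export
gen_timecourse <- function(rates, modality, ntp_conc, times, noise,
                           obs = NULL, trace_id = modality) {
  rates <- as_rate_set(rates)
  traj <- propagate(rates, ntp_conc, times)
  clean <- project_signal(traj, modality, rates, obs)
  n <- add_noise(clean, noise)
  time_course(trace_id, modality, ntp_conc, times, n$values,
              sigma = if (n$sd > 0) n$sd else NULL)
}

#' Reference fluorescence observation model
#'
#' Scale and offset chosen so that complete translocation triples the
#' fluorescence over the quenched baseline, matching the 3-fold
#' enhancement observed when the downstream 6-MI reporter reaches the
#' duplex edge in the uridine-extended TEC.
#'
#' @return An [observation_model()] with `offset = 1`, `scale = 2`.
#' @export
reference_fluor_obs <- function() {
  observation_model("fluorescence", scale = 2, offset = 1)
}

#' Simulate a full single-nucleotide dataset for one NTP
#'
#' One fluorescence trace per design concentration plus one HCl- and one
#' EDTA-quenched RNA-extension course at the design quench
#' concentration. Per-trace sub-seeds are derived deterministically from
#' the noise seed.
#'
#' @param rates a [rate_set()].
#' @param design an [experiment_design()].
#' @param noise a [noise_spec()].
#' @param label prefix for trace ids.
#' @param obs fluorescence [observation_model()].
#' @return A [kinetic_dataset()].
#' @export
gen_ntp_dataset <- function(rates, design = experiment_design(),
                            noise, label = "NTP",
                            obs = reference_fluor_obs()) {
  traces <- list()
  for (i in seq_along(design$fluor_conc)) {
    conc <- design$fluor_conc[i]
    sub <- noise_spec(noise$kind, noise$sd,
                      (noise$seed + 101L * i) %% 2147483629L)
    traces[[length(traces) + 1L]] <- gen_timecourse(
      rates, "fluorescence", conc, design$fluor_times, sub, obs,
      trace_id = sprintf("%s_fluor_%guM", label, conc))
  }
  for (mod in c("hcl_quench", "edta_quench")) {
    sub <- noise_spec(noise$kind, noise$sd,
                      (noise$seed + 101L * (length(traces) + 1L)) %%
                        2147483629L)
    traces[[length(traces) + 1L]] <- gen_timecourse(
      rates, mod, design$quench_conc, design$quench_times, sub,
      trace_id = sprintf("%s_%s", label, mod))
  }
  kinetic_dataset(traces)
}

#' Simulate paired concentration-series datasets for two nucleotides
#'
#' Emulates the combined stopped-flow/quench-flow design used to compare
#' UTP with its C-nucleoside analog triphosphate: for each rate set, a
#' fluorescence concentration series plus HCl and EDTA quench courses.
#'
#' @param rates_u,rates_psi [rate_set()]s for the two nucleotides.
#' @param design an [experiment_design()].
#' @param noise a [noise_spec()]; the second dataset uses a sub-seed
#'   offset so the two datasets have independent noise.
#' @return Named list of two [kinetic_dataset()]s (`u`, `psi`).
#' @export
gen_fig_datasets <- function(rates_u, rates_psi,
                             design = experiment_design(), noise) {
  noise2 <- noise_spec(noise$kind, noise$sd,
                       (noise$seed + 77003L) %% 2147483629L)
  list(u = gen_ntp_dataset(rates_u, design, noise, label = "U"),
       psi = gen_ntp_dataset(rates_psi, design, noise2, label = "Psi"))
}

#' Simulate an empirical-phase time course
#'
#' Forward model for the phase-fit module: evaluates a two-phase
#' (exponential + stretched exponential) or cleavage
#' (stretched exponential with resistant fraction) parameter set and
#' adds seeded Gaussian noise.
#'
#' @param fit_params a `two_phase_fit`/[fit_two_phase()]-style list
#'   (fields `A_fast`, `k_fast`, `A_slow`, `tau_slow`, `beta_slow`) or a
#'   `cleavage_fit`-style list (fields `cleavable`, `tau`, `beta`).
#' @param times time grid (s).
#' @param noise a [noise_spec()].
#' @param trace_id trace label.
#' @return A [time_course()] with modality `"hcl_quench"` (quench-flow
#'   derived extension/cleavage fractions).
#' @export
gen_phase_course <- function(fit_params, times, noise,
                             trace_id = "phase") {
  clean <- if (!is.null(fit_params$cleavable))
    fit_params$cleavable * (1 - exp(-(times / fit_params$tau)^
                                      fit_params$beta))
  else
    eval_two_phase(fit_params, times)
  n <- add_noise(clean, noise)
  time_course(trace_id, "hcl_quench", 200, times, n$values,
              sigma = if (n$sd > 0) n$sd else NULL)
}

#' Reference empirical-phase parameter sets
#'
#' `reference_two_phase()` describes guanosine incorporation following a
#' single analog (or uridine) incorporation: a fast phase of ~14 1/s
#' carrying 50-60\% of the amplitude and a kinetically dispersed slow
#' phase whose median time is about 1 s. `reference_cleavage()` gives the
#' stretched-exponential parameters of Gre-factor-facilitated RNA
#' cleavage for the uridine+guanosine extended TEC (`"TEC-U-G"`, median
#' cleavage time 50 s, 40\% resistant) and the analog-extended TEC
#' (`"TEC-OZM-G"`, median time 3.5 s, 20\% resistant), a greater than
#' 10-fold rate difference.
#'
#' @param tec which TEC the parameters describe.
#' @return A parameter list consumable by [gen_phase_course()].
#' @export
reference_two_phase <- function(tec = c("TEC-U", "TEC-OZM", "TEC-Psi")) {
  tec <- match.arg(tec)
  beta <- 0.6
  t_med <- 1.0                      # slow-phase median time, s
  list(A_fast = 0.55, k_fast = 14, A_slow = 0.45,
       tau_slow = t_med / log(2)^(1 / beta), beta_slow = beta)
}

#' @rdname reference_two_phase
#' @export
reference_cleavage <- function(tec = c("TEC-U-G", "TEC-OZM-G")) {
  tec <- match.arg(tec)
  if (tec == "TEC-U-G") {
    beta <- 0.5; t_med <- 50; resistant <- 0.4
  } else {
    beta <- 0.7; t_med <- 3.5; resistant <- 0.2
  }
  list(cleavable = 1 - resistant, tau = t_med / log(2)^(1 / beta),
       beta = beta)
}

#' Lane-simulation specification
#'
#' Describes one synthetic gel lane as Gaussian bands on a constant
#' baseline. Band areas are total pixel counts; rows are discretized by
#' integrating the Gaussian over each row.
#'
#' @param bands data frame with columns `center` (row), `width` (rows,
#'   Gaussian sd) and `area` (counts).
#' @param baseline constant per-row baseline counts.
#' @param n_rows lane length (rows).
#' @return An object of class `lane_sim_spec`.
#' @export
lane_sim_spec <- function(bands, baseline = 0, n_rows = 200L) {
  stopifnot(is.data.frame(bands),
            all(c("center", "width", "area") %in% names(bands)))
  if (any(bands$area < 0)) stop("band areas must be >= 0", call. = FALSE)
  if (any(bands$center < 1 | bands$center > n_rows))
    stop("band centers must lie within the lane", call. = FALSE)
  if (baseline < 0) stop("baseline must be >= 0", call. = FALSE)
  structure(list(bands = bands, baseline = baseline,
                 n_rows = as.integer(n_rows)),
            class = "lane_sim_spec")
}

lane_clean_counts <- function(spec) {
  rows <- seq_len(spec$n_rows)
  counts <- rep(spec$baseline, spec$n_rows)
  for (i in seq_len(nrow(spec$bands))) {
    b <- spec$bands[i, ]
    counts <- counts + b$area *
      (stats::pnorm(rows + 0.5, b$center, b$width) -
         stats::pnorm(rows - 0.5, b$center, b$width))
  }
  counts
}

#' Simulate a control/analog chase lane pair
#'
#' Builds two lane profiles of equal length as Gaussian band mixtures on
#' a baseline with seeded Gaussian noise, truncated at zero counts.
#'
#' @param u_spec,ozm_spec [lane_sim_spec()]s of equal `n_rows`.
#' @param noise a [noise_spec()] (absolute sd in counts, or relative to
#'   the clean count range of each lane).
#' @return Named list of two [lane_profile()]s (`u`, `ozm`).
#' @export
gen_lane_pair <- function(u_spec, ozm_spec, noise) {
  if (u_spec$n_rows != ozm_spec$n_rows)
    stop("lane lengths must match", call. = FALSE)
  clean_u <- lane_clean_counts(u_spec)
  clean_oz <- lane_clean_counts(ozm_spec)
  nu <- add_noise(clean_u, noise)
  noise2 <- noise_spec(noise$kind, noise$sd,
                       (noise$seed + 40013L) %% 2147483629L)
  noz <- add_noise(clean_oz, noise2)
  list(u = lane_profile("U_chase", pmax(nu$values, 0)),
       ozm = lane_profile("OZM_chase", pmax(noz$values, 0)))
}
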