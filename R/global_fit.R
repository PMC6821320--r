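#' @importFrom minpack.lm nls.lm nls.lm.control
#' @importFrom lhs randomLHS
NULL

default_bounds <- function() {
  list(k_act = c(1e-3, 1e3), k_inact = c(1e-4, 1e3),
       k_on = c(1e-3, 1e3), k_off = c(1e-2, 1e4),
       k_inc = c(1e-2, 1e4), k_tra = c(1e-1, 1e5),
       f_inactive0 = c(1e-3, 0.6))
}

#' Specification of a global fit
#'
#' @param float character vector of [rate_set()] field names to float;
#'   the remaining fields are held at their values in the starting rate
#'   set. Fluorescence scale/offset nuisances are always profiled
#'   analytically per trace and need not be listed.
#' @param lower,upper optional named numeric vectors overriding the
#'   default box bounds for floated parameters.
#' @param restarts number of multi-start optimizations (>= 1); starts
#'   beyond the first are drawn from a Latin hypercube over the
#'   log-transformed box.
#' @param seed integer seed controlling the restart draws.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param ftol relative reduction tolerance passed to the optimizer.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(float = rate_set_fields, lower = NULL, upper = NULL,
                     restarts = 8L, seed = 1L, maxiter = 200L,
                     ftol = 1e-10) {
  float <- match.arg(float, rate_set_fields, several.ok = TRUE)
  bounds <- default_bounds()
  for (nm in names(lower)) bounds[[nm]][1L] <- lower[[nm]]
  for (nm in names(upper)) bounds[[nm]][2L] <- upper[[nm]]
  for (nm in float)
    if (bounds[[nm]][1L] >= bounds[[nm]][2L])
      stop("bounds for ", nm, " must satisfy lower < upper", call. = FALSE)
  if (restarts < 1L) stop("restarts must be >= 1", call. = FALSE)
  structure(list(float = float, bounds = bounds,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 maxiter = as.integer(maxiter), ftol = ftol),
            class = "fit_spec")
}

# Default per-trace sigma: constant 3% of the trace's signal range with a
# floor of 1e-3 of the range; unit sigma for a flat trace.
trace_sigma <- function(tc) {
  if (!is.null(tc$sigma)) return(tc$sigma)
  rng <- diff(range(tc$values))
  if (rng <= 0) return(rep(1, length(tc$values)))
  rep(max(0.03 * rng, 1e-3 * rng), length(tc$values))
}

# Model curves for every trace of a dataset under one rate set, with
# trajectory caching across traces sharing (ntp, time grid). Nuisances:
# NULL => weighted-least-squares profiled scale/offset per fluorescence
# trace (variable projection); otherwise a named list of c(scale, offset).
dataset_model <- function(rates, dataset, nuisances = NULL) {
  cache <- new.env(parent = emptyenv())
  lapply(dataset, function(tc) {
    key <- paste(tc$ntp_conc, length(tc$times), tc$times[1L],
                 tc$times[length(tc$times)], sep = "|")
    traj <- get0(key, envir = cache)
    if (is.null(traj)) {
      traj <- propagate(rates, tc$ntp_conc, tc$times)
      assign(key, traj, envir = cache)
    }
    sigma <- trace_sigma(tc)
    if (tc$modality == "fluorescence") {
      post <- as.numeric(traj$occupancies[, "POST"])
      nu <- nuisances[[tc$trace_id]]
      if (is.null(nu)) {
        w <- 1 / sigma^2
        fit <- stats::lm.wfit(cbind(offset = 1, scale = post),
                              tc$values, w)
        nu <- c(scale = unname(fit$coefficients["scale"]),
                offset = unname(fit$coefficients["offset"]))
        if (!is.finite(nu[["scale"]])) nu[["scale"]] <- 0  # flat POST
      }
      model <- nu[["offset"]] + nu[["scale"]] * post
      list(model = model, sigma = sigma, nuisance = nu)
    } else {
      model <- project_signal(traj, tc$modality, rates)
      list(model = model, sigma = sigma, nuisance = NULL)
    }
  })
}

#' Weighted chi-square of a rate set against a dataset
#'
#' Computes \eqn{\sum_i ((y_i - \hat y_i)/\sigma_i)^2} over all points of
#' all traces, with per-modality model curves from the four-step scheme.
#' Fluorescence traces carry instrument-scaled intensities, so their
#' scale and offset are nuisance parameters: supply them explicitly via
#' `nuisances`, or leave `NULL` to use the weighted-least-squares optimal
#' pair per trace (the value minimized by [fit_global()]). Traces without
#' a `sigma` column use the default rule: a per-trace constant equal to
#' 3\% of the trace's signal range.
#'
#' @param rates a [rate_set()].
#' @param dataset a [kinetic_dataset()].
#' @param nuisances optional named list (by fluorescence trace_id) of
#'   `c(scale, offset)`.
#' @return Non-negative scalar.
#' @export
chi_square <- function(rates, dataset, nuisances = NULL) {
  mods <- dataset_model(as_rate_set(rates), dataset, nuisances)
  sum(vapply(seq_along(dataset), function(i) {
    tc <- dataset[[i]]
    m <- mods[[i]]
    sum(((tc$values - m$model) / m$sigma)^2)
  }, numeric(1)))
}

fit_residuals <- function(theta, float, fixed_rates, dataset) {
  pars <- as.list(unclass(fixed_rates))
  pars[float] <- as.list(exp(theta))
  rates <- tryCatch(do.call(rate_set, pars), error = function(e) NULL)
  if (is.null(rates)) return(rep(1e6, n_points(dataset)))
  mods <- tryCatch(dataset_model(rates, dataset),
                   error = function(e) NULL)
  if (is.null(mods)) return(rep(1e6, n_points(dataset)))
  unlist(lapply(seq_along(dataset), function(i)
    (dataset[[i]]$values - mods[[i]]$model) / mods[[i]]$sigma),
    use.names = FALSE)
}

n_points <- function(dataset)
  sum(vapply(dataset, function(tc) length(tc$times), integer(1)))

check_identifiability <- function(dataset) {
  mods <- vapply(dataset, `[[`, "", "modality")
  concs <- vapply(dataset, `[[`, 0, "ntp_conc")
  if (length(unique(mods)) < 2L &&
      length(unique(concs[mods == "fluorescence"])) < 3L)
    warning("dataset has a single modality and < 3 NTP concentrations: ",
            "k_on and k_off are unlikely to be jointly identifiable",
            call. = FALSE)
}

#' Global weighted least-squares fit of the four-step scheme
#'
#' Simultaneously fits all traces of a dataset (stopped-flow fluorescence
#' concentration series, HCl- and EDTA-quenched RNA-extension courses) to
#' the four-step scheme with one shared rate set. Rates are optimized on
#' a log scale by bounded Levenberg-Marquardt with Latin-hypercube
#' multi-starts; per-trace fluorescence scale/offset nuisances are
#' profiled analytically at every step. Ties between restarts (chi-square
#' within 1e-9) resolve to the lowest restart index, so the result is
#' deterministic given the restart seed.
#'
#' @param dataset a [kinetic_dataset()].
#' @param spec a [fit_spec()].
#' @param start optional [rate_set()] supplying the fixed parameter
#'   values and the first start point (defaults to the geometric midpoint
#'   of the box for floated parameters and [reference_rates()] for fixed
#'   ones).
#' @return An object of class `fit_result`: `rates` (best-fit
#'   [rate_set()]), `nuisances` (per fluorescence trace), `chisq`,
#'   `residuals` (per trace), `converged`, `restart_chisq`, `spec`.
#' @export
fit_global <- function(dataset, spec = fit_spec(), start = NULL) {
  stopifnot(inherits(dataset, "kinetic_dataset"), inherits(spec, "fit_spec"))
  check_identifiability(dataset)
  if (is.null(start)) start <- reference_rates("UTP")
  start <- as_rate_set(start)
  float <- spec$float
  lo <- log(vapply(spec$bounds[float], `[`, numeric(1), 1L))
  hi <- log(vapply(spec$bounds[float], `[`, numeric(1), 2L))
  theta0 <- pmin(pmax(log(unclass(start)[float]), lo), hi)
  starts <- matrix(theta0, nrow = 1L,
                   dimnames = list(NULL, float))
  if (spec$restarts > 1L) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(spec$seed)
    u <- lhs::randomLHS(spec$restarts - 1L, length(float))
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
    extra <- sweep(sweep(u, 2L, hi - lo, `*`), 2L, lo, `+`)
    colnames(extra) <- float
    starts <- rbind(starts, extra)
  }
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], lower = lo, upper = hi,
        fn = fit_residuals, float = float, fixed_rates = start,
        dataset = dataset,
        control = minpack.lm::nls.lm.control(
          maxiter = spec$maxiter, ftol = spec$ftol, ptol = 1e-10)),
      error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok))
    stop("all ", spec$restarts, " restarts failed to converge",
         call. = FALSE)
  chis <- vapply(runs, function(r)
    if (is.null(r)) Inf else sum(r$fvec^2), numeric(1))
  best_i <- which(chis <= min(chis) + 1e-9)[1L]
  best <- runs[[best_i]]
  pars <- as.list(unclass(start))
  pars[float] <- as.list(exp(best$par))
  rates <- do.call(rate_set, pars)
  mods <- dataset_model(rates, dataset)
  nuis <- lapply(mods, `[[`, "nuisance")
  names(nuis) <- names(dataset)
  nuis <- nuis[!vapply(nuis, is.null, logical(1))]
  resid <- lapply(seq_along(dataset), function(i)
    dataset[[i]]$values - mods[[i]]$model)
  names(resid) <- names(dataset)
  structure(list(rates = rates, nuisances = nuis,
                 chisq = sum(best$fvec^2), residuals = resid,
                 converged = best$info %in% 1:4,
                 restart_chisq = chis, best_restart = best_i,
                 spec = spec, start = start),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Global four-step fit: chi-square = %.6g (%s)\n", x$chisq,
              if (x$converged) "converged" else "not converged"))
  print(x$rates)
  if (length(x$nuisances))
    cat(sprintf("  %d fluorescence trace(s) with profiled scale/offset\n",
                length(x$nuisances)))
  invisible(x)
}

# chi-square with parameter `name` fixed at `value`, re-optimizing the
# other floated parameters (warm-started from the best fit).
profile_chisq <- function(value, name, fit, dataset) {
  spec <- fit$spec
  float <- setdiff(spec$float, name)
  pars <- as.list(unclass(fit$rates))
  pars[[name]] <- value
  fixed <- do.call(rate_set, pars)
  if (!length(float)) return(chi_square(fixed, dataset))
  lo <- log(vapply(spec$bounds[float], `[`, numeric(1), 1L))
  hi <- log(vapply(spec$bounds[float], `[`, numeric(1), 2L))
  theta0 <- pmin(pmax(log(unclass(fit$rates)[float]), lo), hi)
  r <- tryCatch(
    minpack.lm::nls.lm(par = theta0, lower = lo, upper = hi,
                       fn = fit_residuals, float = float,
                       fixed_rates = fixed, dataset = dataset,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 100L, ftol = 1e-9, ptol = 1e-9)),
    error = function(e) NULL)
  if (is.null(r)) return(Inf)
  sum(r$fvec^2)
}

#' Chi-square profile confidence bounds
#'
#' For each floated parameter, scans away from the best fit with
#' re-optimization of all other parameters and bisects to the parameter
#' values at which the re-optimized chi-square reaches
#' `threshold_factor` times the minimum (default a 10\% increase). A side
#' whose re-optimized chi-square never reaches the threshold inside the
#' box is reported at the box limit and flagged as clipped.
#'
#' @param fit a converged [fit_global()] result.
#' @param dataset the fitted [kinetic_dataset()].
#' @param threshold_factor multiplicative chi-square threshold (> 1, or
#'   exactly 1 for the degenerate point bound).
#' @param max_eval maximum chi-square evaluations per side.
#' @param rel_tol relative bracket tolerance of the bisection.
#' @return An object of class `profile_bounds`: data frame with one row
#'   per floated parameter (`parameter`, `best`, `lower`, `upper`,
#'   `chisq_lower`, `chisq_upper`, `clipped_lower`, `clipped_upper`) and
#'   attributes `chisq_min`, `threshold_factor`.
#' @export
profile_bounds <- function(fit, dataset, threshold_factor = 1.10,
                           max_eval = 60L, rel_tol = 1e-3) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged)
    stop("profile_bounds requires a converged fit", call. = FALSE)
  if (threshold_factor < 1)
    stop("threshold_factor must be >= 1", call. = FALSE)
  target <- threshold_factor * fit$chisq
  rows <- lapply(fit$spec$float, function(name) {
    best <- fit$rates[[name]]
    if (threshold_factor == 1)
      return(data.frame(parameter = name, best = best, lower = best,
                        upper = best, chisq_lower = fit$chisq,
                        chisq_upper = fit$chisq, clipped_lower = FALSE,
                        clipped_upper = FALSE))
    box <- fit$spec$bounds[[name]]
    side <- function(limit) {
      # bisect in log space between best and the box limit
      f_lim <- profile_chisq(limit, name, fit, dataset)
      if (f_lim < target)
        return(list(value = limit, chisq = f_lim, clipped = TRUE))
      a <- log(best); b <- log(limit)
      n <- 2L
      repeat {
        m <- (a + b) / 2
        fm <- profile_chisq(exp(m), name, fit, dataset)
        n <- n + 1L
        if (abs(fm - target) < 5e-3 * target || n >= max_eval)
          break
        if (fm < target) a <- m else b <- m
        if (abs(b - a) < rel_tol) {
          m <- (a + b) / 2
          fm <- profile_chisq(exp(m), name, fit, dataset)
          break
        }
      }
      list(value = exp(m), chisq = fm, clipped = FALSE)
    }
    lo <- side(box[1L])
    hi <- side(box[2L])
    data.frame(parameter = name, best = best, lower = lo$value,
               upper = hi$value, chisq_lower = lo$chisq,
               chisq_upper = hi$chisq, clipped_lower = lo$clipped,
               clipped_upper = hi$clipped)
  })
  out <- do.call(rbind, rows)
  attr(out, "chisq_min") <- fit$chisq
  attr(out, "threshold_factor") <- threshold_factor
  class(out) <- c("profile_bounds", class(out))
  out
}

#' @export
print.profile_bounds <- function(x, ...) {
  cat(sprintf(
    "Profile bounds at %.3g x chi-square minimum (%.6g)\n",
    attr(x, "threshold_factor"), attr(x, "chisq_min")))
  print.data.frame(x, digits = 6, row.names = FALSE)
  invisible(x)
}
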