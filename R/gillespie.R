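#' Stochastic-simulation oracle for the four-step scheme
#'
#' Simulates an ensemble of independent TEC molecules through the
#' continuous-time Markov chain `I <-> A <-> AN -> PRE -> POST` at fixed
#' NTP concentration and reports the state fractions at the requested
#' times with binomial standard errors. This is a deliberately
#' independent implementation (exponential holding times and jump-chain
#' draws, no matrix exponentials) used to validate [propagate()].
#'
#' Because the molecules are independent and the chain is memoryless, the
#' ensemble is advanced interval by interval: within each interval,
#' molecules draw exponential waiting times from their current state's
#' total exit rate; a draw beyond the interval end leaves the molecule in
#' place (the clock restarts at the next interval by memorylessness).
#'
#' @param rates a [rate_set()].
#' @param ntp_conc NTP concentration (uM).
#' @param n_molecules ensemble size (>= 1).
#' @param seed integer seed; the same seed reproduces the output exactly.
#' @param times strictly increasing query times (s).
#' @return List with `times`, `fractions` (matrix, rows = times, columns
#'   = states) and `se` (matrix of binomial standard errors, bounded by
#'   `sqrt(0.25 / n_molecules)`).
#' @examples
#' g <- gillespie_oracle(reference_rates("UTP"), 200, 2000, seed = 1,
#'                       times = c(0.02, 0.1))
#' g$fractions
#' @export
gillespie_oracle <- function(rates, ntp_conc, n_molecules, seed, times) {
  rates <- as_rate_set(rates)
  check_times(times)
  if (n_molecules < 1) stop("n_molecules must be >= 1", call. = FALSE)
  k_bind <- rates[["k_on"]] * ntp_conc
  # exit rates and jump targets per state (states indexed 1..5)
  exit <- c(rates[["k_act"]],
            rates[["k_inact"]] + k_bind,
            rates[["k_off"]] + rates[["k_inc"]],
            rates[["k_tra"]],
            0)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  f0 <- rates[["f_inactive0"]]
  n_inact <- round(f0 * n_molecules)
  state <- c(rep.int(1L, n_inact), rep.int(2L, n_molecules - n_inact))
  fractions <- matrix(0, length(times), 5,
                      dimnames = list(NULL, scheme_states))
  t_prev <- 0
  for (k in seq_along(times)) {
    span <- times[k] - t_prev
    elapsed <- numeric(n_molecules)
    repeat {
      live <- which(exit[state] > 0 & elapsed < span)
      if (!length(live)) break
      dt <- stats::rexp(length(live), exit[state[live]])
      elapsed[live] <- elapsed[live] + dt
      jump <- live[elapsed[live] <= span]
      if (length(jump)) {
        u <- stats::runif(length(jump))
        s <- state[jump]
        new_state <- s
        # state 1 (I) -> A always
        new_state[s == 1L] <- 2L
        # state 2 (A): to I with prob k_inact/exit, else to AN
        i2 <- s == 2L
        new_state[i2] <- ifelse(u[i2] < rates[["k_inact"]] / exit[2L],
                                1L, 3L)
        # state 3 (AN): to A with prob k_off/exit, else to PRE
        i3 <- s == 3L
        new_state[i3] <- ifelse(u[i3] < rates[["k_off"]] / exit[3L],
                                2L, 4L)
        # state 4 (PRE) -> POST
        new_state[s == 4L] <- 5L
        state[jump] <- new_state
      }
    }
    p <- tabulate(state, nbins = 5L) / n_molecules
    fractions[k, ] <- p
    t_prev <- times[k]
  }
  se <- sqrt(fractions * (1 - fractions) / n_molecules)
  list(times = times, fractions = fractions, se = se,
       n_molecules = n_molecules, seed = seed)
}
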