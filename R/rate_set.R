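#' Rate constants of the four-step nucleotide-addition scheme
#'
#' A `rate_set` holds the six rate constants of the four-step
#' transcription-elongation-complex (TEC) nucleotide-addition scheme plus
#' the initial fraction of TECs in the inactive state:
#'
#' \deqn{I \rightleftharpoons A \rightleftharpoons A{\cdot}N \rightarrow
#'       PRE \rightarrow POST}
#'
#' The initial TEC slowly and reversibly isomerizes between an inactive
#' state `I` and an active state `A` (`k_act`, `k_inact`), the active
#' state binds the NTP substrate reversibly (`k_on`, `k_off`), undergoes
#' irreversible incorporation of the nucleotide into RNA (`k_inc`), and
#' finally translocates irreversibly (`k_tra`). Because translocation is
#' modeled as irreversible, `k_tra` is an apparent rate equal to the sum
#' of the forward and backward translocation rates.
#'
#' @param k_act inactive-to-active isomerization rate (1/s).
#' @param k_inact active-to-inactive isomerization rate (1/s).
#' @param k_on bimolecular NTP association rate (1/uM/s).
#' @param k_off NTP dissociation rate (1/s).
#' @param k_inc irreversible nucleotide-incorporation rate (1/s).
#' @param k_tra apparent irreversible translocation rate (1/s), the sum of
#'   the forward and backward translocation rates.
#' @param f_inactive0 initial fraction of TECs in the inactive state,
#'   in \[0, 1\].
#' @return An object of class `rate_set`: a named numeric vector with the
#'   seven fields above.
#' @examples
#' rate_set(k_act = 1, k_inact = 0.1, k_on = 1, k_off = 70,
#'          k_inc = 55, k_tra = 200, f_inactive0 = 0.1)
#' @export
rate_set <- function(k_act, k_inact, k_on, k_off, k_inc, k_tra,
                     f_inactive0 = 0) {
  x <- c(k_act = k_act, k_inact = k_inact, k_on = k_on, k_off = k_off,
         k_inc = k_inc, k_tra = k_tra, f_inactive0 = f_inactive0)
  validate_rate_set(x)
  class(x) <- "rate_set"
  x
}

#' @rdname rate_set
#' @param x object to test or validate.
#' @export
is_rate_set <- function(x) inherits(x, "rate_set")

rate_set_fields <- c("k_act", "k_inact", "k_on", "k_off", "k_inc",
                     "k_tra", "f_inactive0")

validate_rate_set <- function(x) {
  if (!is.numeric(x) || !setequal(names(x), rate_set_fields))
    stop("a rate_set must have exactly the fields: ",
         paste(rate_set_fields, collapse = ", "), call. = FALSE)
  rates <- x[setdiff(rate_set_fields, "f_inactive0")]
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  f0 <- x[["f_inactive0"]]
  if (!is.finite(f0) || f0 < 0 || f0 > 1)
    stop("f_inactive0 must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Four-step TEC scheme rate set\n")
  cat(sprintf("  %-12s %s\n", names(x), format(unname(unclass(x)),
                                               digits = 6)), sep = "")
  invisible(x)
}

as_rate_set <- function(x) {
  if (is_rate_set(x)) return(x)
  x <- unlist(x)
  do.call(rate_set, as.list(x[rate_set_fields]))
}

#' Read and write rate sets as key-value text
#'
#' Rate sets are stored as plain `key = value` text with exactly the
#' `rate_set` field names; comment lines starting with `#` and blank
#' lines are ignored. Unknown keys are rejected.
#'
#' @param path file path.
#' @return `read_rate_set` returns a [rate_set()]; `write_rate_set`
#'   invisibly returns `path`.
#' @export
read_rate_set <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[=:]")
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("malformed rate-set line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(parts, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(parts, `[[`, "", 2L))))
  unknown <- setdiff(keys, rate_set_fields)
  if (length(unknown))
    stop("unknown rate-set key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicated rate-set key(s)", call. = FALSE)
  missing <- setdiff(rate_set_fields, keys)
  if (length(missing))
    stop("missing rate-set key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(is.na(vals)))
    stop("non-numeric rate-set value(s)", call. = FALSE)
  names(vals) <- keys
  do.call(rate_set, as.list(vals[rate_set_fields]))
}

#' @rdname read_rate_set
#' @param rates a [rate_set()].
#' @param header optional character vector written as leading `#` comment
#'   lines (provenance).
#' @export
write_rate_set <- function(rates, path, header = NULL) {
  rates <- as_rate_set(rates)
  lines <- character(0)
  if (length(header)) lines <- paste0("# ", header)
  lines <- c(lines, sprintf("%s = %s", rate_set_fields,
                            format(unname(unclass(rates)), digits = 17)))
  writeLines(lines, path)
  invisible(path)
}

#' Reference rate sets for uridine and pseudouridine incorporation
#'
#' Bundled rate sets used to parameterize the synthetic-data generators.
#' They describe single-round UMP (or Psi-MP) incorporation and
#' translocation by the \emph{E. coli} RNA polymerase elongation complex
#' at 25 C: an approximately 10\% slow (inactive) TEC fraction that
#' interconverts with the active state more than an order of magnitude
#' more slowly than nucleotide addition, reversible NTP binding with
#' moderate affinity, incorporation at tens per second, and fast apparent
#' translocation so that the translocation step adds only a small delay
#' at saturating substrate. The pseudouridine triphosphate set differs
#' from the UTP set only in a 2-fold larger association rate constant,
#' with equal incorporation and translocation rates.
#'
#' @param ntp `"UTP"` or `"PsiTP"`.
#' @return A [rate_set()].
#' @examples
#' reference_rates("UTP")
#' reference_rates("PsiTP")[["k_on"]] / reference_rates("UTP")[["k_on"]]
#' @export
reference_rates <- function(ntp = c("UTP", "PsiTP")) {
  ntp <- match.arg(ntp)
  base <- list(k_act = 1, k_inact = 0.1, k_on = 1, k_off = 70,
               k_inc = 55, k_tra = 200, f_inactive0 = 0.1)
  if (ntp == "PsiTP") base$k_on <- 2 * base$k_on
  do.call(rate_set, base)
}
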