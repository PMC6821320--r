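time_course_modalities <- c("hcl_quench", "edta_quench", "fluorescence")

#' A single measured or simulated time course
#'
#' @param trace_id unique label for the trace.
#' @param modality one of `"hcl_quench"`, `"edta_quench"`,
#'   `"fluorescence"`.
#' @param ntp_conc NTP concentration (uM).
#' @param times non-negative strictly increasing times (s).
#' @param values signal values, same length as `times`.
#' @param sigma optional per-point standard deviation (single value or
#'   vector); when absent, fitting applies the default rule (3\% of the
#'   trace's signal range, see [fit_global()]).
#' @return An object of class `time_course`.
#' @export
time_course <- function(trace_id, modality, ntp_conc, times, values,
                        sigma = NULL) {
  modality <- match.arg(modality, time_course_modalities)
  check_times(times)
  if (length(values) != length(times))
    stop("values and times must have equal length", call. = FALSE)
  if (!is.null(sigma)) {
    sigma <- rep_len(as.numeric(sigma), length(times))
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("sigma must be > 0 where supplied", call. = FALSE)
  }
  if (!is.numeric(ntp_conc) || ntp_conc < 0)
    stop("ntp_conc must be non-negative (uM)", call. = FALSE)
  structure(list(trace_id = as.character(trace_id), modality = modality,
                 ntp_conc = ntp_conc, times = as.numeric(times),
                 values = as.numeric(values), sigma = sigma),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("time_course '%s': %s, [NTP] = %g uM, %d points (%g-%g s)\n",
              x$trace_id, x$modality, x$ntp_conc, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' A collection of time courses sharing one rate set
#'
#' @param ... [time_course()] objects, or a single list of them.
#' @return An object of class `kinetic_dataset` (a list of traces with
#'   unique `trace_id`s).
#' @export
kinetic_dataset <- function(...) {
  traces <- list(...)
  if (length(traces) == 1L && !inherits(traces[[1L]], "time_course"))
    traces <- traces[[1L]]
  if (!length(traces))
    stop("a dataset must contain at least one trace", call. = FALSE)
  ok <- vapply(traces, inherits, logical(1), "time_course")
  if (!all(ok)) stop("all elements must be time_course objects",
                     call. = FALSE)
  ids <- vapply(traces, `[[`, "", "trace_id")
  if (anyDuplicated(ids))
    stop("trace_ids must be unique", call. = FALSE)
  names(traces) <- ids
  structure(traces, class = "kinetic_dataset")
}

#' @export
print.kinetic_dataset <- function(x, ...) {
  cat(sprintf("kinetic_dataset: %d trace(s)\n", length(x)))
  for (tc in x)
    cat(sprintf("  %-14s %-12s %8g uM  %4d pts\n", tc$trace_id,
                tc$modality, tc$ntp_conc, length(tc$times)))
  invisible(x)
}

#' Read and write time-course datasets as delimited text
#'
#' The on-disk format is comma-separated with header
#' `trace_id,modality,ntp_uM,time_s,value,sigma`; `sigma` may be empty.
#' Leading lines starting with `#` are treated as provenance comments and
#' skipped on read. Rows of one trace must be in strictly increasing time
#' order; violations are reported with the offending trace.
#'
#' @param path file path.
#' @return `read_timecourses` returns a [kinetic_dataset()];
#'   `write_timecourses` invisibly returns `path`.
#' @export
read_timecourses <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("trace_id", "modality", "ntp_uM", "time_s", "value", "sigma")
  if (!all(need %in% names(df)))
    stop("time-course file must have header ",
         paste(need, collapse = ","), call. = FALSE)
  bad_mod <- setdiff(unique(df$modality), time_course_modalities)
  if (length(bad_mod))
    stop("unknown modality value(s): ", paste(bad_mod, collapse = ", "),
         call. = FALSE)
  traces <- lapply(split(df, factor(df$trace_id,
                                    levels = unique(df$trace_id))),
                   function(d) {
    if (length(unique(d$modality)) != 1L || length(unique(d$ntp_uM)) != 1L)
      stop("trace '", d$trace_id[1L],
           "': modality and ntp_uM must be constant within a trace",
           call. = FALSE)
    if (any(diff(d$time_s) <= 0))
      stop("trace '", d$trace_id[1L],
           "': times must be strictly increasing (rows ",
           paste(which(diff(d$time_s) <= 0) + 1L, collapse = ", "), ")",
           call. = FALSE)
    sigma <- d$sigma
    if (all(is.na(sigma))) sigma <- NULL
    else if (any(is.na(sigma)))
      stop("trace '", d$trace_id[1L],
           "': sigma must be supplied for all points or none",
           call. = FALSE)
    time_course(d$trace_id[1L], d$modality[1L], d$ntp_uM[1L],
                d$time_s, d$value, sigma)
  })
  kinetic_dataset(unname(traces))
}

#' @rdname read_timecourses
#' @param dataset a [kinetic_dataset()].
#' @param header optional character vector written as leading `#`
#'   comment lines.
#' @export
write_timecourses <- function(dataset, path, header = NULL) {
  rows <- lapply(dataset, function(tc) {
    data.frame(trace_id = tc$trace_id, modality = tc$modality,
               ntp_uM = tc$ntp_conc, time_s = tc$times,
               value = tc$values,
               sigma = if (is.null(tc$sigma)) NA_real_ else tc$sigma)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
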