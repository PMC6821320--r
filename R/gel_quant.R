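#' Gel lane profiles and band windows
#'
#' A `lane_profile` holds the per-row pixel counts of one gel lane,
#' ordered from the top of the lane (well, longest RNA) to the bottom
#' (shortest RNA). A `band_window` is an inclusive row range labeled by
#' the sequence position of the band (e.g. `"+7"`).
#'
#' @param lane_id lane label.
#' @param counts non-negative pixel counts, length >= 2.
#' @return `lane_profile` returns an object of class `lane_profile`.
#' @export
lane_profile <- function(lane_id, counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L)
    stop("a lane profile needs at least 2 rows", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0", call. = FALSE)
  structure(list(lane_id = as.character(lane_id), counts = counts),
            class = "lane_profile")
}

#' @rdname lane_profile
#' @param site_label band label (sequence position).
#' @param row_start,row_end inclusive row range, top-to-bottom
#'   coordinates, `row_start <= row_end`.
#' @export
band_window <- function(site_label, row_start, row_end) {
  if (row_start < 1L || row_end < row_start)
    stop("need 1 <= row_start <= row_end", call. = FALSE)
  structure(list(site_label = as.character(site_label),
                 row_start = as.integer(row_start),
                 row_end = as.integer(row_end)),
            class = "band_window")
}

#' Linearly scale lane profiles to the full 8-bit grayscale range
#'
#' Applies one linear map per panel sending the panel-wide minimum count
#' to 0 and the panel-wide maximum to 255; all lanes of a panel share the
#' same map, so relative band intensities across lanes are preserved (up
#' to the shared affine transform). This scaling is for visualization;
#' quantitative ratios are computed on raw counts.
#'
#' @param profiles a single [lane_profile()] or a list of them treated
#'   as one panel.
#' @return Scaled profile(s) of the same shape as the input.
#' @export
scale_to_8bit <- function(profiles) {
  single <- inherits(profiles, "lane_profile")
  panel <- if (single) list(profiles) else profiles
  all_counts <- unlist(lapply(panel, `[[`, "counts"))
  lo <- min(all_counts); hi <- max(all_counts)
  if (hi <= lo)
    stop("panel has zero dynamic range (all counts equal)", call. = FALSE)
  out <- lapply(panel, function(p)
    lane_profile(p$lane_id, (p$counts - lo) / (hi - lo) * 255))
  if (single) out[[1L]] else out
}

#' Integrated pixel counts of a band
#'
#' Sums the lane counts over the rows of a band window.
#'
#' @param profile a [lane_profile()].
#' @param window a [band_window()] within the profile extent.
#' @return Non-negative scalar.
#' @export
band_integral <- function(profile, window) {
  n <- length(profile$counts)
  if (window$row_end > n)
    stop("band window [", window$row_start, ", ", window$row_end,
         "] exceeds lane extent (", n, " rows)", call. = FALSE)
  sum(profile$counts[window$row_start:window$row_end])
}

#' Arrest fraction from a chase-lane pair
#'
#' Quantifies the fraction of TECs arrested at an analog-responsive site
#' as the ratio of the pixel counts in the arrest band of the
#' analog-chase lane to the pixel counts at-and-above the corresponding
#' site in the control (U-chase) lane. The at-and-above denominator makes
#' the measure immune to the loss of long analog-containing RNAs that
#' enter the gel poorly, though it does not correct for lane-loading
#' differences; a ratio above 1 (possible only with unequal loadings) is
#' returned as-is with a flag. Ratios use raw counts; apply
#' [scale_to_8bit()] only for display.
#'
#' @param ozm_profile analog-chase [lane_profile()].
#' @param u_profile control-chase [lane_profile()].
#' @param arrest_window [band_window()] of the arrest band in the
#'   analog-chase lane.
#' @param at_and_above_window [band_window()] spanning from the lane top
#'   down through the arrest site in the control lane.
#' @param subtract_baseline subtract each lane's minimum row count as a
#'   constant baseline before integrating (off by default).
#' @return List with `fraction`, `flagged` (TRUE when the ratio exceeds
#'   1), `numerator`, `denominator`.
#' @examples
#' u <- lane_profile("U", c(50, 80, 40, 20, 10))
#' oz <- lane_profile("OZM", c(30, 40, 38, 15, 8))
#' arrest_fraction(oz, u, band_window("+7", 3, 3),
#'                 band_window("+7", 1, 3))
#' @export
arrest_fraction <- function(ozm_profile, u_profile, arrest_window,
                            at_and_above_window,
                            subtract_baseline = FALSE) {
  if (subtract_baseline) {
    ozm_profile <- lane_profile(ozm_profile$lane_id,
                                ozm_profile$counts - min(ozm_profile$counts))
    u_profile <- lane_profile(u_profile$lane_id,
                              u_profile$counts - min(u_profile$counts))
  }
  num <- band_integral(ozm_profile, arrest_window)
  den <- band_integral(u_profile, at_and_above_window)
  if (den <= 0)
    stop("at-and-above window of the control lane has zero counts",
         call. = FALSE)
  ratio <- num / den
  list(fraction = ratio, flagged = ratio > 1, numerator = num,
       denominator = den)
}

#' Read and write lane profiles as tab-separated text
#'
#' Format: header `lane_id\trow\tcount`, one row per lane row; leading
#' `#` lines are provenance comments.
#'
#' @param path file path.
#' @return `read_lane_profiles` returns a named list of
#'   [lane_profile()]s.
#' @export
read_lane_profiles <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("lane_id", "row", "count")
  if (!all(need %in% names(df)))
    stop("lane-profile file must have header ",
         paste(need, collapse = "\t"), call. = FALSE)
  lanes <- lapply(split(df, factor(df$lane_id, levels = unique(df$lane_id))),
                  function(d) {
    d <- d[order(d$row), ]
    if (!identical(as.integer(d$row), seq_len(nrow(d))))
      stop("lane '", d$lane_id[1L], "': rows must be 1..n", call. = FALSE)
    lane_profile(d$lane_id[1L], d$count)
  })
  lanes
}

#' @rdname read_lane_profiles
#' @param profiles a list of [lane_profile()]s.
#' @param header optional character vector of `#` comment lines.
#' @export
write_lane_profiles <- function(profiles, path, header = NULL) {
  if (inherits(profiles, "lane_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(lane_id = p$lane_id, row = seq_along(p$counts),
               count = p$counts)))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(format(df, digits = 17, trim = TRUE), con,
                     row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
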