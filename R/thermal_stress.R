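#' Build a daily sea-surface temperature series
#'
#' Validates and, where needed, repairs a daily SST record for one island
#' buffer. Dates must be daily; internal gaps of up to `max_gap` days are
#' filled by linear interpolation, longer gaps are an error. The result is a
#' contiguous series suitable for climatology and DHW computation.
#'
#' @param island_id identifier for the island/atoll buffer.
#' @param dates `Date` vector (need not be complete; gaps are filled).
#' @param sst sea-surface temperature in degrees Celsius, same length as
#'   `dates`.
#' @param max_gap longest internal run of missing days that may be
#'   interpolated (default 3).
#' @return An object of class `sst_series`: a data frame with columns
#'   `date` and `sst`, attribute `island_id`.
#' @export
sst_series <- function(island_id, dates, sst, max_gap = 3) {
  if (length(dates) != length(sst)) stop("dates and sst differ in length")
  dates <- as.Date(dates)
  if (anyDuplicated(dates)) stop("duplicated dates in SST series")
  o <- order(dates)
  dates <- dates[o]
  sst <- as.numeric(sst)[o]
  full <- seq(dates[1], dates[length(dates)], by = "day")
  x <- rep(NA_real_, length(full))
  x[match(dates, full)] <- sst
  if (anyNA(x)) {
    runs <- rle(is.na(x))
    if (any(runs$lengths[runs$values] > max_gap)) {
      stop("SST gap longer than ", max_gap, " days; refusing to interpolate")
    }
    x <- zoo::na.approx(x, na.rm = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite SST after gap filling")
  out <- data.frame(date = full, sst = x)
  attr(out, "island_id") <- island_id
  class(out) <- c("sst_series", "data.frame")
  out
}

#' Read daily SST series from CSV
#'
#' Expects columns `island_id`, `date`, `sst`; returns a named list of
#' [sst_series()] objects, one per island.
#'
#' @param path CSV file path.
#' @param max_gap passed to [sst_series()].
#' @export
read_sst_csv <- function(path, max_gap = 3) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("island_id", "date", "sst")
  if (!all(need %in% names(d))) {
    stop("SST CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(d, d$island_id), function(g) {
    sst_series(g$island_id[1], as.Date(g$date), g$sst, max_gap = max_gap)
  })
  out[order(names(out))]
}

#' Maximum of the Monthly Mean SST climatology (MMM)
#'
#' The MMM is the warmest calendar-month mean of daily SST over the
#' climatology years; the coral bleaching threshold is MMM + 1 degree C.
#' By default the climatology uses every complete calendar year in the
#' record except the final (event) year. Leap days count in February.
#'
#' @param series an [sst_series()].
#' @param climatology_years integer years to pool; every calendar month must
#'   be represented across them.
#' @return MMM in degrees Celsius (scalar).
#' @export
compute_mmm <- function(series, climatology_years = NULL) {
  stopifnot(inherits(series, "sst_series"))
  yr <- as.integer(format(series$date, "%Y"))
  mo <- as.integer(format(series$date, "%m"))
  if (is.null(climatology_years)) {
    # complete years only, excluding the last year of record
    tab <- table(yr)
    complete <- as.integer(names(tab))[tab >= 365]
    climatology_years <- setdiff(complete, max(yr))
    if (length(climatology_years) == 0) climatology_years <- complete
  }
  if (!all(climatology_years %in% yr)) {
    stop("climatology years absent from series: ",
         paste(setdiff(climatology_years, yr), collapse = ", "))
  }
  keep <- yr %in% climatology_years
  present <- sort(unique(mo[keep]))
  if (length(present) < 12) {
    stop("month(s) missing from climatology: ",
         paste(month.abb[setdiff(1:12, present)], collapse = ", "))
  }
  monthly <- tapply(series$sst[keep], mo[keep], mean)
  max(monthly)
}

#' HotSpots and Degree Heating Weeks from daily SST
#'
#' HotSpot on day d is `max(0, sst_d - mmm)`. DHW on day d accumulates
#' qualifying HotSpots (those at or above `min_hotspot`, the satellite
#' product convention of 1 degree C) over the trailing 84 days (12 weeks),
#' divided by 7 to express the result in degree C-weeks. The first 83 days
#' carry partial-window values and are flagged as spin-up.
#'
#' @param series an [sst_series()] of length at least 84 days.
#' @param mmm climatology maximum from [compute_mmm()].
#' @param min_hotspot minimum HotSpot magnitude that accumulates
#'   (default 1 degree C; set 0 to accumulate all positive anomalies).
#' @return An object of class `thermal_metrics`: data frame with columns
#'   `date`, `sst`, `hotspot`, `dhw`, `spin_up`; attributes `mmm`,
#'   `bleaching_threshold` (= mmm + 1) and `island_id`.
#' @export
compute_dhw <- function(series, mmm, min_hotspot = 1) {
  stopifnot(inherits(series, "sst_series"))
  n <- nrow(series)
  if (n < 84) stop("series shorter than the 84-day DHW window")
  hotspot <- pmax(0, series$sst - mmm)
  qual <- ifelse(hotspot >= min_hotspot, hotspot, 0)
  cs <- cumsum(qual)
  lag <- c(rep(0, 84), cs[seq_len(n - 84)])
  dhw <- (cs - lag) / 7
  out <- data.frame(
    date = series$date, sst = series$sst, hotspot = hotspot,
    dhw = dhw, spin_up = seq_len(n) < 84
  )
  attr(out, "mmm") <- mmm
  attr(out, "bleaching_threshold") <- mmm + 1
  attr(out, "island_id") <- attr(series, "island_id")
  class(out) <- c("thermal_metrics", "data.frame")
  out
}

#' Summarize a thermal-stress event window
#'
#' @param metrics a `thermal_metrics` object from [compute_dhw()].
#' @param window `Date` vector of length 2 (start, end inclusive); default
#'   the full post-spin-up record.
#' @return List with `max_dhw` (degree C-weeks), `days_above_threshold`
#'   (days with SST above MMM + 1), and `peak_date` (earliest day reaching
#'   the maximum DHW).
#' @export
event_summary <- function(metrics, window = NULL) {
  stopifnot(inherits(metrics, "thermal_metrics"))
  if (is.null(window)) {
    window <- range(metrics$date[!metrics$spin_up])
  }
  window <- as.Date(window)
  keep <- metrics$date >= window[1] & metrics$date <= window[2]
  if (!any(keep)) stop("empty event window")
  m <- metrics[keep, ]
  imax <- which(m$dhw == max(m$dhw))[1]  # earliest on ties
  list(
    max_dhw = m$dhw[imax],
    days_above_threshold = sum(m$sst > attr(metrics, "bleaching_threshold")),
    peak_date = m$date[imax]
  )
}
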