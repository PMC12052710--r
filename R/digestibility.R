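#' Marker measurement panel
#'
#' Bundles the four concentrations entering the internal-marker degradation
#' formula, all on a dry-matter basis (g/kg DM): acid-insoluble ash in feed
#' (`A`) and rumen contents (`B`), and the fiber fraction (NDF or ADF) in feed
#' (`FA`) and rumen contents (`FB`). Acid-insoluble ash is indigestible, so it
#' concentrates in digesta as digestible matter disappears; the ratio `A/B`
#' converts digesta concentrations back to the feed basis.
#'
#' All fields are vectorized: each may hold one value per animal.
#'
#' @param A acid-insoluble ash concentration in feed; must be > 0.
#' @param B acid-insoluble ash concentration in rumen contents; must be > 0.
#' @param FA fiber concentration in feed; must be > 0.
#' @param FB fiber concentration in rumen contents; must be >= 0.
#' @param fiber_kind `"NDF"` or `"ADF"` (label only).
#' @return an object of class `marker_measurement` (a list of the four
#'   concentration vectors plus the fiber label).
#' @examples
#' marker_measurement(A = 2, B = 4, FA = 400, FB = 300)
#' @export
marker_measurement <- function(A, B, FA, FB, fiber_kind = c("NDF", "ADF")) {
  fiber_kind <- match.arg(fiber_kind)
  n <- max(length(A), length(B), length(FA), length(FB))
  A <- rep_len(as.numeric(A), n)
  B <- rep_len(as.numeric(B), n)
  FA <- rep_len(as.numeric(FA), n)
  FB <- rep_len(as.numeric(FB), n)
  if (anyNA(c(A, B, FA, FB))) stop("marker concentrations must not be NA",
                                   call. = FALSE)
  if (any(A <= 0) || any(B <= 0) || any(FA <= 0)) {
    stop("A, B and FA must all be strictly positive", call. = FALSE)
  }
  if (any(FB < 0)) stop("FB must be non-negative", call. = FALSE)
  structure(list(A = A, B = B, FA = FA, FB = FB, fiber_kind = fiber_kind),
            class = "marker_measurement")
}

#' Fiber degradation rate from internal-marker concentrations
#'
#' Indirect digestibility estimate using acid-insoluble ash as the internal
#' marker: \deqn{D = (1 - (A/B) \times (FB/FA)) \times 100}
#' expressed in percent. `A/B` corrects for the concentration of indigestible
#' marker in digesta relative to feed, so `(A/B) * FB` is the residual fiber
#' per unit of feed fiber.
#'
#' Sampling noise can push the estimate below zero (residual fiber apparently
#' exceeding intake); negative rates are returned with a warning rather than
#' clamped, since silently truncating them would bias downstream extreme-group
#' assignment.
#'
#' @param m a [marker_measurement()].
#' @return numeric vector of degradation rates in percent (one per animal).
#' @examples
#' degradation_rate(marker_measurement(A = 2, B = 4, FA = 400, FB = 300))
#' # 62.5
#' @export
degradation_rate <- function(m) {
  if (!inherits(m, "marker_measurement")) {
    stop("`m` must be a marker_measurement", call. = FALSE)
  }
  rate <- (1 - (m$A / m$B) * (m$FB / m$FA)) * 100
  if (any(rate < 0)) {
    warning(sum(rate < 0),
            " negative degradation rate(s); returned unclamped", call. = FALSE)
  }
  rate
}

#' Per-interval growth and feed-efficiency metrics
#'
#' Average daily gain over an interval is the body-weight difference divided
#' by the interval length; the feed conversion ratio is daily feed intake per
#' unit daily gain (lower = more efficient):
#' \deqn{ADG = (BW_{end} - BW_{start}) / days, \quad FCR = FI / ADG}
#'
#' When a lamb does not gain weight over an interval (`ADG == 0`) its FCR is
#' undefined and reported as `NA`, never as infinity.
#'
#' @param bw_by_age named numeric vector of body weights (kg); names are ages
#'   in days, strictly increasing.
#' @param fi_by_interval numeric vector of average daily feed intake (kg/d),
#'   one per interval, or a single value recycled.
#' @param intervals two-column matrix or data.frame of `(start_day, end_day)`
#'   pairs; both endpoints must be ages present in `bw_by_age`.
#' @return data.frame with columns `start_day`, `end_day`, `days`, `adg`
#'   (kg/d), `fi` (kg/d) and `fcr`.
#' @examples
#' growth_metrics(c(`80` = 20, `100` = 25), fi_by_interval = 1.25,
#'                intervals = cbind(80, 100))
#' @export
growth_metrics <- function(bw_by_age, fi_by_interval, intervals) {
  ages <- as.numeric(names(bw_by_age))
  if (anyNA(ages) || is.unsorted(ages, strictly = TRUE)) {
    stop("`bw_by_age` must be named by strictly increasing ages (days)",
         call. = FALSE)
  }
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2L) stop("`intervals` needs start and end columns",
                                  call. = FALSE)
  start <- intervals[, 1L]
  end <- intervals[, 2L]
  if (any(end <= start)) stop("interval end must exceed start", call. = FALSE)
  missing_age <- setdiff(c(start, end), ages)
  if (length(missing_age)) {
    stop("no body weight recorded at age(s): ",
         paste(missing_age, collapse = ", "), call. = FALSE)
  }
  fi <- rep_len(as.numeric(fi_by_interval), length(start))
  days <- end - start
  adg <- (bw_by_age[as.character(end)] - bw_by_age[as.character(start)]) / days
  adg <- unname(adg)
  fcr <- ifelse(adg == 0, NA_real_, fi / adg)
  data.frame(start_day = start, end_day = end, days = days,
             adg = adg, fi = fi, fcr = fcr)
}
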