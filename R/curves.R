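#' OD600 to biomass conversion
#'
#' Evaluates the empirical calibration cubic
#' `biomass = -2e6*OD^3 + 3e7*OD^2 + 3e6*OD + 2.203e5`,
#' giving the number of cells in a 200 ul well at a given OD600 reading. The
#' polynomial is strictly increasing on the calibration range OD in
#' \eqn{[0, 2]}.
#'
#' @param od numeric vector of OD600 readings in `[0, 2]`.
#' @param check if `TRUE` (default) error on readings outside the calibration
#'   range; set `FALSE` to extrapolate at your own risk.
#' @return Numeric vector of biomass (cells per well).
#' @examples
#' od_to_biomass(0)    # 220300, the calibration intercept
#' od_to_biomass(0.8)
#' @seealso [biomass_to_od()] for the inverse.
#' @export
od_to_biomass <- function(od, check = TRUE) {
  if (!is.numeric(od) || any(!is.finite(od))) {
    stop("'od' must be finite numeric", call. = FALSE)
  }
  if (check && (any(od < 0) || any(od > 2))) {
    stop("OD outside the calibration range [0, 2]; pass check = FALSE to ",
         "extrapolate", call. = FALSE)
  }
  ((od_coef[4] * od + od_coef[3]) * od + od_coef[2]) * od + od_coef[1]
}

# calibration cubic coefficients, ascending powers (cells per OD^k)
od_coef <- c(2.203e5, 3e6, 3e7, -2e6)

#' Biomass to OD600 conversion
#'
#' Inverts the calibration cubic of [od_to_biomass()] by bracketed
#' root-finding on OD in `[0, 2]`, where the cubic is strictly increasing so
#' the root is unique. The result satisfies
#' `|od_to_biomass(result) - biomass| < 1` cell.
#'
#' @param biomass numeric vector of cell counts per well; must lie between
#'   `od_to_biomass(0)` and `od_to_biomass(2)`.
#' @return Numeric vector of OD600 values.
#' @examples
#' biomass_to_od(od_to_biomass(0.8))
#' @export
biomass_to_od <- function(biomass) {
  if (!is.numeric(biomass) || any(!is.finite(biomass))) {
    stop("'biomass' must be finite numeric", call. = FALSE)
  }
  lo <- od_to_biomass(0)
  hi <- od_to_biomass(2)
  if (any(biomass < lo) || any(biomass > hi)) {
    stop(sprintf(
      "biomass outside the calibration range [%.4g, %.4g] cells", lo, hi),
      call. = FALSE)
  }
  vapply(biomass, function(b) {
    if (b == lo) return(0)
    if (b == hi) return(2)
    uniroot(function(x) od_to_biomass(x) - b, interval = c(0, 2),
            tol = 1e-12)$root
  }, numeric(1))
}

#' Growth curve container
#'
#' A light wrapper validating a single well's time series: a data frame with
#' a strictly increasing `time_h` column and an `od` (or `biomass`) column,
#' plus culture metadata.
#'
#' @param time_h sampling times in hours.
#' @param od OD600 readings (optional if `biomass` given).
#' @param biomass cell counts per well (optional if `od` given).
#' @param culture_type,environment,replicate,week optional metadata recorded
#'   as attributes.
#' @return A data frame of class `qnq_curve`.
#' @export
growth_curve <- function(time_h, od = NULL, biomass = NULL,
                         culture_type = NA_character_,
                         environment = NA_character_,
                         replicate = NA_integer_, week = NA_integer_) {
  if (length(time_h) < 2L) stop("a growth curve needs at least 2 points",
                                call. = FALSE)
  if (any(diff(time_h) <= 0)) stop("'time_h' must be strictly increasing",
                                   call. = FALSE)
  if (is.null(od) && is.null(biomass)) {
    stop("provide 'od' or 'biomass'", call. = FALSE)
  }
  cols <- list(time_h = time_h)
  for (nm in c("od", "biomass")) {
    v <- get(nm)
    if (!is.null(v)) {
      if (length(v) != length(time_h) || any(!is.finite(v))) {
        stop("'", nm, "' must be finite and match 'time_h' in length",
             call. = FALSE)
      }
      cols[[nm]] <- v
    }
  }
  out <- as.data.frame(cols)
  attr(out, "meta") <- list(culture_type = culture_type,
                            environment = environment,
                            replicate = replicate, week = week)
  class(out) <- c("qnq_curve", "data.frame")
  out
}

curve_biomass <- function(curve) {
  if (!is.null(curve$biomass)) curve$biomass else od_to_biomass(curve$od)
}

#' Lag-phase length by the OD-increment threshold rule
#'
#' The lag is the first sampled time at which the OD has risen by
#' `delta_od` (default 0.01) above the OD at the start of regrowth. The
#' estimate is reported on the sampling grid, so it overshoots the true
#' growth onset by up to one sampling interval plus the time needed to grow
#' `delta_od` of OD. If the increment is never reached the curve's lag is
#' not observable and `NA` is returned (downstream statistics drop and count
#' these).
#'
#' @param curve a [growth_curve()] or data frame with `time_h` and `od`.
#' @param delta_od OD increment defining the end of the lag.
#' @return Lag length in hours, or `NA_real_` if never reached.
#' @examples
#' lag_threshold(growth_curve(0:10 / 2, od = 0.1 + 0.004 * (0:10)))
#' @export
lag_threshold <- function(curve, delta_od = 0.01) {
  if (is.null(curve$od)) stop("lag_threshold() needs the curve in OD units",
                              call. = FALSE)
  if (nrow(curve) < 2L) stop("a growth curve needs at least 2 points",
                             call. = FALSE)
  hit <- which(curve$od - curve$od[1] >= delta_od - 1e-12)
  if (!length(hit)) return(NA_real_)
  curve$time_h[hit[1]]
}

#' Lag-phase length from the maximum growth rate
#'
#' Converts the curve to biomass and locates the time of maximal growth rate,
#' using centred finite differences on the raw sampling grid (no smoothing by
#' default). `method = "second_derivative"` instead returns the time at which
#' the second difference of biomass is maximal (the steepest acceleration,
#' an alternative reading of "time to reach maximum growth rate"). Ties are
#' broken by the earliest time; a flat curve has no defined lag and yields
#' `NA`.
#'
#' @inheritParams lag_threshold
#' @param method `"first_derivative"` (maximum growth rate, default) or
#'   `"second_derivative"`.
#' @param prefilter apply a 3-point running-median prefilter to biomass
#'   before differencing (for noisy curves).
#' @return Time of maximal (first or second) derivative in hours, or
#'   `NA_real_` for a flat curve.
#' @export
lag_max_growth <- function(curve,
                           method = c("first_derivative",
                                      "second_derivative"),
                           prefilter = FALSE) {
  method <- match.arg(method)
  if (nrow(curve) < 5L) {
    stop("lag_max_growth() needs at least 5 points", call. = FALSE)
  }
  b <- curve_biomass(curve)
  t <- curve$time_h
  if (prefilter) b <- stats::runmed(b, k = 3)
  n <- length(b)
  if (max(b) - min(b) < .Machine$double.eps * max(abs(b), 1) * 100) {
    return(NA_real_)
  }
  if (method == "first_derivative") {
    idx <- 2:(n - 1L)
    deriv <- (b[idx + 1L] - b[idx - 1L]) / (t[idx + 1L] - t[idx - 1L])
  } else {
    idx <- 2:(n - 1L)
    h1 <- t[idx] - t[idx - 1L]
    h2 <- t[idx + 1L] - t[idx]
    deriv <- 2 * (h1 * b[idx + 1L] - (h1 + h2) * b[idx] + h2 * b[idx - 1L]) /
      (h1 * h2 * (h1 + h2))
  }
  t[idx[which.max(deriv)]]
}

#' Relative biomass against the mixed-culture reference
#'
#' Divides each culture's biomass by the mean biomass of the mixed-culture
#' replicates at the same time point (and week/environment stratum, which the
#' caller selects by subsetting). By construction the mixed replicates
#' average exactly 1 at every time point.
#'
#' @param data long-format data frame with columns `culture_type` (containing
#'   `"mixed"` rows), `replicate`, `time_h`, and `biomass` (or `od`, which is
#'   converted).
#' @return The input with a `relative_biomass` column and a `mixed_mean`
#'   reference column.
#' @export
relative_biomass_vs_mixed <- function(data) {
  data <- as.data.frame(data)
  need <- c("culture_type", "replicate", "time_h")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (is.null(data$biomass)) {
    if (is.null(data$od)) stop("need a 'biomass' or 'od' column",
                               call. = FALSE)
    data$biomass <- od_to_biomass(data$od)
  }
  mixed <- data[data$culture_type == "mixed", ]
  if (!nrow(mixed)) stop("no mixed-culture reference rows present",
                         call. = FALSE)
  ref <- tapply(mixed$biomass, mixed$time_h, mean)
  times <- as.numeric(names(ref))
  if (!all(data$time_h %in% times)) {
    stop("mixed reference missing at some time points", call. = FALSE)
  }
  data$mixed_mean <- as.numeric(ref[match(data$time_h, times)])
  if (any(data$mixed_mean == 0)) {
    stop("mixed-culture mean biomass is zero at some time point; relative ",
         "biomass undefined", call. = FALSE)
  }
  data$relative_biomass <- data$biomass / data$mixed_mean
  data
}

#' Relative biomass of complex- versus simple-environment cultures
#'
#' For each culture type and time point, the ratio of the mean biomass of
#' cultures starved in the complex environment (spent medium) to the mean
#' biomass of the same cell type starved in the simple environment (sterile
#' water). The simple environment is the reference line at 1.
#'
#' @param curves_complex,curves_simple long-format data frames with columns
#'   `culture_type`, `time_h`, and `biomass` (or `od`), on identical time
#'   grids per culture type. No interpolation is performed: mismatched grids
#'   are an error.
#' @return Data frame with columns `culture_type`, `time_h`,
#'   `biomass_complex`, `biomass_simple`, `relative_biomass`.
#' @export
relative_biomass_env <- function(curves_complex, curves_simple) {
  prep <- function(d, label) {
    d <- as.data.frame(d)
    if (is.null(d$biomass)) {
      if (is.null(d$od)) stop("need a 'biomass' or 'od' column in ", label,
                              call. = FALSE)
      d$biomass <- od_to_biomass(d$od)
    }
    if (!all(c("culture_type", "time_h") %in% names(d))) {
      stop("need 'culture_type' and 'time_h' columns in ", label,
           call. = FALSE)
    }
    agg <- stats::aggregate(biomass ~ culture_type + time_h, data = d,
                            FUN = mean)
    agg[order(agg$culture_type, agg$time_h), ]
  }
  cx <- prep(curves_complex, "curves_complex")
  sx <- prep(curves_simple, "curves_simple")
  key_c <- paste(cx$culture_type, cx$time_h)
  key_s <- paste(sx$culture_type, sx$time_h)
  if (nrow(cx) != nrow(sx) || !all(key_c == key_s)) {
    stop("complex and simple data are not aligned on the same culture ",
         "types and time grid (no silent interpolation is performed)",
         call. = FALSE)
  }
  if (any(sx$biomass == 0)) {
    stop("simple-environment biomass is zero at some time point; ratio ",
         "undefined", call. = FALSE)
  }
  data.frame(culture_type = cx$culture_type, time_h = cx$time_h,
             biomass_complex = cx$biomass, biomass_simple = sx$biomass,
             relative_biomass = cx$biomass / sx$biomass)
}
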