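#' Construct and validate a growth curve
#'
#' @param time hours, strictly increasing, >= 3 points, time[1] >= 0.
#' @param od OD600 readings >= 0.
#' @param strain,condition,batch optional identifiers.
#' @return list of class `growth_curve`.
#' @export
growth_curve <- function(time, od, strain = NA_character_,
                         condition = NA_character_, batch = NA_character_) {
  if (length(time) != length(od)) stop("time and od lengths differ")
  if (length(time) < 3) stop("growth curves need >= 3 time points")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  if (time[1] < 0) stop("time must start at >= 0")
  if (any(od < 0)) stop("OD readings must be >= 0")
  structure(list(time = as.numeric(time), od = as.numeric(od),
                 strain = strain, condition = condition, batch = batch),
            class = "growth_curve")
}

#' Area under a growth curve
#'
#' Trapezoidal integral of OD600 over the recorded span (OD * hours), the
#' growth metric used for dose selection.
#'
#' @param curve a `growth_curve`.
#' @return numeric area.
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  pracma::trapz(curve$time, curve$od)
}

#' Growth relative to an untreated control
#'
#' 100 * AUC(treated) / AUC(control); 70 percent of control corresponds to
#' roughly 30 percent growth inhibition (the IC30 dose-selection level).
#'
#' @param treated,control `growth_curve` objects.
#' @return percent of control growth.
#' @export
relative_growth <- function(treated, control) {
  a_c <- auc(control)
  if (a_c <= 0) stop("control AUC must be > 0")
  100 * auc(treated) / a_c
}

#' Interpolate an ICx dose from a dose-response table
#'
#' Linear interpolation in log10 dose to the (100 - x) percent growth level,
#' after isotonic projection to a non-increasing dose-response (flagged when
#' the projection changes anything). Exact when the level coincides with a
#' measured dose.
#'
#' @param doses positive doses (>= 2).
#' @param growth relative growth (percent of control) at each dose.
#' @param x inhibition percentage (default 30 for IC30).
#' @return the interpolated dose, with attribute `smoothed` (logical).
#' @export
icx_from_doses <- function(doses, growth, x = 30) {
  stopifnot(length(doses) == length(growth), length(doses) >= 2,
            all(doses > 0), x > 0, x < 100)
  o <- order(doses)
  doses <- doses[o]; growth <- growth[o]
  if (anyDuplicated(doses)) stop("duplicate doses")
  iso <- -stats::isoreg(log10(doses), -growth)$yf  # non-increasing projection
  smoothed <- any(abs(iso - growth) > 1e-9)
  level <- 100 - x
  hit <- which(abs(iso - level) < 1e-9)
  if (length(hit)) {
    res <- doses[hit[1]]
  } else {
    if (level > max(iso) || level < min(iso)) {
      stop("dose range does not span IC", x)
    }
    below <- which(iso < level)[1]      # first dose past the level
    above <- below - 1L
    lx <- log10(doses)
    f <- (iso[above] - level) / (iso[above] - iso[below])
    res <- 10^(lx[above] + f * (lx[below] - lx[above]))
  }
  attr(res, "smoothed") <- smoothed
  res
}

#' Doubling time from the exponential phase of a growth curve
#'
#' Finds the sliding window of `window` points with the highest R-squared of
#' a linear fit to ln(OD) versus time among windows with positive slope, and
#' returns ln(2) / slope. Returns NA (with a `reason` attribute) when no
#' window reaches the R-squared floor or no growth is detected. Invariant to
#' multiplying the whole curve by a positive constant.
#'
#' @param curve a `growth_curve` (zero ODs are dropped from the log fit).
#' @param window window width in points (default 10, shrunk to the curve
#'   length when necessary).
#' @param r2_floor minimum R-squared for an acceptable window (default 0.98).
#' @return doubling time in hours, or NA.
#' @export
doubling_time <- function(curve, window = 10, r2_floor = 0.98) {
  stopifnot(inherits(curve, "growth_curve"))
  keep <- curve$od > 0
  t <- curve$time[keep]; y <- log(curve$od[keep])
  if (length(t) < 3) return(structure(NA_real_, reason = "too few positive ODs"))
  w <- min(window, length(t))
  if (w < 3) w <- 3
  best_r2 <- -Inf; best_slope <- NA_real_
  for (i in seq_len(length(t) - w + 1L)) {
    idx <- i:(i + w - 1L)
    fit <- stats::lm.fit(cbind(1, t[idx]), y[idx])
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope <= 0) next
    tss <- sum((y[idx] - mean(y[idx]))^2)
    if (tss <= 0) next
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 > best_r2) { best_r2 <- r2; best_slope <- slope }
  }
  if (!is.finite(best_r2) || best_r2 < r2_floor) {
    return(structure(NA_real_, reason = "no log-linear window above R2 floor"))
  }
  unname(log(2) / best_slope)
}

#' Normalize mutant doubling times to within-batch wild-type controls
#'
#' Each mutant measurement is divided by the mean wild-type doubling time of
#' its own batch, controlling for batch effects in multi-plate assays.
#'
#' @param times data frame with columns `strain`, `batch`, `doubling_time`.
#' @param wildtype strain name of the wild-type control (default "WT").
#' @return `times` with an added `relative_doubling` column (NA for wild-type
#'   rows is not produced; wild types are normalized to their batch mean too).
#' @export
normalize_to_control <- function(times, wildtype = "WT") {
  need <- c("strain", "batch", "doubling_time")
  if (!all(need %in% names(times))) {
    stop("times must have columns ", paste(need, collapse = ", "))
  }
  wt_mean <- tapply(times$doubling_time[times$strain == wildtype],
                    times$batch[times$strain == wildtype], mean)
  missing <- setdiff(unique(times$batch), names(wt_mean))
  if (length(missing)) {
    stop("batch lacking a wild-type control: ", paste(missing, collapse = ", "))
  }
  times$relative_doubling <- times$doubling_time / wt_mean[times$batch]
  times
}
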