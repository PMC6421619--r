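# Summary metrics over trajectories: time-unit conversion, spatial means,
# between-scenario percent differences, front positions and fill time.

#' Convert between months and dimensionless time
#'
#' The model's unit of time is the matrix-production timescale
#' ([matrix_timescale_hours()], about 267 h at the default parameters).
#' Months are mean calendar months of 30.44 days, so one month is about
#' 2.74 time units.
#'
#' @param months,tbar values to convert.
#' @param timescale_hours the model timescale in hours.
#' @return The converted times.
#' @export
months_to_tbar <- function(months,
                           timescale_hours = matrix_timescale_hours()) {
  months * tbar_per_month(timescale_hours)
}

#' @rdname months_to_tbar
#' @export
tbar_to_months <- function(tbar,
                           timescale_hours = matrix_timescale_hours()) {
  tbar / tbar_per_month(timescale_hours)
}

#' @rdname months_to_tbar
#' @export
tbar_per_month <- function(timescale_hours = matrix_timescale_hours()) {
  30.44 * 24 / timescale_hours
}

traj_months <- function(traj) {
  if (!is.null(traj$months)) return(traj$months)
  tbar_to_months(traj$times)
}

#' Interpolate a field profile at a given time
#'
#' Linear interpolation between the two stored states bracketing
#' `t_months`.
#'
#' @param traj a `cart_trajectory` (with stored month stamps, as produced by
#'   [run_scenario()]).
#' @param field one of `"cs"`, `"cc"`, `"n"`, `"m"`, `"g"`, `"b"`.
#' @param t_months evaluation time in months; must lie within the stored
#'   span.
#' @return Numeric profile over the grid nodes.
#' @export
profile_at <- function(traj, field, t_months) {
  stopifnot(inherits(traj, "cart_trajectory"))
  field <- match.arg(field, FIELDS)
  mo <- traj_months(traj)
  tol <- 1e-9 * max(1, abs(mo[length(mo)]))
  if (t_months < mo[1L] - tol || t_months > mo[length(mo)] + tol) {
    stop("time ", t_months, " months lies outside the stored span [",
         mo[1L], ", ", mo[length(mo)], "]", call. = FALSE)
  }
  t_months <- min(max(t_months, mo[1L]), mo[length(mo)])
  i <- findInterval(t_months, mo, rightmost.closed = TRUE)
  mat <- traj$fields[[field]]
  if (i >= length(mo)) return(mat[length(mo), ])
  w <- (t_months - mo[i]) / (mo[i + 1L] - mo[i])
  (1 - w) * mat[i, ] + w * mat[i + 1L, ]
}

trapz_mean <- function(u) {
  N <- length(u)
  (0.5 * u[1L] + sum(u[2:(N - 1L)]) + 0.5 * u[N]) / (N - 1L)
}

#' Spatial mean of a field
#'
#' Trapezoidal average of the field profile over the scaled defect depth
#' `x` in \[0, 1\] at the requested time (profiles interpolated linearly
#' between stored stamps). Because the domain has unit scaled length, the
#' spatial mean equals the total scaled amount in the defect.
#'
#' @inheritParams profile_at
#' @return A single number.
#' @export
spatial_mean <- function(traj, field, t_months) {
  trapz_mean(profile_at(traj, field, t_months))
}

#' Spatial-mean time series for all fields
#'
#' @param traj a `cart_trajectory`.
#' @param fields fields to include.
#' @return A data frame with `time_months` and one column per field,
#'   holding the trapezoidal spatial means at every stored stamp.
#' @export
mean_series <- function(traj, fields = FIELDS) {
  stopifnot(inherits(traj, "cart_trajectory"))
  fields <- match.arg(fields, FIELDS, several.ok = TRUE)
  out <- data.frame(time_months = traj_months(traj))
  for (f in fields) {
    out[[f]] <- apply(traj$fields[[f]], 1L, trapz_mean)
  }
  out
}

#' Percent difference between two scenarios
#'
#' `100 * (mean_a - mean_b) / mean_b`, where each mean is the spatial mean
#' of `field` at `t_months`; `b` is the baseline.
#'
#' @param a,b `cart_trajectory` objects spanning `t_months`.
#' @inheritParams profile_at
#' @return Percent difference (positive when `a` exceeds the baseline).
#' @export
percent_difference <- function(a, b, field, t_months) {
  ma <- spatial_mean(a, field, t_months)
  mb <- spatial_mean(b, field, t_months)
  if (mb == 0) {
    stop("baseline spatial mean of '", field, "' at ", t_months,
         " months is zero; percent difference undefined", call. = FALSE)
  }
  100 * (ma - mb) / mb
}

#' Position of a migrating front
#'
#' The largest depth `x` at which the profile crosses `level` times its
#' maximum, linearly interpolated between nodes. Used to track the
#' stem-cell and chondrocyte fronts that migrate up the defect towards the
#' nutrient reservoir.
#'
#' @param profile numeric field profile over the grid nodes.
#' @param x node coordinates (same length).
#' @param level crossing level as a fraction of the profile maximum, in
#'   (0, 1).
#' @return The front position, or `NA_real_` (with a "no front" message
#'   attribute unset) when the profile is identically nonpositive.
#' @export
front_position <- function(profile, x, level = 0.5) {
  stopifnot(length(profile) == length(x), level > 0, level < 1)
  pk <- max(profile)
  if (pk <= 0) return(NA_real_)
  thr <- level * pk
  above <- profile >= thr
  i_last <- max(which(above))
  if (i_last == length(x)) return(x[length(x)])
  # interpolate the crossing between the last node above and the next below
  u1 <- profile[i_last]
  u2 <- profile[i_last + 1L]
  x[i_last] + (u1 - thr) / (u1 - u2) * (x[i_last + 1L] - x[i_last])
}

#' Front-position time series from a trajectory
#'
#' @inheritParams profile_at
#' @param level crossing level passed to [front_position()].
#' @return A data frame with `time_months` and `front`.
#' @export
front_series <- function(traj, field, level = 0.5) {
  stopifnot(inherits(traj, "cart_trajectory"))
  field <- match.arg(field, FIELDS)
  mo <- traj_months(traj)
  fr <- vapply(seq_along(mo), function(i) {
    front_position(traj$fields[[field]][i, ], traj$grid$x, level)
  }, numeric(1))
  data.frame(time_months = mo, front = fr)
}

#' Time for the defect to fill with matrix
#'
#' The earliest stored month at which the matrix density exceeds
#' `threshold` at every depth (the defect reads as "filled" when even its
#' emptiest point holds that fraction of the maximum matrix density).
#'
#' @param traj a `cart_trajectory`.
#' @param threshold fill criterion as a fraction of the maximum matrix
#'   density, in (0, 1); default 0.9.
#' @return The fill time in months, or `NA_real_` if not reached within the
#'   simulated horizon.
#' @export
fill_time <- function(traj, threshold = 0.9) {
  stopifnot(inherits(traj, "cart_trajectory"),
            threshold > 0, threshold < 1)
  mo <- traj_months(traj)
  filled <- apply(traj$fields$m, 1L, min) >= threshold
  if (!any(filled)) return(NA_real_)
  mo[which(filled)[1L]]
}
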