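# Persistence time from the persistent-random-walk (PRW) MSD model
#
#   MSD(t) = n_d * S^2 * P * (t - P * (1 - exp(-t / P)))
#
# with S the cell speed, P the persistence time and n_d the dimensionality
# (2 for migration on a substrate). Short lags are ballistic
# (MSD ~ n_d S^2 t^2 / 2), long lags diffusive (MSD ~ n_d S^2 P t).

#' Persistent-random-walk MSD model
#'
#' @param t Lag time(s), minutes (>= 0).
#' @param S Speed, micrometers per minute.
#' @param P Persistence time, minutes (> 0).
#' @param n_d Dimensionality (default 2).
#' @return Model MSD in square micrometers.
#' @export
prw_msd <- function(t, S, P, n_d = 2) {
  if (any(P <= 0)) stop("persistence time P must be positive", call. = FALSE)
  stopifnot(all(t >= 0))
  n_d * S^2 * P * (t - P * (1 - exp(-t / P)))
}

#' Population-averaged MSD curve in physical units
#'
#' Pools squared displacements over all cells and all overlapping start
#' frames at each lag, then converts to minutes and square micrometers.
#'
#' @param tracks Track tibble (`cell_id`, `frame`, `x`, `y`, pixels).
#' @param config An [acquisition()] object.
#' @param max_lag_frames Largest lag in frames (default: longest available).
#' @param by_cell If TRUE, return one curve per cell instead of pooling.
#' @return Tibble with `t_min`, `msd_um2`, `n_pairs` (plus `cell_id` when
#'   `by_cell = TRUE`).
#' @export
msd_curve <- function(tracks, config = acquisition(), max_lag_frames = NULL,
                      by_cell = FALSE) {
  tracks <- validate_tracks(tracks)
  px2 <- config$pixel_size_um^2
  per_cell <- tracks |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_split() |>
    purrr::map(function(d) {
      m <- msd_track(d)
      m$cell_id <- d$cell_id[1]
      m
    }) |>
    dplyr::bind_rows() |>
    dplyr::filter(!is.na(.data$msd_px2))
  if (!is.null(max_lag_frames)) {
    per_cell <- dplyr::filter(per_cell, .data$lag_frames <= max_lag_frames)
  }
  if (by_cell) {
    return(per_cell |>
             dplyr::transmute(cell_id = .data$cell_id,
                              t_min = .data$lag_frames * config$frame_interval_min,
                              msd_um2 = .data$msd_px2 * px2,
                              n_pairs = .data$n_pairs))
  }
  per_cell |>
    dplyr::group_by(.data$lag_frames) |>
    dplyr::summarise(
      msd_px2 = stats::weighted.mean(.data$msd_px2, .data$n_pairs),
      n_pairs = sum(.data$n_pairs), .groups = "drop") |>
    dplyr::transmute(t_min = .data$lag_frames * config$frame_interval_min,
                     msd_um2 = .data$msd_px2 * px2,
                     n_pairs = .data$n_pairs)
}

#' Fit the PRW model to an MSD curve
#'
#' Unweighted nonlinear least squares over the lag window, with multi-start
#' initialization of P (the model's long plateau in P makes a single start
#' prone to local minima): starts are P in {frame interval, 30, 120, 480}
#' minutes and S from the short-lag ballistic limit of the first point. The
#' best converged start by residual sum of squares wins. A fit whose P
#' estimate reaches the top of the lag window is unidentifiable (a ballistic
#' track looks persistent at every scale the data covers) and is flagged not
#' converged.
#'
#' @param curve Tibble with `t_min` (minutes) and `msd_um2` columns.
#' @param fit_window Lag-time window `c(min, max)` in minutes used for the
#'   fit; default 0-240 (persistence fits conventionally sample lags of up to
#'   a few hours).
#' @param n_d Dimensionality (default 2).
#' @return An object of class `prw_fit`: list with `S` (um/min), `P` (min),
#'   `n_d`, `rss`, `n_lags_used`, `converged`, plus the fitted window and
#'   data. `P` is `NA` when no start converges.
#' @export
fit_persistence <- function(curve, fit_window = c(0, 240), n_d = 2) {
  stopifnot(all(c("t_min", "msd_um2") %in% names(curve)),
            length(fit_window) == 2, fit_window[2] > fit_window[1])
  d <- curve |>
    dplyr::filter(.data$t_min >= fit_window[1], .data$t_min <= fit_window[2],
                  .data$t_min > 0, is.finite(.data$msd_um2))
  if (nrow(d) < 4) {
    stop("need at least 4 MSD points inside the fit window, got ", nrow(d),
         call. = FALSE)
  }
  t1 <- d$t_min[which.min(d$t_min)]
  msd1 <- d$msd_um2[which.min(d$t_min)]
  s0 <- sqrt(max(2 * msd1 / (n_d * t1^2), 1e-12))  # ballistic-limit guess
  starts <- unique(pmin(c(t1, 30, 120, 480), fit_window[2] * 4))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        msd_um2 ~ n_d * S^2 * P * (t_min - P * (1 - exp(-t_min / P))),
        data = d,
        start = list(S = s0, P = p0),
        lower = c(S = 0, P = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                             ptol = 1e-10)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      co <- stats::coef(fit)
      best <- list(S = unname(co["S"]), P = unname(co["P"]), rss = rss)
    }
  }
  if (is.null(best)) {
    out <- list(S = NA_real_, P = NA_real_, n_d = n_d, rss = NA_real_,
                n_lags_used = nrow(d), converged = FALSE,
                fit_window = fit_window, data = d)
  } else {
    identifiable <- best$P < fit_window[2]
    out <- list(S = best$S, P = best$P, n_d = n_d, rss = best$rss,
                n_lags_used = nrow(d), converged = identifiable,
                fit_window = fit_window, data = d)
  }
  class(out) <- "prw_fit"
  out
}

#' @export
print.prw_fit <- function(x, ...) {
  cat("<prw_fit>\n")
  cat(sprintf("  S (speed)           : %.4g um/min\n", x$S))
  cat(sprintf("  P (persistence time): %.4g min\n", x$P))
  cat(sprintf("  lags used: %d in [%g, %g] min; rss = %.4g; converged: %s\n",
              x$n_lags_used, x$fit_window[1], x$fit_window[2], x$rss,
              x$converged))
  invisible(x)
}

#' Fit persistence per cell
#'
#' Runs [fit_persistence()] on each cell's own MSD curve; cells whose curve
#' has too few points inside the window, or where no start converges, get
#' `NA` estimates with `converged = FALSE`.
#'
#' @inheritParams msd_curve
#' @inheritParams fit_persistence
#' @return Tibble with one row per cell: `cell_id`, `S_um_per_min`, `P_min`,
#'   `rss`, `n_lags_used`, `converged`.
#' @export
fit_persistence_per_cell <- function(tracks, config = acquisition(),
                                     fit_window = c(0, 240), n_d = 2) {
  curves <- msd_curve(tracks, config, by_cell = TRUE)
  curves |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_split() |>
    purrr::map(function(d) {
      fit <- tryCatch(fit_persistence(d, fit_window, n_d),
                      error = function(e) NULL)
      if (is.null(fit)) {
        tibble::tibble(cell_id = d$cell_id[1], S_um_per_min = NA_real_,
                       P_min = NA_real_, rss = NA_real_,
                       n_lags_used = nrow(d), converged = FALSE)
      } else {
        tibble::tibble(cell_id = d$cell_id[1], S_um_per_min = fit$S,
                       P_min = fit$P, rss = fit$rss,
                       n_lags_used = fit$n_lags_used, converged = fit$converged)
      }
    }) |>
    dplyr::bind_rows()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PRW persistence fit
#'
#' @param x A `prw_fit` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @method tidy prw_fit
#' @export
tidy.prw_fit <- function(x, ...) {
  tibble::tibble(term = c("S_um_per_min", "P_min"),
                 estimate = c(x$S, x$P))
}

#' One-row summary of a PRW persistence fit
#'
#' @param x A `prw_fit` object.
#' @param ... Unused.
#' @return Tibble with `S_um_per_min`, `P_min`, `n_d`, `rss`, `n_lags_used`,
#'   `converged`.
#' @method glance prw_fit
#' @export
glance.prw_fit <- function(x, ...) {
  tibble::tibble(S_um_per_min = x$S, P_min = x$P, n_d = x$n_d, rss = x$rss,
                 n_lags_used = x$n_lags_used, converged = x$converged)
}
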