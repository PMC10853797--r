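#' Scan plan
#'
#' Defines a systematic grid scan of one spiral parameter. Angular
#' parameters (\code{phi0}, \code{theta_start}, \code{theta_end}) are given
#' in degrees at this interface; lengths in nm.
#'
#' @param parameter One of \code{"r"}, \code{"p"}, \code{"phi0"},
#'   \code{"center_x"}, \code{"center_y"}, \code{"center_z"},
#'   \code{"theta_start"}, \code{"theta_end"}, \code{"h"}.
#' @param lo,hi Scan bounds (lo < hi).
#' @param step Grid step (> 0).
#' @param objective \code{"per_atom"} (default; comparable across radii
#'   where point counts differ) or \code{"total"}.
#' @return An object of class \code{"scan_plan"}.
#' @export
scan_plan <- function(parameter, lo, hi, step,
                      objective = c("per_atom", "total")) {
  parameter <- match.arg(parameter, c("r", "p", "phi0", "center_x",
                                      "center_y", "center_z",
                                      "theta_start", "theta_end", "h"))
  objective <- match.arg(objective)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("scan_plan: lo must be < hi", call. = FALSE)
  if (!is.finite(step) || step <= 0)
    stop("scan_plan: step must be > 0", call. = FALSE)
  if ((hi - lo) / step > 1e6)
    stop("scan_plan: more than 1e6 grid values", call. = FALSE)
  structure(list(parameter = parameter, lo = lo, hi = hi, step = step,
                 objective = objective), class = "scan_plan")
}

plan_values <- function(plan) seq(plan$lo, plan$hi, by = plan$step)

angular_param <- function(parameter)
  parameter %in% c("phi0", "theta_start", "theta_end")

# set one scan parameter (interface units: deg for angles) on a spec
set_spec_param <- function(spec, parameter, value) {
  v <- if (angular_param(parameter)) value * pi / 180 else value
  switch(parameter,
         r = { spec$r <- v; spec },
         p = { spec$p <- v; spec },
         phi0 = { spec$phi0 <- v; spec },
         h = { spec$h <- v; spec },
         theta_start = { spec$theta_start <- v; spec },
         theta_end = { spec$theta_end <- v; spec },
         center_x = { spec$center[1] <- v; spec },
         center_y = { spec$center[2] <- v; spec },
         center_z = { spec$center[3] <- v; spec })
}

get_spec_param <- function(spec, parameter) {
  v <- switch(parameter,
              r = spec$r, p = spec$p, phi0 = spec$phi0, h = spec$h,
              theta_start = spec$theta_start, theta_end = spec$theta_end,
              center_x = spec$center[1], center_y = spec$center[2],
              center_z = spec$center[3])
  if (angular_param(parameter)) v * 180 / pi else v
}

objective_value <- function(fit, objective)
  if (objective == "total") fit$energy_total else fit$energy_per_atom

#' Systematic scan of one spiral parameter
#'
#' Evaluates the fitting energy of the (multi-entry) trace generated from
#' \code{base} at every grid value of one parameter, in ascending order.
#' The best value is the lowest objective; exact ties break toward the
#' lowest parameter value, so scanning is fully deterministic. phi0 scans
#' are taken modulo 360/n_entries degrees, the period of a multi-start
#' family.
#'
#' @param base A \code{\link{spiral_spec}}: all parameters except the
#'   scanned one.
#' @param plan A \code{\link{scan_plan}}.
#' @param grid A \code{\link{density_grid}}.
#' @return A data.frame of class \code{"scan_result"} with columns
#'   \code{value} (interface units), \code{energy_total},
#'   \code{energy_per_atom}, \code{n_points}, \code{outside_fraction},
#'   \code{objective}; attributes \code{best} (row index of the argmin)
#'   and \code{plan}.
#' @export
scan_parameter <- function(base, plan, grid) {
  validate_spiral_spec(base)
  stopifnot(inherits(plan, "scan_plan"), inherits(grid, "density_grid"))
  vals <- plan_values(plan)
  rows <- lapply(vals, function(v) {
    fit <- fitting_energy(make_trace(set_spec_param(base, plan$parameter, v)),
                          grid)
    data.frame(value = v, energy_total = fit$energy_total,
               energy_per_atom = fit$energy_per_atom,
               n_points = fit$n_points,
               outside_fraction = fit$outside_fraction)
  })
  res <- do.call(rbind, rows)
  if (all(res$outside_fraction == 1))
    stop(paste("scan_parameter: every trace lies fully outside the map;",
               "check center and extent"), call. = FALSE)
  res$objective <- if (plan$objective == "total") res$energy_total else
    res$energy_per_atom
  attr(res, "best") <- which.min(res$objective)  # first minimum = lowest value
  attr(res, "plan") <- plan
  class(res) <- c("scan_result", "data.frame")
  res
}

#' @export
print.scan_result <- function(x, ...) {
  plan <- attr(x, "plan")
  b <- attr(x, "best")
  cat(sprintf("<scan_result: %s in [%g, %g] step %g, %d evaluations>\n",
              plan$parameter, plan$lo, plan$hi, plan$step, nrow(x)))
  cat(sprintf("  best %s = %g (objective %s = %.6g)\n",
              plan$parameter, x$value[b], plan$objective, x$objective[b]))
  invisible(x)
}

#' Best value of a scan
#'
#' @param result A \code{scan_result}.
#' @return The parameter value at the argmin (interface units).
#' @export
scan_best <- function(result) result$value[attr(result, "best")]

#' Coordinate descent over spiral parameters
#'
#' Cycles through the given scan plans, updating the spec to each scan's
#' argmin (the protocol used for tracing noisy maps: at each local minimum
#' of r, optimize phi0, then r again). Stops when a full round moves no
#' parameter by more than its own step, or after \code{max_rounds} rounds
#' (then flagged unconverged, not an error).
#'
#' @param base Starting \code{\link{spiral_spec}}.
#' @param plans List of \code{\link{scan_plan}}s, applied in order within
#'   each round.
#' @param grid A \code{\link{density_grid}}.
#' @param max_rounds Maximum number of full rounds.
#' @return A list of class \code{"descent_result"}: \code{spec} (final),
#'   \code{fit} (final \code{fit_result}), \code{converged},
#'   \code{rounds}, and \code{trail} (data.frame: round, parameter, value,
#'   objective).
#' @export
coordinate_descent <- function(base, plans, grid, max_rounds = 10L) {
  if (inherits(plans, "scan_plan")) plans <- list(plans)
  if (length(plans) < 1L)
    stop("coordinate_descent: need at least one scan_plan", call. = FALSE)
  spec <- base
  trail <- list()
  converged <- FALSE
  round <- 0L
  while (round < max_rounds && !converged) {
    round <- round + 1L
    moved <- FALSE
    for (plan in plans) {
      old <- get_spec_param(spec, plan$parameter)
      res <- scan_parameter(spec, plan, grid)
      new <- scan_best(res)
      if (abs(new - old) > plan$step) moved <- TRUE
      spec <- set_spec_param(spec, plan$parameter, new)
      trail[[length(trail) + 1L]] <-
        data.frame(round = round, parameter = plan$parameter, value = new,
                   objective = res$objective[attr(res, "best")])
    }
    if (!moved) converged <- TRUE
  }
  fit <- fitting_energy(make_trace(spec), grid)
  structure(list(spec = spec, fit = fit, converged = converged,
                 rounds = round, trail = do.call(rbind, trail)),
            class = "descent_result")
}

#' @export
print.descent_result <- function(x, ...) {
  cat(sprintf("<descent_result: %s after %d round(s)>\n",
              if (x$converged) "converged" else "NOT converged", x$rounds))
  print(x$fit)
  invisible(x)
}

#' Detect winding shells from an energy-versus-radius curve
#'
#' Scans r over \code{r_plan}, finds discrete local minima of the
#' objective curve whose prominence is at least
#' \code{min_prominence * (max - min)} of the curve, and refines each
#' shell with a local phi0 scan (over one period 360/n_entries degrees).
#' Concentric spooled DNA shows up as near-equally spaced minima; the mean
#' consecutive spacing is reported.
#'
#' @param base A \code{\link{spiral_spec}} providing all non-scanned
#'   parameters.
#' @param r_plan A \code{\link{scan_plan}} with \code{parameter = "r"}.
#' @param grid A \code{\link{density_grid}}.
#' @param min_prominence Prominence threshold as a fraction of the curve's
#'   total range. Default 0.05.
#' @param phi0_step Step of the per-shell phi0 refinement, degrees.
#' @return A data.frame of class \code{"shell_table"} with columns
#'   \code{shell}, \code{r}, \code{phi0} (deg), \code{energy}
#'   (objective after phi0 refinement); attributes \code{spacing} (mean
#'   consecutive radius difference, NA for < 2 shells) and \code{scan}
#'   (the full r scan).
#' @export
detect_shells <- function(base, r_plan, grid, min_prominence = 0.05,
                          phi0_step = 2) {
  stopifnot(inherits(r_plan, "scan_plan"))
  if (r_plan$parameter != "r")
    stop("detect_shells: r_plan must scan parameter 'r'", call. = FALSE)
  scan <- scan_parameter(base, r_plan, grid)
  e <- scan$objective
  mins <- local_minima_prominent(e, min_prominence * (max(e) - min(e)))
  if (length(mins) == 0L) {
    warning("detect_shells: no prominent minima in the energy-vs-r curve",
            call. = FALSE)
    tab <- data.frame(shell = integer(), r = numeric(), phi0 = numeric(),
                      energy = numeric())
  } else {
    period <- 360 / base$n_entries
    rows <- lapply(seq_along(mins), function(i) {
      r_i <- scan$value[mins[i]]
      spec_i <- set_spec_param(base, "r", r_i)
      pscan <- scan_parameter(
        spec_i, scan_plan("phi0", 0, period - phi0_step / 2, phi0_step,
                          objective = r_plan$objective), grid)
      data.frame(shell = i, r = r_i, phi0 = scan_best(pscan),
                 energy = pscan$objective[attr(pscan, "best")])
    })
    tab <- do.call(rbind, rows)
  }
  attr(tab, "spacing") <- if (nrow(tab) >= 2L) mean(diff(tab$r)) else
    NA_real_
  attr(tab, "scan") <- scan
  class(tab) <- c("shell_table", "data.frame")
  tab
}

#' @export
print.shell_table <- function(x, ...) {
  cat(sprintf("<shell_table: %d shell(s), mean spacing %s nm>\n", nrow(x),
              if (is.na(attr(x, "spacing"))) "NA" else
                sprintf("%.3f", attr(x, "spacing"))))
  print.data.frame(x)
  invisible(x)
}

# indices of local minima of e with prominence >= thresh.
# Prominence of a minimum: the smaller, over the two sides, of the climb
# from the minimum to the highest point reached before meeting a deeper
# minimum (or the curve end).
local_minima_prominent <- function(e, thresh) {
  n <- length(e)
  if (n < 3L) return(integer())
  cand <- which(e[2:(n - 1)] < e[1:(n - 2)] & e[2:(n - 1)] <= e[3:n]) + 1L
  keep <- vapply(cand, function(i) {
    left <- e[seq_len(i - 1)]
    right <- e[seq.int(i + 1, n)]
    climb_l <- prominence_side(rev(left), e[i])
    climb_r <- prominence_side(right, e[i])
    min(climb_l, climb_r) >= thresh
  }, logical(1))
  cand[keep]
}

prominence_side <- function(side, v) {
  deeper <- which(side < v)
  stop_at <- if (length(deeper)) deeper[1] - 1L else length(side)
  if (stop_at == 0L) return(0)
  max(side[seq_len(stop_at)]) - v
}

#' Export scan results as CSV
#'
#' @param result A \code{scan_result}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_scan_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
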