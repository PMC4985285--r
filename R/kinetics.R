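#' Dilution series for a kinetics titration
#'
#' Ascending analyte concentrations `top / factor^(steps-1-i)`, the series
#' injected in a single-cycle kinetics run (default two-fold from the top).
#'
#' @param top Top (highest) concentration, molar.
#' @param steps Number of concentrations.
#' @param factor Dilution factor between consecutive steps.
#' @return Ascending numeric vector of length `steps`.
#' @examples
#' dilution_series(50e-9, 5)  # 3.125 to 50 nM
#' @export
dilution_series <- function(top, steps, factor = 2) {
  stopifnot(top > 0, steps >= 1, factor > 0)
  top / factor^((steps - 1):0)
}

#' Single-cycle kinetics protocol
#'
#' Sequential injections of ascending analyte concentrations without
#' surface regeneration: each association phase is followed by a short
#' dissociation gap, and the last injection by an extended final
#' dissociation from which the off-rate is best constrained.
#'
#' @param concentrations Strictly positive, strictly ascending molar
#'   concentrations (default the 3.125-50 nM two-fold series).
#' @param t_assoc Association duration per injection, s.
#' @param t_gap Inter-injection dissociation, s.
#' @param t_final Final dissociation, s.
#' @return An `sck_protocol` object.
#' @export
sck_protocol <- function(concentrations = dilution_series(50e-9, 5),
                         t_assoc = 120, t_gap = 10, t_final = 600) {
  stopifnot(all(concentrations > 0), !is.unsorted(concentrations,
                                                  strictly = TRUE),
            t_assoc > 0, t_gap >= 0, t_final > 0)
  structure(list(concentrations = concentrations, t_assoc = t_assoc,
                 t_gap = t_gap, t_final = t_final),
            class = "sck_protocol")
}

# phase table: one row per phase with start time, duration, concentration
# (0 during dissociation), label
protocol_phases <- function(protocol) {
  conc <- protocol$concentrations
  n <- length(conc)
  phases <- list()
  t0 <- 0
  for (i in seq_len(n)) {
    phases[[length(phases) + 1L]] <-
      data.frame(label = sprintf("assoc%d", i), start = t0,
                 duration = protocol$t_assoc, conc = conc[i])
    t0 <- t0 + protocol$t_assoc
    if (i < n && protocol$t_gap > 0) {
      phases[[length(phases) + 1L]] <-
        data.frame(label = sprintf("dissoc%d", i), start = t0,
                   duration = protocol$t_gap, conc = 0)
      t0 <- t0 + protocol$t_gap
    }
  }
  phases[[length(phases) + 1L]] <-
    data.frame(label = "dissoc_final", start = t0,
               duration = protocol$t_final, conc = 0)
  do.call(rbind, phases)
}

# closed-form 1:1 Langmuir response on a time grid, phase boundaries exact:
# association from level R0 at concentration C relaxes to
# Req = kon*C*Rmax / (kon*C + koff) with rate (kon*C + koff);
# dissociation decays as R0 * exp(-koff * t)
langmuir_response <- function(times, protocol, kon, koff, Rmax,
                              bulk_shift = 0) {
  ph <- protocol_phases(protocol)
  resp <- numeric(length(times))
  phase_lab <- character(length(times))
  R0 <- 0
  for (i in seq_len(nrow(ph))) {
    t_start <- ph$start[i]
    t_end <- t_start + ph$duration[i]
    last <- i == nrow(ph)
    sel <- times >= t_start & (if (last) times <= t_end else times < t_end)
    dt <- times[sel] - t_start
    C <- ph$conc[i]
    if (C > 0) {
      kobs <- kon * C + koff
      Req <- kon * C * Rmax / kobs
      resp[sel] <- Req + (R0 - Req) * exp(-kobs * dt)
      bulk <- bulk_shift
    } else {
      resp[sel] <- R0 * exp(-koff * dt)
      bulk <- 0
    }
    resp[sel] <- resp[sel] + bulk
    phase_lab[sel] <- ph$label[i]
    # carry the binding level (without bulk) across the phase boundary
    dt_end <- t_end - t_start
    R0 <- if (C > 0) {
      kobs <- kon * C + koff
      Req <- kon * C * Rmax / kobs
      Req + (R0 - Req) * exp(-kobs * dt_end)
    } else R0 * exp(-koff * dt_end)
  }
  list(response = resp, phase = phase_lab)
}

#' Simulate a single-cycle kinetics sensorgram
#'
#' Piecewise closed-form 1:1 Langmuir binding under an SCK protocol, with
#' optional additive Gaussian noise and a per-injection bulk
#' refractive-index step (a constant added during association phases only,
#' zero by default; bulk steps do not alter the off-rate information).
#'
#' @param protocol An [sck_protocol()].
#' @param kon Association rate constant, 1/(M s).
#' @param koff Dissociation rate constant, 1/s.
#' @param Rmax Saturation response, RU.
#' @param sampling_rate Samples per second (default 1 Hz).
#' @param noise_sd Additive Gaussian noise, RU.
#' @param bulk_shift Bulk step during injections, RU.
#' @param seed Seed used when `noise_sd > 0`.
#' @return A `sensorgram`: data.frame with `time`, `response`, `phase`.
#' @export
simulate_sck <- function(protocol, kon, koff, Rmax, sampling_rate = 1,
                         noise_sd = 0, bulk_shift = 0, seed = 1L) {
  stopifnot(kon > 0, koff >= 0, Rmax > 0, sampling_rate > 0)
  ph <- protocol_phases(protocol)
  total <- ph$start[nrow(ph)] + ph$duration[nrow(ph)]
  times <- seq(0, total, by = 1 / sampling_rate)
  lr <- langmuir_response(times, protocol, kon, koff, Rmax, bulk_shift)
  resp <- lr$response
  if (noise_sd > 0) {
    set.seed(seed)
    resp <- resp + rnorm(length(resp), 0, noise_sd)
  }
  structure(data.frame(time = times, response = resp, phase = lr$phase,
                       stringsAsFactors = FALSE),
            class = c("sensorgram", "data.frame"), protocol = protocol)
}

#' Subtract a reference channel
#'
#' Differential response: sample minus empty reference channel, point by
#' point. Bulk steps present in both channels cancel in the difference.
#'
#' @param sample,reference `sensorgram`s on identical time grids.
#' @return The differential `sensorgram`.
#' @export
subtract_reference <- function(sample, reference) {
  if (nrow(sample) != nrow(reference) ||
      any(abs(sample$time - reference$time) > 1e-9))
    stop("sample and reference must share an identical time grid")
  sample$response <- sample$response - reference$response
  sample
}

#' KD from rate constants
#'
#' Equilibrium dissociation constant as the off-rate over on-rate ratio.
#'
#' @param kon Association rate constant, 1/(M s) (> 0).
#' @param koff Dissociation rate constant, 1/s.
#' @return KD in molar.
#' @examples
#' kd_from_rates(1.79e5, 1.63e-4)
#' @export
kd_from_rates <- function(kon, koff) {
  stopifnot(kon > 0, koff >= 0)
  koff / kon
}

# initial-guess heuristic: koff from the log-linear slope of the terminal
# dissociation, Rmax from the span, kon from the initial association slope
fit_initial_guess <- function(sensorgram, protocol) {
  fin <- sensorgram[sensorgram$phase == "dissoc_final", ]
  koff0 <- 1e-3
  if (nrow(fin) > 10) {
    pos <- fin$response > max(fin$response, 1e-6) * 1e-3
    if (sum(pos) > 10) {
      sl <- coef(lm(log(fin$response[pos]) ~ fin$time[pos]))[[2L]]
      if (is.finite(sl) && sl < 0) koff0 <- min(max(-sl, 1e-7), 1)
    }
  }
  Rmax0 <- max(sensorgram$response) * 3
  a1 <- sensorgram[sensorgram$phase == "assoc1", ]
  kon0 <- 1e5
  if (nrow(a1) > 5) {
    k <- min(nrow(a1), 20L)
    slope <- coef(lm(a1$response[1:k] ~ a1$time[1:k]))[[2L]]
    C1 <- protocol$concentrations[1L]
    if (is.finite(slope) && slope > 0)
      kon0 <- min(max(slope / (C1 * Rmax0), 1e2), 1e8)
  }
  c(kon = kon0, koff = koff0, Rmax = Rmax0)
}

#' Fit the 1:1 Langmuir model to an SCK sensorgram
#'
#' Nonlinear least squares over (kon, koff, Rmax) in log-parameter space
#' (rates span orders of magnitude). Initial values come from a documented
#' heuristic (terminal-dissociation slope for koff, initial association
#' slope for kon) unless supplied. Non-convergence raises an error with
#' diagnostics rather than returning a best-so-far.
#'
#' @param sensorgram A `sensorgram` (time/response/phase).
#' @param protocol The [sck_protocol()] it was acquired under.
#' @param initial_guess Optional named vector `c(kon=, koff=, Rmax=)`.
#' @param fit_bulk Also float a per-injection bulk constant (off by
#'   default).
#' @param max_iter Maximum optimizer iterations.
#' @param tol Convergence tolerance passed to the optimizer.
#' @return A `kinetic_fit` list: `kon`, `koff`, `Rmax`, `kd`,
#'   `residual_norm`, `initial`, `converged`, `bulk`.
#' @export
fit_1to1 <- function(sensorgram, protocol, initial_guess = NULL,
                     fit_bulk = FALSE, max_iter = 500L, tol = 1e-12) {
  stopifnot(inherits(protocol, "sck_protocol"))
  times <- sensorgram$time
  obs <- sensorgram$response
  init <- initial_guess %||% fit_initial_guess(sensorgram, protocol)
  stopifnot(all(c("kon", "koff", "Rmax") %in% names(init)), all(init > 0))

  model <- function(lkon, lkoff, lRmax, bulk = 0) {
    langmuir_response(times, protocol, exp(lkon), exp(lkoff), exp(lRmax),
                      bulk_shift = bulk)$response
  }
  df <- data.frame(obs = obs)
  fit <- NULL
  start <- list(lkon = log(init[["kon"]]), lkoff = log(init[["koff"]]),
                lRmax = log(init[["Rmax"]]))
  form <- if (fit_bulk) obs ~ model(lkon, lkoff, lRmax, bulk) else
    obs ~ model(lkon, lkoff, lRmax)
  if (fit_bulk) start$bulk <- 0
  fit <- tryCatch(
    nls(form, data = df, start = start, algorithm = "port",
        control = nls.control(maxiter = max_iter, tol = tol,
                              warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # fall back to direct least squares on the same objective
    obj <- function(p) {
      r <- obs - model(p[1], p[2], p[3], if (fit_bulk) p[4] else 0)
      sum(r * r)
    }
    p0 <- unlist(start)
    opt <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    opt <- optim(opt$par, obj, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-14))
    if (opt$convergence != 0)
      stop("1:1 Langmuir fit did not converge (optim code ",
           opt$convergence, ", residual SS ", format(opt$value),
           ", start kon=", format(init[["kon"]]),
           " koff=", format(init[["koff"]]), ")")
    p <- opt$par
    rn <- sqrt(opt$value)
    bulk <- if (fit_bulk) p[[4L]] else 0
    p <- exp(p[1:3])
  } else {
    cf <- coef(fit)
    p <- exp(cf[c("lkon", "lkoff", "lRmax")])
    bulk <- if (fit_bulk) cf[["bulk"]] else 0
    rn <- sqrt(sum(stats::resid(fit)^2))
  }
  out <- list(kon = unname(p[1]), koff = unname(p[2]), Rmax = unname(p[3]),
              kd = unname(p[2] / p[1]), residual_norm = rn,
              initial = init, converged = TRUE, bulk = bulk)
  stopifnot(abs(out$kon * out$kd - out$koff) <= 1e-12 * out$koff)
  structure(out, class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "1:1 Langmuir fit: kon = %.3g 1/(M s), koff = %.3g 1/s, Rmax = %.3g RU\n",
    x$kon, x$koff, x$Rmax))
  cat(sprintf("  KD = %.3g M, residual norm = %.3g RU\n", x$kd,
              x$residual_norm))
  invisible(x)
}
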