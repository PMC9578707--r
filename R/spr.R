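#' Simulate 1:1 Langmuir SPR sensorgrams
#'
#' Closed-form 1:1 binding model. During association at analyte
#' concentration C,
#' `R(t) = Req * (1 - exp(-(kon*C + koff) * t))` with
#' `Req = Rmax * C / (C + KD)` and `KD = koff/kon`; during dissociation,
#' `R(t) = R(t_assoc) * exp(-koff * (t - t_assoc))`. Additive Gaussian noise
#' of standard deviation `noise_sd` models instrument noise on pre-referenced
#' traces.
#'
#' @param kon association rate constant, 1/(M s).
#' @param koff dissociation rate constant, 1/s.
#' @param rmax maximal response, RU.
#' @param concentrations analyte concentrations, M (typically a twofold
#'   dilution series).
#' @param t_assoc,t_dissoc association and dissociation durations, s.
#' @param dt sampling interval, s.
#' @param noise_sd noise standard deviation, RU (default 0).
#' @return data.frame of class `sensorgrams` with columns `time`, `response`,
#'   `concentration`, `phase`.
#' @examples
#' tr <- simulate_sensorgram(1e5, 7e-3, 100, c(35e-9, 70e-9, 140e-9))
#' head(tr)
#' @export
simulate_sensorgram <- function(kon, koff, rmax, concentrations,
                                t_assoc = 300, t_dissoc = 300, dt = 1,
                                noise_sd = 0) {
  if (kon <= 0 || koff <= 0 || rmax <= 0) stop("rate parameters must be > 0")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  kd <- koff / kon
  out <- lapply(concentrations, function(C) {
    t_a <- seq(0, t_assoc, by = dt)
    t_d <- seq(t_assoc + dt, t_assoc + t_dissoc, by = dt)
    req <- rmax * C / (C + kd)
    r_a <- req * (1 - exp(-(kon * C + koff) * t_a))
    r_end <- req * (1 - exp(-(kon * C + koff) * t_assoc))
    r_d <- r_end * exp(-koff * (t_d - t_assoc))
    data.frame(time = c(t_a, t_d), response = c(r_a, r_d),
               concentration = C,
               phase = c(rep("association", length(t_a)),
                         rep("dissociation", length(t_d))))
  })
  out <- do.call(rbind, out)
  if (noise_sd > 0)
    out$response <- out$response + stats::rnorm(nrow(out), sd = noise_sd)
  attr(out, "t_assoc") <- t_assoc
  class(out) <- c("sensorgrams", "data.frame")
  out
}

langmuir_response <- function(kon, koff, rmax, time, conc, t_assoc) {
  kd <- koff / kon
  req <- rmax * conc / (conc + kd)
  r_end <- req * (1 - exp(-(kon * conc + koff) * t_assoc))
  ifelse(time <= t_assoc,
         req * (1 - exp(-(kon * conc + koff) * time)),
         r_end * exp(-koff * (time - t_assoc)))
}

#' Fit a 1:1 Langmuir model to a sensorgram series
#'
#' Global nonlinear least squares over all concentration traces
#' simultaneously (shared kon, koff, Rmax), on log-parameters so positivity
#' is guaranteed, using Levenberg-Marquardt with multi-start initialization
#' (log-spaced kon starts; koff seeded from a log-linear fit of the
#' dissociation tails). The best of the converged starts is returned.
#'
#' If the traces contain no association-phase data, kon is unidentifiable:
#' koff is fit from the decay alone and kon/KD are reported as `NA` with
#' `kon_identifiable = FALSE`.
#'
#' @param traces a `sensorgrams` data.frame (columns `time`, `response`,
#'   `concentration`, `phase`; attribute or argument `t_assoc`).
#' @param t_assoc end of the association phase, s (taken from the traces'
#'   attribute when absent).
#' @param n_starts number of log-spaced kon starts (default 8).
#' @return Object of class `kinetics_fit` with elements `kon`, `koff`, `kd`,
#'   `rmax`, `rss`, `kon_identifiable`, `n_traces`.
#' @export
fit_kinetic <- function(traces, t_assoc = NULL, n_starts = 8) {
  traces <- as.data.frame(traces)
  req_cols <- c("time", "response", "concentration")
  if (!all(req_cols %in% names(traces)))
    stop("traces need columns time, response, concentration")
  if (is.null(t_assoc)) t_assoc <- attr(traces, "t_assoc")
  if (is.null(t_assoc)) {
    if (!"phase" %in% names(traces))
      stop("supply t_assoc or a phase column")
    t_assoc <- max(traces$time[traces$phase == "association"], 0)
  }

  has_assoc <- any(traces$time <= t_assoc & traces$response != 0)
  dis <- traces[traces$time > t_assoc & traces$response > 0, , drop = FALSE]

  # seed koff from log-linear decay of the dissociation tails
  koff0 <- 1e-2
  if (nrow(dis) > 3) {
    sl <- unname(stats::coef(stats::lm(log(response) ~ time, data = dis))[2])
    if (is.finite(sl) && sl < 0) koff0 <- -sl
  }

  if (!has_assoc) {
    fit <- minpack.lm::nls.lm(
      par = list(lk = log(koff0), lA = log(max(dis$response))),
      fn = function(p) {
        dis$response - exp(p$lA) * exp(-exp(p$lk) * (dis$time - t_assoc))
      })
    koff <- exp(fit$par$lk)
    out <- list(kon = NA_real_, koff = koff, kd = NA_real_, rmax = NA_real_,
                rss = sum(fit$fvec^2), kon_identifiable = FALSE,
                n_traces = length(unique(traces$concentration)))
    class(out) <- "kinetics_fit"
    return(out)
  }

  resid_fn <- function(p) {
    traces$response - langmuir_response(exp(p[1]), exp(p[2]), exp(p[3]),
                                        traces$time, traces$concentration,
                                        t_assoc)
  }
  rmax0 <- max(traces$response) * 1.2
  kon_starts <- 10^seq(3, 7, length.out = n_starts)
  best <- NULL
  for (k0 in kon_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(log(k0), log(koff0), log(rmax0)),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("kinetic fit failed to converge from any start; check trace quality ",
         "and t_assoc")
  p <- unname(exp(best$fit$par))
  out <- list(kon = p[1], koff = p[2], kd = p[2] / p[1], rmax = p[3],
              rss = best$rss, kon_identifiable = TRUE,
              n_traces = length(unique(traces$concentration)))
  class(out) <- "kinetics_fit"
  out
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("1:1 Langmuir kinetic fit\n")
  if (x$kon_identifiable) {
    cat(sprintf("  kon  = %.4g 1/(M s)\n  koff = %.4g 1/s\n  KD   = %.4g M\n  Rmax = %.4g RU\n",
                x$kon, x$koff, x$kd, x$rmax))
  } else {
    cat(sprintf("  koff = %.4g 1/s (dissociation-only data: kon/KD unidentifiable)\n",
                x$koff))
  }
  cat(sprintf("  RSS = %.4g over %d trace(s)\n", x$rss, x$n_traces))
  invisible(x)
}

#' @export
coef.kinetics_fit <- function(object, ...) {
  c(kon = object$kon, koff = object$koff, kd = object$kd, rmax = object$rmax)
}

#' Steady-state (equilibrium) binding fit
#'
#' Least-squares fit of the binding isotherm
#' `Req(C) = Rmax * C / (C + KD)` to equilibrium responses at a series of
#' analyte concentrations. When the fitted KD lies above the highest tested
#' concentration the curve never approaches saturation and the fit is
#' flagged `underdetermined`.
#'
#' @param concentrations analyte concentrations, M (>= 3 recommended,
#'   spanning KD).
#' @param responses equilibrium responses, RU.
#' @return Object of class `steady_state_fit` with `kd`, `rmax`, `rss`,
#'   `underdetermined`.
#' @export
fit_steady_state <- function(concentrations, responses) {
  if (length(concentrations) != length(responses))
    stop("concentrations and responses differ in length")
  if (length(concentrations) < 2) stop("need >= 2 concentrations")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  fit <- minpack.lm::nls.lm(
    par = c(lkd = log(stats::median(concentrations)),
            lrmax = log(max(responses) * 1.5)),
    fn = function(p) {
      responses - exp(p[2]) * concentrations / (concentrations + exp(p[1]))
    },
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15))
  kd <- exp(fit$par[[1]])
  rmax <- exp(fit$par[[2]])
  out <- list(kd = kd, rmax = rmax, rss = sum(fit$fvec^2),
              underdetermined = kd > max(concentrations))
  class(out) <- "steady_state_fit"
  out
}

#' @export
print.steady_state_fit <- function(x, ...) {
  cat(sprintf("Steady-state binding fit: KD = %.4g M, Rmax = %.4g RU, RSS = %.4g\n",
              x$kd, x$rmax, x$rss))
  if (x$underdetermined)
    cat("  warning: KD exceeds the highest tested concentration; ",
        "fit is underdetermined\n")
  invisible(x)
}

#' @export
coef.steady_state_fit <- function(object, ...) {
  c(kd = object$kd, rmax = object$rmax)
}

#' Write a kinetic or steady-state fit report as JSON
#'
#' @param fit a `kinetics_fit` or `steady_state_fit`.
#' @param path output file.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, c("kinetics_fit", "steady_state_fit")))
  jsonlite::write_json(c(list(model = if (inherits(fit, "kinetics_fit"))
    "langmuir_1to1_kinetic" else "steady_state"), unclass(fit)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write sensorgram TSV files
#'
#' Columns: `time`, `response`, `concentration`, `phase`.
#'
#' @param path TSV path.
#' @return A `sensorgrams` data.frame.
#' @export
read_sensorgrams <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("time", "response", "concentration") %in% names(df)))
    stop("sensorgram file needs time, response, concentration columns")
  if ("phase" %in% names(df))
    attr(df, "t_assoc") <- max(df$time[df$phase == "association"], 0)
  class(df) <- c("sensorgrams", "data.frame")
  df
}

#' @rdname read_sensorgrams
#' @param traces a `sensorgrams` data.frame.
#' @export
write_sensorgrams <- function(traces, path) {
  utils::write.table(as.data.frame(traces), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
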