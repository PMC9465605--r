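#' In-vitro microdialysis recovery
#'
#' Relative recovery of a probe from a beaker experiment: mean dialysate
#' concentration divided by mean beaker (bulk) concentration.
#'
#' @param dialysate Dialysate sample concentrations (any common unit).
#' @param beaker Beaker reference concentrations (same unit).
#' @return Recovery fraction.
#' @examples
#' recovery_from_beaker(c(138, 142), c(995, 1005))  # 0.14
#' @export
recovery_from_beaker <- function(dialysate, beaker) {
  if (!length(dialysate) || !length(beaker))
    stop("recovery_from_beaker: empty input")
  if (any(!is.finite(dialysate)) || any(!is.finite(beaker)))
    stop("recovery_from_beaker: non-finite input")
  if (any(dialysate < 0)) stop("recovery_from_beaker: negative dialysate")
  mb <- mean(beaker)
  if (mb <= 0) stop("recovery_from_beaker: beaker mean must be positive")
  mean(dialysate) / mb
}

#' Recovery-correct dialysate concentrations
#'
#' Converts measured dialysate concentrations to the surrounding ISF
#' concentration by dividing by the (time-invariant) in-vitro recovery.
#'
#' @param dialysate_conc Dialysate concentrations (nM).
#' @param recovery Recovery fraction in (0, 1].
#' @return ISF concentrations (nM).
#' @export
apply_recovery <- function(dialysate_conc, recovery) {
  if (!is.finite(recovery) || recovery <= 0 || recovery > 1)
    stop("apply_recovery: recovery must lie in (0, 1]")
  if (any(dialysate_conc < 0, na.rm = TRUE))
    stop("apply_recovery: negative dialysate concentration")
  dialysate_conc / recovery
}

#' Interval-average dialysate sampling of a simulation
#'
#' Microdialysate collected over an interval reflects the time-average of
#' the surrounding concentration, attenuated by the probe recovery. For
#' each collection window this returns `recovery` times the trapezoidal
#' time-average of the compartment concentration, stamped at the window
#' midpoint. Probe kinetics and lag are neglected.
#'
#' @param sim An `rpbpk_sim`.
#' @param compartment Compartment id, typically `"brain_isf"`.
#' @param windows Two-column matrix (or data.frame) of window start/end
#'   times (h); non-overlapping, ascending, within the simulation span.
#' @param recovery Recovery fraction in (0, 1].
#' @return data.frame with `t_mid`, `t0`, `t1`, `conc_dialysate` (nM).
#' @examples
#' sim <- simulate_rpbpk(phys_params(), drug_egfrviii_tcb(),
#'                       iv_bolus(15, 0.310, 195000))
#' window_average_sampling(sim, "brain_isf", dialysate_windows(), 0.14)
#' @export
window_average_sampling <- function(sim, compartment, windows, recovery) {
  stopifnot(inherits(sim, "rpbpk_sim"))
  if (!is.finite(recovery) || recovery <= 0 || recovery > 1)
    stop("window_average_sampling: recovery must lie in (0, 1]")
  windows <- as.matrix(windows)
  if (ncol(windows) != 2) stop("window_average_sampling: windows need 2 columns")
  if (any(windows[, 2] <= windows[, 1]))
    stop("window_average_sampling: window end must exceed start")
  if (nrow(windows) > 1) {
    if (is.unsorted(windows[, 1]))
      stop("window_average_sampling: windows must be ascending")
    if (any(windows[-1, 1] < windows[-nrow(windows), 2] - 1e-12))
      stop("window_average_sampling: windows overlap")
  }
  if (min(windows) < min(sim$t) - 1e-12 || max(windows) > max(sim$t) + 1e-12)
    stop("window_average_sampling: window outside the simulation span")
  conc <- sim_conc(sim, compartment)
  t <- sim$t
  avg <- vapply(seq_len(nrow(windows)), function(i) {
    w0 <- windows[i, 1]; w1 <- windows[i, 2]
    # trapezoid over the window with interpolated endpoints
    inside <- t > w0 & t < w1
    tt <- c(w0, t[inside], w1)
    cc <- c(stats::approx(t, conc, w0)$y, conc[inside],
            stats::approx(t, conc, w1)$y)
    auc_trapezoid(tt, pmax(cc, 0)) / (w1 - w0)
  }, 1.0)
  data.frame(t_mid = rowMeans(windows), t0 = windows[, 1], t1 = windows[, 2],
             conc_dialysate = recovery * avg)
}

#' Study dialysate collection windows
#'
#' 30-minute collection intervals for the first 8 h post-dose, 4-hour
#' intervals from 8 h to 48 h (16 + 10 = 26 windows).
#'
#' @return 26 x 2 matrix of window start/end times (h).
#' @export
dialysate_windows <- function() {
  early <- cbind(seq(0, 7.5, by = 0.5), seq(0.5, 8, by = 0.5))
  late <- cbind(seq(8, 44, by = 4), seq(12, 48, by = 4))
  w <- rbind(early, late)
  colnames(w) <- c("t0", "t1")
  w
}
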