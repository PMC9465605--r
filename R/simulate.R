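#' Default simulation output grid
#'
#' 0.01 h resolution over the first hour (short ICV infusions must be
#' resolved), 0.1 h thereafter.
#'
#' @param t_end End of the simulation window (h).
#' @return Sorted numeric vector of output times starting at 0.
#' @export
default_grid <- function(t_end = 48) {
  if (!is.finite(t_end) || t_end <= 0) stop("default_grid: t_end must be > 0")
  sort(unique(c(seq(0, min(1, t_end), by = 0.01),
                if (t_end > 1) seq(1, t_end, by = 0.1),
                t_end)))
}

#' Simulate the reduced brain PBPK model
#'
#' Integrates the 13-state system with a stiff Rosenbrock (RODAS3) solver.
#' The initial state is drug-free with the endosomal FcRn pool at its
#' steady-state amount `FcRn_SS * V_tissue_endo`. Bolus doses are applied as
#' instantaneous additions; infusions as constant-rate inputs, with the
#' integration split at every dose boundary so no event is stepped over.
#'
#' @param phys A [phys_params()] object.
#' @param drug A [drug_params()] object.
#' @param doses A `dose_event` or list of them (see [iv_bolus()],
#'   [icv_infusion()]).
#' @param t_grid Output time grid (h), sorted, starting at or after 0; must
#'   cover all dose events. Default [default_grid()] to 48 h.
#' @param rtol,atol Relative / absolute (nmol) solver tolerances.
#' @return An object of class `rpbpk_sim` with elements `t` (output grid),
#'   `amounts` (length(t) x 13 matrix, nmol), `conc` (nM, amount divided by
#'   compartment volume), `doses`, `phys`, `drug`, and solver diagnostics.
#' @examples
#' sim <- simulate_rpbpk(phys_params(), drug_egfrviii_tcb(),
#'                       iv_bolus(15, 0.310, 195000), t_grid = seq(0, 24, 0.1))
#' max(sim$conc[, "plasma"])
#' @export
simulate_rpbpk <- function(phys, drug, doses, t_grid = default_grid(48),
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(phys, "phys_params"), inherits(drug, "drug_params"))
  doses <- as_dose_list(doses)
  t_grid <- as.numeric(t_grid)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("simulate_rpbpk: t_grid must be strictly increasing")
  t0 <- t_grid[1]; t_end <- t_grid[length(t_grid)]
  for (ev in doses) {
    if (ev$t_start < t0 || ev$t_start + ev$duration > t_end + 1e-12)
      stop("simulate_rpbpk: dose event outside the span of t_grid")
  }

  pv <- pack_phys(phys); dv <- pack_drug(drug)
  vols <- state_volumes(phys)
  ns <- length(vols)
  idx <- stats::setNames(seq_len(ns), state_names())

  y <- numeric(ns)
  y[idx["tissue_endo_FcRn"]] <- phys[["FcRn_SS"]] * phys[["V_tissue_endo"]]

  # segment boundaries: grid ends plus every bolus time / infusion edge
  bounds <- t0
  for (ev in doses) {
    bounds <- c(bounds, ev$t_start,
                if (ev$duration > 0) ev$t_start + ev$duration)
  }
  bounds <- sort(unique(pmin(pmax(c(bounds, t_end), t0), t_end)))

  out <- matrix(NA_real_, length(t_grid), ns,
                dimnames = list(NULL, state_names()))
  nsteps <- 0
  done <- rep(FALSE, length(t_grid))

  for (k in seq_len(length(bounds))) {
    tk <- bounds[k]
    # apply boluses scheduled at this boundary
    for (ev in doses) {
      if (ev$duration == 0 && abs(ev$t_start - tk) < 1e-12)
        y[idx[ev$target]] <- y[idx[ev$target]] + ev$amount
    }
    # record grid points sitting exactly on this boundary (post-bolus value)
    at <- !done & abs(t_grid - tk) < 1e-12
    if (any(at)) { out[at, ] <- matrix(y, sum(at), ns, byrow = TRUE); done[at] <- TRUE }
    if (k == length(bounds)) break
    tk1 <- bounds[k + 1]

    # constant infusion vector over (tk, tk1)
    inf <- numeric(ns)
    for (ev in doses) {
      if (ev$duration > 0 && ev$t_start < tk1 - 1e-12 &&
          ev$t_start + ev$duration > tk + 1e-12)
        inf[idx[ev$target]] <- inf[idx[ev$target]] + ev$amount / ev$duration
    }

    sel <- !done & t_grid > tk + 1e-12 & t_grid <= tk1 + 1e-12
    res <- .integrate_segment(y, tk, tk1, t_grid[sel], pv, dv, inf,
                              rtol, atol)
    if (any(sel)) { out[sel, ] <- res$y; done[sel] <- TRUE }
    y <- as.numeric(res$yend)
    nsteps <- nsteps + res$nsteps
  }

  conc <- sweep(out, 2, vols, "/")
  structure(list(t = t_grid, amounts = out, conc = conc, doses = doses,
                 phys = phys, drug = drug,
                 solver = list(rtol = rtol, atol = atol, nsteps = nsteps)),
            class = "rpbpk_sim")
}

#' Evaluate the model right-hand side
#'
#' Derivatives (nmol/h) of the 13 amounts at a given state. Exposed mainly
#' for flux-level checks; simulation should go through [simulate_rpbpk()].
#'
#' @param state Named or unnamed numeric vector of 13 amounts (nmol).
#' @param phys,drug Parameter objects.
#' @param infusion_rate Optional named vector of constant infusion rates
#'   (nmol/h) into target compartments, e.g. `c(csf_LV = 18.5)`.
#' @return Named numeric vector of 13 derivatives (nmol/h).
#' @export
rpbpk_rhs <- function(state, phys, drug, infusion_rate = NULL) {
  stopifnot(inherits(phys, "phys_params"), inherits(drug, "drug_params"))
  state <- as.numeric(state)
  if (length(state) != 13) stop("rpbpk_rhs: state must have 13 elements")
  if (any(!is.finite(state))) stop("rpbpk_rhs: non-finite state")
  inf <- numeric(13)
  if (!is.null(infusion_rate)) {
    if (is.null(names(infusion_rate)))
      stop("rpbpk_rhs: infusion_rate must be named by compartment id")
    bad <- setdiff(names(infusion_rate), state_names())
    if (length(bad))
      stop("rpbpk_rhs: unknown compartment id '", bad[1], "'")
    inf[match(names(infusion_rate), state_names())] <- infusion_rate
  }
  d <- .rhs_cpp(state, pack_phys(phys), pack_drug(drug), inf)
  stats::setNames(as.numeric(d), state_names())
}

#' @export
print.rpbpk_sim <- function(x, ...) {
  cat(sprintf("rPBPK simulation: %s, %d dose event(s), t in [%g, %g] h (%d points)\n",
              x$drug$name, length(x$doses), min(x$t), max(x$t), length(x$t)))
  cat(sprintf("  solver: RODAS3, rtol %.1e, atol %.1e, %d steps\n",
              x$solver$rtol, x$solver$atol, as.integer(x$solver$nsteps)))
  invisible(x)
}

#' Tidy a simulation into a concentration table
#'
#' @param x An `rpbpk_sim` object.
#' @param row.names,optional Unused, for generic consistency.
#' @param ... Unused.
#' @return A data.frame with `time_h` and one nM concentration column per
#'   compartment.
#' @export
as.data.frame.rpbpk_sim <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time_h = x$t, x$conc, check.names = FALSE)
}

# Concentration trajectory of one compartment.
sim_conc <- function(sim, compartment) {
  if (!compartment %in% colnames(sim$conc))
    stop("unknown compartment id '", compartment, "'")
  sim$conc[, compartment]
}
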