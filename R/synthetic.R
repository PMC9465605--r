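#' Default study design
#'
#' The sampling schedule of the rat PK study the generator emulates:
#' serum and CSF sampled at -0.5 (pre-dose), 0.5, 1, 3, 4.5, 6, 12, 24 and
#' 48 h; microdialysate collected as 30-min interval averages over 0-8 h
#' and 4-h interval averages over 8-48 h; 5 animals per dose group; mean
#' body weight 0.310 kg.
#'
#' Residual-error magnitudes are calibration choices (the study reports
#' only the error-model classes): proportional with 15% SD on serum,
#' additive with 10 nM SD on CSF (cisterna magna scale) and 0.5 nM SD on
#' the ISF dialysate scale.
#'
#' @param compound `"EGFRvIII-TCB"` (three groups: 15 mg/kg IV, 3 mg/kg
#'   ICV, 1 mg/kg ICV; assay LLOQ 2.5 ng/ml) or `"DP47"` (one 15 mg/kg IV
#'   group; LLOQ 1.4 ng/ml).
#' @return Object of class `study_design` (a list).
#' @export
default_design <- function(compound = c("EGFRvIII-TCB", "DP47")) {
  compound <- match.arg(compound)
  groups <- if (compound == "EGFRvIII-TCB") {
    data.frame(group = c("IV-15", "ICV-3", "ICV-1"),
               route = c("IV", "ICV", "ICV"),
               dose_mgkg = c(15, 3, 1),
               n = c(5L, 5L, 5L))
  } else {
    data.frame(group = "IV-15", route = "IV", dose_mgkg = 15, n = 5L)
  }
  structure(list(
    compound = compound,
    groups = groups,
    serum_csf_times = c(-0.5, 0.5, 1, 3, 4.5, 6, 12, 24, 48),
    dialysate_windows = dialysate_windows(),
    body_weight = 0.310,
    lloq_ngml = if (compound == "EGFRvIII-TCB") 2.5 else 1.4,
    prop_sd_serum = 0.15,
    add_sd_csf = 10,
    add_sd_isf = 0.5
  ), class = "study_design")
}

#' LLOQ in molar units
#'
#' Converts an assay lower limit of quantification from ng/ml to nM.
#'
#' @param lloq_ngml LLOQ in ng/ml.
#' @param MW Molecular weight (g/mol).
#' @return LLOQ in nM.
#' @examples
#' lloq_nM(2.5, 195000)  # ~0.0128 nM
#' @export
lloq_nM <- function(lloq_ngml, MW) {
  if (!is.finite(lloq_ngml) || lloq_ngml <= 0) stop("lloq_nM: LLOQ must be > 0")
  if (!is.finite(MW) || MW <= 0) stop("lloq_nM: MW must be > 0")
  lloq_ngml * 1e3 / MW  # ng/ml = ug/L; /MW g/mol -> umol/L * 1e3 = nM
}

#' Generate a synthetic PK dataset
#'
#' Simulates each dose group of the design, samples serum and CSF
#' (cisterna magna) at the scheduled times, samples brain ISF as
#' recovery-attenuated dialysate window averages, and adds residual noise:
#' mean-one log-normal multiplicative noise on serum (guaranteeing positive
#' concentrations) and additive Gaussian noise on CSF and dialysate
#' (negatives truncated to zero and flagged below-LLOQ). Observations below
#' the assay LLOQ (converted to nM) are flagged as censored with their
#' noisy value retained. Pre-dose samples carry zero drug and are censored.
#' Fully reproducible from the seed.
#'
#' @param design A [default_design()] object (or modified copy).
#' @param phys A [phys_params()] object.
#' @param drug A [drug_params()] object; the generating "truth".
#' @param seed Integer seed.
#' @param prop_sd_serum,add_sd_csf,add_sd_isf Optional overrides of the
#'   design's residual SDs (useful for noise-free data: set all to 0).
#' @return data.frame with columns `subject`, `group`, `route`,
#'   `dose_mgkg`, `matrix` (`serum`, `CSF`, `ISF-dialysate`), `time_h`,
#'   `conc_nM`, `bloq`, and window edges `t0`, `t1` (NA for point samples).
#' @export
generate_dataset <- function(design, phys, drug, seed = 1,
                             prop_sd_serum = design$prop_sd_serum,
                             add_sd_csf = design$add_sd_csf,
                             add_sd_isf = design$add_sd_isf) {
  stopifnot(inherits(design, "study_design"),
            inherits(phys, "phys_params"), inherits(drug, "drug_params"))
  if (any(c(prop_sd_serum, add_sd_csf, add_sd_isf) < 0))
    stop("generate_dataset: error SDs must be non-negative")
  set.seed(seed)
  lloq <- lloq_nM(design$lloq_ngml, drug$MW)
  times <- design$serum_csf_times
  post <- times[times >= 0]
  win <- design$dialysate_windows
  t_end <- max(48, times, win)

  rows <- list()
  subj_id <- 0L
  for (gi in seq_len(nrow(design$groups))) {
    g <- design$groups[gi, ]
    ev <- if (g$route == "IV")
      iv_bolus(g$dose_mgkg, design$body_weight, drug$MW)
    else
      icv_infusion(g$dose_mgkg, design$body_weight, drug$MW)
    tg <- sort(unique(c(default_grid(t_end), post, as.numeric(win))))
    sim <- simulate_rpbpk(phys, drug, ev, t_grid = tg)
    serum <- stats::approx(sim$t, sim$conc[, "plasma"], post)$y
    csf <- stats::approx(sim$t, sim$conc[, "csf_CM"], post)$y
    dial <- window_average_sampling(sim, "brain_isf", win, drug$recovery)

    for (a in seq_len(g$n)) {
      subj_id <- subj_id + 1L
      id <- sprintf("R%02d", subj_id)
      # serum: mean-one log-normal multiplicative error
      if (prop_sd_serum > 0) {
        sdlog <- sqrt(log(1 + prop_sd_serum^2))
        fac <- rlnorm(length(serum), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else fac <- rep(1, length(serum))
      y_serum <- serum * fac
      # CSF and dialysate: additive Gaussian, truncated at zero
      y_csf <- pmax(csf + rnorm(length(csf), 0, add_sd_csf), 0)
      y_dial <- pmax(dial$conc_dialysate + rnorm(nrow(dial), 0, add_sd_isf), 0)

      mk <- function(matrix, t, y, t0 = NA_real_, t1 = NA_real_) {
        data.frame(subject = id, group = g$group, route = g$route,
                   dose_mgkg = g$dose_mgkg, matrix = matrix, time_h = t,
                   conc_nM = y, bloq = y < lloq, t0 = t0, t1 = t1)
      }
      pre <- mk("serum", -0.5, 0)
      pre$bloq <- TRUE
      pre_csf <- mk("CSF", -0.5, 0)
      pre_csf$bloq <- TRUE
      rows[[length(rows) + 1L]] <- rbind(
        pre, mk("serum", post, y_serum),
        pre_csf, mk("CSF", post, y_csf),
        mk("ISF-dialysate", dial$t_mid, y_dial, dial$t0, dial$t1))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
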