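#' State layout of the reduced brain PBPK model
#'
#' The model tracks 13 amounts (nmol; the two FcRn receptor species are in
#' nmol of receptor): plasma, lymph, the lumped rest-of-body tissue
#' (vascular, endosomal free drug, endosomal FcRn complex, free endosomal
#' FcRn, interstitial), brain vasculature, the four CSF sub-compartments
#' (lateral ventricles, third+fourth ventricles, cisterna magna,
#' subarachnoid space) and brain interstitial fluid.
#'
#' @return Character vector of the 13 state identifiers, in solver order.
#' @export
state_names <- function() {
  c("plasma", "lymph", "tissue_vasc", "tissue_endo_free",
    "tissue_endo_complex", "tissue_endo_FcRn", "tissue_isf", "brain_vasc",
    "csf_LV", "csf_TFV", "csf_CM", "csf_SAS", "brain_isf")
}

#' Physiological parameter set for the rat
#'
#' Fixed physiological constants of the model: compartment volumes (L),
#' blood/lymph/CSF/ISF flows (L/h), the fixed reflection coefficients and the
#' endosomal FcRn constants. Defaults are the reported rat values used
#' throughout; any subset can be overridden.
#'
#' The brain lymph flow must equal the sum of CSF and ISF production
#' (`L_b = Q_CSF + Q_ISF`): the fluid produced at the brain barriers drains
#' via brain lymph.
#'
#' @param ... Named overrides of individual parameters, e.g.
#'   `phys_params(Q_CSF = 1.5e-4)`.
#' @return Object of class `phys_params`: a named numeric vector of the 26
#'   constants.
#' @examples
#' phys <- phys_params()
#' phys[["V_plasma"]]
#' @export
phys_params <- function(...) {
  p <- c(
    V_plasma      = 0.0067,   # L, serum/plasma volume (BW-corrected, Hct 0.45)
    V_lymph       = 0.0011,   # L
    V_tissue_vasc = 0.0079,   # L, plasma in rest-of-body vasculature
    V_tissue_endo = 0.0013,   # L, rest-of-body endosomal space
    V_tissue_isf  = 0.0483,   # L, rest-of-body interstitial fluid
    V_brain_vasc  = 5.02e-5,  # L, plasma in brain vasculature
    V_brain_isf   = 4.1e-4,   # L, brain interstitial fluid
    V_LV          = 5e-5,     # L, both lateral ventricles
    V_TFV         = 5e-5,     # L, third + fourth ventricles
    V_CM          = 1.7e-5,   # L, cisterna magna (CSF sampling site)
    V_SAS         = 1.8e-4,   # L, subarachnoid space
    Q_t           = 2.88,     # L/h, rest-of-body blood (plasma) flow
    Q_b           = 0.0653,   # L/h, brain blood (plasma) flow
    L_t           = 0.0058,   # L/h, tissue lymph flow
    L_b           = 1.62e-4,  # L/h, brain lymph flow (= Q_CSF + Q_ISF)
    Q_CSF         = 1.32e-4,  # L/h, CSF production/circulation flow
    Q_ISF         = 3.0e-5,   # L/h, ISF production/circulation flow
    sigma_TV      = 0.9212,   # vascular reflection, tissue
    sigma_TL      = 0.2,      # lymphatic reflection, tissue ISF
    sigma_BISF    = 0.2,      # reflection on brain-ISF outflow
    sigma_CSF     = 0.2,      # reflection on SAS outflow
    FcRn_SS       = 49800,    # nM, steady-state endosomal FcRn concentration
    FR            = 0.715,    # fraction of FcRn complex recycled to vasculature
    k_CLupT       = 0.55,     # 1/h, endosomal uptake rate
    k_on_FcRn     = 0.8,      # 1/(nM h), FcRn association rate
    k_off_FcRn    = 144       # 1/h, FcRn dissociation rate
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("phys_params: overrides must be named")
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      stop("phys_params: unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- as.numeric(unlist(dots))
  }
  validate_phys(p)
  structure(p, class = "phys_params")
}

validate_phys <- function(p) {
  vols_flows <- c("V_plasma", "V_lymph", "V_tissue_vasc", "V_tissue_endo",
                  "V_tissue_isf", "V_brain_vasc", "V_brain_isf", "V_LV",
                  "V_TFV", "V_CM", "V_SAS", "Q_t", "Q_b", "L_t", "L_b",
                  "Q_CSF", "Q_ISF")
  if (any(!is.finite(p)) )
    stop("phys_params: all parameters must be finite")
  if (any(p[vols_flows] <= 0))
    stop("phys_params: volumes and flows must be strictly positive")
  sig <- p[c("sigma_TV", "sigma_TL", "sigma_BISF", "sigma_CSF")]
  if (any(sig < 0 | sig > 1))
    stop("phys_params: reflection coefficients must lie in [0, 1]")
  if (p[["FR"]] < 0 || p[["FR"]] > 1)
    stop("phys_params: FR must lie in [0, 1]")
  rel <- abs(p[["L_b"]] - (p[["Q_CSF"]] + p[["Q_ISF"]])) / p[["L_b"]]
  if (rel > 1e-9)
    stop("phys_params: L_b must equal Q_CSF + Q_ISF (brain fluid balance); ",
         "got relative discrepancy ", format(rel))
  invisible(p)
}

#' Compartment volumes in state order
#'
#' Maps each of the 13 states to its distribution volume (L). The three
#' endosomal species share the tissue endosomal volume.
#'
#' @param phys A [phys_params()] object.
#' @return Named numeric vector of 13 volumes (L), names as [state_names()].
#' @export
state_volumes <- function(phys) {
  v <- c(phys[["V_plasma"]], phys[["V_lymph"]], phys[["V_tissue_vasc"]],
         phys[["V_tissue_endo"]], phys[["V_tissue_endo"]],
         phys[["V_tissue_endo"]], phys[["V_tissue_isf"]],
         phys[["V_brain_vasc"]], phys[["V_LV"]], phys[["V_TFV"]],
         phys[["V_CM"]], phys[["V_SAS"]], phys[["V_brain_isf"]])
  names(v) <- state_names()
  v
}

#' Drug-specific parameter set
#'
#' Drug-dependent parameters of the model: molecular weight, the three
#' estimated reflection coefficients (BBB, BCSFB, CSF-ISF barrier), the
#' endosomal degradation rate and the in-vitro microdialysis recovery.
#'
#' Reflection coefficients must lie strictly inside (0, 1): they are
#' estimated on the logit scale, which cannot represent the endpoints.
#'
#' @param name Compound label.
#' @param MW Molecular weight (g/mol).
#' @param sigma_BBB Reflection coefficient for net uptake from brain
#'   vasculature into brain ISF across the blood-brain barrier.
#' @param sigma_BCSFB Reflection coefficient for net uptake from brain
#'   vasculature into ventricular CSF across the blood-CSF barrier.
#' @param sigma_CSF_ISF Reflection coefficient on the glymphatic transfer
#'   from the subarachnoid space into brain ISF.
#' @param k_deg Endosomal degradation rate of unbound antibody (1/h).
#' @param recovery In-vitro microdialysis recovery fraction in (0, 1].
#' @return Object of class `drug_params`.
#' @examples
#' drug_params("mAb-X", MW = 150000, sigma_BBB = 0.99, sigma_BCSFB = 0.98,
#'             sigma_CSF_ISF = 0.999, k_deg = 25)
#' @export
drug_params <- function(name, MW, sigma_BBB, sigma_BCSFB, sigma_CSF_ISF,
                        k_deg, recovery = 1.0) {
  stopifnot(is.character(name), length(name) == 1)
  for (s in c(sigma_BBB, sigma_BCSFB, sigma_CSF_ISF))
    if (!is.finite(s) || s <= 0 || s >= 1)
      stop("drug_params: reflection coefficients must lie strictly in (0, 1)")
  if (!is.finite(k_deg) || k_deg < 0) stop("drug_params: k_deg must be >= 0")
  if (!is.finite(MW) || MW <= 0) stop("drug_params: MW must be positive")
  if (!is.finite(recovery) || recovery <= 0 || recovery > 1)
    stop("drug_params: recovery must lie in (0, 1]")
  structure(list(name = name, MW = MW, sigma_BBB = sigma_BBB,
                 sigma_BCSFB = sigma_BCSFB, sigma_CSF_ISF = sigma_CSF_ISF,
                 k_deg = k_deg, recovery = recovery),
            class = "drug_params")
}

#' Fitted parameter sets for the three tool compounds
#'
#' Convenience constructors carrying the reported estimates for the
#' EGFRvIII-targeting T-cell bispecific (195 kDa, recovery 14%) and the two
#' non-binding DP47 control molecules (TCB 195 kDa and IgG 143 kDa, recovery
#' 10% each). The DP47 molecules share the CSF-ISF barrier coefficient
#' estimated from the bispecific, which is the only compound with ICV data.
#'
#' @return A `drug_params` object.
#' @export
drug_egfrviii_tcb <- function() {
  drug_params("EGFRvIII-TCB", MW = 195000, sigma_BBB = 0.9853,
              sigma_BCSFB = 0.9767, sigma_CSF_ISF = 0.9994, k_deg = 82.4,
              recovery = 0.14)
}

#' @rdname drug_egfrviii_tcb
#' @export
drug_dp47_igg <- function() {
  drug_params("DP47-IgG", MW = 143000, sigma_BBB = 0.9919,
              sigma_BCSFB = 0.9865, sigma_CSF_ISF = 0.9994, k_deg = 27.3,
              recovery = 0.10)
}

#' @rdname drug_egfrviii_tcb
#' @export
drug_dp47_tcb <- function() {
  drug_params("DP47-TCB", MW = 195000, sigma_BBB = 0.9946,
              sigma_BCSFB = 0.9855, sigma_CSF_ISF = 0.9994, k_deg = 7.76,
              recovery = 0.10)
}

# Pack parameters into the fixed vectors the C++ core expects.
pack_phys <- function(phys) {
  as.numeric(phys[c("V_plasma", "V_lymph", "V_tissue_vasc", "V_tissue_endo",
                    "V_tissue_isf", "V_brain_vasc", "V_brain_isf", "V_LV",
                    "V_TFV", "V_CM", "V_SAS", "Q_t", "Q_b", "L_t", "L_b",
                    "Q_CSF", "Q_ISF", "sigma_TV", "sigma_TL", "sigma_BISF",
                    "sigma_CSF", "FcRn_SS", "FR", "k_CLupT", "k_on_FcRn",
                    "k_off_FcRn")])
}

pack_drug <- function(drug) {
  c(drug$sigma_BBB, drug$sigma_BCSFB, drug$sigma_CSF_ISF, drug$k_deg)
}

#' @export
print.phys_params <- function(x, ...) {
  cat("Physiological parameter set (26 constants)\n")
  print(unclass(x))
  invisible(x)
}

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf(paste0(
    "Drug parameters: %s (MW %.0f g/mol)\n",
    "  sigma_BBB = %.4f  sigma_BCSFB = %.4f  sigma_CSF_ISF = %.4f\n",
    "  k_deg = %.3g 1/h  microdialysis recovery = %.2f\n"),
    x$name, x$MW, x$sigma_BBB, x$sigma_BCSFB, x$sigma_CSF_ISF,
    x$k_deg, x$recovery))
  invisible(x)
}
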