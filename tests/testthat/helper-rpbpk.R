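# Shared fixtures and an independent R-side reimplementation of the flux
# topology used as an oracle against the compiled core.

fix_phys <- function(...) phys_params(...)
fix_drug <- function(...) {
  args <- list(...)
  base <- list(name = "EGFRvIII-TCB", MW = 195000, sigma_BBB = 0.9853,
               sigma_BCSFB = 0.9767, sigma_CSF_ISF = 0.9994, k_deg = 82.4,
               recovery = 0.14)
  base[names(args)] <- args
  do.call(drug_params, base)
}

BW <- 0.310

# Independent right-hand side written directly from the flux list, kept
# deliberately separate from the packaged implementation.
ref_rhs <- function(A, phys, drug, inf = numeric(13)) {
  v <- state_volumes(phys)
  C <- A / v
  p <- as.list(phys); d <- drug
  dA <- setNames(numeric(13), state_names())
  flow <- function(from, to, q) {
    f <- q * C[[from]]
    dA[[from]] <<- dA[[from]] - f
    if (!is.na(to)) dA[[to]] <<- dA[[to]] + f
  }
  flow("plasma", "tissue_vasc", p$Q_t)
  flow("plasma", "brain_vasc", p$Q_b)
  flow("tissue_vasc", "plasma", p$Q_t - p$L_t)
  flow("brain_vasc", "plasma", p$Q_b - p$L_b)
  flow("tissue_vasc", "tissue_isf", (1 - p$sigma_TV) * p$L_t)
  flow("tissue_isf", "lymph", (1 - p$sigma_TL) * p$L_t)
  flow("lymph", "plasma", p$L_t + p$L_b)
  # endosome
  flow("tissue_vasc", "tissue_endo_free", p$k_CLupT * p$V_tissue_endo)
  bind <- p$k_on_FcRn * C[["tissue_endo_free"]] * C[["tissue_endo_FcRn"]] *
    p$V_tissue_endo
  dA[["tissue_endo_free"]] <- dA[["tissue_endo_free"]] - bind
  dA[["tissue_endo_complex"]] <- dA[["tissue_endo_complex"]] + bind
  dA[["tissue_endo_FcRn"]] <- dA[["tissue_endo_FcRn"]] - bind
  off <- p$k_off_FcRn * A[["tissue_endo_complex"]]
  dA[["tissue_endo_complex"]] <- dA[["tissue_endo_complex"]] - off
  dA[["tissue_endo_free"]] <- dA[["tissue_endo_free"]] + off
  dA[["tissue_endo_FcRn"]] <- dA[["tissue_endo_FcRn"]] + off
  exo <- p$k_CLupT * A[["tissue_endo_complex"]]
  dA[["tissue_endo_complex"]] <- dA[["tissue_endo_complex"]] - exo
  dA[["tissue_vasc"]] <- dA[["tissue_vasc"]] + p$FR * exo
  dA[["tissue_isf"]] <- dA[["tissue_isf"]] + (1 - p$FR) * exo
  dA[["tissue_endo_FcRn"]] <- dA[["tissue_endo_FcRn"]] + exo
  dA[["tissue_endo_free"]] <- dA[["tissue_endo_free"]] -
    d$k_deg * A[["tissue_endo_free"]]
  # brain barriers
  flow("brain_vasc", "csf_LV", (1 - d$sigma_BCSFB) * p$Q_CSF / 2)
  flow("brain_vasc", "csf_TFV", (1 - d$sigma_BCSFB) * p$Q_CSF / 2)
  flow("brain_vasc", "brain_isf", (1 - d$sigma_BBB) * p$Q_ISF)
  # CSF chain
  flow("csf_LV", "csf_TFV", (p$Q_CSF + p$Q_ISF) / 2)
  flow("csf_TFV", "csf_CM", p$Q_CSF + p$Q_ISF)
  flow("csf_CM", "csf_SAS", p$Q_CSF + p$Q_ISF)
  flow("csf_SAS", "brain_isf", (1 - d$sigma_CSF_ISF) * p$Q_ISF)
  flow("csf_SAS", "lymph", (1 - p$sigma_CSF) * p$Q_CSF)
  # brain ISF efflux: total (1 - sigma_BISF) Q_ISF
  flow("brain_isf", "csf_LV", (1 - p$sigma_BISF) * p$Q_ISF / 4)
  flow("brain_isf", "csf_TFV", (1 - p$sigma_BISF) * p$Q_ISF / 4)
  flow("brain_isf", "lymph", (1 - p$sigma_BISF) * p$Q_ISF / 2)
  dA + inf
}

drug_states <- function() setdiff(state_names(), "tissue_endo_FcRn")

total_drug <- function(sim) rowSums(sim$amounts[, drug_states(), drop = FALSE])

# noise-free dataset cache (built once per test run)
noisefree_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(default_design("EGFRvIII-TCB"), fix_phys(),
                                 fix_drug(), seed = 1, prop_sd_serum = 0,
                                 add_sd_csf = 0, add_sd_isf = 0)
    cache
  }
})
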