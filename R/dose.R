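#' Convert a mg/kg dose to nmol
#'
#' Doses are prescribed in mg/kg body weight; the model works in molar
#' amounts. `dose * BW / MW`, expressed in nmol.
#'
#' @param dose_mgkg Dose in mg per kg body weight.
#' @param body_weight Body weight in kg (study mean: 0.310 kg).
#' @param MW Molecular weight in g/mol.
#' @return Dose amount in nmol.
#' @examples
#' dose_from_mgkg(15, 0.310, 195000)  # ~23.85 nmol
#' @export
dose_from_mgkg <- function(dose_mgkg, body_weight, MW) {
  if (!is.finite(dose_mgkg) || dose_mgkg <= 0)
    stop("dose_from_mgkg: dose must be positive")
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("dose_from_mgkg: body weight must be positive")
  if (!is.finite(MW) || MW <= 0)
    stop("dose_from_mgkg: MW must be positive")
  # mg = dose * BW; nmol = mg * 1e-3 g / (MW g/mol) * 1e9
  dose_mgkg * body_weight * 1e6 / MW
}

new_dose_event <- function(route, amount, t_start, duration, target) {
  route <- match.arg(route, c("IV", "ICV"))
  if (!is.finite(amount) || amount <= 0)
    stop("dose_event: amount must be positive")
  if (!is.finite(duration) || duration < 0)
    stop("dose_event: duration must be non-negative")
  if (route == "IV" && target != "plasma")
    stop("dose_event: IV doses target plasma")
  if (route == "ICV" && target != "csf_LV")
    stop("dose_event: ICV doses target the lateral ventricle (csf_LV)")
  if (!target %in% state_names())
    stop("dose_event: unknown compartment id '", target, "'")
  structure(list(route = route, amount = amount, t_start = t_start,
                 duration = duration, target = target),
            class = "dose_event")
}

#' Intravenous bolus dose event
#'
#' IV doses are applied as an instantaneous addition to plasma (tail-vein
#' injection; injection duration neglected).
#'
#' @inheritParams dose_from_mgkg
#' @param t_start Dose time (h), default 0.
#' @return A `dose_event`.
#' @examples
#' iv_bolus(15, 0.310, 195000)
#' @export
iv_bolus <- function(dose_mgkg, body_weight, MW, t_start = 0) {
  new_dose_event("IV", dose_from_mgkg(dose_mgkg, body_weight, MW),
                 t_start, 0, "plasma")
}

#' Intracerebroventricular infusion dose event
#'
#' ICV doses are delivered into a lateral ventricle as a constant-rate
#' infusion: the formulation volume `dose * BW / formulation_conc` is infused
#' at `flow_rate`, so the infusion duration follows from the dose.
#'
#' @inheritParams dose_from_mgkg
#' @param formulation_conc Formulation concentration in mg/ml (study: 20).
#' @param flow_rate Infusion rate in microlitre/min (study: 3).
#' @param t_start Infusion start time (h), default 0.
#' @return A `dose_event` with route `"ICV"`, target `csf_LV`, duration in h.
#' @examples
#' ev <- icv_infusion(3, 0.310, 195000)   # 46.5 ul over 15.5 min
#' ev$duration * 60                        # minutes
#' @export
icv_infusion <- function(dose_mgkg, body_weight, MW, formulation_conc = 20,
                         flow_rate = 3, t_start = 0) {
  if (!is.finite(formulation_conc) || formulation_conc <= 0)
    stop("icv_infusion: formulation concentration must be positive")
  if (!is.finite(flow_rate) || flow_rate <= 0)
    stop("icv_infusion: flow rate must be positive")
  amount <- dose_from_mgkg(dose_mgkg, body_weight, MW)  # also validates
  vol_ml <- dose_mgkg * body_weight / formulation_conc  # mg / (mg/ml)
  duration_h <- vol_ml / (flow_rate * 60 * 1e-3)        # ml / (ml/h)
  new_dose_event("ICV", amount, t_start, duration_h, "csf_LV")
}

#' @export
print.dose_event <- function(x, ...) {
  if (x$duration > 0)
    cat(sprintf("%s infusion: %.4g nmol into %s over %.4g h from t = %g h\n",
                x$route, x$amount, x$target, x$duration, x$t_start))
  else
    cat(sprintf("%s bolus: %.4g nmol into %s at t = %g h\n",
                x$route, x$amount, x$target, x$t_start))
  invisible(x)
}

# Normalize doses argument: a single dose_event or list of them.
as_dose_list <- function(doses) {
  if (inherits(doses, "dose_event")) doses <- list(doses)
  if (!is.list(doses) || !all(vapply(doses, inherits, TRUE, "dose_event")))
    stop("doses must be a dose_event or a list of dose_event objects")
  doses
}
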