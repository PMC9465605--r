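#' Logit and inverse-logit transforms
#'
#' Reflection coefficients are estimated on the logit scale, which maps
#' (0, 1) onto the real line and keeps estimates inside the unit interval.
#'
#' @param p Fraction strictly inside (0, 1).
#' @param x Real number.
#' @return `logit` returns `log(p / (1 - p))`; `inv_logit` its inverse.
#' @examples
#' logit(0.9853)
#' inv_logit(logit(0.5))
#' @export
logit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("logit: argument must lie strictly in (0, 1)")
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Prediction error of an exposure metric
#'
#' `PE% = (AUC_pred - AUC_obs) / AUC_obs * 100`.
#'
#' @param auc_pred,auc_obs Predicted and observed AUC (nM*h); `auc_obs > 0`.
#' @return Signed percentage.
#' @export
prediction_error <- function(auc_pred, auc_obs) {
  if (!is.finite(auc_obs) || auc_obs <= 0)
    stop("prediction_error: observed AUC must be positive")
  (auc_pred - auc_obs) / auc_obs * 100
}

# ---------------------------------------------------------------------------
# Generic bounded least squares on transformed parameters.
#
# resid_fn(theta) returns the residual vector. Minimization by stats::nlminb
# (PORT: bounded quasi-Newton with trust-region model) with optional
# multi-start; the reported trace is the best objective after each
# evaluation, which is non-increasing by construction (monotone acceptance).
ls_fit <- function(resid_fn, start, lower = -Inf, upper = Inf,
                   n_starts = 5, seed = 1, start_spread = 1.0,
                   control = list(rel.tol = 1e-12, x.tol = 1e-10,
                                  iter.max = 300, eval.max = 600)) {
  stopifnot(n_starts >= 1)
  trace_env <- new.env()
  make_obj <- function() {
    trace_env$best <- Inf
    trace_env$trace <- numeric(0)
    function(theta) {
      r <- resid_fn(theta)
      v <- sum(r * r)
      if (!is.finite(v)) v <- 1e300
      trace_env$best <- min(trace_env$best, v)
      trace_env$trace <- c(trace_env$trace, trace_env$best)
      v
    }
  }
  starts <- list(start)
  if (n_starts > 1) {
    set.seed(seed)
    for (k in seq_len(n_starts - 1))
      starts[[k + 1]] <- pmin(pmax(
        start + runif(length(start), -start_spread, start_spread),
        lower + 1e-8), upper - 1e-8)
  }
  best <- NULL; best_trace <- NULL
  for (s in starts) {
    obj <- make_obj()
    res <- tryCatch(stats::nlminb(s, obj, lower = lower, upper = upper,
                                  control = control),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$objective < best$objective) {
      best <- res
      best_trace <- trace_env$trace
    }
  }
  if (is.null(best)) stop("ls_fit: optimization failed from every start")
  list(par = best$par, objective = best$objective,
       convergence = best$convergence, message = best$message,
       trace = best_trace, n_starts = n_starts)
}

# Asymptotic SE of transformed parameters from the linearized covariance
# s^2 (J'J)^-1, with J the finite-difference residual Jacobian at the
# optimum. Residuals are already weighted (weights folded into resid_fn).
ls_se <- function(resid_fn, par, n_obs) {
  p <- length(par)
  r0 <- resid_fn(par)
  J <- matrix(NA_real_, length(r0), p)
  for (j in seq_len(p)) {
    h <- 1e-5 * max(1, abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (resid_fn(up) - resid_fn(dn)) / (2 * h)
  }
  ssr <- sum(r0 * r0)
  dof <- max(n_obs - p, 1)
  s2 <- ssr / dof
  JtJ <- crossprod(J)
  cov <- tryCatch(s2 * solve(JtJ), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0)) {
    se <- rep(Inf, p)
  } else {
    se <- sqrt(diag(cov))
  }
  list(se = se, s2 = s2, jacobian = J)
}

new_rpbpk_fit <- function(stage, par_names, transformed, natural, resid_fn,
                          opt, n_obs, flag = NULL, scale = NULL) {
  se <- ls_se(resid_fn, opt$par, n_obs)
  cv <- 100 * se$se / abs(transformed)
  structure(list(
    stage = stage,
    estimates = setNames(natural, par_names),
    transformed_estimates = setNames(transformed, par_names),
    transform_scale = scale,
    cv_percent = setNames(cv, par_names),
    se_transformed = setNames(se$se, par_names),
    objective = opt$objective,
    n_obs = n_obs,
    residuals = resid_fn(opt$par),
    trace = opt$trace,
    convergence = opt$convergence,
    flag = flag,
    resid_fn = resid_fn
  ), class = "rpbpk_fit")
}

#' Asymptotic coefficient of variation of fitted parameters
#'
#' Per-parameter CV% from the linearized least-squares covariance
#' `s^2 (J'J)^-1`, with `J` the finite-difference Jacobian of the (weighted)
#' residual vector at the optimum, reported on the estimation scale (log for
#' `k_deg`, logit for reflection coefficients). A singular information
#' matrix yields infinite CV (flagged non-identifiable).
#'
#' @param fit An `rpbpk_fit` from [fit_stage1_serum()] or
#'   [fit_stage2_brain()].
#' @return Named vector of CV percentages.
#' @export
asymptotic_cv <- function(fit) {
  stopifnot(inherits(fit, "rpbpk_fit"))
  se <- ls_se(fit$resid_fn, fit$transformed_estimates, fit$n_obs)
  100 * se$se / abs(fit$transformed_estimates)
}

# ---------------------------------------------------------------------------
# Observation-table plumbing shared by the two stages.

# Split the table into dose groups and build per-group dose events and the
# simulation grid (union of the default grid and every observation /
# window edge, so interval averages match the generator's resolution).
fit_groups <- function(data, drug, body_weight) {
  groups <- unique(data$group)
  lapply(groups, function(g) {
    d <- data[data$group == g, , drop = FALSE]
    route <- unique(d$route); dose <- unique(d$dose_mgkg)
    if (length(route) != 1 || length(dose) != 1)
      stop("fit: group '", g, "' mixes routes or dose levels")
    ev <- if (route == "IV") iv_bolus(dose, body_weight, drug$MW)
          else icv_infusion(dose, body_weight, drug$MW)
    tmax <- max(d$time_h, d$t1, 48, na.rm = TRUE)
    tg <- sort(unique(c(default_grid(tmax), d$time_h,
                        d$t0[!is.na(d$t0)], d$t1[!is.na(d$t1)])))
    tg <- tg[tg >= 0]
    list(name = g, data = d, dose = ev, t_grid = tg)
  })
}

# Model predictions matching each observation row of one group.
# CSF observations are sampled at the cisterna magna; dialysate rows are
# predicted as interval averages of brain ISF when window edges (t0, t1)
# are present, pointwise otherwise. Predictions for dialysate rows are on
# the ISF scale (recovery handled by the caller).
predict_group <- function(grp, phys, drug) {
  sim <- simulate_rpbpk(phys, drug, grp$dose, t_grid = grp$t_grid)
  d <- grp$data
  pred <- numeric(nrow(d))
  for (m in unique(d$matrix)) {
    i <- which(d$matrix == m)
    if (m == "serum") {
      pred[i] <- stats::approx(sim$t, sim$conc[, "plasma"], d$time_h[i])$y
    } else if (m == "CSF") {
      pred[i] <- stats::approx(sim$t, sim$conc[, "csf_CM"], d$time_h[i])$y
    } else if (m %in% c("ISF-dialysate", "ISF")) {
      has_win <- !is.null(d$t0) && !anyNA(d$t0[i]) && !anyNA(d$t1[i])
      if (has_win) {
        # pooled animals share the collection schedule: average each unique
        # window once, then map back to rows
        wins <- unique(data.frame(t0 = d$t0[i], t1 = d$t1[i]))
        wins <- wins[order(wins$t0), , drop = FALSE]
        wa <- window_average_sampling(sim, "brain_isf",
                                      as.matrix(wins), recovery = 1)
        key <- match(paste(d$t0[i], d$t1[i]), paste(wins$t0, wins$t1))
        pred[i] <- wa$conc_dialysate[key]
      } else {
        pred[i] <- stats::approx(sim$t, sim$conc[, "brain_isf"], d$time_h[i])$y
      }
    } else stop("fit: unknown matrix '", m, "'")
  }
  pred
}

#' Stage 1: fit the endosomal degradation rate to serum data
#'
#' Naive-pooled nonlinear least squares: all animals' serum observations
#' after IV dosing are pooled and the endosomal degradation rate `k_deg`
#' (the only free parameter, log-transformed internally) is estimated under
#' a proportional error model, minimizing
#' `sum(((obs - pred) / pred)^2)`. Weights use model predictions, not
#' observations, to avoid transformation bias. Pre-dose and below-LLOQ
#' records are excluded.
#'
#' @param data Observation data.frame (see [read_pk_table()]); serum records
#'   from IV groups are selected automatically.
#' @param phys A [phys_params()] object.
#' @param drug A [drug_params()] object; its `k_deg` is the starting value.
#' @param body_weight Body weight (kg) used for dose conversion.
#' @param n_starts Number of optimizer starts (1 = single-start
#'   reproduction mode mirroring a plain local search).
#' @param seed Seed for the multi-start perturbations.
#' @return An `rpbpk_fit` (stage `"serum"`) with the `k_deg` estimate, CV%
#'   on the log scale, objective, residuals and optimizer trace. A design
#'   with a single distinct sampling time is returned flagged
#'   `"non-identifiable"`.
#' @export
fit_stage1_serum <- function(data, phys, drug, body_weight = 0.310,
                             n_starts = 5, seed = 1) {
  data <- validate_pk_table(data)
  d <- data[data$matrix == "serum" & data$route == "IV" &
            data$time_h >= 0 & !data$bloq, , drop = FALSE]
  if (nrow(d) == 0) stop("fit_stage1_serum: no serum records after IV dosing")
  if (nrow(d) < 3) stop("fit_stage1_serum: need at least 3 serum observations")
  flag <- NULL
  if (length(unique(d$time_h)) < 2) flag <- "non-identifiable"

  grps <- fit_groups(d, drug, body_weight)
  obs <- unlist(lapply(grps, function(g) g$data$conc_nM))
  resid_fn <- function(theta) {
    dd <- drug
    dd$k_deg <- exp(theta[1])
    pred <- unlist(lapply(grps, function(g) predict_group(g, phys, dd)))
    (obs - pred) / pred
  }
  if (!is.null(flag)) {
    opt <- list(par = log(max(drug$k_deg, 1e-6)), objective = NA_real_,
                convergence = NA_integer_, trace = numeric(0),
                n_starts = 0, message = "skipped: non-identifiable design")
    fit <- new_rpbpk_fit("serum", "k_deg", opt$par, exp(opt$par), resid_fn,
                         opt, nrow(d), flag = flag, scale = "log")
    return(fit)
  }
  opt <- ls_fit(resid_fn, log(max(drug$k_deg, 1e-6)),
                n_starts = n_starts, seed = seed, start_spread = 1.5)
  new_rpbpk_fit("serum", "k_deg", opt$par, exp(opt$par), resid_fn, opt,
                nrow(d), scale = "log")
}

#' Stage 2: fit brain-uptake reflection coefficients to CSF and ISF data
#'
#' With `k_deg` fixed from stage 1, the brain-uptake parameters (any
#' non-empty subset of `sigma_BBB`, `sigma_BCSFB`, `sigma_CSF_ISF`) are
#' estimated by simultaneous naive-pooled least squares on all CSF and
#' ISF records across the supplied dose groups, under a constant
#' (unweighted) error model, in logit space. Dialysate observations are
#' recovery-corrected to the ISF scale before fitting, so the constant
#' error is shared by CSF and ISF on a common nM scale.
#'
#' With single-route (IV-only) data the CSF-ISF barrier coefficient is not
#' identifiable and must be fixed (excluded from `free`), mirroring the
#' study design where it was estimable only for the compound with both IV
#' and ICV arms.
#'
#' @inheritParams fit_stage1_serum
#' @param drug A [drug_params()]; `k_deg` is held fixed at its value, and
#'   the free sigmas start from their values in this object.
#' @param free Character vector naming the free reflection coefficients.
#' @return An `rpbpk_fit` (stage `"brain"`) with natural-scale estimates and
#'   CV% on the logit scale.
#' @export
fit_stage2_brain <- function(data, phys, drug,
                             free = c("sigma_BBB", "sigma_BCSFB",
                                      "sigma_CSF_ISF"),
                             body_weight = 0.310, n_starts = 5, seed = 1) {
  data <- validate_pk_table(data)
  all_sigmas <- c("sigma_BBB", "sigma_BCSFB", "sigma_CSF_ISF")
  if (length(free) == 0) stop("fit_stage2_brain: empty free parameter set")
  if (!all(free %in% all_sigmas))
    stop("fit_stage2_brain: free must be a subset of ",
         paste(all_sigmas, collapse = ", "))
  d <- data[data$matrix %in% c("CSF", "ISF-dialysate", "ISF") &
            data$time_h >= 0 & !data$bloq, , drop = FALSE]
  if (nrow(d) == 0) stop("fit_stage2_brain: no CSF/ISF records")
  routes <- unique(d$route)
  if (identical(routes, "IV") && "sigma_CSF_ISF" %in% free)
    stop("fit_stage2_brain: sigma_CSF_ISF is not identifiable from ",
         "IV-only data; fix it (drop from 'free')")

  grps <- fit_groups(d, drug, body_weight)
  obs <- unlist(lapply(grps, function(g) {
    o <- g$data$conc_nM
    dial <- g$data$matrix == "ISF-dialysate"
    o[dial] <- apply_recovery(o[dial], drug$recovery)
    o
  }))
  resid_fn <- function(theta) {
    dd <- drug
    for (j in seq_along(free)) dd[[free[j]]] <- inv_logit(theta[j])
    pred <- unlist(lapply(grps, function(g) predict_group(g, phys, dd)))
    obs - pred
  }
  start <- logit(unlist(drug[free]))
  opt <- ls_fit(resid_fn, start, n_starts = n_starts, seed = seed,
                start_spread = 1.0)
  new_rpbpk_fit("brain", free, opt$par, inv_logit(opt$par), resid_fn, opt,
                nrow(d), scale = "logit")
}

#' Two-stage estimation in one call
#'
#' Runs [fit_stage1_serum()], fixes the estimated `k_deg`, then runs
#' [fit_stage2_brain()].
#'
#' @inheritParams fit_stage2_brain
#' @return List with elements `stage1` and `stage2` (`rpbpk_fit` objects)
#'   and `drug` (the input drug parameters updated with all estimates).
#' @export
fit_two_stage <- function(data, phys, drug,
                          free = c("sigma_BBB", "sigma_BCSFB",
                                   "sigma_CSF_ISF"),
                          body_weight = 0.310, n_starts = 5, seed = 1) {
  s1 <- fit_stage1_serum(data, phys, drug, body_weight, n_starts, seed)
  drug2 <- drug
  drug2$k_deg <- s1$estimates[["k_deg"]]
  s2 <- fit_stage2_brain(data, phys, drug2, free, body_weight, n_starts, seed)
  for (nm in names(s2$estimates)) drug2[[nm]] <- s2$estimates[[nm]]
  list(stage1 = s1, stage2 = s2, drug = drug2)
}

#' Local sensitivity analysis
#'
#' Normalized local sensitivities `d log(output) / d log(parameter)` of a
#' scalar simulation metric with respect to every physiological and
#' drug parameter, by central finite differences with a symmetric
#' multiplicative perturbation. Parameters bounded above by 1 (reflection
#' coefficients, FR) fall back to a one-sided downward difference when the
#' upward perturbation would leave the unit interval; zero-valued
#' parameters are skipped (no multiplicative perturbation exists).
#'
#' @param phys,drug Parameter objects.
#' @param doses Dose events.
#' @param metric Function mapping an `rpbpk_sim` to a scalar, e.g.
#'   `function(sim) auc_trapezoid(sim$t, sim$conc[, "plasma"])`.
#' @param perturbation Relative perturbation in (0, 0.5], default 0.1.
#' @param parameters Optional character vector restricting which parameters
#'   are perturbed.
#' @param t_grid Simulation grid passed to [simulate_rpbpk()].
#' @return Named vector of sensitivity coefficients.
#' @export
local_sensitivity <- function(phys, drug, doses, metric, perturbation = 0.1,
                              parameters = NULL, t_grid = default_grid(48)) {
  if (!is.finite(perturbation) || perturbation <= 0 || perturbation > 0.5)
    stop("local_sensitivity: perturbation must lie in (0, 0.5]")
  base_names <- c(names(phys_params()),
                  "sigma_BBB", "sigma_BCSFB", "sigma_CSF_ISF", "k_deg")
  if (is.null(parameters)) parameters <- base_names
  bad <- setdiff(parameters, base_names)
  if (length(bad))
    stop("local_sensitivity: unknown parameter(s): ", paste(bad, collapse = ", "))

  eval_metric <- function(ph, dr) {
    m <- metric(simulate_rpbpk(ph, dr, doses, t_grid = t_grid))
    if (!is.finite(m)) stop("local_sensitivity: metric is non-finite")
    m
  }
  get_par <- function(nm) {
    if (nm %in% names(phys)) phys[[nm]] else drug[[nm]]
  }
  with_par <- function(nm, val) {
    if (nm %in% names(phys)) {
      p2 <- unclass(phys); p2[[nm]] <- val
      # fluid-balance invariant: scaling Q_CSF/Q_ISF/L_b must stay consistent
      if (nm %in% c("Q_CSF", "Q_ISF"))
        p2[["L_b"]] <- p2[["Q_CSF"]] + p2[["Q_ISF"]]
      if (nm == "L_b") {
        sc <- val / (p2[["Q_CSF"]] + p2[["Q_ISF"]])
        p2[["Q_CSF"]] <- p2[["Q_CSF"]] * sc
        p2[["Q_ISF"]] <- p2[["Q_ISF"]] * sc
      }
      list(phys = structure(p2, class = "phys_params"), drug = drug)
    } else {
      d2 <- drug; d2[[nm]] <- val
      list(phys = phys, drug = d2)
    }
  }
  sens <- setNames(rep(NA_real_, length(parameters)), parameters)
  for (nm in parameters) {
    p0 <- get_par(nm)
    if (p0 == 0) next
    up <- p0 * (1 + perturbation)
    dn <- p0 * (1 - perturbation)
    bounded1 <- nm %in% c("sigma_TV", "sigma_TL", "sigma_BISF", "sigma_CSF",
                          "FR", "sigma_BBB", "sigma_BCSFB", "sigma_CSF_ISF")
    if (bounded1 && up >= 1) up <- p0  # one-sided downward
    mu <- with_par(nm, up); md <- with_par(nm, dn)
    m_up <- eval_metric(mu$phys, mu$drug)
    m_dn <- eval_metric(md$phys, md$drug)
    if (m_up == m_dn) { sens[nm] <- 0; next }
    if (m_up <= 0 || m_dn <= 0)
      stop("local_sensitivity: metric must stay positive for log sensitivity")
    sens[nm] <- (log(m_up) - log(m_dn)) / (log(up) - log(dn))
  }
  sens
}

#' @export
print.rpbpk_fit <- function(x, ...) {
  cat(sprintf("rPBPK %s-stage fit: %d observations, objective %.6g\n",
              x$stage, x$n_obs, x$objective))
  if (!is.null(x$flag)) cat("  FLAG:", x$flag, "\n")
  tab <- data.frame(estimate = x$estimates,
                    transformed = x$transformed_estimates,
                    cv_percent = x$cv_percent)
  print(tab)
  invisible(x)
}
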