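#' Linear trapezoidal AUC
#'
#' Area under a concentration-time curve by the linear trapezoidal rule,
#' the convention used for all exposure metrics in this package.
#'
#' @param t Sampling times (h), strictly increasing, at least two.
#' @param c Concentrations (nM), non-negative, same length as `t`.
#' @return AUC in nM*h.
#' @examples
#' auc_trapezoid(c(0, 1, 2), c(0, 10, 0))  # 10
#' @export
auc_trapezoid <- function(t, c) {
  if (length(t) < 2) stop("auc_trapezoid: need at least two points")
  if (length(t) != length(c)) stop("auc_trapezoid: t and c lengths differ")
  if (any(!is.finite(t)) || any(!is.finite(c)))
    stop("auc_trapezoid: non-finite input")
  if (any(diff(t) <= 0))
    stop("auc_trapezoid: times must be strictly increasing (no duplicates)")
  if (any(c < 0)) stop("auc_trapezoid: negative concentrations")
  sum(diff(t) * (c[-length(c)] + c[-1]) / 2)
}

#' Maximum concentration and its time
#'
#' Observed Cmax and Tmax; ties resolved to the earliest time.
#'
#' @inheritParams auc_trapezoid
#' @return Named numeric vector `c(cmax = , tmax = )`.
#' @export
cmax_tmax <- function(t, c) {
  if (length(t) == 0) stop("cmax_tmax: empty series")
  if (length(t) != length(c)) stop("cmax_tmax: t and c lengths differ")
  if (any(diff(t) <= 0)) stop("cmax_tmax: times must be strictly increasing")
  i <- which.max(c)  # which.max returns the first maximum: earliest-time tie rule
  c(cmax = c[i], tmax = t[i])
}

#' Per-subject non-compartmental analysis
#'
#' Computes AUC(0 - tlast), Cmax and Tmax per subject and matrix from an
#' observation table. Pre-dose samples (t < 0) and below-LLOQ observations
#' are excluded. Dialysate concentrations can be recovery-corrected to the
#' ISF scale before analysis.
#'
#' @param data Observation data.frame as returned by [generate_dataset()] or
#'   [read_pk_table()]: columns `subject`, `group`, `matrix`, `time_h`,
#'   `conc_nM`, `bloq`.
#' @param recovery Optional microdialysis recovery fraction; when given,
#'   `ISF-dialysate` concentrations are divided by it (see
#'   [apply_recovery()]) so that exposure is on the ISF scale.
#' @return data.frame with one row per subject x matrix: `subject`, `group`,
#'   `matrix`, `n_obs`, `auc_0_tlast`, `cmax`, `tmax`.
#' @export
nca_subject <- function(data, recovery = NULL) {
  data <- validate_pk_table(data)
  data <- data[data$time_h >= 0 & !data$bloq, , drop = FALSE]
  if (!nrow(data)) stop("nca_subject: no quantifiable post-dose observations")
  if (!is.null(recovery)) {
    isf <- data$matrix == "ISF-dialysate"
    data$conc_nM[isf] <- apply_recovery(data$conc_nM[isf], recovery)
  }
  keys <- unique(data[, c("subject", "group", "matrix")])
  res <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    d <- data[data$subject == keys$subject[i] & data$matrix == keys$matrix[i], ]
    d <- d[order(d$time_h), ]
    auc <- if (nrow(d) >= 2) auc_trapezoid(d$time_h, d$conc_nM) else NA_real_
    ct <- cmax_tmax(d$time_h, d$conc_nM)
    data.frame(subject = keys$subject[i], group = keys$group[i],
               matrix = keys$matrix[i], n_obs = nrow(d),
               auc_0_tlast = auc, cmax = ct[["cmax"]], tmax = ct[["tmax"]])
  }))
  rownames(res) <- NULL
  res
}

#' Group-level NCA summary with exposure ratios
#'
#' Summarises per-subject NCA results as mean and sample SD per
#' group x matrix (each animal one subject), and computes the cross-matrix
#' exposure ratios CSF/serum, ISF/serum and ISF/CSF (in percent) from the
#' group-mean AUCs. With a single subject the SD is reported as `NA`.
#'
#' @param per_subject Output of [nca_subject()].
#' @return List with `summary` (data.frame of mean/sd per group x matrix)
#'   and `ratios` (data.frame per group with the three percent ratios, plus
#'   per-group Tmax min-max in serum).
#' @export
nca_summarize <- function(per_subject) {
  stopifnot(is.data.frame(per_subject), nrow(per_subject) >= 1)
  agg <- function(v) c(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_)
  keys <- unique(per_subject[, c("group", "matrix")])
  summ <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    d <- per_subject[per_subject$group == keys$group[i] &
                     per_subject$matrix == keys$matrix[i], ]
    a <- agg(d$auc_0_tlast); cm <- agg(d$cmax)
    data.frame(group = keys$group[i], matrix = keys$matrix[i],
               n = nrow(d), auc_mean = a[["mean"]], auc_sd = a[["sd"]],
               cmax_mean = cm[["mean"]], cmax_sd = cm[["sd"]],
               tmax_min = min(d$tmax), tmax_max = max(d$tmax))
  }))
  rownames(summ) <- NULL

  mean_auc <- function(g, m) {
    v <- summ$auc_mean[summ$group == g & summ$matrix == m]
    if (length(v)) v else NA_real_
  }
  ratios <- do.call(rbind, lapply(unique(summ$group), function(g) {
    se <- mean_auc(g, "serum"); cs <- mean_auc(g, "CSF")
    isf <- mean_auc(g, "ISF-dialysate")
    if (is.na(isf)) isf <- mean_auc(g, "ISF")
    data.frame(group = g,
               csf_serum_pct = 100 * cs / se,
               isf_serum_pct = 100 * isf / se,
               isf_csf_pct = 100 * isf / cs)
  }))
  rownames(ratios) <- NULL
  list(summary = summ, ratios = ratios)
}
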