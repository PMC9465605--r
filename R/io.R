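#' Read a PK observation table
#'
#' Reads a delimited observation table with the schema used throughout the
#' package: columns `subject`, `group`, `route` (IV/ICV), `dose_mgkg`,
#' `matrix` (`serum`, `CSF`, `ISF-dialysate` or `ISF`), `time_h`, `conc_nM`
#' and `bloq` (logical below-LLOQ flag); optional dialysate window edges
#' `t0`, `t1`. Concentrations are nM throughout; a `units` column equal to
#' `"ng/ml"` triggers conversion at ingestion using `MW`.
#'
#' @param path CSV file path.
#' @param MW Molecular weight (g/mol), required only for ng/ml conversion.
#' @return Validated observation data.frame.
#' @export
read_pk_table <- function(path, MW = NULL) {
  if (!file.exists(path)) stop("read_pk_table: file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(d$units)) {
    ngml <- d$units == "ng/ml"
    if (any(ngml)) {
      if (is.null(MW))
        stop("read_pk_table: ng/ml units present but MW not supplied")
      d$conc_nM[ngml] <- d$conc_nM[ngml] * 1e3 / MW
    }
    d$units <- NULL
  }
  validate_pk_table(d)
}

# Shared validation with row-numbered messages.
validate_pk_table <- function(d) {
  required <- c("subject", "group", "route", "dose_mgkg", "matrix",
                "time_h", "conc_nM", "bloq")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("observation table: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  d$bloq <- as.logical(d$bloq)
  bad_matrix <- which(!d$matrix %in% c("serum", "CSF", "ISF-dialysate", "ISF"))
  if (length(bad_matrix))
    stop("observation table: unknown matrix '", d$matrix[bad_matrix[1]],
         "' in row ", bad_matrix[1])
  bad_route <- which(!d$route %in% c("IV", "ICV"))
  if (length(bad_route))
    stop("observation table: unknown route '", d$route[bad_route[1]],
         "' in row ", bad_route[1])
  bad_time <- which(d$time_h < 0 & d$time_h != -0.5)
  if (length(bad_time))
    stop("observation table: negative time other than the -0.5 h pre-dose ",
         "sample in row ", bad_time[1])
  bad_conc <- which(!is.finite(d$conc_nM) | (d$conc_nM < 0 & !d$bloq))
  if (length(bad_conc))
    stop("observation table: invalid concentration in row ", bad_conc[1])
  if (is.null(d$t0)) { d$t0 <- NA_real_; d$t1 <- NA_real_ }
  d
}

#' Write a PK observation table
#'
#' @param data Observation data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_table <- function(data, path) {
  write.csv(validate_pk_table(data), path, row.names = FALSE)
  invisible(path)
}

#' Write simulated trajectories as CSV
#'
#' Time versus per-compartment concentration (nM), full double precision
#' (round-trips to better than 12 significant digits).
#'
#' @param sim An `rpbpk_sim`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(sim, path) {
  stopifnot(inherits(sim, "rpbpk_sim"))
  df <- as.data.frame(sim)
  # format with 17 significant digits so read.csv reproduces the doubles
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  out <- data.frame(lapply(df, fmt), check.names = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' JSON configuration with optional blocks `physiology` (parameter
#' overrides), `drug` (fields of [drug_params()]; or `preset` naming one of
#' the built-in compounds), `doses` (list of
#' `{route, dose_mgkg, t_start, ...}`), and `simulation`
#' (`t_end`, `rtol`, `atol`, `body_weight`).
#'
#' @param path JSON file path.
#' @return List with `phys`, `drug`, `doses`, `simulation`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  phys <- do.call(phys_params, as.list(cfg$physiology))
  drug <- if (!is.null(cfg$drug$preset)) {
    switch(cfg$drug$preset,
           "EGFRvIII-TCB" = drug_egfrviii_tcb(),
           "DP47-IgG" = drug_dp47_igg(),
           "DP47-TCB" = drug_dp47_tcb(),
           stop("read_config: unknown drug preset '", cfg$drug$preset, "'"))
  } else {
    do.call(drug_params, as.list(cfg$drug))
  }
  simcfg <- as.list(cfg$simulation)
  if (is.null(simcfg$t_end)) simcfg$t_end <- 48
  if (is.null(simcfg$rtol)) simcfg$rtol <- 1e-8
  if (is.null(simcfg$atol)) simcfg$atol <- 1e-10
  if (is.null(simcfg$body_weight)) simcfg$body_weight <- 0.310
  doses <- list()
  if (!is.null(cfg$doses)) {
    dd <- cfg$doses
    if (is.data.frame(dd)) dd <- split(dd, seq_len(nrow(dd)))
    doses <- lapply(dd, function(x) {
      x <- as.list(x)
      t_start <- if (is.null(x$t_start)) 0 else x$t_start
      if (toupper(x$route) == "IV")
        iv_bolus(x$dose_mgkg, simcfg$body_weight, drug$MW, t_start)
      else
        icv_infusion(x$dose_mgkg, simcfg$body_weight, drug$MW,
                     formulation_conc = x$formulation_conc %||% 20,
                     flow_rate = x$flow_rate %||% 3, t_start = t_start)
    })
    names(doses) <- NULL
  }
  list(phys = phys, drug = drug, doses = doses, simulation = simcfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
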