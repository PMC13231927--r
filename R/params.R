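#' Population pharmacokinetic parameter set
#'
#' Constructs and validates the fixed effects, variance components and
#' residual-error magnitude of the pediatric vancomycin population model.
#' All clearances and volumes are expressed for a 70 kg reference subject;
#' random-effect magnitudes are standard deviations on the log scale (for
#' variabilities in the 10-40% range these are numerically close to the
#' apparent coefficients of variation usually quoted).
#'
#' @param tvcl Typical clearance, L/h per 70 kg.
#' @param theta_scr Renal covariate slope on clearance, per umol/L of the
#'   deviation of serum creatinine from its age standard.
#' @param hill Hill coefficient of the sigmoidal maturation function
#'   (unitless).
#' @param tm50 Postmenstrual age at half-maximal maturation, weeks.
#' @param tvv1 Typical central volume of distribution, L per 70 kg.
#' @param tvq Typical intercompartmental clearance, L/h per 70 kg.
#' @param tvv2 Typical peripheral volume of distribution, L per 70 kg.
#' @param omega_cl SD of the log-scale interindividual variability on CL.
#' @param omega_v1 SD of the log-scale interindividual variability on V1.
#' @param omega_iov_cl SD of the log-scale interoccasion variability on CL.
#' @param sigma_prop Proportional residual error SD (fraction of the
#'   prediction).
#' @param pna_max,pna_t50 Optional parameters of the postnatal-age
#'   transition factor (amplitude in `[0,1]`; half-time in days). `NA` by
#'   default: the final model does not use this factor and no values are
#'   shipped.
#'
#' @return An object of class `pop_params` (a named list).
#' @seealso [vanco_params()] for the published final estimates.
#' @export
#' @examples
#' p <- pop_params(tvcl = 7.56, theta_scr = 0.0188, hill = 3.4, tm50 = 47.7,
#'                 tvv1 = 85.6, tvq = 1.30, tvv2 = 286, omega_cl = 0.221,
#'                 omega_v1 = 0.329, omega_iov_cl = 0.187, sigma_prop = 0.233)
#' p$tvcl
pop_params <- function(tvcl, theta_scr, hill, tm50, tvv1, tvq, tvv2,
                       omega_cl, omega_v1, omega_iov_cl, sigma_prop,
                       pna_max = NA_real_, pna_t50 = NA_real_) {
  p <- list(tvcl = tvcl, theta_scr = theta_scr, hill = hill, tm50 = tm50,
            tvv1 = tvv1, tvq = tvq, tvv2 = tvv2,
            omega_cl = omega_cl, omega_v1 = omega_v1,
            omega_iov_cl = omega_iov_cl, sigma_prop = sigma_prop,
            pna_max = pna_max, pna_t50 = pna_t50)
  validate_pop_params(p)
}

validate_pop_params <- function(p) {
  pos <- c("tvcl", "theta_scr", "hill", "tm50", "tvv1", "tvq", "tvv2")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      stop("pop_params: '", f, "' must be a single positive finite number",
           call. = FALSE)
  }
  nneg <- c("omega_cl", "omega_v1", "omega_iov_cl", "sigma_prop")
  for (f in nneg) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] < 0)
      stop("pop_params: '", f, "' must be a single non-negative finite number",
           call. = FALSE)
  }
  if (!is.na(p$pna_max) && (p$pna_max < 0 || p$pna_max > 1))
    stop("pop_params: 'pna_max' must lie in [0, 1]", call. = FALSE)
  if (!is.na(p$pna_t50) && p$pna_t50 <= 0)
    stop("pop_params: 'pna_t50' must be positive", call. = FALSE)
  structure(p, class = "pop_params")
}

#' Final published parameter estimates
#'
#' Loads the packaged parameter file `table2_final.json` holding the final
#' estimates of the pediatric vancomycin model: TVCL 7.56 L/h/70 kg,
#' creatinine slope 0.0188, Hill 3.4 (fixed), TM50 47.7 weeks (fixed),
#' V1 85.6 L/70 kg, Q 1.30 L/h/70 kg, V2 286 L/70 kg, IIV on CL 22.1% and
#' V1 32.9%, IOV on CL 18.7%, proportional residual error 23.3%.
#'
#' @return A [pop_params()] object.
#' @export
#' @examples
#' vanco_params()$tvcl
vanco_params <- function() {
  path <- system.file("extdata", "table2_final.json", package = "pedvanc",
                      mustWork = TRUE)
  read_params(path)
}

#' Read / write a parameter set as JSON
#'
#' Parameter files are flat JSON objects keyed by the `pop_params` field
#' names. Optional fields (`pna_max`, `pna_t50`) may be absent.
#'
#' @param path File path.
#' @return `read_params` returns a [pop_params()] object; `write_params`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("tvcl", "theta_scr", "hill", "tm50", "tvv1", "tvq", "tvv2",
            "omega_cl", "omega_v1", "omega_iov_cl", "sigma_prop")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("parameter file is missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  pop_params(tvcl = x$tvcl, theta_scr = x$theta_scr, hill = x$hill,
             tm50 = x$tm50, tvv1 = x$tvv1, tvq = x$tvq, tvv2 = x$tvv2,
             omega_cl = x$omega_cl, omega_v1 = x$omega_v1,
             omega_iov_cl = x$omega_iov_cl, sigma_prop = x$sigma_prop,
             pna_max = if (is.null(x$pna_max)) NA_real_ else x$pna_max,
             pna_t50 = if (is.null(x$pna_t50)) NA_real_ else x$pna_t50)
}

#' @rdname read_params
#' @param pop A [pop_params()] object.
#' @export
write_params <- function(pop, path) {
  stopifnot(inherits(pop, "pop_params"))
  x <- unclass(pop)
  if (is.na(x$pna_max)) x$pna_max <- NULL
  if (is.na(x$pna_t50)) x$pna_t50 <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Population PK parameters (70 kg reference)\n")
  cat(sprintf("  CL %0.3g L/h  V1 %0.3g L  Q %0.3g L/h  V2 %0.3g L\n",
              x$tvcl, x$tvv1, x$tvq, x$tvv2))
  cat(sprintf("  maturation: Hill %0.3g, TM50 %0.3g wk;  SCR slope %0.4g\n",
              x$hill, x$tm50, x$theta_scr))
  cat(sprintf("  IIV CL %0.3g, IIV V1 %0.3g, IOV CL %0.3g (log-SD); prop. error %0.3g\n",
              x$omega_cl, x$omega_v1, x$omega_iov_cl, x$sigma_prop))
  invisible(x)
}
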