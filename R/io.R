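## NONMEM-convention event-record I/O and subject extraction.
##
## A TDM dataset is a data frame with one row per dose or observation
## event: ID, TIME (h), AMT (mg; dose rows), RATE (mg/h) and/or DUR (h),
## DV (mg/L; observation rows), EVID (1 dose / 0 observation), MDV,
## OCC, and the covariates AGE (years), WT (kg), SCR (umol/L), PMA
## (weeks, optional). Unknown columns are preserved.

tdm_required <- c("ID", "TIME", "AMT", "DV", "EVID")

#' Validate a data frame as a TDM dataset
#'
#' Checks the NONMEM-style column contract, derives infusion durations
#' from `AMT`/`RATE` when `DUR` is absent, fills `MDV` from `EVID` and
#' assigns occasasions by the 24-h dose-gap rule when `OCC` is missing.
#' Errors name the offending row numbers.
#'
#' @param df A data frame of event records.
#' @return A `tdm_dataset`.
#' @export
as_tdm_dataset <- function(df) {
  miss <- setdiff(tdm_required, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df)) {
    if (any(!is.finite(df$TIME)) || any(df$TIME < 0))
      stop("invalid TIME in row(s): ",
           paste(which(!is.finite(df$TIME) | df$TIME < 0), collapse = ", "),
           call. = FALSE)
    bad <- df$EVID == 1 & !is.na(df$DV)
    if (any(bad))
      stop("dose record with a DV value in row(s): ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    for (id in unique(df$ID)) {
      tt <- df$TIME[df$ID == id]
      if (is.unsorted(tt))
        stop("non-monotone TIME within subject ", id, " (row(s): ",
             paste(which(df$ID == id)[which(diff(tt) < 0) + 1L],
                   collapse = ", "), ")", call. = FALSE)
    }
    if (is.null(df$DUR) || all(is.na(df$DUR)) || all(df$DUR == 0)) {
      if (!is.null(df$RATE)) {
        df$DUR <- ifelse(df$EVID == 1 & df$RATE > 0, df$AMT / df$RATE, 0)
      } else stop("dose records need DUR or RATE", call. = FALSE)
    }
    bad_dur <- df$EVID == 1 & (is.na(df$DUR) | df$DUR <= 0)
    if (any(bad_dur))
      stop("dose record without a positive duration in row(s): ",
           paste(which(bad_dur), collapse = ", "), call. = FALSE)
  } else if (is.null(df$DUR)) df$DUR <- numeric(0)
  if (is.null(df$MDV)) df$MDV <- as.integer(df$EVID != 0)
  if (is.null(df$RATE))
    df$RATE <- ifelse(df$EVID == 1, df$AMT / df$DUR, 0)
  if (is.null(df$OCC)) {
    df$OCC <- NA_integer_
    for (id in unique(df$ID)) {
      i <- which(df$ID == id)
      dose_i <- i[df$EVID[i] == 1]
      occ_d <- assign_occasions(df$TIME[dose_i])
      df$OCC[dose_i] <- occ_d
      obs_i <- i[df$EVID[i] == 0]
      df$OCC[obs_i] <- vapply(df$TIME[obs_i], function(tt) {
        j <- which(df$TIME[dose_i] <= tt + 1e-9)
        if (length(j)) occ_d[max(j)] else 1L
      }, integer(1))
    }
  }
  structure(df, class = unique(c("tdm_dataset", class(df))))
}

#' Occasion assignment by dose gap
#'
#' A new treatment occasion begins whenever the gap between consecutive
#' doses exceeds `gap` hours (default 24).
#'
#' @param dose_times Sorted dose start times, h.
#' @param gap Gap threshold, h.
#' @return Integer occasion indices.
#' @export
assign_occasions <- function(dose_times, gap = 24) {
  if (!length(dose_times)) return(integer(0))
  cumsum(c(1L, as.integer(diff(dose_times) > gap)))
}

#' Read / write a TDM dataset as CSV
#'
#' Comma-separated, `.` decimal, UTF-8; header row with the NONMEM-style
#' column names. `read_tdm` validates via [as_tdm_dataset()]; a write
#' followed by a read restores the dataset.
#'
#' @param path File path.
#' @return `read_tdm`: a `tdm_dataset`. `write_tdm`: `path`, invisibly.
#' @export
read_tdm <- function(path) {
  df <- utils::read.csv(path)
  as_tdm_dataset(df)
}

#' @rdname read_tdm
#' @param ds A `tdm_dataset`.
#' @export
write_tdm <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Extract one subject's data for estimation
#'
#' @param ds A `tdm_dataset`.
#' @param id Subject identifier.
#' @return A list: `id`, `cov` ([subject_covariates()]), `reg`
#'   ([regimen()]), `obs` (data frame `time`, `dv`, `occ`), `cont`
#'   (infusion-mode flag when a `CONT` column is present).
#' @export
subject_data <- function(ds, id) {
  d <- ds[ds$ID == id, , drop = FALSE]
  if (!nrow(d)) stop("no records for subject ", id, call. = FALSE)
  dose <- d[d$EVID == 1, , drop = FALSE]
  obs <- d[d$EVID == 0, , drop = FALSE]
  cov <- subject_covariates(
    age = d$AGE[1], wt = d$WT[1], scr = d$SCR[1],
    pma = if (!is.null(d$PMA) && !is.na(d$PMA[1])) d$PMA[1] else NULL)
  reg <- regimen(time = dose$TIME, amt = dose$AMT, dur = dose$DUR,
                 occ = dose$OCC,
                 horizon = max(d$TIME) + 24)
  list(id = id, cov = cov, reg = reg,
       obs = data.frame(time = obs$TIME, dv = obs$DV, occ = obs$OCC),
       cont = if (!is.null(d$CONT)) d$CONT[d$EVID == 0] else NULL)
}

# all subjects of a dataset as estimation-ready lists
prepare_subjects <- function(ds) {
  lapply(unique(ds$ID), function(id) subject_data(ds, id))
}
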