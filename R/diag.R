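#' Conditional weighted residuals
#'
#' CWRES from the FOCE-I linearization at each subject's conditional
#' mode: the residual of the observation vector about its linearized
#' marginal mean, decorrelated by the Cholesky factor of the linearized
#' marginal covariance. Under a correctly specified model these are
#' approximately standard normal. A singular covariance is ridged by
#' 1e-10 with a warning.
#'
#' @param pop A [pop_params()] object (fitted or fixed).
#' @param dataset A `tdm_dataset`.
#' @param estimate_kappa Include IOV effects in the conditional modes.
#' @return A data frame with one row per observation: `ID`, `TIME`,
#'   `TAPD` (time after previous dose), `DV`, `PRED` (typical
#'   prediction), `IPRED` (individual prediction at the mode), `EPRED`
#'   (linearized marginal mean), `CWRES`.
#' @export
cwres <- function(pop, dataset, estimate_kappa = TRUE) {
  subs <- prepare_subjects(dataset)
  out <- lapply(subs, function(sub) {
    if (nrow(sub$obs) == 0L) return(NULL)
    ctx <- subject_context(pop, sub, estimate_kappa)
    m <- map_mode(ctx)
    fs <- foce_subject(ctx, m$par)
    typ <- typical_params(pop, sub$cov)
    data.frame(ID = sub$id, TIME = sub$obs$time,
               TAPD = tapd(sub$reg, sub$obs$time),
               DV = sub$obs$dv,
               PRED = concentration(typ, sub$reg, sub$obs$time),
               IPRED = fs$ipred, EPRED = fs$epred, CWRES = fs$cwres)
  })
  do.call(rbind, out)
}

# time after previous dose start (the binning variable of the VPC)
tapd <- function(reg, t) {
  vapply(t, function(tt) {
    i <- which(reg$time <= tt + 1e-9)
    if (length(i)) tt - max(reg$time[i]) else tt
  }, numeric(1))
}

#' Goodness-of-fit tables
#'
#' Per-observation population predictions (all random effects zero) and
#' individual predictions (MAP modes), with identity-line regression
#' summaries for both.
#'
#' @inheritParams cwres
#' @return A list: `table` (data frame `ID, TIME, DV, PRED, IPRED`) and
#'   `slopes` (intercept/slope of `DV ~ PRED` and `DV ~ IPRED`).
#' @export
gof_tables <- function(pop, dataset, estimate_kappa = TRUE) {
  subs <- prepare_subjects(dataset)
  tab <- do.call(rbind, lapply(subs, function(sub) {
    if (nrow(sub$obs) == 0L) return(NULL)
    typ <- typical_params(pop, sub$cov)
    fit <- map_estimate(pop, sub, estimate_kappa)
    data.frame(ID = sub$id, TIME = sub$obs$time, DV = sub$obs$dv,
               PRED = concentration(typ, sub$reg, sub$obs$time),
               IPRED = fit$ipred)
  }))
  slopes <- rbind(
    PRED = stats::coef(stats::lm(DV ~ PRED, data = tab)),
    IPRED = stats::coef(stats::lm(DV ~ IPRED, data = tab)))
  colnames(slopes) <- c("intercept", "slope")
  list(table = tab, slopes = slopes)
}

#' VPC configuration
#'
#' @param n_sim Number of simulated replicates (default 1000).
#' @param n_bins Number of quantile-based bins on time after previous
#'   dose (ignored when `bin_edges` given).
#' @param bin_edges Optional explicit bin edges, h.
#' @param percentiles Summary percentiles (default 5th, 50th, 95th).
#' @param ci Confidence level for the simulated percentile bands.
#' @param stratify Split by infusion mode using the dataset's `CONT`
#'   flag column (intermittent vs continuous), when present.
#' @param min_bin Minimum observations per bin; smaller bins are merged
#'   with their neighbor.
#' @return A list of class `vpc_config`.
#' @export
vpc_config <- function(n_sim = 1000, n_bins = 6, bin_edges = NULL,
                       percentiles = c(0.05, 0.5, 0.95), ci = 0.95,
                       stratify = FALSE, min_bin = 5L) {
  stopifnot(length(percentiles) == 3L, !is.unsorted(percentiles),
            ci > 0, ci < 1)
  structure(list(n_sim = n_sim, n_bins = n_bins, bin_edges = bin_edges,
                 percentiles = percentiles, ci = ci, stratify = stratify,
                 min_bin = min_bin), class = "vpc_config")
}

# quantile bin assignment with small-bin merging
make_bins <- function(x, cfg) {
  edges <- cfg$bin_edges
  if (is.null(edges)) {
    probs <- seq(0, 1, length.out = cfg$n_bins + 1)
    edges <- unique(stats::quantile(x, probs, names = FALSE))
  }
  edges[1] <- min(edges[1], min(x)); edges[length(edges)] <- max(edges[length(edges)], max(x))
  bin <- cut(x, edges, include.lowest = TRUE, labels = FALSE)
  # merge bins with too few observations into their left neighbor
  repeat {
    counts <- tabulate(bin, nbins = max(bin))
    small <- which(counts > 0 & counts < cfg$min_bin)
    if (!length(small) || length(unique(bin[!is.na(bin)])) <= 1) break
    s <- small[1]
    target <- if (s > 1) s - 1L else s + 1L
    bin[bin == s] <- target
    bin <- match(bin, sort(unique(bin))) # relabel consecutively
  }
  bin
}

#' Prediction-corrected visual predictive check
#'
#' Bins observations by time after previous dose, prediction-corrects
#' each observation by the ratio of its bin's median population
#' prediction to its own (`DV_pc = DV * median(PRED in bin) / PRED`),
#' and compares observed bin percentiles against confidence bands of the
#' same percentiles computed from datasets re-simulated under the model
#' (same subjects, regimens and sampling times; fresh random effects and
#' residual errors; identical prediction correction).
#'
#' @param pop A [pop_params()] object.
#' @param dataset A `tdm_dataset`.
#' @param cfg A [vpc_config()].
#' @param seed Integer seed for the simulation replicates.
#' @return A data frame with one row per stratum x bin: observation
#'   count, bin midpoint, observed percentiles (`obs_lo`, `obs_med`,
#'   `obs_hi`) and simulated confidence bands for each
#'   (`lo_lo ... hi_hi`).
#' @export
pcvpc <- function(pop, dataset, cfg = vpc_config(), seed = 1L) {
  stopifnot(inherits(cfg, "vpc_config"))
  subs <- prepare_subjects(dataset)
  subs <- Filter(function(s) nrow(s$obs) > 0, subs)
  # per-observation bookkeeping across subjects
  obs_tab <- do.call(rbind, lapply(seq_along(subs), function(i) {
    sub <- subs[[i]]
    typ <- typical_params(pop, sub$cov)
    data.frame(subj = i, time = sub$obs$time, dv = sub$obs$dv,
               tapd = tapd(sub$reg, sub$obs$time),
               pred = concentration(typ, sub$reg, sub$obs$time),
               strat = if (cfg$stratify && !is.null(sub$cont))
                 sub$cont else 0L)
  }))
  # simulate all replicates once: obs_tab rows are ordered subject by
  # subject, matching the concatenation below
  set.seed(seed)
  sim_dv <- matrix(NA_real_, nrow(obs_tab), cfg$n_sim)
  for (r in seq_len(cfg$n_sim)) {
    f <- unlist(lapply(seq_along(subs), function(i) {
      sub <- subs[[i]]
      ind <- draw_individual(pop, sub$cov, n_occasions = max(sub$reg$occ))
      concentration(ind, sub$reg, sub$obs$time)
    }))
    sim_dv[, r] <- f * (1 + pop$sigma_prop * stats::rnorm(length(f)))
  }
  qs <- function(x) stats::quantile(x, cfg$percentiles, names = FALSE)
  res <- lapply(split(seq_len(nrow(obs_tab)), obs_tab$strat), function(ix) {
    ot <- obs_tab[ix, ]
    ot$bin <- make_bins(ot$tapd, cfg)
    med_pred <- stats::ave(ot$pred, ot$bin, FUN = stats::median)
    corr <- med_pred / ot$pred
    obs_q <- do.call(rbind, lapply(split(ot$dv * corr, ot$bin), qs))
    n_bin <- nrow(obs_q)
    sim_q <- array(NA_real_, c(cfg$n_sim, n_bin, 3))
    for (r in seq_len(cfg$n_sim)) {
      pc <- sim_dv[ix, r] * corr
      sim_q[r, , ] <- do.call(rbind, lapply(split(pc, ot$bin), qs))
    }
    a <- (1 - cfg$ci) / 2
    ci_lo <- apply(sim_q, c(2, 3), stats::quantile, a)
    ci_hi <- apply(sim_q, c(2, 3), stats::quantile, 1 - a)
    dim(ci_lo) <- dim(ci_hi) <- c(n_bin, 3)
    data.frame(
      strat = ot$strat[1],
      bin = sort(unique(ot$bin)),
      n = as.vector(table(ot$bin)),
      t_mid = vapply(split(ot$tapd, ot$bin), stats::median, numeric(1)),
      obs_lo = obs_q[, 1], obs_med = obs_q[, 2], obs_hi = obs_q[, 3],
      lo_lo = ci_lo[, 1], lo_hi = ci_hi[, 1],
      med_lo = ci_lo[, 2], med_hi = ci_hi[, 2],
      hi_lo = ci_lo[, 3], hi_hi = ci_hi[, 3])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
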