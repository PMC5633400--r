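# Unedited-allele (wt) fraction from multiplex qPCR Cq tables by the
# delta-delta-Cq method, with replicate summarization, first-order error
# propagation, and the calibration-slope probe-compatibility check.
#
# Assumptions: amplification efficiency 2.0 on both channels (the
# calibration-slope check is the guard); the calibrator is a designated
# wild-type control sample whose wt fraction is 100% by construction.

QPCR_CHANNELS <- c("target", "reference")

check_wells <- function(wells) {
  req <- c("sample_id", "channel", "replicate", "cq")
  miss <- setdiff(req, names(wells))
  if (length(miss)) {
    stop("well table lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(wells$flag)) wells$flag <- ""
  wells$flag[is.na(wells$flag)] <- ""
  if (!all(wells$channel %in% QPCR_CHANNELS)) {
    stop("channel must be one of: ", paste(QPCR_CHANNELS, collapse = ", "),
         call. = FALSE)
  }
  bad <- wells$flag == "" & (!is.finite(wells$cq) | wells$cq <= 0)
  if (any(bad)) {
    stop("unflagged wells must carry a positive numeric Cq", call. = FALSE)
  }
  wells
}

#' Summarize replicate wells per sample and channel
#'
#' Replicates flagged `noamp` are excluded. With three or more usable
#' replicates, a replicate farther than `outlier_cycles` from the replicate
#' median is flagged as an outlier and excluded from the mean.
#'
#' @param wells data.frame of wells (`sample_id`, `channel`, `replicate`,
#'   `cq`, optional `flag`).
#' @param outlier_cycles outlier cutoff in cycles (default 0.5).
#' @return data.frame per (sample, channel): `n`, `n_used`, `mean_cq`, `sd`,
#'   `sem`, `n_outliers`, `flag` (`"noamp"` when every replicate failed).
#' @export
summarize_replicates <- function(wells, outlier_cycles = 0.5) {
  wells <- check_wells(wells)
  groups <- split(wells, list(wells$sample_id, wells$channel), drop = TRUE)
  out <- lapply(groups, function(g) {
    base <- data.frame(sample_id = g$sample_id[1], channel = g$channel[1],
                       n = nrow(g), stringsAsFactors = FALSE)
    cq <- g$cq[g$flag != "noamp"]
    if (length(cq) == 0L) {
      return(cbind(base, data.frame(n_used = 0L, mean_cq = NA_real_,
                                    sd = NA_real_, sem = NA_real_,
                                    n_outliers = 0L, flag = "noamp")))
    }
    out_flag <- rep(FALSE, length(cq))
    if (length(cq) >= 3L) out_flag <- abs(cq - median(cq)) > outlier_cycles
    used <- cq[!out_flag]
    if (length(used) == 0L) used <- cq  # degenerate: keep everything
    s <- if (length(used) > 1L) sd(used) else 0
    cbind(base, data.frame(n_used = length(used), mean_cq = mean(used),
                           sd = s, sem = s / sqrt(length(used)),
                           n_outliers = sum(out_flag), flag = ""))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sample_id, res$channel), , drop = FALSE]
}

#' Wild-type allele fraction by the delta-delta-Cq method
#'
#' Per sample, `dCq = mean Cq(target) - mean Cq(reference)`;
#' `ddCq = dCq(sample) - dCq(calibrator)`; the wt fraction is
#' `100 * 2^(-ddCq)`, reported clipped to [0, 100] with the raw value
#' retained. The SEM is propagated to the percentage scale from replicate
#' Cq variability (first order). In `dropoff` mode both channels come from
#' the same multiplexed reaction; in `trans_multiplex` mode the reference
#' channel is an external single-copy reference assay — the arithmetic is
#' identical, the mode is recorded and checked against the well layout.
#'
#' @param wells data.frame of wells.
#' @param calibrator_id sample id of the wild-type calibrator (present with
#'   both channels).
#' @param mode `"dropoff"` or `"trans_multiplex"`.
#' @param outlier_cycles passed to [summarize_replicates()].
#' @return data.frame of class `ddcq_result`: per sample `delta_cq`,
#'   `delta_delta_cq`, `wt_percent` (clipped), `wt_percent_raw`,
#'   `sem_percent`, `flag`.
#' @export
ddcq_wt_fraction <- function(wells, calibrator_id,
                             mode = c("dropoff", "trans_multiplex"),
                             outlier_cycles = 0.5) {
  mode <- match.arg(mode)
  s <- summarize_replicates(wells, outlier_cycles)
  samples <- unique(s$sample_id)
  if (!calibrator_id %in% samples) {
    stop("calibrator sample not present: ", calibrator_id, call. = FALSE)
  }
  get <- function(id, ch) s[s$sample_id == id & s$channel == ch, ]
  cal_t <- get(calibrator_id, "target")
  cal_r <- get(calibrator_id, "reference")
  if (nrow(cal_t) == 0L || nrow(cal_r) == 0L || cal_t$flag == "noamp" ||
      cal_r$flag == "noamp") {
    stop("calibrator must amplify on both channels", call. = FALSE)
  }
  dcq_cal <- cal_t$mean_cq - cal_r$mean_cq
  var_cal <- cal_t$sem^2 + cal_r$sem^2

  rows <- lapply(samples, function(id) {
    t <- get(id, "target")
    r <- get(id, "reference")
    base <- data.frame(sample_id = id, mode = mode,
                       stringsAsFactors = FALSE)
    if (nrow(t) == 0L || nrow(r) == 0L) {
      return(cbind(base, data.frame(
        delta_cq = NA_real_, delta_delta_cq = NA_real_,
        wt_percent = NA_real_, wt_percent_raw = NA_real_,
        sem_percent = NA_real_, flag = "missing_channel")))
    }
    if (r$flag == "noamp") {
      return(cbind(base, data.frame(
        delta_cq = NA_real_, delta_delta_cq = NA_real_,
        wt_percent = NA_real_, wt_percent_raw = NA_real_,
        sem_percent = NA_real_, flag = "no_reference_amplification")))
    }
    if (t$flag == "noamp") {
      return(cbind(base, data.frame(
        delta_cq = NA_real_, delta_delta_cq = NA_real_,
        wt_percent = 0, wt_percent_raw = 0, sem_percent = NA_real_,
        flag = "below_detection")))
    }
    dcq <- t$mean_cq - r$mean_cq
    ddcq <- dcq - dcq_cal
    raw <- 100 * 2^(-ddcq)
    var_dd <- t$sem^2 + r$sem^2 +
      if (id == calibrator_id) 0 else var_cal
    sem_pct <- raw * log(2) * sqrt(var_dd)
    cbind(base, data.frame(
      delta_cq = dcq, delta_delta_cq = ddcq,
      wt_percent = clamp(raw, 0, 100), wt_percent_raw = raw,
      sem_percent = sem_pct,
      flag = if (raw > 100) "above_calibrator" else ""))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("ddcq_result", "data.frame")
  attr(res, "calibrator_id") <- calibrator_id
  res
}

#' @export
print.ddcq_result <- function(x, ...) {
  cat(sprintf("ddCq wt-fraction estimates (calibrator: %s)\n",
              attr(x, "calibrator_id")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Calibration-curve slope check (probe compatibility)
#'
#' Fits `dCq` against `log10(input)` by ordinary least squares over a
#' dilution series; a near-zero slope indicates the target and reference
#' probes amplify with compatible efficiencies so the delta-delta-Cq
#' assumption holds.
#'
#' @param series data.frame of wells with an extra `log10_input` column
#'   (at least 3 distinct input levels), or a data.frame with columns
#'   `log10_input` and `delta_cq` (one row per level).
#' @param threshold pass when `|slope| <= threshold` (dCq per log10 input).
#' @return list: `slope`, `intercept`, `r_squared`, `pass`, `levels`.
#' @export
calibration_slope <- function(series, threshold = 0.1) {
  if (all(c("log10_input", "delta_cq") %in% names(series))) {
    df <- series[, c("log10_input", "delta_cq")]
  } else {
    series <- check_wells(series)
    if (is.null(series$log10_input)) {
      stop("dilution series needs a log10_input column", call. = FALSE)
    }
    levels <- split(series, series$log10_input)
    df <- do.call(rbind, lapply(levels, function(g) {
      s <- summarize_replicates(g)
      t <- s[s$channel == "target", ]
      r <- s[s$channel == "reference", ]
      data.frame(log10_input = g$log10_input[1],
                 delta_cq = t$mean_cq - r$mean_cq)
    }))
  }
  if (length(unique(df$log10_input)) < 3L) {
    stop("calibration series needs >= 3 distinct input levels",
         call. = FALSE)
  }
  fit <- lm(delta_cq ~ log10_input, data = df)
  slope <- unname(coef(fit)[2])
  r2 <- if (sd(df$delta_cq) == 0) 1 else suppressWarnings(summary(fit)$r.squared)
  list(slope = slope, intercept = unname(coef(fit)[1]), r_squared = r2,
       pass = abs(slope) <= threshold, levels = nrow(df))
}
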