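# Digital PCR: two-channel partition classification, Poisson occupancy
# estimation, and the wt-fraction ratio estimator with a delta-method
# confidence interval.
#
# Model: both probe sites sit on the same short amplicon, so the occupancy
# of the two sites is perfectly linked (one molecule carries both); the wt
# fraction is the ratio of Poisson mean occupancies
# 100 * lambda_target / lambda_reference.

#' Classify dPCR partitions into two-channel positivity classes
#'
#' Accepts boolean calls (`ref_positive`, `target_positive`) or raw
#' two-channel fluorescence (`fluor_ref`, `fluor_target`). With raw input,
#' per-channel thresholds are either user-fixed or set automatically at the
#' deepest density valley between the two largest modes of the per-channel
#' fluorescence distribution; a unimodal channel is an error instructing
#' manual thresholds.
#'
#' @param chip data.frame of partitions.
#' @param thresholds optional numeric `c(ref, target)` fluorescence
#'   thresholds.
#' @return list of class `dpcr_classes`: `counts` (double_pos, ref_only,
#'   target_only, double_neg), `n_total`, `thresholds` (if used), `calls`
#'   (per-partition class), `anomaly` flag for target-only partitions.
#' @export
classify_partitions <- function(chip, thresholds = NULL) {
  stopifnot(is.data.frame(chip))
  if (nrow(chip) < 100L) {
    stop("need >= 100 readable partitions", call. = FALSE)
  }
  if (all(c("ref_positive", "target_positive") %in% names(chip))) {
    rp <- as.logical(chip$ref_positive)
    tp <- as.logical(chip$target_positive)
    thresholds_used <- NULL
  } else if (all(c("fluor_ref", "fluor_target") %in% names(chip))) {
    if (is.null(thresholds)) {
      thresholds <- c(auto_threshold(chip$fluor_ref, "reference"),
                      auto_threshold(chip$fluor_target, "target"))
    }
    rp <- chip$fluor_ref > thresholds[1]
    tp <- chip$fluor_target > thresholds[2]
    thresholds_used <- thresholds
  } else {
    stop("chip must carry boolean calls or two-channel fluorescence",
         call. = FALSE)
  }
  calls <- ifelse(rp & tp, "double_pos",
                  ifelse(rp, "ref_only",
                         ifelse(tp, "target_only", "double_neg")))
  counts <- c(double_pos = sum(rp & tp), ref_only = sum(rp & !tp),
              target_only = sum(!rp & tp), double_neg = sum(!rp & !tp))
  structure(list(counts = counts, n_total = nrow(chip),
                 thresholds = thresholds_used, calls = calls,
                 anomaly = unname(counts["target_only"] > 0)),
            class = "dpcr_classes")
}

# Valley threshold between the two dominant modes of a channel histogram.
# A channel counts as bimodal only when two substantial modes (>= 5% of the
# tallest peak) are separated by a valley dropping below half the smaller
# mode; anything else is reported unimodal and requires manual thresholds.
auto_threshold <- function(x, channel) {
  d <- density(x, n = 512)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  is_max <- is_max[y[is_max] >= 0.05 * max(y)]
  unimodal <- function() {
    stop(sprintf(
      "channel '%s' fluorescence looks unimodal; supply manual thresholds",
      channel), call. = FALSE)
  }
  if (length(is_max) < 2L) unimodal()
  top2 <- is_max[order(y[is_max], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(y[lo:hi]) - 1L
  if (y[valley] > 0.5 * min(y[top2])) unimodal()
  d$x[valley]
}

#' @export
print.dpcr_classes <- function(x, ...) {
  cat(sprintf("dPCR partition classes (n = %d):\n", x$n_total))
  print(x$counts)
  if (!is.null(x$thresholds)) {
    cat(sprintf("  auto/fixed thresholds: ref %.0f, target %.0f\n",
                x$thresholds[1], x$thresholds[2]))
  }
  if (x$anomaly) cat("  note: target-only partitions present (anomalous)\n")
  invisible(x)
}

#' Poisson mean occupancy from a positive-partition count
#'
#' `lambda = -ln(1 - positives/total)`; the 95% CI transforms a Wilson
#' score interval on the positive proportion (well-behaved near 0 and 1).
#'
#' @param positives positive partitions.
#' @param total readable partitions.
#' @param conf confidence level.
#' @return list: `lambda`, `ci` (length 2), `p`.
#' @export
poisson_lambda <- function(positives, total, conf = 0.95) {
  stopifnot(total >= 1L, positives >= 0L, positives <= total)
  if (positives == total) {
    stop("chip saturated (all partitions positive): lambda is infinite; ",
         "dilute and rerun", call. = FALSE)
  }
  p <- positives / total
  z <- qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / total
  center <- (p + z^2 / (2 * total)) / denom
  half <- z * sqrt(p * (1 - p) / total + z^2 / (4 * total^2)) / denom
  ci_p <- clamp(c(center - half, center + half), 0, 1 - 1e-12)
  list(lambda = -log(1 - p), ci = -log(1 - ci_p), p = p)
}

#' Wild-type fraction from dPCR class counts
#'
#' `lambda_target` uses target-positive partitions (double positive +
#' target-only), `lambda_reference` uses reference-positive partitions
#' (double positive + reference-only); the wt fraction is
#' `100 * lambda_target / lambda_reference`. The 95% CI is a first-order
#' (delta-method) interval on the log ratio using the full multinomial
#' covariance of the two positive fractions — the shared double-positive
#' class makes them strongly correlated.
#'
#' @param classes a [classify_partitions()] result or a named count vector.
#' @param conf confidence level.
#' @return object of class `dpcr_estimate`: `lambda_reference`,
#'   `lambda_target`, `wt_percent` (clipped to [0,100], raw retained),
#'   `ci95` on the percentage scale, `flags`.
#' @export
wt_fraction_dpcr <- function(classes, conf = 0.95) {
  counts <- if (inherits(classes, "dpcr_classes")) classes$counts
            else classes
  req <- c("double_pos", "ref_only", "target_only", "double_neg")
  stopifnot(all(req %in% names(counts)))
  counts <- counts[req]
  n <- sum(counts)
  p_r <- (counts[["double_pos"]] + counts[["ref_only"]]) / n
  p_t <- (counts[["double_pos"]] + counts[["target_only"]]) / n
  if (p_r == 0) stop("no reference-positive partitions: no template",
                     call. = FALSE)
  if (p_r == 1) stop("reference channel saturated; dilute and rerun",
                     call. = FALSE)
  lam_r <- -log(1 - p_r)
  lam_t <- -log(1 - p_t)
  raw <- 100 * lam_t / lam_r
  flags <- character(0)
  if (counts[["target_only"]] > 0) flags <- c(flags, "target_only_partitions")
  if (lam_t > lam_r) flags <- c(flags, "target_exceeds_reference")

  if (lam_t == 0) {
    ci <- c(0, 0)
    se_log <- NA_real_
  } else {
    p_both <- counts[["double_pos"]] / n
    var_pr <- p_r * (1 - p_r) / n
    var_pt <- p_t * (1 - p_t) / n
    cov_pp <- (p_both - p_r * p_t) / n
    var_lr <- var_pr / (1 - p_r)^2
    var_lt <- var_pt / (1 - p_t)^2
    cov_l <- cov_pp / ((1 - p_r) * (1 - p_t))
    se_log <- sqrt(max(0, var_lt / lam_t^2 + var_lr / lam_r^2 -
                         2 * cov_l / (lam_t * lam_r)))
    z <- qnorm(1 - (1 - conf) / 2)
    ci <- raw * exp(c(-1, 1) * z * se_log)
  }
  structure(list(lambda_reference = lam_r, lambda_target = lam_t,
                 wt_percent = clamp(raw, 0, 100), wt_percent_raw = raw,
                 ci95 = ci, se_log = se_log, n_partitions = n,
                 counts = counts, flags = flags),
            class = "dpcr_estimate")
}

#' @export
print.dpcr_estimate <- function(x, ...) {
  cat(sprintf(
    "dPCR estimate: wt = %.2f%% (95%% CI %.2f-%.2f); lambda ref %.4f, target %.4f; n = %d\n",
    x$wt_percent, x$ci95[1], x$ci95[2], x$lambda_reference,
    x$lambda_target, x$n_partitions))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
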