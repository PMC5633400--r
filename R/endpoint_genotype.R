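# Control-anchored genotype calling from competitive allele-specific probe
# endpoint fluorescence. Samples are normalized per channel against
# NTC-subtracted control maxima and classified by nearest control centroid
# in (signal angle, amplitude) space; distances are scaled by the pooled
# within-control spread so calls are invariant to common-mode gain changes.

GENOTYPE_ROLES <- c("unknown", "control_WT", "control_HET", "control_HOMO",
                    "NTC")

#' Call genotypes from an allelic-discrimination endpoint table
#'
#' Requires at least one control per genotype class. Channels are normalized
#' by the NTC-subtracted control maxima; each sample is then described by
#' its signal angle `atan2(mut, wt)` and amplitude, and assigned the nearest
#' control centroid (distances scaled per axis by the pooled within-control
#' SD). A sample farther than `mosaic_cutoff` scale units from every
#' centroid but above the no-template noise floor is reported as
#' `founder_mosaic_candidate` (mosaic founders carry allele mixtures that
#' fall between the discrete control clusters); a sample at the noise floor
#' is `indeterminate`. NTC rows never receive a genotype.
#'
#' @param samples data.frame: `sample_id`, `role` (one of
#'   `r paste(GENOTYPE_ROLES, collapse = ", ")`), `fluor_wt`, `fluor_mut`.
#' @param mosaic_cutoff centroid-distance cutoff in within-control SD units.
#' @param noise_margin multiple of the NTC spread defining the detection
#'   floor.
#' @return data.frame of class `genotype_calls`: `sample_id`, `role`,
#'   `call`, `distance` (to the nearest centroid, SD units), `nearest`.
#' @export
call_genotypes <- function(samples, mosaic_cutoff = 3, noise_margin = 3) {
  req <- c("sample_id", "role", "fluor_wt", "fluor_mut")
  stopifnot(all(req %in% names(samples)))
  if (!all(samples$role %in% GENOTYPE_ROLES)) {
    stop("role must be one of: ", paste(GENOTYPE_ROLES, collapse = ", "),
         call. = FALSE)
  }
  if (any(samples$fluor_wt < 0 | samples$fluor_mut < 0)) {
    stop("fluorescence must be >= 0", call. = FALSE)
  }
  ctrl_classes <- c(control_WT = "WT", control_HET = "HET",
                    control_HOMO = "HOMO")
  missing_ctrl <- names(ctrl_classes)[!names(ctrl_classes) %in% samples$role]
  if (length(missing_ctrl)) {
    stop("missing control class(es): ", paste(missing_ctrl, collapse = ", "),
         call. = FALSE)
  }

  ntc <- samples[samples$role == "NTC", , drop = FALSE]
  ntc_wt <- if (nrow(ntc)) mean(ntc$fluor_wt) else 0
  ntc_mut <- if (nrow(ntc)) mean(ntc$fluor_mut) else 0
  ctrl <- samples[samples$role %in% names(ctrl_classes), , drop = FALSE]
  max_wt <- max(ctrl$fluor_wt - ntc_wt)
  max_mut <- max(ctrl$fluor_mut - ntc_mut)
  if (max_wt <= 0 || max_mut <= 0) {
    stop("controls do not rise above the no-template background",
         call. = FALSE)
  }
  nx <- pmax(0, (samples$fluor_wt - ntc_wt) / max_wt)
  ny <- pmax(0, (samples$fluor_mut - ntc_mut) / max_mut)
  angle <- atan2(ny, nx)
  amp <- sqrt(nx^2 + ny^2)

  is_ctrl <- samples$role %in% names(ctrl_classes)
  cls <- ctrl_classes[samples$role[is_ctrl]]
  cent_angle <- tapply(angle[is_ctrl], cls, mean)
  cent_amp <- tapply(amp[is_ctrl], cls, mean)
  # pooled within-control spread per axis (floor keeps single-replicate
  # controls usable)
  spread <- function(v) {
    s <- unlist(lapply(split(v, cls), function(g) g - mean(g)))
    max(sqrt(mean(s^2)), 0.02)
  }
  s_angle <- spread(angle[is_ctrl])
  s_amp <- spread(amp[is_ctrl])

  ntc_amp <- if (nrow(ntc)) {
    sqrt(pmax(0, (ntc$fluor_wt - ntc_wt) / max_wt)^2 +
           pmax(0, (ntc$fluor_mut - ntc_mut) / max_mut)^2)
  } else 0
  floor_amp <- max(ntc_amp) + noise_margin * max(sd(ntc_amp), 0.01)

  k <- names(cent_angle)
  res <- lapply(seq_len(nrow(samples)), function(i) {
    if (samples$role[i] == "NTC") {
      return(data.frame(sample_id = samples$sample_id[i], role = "NTC",
                        call = NA_character_, distance = NA_real_,
                        nearest = NA_character_, stringsAsFactors = FALSE))
    }
    d <- sqrt(((angle[i] - cent_angle) / s_angle)^2 +
                ((amp[i] - cent_amp) / s_amp)^2)
    j <- which.min(d)
    call <- if (amp[i] < floor_amp) "indeterminate"
            else if (d[j] > mosaic_cutoff) "founder_mosaic_candidate"
            else k[j]
    data.frame(sample_id = samples$sample_id[i], role = samples$role[i],
               call = call, distance = unname(d[j]), nearest = k[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("genotype_calls", "data.frame")
  attr(out, "centroids") <- data.frame(class = k, angle = unname(cent_angle),
                                       amplitude = unname(cent_amp))
  out
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat("Endpoint genotype calls:\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Dose-response linearity check for a competitive probe assay
#'
#' Least-squares fit of the normalized mutant-channel signal against the
#' known mutant fraction of a dilution/mixing series.
#'
#' @param dose_series data.frame: `known_fraction` (in [0, 1] or percent),
#'   `fluor_mut`, optional `fluor_wt` (used for normalization when present).
#' @param r2_threshold pass when `r^2 >= r2_threshold`.
#' @return list: `slope`, `intercept`, `r_squared`, `pass`.
#' @export
linearity_check <- function(dose_series, r2_threshold = 0.98) {
  stopifnot(all(c("known_fraction", "fluor_mut") %in% names(dose_series)))
  if (nrow(dose_series) < 3L) {
    stop("dose series needs >= 3 known fractions", call. = FALSE)
  }
  y <- dose_series$fluor_mut
  if (!is.null(dose_series$fluor_wt)) {
    tot <- dose_series$fluor_mut + dose_series$fluor_wt
    y <- ifelse(tot > 0, dose_series$fluor_mut / tot, 0)
  } else if (max(y) > 0) {
    y <- y / max(y)
  }
  fit <- lm(y ~ known_fraction, data = data.frame(
    y = y, known_fraction = dose_series$known_fraction))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, pass = r2 >= r2_threshold)
}
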