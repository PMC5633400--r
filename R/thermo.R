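# Nearest-neighbor hybridization thermodynamics for DNA probes with optional
# locked-nucleic-acid (LNA) substitutions. Two-state model: dH/dS summed over
# stacks at the 1 M Na+ reference, divalent-cation salt correction applied to
# Tm, and the equilibrium bound fraction evaluated at the annealing
# temperature. Probe lengths are capped at 60 nt; no secondary-structure
# partition function is attempted.

#' Buffer conditions for hybridization calculations
#'
#' Defaults reproduce standard multiplex qPCR chemistry: 3.0 mM Mg2+ and
#' 0.8 mM total dNTPs (dNTPs chelate Mg2+ roughly 1:1, so the free-Mg2+
#' concentration used in the salt correction is `mg_mM - dntp_mM`), 50 mM
#' monovalent cation, 250 nM probe, and a 60 C annealing/extension step.
#'
#' @param monovalent_mM monovalent cation concentration (mM).
#' @param mg_mM total Mg2+ concentration (mM).
#' @param dntp_mM total dNTP concentration (mM).
#' @param strand_conc_nM total oligo concentration (nM).
#' @param anneal_temp_C annealing temperature (C).
#' @return an object of class `buffer_conditions`.
#' @export
buffer_conditions <- function(monovalent_mM = 50, mg_mM = 3.0, dntp_mM = 0.8,
                              strand_conc_nM = 250, anneal_temp_C = 60) {
  vals <- c(monovalent_mM, mg_mM, dntp_mM, strand_conc_nM)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all concentrations must be finite and >= 0", call. = FALSE)
  }
  if (strand_conc_nM <= 0) stop("strand_conc_nM must be > 0", call. = FALSE)
  structure(list(monovalent_mM = monovalent_mM, mg_mM = mg_mM,
                 dntp_mM = dntp_mM, strand_conc_nM = strand_conc_nM,
                 anneal_temp_C = anneal_temp_C),
            class = "buffer_conditions")
}

#' Construct a probe/template duplex
#'
#' @param probe_sequence probe oligo, 5'->3', 8-60 nt.
#' @param template_sequence the strand the probe binds, 5'->3'. If `NULL`,
#'   the exact complement of the probe is used.
#' @param lna_positions 0-based indices of locked bases in the probe.
#' @param alignment_offset 0-based start of the probe footprint on the
#'   template (the 5'-most template position covered by the probe).
#' @return an object of class `duplex`.
#' @export
duplex <- function(probe_sequence, template_sequence = NULL,
                   lna_positions = integer(), alignment_offset = 0L) {
  probe <- assert_dna(probe_sequence, "probe_sequence")
  L <- nchar(probe)
  if (L < 8L || L > 60L) stop("probe length must be in [8, 60]", call. = FALSE)
  if (is.null(template_sequence)) {
    template_sequence <- revcomp(probe)
    alignment_offset <- 0L
  }
  template <- assert_dna(template_sequence, "template_sequence")
  lna_positions <- sort(unique(as.integer(lna_positions)))
  if (length(lna_positions) && (min(lna_positions) < 0L ||
                                max(lna_positions) >= L)) {
    stop("every lna_position must be a valid 0-based probe index",
         call. = FALSE)
  }
  if (alignment_offset < 0L || alignment_offset + L > nchar(template)) {
    stop("probe cannot be paired with the template at the given offset",
         call. = FALSE)
  }
  structure(list(probe_sequence = probe, template_sequence = template,
                 lna_positions = lna_positions,
                 alignment_offset = as.integer(alignment_offset)),
            class = "duplex")
}

# Aligned-duplex thermodynamic summation.
# top/bot: equal-length character vectors; top = probe bases 5'->3' ('-' for
# template bulge), bot = template bases written 3'->5' under the probe ('-'
# for probe bulge). lna: logical per column (locked probe base).
compute_thermo_aligned <- function(top, bot, lna, cond,
                                   bulge_dg37 = 3.0) {
  n <- length(top)
  gap <- top == "-" | bot == "-"
  paired <- !gap
  matched <- paired & bot == complement_base(top)
  mismatched <- paired & !matched
  frac_bad <- (sum(mismatched) + sum(gap)) / n
  if (frac_bad > 0.30 + 1e-9) {
    stop("more than 30% of duplex positions are mismatched or bulged",
         call. = FALSE)
  }

  dH <- 0
  dS <- 0
  for (i in seq_len(n - 1L)) {
    if (gap[i] || gap[i + 1L]) next
    key <- paste0(top[i], top[i + 1L], "/", bot[i], bot[i + 1L])
    if (matched[i] && matched[i + 1L]) {
      dH <- dH + nn_lookup(key, .NN_DH)
      dS <- dS + nn_lookup(key, .NN_DS)
      # LNA stabilization: one increment per locked matched base per stack
      for (j in c(i, i + 1L)) {
        if (lna[j]) {
          dH <- dH + .LNA_MATCH_DH[[top[j]]]
          dS <- dS + .LNA_MATCH_DS[[top[j]]]
        }
      }
    } else if (xor(matched[i], matched[i + 1L])) {
      h <- nn_lookup(key, .MM_DH)
      s <- nn_lookup(key, .MM_DS)
      if (is.na(h)) { h <- .DOUBLE_MM_DH; s <- .DOUBLE_MM_DS }
      dH <- dH + h
      dS <- dS + s
    } else {
      dH <- dH + .DOUBLE_MM_DH
      dS <- dS + .DOUBLE_MM_DS
    }
  }

  # Extra LNA penalty for a mismatch at or within one position of a lock.
  for (m in which(mismatched)) {
    near <- seq(max(1L, m - 1L), min(n, m + 1L))
    if (any(lna[near])) {
      dH <- dH + 2 * .LNA_MISMATCH_DH
      dS <- dS + 2 * .LNA_MISMATCH_DS
    }
  }

  # Bulge penalty: fixed destabilization per bulged base.
  n_bulge <- sum(gap)
  if (n_bulge > 0L) dS <- dS - n_bulge * bulge_dg37 * 1000 / 310.15

  # Initiation from terminal paired bases.
  ends <- c(which(paired)[1L], tail(which(paired), 1L))
  for (e in ends) {
    init <- if (top[e] %in% c("G", "C")) .INIT_GC else .INIT_AT
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }

  ct <- cond$strand_conc_nM * 1e-9
  denom <- dS + .GAS_CONSTANT * log(ct / 4)
  tm1m_K <- dH * 1000 / denom
  fGC <- sum(top[matched] %in% c("G", "C")) / max(1L, sum(paired))
  tm_K <- salt_corrected_tm(tm1m_K, fGC, sum(paired),
                            mon_M = cond$monovalent_mM * 1e-3,
                            mg_free_M = max(0, cond$mg_mM - cond$dntp_mM) * 1e-3)
  bf <- bound_fraction_two_state(dH, tm_K, cond$anneal_temp_C + 273.15)
  structure(list(dH = unname(dH), dS = unname(dS), tm_C = unname(tm_K) - 273.15,
                 bound_fraction_at_anneal = unname(bf),
                 n_mismatch = sum(mismatched), n_bulge = n_bulge),
            class = "thermo_result")
}

# Two-state bound fraction; equals 0.5 exactly at T = Tm at the reference
# strand concentration (the effective entropy is re-anchored at the
# salt-corrected Tm, so the salt correction carries through).
bound_fraction_two_state <- function(dH, tm_K, temp_K) {
  if (!is.finite(tm_K) || tm_K <= 0) return(NA_real_)
  lnKC <- dH * 1000 / .GAS_CONSTANT * (1 / tm_K - 1 / temp_K)
  1 / (1 + exp(-lnKC))
}

# Divalent/monovalent salt correction of the 1 M Na+ Tm (Kelvin), following
# the standard empirical Mg2+ correction with the sqrt(Mg)/Na regime switch.
salt_corrected_tm <- function(tm1m_K, fGC, nbp, mon_M, mg_free_M) {
  if (!is.finite(tm1m_K)) return(tm1m_K)
  mono_corr <- function(tmK, na) {
    1 / (1 / tmK + (4.29 * fGC - 3.95) * 1e-5 * log(na) +
           9.40e-6 * log(na)^2)
  }
  mg_corr <- function(tmK, mg, a, d, g) {
    lnmg <- log(mg)
    inv <- 1 / tmK + a - 9.11e-6 * lnmg + fGC * (6.26e-5 + d * lnmg) +
      1 / (2 * (nbp - 1)) * (-4.82e-4 + 5.25e-4 * lnmg + g * lnmg^2)
    1 / inv
  }
  a0 <- 3.92e-5; d0 <- 1.42e-5; g0 <- 8.31e-5
  if (mg_free_M <= 0) {
    if (mon_M <= 0) return(tm1m_K)
    return(mono_corr(tm1m_K, mon_M))
  }
  if (mon_M <= 0) return(mg_corr(tm1m_K, mg_free_M, a0, d0, g0))
  ratio <- sqrt(mg_free_M) / mon_M
  if (ratio < 0.22) return(mono_corr(tm1m_K, mon_M))
  if (ratio < 6.0) {
    lnm <- log(mon_M)
    a <- a0 * (0.843 - 0.352 * sqrt(mon_M) * lnm)
    d <- d0 * (1.279 - 4.03e-3 * lnm - 8.03e-3 * lnm^2)
    g <- g0 * (0.486 - 0.258 * lnm + 5.25e-3 * lnm^3)
    return(mg_corr(tm1m_K, mg_free_M, a, d, g))
  }
  mg_corr(tm1m_K, mg_free_M, a0, d0, g0)
}

#' Melting temperature and bound fraction of a probe/template duplex
#'
#' Sums nearest-neighbor stack enthalpies/entropies (with LNA perturbation
#' terms at locked positions and published internal-mismatch parameters at
#' mismatched positions), computes the two-state Tm with divalent-cation
#' salt correction, and evaluates the equilibrium bound fraction at the
#' annealing temperature.
#'
#' @param dpx a [duplex()].
#' @param cond a [buffer_conditions()].
#' @param bulge_dg37 destabilization per bulged base (kcal/mol at 37 C).
#' @return an object of class `thermo_result` with elements `dH` (kcal/mol),
#'   `dS` (cal/(mol K)), `tm_C`, and `bound_fraction_at_anneal`.
#' @examples
#' d <- duplex("ATGCAGTCAGGTCAGGTACA")
#' melting_temperature(d, buffer_conditions())
#' @export
melting_temperature <- function(dpx, cond = buffer_conditions(),
                                bulge_dg37 = 3.0) {
  stopifnot(inherits(dpx, "duplex"), inherits(cond, "buffer_conditions"))
  L <- nchar(dpx$probe_sequence)
  site <- substr(dpx$template_sequence, dpx$alignment_offset + 1L,
                 dpx$alignment_offset + L)
  eff <- revcomp(site)  # what a perfectly matching probe would read
  top <- strsplit(dpx$probe_sequence, "")[[1]]
  bot <- strsplit(chartr("ACGT", "TGCA", eff), "")[[1]]
  lna <- rep(FALSE, L)
  lna[dpx$lna_positions + 1L] <- TRUE
  compute_thermo_aligned(top, bot, lna, cond, bulge_dg37)
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf(
    "Duplex thermodynamics: dH = %.1f kcal/mol, dS = %.1f cal/(mol K)\n",
    x$dH, x$dS))
  cat(sprintf("  Tm = %.2f C; bound fraction at anneal = %.3f\n",
              x$tm_C, x$bound_fraction_at_anneal))
  if (x$n_mismatch > 0 || x$n_bulge > 0) {
    cat(sprintf("  (%d mismatch(es), %d bulged base(s))\n",
                x$n_mismatch, x$n_bulge))
  }
  invisible(x)
}

# Align a probe against an arbitrary template region (fit alignment: the
# probe is globally aligned, the template region's ends are free) and return
# the aligned top/bot/lna vectors for compute_thermo_aligned().
probe_template_alignment <- function(probe, lna_positions, target_eff) {
  if (nchar(probe) == nchar(target_eff)) {
    top <- strsplit(probe, "")[[1]]
    eff <- strsplit(target_eff, "")[[1]]
  } else {
    fit <- nw_align_cpp(probe, target_eff, 1L, -2L, 5L, 1L, TRUE)
    top <- strsplit(fit$aligned_a, "")[[1]]
    eff <- strsplit(fit$aligned_b, "")[[1]]
    # trim free end gaps of the probe (unbound template overhang)
    keep <- cumsum(top != "-") > 0 & rev(cumsum(rev(top != "-")) > 0)
    top <- top[keep]
    eff <- eff[keep]
  }
  lna <- rep(FALSE, length(top))
  probe_idx <- cumsum(top != "-")
  lna[top != "-" & (probe_idx - 1L) %in% lna_positions] <- TRUE
  bot <- ifelse(eff == "-", "-", chartr("ACGT", "TGCA", eff))
  list(top = top, bot = bot, lna = lna)
}

#' Mismatch discrimination of a probe between wild-type and variant templates
#'
#' Evaluates the probe duplex on the wild-type template and on a variant
#' template (substitutions, insertions or deletions under the probe
#' footprint; the variant footprint is recovered by a fit alignment) and
#' returns the Tm and bound-fraction penalties of the variant duplex.
#'
#' @param probe a [probe_design()] (or any list with `sequence`,
#'   `lna_positions`, `footprint`, `strand`).
#' @param wt_template wild-type reference sequence (plus strand).
#' @param variant_template variant sequence on the same coordinates.
#' @param cond a [buffer_conditions()].
#' @param bulge_dg37 destabilization per bulged base (kcal/mol at 37 C).
#' @param pad template context (nt) searched on each side of the footprint
#'   when fitting the probe to the variant.
#' @return list with `delta_tm_C` (wt Tm minus variant Tm),
#'   `delta_bound_fraction`, and the two `thermo_result` objects.
#' @export
mismatch_discrimination <- function(probe, wt_template, variant_template,
                                    cond = buffer_conditions(),
                                    bulge_dg37 = 3.0, pad = 12L) {
  wt_template <- assert_dna(wt_template, "wt_template")
  variant_template <- assert_dna(variant_template, "variant_template")
  fp <- probe$footprint
  strand <- probe$strand %||% "+"
  region <- function(seq, s, e) substr(seq, max(1L, s + 1L), min(nchar(seq), e))
  eff_of <- function(reg) if (strand == "+") reg else revcomp(reg)

  wt_reg <- region(wt_template, fp[1], fp[2])
  wt_aln <- probe_template_alignment(probe$sequence, probe$lna_positions,
                                     eff_of(wt_reg))
  wt_res <- compute_thermo_aligned(wt_aln$top, wt_aln$bot, wt_aln$lna, cond,
                                   bulge_dg37)

  var_reg <- region(variant_template, fp[1] - pad, fp[2] + pad)
  var_aln <- probe_template_alignment(probe$sequence, probe$lna_positions,
                                      eff_of(var_reg))
  var_res <- compute_thermo_aligned(var_aln$top, var_aln$bot, var_aln$lna,
                                    cond, bulge_dg37)

  if (var_res$n_mismatch == 0 && var_res$n_bulge == 0) {
    warning("variant is identical to wild type under the probe footprint; ",
            "no discrimination (delta Tm = 0)", call. = FALSE)
  }
  list(delta_tm_C = wt_res$tm_C - var_res$tm_C,
       delta_bound_fraction = wt_res$bound_fraction_at_anneal -
         var_res$bound_fraction_at_anneal,
       wt = wt_res, variant = var_res)
}
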