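# Constraint-based construction of drop-off assays: an amplicon (~134 bp)
# around the Cas9 cut site, a primer pair, an LNA target probe whose locked
# triplet straddles the cut, and an internal reference probe in the same
# amplicon but distal to the cut. Probes must melt 3-6 C above the hotter
# primer so they are bound before extension; the two probes must have
# similar Tm. Search is deterministic: candidate geometries are enumerated
# in a fixed order and ties break on coordinates.

PROBE_ROLES <- c("target", "internal_reference", "external_reference",
                 "allele_wt", "allele_mut")
PROBE_CHANNELS <- c("FAM", "VIC")

#' Construct a probe design
#'
#' @param sequence probe oligo 5'->3'.
#' @param lna_positions 0-based locked-base indices.
#' @param channel fluorophore channel, `"FAM"` or `"VIC"`.
#' @param role probe role.
#' @param tm_C predicted melting temperature (filled by the designer).
#' @param footprint 0-based half-open interval on the reference.
#' @param strand `"+"` if the probe sequence equals the reference strand of
#'   its footprint, `"-"` if it is the reverse complement.
#' @return object of class `probe_design`.
#' @export
probe_design <- function(sequence, lna_positions = integer(),
                         channel = c("FAM", "VIC"),
                         role = PROBE_ROLES, tm_C = NA_real_,
                         footprint = c(NA_integer_, NA_integer_),
                         strand = "+") {
  channel <- match.arg(channel)
  role <- match.arg(role)
  sequence <- assert_dna(sequence, "probe sequence")
  lna_positions <- sort(unique(as.integer(lna_positions)))
  if (length(lna_positions) &&
      (min(lna_positions) < 0 || max(lna_positions) >= nchar(sequence))) {
    stop("lna_positions out of probe range", call. = FALSE)
  }
  structure(list(sequence = sequence, lna_positions = lna_positions,
                 channel = channel, role = role, tm_C = tm_C,
                 footprint = as.integer(footprint), strand = strand),
            class = "probe_design")
}

#' @export
print.probe_design <- function(x, ...) {
  cat(sprintf("<probe %s/%s> %s  Tm %.1f C  [%d,%d) %s\n", x$role,
              x$channel, lna_notation(x$sequence, x$lna_positions), x$tm_C,
              x$footprint[1], x$footprint[2], x$strand))
  invisible(x)
}

# '+N' dialect: '+' prefixes each locked base.
lna_notation <- function(sequence, lna_positions) {
  s <- strsplit(sequence, "")[[1]]
  s[lna_positions + 1L] <- paste0("+", s[lna_positions + 1L])
  paste(s, collapse = "")
}

#' Design constraints for drop-off assay construction
#'
#' @param amplicon_length_range allowed amplicon lengths (bp); the range is
#'   centered on the 134-bp target honored when feasible.
#' @param amplicon_length_target preferred amplicon length.
#' @param primer_length_range,primer_tm_range,primer_gc_range primer windows.
#' @param probe_length_range,probe_gc_range probe windows.
#' @param probe_primer_tm_offset allowed probe-minus-primer Tm window (C).
#' @param probe_tm_tolerance maximum |Tm(target) - Tm(reference probe)|.
#' @param min_ref_probe_cut_distance minimum distance (nt) between the
#'   reference-probe footprint and the cut site.
#' @param max_homopolymer maximum homopolymer run in primers/probes.
#' @return object of class `design_constraints`.
#' @export
design_constraints <- function(amplicon_length_range = c(110L, 160L),
                               amplicon_length_target = 134L,
                               primer_length_range = c(18L, 27L),
                               primer_tm_range = c(57, 63),
                               primer_gc_range = c(0.30, 0.70),
                               probe_length_range = c(15L, 32L),
                               probe_gc_range = c(0.25, 0.80),
                               probe_primer_tm_offset = c(3, 6),
                               probe_tm_tolerance = 2,
                               min_ref_probe_cut_distance = 10L,
                               max_homopolymer = 4L) {
  ranges <- list(amplicon_length_range, primer_length_range, primer_tm_range,
                 primer_gc_range, probe_length_range, probe_gc_range,
                 probe_primer_tm_offset)
  if (any(vapply(ranges, function(r) r[1] > r[2], TRUE))) {
    stop("all constraint ranges must be non-empty", call. = FALSE)
  }
  structure(as.list(environment()), class = "design_constraints")
}

#' Construct a drop-off assay object
#'
#' @param reference_id identifier of the reference sequence.
#' @param fw_primer,rv_primer lists with `sequence`, `footprint`, `tm_C`.
#' @param target_probe,reference_probe [probe_design()] objects.
#' @param amplicon 0-based half-open amplicon interval on the reference.
#' @param cut_site 0-based inter-base cut coordinate (blunt DSB between
#'   `cut_site - 1` and `cut_site`, 3 nt 5' of the PAM).
#' @param reference optional reference sequence (kept for validation).
#' @return object of class `dropoff_assay`.
#' @export
dropoff_assay <- function(reference_id, fw_primer, rv_primer, target_probe,
                          reference_probe, amplicon, cut_site,
                          reference = NULL) {
  structure(list(reference_id = reference_id, fw_primer = fw_primer,
                 rv_primer = rv_primer, target_probe = target_probe,
                 reference_probe = reference_probe,
                 amplicon = as.integer(amplicon),
                 cut_site = as.integer(cut_site), reference = reference),
            class = "dropoff_assay")
}

#' @export
print.dropoff_assay <- function(x, ...) {
  cat(sprintf("Drop-off assay on %s: amplicon [%d,%d) (%d bp), cut %d\n",
              x$reference_id, x$amplicon[1], x$amplicon[2],
              diff(x$amplicon), x$cut_site))
  cat(sprintf("  fw  %s  Tm %.1f\n", x$fw_primer$sequence, x$fw_primer$tm_C))
  cat(sprintf("  rv  %s  Tm %.1f\n", x$rv_primer$sequence, x$rv_primer$tm_C))
  print(x$target_probe)
  print(x$reference_probe)
  invisible(x)
}

# Cached perfect-match Tm of an oligo (optionally with LNA positions).
oligo_tm <- function(seq, cond, lna = integer(), cache = NULL) {
  key <- paste0(seq, "|", paste(lna, collapse = ","))
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  tm <- melting_temperature(duplex(seq, lna_positions = lna), cond)$tm_C
  if (!is.null(cache)) cache[[key]] <- tm
  tm
}

# Rough log-linear Tm estimate used only to pick a starting probe length.
tm_rough <- function(seq) {
  L <- nchar(seq)
  81.5 + 16.6 * log10(0.05) + 41 * gc_fraction(seq) - 600 / L
}

pick_primer <- function(amp_seq, side, cons, cond, cache) {
  best <- NULL
  for (len in seq(cons$primer_length_range[1], cons$primer_length_range[2])) {
    if (len > nchar(amp_seq)) break
    s <- if (side == "fw") substr(amp_seq, 1L, len)
         else revcomp(substr(amp_seq, nchar(amp_seq) - len + 1L,
                             nchar(amp_seq)))
    gc <- gc_fraction(s)
    if (gc < cons$primer_gc_range[1] || gc > cons$primer_gc_range[2]) next
    if (max_homopolymer(s) > cons$max_homopolymer) next
    tm <- oligo_tm(s, cond, cache = cache)
    if (tm < cons$primer_tm_range[1] || tm > cons$primer_tm_range[2]) next
    dev <- abs(tm - mean(cons$primer_tm_range))
    if (is.null(best) || dev < best$dev) {
      best <- list(sequence = s, tm_C = tm, length = len, dev = dev)
    }
  }
  best
}

# Locked triplet spanning the cut (template positions cut-1, cut, cut+1),
# shifted minimally if locking would sit on a >= 4 G run.
lna_triplet_positions <- function(probe_seq, cut_idx) {
  L <- nchar(probe_seq)
  for (shift in c(0L, -1L, 1L, -2L, 2L)) {
    start <- cut_idx - 1L + shift
    if (start < 1L || start + 2L > L - 1L) next
    idx <- start + 0:2
    run <- substr(probe_seq, max(1L, idx[1] - 1L + 1L),
                  min(L, idx[3] + 1L + 1L))
    if (max_homopolymer(run) >= 4L && grepl("GGGG", run)) next
    return(idx)
  }
  NULL
}

#' Design ranked drop-off assays for a cut site
#'
#' Enumerates amplicon geometries around the cut site (lengths ordered by
#' distance to the target length, then centering shifts), picks primers by
#' Tm fit, places the LNA target probe across the cut and an internal
#' reference probe distal to it, and keeps every candidate that passes
#' [validate_assay()]. Candidates are ranked by a composite penalty (Tm
#' deviations, GC extremes, homopolymer runs, amplicon-length deviation).
#' Deterministic given inputs.
#'
#' @param reference_seq reference sequence (ACGT).
#' @param cut_site 0-based inter-base cut coordinate.
#' @param constraints a [design_constraints()].
#' @param cond a [buffer_conditions()].
#' @param n_candidates maximum number of assays returned.
#' @param reference_id identifier recorded in the assays.
#' @param max_geometries cap on amplicon geometries examined.
#' @return list of [dropoff_assay()] objects, best first; when empty, the
#'   attribute `failure_report` tabulates which constraint eliminated
#'   candidates.
#' @export
design_dropoff_assay <- function(reference_seq, cut_site,
                                 constraints = design_constraints(),
                                 cond = buffer_conditions(),
                                 n_candidates = 3L,
                                 reference_id = "reference",
                                 max_geometries = 40L) {
  ref <- assert_dna(reference_seq, "reference_seq")
  cons <- constraints
  n <- nchar(ref)
  max_amp <- cons$amplicon_length_range[2]
  min_amp <- cons$amplicon_length_range[1]
  if (nchar(ref) < max_amp) {
    stop("reference shorter than the maximum amplicon length", call. = FALSE)
  }
  if (cut_site < ceiling(min_amp / 2) || cut_site > n - ceiling(min_amp / 2)) {
    stop("cut site too close to the reference end for any amplicon",
         call. = FALSE)
  }
  cache <- new.env(parent = emptyenv())
  fails <- c(primer = 0L, target_probe = 0L, reference_probe = 0L,
             validation = 0L)
  lens <- seq(min_amp, max_amp)
  lens <- lens[order(abs(lens - cons$amplicon_length_target), lens)]
  shifts <- order(abs(seq(-12L, 12L)))  # 0, -1, 1, ...
  shifts <- seq(-12L, 12L)[shifts]
  geoms <- expand.grid(shift = shifts, len = lens)
  geoms <- geoms[order(abs(geoms$len - cons$amplicon_length_target),
                       abs(geoms$shift)), ]
  results <- list()
  tried <- 0L
  for (g in seq_len(nrow(geoms))) {
    if (tried >= max_geometries || length(results) >= 3L * n_candidates) break
    L <- geoms$len[g]
    start <- cut_site - L %/% 2L + geoms$shift[g]
    if (start < 0L || start + L > n) next
    tried <- tried + 1L
    amp <- substr(ref, start + 1L, start + L)
    fw <- pick_primer(amp, "fw", cons, cond, cache)
    rv <- pick_primer(amp, "rv", cons, cond, cache)
    if (is.null(fw) || is.null(rv)) { fails["primer"] <- fails["primer"] + 1L; next }
    pmax_tm <- max(fw$tm_C, rv$tm_C)
    tm_lo <- pmax_tm + cons$probe_primer_tm_offset[1]
    tm_hi <- pmax_tm + cons$probe_primer_tm_offset[2]
    inner <- c(start + fw$length + 1L, start + L - rv$length - 1L)

    tp <- find_target_probe(ref, cut_site, inner, tm_lo, tm_hi, cons, cond,
                            cache)
    if (is.null(tp)) { fails["target_probe"] <- fails["target_probe"] + 1L; next }
    rp <- find_reference_probe(ref, cut_site, inner, tp, tm_lo, tm_hi, cons,
                               cond, cache)
    if (is.null(rp)) { fails["reference_probe"] <- fails["reference_probe"] + 1L; next }

    assay <- dropoff_assay(
      reference_id,
      fw_primer = list(sequence = fw$sequence, tm_C = fw$tm_C,
                       footprint = c(start, start + fw$length)),
      rv_primer = list(sequence = rv$sequence, tm_C = rv$tm_C,
                       footprint = c(start + L - rv$length, start + L)),
      target_probe = tp, reference_probe = rp,
      amplicon = c(start, start + L), cut_site = cut_site, reference = ref)
    rep_ <- validate_assay(assay, cond, cons)
    if (!all(rep_$pass)) { fails["validation"] <- fails["validation"] + 1L; next }
    mid <- (tm_lo + tm_hi) / 2
    penalty <- 0.1 * abs(L - cons$amplicon_length_target) +
      abs(tp$tm_C - rp$tm_C) +
      abs(tp$tm_C - mid) + abs(rp$tm_C - mid) +
      2 * max(0, abs(gc_fraction(tp$sequence) - 0.5) - 0.15) +
      2 * max(0, abs(gc_fraction(rp$sequence) - 0.5) - 0.15)
    results[[length(results) + 1L]] <- list(assay = assay, penalty = penalty,
                                            start = start)
  }
  if (length(results) == 0L) {
    out <- list()
    attr(out, "failure_report") <- fails
    return(out)
  }
  ord <- order(vapply(results, function(r) r$penalty, 1),
               vapply(results, function(r) as.numeric(r$start), 1))
  out <- lapply(results[head(ord, n_candidates)], `[[`, "assay")
  attr(out, "failure_report") <- fails
  out
}

find_target_probe <- function(ref, cut_site, inner, tm_lo, tm_hi, cons,
                              cond, cache) {
  best <- NULL
  for (len in seq(cons$probe_length_range[1], cons$probe_length_range[2])) {
    for (shift in c(0L, -1L, 1L, -2L, 2L)) {
      s0 <- cut_site - len %/% 2L + shift
      if (s0 < inner[1] || s0 + len > inner[2]) next
      if (cut_site - s0 < 3L || (s0 + len) - cut_site < 3L) next
      seq_ <- substr(ref, s0 + 1L, s0 + len)
      gc <- gc_fraction(seq_)
      if (gc < cons$probe_gc_range[1] || gc > cons$probe_gc_range[2]) next
      if (max_homopolymer(seq_) > cons$max_homopolymer) next
      lna <- lna_triplet_positions(seq_, cut_site - s0)
      if (is.null(lna)) next
      tm <- oligo_tm(seq_, cond, lna = lna, cache = cache)
      if (tm < tm_lo || tm > tm_hi) next
      dev <- abs(tm - (tm_lo + tm_hi) / 2)
      if (is.null(best) || dev < best_dev) {
        best <- probe_design(seq_, lna_positions = lna, channel = "FAM",
                             role = "target", tm_C = tm,
                             footprint = c(s0, s0 + len), strand = "+")
        best_dev <- dev
      }
    }
    if (!is.null(best) && best_dev < 0.5) break
  }
  best
}

find_reference_probe <- function(ref, cut_site, inner, target_probe, tm_lo,
                                 tm_hi, cons, cond, cache) {
  tp_fp <- target_probe$footprint
  min_d <- cons$min_ref_probe_cut_distance
  best <- NULL
  best_dev <- Inf
  n_found <- 0L
  starts <- seq(inner[1], inner[2] - cons$probe_length_range[1], by = 1L)
  # prefer the side with more room, scanning outward from the target probe
  starts <- starts[order(pmin(abs(starts - tp_fp[2]),
                              abs(starts - tp_fp[1])))]
  for (s0 in starts) {
    # pick a starting length from the rough estimate, then refine locally
    lens <- seq(cons$probe_length_range[1], cons$probe_length_range[2])
    rough <- vapply(lens, function(l) {
      if (s0 + l > inner[2]) return(NA_real_)
      tm_rough(substr(ref, s0 + 1L, s0 + l))
    }, 1)
    ord <- order(abs(rough - (tm_lo + tm_hi) / 2 - 8), na.last = NA)
    tries <- 0L
    for (l in lens[head(ord, 6L)]) {
      e0 <- s0 + l
      if (e0 > inner[2]) next
      if (!(e0 <= cut_site - min_d || s0 >= cut_site + min_d)) next
      if (intervals_overlap(c(s0, e0), tp_fp)) next
      seq_ <- substr(ref, s0 + 1L, e0)
      gc <- gc_fraction(seq_)
      if (gc < cons$probe_gc_range[1] || gc > cons$probe_gc_range[2]) next
      if (max_homopolymer(seq_) > cons$max_homopolymer) next
      tries <- tries + 1L
      tm <- oligo_tm(seq_, cond, cache = cache)
      if (tm < tm_lo || tm > tm_hi) next
      if (abs(tm - target_probe$tm_C) > cons$probe_tm_tolerance) next
      dev <- abs(tm - target_probe$tm_C)
      n_found <- n_found + 1L
      if (dev < best_dev) {
        best <- probe_design(seq_, channel = "VIC",
                             role = "internal_reference", tm_C = tm,
                             footprint = c(s0, e0), strand = "+")
        best_dev <- dev
      }
    }
    if (n_found >= 4L || (!is.null(best) && best_dev < 0.3)) break
  }
  best
}

#' Design a competitive allele-specific probe pair
#'
#' Two differentially labeled probes over the same footprint, identical
#' except at the variant position, each carrying a locked doublet covering
#' the discriminating site.
#'
#' @param reference_seq reference sequence.
#' @param variant list with `pos` (0-based), `ref`, `alt` single bases.
#' @param site 0-based variant coordinate (defaults to `variant$pos`).
#' @param probe_length probe footprint length.
#' @param cond a [buffer_conditions()].
#' @return list with elements `wt` and `mut` ([probe_design()] objects).
#' @export
design_allele_probes <- function(reference_seq, variant,
                                 site = variant$pos, probe_length = 24L,
                                 cond = buffer_conditions()) {
  ref <- assert_dna(reference_seq, "reference_seq")
  stopifnot(is.list(variant), !is.null(variant$ref), !is.null(variant$alt))
  if (substr(ref, site + 1L, site + 1L) != variant$ref) {
    stop("variant ref base does not match the reference at `site`",
         call. = FALSE)
  }
  s0 <- site - probe_length %/% 2L
  if (s0 < 0L || s0 + probe_length > nchar(ref)) {
    stop("probe footprint extends beyond the reference", call. = FALSE)
  }
  v <- site - s0
  if (v < 2L || v > probe_length - 3L) {
    stop("variant within 2 nt of the probe end: no terminal discrimination",
         call. = FALSE)
  }
  wt_seq <- substr(ref, s0 + 1L, s0 + probe_length)
  mut_seq <- wt_seq
  substr(mut_seq, v + 1L, v + 1L) <- variant$alt
  lna <- c(v, v + 1L)
  wt <- probe_design(wt_seq, lna_positions = lna, channel = "VIC",
                     role = "allele_wt",
                     tm_C = oligo_tm(wt_seq, cond, lna),
                     footprint = c(s0, s0 + probe_length), strand = "+")
  mut <- probe_design(mut_seq, lna_positions = lna, channel = "FAM",
                      role = "allele_mut",
                      tm_C = oligo_tm(mut_seq, cond, lna),
                      footprint = c(s0, s0 + probe_length), strand = "+")
  list(wt = wt, mut = mut)
}

#' Validate a drop-off assay against its design constraints
#'
#' Reporting operation: re-measures every geometric and thermodynamic
#' invariant of the assay and returns a per-constraint pass/fail table.
#'
#' @param assay a [dropoff_assay()].
#' @param cond a [buffer_conditions()].
#' @param constraints a [design_constraints()].
#' @return data.frame of class `assay_report` with columns `constraint`,
#'   `pass`, `value`.
#' @export
validate_assay <- function(assay, cond = buffer_conditions(),
                           constraints = design_constraints()) {
  cons <- constraints
  tp <- assay$target_probe
  rp <- assay$reference_probe
  amp <- assay$amplicon
  cut <- assay$cut_site
  fw_fp <- assay$fw_primer$footprint
  rv_fp <- assay$rv_primer$footprint
  tms <- c(target = tp$tm_C, reference = rp$tm_C)
  if (anyNA(tms)) {
    tms["target"] <- oligo_tm(tp$sequence, cond, tp$lna_positions)
    tms["reference"] <- oligo_tm(rp$sequence, cond, rp$lna_positions)
  }
  ptm <- c(assay$fw_primer$tm_C, assay$rv_primer$tm_C)
  offset <- min(tms) - max(ptm)

  lna_sorted <- sort(tp$lna_positions)
  runs <- if (length(lna_sorted)) rle(diff(lna_sorted) == 1L) else NULL
  has_triplet <- !is.null(runs) &&
    any(runs$values & runs$lengths >= 2L)
  # locked triplet must overlap the cut: at least one locked base maps to
  # template positions cut-1 .. cut+1
  lna_template <- tp$footprint[1] + lna_sorted
  triplet_on_cut <- has_triplet &&
    any(lna_template >= cut - 1L & lna_template <= cut + 1L)

  ref_dist <- if (rp$footprint[2] <= cut) cut - rp$footprint[2]
              else if (rp$footprint[1] >= cut) rp$footprint[1] - cut
              else -1L

  checks <- list(
    list("probes_inside_amplicon",
         tp$footprint[1] >= amp[1] && tp$footprint[2] <= amp[2] &&
           rp$footprint[1] >= amp[1] && rp$footprint[2] <= amp[2], NA),
    list("probes_nonoverlapping",
         !intervals_overlap(tp$footprint, rp$footprint), NA),
    list("probe_primer_nonoverlap",
         !intervals_overlap(tp$footprint, fw_fp) &&
           !intervals_overlap(tp$footprint, rv_fp) &&
           !intervals_overlap(rp$footprint, fw_fp) &&
           !intervals_overlap(rp$footprint, rv_fp), NA),
    list("target_contains_cut",
         tp$footprint[1] < cut && cut < tp$footprint[2], NA),
    list("target_lna_triplet_on_cut", isTRUE(triplet_on_cut), NA),
    list("reference_distal", ref_dist >= 0L, ref_dist),
    list("reference_min_distance",
         ref_dist >= cons$min_ref_probe_cut_distance, ref_dist),
    list("channels_differ", tp$channel != rp$channel, NA),
    list("probe_primer_tm_window",
         offset >= cons$probe_primer_tm_offset[1] - 1e-9 &&
           offset <= cons$probe_primer_tm_offset[2] + 1e-9, offset),
    list("probe_tm_balance",
         abs(tms["target"] - tms["reference"]) <=
           cons$probe_tm_tolerance + 1e-9,
         abs(tms["target"] - tms["reference"]))
  )
  out <- data.frame(
    constraint = vapply(checks, `[[`, "", 1),
    pass = vapply(checks, function(c_) isTRUE(c_[[2]]), TRUE),
    value = vapply(checks, function(c_) as.numeric(c_[[3]]), 1),
    stringsAsFactors = FALSE)
  class(out) <- c("assay_report", "data.frame")
  out
}
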