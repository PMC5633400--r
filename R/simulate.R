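# Seeded generative models: mosaic founder allele populations,
# probe-binding-aware qPCR plates, dPCR chips, clone-sequencing draws and
# endpoint-fluorescence samples. All generators are deterministic given
# (configuration, seed); the RNG is namespaced per operation so partial
# pipeline reruns reproduce exactly.

# Synthetic 300-nt reference locus, generated once and frozen. It mimics the
# geometry of a CRISPR target amplicon: a 20-nt protospacer at [133, 153),
# an AGG PAM at [153, 156), the blunt cut site at inter-base coordinate 150
# (3 nt 5' of the PAM), and an HDR donor design comprising a target-codon
# substitution, a PAM-inactivating substitution and two silent substitutions
# creating an EcoRI site (GACTCC -> GAATTC at [140, 146)). This locus is
# synthetic; it stands in for the study-type amplicon whose primer/probe
# sequences are not part of the package.
.EXAMPLE_REFERENCE <- paste0(
  "AGAAGTCTTGGAGCGTCATGACTGGCAAGGATATCAGTTCGCTTTAAGAGTGCTAACTATCGGTATAGGGACGAT",
  "CTTAAAGTGTCTTATATTGACCTTGAGTAAAGCCGTCATAGTTTGGTTGTGTCGTCGAACCATAGGACTCCTATT",
  "TGTAGGTCAACACCAATTCCAGATGGTGCAAGTATATCACCCGGATAACCCGCTTGTTTCGGGCCCAGGTGTATA",
  "CGCGCAGTGTAGTCCAAGATATGATAGCGGGTCCAACAAAGGCCGACATGAGTGTAACGGGCTATTATTGTTAAA")

#' Synthetic example locus
#'
#' A frozen synthetic CRISPR target amplicon with cut site, PAM, HDR donor
#' template and a 70-nt analysis window centered on the cut site. Used as the
#' default locus by all simulators.
#'
#' @return list with `reference`, `cut_site` (0-based inter-base coordinate),
#'   `protospacer`, `pam` (0-based half-open intervals), `hdr`
#'   ([hdr_template()]) and `window` (0-based half-open).
#' @export
dropoff_example_locus <- function() {
  hdr <- hdr_template(data.frame(
    name = c("silent_restriction_site", "silent_restriction_site",
             "target_codon", "pam_mutation"),
    pos = c(142L, 144L, 147L, 154L),
    ref = c("C", "C", "A", "G"),
    alt = c("A", "T", "G", "A"),
    stringsAsFactors = FALSE))
  list(reference = .EXAMPLE_REFERENCE, cut_site = 150L,
       protospacer = c(133L, 153L), pam = c(153L, 156L),
       hdr = hdr, window = c(115L, 185L))
}

DEFAULT_CATEGORY_PROBS <- c(wt = 0.12, HDR = 0.07, partial_HDR = 0.10,
                            deletion = 0.40, insertion = 0.12,
                            point_mutation = 0.07, mixed = 0.12)

#' Construct an allele population
#'
#' @param alleles data.frame with columns `sequence`, `category`, `fraction`.
#' @param locus locus description as from [dropoff_example_locus()].
#' @return object of class `allele_population`.
#' @export
allele_population <- function(alleles, locus = dropoff_example_locus()) {
  stopifnot(is.data.frame(alleles),
            all(c("sequence", "category", "fraction") %in% names(alleles)))
  if (any(alleles$fraction <= 0) ||
      abs(sum(alleles$fraction) - 1) > 1e-9) {
    stop("allele fractions must be > 0 and sum to 1", call. = FALSE)
  }
  if (!all(alleles$category %in% ALLELE_CATEGORIES)) {
    stop("unknown allele category", call. = FALSE)
  }
  structure(list(alleles = alleles, locus = locus),
            class = "allele_population")
}

#' @export
print.allele_population <- function(x, ...) {
  cat(sprintf("Allele population: %d allele(s); wt fraction %.1f%%\n",
              nrow(x$alleles), wt_fraction_true(x)))
  for (i in seq_len(nrow(x$alleles))) {
    cat(sprintf("  %5.1f%%  %s\n", 100 * x$alleles$fraction[i],
                x$alleles$category[i]))
  }
  invisible(x)
}

#' True wild-type percentage of a simulated population
#' @param population an [allele_population()].
#' @return percentage in [0, 100].
#' @export
wt_fraction_true <- function(population) {
  100 * sum(population$alleles$fraction[population$alleles$category == "wt"])
}

# -- allele sequence generators (operate on the full reference string) ------

splice <- function(seq, start, end, replacement) {
  # replace 0-based [start, end) by `replacement`
  paste0(substr(seq, 1L, start), replacement,
         substr(seq, end + 1L, nchar(seq)))
}

gen_allele_sequence <- function(category, locus) {
  ref <- locus$reference
  cut <- locus$cut_site
  w <- locus$window
  comp <- locus$hdr$components
  rand_sub <- function(exclude_pos) {
    cand <- setdiff(seq(cut - 15L, cut + 15L), comp$pos)
    pos <- sample(cand, 1L)
    refb <- substr(ref, pos + 1L, pos + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
    list(pos = pos, ref = refb, alt = alt)
  }
  mk_del <- function(max_len = 12L) {
    len <- sample(seq_len(max_len), 1L)
    a <- sample(0:len, 1L)
    start <- max(w[1] + 2L, cut - a)
    end <- min(w[2] - 2L, start + len)
    c(start, end)
  }
  mk_ins <- function(max_len = 6L) {
    paste(sample(c("A", "C", "G", "T"), sample(seq_len(max_len), 1L),
                 replace = TRUE), collapse = "")
  }
  switch(category,
    wt = ref,
    HDR = apply_substitutions(ref, comp),
    partial_HDR = {
      nms <- unique(comp$name)
      k <- sample(seq_len(length(nms) - 1L), 1L)
      keep <- sample(nms, k)
      apply_substitutions(ref, comp[comp$name %in% keep, , drop = FALSE])
    },
    deletion = {
      d <- mk_del()
      splice(ref, d[1], d[2], "")
    },
    insertion = splice(ref, cut, cut, mk_ins()),
    point_mutation = {
      s <- rand_sub()
      apply_substitutions(ref, data.frame(pos = s$pos, ref = s$ref,
                                          alt = s$alt))
    },
    mixed = {
      kind <- sample(c("del_sub", "ins_sub", "del_ins"), 1L)
      if (kind == "del_sub") {
        d <- mk_del(6L)
        pos <- sample(setdiff(seq(cut + 10L, cut + 18L), comp$pos), 1L)
        refb <- substr(ref, pos + 1L, pos + 1L)
        alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
        out <- apply_substitutions(ref, data.frame(pos = pos, ref = refb,
                                                   alt = alt))
        splice(out, d[1], d[2], "")
      } else if (kind == "ins_sub") {
        pos <- sample(setdiff(seq(cut + 10L, cut + 18L), comp$pos), 1L)
        refb <- substr(ref, pos + 1L, pos + 1L)
        alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
        out <- apply_substitutions(ref, data.frame(pos = pos, ref = refb,
                                                   alt = alt))
        splice(out, cut, cut, mk_ins())
      } else {
        dstart <- sample(seq(cut - 18L, cut - 12L), 1L)
        dlen <- sample(1:4, 1L)
        out <- splice(ref, cut, cut, mk_ins())
        splice(out, dstart, dstart + dlen, "")
      }
    },
    stop("unknown category: ", category, call. = FALSE))
}

#' Simulate one mosaic founder animal
#'
#' Draws 1-5 distinct alleles (uniform allele count by default), assigns each
#' a category from `category_probs`, generates a concrete edited sequence per
#' category (indels at the cut site, HDR component subsets for partial HDR),
#' and assigns Dirichlet(1) fractions. Identical sequences (e.g. two `wt`
#' draws) are collapsed with summed fractions.
#'
#' @param category_probs named probabilities over the seven allele
#'   categories; must sum to 1.
#' @param allele_count_range integer range the allele count is drawn
#'   uniformly from.
#' @param locus locus description.
#' @param seed integer seed.
#' @return an [allele_population()].
#' @export
simulate_founder <- function(category_probs = DEFAULT_CATEGORY_PROBS,
                             allele_count_range = 1:5,
                             locus = dropoff_example_locus(), seed = 1L) {
  if (abs(sum(category_probs) - 1) > 1e-9) {
    stop("category probabilities must sum to 1", call. = FALSE)
  }
  if (!all(names(category_probs) %in% ALLELE_CATEGORIES)) {
    stop("unknown category in category_probs", call. = FALSE)
  }
  with_op_seed(seed, "founder", {
    n <- if (length(allele_count_range) == 1L) allele_count_range
         else sample(allele_count_range, 1L)
    cats <- sample(names(category_probs), n, replace = TRUE,
                   prob = category_probs)
    seqs <- character(n)
    for (i in seq_len(n)) {
      for (try in 1:50) {
        s <- gen_allele_sequence(cats[i], locus)
        if (!s %in% seqs[seq_len(i - 1L)]) break
      }
      seqs[i] <- s
    }
    keep <- !duplicated(seqs)
    seqs <- seqs[keep]
    cats <- cats[keep]
    frac <- rgamma(length(seqs), 1)
    frac <- frac / sum(frac)
    allele_population(data.frame(sequence = seqs, category = cats,
                                 fraction = frac, stringsAsFactors = FALSE),
                      locus)
  })
}

# -- assay physics ----------------------------------------------------------

#' Assay physics for the signal simulators
#'
#' Binding efficiencies may be given per category (named vectors over the
#' allele categories, values in [0, 1]); when `NULL`, the target probe binds
#' `wt` alleles with efficiency 1 and everything else with `edited_binding`
#' (default 0, the idealized fully discriminating LNA probe), and the
#' reference probe binds every allele with efficiency 1. Alternatively, when
#' an assay and buffer conditions are supplied to the simulators, binding can
#' be derived from the thermodynamic model (bound fraction relative to the
#' wild-type duplex).
#'
#' @param cq_sigma per-replicate, per-channel Gaussian Cq noise (cycles).
#' @param cq0 baseline quantification cycle of an undiluted calibrator.
#' @param efficiency per-cycle amplification factor.
#' @param target_binding,reference_binding optional named per-category
#'   binding efficiency vectors in [0, 1].
#' @param edited_binding target-probe binding of non-wt alleles when
#'   `target_binding` is not supplied.
#' @param dpcr_fluor two-cluster fluorescence rendering parameters for
#'   simulated chips.
#' @param endpoint endpoint-fluorescence cluster parameters (channel scale,
#'   within-cluster SD, floor).
#' @return object of class `assay_physics`.
#' @export
assay_physics <- function(cq_sigma = 0.1, cq0 = 24, efficiency = 2,
                          target_binding = NULL, reference_binding = NULL,
                          edited_binding = 0,
                          dpcr_fluor = list(neg_mean = 600, pos_mean = 4200,
                                            sd = 320),
                          endpoint = list(scale = 3000, sd = 60,
                                          floor = 100)) {
  stopifnot(cq_sigma >= 0, efficiency > 1)
  for (b in list(target_binding, reference_binding)) {
    if (!is.null(b) && (any(b < 0) || any(b > 1))) {
      stop("binding efficiencies must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(cq_sigma = cq_sigma, cq0 = cq0, efficiency = efficiency,
                 target_binding = target_binding,
                 reference_binding = reference_binding,
                 edited_binding = edited_binding,
                 dpcr_fluor = dpcr_fluor, endpoint = endpoint),
            class = "assay_physics")
}

# Per-allele binding efficiencies of one probe role for a population.
binding_efficiencies <- function(population, role, physics,
                                 assay = NULL, cond = NULL) {
  cats <- population$alleles$category
  override <- if (role == "target") physics$target_binding
              else physics$reference_binding
  if (!is.null(override)) {
    b <- override[cats]
    if (anyNA(b)) b[is.na(b)] <- override["default"]
    if (anyNA(b)) stop("binding override missing category", call. = FALSE)
    return(unname(b))
  }
  if (!is.null(assay)) {
    cond <- cond %||% buffer_conditions()
    probe <- if (role == "target") assay$target_probe
             else assay$reference_probe
    ref <- population$locus$reference
    bf_wt <- mismatch_discrimination(probe, ref, ref, cond)$wt
    vapply(population$alleles$sequence, function(s) {
      if (identical(s, ref)) return(1)
      md <- suppressWarnings(mismatch_discrimination(probe, ref, s, cond))
      clamp(md$variant$bound_fraction_at_anneal /
              bf_wt$bound_fraction_at_anneal, 0, 1)
    }, 1, USE.NAMES = FALSE)
  } else if (role == "target") {
    ifelse(cats == "wt", 1, physics$edited_binding)
  } else {
    rep(1, length(cats))
  }
}

#' Simulate a multiplex qPCR plate
#'
#' The effective signal of each channel is the binding-weighted allele
#' fraction sum; `Cq = cq0 - log(signal)/log(efficiency)` plus independent
#' Gaussian noise per replicate and channel. A zero target signal yields
#' no-amplification flagged wells.
#'
#' @param populations a single [allele_population()] or a named list of them
#'   (one entry per sample; include a pure-wt calibrator for downstream
#'   delta-delta-Cq analysis).
#' @param physics an [assay_physics()].
#' @param replicates wells per sample and channel.
#' @param seed integer seed.
#' @param assay optional [design_dropoff_assay()] result used to derive
#'   thermodynamic binding efficiencies.
#' @param cond optional [buffer_conditions()] for the thermodynamic path.
#' @return data.frame of wells: `sample_id`, `channel`, `replicate`, `cq`,
#'   `flag`.
#' @export
simulate_qpcr <- function(populations, physics = assay_physics(),
                          replicates = 3L, seed = 1L, assay = NULL,
                          cond = NULL) {
  if (inherits(populations, "allele_population")) {
    populations <- list(sample1 = populations)
  }
  stopifnot(length(names(populations)) == length(populations))
  with_op_seed(seed, "qpcr", {
    rows <- lapply(names(populations), function(id) {
      pop <- populations[[id]]
      bt <- binding_efficiencies(pop, "target", physics, assay, cond)
      br <- binding_efficiencies(pop, "reference", physics, assay, cond)
      S <- sum(pop$alleles$fraction * bt)
      R <- sum(pop$alleles$fraction * br)
      mk <- function(channel, signal) {
        if (signal <= 0) {
          data.frame(sample_id = id, channel = channel,
                     replicate = seq_len(replicates), cq = NA_real_,
                     flag = "noamp", stringsAsFactors = FALSE)
        } else {
          cq <- physics$cq0 - log(signal) / log(physics$efficiency) +
            rnorm(replicates, 0, physics$cq_sigma)
          data.frame(sample_id = id, channel = channel,
                     replicate = seq_len(replicates), cq = cq, flag = "",
                     stringsAsFactors = FALSE)
        }
      }
      rbind(mk("target", S), mk("reference", R))
    })
    do.call(rbind, rows)
  })
}

#' Simulate a digital PCR chip
#'
#' Poisson copy loading per partition; each copy's allele is drawn from the
#' population fractions; a partition is positive on a channel if at least one
#' of its copies binds that channel's probe (Bernoulli per copy with the
#' allele's binding efficiency).
#'
#' @param population an [allele_population()].
#' @param n_partitions number of partitions (chip wells).
#' @param mean_copies mean template copies per partition (lambda).
#' @param physics an [assay_physics()].
#' @param seed integer seed.
#' @param fluorescence also render per-partition two-channel fluorescence
#'   from the two-cluster parameters in `physics$dpcr_fluor`.
#' @return data.frame with `partition_id`, `ref_positive`, `target_positive`
#'   (and `fluor_ref`, `fluor_target` if rendered); the generating call
#'   truth is attached as attribute `truth`.
#' @export
simulate_dpcr_chip <- function(population, n_partitions = 20000L,
                               mean_copies = 0.8, physics = assay_physics(),
                               seed = 1L, fluorescence = FALSE) {
  stopifnot(n_partitions >= 100L, mean_copies > 0)
  with_op_seed(seed, "dpcr", {
    bt <- binding_efficiencies(population, "target", physics)
    br <- binding_efficiencies(population, "reference", physics)
    copies <- rpois(n_partitions, mean_copies)
    total <- sum(copies)
    pid <- rep.int(seq_len(n_partitions), copies)
    aidx <- sample.int(nrow(population$alleles), total, replace = TRUE,
                       prob = population$alleles$fraction)
    t_hit <- rbinom(total, 1L, bt[aidx]) == 1L
    r_hit <- rbinom(total, 1L, br[aidx]) == 1L
    target_positive <- tabulate(pid[t_hit], n_partitions) > 0L
    ref_positive <- tabulate(pid[r_hit], n_partitions) > 0L
    chip <- data.frame(partition_id = seq_len(n_partitions),
                       ref_positive = ref_positive,
                       target_positive = target_positive)
    if (fluorescence) {
      fl <- physics$dpcr_fluor
      chip$fluor_ref <- rnorm(n_partitions,
                              ifelse(ref_positive, fl$pos_mean, fl$neg_mean),
                              fl$sd)
      chip$fluor_target <- rnorm(n_partitions,
                                 ifelse(target_positive, fl$pos_mean,
                                        fl$neg_mean), fl$sd)
    }
    attr(chip, "truth") <- list(wt_percent = wt_fraction_true(population),
                                mean_copies = mean_copies)
    chip
  })
}

#' Simulate clone (plasmid-isolate) sequencing draws
#'
#' Multinomial draw of alleles from the population; emits full amplicon
#' sequences, named `<animal_id>.clone<N>`.
#'
#' @param population an [allele_population()].
#' @param n_clones number of clones to draw.
#' @param seed integer seed.
#' @param animal_id identifier encoded into clone names.
#' @return named character vector of clone sequences with the generating
#'   categories attached as attribute `categories`.
#' @export
simulate_clones <- function(population, n_clones = 15L, seed = 1L,
                            animal_id = "animal1") {
  stopifnot(n_clones >= 1L)
  with_op_seed(seed, "clones", {
    idx <- sample.int(nrow(population$alleles), n_clones, replace = TRUE,
                      prob = population$alleles$fraction)
    seqs <- population$alleles$sequence[idx]
    names(seqs) <- sprintf("%s.clone%d", animal_id, seq_len(n_clones))
    attr(seqs, "categories") <- population$alleles$category[idx]
    seqs
  })
}

#' Simulate endpoint-fluorescence samples
#'
#' Two-channel Gaussian draws around genotype-specific centroids; the HET
#' centroid is by construction the midpoint of the WT and HOMO centroids,
#' and a mosaic sample's centroid is interpolated along the WT-HOMO axis by
#' its mutant fraction.
#'
#' @param genotype one of `"WT"`, `"HET"`, `"HOMO"`, `"NTC"`, or a mutant
#'   fraction in [0, 1] for a mosaic sample.
#' @param n number of samples to draw.
#' @param physics an [assay_physics()]; `physics$endpoint` holds the channel
#'   scale, within-cluster SD and the no-template noise floor.
#' @param seed integer seed.
#' @return data.frame with `fluor_wt`, `fluor_mut`.
#' @export
simulate_endpoint <- function(genotype, n = 1L, physics = assay_physics(),
                              seed = 1L) {
  ep <- physics$endpoint
  centroid <- endpoint_centroid(genotype, ep)
  with_op_seed(seed, "endpoint", {
    data.frame(fluor_wt = pmax(0, rnorm(n, centroid[1], ep$sd)),
               fluor_mut = pmax(0, rnorm(n, centroid[2], ep$sd)))
  })
}

endpoint_centroid <- function(genotype, ep) {
  wt_c <- c(ep$floor + ep$scale, ep$floor)
  ho_c <- c(ep$floor, ep$floor + ep$scale)
  if (is.numeric(genotype)) {
    stopifnot(genotype >= 0, genotype <= 1)
    return(wt_c + genotype * (ho_c - wt_c))
  }
  switch(genotype,
         WT = wt_c,
         HOMO = ho_c,
         HET = (wt_c + ho_c) / 2,
         NTC = c(ep$floor, ep$floor),
         stop("unknown genotype: ", genotype, call. = FALSE))
}
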