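# Nearest-neighbor thermodynamics: duplex symmetry, agreement with the
# independent oracle, LNA stabilization/discrimination, and the two-state
# bound-fraction definition.

test_that("Tm is invariant under duplex reversal (strand symmetry)", {
  set.seed(11)
  for (i in 1:10) {
    p <- random_dna(20)
    t1 <- melting_temperature(duplex(p))$tm_C
    t2 <- melting_temperature(duplex(revcomp(revcomp(p))))$tm_C
    # reverse-complement of the probe hybridized to the complement of its
    # template is the same physical duplex
    d_rev <- duplex(revcomp(p), template_sequence = p)
    t3 <- melting_temperature(d_rev)$tm_C
    expect_equal(t1, t2, tolerance = 1e-12)
    expect_equal(t1, t3, tolerance = 1e-9)
  }
})

test_that("perfect-match Tm agrees with the independent NN oracle", {
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    len <- sample(12:35, 1)
    p <- random_dna(len, gc = runif(1, 0.3, 0.7))
    tm_pkg <- melting_temperature(duplex(p), buffer_conditions())$tm_C
    tm_or <- oracle_tm_perfect(p)
    worst <- max(worst, abs(tm_pkg - tm_or))
  }
  expect_lt(worst, 1.5)
})

test_that("a 50% GC unmodified 20-mer lands in the qPCR-typical Tm range", {
  tm <- melting_temperature(duplex("ATGCAGTCAGGTCAGGTACA"))$tm_C
  expect_gt(tm, 50)
  expect_lt(tm, 72)
})

test_that("LNA substitutions raise the perfect-match Tm", {
  set.seed(13)
  for (i in 1:20) {
    p <- random_dna(22)
    base_tm <- melting_temperature(duplex(p))$tm_C
    k <- sample(1:4, 1)
    lna <- sample(0:(nchar(p) - 1), k)
    tm_lna <- melting_temperature(duplex(p, lna_positions = lna))$tm_C
    expect_gt(tm_lna, base_tm)
  }
})

test_that("each added internal mismatch never increases Tm", {
  set.seed(17)
  for (i in 1:10) {
    p <- random_dna(24)
    tmpl <- revcomp(p)
    tms <- numeric(4)
    tms[1] <- melting_temperature(duplex(p, tmpl))$tm_C
    mml <- strsplit(tmpl, "")[[1]]
    pos <- sample(5:20, 3)
    for (k in 1:3) {
      mml[pos[k]] <- setdiff(c("A", "C", "G", "T"), mml[pos[k]])[1]
      tms[k + 1] <- melting_temperature(
        duplex(p, paste(mml, collapse = "")))$tm_C
    }
    expect_true(all(diff(tms) <= 1e-9))
  }
})

test_that("Tm is non-decreasing in GC content at fixed length", {
  set.seed(19)
  tms <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), function(gc) {
    mean(vapply(1:5, function(i) {
      melting_temperature(duplex(random_dna(24, gc)))$tm_C
    }, 1))
  }, 1)
  expect_true(all(diff(tms) > 0))
})

test_that("bound fraction is 0.5 at Tm and decreases with temperature", {
  p <- "ACGTGCTAGCTAGGCTAACG"
  res <- melting_temperature(duplex(p))
  at_tm <- melting_temperature(duplex(p),
                               buffer_conditions(anneal_temp_C = res$tm_C))
  expect_equal(at_tm$bound_fraction_at_anneal, 0.5, tolerance = 1e-9)
  temps <- seq(res$tm_C - 15, res$tm_C + 15, by = 5)
  bf <- vapply(temps, function(tc) {
    melting_temperature(duplex(p),
                        buffer_conditions(anneal_temp_C = tc))$bound_fraction_at_anneal
  }, 1)
  expect_true(all(diff(bf) < 0))
  expect_true(all(bf >= 0 & bf <= 1))
})

test_that("mismatch under the LNA triplet is penalized at least as much as without", {
  set.seed(23)
  for (i in 1:15) {
    p <- random_dna(24)
    probe_plain <- probe_design(p, integer(), "FAM", "target",
                                footprint = c(0L, 24L))
    probe_lna <- probe_design(p, 10:12, "FAM", "target",
                              footprint = c(0L, 24L))
    wt <- p  # strand "+": probe reads the reference strand of its footprint
    var <- strsplit(p, "")[[1]]
    var[12] <- setdiff(c("A", "C", "G", "T"), var[12])[1]
    var <- paste(var, collapse = "")
    d_plain <- mismatch_discrimination(probe_plain, wt, var)$delta_tm_C
    d_lna <- mismatch_discrimination(probe_lna, wt, var)$delta_tm_C
    expect_gte(d_lna + 1e-9, d_plain)
    expect_gt(d_plain, 0)
  }
})

test_that("variant identical to wild type warns and reports zero penalty", {
  p <- "ACGTGCTAGCTAGGCTAACGTTGA"
  probe <- probe_design(p, 10:12, "FAM", "target", footprint = c(0L, 24L))
  expect_warning(md <- mismatch_discrimination(probe, p, p),
                 "no discrimination")
  expect_equal(md$delta_tm_C, 0, tolerance = 1e-9)
})

test_that("a deletion > 3 nt under the probe center abolishes binding", {
  locus <- test_locus
  assays <- design_dropoff_assay(locus$reference, locus$cut_site)
  expect_gt(length(assays), 0)
  tp <- assays[[1]]$target_probe
  tp_oligo <- probe_design(tp$sequence, integer(), tp$channel, tp$role,
                           footprint = tp$footprint, strand = tp$strand)
  var <- splice_seq(locus$reference, locus$cut_site - 3,
                    locus$cut_site + 2, "")
  for (probe in list(tp, tp_oligo)) {
    md <- mismatch_discrimination(probe, locus$reference, var)
    expect_lt(md$variant$bound_fraction_at_anneal, 0.05)
  }
})

test_that("invalid duplex inputs are rejected", {
  expect_error(duplex("ACGTNXQ"), "non-ACGT")
  expect_error(duplex("ACGT"), "length")
  expect_error(duplex("ACGTACGTACGT", "ACGT"), "offset")
  expect_error(duplex("ACGTACGTACGT", lna_positions = 40), "lna_position")
  expect_error(buffer_conditions(mg_mM = -1), "concentrations")
})

test_that("heavily mismatched duplexes are refused", {
  p <- "ACGTACGTACGTACGTACGT"
  t_bad <- revcomp(chartr("ACGT", "CATG", p))  # everything mismatched
  expect_error(melting_temperature(duplex(p, t_bad)), "30%")
})
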