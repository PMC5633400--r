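# Drop-off assay design: geometry, Tm windows, determinism, validation.

test_that("the example locus yields a valid ranked design", {
  assays <- design_dropoff_assay(test_locus$reference, test_locus$cut_site)
  expect_gt(length(assays), 0)
  a <- assays[[1]]
  rep_ <- validate_assay(a)
  expect_true(all(rep_$pass))
  L <- diff(a$amplicon)
  expect_gte(L, design_constraints()$amplicon_length_range[1])
  expect_lte(L, design_constraints()$amplicon_length_range[2])
  # the target probe straddles the cut and carries a locked triplet
  expect_true(a$target_probe$footprint[1] < a$cut_site &&
                a$cut_site < a$target_probe$footprint[2])
  expect_gte(length(a$target_probe$lna_positions), 3)
  # the reference probe never contains the cut
  expect_true(a$reference_probe$footprint[2] <= a$cut_site ||
                a$reference_probe$footprint[1] >= a$cut_site)
})

test_that("design is deterministic", {
  a1 <- design_dropoff_assay(test_locus$reference, test_locus$cut_site)
  a2 <- design_dropoff_assay(test_locus$reference, test_locus$cut_site)
  expect_identical(a1, a2)
})

test_that("geometrically impossible cut sites are input errors", {
  set.seed(53)
  ref <- random_dna(600)
  expect_error(design_dropoff_assay(ref, 20), "cut site")
  expect_error(design_dropoff_assay(random_dna(100), 50), "reference")
})

test_that("emitted designs always satisfy an independent constraint check", {
  set.seed(59)
  for (i in 1:10) {
    ref <- random_dna(600)
    assays <- design_dropoff_assay(ref, 300)
    for (a in assays) {
      # independent geometric re-check (not via validate_assay)
      tp <- a$target_probe$footprint
      rp <- a$reference_probe$footprint
      expect_true(tp[1] >= a$amplicon[1] && tp[2] <= a$amplicon[2])
      expect_true(rp[1] >= a$amplicon[1] && rp[2] <= a$amplicon[2])
      expect_true(tp[2] <= rp[1] || rp[2] <= tp[1])
      expect_true(tp[1] < a$cut_site && a$cut_site < tp[2])
      expect_false(rp[1] < a$cut_site && a$cut_site < rp[2])
      expect_true(a$target_probe$channel != a$reference_probe$channel)
      off <- min(a$target_probe$tm_C, a$reference_probe$tm_C) -
        max(a$fw_primer$tm_C, a$rv_primer$tm_C)
      expect_gte(off, 3 - 1e-9)
      expect_lte(off, 6 + 1e-9)
    }
  }
})

test_that("validate_assay flags a reference probe overlapping the cut", {
  assays <- design_dropoff_assay(test_locus$reference, test_locus$cut_site)
  a <- assays[[1]]
  bad <- a
  bad$reference_probe <- a$target_probe  # sits on the cut
  bad$reference_probe$channel <- "VIC"
  rep_ <- validate_assay(bad)
  expect_false(rep_$pass[rep_$constraint == "reference_distal"])
})

test_that("validate_assay enforces the 3-6 C probe-primer Tm window", {
  assays <- design_dropoff_assay(test_locus$reference, test_locus$cut_site)
  a <- assays[[1]]
  squeezed <- a
  squeezed$fw_primer$tm_C <- a$target_probe$tm_C - 1  # probes only 1 C above
  rep_ <- validate_assay(squeezed)
  expect_false(rep_$pass[rep_$constraint == "probe_primer_tm_window"])
})

test_that("allele-specific probe pairs discriminate by construction", {
  ref <- test_locus$reference
  comp <- test_locus$hdr$components
  codon <- comp[comp$name == "target_codon", ]
  pr <- design_allele_probes(ref, list(pos = codon$pos, ref = codon$ref,
                                       alt = codon$alt))
  expect_identical(nchar(pr$wt$sequence), nchar(pr$mut$sequence))
  diff_at <- which(strsplit(pr$wt$sequence, "")[[1]] !=
                     strsplit(pr$mut$sequence, "")[[1]])
  expect_length(diff_at, 1)
  expect_true((diff_at - 1) %in% pr$wt$lna_positions)
  expect_false(pr$wt$channel == pr$mut$channel)

  mut_template <- apply_subs <- ref
  substr(mut_template, codon$pos + 1, codon$pos + 1) <- codon$alt
  # wt probe on mutant template is penalized; mut probe is a perfect match
  md_wt <- mismatch_discrimination(pr$wt, ref, mut_template)
  expect_gt(md_wt$delta_tm_C, 0)
  md_mut <- suppressWarnings(
    mismatch_discrimination(pr$mut, mut_template, mut_template))
  expect_equal(md_mut$delta_tm_C, 0, tolerance = 1e-9)
})

test_that("variants too close to the probe end are design errors", {
  ref <- test_locus$reference
  expect_error(design_allele_probes(ref, list(pos = 0L, ref = substr(ref, 1, 1),
                                              alt = "A"), probe_length = 24),
               "probe")
  expect_error(design_allele_probes(ref, list(pos = 147L, ref = "A",
                                              alt = "G"), probe_length = 4),
               "terminal|footprint|probe")
})
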