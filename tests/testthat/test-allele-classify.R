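# Alignment and allele-taxonomy classification.

ref70 <- test_locus$reference

test_that("identical clone aligns gap-free at 100% identity", {
  aln <- align_to_reference(ref70, ref70)
  expect_equal(aln$identity, 1)
  expect_equal(nrow(aln$variants), 0)
  expect_false(grepl("-", aln$aligned_ref, fixed = TRUE))
})

test_that("a 4-nt deletion in unique context is called at exact coordinates", {
  clone <- splice_seq(ref70, 160, 164, "")
  aln <- align_to_reference(clone, ref70)
  expect_equal(nrow(aln$variants), 1)
  expect_equal(aln$variants$type, "del")
  expect_equal(aln$variants$pos, 160)
  expect_equal(aln$variants$ref, substr(ref70, 161, 164))
})

test_that("deletions inside homopolymer runs are reported left-shifted", {
  ref <- paste0(random_dna_fixed <- "ACGTGATCCGT", "AAAA", "CCGTAGGTACCA",
                "GTTACGGATCCA")
  # delete the last A of the run; normalization must report the first
  clone <- paste0("ACGTGATCCGT", "AAA", "CCGTAGGTACCA", "GTTACGGATCCA")
  aln <- align_to_reference(clone, ref, min_identity = 0.5)
  expect_equal(aln$variants$type, "del")
  expect_equal(aln$variants$pos, 11)  # first A of the run
})

test_that("alignment agrees with the exhaustive DP oracle on random cases", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(40:120, 1)
    ref <- random_dna(n)
    clone <- ref
    for (k in seq_len(sample(1:3, 1))) {
      op <- sample(c("sub", "del", "ins"), 1)
      p <- sample(10:(n - 12), 1)
      if (op == "sub") {
        b <- substr(clone, p, p)
        substr(clone, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
      } else if (op == "del") {
        clone <- paste0(substr(clone, 1, p), substr(clone, p + 3,
                                                    nchar(clone)))
      } else {
        clone <- paste0(substr(clone, 1, p), random_dna(2),
                        substr(clone, p + 1, nchar(clone)))
      }
    }
    aln <- align_to_reference(clone, ref, min_identity = 0.3)
    orc <- oracle_nw(ref, clone)
    expect_identical(aln$score, as.integer(orc$score))
    ov <- oracle_variants(orc$aligned_a, orc$aligned_b, ref)
    expect_identical(variant_signature(aln$variants), variant_signature(ov))
  }
})

test_that("classification is invariant to clone orientation", {
  pop <- simulate_founder(seed = 42)
  clones <- simulate_clones(pop, 6, seed = 42)
  for (i in seq_along(clones)) {
    fwd <- classify_allele(align_to_reference(clones[[i]], ref70),
                           test_locus$hdr, test_locus$window)
    rev <- classify_allele(align_to_reference(revcomp(clones[[i]]), ref70),
                           test_locus$hdr, test_locus$window)
    expect_identical(fwd$category, rev$category)
    expect_identical(fwd$variant_key, rev$variant_key)
  }
})

test_that("HDR component subsets map to the allele taxonomy", {
  comp <- test_locus$hdr$components
  mk <- function(rows) {
    s <- strsplit(ref70, "")[[1]]
    s[rows$pos + 1] <- rows$alt
    paste(s, collapse = "")
  }
  classify <- function(clone) {
    classify_allele(align_to_reference(clone, ref70), test_locus$hdr,
                    test_locus$window)
  }
  full <- classify(mk(comp))
  expect_identical(full$category, "HDR")
  expect_setequal(full$hdr_components_present,
                  c("target_codon", "pam_mutation",
                    "silent_restriction_site"))

  partial <- classify(mk(comp[comp$name != "target_codon", ]))
  expect_identical(partial$category, "partial_HDR")
  expect_setequal(partial$hdr_components_present,
                  c("pam_mutation", "silent_restriction_site"))

  expect_identical(classify(ref70)$category, "wt")

  # 2-nt deletion plus a substitution -> mixed
  clone <- splice_seq(ref70, 149, 151, "")
  substr(clone, 166, 166) <- setdiff(c("A", "C", "G", "T"),
                                     substr(clone, 166, 166))[1]
  expect_identical(classify(clone)$category, "mixed")

  # components plus an indel -> mixed
  clone2 <- splice_seq(mk(comp), 158, 160, "")
  expect_identical(classify(clone2)$category, "mixed")
})

test_that("unalignable and truncated clones raise informative errors", {
  set.seed(5)
  expect_error(align_to_reference(random_dna(300), ref70), "unalignable")
  expect_error(align_to_reference(random_dna(50), ref70), "0.5-1.5x")
})

test_that("window coverage is enforced", {
  # clone truncated before the right edge of the window
  clone <- substr(ref70, 1, 150)
  aln <- align_to_reference(clone, ref70, min_identity = 0.4)
  expect_error(classify_allele(aln, test_locus$hdr, test_locus$window),
               "incomplete")
})

test_that("founder summaries count categories and distinct alleles", {
  recs <- lapply(1:15, function(i) {
    classify_allele(align_to_reference(ref70, ref70), test_locus$hdr,
                    test_locus$window, clone_id = paste0("m1.clone", i))
  })
  s <- summarize_founder(recs, "m1")
  expect_equal(s$n_distinct_alleles, 1)
  expect_equal(s$wt_percent, 100)
  expect_equal(sum(s$category_fractions), 1, tolerance = 1e-9)

  pop <- simulate_founder(allele_count_range = 5, seed = 99)
  clones <- simulate_clones(pop, 40, seed = 99)
  recs2 <- lapply(seq_along(clones), function(i) {
    classify_allele(align_to_reference(clones[[i]], ref70), test_locus$hdr,
                    test_locus$window, clone_id = names(clones)[i])
  })
  s2 <- summarize_founder(recs2, "m2")
  expect_lte(s2$n_distinct_alleles, nrow(pop$alleles))
  expect_equal(sum(s2$category_fractions), 1, tolerance = 1e-9)
})

test_that("HDR component Venn counts equal brute-force enumeration", {
  comp <- test_locus$hdr$components
  mk <- function(names_keep) {
    rows <- comp[comp$name %in% names_keep, , drop = FALSE]
    s <- strsplit(ref70, "")[[1]]
    s[rows$pos + 1] <- rows$alt
    paste(s, collapse = "")
  }
  spec_sets <- list(c("pam_mutation"), c("pam_mutation"),
                    c("pam_mutation"),
                    c("target_codon", "pam_mutation",
                      "silent_restriction_site"),
                    c("target_codon", "pam_mutation",
                      "silent_restriction_site"),
                    c("target_codon", "silent_restriction_site"),
                    character(0))
  recs <- lapply(spec_sets, function(ss) {
    classify_allele(align_to_reference(mk(ss), ref70), test_locus$hdr,
                    test_locus$window)
  })
  venn <- hdr_component_venn(recs)
  brute <- table(vapply(spec_sets, function(ss) {
    paste(intersect(c("target_codon", "pam_mutation",
                      "silent_restriction_site"), ss), collapse = "+")
  }, ""))
  for (k in seq_len(nrow(venn))) {
    expected <- if (venn$subset[k] %in% names(brute)) {
      as.integer(brute[[venn$subset[k]]])
    } else 0L
    expect_identical(venn$count[k], expected)
  }
  # all-wt input: every subset zero
  wt_recs <- lapply(1:3, function(i) {
    classify_allele(align_to_reference(ref70, ref70), test_locus$hdr,
                    test_locus$window)
  })
  expect_true(all(hdr_component_venn(wt_recs)$count == 0))
})
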