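# Generative models: determinism, distributional calibration, and
# generator/analyzer closed forms.

test_that("all generators are bit-reproducible given a seed", {
  p1 <- simulate_founder(seed = 5)
  p2 <- simulate_founder(seed = 5)
  expect_identical(p1, p2)
  expect_false(identical(p1, simulate_founder(seed = 6)))

  pops <- list(s = two_allele_population(0.4), cal = calibrator_population())
  expect_identical(simulate_qpcr(pops, seed = 9),
                   simulate_qpcr(pops, seed = 9))
  expect_identical(simulate_dpcr_chip(pops$s, 1000, 0.8, seed = 9),
                   simulate_dpcr_chip(pops$s, 1000, 0.8, seed = 9))
  expect_identical(simulate_clones(pops$s, 10, seed = 9),
                   simulate_clones(pops$s, 10, seed = 9))
  expect_identical(simulate_endpoint("HET", 5, seed = 9),
                   simulate_endpoint("HET", 5, seed = 9))
})

test_that("simulators do not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(simulate_founder(seed = 1))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("a wt-only configuration yields a single wild-type allele", {
  pop <- simulate_founder(category_probs = c(wt = 1), seed = 3)
  expect_equal(nrow(pop$alleles), 1)
  expect_identical(pop$alleles$category, "wt")
  expect_equal(pop$alleles$fraction, 1)
  expect_identical(pop$alleles$sequence, test_locus$reference)
})

test_that("category frequencies match the configured probabilities", {
  probs <- c(wt = 0.2, deletion = 0.5, insertion = 0.3)
  n <- 4000
  cats <- vapply(seq_len(n), function(i) {
    simulate_founder(category_probs = probs, allele_count_range = 1,
                     seed = i)$alleles$category
  }, "")
  freq <- table(factor(cats, levels = names(probs))) / n
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(freq - probs) < 3.5 * se))
})

test_that("allele counts are capped and fractions sum to one", {
  for (s in 1:30) {
    pop <- simulate_founder(seed = s)
    expect_lte(nrow(pop$alleles), 5)
    expect_gte(nrow(pop$alleles), 1)
    expect_equal(sum(pop$alleles$fraction), 1, tolerance = 1e-9)
  }
})

test_that("qPCR signal model follows the closed forms", {
  # 100% wt, perfect binding: ddCq vs wt calibrator = 0
  pops <- list(s = calibrator_population(), cal = calibrator_population())
  w <- simulate_qpcr(pops, assay_physics(cq_sigma = 0), seed = 1)
  res <- ddcq_wt_fraction(w, "cal")
  expect_equal(res$wt_percent[res$sample_id == "s"], 100, tolerance = 1e-9)

  # 25% wt, target binds only wt: Cq(target) shifts by log2(4) = 2 cycles
  pops2 <- list(s = two_allele_population(0.25),
                cal = calibrator_population())
  w2 <- simulate_qpcr(pops2, assay_physics(cq_sigma = 0), seed = 1)
  cq_t <- function(id) mean(w2$cq[w2$sample_id == id &
                                    w2$channel == "target"])
  expect_equal(cq_t("s") - cq_t("cal"), 2, tolerance = 1e-9)

  # partial binding closed form: 25% wt + 75% edited bound at 0.5
  # -> apparent wt = 100 * (0.25 + 0.5 * 0.75) = 62.5%
  w3 <- simulate_qpcr(list(s = two_allele_population(0.25),
                           cal = calibrator_population()),
                      assay_physics(cq_sigma = 0, edited_binding = 0.5),
                      seed = 1)
  res3 <- ddcq_wt_fraction(w3, "cal")
  expect_equal(res3$wt_percent[res3$sample_id == "s"], 62.5,
               tolerance = 1e-9)

  # zero target signal -> no-amplification wells
  w4 <- simulate_qpcr(list(s = two_allele_population(0)),
                      assay_physics(cq_sigma = 0), seed = 1)
  expect_true(all(w4$flag[w4$channel == "target"] == "noamp"))
})

test_that("dPCR chip loading follows Poisson occupancy", {
  pop <- calibrator_population()
  chip <- simulate_dpcr_chip(pop, 20000, 0.6, seed = 21)
  p_ref <- mean(chip$ref_positive)
  expect_lt(abs(p_ref - (1 - exp(-0.6))), 3 * sqrt(0.45 * 0.55 / 20000) + 0.005)
  # all-wt with perfect binding: target set equals reference set
  expect_identical(chip$target_positive, chip$ref_positive)

  # 0% wt: no target-positive partitions
  chip0 <- simulate_dpcr_chip(two_allele_population(0), 5000, 0.8,
                              seed = 22)
  expect_equal(sum(chip0$target_positive), 0)
})

test_that("dPCR round trip recovers the generating wt fraction", {
  for (f in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
    chip <- simulate_dpcr_chip(two_allele_population(f), 20000, 0.8,
                               seed = round(1000 * f))
    est <- wt_fraction_dpcr(classify_partitions(chip))
    expect_lt(abs(est$wt_percent - 100 * f), 2.5)
  }
})

test_that("clone draws are multinomial in the allele fractions", {
  pop <- two_allele_population(0.5)
  counts <- vapply(1:400, function(s) {
    cl <- simulate_clones(pop, 15, seed = s)
    sum(attr(cl, "categories") == "wt")
  }, 1)
  # Binomial(15, 0.5): mean 7.5, var 3.75
  expect_lt(abs(mean(counts) - 7.5), 4 * sqrt(3.75 / 400))
  expect_lt(abs(var(counts) - 3.75), 1.1)
  # single-allele population: all clones identical
  cl <- simulate_clones(calibrator_population(), 8, seed = 2)
  expect_equal(length(unique(unname(cl))), 1)
})

test_that("simulated founders round trip through classification", {
  for (s in 101:130) {
    pop <- simulate_founder(seed = s)
    clones <- simulate_clones(pop, 8, seed = s)
    got <- vapply(seq_along(clones), function(i) {
      aln <- align_to_reference(clones[[i]], test_locus$reference)
      classify_allele(aln, test_locus$hdr, test_locus$window)$category
    }, "")
    expect_identical(got, attr(clones, "categories"))
  }
})
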