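# Small fixture builders used across tests.

test_locus <- dropoff_example_locus()

splice_seq <- function(seq, start, end, replacement) {
  paste0(substr(seq, 1, start), replacement, substr(seq, end + 1, nchar(seq)))
}

# A two-allele population: wild type at fraction `f_wt` plus one fixed
# 5-nt deletion allele spanning the cut site.
two_allele_population <- function(f_wt, locus = test_locus) {
  del <- splice_seq(locus$reference, locus$cut_site - 3, locus$cut_site + 2,
                    "")
  if (f_wt >= 1) {
    return(allele_population(data.frame(sequence = locus$reference,
                                        category = "wt", fraction = 1),
                             locus))
  }
  if (f_wt <= 0) {
    return(allele_population(data.frame(sequence = del,
                                        category = "deletion", fraction = 1),
                             locus))
  }
  allele_population(data.frame(sequence = c(locus$reference, del),
                               category = c("wt", "deletion"),
                               fraction = c(f_wt, 1 - f_wt)),
                    locus)
}

calibrator_population <- function(locus = test_locus) {
  two_allele_population(1, locus)
}

# deterministic wells for arithmetic tests
wells_df <- function(sample_id, target, reference, flag = "") {
  rbind(
    data.frame(sample_id = sample_id, channel = "target",
               replicate = seq_along(target), cq = target, flag = flag,
               stringsAsFactors = FALSE),
    data.frame(sample_id = sample_id, channel = "reference",
               replicate = seq_along(reference), cq = reference, flag = flag,
               stringsAsFactors = FALSE))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
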