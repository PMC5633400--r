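# Nearest-neighbor thermodynamic parameter tables.
#
# Perfect-match stacks: the unified DNA/DNA nearest-neighbor set
# (dH kcal/mol, dS cal/(mol K), 1 M NaCl reference). Internal single
# mismatches: the standard published internal-mismatch extension of the same
# set. Keys are written top-strand 5'->3' over bottom-strand 3'->5'
# ("AG/TT" = 5'-AG-3' paired with 3'-TT-5'); a key absent in this
# orientation is looked up reversed.

.NN_DH <- c(
  "AA/TT" = -7.9,  "AT/TA" = -7.2,  "TA/AT" = -7.2,  "CA/GT" = -8.5,
  "GT/CA" = -8.4,  "CT/GA" = -7.8,  "GA/CT" = -8.2,  "CG/GC" = -10.6,
  "GC/CG" = -9.8,  "GG/CC" = -8.0
)
.NN_DS <- c(
  "AA/TT" = -22.2, "AT/TA" = -20.4, "TA/AT" = -21.3, "CA/GT" = -22.7,
  "GT/CA" = -22.4, "CT/GA" = -21.0, "GA/CT" = -22.2, "CG/GC" = -27.2,
  "GC/CG" = -24.4, "GG/CC" = -19.9
)

# Duplex initiation, per terminal base pair.
.INIT_GC <- c(dH = 0.1, dS = -2.8)
.INIT_AT <- c(dH = 2.3, dS = 4.1)

# Internal single-mismatch stacks (one Watson-Crick pair + one mismatch).
.MM_DH <- c(
  # G.T mismatches
  "AG/TT" =  1.0, "AT/TG" = -2.5, "CG/GT" = -4.1, "CT/GG" = -2.8,
  "GG/CT" =  3.3, "GG/TT" =  5.8, "GT/CG" = -4.4, "GT/TG" =  4.1,
  "TG/AT" = -0.1, "TG/GT" = -1.4, "TT/AG" = -1.3,
  # G.A mismatches
  "AA/TG" = -0.6, "AG/TA" = -0.7, "CA/GG" = -0.7, "CG/GA" = -4.0,
  "GA/CG" = -0.6, "GG/CA" =  0.5, "TA/AG" =  0.7, "TG/AA" =  3.0,
  # C.T mismatches
  "AC/TT" =  0.7, "AT/TC" = -1.2, "CC/GT" = -0.8, "CT/GC" = -1.5,
  "GC/CT" =  2.3, "GT/CC" =  5.2, "TC/AT" =  1.2, "TT/AC" =  1.0,
  # A.C mismatches
  "AA/TC" =  2.3, "AC/TA" =  5.3, "CA/GC" =  1.9, "CC/GA" =  0.6,
  "GA/CC" =  5.2, "GC/CA" = -0.7, "TA/AC" =  3.4, "TC/AA" =  7.6,
  # A.A, C.C, G.G, T.T
  "AA/TA" =  1.2, "CA/GA" = -0.9, "GA/CA" = -2.9, "TA/AA" =  4.7,
  "AC/TC" =  0.0, "CC/GC" = -1.5, "GC/CC" =  3.6, "TC/AC" =  6.1,
  "AG/TG" = -3.1, "CG/GG" = -4.9, "GG/CG" = -6.0, "TG/AG" =  1.6,
  "AT/TT" = -2.7, "CT/GT" = -5.0, "GT/CT" = -2.2, "TT/AT" =  0.2
)
.MM_DS <- c(
  "AG/TT" =   0.9, "AT/TG" =  -8.3, "CG/GT" = -11.7, "CT/GG" =  -8.0,
  "GG/CT" =  10.4, "GG/TT" =  16.3, "GT/CG" = -12.3, "GT/TG" =   9.5,
  "TG/AT" =  -1.7, "TG/GT" =  -6.2, "TT/AG" =  -5.3,
  "AA/TG" =  -2.3, "AG/TA" =  -2.3, "CA/GG" =  -2.3, "CG/GA" = -13.2,
  "GA/CG" =  -1.0, "GG/CA" =   3.2, "TA/AG" =   0.7, "TG/AA" =   7.4,
  "AC/TT" =   0.2, "AT/TC" =  -6.2, "CC/GT" =  -4.5, "CT/GC" =  -6.1,
  "GC/CT" =   5.4, "GT/CC" =  13.5, "TC/AT" =   0.7, "TT/AC" =   0.7,
  "AA/TC" =   4.6, "AC/TA" =  14.6, "CA/GC" =   3.7, "CC/GA" =  -0.6,
  "GA/CC" =  14.2, "GC/CA" =  -3.8, "TA/AC" =   8.0, "TC/AA" =  20.2,
  "AA/TA" =   1.7, "CA/GA" =  -4.2, "GA/CA" =  -9.8, "TA/AA" =  12.9,
  "AC/TC" =  -4.4, "CC/GC" =  -7.2, "GC/CC" =   8.9, "TC/AC" =  16.4,
  "AG/TG" =  -9.5, "CG/GG" = -15.3, "GG/CG" = -15.8, "TG/AG" =   3.6,
  "AT/TT" = -10.8, "CT/GT" = -15.8, "GT/CT" =  -8.4, "TT/AT" =  -1.5
)

# LNA perturbation terms, per locked base and adjacent stack. A locked base
# stabilizes each matched stack it participates in (values summarized from
# the published LNA nearest-neighbor increment set, which reports average
# stabilization of roughly -0.6 to -0.9 kcal/mol dG37 per modified stack,
# strongest for locked G/C). A mismatch at or adjacent to a locked position
# additionally destabilizes beyond the unmodified mismatch penalty, the
# physical basis of LNA mismatch discrimination.
.LNA_MATCH_DH <- c(A = -2.6, C = -3.0, G = -3.2, T = -2.4)
.LNA_MATCH_DS <- c(A = -6.5, C = -7.0, G = -7.6, T = -5.8)
# Extra mismatch penalty (per adjacent stack), ~ +0.7 kcal/mol dG37.
.LNA_MISMATCH_DH <- 0.0
.LNA_MISMATCH_DS <- -2.3

# Fallback for stacks with two adjacent mismatched pairs (no published NN
# parameters): destabilization of ~ +1.0 kcal/mol dG37 per stack.
.DOUBLE_MM_DH <- 0.0
.DOUBLE_MM_DS <- -3.2

.GAS_CONSTANT <- 1.9872  # cal/(mol K)

nn_lookup <- function(keys, table) {
  v <- table[keys]
  miss <- is.na(v)
  if (any(miss)) {
    rev_keys <- vapply(strsplit(keys[miss], ""), function(s) {
      paste(rev(s), collapse = "")
    }, "")
    v[miss] <- table[rev_keys]
  }
  v
}
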