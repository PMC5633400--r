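# Shared sequence and small-numeric helpers. Coordinates are 0-based
# half-open internally; conversion to 1-based inclusive happens only in
# human-facing reports (see io.R).

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA strings (IUPAC alphabet).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

assert_dna <- function(x, what = "sequence", iupac = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop(sprintf("%s must be a single non-empty character string", what),
         call. = FALSE)
  }
  alphabet <- if (iupac) IUPAC_CHARS else c("A", "C", "G", "T")
  bad <- setdiff(unique(strsplit(toupper(x), "")[[1]]), alphabet)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-%s characters: %s", what,
                 if (iupac) "IUPAC" else "ACGT", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  toupper(x)
}

gc_fraction <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  sum(s %in% c("G", "C")) / length(s)
}

max_homopolymer <- function(seq) {
  r <- rle(strsplit(seq, "")[[1]])
  max(r$lengths)
}

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Namespaced seeding: each stochastic operation perturbs the user seed by a
# fixed operation offset so partial pipeline reruns stay reproducible.
OP_SEED_OFFSETS <- c(founder = 1L, qpcr = 2L, dpcr = 3L, clones = 4L,
                     endpoint = 5L, reference = 6L)

with_op_seed <- function(seed, op, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  offset <- OP_SEED_OFFSETS[[op]]
  derived <- (as.double(seed) * 7L + offset * 1000003) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(derived))
  force(expr)
}

# 0-based half-open -> 1-based inclusive (for reports)
to1based <- function(interval) c(interval[1] + 1L, interval[2])

intervals_overlap <- function(a, b) a[1] < b[2] && b[1] < a[2]
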