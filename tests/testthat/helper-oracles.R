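# Independent oracles used to cross-check the package implementation.
# These are deliberately separate codings: their parameter tables are frozen
# literals and their algorithms are written from the definitions, not shared
# with the package internals.

# ---- nearest-neighbor Tm oracle ------------------------------------------

ORACLE_NN <- local({
  dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
          GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0, TT = -7.9, TG = -8.5,
          AC = -8.4, AG = -7.8, TC = -8.2)
  # complete the symmetric pairs explicitly: key = top dinucleotide 5'->3'
  dh <- c(dh, CC = -8.0)
  ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
          TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
          CC = -19.9)
  list(dh = dh, ds = ds)
})

# Tm of a perfect-match unmodified duplex, two-state, 1 M reference plus the
# empirical Mg2+/monovalent correction; an independent re-summation.
oracle_tm_perfect <- function(probe, monovalent_mM = 50, mg_mM = 3.0,
                              dntp_mM = 0.8, strand_conc_nM = 250) {
  bases <- strsplit(probe, "")[[1]]
  n <- length(bases)
  dH <- 0; dS <- 0
  for (i in 1:(n - 1)) {
    k <- paste0(bases[i], bases[i + 1])
    dH <- dH + ORACLE_NN$dh[[k]]
    dS <- dS + ORACLE_NN$ds[[k]]
  }
  for (term in c(bases[1], bases[n])) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  ct <- strand_conc_nM * 1e-9
  tm1 <- dH * 1000 / (dS + 1.9872 * log(ct / 4))
  fgc <- mean(bases %in% c("G", "C"))
  mg <- max(0, mg_mM - dntp_mM) * 1e-3
  mon <- monovalent_mM * 1e-3
  inv_corr <- function(a, d, g) {
    lm_ <- log(mg)
    1 / tm1 + a - 9.11e-6 * lm_ + fgc * (6.26e-5 + d * lm_) +
      (-4.82e-4 + 5.25e-4 * lm_ + g * lm_^2) / (2 * (n - 1))
  }
  if (mg <= 0) {
    tm <- 1 / (1 / tm1 + (4.29 * fgc - 3.95) * 1e-5 * log(mon) +
                 9.40e-6 * log(mon)^2)
  } else if (mon <= 0) {
    tm <- 1 / inv_corr(3.92e-5, 1.42e-5, 8.31e-5)
  } else {
    ratio <- sqrt(mg) / mon
    if (ratio < 0.22) {
      tm <- 1 / (1 / tm1 + (4.29 * fgc - 3.95) * 1e-5 * log(mon) +
                   9.40e-6 * log(mon)^2)
    } else if (ratio < 6) {
      lnm <- log(mon)
      tm <- 1 / inv_corr(3.92e-5 * (0.843 - 0.352 * sqrt(mon) * lnm),
                         1.42e-5 * (1.279 - 4.03e-3 * lnm -
                                      8.03e-3 * lnm^2),
                         8.31e-5 * (0.486 - 0.258 * lnm +
                                      5.25e-3 * lnm^3))
    } else {
      tm <- 1 / inv_corr(3.92e-5, 1.42e-5, 8.31e-5)
    }
  }
  tm - 273.15
}

# ---- affine Needleman-Wunsch oracle --------------------------------------

# Exhaustive dynamic program written from the recurrence definitions; gap of
# length L costs open + L * ext. Tie preferences mirror the documented
# contract: end/match state M > X > Y; within a gap state extension first.
oracle_nw <- function(a, b, match = 1, mismatch = -2, open = 5, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  if (n > 0) X[2:(n + 1), 1] <- -open - ext * (1:n)
  if (m > 0) Y[1, 2:(m + 1)] <- -open - ext * (1:m)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(X[i - 1, j] - ext, M[i - 1, j] - open - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(Y[i, j - 1] - ext, M[i, j - 1] - open - ext,
                     X[i, j - 1] - open - ext)
    }
  }
  sc <- c(M = M[n + 1, m + 1], X = X[n + 1, m + 1], Y = Y[n + 1, m + 1])
  st <- names(sc)[which.max(sc)]  # which.max takes the first max: M > X > Y
  aa <- character(0); bb <- character(0)
  i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    if (st == "M") {
      aa <- c(A[i - 1], aa); bb <- c(B[j - 1], bb)
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      tgt <- M[i, j] - s
      st <- if (isTRUE(all.equal(M[i - 1, j - 1], tgt))) "M"
            else if (isTRUE(all.equal(X[i - 1, j - 1], tgt))) "X" else "Y"
      i <- i - 1; j <- j - 1
    } else if (st == "X") {
      aa <- c(A[i - 1], aa); bb <- c("-", bb)
      v <- X[i, j]
      st <- if (isTRUE(all.equal(X[i - 1, j] - ext, v))) "X"
            else if (isTRUE(all.equal(M[i - 1, j] - open - ext, v))) "M"
            else "Y"
      i <- i - 1
    } else {
      aa <- c("-", aa); bb <- c(B[j - 1], bb)
      v <- Y[i, j]
      st <- if (isTRUE(all.equal(Y[i, j - 1] - ext, v))) "Y"
            else if (isTRUE(all.equal(M[i, j - 1] - open - ext, v))) "M"
            else "X"
      j <- j - 1
    }
  }
  list(score = max(sc), aligned_a = paste(aa, collapse = ""),
       aligned_b = paste(bb, collapse = ""))
}

# Independent variant extraction + left normalization from an aligned pair
# (reference on top, query below).
oracle_variants <- function(aligned_ref, aligned_query, reference) {
  ra <- strsplit(aligned_ref, "")[[1]]
  qa <- strsplit(aligned_query, "")[[1]]
  refc <- strsplit(reference, "")[[1]]
  vars <- list()
  rp <- 0; i <- 1; n <- length(ra)
  while (i <= n) {
    if (ra[i] == "-") {
      j <- i; while (j <= n && ra[j] == "-") j <- j + 1
      vars[[length(vars) + 1]] <- list(pos = rp, ref = "",
                                       alt = paste(qa[i:(j - 1)], collapse = ""),
                                       type = "ins")
      i <- j
    } else if (qa[i] == "-") {
      j <- i; while (j <= n && qa[j] == "-") j <- j + 1
      vars[[length(vars) + 1]] <- list(pos = rp,
                                       ref = paste(ra[i:(j - 1)], collapse = ""),
                                       alt = "", type = "del")
      rp <- rp + (j - i); i <- j
    } else {
      if (ra[i] != qa[i]) {
        vars[[length(vars) + 1]] <- list(pos = rp, ref = ra[i], alt = qa[i],
                                         type = "sub")
      }
      rp <- rp + 1; i <- i + 1
    }
  }
  # left shift, bounded by the previous variant's end
  lo <- 0
  for (k in seq_along(vars)) {
    v <- vars[[k]]
    if (v$type == "del") {
      p <- v$pos; L <- nchar(v$ref)
      while (p > lo && refc[p] == refc[p + L]) p <- p - 1
      v$pos <- p; v$ref <- paste(refc[(p + 1):(p + L)], collapse = "")
      lo <- p + L
    } else if (v$type == "ins") {
      p <- v$pos; s <- strsplit(v$alt, "")[[1]]
      while (p > lo && refc[p] == s[length(s)]) {
        s <- c(refc[p], s[-length(s)]); p <- p - 1
      }
      v$pos <- p; v$alt <- paste(s, collapse = "")
      lo <- max(lo, p)
    } else lo <- v$pos + 1
    vars[[k]] <- v
  }
  if (!length(vars)) {
    return(data.frame(pos = integer(), ref = character(),
                      alt = character(), type = character()))
  }
  df <- do.call(rbind, lapply(vars, as.data.frame))
  df[order(df$pos), ]
}

variant_signature <- function(v) {
  if (nrow(v) == 0) return("")
  paste(sprintf("%d:%s>%s", v$pos, v$ref, v$alt), collapse = ";")
}
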