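# Clone/amplicon classification: global pairwise alignment to the reference,
# variant calling with left-shifted (normalized) indels, assignment to the
# allele taxonomy (wt, HDR, partial_HDR, deletion, insertion, point_mutation,
# mixed), HDR component decomposition, and per-animal mosaicism summaries.

ALLELE_CATEGORIES <- c("wt", "HDR", "partial_HDR", "deletion", "insertion",
                       "point_mutation", "mixed")
HDR_COMPONENT_NAMES <- c("target_codon", "pam_mutation",
                         "silent_restriction_site")

#' Define an HDR donor template
#'
#' The designed homology-directed-repair (HDR) allele is described by its
#' component substitutions: the target codon change, the PAM-inactivating
#' mutation, and the silent substitutions creating a diagnostic restriction
#' site (e.g. EcoRI GAATTC). A component may span several base substitutions;
#' it counts as present in a clone only when all of its substitutions are
#' observed.
#'
#' @param components data.frame with columns `name` (one of
#'   `r paste(HDR_COMPONENT_NAMES, collapse = ", ")`), `pos` (0-based
#'   reference coordinate), `ref`, `alt` (single bases).
#' @param restriction_site optional recognition sequence created by the
#'   silent component (documentation only).
#' @return object of class `hdr_template`.
#' @export
hdr_template <- function(components, restriction_site = "GAATTC") {
  stopifnot(is.data.frame(components),
            all(c("name", "pos", "ref", "alt") %in% names(components)))
  if (!all(components$name %in% HDR_COMPONENT_NAMES)) {
    stop("component names must be in: ",
         paste(HDR_COMPONENT_NAMES, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(components$pos)) {
    stop("HDR components must not overlap", call. = FALSE)
  }
  components$pos <- as.integer(components$pos)
  structure(list(components = components,
                 restriction_site = restriction_site),
            class = "hdr_template")
}

# Apply a set of substitution rows to a reference string.
apply_substitutions <- function(reference, rows) {
  s <- strsplit(reference, "")[[1]]
  stopifnot(all(s[rows$pos + 1L] == rows$ref))
  s[rows$pos + 1L] <- rows$alt
  paste(s, collapse = "")
}

empty_variants <- function() {
  data.frame(pos = integer(), ref = character(), alt = character(),
             type = character(), stringsAsFactors = FALSE)
}

# Extract variants from an aligned (reference, query) pair of equal-length
# strings with '-' gaps. Coordinates are 0-based on the reference;
# insertions are anchored at the reference position they precede.
variants_from_alignment <- function(aligned_ref, aligned_query) {
  ra <- strsplit(aligned_ref, "")[[1]]
  qa <- strsplit(aligned_query, "")[[1]]
  out <- list()
  rp <- 0L
  i <- 1L
  n <- length(ra)
  while (i <= n) {
    if (ra[i] != "-" && qa[i] != "-") {
      if (ra[i] != qa[i]) {
        out[[length(out) + 1L]] <- list(pos = rp, ref = ra[i], alt = qa[i],
                                        type = "sub")
      }
      rp <- rp + 1L
      i <- i + 1L
    } else if (qa[i] == "-") {
      j <- i
      while (j <= n && qa[j] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- list(pos = rp,
                                      ref = paste(ra[i:(j - 1L)], collapse = ""),
                                      alt = "", type = "del")
      rp <- rp + (j - i)
      i <- j
    } else {
      j <- i
      while (j <= n && ra[j] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- list(pos = rp, ref = "",
                                      alt = paste(qa[i:(j - 1L)], collapse = ""),
                                      type = "ins")
      i <- j
    }
  }
  if (length(out) == 0L) return(empty_variants())
  do.call(rbind, lapply(out, function(v) {
    data.frame(pos = v$pos, ref = v$ref, alt = v$alt, type = v$type,
               stringsAsFactors = FALSE)
  }))
}

# Left-shift indels within repeat context (parsimony-style normalization);
# a variant never shifts past the end of the preceding variant.
normalize_variants <- function(variants, reference) {
  if (nrow(variants) == 0L) return(variants)
  refc <- strsplit(reference, "")[[1]]
  variants <- variants[order(variants$pos,
                             match(variants$type, c("del", "ins", "sub"))), ,
                       drop = FALSE]
  floor_pos <- 0L
  for (k in seq_len(nrow(variants))) {
    v <- variants[k, ]
    if (v$type == "del") {
      p <- v$pos
      len <- nchar(v$ref)
      while (p > floor_pos && refc[p] == refc[p + len]) p <- p - 1L
      variants$pos[k] <- p
      variants$ref[k] <- paste(refc[(p + 1L):(p + len)], collapse = "")
      floor_pos <- p + len
    } else if (v$type == "ins") {
      p <- v$pos
      s <- strsplit(v$alt, "")[[1]]
      len <- length(s)
      while (p > floor_pos && refc[p] == s[len]) {
        s <- c(refc[p], s[-len])
        p <- p - 1L
      }
      variants$pos[k] <- p
      variants$alt[k] <- paste(s, collapse = "")
      floor_pos <- max(floor_pos, p)
    } else {
      floor_pos <- v$pos + 1L
    }
  }
  variants[order(variants$pos), , drop = FALSE]
}

#' Globally align a clone sequence to the reference amplicon
#'
#' Affine-gap global alignment with deterministic tie-breaking; the clone
#' orientation is auto-detected (the reverse complement is tried and the
#' higher-scoring orientation kept). Indels are normalized by left-shifting
#' within homopolymer/repeat context.
#'
#' @param clone_seq clone sequence (ACGT).
#' @param reference reference amplicon sequence.
#' @param match,mismatch,gap_open,gap_ext alignment scores; defaults favor
#'   parsimonious indel calls at amplicon scale.
#' @param min_identity identity floor below which the clone is rejected as
#'   unalignable (likely off-target amplicon or vector sequence).
#' @return object of class `clone_alignment`: score, aligned strings,
#'   identity, orientation, and a normalized variant table
#'   (`pos` 0-based, `ref`, `alt`, `type`).
#' @export
align_to_reference <- function(clone_seq, reference, match = 1L,
                               mismatch = -2L, gap_open = 5L, gap_ext = 1L,
                               min_identity = 0.6) {
  clone_seq <- assert_dna(clone_seq, "clone_seq")
  reference <- assert_dna(reference, "reference")
  if (nchar(clone_seq) < 0.5 * nchar(reference) ||
      nchar(clone_seq) > 1.5 * nchar(reference)) {
    stop("clone length outside 0.5-1.5x the reference length", call. = FALSE)
  }
  fwd <- nw_align_cpp(reference, clone_seq, match, mismatch, gap_open,
                      gap_ext, FALSE)
  rev <- nw_align_cpp(reference, revcomp(clone_seq), match, mismatch,
                      gap_open, gap_ext, FALSE)
  orientation <- if (rev$score > fwd$score) "-" else "+"
  aln <- if (orientation == "-") rev else fwd
  ra <- strsplit(aln$aligned_a, "")[[1]]
  qa <- strsplit(aln$aligned_b, "")[[1]]
  identity <- sum(ra == qa & ra != "-") / length(ra)
  if (identity < min_identity) {
    stop(sprintf("clone identity %.2f below floor %.2f: unalignable clone",
                 identity, min_identity), call. = FALSE)
  }
  variants <- normalize_variants(variants_from_alignment(aln$aligned_a,
                                                         aln$aligned_b),
                                 reference)
  structure(list(score = aln$score, aligned_ref = aln$aligned_a,
                 aligned_query = aln$aligned_b, identity = identity,
                 orientation = orientation, variants = variants,
                 reference = reference),
            class = "clone_alignment")
}

#' @export
print.clone_alignment <- function(x, ...) {
  cat(sprintf("Clone alignment: score %d, identity %.1f%%, strand %s, %d variant(s)\n",
              x$score, 100 * x$identity, x$orientation, nrow(x$variants)))
  invisible(x)
}

variant_in_window <- function(variants, window) {
  if (nrow(variants) == 0L) return(logical(0))
  w1 <- window[1]; w2 <- window[2]
  mapply(function(pos, ref, type) {
    switch(type,
           sub = pos >= w1 && pos < w2,
           del = pos < w2 && (pos + nchar(ref)) > w1,
           ins = pos > w1 && pos < w2)
  }, variants$pos, variants$ref, variants$type)
}

variant_key <- function(variants) {
  if (nrow(variants) == 0L) return("")
  paste(sprintf("%d:%s>%s", variants$pos, variants$ref, variants$alt),
        collapse = ";")
}

#' Classify one aligned clone into the allele taxonomy
#'
#' Variants inside the analysis window drive the category call; variants
#' outside the window are recorded separately. Categories: `wt` (no variants
#' in window); `HDR` (all HDR components present, nothing else);
#' `partial_HDR` (a nonempty proper subset of components, nothing else);
#' `deletion` / `insertion` / `point_mutation` (a single variant class,
#' no HDR components); `mixed` (two or more variant classes, or HDR
#' components combined with other edits).
#'
#' @param aln a [align_to_reference()] result.
#' @param hdr an [hdr_template()].
#' @param window 0-based half-open analysis window `c(start, end)` on the
#'   reference.
#' @param clone_id optional clone identifier.
#' @return object of class `allele_record`.
#' @export
classify_allele <- function(aln, hdr, window, clone_id = NA_character_) {
  stopifnot(inherits(aln, "clone_alignment"), inherits(hdr, "hdr_template"),
            length(window) == 2L, window[1] < window[2])
  if (window[2] > nchar(aln$reference)) {
    stop("analysis window exceeds the reference", call. = FALSE)
  }
  # window must be covered by the clone: no end-gap columns of the query
  # may overlap the window
  qa <- strsplit(aln$aligned_query, "")[[1]]
  ra <- strsplit(aln$aligned_ref, "")[[1]]
  rp <- cumsum(ra != "-")  # reference position after each column (1-based)
  qcov <- which(qa != "-")
  if (length(qcov) == 0L ||
      rp[qcov[1]] - 1L > window[1] || rp[qcov[length(qcov)]] < window[2]) {
    stop("clone does not cover the full analysis window: incomplete clone",
         call. = FALSE)
  }

  v <- aln$variants
  inw <- variant_in_window(v, window)
  vw <- v[inw, , drop = FALSE]
  vout <- v[!inw, , drop = FALSE]

  comp <- hdr$components
  comp_present <- vapply(split(comp, comp$name), function(rows) {
    all(vapply(seq_len(nrow(rows)), function(i) {
      any(vw$type == "sub" & vw$pos == rows$pos[i] & vw$alt == rows$alt[i])
    }, TRUE))
  }, TRUE)
  present <- names(comp_present)[comp_present]

  is_comp_sub <- if (nrow(vw) == 0L) logical(0) else {
    vw$type == "sub" &
      mapply(function(pos, alt) {
        any(comp$pos == pos & comp$alt == alt)
      }, vw$pos, vw$alt, USE.NAMES = FALSE) &
      vapply(vw$pos, function(p) {
        nm <- comp$name[comp$pos == p]
        length(nm) == 1L && nm %in% present
      }, TRUE)
  }
  other <- vw[!is_comp_sub, , drop = FALSE]
  all_components <- setdiff(unique(comp$name), character(0))

  category <- if (nrow(vw) == 0L) {
    "wt"
  } else if (nrow(other) == 0L) {
    if (setequal(present, all_components)) "HDR" else "partial_HDR"
  } else if (length(present) > 0L) {
    "mixed"
  } else {
    classes <- unique(other$type)
    if (length(classes) > 1L) "mixed"
    else switch(classes, sub = "point_mutation", del = "deletion",
                ins = "insertion")
  }

  structure(list(clone_id = clone_id, category = category,
                 variants_window = vw, variants_outside = vout,
                 hdr_components_present = present,
                 variant_key = variant_key(v),
                 window = window),
            class = "allele_record")
}

#' @export
print.allele_record <- function(x, ...) {
  cat(sprintf("Allele %s: %s (%d in-window variant(s); components: %s)\n",
              x$clone_id %||% "?", x$category, nrow(x$variants_window),
              if (length(x$hdr_components_present))
                paste(x$hdr_components_present, collapse = "+") else "none"))
  invisible(x)
}

#' Summarize the allelic composition of one founder animal
#'
#' @param records list of [classify_allele()] results for one animal.
#' @param animal_id optional identifier.
#' @return object of class `founder_summary`: clone count, distinct allele
#'   count (exact variant-set identity after normalization), per-category
#'   fractions, and the wild-type percentage.
#' @export
summarize_founder <- function(records, animal_id = NA_character_) {
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, TRUE, "allele_record")))
  cats <- vapply(records, function(r) r$category, "")
  keys <- vapply(records, function(r) r$variant_key, "")
  fractions <- setNames(numeric(length(ALLELE_CATEGORIES)), ALLELE_CATEGORIES)
  tab <- table(factor(cats, levels = ALLELE_CATEGORIES))
  fractions[] <- as.numeric(tab) / length(records)
  structure(list(animal_id = animal_id, n_clones = length(records),
                 n_distinct_alleles = length(unique(keys)),
                 category_fractions = fractions,
                 wt_percent = 100 * fractions[["wt"]]),
            class = "founder_summary")
}

#' @export
print.founder_summary <- function(x, ...) {
  cat(sprintf("Founder %s: %d clones, %d distinct allele(s), wt = %.1f%%\n",
              x$animal_id %||% "?", x$n_clones, x$n_distinct_alleles,
              x$wt_percent))
  nz <- x$category_fractions[x$category_fractions > 0]
  if (length(nz)) {
    cat("  ", paste(sprintf("%s %.0f%%", names(nz), 100 * nz),
                    collapse = ", "), "\n")
  }
  invisible(x)
}

#' HDR component co-occurrence counts (Venn decomposition)
#'
#' Counts clones by the exact subset of HDR components they carry (the
#' 2^3 - 1 nonempty subsets of target codon / PAM mutation / silent
#' restriction site).
#'
#' @param records list of [classify_allele()] results.
#' @return data.frame with columns `subset` and `count`; full-component
#'   clones appear under the subset joining all component names.
#' @export
hdr_component_venn <- function(records) {
  stopifnot(all(vapply(records, inherits, TRUE, "allele_record")))
  subsets <- unlist(lapply(seq_along(HDR_COMPONENT_NAMES), function(k) {
    combn(HDR_COMPONENT_NAMES, k, paste, collapse = "+")
  }))
  counts <- setNames(integer(length(subsets)), subsets)
  for (r in records) {
    p <- sort(r$hdr_components_present)
    if (length(p) == 0L) next
    key <- paste(intersect(HDR_COMPONENT_NAMES, p), collapse = "+")
    counts[key] <- counts[key] + 1L
  }
  data.frame(subset = names(counts), count = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}
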