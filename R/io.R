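# Readers/writers for the toolkit's table and sequence formats. One
# canonical dialect: CSV (comma, UTF-8, mandatory header) for instrument-
# style inputs, TSV for human-facing reports, JSON for assay definitions and
# HDR templates, FASTA for sequences. Coordinates in reports are 1-based
# inclusive; everything internal stays 0-based half-open.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_csv_required <- function(path, required) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a qPCR Cq table (CSV)
#'
#' Expected columns: `sample_id`, `channel`, `replicate`, `cq`, `flag`.
#' A well with `flag = "noamp"` may carry an empty/NA Cq; any other
#' malformed row is dropped and collected into the `error_report` attribute.
#'
#' @param path CSV file.
#' @return data.frame of wells.
#' @export
read_cq_table <- function(path) {
  df <- read_csv_required(path, c("sample_id", "channel", "replicate", "cq",
                                  "flag"))
  df$flag[is.na(df$flag)] <- ""
  df$cq <- suppressWarnings(as.numeric(df$cq))
  bad <- df$flag != "noamp" & (!is.finite(df$cq) | df$cq <= 0)
  errors <- df[bad, , drop = FALSE]
  df <- df[!bad, , drop = FALSE]
  if (nrow(df) == 0L) stop("no usable wells in ", path, call. = FALSE)
  attr(df, "error_report") <- errors
  df
}

#' Write a qPCR Cq table (CSV)
#' @param wells data.frame of wells.
#' @param path output CSV.
#' @export
write_cq_table <- function(wells, path) {
  cols <- c("sample_id", "channel", "replicate", "cq", "flag")
  if (is.null(wells$flag)) wells$flag <- ""
  utils::write.csv(wells[, cols], path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}

#' Read a dPCR partition table (CSV)
#'
#' Either boolean calls (`partition_id`, `ref_positive`, `target_positive`)
#' or raw fluorescence (`partition_id`, `fluor_ref`, `fluor_target`).
#' @param path CSV file.
#' @return data.frame of partitions.
#' @export
read_partition_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("ref_positive", "target_positive") %in% names(df))) {
    df$ref_positive <- as.logical(df$ref_positive)
    df$target_positive <- as.logical(df$target_positive)
  } else if (!all(c("fluor_ref", "fluor_target") %in% names(df))) {
    stop(basename(path), ": need ref_positive/target_positive or ",
         "fluor_ref/fluor_target columns", call. = FALSE)
  }
  df
}

#' Write a dPCR partition table (CSV)
#' @param chip data.frame of partitions.
#' @param path output CSV.
#' @export
write_partition_table <- function(chip, path) {
  utils::write.csv(chip, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an endpoint-fluorescence table (CSV)
#'
#' Expected columns: `sample_id`, `role`, `fluor_wt`, `fluor_mut`.
#' @param path CSV file.
#' @return data.frame of endpoint samples.
#' @export
read_endpoint_table <- function(path) {
  read_csv_required(path, c("sample_id", "role", "fluor_wt", "fluor_mut"))
}

#' Write an endpoint-fluorescence table (CSV)
#' @param samples data.frame of endpoint samples.
#' @param path output CSV.
#' @export
write_endpoint_table <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a (multi-)FASTA file
#'
#' IDs are preserved verbatim; sequences are uppercased. Empty files and
#' duplicated IDs are format errors.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) {
                    stop("failed to parse FASTA ", basename(path), ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- names(set)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA IDs in ", basename(path), call. = FALSE)
  }
  setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output FASTA.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 70L)
  invisible(path)
}

#' Read an HDR template definition (JSON)
#'
#' JSON object with a `components` array (fields `name`, `pos`, `ref`,
#' `alt`) and optional `restriction_site`.
#' @param path JSON file.
#' @return an [hdr_template()].
#' @export
read_hdr_template <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  hdr_template(as.data.frame(j$components),
               restriction_site = j$restriction_site %||% "GAATTC")
}

#' Write an HDR template definition (JSON)
#' @param hdr an [hdr_template()].
#' @param path output JSON.
#' @export
write_hdr_template <- function(hdr, path) {
  jsonlite::write_json(list(components = hdr$components,
                            restriction_site = hdr$restriction_site),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an assay sheet (TSV, one row per oligo)
#'
#' Locked bases are marked in the `+N` dialect (`"AC+G+T+GA"`); coordinates
#' are 1-based inclusive.
#'
#' @param assay a [dropoff_assay()].
#' @param path output TSV.
#' @export
write_assay_sheet <- function(assay, path) {
  row <- function(name, seq, lna, channel, tm, fp, strand) {
    data.frame(name = name, sequence = lna_notation(seq, lna),
               channel = channel, tm_C = round(tm, 2),
               start = fp[1] + 1L, end = fp[2], strand = strand,
               stringsAsFactors = FALSE)
  }
  tp <- assay$target_probe
  rp <- assay$reference_probe
  df <- rbind(
    row("fw_primer", assay$fw_primer$sequence, integer(), "",
        assay$fw_primer$tm_C, assay$fw_primer$footprint, "+"),
    row("rv_primer", assay$rv_primer$sequence, integer(), "",
        assay$rv_primer$tm_C, assay$rv_primer$footprint, "-"),
    row("target_probe", tp$sequence, tp$lna_positions, tp$channel, tp$tm_C,
        tp$footprint, tp$strand),
    row("reference_probe", rp$sequence, rp$lna_positions, rp$channel,
        rp$tm_C, rp$footprint, rp$strand))
  write_tsv(df, path)
}

#' Write a machine-readable assay definition (JSON)
#' @param assay a [dropoff_assay()].
#' @param path output JSON.
#' @export
write_assay_json <- function(assay, path) {
  strip <- function(p) p[setdiff(names(p), "reference")]
  x <- list(reference_id = assay$reference_id,
            amplicon = assay$amplicon, cut_site = assay$cut_site,
            fw_primer = assay$fw_primer, rv_primer = assay$rv_primer,
            target_probe = unclass(assay$target_probe),
            reference_probe = unclass(assay$reference_probe))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an assay definition (JSON)
#' @param path JSON file written by [write_assay_json()].
#' @return a [dropoff_assay()].
#' @export
read_assay_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk_probe <- function(p) {
    probe_design(p$sequence, lna_positions = unlist(p$lna_positions),
                 channel = p$channel, role = p$role, tm_C = p$tm_C,
                 footprint = unlist(p$footprint), strand = p$strand)
  }
  dropoff_assay(j$reference_id,
                fw_primer = as.list(j$fw_primer),
                rv_primer = as.list(j$rv_primer),
                target_probe = mk_probe(j$target_probe),
                reference_probe = mk_probe(j$reference_probe),
                amplicon = unlist(j$amplicon), cut_site = j$cut_site)
}
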