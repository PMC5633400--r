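# The umbrella pipeline runner behind the command-line interface. Every
# subcommand reads/writes the package's canonical formats and drops a
# provenance JSON (inputs hashed, resolved configuration, versions, seed)
# sufficient to reproduce the outputs exactly; no timestamps are recorded so
# reruns are byte-identical.

PIPELINE_SUBCOMMANDS <- c("simulate", "qpcr", "dpcr", "classify", "genotype",
                          "design", "report", "cohort")

pipeline_defaults <- function() {
  list(
    seed = 1L,
    n_animals = 20L,
    clones_per_animal = 15L,
    n_partitions = 20000L,
    mean_copies = 0.8,
    cq_sigma = 0.1,
    calibrator = "calibrator",
    mode = "dropoff",
    window = NULL,
    cut = NULL,
    thresholds = NULL,
    permissive = FALSE
  )
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  if (is.null(config$subcommand) ||
      !config$subcommand %in% PIPELINE_SUBCOMMANDS) {
    stop("config$subcommand must be one of: ",
         paste(PIPELINE_SUBCOMMANDS, collapse = ", "), call. = FALSE)
  }
  allowed <- c(names(pipeline_defaults()), "subcommand", "out",
               "cq_table", "partitions", "endpoint", "ref_fasta", "clones",
               "hdr_json")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  modifyList(pipeline_defaults(), config)
}

write_provenance <- function(cfg, out_dir, inputs, outputs) {
  # paths are recorded relative to the output directory so a rerun into any
  # directory with the same configuration and seed is byte-identical
  cfg_echo <- cfg[setdiff(names(cfg), "out")]
  prov <- list(
    tool = "dropoffr",
    version = as.character(packageVersion("dropoffr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg_echo[order(names(cfg_echo))],
    inputs = lapply(inputs, function(p) {
      list(path = basename(p), md5 = unname(md5sum(p)))
    }),
    outputs = lapply(unname(outputs), basename))
  path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run a dropoffr pipeline subcommand
#'
#' Subcommands: `simulate` (write a synthetic founder cohort: clone FASTA,
#' Cq table, per-animal dPCR partition tables, truth table), `qpcr`, `dpcr`,
#' `classify`, `genotype`, `design`, `report` (join per-animal estimates),
#' and `cohort` (simulate + all analyses + report in one run). Every run
#' writes a `provenance.json` describing inputs, configuration and versions;
#' reruns with the same configuration and seed are byte-identical.
#'
#' @param config named list or path to a JSON config. Required fields:
#'   `subcommand`, `out` (output directory); further fields depend on the
#'   subcommand (e.g. `cq_table`, `partitions`, `ref_fasta`, `clones`,
#'   `hdr_json`, `cut`, `seed`, `n_animals`).
#' @return (invisibly) list with `status` (0 on success), `outputs` and the
#'   provenance path.
#' @export
run_pipeline <- function(config) {
  cfg <- resolve_config(config)
  out_dir <- cfg$out
  if (is.null(out_dir)) stop("config$out (output directory) is required",
                             call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- switch(cfg$subcommand,
    simulate = pipeline_simulate(cfg, out_dir),
    qpcr = pipeline_qpcr(cfg, out_dir),
    dpcr = pipeline_dpcr(cfg, out_dir),
    classify = pipeline_classify(cfg, out_dir),
    genotype = pipeline_genotype(cfg, out_dir),
    design = pipeline_design(cfg, out_dir),
    report = pipeline_report(cfg, out_dir),
    cohort = pipeline_cohort(cfg, out_dir))
  inputs <- unlist(cfg[c("cq_table", "partitions", "endpoint", "ref_fasta",
                         "clones", "hdr_json")], use.names = FALSE)
  inputs <- as.character(inputs[!is.na(inputs)])
  inputs <- inputs[file.exists(inputs)]
  prov <- write_provenance(cfg, out_dir, as.list(inputs), outputs)
  invisible(list(status = 0L, outputs = outputs, provenance = prov))
}

simulate_cohort_data <- function(cfg) {
  locus <- dropoff_example_locus()
  physics <- assay_physics(cq_sigma = cfg$cq_sigma)
  animals <- sprintf("animal%02d", seq_len(cfg$n_animals))
  pops <- setNames(lapply(seq_along(animals), function(i) {
    simulate_founder(locus = locus, seed = cfg$seed * 1000 + i)
  }), animals)
  clones <- unlist(lapply(seq_along(animals), function(i) {
    s <- simulate_clones(pops[[i]], cfg$clones_per_animal,
                         seed = cfg$seed * 1000 + i,
                         animal_id = animals[i])
    attr(s, "categories") <- NULL
    s
  }))
  calib <- allele_population(data.frame(sequence = locus$reference,
                                        category = "wt", fraction = 1),
                             locus)
  wells <- simulate_qpcr(c(pops, list(calibrator = calib)),
                         physics = physics, seed = cfg$seed)
  chips <- lapply(seq_along(animals), function(i) {
    simulate_dpcr_chip(pops[[i]], n_partitions = cfg$n_partitions,
                       mean_copies = cfg$mean_copies, physics = physics,
                       seed = cfg$seed * 1000 + i)
  })
  names(chips) <- animals
  truth <- data.frame(
    animal_id = animals,
    n_alleles = vapply(pops, function(p) nrow(p$alleles), 1L),
    wt_percent_true = vapply(pops, wt_fraction_true, 1))
  list(locus = locus, pops = pops, clones = clones, wells = wells,
       chips = chips, truth = truth, animals = animals)
}

pipeline_simulate <- function(cfg, out_dir) {
  dat <- simulate_cohort_data(cfg)
  outs <- character(0)
  outs <- c(outs, write_fasta(dat$clones, file.path(out_dir, "clones.fasta")))
  outs <- c(outs, write_cq_table(dat$wells, file.path(out_dir,
                                                      "cq_table.csv")))
  ref_path <- file.path(out_dir, "reference.fasta")
  outs <- c(outs, write_fasta(c(reference = dat$locus$reference), ref_path))
  outs <- c(outs, write_hdr_template(dat$locus$hdr,
                                     file.path(out_dir, "hdr_template.json")))
  for (a in dat$animals) {
    p <- file.path(out_dir, sprintf("partitions_%s.csv", a))
    outs <- c(outs, write_partition_table(dat$chips[[a]], p))
  }
  outs <- c(outs, write_tsv(dat$truth, file.path(out_dir, "truth.tsv")))
  outs
}

pipeline_qpcr <- function(cfg, out_dir) {
  wells <- read_cq_table(cfg$cq_table)
  res <- ddcq_wt_fraction(wells, cfg$calibrator, mode = cfg$mode)
  write_tsv(as.data.frame(res), file.path(out_dir, "qpcr_results.tsv"))
}

pipeline_dpcr <- function(cfg, out_dir) {
  paths <- cfg$partitions
  rows <- lapply(paths, function(p) {
    chip <- read_partition_table(p)
    cls <- classify_partitions(chip, thresholds = cfg$thresholds)
    est <- wt_fraction_dpcr(cls)
    data.frame(chip = sub("^partitions_(.*)\\.csv$", "\\1", basename(p)),
               n_partitions = est$n_partitions,
               double_pos = est$counts[["double_pos"]],
               ref_only = est$counts[["ref_only"]],
               target_only = est$counts[["target_only"]],
               double_neg = est$counts[["double_neg"]],
               lambda_reference = est$lambda_reference,
               lambda_target = est$lambda_target,
               wt_percent = est$wt_percent,
               ci_low = est$ci95[1], ci_high = est$ci95[2],
               flags = paste(est$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), file.path(out_dir, "dpcr_results.tsv"))
}

pipeline_classify <- function(cfg, out_dir) {
  ref <- read_fasta(cfg$ref_fasta)[[1]]
  clones <- read_fasta(cfg$clones)
  hdr <- read_hdr_template(cfg$hdr_json)
  window <- if (!is.null(cfg$window)) as.integer(cfg$window)
            else dropoff_example_locus()$window
  animal_of <- sub("\\.clone\\d+$", "", names(clones))
  records <- lapply(seq_along(clones), function(i) {
    aln <- align_to_reference(clones[[i]], ref)
    classify_allele(aln, hdr, window, clone_id = names(clones)[i])
  })
  var_rows <- do.call(rbind, lapply(records, function(r) {
    v <- rbind(r$variants_window, r$variants_outside)
    if (nrow(v) == 0L) {
      return(data.frame(clone_id = r$clone_id, category = r$category,
                        pos = NA_integer_, ref = "", alt = "", type = "",
                        stringsAsFactors = FALSE))
    }
    data.frame(clone_id = r$clone_id, category = r$category,
               pos = v$pos + 1L, ref = v$ref, alt = v$alt, type = v$type,
               stringsAsFactors = FALSE)
  }))
  outs <- write_tsv(var_rows, file.path(out_dir, "clone_variants.tsv"))
  summaries <- lapply(split(records, animal_of), function(rs) {
    s <- summarize_founder(rs, animal_id = sub("\\.clone\\d+$", "",
                                               rs[[1]]$clone_id))
    data.frame(animal_id = s$animal_id, n_clones = s$n_clones,
               n_distinct_alleles = s$n_distinct_alleles,
               wt_percent = s$wt_percent,
               t(s$category_fractions), stringsAsFactors = FALSE)
  })
  outs <- c(outs, write_tsv(do.call(rbind, summaries),
                            file.path(out_dir, "founder_summary.tsv")))
  outs <- c(outs, write_tsv(hdr_component_venn(records),
                            file.path(out_dir, "venn_counts.tsv")))
  outs
}

pipeline_genotype <- function(cfg, out_dir) {
  samples <- read_endpoint_table(cfg$endpoint)
  calls <- call_genotypes(samples)
  write_tsv(as.data.frame(calls), file.path(out_dir, "genotype_calls.tsv"))
}

pipeline_design <- function(cfg, out_dir) {
  ref <- read_fasta(cfg$ref_fasta)[[1]]
  if (is.null(cfg$cut)) stop("design needs config$cut", call. = FALSE)
  assays <- design_dropoff_assay(ref, as.integer(cfg$cut))
  if (length(assays) == 0L) {
    stop("no assay satisfied the design constraints; failure report: ",
         paste(names(attr(assays, "failure_report")),
               attr(assays, "failure_report"), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  c(write_assay_sheet(assays[[1]], file.path(out_dir, "assay_sheet.tsv")),
    write_assay_json(assays[[1]], file.path(out_dir, "assay.json")))
}

pipeline_report <- function(cfg, out_dir) {
  qp <- utils::read.delim(file.path(out_dir, "qpcr_results.tsv"))
  dp <- utils::read.delim(file.path(out_dir, "dpcr_results.tsv"))
  fs <- utils::read.delim(file.path(out_dir, "founder_summary.tsv"))
  tr_path <- file.path(out_dir, "truth.tsv")
  rep_ <- merge(fs[, c("animal_id", "n_clones", "n_distinct_alleles",
                       "wt_percent")],
                qp[, c("sample_id", "wt_percent")],
                by.x = "animal_id", by.y = "sample_id",
                suffixes = c("_seq", "_qpcr"))
  rep_ <- merge(rep_, setNames(dp[, c("chip", "wt_percent")],
                               c("animal_id", "wt_percent_dpcr")),
                by = "animal_id")
  if (file.exists(tr_path)) {
    rep_ <- merge(rep_, utils::read.delim(tr_path), by = "animal_id")
  }
  rep_ <- rep_[order(rep_$animal_id), ]
  write_tsv(rep_, file.path(out_dir, "cohort_report.tsv"))
}

pipeline_cohort <- function(cfg, out_dir) {
  outs <- pipeline_simulate(cfg, out_dir)
  outs <- c(outs, pipeline_qpcr(
    modifyList(cfg, list(cq_table = file.path(out_dir, "cq_table.csv"))),
    out_dir))
  parts <- file.path(out_dir, sprintf("partitions_animal%02d.csv",
                                      seq_len(cfg$n_animals)))
  outs <- c(outs, pipeline_dpcr(modifyList(cfg, list(partitions = parts)),
                                out_dir))
  outs <- c(outs, pipeline_classify(
    modifyList(cfg, list(ref_fasta = file.path(out_dir, "reference.fasta"),
                         clones = file.path(out_dir, "clones.fasta"),
                         hdr_json = file.path(out_dir, "hdr_template.json"))),
    out_dir))
  c(outs, pipeline_report(cfg, out_dir))
}
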