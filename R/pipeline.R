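#' Validate a pipeline configuration
#'
#' Accepts a nested list or a YAML file path. The schema is checked before
#' any stage runs and unknown keys are rejected, so typos fail fast.
#' Sections: `sim` ([sim_config()] arguments), `quant` ([quant_config()]
#' arguments), `caller` (deletion/SNV thresholds), plus top-level `seed`,
#' `outdir`, `verbosity`.
#'
#' @param config A list or a YAML file path.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) {
    abort("config must be a list or a YAML path", class = "skipscreen_config_error")
  }
  top_keys <- c("seed", "outdir", "verbosity", "sim", "quant", "caller")
  unknown <- setdiff(names(config), top_keys)
  if (length(unknown)) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
          class = "skipscreen_config_error")
  }
  check_section <- function(sec, allowed) {
    bad <- setdiff(names(config[[sec]] %||% list()), allowed)
    if (length(bad)) {
      abort(sprintf("unknown keys in config$%s: %s", sec,
                    paste(bad, collapse = ", ")),
            class = "skipscreen_config_error")
    }
  }
  check_section("sim", setdiff(names(formals(sim_config)), "seed"))
  check_section("quant", names(formals(quant_config)))
  check_section("caller", c("min_split", "min_disc", "min_depth", "tol",
                            "min_gap", "snv_window", "snv_min_alt",
                            "snv_min_frac", "snv_min_depth"))
  seed <- assert_scalar_int(config$seed %||% 1L, "seed")
  out <- list(
    seed = seed,
    outdir = config$outdir %||% "skipscreen_run",
    verbosity = config$verbosity %||% 0L,
    sim = do.call(sim_config, c(list(seed = seed), config$sim %||% list())),
    quant = do.call(quant_config, config$quant %||% list()),
    caller = utils::modifyList(
      list(min_split = 3L, min_disc = 5L, min_depth = 10L, tol = 5L,
           min_gap = 50L, snv_window = 8L, snv_min_alt = 4L,
           snv_min_frac = 0.2, snv_min_depth = 8L),
      config$caller %||% list()))
  structure(out, class = "pipeline_config")
}

log_msg <- function(config, ...) {
  if ((config$verbosity %||% 0L) > 0L) message(sprintf(...))
}

# write JSON atomically (write to temp in the same dir, then rename)
write_json_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the simulation stage: write the cohort to disk
#'
#' @param config A [pipeline_config()].
#' @return The simulation output directory, invisibly.
#' @export
run_simulate <- function(config) {
  config <- as_pipeline_config(config)
  sim <- simulate_cohort(config$sim)
  dir <- file.path(config$outdir, "sim")
  dir.create(file.path(dir, "amplicon"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  log_msg(config, "simulate: seed %d, config hash %s", config$seed,
          rlang::hash(unclass(config)))

  write_fasta(sim$reference$seq, "PLCG2_locus", file.path(dir, "reference.fa"))
  write_gene_model(sim$reference$model, file.path(dir, "gene_model.tsv"))
  write_repeat_bed(sim$repeat_track, file.path(dir, "repeats.bed"))

  origins <- list()
  for (sid in names(sim$amplicon)) {
    write_fastq_pair(sim$amplicon[[sid]]$reads,
                     file.path(dir, "amplicon", sid))
    origins[[sid]] <- sim$amplicon[[sid]]$truth
  }
  for (trio in names(sim$trios)) {
    tdir <- file.path(dir, "trios", trio)
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    for (m in names(sim$trios[[trio]]$members)) {
      write_fastq_pair(sim$trios[[trio]]$members[[m]], file.path(tdir, m))
    }
  }
  write_report_tsv(sim$truth$roster, file.path(dir, "truth", "roster.tsv"))
  write_report_tsv(bind_rows(origins), file.path(dir, "truth", "read_origins.tsv"))
  mx <- purrr::imap(sim$truth$mixtures, function(m, sid) {
    tibble(subject_id = sid, isoform = names(m), fraction = unname(m))
  }) |> bind_rows()
  write_report_tsv(mx, file.path(dir, "truth", "mixtures.tsv"))
  sites <- sim$trios$proband2$truth$informative_sites
  if (!is.null(sites)) {
    write_report_tsv(sites, file.path(dir, "truth", "informative_sites.tsv"))
  }
  write_json_atomic(
    list(seed = config$seed,
         deletion = sim$lesions$deletion, snv = sim$lesions$snv),
    file.path(dir, "truth", "lesions.json"))
  invisible(dir)
}

#' Run the cDNA screen stage: align, quantify and flag candidates
#'
#' @param config A [pipeline_config()].
#' @return A [flag_candidates()] `cohort_screen`, invisibly.
#' @export
run_rnaseq <- function(config) {
  config <- as_pipeline_config(config)
  dir <- file.path(config$outdir, "sim")
  if (!dir.exists(dir)) abort("run_simulate output not found; run it first",
                              class = "skipscreen_stage_error")
  model <- read_gene_model(file.path(dir, "gene_model.tsv"))
  gseq <- unname(read_fasta(file.path(dir, "reference.fa"))[1])
  cdna <- make_isoform(model, gseq, NULL)
  idx <- index_reference(cdna, align_params()$k)
  roster <- read_report_tsv(file.path(dir, "truth", "roster.tsv"))

  quants <- purrr::map(roster$subject_id, function(sid) {
    reads <- read_fastq_pair(
      file.path(dir, "amplicon", sprintf("%s_R%d.fastq", sid, 1:2)))
    aln <- align_reads(reads, idx, model, mode = "cdna")
    quantify_subject(aln, model, config$quant, subject_id = sid)
  }) |> bind_rows()
  screen <- flag_candidates(quants, roster[, c("subject_id", "role")],
                            model, config$quant)

  odir <- file.path(config$outdir, "rnaseq")
  dir.create(odir, recursive = TRUE, showWarnings = FALSE)
  write_report_tsv(
    screen$quants |> mutate(bin = as.character(.data$bin)),
    file.path(odir, "quant.tsv"))
  write_report_tsv(
    screen$candidates |>
      select("subject_id", "role", "label", "fraction", "frame") |>
      arrange(.data$subject_id, .data$label),
    file.path(odir, "candidates.tsv"))
  write_json_atomic(
    list(seed = config$seed,
         candidates = purrr::pmap(
           screen$candidates[, c("subject_id", "label", "fraction")],
           function(subject_id, label, fraction) {
             list(subject_id = subject_id, label = label, fraction = fraction)
           })),
    file.path(odir, "report.json"))
  invisible(screen)
}

#' Run the trio genomic stage: deletion call, SNV screen, VCF and report
#'
#' @param config A [pipeline_config()].
#' @param trios Trio directory names under `sim/trios` to process.
#' @return Named list per trio with `deletion`, `snv`, `origin`, invisibly.
#' @export
run_wgs <- function(config, trios = NULL) {
  config <- as_pipeline_config(config)
  dir <- file.path(config$outdir, "sim")
  model <- read_gene_model(file.path(dir, "gene_model.tsv"))
  gseq <- unname(read_fasta(file.path(dir, "reference.fa"))[1])
  idx <- index_reference(gseq, align_params()$k)
  trios <- trios %||% list.dirs(file.path(dir, "trios"), recursive = FALSE,
                                full.names = FALSE)
  odir <- file.path(config$outdir, "wgs")
  dir.create(odir, recursive = TRUE, showWarnings = FALSE)
  cal <- config$caller
  sites_path <- file.path(dir, "truth", "informative_sites.tsv")
  sites <- if (file.exists(sites_path)) read_report_tsv(sites_path) else NULL

  out <- purrr::map(setNames(trios, trios), function(trio) {
    tdir <- file.path(dir, "trios", trio)
    aln <- purrr::map(setNames(c("child", "mother", "father"),
                               c("child", "mother", "father")),
                      function(m) {
      reads <- read_fastq_pair(file.path(tdir, sprintf("%s_R%d.fastq", m, 1:2)))
      align_reads(reads, idx, model, mode = "genomic", keep_seq = TRUE)
    })
    del <- call_deletion(aln, model,
                         insert_mean = config$sim$insert_mean,
                         insert_sd = config$sim$insert_sd,
                         min_split = cal$min_split, min_disc = cal$min_disc,
                         min_depth = cal$min_depth, tol = cal$tol,
                         min_gap = cal$min_gap)
    snv <- splice_region_snv_screen(aln, gseq, model,
                                    window = cal$snv_window,
                                    min_alt = cal$snv_min_alt,
                                    min_frac = cal$snv_min_frac,
                                    min_depth = cal$snv_min_depth)
    origin <- if (!is.null(del) && isTRUE(del$de_novo) && !is.null(sites)) {
      parent_of_origin(del, aln$child, sites, tol = cal$tol)
    } else NULL
    write_trio_vcf(file.path(odir, paste0(trio, ".vcf")), gseq, model$chrom,
                   deletion = del, snv_calls = snv$calls)
    if (!is.null(del)) {
      write_json_atomic(
        list(trio = trio, chrom = del$chrom, start = del$start, end = del$end,
             length = del$length, de_novo = del$de_novo,
             inheritance = del$inheritance,
             affected_exons = del$affected_exons,
             origin = origin$origin %||% NA),
        file.path(odir, paste0(trio, "_deletion.json")))
      write_report_tsv(del$members, file.path(odir, paste0(trio, "_trio.tsv")))
    }
    list(deletion = del, snv = snv, origin = origin)
  })
  invisible(out)
}

#' Run the mechanism stage: repeat intersection at deletion breakpoints
#'
#' @param config A [pipeline_config()].
#' @param pad Breakpoint padding (nt).
#' @return Named list of [classify_mechanism()] calls per trio with a
#'   deletion, invisibly.
#' @export
run_mechanism <- function(config, pad = 10L) {
  config <- as_pipeline_config(config)
  track <- read_repeat_bed(file.path(config$outdir, "sim", "repeats.bed"))
  odir <- file.path(config$outdir, "mechanism")
  dir.create(odir, recursive = TRUE, showWarnings = FALSE)
  del_files <- list.files(file.path(config$outdir, "wgs"),
                          pattern = "_deletion\\.json$", full.names = TRUE)
  out <- purrr::map(setNames(del_files, sub("_deletion\\.json$", "",
                                            basename(del_files))),
                    function(f) {
    del <- jsonlite::read_json(f, simplifyVector = TRUE)
    mech <- classify_mechanism(
      breakpoint_repeat_intersect(del, track, pad = pad))
    write_json_atomic(
      list(trio = del$trio, classification = mech$classification,
           left_elements = nrow(mech$left), right_elements = nrow(mech$right)),
      file.path(odir, paste0(del$trio, "_mechanism.json")))
    mech
  })
  invisible(out)
}

#' Run the whole pipeline and write a linked cohort report
#'
#' Stage order follows the screen's workflow: simulate (or reuse) the cohort,
#' quantify skip transcripts and flag candidates, sequence the flagged
#' probands' trios for the underlying lesion, and classify the deletion
#' mechanism. The JSON report links each candidate subject to its lesion and
#' mechanism. Re-running with the same seed reproduces the report
#' byte-identically.
#'
#' @param config A [pipeline_config()] (or list/YAML path).
#' @return List with `screen`, `wgs`, `mechanism` and the report path,
#'   invisibly.
#' @export
run_all <- function(config) {
  config <- as_pipeline_config(config)
  run_simulate(config)
  screen <- run_rnaseq(config)
  wgs <- run_wgs(config)
  mech <- run_mechanism(config)

  lesion_of <- function(sid) {
    if (sid %in% names(wgs)) {
      w <- wgs[[sid]]
      if (!is.null(w$deletion)) {
        return(list(type = "genomic_deletion", label = w$deletion$label,
                    de_novo = w$deletion$de_novo,
                    inheritance = w$deletion$inheritance,
                    origin = w$origin$origin %||% NA,
                    mechanism = mech[[sid]]$classification %||% NA))
      }
      if (nrow(w$snv$calls) > 0) {
        return(list(type = "splice_snv", label = w$snv$calls$label[1],
                    inheritance = w$snv$calls$inheritance[1]))
      }
    }
    list(type = "none")
  }
  cand_subjects <- sort(unique(screen$candidates$subject_id))
  report <- list(
    seed = config$seed,
    n_subjects = nrow(screen$roster),
    candidates = lapply(cand_subjects, function(sid) {
      rows <- screen$candidates[screen$candidates$subject_id == sid, ]
      list(subject_id = sid,
           role = rows$role[1],
           transcripts = purrr::pmap(rows[, c("label", "fraction", "frame")],
                                     function(label, fraction, frame) {
                                       list(label = label, fraction = fraction,
                                            frame = frame)
                                     }),
           lesion = lesion_of(sid))
    }))
  path <- file.path(config$outdir, "report.json")
  write_json_atomic(report, path)
  invisible(list(screen = screen, wgs = wgs, mechanism = mech,
                 report = path))
}

as_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) config else pipeline_config(config)
}
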