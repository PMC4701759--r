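# Stage orchestration: compose simulate / match / score / classify /
# compare into a reproducible run writing plain TSV outputs. A thin
# command-line wrapper over these functions ships in
# inst/scripts/wophage.R.

#' Pipeline configuration
#'
#' Collects input paths, thresholds and model options for [run_pipeline].
#' The configuration is echoed (as YAML-like key: value text) into the
#' output directory of every run for provenance.
#'
#' @param db_fasta Path to the protein database FASTA.
#' @param evidence_tsv Path to the peptide-evidence TSV.
#' @param annotation_tsv Optional annotation TSV (locus_tag, class, ...).
#' @param region_tsv Optional region-definition TSV; packaged WO regions
#'   used when `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param confidence Peptide confidence threshold (fixed at 0.95 by the
#'   counting rules; recorded for provenance).
#' @param stringent_min Per-cell unique-peptide threshold of the stringent
#'   filter.
#' @param model `"multi"` or `"uni"` abundance model.
#' @param sim Optional [sim_config] for the `simulate` stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(db_fasta = NULL, evidence_tsv = NULL,
                            annotation_tsv = NULL, region_tsv = NULL,
                            out_dir = ".", confidence = 0.95,
                            stringent_min = 2,
                            model = c("multi", "uni"), sim = NULL) {
  model <- match.arg(model)
  cfg <- list(db_fasta = db_fasta, evidence_tsv = evidence_tsv,
              annotation_tsv = annotation_tsv, region_tsv = region_tsv,
              out_dir = out_dir, confidence = confidence,
              stringent_min = stringent_min, model = model, sim = sim)
  class(cfg) <- "pipeline_config"
  cfg
}

.echo_config <- function(config, path) {
  flat <- config[!vapply(config, is.null, logical(1))]
  flat$sim <- if (!is.null(config$sim)) "sim_config" else NULL
  lines <- vapply(names(flat), function(k)
    sprintf("%s: %s", k, paste(format(flat[[k]]), collapse = " ")),
    character(1))
  writeLines(lines, path)
}

.check_inputs <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing))
    stop("input file(s) not found: ",
         paste(unlist(missing), collapse = ", "), call. = FALSE)
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` writes a synthetic database, evidence and truth table;
#' `match` builds the detection matrix and filter sets; `score` fits the
#' abundance model and writes the RAL/SR report; `classify` assigns prophage
#' regions and writes the tally; `pipeline` = match, score, classify.
#' All outputs are TSV; identical configuration and inputs give identical
#' output bytes (stochastic stages are fixed by the simulation seed).
#'
#' @param stage One of `"simulate"`, `"match"`, `"score"`, `"classify"`,
#'   `"pipeline"`.
#' @param config A [pipeline_config].
#' @return Invisibly, a named list of the objects computed by the stage(s).
#' @export
run_pipeline <- function(stage = c("pipeline", "simulate", "match", "score",
                                   "classify"),
                         config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  if (stage != "simulate")
    .check_inputs(list(config$db_fasta, config$evidence_tsv,
                       config$annotation_tsv, config$region_tsv))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  .echo_config(config, file.path(config$out_dir, "config_echo.txt"))
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- c(sprintf("wophage %s",
                         as.character(utils::packageVersion("wophage"))),
                 sprintf("stage: %s", stage))
  log_it <- function(...) log_lines <<- c(log_lines, sprintf(...))
  out <- list()

  if (stage == "simulate") {
    if (is.null(config$sim))
      stop("simulate stage needs a sim_config", call. = FALSE)
    proteome <- generate_proteome(config$sim)
    evidence <- simulate_detection(proteome, config$sim)
    write_fasta(proteome$db, file.path(config$out_dir, "proteome.fasta"))
    write_evidence(evidence, file.path(config$out_dir, "evidence.tsv"))
    write_truth_table(proteome$truth,
                      file.path(config$out_dir, "truth.tsv"))
    utils::write.table(proteome$groups,
                       file.path(config$out_dir, "groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_it("seed: %d", config$sim$seed)
    log_it("proteins: %d (db entries %d)", nrow(proteome$truth),
           nrow(proteome$db))
    log_it("evidence rows: %d", nrow(evidence))
    out <- list(proteome = proteome, evidence = evidence)
    writeLines(log_lines, log_path)
    return(invisible(out))
  }

  db <- read_fasta(config$db_fasta)
  evidence <- read_evidence(config$evidence_tsv)
  log_it("db proteins: %d", nrow(db))
  log_it("evidence rows: %d (counted %d)", nrow(evidence),
         sum(evidence$counted))
  matrix <- map_peptides(evidence, db)
  out$matrix <- matrix

  if (stage %in% c("match", "pipeline")) {
    write_detection_matrix(matrix,
                           file.path(config$out_dir,
                                     "detection_matrix.tsv"))
    stringent <- apply_detection_filter(matrix, "stringent",
                                        config$stringent_min)
    relaxed <- apply_detection_filter(matrix, "relaxed")
    writeLines(stringent, file.path(config$out_dir, "stringent_set.txt"))
    writeLines(relaxed, file.path(config$out_dir, "relaxed_set.txt"))
    log_it("stringent: %d, relaxed: %d", length(stringent),
           length(relaxed))
    out$stringent <- stringent
    out$relaxed <- relaxed
  }
  if (stage %in% c("score", "pipeline")) {
    report <- abundance_report(matrix, model = config$model)
    write_abundance_report(report,
                           file.path(config$out_dir,
                                     "abundance_report.tsv"))
    fit <- attr(report, "fit")
    coefs <- data.frame(term = names(fit$coefficients),
                        estimate = fit$coefficients,
                        stringsAsFactors = FALSE)
    utils::write.table(coefs,
                       file.path(config$out_dir, "model_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_it("model: %svariable, %d observations", config$model,
           length(fit$residuals))
    out$report <- report
  }
  if (stage %in% c("classify", "pipeline")) {
    detected <- matrix$proteins[matrix$total_unique > 0]
    # one tally entry per homolog group, under its representative (the
    # first member in database order)
    grp <- ifelse(nzchar(db$homolog_group), db$homolog_group, db$locus_tag)
    names(grp) <- db$locus_tag
    det_groups <- unique(grp[detected])
    detected <- vapply(det_groups, function(g)
      db$locus_tag[grp == g][1], character(1), USE.NAMES = FALSE)
    ann <- if (!is.null(config$annotation_tsv)) {
      read_annotation(config$annotation_tsv)
    } else {
      data.frame(locus_tag = db$locus_tag,
                 class = db$functional_class, stringsAsFactors = FALSE)
    }
    defs <- if (!is.null(config$region_tsv))
      read_region_defs(config$region_tsv) else wo_region_defs()
    idx <- match(detected, ann$locus_tag)
    if (anyNA(idx))
      stop("annotation missing for: ",
           paste(detected[is.na(idx)], collapse = ", "), call. = FALSE)
    classified <- data.frame(locus_tag = detected,
                             region = assign_region(detected, defs),
                             class = ann$class[idx],
                             stringsAsFactors = FALSE)
    tally <- region_tally(classified, region_order = defs$region)
    write_region_tally(tally, file.path(config$out_dir, "tally.tsv"))
    log_it("classified proteins: %d", tally$grand_total)
    out$tally <- tally
  }
  writeLines(log_lines, log_path)
  invisible(out)
}
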