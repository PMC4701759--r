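# Synthetic proteome and MS-detection generator. Emulates the statistical
# structure the abundance analysis assumes: K data sets, per-protein
# unique-peptide counts that increase with true abundance and with protein
# mass, a 95%-confidence flag on peptide evidence, and homolog groups
# spanning several genome variants. Ground truth is returned alongside so
# recovery can be scored.

# amino-acid background frequencies (approximate bacterial proteome
# composition) used for random sequence generation
AA_BACKGROUND <- c(
  A = 0.083, R = 0.057, N = 0.044, D = 0.053, C = 0.014, Q = 0.040,
  E = 0.062, G = 0.072, H = 0.022, I = 0.066, L = 0.102, K = 0.058,
  M = 0.025, F = 0.042, P = 0.045, S = 0.060, T = 0.054, W = 0.013,
  Y = 0.033, V = 0.069
)

#' Simulation configuration
#'
#' Defaults describe the study conditions the analysis targets: four MS data
#' sets, protein lengths log-normal with median 300 aa (sigma 0.4 on the
#' natural-log scale), true abundance log10 A ~ Normal(0, 0.6), and a
#' detection model in which the expected unique-peptide count of protein i
#' in data set d is `lambda = alpha * A_i * (L_i / Lbar)^gamma * effect_d`
#' with `alpha = 4` and `gamma = 0.7`. Class probabilities default to the
#' observed class composition of the detected prophage proteome.
#'
#' @param n_proteins Number of base proteins.
#' @param dataset_ids Data-set labels (default the four sets D, E, F, G).
#' @param length_median,length_sdlog Log-normal length distribution (aa).
#' @param class_probs Named probabilities over the eight prophage classes.
#' @param log10_abundance_mean,log10_abundance_sd True-abundance model.
#' @param alpha Detection rate scale (expected peptides per data set for an
#'   average protein).
#' @param gamma Mass exponent of the detection rate.
#' @param dataset_effects Multiplicative per-data-set factors (recycled).
#' @param low_conf_fraction Fraction of evidence rows assigned confidence
#'   0.5 (below the 0.95 counting threshold); the rest get 0.99.
#' @param homolog_fraction Fraction of proteins duplicated into 2-3 genome
#'   variants.
#' @param substitution_rate Per-site substitution rate of homolog variants.
#' @param digest_min_len,digest_max_missed Theoretical digest defining the
#'   samplable peptide set.
#' @param seed Base seed; each generation stage derives its own stream from
#'   (seed, stage name).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_proteins = 500,
                       dataset_ids = c("D", "E", "F", "G"),
                       length_median = 300, length_sdlog = 0.4,
                       class_probs = NULL,
                       log10_abundance_mean = 0, log10_abundance_sd = 0.6,
                       alpha = 4, gamma = 0.7,
                       dataset_effects = 1,
                       low_conf_fraction = 0.05,
                       homolog_fraction = 0.2,
                       substitution_rate = 0.05,
                       digest_min_len = 6, digest_max_missed = 1,
                       seed = 1) {
  if (is.null(class_probs)) {
    counts <- c(HEAD = 20, BP = 9, TAIL = 10, REC = 7, REP = 5, MOD = 7,
                VIR = 19, UK = 41)
    class_probs <- counts / sum(counts)
  }
  cfg <- list(n_proteins = n_proteins, dataset_ids = dataset_ids,
              length_median = length_median, length_sdlog = length_sdlog,
              class_probs = class_probs,
              log10_abundance_mean = log10_abundance_mean,
              log10_abundance_sd = log10_abundance_sd,
              alpha = alpha, gamma = gamma,
              dataset_effects = rep_len(dataset_effects,
                                        length(dataset_ids)),
              low_conf_fraction = low_conf_fraction,
              homolog_fraction = homolog_fraction,
              substitution_rate = substitution_rate,
              digest_min_len = digest_min_len,
              digest_max_missed = digest_max_missed,
              seed = seed)
  problems <- character(0)
  if (cfg$n_proteins < 0) problems <- c(problems, "n_proteins")
  if (length(cfg$dataset_ids) < 1 || anyDuplicated(cfg$dataset_ids))
    problems <- c(problems, "dataset_ids")
  if (cfg$length_median <= 0 || cfg$length_sdlog <= 0)
    problems <- c(problems, "length_median/length_sdlog")
  if (abs(sum(cfg$class_probs) - 1) > 1e-8 || any(cfg$class_probs < 0))
    problems <- c(problems, "class_probs")
  if (cfg$alpha <= 0 || cfg$gamma < 0) problems <- c(problems, "alpha/gamma")
  if (any(cfg$dataset_effects <= 0)) problems <- c(problems, "dataset_effects")
  if (cfg$low_conf_fraction < 0 || cfg$low_conf_fraction > 1)
    problems <- c(problems, "low_conf_fraction")
  if (cfg$homolog_fraction < 0 || cfg$homolog_fraction > 1)
    problems <- c(problems, "homolog_fraction")
  if (cfg$substitution_rate < 0 || cfg$substitution_rate > 1)
    problems <- c(problems, "substitution_rate")
  if (length(problems))
    stop("invalid simulation config: ", paste(problems, collapse = ", "),
         call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# derive a 32-bit stage seed from (base seed, stage name)
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729)) %% .Machine$integer.max
}

# random protein sequence with at least ceiling(L/15) K/R sites
.random_sequence <- function(L) {
  res <- sample(names(AA_BACKGROUND), L, replace = TRUE,
                prob = AA_BACKGROUND)
  need <- ceiling(L / 15)
  kr <- which(res %in% c("K", "R"))
  if (length(kr) < need) {
    cand <- setdiff(seq_len(L), kr)
    add <- sample(cand, need - length(kr))
    res[add] <- sample(c("K", "R"), length(add), replace = TRUE)
  }
  paste(res, collapse = "")
}

# mutate a sequence at the given per-site rate, preserving length
.mutate_sequence <- function(sequence, rate) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(res)) < rate)
  for (i in hit) {
    res[i] <- sample(setdiff(names(AA_BACKGROUND), res[i]), 1)
  }
  paste(res, collapse = "")
}

#' Generate a synthetic proteome
#'
#' Draws protein lengths, classes and true abundances from the configured
#' distributions, builds random sequences guaranteed to yield tryptic
#' peptides, and duplicates a configured fraction of proteins into 2-3
#' genome variants by point substitution (emulating homolog databases from
#' several sequenced genomes). The same (config, seed) always reproduces the
#' same output.
#'
#' @param config A [sim_config].
#' @return List with `db` (a [protein_db]: base proteins from genome
#'   "wSyn0" plus variants from "wSyn1"/"wSyn2"), `groups` (homolog-group
#'   table usable by [aggregate_by_group]), and `truth` (per base protein:
#'   `locus_tag`, `length`, `class`, `log10_abundance`, `group`, and
#'   expected counts `lambda.<dataset>` per data set).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_proteins
  if (n == 0L) {
    empty_db <- protein_db(character(0), character(0))
    return(list(db = empty_db,
                groups = data.frame(group_id = character(0),
                                    locus_tag = character(0),
                                    representative = logical(0)),
                truth = data.frame()))
  }
  set.seed(stage_seed(config$seed, "generate_proteome"))
  L <- pmax(20L, as.integer(round(stats::rlnorm(n, log(config$length_median),
                                                config$length_sdlog))))
  cls <- sample(names(config$class_probs), n, replace = TRUE,
                prob = config$class_probs)
  logA <- stats::rnorm(n, config$log10_abundance_mean,
                       config$log10_abundance_sd)
  locus <- sprintf("SYN%04d", seq_len(n))
  seqs <- vapply(L, .random_sequence, character(1))
  lbar <- mean(L)
  lambda <- outer(10^logA * config$alpha * (L / lbar)^config$gamma,
                  config$dataset_effects)
  colnames(lambda) <- config$dataset_ids

  # homolog variants
  n_dup <- round(config$homolog_fraction * n)
  dup_idx <- if (n_dup > 0) sort(sample(n, n_dup)) else integer(0)
  group <- stats::setNames(rep("", n), locus)
  var_locus <- character(0); var_seq <- character(0)
  var_genome <- character(0); var_group <- character(0)
  var_class <- character(0)
  for (i in dup_idx) {
    g <- sprintf("grp_%s", locus[i])
    group[i] <- g
    n_var <- sample(1:2, 1)  # 2-3 genome variants including the base
    for (v in seq_len(n_var)) {
      var_locus <- c(var_locus, sprintf("%sV%d", locus[i], v))
      var_seq <- c(var_seq, .mutate_sequence(seqs[i],
                                             config$substitution_rate))
      var_genome <- c(var_genome, sprintf("wSyn%d", v))
      var_group <- c(var_group, g)
      var_class <- c(var_class, cls[i])
    }
  }
  db <- protein_db(
    locus_tag = c(locus, var_locus),
    sequence = c(seqs, var_seq),
    genome = c(rep("wSyn0", n), var_genome),
    homolog_group = c(group, var_group),
    functional_class = c(cls, var_class)
  )
  groups <- data.frame(
    group_id = ifelse(nzchar(db$homolog_group), db$homolog_group,
                      db$locus_tag),
    locus_tag = db$locus_tag,
    representative = db$genome == "wSyn0",
    stringsAsFactors = FALSE
  )
  truth <- data.frame(locus_tag = locus, length = L, class = cls,
                      log10_abundance = logA,
                      group = groups$group_id[seq_len(n)],
                      stringsAsFactors = FALSE)
  lam_df <- as.data.frame(lambda)
  names(lam_df) <- paste0("lambda.", config$dataset_ids)
  truth <- cbind(truth, lam_df)
  list(db = db, groups = groups, truth = truth)
}

#' Simulate MS peptide detection
#'
#' For each (base protein, data set) draws a unique-peptide count from a
#' Poisson with the truth-table rate, truncated at the size of the protein's
#' theoretical tryptic peptide set, and samples that many distinct peptides
#' uniformly without replacement from the digest. Evidence confidence is
#' 0.99 except for the configured low-confidence fraction at 0.5.
#'
#' @param proteome Output of [generate_proteome].
#' @param config The same [sim_config].
#' @return An [evidence_table]. Proteins whose digest is empty produce no
#'   evidence (with a warning).
#' @export
simulate_detection <- function(proteome, config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- proteome$truth
  if (!nrow(truth))
    return(evidence_table(character(0), character(0),
                          dataset_ids = config$dataset_ids))
  set.seed(stage_seed(config$seed, "simulate_detection"))
  db <- proteome$db
  base_idx <- match(truth$locus_tag, db$locus_tag)
  digests <- lapply(db$sequence[base_idx], function(s)
    unique(tryptic_digest(s, min_len = config$digest_min_len,
                          max_missed = config$digest_max_missed)$peptide))
  empty <- lengths(digests) == 0L
  if (any(empty))
    warning(sum(empty), " protein(s) with empty digest: zero detections")
  pep <- character(0); ds <- character(0); src <- character(0)
  for (i in seq_len(nrow(truth))) {
    npep <- length(digests[[i]])
    if (npep == 0L) next
    for (d in seq_along(config$dataset_ids)) {
      lam <- truth[[paste0("lambda.", config$dataset_ids[d])]][i]
      k <- min(stats::rpois(1, lam), npep)
      if (k == 0L) next
      chosen <- sample(digests[[i]], k)
      pep <- c(pep, chosen)
      ds <- c(ds, rep(config$dataset_ids[d], k))
      src <- c(src, rep(truth$locus_tag[i], k))
    }
  }
  if (!length(pep))
    return(evidence_table(character(0), character(0),
                          dataset_ids = config$dataset_ids))
  conf <- rep(0.99, length(pep))
  n_low <- round(config$low_conf_fraction * length(pep))
  if (n_low > 0) conf[sample(length(pep), n_low)] <- 0.5
  evidence_table(pep, ds, proteins = src, confidence = conf,
                 dataset_ids = config$dataset_ids)
}

#' Write a truth table as TSV
#'
#' @param truth The `truth` element of [generate_proteome] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
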