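# Protein database and peptide-evidence I/O, and protein mass computation.
# Every downstream stage consumes the types defined here: a protein database
# is a data.frame with one row per protein, an evidence table is a data.frame
# with one row per (peptide, data set) observation.

#' Average amino-acid residue masses
#'
#' Average (not monoisotopic) residue masses in daltons for the 20 standard
#' amino acids. `X` (unknown residue) is assigned the mean of the 20.
#'
#' @format Named numeric vector of length 20.
#' @keywords internal
AA_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

WATER_MASS <- 18.0153

#' Functional classes of WO prophage proteins
#'
#' The eight prophage functional classes (phage head, baseplate, tail,
#' recombination, replication, DNA modification, virulence/host interaction,
#' unknown) plus `NONPHAGE` for chromosomal proteins outside prophage regions.
#'
#' @export
FUNCTIONAL_CLASSES <- c("HEAD", "BP", "TAIL", "REC", "REP", "MOD", "VIR",
                        "UK", "NONPHAGE")

# default threshold below which peptide evidence is excluded from counting
CONFIDENCE_THRESHOLD <- 0.95

#' Compute protein mass in kilodaltons
#'
#' Sums average residue masses over the sequence, adds one water, and divides
#' by 1000. `X` is treated as the mean residue mass. Reporting contexts round
#' to the nearest integer kDa (half-up), as in published abundance tables.
#'
#' @param sequence Character vector of amino-acid sequences (20-letter
#'   alphabet plus `X`).
#' @return Numeric vector of masses in kilodaltons.
#' @examples
#' compute_mass_kda("GG")
#' compute_mass_kda(strrep("G", 50))
#' @export
compute_mass_kda <- function(sequence) {
  if (length(sequence) == 0L) return(numeric(0))
  masses <- c(AA_RESIDUE_MASS, X = mean(AA_RESIDUE_MASS))
  vapply(sequence, function(s) {
    if (is.na(s) || !nzchar(s))
      stop("empty sequence: mass is undefined", call. = FALSE)
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    m <- masses[res]
    if (anyNA(m)) {
      bad <- which(is.na(m))[1]
      stop(sprintf("illegal residue '%s' at position %d", res[bad], bad),
           call. = FALSE)
    }
    (sum(m) + WATER_MASS) / 1000
  }, numeric(1), USE.NAMES = FALSE)
}

#' Round half away from zero
#'
#' Rounding used for all reported integers (kDa, coverage, percentages),
#' matching the convention of the printed tables rather than R's banker's
#' rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Construct a protein database
#'
#' A protein database is a `data.frame` (class `protein_db`) with columns
#' `locus_tag`, `sequence`, `genome`, `homolog_group`, `functional_class`,
#' and `mass_kda`. Mass is recomputed from the sequence when not supplied and
#' validated (within 1%) when it is.
#'
#' @param locus_tag Character vector of unique locus tags (e.g. "WD0612").
#' @param sequence Amino-acid sequences, same length as `locus_tag`.
#' @param genome Source genome/strain label (recycled).
#' @param homolog_group Homolog group id, `""` for ungrouped (recycled).
#' @param functional_class One of [FUNCTIONAL_CLASSES] (recycled).
#' @param mass_kda Optional masses in kDa; computed from `sequence` if `NULL`.
#' @return A `protein_db` data.frame.
#' @export
protein_db <- function(locus_tag, sequence, genome = "unknown",
                       homolog_group = "", functional_class = "UK",
                       mass_kda = NULL) {
  n <- length(locus_tag)
  stopifnot(length(sequence) == n)
  if (n > 0 && anyDuplicated(locus_tag))
    stop("duplicated locus_tag in protein database", call. = FALSE)
  if (any(!nzchar(sequence)))
    stop("protein sequences must be non-empty", call. = FALSE)
  functional_class <- rep_len(as.character(functional_class), n)
  bad <- setdiff(unique(functional_class), FUNCTIONAL_CLASSES)
  if (length(bad))
    stop("unknown functional class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  computed <- if (n) compute_mass_kda(sequence) else numeric(0)
  if (is.null(mass_kda)) {
    mass_kda <- computed
  } else {
    mass_kda <- rep_len(as.numeric(mass_kda), n)
    if (any(mass_kda <= 0)) stop("mass_kda must be positive", call. = FALSE)
    off <- abs(mass_kda - computed) / computed > 0.01
    if (any(off))
      stop("mass_kda inconsistent with sequence for: ",
           paste(locus_tag[off], collapse = ", "), call. = FALSE)
  }
  db <- data.frame(
    locus_tag = as.character(locus_tag),
    sequence = as.character(sequence),
    genome = rep_len(as.character(genome), n),
    homolog_group = rep_len(as.character(homolog_group), n),
    functional_class = functional_class,
    mass_kda = mass_kda,
    stringsAsFactors = FALSE
  )
  class(db) <- c("protein_db", "data.frame")
  db
}

#' Read a protein database from FASTA
#'
#' Headers are parsed as `>LOCUS key=value ...` where the optional keys are
#' `genome=`, `class=`, and `group=`. Mass is computed from the sequence.
#'
#' @param path Path to a protein FASTA file.
#' @return A [protein_db] data.frame, entries in file order; an empty file
#'   yields a zero-row database.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L)
    return(protein_db(character(0), character(0)))
  headers <- names(seqs)
  genome <- rep("unknown", length(seqs))
  grp <- rep("", length(seqs))
  cls <- rep("UK", length(seqs))
  locus <- character(length(seqs))
  for (i in seq_along(headers)) {
    toks <- strsplit(trimws(headers[i]), "\\s+")[[1]]
    if (length(toks) == 0L || !nzchar(toks[1]))
      stop(sprintf("malformed FASTA header at entry %d: '%s'", i, headers[i]),
           call. = FALSE)
    locus[i] <- toks[1]
    for (kv in toks[-1]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop(sprintf("malformed key=value token '%s' in header %d ('%s')",
                     kv, i, headers[i]), call. = FALSE)
      switch(parts[1],
             genome = genome[i] <- parts[2],
             class = cls[i] <- parts[2],
             group = grp[i] <- parts[2],
             stop(sprintf("unknown header key '%s' in header %d ('%s')",
                          parts[1], i, headers[i]), call. = FALSE))
    }
  }
  protein_db(locus, as.character(seqs), genome = genome, homolog_group = grp,
             functional_class = cls)
}

#' Write a protein database to FASTA
#'
#' Inverse of [read_fasta]: headers carry `genome=`, `class=` and `group=`
#' tokens (group omitted when empty) so that a write/read round trip
#' reproduces the database.
#'
#' @param db A [protein_db].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  headers <- vapply(seq_len(nrow(db)), function(i) {
    h <- sprintf("%s genome=%s class=%s", db$locus_tag[i], db$genome[i],
                 db$functional_class[i])
    if (nzchar(db$homolog_group[i]))
      h <- sprintf("%s group=%s", h, db$homolog_group[i])
    h
  }, character(1))
  x <- Biostrings::AAStringSet(db$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Construct a peptide-evidence table
#'
#' One row per observed (peptide, data set) pair, as exported from a
#' search/validation engine. Rows with `confidence` below the 0.95 threshold
#' are retained but flagged `counted = FALSE` and ignored by all counting
#' operations.
#'
#' @param peptide Character vector of peptide sequences.
#' @param dataset_id Data-set label per row (e.g. "D", "E", "F", "G").
#' @param proteins Character vector of semicolon-joined locus tags the search
#'   engine assigned (may be revised by matching), or a list of character
#'   vectors.
#' @param confidence Numeric in \[0, 1\].
#' @param dataset_ids Ordered vector of the K data-set labels; defaults to
#'   the labels present, in order of first appearance. Rows with labels
#'   outside this set are an error.
#' @return An `evidence_table` data.frame with attribute `dataset_ids`.
#' @export
evidence_table <- function(peptide, dataset_id, proteins = "",
                           confidence = 1, dataset_ids = NULL) {
  n <- length(peptide)
  if (n > 0 && any(!nzchar(peptide)))
    stop("peptides must be non-empty strings", call. = FALSE)
  if (is.list(proteins))
    proteins <- vapply(proteins, paste, character(1), collapse = ";")
  tab <- data.frame(
    peptide = as.character(peptide),
    dataset_id = rep_len(as.character(dataset_id), n),
    proteins = rep_len(as.character(proteins), n),
    confidence = rep_len(as.numeric(confidence), n),
    stringsAsFactors = FALSE
  )
  if (any(tab$confidence < 0 | tab$confidence > 1))
    stop("confidence must lie in [0, 1]", call. = FALSE)
  if (is.null(dataset_ids)) dataset_ids <- unique(tab$dataset_id)
  if (anyDuplicated(dataset_ids))
    stop("dataset_ids must be unique", call. = FALSE)
  unknown <- setdiff(unique(tab$dataset_id), dataset_ids)
  if (length(unknown))
    stop("unknown dataset label: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  tab$counted <- tab$confidence >= CONFIDENCE_THRESHOLD
  attr(tab, "dataset_ids") <- as.character(dataset_ids)
  class(tab) <- c("evidence_table", "data.frame")
  tab
}

#' Read a peptide-evidence table from TSV
#'
#' Expects columns `peptide`, `dataset`, `proteins` (semicolon-joined locus
#' tags, possibly empty) and `confidence`.
#'
#' @param path Path to a TSV file with a header row.
#' @param dataset_ids Optional ordered data-set labels (see [evidence_table]).
#' @return An `evidence_table`.
#' @export
read_evidence <- function(path, dataset_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  required <- c("peptide", "dataset", "proteins", "confidence")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  evidence_table(raw$peptide, raw$dataset, raw$proteins,
                 as.numeric(raw$confidence), dataset_ids = dataset_ids)
}

#' Write a peptide-evidence table to TSV
#'
#' @param evidence An `evidence_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path) {
  out <- data.frame(peptide = evidence$peptide,
                    dataset = evidence$dataset_id,
                    proteins = evidence$proteins,
                    confidence = format(evidence$confidence, trim = TRUE,
                                        scientific = FALSE),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein annotation table
#'
#' TSV with columns `locus_tag`, `class`, and optionally `region`, `group`
#' and `kda`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with the annotation columns.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ann <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  missing <- setdiff(c("locus_tag", "class"), names(ann))
  if (length(missing))
    stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(ann$class), FUNCTIONAL_CLASSES)
  if (length(bad))
    stop("unknown functional class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if ("kda" %in% names(ann)) ann$kda <- as.numeric(ann$kda)
  ann
}
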