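# In-silico tryptic digestion, exact-substring peptide-to-protein matching,
# sequence coverage, detection filters, refined-search augmentation, and
# homolog-group aggregation.

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P (the
#' standard trypsin rule). Fragments with up to `max_missed` internal missed
#' cleavage sites are generated; peptides shorter than `min_len` are dropped.
#'
#' @param sequence One amino-acid sequence.
#' @param min_len Minimum peptide length to keep (>= 1).
#' @param max_missed Maximum number of internal missed cleavages (>= 0).
#' @return A data.frame with columns `peptide`, `start`, `end` (1-based
#'   inclusive) and `missed`. Empty sequence yields zero rows.
#' @examples
#' tryptic_digest("AKPAKG")
#' @export
tryptic_digest <- function(sequence, min_len = 1, max_missed = 0) {
  stopifnot(min_len >= 1, max_missed >= 0)
  empty <- data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(sequence) || !nzchar(sequence)) return(empty)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  # cleavage after position i: K/R not followed by P
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)
  starts0 <- bounds[-length(bounds)] + 1L
  ends0 <- bounds[-1]
  nf <- length(starts0)
  s_all <- integer(0); e_all <- integer(0); m_all <- integer(0)
  for (m in 0:max_missed) {
    if (nf <= m) break
    i <- seq_len(nf - m)
    s <- starts0[i]; e <- ends0[i + m]
    keep <- (e - s + 1L) >= min_len
    s_all <- c(s_all, s[keep]); e_all <- c(e_all, e[keep])
    m_all <- c(m_all, rep.int(m, sum(keep)))
  }
  if (!length(s_all)) return(empty)
  o <- order(s_all, e_all)
  data.frame(peptide = substring(sequence, s_all[o], e_all[o]),
             start = s_all[o], end = e_all[o], missed = m_all[o],
             stringsAsFactors = FALSE)
}

# locate containing proteins for each unique peptide via fixed substring scan
.match_peptides_to_db <- function(peptides, db) {
  lapply(peptides, function(p) db$locus_tag[grepl(p, db$sequence,
                                                  fixed = TRUE)])
}

#' Match peptide evidence onto a protein database
#'
#' Matching is exact substring containment of the peptide in the protein
#' sequence. Each distinct peptide is credited once per (protein, data set)
#' cell it occurs in; peptides contained in more than one database protein are
#' credited to every containing protein and flagged shared. Evidence rows
#' below the 95% confidence threshold are ignored for counting. Peptides that
#' match no database protein are collected in an unmatched pool for a later
#' [refined_search].
#'
#' @param evidence An [evidence_table].
#' @param db A [protein_db].
#' @return A `detection_matrix`: list with elements `proteins`, `datasets`,
#'   `counts` (protein x dataset integer matrix of unique-peptide counts),
#'   `peptides` (list of lists of peptide sets per cell), `total_unique`
#'   (per protein, size of the union over data sets), `coverage_pct` (per
#'   protein, from the union), `shared_peptides` (character vector), and
#'   `unmatched` (data.frame peptide/dataset of counted rows matching no
#'   protein). The evidence is retained as attribute `evidence`.
#' @export
map_peptides <- function(evidence, db) {
  datasets <- attr(evidence, "dataset_ids")
  proteins <- db$locus_tag
  counted <- evidence[evidence$counted, , drop = FALSE]
  peps <- unique(counted$peptide)
  hits <- .match_peptides_to_db(peps, db)
  names(hits) <- peps
  shared <- peps[lengths(hits) > 1L]
  unmatched_peps <- peps[lengths(hits) == 0L]
  unmatched <- unique(counted[counted$peptide %in% unmatched_peps,
                              c("peptide", "dataset_id"), drop = FALSE])
  rownames(unmatched) <- NULL

  cell_peps <- lapply(proteins, function(p)
    stats::setNames(vector("list", length(datasets)), datasets))
  names(cell_peps) <- proteins
  for (d in datasets) {
    d_peps <- unique(counted$peptide[counted$dataset_id == d])
    for (p in d_peps) {
      for (prot in hits[[p]])
        cell_peps[[prot]][[d]] <- c(cell_peps[[prot]][[d]], p)
    }
  }
  counts <- matrix(0L, nrow = length(proteins), ncol = length(datasets),
                   dimnames = list(proteins, datasets))
  for (prot in proteins)
    counts[prot, ] <- vapply(cell_peps[[prot]], length, integer(1))
  union_peps <- lapply(cell_peps, function(x) unique(unlist(x)))
  total_unique <- vapply(union_peps, length, integer(1))
  coverage <- vapply(seq_along(proteins), function(i) {
    u <- union_peps[[i]]
    if (!length(u)) return(0)
    compute_coverage(db$sequence[i], u)
  }, numeric(1))
  names(coverage) <- proteins
  out <- list(proteins = proteins, datasets = datasets, counts = counts,
              peptides = cell_peps, total_unique = total_unique,
              coverage_pct = coverage, shared_peptides = shared,
              unmatched = unmatched)
  attr(out, "evidence") <- evidence
  attr(out, "db") <- db
  class(out) <- "detection_matrix"
  out
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf("detection_matrix: %d proteins x %d data sets (%s)\n",
              length(x$proteins), length(x$datasets),
              paste(x$datasets, collapse = ", ")))
  cat(sprintf("  detected proteins: %d; shared peptides: %d; unmatched: %d\n",
              sum(x$total_unique > 0), length(x$shared_peptides),
              nrow(x$unmatched)))
  invisible(x)
}

#' Protein sequence coverage from matched peptides
#'
#' Coverage is the fraction of residues contained in the union of all
#' occurrence intervals of the matched peptides (every occurrence of every
#' peptide counts), expressed as a percentage. Reports round to the nearest
#' integer, and a cell is conventionally rendered `"n/cov"` (number of
#' peptides, percent coverage); see [format_pep_cov].
#'
#' @param sequence Protein sequence (or a single-row [protein_db]).
#' @param peptides Character vector of peptides; each must occur in the
#'   sequence.
#' @return Coverage percentage in \[0, 100\] (unrounded).
#' @export
compute_coverage <- function(sequence, peptides) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  peptides <- unique(peptides)
  if (!length(peptides)) return(0)
  starts <- integer(0); ends <- integer(0)
  for (p in peptides) {
    occ <- gregexpr(p, sequence, fixed = TRUE)[[1]]
    if (occ[1] == -1L)
      stop(sprintf("peptide '%s' is not a substring of the protein", p),
           call. = FALSE)
    starts <- c(starts, as.integer(occ))
    ends <- c(ends, as.integer(occ) + nchar(p) - 1L)
  }
  covered <- IRanges::reduce(IRanges::IRanges(start = starts, end = ends))
  100 * sum(IRanges::width(covered)) / nchar(sequence)
}

#' Render a "peptides/coverage" cell
#'
#' @param n Number of unique peptides.
#' @param coverage_pct Coverage percentage (rounded half-up to integer).
#' @return Character like `"2/5"` for 2 peptides at 5% coverage.
#' @export
format_pep_cov <- function(n, coverage_pct) {
  sprintf("%d/%d", as.integer(n), as.integer(round_half_up(coverage_pct)))
}

#' Stringent and relaxed detection filters
#'
#' The stringent filter keeps a protein only if some single data set
#' contributed at least two unique peptides; the relaxed filter keeps any
#' protein with at least one matched peptide overall (admitting
#' single-peptide detections). The stringent set is always a subset of the
#' relaxed set.
#'
#' @param matrix A `detection_matrix` from [map_peptides].
#' @param mode `"stringent"` or `"relaxed"`.
#' @param min_peptides Per-cell threshold for the stringent filter (default 2).
#' @return Character vector of retained locus tags.
#' @export
apply_detection_filter <- function(matrix, mode = c("stringent", "relaxed"),
                                   min_peptides = 2) {
  mode <- match.arg(mode)
  if (mode == "stringent") {
    keep <- apply(matrix$counts >= min_peptides, 1, any)
  } else {
    keep <- matrix$total_unique >= 1
  }
  matrix$proteins[keep]
}

#' Refined search of unmatched peptides against an augmented database
#'
#' Emulates rerunning the search after new protein sequences become
#' available: the pooled unmatched peptides are re-scanned against the new
#' entries, the detection matrix is rebuilt over the combined database, and a
#' report of newly matched peptides is returned. Previously matched counts
#' never decrease.
#'
#' @param matrix A `detection_matrix` (carrying its evidence).
#' @param new_db A [protein_db] of additional entries; locus tags must not
#'   collide with the original database.
#' @return List with `matrix` (the rebuilt `detection_matrix` over the
#'   combined database) and `new_peptides` (data.frame `locus_tag`,
#'   `peptide`, `dataset_id` of peptides from the unmatched pool now
#'   matched).
#' @export
refined_search <- function(matrix, new_db) {
  db <- attr(matrix, "db")
  evidence <- attr(matrix, "evidence")
  clash <- intersect(db$locus_tag, new_db$locus_tag)
  if (length(clash))
    stop("new_db locus tags collide with existing database: ",
         paste(clash, collapse = ", "), call. = FALSE)
  combined <- rbind(db, new_db)
  class(combined) <- c("protein_db", "data.frame")
  updated <- map_peptides(evidence, combined)
  pool <- matrix$unmatched
  newly <- data.frame(locus_tag = character(0), peptide = character(0),
                      dataset_id = character(0), stringsAsFactors = FALSE)
  if (nrow(pool)) {
    hits <- .match_peptides_to_db(unique(pool$peptide), new_db)
    names(hits) <- unique(pool$peptide)
    rows <- lapply(seq_len(nrow(pool)), function(i) {
      h <- hits[[pool$peptide[i]]]
      if (!length(h)) return(NULL)
      data.frame(locus_tag = h, peptide = pool$peptide[i],
                 dataset_id = pool$dataset_id[i], stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) newly <- do.call(rbind, rows)
  }
  rownames(newly) <- NULL
  list(matrix = updated, new_peptides = newly)
}

#' Aggregate a detection matrix over homolog groups
#'
#' Proteins detected through homologs from several genomes are merged: the
#' per (group, data set) count is the size of the union of the members'
#' peptide sets, and coverage is reported for the group representative.
#'
#' @param matrix A `detection_matrix`.
#' @param groups A data.frame with columns `group_id`, `locus_tag`, and
#'   logical `representative`; the rows must partition the matrix proteins
#'   (each protein in exactly one group).
#' @return A `detection_matrix` whose rows are group ids.
#' @export
aggregate_by_group <- function(matrix, groups) {
  stopifnot(all(c("group_id", "locus_tag", "representative") %in%
                  names(groups)))
  if (anyDuplicated(groups$locus_tag))
    stop("protein assigned to more than one group: ",
         paste(unique(groups$locus_tag[duplicated(groups$locus_tag)]),
               collapse = ", "), call. = FALSE)
  missing <- setdiff(matrix$proteins, groups$locus_tag)
  if (length(missing))
    stop("groups do not cover proteins: ", paste(missing, collapse = ", "),
         call. = FALSE)
  db <- attr(matrix, "db")
  gids <- unique(groups$group_id)
  datasets <- matrix$datasets
  cell_peps <- lapply(gids, function(g)
    stats::setNames(vector("list", length(datasets)), datasets))
  names(cell_peps) <- gids
  reps <- character(length(gids)); names(reps) <- gids
  for (g in gids) {
    members <- groups$locus_tag[groups$group_id == g]
    rep_rows <- groups$representative[groups$group_id == g]
    if (!any(rep_rows))
      stop("group without representative: ", g, call. = FALSE)
    reps[g] <- members[which(rep_rows)[1]]
    for (d in datasets) {
      u <- unique(unlist(lapply(members, function(m)
        matrix$peptides[[m]][[d]])))
      cell_peps[[g]][[d]] <- if (is.null(u)) character(0) else u
    }
  }
  counts <- matrix(0L, nrow = length(gids), ncol = length(datasets),
                   dimnames = list(gids, datasets))
  for (g in gids)
    counts[g, ] <- vapply(cell_peps[[g]], length, integer(1))
  union_peps <- lapply(cell_peps, function(x) unique(unlist(x)))
  total_unique <- vapply(union_peps, length, integer(1))
  # coverage over the representative's sequence, restricted to the peptides
  # that actually occur in it (homolog peptides need not)
  coverage <- vapply(gids, function(g) {
    rep_seq <- db$sequence[db$locus_tag == reps[g]]
    u <- union_peps[[g]]
    u <- u[vapply(u, function(p) grepl(p, rep_seq, fixed = TRUE), logical(1))]
    if (!length(u)) return(0)
    compute_coverage(rep_seq, u)
  }, numeric(1))
  names(coverage) <- gids
  out <- list(proteins = gids, datasets = datasets, counts = counts,
              peptides = cell_peps, total_unique = total_unique,
              coverage_pct = coverage,
              shared_peptides = matrix$shared_peptides,
              unmatched = matrix$unmatched,
              representatives = reps)
  attr(out, "evidence") <- attr(matrix, "evidence")
  attr(out, "db") <- db
  class(out) <- "detection_matrix"
  out
}

#' Write a detection matrix as TSV
#'
#' One row per protein with per-data-set `"n/cov"` cells (unique peptides and
#' integer coverage from that protein's union, in the conventional
#' peptides/coverage notation), the total unique-peptide count, and coverage.
#'
#' @param matrix A `detection_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detection_matrix <- function(matrix, path) {
  db <- attr(matrix, "db")
  key <- if (!is.null(matrix$representatives)) matrix$representatives else
    stats::setNames(matrix$proteins, matrix$proteins)
  cov_int <- as.integer(round_half_up(matrix$coverage_pct))
  cell_cov <- function(prot, d) {
    seq <- db$sequence[db$locus_tag == key[prot]]
    peps <- matrix$peptides[[prot]][[d]]
    peps <- peps[vapply(peps, function(p) grepl(p, seq, fixed = TRUE),
                        logical(1))]
    if (!length(peps)) return(0L)
    as.integer(round_half_up(compute_coverage(seq, peps)))
  }
  cells <- sapply(matrix$datasets, function(d)
    sprintf("%d/%d", matrix$counts[, d],
            vapply(matrix$proteins, cell_cov, integer(1), d = d)),
    simplify = FALSE)
  out <- data.frame(locus = matrix$proteins, cells,
                    total = matrix$total_unique,
                    coverage = cov_int,
                    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
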