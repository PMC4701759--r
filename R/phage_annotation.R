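# Prophage-region assignment from locus-tag ranges and the module-by-class
# tally with percentage roll-ups.

# fixed class column order of the printed tally
TALLY_CLASSES <- c("HEAD", "BP", "TAIL", "REC", "REP", "MOD", "VIR", "UK")

#' Packaged WO prophage region definitions
#'
#' Locus-tag ranges delimiting the WO prophage regions of the wMel genome
#' (WOMelA, WOMelB1, the rickettsial-plasmid-associated WD0611-0620 block,
#' WOMelB2) and the five WO prophages of the wPip genome, plus per-genome
#' orphan categories without ranges. Region definitions are data, not code:
#' users analyzing other genomes supply their own table in the same format.
#'
#' @return A data.frame `region`, `prefix`, `lo`, `hi` (`lo`/`hi` `NA` for
#'   orphan categories).
#' @export
wo_region_defs <- function() {
  read_region_defs(system.file("extdata", "wo_region_defs.tsv",
                               package = "wophage"))
}

#' Read region definitions from TSV
#'
#' @param path TSV with columns `region`, `prefix`, `lo`, `hi`; empty or
#'   missing `lo`/`hi` marks a prefix-wide orphan category.
#' @return A data.frame of region definitions, file order preserved.
#' @export
read_region_defs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  defs <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character")
  missing <- setdiff(c("region", "prefix", "lo", "hi"), names(defs))
  if (length(missing))
    stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  defs$lo <- suppressWarnings(as.integer(defs$lo))
  defs$hi <- suppressWarnings(as.integer(defs$hi))
  ranged <- !is.na(defs$lo) & !is.na(defs$hi)
  if (any(defs$lo[ranged] > defs$hi[ranged]))
    stop("region range with lo > hi", call. = FALSE)
  # ranges sharing a prefix must not overlap
  for (pfx in unique(defs$prefix[ranged])) {
    d <- defs[ranged & defs$prefix == pfx, ]
    if (nrow(d) > 1) {
      o <- order(d$lo)
      if (any(d$lo[o][-1] <= d$hi[o][-nrow(d)]))
        stop("overlapping ranges for prefix ", pfx, call. = FALSE)
    }
  }
  defs
}

# split "WD0612" into prefix "WD" and integer 612
parse_locus_tag <- function(locus_tag) {
  m <- regmatches(locus_tag, regexec("^([A-Za-z]+)([0-9]+)$", locus_tag))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("unparsable locus tag: ",
         paste(locus_tag[bad], collapse = ", "), call. = FALSE)
  data.frame(prefix = vapply(m, `[`, character(1), 2),
             number = as.integer(vapply(m, `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}

#' Assign locus tags to prophage regions
#'
#' A tag of the form prefix + zero-padded number is assigned to the first
#' region definition whose prefix matches and whose range contains the
#' number. Tags matching no range fall back to the orphan category declared
#' for that prefix (a definition row with empty range), else `"NONE"`.
#'
#' @param locus_tag Character vector of locus tags.
#' @param defs Region definitions (default the packaged [wo_region_defs]).
#' @return Character vector of region ids.
#' @examples
#' assign_region(c("WD0570", "WD0615"))
#' @export
assign_region <- function(locus_tag, defs = wo_region_defs()) {
  parsed <- parse_locus_tag(locus_tag)
  ranged <- defs[!is.na(defs$lo) & !is.na(defs$hi), , drop = FALSE]
  orphan <- defs[is.na(defs$lo) | is.na(defs$hi), , drop = FALSE]
  vapply(seq_along(locus_tag), function(i) {
    hit <- which(ranged$prefix == parsed$prefix[i] &
                   ranged$lo <= parsed$number[i] &
                   parsed$number[i] <= ranged$hi)
    if (length(hit)) return(ranged$region[hit[1]])
    oh <- which(orphan$prefix == parsed$prefix[i])
    if (length(oh)) return(orphan$region[oh[1]])
    "NONE"
  }, character(1))
}

#' Region-by-class tally of classified proteins
#'
#' Builds the module-by-functional-class count matrix with row totals, column
#' totals and grand total. Each protein (one row per homolog-group
#' representative) is counted exactly once.
#'
#' @param classified A data.frame with columns `locus_tag`, `region`,
#'   `class` (class values among the eight prophage classes).
#' @param region_order Optional region row order; defaults to the packaged
#'   definition order, with unknown regions appended by appearance.
#' @return A `region_tally`: list with `counts` (region x class matrix),
#'   `row_totals`, `col_totals`, `grand_total`.
#' @export
region_tally <- function(classified, region_order = NULL) {
  stopifnot(all(c("locus_tag", "region", "class") %in% names(classified)))
  bad <- setdiff(unique(classified$class), TALLY_CLASSES)
  if (length(bad))
    stop("unknown class in tally: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(classified$locus_tag))
    stop("duplicated locus_tag: each protein is tallied once", call. = FALSE)
  if (is.null(region_order)) {
    defs <- tryCatch(wo_region_defs(), error = function(e) NULL)
    region_order <- if (!is.null(defs)) defs$region else character(0)
  }
  regions <- unique(c(intersect(region_order, classified$region),
                      setdiff(classified$region, region_order)))
  counts <- matrix(0L, nrow = length(regions), ncol = length(TALLY_CLASSES),
                   dimnames = list(regions, TALLY_CLASSES))
  if (nrow(classified)) {
    tab <- table(factor(classified$region, levels = regions),
                 factor(classified$class, levels = TALLY_CLASSES))
    counts[] <- as.integer(tab)
  }
  out <- list(counts = counts,
              row_totals = rowSums(counts),
              col_totals = colSums(counts),
              grand_total = sum(counts))
  class(out) <- "region_tally"
  out
}

#' @export
print.region_tally <- function(x, ...) {
  m <- cbind(x$counts, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$grand_total))
  print(m)
  invisible(x)
}

#' Percentage of the proteome in a class subset
#'
#' `100 * sum(column totals over the subset) / grand total`, rounded half-up
#' to the nearest integer, as printed in proteome summaries (e.g. structural
#' head+baseplate+tail share of the prophage proteome).
#'
#' @param tally A `region_tally`.
#' @param class_subset Character vector of class names.
#' @return Integer percentage.
#' @export
class_percentages <- function(tally, class_subset) {
  if (tally$grand_total == 0)
    stop("empty tally: percentages undefined", call. = FALSE)
  bad <- setdiff(class_subset, TALLY_CLASSES)
  if (length(bad))
    stop("unknown class: ", paste(bad, collapse = ", "), call. = FALSE)
  as.integer(round_half_up(
    100 * sum(tally$col_totals[class_subset]) / tally$grand_total))
}

#' Write a region tally as TSV
#'
#' Mirrors the printed layout: one row per region with the eight class
#' columns, a Total column, and a final Total row.
#'
#' @param tally A `region_tally`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_tally <- function(tally, path) {
  m <- cbind(tally$counts, Total = tally$row_totals)
  m <- rbind(m, Total = c(tally$col_totals, tally$grand_total))
  out <- data.frame(region = rownames(m), m, stringsAsFactors = FALSE,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged per-protein (region, class) assignments
#'
#' A synthetic per-protein transcription of the published region-by-class
#' cell counts of the WO prophage proteome detected in C/wStr1 cells: locus
#' tags inside each region's range (and placeholder tags for the orphan
#' categories) are generated so that the tally reproduces the printed cells
#' exactly. The printed cells sum to 118 proteins. Individual locus
#' identities are placeholders, not the real protein list.
#'
#' @return A data.frame `locus_tag`, `class` (region assignment follows from
#'   [assign_region]).
#' @export
wo_proteome_classes <- function() {
  path <- system.file("extdata", "wo_proteome_classes.synthetic.tsv",
                      package = "wophage")
  ann <- read_annotation(path)
  ann[, c("locus_tag", "class")]
}
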