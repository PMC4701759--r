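# Pairwise percent identity, concatenated-array comparison, intergenic
# layout, and direct-repeat detection for syntenic gene arrays.

#' Pairwise alignment identity
#'
#' Optimal global (end-to-end) or local (best segment) alignment by dynamic
#' programming with affine gap costs, reporting percent identity over all
#' alignment columns including internal gaps (the convention used by BLAST
#' reports, from which published identity tables derive; values for strongly
#' diverged pairs can differ by a point or two from NCBI output because the
#' exact program parameters are not part of the published record).
#'
#' @param a,b Sequences (character). Both must be non-empty and of the same
#'   alphabet.
#' @param mode `"global"` or `"local"`.
#' @param type `"auto"` (ACGTN-only strings treated as DNA), `"dna"` or
#'   `"protein"`.
#' @param scoring Optional list overriding the defaults. For DNA:
#'   `match = 2, mismatch = -3, gap_open = 5, gap_extend = 2` (BLASTn-like);
#'   for protein: BLOSUM62 with `gap_open = 11, gap_extend = 1`
#'   (BLASTp-like). Supply `match`/`mismatch` or a substitution `matrix`,
#'   plus `gap_open`/`gap_extend` (non-negative costs).
#' @return An `alignment_result`: list with `aligned_a`, `aligned_b`
#'   (gapped strings of equal length), `identities`, `alignment_length`,
#'   `identity_pct`, `score`, `mode`, `type`, `scoring`.
#' @examples
#' align_identity("ACGT", "ACGA",
#'                scoring = list(match = 1, mismatch = -1,
#'                               gap_open = 0, gap_extend = 2))
#' @export
align_identity <- function(a, b, mode = c("global", "local"),
                           type = c("auto", "dna", "protein"),
                           scoring = NULL) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b))
    stop("cannot align an empty sequence", call. = FALSE)
  if (type == "auto") {
    dna_like <- grepl("^[ACGTNacgtn]+$", a) && grepl("^[ACGTNacgtn]+$", b)
    type <- if (dna_like) "dna" else "protein"
  }
  defaults <- if (type == "dna") {
    list(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2)
  } else {
    list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1)
  }
  scoring <- utils::modifyList(defaults, as.list(scoring))
  submat <- if (!is.null(scoring$matrix)) {
    if (is.character(scoring$matrix)) {
      env <- new.env()
      utils::data(list = scoring$matrix, package = "Biostrings", envir = env)
      get(scoring$matrix, envir = env)
    } else scoring$matrix
  } else if (type == "dna") {
    Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                             mismatch = scoring$mismatch,
                                             baseOnly = FALSE)
  } else {
    alpha <- Biostrings::AA_ALPHABET
    m <- matrix(scoring$mismatch, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
    diag(m) <- scoring$match
    m
  }
  xa <- if (type == "dna") Biostrings::DNAString(toupper(a)) else
    Biostrings::AAString(toupper(a))
  xb <- if (type == "dna") Biostrings::DNAString(toupper(b)) else
    Biostrings::AAString(toupper(b))
  aln <- Biostrings::pairwiseAlignment(
    xa, xb, type = mode, substitutionMatrix = submat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  identities <- sum(ca == cb & ca != "-")
  len <- length(ca)
  out <- list(aligned_a = ga, aligned_b = gb, identities = identities,
              alignment_length = len,
              identity_pct = 100 * identities / len,
              score = Biostrings::score(aln), mode = mode, type = type,
              scoring = scoring)
  class(out) <- "alignment_result"
  out
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s %s alignment: %d/%d identities (%.1f%%), score %.1f\n",
              x$mode, x$type, x$identities, x$alignment_length,
              x$identity_pct, x$score))
  invisible(x)
}

#' Identity of concatenated gene arrays
#'
#' Concatenates each side of an ordered list of homologous gene pairs and
#' aligns the concatenations, the procedure used to compare whole syntenic
#' arrays (e.g. a seven-gene block across plasmids) in a single figure.
#'
#' @param gene_pairs A list of length-2 character vectors `(a_i, b_i)`,
#'   in array order.
#' @param ... Passed to [align_identity].
#' @return An `alignment_result` for the concatenated sequences.
#' @export
concat_identity <- function(gene_pairs, ...) {
  if (!length(gene_pairs))
    stop("concat_identity needs at least one gene pair", call. = FALSE)
  a <- paste(vapply(gene_pairs, `[`, character(1), 1), collapse = "")
  b <- paste(vapply(gene_pairs, `[`, character(1), 2), collapse = "")
  align_identity(a, b, ...)
}

#' Construct a gene array
#'
#' An ordered set of ORFs on one contiguous nucleotide sequence, with 1-based
#' inclusive coordinates.
#'
#' @param orfs A data.frame with `locus_tag`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`).
#' @param sequence The contiguous nucleotide sequence (optional, `""` if
#'   only layout is needed).
#' @return A `gene_array` (data.frame sorted by `start`, with the sequence
#'   as attribute).
#' @export
gene_array <- function(orfs, sequence = "") {
  stopifnot(all(c("locus_tag", "start", "end", "strand") %in% names(orfs)))
  if (any(orfs$start > orfs$end))
    stop("ORF with start > end", call. = FALSE)
  if (nzchar(sequence) && any(orfs$end > nchar(sequence)))
    stop("ORF extends past the end of the sequence", call. = FALSE)
  orfs <- orfs[order(orfs$start), , drop = FALSE]
  rownames(orfs) <- NULL
  attr(orfs, "sequence") <- sequence
  class(orfs) <- c("gene_array", "data.frame")
  orfs
}

#' Intergenic layout of a gene array
#'
#' For each consecutive ORF pair reports the intergenic gap
#' `next.start - prev.end - 1`: zero for directly adjacent ORFs, negative for
#' overlapping ORFs. Coordinates are genomic regardless of strand.
#'
#' @param array A [gene_array].
#' @return A data.frame `upstream_locus`, `downstream_locus`, `gap_bp`.
#' @export
intergenic_layout <- function(array) {
  n <- nrow(array)
  if (n < 2L)
    return(data.frame(upstream_locus = character(0),
                      downstream_locus = character(0),
                      gap_bp = integer(0), stringsAsFactors = FALSE))
  data.frame(
    upstream_locus = array$locus_tag[-n],
    downstream_locus = array$locus_tag[-1],
    gap_bp = as.integer(array$start[-1] - array$end[-n] - 1L),
    stringsAsFactors = FALSE
  )
}

#' Extract an ORF sequence from a gene array
#'
#' Minus-strand ORFs are reverse-complemented, so the returned string is the
#' coding-strand sequence suitable for alignment.
#'
#' @param array A [gene_array] with a sequence.
#' @param locus_tag The ORF to extract.
#' @return Nucleotide string.
#' @export
orf_sequence <- function(array, locus_tag) {
  seq <- attr(array, "sequence")
  if (!nzchar(seq)) stop("gene array carries no sequence", call. = FALSE)
  i <- match(locus_tag, array$locus_tag)
  if (is.na(i)) stop("unknown locus tag: ", locus_tag, call. = FALSE)
  s <- substr(seq, array$start[i], array$end[i])
  if (array$strand[i] == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Find direct repeats in a nucleotide sequence
#'
#' Reports maximal non-overlapping same-strand repeat pairs `(pos1, pos2,
#' length)` of length at least `min_len` with at most `max_mismatch`
#' mismatches. A pair is maximal when it can be extended in neither direction
#' without violating the length bounds, the mismatch budget, or
#' non-overlap (`pos2 >= pos1 + length`). Positions are 1-based.
#'
#' @param sequence Nucleotide string.
#' @param min_len Minimum repeat length (>= 3).
#' @param max_mismatch Maximum mismatches tolerated within the pair.
#' @return A data.frame `pos1`, `pos2`, `length`, `mismatches`, sorted by
#'   `pos1` then `pos2`; zero rows when no repeat qualifies.
#' @examples
#' find_direct_repeats("ACGTACGT", min_len = 4)
#' @export
find_direct_repeats <- function(sequence, min_len = 3, max_mismatch = 0) {
  stopifnot(min_len >= 3, max_mismatch >= 0)
  n <- nchar(sequence)
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  out <- list()
  if (n >= 2 * min_len) {
    for (d in min_len:(n - min_len)) {
      # mismatch indicator between positions i and i+d
      mm <- as.integer(res[seq_len(n - d)] != res[seq_len(n - d) + d])
      cmm <- c(0L, cumsum(mm))
      win_mm <- function(i, L) cmm[i + L] - cmm[i]  # mismatches in window
      max_i <- n - d - min_len + 1L
      if (max_i < 1L) next
      for (i in seq_len(max_i)) {
        # longest admissible L at this (i, d): within bounds, budget, and
        # non-overlap (L <= d)
        L_hi <- min(d, n - d - i + 1L)
        if (L_hi < min_len) next
        L <- L_hi
        while (L >= min_len && win_mm(i, L) > max_mismatch) L <- L - 1L
        if (L < min_len) next
        # maximality: no left extension (i-1, L+1) and no right extension
        # (i, L+1) admissible
        left_ok <- i > 1L && L + 1L <= d && win_mm(i - 1L, L + 1L) <= max_mismatch
        right_ok <- L + 1L <= min(d, n - d - i + 1L) &&
          win_mm(i, L + 1L) <= max_mismatch
        if (left_ok || right_ok) next
        out[[length(out) + 1L]] <-
          data.frame(pos1 = i, pos2 = i + d, length = L,
                     mismatches = win_mm(i, L))
      }
    }
  }
  if (!length(out))
    return(data.frame(pos1 = integer(0), pos2 = integer(0),
                      length = integer(0), mismatches = integer(0)))
  rep_df <- unique(do.call(rbind, out))
  rep_df <- rep_df[order(rep_df$pos1, rep_df$pos2), , drop = FALSE]
  rownames(rep_df) <- NULL
  rep_df
}

#' Write an identity matrix in the published table shape
#'
#' Rows are genes, columns strains; each cell a percent identity.
#'
#' @param mat Numeric matrix (genes x strains).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identity_matrix <- function(mat, path) {
  out <- data.frame(gene = rownames(mat), mat, stringsAsFactors = FALSE,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
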