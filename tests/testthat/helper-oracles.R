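# Independent oracles and fixture builders used across the suite. Each
# oracle is a direct, naive computation of the definition, kept free of any
# package internals it is used to check.

# externally studentized residuals by explicit leave-one-out refitting
loo_studentized_oracle <- function(X, y) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    beta <- solve(crossprod(Xi), crossprod(Xi, yi))
    ei <- yi - Xi %*% beta
    s2 <- sum(ei^2) / (nrow(Xi) - ncol(Xi))
    pred <- sum(X[i, ] * beta)
    v <- 1 + drop(t(X[i, ]) %*% solve(crossprod(Xi)) %*% X[i, ])
    (y[i] - pred) / sqrt(s2 * v)
  }, numeric(1))
}

# all global alignments of two short strings under linear gap cost;
# returns the optimal score and the identity fractions achieved by
# score-optimal alignments
enumerate_global_alignments <- function(a, b, match, mismatch, gap) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  acc <- new.env()
  acc$score <- -Inf
  acc$ident <- numeric(0)
  rec <- function(i, j, score, idents, len) {
    if (i > length(A) && j > length(B)) {
      if (score > acc$score) {
        acc$score <- score
        acc$ident <- if (len > 0) idents / len else 0
      } else if (score == acc$score) {
        acc$ident <- c(acc$ident, if (len > 0) idents / len else 0)
      }
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      hit <- A[i] == B[j]
      rec(i + 1, j + 1, score + if (hit) match else mismatch,
          idents + hit, len + 1)
    }
    if (i <= length(A)) rec(i + 1, j, score - gap, idents, len + 1)
    if (j <= length(B)) rec(i, j + 1, score - gap, idents, len + 1)
  }
  rec(1, 1, 0, 0, 0)
  list(score = acc$score, identity_pcts = unique(100 * acc$ident))
}

# best local alignment score by enumerating all substring pairs and
# globally aligning each (empty segments score 0)
enumerate_local_score <- function(a, b, match, mismatch, gap) {
  best <- 0
  na <- nchar(a); nb <- nchar(b)
  for (i1 in seq_len(na)) for (i2 in i1:na)
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      s <- enumerate_global_alignments(substr(a, i1, i2), substr(b, j1, j2),
                                       match, mismatch, gap)$score
      if (s > best) best <- s
    }
  best
}

# per (protein, dataset) unique-peptide counts by scanning every
# (peptide, protein) pair
bf_detection_counts <- function(evidence, db) {
  datasets <- attr(evidence, "dataset_ids")
  counted <- evidence[evidence$counted, , drop = FALSE]
  counts <- matrix(0L, nrow = nrow(db), ncol = length(datasets),
                   dimnames = list(db$locus_tag, datasets))
  for (p in seq_len(nrow(db))) {
    for (d in datasets) {
      peps <- unique(counted$peptide[counted$dataset_id == d])
      hits <- vapply(peps, function(pp)
        grepl(pp, db$sequence[p], fixed = TRUE), logical(1))
      counts[p, d] <- sum(hits)
    }
  }
  counts
}

# maximal non-overlapping direct repeat pairs by naive triple loop
bf_direct_repeats <- function(sequence, min_len, max_mismatch = 0) {
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(res)
  mism <- function(i, j, L) sum(res[i:(i + L - 1)] != res[j:(j + L - 1)])
  admissible <- function(i, j, L) {
    i >= 1 && L >= min_len && j >= i + L && j + L - 1 <= n &&
      mism(i, j, L) <= max_mismatch
  }
  out <- list()
  if (n >= 2 * min_len) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      Lmax <- min(j - i, n - j + 1)
      if (Lmax < min_len) next
      for (L in min_len:Lmax) {
        if (!admissible(i, j, L)) next
        if (admissible(i - 1, j - 1, L + 1) || admissible(i, j, L + 1)) next
        out[[length(out) + 1L]] <-
          data.frame(pos1 = i, pos2 = j, length = L,
                     mismatches = mism(i, j, L))
      }
    }
  }
  if (!length(out))
    return(data.frame(pos1 = integer(0), pos2 = integer(0),
                      length = integer(0), mismatches = integer(0)))
  out <- unique(do.call(rbind, out))
  out <- out[order(out$pos1, out$pos2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random amino-acid sequence (uniform alphabet)
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
          "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
random_aa <- function(L) {
  paste(sample(AA20, L, replace = TRUE), collapse = "")
}

# small protein database with controllable sequences
make_db <- function(seqs, prefix = "P", ...) {
  protein_db(sprintf("%s%03d", prefix, seq_along(seqs)), seqs, ...)
}

# random regression observations valid for fit_loglog_model; factor levels
# are balanced so every level keeps >= 2 observations under leave-one-out
random_observations <- function(n, n_class = 3, n_ds = 4) {
  data.frame(
    locus_tag = sprintf("P%03d", seq_len(n)),
    dataset_id = sample(rep(LETTERS[seq_len(n_ds)], length.out = n)),
    peptide_count = sample(1:40, n, replace = TRUE),
    mass_kda = stats::runif(n, 10, 120),
    functional_class = sample(rep(c("HEAD", "TAIL", "UK")[seq_len(n_class)],
                                  length.out = n)),
    stringsAsFactors = FALSE
  )
}

# TRUE when every leave-one-out subset of the design keeps full column
# rank (the precondition for the leave-one-out refit to exist)
loo_feasible <- function(X) {
  all(vapply(seq_len(nrow(X)), function(i)
    qr(X[-i, , drop = FALSE])$rank == ncol(X), logical(1)))
}

# random observations whose model design admits every leave-one-out refit
draw_loo_observations <- function() {
  repeat {
    obs <- random_observations(sample(12:30, 1), n_class = sample(2:3, 1),
                               n_ds = sample(2:4, 1))
    fit <- tryCatch(fit_loglog_model(obs), error = function(e) NULL)
    if (is.null(fit)) next
    X <- stats::model.matrix(fit$lm)
    if (loo_feasible(X)) return(list(obs = obs, fit = fit, X = X))
  }
}

# random in-protein peptides: k substrings of length len+1 from s
sample_peptides <- function(s, k, len = 8) {
  st <- sample(seq_len(max(1, nchar(s) - len - 1)), k, replace = TRUE)
  substring(s, st, st + len)
}

# database + evidence reproducing a classified proteome so the pipeline can
# run end-to-end on the packaged (region, class) fixture
fixture_pipeline_inputs <- function(dir, seed = 42) {
  set.seed(seed)
  ann <- wo_proteome_classes()
  seqs <- vapply(rep(120, nrow(ann)), function(L) {
    s <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N",
                  "Q", "S", "T", "V", "W", "Y"), L, replace = TRUE)
    s[seq(10, L, by = 12)] <- "K"   # guarantee tryptic sites
    paste(s, collapse = "")
  }, character(1))
  db <- protein_db(ann$locus_tag, seqs, functional_class = ann$class)
  # two tryptic peptides per protein in one data set, one in another
  peps <- lapply(seqs, function(s) {
    d <- tryptic_digest(s, min_len = 6)
    utils::head(d$peptide, 3)
  })
  stopifnot(all(lengths(peps) == 3))
  ev <- evidence_table(
    peptide = unlist(peps),
    dataset_id = rep(c("D", "D", "E"), nrow(ann)),
    proteins = rep(ann$locus_tag, each = 3),
    confidence = 0.99,
    dataset_ids = c("D", "E", "F", "G")
  )
  db_path <- file.path(dir, "fixture_db.fasta")
  ev_path <- file.path(dir, "fixture_evidence.tsv")
  ann_path <- file.path(dir, "fixture_annotation.tsv")
  write_fasta(db, db_path)
  write_evidence(ev, ev_path)
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(db = db_path, evidence = ev_path, annotation = ann_path)
}
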