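# Relative abundance level (RAL) and studentized-residual (SR) scoring.
#
# RAL is the arithmetic mean of a protein's unique-peptide counts over the K
# MS data sets (zeros included). SR is the mass-normalized form: ordinary
# least squares of log10(peptide count) on log10(protein mass), optionally
# adjusted for functional class and data set, followed by external
# studentization of each observation's residual; a protein's SR is the mean
# of its per-observation values. A protein of average abundance for its mass
# has SR near 0; positive values indicate above-average abundance.

#' Relative abundance level
#'
#' Arithmetic mean of unique-peptide counts over all K data sets, zeros
#' included. A protein seen only as 2 peptides in one of four data sets has
#' RAL 0.5.
#'
#' @param counts_per_dataset Non-negative integer vector, one entry per
#'   data set (K >= 1).
#' @return Non-negative mean count.
#' @examples
#' compute_ral(c(2, 3, 4, 7))
#' compute_ral(c(2, 0, 0, 0))
#' @export
compute_ral <- function(counts_per_dataset) {
  if (length(counts_per_dataset) == 0L)
    stop("RAL requires at least one data set", call. = FALSE)
  if (any(counts_per_dataset < 0))
    stop("counts must be non-negative", call. = FALSE)
  mean(counts_per_dataset)
}

#' Assemble regression observations from a detection matrix
#'
#' One observation per (protein, data set) cell with at least one matched
#' peptide; zero-count cells are not observations (their log is undefined)
#' but still enter RAL means.
#'
#' @param matrix A `detection_matrix`.
#' @param db A [protein_db] supplying `mass_kda` and `functional_class`; for
#'   group-level matrices, the representative's values are used.
#' @return A data.frame with `locus_tag`, `dataset_id`, `peptide_count`,
#'   `mass_kda`, `functional_class`.
#' @export
abundance_observations <- function(matrix, db = attr(matrix, "db")) {
  key <- if (!is.null(matrix$representatives)) {
    matrix$representatives
  } else {
    stats::setNames(matrix$proteins, matrix$proteins)
  }
  idx <- match(key[matrix$proteins], db$locus_tag)
  if (anyNA(idx))
    stop("proteins missing from database: ",
         paste(matrix$proteins[is.na(idx)], collapse = ", "), call. = FALSE)
  rows <- which(matrix$counts >= 1L, arr.ind = TRUE)
  data.frame(
    locus_tag = matrix$proteins[rows[, 1]],
    dataset_id = matrix$datasets[rows[, 2]],
    peptide_count = matrix$counts[rows],
    mass_kda = db$mass_kda[idx][rows[, 1]],
    functional_class = db$functional_class[idx][rows[, 1]],
    stringsAsFactors = FALSE
  )
}

#' Fit the log-log peptide-count model
#'
#' Least squares of `log10(peptide_count)` on an intercept and
#' `log10(mass_kda)`; the multivariable form adds functional-class and
#' data-set indicator effects. Returns the pieces needed for external
#' studentization: raw residuals, leverages (hat diagonal), residual degrees
#' of freedom.
#'
#' @param observations Output of [abundance_observations] (or any data.frame
#'   with those columns; `peptide_count >= 1` required).
#' @param model `"multi"` (adjusted for class and data set) or `"uni"`
#'   (log-mass only).
#' @return A `loglog_fit` list: `coefficients`, `fitted`, `residuals`,
#'   `leverage`, `df_residual`, `sigma`, `model`, `observations`, and the
#'   underlying `lm` object.
#' @export
fit_loglog_model <- function(observations, model = c("multi", "uni")) {
  model <- match.arg(model)
  obs <- observations
  if (any(obs$peptide_count < 1))
    stop("zero-count cells are not observations", call. = FALSE)
  obs$log_count <- log10(obs$peptide_count)
  obs$log_mass <- log10(obs$mass_kda)
  terms <- "log_mass"
  if (model == "multi") {
    for (fac in c("functional_class", "dataset_id")) {
      if (length(unique(obs[[fac]])) < 2L)
        stop(sprintf("factor '%s' needs at least 2 levels", fac),
             call. = FALSE)
    }
    obs$functional_class <- factor(obs$functional_class)
    obs$dataset_id <- factor(obs$dataset_id)
    terms <- c(terms, "functional_class", "dataset_id")
  }
  form <- stats::reformulate(terms, response = "log_count")
  fit <- stats::lm(form, data = obs)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design; aliased column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  p <- length(stats::coef(fit))
  if (nrow(obs) < p + 2L)
    stop(sprintf("too few observations (%d) for %d parameters",
                 nrow(obs), p), call. = FALSE)
  out <- list(
    coefficients = stats::coef(fit),
    fitted = as.numeric(stats::fitted(fit)),
    residuals = as.numeric(stats::residuals(fit)),
    leverage = as.numeric(stats::hatvalues(fit)),
    df_residual = fit$df.residual,
    sigma = sqrt(sum(stats::residuals(fit)^2) / fit$df.residual),
    model = model,
    observations = observations,
    lm = fit
  )
  class(out) <- "loglog_fit"
  out
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("log-log peptide-count model (%svariable): %d obs, %d params\n",
              x$model, length(x$residuals),
              length(x$coefficients)))
  cat(sprintf("  log-mass slope %.3f, residual scale %.3f (df %d)\n",
              x$coefficients[["log_mass"]], x$sigma, x$df_residual))
  invisible(x)
}

#' Externally studentized residuals
#'
#' For each observation, the raw residual scaled by its leave-one-out
#' residual standard deviation and leverage:
#' `t_i = e_i / (s_(i) * sqrt(1 - h_ii))`, where `s_(i)` is obtained by the
#' closed-form downdate of the residual sum of squares (no refitting).
#' Observations with leverage 1 get `NA`.
#'
#' @param fit A `loglog_fit`.
#' @return Numeric vector of per-observation studentized residuals.
#' @export
studentized_residuals <- function(fit) {
  e <- fit$residuals
  h <- fit$leverage
  df <- fit$df_residual
  if (df < 2L)
    stop("external studentization requires residual df >= 2", call. = FALSE)
  rss <- sum(e^2)
  # an (essentially) exact fit has zero residual scale at every leave-one-out
  # subset too; the ratio e_i / s_(i) is then pure round-off, so report 0
  if (rss <= 1e-20 * max(1, sum(fit$fitted^2)))
    return(rep(0, length(e)))
  t_i <- rep(NA_real_, length(e))
  ok <- (1 - h) > 1e-12
  s_i2 <- (rss - e[ok]^2 / (1 - h[ok])) / (df - 1)
  s_i2 <- pmax(s_i2, 0)
  t_i[ok] <- e[ok] / sqrt(s_i2 * (1 - h[ok]))
  t_i[ok][s_i2 == 0 & abs(e[ok]) < 1e-12] <- 0
  t_i
}

#' Per-protein SR and the abundance report
#'
#' Averages each protein's per-observation studentized residuals into a
#' single SR and joins it with RAL, total peptides and coverage into the
#' conventional abundance-table layout (Locus, kDa, Pep, Cov, RAL, SR).
#' Proteins with no detections get RAL 0 and missing SR.
#'
#' @param matrix A `detection_matrix`.
#' @param db A [protein_db] (defaults to the matrix's).
#' @param fit Optional pre-computed `loglog_fit`; fitted from the matrix when
#'   `NULL`.
#' @param model Passed to [fit_loglog_model] when fitting here.
#' @return An `abundance_result` data.frame with columns `locus_tag`,
#'   `mass_kda`, `total_peptides`, `coverage_pct`, `ral`, `sr`, `n_obs`.
#' @export
abundance_report <- function(matrix, db = attr(matrix, "db"), fit = NULL,
                             model = "multi") {
  if (is.null(fit)) {
    obs <- abundance_observations(matrix, db)
    fit <- fit_loglog_model(obs, model = model)
  } else {
    obs <- fit$observations
  }
  t_i <- studentized_residuals(fit)
  sr_by <- tapply(t_i, obs$locus_tag, mean, na.rm = TRUE)
  n_by <- tapply(t_i, obs$locus_tag, length)
  key <- if (!is.null(matrix$representatives)) matrix$representatives else
    stats::setNames(matrix$proteins, matrix$proteins)
  idx <- match(key[matrix$proteins], db$locus_tag)
  res <- data.frame(
    locus_tag = matrix$proteins,
    mass_kda = db$mass_kda[idx],
    total_peptides = matrix$total_unique,
    coverage_pct = matrix$coverage_pct,
    ral = apply(matrix$counts, 1, compute_ral),
    sr = as.numeric(sr_by[matrix$proteins]),
    n_obs = as.integer(n_by[matrix$proteins]),
    stringsAsFactors = FALSE
  )
  res$n_obs[is.na(res$n_obs)] <- 0L
  res$sr[res$n_obs == 0L] <- NA_real_
  rownames(res) <- NULL
  attr(res, "fit") <- fit
  class(res) <- c("abundance_result", "data.frame")
  res
}

#' Write the abundance report as TSV
#'
#' Table layout: Locus, kDa (integer), Pep, Cov (integer percent), RAL, SR;
#' undetected proteins print `-` for SR.
#'
#' @param report An `abundance_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_report <- function(report, path) {
  out <- data.frame(
    Locus = report$locus_tag,
    kDa = as.integer(round_half_up(report$mass_kda)),
    Pep = report$total_peptides,
    Cov = as.integer(round_half_up(report$coverage_pct)),
    RAL = round(report$ral, 2),
    SR = ifelse(is.na(report$sr), "-", sprintf("%.2f", report$sr)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean RAL per prophage region
#'
#' Groups abundance results by region and reports per-region mean RAL plus
#' the ratio of the mean over intact-prophage regions to the mean over
#' orphan/degenerate categories, the comparison used to argue that intact
#' prophages are expressed above the background of degenerate ones.
#'
#' @param results An `abundance_result` (or data.frame with `locus_tag`,
#'   `ral`).
#' @param regions Named character vector mapping locus tags to region ids
#'   (every result must be mapped).
#' @param orphan_regions Region ids counted as orphan/degenerate for the
#'   ratio (default: any region id containing "Orphan").
#' @return A data.frame `region`, `n`, `mean_ral`, with attribute
#'   `intact_orphan_ratio`.
#' @export
region_mean_ral <- function(results, regions,
                            orphan_regions = NULL) {
  r <- regions[results$locus_tag]
  if (anyNA(r))
    stop("unmapped locus tags: ",
         paste(results$locus_tag[is.na(r)], collapse = ", "), call. = FALSE)
  agg <- stats::aggregate(results$ral, by = list(region = r),
                          FUN = function(x) c(n = length(x), mean = mean(x)))
  out <- data.frame(region = agg$region,
                    n = as.integer(agg$x[, "n"]),
                    mean_ral = as.numeric(agg$x[, "mean"]),
                    stringsAsFactors = FALSE)
  if (is.null(orphan_regions))
    orphan_regions <- out$region[grepl("Orphan", out$region)]
  orphan <- out$region %in% orphan_regions
  ratio <- if (any(orphan) && any(!orphan)) {
    mean(results$ral[r %in% out$region[!orphan]]) /
      mean(results$ral[r %in% out$region[orphan]])
  } else NA_real_
  attr(out, "intact_orphan_ratio") <- ratio
  out
}
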