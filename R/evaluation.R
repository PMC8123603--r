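# Scoring of 2- and 3-class predictions: class-averaged sensitivity and
# specificity, balanced accuracy, one-vs-rest AUROC, two-class collapse,
# saturation scans and per-domain proportion tests.

#' Three-class sensitivity, specificity and balanced accuracy
#'
#' Sensitivity is the unweighted mean over classes of `TP_c / P_c`,
#' specificity the mean of `TN_c / N_c`, and the balanced accuracy their
#' average — so a uniformly random 3-class classifier scores 33.3% /
#' 66.7% / 50.0% in expectation. Classes absent from the truth are
#' excluded from the means with a warning.
#'
#' @param truth,predicted Character vectors of class labels (`NPDA`,
#'   `NPDB`, `Neutral`).
#' @return List of class `metrics_report`: `sensitivity`, `specificity`,
#'   `bacc` (percentages), plus the per-class confusion quantities.
#' @export
three_class_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predictions must have equal length")
  }
  classes <- ZOOM_CLASSES[ZOOM_CLASSES %in% unique(truth)]
  absent <- setdiff(ZOOM_CLASSES, classes)
  if (length(absent) > 0L) {
    warning("class(es) absent from truth: ",
            paste(absent, collapse = ", "), "; excluded from the mean",
            call. = FALSE)
  }
  per_class <- lapply(classes, function(cls) {
    p <- sum(truth == cls)
    n <- sum(truth != cls)
    tp <- sum(truth == cls & predicted == cls)
    tn <- sum(truth != cls & predicted != cls)
    c(P = p, N = n, TP = tp, TN = tn,
      sens = tp / p, spec = if (n > 0) tn / n else NA_real_)
  })
  names(per_class) <- classes
  sens <- 100 * mean(vapply(per_class, `[[`, 0, "sens"))
  spec <- 100 * mean(vapply(per_class, `[[`, 0, "spec"), na.rm = TRUE)
  out <- list(sensitivity = sens, specificity = spec,
              bacc = (sens + spec) / 2,
              per_class = per_class, classes = classes)
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  BACC %.1f%%",
              x$sensitivity, x$specificity, x$bacc))
  if (!is.null(x$auroc)) cat(sprintf("  AUROC %.1f%%", x$auroc))
  cat("\n")
  invisible(x)
}

#' Binary AUROC by the rank (Mann-Whitney) formulation
#'
#' Midranks handle score ties, so the result equals the exhaustive
#' pair-counting estimate with ties counted one half.
#'
#' @param positive Logical vector marking positives.
#' @param scores Numeric scores (higher = more positive).
#' @return AUROC as a fraction in [0, 1], or `NA` when either class is
#'   empty.
#' @export
auroc_binary <- function(positive, scores) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiclass AUROC as the mean of one-vs-rest AUROCs
#'
#' @param truth Character vector of true classes.
#' @param scores Matrix or data frame of per-class probability scores with
#'   columns `NPDA`, `NPDB`, `Neutral`.
#' @return Percentage; classes without positives are dropped with a
#'   warning.
#' @export
auroc_multiclass <- function(truth, scores) {
  scores <- as.matrix(as.data.frame(scores)[, intersect(ZOOM_CLASSES,
                                                        colnames(as.data.frame(scores))),
                                            drop = FALSE])
  aucs <- vapply(colnames(scores), function(cls) {
    auroc_binary(truth == cls, scores[, cls])
  }, numeric(1))
  if (any(is.na(aucs))) {
    warning("class(es) without positives dropped from AUROC: ",
            paste(names(aucs)[is.na(aucs)], collapse = ", "),
            call. = FALSE)
  }
  100 * mean(aucs, na.rm = TRUE)
}

#' Collapse 3-class outputs to a neutral-vs-disease classifier
#'
#' The disease score of a variant is `P(NPDA) + P(NPDB)` (the complement
#' of `P(Neutral)`); a variant is predicted diseased when that score
#' exceeds `P(Neutral)`, with the exact tie resolved to neutral. Truth is
#' diseased for labels A, B or D (or the corresponding class names).
#'
#' @param truth Character vector of labels (`N`/`A`/`B`/`D` or class
#'   names).
#' @param probabilities Matrix/data frame of 3-class probabilities.
#' @return `metrics_report` with 2-class sensitivity, specificity, BACC
#'   and AUROC (percent), plus the per-variant `disease_score`.
#' @export
collapse_to_two_classes <- function(truth, probabilities) {
  p <- as.matrix(as.data.frame(probabilities)[, ZOOM_CLASSES])
  score <- p[, "NPDA"] + p[, "NPDB"]
  truth_dis <- truth %in% c("A", "B", "D", "NPDA", "NPDB")
  pred_dis <- score > p[, "Neutral"] + 1e-12
  tp <- sum(truth_dis & pred_dis)
  tn <- sum(!truth_dis & !pred_dis)
  sens <- 100 * tp / sum(truth_dis)
  spec <- 100 * tn / sum(!truth_dis)
  out <- list(sensitivity = sens, specificity = spec,
              bacc = (sens + spec) / 2,
              auroc = 100 * auroc_binary(truth_dis, score),
              disease_score = score)
  class(out) <- "metrics_report"
  out
}

#' Saturation mutagenesis scan
#'
#' Predicts every possible amino-acid substitution at the given positions,
#' producing the full position-by-substitution class map, per-residue mean
#' probabilities and per-domain predicted-class fractions.
#'
#' @param positions Integer vector of sequence positions to scan.
#' @param wt Character vector of wild-type residues (one-letter), parallel
#'   to `positions`.
#' @param feature_provider Function `(position, wt, mut)` returning a
#'   one-row data frame / named list of raw feature values, or `NULL` when
#'   no features are available (recorded as missing).
#' @param model A `zoom_model`.
#' @return List of class `saturation_scan`: `scan` (long data frame with
#'   probabilities and class per substitution), `per_residue` (mean
#'   probabilities), `domain_fractions` (predicted-class fractions per
#'   domain), `missing` (substitutions without features).
#' @export
saturation_scan <- function(positions, wt, feature_provider, model) {
  stopifnot(length(positions) == length(wt))
  rows <- list()
  missing <- list()
  for (i in seq_along(positions)) {
    muts <- setdiff(AA1, toupper(wt[i]))
    for (m in muts) {
      fv <- feature_provider(positions[i], toupper(wt[i]), m)
      if (is.null(fv)) {
        missing[[length(missing) + 1L]] <-
          data.frame(position = positions[i], wt = toupper(wt[i]), mut = m,
                     stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(position = positions[i], wt = toupper(wt[i]),
                         mut = m, stringsAsFactors = FALSE),
              as.data.frame(fv))
    }
  }
  if (length(rows) == 0L) stop("no substitution had features")
  tab <- do.call(rbind, rows)
  pred <- predict(model, tab)
  scan <- cbind(tab[, c("position", "wt", "mut")], pred)
  scan$domain <- domain_of(scan$position)
  per_residue <- do.call(rbind, lapply(split(scan, scan$position),
    function(s) data.frame(position = s$position[1L],
                           NPDA = mean(s$NPDA), NPDB = mean(s$NPDB),
                           Neutral = mean(s$Neutral))))
  rownames(per_residue) <- NULL
  domain_fractions <- do.call(rbind, lapply(split(scan, scan$domain),
    function(s) data.frame(domain = s$domain[1L], n = nrow(s),
                           NPDA = mean(s$class == "NPDA"),
                           NPDB = mean(s$class == "NPDB"),
                           Neutral = mean(s$class == "Neutral"))))
  rownames(domain_fractions) <- NULL
  out <- list(scan = scan, per_residue = per_residue,
              domain_fractions = domain_fractions,
              missing = if (length(missing)) do.call(rbind, missing)
                        else NULL)
  class(out) <- "saturation_scan"
  out
}

#' @export
print.saturation_scan <- function(x, ...) {
  cat(sprintf("saturation scan: %d substitutions over %d positions\n",
              nrow(x$scan), length(unique(x$scan$position))))
  print(x$domain_fractions)
  invisible(x)
}

#' Write a saturation-scan matrix as tab-separated text
#'
#' One row per position (`position`, `wt`) and one column per mutant
#' amino acid holding the predicted class.
#'
#' @param scan A `saturation_scan` object.
#' @param path File path.
#' @export
write_scan_matrix <- function(scan, path) {
  s <- scan$scan
  wide <- stats::reshape(s[, c("position", "wt", "mut", "class")],
                         idvar = c("position", "wt"), timevar = "mut",
                         direction = "wide")
  names(wide) <- sub("^class\\.", "", names(wide))
  wide <- wide[order(wide$position),
               c("position", "wt", intersect(AA1, names(wide)))]
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Two-sided pooled two-proportion z-test
#'
#' Compares `k1/n1` against `k2/n2` with the pooled-variance normal
#' approximation, as used for per-domain predicted-class fractions.
#'
#' @param k1,n1,k2,n2 Successes and trials of the two samples.
#' @return List with `z`, `p_value` and the two proportions. A pooled
#'   proportion of exactly 0 or 1 yields z = 0, p = 1.
#' @export
proportion_ztest <- function(k1, n1, k2, n2) {
  if (n1 < 1L || n2 < 1L || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    stop("need 0 <= k <= n and n >= 1 on both sides")
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  if (pool == 0 || pool == 1) {
    return(list(z = 0, p_value = 1, p1 = p1, p2 = p2))
  }
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Write a metrics report as JSON
#'
#' @param report A `metrics_report`.
#' @param path File path.
#' @export
write_metrics_json <- function(report, path) {
  payload <- list(sensitivity = report$sensitivity,
                  specificity = report$specificity,
                  bacc = report$bacc)
  if (!is.null(report$auroc)) payload$auroc <- report$auroc
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE),
             path)
  invisible(path)
}
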