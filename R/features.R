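# Assembly of the 32-column feature table (4 predictor scores + 28 single
# features), z-score standardization over the full variant population, and
# univariate statistical feature selection.

#' The fixed feature registry
#'
#' The 32 named features: four external predictor scores (PROVEAN, DEOGEN2,
#' the stability part of SNPMuSiC, PoPMuSiC), thirteen folding free-energy
#' changes from statistical potentials (three of which — `DDW_sd`,
#' `DDW_sds`, `DDW_sad` — describe distance-dependent tertiary
#' interactions), nine further continuous features (solvent accessibility,
#' volume change, evolutionary conservation and log-odds scores, early
#' folding, PFAM log-odds, distances to metal / carbohydrate / disulfide
#' sites) and six discrete features (domain membership and
#' polarity/aromaticity/charge changes). Predictor and free-energy scores
#' are consumed as precomputed columns, never recomputed.
#'
#' @return Data frame with columns `feature` and `type`
#'   (`"continuous"`/`"discrete"`).
#' @export
feature_registry <- function() {
  ddw <- paste0("DDW_", c("s", "d", "a", "t", "sd", "ds", "st", "at",
                          "ad", "sa", "sds", "sad", "std"))
  continuous <- c("PROVEAN", "DEOGEN2", "SNPMuSiC_SSS", "PoPMuSiC", ddw,
                  "Access", "DeltaV", "EvolCI", "EvolLOR", "EarlyF",
                  "PFAM", "Metal", "Carbohyd", "Disulfide")
  discrete <- c("Saposin", "Catalytic", "Linker", "Polarity", "Aromatic",
                "Charge")
  data.frame(feature = c(continuous, discrete),
             type = rep(c("continuous", "discrete"),
                        c(length(continuous), length(discrete))),
             stringsAsFactors = FALSE)
}

#' Z-score standardization against a reference population
#'
#' Rescales values as `(X - <X>) / sigma_X`, with mean and standard
#' deviation taken over the reference population (all variants of the
#' table, including those of unknown significance, not only training
#' classes). The population convention (divide by n) is the default since
#' the population is a fixed, fully observed set; the sample convention is
#' available.
#'
#' @param values Numeric vector to rescale.
#' @param population Numeric vector the mean/sd are computed on.
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return Numeric vector of z-scores. If the population is constant all
#'   z-scores are 0, with a warning.
#' @examples
#' standardize(2, c(0, 2))  # +1 under the population convention
#' @export
standardize <- function(values, population,
                        sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  population <- population[is.finite(population)]
  if (length(population) < 2L) {
    stop("standardization population must hold at least 2 finite values")
  }
  m <- mean(population)
  s <- stats::sd(population)
  if (sd_type == "population") {
    s <- s * sqrt((length(population) - 1) / length(population))
  }
  if (!is.finite(s) || s == 0) {
    warning("constant feature: standard deviation is 0, z set to 0",
            call. = FALSE)
    return(rep(0, length(values)))
  }
  (values - m) / s
}

#' Standardize the continuous columns of a feature table
#'
#' Applies [standardize()] to every continuous registry feature present in
#' the table, using all rows as the standardization population. Discrete
#' features are coerced to numeric 0/1 and standardized the same way so all
#' columns live on a comparable scale for Euclidean distances. Missing
#' values are imputed to z = 0 (the population mean) after rescaling and
#' flagged in the `imputed` attribute.
#'
#' @param table Data frame holding (a subset of) the registry features.
#' @param sd_type Passed to [standardize()].
#' @return The table with standardized feature columns; attributes
#'   `feature_means`, `feature_sds` and `imputed` record the constants and
#'   the imputed cells.
#' @export
standardize_features <- function(table,
                                 sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  reg <- feature_registry()
  present <- intersect(reg$feature, names(table))
  means <- sds <- stats::setNames(numeric(length(present)), present)
  imputed <- matrix(FALSE, nrow(table), length(present),
                    dimnames = list(NULL, present))
  for (f in present) {
    x <- as.numeric(table[[f]])
    pop <- x[is.finite(x)]
    if (length(pop) == 0L) {
      warning("feature ", f, " is all-missing; excluded", call. = FALSE)
      table[[f]] <- NULL
      next
    }
    z <- suppressWarnings(standardize(x, pop, sd_type = sd_type))
    imputed[, f] <- !is.finite(x)
    z[!is.finite(z)] <- 0
    table[[f]] <- z
    means[f] <- mean(pop)
    n <- length(pop)
    sds[f] <- if (sd_type == "population") {
      stats::sd(pop) * sqrt((n - 1) / n)
    } else {
      stats::sd(pop)
    }
  }
  attr(table, "feature_means") <- means
  attr(table, "feature_sds") <- sds
  attr(table, "imputed") <- imputed
  table
}

#' One-way ANOVA F-test across groups
#'
#' Classic equal-variance one-way ANOVA, used to test whether a continuous
#' feature differs between the neutral, NPDB and NPDA classes.
#'
#' @param groups List of (at least two) numeric vectors, one per class.
#' @return List with `statistic` (F) and `p_value`. Degenerate input with
#'   zero between- and within-group variance yields F = 0, p = 1.
#' @export
anova_f <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(y) == 0) {
    return(list(statistic = 0, p_value = 1))
  }
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  f <- unname(fit$statistic)
  p <- unname(fit$p.value)
  if (!is.finite(f)) {
    # zero within-group variance but groups differ
    f <- Inf
    p <- 0
  }
  list(statistic = f, p_value = p)
}

#' Pearson chi-squared test of independence
#'
#' Uncorrected (no continuity correction) Pearson chi-squared test on a
#' class-by-category contingency table; rows or columns with a zero margin
#' are dropped with a warning.
#'
#' @param table Matrix of non-negative counts, at least 2x2 after margin
#'   pruning.
#' @return List with `statistic`, `p_value` and `df`.
#' @examples
#' chi2_independence(matrix(c(20, 0, 0, 20), 2))  # chi2 = 40
#' @export
chi2_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("contingency table must hold non-negative integers")
  }
  zr <- rowSums(table) == 0
  zc <- colSums(table) == 0
  if (any(zr) || any(zc)) {
    warning("dropping zero-margin rows/columns", call. = FALSE)
    table <- table[!zr, !zc, drop = FALSE]
  }
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("contingency table needs >= 2 rows and columns")
  }
  if (stats::var(as.vector(table)) == 0 && length(unique(table)) == 1L) {
    # uniform table: statistic is exactly 0
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       df = unname(ct$parameter))
}

#' Univariate feature selection over the three variant classes
#'
#' Tests every registry feature of the table for discrimination between
#' the N, B and A classes: continuous features with the one-way ANOVA
#' F-test, discrete features with the uncorrected Pearson chi-squared test.
#' Features with p <= `alpha` (inclusive) are selected.
#'
#' @param table Data frame of raw or standardized feature columns.
#' @param labels Character vector of class labels (`"N"`, `"B"`, `"A"`),
#'   one per row.
#' @param alpha Significance threshold (default 0.05, inclusive).
#' @return Data frame sorted by p-value: `feature`, `test`, `statistic`,
#'   `p_value`, `selected`. Row order of the input does not affect the
#'   result.
#' @export
select_features <- function(table, labels, alpha = 0.05) {
  labels <- as.character(labels)
  if (length(labels) != nrow(table)) {
    stop("one label per table row required")
  }
  classes <- sort(unique(labels))
  if (any(table(labels) < 2L)) {
    stop("need at least 2 variants per class")
  }
  reg <- feature_registry()
  present <- reg[reg$feature %in% names(table), , drop = FALSE]
  out <- lapply(seq_len(nrow(present)), function(i) {
    f <- present$feature[i]
    x <- table[[f]]
    if (all(!is.finite(as.numeric(x)))) {
      warning("feature ", f, " is all-missing; excluded", call. = FALSE)
      return(NULL)
    }
    if (present$type[i] == "continuous") {
      groups <- split(as.numeric(x), labels)
      res <- anova_f(groups)
      test <- "anova_f"
    } else {
      ct <- table(labels, as.character(x))
      res <- tryCatch(chi2_independence(ct),
                      error = function(e) list(statistic = 0, p_value = 1))
      test <- "chi2"
    }
    data.frame(feature = f, test = test, statistic = res$statistic,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$selected <- out$p_value <= alpha
  out <- out[order(out$p_value, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a feature table from delimited text
#'
#' Reads a TSV/CSV feature table (header mandatory) and optionally renames
#' columns to registry names via a two-column mapping file (`from<TAB>to`).
#'
#' @param path Path to the table.
#' @param mapping Optional path to a tab-separated `from`/`to` renaming
#'   file.
#' @return Data frame.
#' @export
read_feature_table <- function(path, mapping = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(mapping)) {
    m <- utils::read.table(mapping, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("from", "to"))
    hit <- match(names(x), m$from)
    names(x)[!is.na(hit)] <- m$to[hit[!is.na(hit)]]
  }
  x
}
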