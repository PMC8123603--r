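# Non-linear curves linking predicted class probabilities to measured
# relative enzymatic activity R (% of wild-type), their least-RMSD fit,
# inversion back to activity estimates, and Pearson correlations.

#' Evaluate the activity-probability curves
#'
#' The three fitted relations between relative activity `R` (percent of
#' wild-type) and class probability:
#' `P(NPDA) = a1 / (a1 + R)`,
#' `P(NPDB) = R * exp(-a2 * R + a3)`,
#' `P(Neutral) = a4 * R + a5 * R^2`.
#'
#' @param R Numeric vector of relative activities (0-100 scale).
#' @param fit An `activity_fit` or a named list/vector with `a1`..`a5`.
#' @return Matrix with columns `NPDA`, `NPDB`, `Neutral` (not clamped).
#' @export
activity_curves <- function(R, fit) {
  a <- as.list(unlist(fit)[c("a1", "a2", "a3", "a4", "a5")])
  cbind(NPDA = a$a1 / (a$a1 + R),
        NPDB = R * exp(-a$a2 * R + a$a3),
        Neutral = a$a4 * R + a$a5 * R^2)
}

rmsd <- function(x, y) sqrt(mean((x - y)^2))

#' Fit the activity-probability curves by least RMSD
#'
#' Each of the three curves is fitted independently to its probability
#' component, minimizing the root-mean-square deviation between curve and
#' points. The NPDA hyperbola and the NPDB hump are profiled over their
#' non-linear parameter on a deterministic coarse grid followed by local
#' refinement (the NPDB amplitude `exp(a3)` and the Neutral polynomial are
#' linear least-squares given the rest), so the procedure is deterministic
#' and needs no random starts.
#'
#' @param R Numeric vector of relative activities (percent scale); at
#'   least 5 distinct values required.
#' @param probabilities Matrix/data frame with columns `NPDA`, `NPDB`,
#'   `Neutral` (one row per record; replicate measurements should be
#'   collapsed to their mean beforehand, see [read_activity_table()]).
#' @return Object of class `activity_fit`: named vector `parameters`
#'   (`a1`..`a5`) and `sigma`, the per-curve RMSD.
#' @export
fit_activity_curves <- function(R, probabilities) {
  p <- as.matrix(as.data.frame(probabilities)[, ZOOM_CLASSES])
  if (length(R) != nrow(p)) stop("R and probabilities sizes differ")
  keep <- is.finite(R) & apply(is.finite(p), 1L, all)
  R <- R[keep]
  p <- p[keep, , drop = FALSE]
  if (length(unique(R)) < 5L) {
    stop("need at least 5 records with distinct R")
  }
  # --- NPDA: 1-parameter hyperbola, profile over log10(a1)
  obj_a1 <- function(la1) rmsd(10^la1 / (10^la1 + R), p[, "NPDA"])
  grid <- seq(-3, 4, by = 0.25)
  best <- grid[which.min(vapply(grid, obj_a1, 0))]
  opt1 <- stats::optimize(obj_a1, c(best - 0.5, best + 0.5), tol = 1e-10)
  a1 <- 10^opt1$minimum
  sigma_a <- opt1$objective
  # --- NPDB: profile over a2; amplitude exp(a3) is linear given a2
  npdb_fit <- function(a2) {
    w <- R * exp(-a2 * R)
    b <- sum(w * p[, "NPDB"]) / sum(w^2)
    b <- max(b, 1e-12)
    list(b = b, rmsd = rmsd(b * w, p[, "NPDB"]))
  }
  a2_grid <- c(seq(0.001, 0.2, by = 0.002), seq(0.25, 1, by = 0.05))
  a2_best <- a2_grid[which.min(vapply(a2_grid,
                                      function(a) npdb_fit(a)$rmsd, 0))]
  opt2 <- stats::optimize(function(a) npdb_fit(a)$rmsd,
                          c(max(1e-6, a2_best / 2), a2_best * 2),
                          tol = 1e-10)
  a2 <- opt2$minimum
  a3 <- log(npdb_fit(a2)$b)
  sigma_b <- opt2$objective
  # --- Neutral: linear least squares in (a4, a5)
  X <- cbind(R, R^2)
  coef_n <- stats::lm.fit(X, p[, "Neutral"])$coefficients
  a4 <- unname(coef_n[1L])
  a5 <- unname(coef_n[2L])
  sigma_n <- rmsd(X %*% coef_n, p[, "Neutral"])
  out <- list(parameters = c(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5),
              sigma = c(NPDA = sigma_a, NPDB = sigma_b,
                        Neutral = sigma_n),
              n = length(R))
  class(out) <- "activity_fit"
  out
}

#' @export
print.activity_fit <- function(x, ...) {
  cat("activity_fit over", x$n, "records\n")
  cat("  a =", paste(sprintf("%.4g", x$parameters), collapse = ", "), "\n")
  cat("  sigma =", paste(sprintf("%s %.3f", names(x$sigma), x$sigma),
                         collapse = "  "), "\n")
  invisible(x)
}

#' Estimate relative activity from class probabilities
#'
#' Inverts each fitted curve where possible — the NPDA hyperbola
#' algebraically (`R = a1 (1 - p) / p`), the Neutral polynomial by the
#' quadratic formula, and the non-monotone NPDB hump numerically on the
#' requested branch (`"descending"`: activities above the hump maximum at
#' `1/a2`; `"ascending"`: below it) — then combines the available
#' estimates by an inverse-variance (`1 / sigma^2`) weighted average.
#' Probabilities outside a curve's range skip that curve.
#'
#' @param p Probability vector `c(NPDA=, NPDB=, Neutral=)`.
#' @param fit An `activity_fit`.
#' @param branch Branch of the NPDB hump (default `"descending"`).
#' @param r_max Upper search bound for numerical inversion (default 400).
#' @return List with `estimate` (combined R), `per_curve` (the three
#'   individual inversions, `NA` where skipped), `branch` and `weights`.
#' @export
invert_activity <- function(p, fit, branch = c("descending", "ascending"),
                            r_max = 400) {
  branch <- match.arg(branch)
  p <- unlist(p)[ZOOM_CLASSES]   # independent curves: no sum constraint
  if (any(!is.finite(p)) || any(p < -1e-10) || any(p > 1 + 1e-10)) {
    stop("probabilities must lie in [0, 1]")
  }
  names(p) <- ZOOM_CLASSES
  a <- fit$parameters
  per <- c(NPDA = NA_real_, NPDB = NA_real_, Neutral = NA_real_)
  # NPDA hyperbola: monotone decreasing, closed form
  if (p[["NPDA"]] > 0 && p[["NPDA"]] <= 1) {
    per[["NPDA"]] <- a[["a1"]] * (1 - p[["NPDA"]]) / p[["NPDA"]]
  }
  # NPDB hump: maximum exp(a3 - 1) / a2 at R = 1 / a2
  g <- function(R) R * exp(-a[["a2"]] * R + a[["a3"]])
  r_peak <- 1 / a[["a2"]]
  g_max <- g(r_peak)
  if (p[["NPDB"]] > 0 && p[["NPDB"]] <= g_max) {
    interval <- if (branch == "ascending") {
      c(0, r_peak)
    } else {
      hi <- r_peak * 2
      while (g(hi) > p[["NPDB"]] && hi < 1e6) hi <- hi * 2
      c(r_peak, hi)
    }
    root <- tryCatch(
      stats::uniroot(function(R) g(R) - p[["NPDB"]], interval,
                     tol = 1e-10)$root,
      error = function(e) NA_real_)
    per[["NPDB"]] <- root
  }
  # Neutral polynomial: quadratic formula on the increasing branch
  a4 <- a[["a4"]]; a5 <- a[["a5"]]
  if (p[["Neutral"]] >= 0 && (a4 > 0 || a5 > 0)) {
    r_n <- if (abs(a5) < 1e-15) {
      p[["Neutral"]] / a4
    } else {
      disc <- a4^2 + 4 * a5 * p[["Neutral"]]
      if (disc >= 0) (-a4 + sqrt(disc)) / (2 * a5) else NA_real_
    }
    if (is.finite(r_n) && r_n >= 0) per[["Neutral"]] <- r_n
  }
  per[is.finite(per) & per > r_max] <- NA_real_
  w <- 1 / pmax(fit$sigma, 1e-6)^2
  ok <- is.finite(per)
  if (!any(ok)) {
    return(list(estimate = NA_real_, per_curve = per, branch = branch,
                weights = w))
  }
  list(estimate = sum(per[ok] * w[ok]) / sum(w[ok]),
       per_curve = per, branch = branch, weights = w)
}

#' Pearson correlation with a t-distribution p-value
#'
#' @param x,y Numeric vectors (at least 3 finite pairs).
#' @return List with `r`, `p_value`, `n`. Zero variance in either vector
#'   yields `NA` with a warning.
#' @export
pearson <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 paired finite values")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Read a relative-activity table
#'
#' Delimited text with columns `variant` and `R` (percent of wild-type
#' activity); optional extra columns (source, zygosity) are preserved on
#' first occurrence. Replicate measurements of the same variant are
#' collapsed to their mean.
#'
#' @param path Path to a TSV/CSV file.
#' @return Data frame with one row per variant.
#' @export
read_activity_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("variant", "R") %in% names(x))) {
    stop("activity table needs 'variant' and 'R' columns")
  }
  if (any(x$R < 0)) stop("relative activity must be >= 0")
  collapsed <- lapply(split(x, x$variant), function(v) {
    v$R[1L] <- mean(v$R)
    v[1L, , drop = FALSE]
  })
  out <- do.call(rbind, collapsed)
  rownames(out) <- NULL
  out
}
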