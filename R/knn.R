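# The 3-class k-nearest-neighbour severity classifier with genotype
# handling and position-level leave-one-out cross-validation.

ZOOM_CLASSES <- c("NPDA", "NPDB", "Neutral")

# Map annotation labels to prediction classes.
label_to_class <- function(labels) {
  out <- c(A = "NPDA", B = "NPDB", N = "Neutral")[as.character(labels)]
  if (any(is.na(out))) {
    stop("labels for training must be in {N, A, B}")
  }
  unname(out)
}

as_prob_vector <- function(p) {
  p <- unlist(p)
  if (length(p) != 3L) stop("class probabilities must have 3 components")
  if (is.null(names(p)) || !all(ZOOM_CLASSES %in% names(p))) {
    names(p) <- ZOOM_CLASSES
  }
  p <- p[ZOOM_CLASSES]
  if (any(p < -1e-10) || abs(sum(p) - 1) > 1e-10) {
    stop("class probabilities must be non-negative and sum to 1")
  }
  p
}

#' Class probabilities from the k nearest training neighbours
#'
#' Probabilities are the class fractions among the k nearest training
#' vectors under Euclidean distance. Distance ties at the k-th rank are
#' broken by including every tied vector and renormalizing, which makes
#' the result independent of training-row order.
#'
#' @param query Numeric vector (one variant) or matrix (one row per
#'   variant) of standardized feature values.
#' @param training Numeric matrix of training vectors (same columns).
#' @param labels Class labels of the training rows: `"NPDA"`, `"NPDB"`,
#'   `"Neutral"` (annotation labels A/B/N are also accepted).
#' @param k Neighbour count; values above the training size are clamped
#'   with a warning.
#' @return Matrix with one row per query and columns `NPDA`, `NPDB`,
#'   `Neutral`.
#' @export
knn_probabilities <- function(query, training, labels, k) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  query <- as.matrix(query)
  training <- as.matrix(training)
  if (nrow(training) == 0L) stop("training set must be non-empty")
  if (ncol(query) != ncol(training)) {
    stop("query and training feature dimensions differ")
  }
  if (all(labels %in% c("N", "A", "B"))) labels <- label_to_class(labels)
  if (!all(labels %in% ZOOM_CLASSES)) {
    stop("training labels must be NPDA/NPDB/Neutral (or A/B/N)")
  }
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(training)) {
    warning("k = ", k, " exceeds training size ", nrow(training),
            "; clamped", call. = FALSE)
    k <- nrow(training)
  }
  d <- cross_dist(query, training)
  out <- matrix(0, nrow(query), 3L,
                dimnames = list(NULL, ZOOM_CLASSES))
  for (i in seq_len(nrow(query))) {
    di <- d[i, ]
    kth <- sort(di, partial = k)[k]
    nb <- which(di <= kth + 1e-12)      # include all k-th-rank ties
    tab <- table(factor(labels[nb], levels = ZOOM_CLASSES))
    out[i, ] <- as.numeric(tab) / length(nb)
  }
  out
}

#' Assign a class from class probabilities
#'
#' Argmax over the three probabilities; when the maximum is tied, the
#' least deleterious involved class wins (Neutral over NPDB/NPDA, NPDB
#' over NPDA), so a three-way tie yields Neutral.
#'
#' @param p Probability vector `c(NPDA=, NPDB=, Neutral=)` or a matrix
#'   with those columns.
#' @return Character vector of classes.
#' @examples
#' classify_probabilities(c(NPDA = 0.5, NPDB = 0, Neutral = 0.5))  # Neutral
#' classify_probabilities(c(NPDA = 0.5, NPDB = 0.5, Neutral = 0))  # NPDB
#' @export
classify_probabilities <- function(p) {
  if (is.null(dim(p))) p <- matrix(as_prob_vector(p), nrow = 1L,
                                   dimnames = list(NULL, ZOOM_CLASSES))
  p <- p[, ZOOM_CLASSES, drop = FALSE]
  apply(p, 1L, function(row) {
    top <- which(row >= max(row) - 1e-12)
    # preference order: least deleterious first
    for (cls in c("Neutral", "NPDB", "NPDA")) {
      if (match(cls, ZOOM_CLASSES) %in% top) return(cls)
    }
  })
}

#' Train the 3-class severity model
#'
#' Standardizes the requested feature columns over all rows of the table
#' (the full variant population, including unknown-significance rows if
#' supplied), keeps the labelled rows as the training set and stores the
#' standardization constants so queries are rescaled identically.
#'
#' @param table Data frame with a `position` column and feature columns.
#' @param labels Vector of labels; rows labelled `N`/`A`/`B` (or the
#'   class names) form the training set, other rows only contribute to
#'   standardization.
#' @param features Character vector of feature columns to use (typically
#'   the selected ones); defaults to every registry feature present.
#' @param k Neighbour count; default `round(sqrt(N))` with N the training
#'   size.
#' @return An object of class `zoom_model`.
#' @export
zoom_train <- function(table, labels, features = NULL, k = NULL) {
  if (is.null(features)) {
    features <- intersect(feature_registry()$feature, names(table))
  }
  missing <- setdiff(features, names(table))
  if (length(missing) > 0L) {
    stop("feature column(s) absent: ", paste(missing, collapse = ", "))
  }
  std <- standardize_features(table[, features, drop = FALSE])
  labels <- as.character(labels)
  trainable <- labels %in% c("N", "A", "B", ZOOM_CLASSES)
  if (!any(trainable)) stop("no trainable (N/A/B) rows")
  lab <- labels[trainable]
  if (all(lab %in% c("N", "A", "B"))) lab <- label_to_class(lab)
  n <- sum(trainable)
  if (is.null(k)) k <- max(1L, round(sqrt(n)))
  model <- list(
    features = colnames(std),
    feature_means = attr(std, "feature_means"),
    feature_sds = attr(std, "feature_sds"),
    training = as.matrix(std[trainable, , drop = FALSE]),
    labels = lab,
    positions = if ("position" %in% names(table)) {
      table$position[trainable]
    } else {
      rep(NA_integer_, n)
    },
    k = as.integer(k))
  class(model) <- "zoom_model"
  model
}

#' @export
print.zoom_model <- function(x, ...) {
  cat(sprintf("zoom_model: %d training variants, %d features, k = %d\n",
              nrow(x$training), length(x$features), x$k))
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$labels)),
                                  table(x$labels)), collapse = " "), "\n")
  invisible(x)
}

# Rescale a raw feature table with a model's stored constants.
model_standardize <- function(model, newdata) {
  missing <- setdiff(model$features, names(newdata))
  if (length(missing) > 0L) {
    stop("feature column(s) absent: ", paste(missing, collapse = ", "))
  }
  z <- sapply(model$features, function(f) {
    x <- as.numeric(newdata[[f]])
    s <- model$feature_sds[[f]]
    z <- if (s > 0) (x - model$feature_means[[f]]) / s else rep(0, length(x))
    z[!is.finite(z)] <- 0
    z
  })
  matrix(z, ncol = length(model$features),
         dimnames = list(NULL, model$features))
}

#' Predict class probabilities for new variants
#'
#' @param object A `zoom_model`.
#' @param newdata Data frame of raw feature values (model features must be
#'   present) or a pre-standardized numeric matrix.
#' @param k Optional override of the stored neighbour count.
#' @param ... Unused.
#' @return Data frame with `NPDA`, `NPDB`, `Neutral` probabilities and the
#'   assigned `class`.
#' @export
predict.zoom_model <- function(object, newdata, k = NULL, ...) {
  q <- if (is.matrix(newdata)) newdata else model_standardize(object, newdata)
  p <- knn_probabilities(q, object$training, object$labels,
                         k = if (is.null(k)) object$k else k)
  out <- as.data.frame(p)
  out$class <- classify_probabilities(p)
  out
}

#' Genotype-level prediction for a recessive disease
#'
#' Each allele's probability vector is the average over the probability
#' vectors of the variants it carries; a wild-type (empty) allele
#' contributes `(NPDA=0, NPDB=0, Neutral=1)`. The genotype probability is
#' the mean of the two allele vectors and the class follows
#' [classify_probabilities()]. Because a wild-type allele forces
#' `P(Neutral) >= 0.5` and ties resolve to the least deleterious class,
#' any genotype with one wild-type allele is predicted Neutral — the
#' recessivity rule.
#'
#' @param allele1,allele2 For each allele either `NULL` (wild-type), a
#'   data frame of raw feature rows for the allele's variants, or a
#'   numeric matrix/vector of per-variant class probabilities with columns
#'   `NPDA`, `NPDB`, `Neutral`.
#' @param model A `zoom_model`; may be omitted when both alleles are given
#'   as probabilities.
#' @return List with `probabilities` (named vector), `class`, and the two
#'   per-allele probability vectors.
#' @export
genotype_predict <- function(allele1, allele2 = NULL, model = NULL) {
  allele_probs <- function(a) {
    if (is.null(a) || (is.data.frame(a) && nrow(a) == 0L)) {
      return(c(NPDA = 0, NPDB = 0, Neutral = 1))
    }
    if (is.data.frame(a)) {
      if (is.null(model)) stop("a model is required for feature input")
      p <- as.matrix(predict(model, a)[, ZOOM_CLASSES])
    } else {
      p <- if (is.null(dim(a))) matrix(as_prob_vector(a), nrow = 1L,
                                       dimnames = list(NULL, ZOOM_CLASSES))
           else as.matrix(a)[, ZOOM_CLASSES, drop = FALSE]
    }
    colMeans(p)
  }
  p1 <- allele_probs(allele1)
  p2 <- allele_probs(allele2)
  p <- (p1 + p2) / 2
  list(probabilities = p, class = classify_probabilities(p),
       allele1 = p1, allele2 = p2)
}

#' Position-level leave-one-out cross-validation
#'
#' For every variant, the model is retrained on all variants whose
#' sequence position differs (every variant sharing the query's position
#' is held out together), then the held-out variant is predicted.
#' Standardization constants are computed once on the full table, matching
#' a population-level rescaling; `k` is clamped per fold when a fold
#' shrinks below it.
#'
#' @param table Data frame with `position` and feature columns.
#' @param labels Training labels (`N`/`A`/`B` or class names).
#' @param features Feature columns to use.
#' @param k Neighbour count; default `round(sqrt(N))` of the full set.
#' @return Data frame with per-variant `NPDA`, `NPDB`, `Neutral`
#'   probabilities, `class` and `position`.
#' @export
loo_by_position <- function(table, labels, features = NULL, k = NULL) {
  if (!"position" %in% names(table)) stop("table needs a position column")
  if (length(unique(table$position)) < 2L) {
    stop("need at least 2 distinct positions")
  }
  model <- zoom_train(table, labels, features = features, k = k)
  n <- nrow(model$training)
  out <- matrix(NA_real_, n, 3L, dimnames = list(NULL, ZOOM_CLASSES))
  for (i in seq_len(n)) {
    keep <- model$positions != model$positions[i]
    if (!any(keep)) {
      stop("position ", model$positions[i], " holds the entire dataset")
    }
    k_i <- min(model$k, sum(keep))
    out[i, ] <- knn_probabilities(model$training[i, , drop = FALSE],
                                  model$training[keep, , drop = FALSE],
                                  model$labels[keep], k = k_i)
  }
  res <- as.data.frame(out)
  res$class <- classify_probabilities(out)
  res$position <- model$positions
  res$label <- model$labels
  res
}

#' Serialize / restore a trained model as plain text
#'
#' The model (feature registry subset, standardization constants, training
#' matrix, labels, positions, k) is written as JSON so that predictions
#' are reproducible bit-for-bit across sessions.
#'
#' @param model A `zoom_model`.
#' @param path File path.
#' @return `read_zoom_model` returns the restored `zoom_model`.
#' @export
write_zoom_model <- function(model, path) {
  payload <- list(
    features = model$features,
    feature_means = as.list(model$feature_means),
    feature_sds = as.list(model$feature_sds),
    training = unclass(as.data.frame(model$training)),
    labels = model$labels,
    positions = model$positions,
    k = model$k)
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE),
             path)
  invisible(path)
}

#' @rdname write_zoom_model
#' @export
read_zoom_model <- function(path) {
  payload <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"))
  model <- list(
    features = payload$features,
    feature_means = unlist(payload$feature_means),
    feature_sds = unlist(payload$feature_sds),
    training = as.matrix(as.data.frame(payload$training)),
    labels = payload$labels,
    positions = payload$positions,
    k = as.integer(payload$k))
  colnames(model$training) <- model$features
  class(model) <- "zoom_model"
  model
}
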