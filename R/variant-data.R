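# Harmonization of variant annotations collected from several sources into
# the three working datasets: S3cl (N/A/B), S2cl (N/disease) and SVUS (U).

VARIANT_LABELS <- c("N", "A", "B", "D", "U")

#' Harmonize a multiset of variant annotation labels
#'
#' Collapses the labels a variant received across annotation sources into a
#' single label over the alphabet N (neutral), A (NPDA-causing), B
#' (NPDB-causing), D (disease-causing, type unresolved) and U (unknown
#' significance). The merging rules, applied in this order of precedence:
#'
#' 1. An N co-occurring with any of D, A or B is a strong conflict: the
#'    merged label is U.
#' 2. U is dominated by any informative label (N, A, B or D).
#' 3. Co-occurrence of A and B merges to D.
#' 4. D is dominated by the more informative A or B.
#'
#' A singleton merges to itself. The result depends only on the set of
#' distinct labels, never on their order or multiplicity.
#'
#' @param labels Character vector (a multiset) of labels in
#'   `c("N","A","B","D","U")`.
#' @return A single harmonized label.
#' @examples
#' merge_labels(c("U", "B"))   # "B"
#' merge_labels(c("D", "A"))   # "A"
#' merge_labels(c("N", "A"))   # "U"
#' merge_labels(c("A", "B"))   # "D"
#' @export
merge_labels <- function(labels) {
  if (length(labels) == 0L) {
    stop("label multiset must be non-empty")
  }
  labels <- toupper(as.character(labels))
  unknown <- setdiff(labels, VARIANT_LABELS)
  if (length(unknown) > 0L) {
    stop("unknown annotation symbol(s): ", paste(unknown, collapse = ", "))
  }
  present <- unique(labels)
  has <- function(x) x %in% present
  informative <- any(present %in% c("A", "B", "D"))
  if (has("N") && informative) {
    return("U")                          # strong conflict
  }
  if (has("A") && has("B")) {
    return("D")
  }
  if (has("A")) return("A")
  if (has("B")) return("B")
  if (has("D")) return("D")
  if (has("N")) return("N")
  "U"
}

#' Read variant annotations from a delimited file
#'
#' Expects a header row with (at least) columns `source`, `position`, `wt`,
#' `mut` and `label`; extra columns are preserved. The delimiter is sniffed
#' from the header (tab or comma). Positions are expected in structure
#' numbering; `offset` is added to positions of files kept in transcript
#' numbering.
#'
#' @param path Path to a TSV or CSV file.
#' @param offset Integer added to every position (default 0).
#' @return A data frame of source annotations.
#' @export
read_variant_annotations <- function(path, offset = 0L) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("source", "position", "wt", "mut", "label")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  x$position <- as.integer(x$position) + as.integer(offset)
  validate_annotations(x)
  x
}

validate_annotations <- function(x) {
  if (any(x$position < 1L)) stop("positions must be >= 1")
  bad <- setdiff(unique(x$label), VARIANT_LABELS)
  if (length(bad) > 0L) {
    stop("unknown annotation symbol(s): ", paste(bad, collapse = ", "))
  }
  if (any(toupper(x$wt) == toupper(x$mut))) {
    stop("wild-type and mutant residues must differ")
  }
  invisible(x)
}

#' Merge per-source variant annotations into one record per variant
#'
#' Within each source, duplicate (position, wt, mut) rows are first
#' collapsed with [merge_labels()]; the per-source labels are then merged
#' across sources the same way. Variants whose cross-source labels contained
#' a strong N-vs-disease conflict, or U alongside several informative
#' labels, are flagged in the `conflict` column.
#'
#' @param annotations Data frame as returned by [read_variant_annotations()]
#'   (columns `source`, `position`, `wt`, `mut`, `label`); several files can
#'   be concatenated with `rbind` beforehand.
#' @param allele_frequency Optional column name holding allele frequencies
#'   to carry through (averaged over duplicate rows).
#' @return A data frame of variant records: `position`, `wt`, `mut`,
#'   `merged_label`, `n_sources`, `conflict` and optionally
#'   `allele_frequency`.
#' @export
merge_variant_sources <- function(annotations, allele_frequency = NULL) {
  validate_annotations(annotations)
  key <- paste(annotations$position, toupper(annotations$wt),
               toupper(annotations$mut), sep = ":")
  per_source <- function(idx) {
    a <- annotations[idx, , drop = FALSE]
    vapply(split(seq_len(nrow(a)), a$source),
           function(i) merge_labels(a$label[i]), character(1))
  }
  groups <- split(seq_along(key), key)
  out <- lapply(groups, function(idx) {
    src_labels <- per_source(idx)
    merged <- merge_labels(src_labels)
    conflict <- ("N" %in% src_labels &&
                   any(src_labels %in% c("A", "B", "D"))) ||
      ("U" %in% src_labels && sum(src_labels != "U") > 1L)
    rec <- data.frame(
      position = annotations$position[idx[1L]],
      wt = toupper(annotations$wt[idx[1L]]),
      mut = toupper(annotations$mut[idx[1L]]),
      merged_label = merged,
      n_sources = length(src_labels),
      conflict = conflict,
      stringsAsFactors = FALSE)
    if (!is.null(allele_frequency)) {
      rec$allele_frequency <-
        mean(annotations[[allele_frequency]][idx], na.rm = TRUE)
    }
    rec
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$position, out$wt, out$mut), , drop = FALSE]
}

#' Partition variant records by structural coverage
#'
#' Marks each record as inside or outside the resolved sequence range(s) of
#' the structure and splits the retained records into the three working
#' datasets: `s3cl` (labels N, A, B), `s2cl` (N plus all disease labels A,
#' B, D) and `svus` (label U).
#'
#' @param records Data frame of variant records with columns `position` and
#'   `merged_label` (see [merge_variant_sources()]).
#' @param resolved_ranges Two-column matrix or data frame of inclusive
#'   `(start, end)` position intervals resolved in the structure; intervals
#'   must not overlap.
#' @return An object of class `dataset_partition`: a list with elements
#'   `records` (all records with an `in_structure` flag), `s3cl`, `s2cl`,
#'   `svus` and `counts` (named vector: retained, rejected and per-label
#'   retained counts).
#' @export
filter_by_structure <- function(records, resolved_ranges) {
  ranges <- as.matrix(resolved_ranges)
  if (nrow(ranges) == 0L) stop("resolved range list must be non-empty")
  if (ncol(ranges) != 2L || any(ranges[, 1L] > ranges[, 2L])) {
    stop("resolved ranges must be (start, end) pairs with start <= end")
  }
  o <- order(ranges[, 1L])
  if (nrow(ranges) > 1L &&
      any(ranges[o, 1L][-1L] <= ranges[o, 2L][-nrow(ranges)])) {
    stop("resolved ranges must not overlap")
  }
  inside <- vapply(records$position, function(p) {
    any(p >= ranges[, 1L] & p <= ranges[, 2L])
  }, logical(1))
  records$in_structure <- inside
  kept <- records[inside, , drop = FALSE]
  lab <- kept$merged_label
  partition <- list(
    records = records,
    s3cl = kept[lab %in% c("N", "A", "B"), , drop = FALSE],
    s2cl = kept[lab %in% c("N", "A", "B", "D"), , drop = FALSE],
    svus = kept[lab == "U", , drop = FALSE],
    counts = c(total = nrow(records),
               retained = nrow(kept),
               rejected = sum(!inside),
               N = sum(lab == "N"), A = sum(lab == "A"),
               B = sum(lab == "B"), D = sum(lab == "D"),
               U = sum(lab == "U")))
  class(partition) <- "dataset_partition"
  partition
}

#' @export
print.dataset_partition <- function(x, ...) {
  cat("Variant dataset partition\n")
  cat(sprintf("  retained in structure: %d of %d (%d rejected)\n",
              x$counts[["retained"]], x$counts[["total"]],
              x$counts[["rejected"]]))
  cat(sprintf("  S3cl (N/A/B): %d  [N=%d A=%d B=%d]\n", nrow(x$s3cl),
              x$counts[["N"]], x$counts[["A"]], x$counts[["B"]]))
  cat(sprintf("  S2cl (N/disease): %d  [D-only=%d]\n", nrow(x$s2cl),
              x$counts[["D"]]))
  cat(sprintf("  SVUS (U): %d\n", nrow(x$svus)))
  invisible(x)
}
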