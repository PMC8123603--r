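# Independent brute-force oracles used to cross-check the package's
# implementations on small instances.

# Exhaustive expected outcomes of label harmonization for every non-empty
# subset of {N, A, B, D, U}, derived by hand from the merging rules
# (N-conflict first, then U elimination, then A+B -> D, then D dominated).
MERGE_TABLE <- c(
  "N" = "N", "A" = "A", "B" = "B", "D" = "D", "U" = "U",
  "A+N" = "U", "B+N" = "U", "D+N" = "U", "N+U" = "N",
  "A+B" = "D", "A+D" = "A", "A+U" = "A", "B+D" = "B", "B+U" = "B",
  "D+U" = "D",
  "A+B+N" = "U", "A+D+N" = "U", "A+N+U" = "U", "B+D+N" = "U",
  "B+N+U" = "U", "D+N+U" = "U", "A+B+D" = "D", "A+B+U" = "D",
  "A+D+U" = "A", "B+D+U" = "B",
  "A+B+D+N" = "U", "A+B+N+U" = "U", "A+D+N+U" = "U", "B+D+N+U" = "U",
  "A+B+D+U" = "D",
  "A+B+D+N+U" = "U")

merge_oracle <- function(labels) {
  key <- paste(sort(unique(labels)), collapse = "+")
  unname(MERGE_TABLE[key])
}

# Plain full-sort kNN with k-th-rank tie inclusion.
naive_knn <- function(query, training, labels, k) {
  d <- sqrt(colSums((t(training) - query)^2))
  kth <- sort(d)[k]
  nb <- which(d <= kth + 1e-12)
  sapply(c("NPDA", "NPDB", "Neutral"),
         function(cls) sum(labels[nb] == cls) / length(nb))
}

# AUROC by exhaustive positive-negative pair counting.
pair_auroc <- function(positive, scores) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Minimum atom-atom distance by explicit double loop.
naive_min_dist <- function(xyz_a, xyz_b) {
  best <- Inf
  for (i in seq_len(nrow(xyz_a))) {
    for (j in seq_len(nrow(xyz_b))) {
      best <- min(best, sqrt(sum((xyz_a[i, ] - xyz_b[j, ])^2)))
    }
  }
  best
}

# Monte-Carlo estimate of each atom's exposed-surface fraction using
# random (not deterministic-spiral) directions.
mc_exposed_fraction <- function(xyz, radii, probe, n_samples = 2000L) {
  expanded <- radii + probe
  vapply(seq_len(nrow(xyz)), function(i) {
    u <- matrix(stats::rnorm(3L * n_samples), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * expanded[i], 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, n_samples)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      dj2 <- rowSums(sweep(pts, 2L, xyz[j, ], "-")^2)
      exposed <- exposed & dj2 >= expanded[j]^2
    }
    mean(exposed)
  }, numeric(1))
}

# Permutation p-value for the one-way ANOVA F statistic.
perm_anova_p <- function(groups, n_perm = 2000L) {
  y <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  f_stat <- function(yy) {
    m <- tapply(yy, g, mean)
    ng <- tabulate(g)
    ssb <- sum(ng * (m - mean(yy))^2)
    ssw <- sum((yy - m[g])^2)
    (ssb / (length(groups) - 1)) / (ssw / (length(yy) - length(groups)))
  }
  obs <- f_stat(y)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (f_stat(sample(y)) >= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# A structure of n random single-atom glycine "residues" in a box.
random_atom_cloud <- function(n, box = 8, seed = 1L) {
  set.seed(seed)
  structure_model(data.frame(
    chain = "A", resno = seq_len(n), resid = "GLY", elety = "CA",
    elesy = "C",
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    stringsAsFactors = FALSE))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3L))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

random_probability_vectors <- function(n, seed) {
  set.seed(seed)
  x <- matrix(stats::rexp(3L * n), ncol = 3L)
  x <- x / rowSums(x)
  colnames(x) <- c("NPDA", "NPDB", "Neutral")
  x
}
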