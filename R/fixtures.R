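# Synthetic data generators: feature tables with the class-ordered
# structure the classifier assumes, toy coordinate files containing
# requested interaction motifs, genotype tables and activity data.
# Everything is seed-reproducible so the whole pipeline runs and is
# testable without any external download.

#' Specification of the synthetic feature-table generator
#'
#' Defaults encode the study conditions: class sizes 40 neutral / 52 NPDB
#' / 37 NPDA, and for every informative feature a class-ordered mean shift
#' (neutral mildest, NPDB intermediate, NPDA most extreme) of
#' `separation` population standard deviations between neutral and NPDA.
#' The informative set mirrors the features found discriminative in the
#' real data (the four predictor scores, the three distance-dependent
#' free-energy terms, accessibility, site distances, the two evolutionary
#' scores and the aromaticity change); all other features carry no signal.
#'
#' @param n_per_class Named vector `c(N=, B=, A=)` of class sizes.
#' @param separation Neutral-to-NPDA mean shift in SD units (default 1.5).
#' @param feature_sd Common class-conditional standard deviation.
#' @param informative Character vector of informative continuous features.
#' @param aromatic_prob Per-class probability of an aromaticity change,
#'   `c(N=, B=, A=)`.
#' @param activity_parameters Generating curve parameters `a1`..`a5`.
#' @param activity_noise_sd Gaussian noise added to generated
#'   probabilities.
#' @param position_range Sequence range positions are drawn from.
#' @param position_pool_frac Fraction of the total variant count used as
#'   the distinct-position pool, so some positions carry several variants
#'   and position-level hold-out differs from plain leave-one-out.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_per_class = c(N = 40L, B = 52L, A = 37L),
                         separation = 1.5,
                         feature_sd = 1,
                         informative = c("PROVEAN", "DEOGEN2",
                                         "SNPMuSiC_SSS", "PoPMuSiC",
                                         "DDW_sd", "DDW_sds", "DDW_sad",
                                         "Access", "Metal", "Carbohyd",
                                         "Disulfide", "EvolCI", "EvolLOR"),
                         aromatic_prob = c(N = 0.10, B = 0.25, A = 0.40),
                         activity_parameters = c(a1 = 5, a2 = 0.08,
                                                 a3 = -1.75, a4 = 0.009,
                                                 a5 = 1e-5),
                         activity_noise_sd = 0.05,
                         position_range = c(83L, 611L),
                         position_pool_frac = 0.6) {
  if (feature_sd <= 0) stop("feature sd must be positive")
  if (any(aromatic_prob < 0 | aromatic_prob > 1)) {
    stop("aromatic change probabilities must lie in [0, 1]")
  }
  reg <- feature_registry()
  informative <- intersect(informative,
                           reg$feature[reg$type == "continuous"])
  spec <- list(n_per_class = n_per_class, separation = separation,
               feature_sd = feature_sd, informative = informative,
               aromatic_prob = aromatic_prob,
               activity_parameters = activity_parameters,
               activity_noise_sd = activity_noise_sd,
               position_range = position_range,
               position_pool_frac = position_pool_frac)
  class(spec) <- "fixture_spec"
  spec
}

#' Generate a labelled synthetic feature table
#'
#' Continuous features are Gaussian per class with means `0`,
#' `separation/2` and `separation` (in units of `feature_sd`) for N, B
#' and A on the informative features and zero signal elsewhere. Discrete
#' features are Bernoulli draws (aromaticity change with class-ordered
#' probabilities, polarity/charge uninformative); domain indicator columns
#' are derived from the drawn positions. Positions are sampled from a
#' reduced pool so several variants share a position.
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer random seed; the same seed yields a bit-identical
#'   table.
#' @return Data frame with `position`, `wt`, `mut`, `label` (N/B/A) and
#'   the full 32-feature registry.
#' @export
make_feature_table <- function(spec = fixture_spec(), seed = 1L) {
  set.seed(seed)
  n <- spec$n_per_class
  labels <- rep(c("N", "B", "A"), c(n[["N"]], n[["B"]], n[["A"]]))
  total <- length(labels)
  class_shift <- c(N = 0, B = spec$separation / 2, A = spec$separation)
  position_seq <- seq(spec$position_range[1L], spec$position_range[2L])
  pool_n <- min(max(2L, ceiling(total * spec$position_pool_frac)),
                length(position_seq))
  pool <- sample(position_seq, pool_n)
  position <- sample(pool, total, replace = TRUE)
  wt <- sample(AA1, total, replace = TRUE)
  mut <- vapply(wt, function(w) sample(setdiff(AA1, w), 1L), "a")
  reg <- feature_registry()
  tab <- data.frame(position = position, wt = wt, mut = mut,
                    label = labels, stringsAsFactors = FALSE)
  for (f in reg$feature[reg$type == "continuous"]) {
    mu <- if (f %in% spec$informative) class_shift[labels] else 0
    tab[[f]] <- stats::rnorm(total, mean = mu, sd = spec$feature_sd)
  }
  dom <- domain_of(position)
  tab$Saposin <- as.integer(dom == "saposin")
  tab$Catalytic <- as.integer(dom == "catalytic")
  tab$Linker <- as.integer(dom == "linker")
  tab$Polarity <- stats::rbinom(total, 1L, 0.45)
  tab$Aromatic <- stats::rbinom(total, 1L, spec$aromatic_prob[labels])
  tab$Charge <- stats::rbinom(total, 1L, 0.30)
  rownames(tab) <- NULL
  tab
}

# ---- toy structures ------------------------------------------------------

ring_coords <- function(center, radius) {
  angles <- seq(0, by = 2 * pi / 6, length.out = 6L)
  cbind(center[1L] + radius * cos(angles),
        center[2L] + radius * sin(angles),
        center[3L])
}

penta_coords <- function(center, radius) {
  angles <- seq(0, by = 2 * pi / 5, length.out = 5L)
  cbind(center[1L] + radius * cos(angles),
        center[2L] + radius * sin(angles),
        center[3L])
}

atom_rows <- function(resno, resid, elety, elesy, xyz) {
  data.frame(chain = "A", resno = resno, resid = resid, elety = elety,
             elesy = elesy, x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             stringsAsFactors = FALSE)
}

# A phenylalanine with its six-ring centered at `center`, plus a CA.
phe_residue <- function(resno, center) {
  ring <- ring_coords(center, 1.39)
  rbind(atom_rows(resno, "PHE", "CA", "C",
                  matrix(center + c(0, 0, 3), 1L)),
        atom_rows(resno, "PHE",
                  c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                  rep("C", 6L), ring))
}

his_residue <- function(resno, center) {
  ring <- penta_coords(center, 1.16)
  rbind(atom_rows(resno, "HIS", "CA", "C",
                  matrix(center + c(0, 0, 3), 1L)),
        atom_rows(resno, "HIS", c("CG", "ND1", "CE1", "NE2", "CD2"),
                  c("C", "N", "C", "N", "C"), ring))
}

single_atom_residue <- function(resno, resid, elety, elesy, at, ca_off) {
  rbind(atom_rows(resno, resid, "CA", "C", matrix(at + ca_off, 1L)),
        atom_rows(resno, resid, elety, elesy, matrix(at, 1L)))
}

TOY_MOTIFS <- c("disulfide_pair", "pi_pi_pair", "cation_pi_pair",
                "amino_pi_pair", "his_pi_pair", "sulfur_pi_pair",
                "buried_cage", "exposed_residue", "zn_site", "glyco_site")

#' Build a toy structure containing requested interaction motifs
#'
#' Each motif is an idealized residue arrangement (ring atoms on regular
#' polygons) placed on its own grid cell, 40 Angstrom from every other
#' motif, with geometry inside the default detection thresholds. A motif
#' name prefixed with `"no_"` is placed 2 Angstrom beyond the
#' corresponding cut-off instead. Motif names: `disulfide_pair`,
#' `pi_pi_pair`, `cation_pi_pair`, `amino_pi_pair`, `his_pi_pair`,
#' `sulfur_pi_pair`, `buried_cage`, `exposed_residue`, `zn_site`,
#' `glyco_site`.
#'
#' @param motifs Character vector of motif names (repeats allowed).
#' @param path Optional path: when given, the structure is written there
#'   as a PDB file.
#' @return List with `model` (a [structure_model()]), `residues` (data
#'   frame mapping each motif instance to its residue numbers) and
#'   `path`.
#' @export
make_toy_structure <- function(motifs, path = NULL) {
  base <- sub("^no_", "", motifs)
  unknown <- setdiff(base, TOY_MOTIFS)
  if (length(unknown) > 0L) {
    stop("unknown motif(s): ", paste(unknown, collapse = ", "))
  }
  thr <- default_interaction_thresholds()
  atoms <- list()
  hetero <- list()
  res_map <- list()
  resno <- 0L
  for (i in seq_along(motifs)) {
    negate <- grepl("^no_", motifs[i])
    m <- base[i]
    cell <- c(((i - 1L) %% 12L) * 40, ((i - 1L) %/% 12L) * 40, 0)
    gap <- function(cutoff, inside) if (negate) cutoff + 2 else inside
    res_used <- integer(0)
    if (m == "disulfide_pair") {
      d <- gap(thr$disulfide, 2.05)
      atoms[[length(atoms) + 1L]] <- rbind(
        single_atom_residue(resno + 1L, "CYS", "SG", "S", cell, c(0, 3, 0)),
        single_atom_residue(resno + 2L, "CYS", "SG", "S", cell + c(d, 0, 0),
                            c(0, -3, 0)))
      res_used <- resno + 1:2
    } else if (m == "pi_pi_pair") {
      d <- gap(thr$pi_pi, 4.5)
      atoms[[length(atoms) + 1L]] <-
        rbind(phe_residue(resno + 1L, cell),
              phe_residue(resno + 2L, cell + c(0, 0, d)))
      res_used <- resno + 1:2
    } else if (m == "cation_pi_pair") {
      d <- gap(thr$cation_pi, 4.0)
      atoms[[length(atoms) + 1L]] <-
        rbind(phe_residue(resno + 1L, cell),
              single_atom_residue(resno + 2L, "LYS", "NZ", "N",
                                  cell + c(0, 0, d), c(0, 3, 0)))
      res_used <- resno + 1:2
    } else if (m == "amino_pi_pair") {
      d <- gap(thr$amino_pi, 4.5)
      atoms[[length(atoms) + 1L]] <-
        rbind(phe_residue(resno + 1L, cell),
              single_atom_residue(resno + 2L, "ASN", "ND2", "N",
                                  cell + c(0, 0, d), c(0, 3, 0)))
      res_used <- resno + 1:2
    } else if (m == "his_pi_pair") {
      d <- gap(thr$his_pi, 5.0)
      atoms[[length(atoms) + 1L]] <-
        rbind(his_residue(resno + 1L, cell),
              phe_residue(resno + 2L, cell + c(0, 0, d)))
      res_used <- resno + 1:2
    } else if (m == "sulfur_pi_pair") {
      d <- gap(thr$sulfur_pi, 4.5)
      atoms[[length(atoms) + 1L]] <-
        rbind(phe_residue(resno + 1L, cell),
              single_atom_residue(resno + 2L, "MET", "SD", "S",
                                  cell + c(0, 0, d), c(0, 3, 0)))
      res_used <- resno + 1:2
    } else if (m == "buried_cage") {
      atoms[[length(atoms) + 1L]] <-
        atom_rows(resno + 1L, "GLY", "CA", "C", matrix(cell, 1L))
      shell <- sphere_points(42L) * 3.0
      hetero[[length(hetero) + 1L]] <-
        atom_rows(9000L + i, "CAG", "C", "C",
                  sweep(shell, 2L, cell, "+"))
      res_used <- resno + 1L
    } else if (m == "exposed_residue") {
      atoms[[length(atoms) + 1L]] <-
        atom_rows(resno + 1L, "GLY", "CA", "C", matrix(cell, 1L))
      res_used <- resno + 1L
    } else if (m == "zn_site") {
      hetero[[length(hetero) + 1L]] <-
        atom_rows(9000L + i, "ZN", "ZN", "ZN", matrix(cell, 1L))
    } else if (m == "glyco_site") {
      atoms[[length(atoms) + 1L]] <-
        single_atom_residue(resno + 1L, "ASN", "CB", "C", cell, c(0, 2, 0))
      res_used <- resno + 1L
    }
    resno <- resno + max(1L, length(res_used))
    res_map[[i]] <- data.frame(
      motif = motifs[i],
      res_first = if (length(res_used)) res_used[1L] else NA_integer_,
      res_last = if (length(res_used)) res_used[length(res_used)]
                 else NA_integer_,
      stringsAsFactors = FALSE)
  }
  atoms <- if (length(atoms)) do.call(rbind, atoms) else
    atom_rows(integer(), character(), character(), character(),
              matrix(numeric(), 0L, 3L))
  hetero <- if (length(hetero)) do.call(rbind, hetero) else NULL
  model <- structure_model(atoms, hetero)
  if (!is.null(path)) write_structure(model, path)
  list(model = model, residues = do.call(rbind, res_map), path = path)
}

#' Generate synthetic activity data from the fitted-curve family
#'
#' Draws relative activities uniformly on [0, 100], evaluates the three
#' probability curves at the generating parameters, adds Gaussian noise
#' and clamps to [0, 1].
#'
#' @param spec A [fixture_spec()] (supplies curve parameters and noise
#'   sd), or a named parameter vector via `parameters`.
#' @param n Number of records (default 69).
#' @param seed Integer random seed.
#' @param parameters,noise_sd Optional overrides of the spec values.
#' @param clamp Clamp noisy probabilities to [0, 1] (default `TRUE`),
#'   emulating bounded probability readouts. `FALSE` keeps the raw
#'   curve-plus-noise observations, the model under which least-squares
#'   parameter recovery is unbiased; clamping censors the noise near the
#'   bounds and biases any estimator that ignores the censoring.
#' @return List with `records` (data frame `variant`, `R`, `NPDA`,
#'   `NPDB`, `Neutral`) and `true_probabilities` (noise-free curve
#'   values).
#' @export
make_activity_data <- function(spec = fixture_spec(), n = 69L, seed = 1L,
                               parameters = NULL, noise_sd = NULL,
                               clamp = TRUE) {
  if (is.null(parameters)) parameters <- spec$activity_parameters
  if (is.null(noise_sd)) noise_sd <- spec$activity_noise_sd
  set.seed(seed)
  R <- stats::runif(n, 0, 100)
  truth <- activity_curves(R, parameters)
  noisy <- truth + matrix(stats::rnorm(3L * n, 0, noise_sd), n, 3L)
  if (clamp) noisy <- pmin(pmax(noisy, 0), 1)
  records <- data.frame(variant = sprintf("V%03d", seq_len(n)), R = R,
                        stringsAsFactors = FALSE)
  records <- cbind(records, as.data.frame(noisy))
  list(records = records, true_probabilities = truth)
}

#' Generate a synthetic genotype table
#'
#' Pairs variants of a feature table into genotypes: homozygous, compound
#' heterozygous and single-allele (one wild-type allele) cases in roughly
#' equal parts. The long format has one row per allele variant; wild-type
#' alleles have no rows.
#'
#' @param table Feature table with `position`, `wt`, `mut` columns.
#' @param n_genotypes Number of genotypes to build.
#' @param seed Integer random seed.
#' @return Data frame `genotype_id`, `allele` (1 or 2), `position`, `wt`,
#'   `mut`.
#' @export
make_genotype_table <- function(table, n_genotypes = 20L, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (g in seq_len(n_genotypes)) {
    kind <- sample(c("hom", "het_compound", "het_wt"), 1L)
    pick <- function() table[sample(nrow(table), 1L), c("position", "wt",
                                                        "mut")]
    v1 <- pick()
    alleles <- switch(kind,
      hom = list(v1, v1),
      het_compound = list(v1, pick()),
      het_wt = list(v1, NULL))
    for (a in 1:2) {
      v <- alleles[[a]]
      if (is.null(v)) next
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(genotype_id = sprintf("G%03d", g), allele = a),
              v)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict classes for a genotype table
#'
#' @param genotypes Long-format genotype table as from
#'   [make_genotype_table()]; genotypes listed with only one allele are
#'   treated as carrying a wild-type second allele.
#' @param table Feature table with `position`, `wt`, `mut` and the model's
#'   feature columns.
#' @param model A `zoom_model`.
#' @return Data frame with one row per genotype: probabilities and class.
#' @export
predict_genotypes <- function(genotypes, table, model) {
  key <- function(d) paste(d$position, d$wt, d$mut, sep = ":")
  tab_key <- key(table)
  out <- lapply(split(genotypes, genotypes$genotype_id), function(g) {
    allele_rows <- function(a) {
      rows <- g[g$allele == a, , drop = FALSE]
      if (nrow(rows) == 0L) return(NULL)
      hit <- match(key(rows), tab_key)
      if (any(is.na(hit))) {
        stop("genotype ", g$genotype_id[1L],
             " references variants absent from the feature table")
      }
      table[hit, , drop = FALSE]
    }
    gp <- genotype_predict(allele_rows(1L), allele_rows(2L), model)
    data.frame(genotype_id = g$genotype_id[1L],
               NPDA = gp$probabilities[["NPDA"]],
               NPDB = gp$probabilities[["NPDB"]],
               Neutral = gp$probabilities[["Neutral"]],
               class = gp$class, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
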