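# Structure handling: coordinate model, residue-residue interaction
# detection (disulfide and aromatic-involving types), solvent
# accessibility, distances to functional sites and domain assignment.

SMPD1_DOMAINS <- data.frame(
  domain = c("saposin", "linker", "catalytic"),
  start = c(83L, 166L, 199L),
  end = c(165L, 198L, 611L),
  stringsAsFactors = FALSE)

# Aromatic ring atom sets. Trp carries both its five- and six-membered
# rings; centroid distances to Trp take the minimum over the two.
RING_ATOMS <- list(
  PHE = list(six = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(six = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(five = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(five = c("CG", "CD1", "CD2", "NE1", "CE2"),
             six = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

#' Construct a structure model from atom tables
#'
#' A `structure_model` is the light-weight coordinate container used by all
#' structural operations: a data frame of polymer atoms (`chain`, `resno`,
#' `resid` 3-letter type, `elety` atom name, `elesy` element, `x`, `y`,
#' `z`) and an analogous data frame of hetero atoms (ions, glycans, ...).
#'
#' @param atoms Data frame of polymer atoms.
#' @param hetero Optional data frame of hetero atoms (same columns).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, hetero = NULL) {
  required <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0L) {
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite")
  }
  if (is.null(hetero)) {
    hetero <- atoms[0L, required, drop = FALSE]
  }
  out <- list(atoms = atoms[, required, drop = FALSE],
              hetero = hetero[, required, drop = FALSE])
  class(out) <- "structure_model"
  out
}

#' Read a protein structure from a PDB or mmCIF file
#'
#' Thin wrapper around [bio3d::read.pdb()] / [bio3d::read.cif()]. Only the
#' first model is used; if `chain` is `NULL` the first chain encountered is
#' kept.
#'
#' @param path Path to a `.pdb` or `.cif` coordinate file.
#' @param chain Chain identifier to keep (default: first chain).
#' @return A [structure_model()].
#' @export
read_structure <- function(path, chain = NULL) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  at <- pdb$atom
  if (is.null(chain)) {
    chain <- at$chain[at$type == "ATOM"][1L]
    if (is.na(chain)) chain <- at$chain[1L]
  }
  at <- at[at$chain == chain | at$type == "HETATM", , drop = FALSE]
  cols <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                     elety = at$elety, elesy = at$elesy,
                     x = at$x, y = at$y, z = at$z,
                     stringsAsFactors = FALSE)
  is_het <- at$type == "HETATM" | !(at$resid %in% AA3)
  structure_model(cols[!is_het, , drop = FALSE],
                  cols[is_het, , drop = FALSE])
}

#' Write a structure model to a PDB file
#'
#' @param model A [structure_model()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_structure <- function(model, path) {
  all_at <- rbind(model$atoms, model$hetero)
  n_poly <- nrow(model$atoms)
  xyz <- as.vector(t(as.matrix(all_at[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = c(rep("ATOM", n_poly), rep("HETATM", nrow(all_at) - n_poly)),
    resno = all_at$resno, resid = all_at$resid, chain = all_at$chain,
    eleno = seq_len(nrow(all_at)), elety = all_at$elety,
    elesy = all_at$elesy)
  invisible(path)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms in %d residues, %d hetero atoms\n",
              nrow(x$atoms), length(unique(x$atoms$resno)),
              nrow(x$hetero)))
  invisible(x)
}

#' Apply a rigid-body transform to a structure model
#'
#' @param model A [structure_model()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @return The transformed model.
#' @export
transform_structure <- function(model, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  tf <- function(df) {
    if (nrow(df) == 0L) return(df)
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rotation)
    df$x <- xyz[, 1L] + translation[1L]
    df$y <- xyz[, 2L] + translation[2L]
    df$z <- xyz[, 3L] + translation[3L]
    df
  }
  model$atoms <- tf(model$atoms)
  model$hetero <- tf(model$hetero)
  model
}

coords <- function(df) {
  as.matrix(df[, c("x", "y", "z"), drop = FALSE])
}

cross_dist <- function(a, b) {
  # Euclidean distances between rows of two coordinate matrices.
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))   # guard tiny negatives from cancellation
}

empty_catalog <- function() {
  data.frame(type = character(), res_a = integer(), res_b = integer(),
             resid_a = character(), resid_b = character(),
             distance = numeric(), stringsAsFactors = FALSE)
}

#' Default geometric thresholds for interaction detection
#'
#' Distance cut-offs (Angstrom) defining each interaction type:
#' disulfide SG-SG, pi-pi ring-centroid to ring-centroid, cation-pi
#' cationic reference atom (Lys NZ, Arg CZ) to centroid, amino-pi amide
#' nitrogen (Asn ND2, Gln NE2) to centroid, His-pi centroid to centroid,
#' and sulfur-pi sulfur atom (Met SD, Cys SG) to centroid.
#'
#' @return Named list of cut-offs.
#' @export
default_interaction_thresholds <- function() {
  list(disulfide = 2.3, pi_pi = 7.0, cation_pi = 6.0,
       amino_pi = 6.0, his_pi = 7.0, sulfur_pi = 5.3)
}

#' Read / write interaction threshold configuration
#'
#' Plain `key: value` YAML-style files; unknown keys are rejected.
#'
#' @param path File path.
#' @param thresholds Named list as from [default_interaction_thresholds()].
#' @return `read_interaction_thresholds`: a named list merged over the
#'   defaults.
#' @export
read_interaction_thresholds <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  parts <- strsplit(lines, ":")
  keys <- trimws(vapply(parts, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(parts, `[`, "", 2L)))
  defaults <- default_interaction_thresholds()
  bad <- setdiff(keys, names(defaults))
  if (length(bad) > 0L) {
    stop("unknown threshold key(s): ", paste(bad, collapse = ", "))
  }
  defaults[keys] <- vals
  defaults
}

#' @rdname read_interaction_thresholds
#' @export
write_interaction_thresholds <- function(thresholds, path) {
  writeLines(sprintf("%s: %s", names(thresholds),
                     unlist(thresholds)), path)
  invisible(path)
}

#' Detect disulfide bridges
#'
#' Finds Cys pairs whose SG-SG distance is at most `max_ss_dist`, pairing
#' greedily by increasing distance so each Cys joins at most one bridge.
#' Cys residues lacking an SG atom are skipped with a warning.
#'
#' @param model A [structure_model()].
#' @param max_ss_dist SG-SG cut-off in Angstrom (default 2.3).
#' @return An interaction catalog data frame (`type`, `res_a`, `res_b`,
#'   `resid_a`, `resid_b`, `distance`).
#' @export
find_disulfides <- function(model, max_ss_dist = 2.3) {
  cys <- model$atoms[model$atoms$resid == "CYS", , drop = FALSE]
  cys_res <- unique(cys$resno)
  sg <- cys[cys$elety == "SG", , drop = FALSE]
  no_sg <- setdiff(cys_res, sg$resno)
  for (r in no_sg) {
    warning("Cys ", r, " has no SG atom; skipped", call. = FALSE)
  }
  if (nrow(sg) < 2L) return(empty_catalog())
  d <- cross_dist(coords(sg), coords(sg))
  pairs <- which(upper.tri(d) & d <= max_ss_dist, arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(empty_catalog())
  ord <- order(d[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used <- integer(0)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ra <- sg$resno[pairs[i, 1L]]
    rb <- sg$resno[pairs[i, 2L]]
    if (ra %in% used || rb %in% used || ra == rb) next
    keep[i] <- TRUE
    used <- c(used, ra, rb)
  }
  pairs <- pairs[keep, , drop = FALSE]
  out <- data.frame(
    type = "disulfide",
    res_a = pmin(sg$resno[pairs[, 1L]], sg$resno[pairs[, 2L]]),
    res_b = pmax(sg$resno[pairs[, 1L]], sg$resno[pairs[, 2L]]),
    resid_a = "CYS", resid_b = "CYS",
    distance = d[pairs],
    stringsAsFactors = FALSE)
  out[order(out$res_a), , drop = FALSE]
}

ring_centroids <- function(model) {
  arom <- model$atoms[model$atoms$resid %in% names(RING_ATOMS), ,
                      drop = FALSE]
  out <- list()
  for (r in unique(arom$resno)) {
    res <- arom[arom$resno == r, , drop = FALSE]
    rings <- RING_ATOMS[[res$resid[1L]]]
    for (ring_name in names(rings)) {
      sel <- res[res$elety %in% rings[[ring_name]], , drop = FALSE]
      if (nrow(sel) < length(rings[[ring_name]])) {
        warning(res$resid[1L], " ", r, " misses ring atoms; skipped",
                call. = FALSE)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        resno = r, resid = res$resid[1L], ring = ring_name,
        x = mean(sel$x), y = mean(sel$y), z = mean(sel$z),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(resno = integer(), resid = character(),
                      ring = character(), x = numeric(), y = numeric(),
                      z = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Minimum centroid distance between two residues given the centroid table.
min_centroid_dist <- function(cent, res_a, res_b) {
  ca <- cent[cent$resno == res_a, , drop = FALSE]
  cb <- cent[cent$resno == res_b, , drop = FALSE]
  min(cross_dist(coords(ca), coords(cb)))
}

# Reference atoms of the non-ring partner per interaction type.
partner_atoms <- function(model, type) {
  at <- model$atoms
  switch(type,
    cation_pi = at[(at$resid == "LYS" & at$elety == "NZ") |
                     (at$resid == "ARG" & at$elety == "CZ"), , drop = FALSE],
    amino_pi = at[(at$resid == "ASN" & at$elety == "ND2") |
                    (at$resid == "GLN" & at$elety == "NE2"), , drop = FALSE],
    sulfur_pi = at[(at$resid == "MET" & at$elety == "SD") |
                     (at$resid == "CYS" & at$elety == "SG"), , drop = FALSE])
}

#' Detect aromatic-involving residue interactions
#'
#' Enumerates five interaction types by distance criteria:
#' * `pi_pi`: ring centroids of two residues among Phe/Tyr/Trp;
#' * `cation_pi`: Arg (CZ) or Lys (NZ) to an aromatic centroid
#'   (Phe/Tyr/Trp/His); His acts only as the pi partner, never as cation;
#' * `amino_pi`: Asn (ND2) or Gln (NE2) amide nitrogen to an aromatic
#'   centroid (Phe/Tyr/Trp/His);
#' * `his_pi`: His ring centroid to an aromatic centroid (Phe/Tyr/Trp/His);
#' * `sulfur_pi`: Met SD or Cys SG sulfur to an aromatic centroid
#'   (Phe/Tyr/Trp/His).
#'
#' Trp distances use the minimum over its five- and six-membered ring
#' centroids. Each unordered residue pair appears at most once per type.
#'
#' @param model A [structure_model()].
#' @param thresholds Named list of distance cut-offs, see
#'   [default_interaction_thresholds()].
#' @return An interaction catalog data frame.
#' @export
find_aromatic_interactions <- function(model,
                                       thresholds =
                                         default_interaction_thresholds()) {
  cent <- ring_centroids(model)
  rows <- list()
  add <- function(type, ra, rb, ta, tb, d) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, res_a = min(ra, rb), res_b = max(ra, rb),
      resid_a = if (ra <= rb) ta else tb,
      resid_b = if (ra <= rb) tb else ta,
      distance = d, stringsAsFactors = FALSE)
  }
  arom_res <- unique(cent[, c("resno", "resid")])
  # pi-pi among Phe/Tyr/Trp
  ring3 <- arom_res[arom_res$resid %in% c("PHE", "TYR", "TRP"), ,
                    drop = FALSE]
  if (nrow(ring3) >= 2L) {
    for (i in seq_len(nrow(ring3) - 1L)) {
      for (j in seq(i + 1L, nrow(ring3))) {
        d <- min_centroid_dist(cent, ring3$resno[i], ring3$resno[j])
        if (d <= thresholds$pi_pi) {
          add("pi_pi", ring3$resno[i], ring3$resno[j],
              ring3$resid[i], ring3$resid[j], d)
        }
      }
    }
  }
  # His-pi: His vs any aromatic (incl. another His, counted once)
  his <- arom_res[arom_res$resid == "HIS", , drop = FALSE]
  if (nrow(his) > 0L) {
    seen <- character(0)
    for (i in seq_len(nrow(his))) {
      for (j in seq_len(nrow(arom_res))) {
        ra <- his$resno[i]; rb <- arom_res$resno[j]
        if (ra == rb) next
        key <- paste(min(ra, rb), max(ra, rb))
        if (key %in% seen) next
        d <- min_centroid_dist(cent, ra, rb)
        if (d <= thresholds$his_pi) {
          add("his_pi", ra, rb, "HIS", arom_res$resid[j], d)
          seen <- c(seen, key)
        }
      }
    }
  }
  # atom-to-centroid types
  for (type in c("cation_pi", "amino_pi", "sulfur_pi")) {
    donors <- partner_atoms(model, type)
    if (nrow(donors) == 0L || nrow(cent) == 0L) next
    d_mat <- cross_dist(coords(donors), coords(cent))
    for (i in seq_len(nrow(donors))) {
      for (r in unique(cent$resno)) {
        if (donors$resno[i] == r) next
        d <- min(d_mat[i, cent$resno == r])
        if (d <= thresholds[[type]]) {
          add(type, donors$resno[i], r, donors$resid[i],
              cent$resid[cent$resno == r][1L], d)
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty_catalog())
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("type", "res_a", "res_b")]), , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$type, out$res_a, out$res_b), , drop = FALSE]
}

#' Write / read an interaction catalog as tab-separated text
#'
#' @param catalog Catalog data frame from [find_disulfides()] or
#'   [find_aromatic_interactions()].
#' @param path File path.
#' @export
write_interaction_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_interaction_catalog
#' @export
read_interaction_catalog <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

vdw_radius <- function(elesy) {
  r <- VDW_RADII[toupper(elesy)]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Orthonormal frame aligned with the structure's principal axes, with
# signs fixed against the first off-centroid atom so the frame co-rotates
# with any rigid-body transform. Sampling directions expressed in this
# frame make the surface estimate exactly invariant under rotation.
canonical_frame <- function(xyz) {
  if (nrow(xyz) < 3L) return(diag(3))
  centroid <- colMeans(xyz)
  v <- eigen(stats::cov(xyz), symmetric = TRUE)$vectors
  centered <- sweep(xyz, 2L, centroid)
  for (j in 1:3) {
    for (i in seq_len(nrow(centered))) {
      s <- sum(v[, j] * centered[i, ])
      if (abs(s) > 1e-8) {
        if (s < 0) v[, j] <- -v[, j]
        break
      }
    }
  }
  v
}

#' Per-residue solvent accessibility (Shrake-Rupley)
#'
#' Numerical solvent-accessible surface area by sphere-point sampling: each
#' atom is expanded by the probe radius, sampled with a deterministic
#' quasi-uniform point set, and the fraction of points outside all
#' neighbouring expanded spheres contributes to the atom's area. Relative
#' accessibility divides the summed residue area by the residue type's
#' Gly-X-Gly extended-tripeptide maximum and clamps to [0, 1].
#'
#' @param model A [structure_model()]; hetero atoms occlude but are not
#'   reported.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param n_sphere_points Sample points per atom (default 960; minimum 12).
#' @return Data frame with `resno`, `resid`, `asa` (Angstrom squared) and
#'   `rel_acc` (fraction in [0, 1]).
#' @export
solvent_accessibility <- function(model, probe_radius = 1.4,
                                  n_sphere_points = 960L) {
  if (probe_radius <= 0) stop("probe radius must be positive")
  if (n_sphere_points < 12L) stop("need at least 12 sphere points")
  all_at <- rbind(model$atoms, model$hetero)
  xyz <- coords(all_at)
  radii <- vdw_radius(all_at$elesy) + probe_radius
  n_poly <- nrow(model$atoms)
  pts <- sphere_points(n_sphere_points) %*% t(canonical_frame(xyz))
  asa_atom <- numeric(n_poly)
  for (i in seq_len(n_poly)) {
    ri <- radii[i]
    d_to_i <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d_to_i < ri + radii & seq_along(radii) != i)
    surface <- pts * ri + rep(xyz[i, ], each = n_sphere_points)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- colSums((t(surface[exposed, , drop = FALSE]) - xyz[j, ])^2)
      exposed[exposed] <- dj >= radii[j]^2
    }
    asa_atom[i] <- mean(exposed) * 4 * pi * ri^2
  }
  res_key <- paste(model$atoms$chain, model$atoms$resno)
  agg <- rowsum(asa_atom, res_key, reorder = FALSE)
  first <- !duplicated(res_key)
  resid <- model$atoms$resid[first]
  max_asa <- AA_MAX_ASA[aa_three_to_one(resid)]
  data.frame(
    resno = model$atoms$resno[first],
    resid = resid,
    asa = as.vector(agg),
    rel_acc = pmin(1, pmax(0, as.vector(agg) / unname(max_asa))),
    stringsAsFactors = FALSE)
}

#' Distances from a variant residue to functional sites
#'
#' Minimum atom-to-atom distance from the residue at `variant_position` to
#' the nearest of each requested site set: Zn-binding sites, glycosylation
#' (carbohydrate) sites, and disulfide-bonded cysteines. An empty or `NULL`
#' site set yields `NA` (missing), not zero.
#'
#' @param model A [structure_model()].
#' @param variant_position Residue number of the variant.
#' @param zn_sites Residue numbers of Zn hetero groups, or `"auto"` to use
#'   every hetero atom with residue type `ZN`.
#' @param glyco_sites Residue numbers of glycosylated residues.
#' @param disulfide_cys Residue numbers of disulfide-bonded cysteines.
#' @return Named numeric vector `c(dist_metal, dist_carbohyd,
#'   dist_disulfide)` in Angstrom.
#' @export
site_distances <- function(model, variant_position, zn_sites = "auto",
                           glyco_sites = NULL, disulfide_cys = NULL) {
  res_at <- model$atoms[model$atoms$resno == variant_position, ,
                        drop = FALSE]
  if (nrow(res_at) == 0L) {
    stop("no atoms at position ", variant_position)
  }
  res_xyz <- coords(res_at)
  min_dist_to <- function(site_at) {
    if (nrow(site_at) == 0L) return(NA_real_)
    min(cross_dist(res_xyz, coords(site_at)))
  }
  zn_at <- if (identical(zn_sites, "auto")) {
    model$hetero[model$hetero$resid == "ZN", , drop = FALSE]
  } else if (length(zn_sites) > 0L) {
    model$hetero[model$hetero$resno %in% zn_sites, , drop = FALSE]
  } else {
    model$hetero[0L, , drop = FALSE]
  }
  poly_at <- function(positions) {
    if (length(positions) == 0L) return(model$atoms[0L, , drop = FALSE])
    model$atoms[model$atoms$resno %in% positions, , drop = FALSE]
  }
  c(dist_metal = min_dist_to(zn_at),
    dist_carbohyd = min_dist_to(poly_at(glyco_sites)),
    dist_disulfide = min_dist_to(poly_at(disulfide_cys)))
}

#' Domain membership of a sequence position
#'
#' SMPD1 domain ranges in structure numbering: saposin 83-165, Pro-rich
#' linker 166-198, catalytic 199-611; anything else is `none`.
#'
#' @param position Integer vector of residue positions (>= 1).
#' @return Character vector in `c("saposin", "linker", "catalytic",
#'   "none")`.
#' @examples
#' domain_of(c(83, 198, 612))
#' @export
domain_of <- function(position) {
  if (any(position < 1L)) stop("positions must be >= 1")
  out <- rep("none", length(position))
  for (i in seq_len(nrow(SMPD1_DOMAINS))) {
    hit <- position >= SMPD1_DOMAINS$start[i] &
      position <= SMPD1_DOMAINS$end[i]
    out[hit] <- SMPD1_DOMAINS$domain[i]
  }
  out
}
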