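# Structural residue classification: contacts, exposure, interface, hemes.

# Element-based van der Waals radii (Angstrom) for heavy atoms.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                FE = 1.80, CU = 1.40, MG = 1.73, ZN = 1.39)
.vdw_default <- 1.70

# Theoretical maximum accessible surface areas per residue type (Angstrom^2),
# used to normalise ASA into relative exposure. Values from the commonly
# used theoretical (Gly-X-Gly) scale.
.max_asa <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)
.max_asa_default <- 200

.heme_resnames <- c("HEM", "HEA", "HEC", "HEB")
.water_resnames <- c("HOH", "WAT", "DOD", "H2O")

res_key <- function(chain, resno, insert) {
  ins <- ifelse(is.na(insert) | insert == "", "", insert)
  paste0(chain, ":", resno, ins)
}

#' Parse a multi-chain structure from a PDB file
#'
#' Reads ATOM/HETATM records, drops hydrogens and waters, resolves alternate
#' locations to the highest-occupancy conformer (ties broken by record
#' order), and routes hetero residues (hemes, lipids, metals) into a
#' separate hetero-group table so they can never count as polypeptide
#' contact partners.
#'
#' @param path Path to a PDB file.
#' @param encoding Named character vector mapping chain id to genome of
#'   origin, values `"mt"` or `"nuclear"`. Every retained chain must appear.
#' @param chain_filter Optional character vector of chain ids to keep
#'   (default: all chains present in `encoding`).
#' @return An object of class `complex_structure`: list with `atoms` (data
#'   frame of polymer heavy atoms: chain, resno, insert, resid, elety,
#'   x, y, z, key), `residues` (one row per residue, in file order),
#'   `hetero` (data frame of hetero-group heavy atoms with `group` and
#'   `is_heme`), and `encoding`.
#' @export
parse_structure <- function(path, encoding, chain_filter = NULL) {
  stopifnot(file.exists(path))
  if (is.null(names(encoding)) || any(names(encoding) == ""))
    stop("`encoding` must be a named chain -> genome vector")
  if (!all(encoding %in% c("mt", "nuclear")))
    stop("encoding values must be 'mt' or 'nuclear'")
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  # drop hydrogens/deuterium by element symbol (fall back to atom-name guess)
  elesy <- toupper(trimws(at$elesy))
  noelem <- is.na(elesy) | elesy == ""
  if (any(noelem)) {
    guess <- toupper(substr(gsub("^[0-9]", "", trimws(at$elety[noelem])), 1, 1))
    elesy[noelem] <- guess
  }
  at <- at[!(elesy %in% c("H", "D")), , drop = FALSE]
  elesy <- elesy[!(elesy %in% c("H", "D"))]
  at$elesy2 <- elesy
  at <- at[!(at$resid %in% .water_resnames), , drop = FALSE]
  # altloc: keep highest occupancy per (chain, resno, insert, elety)
  alt <- ifelse(is.na(at$alt) | at$alt == "", "", at$alt)
  if (any(alt != "")) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    akey <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
                  at$elety, sep = "|")
    ord <- order(akey, -occ, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno,
                               ifelse(is.na(at$insert), "", at$insert),
                               at$elety, sep = "|")), , drop = FALSE]
    at <- at[order(as.numeric(rownames(at))), , drop = FALSE]
  }
  is_het <- at$type == "HETATM"
  poly <- at[!is_het, , drop = FALSE]
  het <- at[is_het, , drop = FALSE]

  chains_present <- unique(poly$chain)
  keep <- if (is.null(chain_filter)) chains_present else chain_filter
  missing_enc <- setdiff(keep, names(encoding))
  if (length(missing_enc))
    stop("chains missing from encoding: ", paste(missing_enc, collapse = ", "))
  missing_ch <- setdiff(keep, chains_present)
  if (length(missing_ch))
    stop("chains not present in structure: ", paste(missing_ch, collapse = ", "))
  poly <- poly[poly$chain %in% keep, , drop = FALSE]
  if (nrow(poly) == 0L) stop("no polymer atoms left after filtering")

  atoms <- data.frame(
    chain = poly$chain, resno = poly$resno,
    insert = ifelse(is.na(poly$insert), "", poly$insert),
    resid = poly$resid, elety = trimws(poly$elety),
    elesy = poly$elesy2,
    x = poly$x, y = poly$y, z = poly$z,
    stringsAsFactors = FALSE
  )
  atoms$key <- res_key(atoms$chain, atoms$resno, atoms$insert)
  for (ch in keep) {
    if (!any(atoms$chain == ch)) stop("chain ", ch, " has no atoms")
  }
  residues <- atoms[!duplicated(atoms$key),
                    c("chain", "resno", "insert", "resid", "key")]
  rownames(residues) <- NULL

  hetero <- if (nrow(het)) data.frame(
    group = paste0(het$resid, "_", het$chain, "_", het$resno),
    resid = het$resid, chain = het$chain, resno = het$resno,
    elety = trimws(het$elety), elesy = het$elesy2,
    x = het$x, y = het$y, z = het$z,
    is_heme = het$resid %in% .heme_resnames,
    stringsAsFactors = FALSE
  ) else data.frame(group = character(), resid = character(),
                    chain = character(), resno = integer(),
                    elety = character(), elesy = character(),
                    x = numeric(), y = numeric(), z = numeric(),
                    is_heme = logical())

  structure(list(atoms = atoms, residues = residues, hetero = hetero,
                 encoding = encoding[keep]),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("complex_structure:", length(unique(x$atoms$chain)), "chains,",
      nrow(x$residues), "residues,", nrow(x$atoms), "heavy atoms,",
      length(unique(x$hetero$group)), "hetero groups\n")
  invisible(x)
}

#' Minimal heavy-atom distance between two residues
#'
#' The distance between two residues is defined as the minimum Euclidean
#' distance over all pairs of heavy atoms, one from each residue.
#'
#' @param xyz1,xyz2 Numeric matrices (n x 3) of heavy-atom coordinates.
#' @return Distance in Angstrom.
#' @export
residue_min_distance <- function(xyz1, xyz2) {
  xyz1 <- rbind(xyz1); xyz2 <- rbind(xyz2)
  if (nrow(xyz1) == 0L || nrow(xyz2) == 0L)
    stop("residue with no heavy atoms")
  d2 <- outer(rowSums(xyz1^2), rowSums(xyz2^2), "+") -
    2 * tcrossprod(xyz1, xyz2)
  sqrt(max(0, min(d2)))
}

residue_xyz <- function(cx, key) {
  a <- cx$atoms[cx$atoms$key == key, c("x", "y", "z")]
  as.matrix(a)
}

#' Inter-chain contact partners for every residue
#'
#' A residue of chain X has partner chain Y (Y != X) when some heavy atom of
#' a residue of Y lies closer than `cutoff` to one of its heavy atoms.
#' Hetero groups are never partners: contacts are between polypeptides only.
#'
#' @param cx A `complex_structure`.
#' @param cutoff Contact distance cutoff in Angstrom; the default 4.0
#'   corresponds to the upper limit for weak interactions.
#' @return Named list mapping residue key to a character vector of partner
#'   chain ids (possibly empty).
#' @export
build_contact_labels <- function(cx, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  at <- cx$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  partners <- setNames(vector("list", nrow(cx$residues)), cx$residues$key)
  for (k in seq_along(partners)) partners[[k]] <- character()
  chains <- unique(at$chain)
  cut2 <- cutoff^2
  for (i in seq_along(chains)) {
    for (j in seq_along(chains)) {
      if (i >= j) next
      ci <- chains[i]; cj <- chains[j]
      ai <- which(at$chain == ci); aj <- which(at$chain == cj)
      # coarse bounding-box prefilter
      if (min(xyz[ai, 1]) - max(xyz[aj, 1]) > cutoff ||
          min(xyz[aj, 1]) - max(xyz[ai, 1]) > cutoff) next
      d2 <- outer(rowSums(xyz[ai, , drop = FALSE]^2),
                  rowSums(xyz[aj, , drop = FALSE]^2), "+") -
        2 * tcrossprod(xyz[ai, , drop = FALSE], xyz[aj, , drop = FALSE])
      hit <- which(d2 < cut2, arr.ind = TRUE)
      if (nrow(hit)) {
        ki <- unique(at$key[ai[hit[, 1]]])
        kj <- unique(at$key[aj[hit[, 2]]])
        for (k in ki) partners[[k]] <- union(partners[[k]], cj)
        for (k in kj) partners[[k]] <- union(partners[[k]], ci)
      }
    }
  }
  partners
}

# Deterministic near-uniform unit sphere points (golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(elesy) {
  r <- .vdw_radii[elesy]
  r[is.na(r)] <- .vdw_default
  unname(r)
}

# Shrake-Rupley ASA for a set of atoms; returns per-atom areas.
shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 960) {
  if (probe <= 0) stop("probe radius must be positive")
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  ext <- radii + probe
  area <- numeric(n)
  # neighbour lists via squared distances (adequate at these problem sizes)
  for (i in seq_len(n)) {
    ri <- ext[i]
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (ri + ext)^2 & seq_len(n) != i)
    test <- pts * ri + rep(xyz[i, ], each = n_points)
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dj2 <- colSums((t(test[free, , drop = FALSE]) - xyz[j, ])^2)
        free[free] <- dj2 > ext[j]^2
      }
      frac <- sum(free) / n_points
    } else frac <- 1
    area[i] <- 4 * pi * ri^2 * frac
  }
  area
}

#' Per-residue solvent accessible surface area
#'
#' Shrake-Rupley ASA with a rolling probe, summed over each residue's heavy
#' atoms. Call once on an isolated chain (ASA1) and once on the full
#' complex (ASA2); with the same point set, ASA2 <= ASA1 holds exactly for
#' chain residues, so delta-ASA is never negative.
#'
#' @param cx A `complex_structure`.
#' @param chains Chains whose atoms form the evaluation unit (default: all).
#' @param probe_radius Probe radius in Angstrom (water: 1.4).
#' @param sphere_points Number of test points per atom (default 960).
#' @return Named numeric vector: residue key -> ASA in Angstrom^2, covering
#'   residues of `chains`.
#' @export
compute_residue_asa <- function(cx, chains = NULL, probe_radius = 1.4,
                                sphere_points = 960) {
  at <- cx$atoms
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms in evaluation unit")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  area <- shrake_rupley(xyz, atom_radii(at$elesy), probe = probe_radius,
                        n_points = sphere_points)
  tapply(area, at$key, sum)[unique(at$key)]
}

#' Classify residues into the four structural site classes
#'
#' Applies the partitioning rule: residues with any inter-chain contact are
#' `MT_NU_CONTACT` when at least one partner chain is nuclear-encoded, else
#' `MT_MT_CONTACT`; noncontact residues are `EXPOSED_NONCONTACT` or
#' `BURIED_NONCONTACT` by relative solvent exposure in the complex. Exposed
#' noncontact residues additionally carry an `interface` flag: `TRUE` when
#' their accessible area shrinks upon complex formation (delta-ASA > 0).
#'
#' @param cx A `complex_structure`.
#' @param asa1 Named vector of isolated-subunit ASA (per residue key).
#' @param asa2 Named vector of in-complex ASA.
#' @param partners Contact map from [build_contact_labels()].
#' @param chains Chains to classify (default: all mt-encoded chains).
#' @param exposure_threshold Relative in-complex ASA below which a
#'   noncontact residue is considered buried (default 0.05).
#' @param delta_tol Tolerance for numerically negative delta-ASA.
#' @return Data frame (class `site_labels`): chain, resno, insert, resid,
#'   key, site_class, interface (NA outside EXPOSED_NONCONTACT),
#'   asa_isolated, asa_complex, delta_asa, rel_asa, partners
#'   (comma-separated).
#' @export
classify_sites <- function(cx, asa1, asa2, partners, chains = NULL,
                           exposure_threshold = 0.05, delta_tol = 1e-6) {
  if (is.null(chains)) chains <- names(cx$encoding)[cx$encoding == "mt"]
  res <- cx$residues[cx$residues$chain %in% chains, , drop = FALSE]
  miss <- setdiff(res$key, intersect(names(asa1), names(asa2)))
  if (length(miss))
    stop("residues missing ASA values: ", paste(head(miss, 5), collapse = ", "))
  a1 <- as.numeric(asa1[res$key]); a2 <- as.numeric(asa2[res$key])
  dasa <- a1 - a2
  if (any(dasa < -delta_tol))
    stop("negative delta-ASA beyond tolerance for ",
         res$key[which.min(dasa)])
  dasa <- pmax(dasa, 0)
  ref <- .max_asa[res$resid]
  ref[is.na(ref)] <- .max_asa_default
  rel <- a2 / ref
  p <- partners[res$key]
  has_contact <- vapply(p, function(z) length(z) > 0L, logical(1))
  nuc_partner <- vapply(p, function(z)
    any(cx$encoding[z] == "nuclear"), logical(1))
  cls <- ifelse(has_contact,
                ifelse(nuc_partner, "MT_NU_CONTACT", "MT_MT_CONTACT"),
                ifelse(rel >= exposure_threshold,
                       "EXPOSED_NONCONTACT", "BURIED_NONCONTACT"))
  iface <- ifelse(cls == "EXPOSED_NONCONTACT", dasa > 0, NA)
  out <- data.frame(
    chain = res$chain, resno = res$resno, insert = res$insert,
    resid = res$resid, key = res$key, site_class = cls,
    interface = iface, asa_isolated = a1, asa_complex = a2,
    delta_asa = dasa, rel_asa = rel,
    partners = vapply(p, paste, collapse = ",", FUN.VALUE = character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("site_labels", "data.frame")
  out
}

#' Distance from each residue of a chain to the nearest heme group
#'
#' @param cx A `complex_structure` whose hetero table contains at least one
#'   heme group.
#' @param chain_id Chain whose residues are measured.
#' @return Named numeric vector: residue key -> minimal heavy-atom distance
#'   (Angstrom) to any heme group.
#' @export
heme_min_distances <- function(cx, chain_id) {
  hem <- cx$hetero[cx$hetero$is_heme, , drop = FALSE]
  if (nrow(hem) == 0L) stop("structure contains no heme groups")
  at <- cx$atoms[cx$atoms$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain not found: ", chain_id)
  hxyz <- as.matrix(hem[, c("x", "y", "z")])
  axyz <- as.matrix(at[, c("x", "y", "z")])
  d2 <- outer(rowSums(axyz^2), rowSums(hxyz^2), "+") - 2 * tcrossprod(axyz, hxyz)
  dmin <- sqrt(pmax(0, apply(d2, 1, min)))
  out <- tapply(dmin, at$key, min)[unique(at$key)]
  out
}

#' Write a per-residue annotation table
#'
#' @param labels A `site_labels` data frame from [classify_sites()].
#' @param path Output TSV path.
#' @param heme_dist Optional named vector of heme distances to join in.
#' @return The path, invisibly.
#' @export
write_labels_tsv <- function(labels, path, heme_dist = NULL) {
  out <- as.data.frame(labels)
  if (!is.null(heme_dist)) out$heme_dist <- as.numeric(heme_dist[out$key])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-residue annotation table written by [write_labels_tsv()]
#' @param path TSV path.
#' @return A `site_labels` data frame.
#' @export
read_labels_tsv <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA", colClasses = NA)
  out$insert[is.na(out$insert)] <- ""
  out$partners[is.na(out$partners)] <- ""
  class(out) <- c("site_labels", "data.frame")
  out
}
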