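## Geometric measurements on pentamer coordinates: pore-axis estimation,
## perpendicular radial distances, pore-proximal/pore-distal classification,
## interatomic distances and the trans-pore CA-CA collapse metric. Structures
## are bio3d `pdb` objects (PDB or mmCIF input); only the first model and a
## single alternate location are kept.

# n x 3 coordinate matrix of a pdb object (first model)
coord_matrix <- function(pdb) {
  xyz <- pdb$xyz
  if (is.matrix(xyz)) xyz <- xyz[1, ]
  matrix(as.numeric(xyz), ncol = 3, byrow = TRUE)
}

is_hydrogen <- function(atom) {
  sy <- atom$elesy
  if (!is.null(sy) && !all(is.na(sy)) && !all(sy == ""))
    return(trimws(sy) %in% c("H", "D"))
  grepl("^[0-9]*H", trimws(atom$elety))
}

#' Read a structure from PDB or mmCIF
#'
#' Keeps the first model only and filters alternate locations to blank/'A'.
#' Hydrogens are retained (side-chain centroids ignore them downstream).
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`
#' @return a `bio3d` `pdb` object
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  pdb <- if (format == "cif") {
    # bio3d tags read.cif as beta with an unconditional warning; silence it
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  } else {
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  }
  keep <- which(is.na(pdb$atom$alt) | pdb$atom$alt %in% c("", "A"))
  if (length(keep) < nrow(pdb$atom)) {
    sel <- list(atom = keep, xyz = bio3d::atom2xyz(keep))
    class(sel) <- "select"
    pdb <- bio3d::trim.pdb(pdb, sel)
  }
  if (nrow(pdb$atom) == 0L) stop("structure contains no atoms")
  pdb
}

#' Write a structure as PDB
#'
#' @param pdb a `bio3d` `pdb` object
#' @param file output path
#' @export
writeStructurePDB <- function(pdb, file) {
  bio3d::write.pdb(pdb, file = file)
  invisible(file)
}

#' Apply a rigid-body transform to a structure
#'
#' @param pdb a `bio3d` `pdb` object
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 vector (Angstrom)
#' @return the transformed `pdb` object
#' @export
transformStructure <- function(pdb, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3, 3)))
  xyz <- coord_matrix(pdb)
  xyz <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  flat <- as.numeric(t(xyz))
  if (is.matrix(pdb$xyz)) pdb$xyz[1, ] <- flat else pdb$xyz[] <- flat
  pdb$atom$x <- xyz[, 1]; pdb$atom$y <- xyz[, 2]; pdb$atom$z <- xyz[, 3]
  pdb
}

#' Residue selector
#'
#' Identifies the point a residue contributes to a radial measurement:
#' its CA atom, the unweighted centroid of its side-chain heavy atoms
#' (CB outward; falls back to CA for glycine), or one named atom.
#'
#' @param chain chain identifier
#' @param resno residue number (author/deposited numbering)
#' @param aggregate `"sidechain"`, `"CA"` or `"atom"`
#' @param atom atom name, required when `aggregate = "atom"`
#' @return a `ResidueSelector` list
#' @export
residueSelector <- function(chain, resno,
                            aggregate = c("sidechain", "CA", "atom"),
                            atom = NULL) {
  aggregate <- match.arg(aggregate)
  if (aggregate == "atom" && is.null(atom))
    stop("aggregate = 'atom' requires an atom name")
  structure(list(chain = chain, resno = as.integer(resno),
                 aggregate = aggregate, atom = atom),
            class = "ResidueSelector")
}

backbone_names <- c("N", "CA", "C", "O", "OXT")

# Resolve a selector to a single 3D point.
resolve_selector <- function(pdb, sel) {
  stopifnot(inherits(sel, "ResidueSelector"))
  at <- pdb$atom
  idx <- which(at$chain == sel$chain & at$resno == sel$resno)
  if (!length(idx))
    stop(sprintf("no atoms for chain %s residue %d", sel$chain, sel$resno))
  xyz <- coord_matrix(pdb)
  pick <- switch(sel$aggregate,
    CA = {
      i <- idx[trimws(at$elety[idx]) == "CA"]
      if (!length(i))
        stop(sprintf("no CA atom for chain %s residue %d", sel$chain,
                     sel$resno))
      i
    },
    atom = {
      i <- idx[trimws(at$elety[idx]) == sel$atom]
      if (!length(i))
        stop(sprintf("no atom '%s' for chain %s residue %d", sel$atom,
                     sel$chain, sel$resno))
      i
    },
    sidechain = {
      i <- idx[!trimws(at$elety[idx]) %in% backbone_names &
                 !is_hydrogen(at[idx, , drop = FALSE])]
      if (!length(i)) i <- idx[trimws(at$elety[idx]) == "CA"]  # glycine
      if (!length(i))
        stop(sprintf("no side-chain or CA atoms for chain %s residue %d",
                     sel$chain, sel$resno))
      i
    })
  colMeans(xyz[pick, , drop = FALSE])
}

#' Estimate the pore axis of a pentamer
#'
#' Anchor = centroid of the selected atoms; direction = principal axis
#' (largest-variance eigenvector of the coordinate covariance). On an exactly
#' C5-symmetric assembly this is the symmetry axis. Default selection is all
#' CA atoms; pass the CA atoms of the five pore-lining M2 segments when
#' chain annotations are available. The direction sign is fixed
#' deterministically (largest-magnitude component positive); radial distances
#' do not depend on it.
#'
#' @param pdb a `bio3d` `pdb` object
#' @param selection optional integer atom indices (rows of `pdb$atom`) to use
#' @return a [PoreAxis-class]
#' @export
estimatePoreAxis <- function(pdb, selection = NULL) {
  xyz <- coord_matrix(pdb)
  if (is.null(selection))
    selection <- which(trimws(pdb$atom$elety) == "CA")
  if (length(selection) < 3L)
    stop("need at least 3 selected atoms to estimate an axis")
  x <- xyz[selection, , drop = FALSE]
  ctr <- colMeans(x)
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  d <- ev$vectors[, 1]
  j <- which.max(abs(d))
  if (d[j] < 0) d <- -d
  poreAxis(anchor = ctr, direction = d)
}

point_radial_distance <- function(p, axis) {
  v <- p - axis@anchor
  proj <- sum(v * axis@direction)
  sqrt(max(sum(v^2) - proj^2, 0))
}

#' Perpendicular distance of a residue from the pore axis
#'
#' @param pdb a `bio3d` `pdb` object
#' @param axis a [PoreAxis-class]
#' @param selector a [residueSelector()]
#' @return radial distance in Angstrom (>= 0)
#' @export
radialDistance <- function(pdb, axis, selector) {
  stopifnot(is(axis, "PoreAxis"))
  point_radial_distance(resolve_selector(pdb, selector), axis)
}

#' Classify a residue as pore-proximal or pore-distal of a reference
#'
#' Compares the radial distances of a query and a reference residue:
#' pore-proximal if `r_query < r_ref - epsilon`, pore-distal if
#' `r_query > r_ref + epsilon`, indeterminate inside the tie band. The
#' default tie band of 0.3 A stays below the coordinate uncertainty of
#' typical ~3 A cryo-EM models.
#'
#' @inheritParams radialDistance
#' @param query,reference [residueSelector()]s (must differ)
#' @param epsilon tie band in Angstrom
#' @return a [RadialClassification-class]
#' @export
classifyRadialPosition <- function(pdb, axis, query, reference,
                                   epsilon = 0.3) {
  if (identical(query$chain, reference$chain) &&
      identical(query$resno, reference$resno))
    stop("query and reference must be different residues")
  rq <- radialDistance(pdb, axis, query)
  rr <- radialDistance(pdb, axis, reference)
  dv <- rq - rr
  verdict <- if (dv < -epsilon) "pore-proximal"
             else if (dv > epsilon) "pore-distal" else "indeterminate"
  new("RadialClassification", r_query = rq, r_reference = rr,
      epsilon = epsilon, verdict = verdict)
}

#' Distance between two named atoms
#'
#' Euclidean heavy-atom distance, e.g. a hydrogen-bond donor-acceptor
#' N...O separation.
#'
#' @param pdb a `bio3d` `pdb` object
#' @param spec1,spec2 lists with `chain`, `resno`, `atom`
#' @return distance in Angstrom
#' @export
atomPairDistance <- function(pdb, spec1, spec2) {
  get_point <- function(spec) {
    resolve_selector(pdb, residueSelector(spec$chain, spec$resno,
                                          aggregate = "atom",
                                          atom = spec$atom))
  }
  sqrt(sum((get_point(spec1) - get_point(spec2))^2))
}

#' Trans-pore collapse metric
#'
#' Distance between the backbone CA atoms of the designated pore-facing
#' residue in the two principal (alpha) subunits, used as a single-number
#' measure of pore collapse for one coordinate set.
#'
#' @param pdb a `bio3d` `pdb` object
#' @param chains length-2 character vector: the two alpha-subunit chain ids
#' @param resno residue number (default 255)
#' @return CA-CA distance in Angstrom
#' @export
poreCollapseMetric <- function(pdb, chains, resno = 255L) {
  stopifnot(length(chains) == 2L)
  p1 <- resolve_selector(pdb, residueSelector(chains[1], resno, "CA"))
  p2 <- resolve_selector(pdb, residueSelector(chains[2], resno, "CA"))
  sqrt(sum((p1 - p2)^2))
}
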