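# Core computational geometry: rigid superposition, backbone dihedrals,
# solvent-accessible surface area, and sequence-independent segment
# superposition of internal repeats.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping point set
#' `coords_b` onto `coords_a` via singular value decomposition of the
#' covariance matrix.  Reflections are disallowed: the returned rotation
#' always has determinant +1.
#'
#' @param coords_a,coords_b N x 3 matrices (N >= 3) of corresponding points.
#' @return list of class `rigid_transform` with `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd`; the fit maps a point x of b to
#'   `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b) || ncol(coords_a) != 3 || ncol(coords_b) != 3)
    stop("coordinate sets must be N x 3 with equal N")
  n <- nrow(coords_a)
  if (n < 3) stop("at least 3 point pairs required")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  if (svd(A)$d[2] < 1e-8 || svd(B)$d[2] < 1e-8)
    stop("degenerate (collinear) point set")
  H <- t(B) %*% A
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  structure(list(rotation = R, translation = as.numeric(ca - cb %*% t(R)),
                 rmsd = rmsd), class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param transform a `rigid_transform`
#' @param coords N x 3 matrix
#' @export
apply_transform <- function(transform, coords) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Rigidly move a structure
#'
#' Applies `x -> x R^T + t` to all atom coordinates.
#'
#' @param structure a `structure3d`
#' @param rotation 3 x 3 proper rotation matrix
#' @param translation length-3 vector (Angstrom)
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- cbind(structure$atoms$x, structure$atoms$y, structure$atoms$z)
  xyz <- sweep(xyz %*% t(rotation), 2, translation, "+")
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Signed dihedral angle of four points (degrees, IUPAC convention)
#' @param p1,p2,p3,p4 length-3 coordinate vectors
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

backbone_coords <- function(structure, chain) {
  at <- structure$atoms
  at <- at[at$chain == chain & at$kind == "polymer", , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain, "' has no polymer residues")
  key <- res_key(at$chain, at$resno, at$icode)
  ukey <- unique(key)
  pick <- function(name) {
    idx <- match(paste(ukey, name), paste(key, at$atom))
    cbind(at$x[idx], at$y[idx], at$z[idx])
  }
  list(key = ukey,
       resno = at$resno[match(ukey, key)],
       icode = at$icode[match(ukey, key)],
       N = pick("N"), CA = pick("CA"), C = pick("C"))
}

#' Backbone phi/psi dihedrals of a chain
#'
#' phi(i) is computed from C(i-1), N(i), CA(i), C(i) and psi(i) from N(i),
#' CA(i), C(i), N(i+1).  Angles are undefined (NA) at chain termini, where a
#' backbone atom is missing, or across a chain break (C(i)-N(i+1) distance
#' above `break_cutoff`).
#'
#' @param structure a `structure3d`
#' @param chain chain id
#' @param break_cutoff maximum peptide C-N bond length in Angstrom (default
#'   2.5) before residues are treated as non-contiguous.
#' @return data.frame with key, resno, icode, phi, psi.
#' @export
backbone_dihedrals <- function(structure, chain, break_cutoff = 2.5) {
  bb <- backbone_coords(structure, chain)
  n <- length(bb$key)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  has <- function(M, i) i >= 1 && i <= n && !any(is.na(M[i, ]))
  linked <- function(i) {
    # peptide bond between residue i and i+1
    if (!has(bb$C, i) || !has(bb$N, i + 1)) return(FALSE)
    sqrt(sum((bb$C[i, ] - bb$N[i + 1, ])^2)) <= break_cutoff
  }
  for (i in seq_len(n)) {
    if (i > 1 && linked(i - 1) && has(bb$N, i) && has(bb$CA, i) && has(bb$C, i))
      phi[i] <- dihedral_angle(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    if (i < n && linked(i) && has(bb$N, i) && has(bb$CA, i) && has(bb$C, i))
      psi[i] <- dihedral_angle(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ])
  }
  data.frame(key = bb$key, resno = bb$resno, icode = bb$icode,
             phi = phi, psi = psi, stringsAsFactors = FALSE)
}

#' Deterministic golden-spiral point lattice on the unit sphere
#' @param n number of points
#' @export
sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Maximum per-residue SASA (Gly-X-Gly, theoretical; Tien et al. 2013)
MAX_SASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174,
              MSE = 224)

atom_radii <- function(elements) {
  r <- VDW_RADII[elements]
  if (anyNA(r)) {
    unknown <- unique(elements[is.na(r)])
    warning("no vdW radius for element(s) ", paste(unknown, collapse = ","),
            "; using ", DEFAULT_VDW, " A")
    r[is.na(r)] <- DEFAULT_VDW
  }
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples each atom's solvent-accessible sphere (vdW radius + probe) on a
#' deterministic golden-spiral lattice and counts points not occluded by any
#' neighbouring atom.  Hydrogens and waters are excluded from the atom set;
#' heteroatoms are excluded by default.
#'
#' @param structure a `structure3d`
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points lattice points per atom (default 960).
#' @param include_hetero include non-water heteroatoms in the atom set.
#' @return list with `atom` (data.frame chain, resno, icode, atom, area) and
#'   `residue` (data.frame chain, resno, icode, resname, key, area,
#'   rel_area); `rel_area` is area divided by the residue type's Gly-X-Gly
#'   maximum (NA for types without a tabulated maximum).
#' @export
shrake_rupley_sasa <- function(structure, probe = 1.4, n_points = 960,
                               include_hetero = FALSE) {
  at <- structure$atoms
  sel <- at$kind == "polymer" | (include_hetero & at$kind == "hetero")
  at <- at[sel & at$element != "H", , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms for SASA computation")
  xyz <- cbind(at$x, at$y, at$z)
  rad <- atom_radii(at$element) + probe
  pts <- sphere_lattice(n_points)
  n <- nrow(at)
  area <- numeric(n)
  maxr <- max(rad)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad[i] + maxr)^2)
    nb <- nb[nb != i]
    nb <- nb[d2[nb] < (rad[i] + rad[nb])^2]
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        free <- free & dj2 > rad[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    area[i] <- 4 * pi * rad[i]^2 * frac
  }
  atom_df <- data.frame(chain = at$chain, resno = at$resno, icode = at$icode,
                        atom = at$atom, area = area, stringsAsFactors = FALSE)
  key <- res_key(at$chain, at$resno, at$icode)
  first <- !duplicated(key)
  res_area <- tapply(area, factor(key, levels = key[first]), sum)
  resname <- at$resname[first]
  res_df <- data.frame(chain = at$chain[first], resno = at$resno[first],
                       icode = at$icode[first], resname = resname,
                       key = key[first], area = as.numeric(res_area),
                       rel_area = as.numeric(res_area) / unname(MAX_SASA[resname]),
                       stringsAsFactors = FALSE)
  list(atom = atom_df, residue = res_df)
}

#' Sequence-independent superposition of two structure segments
#'
#' Iteratively refines an order-preserving residue correspondence between two
#' Calpha segments: starting from a gapless midpoint-anchored pairing, it
#' alternates Kabsch superposition on the current pairs with rebuilding the
#' pairs by dynamic programming on the inter-segment Calpha distance matrix
#' (pair score `max(0, cutoff - d)`, gaps free) until the pair set is stable.
#' Used to demonstrate the structural equivalence of internal repeats.
#'
#' @param structure a `structure3d`
#' @param seg_a,seg_b integer length-2 vectors `c(first, last)` of author
#'   residue numbers (each segment >= 10 residues with Calpha atoms).
#' @param chain_a,chain_b chain ids (default: first chain).
#' @param cutoff distance cutoff in Angstrom for a residue pair to count
#'   (default 5).
#' @param max_iter maximum refinement iterations (default 50).
#' @return list with `pairs` (data.frame resno_a, resno_b, dist),
#'   `n_matched`, `rmsd` and `transform`.
#' @export
superpose_segments <- function(structure, seg_a, seg_b, chain_a = NULL,
                               chain_b = NULL, cutoff = 5.0, max_iter = 50L) {
  if (is.null(chain_a)) chain_a <- structure$atoms$chain[1]
  if (is.null(chain_b)) chain_b <- chain_a
  ca_of <- function(chain, seg) {
    bb <- backbone_coords(structure, chain)
    idx <- which(bb$resno >= seg[1] & bb$resno <= seg[2] & !is.na(bb$CA[, 1]))
    list(resno = bb$resno[idx], xyz = bb$CA[idx, , drop = FALSE])
  }
  A <- ca_of(chain_a, seg_a); B <- ca_of(chain_b, seg_b)
  la <- length(A$resno); lb <- length(B$resno)
  if (la < 10 || lb < 10) stop("both segments must have at least 10 Calpha residues")

  off <- round((lb - la) / 2)                       # midpoint-anchored init
  i <- seq_len(la); j <- i + off
  ok <- j >= 1 & j <= lb
  pairs <- cbind(i[ok], j[ok])
  if (nrow(pairs) < 3) stop("no initial correspondence with >= 3 pairs")

  tr <- NULL
  for (iter in seq_len(max_iter)) {
    tr <- kabsch_superpose(A$xyz[pairs[, 1], , drop = FALSE],
                           B$xyz[pairs[, 2], , drop = FALSE])
    Bt <- apply_transform(tr, B$xyz)
    D <- sqrt(pmax(outer(rowSums(A$xyz^2), rep(1, lb)) +
                     outer(rep(1, la), rowSums(Bt^2)) - 2 * A$xyz %*% t(Bt), 0))
    S <- pmax(cutoff - D, 0)
    new_pairs <- dp_trace(S)
    if (nrow(new_pairs) < 3) break
    if (nrow(new_pairs) == nrow(pairs) && all(new_pairs == pairs)) {
      pairs <- new_pairs; break
    }
    pairs <- new_pairs
  }
  tr <- kabsch_superpose(A$xyz[pairs[, 1], , drop = FALSE],
                         B$xyz[pairs[, 2], , drop = FALSE])
  Bt <- apply_transform(tr, B$xyz[pairs[, 2], , drop = FALSE])
  dist <- sqrt(rowSums((A$xyz[pairs[, 1], , drop = FALSE] - Bt)^2))
  list(pairs = data.frame(resno_a = A$resno[pairs[, 1]],
                          resno_b = B$resno[pairs[, 2]], dist = dist),
       n_matched = nrow(pairs), rmsd = tr$rmsd, transform = tr)
}

# Order-preserving DP alignment on a score matrix; returns matched index
# pairs with positive score.
dp_trace <- function(S) {
  n <- nrow(S); m <- ncol(S)
  f <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    f[i + 1, 2:(m + 1)] <- pmax(f[i, 2:(m + 1)], f[i, 1:m] + S[i, ])
    f[i + 1, ] <- cummax(f[i + 1, ])
  }
  pairs <- matrix(0L, 0, 2)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    if (f[i + 1, j + 1] == f[i, j + 1]) { i <- i - 1 }
    else if (f[i + 1, j + 1] == f[i + 1, j]) { j <- j - 1 }
    else {
      if (S[i, j] > 0) pairs <- rbind(c(i, j), pairs)
      i <- i - 1; j <- j - 1
    }
  }
  pairs
}
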