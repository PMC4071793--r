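# Generators for ground-truth test data: ideal backbones built by
# internal-coordinate chain extension, planted catalytic constellations,
# hollow shells enclosing cavities of known volume, nest backbones with
# prescribed phi/psi alternation, and alignments evolved along a known tree
# under a Poisson substitution model.

# ideal peptide geometry (lengths in Angstrom, angles in degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.5

# place point D given A-B-C, bond length r (C-D), bond angle theta (B-C-D)
# and dihedral chi (A-B-C-D); the NeRF construction
nerf_place <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180; ch <- -chi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- r * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

backbone_structure <- function(xyz, names, resno, id, resname = "GLY") {
  n <- length(names)
  atoms <- data.frame(record = "ATOM", chain = "A", resno = resno,
                      icode = "", resname = resname, kind = "polymer",
                      atom = names, altloc = "",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occ = 1, b = 0,
                      element = substr(names, 1, 1),
                      stringsAsFactors = FALSE)
  new_structure(id = id, atoms = atoms)
}

# build an N/CA/C/O backbone for given per-residue phi/psi (phi[1] and
# psi[n] are not used)
build_backbone <- function(phi, psi, omega = 180, id = "backbone") {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  coords <- matrix(NA_real_, 4 * n, 3)
  nm <- rep(c("N", "CA", "C", "O"), n)
  rn <- rep(seq_len(n), each = 4)
  idx <- function(i, at) (i - 1) * 4 + match(at, c("N", "CA", "C", "O"))
  coords[idx(1, "N"), ] <- c(0, 0, 0)
  coords[idx(1, "CA"), ] <- c(BOND_N_CA, 0, 0)
  ang <- ANGLE_N_CA_C * pi / 180
  coords[idx(1, "C"), ] <- coords[idx(1, "CA"), ] +
    BOND_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    Ni <- coords[idx(i, "N"), ]; CAi <- coords[idx(i, "CA"), ]
    Ci <- coords[idx(i, "C"), ]
    psi_i <- if (i < n) psi[i] else 180
    coords[idx(i, "O"), ] <- nerf_place(Ni, CAi, Ci, BOND_C_O, ANGLE_CA_C_O,
                                        psi_i + 180)
    if (i == n) break
    Nn <- nerf_place(Ni, CAi, Ci, BOND_C_N, ANGLE_CA_C_N, psi[i])
    CAn <- nerf_place(CAi, Ci, Nn, BOND_N_CA, ANGLE_C_N_CA, omega)
    Cn <- nerf_place(Ci, Nn, CAn, BOND_CA_C, ANGLE_N_CA_C, phi[i + 1])
    coords[idx(i + 1, "N"), ] <- Nn
    coords[idx(i + 1, "CA"), ] <- CAn
    coords[idx(i + 1, "C"), ] <- Cn
  }
  backbone_structure(coords, nm, rn, id)
}

#' Build an ideal helix (or any uniform-dihedral backbone)
#'
#' Chain extension with ideal peptide bond lengths and angles; the recovered
#' dihedrals of interior residues equal the inputs to within numerical
#' precision.
#'
#' @param n number of residues (>= 1)
#' @param phi,psi backbone dihedrals in degrees (defaults -57/-47, an
#'   alpha helix)
#' @param omega peptide bond dihedral (default 180, trans)
#' @return a `structure3d` with one chain of glycine residues (N, CA, C, O).
#' @export
build_helix <- function(n, phi = -57, psi = -47, omega = 180) {
  stopifnot(n >= 1)
  build_backbone(rep(phi, n), rep(psi, n), omega = omega,
                 id = sprintf("helix_%d", n))
}

#' Build a backbone carrying a nest motif
#'
#' The residues of `pattern` get phi/psi (-80, -20) for R and (80, 20) for
#' L; one extended flanking residue (phi -120, psi 120, which the nest
#' classifier ignores because |psi| > 90) is added on each side so that all
#' pattern residues have defined dihedrals.  [detect_nests()] reports
#' exactly one nest of `nchar(pattern) + 1` residues per maximal
#' alternating run.
#'
#' @param pattern string over R and L, length >= 2
#' @return a `structure3d`
#' @export
make_nest_backbone <- function(pattern) {
  ch <- strsplit(pattern, "")[[1]]
  if (length(ch) < 2 || !all(ch %in% c("R", "L")))
    stop("pattern must be a string over {R,L} of length >= 2")
  phi <- c(-120, ifelse(ch == "R", -80, 80), -120)
  psi <- c(120, ifelse(ch == "R", -20, 20), 120)
  st <- build_backbone(phi, psi, id = paste0("nest_", pattern))
  st
}

#' A canonical synthetic acid-triad template
#'
#' Three carboxylate groups (Asp, Asp, Glu) in a geometry typical of an
#' inverting glycoside-hydrolase catalytic site: a close acid pair about
#' 5 A apart and a proton-donor acid about 9 A away.  Useful as a default
#' template for planting and matching experiments.
#'
#' @return a `site_template`
#' @export
canonical_triad_template <- function() {
  carboxylate <- function(cc, o1_dir, o2_dir) {
    unname(rbind(cc, cc + 1.25 * o1_dir / sqrt(sum(o1_dir^2)),
                 cc + 1.25 * o2_dir / sqrt(sum(o2_dir^2))))
  }
  members <- list(
    list(classes = ACID_CLASS, atoms = FUNCTIONAL_ATOMS,
         coords = carboxylate(c(0, 0, 0), c(1, 0.6, 0.2), c(-0.4, 1, -0.3))),
    list(classes = ACID_CLASS, atoms = FUNCTIONAL_ATOMS,
         coords = carboxylate(c(5.2, 0.8, 0.3), c(-0.8, 0.7, 0.4), c(0.9, 0.8, -0.5))),
    list(classes = ACID_CLASS, atoms = FUNCTIONAL_ATOMS,
         coords = carboxylate(c(2.6, 8.8, 1.2), c(0.3, -1, 0.2), c(-1, -0.5, -0.4))))
  structure(list(name = "synthetic_gh_triad", members = members,
                 source = list(id = "synthetic", residues = character(0))),
            class = "site_template")
}

random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    if (sum(q^2) > 1e-6) break
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Plant a catalytic constellation into a base structure
#'
#' Rebuilds three (or more) residues of a base structure as acidic residues
#' whose functional atoms are a rigidly transformed copy of a site
#' template's coordinates plus isotropic Gaussian noise, recording the keys
#' and the exact transform as ground truth.  With zero noise,
#' [match_template()] recovers the planted residues at RMSD 0.
#'
#' @param base a `structure3d` (e.g. from [build_helix()]) with enough
#'   residues
#' @param template a `site_template` (default [canonical_triad_template()])
#' @param positions residue numbers to replace (default: evenly spaced)
#' @param noise_sigma isotropic Gaussian coordinate noise in Angstrom
#' @param seed RNG seed
#' @return list with `structure` and `ground_truth` (keys, rotation,
#'   translation, noise_sigma, seed, planted_coords).
#' @export
plant_triad <- function(base, template = canonical_triad_template(),
                        positions = NULL, noise_sigma = 0, seed = 1L) {
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  k <- length(template$members)
  rt <- residue_table(base)
  rt <- rt[rt$kind == "polymer", , drop = FALSE]
  if (nrow(rt) < k) stop("base structure too small")
  if (is.null(positions))
    positions <- rt$resno[round(seq(0.25, 0.75, length.out = k) * nrow(rt))]
  if (length(positions) != k) stop("need one position per template member")

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  R <- random_rotation()
  bb <- backbone_coords(base, rt$chain[1])
  ca_idx <- match(positions, bb$resno)
  target <- colMeans(bb$CA[ca_idx, , drop = FALSE])
  t_all <- do.call(rbind, lapply(template$members, `[[`, "coords"))
  tr_coords <- sweep(t_all %*% t(R), 2, target - colMeans(t_all %*% t(R)), "+")
  noise <- matrix(stats::rnorm(length(tr_coords), 0, noise_sigma),
                  ncol = 3)
  planted <- tr_coords + noise

  atoms <- base$atoms
  arity <- nrow(template$members[[1]]$coords)
  keys <- character(k)
  for (m in seq_len(k)) {
    resno <- positions[m]
    cls <- template$members[[m]]$classes[1]
    sel <- atoms$chain == rt$chain[1] & atoms$resno == resno
    atoms$resname[sel] <- cls
    fa <- template$members[[m]]$atoms[[cls]]
    rows <- (m - 1) * arity + seq_len(arity)
    add <- data.frame(record = "ATOM", chain = rt$chain[1], resno = resno,
                      icode = "", resname = cls, kind = "polymer",
                      atom = fa, altloc = "",
                      x = planted[rows, 1], y = planted[rows, 2],
                      z = planted[rows, 3], occ = 1, b = 0,
                      element = substr(fa, 1, 1), stringsAsFactors = FALSE)
    last <- max(which(sel))
    atoms <- rbind(atoms[seq_len(last), ], add,
                   if (last < nrow(atoms)) atoms[(last + 1):nrow(atoms), ])
    keys[m] <- res_key(rt$chain[1], resno)
  }
  rownames(atoms) <- NULL
  st <- new_structure(id = paste0(base$id, "_triad"), atoms = atoms,
                      cell = base$cell)
  list(structure = st,
       ground_truth = list(kind = "triad", keys = keys, rotation = R,
                           translation = target - colMeans(t_all %*% t(R)),
                           noise_sigma = noise_sigma, seed = seed,
                           planted_coords = planted))
}

#' Hollow shell of pseudo-atoms enclosing a cavity of known volume
#'
#' Places carbon-like pseudo-atoms on concentric golden-spiral spherical
#' lattices so that the enclosed void has radius exactly `inner_radius`
#' once atoms are inflated by their vdW radius plus the probe radius
#' (the same inflation [detect_cavities()] applies), giving an analytic
#' ground-truth volume of (4/3) pi r^3.  Generation fails if the lattice is
#' too sparse to seal the shell (checked by grid flood fill from the
#' outside).
#'
#' @param inner_radius cavity radius in Angstrom (>= 4)
#' @param atom_radius pseudo-atom vdW radius (default 1.7, carbon)
#' @param shell_layers concentric layers (default 2)
#' @param spacing approximate lattice point spacing on each sphere
#'   (default 2.8)
#' @param probe probe radius the detector will use (default 1.4)
#' @return list with `structure` and `ground_truth` (volume, inner_radius).
#' @export
make_cavity_shell <- function(inner_radius, atom_radius = 1.7,
                              shell_layers = 2L, spacing = 2.8,
                              probe = 1.4) {
  if (inner_radius < 4) stop("inner_radius must be at least 4 A")
  inflate <- atom_radius + probe
  build_lattice <- function(offset) {
    coords <- NULL
    for (l in seq_len(shell_layers) - 1) {
      R <- inner_radius + inflate + offset + l * 1.8
      npts <- ceiling(4 * pi * R^2 / spacing^2)
      coords <- rbind(coords, sphere_lattice(npts) * R)
    }
    coords
  }
  # The union of inflated lattice spheres leaves a slightly scalloped void
  # that is larger than the ball of radius inner_radius.  Calibrate a small
  # inward radial offset of the lattice so the mean free-region radius
  # (volume-equivalent, from ray casting) equals inner_radius, making the
  # analytic ground-truth volume accurate.
  dirs <- sphere_lattice(6000)
  free_radius <- function(coords) {
    ux <- dirs %*% t(coords)
    x2 <- rowSums(coords^2)
    disc <- ux^2 - rep(x2 - inflate^2, each = nrow(dirs))
    t1 <- ifelse(disc >= 0, ux - sqrt(pmax(disc, 0)), Inf)
    t1[t1 < 0] <- Inf
    d <- apply(t1, 1, min)
    mean(d^3)^(1 / 3)
  }
  offset <- 0
  for (it in 1:4) {
    coords <- build_lattice(offset)
    fr <- free_radius(coords)
    if (!is.finite(fr))
      stop("shell leaks: lattice spacing too large to seal the cavity")
    offset <- offset - (fr - inner_radius)
  }
  coords <- build_lattice(offset)
  n <- nrow(coords)
  atoms <- data.frame(record = "ATOM", chain = "A", resno = seq_len(n),
                      icode = "", resname = "GLY", kind = "polymer",
                      atom = "CA", altloc = "",
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      occ = 1, b = 0, element = "C",
                      stringsAsFactors = FALSE)
  st <- new_structure(id = sprintf("shell_r%g", inner_radius), atoms = atoms)

  # self-check: flood fill on a coarse grid with the same inflation must
  # not connect the cavity centre to the outside
  gs <- 0.9
  inflate <- atom_radius + probe
  lim <- max(abs(coords)) + inflate + 2
  g <- seq(-lim, lim, by = gs)
  dims <- rep(length(g), 3)
  P <- array(FALSE, dims)
  for (i in seq_len(n)) {
    ix <- which(abs(g - coords[i, 1]) <= inflate)
    iy <- which(abs(g - coords[i, 2]) <= inflate)
    iz <- which(abs(g - coords[i, 3]) <= inflate)
    cube <- outer(outer((g[ix] - coords[i, 1])^2, (g[iy] - coords[i, 2])^2, "+"),
                  (g[iz] - coords[i, 3])^2, "+") <= inflate^2
    P[ix, iy, iz] <- P[ix, iy, iz] | cube
  }
  outside <- array(FALSE, dims)
  outside[1, , ] <- outside[dims[1], , ] <- TRUE
  outside[, 1, ] <- outside[, dims[2], ] <- TRUE
  outside[, , 1] <- outside[, , dims[3]] <- TRUE
  outside <- outside & !P
  repeat {
    grown <- outside
    grown[-1, , ] <- grown[-1, , ] | outside[-dims[1], , ]
    grown[-dims[1], , ] <- grown[-dims[1], , ] | outside[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | outside[, -dims[2], ]
    grown[, -dims[2], ] <- grown[, -dims[2], ] | outside[, -1, ]
    grown[, , -1] <- grown[, , -1] | outside[, , -dims[3]]
    grown[, , -dims[3]] <- grown[, , -dims[3]] | outside[, , -1]
    grown <- grown & !P
    if (identical(grown, outside)) break
    outside <- grown
  }
  ci <- which.min(abs(g))
  core <- which(abs(g) <= inner_radius / 2)
  if (any(outside[core, core, core]))
    stop("shell leaks: lattice spacing too large to seal the cavity")

  list(structure = st,
       ground_truth = list(kind = "cavity", inner_radius = inner_radius,
                           volume = 4 / 3 * pi * inner_radius^3))
}

#' Simulate an alignment along a tree under a Poisson model
#'
#' The root sequence is uniform over the 20 amino acids; along each branch
#' of length t, each non-invariant site substitutes with probability
#' 1 - exp(-rate * t) to a uniformly chosen different residue -- the same
#' Poisson process the distance correction of
#' [pairwise_distance_matrix()] inverts, so simulation followed by distance
#' estimation is a closed loop.  A fixed fraction of sites is invariant.
#'
#' @param tree a `phylo` with branch lengths
#' @param n_columns alignment length
#' @param rate substitution rate (substitutions/site per unit branch length)
#' @param invariant_fraction fraction of sites that never change
#' @param seed RNG seed
#' @return an `aa_alignment` with rows in `tree$tip.label` order.
#' @export
simulate_msa <- function(tree, n_columns, rate = 1, invariant_fraction = 0,
                         seed = 1L) {
  if (rate < 0) stop("rate must be non-negative")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  seqs <- matrix(NA_integer_, nnode, n_columns)
  seqs[root, ] <- sample.int(20, n_columns, replace = TRUE)
  n_inv <- round(invariant_fraction * n_columns)
  invariant <- if (n_inv > 0) sample.int(n_columns, n_inv) else integer(0)
  mutable <- setdiff(seq_len(n_columns), invariant)
  tr <- ape::reorder.phylo(tree, "cladewise")   # parent precedes child
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    t <- tr$edge.length[e]
    s <- seqs[parent, ]
    if (length(mutable) > 0 && rate * t > 0) {
      psub <- 1 - exp(-rate * t)
      hit <- mutable[stats::runif(length(mutable)) < psub]
      if (length(hit) > 0) {
        shift <- sample.int(19, length(hit), replace = TRUE)
        s[hit] <- ((s[hit] - 1 + shift) %% 20) + 1
      }
    }
    seqs[child, ] <- s
  }
  mat <- matrix(AA20[seqs[seq_len(ntip), ]], ntip, n_columns)
  rownames(mat) <- tree$tip.label
  new_alignment(mat)
}

#' Random unrooted tree with additive branch lengths
#'
#' @param n number of taxa
#' @param min_bl,max_bl branch-length range (uniform)
#' @param seed RNG seed
#' @return a `phylo`
#' @export
random_additive_tree <- function(n, min_bl = 0.1, max_bl = 1, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  tr <- ape::rtopology(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

#' Concatenate two structures into one
#'
#' Renumbers the second structure's residues to follow the first (same
#' chain), so composite fixtures (e.g. a cavity shell plus a planted triad
#' inside it) can be assembled.
#'
#' @param a,b `structure3d` objects
#' @return a `structure3d`
#' @export
combine_structures <- function(a, b) {
  offset <- max(a$atoms$resno)
  bb <- b$atoms
  bb$resno <- bb$resno + offset
  bb$chain <- a$atoms$chain[1]
  atoms <- rbind(a$atoms, bb)
  rownames(atoms) <- NULL
  new_structure(id = paste0(a$id, "+", b$id), atoms = atoms, cell = a$cell)
}
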