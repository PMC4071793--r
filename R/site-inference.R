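# Structural evidence for functional sites: catalytic-template extraction
# and 3D matching, backbone nest detection, grid-based cavity detection and
# ranking, exposed-aromatic analysis, and integration of all evidence into
# a ranked per-cavity site report.

# Functional (carboxylate) atom groups: the acid/base chemistry of
# glycoside hydrolysis is carried by the carboxylate, so Asp and Glu are
# treated as one residue class with the carbon anchor first and the two
# chemically equivalent oxygens swappable.
FUNCTIONAL_ATOMS <- list(ASP = c("CG", "OD1", "OD2"),
                         GLU = c("CD", "OE1", "OE2"))
ACID_CLASS <- c("ASP", "GLU")

residue_atoms <- function(structure, chain, resno, icode = "") {
  at <- structure$atoms
  at[at$chain == chain & at$resno == resno & at$icode == icode, , drop = FALSE]
}

parse_res_key <- function(keys) {
  m <- regexec("^(.):(-?[0-9]+)([A-Za-z]?)$", keys)
  parts <- regmatches(keys, m)
  if (any(lengths(parts) != 4)) stop("malformed residue key: ", keys[lengths(parts) != 4][1])
  data.frame(chain = vapply(parts, `[`, "", 2),
             resno = as.integer(vapply(parts, `[`, "", 3)),
             icode = vapply(parts, `[`, "", 4), stringsAsFactors = FALSE)
}

#' Extract a catalytic-site template from a structure
#'
#' Builds a 3D site template from the functional-atom coordinates of the
#' named residues (e.g. the acid triad of a glycoside-hydrolase catalytic
#' site).  Each member records the set of residue classes it may match
#' (Asp and Glu are equivalent by default, matched carboxylate-on-
#' carboxylate) and the ordered functional atoms per class.
#'
#' @param structure a `structure3d`
#' @param residue_keys character vector of residue keys `"chain:resno"`
#' @param name template name (default: structure id)
#' @param class_equivalences named list mapping a residue name to the classes
#'   it may match; default treats ASP and GLU as one class.
#' @param functional_atoms named list of ordered atom names per residue
#'   class; default carboxylate groups.
#' @return a `site_template`: list with `name`, `members` and `source`.
#' @export
extract_template <- function(structure, residue_keys, name = NULL,
                             class_equivalences = list(ASP = ACID_CLASS, GLU = ACID_CLASS),
                             functional_atoms = FUNCTIONAL_ATOMS) {
  rk <- parse_res_key(residue_keys)
  members <- vector("list", nrow(rk))
  for (i in seq_len(nrow(rk))) {
    at <- residue_atoms(structure, rk$chain[i], rk$resno[i], rk$icode[i])
    if (nrow(at) == 0)
      stop("residue ", residue_keys[i], " not found")
    resname <- at$resname[1]
    fa <- functional_atoms[[resname]]
    if (is.null(fa))
      stop("no functional-atom definition for residue type ", resname)
    idx <- match(fa, at$atom)
    if (anyNA(idx))
      stop("residue ", residue_keys[i], " lacks functional atom ",
           fa[which(is.na(idx))[1]])
    classes <- class_equivalences[[resname]]
    if (is.null(classes)) classes <- resname
    arities <- vapply(functional_atoms[classes], length, 0L)
    if (length(unique(arities)) != 1)
      stop("equivalent classes must share functional-atom arity")
    members[[i]] <- list(classes = classes,
                         atoms = functional_atoms[classes],
                         coords = unname(cbind(at$x[idx], at$y[idx], at$z[idx])))
  }
  if (length(members) < 3) stop("a site template needs at least 3 members")
  base::structure(list(name = if (is.null(name)) structure$id else name,
                 members = members,
                 source = list(id = structure$id, residues = residue_keys)),
            class = "site_template")
}

#' Write a site template as JSON
#' @param template a `site_template`
#' @param path output file
#' @export
write_template <- function(template, path) {
  obj <- list(name = template$name,
              members = lapply(template$members, function(m)
                list(classes = m$classes, atoms = m$atoms,
                     coords = unname(split(m$coords, row(m$coords))))),
              source = template$source)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a site template from JSON
#' @param path JSON file written by [write_template()]
#' @export
read_template <- function(path) {
  obj <- jsonlite::read_json(path)
  members <- lapply(obj$members, function(m) {
    list(classes = unlist(m$classes),
         atoms = lapply(m$atoms, unlist),
         coords = do.call(rbind, lapply(m$coords, unlist)))
  })
  structure(list(name = obj$name, members = members,
                 source = lapply(obj$source, unlist)),
            class = "site_template")
}

#' Match a 3D site template against a structure
#'
#' Enumerates tuples of distinct query residues whose residue types match an
#' assignment of the template members (all member permutations allowed, so
#' e.g. Asp can play Glu's role across folds), pre-filtered so every pairwise
#' anchor-atom distance is within `pair_tol` of the template's and below
#' `max_span`.  Each surviving tuple is scored by the minimum Kabsch RMSD
#' over functional atoms across allowed correspondences (member assignment
#' times symmetric-oxygen swaps), and hits with RMSD at or below
#' `rmsd_cutoff` are returned sorted by RMSD (duplicate residue sets keep
#' their best correspondence only).
#'
#' @param structure a `structure3d`
#' @param template a `site_template`
#' @param rmsd_cutoff maximum RMSD in Angstrom (default 2.5)
#' @param max_span maximum pairwise anchor distance in Angstrom (default 15)
#' @param pair_tol pre-filter tolerance on pairwise distances (default 3)
#' @return list of hits: each with `residues` (keys ordered by template
#'   member), `rmsd` and `transform` (maps template coordinates onto the
#'   query).
#' @export
match_template <- function(structure, template, rmsd_cutoff = 2.5,
                           max_span = 15, pair_tol = 3) {
  k <- length(template$members)
  arity <- nrow(template$members[[1]]$coords)
  classes_all <- unique(unlist(lapply(template$members, `[[`, "classes")))

  rt <- residue_table(structure)
  cand <- rt[rt$kind == "polymer" & rt$resname %in% classes_all, , drop = FALSE]
  if (nrow(cand) == 0) return(list())
  # candidate functional-atom coordinates, anchor = first atom of group
  cand_coords <- vector("list", nrow(cand))
  ok <- logical(nrow(cand))
  atoms_def <- list()
  for (m in template$members)
    for (cls in names(m$atoms))
      if (is.null(atoms_def[[cls]])) atoms_def[[cls]] <- m$atoms[[cls]]
  for (i in seq_len(nrow(cand))) {
    at <- residue_atoms(structure, cand$chain[i], cand$resno[i], cand$icode[i])
    fa <- atoms_def[[cand$resname[i]]] %||% FUNCTIONAL_ATOMS[[cand$resname[i]]]
    idx <- match(fa, at$atom)
    if (anyNA(idx)) next
    cand_coords[[i]] <- unname(cbind(at$x[idx], at$y[idx], at$z[idx]))
    ok[i] <- TRUE
  }
  cand <- cand[ok, , drop = FALSE]
  cand_coords <- cand_coords[ok]
  n <- nrow(cand)
  if (n < k) return(list())

  anchors <- do.call(rbind, lapply(cand_coords, function(m) m[1, ]))
  Dq <- as.matrix(stats::dist(anchors))
  t_anchor <- do.call(rbind, lapply(template$members, function(m) m$coords[1, ]))
  Dt <- as.matrix(stats::dist(t_anchor))
  if (max(Dt) > max_span) max_span <- max(Dt) + pair_tol

  # oxygen/symmetric-atom swap alternatives per member: all orderings that
  # keep the anchor first and permute the remaining (chemically equivalent)
  # atoms
  swap_orders <- function(a) {
    rest <- seq_len(a)[-1]
    perms <- perm_all(length(rest))
    lapply(seq_len(nrow(perms)), function(r) c(1L, rest[perms[r, ]]))
  }
  swaps <- swap_orders(arity)
  t_coords <- lapply(template$members, `[[`, "coords")
  member_classes <- lapply(template$members, `[[`, "classes")

  assignments <- perm_all(k)   # row: template member -> tuple slot
  hits <- list()
  combos <- utils::combn(n, k)
  for (ci in seq_len(ncol(combos))) {
    tuple <- combos[, ci]
    if (any(Dq[tuple, tuple][upper.tri(Dq[tuple, tuple])] > max_span)) next
    best <- NULL
    for (ai in seq_len(nrow(assignments))) {
      asg <- tuple[assignments[ai, ]]   # residue for member m
      if (!all(vapply(seq_len(k), function(m)
        cand$resname[asg[m]] %in% member_classes[[m]], TRUE))) next
      dq <- Dq[asg, asg]
      if (any(abs(dq - Dt) > pair_tol)) next
      # min over symmetric-atom swaps applied to the query groups
      q_full <- do.call(rbind, cand_coords[asg])
      t_full <- do.call(rbind, t_coords)
      for (sw in swap_combos(swaps, k)) {
        rows <- unlist(lapply(seq_len(k), function(m) (m - 1) * arity + sw[[m]]))
        tr <- kabsch_superpose(q_full[rows, , drop = FALSE], t_full)
        if (is.null(best) || tr$rmsd < best$rmsd)
          best <- list(rmsd = tr$rmsd, transform = tr, asg = asg)
      }
    }
    if (!is.null(best) && best$rmsd <= rmsd_cutoff) {
      keys <- res_key(cand$chain[best$asg], cand$resno[best$asg],
                      cand$icode[best$asg])
      hits[[length(hits) + 1]] <- list(residues = keys, rmsd = best$rmsd,
                                       transform = best$transform)
    }
  }
  hits[order(vapply(hits, `[[`, 0, "rmsd"))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

perm_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# cartesian product of per-member swap orders (memoised small cases)
swap_combos <- function(swaps, k) {
  grid <- expand.grid(rep(list(seq_along(swaps)), k))
  lapply(seq_len(nrow(grid)), function(r)
    lapply(seq_len(k), function(m) swaps[[grid[r, m]]]))
}

#' Detect backbone nests
#'
#' A nest is a short stretch of residues with alternating right/left-handed
#' backbone conformations whose main-chain NH groups line a small
#' anion-binding concavity.  Residues are classified R when phi is in
#' (-140, -20) and L when phi is in (20, 140), in both cases requiring
#' |psi| <= 90; a maximal run of >= 2 consecutive classified residues with
#' alternating labels is reported as a nest together with the residue that
#' follows it (minimum span 3 residues).
#'
#' @param structure a `structure3d`
#' @param chain chain id (default: first chain)
#' @param phi_r,phi_l phi windows (degrees) for the R and L classes
#' @param psi_max maximum |psi| for classification (degrees)
#' @return list of nests: each with `start_resno`, `end_resno`, `keys` and
#'   `pattern` (string over R/L for the classified run).
#' @export
detect_nests <- function(structure, chain = NULL,
                         phi_r = c(-140, -20), phi_l = c(20, 140),
                         psi_max = 90) {
  if (is.null(chain)) chain <- structure$atoms$chain[1]
  dh <- backbone_dihedrals(structure, chain)
  lab <- rep(NA_character_, nrow(dh))
  okpsi <- !is.na(dh$psi) & abs(dh$psi) <= psi_max
  lab[!is.na(dh$phi) & dh$phi > phi_r[1] & dh$phi < phi_r[2] & okpsi] <- "R"
  lab[!is.na(dh$phi) & dh$phi > phi_l[1] & dh$phi < phi_l[2] & okpsi] <- "L"
  nests <- list()
  i <- 1
  n <- nrow(dh)
  while (i <= n) {
    if (is.na(lab[i])) { i <- i + 1; next }
    j <- i
    while (j < n && !is.na(lab[j + 1]) && lab[j + 1] != lab[j]) j <- j + 1
    if (j - i + 1 >= 2) {
      end <- min(j + 1, n)   # include the following residue
      if (end - i + 1 >= 3)
        nests[[length(nests) + 1]] <-
          list(start_resno = dh$resno[i], end_resno = dh$resno[end],
               keys = dh$key[i:end],
               pattern = paste(lab[i:j], collapse = ""))
    }
    i <- j + 1
  }
  nests
}

# directed sweep: for every voxel, has any protein voxel been seen strictly
# before it along direction d (unit steps)?
sweep_seen <- function(P, d) {
  dims <- dim(P)
  out <- array(FALSE, dims)
  ax <- which(d != 0)[1]
  steps <- if (d[ax] > 0) 2:dims[ax] else (dims[ax] - 1):1
  shift2 <- function(M, s1, s2) {
    R <- matrix(FALSE, nrow(M), ncol(M))
    i <- seq_len(nrow(M)) - s1; j <- seq_len(ncol(M)) - s2
    oi <- i >= 1 & i <= nrow(M); oj <- j >= 1 & j <= ncol(M)
    R[oi, oj] <- M[i[oi], j[oj]]
    R
  }
  oth <- setdiff(1:3, ax)
  s1 <- d[oth[1]]; s2 <- d[oth[2]]
  idx <- function(A, v) {
    if (ax == 1) A[v, , ] else if (ax == 2) A[, v, ] else A[, , v]
  }
  set <- function(A, v, M) {
    if (ax == 1) A[v, , ] <- M else if (ax == 2) A[, v, ] <- M else A[, , v] <- M
    A
  }
  for (v in steps) {
    prev <- v - d[ax]
    M <- shift2(idx(out, prev) | idx(P, prev), s1, s2)
    out <- set(out, v, M)
  }
  out
}

SCAN_DIRECTIONS <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                         c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

#' Detect and rank cavities on a grid
#'
#' Places a cubic grid (spacing `spacing`, 2 A margin) over the structure,
#' marks voxels within vdW radius + probe of any polymer atom as protein,
#' and scans the remaining free voxels along 7 fixed directions (3 axes + 4
#' body diagonals): a free voxel enclosed by protein on both sides in at
#' least `psp_min` directions is a pocket voxel.  Pocket voxels are
#' clustered by 26-connectivity; clusters below `min_volume` are dropped and
#' the rest ranked by volume (ties by centroid lexicographic order).
#' Heteroatoms (bound ligands, waters) are excluded from the protein mask by
#' default so occupied cavities are still found.
#'
#' @param structure a `structure3d`
#' @param spacing grid spacing in Angstrom (default 0.9)
#' @param probe probe radius in Angstrom (default 1.4)
#' @param psp_min minimum enclosed scan directions of 7 (default 5)
#' @param min_volume minimum cavity volume in cubic Angstrom (default 50)
#' @param include_hetero include non-water heteroatoms in the protein mask
#' @return list of cavities ranked by volume: each with `rank`,
#'   `grid_points`, `volume`, `centroid` and `lining_residues` (keys of
#'   residues with an atom within vdW + probe + spacing of the cavity).
#' @export
detect_cavities <- function(structure, spacing = 0.9, probe = 1.4,
                            psp_min = 5, min_volume = 50,
                            include_hetero = FALSE) {
  at <- structure$atoms
  sel <- (at$kind == "polymer" | (include_hetero & at$kind == "hetero")) &
    at$element != "H"
  at <- at[sel, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms for cavity detection")
  xyz <- cbind(at$x, at$y, at$z)
  rad <- atom_radii(at$element) + probe

  lo <- apply(xyz, 2, min) - 2
  hi <- apply(xyz, 2, max) + 2
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  dims <- c(length(gx), length(gy), length(gz))
  P <- array(FALSE, dims)
  for (i in seq_len(nrow(at))) {
    R <- rad[i]
    ix <- which(abs(gx - xyz[i, 1]) <= R)
    iy <- which(abs(gy - xyz[i, 2]) <= R)
    iz <- which(abs(gz - xyz[i, 3]) <= R)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - xyz[i, 1])^2
    dy2 <- (gy[iy] - xyz[i, 2])^2
    dz2 <- (gz[iz] - xyz[i, 3])^2
    cube <- outer(outer(dx2, dy2, "+"), dz2, "+") <= R^2
    P[ix, iy, iz] <- P[ix, iy, iz] | cube
  }

  count <- array(0L, dims)
  for (r in seq_len(nrow(SCAN_DIRECTIONS))) {
    d <- SCAN_DIRECTIONS[r, ]
    enc <- sweep_seen(P, d) & sweep_seen(P, -d)
    count <- count + enc
  }
  pocket <- !P & count >= psp_min
  if (!any(pocket)) return(list())

  # 26-connected clustering of pocket voxels
  vox <- which(pocket)
  coord <- arrayInd(vox, dims)
  lin <- function(m) (m[, 3] - 1) * dims[1] * dims[2] + (m[, 2] - 1) * dims[1] + m[, 1]
  label <- integer(length(vox))
  names(label) <- as.character(vox)
  lookup <- new.env(hash = TRUE, size = length(vox))
  for (i in seq_along(vox)) assign(as.character(vox[i]), i, envir = lookup)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  cid <- 0
  for (i in seq_along(vox)) {
    if (label[i] != 0) next
    cid <- cid + 1
    frontier <- i
    label[i] <- cid
    while (length(frontier) > 0) {
      fc <- coord[frontier, , drop = FALSE]
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r)
        sweep(fc, 2, offs[r, ], "+")))
      okb <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[okb, , drop = FALSE]
      nl <- unique(lin(nb))
      hit <- vapply(as.character(nl), function(kk)
        if (exists(kk, envir = lookup, inherits = FALSE))
          get(kk, envir = lookup) else 0L, 0L)
      hit <- hit[hit > 0]
      hit <- unique(hit[label[hit] == 0])
      label[hit] <- cid
      frontier <- hit
    }
  }

  clusters <- split(seq_along(vox), label)
  out <- list()
  rt_at <- structure$atoms[structure$atoms$kind == "polymer" &
                             structure$atoms$element != "H", , drop = FALSE]
  axyz <- cbind(rt_at$x, rt_at$y, rt_at$z)
  arad <- atom_radii(rt_at$element)
  for (cl in clusters) {
    npts <- length(cl)
    volume <- npts * spacing^3
    if (volume < min_volume) next
    cc <- coord[cl, , drop = FALSE]
    pts <- cbind(gx[cc[, 1]], gy[cc[, 2]], gz[cc[, 3]])
    centroid <- colMeans(pts)
    contact <- arad + probe + spacing
    lining <- logical(nrow(rt_at))
    bblo <- apply(pts, 2, min) - max(contact)
    bbhi <- apply(pts, 2, max) + max(contact)
    near <- which(axyz[, 1] >= bblo[1] & axyz[, 1] <= bbhi[1] &
                    axyz[, 2] >= bblo[2] & axyz[, 2] <= bbhi[2] &
                    axyz[, 3] >= bblo[3] & axyz[, 3] <= bbhi[3])
    for (ai in near) {
      d2 <- (pts[, 1] - axyz[ai, 1])^2 + (pts[, 2] - axyz[ai, 2])^2 +
        (pts[, 3] - axyz[ai, 3])^2
      if (any(d2 <= contact[ai]^2)) lining[ai] <- TRUE
    }
    lres <- unique(res_key(rt_at$chain[lining], rt_at$resno[lining],
                           rt_at$icode[lining]))
    out[[length(out) + 1]] <- list(grid_points = npts, volume = volume,
                                   centroid = centroid,
                                   lining_residues = lres)
  }
  if (length(out) == 0) return(list())
  vols <- vapply(out, `[[`, 0, "volume")
  cents <- do.call(rbind, lapply(out, `[[`, "centroid"))
  ord <- order(-vols, cents[, 1], cents[, 2], cents[, 3])
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$rank <- i
  out
}

#' Solvent-exposed aromatic residues
#'
#' Aromatic residues whose relative SASA reaches `threshold`, sorted by
#' decreasing exposure.  Solvent-exposed aromatics are a hallmark of
#' carbohydrate-binding surfaces, where their flat faces stack against
#' sugar rings.
#'
#' @param structure a `structure3d`
#' @param sasa output of [shrake_rupley_sasa()]
#' @param types aromatic residue types considered
#' @param threshold minimum relative SASA (default 0.2)
#' @return data.frame with chain, resno, icode, resname, key, rel_area.
#' @export
exposed_aromatics <- function(structure, sasa,
                              types = c("TRP", "TYR", "PHE", "HIS"),
                              threshold = 0.2) {
  res <- sasa$residue
  res <- res[res$resname %in% types & !is.na(res$rel_area) &
               res$rel_area >= threshold, , drop = FALSE]
  res <- res[order(-res$rel_area), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("chain", "resno", "icode", "resname", "key", "rel_area")]
}

#' Integrate structural and evolutionary evidence into a site report
#'
#' Scores every cavity by a weighted sum of five evidence terms: relative
#' volume (volume / largest volume), mean conservation of lining residues,
#' best template hit among the lining residues (scored
#' `(cutoff - rmsd) / cutoff`), presence of a nest in the lining, and the
#' number of exposed aromatics within `aromatic_radius` of the cavity
#' centroid (capped at 5, scaled to `[0,1]`).  The composite score is
#' monotone in each component; ties are broken by volume then centroid
#' order, so ranking is deterministic.
#'
#' @param structure a `structure3d`
#' @param cavities output of [detect_cavities()]
#' @param profile optional `conservation_profile`
#' @param hits optional output of [match_template()]
#' @param nests optional output of [detect_nests()]
#' @param aromatics optional output of [exposed_aromatics()]
#' @param weights numeric length 5: volume, conservation, template, nest,
#'   aromatics (default `c(1, 1, 2, 0.5, 0.5)`)
#' @param rmsd_cutoff template-score normalisation cutoff (default 2.5)
#' @param aromatic_radius centroid radius for the aromatic count (default 10)
#' @return a `site_report`: list with `sites` (ranked list of per-cavity
#'   evidence records) and `weights`.
#' @export
integrate_evidence <- function(structure, cavities, profile = NULL,
                               hits = NULL, nests = NULL, aromatics = NULL,
                               weights = c(1, 1, 2, 0.5, 0.5),
                               rmsd_cutoff = 2.5, aromatic_radius = 10) {
  if (length(weights) != 5) stop("weights must have length 5")
  if (length(cavities) == 0)
    return(base::structure(list(sites = list(), weights = weights),
                     class = "site_report"))
  vols <- vapply(cavities, `[[`, 0, "volume")
  vmax <- max(vols)
  arom_ca <- NULL
  if (!is.null(aromatics) && nrow(aromatics) > 0) {
    bb <- backbone_coords(structure, aromatics$chain[1])
    arom_ca <- bb$CA[match(aromatics$key, bb$key), , drop = FALSE]
  }
  score_rows <- lapply(cavities, function(cv) {
    lining <- cv$lining_residues
    cons <- 0
    if (!is.null(profile)) {
      sc <- profile$residue_scores$score[profile$residue_scores$key %in% lining]
      if (length(sc) > 0) cons <- mean(sc)
    }
    tmpl <- 0; best_hit <- NULL
    if (!is.null(hits) && length(hits) > 0) {
      for (h in hits) {
        if (all(h$residues %in% lining)) {
          s <- max(0, (rmsd_cutoff - h$rmsd) / rmsd_cutoff)
          if (s > tmpl) { tmpl <- s; best_hit <- h }
        }
      }
    }
    nest_in <- FALSE; nest_keys <- character(0)
    if (!is.null(nests)) {
      for (ns in nests) if (any(ns$keys %in% lining)) {
        nest_in <- TRUE
        nest_keys <- union(nest_keys, ns$keys[ns$keys %in% lining])
      }
    }
    n_arom <- 0
    if (!is.null(arom_ca) && nrow(arom_ca) > 0) {
      d <- sqrt(rowSums(sweep(arom_ca, 2, cv$centroid)^2))
      n_arom <- sum(d <= aromatic_radius, na.rm = TRUE)
    }
    terms <- c(volume = cv$volume / vmax, conservation = cons,
               template = tmpl, nest = as.numeric(nest_in),
               aromatics = min(n_arom, 5) / 5)
    list(cavity = cv, terms = as.list(terms),
         template_hit = best_hit, nest_residues = nest_keys,
         n_exposed_aromatics = n_arom,
         composite = sum(weights * terms))
  })
  comp <- vapply(score_rows, `[[`, 0, "composite")
  cents <- do.call(rbind, lapply(cavities, `[[`, "centroid"))
  ord <- order(-comp, -vols, cents[, 1], cents[, 2], cents[, 3])
  sites <- score_rows[ord]
  for (i in seq_along(sites)) sites[[i]]$rank <- i
  base::structure(list(sites = sites, weights = weights), class = "site_report")
}

#' @export
print.site_report <- function(x, ...) {
  cat(sprintf("<site_report> %d candidate sites\n", length(x$sites)))
  for (s in x$sites) {
    cat(sprintf("  #%d composite %.3f volume %.0f A^3 (%d lining residues)%s\n",
                s$rank, s$composite, s$cavity$volume,
                length(s$cavity$lining_residues),
                if (!is.null(s$template_hit))
                  sprintf(" template hit rmsd %.2f A [%s]",
                          s$template_hit$rmsd,
                          paste(s$template_hit$residues, collapse = ","))
                else ""))
  }
  invisible(x)
}
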