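# Fixtures built in code: minimal PDB text, small alignments, rigid motions.

mini_pdb <- function() {
  paste(
    "CRYST1   77.080   77.080  155.300  90.00  90.00  90.00 P 43 21 2     8",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA AALA A   1      12.000   6.000  -6.000  0.60 10.00           C",
    "ATOM      3  CA BALA A   1      12.500   6.100  -6.100  0.40 11.00           C",
    "ATOM      4  C   ALA A   1      13.000   6.500  -5.500  1.00  0.00           C",
    "ATOM      5  N   GLY A   2      13.500   7.000  -5.000  1.00  0.00           N",
    "HETATM    6 SE   MSE A   3      14.000   8.000  -4.000  1.00  0.00          SE",
    "HETATM    7  C1  GOL A 100       2.000   1.000   0.000  1.00  0.00           C",
    "HETATM    8  O   HOH A 101       1.000   2.000   3.000  1.00  0.00           O",
    sep = "\n")
}

# rename a structure's polymer residues so they spell a given one-letter
# sequence (backbone-only fixtures; sidechains are not built)
with_sequence <- function(st, seq1) {
  aa3 <- names(funsite:::AA3TO1)[match(strsplit(seq1, "")[[1]],
                                       funsite:::AA3TO1)]
  rt <- residue_table(st)
  stopifnot(length(aa3) == nrow(rt))
  st$atoms$resname <- aa3[match(res_key(st), rt$key)]
  st
}

res_key <- function(st) {
  funsite:::res_key(st$atoms$chain, st$atoms$resno, st$atoms$icode)
}

# character-matrix alignment from named sequences
aln_from <- function(...) {
  seqs <- c(...)
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- names(seqs)
  funsite:::new_alignment(mat)
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

random_rotation_seeded <- function(seed) {
  set.seed(seed)
  funsite:::random_rotation()
}

# two structural repeats (irregular backbone), second rigidly moved with
# optional coordinate noise; returns structure with repeats at resno 1..n
# and 101..(100+n)
duplicated_repeat <- function(n = 40, noise = 0.5, seed = 5) {
  set.seed(seed)
  phi <- runif(n, -130, -50); psi <- runif(n, -60, 150)
  s1 <- funsite:::build_backbone(phi, psi, id = "rep")
  at <- s1$atoms
  xyz <- cbind(at$x, at$y, at$z)
  R <- funsite:::random_rotation()
  xyz2 <- sweep(xyz %*% t(R), 2, c(30, 5, -10), "+") +
    matrix(rnorm(length(xyz), 0, noise / sqrt(3)), ncol = 3)
  at2 <- at
  at2$x <- xyz2[, 1]; at2$y <- xyz2[, 2]; at2$z <- xyz2[, 3]
  at2$resno <- at2$resno + 100
  funsite:::new_structure("dup", rbind(at, at2))
}

# alignment with two clearly separated blocks plus shared constant columns
# (keeps all pairwise p-distances below 1 so Poisson distances exist)
two_block_alignment <- function() {
  blk <- cbind(rbind(a = rep(c("A", "C"), 10), b = rep(c("A", "C"), 10),
                     c = rep(c("W", "Y"), 10), d = rep(c("W", "Y"), 10)),
               matrix("G", 4, 10))
  blk[2, 1:2] <- c("C", "A"); blk[4, 1:2] <- c("Y", "W")
  rownames(blk) <- c("a", "b", "c", "d")
  funsite:::new_alignment(blk)
}

# composite fixture: hollow shell with a triad planted inside the cavity
# and a nest backbone placed off-centre
all_evidence_fixture <- function(radius = 8, seed = 2) {
  tpl <- canonical_triad_template()
  sh <- make_cavity_shell(radius)
  st <- sh$structure
  xyz <- cbind(st$atoms$x, st$atoms$y, st$atoms$z)
  set.seed(1)
  best <- NULL
  for (i in 1:2000) {
    s3 <- sample(nrow(xyz), 3)
    d <- sqrt(sum(colMeans(xyz[s3, ])^2))
    if (is.null(best) || d < best$d) best <- list(d = d, s3 = s3)
  }
  p <- plant_triad(st, tpl, positions = st$atoms$resno[best$s3], seed = seed)
  ns <- make_nest_backbone("RLR")
  nsat <- ns$atoms
  nsat$x <- nsat$x - mean(nsat$x) + 3
  nsat$y <- nsat$y - mean(nsat$y)
  nsat$z <- nsat$z - mean(nsat$z) - 2
  ns$atoms <- nsat
  list(structure = combine_structures(p$structure, ns), template = tpl,
       triad_keys = p$ground_truth$keys, shell_truth = sh$ground_truth)
}
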