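test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  a <- matrix(rnorm(12), 4)
  expect_equal(kabsch_superpose(a, a)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kabsch_superpose(a, a)$rotation, diag(3), tolerance = 1e-9)
  b <- sweep(a %*% t(rotation_z(90)), 2, c(5, 0, 0), "+")
  tr <- kabsch_superpose(a, b)
  expect_equal(tr$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_transform(tr, b), a, tolerance = 1e-9)
  expect_error(kabsch_superpose(a[1:2, ], b[1:2, ]), "at least 3")
  col <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(col, col), "degenerate")
})

test_that("Kabsch RMSD matches an exhaustive rotation-grid oracle", {
  # oracle: coarse quaternion grid + local refinement with optim
  set.seed(42)
  a <- matrix(rnorm(12), 4)
  b <- matrix(rnorm(12), 4)
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  obj <- function(q) sqrt(mean(rowSums((bc %*% t(quat_rot(q)) - ac)^2)))
  best <- Inf; bestq <- NULL
  for (i in 1:2000) {
    q <- rnorm(4)
    v <- obj(q)
    if (v < best) { best <- v; bestq <- q }
  }
  ref <- optim(bestq, obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))$value
  expect_equal(kabsch_superpose(a, b)$rmsd, ref, tolerance = 1e-6)
})

test_that("Kabsch RMSD is invariant under rigid motions of either set", {
  set.seed(7)
  a <- matrix(rnorm(18), 6)
  b <- matrix(rnorm(18), 6)
  r0 <- kabsch_superpose(a, b)$rmsd
  for (s in 1:5) {
    R <- random_rotation_seeded(s)
    t <- rnorm(3, 0, 10)
    expect_equal(kabsch_superpose(a, sweep(b %*% t(R), 2, t, "+"))$rmsd, r0,
                 tolerance = 1e-9)
    expect_equal(kabsch_superpose(sweep(a %*% t(R), 2, t, "+"), b)$rmsd, r0,
                 tolerance = 1e-9)
  }
})

test_that("dihedral of four points is rigid-invariant and negates on mirror", {
  p <- list(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0.5, 1, 1))
  d0 <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
  R <- random_rotation_seeded(3)
  t <- c(4, -2, 9)
  pm <- lapply(p, function(x) as.numeric(R %*% x) + t)
  expect_equal(dihedral_angle(pm[[1]], pm[[2]], pm[[3]], pm[[4]]), d0,
               tolerance = 1e-9)
  mir <- lapply(p, function(x) x * c(1, 1, -1))
  expect_equal(dihedral_angle(mir[[1]], mir[[2]], mir[[3]], mir[[4]]), -d0,
               tolerance = 1e-9)
})

test_that("backbone dihedrals invert the helix generator", {
  h <- build_helix(12, phi = -57, psi = -47)
  dh <- backbone_dihedrals(h, "A")
  interior <- 2:11
  expect_equal(dh$phi[interior], rep(-57, 10), tolerance = 0.5 / 57)
  expect_equal(dh$psi[interior], rep(-47, 10), tolerance = 0.5 / 47)
  expect_true(is.na(dh$phi[1]))
  expect_true(is.na(dh$psi[12]))
  two <- build_helix(2)
  dh2 <- backbone_dihedrals(two, "A")
  expect_true(is.na(dh2$phi[1]) && is.na(dh2$psi[2]))
})

test_that("a numbering gap with a long C-N distance breaks dihedral continuity", {
  h <- build_helix(10)
  at <- h$atoms
  shift <- at$resno > 5
  at$x[shift] <- at$x[shift] + 20     # physically separate residues 6-10
  at$resno[shift] <- at$resno[shift] + 10
  broken <- funsite:::new_structure("broken", at)
  dh <- backbone_dihedrals(broken, "A")
  expect_true(is.na(dh$phi[dh$resno == 16]))
  expect_true(is.na(dh$psi[dh$resno == 5]))
  expect_false(is.na(dh$phi[dh$resno == 17]))
})

test_that("SASA of an isolated atom matches the analytic sphere", {
  at <- data.frame(record = "ATOM", chain = "A", resno = 1, icode = "",
                   resname = "GLY", kind = "polymer", atom = "CA",
                   altloc = "", x = 0, y = 0, z = 0, occ = 1, b = 0,
                   element = "C", stringsAsFactors = FALSE)
  st <- funsite:::new_structure("one", at)
  s <- shrake_rupley_sasa(st)
  expect_equal(s$atom$area, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
  # two distant atoms keep full area
  at2 <- rbind(at, transform(at, resno = 2, x = 10))
  s2 <- shrake_rupley_sasa(funsite:::new_structure("two", at2))
  expect_equal(s2$atom$area, rep(4 * pi * 3.1^2, 2), tolerance = 0.02)
})

test_that("SASA is rigid-invariant and non-increasing when atoms are added", {
  h <- build_helix(8)
  s0 <- shrake_rupley_sasa(h)
  # translation moves the point lattice with the atoms: exact
  shifted <- transform_structure(h, diag(3), c(11, -4, 2))
  expect_equal(shrake_rupley_sasa(shifted)$atom$area, s0$atom$area,
               tolerance = 1e-9)
  # rotation re-samples the fixed lattice: equal to lattice resolution
  moved <- transform_structure(h, random_rotation_seeded(9), c(11, -4, 2))
  s1 <- shrake_rupley_sasa(moved)
  expect_equal(s1$residue$area, s0$residue$area, tolerance = 0.02)
  h12 <- build_helix(12)
  s2 <- shrake_rupley_sasa(h12)
  shared <- seq_len(nrow(s0$atom) - 4)  # skip the old C-terminal boundary
  expect_true(all(s2$atom$area[shared] <= s0$atom$area[shared] + 1e-9))
})

test_that("an atom enclosed in a tight shell has zero accessible area", {
  core <- data.frame(record = "ATOM", chain = "A", resno = 1, icode = "",
                     resname = "TRP", kind = "polymer", atom = "CA",
                     altloc = "", x = 0, y = 0, z = 0, occ = 1, b = 0,
                     element = "C", stringsAsFactors = FALSE)
  shell_xyz <- sphere_lattice(400) * 3.4
  shell <- data.frame(record = "ATOM", chain = "A",
                      resno = 1 + seq_len(nrow(shell_xyz)), icode = "",
                      resname = "GLY", kind = "polymer", atom = "CA",
                      altloc = "", x = shell_xyz[, 1], y = shell_xyz[, 2],
                      z = shell_xyz[, 3], occ = 1, b = 0, element = "C",
                      stringsAsFactors = FALSE)
  st <- funsite:::new_structure("buried", rbind(core, shell))
  s <- shrake_rupley_sasa(st)
  expect_equal(s$atom$area[1], 0)
})

test_that("unknown elements fall back to a default radius with a warning", {
  at <- data.frame(record = "HETATM", chain = "A", resno = 1, icode = "",
                   resname = "UNL", kind = "polymer", atom = "Q1",
                   altloc = "", x = 0, y = 0, z = 0, occ = 1, b = 0,
                   element = "Q", stringsAsFactors = FALSE)
  expect_warning(s <- shrake_rupley_sasa(funsite:::new_structure("q", at)),
                 "radius")
  expect_equal(s$atom$area, 4 * pi * 3.1^2, tolerance = 0.02)
})

test_that("segment superposition of a segment onto itself is the identity", {
  h <- build_helix(30)
  sa <- superpose_segments(h, c(1, 15), c(1, 15))
  expect_equal(sa$n_matched, 15)
  expect_equal(sa$rmsd, 0, tolerance = 1e-9)
  expect_equal(sa$pairs$resno_a, sa$pairs$resno_b)
})

test_that("segment superposition recovers a noisy duplicated repeat", {
  st <- duplicated_repeat(n = 40, noise = 0.5, seed = 5)
  sa <- superpose_segments(st, c(1, 40), c(101, 140))
  expect_equal(sa$n_matched, 40)
  expect_true(sa$rmsd >= 0.3 && sa$rmsd <= 0.8)
  expect_equal(sa$pairs$resno_b - sa$pairs$resno_a, rep(100, 40))
  expect_error(superpose_segments(st, c(1, 5), c(101, 105)), "at least 10")
})
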