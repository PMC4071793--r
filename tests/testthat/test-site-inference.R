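test_that("template extraction records carboxylate groups and errors on missing atoms", {
  p <- plant_triad(build_helix(40), noise_sigma = 0.1, seed = 1)
  tpl <- extract_template(p$structure, p$ground_truth$keys)
  expect_s3_class(tpl, "site_template")
  expect_length(tpl$members, 3)
  expect_equal(sum(vapply(tpl$members, function(m) nrow(m$coords), 0L)), 9)
  expect_setequal(tpl$members[[1]]$classes, c("ASP", "GLU"))
  # residue lacking a carboxylate oxygen
  broken <- p$structure
  broken$atoms <- broken$atoms[!(broken$atoms$atom == "OD2" &
                                   broken$atoms$resno == 10), ]
  expect_error(extract_template(broken, p$ground_truth$keys), "OD2")
})

test_that("template JSON round-trips through the schema", {
  tpl <- canonical_triad_template()
  tf <- withr::local_tempfile(fileext = ".json")
  write_template(tpl, tf)
  tpl2 <- read_template(tf)
  expect_equal(tpl2$name, tpl$name)
  for (i in 1:3) {
    expect_equal(tpl2$members[[i]]$classes, tpl$members[[i]]$classes)
    expect_equal(unname(tpl2$members[[i]]$coords), tpl$members[[i]]$coords)
  }
})

test_that("a template extracted from the query hits itself first at RMSD 0", {
  p <- plant_triad(build_helix(40), noise_sigma = 0.1, seed = 1)
  tpl <- extract_template(p$structure, p$ground_truth$keys)
  hits <- match_template(p$structure, tpl)
  expect_gte(length(hits), 1)
  expect_equal(hits[[1]]$rmsd, 0, tolerance = 1e-9)
  expect_setequal(hits[[1]]$residues, p$ground_truth$keys)
})

test_that("planted triads are recovered at the oracle Kabsch RMSD", {
  tpl <- canonical_triad_template()
  t_all <- do.call(rbind, lapply(tpl$members, `[[`, "coords"))
  base <- build_helix(40)
  for (seed in c(3, 7, 11)) {
    for (sigma in c(0, 0.2, 0.5)) {
      p <- plant_triad(base, tpl, noise_sigma = sigma, seed = seed)
      hits <- match_template(p$structure, tpl)
      expect_gte(length(hits), 1)
      expect_setequal(hits[[1]]$residues, p$ground_truth$keys)
      oracle <- kabsch_superpose(p$ground_truth$planted_coords, t_all)$rmsd
      expect_equal(hits[[1]]$rmsd, oracle, tolerance = 1e-6)
    }
  }
})

test_that("heavily perturbed triads fall outside the RMSD cutoff", {
  p <- plant_triad(build_helix(40), noise_sigma = 3, seed = 7)
  expect_length(match_template(p$structure, canonical_triad_template()), 0)
})

test_that("template matching is invariant under rigid motion of the query", {
  tpl <- canonical_triad_template()
  p <- plant_triad(build_helix(40), tpl, noise_sigma = 0.3, seed = 5)
  h0 <- match_template(p$structure, tpl)
  for (s in 1:3) {
    moved <- transform_structure(p$structure, random_rotation_seeded(s),
                                 c(7, -12, 3) * s)
    h1 <- match_template(moved, tpl)
    expect_equal(length(h1), length(h0))
    expect_equal(h1[[1]]$residues, h0[[1]]$residues)
    expect_equal(h1[[1]]$rmsd, h0[[1]]$rmsd, tolerance = 1e-6)
  }
})

test_that("nest detection reports one nest per maximal alternating run", {
  expect_length(detect_nests(build_helix(20)), 0)   # all-R helix: no nest
  n1 <- detect_nests(make_nest_backbone("RL"))
  expect_length(n1, 1)
  expect_length(n1[[1]]$keys, 3)
  expect_equal(n1[[1]]$pattern, "RL")
  n2 <- detect_nests(make_nest_backbone("RLRL"))
  expect_length(n2, 1)
  expect_length(n2[[1]]$keys, 5)
  expect_length(detect_nests(make_nest_backbone("RRRR")), 0)
  n3 <- detect_nests(make_nest_backbone("LRL"))
  expect_equal(n3[[1]]$pattern, "LRL")
})

test_that("nest detection is invariant to rigid motion", {
  st <- make_nest_backbone("RLR")
  n0 <- detect_nests(st)
  moved <- transform_structure(st, random_rotation_seeded(8), c(-4, 9, 1))
  n1 <- detect_nests(moved)
  expect_equal(n1, n0)
})

test_that("a convex helix has no cavity at the default minimum volume", {
  expect_length(detect_cavities(build_helix(20)), 0)
})

test_that("shell cavities recover the analytic volume within 15%", {
  for (r in c(5, 6, 8)) {
    sh <- make_cavity_shell(r)
    cv <- detect_cavities(sh$structure)
    expect_gte(length(cv), 1)
    truth <- sh$ground_truth$volume
    expect_lt(abs(cv[[1]]$volume - truth) / truth, 0.15)
    expect_equal(cv[[1]]$volume, cv[[1]]$grid_points * 0.9^3)
    expect_equal(cv[[1]]$centroid, c(0, 0, 0), tolerance = 0.5)
  }
})

test_that("cavity volume error shrinks as the grid is refined", {
  sh <- make_cavity_shell(6)
  errs <- vapply(c(1.2, 0.9, 0.6), function(s) {
    cv <- detect_cavities(sh$structure, spacing = s)
    abs(cv[[1]]$volume - sh$ground_truth$volume) / sh$ground_truth$volume
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("cavity detection is invariant to rigid motion", {
  sh <- make_cavity_shell(5)
  cv0 <- detect_cavities(sh$structure)
  moved <- transform_structure(sh$structure, random_rotation_seeded(4),
                               c(13, -6, 21))
  cv1 <- detect_cavities(moved)
  expect_equal(length(cv1), length(cv0))
  expect_equal(cv1[[1]]$volume, cv0[[1]]$volume,
               tolerance = 0.05)
})

test_that("exposed aromatics are found when exposed and dropped when buried", {
  # extended Gly-Trp-Gly: Trp fully exposed
  st <- build_helix(3, phi = -120, psi = 120)
  at <- st$atoms
  at$resname[at$resno == 2] <- "TRP"
  st$atoms <- at
  sasa <- shrake_rupley_sasa(st)
  ar <- exposed_aromatics(st, sasa)
  expect_equal(ar$resno, 2)
  expect_equal(ar$resname, "TRP")
  # the same Trp packed inside a solid block of pseudo-atoms is buried
  at2 <- at
  at2$x <- at2$x - mean(at2$x); at2$y <- at2$y - mean(at2$y)
  at2$z <- at2$z - mean(at2$z)
  g <- seq(-8, 8, by = 1.5)
  grid <- as.matrix(expand.grid(g, g, g))
  pxyz <- cbind(at2$x, at2$y, at2$z)
  keep <- apply(grid, 1, function(p)
    min(sqrt(rowSums(sweep(pxyz, 2, p)^2))) > 1.0)
  grid <- grid[keep, ]
  block <- data.frame(record = "ATOM", chain = "A",
                      resno = 100 + seq_len(nrow(grid)), icode = "",
                      resname = "GLY", kind = "polymer", atom = "CA",
                      altloc = "", x = grid[, 1], y = grid[, 2],
                      z = grid[, 3], occ = 1, b = 0, element = "C",
                      stringsAsFactors = FALSE)
  buried <- funsite:::new_structure("buried", rbind(at2, block))
  sasa2 <- shrake_rupley_sasa(buried)
  expect_length(exposed_aromatics(buried, sasa2)$resno, 0)
})

test_that("evidence integration ranks the all-evidence cavity first", {
  fx <- all_evidence_fixture()
  st <- fx$structure
  sasa <- shrake_rupley_sasa(st)
  cav <- detect_cavities(st)
  hits <- match_template(st, fx$template)
  nests <- detect_nests(st)
  arom <- exposed_aromatics(st, sasa)
  rep <- integrate_evidence(st, cav, hits = hits, nests = nests,
                            aromatics = arom)
  expect_gte(length(rep$sites), 1)
  top <- rep$sites[[1]]
  expect_true(all(fx$triad_keys %in% top$cavity$lining_residues))
  expect_false(is.null(top$template_hit))
  expect_gt(top$terms$nest, 0)
})

test_that("without evidence the composite reflects the volume term only", {
  sh <- make_cavity_shell(5)
  cav <- detect_cavities(sh$structure)
  rep <- integrate_evidence(sh$structure, cav)
  for (s in rep$sites) {
    expect_equal(s$composite, s$terms$volume * 1)
    expect_equal(s$terms$conservation + s$terms$template + s$terms$nest +
                   s$terms$aromatics, 0)
  }
  expect_error(integrate_evidence(sh$structure, cav, weights = c(1, 2)),
               "length 5")
})

test_that("improving one evidence term never lowers a cavity's rank", {
  fx <- all_evidence_fixture()
  st <- fx$structure
  cav <- detect_cavities(st)
  hits <- match_template(st, fx$template)
  base <- integrate_evidence(st, cav)
  with_tmpl <- integrate_evidence(st, cav, hits = hits)
  rank_of <- function(rep, vol) {
    for (s in rep$sites) if (abs(s$cavity$volume - vol) < 1e-9) return(s$rank)
    NA_integer_
  }
  v1 <- cav[[1]]$volume
  expect_lte(rank_of(with_tmpl, v1), rank_of(base, v1))
  # two identical cavities tie-break deterministically
  rep1 <- integrate_evidence(st, cav)
  rep2 <- integrate_evidence(st, cav)
  expect_identical(lapply(rep1$sites, `[[`, "rank"),
                   lapply(rep2$sites, `[[`, "rank"))
})
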