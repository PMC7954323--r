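# PDB reading, sequence-to-structure mapping, Shrake-Rupley solvent
# accessibility, inter-residue geometry and single-linkage clustering.

test_that("toy PDB files round-trip through the reader", {
  ts <- generate_toy_structure(list(n_res = 3, geometry = "extended"),
                               seed = 1)
  st <- read_structure(ts$pdb)
  expect_equal(nrow(st$residues), 3)
  expect_equal(nrow(st$atoms), 6)          # CA + pseudo side chain each
  expect_equal(st$sequence, ts$manifest$sequence)
})

test_that("altloc resolves to highest occupancy and hetero atoms drop", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END"), pdb)
  st <- read_structure(pdb)
  expect_equal(nrow(st$residues), 2)       # water excluded
  a1 <- st$atoms[st$atoms$residx == 1, ]
  expect_equal(nrow(a1), 1)
  expect_equal(a1$x, 5.0)                  # occupancy 0.60 altloc kept
  expect_error(read_structure(tempfile(fileext = ".pdb")))
})

test_that("sequence-to-structure maps cover identities and substitutions", {
  ts <- generate_toy_structure(list(n_res = 30, geometry = "ideal_helix"),
                               seed = 6)
  st <- read_structure(ts$pdb)
  m <- map_sequence_to_structure(st$sequence, st)
  expect_equal(attr(m, "coverage_pct"), 100)
  expect_true(attr(m, "usable"))
  expect_equal(m$isoform_pos, m$residx)

  # five substitutions keep the identity map
  ch <- strsplit(st$sequence, "")[[1]]
  pos <- c(3, 9, 15, 21, 27)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "D"), ch[p])[1]
  m2 <- map_sequence_to_structure(paste(ch, collapse = ""), st)
  expect_equal(m2$isoform_pos, m2$residx)
  expect_lt(attr(m2, "identity_pct"), 100)

  # an isoform covering half the structure is flagged unusable
  half <- substr(st$sequence, 1, 15)
  m3 <- map_sequence_to_structure(half, st)
  expect_lt(attr(m3, "coverage_pct"), 80)
  expect_false(attr(m3, "usable"))
})

test_that("isolated-atom SASA equals the analytic sphere area", {
  st <- make_structure(list(matrix(c(0, 0, 0), 1)))
  sasa <- compute_rasa(st)
  analytic <- 4 * pi * (1.70 + 1.4)^2     # carbon + probe
  expect_lt(abs(sasa$sasa[1] - analytic) / analytic, 0.02)
  # a lone residue is fully exposed relative to its reference max
  ts <- generate_toy_structure(list(n_res = 1, geometry = "extended",
                                    sequence = "A"), seed = 1)
  st1 <- read_structure(ts$pdb)
  s1 <- compute_rasa(st1)
  expect_true(s1$exposed[1])
  expect_gt(s1$rasa[1], 100)   # two bare atoms exceed the folded reference
})

test_that("total SASA is invariant under rigid rotation", {
  set.seed(5)
  coords <- lapply(1:8, function(i) matrix(rnorm(6, sd = 4), 2))
  st <- make_structure(coords)
  s0 <- sum(compute_rasa(st)$sasa)
  th <- 0.7; R <- matrix(c(cos(th), -sin(th), 0,
                           sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- lapply(coords, function(m) m %*% R + 3)
  s1 <- sum(compute_rasa(make_structure(rot))$sasa)
  expect_lt(abs(s1 - s0) / s0, 0.005)
})

test_that("exposure is strictly above the rASA cutoff", {
  ts <- generate_toy_structure(list(n_res = 5, geometry = "ideal_helix"),
                               seed = 2)
  st <- read_structure(ts$pdb)
  s <- compute_rasa(st)
  # setting the cutoff to a residue's own rASA makes it buried (strict >)
  s2 <- compute_rasa(st, exposed_cutoff = s$rasa[2])
  expect_false(s2$exposed[2])
  s3 <- compute_rasa(st, exposed_cutoff = s$rasa[2] - 1e-9)
  expect_true(s3$exposed[2])
  # rASA stays within the physically plausible band
  expect_true(all(s$rasa >= 0 & s$rasa <= 250))
  expect_true(all(s$sasa >= 0))
})

test_that("occluding cages bury the enclosed residues", {
  ts <- generate_toy_structure(list(n_res = 30, geometry = "ideal_helix",
                                    cage = 10:18), seed = 9)
  st <- read_structure(ts$pdb)
  s <- compute_rasa(st)
  expect_true(all(s$rasa[10:18] < 10))
  expect_true(all(!s$exposed[10:18]))
})

test_that("exposure fractions count exposed residues", {
  sasa <- data.frame(residx = 1:6, aa = "A", sasa = 1,
                     rasa = c(50, 50, 50, 5, 5, 5),
                     exposed = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(exposure_fraction(1:3, sasa), 1)
  expect_equal(exposure_fraction(1:6, sasa), 0.5)
  expect_error(exposure_fraction(integer(0), sasa), "empty")
  set.seed(8)
  for (k in 1:20) {
    sub <- sample(1:6, sample(1:6, 1))
    expect_equal(exposure_fraction(sub, sasa),
                 sum(sasa$exposed[sub]) / length(sub))
  }
})

test_that("minimum residue distances match the pairwise oracle", {
  st <- make_structure(list(matrix(c(0, 0, 0), 1),
                            matrix(c(0, 0, 0, 9, 9, 9), 2, byrow = TRUE),
                            matrix(c(5, 0, 0), 1)))
  expect_equal(min_residue_distance(1, 2, st), 0)   # shared position
  expect_equal(min_residue_distance(1, 3, st), 5)
  set.seed(12)
  coords <- lapply(1:6, function(i) matrix(rnorm(9, sd = 6), 3))
  st2 <- make_structure(coords)
  dm <- residue_distance_matrix(st2)
  for (i in 1:5) for (j in (i + 1):6) {
    oracle <- min(sqrt(.rowSums((coords[[i]][rep(1:3, each = 3), ] -
                                   coords[[j]][rep(1:3, 3), ])^2, 9, 3)))
    expect_equal(dm[i, j], oracle, tolerance = 1e-9)
    expect_equal(min_residue_distance(i, j, st2), oracle,
                 tolerance = 1e-9)
  }
})

test_that("single-linkage clustering matches connected components", {
  # chain A-B 7, B-C 7, A-C 13: one cluster by transitivity
  st <- make_structure(list(matrix(c(0, 0, 0), 1),
                            matrix(c(7, 0, 0), 1),
                            matrix(c(10.5, 6.06, 0), 1)))
  cl <- cluster_variable_residues(st, 1:3, link = 8, min_size = 3)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members, 1:3)
  expect_equal(cl[[1]]$size, 3)
  expect_equal(cl[[1]]$center_of_mass,
               colMeans(rbind(c(0, 0, 0), c(7, 0, 0), c(10.5, 6.06, 0))))

  # three mutually close residues form a cluster, two isolated do not
  st2 <- make_structure(list(matrix(c(0, 0, 0), 1), matrix(c(4, 0, 0), 1),
                             matrix(c(0, 4, 0), 1),
                             matrix(c(50, 0, 0), 1),
                             matrix(c(60, 0, 0), 1)))
  cl2 <- cluster_variable_residues(st2, 1:5)
  expect_length(cl2, 1)
  expect_equal(cl2[[1]]$members, 1:3)
  expect_length(cluster_variable_residues(st2, 4:5), 0)

  # order invariance + brute-force component oracle on random points
  set.seed(31)
  for (k in 1:10) {
    coords <- lapply(1:12, function(i) matrix(stats::runif(3, 0, 25), 1))
    stk <- make_structure(coords)
    dm <- residue_distance_matrix(stk)
    got <- cluster_variable_residues(stk, 1:12, link = 8, min_size = 1,
                                     dmat = dm)
    shuffled <- cluster_variable_residues(stk, sample(12), link = 8,
                                          min_size = 1, dmat = dm)
    canon <- function(cl) unname(sort(vapply(cl, function(c)
      paste(c$members, collapse = ","), character(1))))
    expect_equal(canon(got), canon(shuffled))
    comp <- oracle_components(dm, 8)
    oracle <- sort(vapply(split(1:12, comp), paste, character(1),
                          collapse = ","))
    expect_equal(canon(got), unname(oracle))
  }
})

test_that("cluster-to-site distances honour the in-cluster zero rule", {
  st <- make_structure(list(matrix(c(0, 0, 0), 1), matrix(c(4, 0, 0), 1),
                            matrix(c(0, 4, 0), 1), matrix(c(20, 0, 0), 1),
                            matrix(c(2, 2, 7), 1)))
  cl <- cluster_variable_residues(st, 1:3)[[1]]
  expect_equal(com_to_site_distance(cl, c(2, 4), st), 0)  # member site
  d <- com_to_site_distance(cl, 4, st)
  expect_equal(d, sqrt(sum((c(20, 0, 0) - cl$center_of_mass)^2)))
  # multiple sites: exhaustive minimum
  d2 <- com_to_site_distance(cl, 4:5, st)
  expect_equal(d2, min(d, sqrt(sum((c(2, 2, 7) - cl$center_of_mass)^2))))
  expect_error(com_to_site_distance(cl, integer(0), st), "empty")
})
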