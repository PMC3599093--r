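# A synthetic "contact gas": atoms with random types from a small type
# pool, uniformly mixed in a box. Expected and observed contact counts
# then agree up to sampling noise and all pair energies sit near zero.
make_gas <- function(n_atoms, seed, box = 33) {
  set.seed(seed)
  pool <- data.frame(aa = c("A", "A", "G", "S", "C"),
                     name = c("CA", "CB", "CA", "OG", "SG"))
  pick <- sample(nrow(pool), n_atoms, replace = TRUE)
  xyz <- matrix(stats::runif(3L * n_atoms, 0, box), n_atoms, 3L)
  bare_structure(xyz, pool$aa[pick], pool$name[pick],
                 resno = seq_len(n_atoms))
}

test_that("the heavy-atom type alphabet has 167 unique members", {
  tt <- atom_type_table()
  expect_equal(nrow(tt), 167L)
  expect_false(any(duplicated(tt$type)))
  expect_equal(sum(tt$aa == "GLY"), 4L)   # backbone only
  expect_equal(sum(tt$aa == "TRP"), 14L)  # largest residue
})

test_that("a uniformly mixed gas trains to near-zero energies", {
  pot <- train_contact_potential(list(make_gas(2000, seed = 31)),
                                 cutoff = 5.0)
  expect_lt(max(abs(pot$energy)), 0.1)
})

test_that("unseen pairs get positive finite energy; matrix is symmetric", {
  # two far-apart residue groups of fixed types: LYS NZ never meets SER OG
  xyz <- matrix(c(0, 0, 0, 4, 0, 0,
                  50, 0, 0, 54, 0, 0), 4L, 3L, byrow = TRUE)
  s <- bare_structure(xyz, c("K", "K", "S", "S"),
                      c("NZ", "NZ", "OG", "OG"), resno = c(1L, 3L, 6L, 8L))
  pot <- train_contact_potential(list(s), cutoff = 5.0, pseudocount = 1)
  e_unseen <- pot$energy["LYS:NZ", "SER:OG"]
  expect_true(is.finite(e_unseen))
  expect_gt(e_unseen, 0)
  expect_identical(pot$energy, t(pot$energy))
  expect_error(train_contact_potential(list(bare_structure(
    matrix(c(0, 0, 0), 1L), "G", "CA")), cutoff = 5.0),
    "training set too small")
})

test_that("residue energies match a brute-force double-loop oracle", {
  pot <- shared_potential()
  ag <- make_toy_antigen(25, seed = 77)
  got <- residue_energies(ag, pot)

  at <- ag$atoms[ag$atoms$is_heavy, ]
  ty <- paste(aa3_of(at$aa), at$name, sep = ":")
  want <- numeric(n_residues(ag))
  for (i in seq_len(nrow(at) - 1L)) {
    for (j in (i + 1L):nrow(at)) {
      if (abs(at$res_index[i] - at$res_index[j]) < 2L) next
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
      if (d > pot$cutoff) next
      e <- pot$energy[ty[i], ty[j]]
      want[at$res_index[i]] <- want[at$res_index[i]] + e
      want[at$res_index[j]] <- want[at$res_index[j]] + e
    }
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("isolated and two-residue contact cases follow the formulas", {
  pot <- shared_potential()
  # two CYS SG atoms 4 A apart, sequence separation 2
  xyz <- matrix(c(0, 0, 0, 50, 50, 50, 4, 0, 0), 3L, 3L, byrow = TRUE)
  s <- bare_structure(xyz, c("C", "A", "C"), c("SG", "CB", "SG"),
                      resno = 1:3)
  e <- residue_energies(s, pot)
  expect_equal(e[2L], 0)  # no contacts within cutoff
  expect_equal(e[1L], e[3L])
  expect_equal(e[1L], pot$energy["CYS:SG", "CYS:SG"])
})

test_that("local averaging covers sphere, singleton and zero radius", {
  pot <- shared_potential()
  # three residues mutually within 8 A
  xyz <- matrix(c(0, 0, 0, 5, 0, 0, 2.5, 4, 0), 3L, 3L, byrow = TRUE)
  s <- bare_structure(xyz, c("A", "A", "A"), c("CB", "CB", "CB"),
                      resno = 1:3)
  prof <- energy_profile(s, pot, surface = 1:3, radius = 8.0)
  manual <- residue_energies(s, pot)
  expect_equal(prof$local_avg, rep(mean(manual), 3L))
  prof0 <- energy_profile(s, pot, surface = 1:3, radius = 0)
  expect_equal(prof0$local_avg, manual)
  prof_far <- energy_profile(s, pot, surface = c(1L, 2L), radius = 1.0)
  expect_equal(prof_far$local_avg[1L], manual[1L])  # no neighbours
})

test_that("energy ranking respects fraction, ties and determinism", {
  fake_profile <- structure(list(
    energy = c(5, 1, 1, 1, 4, 3, 2, 2, 6, 0),
    local_avg = c(2, 2, 2, 2, 2, 2, 2, 2, 2, 2),
    surface = 1:10), class = "energy_profile")
  top2 <- rank_by_energy(fake_profile, 1:10, 0.2)
  expect_equal(top2, c(9L, 1L))  # equal local avg, raw energy breaks tie
  expect_equal(rank_by_energy(fake_profile, 1:10, 1.0),
               c(9L, 1L, 5L, 6L, 7L, 8L, 2L, 3L, 4L, 10L))
  expect_error(rank_by_energy(fake_profile, integer(0)), "empty surface")
})

test_that("energies are invariant under rigid motion", {
  pot <- shared_potential()
  ag <- make_toy_antigen(20, seed = 12)
  moved <- rigid_move(ag)
  expect_equal(residue_energies(moved, pot), residue_energies(ag, pot),
               tolerance = 1e-9)
})

test_that("potentials from disjoint halves of a structured set correlate", {
  # a gas with spatially sorted types: each type concentrates in its own
  # slab, so pair contact preferences are strong and systematic; two
  # disjoint samples must then recover near-identical energies
  sorted_gas <- function(n, seed) {
    set.seed(seed)
    pool <- data.frame(aa = c("A", "A", "G", "S", "C", "V"),
                       name = c("CA", "CB", "CA", "OG", "SG", "CG1"))
    pick <- sample(nrow(pool), n, replace = TRUE)
    xyz <- cbind(stats::rnorm(n, mean = 8 * pick, sd = 3),
                 stats::runif(n, 0, 20), stats::runif(n, 0, 20))
    bare_structure(xyz, pool$aa[pick], pool$name[pick],
                   resno = seq_len(n))
  }
  pot_a <- train_contact_potential(list(sorted_gas(2500, seed = 61)))
  pot_b <- train_contact_potential(list(sorted_gas(2500, seed = 62)))
  seen <- c("ALA:CA", "ALA:CB", "GLY:CA", "SER:OG", "CYS:SG", "VAL:CG1")
  v <- upper.tri(pot_a$energy[seen, seen], diag = TRUE)
  expect_gt(stats::cor(pot_a$energy[seen, seen][v],
                       pot_b$energy[seen, seen][v]), 0.9)
})

test_that("planted patches surface in the top local-energy fraction", {
  fx <- shared_fixtures()
  lab <- shared_labeled()
  pot <- shared_potential()
  hit <- vapply(seq_along(fx), function(i) {
    surf <- lab[[i]]$surface
    prof <- energy_profile(fx[[i]]$structure, pot, surf)
    top <- rank_by_energy(prof, surf, 0.2)
    any(lab[[i]]$ce %in% top)
  }, logical(1))
  expect_gte(mean(hit), 0.8)
})
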