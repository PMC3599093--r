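# A hand-made prediction scenario: residues on a line, synthetic SR and
# energy values, so anchor selection is fully controlled.
line_scenario <- function(n = 30L, spacing_a = 5.0) {
  xyz <- cbind((seq_len(n) - 1L) * spacing_a, 0, 0)
  s <- bare_structure(xyz, rep("A", n), rep("CB", n), resno = seq_len(n))
  res <- residue_table(s)
  res$sr <- rep(0.35, n)
  res$n_surface_atoms <- 1L
  res$is_surface <- TRUE
  tab <- structure(list(atoms = NULL, residues = res, min_sr = 0.05),
                   class = "surface_table")
  list(structure = s, table = tab)
}

fake_profile <- function(energy, surface = seq_along(energy)) {
  structure(list(energy = energy, local_avg = energy, surface = surface),
            class = "energy_profile")
}

test_that("anchor selection enforces the separation rule", {
  sc <- line_scenario(10L, spacing_a = 5.0)
  cfg <- predictor_config(top_energy_fraction = 0.2)
  # residues 5 and 6 carry the top energies but are 5 A apart
  prof <- fake_profile(c(1, 1, 1, 1, 9, 8, 1, 1, 1, 1))
  got <- select_anchors(prof, sc$table, sc$structure, cfg)
  expect_equal(got, 5L)

  # residues 2 and 9 are 35 A apart: both kept
  prof2 <- fake_profile(c(1, 9, 1, 1, 1, 1, 1, 1, 8, 1))
  expect_equal(select_anchors(prof2, sc$table, sc$structure, cfg),
               c(2L, 9L))
})

test_that("anchor selection matches a brute-force greedy oracle", {
  set.seed(55)
  for (rep in 1:5) {
    sc <- line_scenario(30L, spacing_a = 4.0)
    e <- stats::runif(30, 0, 10)
    sr <- stats::runif(30, 0, 1)
    sc$table$residues$sr <- sr
    prof <- fake_profile(e)
    cfg <- predictor_config()
    got <- select_anchors(prof, sc$table, sc$structure, cfg)

    # oracle: rank all 30 by energy, keep top ceiling(0.2*30) = 6, filter
    # SR band, then greedy 12-A exclusion on the line
    ord <- order(-e, seq_len(30))
    top <- ord[1:6]
    cand <- top[sr[top] >= 0.2 & sr[top] <= 0.5]
    kept <- integer(0)
    for (r in cand) {
      if (all(abs(r - kept) * 4.0 >= 12)) kept <- c(kept, r)
    }
    expect_equal(got, kept)
  }
})

test_that("cluster growth is a CA-sphere membership filter", {
  sc <- line_scenario(12L, spacing_a = 4.0)
  cfg <- predictor_config()
  cl <- grow_cluster(6L, sc$structure, seq_len(12L), cfg)
  # 10 A at 4-A spacing reaches 2 residues each side
  expect_equal(cl$members, 4:8)
  expect_true(6L %in% cl$members)

  cfg0 <- predictor_config(grow_radius = 0)
  expect_equal(grow_cluster(6L, sc$structure, seq_len(12L), cfg0)$members,
               6L)
})

test_that("cluster scoring respects the weight boundaries", {
  sc <- line_scenario(24L, spacing_a = 5.0)
  cfg <- predictor_config()
  prof <- fake_profile(c(rep(8, 4), rep(1, 16), rep(5, 4)))
  keys <- enumerate_pair_alphabet()
  tab <- data.frame(pair = keys, cei = stats::runif(210),
                    stringsAsFactors = FALSE)
  attr(tab, "radius") <- 4.0
  class(tab) <- c("cei_table", "data.frame")
  clusters <- lapply(c(2L, 12L, 22L), grow_cluster, structure =
                       sc$structure, surface = seq_len(24L), cfg = cfg)
  scored <- score_clusters(clusters, prof, sc$structure, tab, cfg)
  es <- vapply(scored, `[[`, numeric(1), "energy_score")
  expect_equal(es[1L], 1)  # highest mean energy cluster
  expect_equal(es[2L], 0)  # lowest
  # single-cluster normalization convention
  solo <- score_clusters(clusters[1L], prof, sc$structure, tab, cfg)
  expect_equal(solo[[1L]]$energy_score, 1)
  expect_equal(solo[[1L]]$combined_score,
               cfg$w_eg + cfg$w_gaap * solo[[1L]]$cei_score)
})

test_that("prediction recovers planted patches and obeys the contract", {
  fx <- shared_fixtures()
  preds <- shared_predictions()
  lab <- shared_labeled()
  overlap <- logical(0)
  for (i in seq_along(fx)) {
    pr <- preds[[i]]
    expect_lte(length(pr$clusters), 3L)
    if (length(pr$anchors) > 1L) {
      ca <- ca_coords(fx[[i]]$structure)
      expect_gte(min(stats::dist(ca[pr$anchors, , drop = FALSE])), 12)
    }
    for (cl in pr$clusters) {
      expect_true(all(cl$members %in% lab[[i]]$surface))
      expect_true(cl$anchor %in% cl$members)
      expect_equal(cl$combined_score,
                   pr$cfg$w_eg * cl$energy_score +
                     pr$cfg$w_gaap * cl$cei_score)
    }
    if (length(pr$clusters) > 0L) {
      jac <- length(intersect(pr$clusters[[1L]]$members, fx[[i]]$ce)) /
        length(union(pr$clusters[[1L]]$members, fx[[i]]$ce))
      overlap <- c(overlap, jac > 0)
    }
  }
  # rank-1 clusters overlap the planted patch on most fixtures
  expect_gte(mean(overlap), 0.7)
})

test_that("prediction is deterministic and truncates at top_k", {
  fx <- shared_fixtures()[[1L]]
  pot <- shared_potential()
  cei <- shared_cei()
  p1 <- predict_epitopes(fx$structure, pot, cei)
  p2 <- predict_epitopes(fx$structure, pot, cei)
  expect_equal(lapply(p1$clusters, `[[`, "members"),
               lapply(p2$clusters, `[[`, "members"))
  k1 <- predict_epitopes(fx$structure, pot, cei,
                         cfg = predictor_config(top_k = 1))
  expect_lte(length(k1$clusters), 1L)
  if (length(k1$clusters) == 1L && length(p1$clusters) > 0L)
    expect_equal(k1$clusters[[1L]]$anchor, p1$clusters[[1L]]$anchor)
})

test_that("ranking is invariant under translation of the antigen", {
  # the voxel lattice follows the atom bounding box, so a rigid shift
  # (grid-aligned or not) reproduces the pipeline exactly; rotational
  # robustness of the energies is covered in the energy tests
  fx <- shared_fixtures()[[2L]]
  pot <- shared_potential()
  cei <- shared_cei()
  p1 <- predict_epitopes(fx$structure, pot, cei)
  p2 <- predict_epitopes(rigid_move(fx$structure, angle = 0,
                                    shift = c(7.3, -2.1, 4.9)),
                         pot, cei)
  expect_equal(length(p1$clusters), length(p2$clusters))
  if (length(p1$clusters) > 0L) {
    expect_equal(p1$clusters[[1L]]$anchor, p2$clusters[[1L]]$anchor)
    expect_equal(p1$clusters[[1L]]$members, p2$clusters[[1L]]$members)
  }
})

test_that("prediction JSON export writes ranked clusters", {
  fx <- shared_fixtures()[[1L]]
  pr <- shared_predictions()[[1L]]
  path <- withr::local_tempfile(fileext = ".json")
  write_prediction(pr, fx$structure, path)
  obj <- jsonlite::read_json(path)
  expect_equal(length(obj$clusters), length(pr$clusters))
  expect_equal(obj$clusters[[1L]]$rank, 1)
  expect_equal(length(obj$clusters[[1L]]$members),
               length(pr$clusters[[1L]]$members))
})
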