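# A square of four residues: (0,0), (4,0), (0,4), (4,4) with single CB
# atoms. At radius 4 the four edges are pairs, the diagonals (5.7 A) are
# not.
square_structure <- function(aa = c("A", "H", "Q", "A")) {
  xyz <- matrix(c(0, 0, 0, 4, 0, 0, 0, 4, 0, 4, 4, 0), 4L, 3L,
                byrow = TRUE)
  bare_structure(xyz, aa, rep("CB", 4L), resno = 1:4)
}

test_that("the pair alphabet has 210 unordered keys", {
  keys <- enumerate_pair_alphabet()
  expect_length(keys, 210L)
  expect_false(any(duplicated(keys)))
  expect_true(pair_key("H", "Q") %in% keys)
  expect_equal(pair_key("Q", "H"), pair_key("H", "Q"))
  homo <- paste(sort(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                       "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")),
                sort(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                       "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")),
                sep = ":")
  expect_true(all(homo %in% keys))
})

test_that("geometric pairs respect the distance cutoff", {
  far <- bare_structure(matrix(c(0, 0, 0, 10, 0, 0), 2L, byrow = TRUE),
                        c("A", "H"), c("CB", "CB"), resno = 1:2)
  expect_equal(nrow(extract_geometric_pairs(far, 1:2, 4.0)), 0L)

  tri <- bare_structure(matrix(c(0, 0, 0, 3, 0, 0, 1.5, 2.5, 0), 3L,
                               byrow = TRUE),
                        c("A", "H", "Q"), rep("CB", 3L), resno = 1:3)
  p <- extract_geometric_pairs(tri, 1:3, 4.0)
  expect_setequal(p$pair, c("A:H", "A:Q", "H:Q"))

  sq <- square_structure()
  p4 <- extract_geometric_pairs(sq, 1:4, 4.0)
  expect_equal(nrow(p4), 4L)  # edges only, diagonals excluded
})

test_that("pair extraction matches an exhaustive double-loop oracle", {
  ag <- make_toy_antigen(12, seed = 21)
  surf <- seq_len(12L)
  got <- extract_geometric_pairs(ag, surf, 4.0)
  res <- residue_table(ag)
  at <- ag$atoms[ag$atoms$is_heavy, ]
  want <- character(0)
  for (i in 1:11) {
    for (j in (i + 1):12) {
      ai <- at[at$res_index == i, c("x", "y", "z")]
      aj <- at[at$res_index == j, c("x", "y", "z")]
      dmin <- min(sqrt(pmax(outer(rowSums(ai^2), rowSums(aj^2), "+") -
                              2 * as.matrix(ai) %*% t(as.matrix(aj)), 0)))
      if (dmin <= 4.0)
        want <- c(want, paste(i, j))
    }
  }
  expect_setequal(paste(got$res_i, got$res_j), want)
})

test_that("GAAP tallies split pairs by epitope labels", {
  sq <- square_structure()
  all4 <- list(structure = sq, ce = 1:4, surface = 1:4)
  none <- list(structure = sq, ce = integer(0), surface = 1:4)
  t_all <- tally_gaap(list(all4), radius = 4.0)
  expect_equal(t_all$total_minus, 0)
  expect_equal(t_all$total_plus, 4)
  t_none <- tally_gaap(list(none), radius = 4.0)
  expect_equal(t_none$total_plus, 0)
  expect_equal(t_none$total_minus, 4)

  # hand count: CE = {1 (A), 2 (H)}; edges 1-2 (A:H) positive; edges
  # 1-3 (A:Q), 2-4 (H:A), 3-4 (Q:A) touch a non-CE residue
  t_mix <- tally_gaap(list(list(structure = sq, ce = 1:2, surface = 1:4)),
                      radius = 4.0)
  expect_equal(unname(t_mix$n_plus["A:H"]), 1)
  expect_equal(t_mix$total_plus, 1)
  expect_equal(unname(t_mix$n_minus["A:Q"]), 2)
  expect_equal(unname(t_mix$n_minus["A:H"]), 1)
  expect_equal(t_mix$total_minus, 3)
  expect_error(tally_gaap(list()), "empty dataset")
})

test_that("CEI reproduces hand-computed log-ratios and normalization", {
  counts <- structure(list(
    radius = 4.0,
    n_plus = stats::setNames(c(8, 2), c("A:A", "A:C")),
    n_minus = stats::setNames(c(2, 8), c("A:A", "A:C")),
    total_plus = 10, total_minus = 10), class = "gaap_counts")
  cei <- compute_cei(counts, pseudocount = 0)
  expect_equal(cei$raw[cei$pair == "A:A"], log10(0.8 / 0.2))
  expect_equal(cei$raw[cei$pair == "A:C"], -log10(0.8 / 0.2))
  expect_equal(cei$cei[cei$pair == "A:A"], 1)
  expect_equal(cei$cei[cei$pair == "A:C"], 0)

  # label swap flips every raw value
  swapped <- counts
  swapped$n_plus <- counts$n_minus
  swapped$n_minus <- counts$n_plus
  cei_sw <- compute_cei(swapped, pseudocount = 0)
  expect_equal(cei_sw$raw, -cei$raw)

  # constant ratios collapse to the 0.5 convention
  flat <- counts
  flat$n_minus <- counts$n_plus
  cei_flat <- compute_cei(flat, pseudocount = 0)
  expect_true(all(cei_flat$cei == 0.5))
})

test_that("CEI values stay in [0,1] for random counts", {
  set.seed(99)
  keys <- enumerate_pair_alphabet()
  for (rep in 1:5) {
    counts <- structure(list(
      radius = 4.0,
      n_plus = stats::setNames(rpois(210, 3), keys),
      n_minus = stats::setNames(rpois(210, 3), keys),
      total_plus = 0, total_minus = 0), class = "gaap_counts")
    counts$total_plus <- sum(counts$n_plus)
    counts$total_minus <- sum(counts$n_minus)
    cei <- compute_cei(counts, pseudocount = 1)
    expect_true(all(cei$cei >= 0 & cei$cei <= 1))
    expect_equal(sum(cei$f_plus), 1)
    expect_equal(sum(cei$f_minus), 1)
  }
})

test_that("the CEI table is invariant to antigen input order", {
  lab <- shared_labeled()[1:6]
  c1 <- compute_cei(tally_gaap(lab))
  c2 <- compute_cei(tally_gaap(rev(lab)))
  expect_equal(c1$cei, c2$cei)
})

test_that("cluster CEI averages internal pair indices", {
  sq <- square_structure()
  keys <- enumerate_pair_alphabet()
  cei_vals <- stats::setNames(rep(0.25, 210), keys)
  cei_vals["A:H"] <- 0.7
  tab <- data.frame(pair = keys, cei = unname(cei_vals),
                    stringsAsFactors = FALSE)
  attr(tab, "radius") <- 4.0
  class(tab) <- c("cei_table", "data.frame")

  # single internal pair with cei 0.7
  expect_equal(cluster_cei(1:2, sq, tab), 0.7)
  # no internal pairs (diagonal residues, 5.7 A apart)
  expect_equal(cluster_cei(c(1L, 4L), sq, tab), 0)
  # full square: mean over its four edge pairs
  p <- extract_geometric_pairs(sq, 1:4, 4.0)
  expect_equal(cluster_cei(1:4, sq, tab),
               mean(tab$cei[match(p$pair, tab$pair)]))
})

test_that("enriched planted patches push their pair to the top CEI", {
  cei <- shared_cei()
  top <- cei$pair[order(-cei$cei)][1:3]
  expect_true("H:Q" %in% top)
})

test_that("CEI tables round-trip through JSON", {
  cei <- shared_cei()
  path <- withr::local_tempfile(fileext = ".json")
  write_cei(cei, path)
  back <- read_cei(path)
  expect_equal(back$cei, cei$cei)
  expect_equal(attr(back, "radius"), attr(cei, "radius"))
})
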