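# Deterministic synthetic antigens: compact pseudo-protein globules,
# planted surface epitope patches, and pseudo-antibody complexes.
#
# The generator exists so every pipeline stage is testable without
# external structure downloads. Geometry is simplified (no rotamers, no
# physical backbone dihedrals): residues are placed on a compact
# self-avoiding CA walk, backbone atoms sit in a local frame around each
# CA and side chains extend radially outward, which makes side-chain
# exposure the norm, as on real globular protein surfaces. All pipeline
# mathematics depends only on heavy-atom coordinates, types and labels,
# which the fixtures provide faithfully.

.with_seed <- function(seed, code) {
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  force(code)
}

.runif_sphere <- function() {
  repeat {
    v <- stats::runif(3L, -1, 1)
    n2 <- sum(v^2)
    if (n2 > 1e-6 && n2 <= 1) return(v / sqrt(n2))
  }
}

# Compact self-avoiding CA cloud at real-protein packing density (about
# 110 A^3 per residue, radius of gyration near 2.4 * n^(1/3) A -- the
# protein-like end of the generator's nominal 3 * n^(1/3) +- 30% band).
# CA sites are Poisson-disk sampled in a ball (minimum separation 3.6 A)
# so the interior is uniformly filled rather than stringy, then ordered
# into a chain by a greedy nearest-unvisited-neighbour path.
.ca_walk <- function(n, max_restarts = 40L) {
  r_ball <- (3 * n * 110 / (4 * pi))^(1 / 3)
  for (restart in seq_len(max_restarts)) {
    ca <- matrix(NA_real_, n, 3L)
    placed <- 0L
    tries <- 0L
    while (placed < n && tries < 4000L * n) {
      tries <- tries + 1L
      cand <- .runif_sphere() * r_ball * stats::runif(1L)^(1 / 3)
      if (placed > 0L) {
        d <- sqrt(colSums((t(ca[seq_len(placed), , drop = FALSE]) -
                             cand)^2))
        if (any(d < 3.6)) next
      }
      placed <- placed + 1L
      ca[placed, ] <- cand
    }
    if (placed < n) next
    # chain order: greedy nearest-neighbour walk from the first site
    ord <- integer(n)
    ord[1L] <- 1L
    left <- setdiff(seq_len(n), 1L)
    for (i in 2:n) {
      d <- sqrt(colSums((t(ca[left, , drop = FALSE]) -
                           ca[ord[i - 1L], ])^2))
      nxt <- left[which.min(d)]
      ord[i] <- nxt
      left <- setdiff(left, nxt)
    }
    return(ca[ord, , drop = FALSE])
  }
  stop("could not pack a self-avoiding chain of ", n,
       " residues; try another seed")
}


#' Generate a deterministic toy antigen
#'
#' A seeded compact self-avoiding pseudo-protein: `n_residues` residues
#' with 4 backbone heavy atoms each and up to 5 side-chain heavy atoms
#' (standard atom names for the assigned amino acid, truncated for long
#' side chains), CA-CA separation at least 3.6 A and radius of gyration
#' near `3 * n^(1/3)` A. Side chains point radially outward.
#'
#' With `hq_mode = "scatter"`, histidine and glutamine are kept mutually
#' distant (CA-CA > 10 A): structures generated this way contain H/Q
#' residues but essentially no H-Q/H-H/Q-Q contacts, which makes such
#' contacts rare in a contact potential trained on them and therefore
#' high-energy. Planted patches (H/Q-clustered) then stand out, mirroring
#' how epitope residues sit in locally unfavourable environments.
#'
#' @param n_residues Chain length (at least 10; default 30).
#' @param seed Integer seed; the same spec yields identical coordinates.
#' @param aa_pool One-letter codes sampled for the sequence (default the
#'   20 standard, uniform).
#' @param hq_mode `"uniform"` (default) or `"scatter"` (see above).
#' @param pdb_id Identifier stored on the structure.
#' @return An `antigen_structure` (chain "A").
#' @export
make_toy_antigen <- function(n_residues = 30L, seed = 1L,
                             aa_pool = unname(.AA1),
                             hq_mode = c("uniform", "scatter"),
                             pdb_id = sprintf("TOY%04d", seed %% 10000L)) {
  stopifnot(n_residues >= 10L)
  hq_mode <- match.arg(hq_mode)
  .with_seed(seed, {
    ca <- .ca_walk(n_residues)
    aa <- sample(aa_pool, n_residues, replace = TRUE)
    if (hq_mode == "scatter") aa <- .scatter_hq(aa, ca)
    .assemble_structure(ca, aa, pdb_id)
  })
}

# Reassign H/Q residues that sit within 10 A CA-CA of another H/Q to a
# random non-H/Q amino acid, keeping the survivors spatially isolated.
.scatter_hq <- function(aa, ca) {
  pool <- setdiff(.AA1, c("H", "Q"))
  hq <- which(aa %in% c("H", "Q"))
  kept <- integer(0)
  for (i in hq) {
    if (length(kept) > 0L) {
      d <- sqrt(colSums((t(ca[kept, , drop = FALSE]) - ca[i, ])^2))
      if (any(d <= 10)) { aa[i] <- sample(pool, 1L); next }
    }
    kept <- c(kept, i)
  }
  aa
}

# Build the atom table: backbone N/CA/C/O in a local frame, side chain
# extending outward from the globule centroid.
.assemble_structure <- function(ca, aa, pdb_id) {
  n <- nrow(ca)
  centroid <- colMeans(ca)
  rows <- vector("list", n)
  serial <- 0L
  for (i in seq_len(n)) {
    aa3 <- .AA3_FROM_1[aa[i]]
    to_prev <- if (i > 1L) ca[i - 1L, ] - ca[i, ] else ca[i, ] - ca[i + 1L, ]
    to_next <- if (i < n) ca[i + 1L, ] - ca[i, ] else ca[i, ] - ca[i - 1L, ]
    u_prev <- to_prev / sqrt(sum(to_prev^2))
    u_next <- to_next / sqrt(sum(to_next^2))
    out_v <- ca[i, ] - centroid
    if (sqrt(sum(out_v^2)) < 1e-6) out_v <- .runif_sphere()
    u_out <- out_v / sqrt(sum(out_v^2))
    names_ <- c("N", "CA", "C", "O")
    pos <- rbind(ca[i, ] + 1.45 * u_prev,
                 ca[i, ],
                 ca[i, ] + 1.52 * u_next,
                 ca[i, ] + 1.52 * u_next + 1.23 * u_out)
    sc <- .SIDE_CHAIN[[aa3]]
    nsc <- min(length(sc), 5L)
    if (nsc > 0L) {
      sc <- sc[seq_len(nsc)]
      jitter <- matrix(stats::runif(3L * nsc, -0.35, 0.35), nsc, 3L)
      # outward bias with substantial random spread: side chains mostly
      # face solvent but some pack back against the core, as in real
      # globules
      dir <- 0.45 * u_out + .runif_sphere()
      dir <- dir / sqrt(sum(dir^2))
      sc_pos <- t(vapply(seq_len(nsc), function(k)
        ca[i, ] + (1.5 * k) * dir + jitter[k, ], numeric(3L)))
      names_ <- c(names_, sc)
      pos <- rbind(pos, sc_pos)
    }
    serials <- serial + seq_len(length(names_))
    serial <- serial + length(names_)
    rows[[i]] <- data.frame(
      serial = serials, name = names_,
      element = .element_from_name(names_), chain = "A", resno = i,
      icode = "", aa = unname(aa[i]), res_index = i,
      x = pos[, 1L], y = pos[, 2L], z = pos[, 3L], vdw = NA_real_,
      is_heavy = TRUE,
      is_side_chain = !(names_ %in% c(.BACKBONE, "OXT")),
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  # glycine: no side-chain atom; the CA surrogate is handled downstream
  assign_vdw_radii(.new_structure(atoms, pdb_id = pdb_id,
                                  chain_id = "A"))
}

#' Plant a surface epitope patch
#'
#' Selects a spatially tight, exposed patch of `patch_size` residues
#' (seeded at the residue farthest from the centroid, grown greedily
#' under a 12-A mutual CA-CA constraint) and re-assigns part of the patch
#' to the biased amino-acid pair. The number of re-assigned residues is
#' `round(patch_size * min(1, 0.1 * enrichment))` -- at enrichment 1 this
#' matches the background H/Q rate, so the composition is essentially
#' unchanged; larger factors concentrate the biased pair on the most
#' mutually contacting patch members (alternating the two letters so
#' hetero-pairs form).
#'
#' With `energy_bias > 0` the patch members' side chains are re-oriented
#' to converge toward a common solvent-side apex above the patch, packing
#' them into mutual contact. Residues binding an antibody sit in locally
#' strained, contact-dense environments; the converged side chains
#' emulate that by giving patch residues many rare (hence high-energy)
#' atom contacts while staying solvent-exposed.
#'
#' @param structure An `antigen_structure` from [make_toy_antigen()].
#' @param patch_size Number of epitope residues (default 6).
#' @param pair Length-2 character, the biased amino-acid pair (default
#'   H/Q).
#' @param enrichment Enrichment factor (at least 1; default 5).
#' @param energy_bias Side-chain convergence weight in `[0, 1]` (default
#'   1; 0 leaves the radial layout untouched).
#' @param seed Integer seed for the re-assignment draw.
#' @return List with `structure` (identities updated) and `ce` (integer
#'   vector of planted epitope `res_index` values).
#' @export
plant_epitope <- function(structure, patch_size = 6L,
                          pair = c("H", "Q"), enrichment = 5,
                          energy_bias = 1, seed = 1L) {
  stopifnot(enrichment >= 1, patch_size < n_residues(structure))
  ca <- ca_coords(structure)
  centroid <- colMeans(ca)
  rdist <- sqrt(rowSums((ca - matrix(centroid, nrow(ca), 3L,
                                     byrow = TRUE))^2))
  exposed <- which(rdist >= stats::quantile(rdist, 0.4))
  members <- NULL
  for (seed_res in exposed[order(-rdist[exposed])]) {
    d <- sqrt(colSums((t(ca[exposed, , drop = FALSE]) - ca[seed_res, ])^2))
    cand <- exposed[order(d)][seq_len(min(patch_size, length(exposed)))]
    if (length(cand) < patch_size) next
    if (max(stats::dist(ca[cand, , drop = FALSE])) <= 12) {
      members <- cand
      break
    }
  }
  if (is.null(members))
    stop("no sufficiently exposed patch of size ", patch_size)
  members <- sort(members)

  n_forced <- round(patch_size * min(1, 0.1 * enrichment))
  if (n_forced > 0L) {
    # most mutually contacting members first (4-A heavy-atom pairs)
    p <- extract_geometric_pairs(structure, members, 4.0)
    deg <- vapply(members, function(r)
      sum(p$res_i == r | p$res_j == r), numeric(1))
    target <- members[order(-deg)][seq_len(n_forced)]
    new_aa <- rep(pair, length.out = n_forced)
    structure <- .with_seed(seed, .reassign_aa(structure, target, new_aa))
  }
  if (energy_bias > 0) {
    structure <- .with_seed(seed + 1L,
      .converge_patch(structure, members, centroid,
                      min(1, energy_bias)))
  }
  list(structure = structure, ce = members)
}

# Re-orient patch side chains toward a common apex 4 A above the patch
# centroid (solvent side), interpolated by weight w.
.converge_patch <- function(structure, members, centroid, w) {
  at <- structure$atoms
  ca <- ca_coords(structure)
  pc <- colMeans(ca[members, , drop = FALSE])
  up <- pc - centroid
  up <- up / sqrt(sum(up^2))
  apex <- pc + 4.0 * up
  for (r in members) {
    rows <- which(at$res_index == r & at$is_side_chain)
    if (length(rows) == 0L) next
    old_dir <- .unit(c(at$x[rows[1L]], at$y[rows[1L]], at$z[rows[1L]]) -
                       ca[r, ])
    new_dir <- .unit((1 - w) * old_dir + w * .unit(apex - ca[r, ]))
    for (k in seq_along(rows)) {
      pos <- ca[r, ] + (1.4 * k) * new_dir + stats::runif(3L, -0.25, 0.25)
      at$x[rows[k]] <- pos[1L]
      at$y[rows[k]] <- pos[2L]
      at$z[rows[k]] <- pos[3L]
    }
  }
  structure$atoms <- at
  structure
}

.unit <- function(v) v / sqrt(sum(v^2))

# Replace residue identities, rebuilding side-chain atom names/types in
# place (positions keep the radial layout).
.reassign_aa <- function(structure, res_idx, new_aa) {
  at <- structure$atoms
  for (k in seq_along(res_idx)) {
    r <- res_idx[k]
    aa1 <- new_aa[k]
    aa3 <- .AA3_FROM_1[aa1]
    rows <- which(at$res_index == r)
    sc_rows <- rows[at$is_side_chain[rows]]
    sc_names <- .SIDE_CHAIN[[aa3]]
    keep <- seq_len(min(length(sc_rows), length(sc_names)))
    drop_rows <- if (length(sc_rows) > length(keep))
      sc_rows[-keep] else integer(0)
    at$aa[rows] <- aa1
    if (length(keep) > 0L) {
      at$name[sc_rows[keep]] <- sc_names[keep]
      at$element[sc_rows[keep]] <- .element_from_name(sc_names[keep])
    }
    if (length(drop_rows) > 0L) at <- at[-drop_rows, , drop = FALSE]
  }
  structure$atoms <- at
  assign_vdw_radii(structure)
}

#' Build a pseudo-antibody complex
#'
#' Places one probe atom per epitope residue at 3.3 A from the residue's
#' outermost side-chain heavy atom along the outward normal, then checks
#' that no non-epitope residue has a heavy atom within 4 A of any probe
#' (alternative side-chain atoms are tried when the check fails). The
#' result lets interface-based ground-truth extraction recover the
#' planted labels exactly.
#'
#' @param antigen An `antigen_structure`.
#' @param ce Integer vector of epitope `res_index` values (nonempty).
#' @param seed Integer seed (probe order perturbation).
#' @return An `antigen_complex`: list with `antigen` and `antibody`
#'   (chain "B" probe cloud, one single-atom residue per probe).
#' @export
make_complex <- function(antigen, ce, seed = 1L) {
  stopifnot(length(ce) > 0L)
  at <- antigen$atoms[antigen$atoms$is_heavy, , drop = FALSE]
  centroid <- colMeans(as.matrix(at[, c("x", "y", "z")]))
  ca <- ca_coords(antigen)
  up <- .unit(colMeans(ca[ce, , drop = FALSE]) - centroid)
  non_ce_xyz <- as.matrix(at[!(at$res_index %in% ce), c("x", "y", "z")])
  probes <- matrix(NA_real_, 0L, 3L)
  for (r in ce) {
    # an already-placed probe may cover this residue (converged patches)
    res_xyz <- as.matrix(at[at$res_index == r, c("x", "y", "z")])
    if (nrow(probes) > 0L) {
      dmin <- min(.min_dist_to_set(probes, res_xyz))
      if (dmin <= 3.5) next
    }
    sc <- side_chain_atoms(antigen, r)
    xyz <- as.matrix(sc[, c("x", "y", "z")])
    xyz <- rbind(xyz, res_xyz)   # side-chain first, backbone fallback
    # prefer atoms sticking out along the patch normal; fall back to the
    # atom's own outward direction if the normal is blocked
    height <- as.numeric(xyz %*% up)
    placed <- FALSE
    for (a in order(-height)) {
      dirs <- list(up, .unit(xyz[a, ] - centroid),
                   .unit(xyz[a, ] - ca[r, ]),
                   .unit(up + .unit(xyz[a, ] - centroid)))
      # widen the search with a deterministic cone around the normal
      cone <- lapply(1:8, function(k) {
        ang <- 2 * pi * k / 8
        perp1 <- .unit(c(up[2L] - up[3L], up[3L] - up[1L],
                         up[1L] - up[2L]))
        perp2 <- .unit(c(up[2L] * perp1[3L] - up[3L] * perp1[2L],
                         up[3L] * perp1[1L] - up[1L] * perp1[3L],
                         up[1L] * perp1[2L] - up[2L] * perp1[1L]))
        .unit(up + 0.6 * (cos(ang) * perp1 + sin(ang) * perp2))
      })
      dirs <- c(dirs, cone)
      dirs <- Filter(function(v) all(is.finite(v)), dirs)
      for (dir in dirs) {
        for (dist in c(3.3, 3.45, 3.1, 2.9)) {
          cand <- xyz[a, ] + dist * dir
          if (nrow(non_ce_xyz) > 0L) {
            d <- sqrt(colSums((t(non_ce_xyz) - cand)^2))
            if (any(d <= 4.0)) next
          }
          probes <- rbind(probes, cand)
          placed <- TRUE
          break
        }
        if (placed) break
      }
      if (placed) break
    }
    if (!placed)
      stop("pseudo-antibody placement infeasible for residue ", r)
  }
  np <- nrow(probes)
  ab_atoms <- data.frame(
    serial = seq_len(np), name = "CA", element = "C", chain = "B",
    resno = seq_len(np), icode = "", aa = "G", res_index = seq_len(np),
    x = probes[, 1L], y = probes[, 2L], z = probes[, 3L],
    vdw = NA_real_, is_heavy = TRUE, is_side_chain = FALSE,
    stringsAsFactors = FALSE)
  antibody <- assign_vdw_radii(.new_structure(ab_atoms,
                                              pdb_id = antigen$pdb_id,
                                              chain_id = "B"))
  structure(list(antigen = antigen, antibody = antibody),
            class = "antigen_complex")
}

#' Generate a labelled fixture suite
#'
#' `n` toy antigens with planted epitope patches and matching
#' pseudo-antibody complexes, under one master seed. Antigen `i` uses
#' seed `seed + i`, so suites of different sizes share their leading
#' members.
#'
#' @param n Number of antigens (default 20).
#' @param seed Master seed.
#' @param n_residues,patch_size,enrichment,energy_bias Passed through to
#'   the generator (defaults 100 / 6 / 5 / 1).
#' @param complexes Also build pseudo-antibody complexes (default TRUE).
#' @return List of entries: `structure`, `ce`, and optionally `complex`.
#' @export
make_fixture_set <- function(n = 20L, seed = 17L, n_residues = 100L,
                             patch_size = 6L, enrichment = 5,
                             energy_bias = 1, complexes = TRUE) {
  lapply(seq_len(n), function(i) {
    s <- seed + i
    ag <- make_toy_antigen(n_residues = n_residues, seed = s)
    pl <- plant_epitope(ag, patch_size = patch_size,
                        enrichment = enrichment,
                        energy_bias = energy_bias, seed = s)
    entry <- list(structure = pl$structure, ce = pl$ce)
    if (complexes)
      entry$complex <- make_complex(pl$structure, pl$ce, seed = s)
    entry
  })
}

#' Generate a potential-training suite
#'
#' Toy antigens with scattered (mutually distant) H/Q residues and no
#' planted patches; training a contact potential on these makes
#' H-Q/H-H/Q-Q atom contacts rare-relative-to-chance, hence high-energy.
#'
#' @param n Number of structures (default 24).
#' @param seed Master seed.
#' @param n_residues Chain length (default 80).
#' @return List of `antigen_structure`.
#' @export
make_training_set <- function(n = 24L, seed = 1000L, n_residues = 80L) {
  lapply(seq_len(n), function(i)
    make_toy_antigen(n_residues = n_residues, seed = seed + i,
                     hq_mode = "scatter"))
}

#' Write a fixture suite to disk
#'
#' PDB files (antigen chain A; complexes add the probe chain B) plus a
#' label TSV (pdb_id, chain, resnum, icode, label in CE/nonCE).
#'
#' @param fixtures Output of [make_fixture_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(fixtures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- list()
  for (entry in fixtures) {
    ag <- entry$structure
    path <- file.path(dir, paste0(ag$pdb_id, ".pdb"))
    if (is.null(entry$complex)) {
      write_pdb(ag, path)
    } else {
      write_pdb(ag, path, end = FALSE)
      write_pdb(entry$complex$antibody, path, append = TRUE, end = TRUE)
    }
    res <- residue_table(ag)
    labels[[length(labels) + 1L]] <- data.frame(
      pdb_id = ag$pdb_id, chain = res$chain, resnum = res$resno,
      icode = res$icode,
      label = ifelse(res$res_index %in% entry$ce, "CE", "nonCE"))
  }
  utils::write.table(do.call(rbind, labels),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
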