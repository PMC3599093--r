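# Shared fixtures for the suite, computed lazily and cached for the
# session so expensive stages (potential training, the 20-antigen planted
# suite) run once.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache, inherits = FALSE))
    assign(name, expr, envir = .cache)
  get(name, envir = .cache, inherits = FALSE)
}

shared_potential <- function() {
  cached("potential", train_contact_potential(make_training_set()))
}

shared_fixtures <- function() {
  cached("fixtures", make_fixture_set(n = 20L, seed = 17L))
}

# Per-fixture surface tables and surface-restricted labels.
shared_labeled <- function() {
  cached("labeled", lapply(shared_fixtures(), function(e) {
    st <- compute_surface_table(e$structure)
    surf <- surface_residues(st)
    list(structure = e$structure, ce = intersect(e$ce, surf),
         surface = surf, st = st)
  }))
}

shared_cei <- function() {
  cached("cei", compute_cei(tally_gaap(shared_labeled())))
}

shared_predictions <- function() {
  cached("predictions", {
    fx <- shared_fixtures()
    lab <- shared_labeled()
    lapply(seq_along(fx), function(i)
      predict_epitopes(fx[[i]]$structure, shared_potential(),
                       shared_cei(), surface_table = lab[[i]]$st))
  })
}

# A tiny hand-written PDB: one ALA with an altloc'd CB, one water, one
# hydrogen.
tiny_pdb_text <- function() {
  paste(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB AALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  CB BALA A   1       2.100  -0.800  -1.300  1.00  0.00           C",
    "ATOM      7  H   ALA A   1       0.500   0.500   0.500  1.00  0.00           H",
    "HETATM    8  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END"), collapse = "\n")
}

# Direct construction of a bare structure from coordinates/types,
# bypassing the generator (for hand-built geometric cases).
bare_structure <- function(xyz, aa, name, resno = seq_len(nrow(xyz)),
                           chain = "A") {
  lines <- vapply(seq_len(nrow(xyz)), function(i) {
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, substr(paste0(" ", name[i]), 1, 4),
            aa3_of(aa[i]), chain, resno[i],
            xyz[i, 1], xyz[i, 2], xyz[i, 3])
  }, character(1))
  parse_pdb(paste(c(lines, "END"), collapse = "\n"), chain)
}

aa3_of <- function(a1) {
  c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
    E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
    M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
    Y = "TYR", V = "VAL")[a1]
}

# Rigid rotation + translation of an antigen_structure.
rigid_move <- function(structure, angle = 0.7, shift = c(5, -3, 2)) {
  ca <- cos(angle); sa <- sin(angle)
  rot <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3L, 3L, byrow = TRUE)
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2L, shift, "+")
  structure$atoms$x <- xyz[, 1L]
  structure$atoms$y <- xyz[, 2L]
  structure$atoms$z <- xyz[, 3L]
  structure
}

# Hand-built complex: a 10-residue antigen line (6-A spacing so no
# residue-residue expansion at 4 A) with probe atoms z A above four
# chosen residues.
line_complex <- function(contact = c(2L, 4L, 6L, 8L), z = 3.5) {
  xyz <- cbind((0:9) * 6.0, 0, 0)
  antigen <- bare_structure(xyz, rep("A", 10L), rep("CB", 10L),
                            resno = 1:10)
  ab_xyz <- cbind((contact - 1L) * 6.0, 0, z)
  antibody <- bare_structure(ab_xyz, rep("G", length(contact)),
                             rep("CA", length(contact)),
                             resno = seq_along(contact), chain = "A")
  antibody$chain_id <- "B"
  antibody$atoms$chain <- "B"
  list(antigen = antigen, antibody = antibody)
}
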