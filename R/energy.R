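# Knowledge-based heavy-atom contact potential and residue energy
# profiles.
#
# Heavy atoms are typed by (residue, atom name) -- 167 types over the 20
# standard amino acids. For a training set of structures, the observed
# number of contacts O(a, b) (heavy-atom pairs within a distance cutoff,
# residues separated by at least two sequence positions) is compared with
# the expectation under random mixing, E(a, b) = T * x_a * x_b *
# (2 - delta_ab), where T is the total contact count and x_t the mole
# fraction of type t among contact endpoints. The pair energy is
# -log10((O + pseudocount) / (E + pseudocount)): positive when a pair is
# rarer than chance, i.e. unfavourable. Residues engaged in antibody
# binding are expected to sit in such unfavourable local environments, so
# higher energy is treated as more epitope-like.

#' The heavy-atom type alphabet
#'
#' @return Data frame with `aa` (three-letter code), `atom` (PDB name) and
#'   `type` ("AA3:NAME") for all 167 heavy-atom types of the 20 standard
#'   amino acids.
#' @export
atom_type_table <- function() {
  rows <- lapply(.AA3, function(aa) {
    atoms <- c(.BACKBONE, .SIDE_CHAIN[[aa]])
    data.frame(aa = aa, atom = atoms,
               type = paste(aa, atoms, sep = ":"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Atom types ("AA3:NAME") for each atom row; NA for hydrogens/unknowns.
.atom_types <- function(structure) {
  at <- structure$atoms
  ty <- rep(NA_character_, nrow(at))
  heavy <- at$is_heavy
  ty[heavy] <- paste(.AA3_FROM_1[at$aa[heavy]], at$name[heavy], sep = ":")
  ty
}

# Qualifying contacts of a structure: heavy-atom pairs with residue
# sequence separation >= min_sep and distance <= cutoff. Returns a data
# frame with type indices (into `types`) and residue indices.
.structure_contacts <- function(structure, cutoff, types, min_sep = 2L) {
  at <- structure$atoms[structure$atoms$is_heavy, , drop = FALSE]
  n <- nrow(at)
  if (n < 2L) {
    return(data.frame(ti = integer(0), tj = integer(0),
                      ri = integer(0), rj = integer(0)))
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  # separation in author numbering, so numbering gaps count as distance
  sep <- abs(outer(at$resno, at$resno, "-"))
  hit <- which(upper.tri(d) & d <= cutoff & sep >= min_sep,
               arr.ind = TRUE)
  ty <- paste(.AA3_FROM_1[at$aa], at$name, sep = ":")
  ti <- match(ty[hit[, 1L]], types)
  tj <- match(ty[hit[, 2L]], types)
  keep <- !is.na(ti) & !is.na(tj)
  data.frame(ti = ti[keep], tj = tj[keep],
             ri = at$res_index[hit[keep, 1L]],
             rj = at$res_index[hit[keep, 2L]])
}

#' Train a knowledge-based contact potential
#'
#' @param structures List of `antigen_structure` objects.
#' @param cutoff Contact distance cutoff in angstrom (default 5.0).
#' @param pseudocount Additive smoothing applied to observed and expected
#'   counts (default 1.0); keeps all energies finite.
#' @param min_sep Minimum residue sequence separation for a contact
#'   (default 2).
#' @return A `contact_potential`: list with `cutoff`, `pseudocount`,
#'   `types` (type table), symmetric `energy` matrix (167 x 167) and
#'   `provenance` (structure ids).
#' @export
train_contact_potential <- function(structures, cutoff = 5.0,
                                    pseudocount = 1.0, min_sep = 2L) {
  stopifnot(length(structures) >= 1L, cutoff > 0)
  tt <- atom_type_table()
  nt <- nrow(tt)
  lower <- matrix(0, nt, nt)   # counts at [max(type), min(type)]
  for (s in structures) {
    ct <- .structure_contacts(s, cutoff, tt$type, min_sep)
    if (nrow(ct) == 0L) next
    m <- pmin(ct$ti, ct$tj)
    M <- pmax(ct$ti, ct$tj)
    lower <- lower + matrix(tabulate((m - 1L) * nt + M, nbins = nt * nt),
                            nt, nt)
  }
  obs <- lower + t(lower)
  diag(obs) <- diag(lower)
  total <- (sum(obs) + sum(diag(obs))) / 2   # T: each contact once
  if (total == 0) stop("training set too small: no contacts found")
  # endpoint counts: diag pairs contribute two endpoints of the same type
  endpoint <- rowSums(obs) + diag(obs)
  x <- endpoint / (2 * total)
  expd <- total * outer(x, x) * (2 - diag(nt))
  diag(expd) <- total * x^2                  # 2 - delta_ab = 1 on diagonal
  o <- obs
  o[upper.tri(o)] <- t(o)[upper.tri(o)]      # already symmetric; keep tidy
  energy <- -log10((o + pseudocount) / (expd + pseudocount))
  dimnames(energy) <- list(tt$type, tt$type)
  structure(list(cutoff = cutoff, pseudocount = pseudocount,
                 min_sep = min_sep, types = tt, energy = energy,
                 provenance = vapply(structures, function(s)
                   if (nzchar(s$pdb_id)) s$pdb_id else "unnamed",
                   character(1))),
            class = "contact_potential")
}

#' @export
print.contact_potential <- function(x, ...) {
  cat(sprintf(
    "<contact_potential> %d atom types, cutoff %.1f A, trained on %d structures\n",
    nrow(x$types), x$cutoff, length(x$provenance)))
  invisible(x)
}

#' Per-residue contact energies
#'
#' Each residue's energy is the sum of pair energies over all of its
#' qualifying heavy-atom contacts (distance within the potential's cutoff,
#' sequence separation at least the potential's minimum). Both residues of
#' a contact accumulate the term; residues with no qualifying contacts get
#' zero.
#'
#' @param structure An `antigen_structure`.
#' @param potential A `contact_potential`.
#' @return Numeric vector of energies, one per residue (by `res_index`).
#' @export
residue_energies <- function(structure, potential) {
  n <- n_residues(structure)
  e <- numeric(n)
  ct <- .structure_contacts(structure, potential$cutoff,
                            potential$types$type, potential$min_sep)
  if (nrow(ct) > 0L) {
    val <- potential$energy[cbind(ct$ti, ct$tj)]
    sums <- rowsum(c(val, val), c(ct$ri, ct$rj))
    e[as.integer(rownames(sums))] <- sums[, 1L]
  }
  e
}

#' Energy of one residue
#'
#' @inheritParams residue_energies
#' @param res_index Residue index.
#' @return Scalar energy.
#' @export
residue_energy <- function(structure, res_index, potential) {
  residue_energies(structure, potential)[res_index]
}

#' Locally averaged energy profile
#'
#' For every surface residue, the mean raw energy over the surface
#' residues whose CA lies within `radius` of its own CA (itself included).
#' A sequence-window variant (mean over residues within `window_size / 2`
#' sequence positions) is available via `window = "sequence"`.
#'
#' @param structure An `antigen_structure`.
#' @param potential A `contact_potential`.
#' @param surface Integer vector of surface `res_index` values.
#' @param radius Spatial averaging radius in angstrom (default 8).
#' @param window `"sphere"` (default) or `"sequence"`.
#' @param window_size Sequence window width when `window = "sequence"`
#'   (default 8 residues).
#' @return An `energy_profile`: list with per-residue `energy`,
#'   `local_avg` (NA off-surface), `surface`, and the averaging
#'   parameters.
#' @export
energy_profile <- function(structure, potential, surface,
                           radius = 8.0, window = c("sphere", "sequence"),
                           window_size = 8L) {
  window <- match.arg(window)
  e <- residue_energies(structure, potential)
  n <- length(e)
  la <- rep(NA_real_, n)
  if (length(surface) > 0L) {
    if (window == "sphere") {
      ca <- ca_coords(structure)[surface, , drop = FALSE]
      d <- as.matrix(stats::dist(ca))
      for (i in seq_along(surface)) {
        nb <- surface[d[i, ] <= radius]
        la[surface[i]] <- mean(e[nb])
      }
    } else {
      half <- window_size / 2
      for (i in seq_along(surface)) {
        nb <- surface[abs(surface - surface[i]) <= half]
        la[surface[i]] <- mean(e[nb])
      }
    }
  }
  structure(list(energy = e, local_avg = la, surface = surface,
                 radius = radius, window = window,
                 window_size = window_size),
            class = "energy_profile")
}

#' Rank surface residues by local-average energy
#'
#' Returns the top fraction (default 20%) of surface residues by
#' descending local-average energy; ties broken by higher raw residue
#' energy, then by lower residue index.
#'
#' @param profile An `energy_profile`.
#' @param surface Integer vector of surface residue indices (default: the
#'   profile's).
#' @param top_fraction Fraction to keep (default 0.2); the count is
#'   `ceiling(top_fraction * length(surface))`.
#' @return Ordered integer vector of residue indices.
#' @export
rank_by_energy <- function(profile, surface = profile$surface,
                           top_fraction = 0.2) {
  if (length(surface) == 0L) stop("empty surface set")
  ord <- order(-profile$local_avg[surface], -profile$energy[surface],
               surface)
  k <- ceiling(top_fraction * length(surface))
  surface[ord][seq_len(min(k, length(surface)))]
}

#' Serialize / load a contact potential as JSON
#'
#' @param potential A `contact_potential`.
#' @param path JSON file path.
#' @return `path` invisibly (write); a `contact_potential` (read).
#' @export
write_potential <- function(potential, path) {
  obj <- list(cutoff = potential$cutoff,
              pseudocount = potential$pseudocount,
              min_sep = potential$min_sep,
              types = potential$types$type,
              energy = potential$energy,
              provenance = potential$provenance)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_potential
#' @export
read_potential <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tt <- atom_type_table()
  stopifnot(identical(obj$types, tt$type))
  en <- as.matrix(obj$energy)
  dimnames(en) <- list(tt$type, tt$type)
  structure(list(cutoff = obj$cutoff, pseudocount = obj$pseudocount,
                 min_sep = obj$min_sep, types = tt, energy = en,
                 provenance = obj$provenance),
            class = "contact_potential")
}

#' Export an energy profile as TSV
#'
#' @param profile An `energy_profile`.
#' @param structure The matching `antigen_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_energy_profile <- function(profile, structure, path) {
  res <- residue_table(structure)
  out <- data.frame(chain = res$chain, resnum = res$resno, aa = res$aa,
                    energy = sprintf("%.6f", profile$energy),
                    local_avg = ifelse(is.na(profile$local_avg), "NA",
                                       sprintf("%.6f", profile$local_avg)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
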