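# Residue surface rates SR aggregated from per-atom rates AR.
#
# SR(r) = (1/N) * sum of AR over the residue's N side-chain "surface
# atoms" (side-chain heavy atoms with AR > 0). A residue whose side chain
# is fully buried (N = 0) gets SR = 0 and is never a surface residue.

#' Residue surface rate from atom rates
#'
#' @param ar Numeric vector of AR values for the residue's side-chain
#'   heavy atoms.
#' @return SR in `[0, 1]`: the mean over atoms with AR > 0, or 0 if none.
#' @export
residue_surface_rate <- function(ar) {
  ar <- ar[!is.na(ar)]
  surf <- ar[ar > 0]
  if (length(surf) == 0L) return(0)
  mean(surf)
}

#' Compute the per-structure surface table
#'
#' Runs the morphological shell extraction, evaluates AR for every heavy
#' atom and aggregates side-chain rates into residue SR values. Surface
#' membership requires SR at or above `min_sr` (and at least one exposed
#' side-chain atom).
#'
#' @param structure An `antigen_structure`.
#' @param spacing,b1_radius,b2_radius Grid parameters, see
#'   [surface_shell()].
#' @param min_sr Minimum SR for a residue to count as surface (default
#'   0.05).
#' @return A `surface_table`: list with `atoms` (per-atom AR), `residues`
#'   (res_index, chain, resno, icode, aa, sr, n_surface_atoms,
#'   is_surface) and the parameters used.
#' @export
compute_surface_table <- function(structure, spacing = 1.0,
                                  b1_radius = 1.5,
                                  b2_radius = b1_radius + spacing,
                                  min_sr = 0.05) {
  sr_out <- surface_rates(structure, spacing, b1_radius, b2_radius)
  at <- structure$atoms
  atoms <- data.frame(serial = at$serial, name = at$name,
                      res_index = at$res_index, ar = sr_out$ar,
                      is_side_chain = at$is_side_chain,
                      stringsAsFactors = FALSE)

  res <- residue_table(structure)
  sr <- numeric(nrow(res))
  nsa <- integer(nrow(res))
  for (i in seq_len(nrow(res))) {
    sc <- side_chain_atoms(structure, res$res_index[i])
    ar <- sr_out$ar[match(sc$serial, at$serial)]
    ar <- ar[!is.na(ar)]
    nsa[i] <- sum(ar > 0)
    sr[i] <- residue_surface_rate(ar)
  }
  res$sr <- sr
  res$n_surface_atoms <- nsa
  res$is_surface <- nsa > 0L & sr >= min_sr
  structure(list(atoms = atoms, residues = res, min_sr = min_sr,
                 spacing = spacing, b1_radius = b1_radius,
                 b2_radius = b2_radius),
            class = "surface_table")
}

#' @export
print.surface_table <- function(x, ...) {
  cat(sprintf("<surface_table> %d residues, %d surface (min_sr = %.2f)\n",
              nrow(x$residues), sum(x$residues$is_surface), x$min_sr))
  invisible(x)
}

#' Surface residues above an SR threshold
#'
#' @param table A `surface_table`.
#' @param min_sr SR threshold; defaults to the table's own threshold.
#' @return Integer vector of `res_index` values with at least one exposed
#'   side-chain atom and SR at or above the threshold.
#' @export
surface_residues <- function(table, min_sr = table$min_sr) {
  r <- table$residues
  r$res_index[r$n_surface_atoms > 0L & r$sr >= min_sr]
}

#' Export the residue surface table as TSV
#'
#' Columns chain, resnum, icode, aa, SR, N, is_surface; rows ordered by
#' residue so repeated exports are byte-identical.
#'
#' @param table A `surface_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_surface_table <- function(table, path) {
  r <- table$residues[order(table$residues$res_index), , drop = FALSE]
  out <- data.frame(chain = r$chain, resnum = r$resno, icode = r$icode,
                    aa = r$aa, SR = sprintf("%.6f", r$sr),
                    N = r$n_surface_atoms,
                    is_surface = tolower(as.character(r$is_surface)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
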