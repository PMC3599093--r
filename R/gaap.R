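# Geometrically related amino-acid pairs (GAAP) and the conformational
# epitope index (CEI).
#
# Two surface residues form a geometric pair when their minimal
# heavy-atom distance is within a radius (2-6 A, default 4). Pair counts
# are tallied separately for epitope-labelled surfaces (both residues
# epitope) and the remaining surface pairs; the CEI of a pair is the
# min-max-normalized log10 ratio of its smoothed frequencies in the two
# sets. Candidate patches are scored by the mean CEI of their internal
# pairs.

#' The 210 unordered amino-acid pairs
#'
#' All unordered pairs over the 20 standard one-letter codes, homo-pairs
#' included: C(20, 2) + 20 = 210 keys of the form "A:C" (letters sorted).
#'
#' @return Character vector of length 210.
#' @export
enumerate_pair_alphabet <- function() {
  aa <- sort(.AA1)
  keys <- character(0)
  for (i in seq_along(aa))
    for (j in i:length(aa))
      keys <- c(keys, paste(aa[i], aa[j], sep = ":"))
  keys
}

#' Canonical pair key for two amino acids
#' @param a,b One-letter amino-acid codes (vectorized).
#' @return Character keys with letters sorted.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = ":")
}

#' Extract geometric residue pairs
#'
#' All unordered residue pairs within `residue_set` whose minimal
#' heavy-atom distance is at most `radius`.
#'
#' @param structure An `antigen_structure`.
#' @param residue_set Integer vector of `res_index` values.
#' @param radius Pair radius in angstrom (default 4.0).
#' @return Data frame with `res_i`, `res_j` (res_i < res_j), `aa_i`,
#'   `aa_j`, `pair` (canonical key); one row per pair instance.
#' @export
extract_geometric_pairs <- function(structure, residue_set, radius = 4.0) {
  empty <- data.frame(res_i = integer(0), res_j = integer(0),
                      aa_i = character(0), aa_j = character(0),
                      pair = character(0), stringsAsFactors = FALSE)
  residue_set <- sort(unique(residue_set))
  if (length(residue_set) < 2L) return(empty)
  at <- structure$atoms
  at <- at[at$is_heavy & at$res_index %in% residue_set, , drop = FALSE]
  d <- as.matrix(stats::dist(as.matrix(at[, c("x", "y", "z")])))
  hit <- which(upper.tri(d) & d <= radius, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  ri <- at$res_index[hit[, 1L]]
  rj <- at$res_index[hit[, 2L]]
  keep <- ri != rj
  if (!any(keep)) return(empty)
  p <- unique(data.frame(res_i = pmin(ri[keep], rj[keep]),
                         res_j = pmax(ri[keep], rj[keep])))
  res <- residue_table(structure)
  p$aa_i <- res$aa[match(p$res_i, res$res_index)]
  p$aa_j <- res$aa[match(p$res_j, res$res_index)]
  p$pair <- pair_key(p$aa_i, p$aa_j)
  p <- p[order(p$res_i, p$res_j), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Tally GAAP counts over a labelled antigen set
#'
#' Positive counts accumulate pair instances whose two residues are both
#' epitope-labelled; negative counts accumulate surface pairs touching at
#' least one non-epitope residue.
#'
#' @param labeled List of entries, each a list with `structure`
#'   (`antigen_structure`), `ce` (epitope `res_index` vector) and
#'   `surface` (surface `res_index` vector, a superset of `ce`).
#' @param radius Pair radius in angstrom.
#' @return A `gaap_counts`: list with `radius`, named count vectors
#'   `n_plus`, `n_minus` over the 210-pair alphabet and scalars
#'   `total_plus`, `total_minus`.
#' @export
tally_gaap <- function(labeled, radius = 4.0) {
  if (length(labeled) == 0L) stop("empty dataset")
  keys <- enumerate_pair_alphabet()
  n_plus <- n_minus <- stats::setNames(numeric(length(keys)), keys)
  for (entry in labeled) {
    stopifnot(all(entry$ce %in% entry$surface))
    p <- extract_geometric_pairs(entry$structure, entry$surface, radius)
    if (nrow(p) == 0L) next
    both_ce <- p$res_i %in% entry$ce & p$res_j %in% entry$ce
    tp <- table(p$pair[both_ce])
    tm <- table(p$pair[!both_ce])
    n_plus[names(tp)] <- n_plus[names(tp)] + as.numeric(tp)
    n_minus[names(tm)] <- n_minus[names(tm)] + as.numeric(tm)
  }
  structure(list(radius = radius, n_plus = n_plus, n_minus = n_minus,
                 total_plus = sum(n_plus), total_minus = sum(n_minus)),
            class = "gaap_counts")
}

#' Compute the CEI table from GAAP counts
#'
#' Smoothed frequencies `f = (N + pseudocount) / (Total + 210 *
#' pseudocount)` are formed for both label classes; `raw = log10(f+ /
#' f-)` and CEI is its min-max normalization to `[0, 1]`. If all raw
#' values coincide the normalization is degenerate and every CEI is set
#' to 0.5.
#'
#' @param counts A `gaap_counts`.
#' @param pseudocount Additive smoothing (default 1.0). With 0, pairs
#'   absent from a class produce infinite raw values; requires nonzero
#'   counts.
#' @return A `cei_table`: data frame (`pair`, `aa1`, `aa2`, `n_plus`,
#'   `n_minus`, `f_plus`, `f_minus`, `raw`, `cei`) with attributes
#'   `radius`, `pseudocount`, `normalization`.
#' @export
compute_cei <- function(counts, pseudocount = 1.0) {
  if (counts$total_plus <= 0 || counts$total_minus <= 0)
    stop("degenerate totals: both label classes need at least one pair")
  keys <- names(counts$n_plus)
  npair <- length(keys)
  f_plus <- (counts$n_plus + pseudocount) /
    (counts$total_plus + npair * pseudocount)
  f_minus <- (counts$n_minus + pseudocount) /
    (counts$total_minus + npair * pseudocount)
  raw <- log10(f_plus / f_minus)
  fin <- raw[is.finite(raw)]
  if (length(fin) == 0L || max(fin) - min(fin) < 1e-12) {
    cei <- rep(0.5, npair)
  } else {
    cei <- (raw - min(fin)) / (max(fin) - min(fin))
    cei[raw == -Inf] <- 0
    cei[raw == Inf] <- 1
    cei <- pmin(pmax(cei, 0), 1)
  }
  out <- data.frame(pair = keys,
                    aa1 = substr(keys, 1L, 1L),
                    aa2 = substr(keys, 3L, 3L),
                    n_plus = unname(counts$n_plus),
                    n_minus = unname(counts$n_minus),
                    f_plus = unname(f_plus), f_minus = unname(f_minus),
                    raw = unname(raw), cei = unname(cei),
                    stringsAsFactors = FALSE)
  attr(out, "radius") <- counts$radius
  attr(out, "pseudocount") <- pseudocount
  attr(out, "normalization") <- "minmax"
  class(out) <- c("cei_table", "data.frame")
  out
}

#' Mean CEI of a residue cluster
#'
#' Average CEI over the geometric pair instances formed inside the
#' cluster at the table's radius; clusters with no internal pair score 0.
#'
#' @param members Integer vector of cluster `res_index` values.
#' @param structure The `antigen_structure`.
#' @param table A `cei_table`.
#' @param radius Pair radius; defaults to the table's.
#' @return Scalar in `[0, 1]`.
#' @export
cluster_cei <- function(members, structure, table,
                        radius = attr(table, "radius")) {
  p <- extract_geometric_pairs(structure, members, radius)
  if (nrow(p) == 0L) return(0)
  mean(table$cei[match(p$pair, table$pair)])
}

#' Serialize / load a CEI table
#'
#' TSV for the table body plus a JSON side-car with metadata when `path`
#' ends in `.json`, or a single JSON document holding both.
#'
#' @param table A `cei_table`.
#' @param path Output path (`.json`).
#' @return `path` invisibly (write); `cei_table` (read).
#' @export
write_cei <- function(table, path) {
  obj <- list(radius = attr(table, "radius"),
              pseudocount = attr(table, "pseudocount"),
              normalization = attr(table, "normalization"),
              table = as.data.frame(table))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cei
#' @export
read_cei <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- obj$table
  attr(out, "radius") <- obj$radius
  attr(out, "pseudocount") <- obj$pseudocount
  attr(out, "normalization") <- obj$normalization
  class(out) <- c("cei_table", "data.frame")
  out
}
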