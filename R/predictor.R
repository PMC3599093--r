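# Four-stage epitope prediction: surface extraction, energy profiling,
# anchor selection + cluster growth, weighted ranking.

#' Predictor configuration
#'
#' Defaults: anchors are drawn from the top 20% of surface residues by
#' local-average energy, restricted to surface rates in `[0.2, 0.5]`,
#' thinned so that kept anchors are at least 12 A apart (CA-CA); each
#' anchor grows into the surface residues within a 10-A CA sphere; the
#' combined score weights the normalized cluster energy by 0.8 and the
#' mean pair index (CEI) by 0.2; the top 3 clusters are reported.
#'
#' @param top_energy_fraction Fraction of surface residues eligible as
#'   anchors (default 0.2).
#' @param sr_band Length-2 numeric, inclusive SR interval for anchors
#'   (default `c(0.2, 0.5)`).
#' @param sr_band_mode `"value"` (SR interval, default) or `"quantile"`
#'   (interpret the band as SR quantiles of the surface distribution).
#' @param anchor_min_separation Minimum CA-CA distance between kept
#'   anchors (default 12).
#' @param grow_radius Cluster growth radius (default 10).
#' @param w_eg,w_gaap Score weights, must sum to 1 (defaults 0.8 / 0.2).
#' @param top_k Number of clusters reported (default 3).
#' @param spacing,b1_radius,b2_radius,min_sr Surface-stage parameters.
#' @param avg_radius Local energy averaging radius (default 8).
#' @param window Energy averaging mode, `"sphere"` or `"sequence"`.
#' @param pair_radius Radius for CEI pair extraction (default 4).
#' @return A `predictor_config` list.
#' @export
predictor_config <- function(top_energy_fraction = 0.2,
                             sr_band = c(0.2, 0.5),
                             sr_band_mode = c("value", "quantile"),
                             anchor_min_separation = 12.0,
                             grow_radius = 10.0,
                             w_eg = 0.8, w_gaap = 0.2, top_k = 3L,
                             spacing = 1.0, b1_radius = 1.5,
                             b2_radius = b1_radius + spacing,
                             min_sr = 0.05, avg_radius = 8.0,
                             window = "sphere", pair_radius = 4.0) {
  stopifnot(abs(w_eg + w_gaap - 1) < 1e-9, top_k >= 1L,
            length(sr_band) == 2L, sr_band[1L] <= sr_band[2L])
  structure(list(top_energy_fraction = top_energy_fraction,
                 sr_band = sr_band,
                 sr_band_mode = match.arg(sr_band_mode),
                 anchor_min_separation = anchor_min_separation,
                 grow_radius = grow_radius, w_eg = w_eg, w_gaap = w_gaap,
                 top_k = as.integer(top_k), spacing = spacing,
                 b1_radius = b1_radius, b2_radius = b2_radius,
                 min_sr = min_sr, avg_radius = avg_radius,
                 window = window, pair_radius = pair_radius),
            class = "predictor_config")
}

#' Select mutually exclusive high-energy anchors
#'
#' Candidates are the top `top_energy_fraction` of surface residues by
#' local-average energy whose SR lies in the configured band; a greedy
#' pass in descending energy order keeps a candidate only if its CA is at
#' least `anchor_min_separation` from every already-kept anchor.
#'
#' @param profile An `energy_profile`.
#' @param table A `surface_table`.
#' @param structure The `antigen_structure`.
#' @param cfg A `predictor_config`.
#' @return Integer vector of anchor `res_index` values (possibly empty),
#'   in selection order.
#' @export
select_anchors <- function(profile, table, structure, cfg) {
  surface <- surface_residues(table)
  if (length(surface) == 0L) return(integer(0))
  top <- rank_by_energy(profile, surface, cfg$top_energy_fraction)
  sr <- table$residues$sr[match(top, table$residues$res_index)]
  band <- cfg$sr_band
  if (cfg$sr_band_mode == "quantile") {
    all_sr <- table$residues$sr[match(surface, table$residues$res_index)]
    band <- stats::quantile(all_sr, probs = cfg$sr_band, names = FALSE)
  }
  cand <- top[sr >= band[1L] & sr <= band[2L]]
  if (length(cand) == 0L) return(integer(0))
  ca <- ca_coords(structure)
  kept <- integer(0)
  for (r in cand) {
    if (length(kept) == 0L) { kept <- r; next }
    d <- sqrt(colSums((t(ca[kept, , drop = FALSE]) - ca[r, ])^2))
    if (all(d >= cfg$anchor_min_separation)) kept <- c(kept, r)
  }
  kept
}

#' Grow a cluster around an anchor
#'
#' @param anchor Anchor `res_index` (must be a surface residue).
#' @param structure The `antigen_structure`.
#' @param surface Integer vector of surface residue indices.
#' @param cfg A `predictor_config`.
#' @return An `epitope_cluster`: list with `anchor`, `members` (surface
#'   residues within `grow_radius` of the anchor's CA, anchor included)
#'   and empty scores.
#' @export
grow_cluster <- function(anchor, structure, surface, cfg) {
  stopifnot(anchor %in% surface)
  ca <- ca_coords(structure)
  d <- sqrt(colSums((t(ca[surface, , drop = FALSE]) - ca[anchor, ])^2))
  members <- sort(unique(c(anchor, surface[d <= cfg$grow_radius])))
  structure(list(anchor = anchor, members = members,
                 energy_score = NA_real_, cei_score = NA_real_,
                 combined_score = NA_real_, rank = NA_integer_),
            class = "epitope_cluster")
}

# Min-max normalize cluster mean energies; all-equal (incl. singleton)
# collapses to 1 so a lone cluster keeps full energy weight.
.normalize_cluster_energies <- function(mean_e) {
  rng <- range(mean_e)
  if (diff(rng) < 1e-12) return(rep(1, length(mean_e)))
  (mean_e - rng[1L]) / diff(rng)
}

#' Score clusters with weighted energy and CEI
#'
#' The energy score of each cluster is the min-max normalization (across
#' this antigen's clusters) of its mean member local-average energy; the
#' CEI score is [cluster_cei()]; the combined score is their weighted sum.
#'
#' @param clusters List of `epitope_cluster`.
#' @param profile An `energy_profile`.
#' @param structure The `antigen_structure`.
#' @param cei_table A `cei_table`.
#' @param cfg A `predictor_config`.
#' @return The cluster list with scores filled in.
#' @export
score_clusters <- function(clusters, profile, structure, cei_table, cfg) {
  if (length(clusters) == 0L) return(clusters)
  mean_e <- vapply(clusters, function(cl)
    mean(profile$local_avg[cl$members], na.rm = TRUE), numeric(1))
  es <- .normalize_cluster_energies(mean_e)
  for (i in seq_along(clusters)) {
    cs <- cluster_cei(clusters[[i]]$members, structure, cei_table,
                      cfg$pair_radius)
    clusters[[i]]$energy_score <- es[i]
    clusters[[i]]$cei_score <- cs
    clusters[[i]]$combined_score <- cfg$w_eg * es[i] + cfg$w_gaap * cs
  }
  clusters
}

# Order scored clusters: combined desc, energy desc, anchor asc; assign
# ranks and truncate to top_k.
.rank_clusters <- function(clusters, cfg) {
  if (length(clusters) == 0L) return(clusters)
  comb <- vapply(clusters, `[[`, numeric(1), "combined_score")
  es <- vapply(clusters, `[[`, numeric(1), "energy_score")
  anc <- vapply(clusters, `[[`, numeric(1), "anchor")
  ord <- order(-comb, -es, anc)
  clusters <- clusters[ord][seq_len(min(cfg$top_k, length(clusters)))]
  for (i in seq_along(clusters)) clusters[[i]]$rank <- i
  clusters
}

#' Predict conformational epitope clusters
#'
#' Runs the full four-stage workflow on one antigen chain: morphological
#' surface extraction and surface rates, contact-energy profiling with
#' local averaging, anchor selection and cluster growth, and weighted
#' energy + CEI ranking. Returns at most `cfg$top_k` clusters.
#'
#' @param structure An `antigen_structure`.
#' @param potential A trained `contact_potential`.
#' @param cei_table A `cei_table`.
#' @param cfg A `predictor_config` (defaults).
#' @param surface_table Optional precomputed `surface_table` (skips the
#'   morphology stage when supplied).
#' @return An `epitope_prediction`: list with `clusters` (ranked
#'   `epitope_cluster`s), `surface_table`, `profile`, `anchors`, `cfg`
#'   and a `diagnostic` message when empty.
#' @export
predict_epitopes <- function(structure, potential, cei_table,
                             cfg = predictor_config(),
                             surface_table = NULL) {
  st <- surface_table
  if (is.null(st))
    st <- compute_surface_table(structure, cfg$spacing, cfg$b1_radius,
                                cfg$b2_radius, cfg$min_sr)
  surface <- surface_residues(st)
  if (length(surface) == 0L) {
    return(structure(list(clusters = list(), surface_table = st,
                          profile = NULL, anchors = integer(0), cfg = cfg,
                          diagnostic = "no surface residues"),
                     class = "epitope_prediction"))
  }
  prof <- energy_profile(structure, potential, surface,
                         radius = cfg$avg_radius, window = cfg$window)
  anchors <- select_anchors(prof, st, structure, cfg)
  if (length(anchors) == 0L) {
    return(structure(list(clusters = list(), surface_table = st,
                          profile = prof, anchors = anchors, cfg = cfg,
                          diagnostic = "no anchor candidates"),
                     class = "epitope_prediction"))
  }
  clusters <- lapply(anchors, grow_cluster, structure = structure,
                     surface = surface, cfg = cfg)
  clusters <- score_clusters(clusters, prof, structure, cei_table, cfg)
  clusters <- .rank_clusters(clusters, cfg)
  structure(list(clusters = clusters, surface_table = st, profile = prof,
                 anchors = anchors, cfg = cfg, diagnostic = NULL),
            class = "epitope_prediction")
}

#' @export
print.epitope_prediction <- function(x, ...) {
  if (length(x$clusters) == 0L) {
    cat("<epitope_prediction> no clusters:", x$diagnostic, "\n")
    return(invisible(x))
  }
  cat(sprintf("<epitope_prediction> %d cluster(s):\n", length(x$clusters)))
  for (cl in x$clusters) {
    cat(sprintf(
      "  #%d anchor %d | %d residues | energy %.3f, CEI %.3f, combined %.3f\n",
      cl$rank, cl$anchor, length(cl$members), cl$energy_score,
      cl$cei_score, cl$combined_score))
  }
  invisible(x)
}

#' Export a prediction as JSON
#'
#' @param prediction An `epitope_prediction`.
#' @param structure The `antigen_structure` (for residue numbering).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(prediction, structure, path) {
  res <- residue_table(structure)
  clusters <- lapply(prediction$clusters, function(cl) {
    m <- match(cl$members, res$res_index)
    list(rank = cl$rank,
         anchor = list(chain = res$chain[match(cl$anchor, res$res_index)],
                       resno = res$resno[match(cl$anchor, res$res_index)]),
         members = data.frame(chain = res$chain[m], resno = res$resno[m],
                              icode = res$icode[m], aa = res$aa[m]),
         energy_score = cl$energy_score, cei_score = cl$cei_score,
         combined_score = cl$combined_score)
  })
  obj <- list(pdb_id = structure$pdb_id, chain = structure$chain_id,
              parameters = unclass(prediction$cfg), clusters = clusters,
              diagnostic = prediction$diagnostic)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
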