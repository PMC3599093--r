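# Ground-truth epitope extraction from antigen-antibody complexes,
# confusion metrics, and k-fold cross-validation over score-weight grids.

#' Ground-truth epitope residues from a complex
#'
#' Two interface conventions are supported. `"discotope"`: residues with
#' any heavy atom within 4 A of an antibody heavy atom ("tied" residues)
#' plus antigen residues with any heavy atom within 4 A of a tied
#' residue's heavy atoms. `"epitome"`: residues with any heavy atom
#' within 6 A of an antibody heavy atom (the whole antibody stands in for
#' its complementarity-determining regions, which cannot be located
#' without a numbering scheme).
#'
#' @param antigen,antibody `antigen_structure` objects from the same
#'   complex.
#' @param mode `"discotope"` or `"epitome"`.
#' @param contact_cutoff Direct-contact cutoff (default 4 for discotope,
#'   6 for epitome).
#' @param expand_cutoff Neighbour expansion cutoff in discotope mode
#'   (default 4).
#' @return Integer vector of epitope `res_index` values in the antigen
#'   (empty, with a warning, if there are no contacts).
#' @export
true_epitope_residues <- function(antigen, antibody,
                                  mode = c("discotope", "epitome"),
                                  contact_cutoff = NULL,
                                  expand_cutoff = 4.0) {
  mode <- match.arg(mode)
  if (is.null(contact_cutoff))
    contact_cutoff <- if (mode == "discotope") 4.0 else 6.0
  ag <- antigen$atoms[antigen$atoms$is_heavy, , drop = FALSE]
  ab <- antibody$atoms[antibody$atoms$is_heavy, , drop = FALSE]
  if (nrow(ag) == 0L || nrow(ab) == 0L) stop("empty structure")
  dmin <- .min_dist_to_set(as.matrix(ag[, c("x", "y", "z")]),
                           as.matrix(ab[, c("x", "y", "z")]))
  tied_atoms <- dmin <= contact_cutoff
  tied <- sort(unique(ag$res_index[tied_atoms]))
  if (length(tied) == 0L) {
    warning("no antigen-antibody contacts within ", contact_cutoff, " A")
    return(integer(0))
  }
  if (mode == "epitome") return(tied)
  tied_xyz <- as.matrix(ag[ag$res_index %in% tied, c("x", "y", "z")])
  dmin2 <- .min_dist_to_set(as.matrix(ag[, c("x", "y", "z")]), tied_xyz)
  expanded <- sort(unique(ag$res_index[dmin2 <= expand_cutoff]))
  sort(unique(c(tied, expanded)))
}

# For each row of `a`, the minimal Euclidean distance to any row of `b`.
.min_dist_to_set <- function(a, b) {
  cross <- a %*% t(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * cross
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' Confusion counts for a predicted residue set
#'
#' @param predicted,truth Integer residue-index vectors, both subsets of
#'   `universe`.
#' @param universe Evaluation universe (surface residues).
#' @return A `confusion_counts` list: TP, FP, TN, FN.
#' @export
confusion <- function(predicted, truth, universe) {
  predicted <- unique(predicted); truth <- unique(truth)
  if (!all(predicted %in% universe) || !all(truth %in% universe))
    stop("predicted and truth sets must lie within the universe")
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  tn <- length(universe) - tp - fp - fn
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn),
            class = "confusion_counts")
}

#' Sensitivity, specificity, PPV and accuracy
#'
#' SE = TP/(TP+FN); SP = TN/(TN+FP); PPV = TP/(TP+FP);
#' ACC = (TP+TN)/(TP+TN+FN+FP). Any 0/0 is reported as 0 and flagged.
#'
#' @param cm A `confusion_counts`.
#' @return A `metrics_record`: list SE, SP, PPV, ACC plus `degenerate`
#'   (logical, any 0/0 encountered).
#' @export
metrics <- function(cm) {
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  se <- safe(cm$TP, cm$TP + cm$FN)
  sp <- safe(cm$TN, cm$TN + cm$FP)
  ppv <- safe(cm$TP, cm$TP + cm$FP)
  acc <- safe(cm$TP + cm$TN, cm$TP + cm$TN + cm$FN + cm$FP)
  degenerate <- any(is.na(c(se, sp, ppv, acc)))
  out <- lapply(list(SE = se, SP = sp, PPV = ppv, ACC = acc),
                function(v) if (is.na(v)) 0 else v)
  structure(c(out, list(degenerate = degenerate, counts = cm)),
            class = "metrics_record")
}

#' Best cluster among the top k
#'
#' Evaluates each of the first `k` ranked clusters against the truth set
#' and returns the metrics of the cluster with the highest sensitivity
#' (ties broken by higher accuracy). An empty cluster list yields
#' all-zero metrics with FN = |truth|.
#'
#' @param clusters Ranked list of `epitope_cluster`s.
#' @param truth Integer vector of true epitope residues.
#' @param universe Evaluation universe (surface residues).
#' @param k Number of clusters considered (default 3).
#' @return A `metrics_record`.
#' @export
best_of_top_k <- function(clusters, truth, universe, k = 3L) {
  truth <- intersect(truth, universe)
  if (length(clusters) == 0L)
    return(metrics(confusion(integer(0), truth, universe)))
  clusters <- clusters[seq_len(min(k, length(clusters)))]
  recs <- lapply(clusters, function(cl)
    metrics(confusion(intersect(cl$members, universe), truth, universe)))
  se <- vapply(recs, `[[`, numeric(1), "SE")
  acc <- vapply(recs, `[[`, numeric(1), "ACC")
  recs[[order(-se, -acc)[1L]]]
}

#' k-fold cross-validation over a weight grid
#'
#' Antigens are randomly partitioned into `k_folds` folds (seeded). For
#' each fold, the CEI table is trained on the remaining folds, the
#' held-out antigens are predicted under every weight pair of the grid,
#' and best-of-top-`top_k` metrics are recorded per antigen. Final rows
#' are per-antigen averages over all folds, one row per weight pair.
#'
#' Surface tables, energy profiles and candidate clusters do not depend
#' on the fold or the weights, so they are computed once per antigen and
#' re-ranked under each fold's CEI table and each weight pair.
#'
#' @param dataset List of entries: `structure`, `ce` (true epitope
#'   residues), optionally `surface` (else computed).
#' @param potential A `contact_potential` (trained independently of the
#'   fold split).
#' @param k_folds Number of folds (default 10).
#' @param weight_grid Two-column matrix or data frame of (w_eg, w_gaap)
#'   rows; default the 11-point grid 0, 0.1, ..., 1.
#' @param seed Integer seed controlling the fold assignment.
#' @param cfg Base `predictor_config`; its weights are overridden by the
#'   grid.
#' @param mode Truth convention already applied to `ce` (stored in the
#'   output for bookkeeping).
#' @return A `cv_result`: data frame with columns `w_eg`, `w_gaap`, `SE`,
#'   `SP`, `PPV`, `ACC` (one row per weight pair) plus attributes `folds`
#'   (assignment) and `seed`.
#' @export
cross_validate <- function(dataset, potential, k_folds = 10L,
                           weight_grid = NULL, seed = 1L,
                           cfg = predictor_config(), mode = "discotope") {
  n <- length(dataset)
  if (n < k_folds) stop("fewer antigens than folds")
  if (is.null(weight_grid)) {
    w <- seq(0, 1, by = 0.1)
    weight_grid <- data.frame(w_eg = w, w_gaap = 1 - w)
  }
  weight_grid <- as.data.frame(weight_grid)
  names(weight_grid) <- c("w_eg", "w_gaap")

  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k_folds), n))

  # Fold-independent per-antigen state.
  prepared <- lapply(dataset, function(entry) {
    st <- compute_surface_table(entry$structure, cfg$spacing,
                                cfg$b1_radius, cfg$b2_radius, cfg$min_sr)
    surface <- surface_residues(st)
    if (is.null(entry$surface)) entry$surface <- surface
    prof <- energy_profile(entry$structure, potential, surface,
                           radius = cfg$avg_radius, window = cfg$window)
    anchors <- if (length(surface) > 0L)
      select_anchors(prof, st, entry$structure, cfg) else integer(0)
    clusters <- lapply(anchors, grow_cluster,
                       structure = entry$structure, surface = surface,
                       cfg = cfg)
    mean_e <- vapply(clusters, function(cl)
      mean(prof$local_avg[cl$members], na.rm = TRUE), numeric(1))
    list(entry = entry, st = st, surface = surface, clusters = clusters,
         energy_score = if (length(clusters) > 0L)
           .normalize_cluster_energies(mean_e) else numeric(0))
  })

  acc <- array(NA_real_, dim = c(nrow(weight_grid), 4L, n),
               dimnames = list(NULL, c("SE", "SP", "PPV", "ACC"), NULL))
  for (f in seq_len(k_folds)) {
    train_idx <- which(fold != f)
    labeled <- lapply(prepared[train_idx], function(p)
      list(structure = p$entry$structure,
           ce = intersect(p$entry$ce, p$surface), surface = p$surface))
    counts <- tally_gaap(labeled, radius = cfg$pair_radius)
    cei <- compute_cei(counts)
    for (i in which(fold == f)) {
      p <- prepared[[i]]
      truth <- intersect(p$entry$ce, p$surface)
      cei_scores <- vapply(p$clusters, function(cl)
        cluster_cei(cl$members, p$entry$structure, cei,
                    cfg$pair_radius), numeric(1))
      for (wi in seq_len(nrow(weight_grid))) {
        cl <- p$clusters
        for (j in seq_along(cl)) {
          cl[[j]]$energy_score <- p$energy_score[j]
          cl[[j]]$cei_score <- cei_scores[j]
          cl[[j]]$combined_score <-
            weight_grid$w_eg[wi] * p$energy_score[j] +
            weight_grid$w_gaap[wi] * cei_scores[j]
        }
        wcfg <- cfg
        wcfg$w_eg <- weight_grid$w_eg[wi]
        wcfg$w_gaap <- weight_grid$w_gaap[wi]
        ranked <- .rank_clusters(cl, wcfg)
        rec <- best_of_top_k(ranked, truth, p$surface, k = cfg$top_k)
        acc[wi, , i] <- c(rec$SE, rec$SP, rec$PPV, rec$ACC)
      }
    }
  }
  out <- weight_grid
  for (m in c("SE", "SP", "PPV", "ACC"))
    out[[m]] <- apply(acc[, m, , drop = FALSE], 1L, mean)
  attr(out, "folds") <- fold
  attr(out, "seed") <- seed
  attr(out, "mode") <- mode
  class(out) <- c("cv_result", "data.frame")
  out
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Export a cross-validation report as TSV
#'
#' One row per weight pair with SE/SP/PPV/ACC columns.
#'
#' @param result A `cv_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_cv_report <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
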