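## End-to-end orchestration: simulate -> (preprocess) -> invert -> connect ->
## network -> statistics -> behavior, collected into a report bundle.

#' Greedily relabel a partition to best match a reference
#'
#' Maps each estimated group to the reference group it overlaps most, in
#' decreasing order of overlap, so planted and recovered sub-networks can be
#' compared pair by pair.
#'
#' @param estimated,reference Integer membership vectors of equal length.
#' @return Integer vector: `estimated` relabeled into reference labels
#'   (unmatched groups keep fresh labels).
#' @export
relabel_partition <- function(estimated, reference) {
  eg <- sort(unique(estimated)); rg <- sort(unique(reference))
  ov <- outer(eg, rg, Vectorize(function(a, b) sum(estimated == a & reference == b)))
  map <- stats::setNames(rep(NA_integer_, length(eg)), eg)
  used <- integer(0)
  ord <- order(ov, decreasing = TRUE)
  for (k in ord) {
    i <- (k - 1) %% length(eg) + 1; j <- (k - 1) %/% length(eg) + 1
    if (is.na(map[i]) && !(rg[j] %in% used)) { map[i] <- rg[j]; used <- c(used, rg[j]) }
  }
  nxt <- max(rg) + 1L
  for (i in seq_along(map)) if (is.na(map[i])) { map[i] <- nxt; nxt <- nxt + 1L }
  unname(map[match(estimated, eg)])
}

condition_contrasts <- function(conditions) {
  tasks <- unique(sub("-(IL|IT)$", "", conditions[grepl("-(IL|IT)$", conditions)]))
  out <- list()
  for (tk in tasks) {
    il <- paste0(tk, "-IL"); it <- paste0(tk, "-IT")
    if (il %in% conditions && it %in% conditions)
      out[[tk]] <- c(il = il, it = it)
  }
  out
}

#' Run the full source-space network analysis on simulated data
#'
#' Executes the analysis chain end to end: generate source epochs per
#' subject, condition, and window; project to the scalp and (optionally)
#' contaminate and clean them; invert with the standardized minimum-norm
#' operator; compute lagged-phase-synchronization matrices per window;
#' derive the event-related (c1) and absolute (c2) indices; identify K
#' sub-networks from the average-linkage dendrogram of the group-mean SDP
#' matrix; sum intra-/inter-group connectivity; run paired tmax tests
#' between each task's IL and IT conditions (p1 for c1, p2 for c2) on the
#' group sums and on per-ROI event-related clustering coefficients; and
#' correlate response times with event-related clustering via the
#' max-statistic Spearman test. Deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @param K Number of sub-networks to cut from the dendrogram.
#' @param distance_method Passed to [node_distance_matrix()].
#' @param project If `TRUE`, run through the scalp (forward model + inverse);
#'   if `FALSE`, analyze the simulated source epochs directly.
#' @param artifacts If `TRUE`, inject EOG/EMG artifacts and run the full
#'   cleaning chain (band-pass 1-30 Hz, common average, SOBI EOG removal,
#'   BSS-CCA EMG removal, trial rejection) before inversion. Considerably
#'   slower; intended for small configurations.
#' @param n_perm Permutations for all tests.
#' @param lambda Inverse-operator regularization (default as in
#'   [build_inverse_operator()]).
#' @return Object of class `report_bundle`; see Details in the package
#'   vignette. Contains the partition table, dendrograms, group-mean
#'   matrices, per-subject indices, permutation results, the RT correlation
#'   tables, and the resolved configuration.
#' @export
run_full_analysis <- function(config, K = 4L,
                              distance_method = "profile_correlation",
                              project = TRUE, artifacts = FALSE,
                              n_perm = 1999L, lambda = NULL) {
  gt <- simulation_ground_truth(config)
  lf <- NULL; inv <- NULL
  if (project) {
    lf <- make_leadfield(config$n_channels, config$n_rois, seed = config$seed)
    inv <- build_inverse_operator(lf, lambda = lambda)
  }
  R <- config$n_rois
  conds <- config$conditions
  nS <- config$n_subjects
  labs <- roi_labels_for(R)

  c1_arr <- array(NA_real_, c(nS, R, R, length(conds)))
  c2_arr <- array(NA_real_, c(nS, R, R, length(conds)))
  base_arr <- array(NA_real_, c(nS, R, R, length(conds)))
  erC <- array(NA_real_, c(nS, R, length(conds)),
               dimnames = list(NULL, labs, conds))
  absC <- erC
  for (s in seq_len(nS)) for (ci in seq_along(conds)) {
    se <- simulate_source_epochs(config, s, conds[ci], ground_truth = gt)
    lpsm <- list()
    for (win in c("baseline", "sdp")) {
      ep <- se[[win]]
      if (project) {
        ch <- project_to_channels(ep, lf, config$sensor_snr_db,
                                  seed = derive_seed(config$seed, 400L, s, ci,
                                                     match(win, c("baseline", "sdp"))))
        if (artifacts) {
          art <- inject_artifacts(ch, config,
                                  seed = derive_seed(config$seed, 401L, s, ci))
          ch <- bandpass_filter(art$epochs, 1, 30)
          ch <- rereference_common_average(ch)
          ch <- remove_eog_components(ch, art$eog, threshold = 0.7)
          ch <- bsscca_remove_emg(ch, autocorr_threshold = 0.85)
          ch <- reject_noisy_trials(ch)
        }
        ep <- apply_inverse(ch, inv)
      }
      lpsm[[win]] <- lagged_phase_synchronization(
        band_cross_spectra(ep, band = config$band))
    }
    c2 <- lpsm$sdp
    c1 <- event_related_index(lpsm$sdp, lpsm$baseline)
    c1_arr[s, , , ci] <- c1$values
    c2_arr[s, , , ci] <- c2$values
    base_arr[s, , , ci] <- lpsm$baseline$values
    Cs <- weighted_clustering_coefficient(lpsm$sdp$values)
    Cb <- weighted_clustering_coefficient(lpsm$baseline$values)
    erC[s, , ci] <- event_related_clustering(Cs, Cb)
    absC[s, , ci] <- Cs
  }

  ## sub-network identification on group-mean absolute SDP matrices
  mean_c2 <- lapply(seq_along(conds), function(ci)
    apply(c2_arr[, , , ci, drop = FALSE], c(2L, 3L), mean))
  names(mean_c2) <- conds
  grand <- Reduce(`+`, mean_c2) / length(mean_c2)
  rownames(grand) <- colnames(grand) <- labs
  dendros <- lapply(mean_c2, function(m) {
    rownames(m) <- colnames(m) <- labs
    average_linkage(node_distance_matrix(m, method = distance_method))
  })
  part <- cut_to_groups(average_linkage(
    node_distance_matrix(grand, method = distance_method)), K = K)
  grp <- relabel_partition(part$groups, gt$partition)
  npair <- if (K > 1) K * (K - 1) / 2 else 0

  ## per-subject intra/inter sums. The c2 sums are group sums of the absolute
  ## SDP matrix. The c1 (event-related) group quantities are the relative
  ## change of the *summed* connectivity, (sum_sdp - sum_baseline) /
  ## sum_baseline: normalizing after aggregation keeps the denominator away
  ## from the single-edge sampling floor that makes edgewise c1 ratios
  ## heavy-tailed for weakly coupled group pairs.
  gs <- function(arr, s, ci) group_connectivity(arr[s, , , ci], grp)
  ids <- sort(unique(grp))
  intra_c1 <- array(NA_real_, c(nS, length(ids), length(conds)),
                    dimnames = list(NULL, as.character(ids), conds))
  intra_c2 <- intra_c1
  pr_names <- if (length(ids) > 1)
    apply(utils::combn(ids, 2L), 2L, paste, collapse = ":") else character(0)
  inter_c1 <- array(NA_real_, c(nS, length(pr_names), length(conds)),
                    dimnames = list(NULL, pr_names, conds))
  inter_c2 <- inter_c1
  for (s in seq_len(nS)) for (ci in seq_along(conds)) {
    g2 <- gs(c2_arr, s, ci); gb <- gs(base_arr, s, ci)
    intra_c2[s, , ci] <- g2$intra
    intra_c1[s, , ci] <- (g2$intra - gb$intra) / pmax(gb$intra, 1e-6)
    if (length(pr_names)) {
      inter_c2[s, , ci] <- g2$inter
      inter_c1[s, , ci] <- (g2$inter - gb$inter) / pmax(gb$inter, 1e-6)
    }
  }

  ## paired IL vs IT tmax tests per task, intra and inter families separately
  contrasts <- condition_contrasts(conds)
  stats_tabs <- list()
  for (tk in names(contrasts)) {
    il <- match(contrasts[[tk]]["il"], conds); it <- match(contrasts[[tk]]["it"], conds)
    sd_seed <- derive_seed(config$seed, 500L, match(tk, names(contrasts)))
    res <- list(
      intra = list(
        c1 = paired_tmax(intra_c1[, , il], intra_c1[, , it], n_perm, sd_seed),
        c2 = paired_tmax(intra_c2[, , il], intra_c2[, , it], n_perm, sd_seed + 1L)),
      clustering = list(
        er = paired_tmax(erC[, , il], erC[, , it], n_perm, sd_seed + 4L),
        abs = paired_tmax(absC[, , il], absC[, , it], n_perm, sd_seed + 5L))
    )
    if (length(pr_names))
      res$inter <- list(
        c1 = paired_tmax(inter_c1[, , il], inter_c1[, , it], n_perm, sd_seed + 2L),
        c2 = paired_tmax(inter_c2[, , il], inter_c2[, , it], n_perm, sd_seed + 3L))
    stats_tabs[[tk]] <- res
  }

  ## behavior: response times vs event-related clustering, per condition
  beh <- simulate_behavior(gt, config)
  rt_tests <- list()
  for (ci in seq_along(conds)) {
    rt_tests[[conds[ci]]] <- rt_correlation_analysis(
      beh$table, erC[, , ci], condition = conds[ci], n_perm = n_perm,
      seed = derive_seed(config$seed, 600L, ci))
  }

  structure(list(
    config = config,
    ground_truth = gt,
    leadfield = lf,
    partition = data.frame(roi = labs, group = grp),
    partition_raw = part,
    dendrograms = dendros,
    mean_connectivity = mean_c2,
    grand_mean_connectivity = grand,
    indices = list(c1 = c1_arr, c2 = c2_arr,
                   er_clustering = erC, abs_clustering = absC,
                   intra_c1 = intra_c1, intra_c2 = intra_c2,
                   inter_c1 = inter_c1, inter_c2 = inter_c2),
    stats = stats_tabs,
    behavior = beh$table,
    rt_tests = rt_tests
  ), class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d subjects, %d conditions, %d ROIs, K = %d groups\n",
              x$config$n_subjects, length(x$config$conditions),
              x$config$n_rois, max(x$partition$group)))
  for (tk in names(x$stats)) {
    s <- x$stats[[tk]]
    if (!is.null(s$inter)) {
      sig <- names(which(s$inter$c1$p_corrected < 0.05))
      cat(sprintf("  task %s: inter-group c1 significant pairs: %s\n", tk,
                  if (length(sig)) paste(sig, collapse = ", ") else "none"))
    }
  }
  invisible(x)
}

#' Export a report bundle to plain-text files
#'
#' Writes connectivity matrices and statistics tables as CSV, the partition
#' and configuration as JSON, dendrograms as Newick (via \pkg{ape}) plus
#' merge-table CSV, and a plain-text run log.
#'
#' @param bundle A [run_full_analysis()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(obj, name) {
    p <- file.path(dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(bundle$partition, "partition.csv")
  for (cond in names(bundle$mean_connectivity)) {
    m <- bundle$mean_connectivity[[cond]]
    rownames(m) <- colnames(m) <- bundle$partition$roi
    p <- file.path(dir, sprintf("connectivity_mean_%s.csv", gsub("[^A-Za-z0-9]", "_", cond)))
    utils::write.csv(m, p)
    paths <- c(paths, p)
  }
  for (tk in names(bundle$stats)) {
    s <- bundle$stats[[tk]]
    rows <- list()
    fam <- function(res, family, index) data.frame(
      task = tk, family = family, index = index,
      variable = names(res$statistic) %||% seq_along(res$statistic),
      t = res$statistic, p_corrected = res$p_corrected, row.names = NULL)
    rows[[1]] <- fam(s$intra$c1, "intra", "c1")
    rows[[2]] <- fam(s$intra$c2, "intra", "c2")
    if (!is.null(s$inter)) {
      rows[[3]] <- fam(s$inter$c1, "inter", "c1")
      rows[[4]] <- fam(s$inter$c2, "inter", "c2")
    }
    wr(do.call(rbind, rows), sprintf("group_stats_%s.csv", tk))
    wr(fam(s$clustering$er, "clustering", "event_related"),
       sprintf("clustering_stats_%s.csv", tk))
  }
  rt_rows <- lapply(names(bundle$rt_tests), function(cond) {
    r <- bundle$rt_tests[[cond]]
    data.frame(condition = cond, roi = names(r$statistic),
               rho = r$statistic, p_corrected = r$p_corrected, row.names = NULL)
  })
  wr(do.call(rbind, rt_rows), "rt_correlation.csv")
  for (cond in names(bundle$dendrograms)) {
    h <- bundle$dendrograms[[cond]]
    stem <- gsub("[^A-Za-z0-9]", "_", cond)
    wr(data.frame(merge_a = h$merge[, 1], merge_b = h$merge[, 2], height = h$height),
       sprintf("dendrogram_%s.csv", stem))
    if (requireNamespace("ape", quietly = TRUE)) {
      p <- file.path(dir, sprintf("dendrogram_%s.nwk", stem))
      ape::write.tree(ape::as.phylo(h), p)
      paths <- c(paths, p)
    }
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    p <- file.path(dir, "config.json")
    cfg <- unclass(bundle$config)
    jsonlite::write_json(cfg, p, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "run_log.txt")
  writeLines(c(sprintf("lpsnet run, seed %d", bundle$config$seed),
               sprintf("subjects: %d, conditions: %s", bundle$config$n_subjects,
                       paste(bundle$config$conditions, collapse = ", ")),
               sprintf("band: %.1f-%.1f Hz", bundle$config$band[1], bundle$config$band[2]),
               sprintf("files: %s", paste(basename(paths), collapse = ", "))), p)
  invisible(c(paths, p))
}
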