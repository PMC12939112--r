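#' Process one CT scan end to end
#'
#' Runs the full scan-level chain: airway segmentation, lung segmentation,
#' multiscale vesselness, maxima detection, tree linking, artery/vein
#' separation and morphometry. If a ground-truth graph is supplied, the
#' length-weighted labeling accuracy is computed (with the global-swap
#' allowance only when the scan has no airway evidence). A segmentation
#' failure is reported in the returned status, not raised, so batch runs can
#' continue.
#'
#' @param volume A [ct_volume()].
#' @param truth Optional ground-truth [vessel_graph()] with the same
#'   segment topology semantics (accuracy is matched per predicted segment
#'   against the nearest truth tube, see [match_to_truth()]).
#' @param config Parameter list, see [default_config()].
#' @return List: `status` (`"processed"` or `"segmentation-failed"`),
#'   `graph`, `report`, `lungs`, `accuracy` (or NA), `message`.
#' @export
process_scan <- function(volume, truth = NULL, config = default_config()) {
  res <- tryCatch({
    airways <- segment_airways(volume, config = config)
    lungs <- segment_lungs(volume, airways, config = config)
    field <- compute_vesselness(volume, lungs, config = config)
    nodes <- detect_maxima(field, config = config, volume = volume)
    graph <- link_candidates(nodes, field, lungs, config = config)
    av <- separate_arteries_veins(graph, airways, config = config)
    report <- compute_report(av$graph, lungs)
    accuracy <- NA_real_
    if (!is.null(truth) && length(av$graph$segments) > 0) {
      matched <- match_to_truth(av$graph, truth)
      has_airway <- sum(airways$labels == 3L) > 0
      accuracy <- label_accuracy(matched$predicted, matched$truth,
                                 allow_swap = !has_airway)
    }
    list(status = "processed", graph = av$graph, report = report,
         lungs = lungs, accuracy = accuracy, message = "")
  }, pulmovasc_segmentation_failure = function(e) {
    list(status = "segmentation-failed", graph = NULL, report = NULL,
         lungs = NULL, accuracy = NA_real_, message = conditionMessage(e))
  })
  res
}

#' Match predicted segments to ground-truth tubes
#'
#' Assigns each predicted segment the label of the nearest ground-truth
#' tube (mean point-to-polyline distance), producing a pair of graphs with
#' identical segment ids for [label_accuracy()].
#'
#' @param predicted Predicted [vessel_graph()].
#' @param truth Ground-truth [vessel_graph()].
#' @return List of two graphs (`predicted`, `truth`) sharing segment ids.
#' @export
match_to_truth <- function(predicted, truth) {
  tpts <- lapply(truth$segments, function(s) s$points)
  tlab <- vapply(truth$segments, function(s) s$label, character(1))
  truth_labels <- vapply(predicted$segments, function(s) {
    dmean <- vapply(tpts, function(tp) {
      mean(vapply(seq_len(nrow(s$points)), function(i)
        sqrt(min(colSums((t(tp) - s$points[i, ])^2))), numeric(1)))
    }, numeric(1))
    tlab[which.min(dmean)]
  }, character(1))
  truth_matched <- predicted
  for (i in seq_along(truth_matched$segments))
    truth_matched$segments[[i]]$label <- truth_labels[i]
  list(predicted = predicted, truth = truth_matched)
}

#' Process a batch of scans with exclusion accounting
#'
#' Mirrors the cohort flow: scans failing segmentation are flagged (not
#' fatal); scans with labeling accuracy below the threshold are marked
#' excluded from the artery/vein subcohort. The manifest accounts for every
#' input scan exactly once.
#'
#' @param scans Named list; each element a list with `volume` and optional
#'   `truth`.
#' @param config Parameter list.
#' @return List: `manifest` tibble (`scan_id`, `status`, `accuracy`),
#'   `results` (per-scan [process_scan()] output), `reports` (bound report
#'   rows for processed scans).
#' @export
run_batch <- function(scans, config = default_config()) {
  ids <- names(scans)
  if (is.null(ids)) ids <- sprintf("scan%03d", seq_along(scans))
  results <- lapply(scans, function(sc)
    process_scan(sc$volume, truth = sc$truth, config = config))
  status <- vapply(results, function(r) r$status, character(1))
  acc <- vapply(results, function(r) r$accuracy, numeric(1))
  status[status == "processed" & !is.na(acc) &
           acc < config$min_av_accuracy] <- "excluded-low-accuracy"
  manifest <- tibble::tibble(scan_id = ids, status = unname(status),
                             accuracy = unname(acc))
  attr(manifest, "config_hash") <- config_hash(config)
  reports <- dplyr::bind_rows(lapply(which(status != "segmentation-failed"),
                                     function(i) {
    dplyr::mutate(results[[i]]$report, scan_id = ids[i], .before = 1)
  }))
  list(manifest = manifest, results = results, reports = reports)
}

#' Cohort-level diagnostic analysis
#'
#' Applies the labeling-accuracy exclusion, computes the Spearman
#' correlation panel (readouts vs hemodynamics, pairwise n), PH vs no-PH
#' group comparisons (Wilcoxon), ROC analyses for the artery/vein ratio per
#' diameter bin plus DMPA and DMPA/DAo, the combined markers
#' DMPA + ratio(6-10) and DMPA/DAo + ratio(6-10), and pairwise DeLong
#' comparisons of combined vs single markers. Artery/vein-specific readouts
#' are analysed on the A/V subcohort; whole-vasculature readouts on the full
#' table.
#'
#' @param table Cohort tibble (see [cohort_columns()]); mPAP required.
#' @param config Parameter list (exclusion threshold).
#' @return A `cohort_stats_bundle` (list of tibbles + `roc` objects).
#' @export
run_cohort <- function(table, config = default_config()) {
  if (!"mPAP" %in% names(table)) stop("mPAP column required", call. = FALSE)
  table$ph_status <- ph_status(table$mPAP)
  if ("DMPA" %in% names(table) && "DAo" %in% names(table))
    table$DMPA_DAo <- table$DMPA / table$DAo
  excl <- apply_exclusions(table, min_accuracy = config$min_av_accuracy)
  av <- excl$av_subcohort
  if (length(unique(stats::na.omit(av$ph_status))) < 2)
    stop("outcome has a single class after exclusions", call. = FALSE)

  hemo <- intersect(c("mPAP", "PVR", "PAWP", "CI", "SvO2", "RAP", "age", "BSA"),
                    names(table))
  av_readouts <- intersect(names(table), c(
    paste0("count_artery_", c("2_4", "4_6", "6_10", "all")),
    paste0("count_vein_", c("2_4", "4_6", "6_10", "all")),
    paste0("density_artery_", c("2_4", "4_6", "6_10", "all")),
    paste0("density_vein_", c("2_4", "4_6", "6_10", "all")),
    paste0("ratio_av_", c("2_4", "4_6", "6_10")),
    paste0("density_diff_av_", c("2_4", "4_6", "6_10")),
    "soam_median_artery", "soam_median_vein"))
  all_readouts <- intersect(names(table), c(
    "n_segments_total", "density_total", "vessel_volume_mm3",
    "normalized_vessel_volume", "soam_median_all", "DMPA", "DMPA_DAo"))

  cor_rows <- list()
  for (r in c(all_readouts, av_readouts)) {
    dat <- if (r %in% av_readouts) av else table
    for (h in hemo) {
      ok <- stats::complete.cases(dat[[r]], dat[[h]])
      if (sum(ok) < 3) next
      sc <- spearman_cor(dat[[r]], dat[[h]])
      cor_rows[[length(cor_rows) + 1]] <-
        dplyr::mutate(sc, readout = r, variable = h, .before = 1)
    }
  }
  correlations <- dplyr::bind_rows(cor_rows)

  cmp_rows <- list()
  for (r in c(all_readouts, av_readouts)) {
    dat <- if (r %in% av_readouts) av else table
    g1 <- dat[[r]][!dat$ph_status]
    g2 <- dat[[r]][dat$ph_status]
    if (sum(!is.na(g1)) == 0 || sum(!is.na(g2)) == 0) next
    rt <- rank_tests(list(g1, g2))
    cmp_rows[[length(cmp_rows) + 1]] <- tibble::tibble(
      readout = r,
      median_no_ph = stats::median(g1, na.rm = TRUE),
      median_ph = stats::median(g2, na.rm = TRUE),
      statistic = rt$statistic, p = rt$p.value,
      n_no_ph = sum(!is.na(g1)), n_ph = sum(!is.na(g2)))
  }
  group_comparisons <- dplyr::bind_rows(cmp_rows)

  roc_markers <- intersect(c("ratio_av_2_4", "ratio_av_4_6", "ratio_av_6_10",
                             "DMPA", "DMPA_DAo"), names(table))
  rocs <- list()
  for (m in roc_markers) {
    dat <- if (m %in% av_readouts) av else table
    ok <- stats::complete.cases(dat[[m]], dat$ph_status)
    if (length(unique(dat$ph_status[ok])) < 2) next
    rocs[[m]] <- roc_delong(dat[[m]][ok], dat$ph_status[ok])
  }

  combos <- list()
  delong_rows <- list()
  for (base in intersect(c("DMPA", "DMPA_DAo"), names(av))) {
    if (!"ratio_av_6_10" %in% names(av)) next
    cols <- c(base, "ratio_av_6_10")
    cc <- stats::complete.cases(av[, c(cols, "ph_status")])
    if (sum(cc) < 10 || length(unique(av$ph_status[cc])) < 2) next
    cm <- combine_markers(av, cols, outcome = "ph_status")
    nm <- paste0(base, "+ratio_av_6_10")
    combos[[nm]] <- cm
    rows <- cm$row_index
    dc <- delong_compare(cm$score, av[[base]][rows], av$ph_status[rows])
    delong_rows[[length(delong_rows) + 1]] <-
      dplyr::mutate(dc, comparison = paste(nm, "vs", base), .before = 1)
  }
  delong <- dplyr::bind_rows(delong_rows)

  roc_summary <- dplyr::bind_rows(c(
    lapply(names(rocs), function(m)
      dplyr::mutate(glance(rocs[[m]]), marker = m, .before = 1)),
    lapply(names(combos), function(m)
      dplyr::mutate(glance(combos[[m]]$roc), marker = m, .before = 1))))

  structure(list(exclusions = excl$log,
                 n_total = nrow(table), n_av_subcohort = nrow(av),
                 correlations = correlations,
                 group_comparisons = group_comparisons,
                 roc = roc_summary, roc_objects = rocs, combos = combos,
                 delong = delong),
            class = "cohort_stats_bundle")
}

#' @export
print.cohort_stats_bundle <- function(x, ...) {
  cat("<cohort_stats_bundle> ", x$n_total, " patients (",
      x$n_av_subcohort, " in the A/V subcohort)\n", sep = "")
  cat("ROC summary:\n")
  print(x$roc)
  invisible(x)
}

#' Write a stats bundle to tidy CSV + JSON summary
#'
#' Deterministic serialization: identical inputs produce byte-identical
#' files.
#'
#' @param bundle A `cohort_stats_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stats_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bundle$correlations, file.path(dir, "correlations.csv"))
  readr::write_csv(bundle$group_comparisons,
                   file.path(dir, "group_comparisons.csv"))
  readr::write_csv(bundle$roc, file.path(dir, "roc.csv"))
  if (nrow(bundle$delong) > 0)
    readr::write_csv(bundle$delong, file.path(dir, "delong.csv"))
  summary <- list(n_total = bundle$n_total,
                  n_av_subcohort = bundle$n_av_subcohort,
                  n_excluded = nrow(bundle$exclusions))
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA),
             file.path(dir, "summary.json"))
  invisible(dir)
}

#' Overlayed ROC curves of a stats bundle
#'
#' @param object A `cohort_stats_bundle`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_stats_bundle <- function(object, ...) {
  dfs <- dplyr::bind_rows(lapply(names(object$roc_objects), function(m)
    dplyr::mutate(object$roc_objects[[m]]$curve, marker = m)))
  ggplot2::ggplot(dfs, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity,
                                    colour = .data$marker)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot a vessel graph as a 2D projection
#'
#' Coronal (x-z) projection of the centerlines, coloured by label, line
#' width proportional to the local radius.
#'
#' @param graph A [vessel_graph()].
#' @return A ggplot.
#' @export
plot_vessel_graph <- function(graph) {
  df <- dplyr::bind_rows(lapply(graph$segments, function(s)
    tibble::tibble(x = s$points[, 1], z = s$points[, 3],
                   radius = s$radii, id = s$id, label = s$label)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   group = .data$id, colour = .data$label,
                                   linewidth = .data$radius)) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(artery = "#3366cc",
                                            vein = "#cc3333",
                                            unknown = "grey50")) +
    ggplot2::scale_linewidth(range = c(0.3, 2.5)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "z (mm)") +
    ggplot2::theme_minimal()
}
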