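#' Threshold-sweep experiment: integrate, detect, evaluate
#'
#' Orchestrates the full experiment.  The baseline ("Origin") network is
#' clustered and scored against every gold standard; then, for each confidence
#' threshold, literature records are integrated into a fresh copy of the
#' original network ([integrate_literature()]), complexes are detected
#' ([detect_complexes()] or a registered detector) and scored
#' ([evaluate_all()]).  Per-metric deltas versus the baseline are reported as
#' relative percent changes, `100 * (value - origin) / origin`, the
#' "percentage units" convention of threshold-sweep tables.
#'
#' @param net the original [ppi_network()] (hygiene-filtered).
#' @param records normalized literature PPI records (see [normalize_names()]).
#' @param golds a named list of gold-standard complex sets.
#' @param thresholds non-empty numeric vector of confidence cutoffs
#'   (default the canonical grid 0, -0.1, ..., -0.9).
#' @param params a [detection_params()] object.
#' @param omega_min inclusive overlap cutoff for the matched fraction.
#' @param rescale weight-adjustment strategy passed to
#'   [integrate_literature()].
#' @param detector name of a registered detector (default `"cluster_one"`).
#' @return an object of class `sweep_result`: a list with
#'   * `table`: one row per (gold standard x threshold) plus an `Origin` row
#'     per gold standard, with columns `gold`, `label`, `threshold`,
#'     `n_added`, `n_clusters`, `n_matched`, `sn`, `ppv`, `acc`, `mmr`,
#'     `delta_acc`, `delta_mmr`;
#'   * `avg_delta`: per-threshold deltas averaged across gold standards.
#' @export
run_sweep <- function(net, records, golds,
                      thresholds = seq(0, -0.9, by = -0.1),
                      params = detection_params(),
                      omega_min = 0.25,
                      rescale = c("minmax", "mean", "none"),
                      detector = "cluster_one") {
  rescale <- match.arg(rescale)
  stopifnot(inherits(net, "ppi_network"),
            length(thresholds) > 0,
            is.list(golds), length(golds) > 0,
            !is.null(names(golds)), all(nzchar(names(golds))))
  detect <- get_detector(detector)

  score_rows <- function(label, threshold, n_added, pred) {
    do.call(rbind, lapply(names(golds), function(g) {
      ev <- evaluate_all(pred, golds[[g]], omega_min)
      data.frame(gold = g, label = label, threshold = threshold,
                 n_added = n_added,
                 n_clusters = ev$n_clusters, n_matched = ev$n_matched,
                 sn = ev$sn, ppv = ev$ppv, acc = ev$acc, mmr = ev$mmr,
                 stringsAsFactors = FALSE)
    }))
  }

  origin_pred <- detect(net, params)
  tab <- score_rows("Origin", NA_real_, 0L, origin_pred)
  for (t in thresholds) {
    ig <- integrate_literature(net, records, t, rescale = rescale)
    pred <- detect(ig$network, params)
    tab <- rbind(tab, score_rows(format(t), t, ig$report$n_added, pred))
  }
  rownames(tab) <- NULL

  rel_delta <- function(x, origin) {
    ifelse(rep(origin > 0, length(x)), 100 * (x - origin) / origin, NA_real_)
  }
  tab$delta_acc <- NA_real_
  tab$delta_mmr <- NA_real_
  for (g in names(golds)) {
    sel <- tab$gold == g
    o_acc <- tab$acc[sel & tab$label == "Origin"]
    o_mmr <- tab$mmr[sel & tab$label == "Origin"]
    tab$delta_acc[sel] <- rel_delta(tab$acc[sel], o_acc)
    tab$delta_mmr[sel] <- rel_delta(tab$mmr[sel], o_mmr)
    tab$delta_acc[sel & tab$label == "Origin"] <- 0
    tab$delta_mmr[sel & tab$label == "Origin"] <- 0
  }

  avg <- stats::aggregate(tab[, c("delta_acc", "delta_mmr")],
                          by = list(label = tab$label), FUN = mean)
  ord <- match(avg$label, c("Origin", vapply(thresholds, format, "")))
  avg <- avg[order(ord), , drop = FALSE]
  rownames(avg) <- NULL

  structure(
    list(table = tab, avg_delta = avg, thresholds = thresholds,
         omega_min = omega_min, params = params, detector = detector),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d threshold(s) x %d gold standard(s)\n",
              length(x$thresholds), length(unique(x$table$gold))))
  print(x$table, digits = 4)
  invisible(x)
}

#' Persist a sweep result
#'
#' Writes `sweep.csv` (the long result table), `sweep.json` (table plus
#' cross-gold average deltas) and `summary.txt`, a plain-text note naming the
#' best threshold per metric and gold standard.
#'
#' @param result a `sweep_result` from [run_sweep()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths of the three files written.
#' @export
write_sweep_report <- function(result, outdir) {
  stopifnot(inherits(result, "sweep_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir,
                                call. = FALSE)
  csv <- file.path(outdir, "sweep.csv")
  utils::write.csv(result$table, csv, row.names = FALSE)

  json <- file.path(outdir, "sweep.json")
  jsonlite::write_json(
    list(table = result$table, avg_delta = result$avg_delta,
         omega_min = result$omega_min, detector = result$detector),
    json, dataframe = "rows", auto_unbox = TRUE, digits = NA)

  txt <- file.path(outdir, "summary.txt")
  lines <- character()
  for (g in unique(result$table$gold)) {
    sub <- result$table[result$table$gold == g & result$table$label != "Origin", ]
    for (metric in c("acc", "mmr")) {
      i <- which.max(sub[[metric]])
      lines <- c(lines, sprintf(
        "gold=%s best_%s_threshold=%s %s=%.6f (origin %.6f)",
        g, metric, sub$label[i], metric, sub[[metric]][i],
        result$table[[metric]][result$table$gold == g &
                                 result$table$label == "Origin"]))
    }
  }
  writeLines(lines, txt)
  invisible(c(csv = csv, json = json, summary = txt))
}
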