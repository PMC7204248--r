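#' Configuration for a full extrapolation evaluation run
#'
#' Encodes the whole workflow: data source (synthetic generator or CSV
#' files, one per cut), the model roster, screening mode, criteria,
#' anchor timepoints and output location.
#'
#' @param input Either `"synthetic"` or a named character vector of CSV
#'   paths, one per cut (names are cut labels, values paths; files need
#'   `time`/`event` columns).
#' @param generator A `generator_params` used when `input = "synthetic"`.
#' @param families Standard families to consider before screening.
#' @param spline_scales Spline transformation scales to fit.
#' @param spline_knots Interior knot counts to fit per scale.
#' @param criteria Information criteria to report.
#' @param strict_screening If `TRUE` (default), families rejected by the
#'   smoothed-hazard screen are dropped from fitting, mirroring standard
#'   practice; if `FALSE` they are fitted anyway and only flagged.
#' @param anchors Named numeric vector of anchor times per cut label;
#'   `NULL` uses each cut's minimum follow-up (for synthetic input, the
#'   lock offsets).
#' @param latest Label of the latest cut; `NULL` uses the last one.
#' @param seed Integer seed for the synthetic generator.
#' @param out_dir Output directory, or `NULL` for no file output.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = "synthetic",
                       generator = generator_params(),
                       families = standard_families(),
                       spline_scales = c("hazard", "odds", "normal"),
                       spline_knots = 1:3,
                       criteria = c("minus2LL", "AIC", "AICc", "HQC", "BIC"),
                       strict_screening = TRUE,
                       anchors = NULL,
                       latest = NULL,
                       seed = 1L,
                       out_dir = NULL) {
  if (length(families) + length(spline_scales) * length(spline_knots) == 0) {
    stop("model roster is empty", call. = FALSE)
  }
  criteria <- match.arg(criteria, ic_criteria, several.ok = TRUE)
  structure(list(input = input, generator = generator,
                 families = families, spline_scales = spline_scales,
                 spline_knots = spline_knots, criteria = criteria,
                 strict_screening = strict_screening, anchors = anchors,
                 latest = latest, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

load_cuts <- function(cfg) {
  if (identical(cfg$input, "synthetic")) {
    sim <- simulate_trial(cfg$generator, seed = cfg$seed)
    cuts <- sim$cuts
    if (is.null(cfg$anchors)) {
      cfg$anchors <- stats::setNames(cfg$generator$lock_offsets, names(cuts))
    }
  } else {
    paths <- cfg$input
    if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
      stop("csv input must be a named vector: names are cut labels",
           call. = FALSE)
    }
    cuts <- lapply(seq_along(paths), function(i) {
      read_dataset(paths[[i]], label = names(paths)[i])
    })
    names(cuts) <- names(paths)
    if (is.null(cfg$anchors)) {
      # default anchor: the cut's minimum follow-up (smallest censored
      # time if any, else max follow-up)
      cfg$anchors <- vapply(cuts, function(d) {
        cens <- d$records$time[d$records$event == 0]
        if (length(cens)) min(cens) else max(d$records$time)
      }, numeric(1))
    }
  }
  list(cuts = cuts, anchors = cfg$anchors)
}

fit_roster <- function(cfg, ds, rejected) {
  fams <- cfg$families
  if (cfg$strict_screening) fams <- setdiff(fams, rejected)
  fits <- list()
  for (f in fams) {
    fits[[f]] <- fit_mle(f, ds)
  }
  for (sc in cfg$spline_scales) {
    for (m in cfg$spline_knots) {
      nm <- sprintf("%d-knot %s", m, sc)
      fits[[nm]] <- fit_spline(sc, m, ds)
    }
  }
  fits
}

#' Run the full extrapolation evaluation
#'
#' For every data cut: estimate the KM curve, run the smoothed-hazard
#' screen, fit the (screened) model roster by maximum likelihood, and
#' score every fit on the requested information criteria. Across cuts:
#' compare every fit against the KM curve of its own cut and of the
#' latest cut at the anchor timepoints (survival point estimate and
#' RMST). Deterministic given `(config, seed)`.
#'
#' @param cfg A [run_config()].
#' @return An object of class `evaluation_bundle`: list with `cuts`
#'   (per-cut list: dataset, km, hazard curve, shape, fits, scores),
#'   `ic_table` (long data frame: cut, model, criterion, score, rank),
#'   `rankings` (per cut, per criterion), `accuracy` (data frame of
#'   accuracy reports), `config`, `log` (one line per fit). If
#'   `cfg$out_dir` is set, CSV/JSON outputs are written there.
#' @export
run_evaluation <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  loaded <- load_cuts(cfg)
  cuts <- loaded$cuts
  anchors <- loaded$anchors
  latest <- cfg$latest %||% names(cuts)[length(cuts)]
  if (!latest %in% names(cuts)) {
    stop(sprintf("latest-cut label '%s' not among cuts (%s)", latest,
                 paste(names(cuts), collapse = ", ")), call. = FALSE)
  }
  log_lines <- character(0)
  per_cut <- list()
  for (lab in names(cuts)) {
    ds <- cuts[[lab]]
    km <- km_estimate(ds)
    min_fu <- anchors[[lab]]
    hz <- smoothed_hazard(ds, max_time = min(min_fu, max(ds$records$time)))
    shape <- classify_hazard_shape(hz)
    t0 <- proc.time()[["elapsed"]]
    fits <- fit_roster(cfg, ds, shape$rejected_families)
    for (nm in names(fits)) {
      log_lines <- c(log_lines,
        sprintf("cut=%s model=%s loglik=%.4f converged=%s", lab, nm,
                fits[[nm]]$loglik, fits[[nm]]$converged))
    }
    log_lines <- c(log_lines,
      sprintf("cut=%s fitted %d models in %.2fs", lab, length(fits),
              proc.time()[["elapsed"]] - t0))
    scores <- lapply(fits, function(f)
      information_criteria(f$loglik, f$k, f$n))
    per_cut[[lab]] <- list(dataset = ds, km = km, hazard = hz,
                           shape = shape, fits = fits, scores = scores,
                           anchor = min_fu)
  }
  # long IC table with within-cut ranks per criterion
  ic_rows <- list()
  rankings <- list()
  for (lab in names(per_cut)) {
    pc <- per_cut[[lab]]
    rankings[[lab]] <- list()
    for (cr in cfg$criteria) {
      rk <- if (length(pc$scores) >= 2) rank_models(pc$scores, cr) else NULL
      rankings[[lab]][[cr]] <- rk
      for (nm in names(pc$scores)) {
        ic_rows[[length(ic_rows) + 1L]] <- data.frame(
          cut = lab, model = nm, criterion = cr,
          score = pc$scores[[nm]][[cr]],
          rank = if (is.null(rk)) 1L else rk$rank[match(nm, rk$label)],
          stringsAsFactors = FALSE)
      }
    }
  }
  ic_table <- do.call(rbind, ic_rows)
  # accuracy vs fitted and latest cut
  km_latest <- per_cut[[latest]]$km
  anchor_latest <- per_cut[[latest]]$anchor
  acc_rows <- list()
  for (lab in names(per_cut)) {
    pc <- per_cut[[lab]]
    for (nm in names(pc$fits)) {
      ar <- prediction_accuracy(pc$fits[[nm]], pc$km, km_latest,
                                anchor_fitted = pc$anchor,
                                anchor_latest = anchor_latest)
      acc_rows[[length(acc_rows) + 1L]] <- data.frame(
        cut = lab, model = nm,
        pe_diff_fitted = round(ar$pe_diff_fitted, 1),
        pe_diff_latest = round(ar$pe_diff_latest, 1),
        rmst_diff_fitted = round(ar$rmst_diff_fitted, 1),
        rmst_diff_latest = round(ar$rmst_diff_latest, 1),
        stringsAsFactors = FALSE)
    }
  }
  accuracy <- do.call(rbind, acc_rows)
  bundle <- structure(list(cuts = per_cut, ic_table = ic_table,
                           rankings = rankings, accuracy = accuracy,
                           latest = latest, config = cfg,
                           log = log_lines),
                      class = "evaluation_bundle")
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

#' @export
print.evaluation_bundle <- function(x, ...) {
  cat(sprintf("Evaluation bundle: %d cuts (%s), %d fitted models, latest = %s\n",
              length(x$cuts), paste(names(x$cuts), collapse = ", "),
              sum(vapply(x$cuts, function(pc) length(pc$fits), numeric(1))),
              x$latest))
  for (lab in names(x$cuts)) {
    pc <- x$cuts[[lab]]
    cat(sprintf("  %s: hazard %s (rejects %s)\n", lab, pc$shape$label,
                if (length(pc$shape$rejected_families))
                  paste(pc$shape$rejected_families, collapse = "/")
                else "none"))
  }
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$ic_table,
                   file.path(out_dir, "ic_scores.csv"), row.names = FALSE)
  utils::write.csv(bundle$accuracy,
                   file.path(out_dir, "prediction_accuracy.csv"),
                   row.names = FALSE)
  for (lab in names(bundle$cuts)) {
    pc <- bundle$cuts[[lab]]
    utils::write.csv(km_as_data_frame(pc$km),
                     file.path(out_dir, sprintf("km_%s.csv", lab)),
                     row.names = FALSE)
    utils::write.csv(hazard_as_data_frame(pc$hazard),
                     file.path(out_dir, sprintf("hazard_%s.csv", lab)),
                     row.names = FALSE)
    screen <- list(cut = lab, shape = pc$shape$label,
                   rejected_families = pc$shape$rejected_families,
                   reason = sprintf(
                     "smoothed hazard classified as %s within the cut's minimum follow-up",
                     pc$shape$label))
    jsonlite::write_json(screen,
                         file.path(out_dir, sprintf("screening_%s.json", lab)),
                         auto_unbox = TRUE, digits = NA)
    for (nm in names(pc$fits)) {
      fn <- gsub("[^A-Za-z0-9]+", "_", sprintf("fit_%s_%s", lab, nm))
      model_to_json(pc$fits[[nm]],
                    file.path(out_dir, paste0(fn, ".json")))
    }
  }
  writeLines(bundle$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Render a human-readable report from an evaluation bundle
#'
#' Writes a markdown summary naming the best model per criterion per
#' cut, a KM-overlay plot per cut (models extrapolated to a 5-year
#' horizon) and a smoothed-hazard plot per cut (truncated at the cut's
#' minimum follow-up).
#'
#' @param bundle An `evaluation_bundle`.
#' @param out_dir Output directory.
#' @param horizon Plot horizon in months (default 60 = 5 years).
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(bundle, out_dir, horizon = 60) {
  stopifnot(inherits(bundle, "evaluation_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lines <- c("# Survival extrapolation evaluation", "")
  for (lab in names(bundle$cuts)) {
    pc <- bundle$cuts[[lab]]
    lines <- c(lines, sprintf("## Cut %s", lab),
               sprintf("- hazard shape: %s; rejected families: %s",
                       pc$shape$label,
                       if (length(pc$shape$rejected_families))
                         paste(pc$shape$rejected_families, collapse = ", ")
                       else "none"))
    if (length(pc$fits) == 0) {
      lines <- c(lines, "- no models fitted after screening", "")
      next
    }
    for (cr in bundle$config$criteria) {
      rk <- bundle$rankings[[lab]][[cr]]
      if (!is.null(rk)) {
        lines <- c(lines, sprintf("- best by %s: %s (%.1f)", cr,
                                  rk$label[1], rk$score[1]))
      }
    }
    lines <- c(lines, "")
    plot_cut(pc, lab, out_dir, horizon)
  }
  writeLines(lines, file.path(out_dir, "summary.md"))
  invisible(out_dir)
}

plot_cut <- function(pc, lab, out_dir, horizon) {
  ok <- tryCatch({
    grDevices::pdf(file.path(out_dir, sprintf("curves_%s.pdf", lab)),
                   width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    km <- pc$km
    graphics::plot(stats::stepfun(km$event_times, c(1, km$survival)),
                   do.points = FALSE, xlim = c(0, horizon),
                   ylim = c(0, 1), xlab = "Months", ylab = "Survival",
                   main = sprintf("Cut %s: KM and fitted models", lab))
    tg <- seq(0.01, horizon, length.out = 200)
    cols <- grDevices::hcl.colors(max(length(pc$fits), 2), "Dark 2")
    i <- 0
    for (nm in names(pc$fits)) {
      i <- i + 1
      graphics::lines(tg, model_survival(pc$fits[[nm]], tg), col = cols[i])
    }
    graphics::legend("topright", legend = names(pc$fits), col = cols[seq_len(i)],
                     lty = 1, cex = 0.6, bty = "n")
    TRUE
  }, error = function(e) FALSE)
  tryCatch({
    grDevices::pdf(file.path(out_dir, sprintf("hazard_%s.pdf", lab)),
                   width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(pc$hazard$grid, pc$hazard$hazard, type = "l",
                   xlab = "Months", ylab = "Hazard (per month)",
                   main = sprintf("Cut %s: smoothed hazard", lab))
    TRUE
  }, error = function(e) FALSE)
  invisible(ok)
}
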