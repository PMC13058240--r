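#' Load a competition-assay dataset from a directory
#'
#' Reads the on-disk layout written by [write_sim_dataset()] (and used for
#' real exports): `monocultures/` and `cocultures/` with one delimited event
#' table plus one YAML metadata sidecar per sample, `plates/` and `od/`
#' likewise, and optionally `ground_truth.tsv`.
#'
#' @param dir Dataset directory.
#' @param column_map Column mapping for the event tables; the default matches
#'   the package's own writer.
#' @return A list shaped like a [simulate_experiment()] result (class
#'   `"sim_dataset"`; `truth` is `NULL` when absent).
#' @export
load_experiment_dir <- function(dir,
                                column_map = c(event_id = "event_id",
                                               intensity_dye = "intensity_dye",
                                               intensity_auto = "intensity_auto",
                                               area = "area",
                                               true_label = "true_label")) {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  read_group <- function(sub, reader) {
    d <- file.path(dir, sub)
    if (!dir.exists(d)) return(list())
    files <- sort(list.files(d, pattern = "\\.tsv$", full.names = TRUE))
    out <- list()
    for (f in files) {
      meta <- read_sample_meta(sub("\\.tsv$", ".meta.yaml", f))
      out[[meta$sample_id]] <- reader(f, meta)
    }
    out
  }
  truth_path <- file.path(dir, "ground_truth.tsv")
  structure(list(
    monocultures = read_group("monocultures", function(f, m)
      read_event_table(f, column_map, m)),
    cocultures = read_group("cocultures", function(f, m)
      read_event_table(f, column_map, m)),
    plates = read_group("plates", read_plate_counts),
    od = read_group("od", read_od_series),
    truth = if (file.exists(truth_path)) read_delim_table(truth_path) else NULL,
    config = NULL), class = "sim_dataset")
}

# Stable hash of the run configuration, for provenance stamping.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

#' Run the full competition-assay analysis pipeline
#'
#' Executes the analysis stages in order on a dataset: (1) two-stage gating
#' of every event table; (2) threshold derivation per stained competitor
#' from the gated monoculture controls (each stained monoculture against the
#' unstained monoculture of its competitor, pooled across time points in
#' `"general"` mode or fitted per time point); (3) classification of every
#' gated coculture with its stained competitor's threshold and frequency
#' estimation with Wilson intervals; (4) per-replicate frequency trends and
#' per-condition aggregation, plus carrying capacity from the OD series;
#' (5) reconciliation against plate-derived frequencies where plate series
#' exist. The report carries a hash of the effective configuration and the
#' package version.
#'
#' @param dataset A `"sim_dataset"` (from [simulate_experiment()] or
#'   [load_experiment_dir()]).
#' @param criterion Threshold criterion, see [select_threshold()].
#' @param mode `"general"` (one threshold per stained competitor, pooled
#'   over time) or `"per_timepoint"`.
#' @param polygon,area Gates, see [gate_cells()].
#' @param focal Competitor whose frequency is reported (default `"a"`).
#' @param out_dir Optional directory; when given, the frequency table,
#'   condition trends and threshold report are written as delimited text and
#'   JSON.
#' @return Object of class `"pipeline_report"`: list with `thresholds`,
#'   `frequencies` (data frame, one row per coculture sample),
#'   `replicate_trends`, `condition_trends`, `capacity`,
#'   `method_agreement` (or `NULL`), `gating` summary, `config_hash`,
#'   `version`.
#' @export
run_pipeline <- function(dataset,
                         criterion = c("closest_topleft",
                                       "balanced_accuracy"),
                         mode = c("general", "per_timepoint"),
                         polygon = default_cell_gate(),
                         area = default_area_gate(),
                         focal = "a",
                         out_dir = NULL) {
  criterion <- match.arg(criterion)
  mode <- match.arg(mode)
  if (!inherits(dataset, "sim_dataset"))
    stop("pipeline stage 'input': expected a sim_dataset", call. = FALSE)
  if (length(dataset$monocultures) == 0L)
    stop("pipeline stage 'threshold': no monoculture controls in dataset",
         call. = FALSE)
  if (length(dataset$cocultures) == 0L)
    stop("pipeline stage 'classify': no cocultures in dataset",
         call. = FALSE)

  # -- stage 1: gating ------------------------------------------------
  gate_one <- function(et) gate_cells(et, polygon, area)
  monos <- lapply(dataset$monocultures, gate_one)
  cocs <- lapply(dataset$cocultures, gate_one)
  gating <- data.frame(
    sample_id = c(names(monos), names(cocs)),
    input = vapply(c(monos, cocs), function(x)
      attr(x, "gating_summary")$retained[1L], numeric(1L)),
    retained = vapply(c(monos, cocs), function(x)
      attr(x, "gating_summary")$retained[3L], numeric(1L)))

  # -- stage 2: thresholds per stained competitor ---------------------
  mono_meta <- lapply(monos, `[[`, "meta")
  competitors <- sort(unique(vapply(mono_meta, `[[`, character(1L),
                                    "competitor_a")))
  if (length(competitors) != 2L)
    stop("pipeline stage 'threshold': expected monocultures of exactly ",
         "two competitors", call. = FALSE)
  controls <- function(comp, kind) {
    sel <- vapply(monos, function(et)
      et$meta$competitor_a == comp &&
        et$meta$culture_kind == paste0("monoculture_", kind), logical(1L))
    monos[sel]
  }
  intensities_by_time <- function(tables) {
    tms <- vapply(tables, function(et) et$meta$time_h, numeric(1L))
    out <- lapply(split(tables, tms), function(grp)
      unlist(lapply(grp, function(et) et$events$intensity_dye),
             use.names = FALSE))
    out
  }
  thresholds <- list()
  for (comp in competitors) {
    other <- setdiff(competitors, comp)
    st <- intensities_by_time(controls(comp, "stained"))
    un <- intensities_by_time(controls(other, "unstained"))
    tps <- intersect(names(st), names(un))
    if (length(tps) == 0L)
      stop("pipeline stage 'threshold': no matching time points for ",
           "competitor ", comp, call. = FALSE)
    samples <- lapply(tps, function(tp)
      list(stained = st[[tp]], unstained = un[[tp]]))
    names(samples) <- tps
    thresholds[[comp]] <- pooled_threshold(samples, mode = mode,
                                           criterion = criterion)
  }

  # -- stage 3: coculture classification ------------------------------
  freq_rows <- lapply(cocs, function(et) {
    m <- et$meta
    thr <- thresholds[[m$stained_competitor]]
    if (mode == "per_timepoint") {
      key <- as.character(m$time_h)
      if (!key %in% names(thr))
        stop("pipeline stage 'classify': no threshold for time ", key,
             call. = FALSE)
      thr <- thr[[key]]
    }
    if (nrow(et$events) == 0L)
      return(data.frame(sample_id = m$sample_id, time_h = m$time_h,
                        initial_ratio = m$initial_ratio,
                        stained_competitor = m$stained_competitor,
                        predator_present = m$predator_present,
                        replicate = m$replicate, n_gated = 0L,
                        n_stained = NA_integer_, freq_stained = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        freq_focal = NA_real_, threshold = thr$threshold))
    est <- estimate_frequency(classify_events(et, thr), meta = m)
    freq_focal <- if (m$stained_competitor == focal)
      est$freq_stained else 1 - est$freq_stained
    data.frame(sample_id = m$sample_id, time_h = m$time_h,
               initial_ratio = m$initial_ratio,
               stained_competitor = m$stained_competitor,
               predator_present = m$predator_present,
               replicate = m$replicate, n_gated = est$n_gated,
               n_stained = est$n_stained, freq_stained = est$freq_stained,
               ci_low = est$ci_low, ci_high = est$ci_high,
               freq_focal = freq_focal, threshold = thr$threshold)
  })
  frequencies <- do.call(rbind, c(freq_rows, make.row.names = FALSE))

  # -- stage 4: dynamics ----------------------------------------------
  frequencies$condition <- sprintf(
    "ratio=%g|stained=%s|predator=%s", frequencies$initial_ratio,
    frequencies$stained_competitor,
    ifelse(frequencies$predator_present, "yes", "no"))
  frequencies$culture <- paste0(frequencies$condition, "|rep=",
                                frequencies$replicate)
  tr <- lapply(split(frequencies, frequencies$culture), function(d) {
    d <- d[!is.na(d$freq_focal), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    est <- fit_frequency_trend(data.frame(time_h = d$time_h,
                                          freq = d$freq_focal))
    data.frame(culture = d$culture[1L], condition = d$condition[1L],
               replicate = d$replicate[1L], slope = est$slope,
               s_logit = est$s_logit, n_points = est$n_points)
  })
  replicate_trends <- do.call(rbind, c(tr[!vapply(tr, is.null, logical(1L))],
                                       make.row.names = FALSE))
  condition_trends <- aggregate_trends(replicate_trends$slope,
                                       replicate_trends$condition)

  capacity <- NULL
  if (length(dataset$od) > 0L) capacity <- carrying_capacity(dataset$od)

  # -- stage 5: plate reconciliation ----------------------------------
  method_agreement <- NULL
  if (length(dataset$plates) > 0L) {
    plate_rows <- lapply(dataset$plates, function(ps) {
      est <- plate_frequency(ps, focal)
      data.frame(sample_id = ps$meta$sample_id,
                 freq_plate = est$freq_stained, flagged = est$flagged)
    })
    plate_df <- do.call(rbind, c(plate_rows, make.row.names = FALSE))
    merged <- merge(frequencies[, c("sample_id", "freq_focal")], plate_df,
                    by = "sample_id")
    merged <- merged[!merged$flagged & !is.na(merged$freq_focal), ]
    if (nrow(merged) >= 3L &&
        stats::sd(merged$freq_focal) > 0 && stats::sd(merged$freq_plate) > 0) {
      method_agreement <- c(
        correlate_methods(merged$freq_focal, merged$freq_plate),
        list(n_excluded = sum(plate_df$flagged)))
    }
  }

  report <- structure(
    list(thresholds = thresholds, frequencies = frequencies,
         replicate_trends = replicate_trends,
         condition_trends = condition_trends, capacity = capacity,
         method_agreement = method_agreement, gating = gating,
         config_hash = config_hash(list(criterion = criterion, mode = mode,
                                        polygon = polygon$vertices,
                                        area = c(area$low, area$high),
                                        focal = focal)),
         version = as.character(utils::packageVersion("dyecomp"))),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> dyecomp ", x$version, " (config ",
      substr(x$config_hash, 1, 8), ")\n", sep = "")
  for (comp in names(x$thresholds)) {
    thr <- x$thresholds[[comp]]
    if (inherits(thr, "stain_threshold"))
      cat(sprintf("  threshold [%s stained]: %.6g (accuracy %.4f)\n",
                  comp, thr$threshold, thr$report$accuracy))
    else
      cat(sprintf("  thresholds [%s stained]: %d per-time-point fits\n",
                  comp, length(thr)))
  }
  cat("  frequencies: ", nrow(x$frequencies), " coculture samples\n",
      sep = "")
  cat("  condition trends: ", nrow(x$condition_trends), " conditions\n",
      sep = "")
  if (!is.null(x$method_agreement))
    cat(sprintf("  plate agreement: r = %.3f (n = %d)\n",
                x$method_agreement$r, x$method_agreement$n))
  invisible(x)
}

#' @rdname run_pipeline
#' @param report A `"pipeline_report"`.
#' @export
write_pipeline_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- c(sprintf("# dyecomp %s", report$version),
             sprintf("# config %s", report$config_hash))
  write_stamped <- function(df, file) {
    path <- file.path(out_dir, file)
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    path
  }
  write_stamped(report$frequencies, "frequencies.tsv")
  write_stamped(report$condition_trends, "condition_trends.tsv")
  if (!is.null(report$capacity))
    write_stamped(report$capacity$per_condition, "carrying_capacity.tsv")
  thr <- lapply(report$thresholds, function(t) {
    if (inherits(t, "stain_threshold"))
      list(threshold = t$threshold, criterion = t$criterion,
           tpr = t$report$tpr, tnr = t$report$tnr,
           accuracy = t$report$accuracy, average = t$report$average)
    else
      lapply(t, function(tt)
        list(threshold = tt$threshold, accuracy = tt$report$accuracy))
  })
  jsonlite::write_json(
    list(version = report$version, config_hash = report$config_hash,
         thresholds = thr,
         method_agreement = report$method_agreement),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

#' Run the pipeline from a plain-text run configuration
#'
#' Validates and executes a YAML run configuration with fields `input_dir`
#' (a [load_experiment_dir()] layout), and optionally `criterion`, `mode`,
#' `focal`, `out_dir`, `gate` (list with `vertices`, an Nx2 matrix of
#' polygon coordinates) and `area_gate` (list with `low`, `high`). All
#' referenced paths are checked before any computation starts.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return A `"pipeline_report"`, see [run_pipeline()].
#' @export
run_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$input_dir))
    stop("run config must name an 'input_dir'", call. = FALSE)
  if (!dir.exists(config$input_dir))
    stop("input_dir not found: ", config$input_dir, call. = FALSE)
  polygon <- if (!is.null(config$gate))
    polygon_gate(do.call(rbind, config$gate$vertices),
                 name = if (is.null(config$gate$name)) "config"
                 else config$gate$name)
  else default_cell_gate()
  area <- if (!is.null(config$area_gate))
    range_gate(config$area_gate$low, config$area_gate$high)
  else default_area_gate()
  dataset <- load_experiment_dir(config$input_dir)
  run_pipeline(dataset,
               criterion = if (is.null(config$criterion))
                 "closest_topleft" else config$criterion,
               mode = if (is.null(config$mode)) "general" else config$mode,
               polygon = polygon, area = area,
               focal = if (is.null(config$focal)) "a" else config$focal,
               out_dir = config$out_dir)
}
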