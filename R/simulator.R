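#' Simulation configuration
#'
#' Parameters of the synthetic competition-assay generator. The generative
#' model mirrors the assay's assumptions: per-cell dye intensity of a
#' stained cell is log-normal at staining and halves with every division
#' (`2^-(g + eps)` with per-cell jitter `eps` absorbing asynchronous
#' division), an independent log-normal autofluorescence draw adds on the
#' linear scale; unstained cells show autofluorescence only. Coculture
#' frequencies follow discrete selection with constant relative fitness, OD
#' follows logistic growth with measurement noise, and plate counts are
#' Poisson at each dilution with the focal competitor binomially thinned at
#' the true frequency.
#'
#' @param seed Integer seed; every output of [simulate_experiment()] is
#'   deterministic given the seed.
#' @param n_events_per_sample Cells acquired per sample (default 2000).
#' @param time_points_h Sampling times in hours (default 0, 2, ..., 10).
#' @param generations_per_interval Named numeric, generations elapsed per
#'   sampling interval for competitors `a` and `b` (default 1 each, giving
#'   five generations over the 10-h assay).
#' @param stain_log_mean,stain_log_sd Natural-log mean and sd of the initial
#'   dye intensity of stained cells (arbitrary units).
#' @param dilution_noise_sd Per-cell sd of the generation jitter `eps`
#'   (generations), modelling asynchronous division.
#' @param autofluor_log_mean,autofluor_log_sd Natural-log parameters of the
#'   autofluorescence intensity.
#' @param autofluor_offset Named numeric additive shift of the
#'   autofluorescence log-mean per competitor (models inter-competitor
#'   autofluorescence differences; default 0 for both).
#' @param relative_fitness_w Per-generation relative fitness of competitor
#'   `a` versus `b` (default 0.8: the focal competitor declines).
#' @param initial_ratios Initial volume fractions of competitor `a` in the
#'   cocultures (default 0.1, 0.5, 0.9).
#' @param predator_mortality Named numeric per-interval survival multipliers
#'   under predation for competitors `a` and `b` (default 0.9 and 0.7: the
#'   predator grazes `b` harder, partially offsetting `a`'s fitness
#'   deficit).
#' @param predator_levels Logical vector of predator treatments simulated
#'   (default without and with).
#' @param n_replicates Replicates per condition (default 3).
#' @param od_params List `od0`, `r`, `K` of the logistic growth curve
#'   (default 0.02, 1.2 per hour, 0.45).
#' @param od_noise_sd OD measurement noise sd (default 0.005).
#' @param plate_dilution_exponents Log10 dilution factors of the plating
#'   series (default 3.79, 4.50, 5.19, 5.89, 6.59, 7.29).
#' @param plated_volume_equivalent Expected colonies on an undiluted plate
#'   at carrying capacity (default 6e6); expected plate totals scale with
#'   the culture's current OD.
#' @return Object of class `"sim_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_events_per_sample = 2000L,
                              time_points_h = seq(0, 10, by = 2),
                              generations_per_interval = c(a = 1, b = 1),
                              stain_log_mean = log(9000),
                              stain_log_sd = 1.6,
                              dilution_noise_sd = 0.3,
                              autofluor_log_mean = log(3),
                              autofluor_log_sd = 0.8,
                              autofluor_offset = c(a = 0, b = 0),
                              relative_fitness_w = 0.8,
                              initial_ratios = c(0.1, 0.5, 0.9),
                              predator_mortality = c(a = 0.9, b = 0.7),
                              predator_levels = c(FALSE, TRUE),
                              n_replicates = 3L,
                              od_params = list(od0 = 0.02, r = 1.2, K = 0.45),
                              od_noise_sd = 0.005,
                              plate_dilution_exponents =
                                c(3.79, 4.50, 5.19, 5.89, 6.59, 7.29),
                              plated_volume_equivalent = 6e6) {
  cfg <- list(seed = as.integer(seed),
              n_events_per_sample = as.integer(n_events_per_sample),
              time_points_h = as.numeric(time_points_h),
              generations_per_interval = generations_per_interval,
              stain_log_mean = stain_log_mean, stain_log_sd = stain_log_sd,
              dilution_noise_sd = dilution_noise_sd,
              autofluor_log_mean = autofluor_log_mean,
              autofluor_log_sd = autofluor_log_sd,
              autofluor_offset = autofluor_offset,
              relative_fitness_w = relative_fitness_w,
              initial_ratios = as.numeric(initial_ratios),
              predator_mortality = predator_mortality,
              predator_levels = predator_levels,
              n_replicates = as.integer(n_replicates),
              od_params = od_params, od_noise_sd = od_noise_sd,
              plate_dilution_exponents = as.numeric(plate_dilution_exponents),
              plated_volume_equivalent = plated_volume_equivalent)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_events_per_sample >= 1L,
              length(time_points_h) >= 1L,
              all(diff(time_points_h) > 0),
              all(c("a", "b") %in% names(generations_per_interval)),
              all(generations_per_interval >= 0),
              stain_log_sd >= 0, dilution_noise_sd >= 0,
              autofluor_log_sd >= 0,
              all(c("a", "b") %in% names(autofluor_offset)),
              relative_fitness_w > 0,
              all(initial_ratios > 0 & initial_ratios < 1),
              all(c("a", "b") %in% names(predator_mortality)),
              all(predator_mortality > 0 & predator_mortality <= 1),
              n_replicates >= 1L,
              all(c("od0", "r", "K") %in% names(od_params)),
              od_noise_sd >= 0,
              length(plate_dilution_exponents) >= 1L,
              plated_volume_equivalent > 0)
  })
  invisible(cfg)
}

#' @rdname simulation_config
#' @param ... Overrides passed to [simulation_config()].
#' @details `paperlike_config()` is the committed preset reproducing the
#'   study design at desk scale: 2000 events per sample, six 2-hourly time
#'   points over 10 h, ratios 0.1/0.5/0.9, both stained assignments, two
#'   predator levels, three replicates, and intensity parameters chosen so
#'   that the stained and unstained distributions overlap slightly at the
#'   first time point (the regime where the threshold choice matters).
#' @export
paperlike_config <- function(seed = 1L, ...) {
  simulation_config(seed = seed, ...)
}

#' @export
print.sim_config <- function(x, ...) {
  n_cc <- length(x$initial_ratios) * 2L * length(x$predator_levels) *
    x$n_replicates * length(x$time_points_h)
  cat("<sim_config> seed ", x$seed, ": ", x$n_events_per_sample,
      " events/sample, ", length(x$time_points_h), " time points, ",
      n_cc, " coculture samples\n", sep = "")
  invisible(x)
}

#' Simulate single-cell dye intensities
#'
#' Draws per-cell dye-channel intensities for a stained or unstained
#' population after a given number of elapsed generations. Stained:
#' `exp(N(stain_log_mean, stain_log_sd)) * 2^-(g + eps)` plus an independent
#' autofluorescence draw (detector counts are additive); unstained:
#' autofluorescence only. Uses the current RNG state.
#'
#' @param kind `"stained"` or `"unstained"`.
#' @param generations_elapsed Generations since staining (`g >= 0`).
#' @param n Number of cells.
#' @param config A [simulation_config()].
#' @param competitor `"a"` or `"b"` (selects the autofluorescence offset).
#' @return Numeric vector of `n` intensities.
#' @export
simulate_intensities <- function(kind = c("stained", "unstained"),
                                 generations_elapsed = 0, n, config,
                                 competitor = "a") {
  kind <- match.arg(kind)
  stopifnot(n >= 1L, generations_elapsed >= 0,
            inherits(config, "sim_config"), competitor %in% c("a", "b"))
  auto <- exp(stats::rnorm(
    n, config$autofluor_log_mean + config$autofluor_offset[[competitor]],
    config$autofluor_log_sd))
  if (kind == "unstained") return(auto)
  eps <- stats::rnorm(n, 0, config$dilution_noise_sd)
  dye <- exp(stats::rnorm(n, config$stain_log_mean, config$stain_log_sd)) *
    2^(-(generations_elapsed + eps))
  dye + auto
}

#' Discrete-selection frequency propagation
#'
#' Frequency of competitor `a` after `g` generations of selection at
#' constant relative fitness `w`, starting from `f0`:
#' `f_g = w^g f0 / (w^g f0 + (1 - f0))`. Optional per-interval survival
#' multipliers model differential predation mortality. On the logit scale
#' the recursion is linear: `logit(f_g) - logit(f0) = g ln(w) +
#' intervals * ln(survival_a / survival_b)`.
#'
#' @param f0 Initial frequency in (0, 1).
#' @param w Relative fitness per generation (`> 0`).
#' @param generations Generations elapsed.
#' @param survival_a,survival_b Per-interval survival multipliers.
#' @param intervals Number of elapsed sampling intervals over which the
#'   survival multipliers apply (default 0: no mortality term).
#' @return Frequency in (0, 1); vectorised over `generations`.
#' @export
propagate_frequency <- function(f0, w, generations, survival_a = 1,
                                survival_b = 1, intervals = 0) {
  stopifnot(all(f0 > 0 & f0 < 1), w > 0, all(generations >= 0),
            survival_a > 0, survival_b > 0)
  log_odds <- stats::qlogis(f0) + generations * log(w) +
    intervals * log(survival_a / survival_b)
  stats::plogis(log_odds)
}

logistic_od <- function(t, od0, r, K) {
  K / (1 + (K - od0) / od0 * exp(-r * t))
}

#' Simulate a complete competition experiment
#'
#' Generates the full synthetic dataset for one experiment: stained and
#' unstained monoculture event-table series for both competitors (known
#' labels), coculture event tables for every ratio x stained-assignment x
#' predator level x replicate x time point (labels recorded as ground
#' truth), a dilution-plating series and an OD series per coculture, and a
#' ground-truth table. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return Object of class `"sim_dataset"`: list with `monocultures` and
#'   `cocultures` (lists of [event_table()]), `plates` (list of
#'   [plate_series()]), `od` (list of [od_series()]), `truth` (data frame
#'   with the true and sampled frequency of competitor `a` per coculture
#'   sample), and `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed, kind = "Mersenne-Twister")
  n <- config$n_events_per_sample
  tps <- config$time_points_h
  gpi <- config$generations_per_interval
  comps <- c("a", "b")

  monocultures <- list()
  for (comp in comps) {
    for (kind in c("stained", "unstained")) {
      for (k in seq_along(tps)) {
        g <- (k - 1L) * gpi[[comp]]
        id <- sprintf("mono_%s_%s_t%g", comp, kind, tps[k])
        meta <- sample_meta(id,
                            culture_kind = paste0("monoculture_", kind),
                            competitor_a = comp,
                            stained_competitor =
                              if (kind == "stained") comp else NA_character_,
                            time_h = tps[k])
        intens <- simulate_intensities(kind, g, n, config, comp)
        # channel-2 autofluorescence kept inside the default polygon gate
        monocultures[[id]] <- event_table(
          data.frame(intensity_dye = intens,
                     intensity_auto = exp(stats::rnorm(n, log(200), 0.4)),
                     area = stats::runif(n, 5, 60),
                     true_label = kind), meta)
      }
    }
  }

  cocultures <- list()
  plates <- list()
  od <- list()
  truth <- list()
  w <- config$relative_fitness_w
  for (ratio in config$initial_ratios) {
    for (stained_comp in comps) {
      for (pred in config$predator_levels) {
        for (repl in seq_len(config$n_replicates)) {
          culture_id <- sprintf("cc_r%g_s%s_p%d_rep%d", ratio,
                                stained_comp, as.integer(pred), repl)
          od_t <- logistic_od(tps, config$od_params$od0,
                              config$od_params$r, config$od_params$K) +
            stats::rnorm(length(tps), 0, config$od_noise_sd)
          od_t <- pmax(od_t, 0)
          od_meta <- sample_meta(culture_id, "coculture", "a", "b",
                                 stained_competitor = stained_comp,
                                 initial_ratio = ratio,
                                 predator_present = pred, replicate = repl,
                                 time_h = 0)
          od[[culture_id]] <- od_series(
            data.frame(time_h = tps, od600 = od_t), od_meta)
          for (k in seq_along(tps)) {
            g_a <- (k - 1L) * gpi[["a"]]
            intervals <- k - 1L
            f_true <- propagate_frequency(
              ratio, w, g_a,
              survival_a = if (pred) config$predator_mortality[["a"]] else 1,
              survival_b = if (pred) config$predator_mortality[["b"]] else 1,
              intervals = if (pred) intervals else 0)
            id <- sprintf("%s_t%g", culture_id, tps[k])
            meta <- sample_meta(id, "coculture", "a", "b",
                                stained_competitor = stained_comp,
                                initial_ratio = ratio,
                                predator_present = pred, replicate = repl,
                                time_h = tps[k])
            n_a <- stats::rbinom(1L, n, f_true)
            comp_of <- c(rep("a", n_a), rep("b", n - n_a))
            intens <- numeric(n)
            labels <- character(n)
            for (comp in comps) {
              idx <- which(comp_of == comp)
              if (length(idx) == 0L) next
              kind <- if (comp == stained_comp) "stained" else "unstained"
              g_c <- (k - 1L) * gpi[[comp]]
              intens[idx] <- simulate_intensities(kind, g_c, length(idx),
                                                  config, comp)
              labels[idx] <- kind
            }
            ord <- sample.int(n)
            cocultures[[id]] <- event_table(
              data.frame(intensity_dye = intens[ord],
                         intensity_auto = exp(stats::rnorm(n, log(200), 0.4)),
                         area = stats::runif(n, 5, 60),
                         true_label = labels[ord]), meta)
            lambda0 <- config$plated_volume_equivalent *
              logistic_od(tps[k], config$od_params$od0, config$od_params$r,
                          config$od_params$K) / config$od_params$K
            totals <- stats::rpois(
              length(config$plate_dilution_exponents),
              lambda0 * 10^(-config$plate_dilution_exponents))
            count_a <- stats::rbinom(length(totals), totals, f_true)
            plates[[id]] <- plate_series(
              data.frame(dilution_exponent = config$plate_dilution_exponents,
                         a = count_a, b = totals - count_a), meta)
            truth[[id]] <- data.frame(
              sample_id = id, time_h = tps[k], initial_ratio = ratio,
              stained_competitor = stained_comp, predator_present = pred,
              replicate = repl, generations_a = g_a,
              generations_b = (k - 1L) * gpi[["b"]],
              freq_a_true = f_true, freq_a_sampled = n_a / n,
              freq_stained_sampled =
                if (stained_comp == "a") n_a / n else 1 - n_a / n)
          }
        }
      }
    }
  }
  structure(list(monocultures = monocultures, cocultures = cocultures,
                 plates = plates, od = od,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", length(x$monocultures), " monoculture and ",
      length(x$cocultures), " coculture event tables, ",
      length(x$plates), " plate series, ", length(x$od), " OD series\n",
      sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits every event table, plate series and OD series in the package's
#' delimited-text formats (with YAML metadata sidecars) plus the
#' ground-truth table, under `dir`.
#'
#' @param dataset A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("monocultures", "cocultures")) {
    d <- file.path(dir, sub)
    dir.create(d, showWarnings = FALSE)
    for (et in dataset[[sub]]) {
      base <- file.path(d, et$meta$sample_id)
      write_event_table(et, paste0(base, ".tsv"))
      write_sample_meta(et$meta, paste0(base, ".meta.yaml"))
    }
  }
  d <- file.path(dir, "plates")
  dir.create(d, showWarnings = FALSE)
  for (ps in dataset$plates) {
    base <- file.path(d, ps$meta$sample_id)
    write_plate_counts(ps, paste0(base, ".tsv"))
    write_sample_meta(ps$meta, paste0(base, ".meta.yaml"))
  }
  d <- file.path(dir, "od")
  dir.create(d, showWarnings = FALSE)
  for (os in dataset$od) {
    base <- file.path(d, os$meta$sample_id)
    write_od_series(os, paste0(base, ".tsv"))
    write_sample_meta(os$meta, paste0(base, ".meta.yaml"))
  }
  utils::write.table(dataset$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
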