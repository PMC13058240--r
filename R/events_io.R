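#' Sample metadata for a culture
#'
#' Constructs the metadata record attached to every event table, OD series
#' and plate series: which culture a file came from (stained or unstained
#' monoculture, or coculture), the two competitors, which of them carries the
#' transient dye, the initial volume fraction of the focal competitor, whether
#' a ciliate predator was added, the replicate number and the sampling time.
#'
#' @param sample_id Character scalar identifying the sample.
#' @param culture_kind One of `"monoculture_stained"`, `"monoculture_unstained"`,
#'   `"coculture"`.
#' @param competitor_a,competitor_b Labels of the two competitors.
#'   `competitor_b` is empty (`""`) for monocultures.
#' @param stained_competitor Label of the stained competitor, or `NA` if no
#'   competitor is stained. Must equal `competitor_a` or `competitor_b`.
#' @param initial_ratio Initial volume fraction of `competitor_a` in a
#'   coculture (in \[0, 1\]); `NA` for monocultures.
#' @param predator_present Logical; was the predator added to the well?
#' @param replicate Positive integer replicate index.
#' @param time_h Sampling time in hours (non-negative).
#' @return An object of class `"sample_meta"` (a named list).
#' @examples
#' sample_meta("cc_r1_t0", "coculture", "I6", "I7",
#'             stained_competitor = "I6", initial_ratio = 0.5,
#'             predator_present = FALSE, replicate = 1, time_h = 0)
#' @export
sample_meta <- function(sample_id,
                        culture_kind = c("coculture", "monoculture_stained",
                                         "monoculture_unstained"),
                        competitor_a, competitor_b = "",
                        stained_competitor = NA_character_,
                        initial_ratio = NA_real_,
                        predator_present = FALSE,
                        replicate = 1L,
                        time_h = 0) {
  culture_kind <- match.arg(culture_kind)
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            is.character(competitor_a), length(competitor_a) == 1L,
            is.character(competitor_b), length(competitor_b) == 1L,
            length(time_h) == 1L, is.finite(time_h), time_h >= 0,
            length(replicate) == 1L, replicate >= 1)
  if (!is.na(stained_competitor) &&
      !stained_competitor %in% c(competitor_a, competitor_b)) {
    stop("'stained_competitor' must equal 'competitor_a' or 'competitor_b'",
         call. = FALSE)
  }
  if (culture_kind == "coculture") {
    if (!is.na(initial_ratio) &&
        (initial_ratio < 0 || initial_ratio > 1)) {
      stop("'initial_ratio' must lie in [0, 1]", call. = FALSE)
    }
  } else if (!is.na(initial_ratio)) {
    stop("'initial_ratio' is undefined for monocultures", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, culture_kind = culture_kind,
         competitor_a = competitor_a, competitor_b = competitor_b,
         stained_competitor = as.character(stained_competitor),
         initial_ratio = as.numeric(initial_ratio),
         predator_present = isTRUE(predator_present),
         replicate = as.integer(replicate), time_h = as.numeric(time_h)),
    class = "sample_meta")
}

#' @export
print.sample_meta <- function(x, ...) {
  cat("<sample_meta> ", x$sample_id, ": ", x$culture_kind, sep = "")
  if (nzchar(x$competitor_b)) {
    cat(" ", x$competitor_a, " vs ", x$competitor_b, sep = "")
  } else {
    cat(" ", x$competitor_a, sep = "")
  }
  if (!is.na(x$stained_competitor))
    cat(", stained:", x$stained_competitor)
  if (!is.na(x$initial_ratio))
    cat(sprintf(", ratio %.2f", x$initial_ratio))
  cat(sprintf(", predator %s, rep %d, t = %g h\n",
              if (x$predator_present) "+" else "-", x$replicate, x$time_h))
  invisible(x)
}

#' Per-cell event table
#'
#' Container for single-cell imaging flow-cytometry events: the dye-channel
#' fluorescence intensity, the autofluorescence-channel intensity, the
#' brightfield area, and (for monocultures and simulated data) the true
#' stained/unstained label. Background-subtracted intensities may be negative
#' and are stored unchanged.
#'
#' @param events A data frame with numeric columns `intensity_dye` (required),
#'   `intensity_auto`, `area`, an optional integer `event_id` and an optional
#'   character `true_label` (`"stained"`, `"unstained"`, or `"unknown"`).
#' @param meta A [sample_meta()] record.
#' @return An object of class `"event_table"`: a list with elements `meta`
#'   and `events` (a data frame, row order preserved).
#' @export
event_table <- function(events, meta) {
  stopifnot(is.data.frame(events), inherits(meta, "sample_meta"))
  if (!"intensity_dye" %in% names(events))
    stop("events must contain an 'intensity_dye' column", call. = FALSE)
  if (!"event_id" %in% names(events))
    events$event_id <- seq_len(nrow(events)) - 1L
  if (!"true_label" %in% names(events))
    events$true_label <- rep("unknown", nrow(events))
  if (!all(events$true_label %in% c("stained", "unstained", "unknown")))
    stop("true_label must be 'stained', 'unstained' or 'unknown'",
         call. = FALSE)
  num_cols <- intersect(c("intensity_dye", "intensity_auto", "area"),
                        names(events))
  for (cl in num_cols) {
    v <- events[[cl]]
    if (!is.numeric(v))
      stop("column '", cl, "' must be numeric", call. = FALSE)
    if (anyNA(v) || any(!is.finite(v)))
      stop("column '", cl, "' contains non-finite values", call. = FALSE)
  }
  keep <- intersect(c("event_id", "intensity_dye", "intensity_auto",
                      "area", "true_label"), names(events))
  structure(list(meta = meta, events = events[, keep, drop = FALSE]),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> ", nrow(x$events), " events, sample ",
      x$meta$sample_id, "\n", sep = "")
  invisible(x)
}

# Delimiter auto-detection: comma or tab, decided from the header line.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com && n_tab > 0L) "\t" else ","
}

read_delim_table <- function(path) {
  sep <- detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read a per-cell event table from delimited text
#'
#' Reads an instrument feature-table export (comma- or tab-delimited with a
#' header, auto-detected) and maps its columns onto the event schema via
#' `column_map`. Row order is preserved; intensities are never clipped or
#' transformed, so negative background-subtracted values pass through intact.
#'
#' @param path Path to a delimited text file with a header line.
#' @param column_map Named character vector mapping schema roles to file
#'   column names. Role `intensity_dye` is mandatory; `intensity_auto`,
#'   `area`, `event_id` and `true_label` are optional. A typical map for an
#'   ImageStream feature export is
#'   `c(intensity_dye = "Intensity_MC_Ch11", intensity_auto = "Intensity_MC_Ch02", area = "Area_M09")`.
#' @param meta A [sample_meta()] record describing the sample.
#' @return An [event_table()]; `true_label` is `"unknown"` unless mapped.
#' @export
read_event_table <- function(path, column_map, meta) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(is.character(column_map), !is.null(names(column_map)))
  if (!"intensity_dye" %in% names(column_map))
    stop("column_map must provide a column for role 'intensity_dye'",
         call. = FALSE)
  raw <- read_delim_table(path)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0L) {
    role <- names(column_map)[match(missing_cols[1L], column_map)]
    stop("column '", missing_cols[1L], "' (role '", role,
         "') not found in ", path, call. = FALSE)
  }
  out <- list()
  for (role in c("event_id", "intensity_dye", "intensity_auto", "area")) {
    if (role %in% names(column_map)) {
      v <- raw[[column_map[[role]]]]
      if (!is.numeric(v)) {
        vn <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(vn) & !is.na(v))
        if (length(bad) > 0L)
          stop("non-numeric value in column '", column_map[[role]],
               "' at row ", bad[1L], call. = FALSE)
        v <- vn
      }
      out[[role]] <- v
    }
  }
  if ("true_label" %in% names(column_map))
    out$true_label <- as.character(raw[[column_map[["true_label"]]]])
  event_table(as.data.frame(out, stringsAsFactors = FALSE), meta)
}

#' Write an event table to delimited text
#'
#' @param x An [event_table()].
#' @param path Output path; tab-delimited with header, full precision.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(x, path) {
  stopifnot(inherits(x, "event_table"))
  df <- x$events
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Dilution-plating colony counts for one sample
#'
#' @param plates Data frame with a numeric `dilution_exponent` column (log10
#'   dilution factor) and one non-negative integer count column per
#'   morphotype. At most one row per dilution exponent.
#' @param meta A [sample_meta()] record.
#' @return Object of class `"plate_series"`.
#' @export
plate_series <- function(plates, meta) {
  stopifnot(is.data.frame(plates), inherits(meta, "sample_meta"))
  if (!"dilution_exponent" %in% names(plates))
    stop("plates must contain a 'dilution_exponent' column", call. = FALSE)
  if (anyDuplicated(plates$dilution_exponent))
    stop("duplicate dilution exponent in plate series", call. = FALSE)
  cnt <- setdiff(names(plates), "dilution_exponent")
  if (length(cnt) == 0L)
    stop("plate series has no morphotype count columns", call. = FALSE)
  for (cl in cnt) {
    v <- plates[[cl]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != round(v)))
      stop("counts for morphotype '", cl,
           "' must be non-negative integers", call. = FALSE)
  }
  structure(list(meta = meta, plates = plates, morphotypes = cnt),
            class = "plate_series")
}

#' Read dilution-plating counts from delimited text
#'
#' Expects a header with `dilution_exponent` followed by one column of colony
#' counts per morphotype. The default experimental series uses log10 dilution
#' exponents 3.79, 4.50, 5.19, 5.89, 6.59, 7.29.
#'
#' @param path Path to a comma- or tab-delimited file.
#' @param meta A [sample_meta()] record.
#' @return A [plate_series()].
#' @export
read_plate_counts <- function(path, meta) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  plate_series(read_delim_table(path), meta)
}

#' @rdname read_plate_counts
#' @param x A [plate_series()].
#' @export
write_plate_counts <- function(x, path) {
  stopifnot(inherits(x, "plate_series"))
  df <- x$plates
  df$dilution_exponent <- sprintf("%.17g", df$dilution_exponent)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Optical-density growth series
#'
#' @param points Data frame with numeric `time_h` (strictly increasing) and
#'   `od600` (non-negative) columns.
#' @param meta A [sample_meta()] record.
#' @return Object of class `"od_series"`.
#' @export
od_series <- function(points, meta) {
  stopifnot(is.data.frame(points), inherits(meta, "sample_meta"))
  if (!all(c("time_h", "od600") %in% names(points)))
    stop("OD series needs 'time_h' and 'od600' columns", call. = FALSE)
  if (any(diff(points$time_h) <= 0))
    stop("OD time points must be strictly increasing", call. = FALSE)
  if (any(points$od600 < 0))
    stop("od600 must be non-negative", call. = FALSE)
  structure(list(meta = meta, points = points[, c("time_h", "od600")]),
            class = "od_series")
}

#' Read / write an OD600 series
#' @param path Delimited text file with `time_h` and `od600` columns.
#' @param meta A [sample_meta()] record.
#' @return An [od_series()].
#' @export
read_od_series <- function(path, meta) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  od_series(read_delim_table(path), meta)
}

#' @rdname read_od_series
#' @param x An [od_series()].
#' @export
write_od_series <- function(x, path) {
  stopifnot(inherits(x, "od_series"))
  df <- x$points
  df[] <- lapply(df, function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata sidecar files
#'
#' Metadata travels in a plain-text sidecar (YAML key: value records, one
#' document per sample) rather than being parsed out of filenames.
#'
#' @param path Path to the sidecar file.
#' @return `read_sample_meta()` returns a [sample_meta()].
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- yaml::read_yaml(path)
  sample_meta(sample_id = rec$sample_id,
              culture_kind = rec$culture_kind,
              competitor_a = rec$competitor_a,
              competitor_b = if (is.null(rec$competitor_b)) "" else rec$competitor_b,
              stained_competitor = if (is.null(rec$stained_competitor))
                NA_character_ else rec$stained_competitor,
              initial_ratio = if (is.null(rec$initial_ratio))
                NA_real_ else rec$initial_ratio,
              predator_present = isTRUE(rec$predator_present),
              replicate = if (is.null(rec$replicate)) 1L else rec$replicate,
              time_h = if (is.null(rec$time_h)) 0 else rec$time_h)
}

#' @rdname read_sample_meta
#' @param meta A [sample_meta()] to serialise.
#' @export
write_sample_meta <- function(meta, path) {
  stopifnot(inherits(meta, "sample_meta"))
  rec <- unclass(meta)
  rec <- rec[!vapply(rec, function(v) length(v) == 1L && is.na(v), logical(1L))]
  yaml::write_yaml(rec, path)
  invisible(path)
}
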