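# Minimal list-mode FCS 3.0/3.1 reader. The canonical on-disk event format
# for this package is delimited text (instrument feature-table exports); this
# adapter exists so raw cytometer files can be mapped onto the same schema.
# Supports float (F), double (D) and fixed-width integer (I) data, both byte
# orders, and one dataset per file.

fcs_text_segment <- function(con, begin, end) {
  seek(con, begin)
  raw_txt <- readBin(con, "raw", n = end - begin + 1L)
  txt <- rawToChar(raw_txt)
  delim <- substr(txt, 1L, 1L)
  parts <- strsplit(substring(txt, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L)
    parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1L, length(parts), by = 2L)]))
  vals <- trimws(parts[seq(2L, length(parts), by = 2L)])
  stats::setNames(as.list(vals), keys)
}

#' Read a list-mode FCS 3.0/3.1 file
#'
#' Thin adapter mapping named FCS parameters onto the event schema. Only
#' list-mode data with float, double or fixed-width integer storage is
#' supported; gating and analysis segments are ignored.
#'
#' @param path Path to an FCS 3.0 or 3.1 file.
#' @param column_map Named character vector mapping schema roles
#'   (`intensity_dye` mandatory; `intensity_auto`, `area` optional) to FCS
#'   parameter short names (`$PnN`).
#' @param meta A [sample_meta()] record.
#' @return An [event_table()] with `true_label = "unknown"`.
#' @export
read_fcs <- function(path, column_map, meta) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(is.character(column_map), "intensity_dye" %in% names(column_map))
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", n = 58L))
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version: ", version, call. = FALSE)
  offs <- as.integer(trimws(substring(
    header, c(11, 19, 27, 35), c(18, 26, 34, 42))))
  kw <- fcs_text_segment(con, offs[1L], offs[2L])
  data_begin <- offs[3L]
  data_end <- offs[4L]
  if (is.na(data_begin) || data_begin == 0L) {
    data_begin <- as.integer(kw[["$BEGINDATA"]])
    data_end <- as.integer(kw[["$ENDDATA"]])
  }
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- kw[["$DATATYPE"]]
  byteord <- kw[["$BYTEORD"]]
  endian <- if (grepl("^1", byteord)) "little" else "big"
  if (!identical(kw[["$MODE"]], "L"))
    stop("only list-mode FCS data is supported", call. = FALSE)
  seek(con, data_begin)
  n_values <- n_par * n_tot
  mat <- switch(dtype,
    "F" = matrix(readBin(con, "numeric", n = n_values, size = 4L,
                         endian = endian),
                 ncol = n_par, byrow = TRUE),
    "D" = matrix(readBin(con, "numeric", n = n_values, size = 8L,
                         endian = endian),
                 ncol = n_par, byrow = TRUE),
    "I" = {
      bits <- as.integer(kw[["$P1B"]])
      if (!all(vapply(seq_len(n_par), function(i)
        as.integer(kw[[sprintf("$P%dB", i)]]) == bits, logical(1L))))
        stop("mixed integer widths are not supported", call. = FALSE)
      if (!bits %in% c(16L, 32L))
        stop("unsupported integer width: ", bits, call. = FALSE)
      matrix(readBin(con, "integer", n = n_values, size = bits / 8L,
                     endian = endian, signed = bits > 16L),
             ncol = n_par, byrow = TRUE)
    },
    stop("unsupported $DATATYPE: ", dtype, call. = FALSE))
  par_names <- vapply(seq_len(n_par), function(i) {
    v <- kw[[sprintf("$P%dN", i)]]
    if (is.null(v)) sprintf("P%d", i) else v
  }, character(1L))
  colnames(mat) <- par_names
  missing_par <- setdiff(unname(column_map), par_names)
  if (length(missing_par) > 0L)
    stop("FCS parameter '", missing_par[1L], "' not found in ", path,
         call. = FALSE)
  out <- list()
  for (role in intersect(c("intensity_dye", "intensity_auto", "area"),
                         names(column_map)))
    out[[role]] <- as.numeric(mat[, column_map[[role]]])
  event_table(as.data.frame(out), meta)
}
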