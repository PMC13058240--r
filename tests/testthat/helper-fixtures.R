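# Fixture builders; everything is generated in code at test time.

demo_meta <- function(id = "s1", kind = "coculture", ...) {
  if (kind == "coculture")
    sample_meta(id, kind, "A", "B", stained_competitor = "A",
                initial_ratio = 0.5, ...)
  else
    sample_meta(id, kind, "A", ...)
}

write_events_fixture <- function(df, sep = ",") {
  path <- tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# Minimal FCS 3.0 writer (float32 or uint16 list mode), used only to test
# the reader; real files come from instruments.
write_fcs_fixture <- function(mat, par_names, path = tempfile(fileext = ".fcs"),
                              datatype = "F") {
  n_par <- ncol(mat); n_tot <- nrow(mat)
  kw <- c("$MODE", "L", "$DATATYPE", datatype,
          "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(n_par), "$TOT", as.character(n_tot))
  for (i in seq_len(n_par)) {
    kw <- c(kw, sprintf("$P%dN", i), par_names[i],
            sprintf("$P%dB", i), if (datatype == "F") "32" else "16",
            sprintf("$P%dR", i), "262144",
            sprintf("$P%dE", i), "0,0")
  }
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  header_len <- 58L
  text_begin <- header_len
  text_end <- text_begin + nchar(text) - 1L
  data_begin <- text_end + 1L
  value_size <- if (datatype == "F") 4L else 2L
  data_end <- data_begin + n_par * n_tot * value_size - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end, data_begin, data_end, 0L, 0L)
  stopifnot(nchar(header) == 58L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  values <- as.vector(t(mat))
  if (datatype == "F")
    writeBin(values, con, size = 4L, endian = "little")
  else
    writeBin(as.integer(values), con, size = 2L, endian = "little")
  path
}
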