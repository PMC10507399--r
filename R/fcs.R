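# Minimal FCS 3.0/3.1 support: list-mode files with a single dataset,
# float (F), double (D) or integer (I) data, little- or big-endian.
# Covers the files this pipeline consumes (post-acquisition, pre-gated
# event tables); keyword handling is deliberately conservative.

#' Read an FCS file
#'
#' Parses the TEXT and DATA segments of an FCS 3.0/3.1 list-mode file and
#' returns the event matrix plus the keyword table. Supports `$DATATYPE`
#' F (32-bit float), D (64-bit double) and I (16/32-bit unsigned integer),
#' with `$BYTEORD` 1,2,3,4 or 4,3,2,1.
#'
#' @param path path to an FCS file.
#' @return list with `data` (event x channel numeric matrix, columns named by
#'   `$PnN`) and `keywords` (named character vector).
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop("FCS file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  header <- readChar(con, 58, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!grepl("^FCS3\\.[01]", version)) {
    stop(sprintf("%s: unsupported FCS version '%s'", path, version),
         call. = FALSE)
  }
  off <- function(a, b) suppressWarnings(as.numeric(trimws(substr(header, a, b))))
  text_start <- off(11, 18); text_end <- off(19, 26)
  data_start <- off(27, 34); data_end <- off(35, 42)

  seek(con, text_start)
  raw_text <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  delim <- substr(raw_text, 1, 1)
  parts <- strsplit(raw_text, delim, fixed = TRUE)[[1]]
  if (length(parts) && !nzchar(parts[1])) parts <- parts[-1]  # leading delim
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- setNames(parts[seq(2, length(parts), 2)], parts[seq(1, length(parts), 2)])

  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  byteord <- kw[["$BYTEORD"]]
  endian <- if (identical(byteord, "4,3,2,1")) "big" else "little"

  if (data_start == 0 || is.na(data_start)) data_start <- as.numeric(kw[["$BEGINDATA"]])
  if (data_end == 0 || is.na(data_end)) data_end <- as.numeric(kw[["$ENDDATA"]])

  ch <- vapply(seq_len(n_par), function(i) kw[[paste0("$P", i, "N")]], "")
  n_val <- n_par * n_tot
  seek(con, data_start)
  if (n_val == 0) {
    vals <- numeric(0)
  } else if (dtype == "F") {
    vals <- readBin(con, "numeric", n = n_val, size = 4, endian = endian)
  } else if (dtype == "D") {
    vals <- readBin(con, "numeric", n = n_val, size = 8, endian = endian)
  } else if (dtype == "I") {
    bits <- unique(vapply(seq_len(n_par),
                          function(i) as.integer(kw[[paste0("$P", i, "B")]]), 1L))
    if (length(bits) != 1 || !bits %in% c(16L, 32L)) {
      stop(path, ": integer data requires uniform $PnB of 16 or 32",
           call. = FALSE)
    }
    if (bits == 16L) {
      vals <- readBin(con, "integer", n = n_val, size = 2, signed = FALSE,
                      endian = endian)
    } else {
      vals <- readBin(con, "integer", n = n_val, size = 4, endian = endian)
      vals[vals < 0] <- vals[vals < 0] + 2^32  # reinterpret as unsigned
    }
  } else {
    stop(sprintf("%s: unsupported $DATATYPE '%s'", path, dtype), call. = FALSE)
  }
  mat <- matrix(as.numeric(vals), nrow = n_tot, ncol = n_par, byrow = TRUE,
                dimnames = list(NULL, ch))
  list(data = mat, keywords = kw)
}

#' Write an FCS 3.1 file
#'
#' Writes an event matrix as a single-dataset FCS 3.1 list-mode file with
#' 32-bit float data, little-endian byte order. Channel names are taken from
#' the matrix column names (`$PnN`); marker labels may be supplied for
#' `$PnS`.
#'
#' @param data event x channel numeric matrix with column names.
#' @param path output path.
#' @param marker_names optional character vector of human-readable labels,
#'   one per channel.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(data, path, marker_names = NULL) {
  data <- as.matrix(data)
  if (is.null(colnames(data))) stop("data must have channel column names",
                                    call. = FALSE)
  n_tot <- nrow(data); n_par <- ncol(data)
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0", "$PAR" = as.character(n_par),
          "$TOT" = as.character(n_tot))
  for (i in seq_len(n_par)) {
    rng <- max(1, ceiling(max(data[, i], 0, na.rm = TRUE)))
    kw[[paste0("$P", i, "B")]] <- "32"
    kw[[paste0("$P", i, "E")]] <- "0,0"
    kw[[paste0("$P", i, "N")]] <- colnames(data)[i]
    kw[[paste0("$P", i, "R")]] <- as.character(rng)
    if (!is.null(marker_names)) kw[[paste0("$P", i, "S")]] <- marker_names[i]
  }
  # fixed-width offsets so TEXT length is known before offsets are final
  build_text <- function(bd, ed) {
    kw[["$BEGINDATA"]] <- sprintf("%010d", bd)
    kw[["$ENDDATA"]] <- sprintf("%010d", ed)
    paste0("/", paste0(names(kw), "/", unname(kw), collapse = "/"), "/")
  }
  text0 <- build_text(0, 0)
  text_start <- 58
  text_end <- text_start + nchar(text0, type = "bytes") - 1
  data_start <- text_end + 1
  data_end <- data_start + 4 * n_par * n_tot - 1
  if (n_tot == 0) data_start <- data_end <- 0
  text <- build_text(data_start, data_end)

  hfield <- function(x) sprintf("%8d", x)
  header <- paste0("FCS3.1    ", hfield(text_start), hfield(text_end),
                   hfield(if (data_end <= 99999999) data_start else 0),
                   hfield(if (data_end <= 99999999) data_end else 0),
                   hfield(0), hfield(0))  # no ANALYSIS segment
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  if (n_tot > 0) {
    writeBin(as.numeric(t(data)), con, size = 4, endian = "little")
  }
  invisible(path)
}
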