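#' Read and write S21 scan containers
#'
#' Two container formats are supported. The text container is a plain file
#' with `# key=value` header lines holding the geometry, labels and a format
#' version, followed by a CSV body with one record per matrix cell:
#' `tx,rx,f,re,im` using 0-based indices. The binary container stores the
#' same information compactly: a magic string, a JSON metadata header and the
#' raw double vectors of the real and imaginary parts; it round-trips the
#' matrix bit-identically.
#'
#' @param path File path.
#' @param format `"text"` or `"binary"`.
#' @param scan An [s21_scan()] (for writing).
#' @return `read_s21_scan()` returns an [s21_scan()]; `write_s21_scan()`
#'   returns `path` invisibly.
#' @name s21_container
NULL

MW_FORMAT_VERSION <- 1L

#' @rdname s21_container
#' @export
write_s21_scan <- function(scan, path, format = c("text", "binary")) {
  stopifnot(inherits(scan, "s21_scan"))
  format <- match.arg(format)
  g <- scan$geometry
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("MWSCAN1\n"), con)
    meta <- jsonlite::toJSON(c(scan_meta_list(scan),
                               list(format_version = MW_FORMAT_VERSION)),
                             auto_unbox = TRUE, digits = NA)
    meta_raw <- charToRaw(as.character(meta))
    writeBin(length(meta_raw), con, size = 4L, endian = "little")
    writeBin(meta_raw, con)
    writeBin(as.vector(Re(scan$matrix)), con, size = 8L, endian = "little")
    writeBin(as.vector(Im(scan$matrix)), con, size = 8L, endian = "little")
    return(invisible(path))
  }
  hdr <- scan_meta_list(scan)
  hdr$format_version <- MW_FORMAT_VERSION
  hdr_lines <- vapply(names(hdr), function(k) {
    v <- hdr[[k]]
    paste0("# ", k, "=", paste(format(v, digits = 17, scientific = FALSE,
                                      trim = TRUE), collapse = ","))
  }, character(1))
  n_rx <- g$n_rx
  row0 <- 0:(nrow(scan$matrix) - 1)
  body <- data.table::data.table(
    tx = rep(row0 %/% n_rx, times = ncol(scan$matrix)),
    rx = rep(row0 %% n_rx, times = ncol(scan$matrix)),
    f = rep(0:(ncol(scan$matrix) - 1), each = nrow(scan$matrix)),
    re = as.vector(Re(scan$matrix)),
    im = as.vector(Im(scan$matrix))
  )
  writeLines(hdr_lines, path)
  data.table::fwrite(body, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

scan_meta_list <- function(scan) {
  g <- scan$geometry
  list(sample_id = scan$sample_id,
       density = scan$density_label,
       health = scan$health_label,
       n_tx = g$n_tx, n_rx = g$n_rx, rx_step_deg = g$rx_step_deg,
       tx_angles_deg = g$tx_angles_deg,
       f_start_hz = g$f_start_hz, f_step_hz = g$f_step_hz, n_freq = g$n_freq)
}

#' @rdname s21_container
#' @export
read_s21_scan <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "binary") return(read_s21_scan_binary(path))
  read_s21_scan_text(path)
}

read_s21_scan_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (magic != "MWSCAN1\n") stop("format error: not a binary scan container",
                                 call. = FALSE)
  n_meta <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n_meta)))
  g <- geometry_from_meta(meta)
  n <- g$n_tx * g$n_rx * g$n_freq
  re <- readBin(con, "double", n, size = 8L, endian = "little")
  im <- readBin(con, "double", n, size = 8L, endian = "little")
  if (length(re) != n || length(im) != n) {
    stop("format error: truncated binary payload", call. = FALSE)
  }
  m <- matrix(complex(real = re, imaginary = im),
              nrow = g$n_tx * g$n_rx, ncol = g$n_freq)
  s21_scan(m, g, meta$sample_id, meta$density, meta$health)
}

geometry_from_meta <- function(meta) {
  scan_geometry(n_tx = meta$n_tx, n_rx = meta$n_rx,
                rx_step_deg = meta$rx_step_deg,
                tx_angles_deg = as.numeric(meta$tx_angles_deg),
                f_start_hz = meta$f_start_hz, f_step_hz = meta$f_step_hz,
                n_freq = meta$n_freq)
}

read_s21_scan_text <- function(path) {
  head_lines <- readLines(path, n = 64L)
  hdr_idx <- grep("^#", head_lines)
  if (length(hdr_idx) == 0 || any(diff(hdr_idx) != 1) || hdr_idx[1] != 1) {
    stop("format error: missing or interleaved header", call. = FALSE)
  }
  kv <- sub("^#\\s*", "", head_lines[hdr_idx])
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(as.list(vals), keys)
  required <- c("sample_id", "density", "health", "n_tx", "n_rx",
                "rx_step_deg", "tx_angles_deg", "f_start_hz", "f_step_hz",
                "n_freq")
  missing <- setdiff(required, keys)
  if (length(missing)) {
    stop("format error: header missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  g <- scan_geometry(
    n_tx = as.integer(meta$n_tx), n_rx = as.integer(meta$n_rx),
    rx_step_deg = as.numeric(meta$rx_step_deg),
    tx_angles_deg = as.numeric(strsplit(meta$tx_angles_deg, ",")[[1]]),
    f_start_hz = as.numeric(meta$f_start_hz),
    f_step_hz = as.numeric(meta$f_step_hz),
    n_freq = as.integer(meta$n_freq)
  )
  body <- data.table::fread(path, skip = length(hdr_idx), header = TRUE)
  expected_cols <- c("tx", "rx", "f", "re", "im")
  if (!identical(names(body), expected_cols)) {
    stop("format error: body columns must be ", paste(expected_cols, collapse = ","),
         call. = FALSE)
  }
  n_rows <- g$n_tx * g$n_rx
  bad <- body$tx < 0 | body$tx >= g$n_tx | body$rx < 0 | body$rx >= g$n_rx |
    body$f < 0 | body$f >= g$n_freq
  if (any(bad)) {
    i <- which(bad)[1]
    stop("format error: cell index out of range at record ", i, " (tx=",
         body$tx[i], ", rx=", body$rx[i], ", f=", body$f[i], ")", call. = FALSE)
  }
  key <- (body$tx * g$n_rx + body$rx) * as.double(g$n_freq) + body$f
  dup <- anyDuplicated(key)
  if (dup) {
    stop("format error: duplicate cell at record ", dup, " (tx=", body$tx[dup],
         ", rx=", body$rx[dup], ", f=", body$f[dup], ")", call. = FALSE)
  }
  if (nrow(body) != n_rows * g$n_freq) {
    present <- rep(FALSE, n_rows * g$n_freq)
    present[key + 1] <- TRUE
    miss <- which(!present)[1] - 1
    stop("format error: missing cell (tx=", miss %/% (g$n_rx * g$n_freq),
         ", rx=", (miss %/% g$n_freq) %% g$n_rx, ", f=", miss %% g$n_freq, ")",
         call. = FALSE)
  }
  m <- matrix(complex(real = 0, imaginary = 0), nrow = n_rows, ncol = g$n_freq)
  m[cbind(body$tx * g$n_rx + body$rx + 1, body$f + 1)] <-
    complex(real = body$re, imaginary = body$im)
  s21_scan(m, g, meta$sample_id, meta$density, meta$health)
}

#' Read or write a sample label table
#'
#' The label table is a CSV with header `sample_id,density,health`; density
#' is one of `LD`, `HD`, `unknown` and health one of `healthy`,
#' `non-healthy`, `unknown`. Sample ids must be unique.
#'
#' @param path CSV file path.
#' @return A tibble with columns `sample_id`, `density`, `health`.
#' @export
read_label_table <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("sample_id", "density", "health")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("label table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[required]
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id: ", tab$sample_id[anyDuplicated(tab$sample_id)],
         call. = FALSE)
  }
  bad_d <- !tab$density %in% c("LD", "HD", "unknown")
  if (any(bad_d)) {
    stop("invalid density label: '", tab$density[which(bad_d)[1]], "'",
         call. = FALSE)
  }
  bad_h <- !tab$health %in% c("healthy", "non-healthy", "unknown")
  if (any(bad_h)) {
    stop("invalid health label: '", tab$health[which(bad_h)[1]], "'",
         call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' @rdname read_label_table
#' @param labels A data frame with columns `sample_id`, `density`, `health`.
#' @export
write_label_table <- function(labels, path) {
  stopifnot(all(c("sample_id", "density", "health") %in% names(labels)))
  readr::write_csv(labels[c("sample_id", "density", "health")], path,
                   progress = FALSE)
  invisible(path)
}
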