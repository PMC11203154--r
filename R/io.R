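# ---------------------------------------------------------------------------
# File formats: raster CSV with '#' metadata header, hypermatrix bundle
# directories with a JSON manifest and checksums. Comma-separated, '.'
# decimal, no quoting, UTF-8; floats written with 17 significant digits so
# bundles round-trip bit-faithfully.
# ---------------------------------------------------------------------------

#' Read a binary raster file
#'
#' The format is delimited text (comma or tab), rows = neurons, columns =
#' time bins, cells 0/1, preceded by '#'-prefixed header lines:
#' `# tau_ms=<float>`, `# t0_bin=<int>`, `# labels=<comma list>` (the last
#' two optional). Any cell not exactly 0 or 1 is rejected with the row and
#' column of the offending cell.
#'
#' @param path file path.
#' @return a [binary_kernel()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list(tau_ms = NULL, t0_bin = 0L, labels = NULL)
  for (h in lines[hdr]) {
    kv <- sub("^#\\s*", "", h)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    if (key == "tau_ms") meta$tau_ms <- as.numeric(val)
    if (key == "t0_bin") meta$t0_bin <- as.integer(val)
    if (key == "labels") meta$labels <- strsplit(val, ",")[[1L]]
  }
  if (is.null(meta$tau_ms))
    stop("missing '# tau_ms=' header in ", path)
  body <- lines[!hdr & nzchar(lines)]
  if (length(body) == 0L) stop("no data rows in ", path)
  sep <- if (grepl("\t", body[1L])) "\t" else ","
  rows <- strsplit(body, sep, fixed = TRUE)
  ncols <- length(rows[[1L]])
  vals <- matrix(NA_integer_, length(rows), ncols)
  for (r in seq_along(rows)) {
    if (length(rows[[r]]) != ncols)
      stop("row ", r, " has ", length(rows[[r]]), " cells, expected ", ncols)
    v <- suppressWarnings(as.integer(trimws(rows[[r]])))
    bad <- which(is.na(v) | !(v %in% c(0L, 1L)))
    if (length(bad) > 0L)
      stop(sprintf("parse error at row %d, column %d: cell '%s' is not 0/1",
                   r, bad[1L], trimws(rows[[r]][bad[1L]])))
    vals[r, ] <- v
  }
  binary_kernel(vals, tau_ms = meta$tau_ms, neuron_labels = meta$labels,
                t0_bin = meta$t0_bin)
}

#' Write a binary raster file
#'
#' Inverse of [read_raster()]; `read_raster(write_raster(k, p))` reproduces
#' the kernel exactly.
#'
#' @param k a binary kernel.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(k, path) {
  k <- to_binary(k)
  hdr <- c(sprintf("# tau_ms=%.17g", k$tau_ms),
           sprintf("# t0_bin=%d", k$t0_bin))
  if (!is.null(k$neuron_labels))
    hdr <- c(hdr, paste0("# labels=", paste(k$neuron_labels,
                                            collapse = ",")))
  body <- apply(k$values, 1L, paste, collapse = ",")
  writeLines(c(hdr, body), path)
  invisible(path)
}

write_float_csv <- function(mat, path) {
  body <- apply(as.matrix(mat), 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(body, path)
  invisible(path)
}

read_float_csv <- function(path) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  do.call(rbind, lapply(rows, as.numeric))
}

#' Write a hypermatrix bundle directory
#'
#' Serialises a kernel and its derived observables into a directory:
#' `kernel.csv` (raster format), `phi.csv`, `pi.csv`, `f.csv`, `omega.csv`,
#' optionally the spin matrices `c.csv`, `q.csv` and the connected variants,
#' plus `meta.json` with clock time, representation, alignment, provenance
#' and per-file md5 checksums. Floats use 17 significant digits.
#'
#' @param k a binary kernel.
#' @param dir target directory (created if missing).
#' @param spin also write the spin matrices.
#' @param connected also write the connected matrices.
#' @param provenance optional character vector recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_hypermatrix <- function(k, dir, spin = TRUE, connected = TRUE,
                              provenance = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- correlation_set(k, "both")
  fo <- cs$first_order
  write_raster(k, file.path(dir, "kernel.csv"))
  write_float_csv(cs$phi, file.path(dir, "phi.csv"))
  write_float_csv(cs$pi, file.path(dir, "pi.csv"))
  write_float_csv(matrix(fo$row_rates, nrow = 1L), file.path(dir, "f.csv"))
  write_float_csv(matrix(fo$col_activity, nrow = 1L),
                  file.path(dir, "omega.csv"))
  if (spin) {
    write_float_csv(cs$spin_c, file.path(dir, "c.csv"))
    write_float_csv(cs$spin_q, file.path(dir, "q.csv"))
  }
  if (connected) {
    write_float_csv(cs$c_star, file.path(dir, "c_star.csv"))
    write_float_csv(cs$q_star, file.path(dir, "q_star.csv"))
  }
  files <- setdiff(list.files(dir), "meta.json")
  sums <- tools::md5sum(file.path(dir, files))
  meta <- list(version = "1.0.0",
               representation = "binary",
               tau_ms = k$tau_ms,
               t0_bin = k$t0_bin,
               n_neurons = n_neurons(k),
               n_bins = n_bins(k),
               provenance = as.list(provenance),
               checksums = as.list(setNames(unname(sums), files)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a hypermatrix bundle directory
#'
#' Validates checksums against the manifest, loads the kernel and any
#' stored matrices, and recomputes derived matrices that are absent.
#'
#' @param dir bundle directory.
#' @param verify_checksums fail on checksum mismatch (default TRUE).
#' @return list with `kernel`, `correlations` (a [correlation_set()]),
#'   `meta`, and the stored matrices under their file stems.
#' @export
read_hypermatrix <- function(dir, verify_checksums = TRUE) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("no meta.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (verify_checksums && length(meta$checksums) > 0L) {
    for (f in names(meta$checksums)) {
      fp <- file.path(dir, f)
      if (!file.exists(fp)) stop("bundle file missing: ", f)
      actual <- unname(tools::md5sum(fp))
      if (!identical(actual, meta$checksums[[f]]))
        stop("checksum mismatch for ", f)
    }
  }
  k <- read_raster(file.path(dir, "kernel.csv"))
  stored <- list()
  for (f in c("phi", "pi", "c", "q", "c_star", "q_star")) {
    fp <- file.path(dir, paste0(f, ".csv"))
    if (file.exists(fp)) stored[[f]] <- read_float_csv(fp)
  }
  list(kernel = k, correlations = correlation_set(k, "both"),
       stored = stored, meta = meta)
}
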