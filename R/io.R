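# Plain-text, diff-friendly serialization: TSV bodies with "# key = value"
# header lines carrying provenance. Readers validate and report offending
# line numbers.

.write_header <- function(con, meta) {
  for (k in names(meta))
    writeLines(sprintf("# %s = %s", k, format(meta[[k]])), con)
}

.read_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[trimws(substr(kv, 1, eq - 1))]] <- trimws(substr(kv, eq + 1, nchar(kv)))
  }
  list(meta = meta, skip = length(hdr))
}

#' Write / read a spike raster as columnar text
#'
#' One row per spike: `neuron_id <TAB> spike_time_ms` (1-based bin).
#' Header lines record the bin size, duration and neuron ids so the
#' raster round-trips exactly, including silent neurons.
#'
#' @param raster a [spike_raster()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, list(format = "spike_raster", bin_ms = 1,
                          n_bins = raster$n_bins,
                          neuron_ids = paste(raster$neuron_ids, collapse = ",")))
  writeLines("neuron_id\tspike_time_ms", con)
  df <- data.frame(neuron_id = rep(raster$neuron_ids, lengths(raster$spikes)),
                   spike_time_ms = unlist(raster$spikes, use.names = FALSE))
  if (nrow(df))
    writeLines(paste(df$neuron_id, df$spike_time_ms, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  h <- .read_header(path)
  if (is.null(h$meta$n_bins)) stop("missing n_bins header")
  n_bins <- as.integer(h$meta$n_bins)
  ids <- strsplit(h$meta$neuron_ids, ",")[[1]]
  body <- readLines(path)[-seq_len(h$skip)]
  body <- body[-1]  # column header
  spikes <- setNames(rep(list(integer()), length(ids)), ids)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad))
      stop(sprintf("malformed raster row at line %d", h$skip + 1 + bad[1]))
    nid <- vapply(parts, `[`, "", 1)
    tms <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
    bad <- which(is.na(tms) | tms < 1 | tms > n_bins)
    if (length(bad))
      stop(sprintf("spike time outside [1, n_bins] at line %d", h$skip + 1 + bad[1]))
    bad <- which(!nid %in% ids)
    if (length(bad))
      stop(sprintf("unknown neuron id at line %d", h$skip + 1 + bad[1]))
    spikes <- lapply(setNames(ids, ids), function(k) sort(tms[nid == k]))
  }
  spike_raster(spikes, n_bins, neuron_ids = ids)
}

#' Write / read a neuron metadata table as TSV
#'
#' @param neurons data frame (must carry `neuron_id`; a `region_group`
#'   column, when present, is validated against the 16 labels).
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_neuron_table <- function(neurons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, list(format = "neuron_table"))
  close(con); on.exit()
  suppressWarnings(write.table(neurons, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_neuron_table
#' @export
read_neuron_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!"neuron_id" %in% names(df)) stop("neuron table must carry neuron_id")
  if ("region_group" %in% names(df)) {
    bad <- which(!df$region_group %in% region_groups())
    if (length(bad)) stop(sprintf("unknown region label in row %d", bad[1]))
  }
  df
}

#' Write / read a directed edge list as TSV
#'
#' Columns: src, dst, then any further edge attributes (weight, strength,
#' sharpness, d_peak, category, sign, delay_ms...). Accepted-edge weights
#' must be positive; a nonpositive weight is rejected with its row number.
#'
#' @param edges data frame with at least `src` and `dst`.
#' @param path file path.
#' @param check_weights validate `weight > 0` (default TRUE).
#' @return `path` (write) or the data frame (read).
#' @export
write_edge_list <- function(edges, path, check_weights = TRUE) {
  if (check_weights && "weight" %in% names(edges) &&
      any(edges$weight <= 0))
    stop("edge weights on accepted edges must be positive")
  con <- file(path, "w")
  .write_header(con, list(format = "edge_list"))
  close(con)
  suppressWarnings(write.table(edges, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, check_weights = TRUE) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!all(c("src", "dst") %in% names(df))) stop("edge list needs src and dst")
  if (check_weights && "weight" %in% names(df)) {
    bad <- which(df$weight <= 0)
    if (length(bad)) stop(sprintf("nonpositive weight in edge row %d", bad[1]))
  }
  df
}

#' Write / read a numeric matrix as TSV with id headers
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}
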