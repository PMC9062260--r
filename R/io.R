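EVENT_LIST_VERSION <- "petchain-events-1"
SINOGRAM_VERSION <- "petchain-sino-1"

#' Write a coincidence event list
#'
#' Gzip CSV table plus a JSON sidecar header (`<path>.json`) carrying the
#' format version, the row count (used to detect truncated writes) and
#' arbitrary metadata (seed, duration, configuration hash).
#'
#' @param events Event data frame or `petchain_acquisition`.
#' @param path Output path (`.csv.gz` recommended).
#' @param meta Named list of extra metadata.
#' @export
write_event_list <- function(events, path, meta = list()) {
  if (inherits(events, "petchain_acquisition")) {
    meta <- utils::modifyList(list(summary = events$summary), meta)
    events <- events$events
  }
  data.table::fwrite(events, path)
  header <- c(list(version = EVENT_LIST_VERSION, n_events = nrow(events),
                   columns = names(events)), meta)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a coincidence event list
#'
#' Verifies the sidecar version and row count.  With `chunk_size` set, the
#' file is streamed in bounded memory and `callback(chunk)` is invoked per
#' chunk; the function then returns the callback results invisibly.
#'
#' @param path File written by [write_event_list()].
#' @param chunk_size Rows per chunk (NULL = read everything).
#' @param callback Function applied to each chunk.
#' @return Event data frame (with a `meta` attribute), or the list of
#'   callback results in chunked mode.
#' @export
read_event_list <- function(path, chunk_size = NULL, callback = NULL) {
  hpath <- paste0(path, ".json")
  if (!file.exists(hpath)) stop("missing event-list header: ", hpath)
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (!identical(header$version, EVENT_LIST_VERSION))
    stop("event-list version mismatch: ", header$version)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  head_line <- readLines(con, 1)
  parse_chunk <- function(lines) {
    if (length(lines) == 0)
      return(stats::setNames(data.frame(matrix(nrow = 0, ncol =
        length(header$columns))), header$columns))
    ch <- data.table::fread(text = c(head_line, lines))
    as.data.frame(ch)
  }
  if (is.null(chunk_size)) {
    ev <- parse_chunk(readLines(con))
    if (nrow(ev) != header$n_events)
      stop("event list truncated: expected ", header$n_events, " rows")
    attr(ev, "meta") <- header
    return(ev)
  }
  out <- list(); total <- 0; i <- 1
  repeat {
    lines <- readLines(con, chunk_size)
    if (length(lines) == 0) break
    ch <- parse_chunk(lines)
    total <- total + nrow(ch)
    out[[i]] <- if (is.null(callback)) NULL else callback(ch)
    i <- i + 1
    if (length(lines) < chunk_size) break
  }
  if (total != header$n_events)
    stop("event list truncated: expected ", header$n_events, " rows")
  invisible(out)
}

#' Write / read a sinogram set
#'
#' A sinogram set bundles bin-congruent arrays (prompts, randoms, scatter,
#' acf, eta, tail mask, ...) with the layout and provenance metadata in a
#' single RDS container with a version field.
#'
#' @param x Named list of arrays plus `layout`.
#' @param path Output path (`.rds`).
#' @param meta Extra metadata.
#' @export
write_sinogram_set <- function(x, path, meta = list()) {
  x$version <- SINOGRAM_VERSION
  x$meta <- utils::modifyList(if (is.null(x$meta)) list() else x$meta, meta)
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_sinogram_set
#' @export
read_sinogram_set <- function(path) {
  x <- readRDS(path)
  if (!identical(x$version, SINOGRAM_VERSION))
    stop("sinogram container version mismatch in ", path)
  x
}

#' Write / read a reconstructed volume as NIfTI
#'
#' Voxel size is stored in the NIfTI header; provenance (configuration
#' hash, seed, calibration scale) goes to a YAML sidecar.
#'
#' @param recon `petchain_recon` object (or array with `voxel`).
#' @param path Output `.nii` / `.nii.gz` path.
#' @param meta Extra metadata for the sidecar.
#' @export
write_volume <- function(recon, path, meta = list()) {
  if (inherits(recon, "petchain_recon")) {
    arr <- recon$values
    meta <- utils::modifyList(list(voxel = recon$voxel,
                                   origin = recon$origin,
                                   scale = recon$scale), meta)
  } else arr <- recon
  img <- RNifti::asNifti(arr, pixdim = meta$voxel)
  RNifti::writeNifti(img, path)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- if (file.exists(paste0(path, ".yaml")))
    yaml::read_yaml(paste0(path, ".yaml")) else list()
  structure(list(values = array(as.numeric(img), dim(img)),
                 voxel = unlist(meta$voxel), origin = unlist(meta$origin),
                 scale = meta$scale, meta = meta),
            class = "petchain_recon")
}
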