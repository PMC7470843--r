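#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered Z then C (axes Z, C, Y, X); a JSON sidecar
#' (`<path>.json`) records channel names, voxel sizes, source id, origin
#' and the intensity scaling used for storage. Samples are stored as 32-bit
#' values after mapping into `[0, 1]` by a power-of-two scale (and an
#' offset when intensities are negative); integer-valued stacks — native
#' camera counts — round-trip exactly, continuous data to ~2^-32 relative
#' precision.
#'
#' @param stack an `image_stack`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$pixels[[1]])
  vals <- unlist(stack$pixels, use.names = FALSE)
  offset <- min(0, min(vals))
  mx <- max(vals - offset, 1e-12)
  scale <- 2^ceiling(log2(mx))
  is_int <- all(vals == round(vals)) && offset == round(offset)
  pages <- vector("list", d[3] * length(stack$pixels))
  k <- 1L
  for (z in seq_len(d[3])) {
    for (ch in names(stack$pixels)) {
      pages[[k]] <- t((stack$pixels[[ch]][, , z] - offset) / scale)
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  sidecar <- list(channels = names(stack$pixels),
                  voxel_xy = stack$voxel_xy, voxel_z = stack$voxel_z,
                  source_id = stack$source_id, origin = stack$origin,
                  dims = as.integer(d), scale = scale, offset = offset,
                  integer_data = is_int, axes = "ZCYX")
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' Without a sidecar the TIFF is read as a single-channel stack of raw
#' `[0, 1]` samples, and voxel sizes must be supplied.
#'
#' @param path `.tif` path.
#' @param voxel_xy,voxel_z fallback voxel sizes (nm) when no sidecar is
#'   present.
#' @return an `image_stack`.
#' @export
read_stack <- function(path, voxel_xy = NULL, voxel_z = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    sc <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    d <- as.integer(sc$dims)
    pix <- stats::setNames(lapply(sc$channels, function(.) array(0, d)),
                           sc$channels)
    k <- 1L
    for (z in seq_len(d[3])) {
      for (ch in sc$channels) {
        v <- t(pages[[k]]) * sc$scale + sc$offset
        if (isTRUE(sc$integer_data)) v <- round(v)
        pix[[ch]][, , z] <- v
        k <- k + 1L
      }
    }
    image_stack(pix, sc$voxel_xy, sc$voxel_z, source_id = sc$source_id,
                origin = as.numeric(sc$origin))
  } else {
    if (is.null(voxel_xy) || is.null(voxel_z))
      stop("no metadata sidecar for ", path,
           ": voxel_xy and voxel_z must be supplied")
    d <- c(dim(t(pages[[1]])), length(pages))
    arr <- array(0, d)
    for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]])
    image_stack(list(ch1 = arr), voxel_xy, voxel_z,
                source_id = basename(path))
  }
}

#' Read a spot seed table
#'
#' CSV with columns `source_id`, `pair_id`, `x`, `y`, `z` (nm, stack-local).
#' Rows failing to parse are reported with their file line numbers.
#' Coordinates are validated against stack bounds at use time, not here.
#'
#' @param path CSV path.
#' @return tibble of seed coordinates (empty file gives zero rows).
#' @export
read_seeds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  need <- c("source_id", "pair_id", "x", "y", "z")
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0)
    return(tibble::tibble(source_id = character(), pair_id = character(),
                          x = numeric(), y = numeric(), z = numeric()))
  if (!all(need %in% names(raw)))
    stop("seed table must have columns: ", paste(need, collapse = ", "))
  num <- lapply(c("x", "y", "z"), function(cc)
    suppressWarnings(as.numeric(raw[[cc]])))
  bad <- which(Reduce(`|`, lapply(num, is.na)) | !nzchar(raw$source_id))
  if (length(bad))
    stop("malformed seed rows at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  tibble::tibble(source_id = raw$source_id, pair_id = raw$pair_id,
                 x = num[[1]], y = num[[2]], z = num[[3]])
}

#' Group seeds into candidate SPB pairs
#'
#' @param seeds tibble from [read_seeds()].
#' @return list of tibbles, one per `(source_id, pair_id)` group.
#' @export
seed_pairs <- function(seeds) {
  if (nrow(seeds) == 0) return(list())
  key <- paste(seeds$source_id, seeds$pair_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(seeds)), key), function(i) seeds[i, ])
  names(out) <- vapply(out, function(g)
    paste(g$source_id[1], g$pair_id[1], sep = ":"), "")
  out[order(names(out))]
}

#' Write a result table as CSV with a JSON schema header file
#'
#' @param tbl data frame / tibble.
#' @param path CSV path; the schema goes to `<path minus .csv>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  schema <- list(columns = lapply(stats::setNames(names(tbl), names(tbl)),
                                  function(cc) class(tbl[[cc]])[1]))
  jsonlite::write_json(schema, paste0(sub("\\.csv$", "", path),
                                      ".schema.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path CSV path.
#' @return tibble with column classes restored from the schema.
#' @export
read_result_table <- function(path) {
  schema_path <- paste0(sub("\\.csv$", "", path), ".schema.json")
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (file.exists(schema_path)) {
    schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
    for (cc in names(schema$columns)) {
      cls <- schema$columns[[cc]]
      if (cc %in% names(tbl) && cls %in% c("numeric", "integer", "logical",
                                           "character"))
        tbl[[cc]] <- methods::as(tbl[[cc]], cls)
    }
  }
  tibble::as_tibble(tbl)
}
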