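# Plain-text I/O for maps and cohort manifests.
#
# Map files: UTF-8 text, one matrix per file. Rows are lines; values are
# whitespace- or comma-separated decimal floats; lines starting with '#' are
# ignored. One magnitude file plus one angle file per map.
#
# Manifest: tab- (or comma-) separated table with header columns
# map_id, magnitude_path, angle_path, label; paths relative to the manifest.

#' Read a matrix from a plain-text map file
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_map_matrix <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0)
    stop("map file contains no data rows: ", path, call. = FALSE)
  rows <- lapply(keep, function(i) {
    toks <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      stop("non-numeric token '", toks[which(is.na(vals))[1]],
           "' in ", path, " line ", i, call. = FALSE)
    vals
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1)
    stop("ragged rows in ", path, ": line ", keep[which(ncols != ncols[1])[1]],
         " has ", ncols[ncols != ncols[1]][1], " values, expected ", ncols[1],
         call. = FALSE)
  do.call(rbind, rows)
}

#' Write a matrix to a plain-text map file
#'
#' @param x Numeric matrix.
#' @param path Output file path.
#' @param digits Significant digits written (default 17, enough for exact
#'   double round-trips).
#' @return `path`, invisibly.
#' @export
write_map_matrix <- function(x, path, digits = 17) {
  stopifnot(is.matrix(x), is.numeric(x))
  fmt <- paste0("%.", digits, "g")
  lines <- apply(x, 1, function(r) paste(sprintf(fmt, r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a CDDM from a magnitude file and an angle file
#'
#' Angle values are wrapped into (-pi, pi] on read; degree input is converted
#' first when `angle_units = "degrees"`.
#'
#' @param magnitude_path,angle_path Paths to the two map files.
#' @param label Optional heart-state label.
#' @param map_id Identifier (default: magnitude file name without extension).
#' @param angle_units `"radians"` (default) or `"degrees"`.
#' @return A [cddm()] object.
#' @export
read_cddm <- function(magnitude_path, angle_path, label = NULL,
                      map_id = NULL,
                      angle_units = c("radians", "degrees")) {
  angle_units <- match.arg(angle_units)
  mag <- read_map_matrix(magnitude_path)
  ang <- read_map_matrix(angle_path)
  if (!identical(dim(mag), dim(ang)))
    stop("shape mismatch between ", magnitude_path, " (",
         paste(dim(mag), collapse = "x"), ") and ", angle_path, " (",
         paste(dim(ang), collapse = "x"), ")", call. = FALSE)
  if (angle_units == "degrees") ang <- ang * pi / 180
  if (is.null(map_id))
    map_id <- sub("\\.[^.]*$", "", basename(magnitude_path))
  cddm(mag, ang, label = label, map_id = map_id)
}

#' Write a CDDM to a directory
#'
#' Writes `<map_id>_mag.txt` and `<map_id>_ang.txt` in the map file format.
#'
#' @param map A `cddm` object with a non-empty `map_id`.
#' @param dir Output directory (created if missing).
#' @return Named character vector with elements `magnitude` and `angle`.
#' @export
write_cddm <- function(map, dir) {
  stopifnot(inherits(map, "cddm"), nzchar(map$map_id))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mp <- file.path(dir, paste0(map$map_id, "_mag.txt"))
  ap <- file.path(dir, paste0(map$map_id, "_ang.txt"))
  write_map_matrix(map$magnitude, mp)
  write_map_matrix(map$angle, ap)
  c(magnitude = mp, angle = ap)
}

#' Build a cohort object from a list of CDDMs
#'
#' A cohort is the in-memory form of a labelled map collection: the list of
#' maps, the manifest table, and the label -> map_id grouping.
#'
#' @param maps List of `cddm` objects with unique non-empty `map_id`s.
#' @param manifest Optional manifest data.frame (as from [read_cohort()]).
#' @return An object of class `cddm_cohort`.
#' @export
as_cohort <- function(maps, manifest = NULL) {
  stopifnot(is.list(maps), all(vapply(maps, inherits, TRUE, "cddm")))
  ids <- vapply(maps, function(m) m$map_id, "")
  if (anyDuplicated(ids))
    stop("duplicate map_ids in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(maps) <- ids
  labels <- vapply(maps, function(m) m$label, "")
  if (is.null(manifest))
    manifest <- data.frame(map_id = ids,
                           magnitude_path = rep(NA_character_, length(ids)),
                           angle_path = rep(NA_character_, length(ids)),
                           label = labels,
                           stringsAsFactors = FALSE)
  groups <- split(ids, labels)
  structure(list(maps = maps, manifest = manifest, groups = groups),
            class = "cddm_cohort")
}

#' @export
print.cddm_cohort <- function(x, ...) {
  cat(sprintf("<cddm_cohort: %d maps, %d groups>\n",
              length(x$maps), length(x$groups)))
  counts <- vapply(x$groups, length, 0L)
  print(counts)
  invisible(x)
}

#' Read a cohort from a manifest file
#'
#' @param manifest_path Path to the manifest table (TSV or CSV; delimiter
#'   sniffed from the header line). Required columns: `map_id`,
#'   `magnitude_path`, `angle_path`, `label`. Paths are resolved relative to
#'   the manifest location. Labels may use any recognized alias; every
#'   resolved label must be one of the 14 canonical codes.
#' @param angle_units Units of the angle files, `"radians"` or `"degrees"`.
#' @return A `cddm_cohort`.
#' @export
read_cohort <- function(manifest_path, angle_units = c("radians", "degrees")) {
  angle_units <- match.arg(angle_units)
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  hdr <- readLines(manifest_path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  man <- read.delim(manifest_path, sep = sep, stringsAsFactors = FALSE,
                    comment.char = "#")
  need <- c("map_id", "magnitude_path", "angle_path", "label")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(man$map_id))
    stop("duplicate map_id in manifest", call. = FALSE)
  man$label <- as_heart_state(man$label)
  base <- dirname(normalizePath(manifest_path))
  maps <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    mp <- file.path(base, man$magnitude_path[i])
    ap <- file.path(base, man$angle_path[i])
    if (!file.exists(mp)) stop("missing map file: ", mp, call. = FALSE)
    if (!file.exists(ap)) stop("missing map file: ", ap, call. = FALSE)
    maps[[i]] <- read_cddm(mp, ap, label = man$label[i],
                           map_id = man$map_id[i], angle_units = angle_units)
  }
  as_cohort(maps, manifest = man)
}

#' Write a cohort to a directory
#'
#' Writes every map's magnitude/angle files plus a `manifest.tsv` with paths
#' relative to the directory.
#'
#' @param cohort A `cddm_cohort`.
#' @param dir Output directory.
#' @return Path to the written manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cddm_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort$maps, function(m) {
    p <- write_cddm(m, dir)
    data.frame(map_id = m$map_id,
               magnitude_path = basename(p[["magnitude"]]),
               angle_path = basename(p[["angle"]]),
               label = m$label, stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  rownames(man) <- NULL
  mpath <- file.path(dir, "manifest.tsv")
  write.table(man, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mpath)
}
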