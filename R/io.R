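# Curve bundles on disk.
#
# Canonical dialect: a directory with
#   bundle.json                      provenance (format_version, convention,
#                                    generator parameters, seed)
#   cells.tsv                        per-cell metadata
#   curves/<cell>_<k>_approach.tsv   '#'-prefixed "key: value" header lines,
#   curves/<cell>_<k>_retract.tsv    then two tab-separated numeric columns
#                                    (z_m, d_m)
# Numbers are written with 17 significant digits so a write -> read round
# trip is bit-identical. An HDF5 encoding of the same layout is available
# when the rhdf5 package is installed.

FORMAT_VERSION <- "1.0"

fmt_num <- function(x) sprintf("%.17g", x)

write_curve_tsv <- function(curve, segment, path) {
  seg <- curve[[segment]]
  hdr <- c(sprintf("# format_version: %s", FORMAT_VERSION),
           sprintf("# segment: %s", segment),
           sprintf("# cell_id: %s", curve$cell_id),
           sprintf("# curve_index: %d", curve$curve_index),
           sprintf("# group: %s", curve$group),
           sprintf("# k_N_per_m: %s", fmt_num(curve$k)),
           sprintf("# setpoint_N: %s", fmt_num(curve$setpoint)),
           sprintf("# R_m: %s", fmt_num(curve$R)),
           sprintf("# speed_m_per_s: %s", fmt_num(curve$speed)),
           "# columns: z_m\td_m")
  body <- paste(fmt_num(seg$z_m), fmt_num(seg$d_m), sep = "\t")
  writeLines(c(hdr, body), path)
}

parse_curve_tsv <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- sub("^#\\s*", "", lines[is_hdr])
  kv <- strsplit(hdr, ":\\s*")
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = ":"), character(1))
  meta <- stats::setNames(as.list(vals), keys)
  need <- function(key, what = key) {
    if (is.null(meta[[key]]))
      stop(sprintf("schema error in %s: missing '%s' header (%s)",
                   basename(path), key, what))
    meta[[key]]
  }
  ver <- need("format_version")
  if (!identical(ver, FORMAT_VERSION))
    stop(sprintf("format version mismatch in %s: file %s, reader %s",
                 basename(path), ver, FORMAT_VERSION))
  cols <- need("columns", "unit declaration")
  if (!identical(cols, "z_m\td_m"))
    stop(sprintf("unit declaration mismatch in %s: columns '%s'",
                 basename(path), cols))
  body <- lines[!is_hdr]
  parts <- strsplit(body, "\t", fixed = TRUE)
  seg <- data.frame(z_m = as.numeric(vapply(parts, `[[`, character(1), 1L)),
                    d_m = as.numeric(vapply(parts, `[[`, character(1), 2L)))
  list(meta = meta, seg = seg,
       k = as.numeric(need("k_N_per_m", "spring constant")),
       setpoint = as.numeric(need("setpoint_N")),
       R = as.numeric(need("R_m")),
       speed = as.numeric(need("speed_m_per_s")),
       cell_id = need("cell_id"), curve_index = as.integer(need("curve_index")),
       group = need("group"), segment = need("segment"))
}

#' Write a curve bundle in the TSV dialect
#'
#' @param bundle a \code{curve_bundle}.
#' @param dir output directory (created; must not exist unless
#'   \code{overwrite}).
#' @param overwrite replace an existing directory.
#' @return \code{dir}, invisibly.
#' @export
write_bundle_tsv <- function(bundle, dir, overwrite = FALSE) {
  stopifnot(inherits(bundle, "curve_bundle"))
  if (dir.exists(dir)) {
    if (!overwrite) stop("directory exists: ", dir)
    unlink(dir, recursive = TRUE)
  }
  dir.create(file.path(dir, "curves"), recursive = TRUE)
  prov <- bundle$provenance
  prov$format_version <- FORMAT_VERSION
  prov$convention <- "deflection_m"
  jsonlite::write_json(prov, file.path(dir, "bundle.json"), auto_unbox = TRUE)
  utils::write.table(bundle$cells, file.path(dir, "cells.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (cu in bundle$curves) {
    stem <- sprintf("%s_%02d", cu$cell_id, cu$curve_index)
    write_curve_tsv(cu, "approach",
                    file.path(dir, "curves", paste0(stem, "_approach.tsv")))
    if (!is.null(cu$retract))
      write_curve_tsv(cu, "retract",
                      file.path(dir, "curves", paste0(stem, "_retract.tsv")))
  }
  invisible(dir)
}

#' Read a curve bundle in the TSV dialect
#'
#' @param dir bundle directory written by \code{\link{write_bundle_tsv}}.
#' @return a \code{curve_bundle}.
#' @export
read_bundle_tsv <- function(dir) {
  if (!dir.exists(dir)) stop("no such bundle directory: ", dir)
  prov <- jsonlite::read_json(file.path(dir, "bundle.json"))
  if (!identical(prov$format_version, FORMAT_VERSION))
    stop(sprintf("format version mismatch: bundle %s, reader %s",
                 prov$format_version, FORMAT_VERSION))
  if (is.null(prov$convention))
    stop("unit declaration missing: bundle.json has no 'convention'")
  cells <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  if ("area_um2" %in% names(cells))
    cells$area_um2 <- as.numeric(cells$area_um2)
  if ("moved_or_morphology_excluded" %in% names(cells))
    cells$moved_or_morphology_excluded <-
      as.logical(cells$moved_or_morphology_excluded)
  files <- sort(list.files(file.path(dir, "curves"), pattern = "_approach\\.tsv$",
                           full.names = TRUE))
  curves <- lapply(files, function(f) {
    ap <- parse_curve_tsv(f)
    rf <- sub("_approach\\.tsv$", "_retract.tsv", f)
    rt <- if (file.exists(rf)) parse_curve_tsv(rf)$seg else NULL
    force_curve(ap$seg, rt, k = ap$k, setpoint = ap$setpoint, R = ap$R,
                speed = ap$speed, cell_id = ap$cell_id,
                curve_index = ap$curve_index, group = ap$group)
  })
  structure(list(curves = curves, cells = cells, truth = NULL,
                 provenance = prov),
            class = "curve_bundle")
}

#' Write / read a curve bundle as HDF5
#'
#' Layout \code{/cells/<id>/curves/<k>/\{approach,retract\}} with calibration
#' attributes on each curve group. Requires the \pkg{rhdf5} package.
#'
#' @param bundle a \code{curve_bundle}.
#' @param path HDF5 file path.
#' @return \code{path} (write) / a \code{curve_bundle} (read).
#' @export
write_bundle_h5 <- function(bundle, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the rhdf5 package is required for HDF5 bundles; ",
         "use write_bundle_tsv() instead")
  stopifnot(inherits(bundle, "curve_bundle"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "cells")
  by_cell <- split(bundle$curves,
                   vapply(bundle$curves, `[[`, character(1), "cell_id"))
  # pass 1: groups and datasets (path-based API)
  for (id in names(by_cell)) {
    g_cell <- sprintf("cells/%s", id)
    rhdf5::h5createGroup(path, g_cell)
    rhdf5::h5createGroup(path, paste0(g_cell, "/curves"))
    for (cu in by_cell[[id]]) {
      g_curve <- sprintf("%s/curves/%02d", g_cell, cu$curve_index)
      rhdf5::h5createGroup(path, g_curve)
      rhdf5::h5write(as.matrix(cu$approach), path, paste0(g_curve, "/approach"))
      if (!is.null(cu$retract))
        rhdf5::h5write(as.matrix(cu$retract), path, paste0(g_curve, "/retract"))
    }
  }
  # pass 2: attributes in one open session
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(FORMAT_VERSION, fid, "format_version")
  rhdf5::h5writeAttribute("deflection_m", fid, "convention")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(bundle$provenance, auto_unbox = TRUE)),
    fid, "provenance_json")
  for (id in names(by_cell)) {
    g_cell <- sprintf("cells/%s", id)
    md <- bundle$cells[bundle$cells$cell_id == id, , drop = FALSE]
    gid <- rhdf5::H5Gopen(fid, g_cell)
    if (nrow(md) == 1L) {
      rhdf5::h5writeAttribute(md$group, gid, "group")
      rhdf5::h5writeAttribute(as.numeric(md$area_um2), gid, "area_um2")
      rhdf5::h5writeAttribute(as.integer(md$moved_or_morphology_excluded),
                              gid, "moved_or_morphology_excluded")
    }
    rhdf5::H5Gclose(gid)
    for (cu in by_cell[[id]]) {
      gid <- rhdf5::H5Gopen(fid, sprintf("%s/curves/%02d", g_cell,
                                         cu$curve_index))
      rhdf5::h5writeAttribute(cu$k, gid, "k_N_per_m")
      rhdf5::h5writeAttribute(cu$setpoint, gid, "setpoint_N")
      rhdf5::h5writeAttribute(cu$R, gid, "R_m")
      rhdf5::h5writeAttribute(cu$speed, gid, "speed_m_per_s")
      rhdf5::h5writeAttribute(cu$curve_index, gid, "curve_index")
      rhdf5::H5Gclose(gid)
    }
  }
  path
}

#' @rdname write_bundle_h5
#' @export
read_bundle_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the rhdf5 package is required for HDF5 bundles")
  if (!file.exists(path)) stop("no such file: ", path)
  root_at <- rhdf5::h5readAttributes(path, "/")
  ver <- as.character(root_at$format_version)[1L]
  if (!identical(ver, FORMAT_VERSION))
    stop(sprintf("format version mismatch: bundle %s, reader %s",
                 ver, FORMAT_VERSION))
  prov <- jsonlite::fromJSON(as.character(root_at$provenance_json)[1L])
  ls_all <- rhdf5::h5ls(path)
  cell_ids <- ls_all$name[ls_all$group == "/cells"]
  curves <- list()
  cells <- list()
  for (id in sort(cell_ids)) {
    ca <- rhdf5::h5readAttributes(path, sprintf("/cells/%s", id))
    cells[[id]] <- data.frame(
      cell_id = id,
      group = if (is.null(ca$group)) NA_character_ else as.character(ca$group),
      area_um2 = if (is.null(ca$area_um2)) NA_real_ else as.numeric(ca$area_um2),
      moved_or_morphology_excluded =
        isTRUE(as.logical(ca$moved_or_morphology_excluded)),
      stringsAsFactors = FALSE)
    kdirs <- ls_all$name[ls_all$group == sprintf("/cells/%s/curves", id)]
    for (kk in sort(kdirs)) {
      g_curve <- sprintf("/cells/%s/curves/%s", id, kk)
      at <- rhdf5::h5readAttributes(path, g_curve)
      if (is.null(at$k_N_per_m))
        stop(sprintf("schema error in %s: missing spring constant attribute",
                     g_curve))
      ap <- as.data.frame(rhdf5::h5read(path, paste0(g_curve, "/approach")))
      names(ap) <- c("z_m", "d_m")
      objs <- ls_all$name[ls_all$group == g_curve]
      rt <- if ("retract" %in% objs) {
        r <- as.data.frame(rhdf5::h5read(path, paste0(g_curve, "/retract")))
        names(r) <- c("z_m", "d_m"); r
      } else NULL
      curves[[length(curves) + 1L]] <-
        force_curve(ap, rt, k = as.numeric(at$k_N_per_m),
                    setpoint = as.numeric(at$setpoint_N),
                    R = as.numeric(at$R_m), speed = as.numeric(at$speed_m_per_s),
                    cell_id = id, curve_index = as.integer(at$curve_index),
                    group = cells[[id]]$group)
    }
  }
  structure(list(curves = curves,
                 cells = do.call(rbind, c(unname(cells),
                                          list(make.row.names = FALSE))),
                 truth = NULL, provenance = prov),
            class = "curve_bundle")
}

#' Write / read a single-channel image as headered TSV text
#'
#' Plain-text carrier for confocal sections (no binary image formats are
#' used): '#'-prefixed "key: value" metadata lines (pixel size, cell id),
#' then one tab-separated row of intensities per image row.
#'
#' @param img an \code{actin_image} (see \code{\link{actin_image}}).
#' @param path output file.
#' @return \code{path} (write) / an \code{actin_image} (read).
#' @export
write_image_tsv <- function(img, path) {
  stopifnot(inherits(img, "actin_image"))
  hdr <- c(sprintf("# format_version: %s", FORMAT_VERSION),
           sprintf("# pixel_size_m: %s", fmt_num(img$pixel_size)),
           sprintf("# cell_id: %s", img$cell_id))
  body <- apply(img$pixels, 1L, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

#' @rdname write_image_tsv
#' @export
read_image_tsv <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- sub("^#\\s*", "", lines[is_hdr])
  kv <- strsplit(hdr, ":\\s*")
  meta <- stats::setNames(lapply(kv, function(x) paste(x[-1L], collapse = ":")),
                          vapply(kv, `[[`, character(1), 1L))
  if (is.null(meta$pixel_size_m))
    stop("schema error: image file lacks pixel_size_m header")
  rows <- strsplit(lines[!is_hdr], "\t", fixed = TRUE)
  px <- do.call(rbind, lapply(rows, as.numeric))
  actin_image(px, pixel_size = as.numeric(meta$pixel_size_m),
              cell_id = if (is.null(meta$cell_id)) "cell" else meta$cell_id)
}
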