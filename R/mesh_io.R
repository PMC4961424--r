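# Mesh file I/O: OFF, ASCII PLY and legacy ASCII VTK polydata.
# Node indices are 0-based on disk (the native convention of all three
# formats) and 1-based in memory. The per-node region label travels as an
# integer point-data field named "region"; additional per-node scalar
# fields (e.g. DF maps) are supported for PLY and VTK.

.fmt_num <- function(x) formatC(x, format = "g", digits = 9)

#' Write a surface mesh to OFF, PLY or VTK
#'
#' The format is inferred from the file extension (`.off`, `.ply`, `.vtk`).
#' PLY and VTK carry the region label as an integer per-vertex field named
#' `region` plus any additional per-node scalar `fields`; OFF stores
#' geometry only.
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param fields named list of per-node numeric vectors to store alongside
#'   the geometry (PLY and VTK only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, fields = list()) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces - 1L
  n <- nrow(v); m <- nrow(f)
  for (fl in fields) if (length(fl) != n)
    stop("field length must equal the node count", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "off") {
    writeLines(c("OFF", paste(n, m, 0)), con)
    writeLines(paste(.fmt_num(v[, 1]), .fmt_num(v[, 2]), .fmt_num(v[, 3])), con)
    writeLines(paste(3, f[, 1], f[, 2], f[, 3]), con)
  } else if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0", paste("element vertex", n),
             "property float x", "property float y", "property float z",
             "property int region")
    for (nm in names(fields)) hdr <- c(hdr, paste("property float", nm))
    hdr <- c(hdr, paste("element face", m),
             "property list uchar int vertex_indices", "end_header")
    writeLines(hdr, con)
    cols <- cbind(.fmt_num(v[, 1]), .fmt_num(v[, 2]), .fmt_num(v[, 3]),
                  mesh$region)
    for (fl in fields) cols <- cbind(cols, .fmt_num(fl))
    writeLines(do.call(paste, as.data.frame(cols)), con)
    writeLines(paste(3, f[, 1], f[, 2], f[, 3]), con)
  } else if (ext == "vtk") {
    writeLines(c("# vtk DataFile Version 3.0", "afsim surface mesh", "ASCII",
                 "DATASET POLYDATA", paste("POINTS", n, "float")), con)
    writeLines(paste(.fmt_num(v[, 1]), .fmt_num(v[, 2]), .fmt_num(v[, 3])), con)
    writeLines(paste("POLYGONS", m, 4 * m), con)
    writeLines(paste(3, f[, 1], f[, 2], f[, 3]), con)
    writeLines(c(paste("POINT_DATA", n), "SCALARS region int 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(as.character(mesh$region), con)
    for (nm in names(fields)) {
      writeLines(c(paste("SCALARS", nm, "float 1"), "LOOKUP_TABLE default"),
                 con)
      writeLines(.fmt_num(fields[[nm]]), con)
    }
  } else {
    stop("unknown mesh format: .", ext, " (expected off, ply or vtk)",
         call. = FALSE)
  }
  invisible(path)
}

.read_face_rows <- function(rows, path) {
  parts <- strsplit(trimws(rows), "\\s+")
  faces <- t(vapply(seq_along(parts), function(i) {
    p <- as.integer(parts[[i]])
    if (p[1] != 3L)
      stop("non-triangle face (", p[1], " vertices) in ", path,
           " at face ", i, call. = FALSE)
    p[2:4]
  }, integer(3)))
  faces + 1L
}

#' Read a surface mesh from OFF, PLY or VTK
#'
#' Inverse of [write_mesh()]. A `region` point-data field, when present, is
#' restored; other per-node scalar fields are returned in the `fields`
#' attribute.
#'
#' @param path input path (`.off`, `.ply` or `.vtk`).
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "off") {
    if (!startsWith(trimws(lines[1]), "OFF"))
      stop("malformed OFF file (missing header): ", path, call. = FALSE)
    cnt <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    n <- cnt[1]; m <- cnt[2]
    v <- matrix(as.numeric(unlist(strsplit(trimws(lines[3:(2 + n)]), "\\s+"))),
                ncol = 3, byrow = TRUE)
    f <- .read_face_rows(lines[(3 + n):(2 + n + m)], path)
    return(new_surface_mesh(v, f))
  }
  if (ext == "ply") {
    hend <- which(trimws(lines) == "end_header")[1]
    if (is.na(hend)) stop("malformed PLY file (no end_header): ", path,
                          call. = FALSE)
    hdr <- lines[1:hend]
    if (!any(grepl("^format ascii", hdr)))
      stop("only ASCII PLY is supported: ", path, call. = FALSE)
    n <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr,
                                                    value = TRUE)))
    m <- as.integer(sub("element face ", "", grep("^element face", hdr,
                                                  value = TRUE)))
    vprops <- sub("^property \\S+ ", "",
                  grep("^property (float|int|double|uchar) ",
                       hdr[seq_len(grep("^element face", hdr)[1])],
                       value = TRUE))
    vrows <- lines[(hend + 1):(hend + n)]
    vals <- matrix(as.numeric(unlist(strsplit(trimws(vrows), "\\s+"))),
                   ncol = length(vprops), byrow = TRUE)
    colnames(vals) <- vprops
    f <- .read_face_rows(lines[(hend + n + 1):(hend + n + m)], path)
    mesh <- new_surface_mesh(vals[, c("x", "y", "z"), drop = FALSE], f,
                             region = if ("region" %in% vprops)
                               as.integer(vals[, "region"]) else NULL)
    extra <- setdiff(vprops, c("x", "y", "z", "region"))
    if (length(extra))
      attr(mesh, "fields") <- as.list(as.data.frame(vals[, extra, drop = FALSE]))
    return(mesh)
  }
  if (ext == "vtk") {
    ip <- grep("^POINTS", lines)[1]
    if (is.na(ip)) stop("malformed VTK file (no POINTS): ", path, call. = FALSE)
    n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
    # one point per line, as written by write_mesh
    coords <- as.numeric(unlist(strsplit(trimws(lines[(ip + 1):(ip + n)]),
                                         "\\s+")))
    if (length(coords) != 3 * n || anyNA(coords))
      stop("malformed VTK POINTS block in ", path, call. = FALSE)
    v <- matrix(coords, ncol = 3, byrow = TRUE)
    ipoly <- grep("^POLYGONS", lines)[1]
    m <- as.integer(strsplit(lines[ipoly], "\\s+")[[1]][2])
    f <- .read_face_rows(lines[(ipoly + 1):(ipoly + m)], path)
    region <- NULL
    fields <- list()
    isc <- grep("^SCALARS", lines)
    for (i in isc) {
      nm <- strsplit(lines[i], "\\s+")[[1]][2]
      vals <- as.numeric(lines[(i + 2):(i + 1 + n)])
      if (nm == "region") region <- as.integer(vals) else fields[[nm]] <- vals
    }
    mesh <- new_surface_mesh(v, f, region = region)
    if (length(fields)) attr(mesh, "fields") <- fields
    return(mesh)
  }
  stop("unknown mesh format: .", ext, " (expected off, ply or vtk)",
       call. = FALSE)
}
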