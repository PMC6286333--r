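#' Read a PLY point cloud
#'
#' Supports `ascii` and `binary_little_endian` PLY with a vertex element
#' carrying float/double properties `x`, `y`, `z` (mandatory, mm) and
#' optionally `nx`, `ny`, `nz`. Other elements and properties are skipped for
#' ASCII files; binary files may only contain the vertex element.
#'
#' @param path file path.
#' @param stage_tag stage tag to attach.
#' @return a `point_cloud`.
#' @export
read_ply <- function(path, stage_tag = "P0") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()     # name -> count
  props <- list()        # element name -> data.frame(type, name)
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L) next
    switch(tok[1],
      format = { fmt <- tok[2] },
      comment = NULL,
      element = {
        cur <- tok[2]
        elements[[cur]] <- as.integer(tok[3])
        props[[cur]] <- data.frame(type = character(), name = character())
      },
      property = {
        if (identical(tok[2], "list")) {
          props[[cur]] <- rbind(props[[cur]],
                                data.frame(type = "list", name = tok[5]))
        } else {
          props[[cur]] <- rbind(props[[cur]],
                                data.frame(type = tok[2], name = tok[3]))
        }
      },
      end_header = break,
      NULL)
  }
  if (is.null(elements$vertex)) stop("PLY file has no vertex element")
  vp <- props$vertex
  if (!all(c("x", "y", "z") %in% vp$name))
    stop("PLY vertex element must carry x, y, z")
  nv <- elements$vertex

  if (identical(fmt, "ascii")) {
    rows <- readLines(con)
    rows <- rows[nzchar(trimws(rows))]
    # vertex element is first by construction of our writers; general files
    # may order elements as declared — honour declaration order
    first <- names(elements)[1]
    if (!identical(first, "vertex"))
      stop("ASCII PLY with vertex not first is unsupported")
    vals <- strsplit(trimws(rows[seq_len(nv)]), "\\s+")
    m <- matrix(as.numeric(unlist(vals)), nrow = nv, byrow = TRUE)
    colnames(m) <- vp$name[seq_len(ncol(m))]
  } else if (identical(fmt, "binary_little_endian")) {
    sizes <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
               int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
               float = 4, float32 = 4, double = 8, float64 = 8)
    if (any(vp$type == "list")) stop("list properties unsupported in binary PLY")
    nprop <- nrow(vp)
    if (!all(vp$type %in% c("float", "float32", "double", "float64")))
      stop("binary PLY vertex properties must be float or double")
    if (length(unique(sizes[vp$type])) == 1L) {
      sz <- sizes[[vp$type[1]]]
      raw <- readBin(con, "double", n = nv * nprop, size = sz,
                     endian = "little")
      m <- matrix(raw, nrow = nv, byrow = TRUE)
    } else {
      m <- matrix(0, nv, nprop)
      for (i in seq_len(nv)) for (j in seq_len(nprop))
        m[i, j] <- readBin(con, "double", 1, size = sizes[[vp$type[j]]],
                           endian = "little")
    }
    colnames(m) <- vp$name
  } else stop("unsupported PLY format: ", fmt)

  pts <- m[, c("x", "y", "z"), drop = FALSE]
  normals <- NULL
  if (all(c("nx", "ny", "nz") %in% colnames(m))) {
    normals <- m[, c("nx", "ny", "nz"), drop = FALSE]
    len <- sqrt(rowSums(normals^2))
    len[len == 0] <- 1
    normals <- normals / len
  }
  point_cloud(pts, normals = normals, stage_tag = stage_tag)
}

#' Write a PLY point cloud
#'
#' @param cloud a `point_cloud`.
#' @param path output file path.
#' @param binary write `binary_little_endian` (default) or `ascii`.
#' @param scalar optional numeric per-vertex scalar (written as property
#'   `quality`), e.g. colormap deviations.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, binary = FALSE, scalar = NULL) {
  pts <- cloud$points
  n <- nrow(pts)
  cols <- pts
  names <- c("x", "y", "z")
  if (!is.null(cloud$normals)) {
    cols <- cbind(cols, cloud$normals)
    names <- c(names, "nx", "ny", "nz")
  }
  if (!is.null(scalar)) {
    stopifnot(length(scalar) == n)
    s <- as.numeric(scalar)
    s[!is.finite(s)] <- -1   # sentinel for gated/missing deviations
    cols <- cbind(cols, s)
    names <- c(names, "quality")
  }
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", n),
           sprintf("property double %s", names),
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (binary) {
    writeBin(as.vector(t(cols)), con, size = 8, endian = "little")
  } else {
    writeLines(apply(cols, 1, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a PCD point cloud
#'
#' Supports ASCII and `binary` PCD v0.7 with FIELDS including `x y z` and
#' optionally `normal_x normal_y normal_z`, all of TYPE F.
#'
#' @param path file path.
#' @param stage_tag stage tag to attach.
#' @return a `point_cloud`.
#' @export
read_pcd <- function(path, stage_tag = "P0") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PCD header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || startsWith(tok[1], "#")) next
    hdr[[tok[1]]] <- tok[-1]
    if (tok[1] == "DATA") break
  }
  fields <- hdr$FIELDS
  if (!all(c("x", "y", "z") %in% fields)) stop("PCD must carry x, y, z fields")
  npts <- as.integer(hdr$POINTS[1])
  sizes <- as.integer(hdr$SIZE)
  mode <- hdr$DATA[1]
  nf <- length(fields)
  if (identical(mode, "ascii")) {
    rows <- readLines(con)
    rows <- rows[nzchar(trimws(rows))]
    vals <- strsplit(trimws(rows[seq_len(npts)]), "\\s+")
    m <- matrix(as.numeric(unlist(vals)), nrow = npts, byrow = TRUE)
  } else if (identical(mode, "binary")) {
    if (length(unique(sizes)) != 1L)
      stop("mixed field sizes unsupported in binary PCD")
    m <- matrix(readBin(con, "double", n = npts * nf, size = sizes[1],
                        endian = "little"),
                nrow = npts, byrow = TRUE)
  } else stop("unsupported PCD DATA mode: ", mode)
  colnames(m) <- fields
  normals <- NULL
  if (all(c("normal_x", "normal_y", "normal_z") %in% fields)) {
    normals <- m[, c("normal_x", "normal_y", "normal_z"), drop = FALSE]
    len <- sqrt(rowSums(normals^2))
    len[len == 0] <- 1
    normals <- normals / len
  }
  point_cloud(m[, c("x", "y", "z"), drop = FALSE], normals = normals,
              stage_tag = stage_tag)
}

#' Write a PCD point cloud (ASCII)
#'
#' @param cloud a `point_cloud`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pcd <- function(cloud, path) {
  n <- n_points(cloud)
  have_n <- !is.null(cloud$normals)
  fields <- if (have_n) "x y z normal_x normal_y normal_z" else "x y z"
  nf <- if (have_n) 6L else 3L
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7",
           paste("FIELDS", fields),
           paste("SIZE", paste(rep(8, nf), collapse = " ")),
           paste("TYPE", paste(rep("F", nf), collapse = " ")),
           paste("COUNT", paste(rep(1, nf), collapse = " ")),
           sprintf("WIDTH %d", n),
           "HEIGHT 1",
           "VIEWPOINT 0 0 0 1 0 0 0",
           sprintf("POINTS %d", n),
           "DATA ascii")
  cols <- if (have_n) cbind(cloud$points, cloud$normals) else cloud$points
  body <- apply(cols, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a binary image as PGM (debug dump of projection images)
#'
#' @param pixels logical or 0/1 matrix (rows = x bins, columns = y bins).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(pixels, path) {
  m <- t(pixels) * 1L
  lines <- c("P2", sprintf("%d %d", ncol(m), nrow(m)), "1",
             apply(m, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
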