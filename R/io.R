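#' Write a mesh to STL
#'
#' @param mesh a \code{triangle_mesh}.
#' @param path output path.
#' @param binary write binary STL (default) or ASCII.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    tri <- matrix(0, nrow(f), 12)
    tri[, 1:3] <- n
    tri[, 4:6] <- v[f[, 1], , drop = FALSE]
    tri[, 7:9] <- v[f[, 2], , drop = FALSE]
    tri[, 10:12] <- v[f[, 3], , drop = FALSE]
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(tri[i, ]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", n[i, 1], n[i, 2], n[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e",
                v[f[i, 1:3], 1], v[f[i, 1:3], 2], v[f[i, 1:3], 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII, auto-detected)
#'
#' STL stores independent triangles; coincident vertices are merged back
#' into a shared vertex table (exact coordinate match).
#'
#' @param path STL path.
#' @return A \code{triangle_mesh}.
#' @export
read_stl <- function(path) {
  head <- readBin(path, "raw", n = 5)
  is_ascii <- identical(rawToChar(head), "solid") && {
    # binary STLs may also start with "solid": check that the size matches
    sz <- file.info(path)$size
    nb <- tryCatch({
      con <- file(path, "rb"); on.exit(close(con))
      invisible(readBin(con, "raw", 80))
      readBin(con, "integer", 1, size = 4, endian = "little")
    }, error = function(e) -1)
    sz != 84 + 50 * nb
  }
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    coords <- matrix(0, 3 * nf, 3)
    for (i in seq_len(nf)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      invisible(readBin(con, "raw", 2))
      coords[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  }
  key <- apply(coords, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

#' Write a mesh to ASCII PLY
#' @param mesh a \code{triangle_mesh}.
#' @param path output path.
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9e %.9e %.9e", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY file
#' @param path PLY path.
#' @return A \code{triangle_mesh}.
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("read_ply: no end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vl <- lines[(endh + 1):(endh + nv)]
  fl <- lines[(endh + nv + 1):(endh + nv + nf)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x)
    as.integer(x[2:4]) + 1L))
  triangle_mesh(verts, faces)
}

#' Write a voxel image as MetaImage (.mhd + .raw)
#'
#' @param img a \code{voxel_image}.
#' @param path path to the .mhd header; the .raw sits next to it.
#' @export
write_mhd <- function(img, path) {
  stopifnot(inherits(img, "voxel_image"))
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  writeLines(c(
    "ObjectType = Image", "NDims = 3", "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %s", paste(dim(img$values), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(img$spacing, collapse = " ")),
    sprintf("Offset = %s", paste(img$origin, collapse = " ")),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", raw_name)), path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.numeric(img$values), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a MetaImage (.mhd + .raw) voxel image
#' @param path path to the .mhd header.
#' @return A \code{voxel_image}.
#' @export
read_mhd <- function(path) {
  hdr <- readLines(path, warn = FALSE)
  get <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)[1]
    trimws(sub("^[^=]*=", "", ln))
  }
  dims <- as.integer(strsplit(get("DimSize"), " +")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), " +")[[1]])
  origin <- as.numeric(strsplit(get("Offset"), " +")[[1]])
  etype <- get("ElementType")
  size <- switch(etype, MET_DOUBLE = 8, MET_FLOAT = 4,
                 stop("read_mhd: unsupported ElementType ", etype))
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  vals <- readBin(raw_path, "numeric", prod(dims), size = size,
                  endian = "little")
  voxel_image(array(vals, dims), spacing = spacing, origin = origin)
}
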