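#' Triangulated surface meshes
#'
#' A `perigyri_mesh` is a minimal triangle-mesh container: an `n x 3` numeric
#' matrix of vertex coordinates in millimetres and an `m x 3` integer matrix of
#' 1-based vertex indices, one row per triangle. Meshes destined for the
#' gyrification index must be closed (every edge shared by exactly two faces)
#' and consistently outward oriented; orientation is checked via the signed
#' volume and flipped with a warning when negative.
#'
#' @param vertices numeric matrix, `n x 3`, vertex coordinates (mm).
#' @param faces integer matrix, `m x 3`, 1-based vertex indices per triangle.
#' @param validate logical; check index ranges and reject degenerate faces.
#' @return An object of class `perigyri_mesh`.
#' @examples
#' m <- cube_mesh()
#' mesh_surface_area(m)
#' @export
mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("'vertices' must have 3 columns")
  if (ncol(faces) != 3L) stop("'faces' must have 3 columns")
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "perigyri_mesh")
  if (validate) {
    if (anyNA(vertices) || any(!is.finite(vertices)))
      stop("non-finite vertex coordinates")
    if (nrow(faces) > 0L) {
      rng <- range(faces)
      if (rng[1] < 1L || rng[2] > nrow(vertices))
        stop("face index out of range: vertices are 1..", nrow(vertices),
             " but faces reference ", rng[1], "..", rng[2])
      a <- triangle_areas(m)
      bad <- which(a < 1e-12)
      if (length(bad))
        stop("degenerate (zero-area) faces at rows: ",
             paste(head(bad, 10L), collapse = ", "))
    }
  }
  m
}

#' @export
print.perigyri_mesh <- function(x, ...) {
  cat("Triangulated mesh: ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  closed <- tryCatch(length(boundary_edges(x)) == 0L, error = function(e) NA)
  cat("  closed: ", closed, "\n", sep = "")
  invisible(x)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Directed-edge bookkeeping; returns character keys "i-j" of boundary
# (unpaired) undirected edges.
boundary_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "-")
  tab <- table(key)
  names(tab)[tab != 2L]
}

mesh_is_closed <- function(mesh) length(boundary_edges(mesh)) == 0L

signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

# Ensure outward orientation (positive signed volume) for closed meshes,
# flipping with a warning when needed.
orient_mesh <- function(mesh) {
  sv <- signed_volume(mesh)
  if (sv < 0) {
    warning("mesh orientation was inward (negative signed volume); flipping",
            call. = FALSE)
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  }
  mesh
}

#' Built-in fixture meshes
#'
#' `cube_mesh()` is the unit cube (12 triangles, area 6, volume 1);
#' `tetrahedron_mesh()` a regular tetrahedron with unit edge;
#' `icosphere()` a geodesic sphere obtained by subdividing an icosahedron
#' `subdivision` times and projecting onto the sphere of radius `radius`.
#'
#' @param subdivision non-negative integer; each level quadruples the faces.
#' @param radius sphere radius (mm).
#' @return A `perigyri_mesh`.
#' @export
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  orient_mesh(mesh(v, f))
}

#' @rdname cube_mesh
#' @export
tetrahedron_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(8)
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  orient_mesh(mesh(v, f))
}

#' @rdname cube_mesh
#' @export
icosphere <- function(subdivision = 3, radius = 1) {
  stopifnot(subdivision >= 0, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivision)) {
    nv <- nrow(v)
    edge_id <- new.env(hash = TRUE, parent = emptyenv())
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_id[[key]]
      if (!is.null(id)) return(id)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      id <- nrow(v)
      edge_id[[key]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    r <- 0L
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- mid(a, b); bc <- mid(b, cc); ca <- mid(cc, a)
      nf[r + 1L, ] <- c(a, ab, ca)
      nf[r + 2L, ] <- c(b, bc, ab)
      nf[r + 3L, ] <- c(cc, ca, bc)
      nf[r + 4L, ] <- c(ab, bc, ca)
      r <- r + 4L
    }
    f <- nf
  }
  orient_mesh(mesh(v * radius, f))
}

#' Read and write surface meshes (OFF and PLY)
#'
#' Readers validate indices and reject degenerate faces; `read_mesh` dispatches
#' on the file extension. PLY support covers ASCII and binary-little-endian
#' files with vertex positions and triangular faces. Writers emit OFF or, for
#' PLY, either `"ascii"` or `"binary_little_endian"` format.
#'
#' @param path file path ending in `.off` or `.ply`.
#' @param mesh a `perigyri_mesh`.
#' @param format PLY encoding for `write_ply`.
#' @return `read_*` return a `perigyri_mesh`; writers return `path` invisibly.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         off = read_off(path),
         ply = read_ply(path),
         stop("unsupported mesh format: .", ext))
}

#' @rdname read_mesh
#' @export
read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!identical(toupper(lines[1]), "OFF")) stop("not an OFF file: ", path)
  toks <- scan(text = paste(lines[-1], collapse = "\n"), quiet = TRUE)
  nv <- as.integer(toks[1]); nf <- as.integer(toks[2])
  pos <- 4L  # skip nv nf ne
  v <- matrix(toks[pos:(pos + 3L * nv - 1L)], nv, 3L, byrow = TRUE)
  pos <- pos + 3L * nv
  f <- matrix(NA_integer_, nf, 3L)
  for (i in seq_len(nf)) {
    k <- as.integer(toks[pos])
    if (k != 3L) stop("non-triangular face in OFF file (row ", i, ")")
    f[i, ] <- as.integer(toks[(pos + 1L):(pos + 3L)]) + 1L
    pos <- pos + k + 1L
  }
  mesh(v, f)
}

#' @rdname read_mesh
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(format(mesh$vertices, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  f0 <- mesh$faces - 1L
  writeLines(sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3]), con)
  invisible(path)
}

#' @rdname read_mesh
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_hdr_line <- function() {
    chars <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("unexpected end of PLY header")
      if (ch == "\n") break
      chars <- c(chars, ch)
    }
    sub("\r$", "", paste(chars, collapse = ""))
  }
  if (read_hdr_line() != "ply") stop("not a PLY file: ", path)
  fmt <- NULL; nv <- NA_integer_; nf <- NA_integer_
  vprops <- character(0); in_vertex <- FALSE
  repeat {
    l <- read_hdr_line()
    t <- strsplit(trimws(l), "\\s+")[[1]]
    if (!length(t)) next
    if (t[1] == "comment") next
    if (t[1] == "format") fmt <- t[2]
    if (t[1] == "element") {
      in_vertex <- t[2] == "vertex"
      if (t[2] == "vertex") nv <- as.integer(t[3])
      if (t[2] == "face") nf <- as.integer(t[3])
    }
    if (t[1] == "property" && in_vertex && t[2] != "list")
      vprops <- c(vprops, t[3])
    if (t[1] == "end_header") break
  }
  if (is.na(nv) || is.na(nf)) stop("PLY header missing vertex or face element")
  ix <- match(c("x", "y", "z"), vprops)
  if (anyNA(ix)) stop("PLY vertex element lacks x/y/z properties")
  np <- length(vprops)
  if (identical(fmt, "ascii")) {
    rest <- readLines(con, warn = FALSE)
    rest <- trimws(rest)
    rest <- rest[nzchar(rest)]
    vt <- scan(text = paste(rest[seq_len(nv)], collapse = "\n"), quiet = TRUE)
    v <- matrix(vt, nv, np, byrow = TRUE)[, ix, drop = FALSE]
    f <- matrix(NA_integer_, nf, 3L)
    for (i in seq_len(nf)) {
      t <- as.integer(strsplit(rest[nv + i], "\\s+")[[1]])
      if (t[1] != 3L) stop("non-triangular PLY face (row ", i, ")")
      f[i, ] <- t[2:4] + 1L
    }
  } else if (identical(fmt, "binary_little_endian")) {
    raw_v <- readBin(con, "numeric", n = nv * np, size = 4L,
                     endian = "little")
    v <- matrix(raw_v, nv, np, byrow = TRUE)[, ix, drop = FALSE]
    f <- matrix(NA_integer_, nf, 3L)
    for (i in seq_len(nf)) {
      k <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
      if (k != 3L) stop("non-triangular PLY face (row ", i, ")")
      f[i, ] <- readBin(con, "integer", 3L, size = 4L, endian = "little") + 1L
    }
  } else stop("unsupported PLY format: ", fmt %||% "<missing>")
  mesh(v, f)
}

#' @rdname read_mesh
#' @export
write_ply <- function(mesh, path,
                      format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  v <- mesh$vertices; f0 <- mesh$faces - 1L
  hdr <- c("ply", paste("format", format, "1.0"),
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(f0)),
           "property list uchar int vertex_indices", "end_header")
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(format(v, digits = 9, trim = TRUE, scientific = FALSE),
                     1, paste, collapse = " "), con)
    writeLines(sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3]), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(as.numeric(t(v)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f0))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}
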