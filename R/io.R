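# Serialization: meshes (STL/OBJ), weights (JSON), windings (JSON/CSV),
# merit reports (JSON/CSV).

#' Write a mesh to ASCII STL or OBJ
#' @param mesh a \code{coil_mesh}
#' @param file output path; format chosen by extension (.stl or .obj)
#' @export
write_mesh <- function(mesh, file) {
  ext <- tolower(tools::file_ext(file))
  V <- mesh$vertices; Tr <- mesh$triangles
  if (ext == "stl") {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines("solid coil_support", con)
    for (t in seq_len(nrow(Tr))) {
      n <- mesh$normals[t, ]
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3) {
        v <- V[Tr[t, k], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid coil_support", con)
  } else if (ext == "obj") {
    lines <- c(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
               sprintf("f %d %d %d", Tr[, 1], Tr[, 2], Tr[, 3]))
    writeLines(lines, file)
  } else stop("unsupported mesh format: ", ext)
  invisible(file)
}

#' Read a mesh from ASCII STL or OBJ (vertex units: meters)
#' @param file path to a .stl or .obj file
#' @return a \code{coil_mesh}
#' @export
read_mesh <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "stl") {
    lines <- readLines(file)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
    # merge duplicate vertices
    key <- apply(round(xyz, 9), 1, paste, collapse = ",")
    uid <- !duplicated(key)
    V <- xyz[uid, , drop = FALSE]
    idx <- match(key, key[uid])
    Tr <- matrix(idx, ncol = 3, byrow = TRUE)
  } else if (ext == "obj") {
    lines <- readLines(file)
    vs <- strsplit(trimws(grep("^v ", lines, value = TRUE)), "\\s+")
    V <- do.call(rbind, lapply(vs, function(p) as.numeric(p[2:4])))
    fs <- strsplit(trimws(grep("^f ", lines, value = TRUE)), "\\s+")
    Tr <- do.call(rbind, lapply(fs, function(p) {
      as.integer(sub("/.*", "", p[2:4]))
    }))
  } else stop("unsupported mesh format: ", ext)
  finish_mesh(V, Tr, orient = "z")
}

mesh_hash <- function(mesh) {
  x <- c(as.vector(round(mesh$vertices, 9)), as.vector(mesh$triangles))
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(x, f)
  unname(tools::md5sum(f))
}

#' Write current weights to JSON
#' @param mesh the support mesh the weights refer to
#' @param lambda internal-node weights (A)
#' @param file output path
#' @export
write_weights <- function(mesh, lambda, file) {
  jsonlite::write_json(
    list(mesh_hash = mesh_hash(mesh),
         node_ids = mesh$internal_nodes,
         values = lambda),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read current weights from JSON
#' @param file path written by \code{\link{write_weights}}
#' @param mesh optional mesh to verify the stored hash against
#' @export
read_weights <- function(file, mesh = NULL) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!is.null(mesh) && !identical(mesh_hash(mesh), x$mesh_hash)) {
    stop("weights were computed on a different mesh (hash mismatch)")
  }
  x
}

#' Write a winding set to JSON
#' @param winding a \code{winding_set}
#' @param file output path
#' @export
write_winding <- function(winding, file) {
  jsonlite::write_json(
    list(wire_cross_section = winding$wire_cross_section,
         loops = lapply(winding$loops, function(l) {
           list(level_A = l$level, region = l$region,
                layer = l$layer %||% 0L, sense = l$sense %||% sign(l$level),
                path = unname(l$path))
         }),
         serial_path = if (!is.null(winding$serial_path)) {
           unname(winding$serial_path)
         }),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a winding set from JSON
#' @param file path written by \code{\link{write_winding}}
#' @export
read_winding <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  loops <- lapply(seq_len(length(x$loops$level_A)), function(i) {
    list(path = x$loops$path[[i]], level = x$loops$level_A[i],
         region = x$loops$region[i], layer = x$loops$layer[i],
         sense = x$loops$sense[i], basin = i)
  })
  new_winding_set(loops,
                  serial_path = x$serial_path,
                  wire_cross_section = x$wire_cross_section)
}

#' Write a merit report to JSON (with the depth-swept table as CSV alongside)
#' @param report a \code{merit_report}
#' @param file output JSON path; the swept curve goes to \code{*_swept.csv}
#' @export
write_report <- function(report, file) {
  jsonlite::write_json(
    list(V_m3 = report$V, d_m = report$d, S_m2 = report$S,
         W_J = report$W, drive_scale_A = report$drive_scale,
         peak_ratio = report$peak_ratio,
         scalp_area_m2 = report$scalp$area,
         scalp_peak_ratio = report$scalp$peak_ratio,
         electrical = report$electrical),
    file, auto_unbox = TRUE, digits = NA)
  csv <- sub("\\.json$", "_swept.csv", file)
  utils::write.csv(report$swept, csv, row.names = FALSE)
  invisible(file)
}
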