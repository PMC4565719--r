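# Mesh file IO (STL binary+ASCII, OBJ, PLY ASCII) and config-driven runners.
# Coordinates are interpreted as centimetres unless a unit scale is given.

#' Read a triangle mesh from STL, OBJ or PLY
#'
#' Format is chosen by file extension. STL may be binary or ASCII (detected);
#' PLY must be ASCII. STL files carry no connectivity, so coincident vertices
#' are merged on read to recover a watertight mesh.
#'
#' @param path file path.
#' @param scale multiply coordinates by this factor on read (e.g. 0.1 for a
#'   file in mm) so the in-memory mesh is in cm.
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path, scale = 1) {
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    "stl" = read_stl(path),
    "obj" = read_obj(path),
    "ply" = read_ply(path),
    stop("unsupported mesh format: .", ext)
  )
  if (scale != 1) mesh$vertices <- mesh$vertices * scale
  mesh
}

#' Write a triangle mesh to STL, OBJ or PLY
#'
#' @param mesh a [tri_mesh()].
#' @param path output path; extension selects the format.
#' @param binary for STL: write binary (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "tri_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "stl" = write_stl(mesh, path, binary = binary),
    "obj" = write_obj(mesh, path),
    "ply" = write_ply(mesh, path),
    stop("unsupported mesh format: .", ext)
  )
  invisible(path)
}

merge_vertices <- function(tri_soup) {
  # tri_soup: 3n x 3 matrix, triples of triangle corners
  key <- apply(round(tri_soup, 9), 1, paste, collapse = " ")
  uid <- !duplicated(key)
  v <- tri_soup[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  f <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_mesh(v, f)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  size <- file.info(path)$size
  if (length(ntri) == 1 && !is.na(ntri) && size == 84 + 50 * ntri) {
    tris <- matrix(0, 3 * ntri, 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      tris[3 * i - 2:0, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
    return(merge_vertices(tris))
  }
  # ASCII
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
  if (nrow(nums) %% 3 != 0) stop("malformed ASCII STL: vertex count not a multiple of 3")
  merge_vertices(nums)
}

write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  normal_of <- function(i) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c_ <- v[f[i, 3], ]
    n <- c(
      (b[2] - a[2]) * (c_[3] - a[3]) - (b[3] - a[3]) * (c_[2] - a[2]),
      (b[3] - a[3]) * (c_[1] - a[1]) - (b[1] - a[1]) * (c_[3] - a[3]),
      (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1])
    )
    nn <- sqrt(sum(n^2))
    if (nn > 0) n / nn else c(0, 0, 1)
  }
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      rec <- c(normal_of(i), t(v[f[i, ], ]))
      writeBin(as.numeric(rec), con, size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      n <- normal_of(i)
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]), con)
      writeLines("    outer loop", con)
      for (j in 1:3) {
        p <- v[f[i, j], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- as.integer(vapply(strsplit(x[-1], "/"), `[[`, character(1), 1))
    if (length(idx) != 3L) stop("read_obj supports triangle faces only")
    idx
  }))
  tri_mesh(v, f)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  f <- mesh$faces
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != "ply") stop("not a PLY file")
  if (!any(grepl("format ascii", lines))) stop("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  start <- which(lines == "end_header") + 1L
  vdat <- lines[start:(start + nv - 1L)]
  fdat <- lines[(start + nv):(start + nv + nf - 1L)]
  v <- do.call(rbind, lapply(strsplit(trimws(vdat), "\\s+"), function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(fdat), "\\s+"), function(x) {
    n <- as.integer(x[1])
    if (n != 3L) stop("read_ply supports triangle faces only")
    as.integer(x[2:4]) + 1L
  }))
  tri_mesh(v, f)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

provenance_block <- function(config) {
  list(
    tool = "osteomech",
    version = as.character(utils::packageVersion("osteomech")),
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Run a body-mass analysis from a configuration
#'
#' Orchestrates the mass pipeline: a toy-body or user-specified hoop body is
#' built, the outline sensitivity report computed, and per-segment plus
#' whole-body tables written as CSV (masses at 3 decimals, cm at 2) and JSON
#' with a provenance block.
#'
#' @param config list (or path to a YAML file) with optional entries
#'   `radial_scale`, `k_max`, `k_min`, `hoops_per_segment`, `out_csv`,
#'   `out_json`, and optionally `segment_table_csv` (a segment estimate table
#'   to combine directly instead of lofting the toy body).
#' @return The `body_mass_report` (or envelope data.frame), invisibly.
#' @export
run_mass <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  variant <- outline_variant(
    radial_scale = config$radial_scale %||% 1.2,
    k_max = config$k_max %||% octagon_k("ellipse-square"),
    k_min = config$k_min %||% octagon_k("ellipse-diamond")
  )
  if (!is.null(config$segment_table_csv)) {
    if (!file.exists(config$segment_table_csv)) {
      stop("segment table not found: ", config$segment_table_csv)
    }
    seg_tbl <- utils::read.csv(config$segment_table_csv, stringsAsFactors = FALSE)
    whole <- body_mass_envelope(seg_tbl)
    report <- structure(list(segments = seg_tbl, whole_body = whole),
      class = "body_mass_report")
  } else {
    body <- make_toy_body(hoops_per_segment = config$hoops_per_segment %||% 9)
    report <- sensitivity_report(body$segments, variant)
  }
  fmt <- function(d) {
    d$mass_kg <- round(d$mass_kg, 3)
    for (cc in intersect(c("x_cm", "y_cm", "z_cm"), names(d))) d[[cc]] <- round(d[[cc]], 2)
    d
  }
  if (!is.null(config$out_csv)) {
    utils::write.csv(rbind_fill_variant(fmt(report$segments), fmt(report$whole_body)),
      config$out_csv, row.names = FALSE)
  }
  if (!is.null(config$out_json)) {
    jsonlite::write_json(
      list(
        provenance = provenance_block(config),
        segments = report$segments, whole_body = report$whole_body
      ),
      config$out_json, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(report)
}

rbind_fill_variant <- function(segments, whole) {
  whole2 <- data.frame(
    segment = "WHOLE BODY", region = "whole", variant = whole$model,
    mass_kg = whole$mass_kg, x_cm = whole$x_cm, y_cm = whole$y_cm, z_cm = whole$z_cm,
    count = 1L
  )
  rbind(segments[, names(whole2)], whole2)
}

#' Run a joint-mobility analysis from a configuration
#'
#' Builds (or reads) the girdle/bone pair, sweeps the six rotation directions
#' over the configured joint spaces, and writes the mobility table as CSV
#' (one row per joint space, six direction columns, angles at 2 decimals)
#' with a provenance header, plus optional JSON.
#'
#' @param config list (or YAML path) with optional entries `girdle_mesh`,
#'   `bone_mesh` (mesh file paths; if absent a synthetic socket fixture is
#'   used), `fixture` (named parameters for [make_socket_joint()]),
#'   `increment`, `joint_spaces`, `limit_lar`, `limit_other`, `out_csv`,
#'   `out_json`. When meshes are read from file, `acs` (origin + axes) and
#'   `socket_center` must be given explicitly.
#' @return The `rom_result` data.frame, invisibly.
#' @export
run_rom <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- sweep_config(
    increment = config$increment %||% 0.5,
    limit_lar = config$limit_lar %||% 360,
    limit_other = config$limit_other %||% 180,
    joint_spaces = config$joint_spaces %||% seq(0, 2.5, by = 0.5)
  )
  if (!is.null(config$girdle_mesh)) {
    for (p in c(config$girdle_mesh, config$bone_mesh)) {
      if (!file.exists(p)) stop("mesh file not found: ", p)
    }
    girdle <- read_mesh(config$girdle_mesh, scale = config$unit_scale %||% 1)
    bone <- read_mesh(config$bone_mesh, scale = config$unit_scale %||% 1)
    if (is.null(config$acs) || is.null(config$socket_center)) {
      stop("acs and socket_center must be configured for mesh-file input")
    }
    acs <- joint_acs(
      as.numeric(config$acs$origin), as.numeric(config$acs$x),
      as.numeric(config$acs$y), as.numeric(config$acs$z)
    )
    socket_center <- as.numeric(config$socket_center)
  } else {
    fx <- do.call(make_socket_joint, config$fixture %||% list())
    girdle <- fx$girdle
    bone <- fx$bone
    acs <- fx$acs
    socket_center <- fx$socket_center
  }
  tbl <- rom_table(girdle, bone, acs, socket_center, cfg)
  if (!is.null(config$out_csv)) {
    con <- file(config$out_csv, "w")
    writeLines(sprintf(
      "# maximal mobility until bone-bone contact, degrees from reference pose; increment %.3g deg; LAR cw/ccw = -x/+x (right lateral view, cranial to the right)",
      cfg$increment
    ), con)
    out <- tbl
    for (cc in setdiff(names(out), c("joint_space_mm", "ref_collision"))) {
      out[[cc]] <- round(out[[cc]], 2)
    }
    utils::write.csv(out, con, row.names = FALSE)
    close(con)
  }
  if (!is.null(config$out_json)) {
    jsonlite::write_json(
      list(provenance = provenance_block(config), increment_deg = cfg$increment,
        table = tbl),
      config$out_json, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(tbl)
}

#' Run a retrodeformation from a configuration
#'
#' Applies rule 1 (restore triad orthogonality) and/or rule 2 (decompress to
#' a round section) to a mesh and writes the corrected mesh plus a JSON
#' transform report.
#'
#' @param config list (or YAML path) with entries `mesh` (file path) or
#'   `mesh_object` (a `tri_mesh`), optional `triad` (origin/e_rc/e_ll/e_dv),
#'   optional `section` (point/normal/lateral_dir), `out_mesh`, `out_json`.
#' @return List with `mesh`, `transforms`, invisibly.
#' @export
run_undistort <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mesh <- if (!is.null(config$mesh_object)) {
    config$mesh_object
  } else {
    if (is.null(config$mesh) || !file.exists(config$mesh)) {
      stop("input mesh not found: ", config$mesh %||% "<missing>")
    }
    read_mesh(config$mesh, scale = config$unit_scale %||% 1)
  }
  transforms <- list()
  if (!is.null(config$triad)) {
    tri <- config$triad
    distorted <- axis_triad(
      as.numeric(tri$origin %||% c(0, 0, 0)),
      as.numeric(tri$e_rc), as.numeric(tri$e_ll), as.numeric(tri$e_dv)
    )
    r1 <- restore_orthogonality(mesh, distorted)
    mesh <- r1$mesh
    transforms$rule1 <- r1$transform
  }
  scale2 <- NULL
  if (!is.null(config$section)) {
    sec <- config$section
    sr <- measure_roundness(
      mesh, as.numeric(sec$point), as.numeric(sec$normal),
      as.numeric(sec$lateral_dir)
    )
    r2 <- decompress_round(mesh, sr)
    mesh <- r2$mesh
    transforms$rule2 <- r2$transform
    scale2 <- r2$scale
  }
  if (!is.null(config$out_mesh)) write_mesh(mesh, config$out_mesh)
  if (!is.null(config$out_json)) {
    tr_list <- lapply(transforms, function(t) {
      list(linear = t$linear, translation = t$translation)
    })
    jsonlite::write_json(
      list(provenance = provenance_block(config), transforms = tr_list,
        rule2_scale = scale2),
      config$out_json, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(list(mesh = mesh, transforms = transforms))
}
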