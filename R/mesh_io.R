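# Mesh file exchange.
#
# MSH 4.1 (ASCII) with a documented physical-group naming convention:
#   volumes:  "extra", "intra_cell<k>"
#   surfaces: "outer", "electrode", "membrane_cell<k>_<REGION>"
# Coordinates in MSH files are micrometres (converted to the internal cm
# representation on read). The VTU writer emits ASCII XML unstructured
# grids with subdomain tags as cell data.

#' Write a tagged mesh to MSH 4.1
#'
#' @param mesh A `tagged_mesh`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msh <- function(mesh, path) {
  V <- cm_to_um(mesh$vertices)
  nv <- nrow(V)
  ncell <- max(0L, mesh$tet_sub)

  vol_names <- c("extra", if (ncell > 0) sprintf("intra_cell%d", seq_len(ncell)))
  mem_groups <- unique(data.frame(cell = mesh$membrane$cell,
                                  region = mesh$membrane$region))
  mem_groups <- mem_groups[order(mem_groups$cell, mem_groups$region), ,
                           drop = FALSE]
  surf_names <- c("outer",
                  if (any(mesh$boundary$label == "ELECTRODE")) "electrode",
                  if (nrow(mem_groups)) sprintf("membrane_cell%d_%s",
                                                mem_groups$cell,
                                                mem_groups$region))
  phys <- data.frame(dim = c(rep(2L, length(surf_names)),
                             rep(3L, length(vol_names))),
                     tag = seq_len(length(surf_names) + length(vol_names)),
                     name = c(surf_names, vol_names))

  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames"); w("%d", nrow(phys))
  for (k in seq_len(nrow(phys))) w('%d %d "%s"', phys$dim[k], phys$tag[k], phys$name[k])
  w("$EndPhysicalNames")

  nsurf <- length(surf_names); nvol <- length(vol_names)
  bb <- apply(V, 2, range)
  w("$Entities"); w("0 0 %d %d", nsurf, nvol)
  for (k in seq_len(nsurf)) {
    w("%d %.17g %.17g %.17g %.17g %.17g %.17g 1 %d 0", k,
      bb[1, 1], bb[1, 2], bb[1, 3], bb[2, 1], bb[2, 2], bb[2, 3],
      phys$tag[phys$name == surf_names[k]])
  }
  for (k in seq_len(nvol)) {
    w("%d %.17g %.17g %.17g %.17g %.17g %.17g 1 %d 0", k,
      bb[1, 1], bb[1, 2], bb[1, 3], bb[2, 1], bb[2, 2], bb[2, 3],
      phys$tag[phys$name == vol_names[k]])
  }
  w("$EndEntities")

  w("$Nodes"); w("1 %d 1 %d", nv, nv)
  w("3 1 0 %d", nv)
  writeLines(as.character(seq_len(nv)), con)
  writeLines(sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), con)
  w("$EndNodes")

  blocks <- list()
  # surface blocks
  out_sel <- mesh$boundary$label == "OUTER"
  blocks[[length(blocks) + 1L]] <- list(dim = 2L, etag = 1L, etype = 2L,
                                        conn = mesh$boundary$verts[out_sel, , drop = FALSE])
  etag <- 2L
  if (any(mesh$boundary$label == "ELECTRODE")) {
    blocks[[length(blocks) + 1L]] <- list(dim = 2L, etag = etag, etype = 2L,
                                          conn = mesh$boundary$verts[!out_sel, , drop = FALSE])
    etag <- etag + 1L
  }
  if (nrow(mem_groups)) {
    for (k in seq_len(nrow(mem_groups))) {
      sel <- mesh$membrane$cell == mem_groups$cell[k] &
        mesh$membrane$region == mem_groups$region[k]
      blocks[[length(blocks) + 1L]] <- list(dim = 2L, etag = etag, etype = 2L,
                                            conn = mesh$membrane$verts[sel, , drop = FALSE])
      etag <- etag + 1L
    }
  }
  for (k in seq_along(vol_names)) {
    sel <- mesh$tet_sub == (k - 1L)
    blocks[[length(blocks) + 1L]] <- list(dim = 3L, etag = k, etype = 4L,
                                          conn = mesh$tets[sel, , drop = FALSE])
  }
  ne <- sum(vapply(blocks, function(b) nrow(b$conn), 0L))
  w("$Elements"); w("%d %d 1 %d", length(blocks), ne, ne)
  eid <- 1L
  for (b in blocks) {
    w("%d %d %d %d", b$dim, b$etag, b$etype, nrow(b$conn))
    if (nrow(b$conn)) {
      ids <- seq.int(eid, length.out = nrow(b$conn))
      writeLines(paste(ids, apply(b$conn, 1, paste, collapse = " ")), con)
      eid <- eid + nrow(b$conn)
    }
  }
  w("$EndElements")
  invisible(path)
}

msh_section <- function(lines, name) {
  i0 <- which(lines == paste0("$", name))
  i1 <- which(lines == paste0("$End", name))
  if (length(i0) != 1L || length(i1) != 1L || i1 <= i0) {
    stop("malformed MSH file: missing section $", name)
  }
  lines[(i0 + 1L):(i1 - 1L)]
}

split_nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])

#' Read a tagged mesh from an MSH 4.1 file
#'
#' Expects ASCII MSH 4.1 with coordinates in micrometres and physical
#' groups following the naming convention `extra`, `intra_cell<k>`,
#' `outer`, `electrode`, `membrane_cell<k>_<REGION>`. The mandatory groups
#' are `extra` and `outer`. The reconstructed mesh is validated against
#' all structural invariants (conforming interface, closed membranes,
#' boundary adjacency); violations raise descriptive errors.
#'
#' @param path Path to the MSH file.
#' @return A `tagged_mesh`.
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  fmt <- split_nums(msh_section(lines, "MeshFormat")[1])
  if (fmt[1] < 4.1 - 1e-9 || fmt[2] != 0) {
    stop("only ASCII MSH 4.1 is supported (got version ", fmt[1], ")")
  }

  pn <- msh_section(lines, "PhysicalNames")
  npn <- as.integer(pn[1])
  phys <- data.frame(dim = integer(npn), tag = integer(npn),
                     name = character(npn))
  for (k in seq_len(npn)) {
    parts <- strsplit(trimws(pn[k + 1L]), "\\s+")[[1]]
    phys$dim[k] <- as.integer(parts[1])
    phys$tag[k] <- as.integer(parts[2])
    phys$name[k] <- gsub('"', "", paste(parts[-(1:2)], collapse = " "))
  }

  en <- msh_section(lines, "Entities")
  cnt <- split_nums(en[1])
  ent_phys <- list()  # key "dim:tag" -> physical tag
  row <- 2L
  for (k in seq_len(cnt[1])) {            # points: tag x y z nPhys phys...
    row <- row + 1L
  }
  for (d in 1:3) {
    for (k in seq_len(cnt[d + 1])) {
      v <- split_nums(en[row])
      npt <- v[8]
      if (npt >= 1) ent_phys[[paste(d, v[1], sep = ":")]] <- as.integer(v[9])
      row <- row + 1L
    }
  }

  nd <- msh_section(lines, "Nodes")
  hdr <- split_nums(nd[1])
  nblocks <- hdr[1]; nnodes <- hdr[2]; maxtag <- hdr[4]
  coord <- matrix(NA_real_, maxtag, 3)
  row <- 2L
  for (b in seq_len(nblocks)) {
    bh <- split_nums(nd[row]); nb <- bh[4]; row <- row + 1L
    tags <- as.integer(nd[row:(row + nb - 1L)]); row <- row + nb
    for (k in seq_len(nb)) {
      coord[tags[k], ] <- split_nums(nd[row])[1:3]
      row <- row + 1L
    }
  }

  el <- msh_section(lines, "Elements")
  hdr <- split_nums(el[1]); nblocks <- hdr[1]
  row <- 2L
  tris <- list(); tri_name <- character(0)
  tets <- list(); tet_name <- character(0)
  for (b in seq_len(nblocks)) {
    bh <- split_nums(el[row]); row <- row + 1L
    dim <- bh[1]; etag <- bh[2]; etype <- bh[3]; nb <- bh[4]
    ptag <- ent_phys[[paste(dim, etag, sep = ":")]]
    pname <- if (!is.null(ptag)) phys$name[phys$dim == dim & phys$tag == ptag] else NA
    conn <- matrix(NA_integer_, nb, if (etype == 2L) 3L else 4L)
    for (k in seq_len(nb)) {
      v <- split_nums(el[row]); row <- row + 1L
      conn[k, ] <- as.integer(v[-1])
    }
    if (etype == 2L) {
      tris[[length(tris) + 1L]] <- conn; tri_name <- c(tri_name, pname)
    } else if (etype == 4L) {
      tets[[length(tets) + 1L]] <- conn; tet_name <- c(tet_name, pname)
    } else {
      stop("unsupported element type ", etype, " (only triangles and tetrahedra)")
    }
  }

  known_vol <- grepl("^(extra|intra_cell[0-9]+)$", tet_name)
  known_surf <- grepl("^(outer|electrode|membrane_cell[0-9]+_[A-Z_0-9]+)$", tri_name)
  unknown <- c(tet_name[!known_vol], tri_name[!known_surf])
  if (length(unknown)) {
    stop("unknown physical group name(s): ", paste(unique(unknown), collapse = ", "))
  }
  for (must in c("extra", "outer")) {
    if (!must %in% c(tet_name, tri_name)) {
      stop("MSH file is missing the mandatory physical group \"", must, "\"")
    }
  }

  used <- sort(unique(c(unlist(tets), unlist(tris))))
  remap <- integer(nrow(coord)); remap[used] <- seq_along(used)
  vertices <- um_to_cm(coord[used, , drop = FALSE])

  T <- do.call(rbind, tets)
  T <- matrix(remap[T], ncol = 4L)
  tet_sub <- unlist(lapply(seq_along(tets), function(k) {
    s <- if (tet_name[k] == "extra") 0L else
      as.integer(sub("^intra_cell", "", tet_name[k]))
    rep(s, nrow(tets[[k]]))
  }))
  vol6 <- tet_signed_volumes(vertices, T)
  neg <- vol6 < 0
  if (any(neg)) T[neg, c(3, 4)] <- T[neg, c(4, 3)]

  # match labelled triangles to tet faces
  faces <- rbind(T[, c(2, 3, 4)], T[, c(1, 3, 4)], T[, c(1, 2, 4)], T[, c(1, 2, 3)])
  ftet <- rep.int(seq_len(nrow(T)), 4L)
  fkey <- face_key(faces)
  mem_v <- NULL; mem_cell <- integer(0); mem_region <- character(0)
  mem_intra <- integer(0); mem_extra <- integer(0)
  bnd_v <- NULL; bnd_lab <- character(0); bnd_tet <- integer(0)
  all_q <- unlist(lapply(tris, function(tk) face_key(matrix(remap[tk], ncol = 3L))))
  keep <- fkey %in% all_q
  face_map <- split(ftet[keep], fkey[keep])
  for (k in seq_along(tris)) {
    tk <- matrix(remap[tris[[k]]], ncol = 3L)
    qk <- face_key(tk)
    for (r in seq_len(nrow(tk))) {
      inc <- face_map[[qk[r]]] %||% integer(0)
      nm <- tri_name[k]
      if (startsWith(nm, "membrane_cell")) {
        if (length(inc) != 2L) {
          stop(sprintf("membrane facet (%s) not shared by exactly two tetrahedra", nm))
        }
        s <- tet_sub[inc]
        if (sum(s == 0L) != 1L) {
          stop("non-conforming interface: membrane facet not between intra- and extracellular tets")
        }
        m <- regmatches(nm, regexec("^membrane_cell([0-9]+)_([A-Z_0-9]+)$", nm))[[1]]
        mem_v <- rbind(mem_v, sort(tk[r, ]))
        mem_cell <- c(mem_cell, as.integer(m[2]))
        mem_region <- c(mem_region, m[3])
        mem_intra <- c(mem_intra, inc[s != 0L])
        mem_extra <- c(mem_extra, inc[s == 0L])
      } else {
        if (length(inc) != 1L) {
          stop(sprintf("boundary facet (%s) must border exactly one tetrahedron", nm))
        }
        bnd_v <- rbind(bnd_v, sort(tk[r, ]))
        bnd_lab <- c(bnd_lab, toupper(nm))
        bnd_tet <- c(bnd_tet, inc)
      }
    }
  }

  mesh <- structure(list(
    vertices = vertices, tets = T, tet_sub = tet_sub,
    tet_region = rep(NA_character_, nrow(T)),
    membrane = list(verts = mem_v %||% matrix(0L, 0, 3), cell = mem_cell,
                    region = mem_region, intra_tet = mem_intra,
                    extra_tet = mem_extra),
    boundary = list(verts = bnd_v %||% matrix(0L, 0, 3), label = bnd_lab,
                    tet = bnd_tet),
    grid = NULL, electrode = NULL, h_um = NA_real_), class = "tagged_mesh")
  if (any(bnd_lab == "ELECTRODE")) {
    sel <- bnd_lab == "ELECTRODE"
    ctr <- facet_centroids(mesh, mesh$boundary$verts[sel, , drop = FALSE])
    mesh$electrode <- list(center_cm = colMeans(ctr), radius_um = NA_real_,
                           area_cm2 = sum(triangle_areas(vertices,
                                                         mesh$boundary$verts[sel, , drop = FALSE])))
  }
  validate_tagged_mesh(mesh)
  mesh
}

face_key <- function(tri) {
  a <- pmin(tri[, 1], tri[, 2], tri[, 3])
  c_ <- pmax(tri[, 1], tri[, 2], tri[, 3])
  b <- tri[, 1] + tri[, 2] + tri[, 3] - a - c_
  paste(a, b, c_)
}

#' Write a mesh (and optional fields) to an ASCII VTU file
#'
#' @param mesh A `tagged_mesh`.
#' @param fields Named list of numeric vectors: length `nrow(vertices)`
#'   entries become point data, length `nrow(tets)` entries cell data.
#'   Subdomain tags are always included as cell data.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vtu <- function(mesh, fields = list(), path) {
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$tets)
  pd <- list(); cd <- list(subdomain = mesh$tet_sub)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (length(f) == nv) {
      pd[[nm]] <- f
    } else if (length(f) == nt) {
      cd[[nm]] <- f
    } else {
      stop(sprintf("field '%s' has length %d; expected %d (points) or %d (cells)",
                   nm, length(f), nv, nt))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  arr <- function(name, x, comps = 1L) {
    w('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
      name, comps)
    writeLines(paste(format(x, digits = 17, scientific = TRUE, trim = TRUE),
                     collapse = " "), con)
    w("</DataArray>")
  }
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w("<UnstructuredGrid>")
  w('<Piece NumberOfPoints="%d" NumberOfCells="%d">', nv, nt)
  w("<Points>")
  arr("Points", as.vector(t(mesh$vertices)), comps = 3L)
  w("</Points>")
  w("<Cells>")
  w('<DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(paste(as.vector(t(mesh$tets)) - 1L, collapse = " "), con)
  w("</DataArray>")
  w('<DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(nt) * 4L, collapse = " "), con)
  w("</DataArray>")
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(10L, nt), collapse = " "), con)
  w("</DataArray>")
  w("</Cells>")
  if (length(pd)) {
    w("<PointData>")
    for (nm in names(pd)) arr(nm, pd[[nm]])
    w("</PointData>")
  }
  w("<CellData>")
  for (nm in names(cd)) arr(nm, cd[[nm]])
  w("</CellData>")
  w("</Piece>")
  w("</UnstructuredGrid>")
  w("</VTKFile>")
  invisible(path)
}
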