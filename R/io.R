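#' Write a mesh (with fields) as VTK unstructured grid (VTU)
#'
#' ASCII XML VTU with quad cells; nodal fields go to `PointData`,
#' per-element fields to `CellData`. Suitable for ParaView.
#'
#' @param mesh an [npwt_mesh()].
#' @param file output path.
#' @param point_data named list of numeric vectors (n) or matrices
#'   (n x k) of nodal values.
#' @param cell_data named list of numeric vectors (ne) of element values.
#' @return the file path, invisibly.
#' @export
write_vtu <- function(mesh, file, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  num <- function(x) paste(formatC(x, format = "g", digits = 9),
                           collapse = " ")
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, ne))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(t(cbind(mesh$nodes, 0))))
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(t(mesh$elems) - 1L, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(4L * seq_len(ne), collapse = " "))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(9L, ne), collapse = " "))
  w('</DataArray>')
  w('</Cells>')
  w('<PointData>')
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    k <- if (is.matrix(v)) ncol(v) else 1L
    w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
              nm, k))
    w(num(if (is.matrix(v)) t(v) else v))
    w('</DataArray>')
  }
  w('</PointData>')
  w('<CellData>')
  reg <- as.integer(factor(mesh$region))
  w('<DataArray type="Int32" Name="region" format="ascii">')
  w(paste(reg, collapse = " "))
  w('</DataArray>')
  for (nm in names(cell_data)) {
    w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
    w(num(cell_data[[nm]]))
    w('</DataArray>')
  }
  w('</CellData>')
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  invisible(file)
}

#' Write a mesh in Gmsh MSH 2.2 (ASCII) format
#'
#' Quad elements carry a physical region id, boundary/interface facets a
#' physical line id; the id-to-name map is written as `$PhysicalNames`.
#'
#' @param mesh an [npwt_mesh()].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_msh <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  regs <- sort(unique(mesh$region))
  tags <- sort(unique(mesh$edges$tag))
  w("$MeshFormat"); w("2.2 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames")
  w(length(regs) + length(tags))
  for (i in seq_along(tags)) w(sprintf('1 %d "%s"', i, tags[i]))
  for (i in seq_along(regs))
    w(sprintf('2 %d "%s"', length(tags) + i, regs[i]))
  w("$EndPhysicalNames")
  w("$Nodes"); w(nrow(mesh$nodes))
  w(sprintf("%d %.17g %.17g 0", seq_len(nrow(mesh$nodes)),
            mesh$nodes[, 1], mesh$nodes[, 2]))
  w("$EndNodes")
  w("$Elements")
  nl <- nrow(mesh$edges); nq <- nrow(mesh$elems)
  w(nl + nq)
  ltag <- match(mesh$edges$tag, tags)
  w(sprintf("%d 1 2 %d %d %d %d", seq_len(nl), ltag, ltag,
            mesh$edges$n1, mesh$edges$n2))
  rtag <- length(tags) + match(mesh$region, regs)
  w(sprintf("%d 3 2 %d %d %d %d %d %d", nl + seq_len(nq), rtag, rtag,
            mesh$elems[, 1], mesh$elems[, 2], mesh$elems[, 3],
            mesh$elems[, 4]))
  w("$EndElements")
  invisible(file)
}

#' Read a mesh written by [write_msh()]
#'
#' @param file MSH 2.2 path.
#' @param axisymmetric interpretation of the coordinates.
#' @return an [npwt_mesh()].
#' @export
read_msh <- function(file, axisymmetric = TRUE) {
  ln <- readLines(file)
  sec <- function(name) {
    a <- which(ln == paste0("$", name)) + 1L
    b <- which(ln == paste0("$End", name)) - 1L
    ln[a:b]
  }
  pn <- sec("PhysicalNames")[-1]
  pp <- do.call(rbind, strsplit(pn, " "))
  pname <- gsub('"', "", pp[, 3])
  nd <- sec("Nodes")[-1]
  nm <- do.call(rbind, lapply(strsplit(nd, " "), as.numeric))
  nodes <- nm[order(nm[, 1]), 2:3, drop = FALSE]
  el <- sec("Elements")[-1]
  em <- strsplit(el, " ")
  typ <- vapply(em, function(x) as.integer(x[2]), 0L)
  phys <- vapply(em, function(x) as.integer(x[4]), 0L)
  lines_i <- typ == 1L
  quads_i <- typ == 3L
  edges <- do.call(rbind, lapply(em[lines_i], function(x)
    as.integer(x[6:7])))
  elems <- do.call(rbind, lapply(em[quads_i], function(x)
    as.integer(x[6:9])))
  # physical ids: lines were numbered 1..nt, surfaces nt+1..nt+nr
  isline <- pp[, 1] == "1"
  lmap <- setNames(pname[isline], pp[isline, 2])
  smap <- setNames(pname[!isline], pp[!isline, 2])
  npwt_mesh(nodes, elems, smap[as.character(phys[quads_i])],
            data.frame(n1 = edges[, 1], n2 = edges[, 2],
                       tag = unname(lmap[as.character(phys[lines_i])]),
                       stringsAsFactors = FALSE),
            axisymmetric = axisymmetric)
}

# plain-list serialisation of the classed parameter objects
.to_plain <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    out <- lapply(x, .to_plain)
    cl <- class(x)
    if (!identical(cl, "list")) out$.class <- cl
    out
  } else x
}

.from_plain <- function(x) {
  if (is.list(x)) {
    cl <- x$.class
    x$.class <- NULL
    out <- lapply(x, .from_plain)
    if (!is.null(cl)) class(out) <- unlist(cl)
    out
  } else x
}

#' Write / read a pipeline configuration as YAML
#'
#' The full [pipeline_config()] round-trips through YAML (numeric values
#' at 15 significant digits).
#'
#' @param config a `pipeline_config`.
#' @param file YAML path.
#' @return `write_config`: the path, invisibly; `read_config`: the
#'   reconstructed `pipeline_config`.
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(.to_plain(config), file, precision = 15)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  .from_plain(yaml::read_yaml(file))
}

# artefact dump for run_pipeline(output_dir = ...)
.write_report <- function(rep, mesh, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(f) file.path(config$output_dir, f)
  utils::write.csv(rep$deformation, od("deformation.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$oxygenation, od("oxygenation.csv"),
                   row.names = FALSE)
  write_config(config, od("config.yaml"))
  write_vtu(mesh, od("limb_mesh.vtu"))
  invisible(config$output_dir)
}

#' Export a stress histogram as CSV (and optionally PNG)
#'
#' @param h a [stress_histogram()].
#' @param csv CSV path (bin left/right edges, centre, count).
#' @param png optional PNG path with a barplot.
#' @return the CSV path, invisibly.
#' @export
export_histogram <- function(h, csv, png = NULL) {
  stopifnot(inherits(h, "stress_histogram"))
  nb <- length(h$counts)
  df <- data.frame(left = h$bin_edges[seq_len(nb)],
                   right = h$bin_edges[-1],
                   centre = (h$bin_edges[seq_len(nb)] + h$bin_edges[-1]) / 2,
                   count = h$counts)
  utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(png)) {
    grDevices::png(png, width = 700, height = 500)
    graphics::barplot(df$count, names.arg = signif(df$centre, 3),
                      xlab = "stress (MPa)", ylab = "frequency",
                      main = sprintf("mode = %.4g MPa", h$mode))
    grDevices::dev.off()
  }
  invisible(csv)
}
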