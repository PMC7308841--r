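#' Read an ASCII point cloud
#'
#' Supports ASCII PLY 1.0 (vertex properties `x y z`, optionally
#' `red green blue` as uchar, `label` as int, and `nx ny nz` as float) and
#' whitespace-delimited XYZ files (3 columns = xyz; 4 = xyz + label;
#' 6 = xyz + rgb; 7 = xyz + rgb + label). Point order is preserved; optional
#' channels absent from the file yield `NULL` fields.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"ply"` or `"xyz"`.
#' @return a [point_cloud()].
#' @export
read_cloud <- function(path, format = c("auto", "ply", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: '", path, "'")
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  if (format == "ply") read_ply(path) else read_xyz(path)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) stop("empty cloud: '", path, "' has no data rows")
  parsed <- lapply(keep, function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[ \t]+")[[1]]))
    if (any(is.na(v)))
      stop("parse error in '", path, "' line ", i, ": non-numeric field")
    v
  })
  nc <- unique(lengths(parsed))
  if (length(nc) != 1)
    stop("parse error in '", path, "': inconsistent column count")
  if (!nc %in% c(3, 4, 6, 7))
    stop("parse error in '", path, "': expected 3, 4, 6 or 7 columns, got ", nc)
  m <- do.call(rbind, parsed)
  pts <- m[, 1:3, drop = FALSE]
  colors <- if (nc >= 6) m[, 4:6, drop = FALSE]
  labels <- if (nc %in% c(4, 7)) m[, nc]
  point_cloud(pts, colors = colors, labels = labels)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop("parse error in '", path, "' line 1: not a PLY file")
  if (!grepl("^format\\s+ascii\\s+1\\.0", trimws(lines[2])))
    stop("parse error in '", path, "' line 2: only 'format ascii 1.0' is supported")
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("parse error in '", path, "': missing end_header")
  n_vertex <- NA_integer_
  props <- character(0)
  in_vertex <- FALSE
  for (i in seq(3, hdr_end - 1)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment") next
    if (tok[1] == "element") {
      in_vertex <- identical(tok[2], "vertex")
      if (in_vertex) {
        n_vertex <- suppressWarnings(as.integer(tok[3]))
        if (is.na(n_vertex))
          stop("parse error in '", path, "' line ", i, ": bad vertex count")
      }
    } else if (tok[1] == "property" && in_vertex) {
      if (identical(tok[2], "list"))
        stop("parse error in '", path, "' line ", i,
             ": list vertex properties are not supported")
      props <- c(props, tok[3])
    }
  }
  if (is.na(n_vertex)) stop("parse error in '", path, "': no vertex element")
  if (n_vertex == 0) stop("empty cloud: '", path, "' declares 0 vertices")
  if (!all(c("x", "y", "z") %in% props))
    stop("parse error in '", path, "': vertex element lacks x/y/z properties")
  data_lines <- lines[(hdr_end + 1):length(lines)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) < n_vertex)
    stop("parse error in '", path, "': ", n_vertex, " vertices declared, ",
         length(data_lines), " data rows found")
  vals <- suppressWarnings(
    as.numeric(unlist(strsplit(trimws(data_lines[seq_len(n_vertex)]), "\\s+"))))
  if (length(vals) != n_vertex * length(props) || any(is.na(vals))) {
    ## locate the first bad row for the error message
    for (r in seq_len(n_vertex)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(data_lines[r]), "\\s+")[[1]]))
      if (length(v) != length(props) || any(is.na(v)))
        stop("parse error in '", path, "' line ", hdr_end + r,
             ": malformed vertex row")
    }
    stop("parse error in '", path, "': malformed vertex data")
  }
  m <- matrix(vals, nrow = n_vertex, byrow = TRUE,
              dimnames = list(NULL, props))
  colors <- if (all(c("red", "green", "blue") %in% props))
    m[, c("red", "green", "blue"), drop = FALSE]
  normals <- if (all(c("nx", "ny", "nz") %in% props))
    m[, c("nx", "ny", "nz"), drop = FALSE]
  labels <- if ("label" %in% props) m[, "label"]
  point_cloud(m[, c("x", "y", "z"), drop = FALSE], colors = colors,
              labels = labels, normals = normals)
}

#' Write an ASCII point cloud
#'
#' Coordinates are written with six decimal places, so a read/write round
#' trip reproduces coordinates to within 1e-6 and colour/label channels
#' exactly. PLY output stores labels as an integer vertex property and
#' normals as `nx ny nz` float properties, interoperable with common
#' point-cloud editors.
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @param format `"auto"` (by extension), `"ply"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "xyz")) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  fmt_pts <- sprintf("%.6f %.6f %.6f", cloud$points[, 1], cloud$points[, 2],
                     cloud$points[, 3])
  body <- fmt_pts
  if (format == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(cloud$points)),
             "property float x", "property float y", "property float z")
    if (!is.null(cloud$normals)) {
      hdr <- c(hdr, "property float nx", "property float ny", "property float nz")
      body <- paste(body, sprintf("%.6f %.6f %.6f", cloud$normals[, 1],
                                  cloud$normals[, 2], cloud$normals[, 3]))
    }
    if (!is.null(cloud$colors)) {
      hdr <- c(hdr, "property uchar red", "property uchar green",
               "property uchar blue")
      body <- paste(body, sprintf("%d %d %d", cloud$colors[, 1],
                                  cloud$colors[, 2], cloud$colors[, 3]))
    }
    if (!is.null(cloud$labels)) {
      hdr <- c(hdr, "property int label")
      body <- paste(body, sprintf("%d", cloud$labels))
    }
    out <- c(hdr, "end_header", body)
  } else {
    if (!is.null(cloud$colors))
      body <- paste(body, sprintf("%d %d %d", cloud$colors[, 1],
                                  cloud$colors[, 2], cloud$colors[, 3]))
    if (!is.null(cloud$labels)) body <- paste(body, sprintf("%d", cloud$labels))
    out <- body
  }
  write_atomic(path, function(tmp) writeLines(out, tmp))
  invisible(path)
}

#' Rescale a cloud to metric units using reference markers
#'
#' Multiplies all coordinates by `known_distance_m / d`, where `d` is the
#' separation of the designated marker pair in cloud units, so that the pair
#' is exactly `known_distance_m` apart afterwards. When additional pairs with
#' known distances are supplied, their implied scale factors are compared and
#' a warning is issued if any disagrees by more than 1%.
#'
#' @param cloud a [point_cloud()].
#' @param markers a [marker_set()].
#' @return the rescaled [point_cloud()]; the scale factor applied is stored
#'   in the `"scale_factor"` attribute.
#' @export
rescale_with_markers <- function(cloud, markers) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(markers, "marker_set"))
  p <- markers$positions
  d <- vec_norm(p[markers$pair[1], ] - p[markers$pair[2], ])
  if (d < .Machine$double.eps)
    stop("degenerate scale: designated markers are coincident")
  s <- markers$known_distance_m / d
  ep <- markers$extra_pairs
  if (!is.null(ep) && nrow(ep)) {
    for (r in seq_len(nrow(ep))) {
      dr <- vec_norm(p[ep$i[r], ] - p[ep$j[r], ])
      if (dr < .Machine$double.eps) next
      sr <- ep$dist_m[r] / dr
      if (abs(sr / s - 1) > 0.01)
        warning(sprintf(
          "marker scale inconsistency: pair (%d,%d) implies scale %.6g vs %.6g (%.2f%% off)",
          ep$i[r], ep$j[r], sr, s, 100 * abs(sr / s - 1)))
    }
  }
  out <- point_cloud(cloud$points * s, colors = cloud$colors,
                     labels = cloud$labels, normals = cloud$normals)
  attr(out, "scale_factor") <- s
  out
}

#' Read an organ segmentation
#'
#' Two JSON dialects are accepted. Explicit index lists:
#' `{"format": "indices", "organs": {"stem": [...], "branch_1": [...],
#' "leaf_1": [...]}}` with 0-based point indices (the convention of common
#' point-cloud editors and Python tooling; converted to 1-based internally).
#' Or a label legend: `{"format": "legend", "legend": {"0": "stem",
#' "1": "branch_1", "2": "leaf_1"}}`, resolved against the cloud's per-point
#' integer label channel. Organ names must be `"stem"`, `"branch_k"` or
#' `"leaf_k"` with k = 1, 2, ... giving the organ order.
#'
#' @param path JSON file.
#' @param cloud the [point_cloud()] the segmentation refers to.
#' @return a [segmented_plant()]; invariants (disjointness, index range,
#'   non-empty stem) are verified and violations raise errors.
#' @export
read_segmentation <- function(path, cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!file.exists(path)) stop("file not found: '", path, "'")
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  fmt <- spec$format %||% if (!is.null(spec$legend)) "legend" else "indices"
  if (fmt == "legend") {
    if (is.null(cloud$labels))
      stop("legend segmentation requires a cloud with a label channel")
    legend <- unlist(spec$legend)
    ids <- as.integer(names(legend))
    organs <- lapply(ids, function(id) which(cloud$labels == id))
    names(organs) <- unname(legend)
  } else {
    organs <- spec$organs %||% spec
    organs <- lapply(organs, function(v) as.integer(v) + 1L)  # 0- to 1-based
  }
  nm <- names(organs)
  b_idx <- grep("^branch_[0-9]+$", nm)
  l_idx <- grep("^leaf_[0-9]+$", nm)
  known <- c(which(nm == "stem"), b_idx, l_idx)
  if (length(setdiff(seq_along(nm), known)))
    stop("unknown organ name(s): ",
         paste(nm[setdiff(seq_along(nm), known)], collapse = ", "))
  if (!"stem" %in% nm || length(organs[["stem"]]) == 0)
    stop("missing stem: segmentation defines no non-empty 'stem' organ")
  ord <- function(idx, prefix) {
    k <- as.integer(sub(prefix, "", nm[idx]))
    idx[order(k)]
  }
  segmented_plant(cloud, stem = organs[["stem"]],
                  branches = unname(organs[ord(b_idx, "branch_")]),
                  leaves = unname(organs[ord(l_idx, "leaf_")]))
}

#' Write an organ segmentation
#'
#' Writes the explicit index-list JSON dialect of [read_segmentation()]
#' (0-based indices).
#'
#' @param plant a [segmented_plant()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(plant, path) {
  stopifnot(inherits(plant, "segmented_plant"))
  organs <- c(list(stem = plant$stem - 1L),
              stats::setNames(lapply(plant$branches, function(i) i - 1L),
                              if (length(plant$branches))
                                paste0("branch_", seq_along(plant$branches))),
              stats::setNames(lapply(plant$leaves, function(i) i - 1L),
                              if (length(plant$leaves))
                                paste0("leaf_", seq_along(plant$leaves))))
  write_atomic(path, function(tmp)
    jsonlite::write_json(list(format = "indices", organs = organs), tmp))
  invisible(path)
}

#' Write a trait record to CSV
#'
#' Long format with columns `plant_id`, `trait`, `organ_index`, `value`,
#' `unit`; missing trait values are emitted as empty cells.
#'
#' @param record a [trait_record()], or a list of them.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_traits <- function(record, path) {
  if (inherits(record, "trait_record")) record <- list(record)
  df <- do.call(rbind, lapply(record, as.data.frame))
  write_atomic(path, function(tmp)
    write.csv(df, tmp, row.names = FALSE, na = ""))
  invisible(path)
}

#' Read a trait CSV written by [write_traits()]
#'
#' @param path CSV file.
#' @return a list of [trait_record()] objects, one per `plant_id`, in file
#'   order.
#' @export
read_traits <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "trait", "organ_index", "value")
  if (!all(need %in% names(df)))
    stop("trait table must have columns ", paste(need, collapse = ", "))
  df$value <- as.numeric(df$value)
  ids <- unique(df$plant_id)
  lapply(ids, function(id) df_to_trait_record(df[df$plant_id == id, ]))
}
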