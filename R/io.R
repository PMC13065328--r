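#' Read a contact table
#'
#' Tab-separated electrode table with columns `id`, `x`, `y`, `z`,
#' `label`, `hemisphere` (coordinates in meters); extra columns are kept.
#'
#' @param path file path.
#' @return Data frame of contacts.
#' @export
read_electrodes <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "z", "label", "hemisphere")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tab
}

#' Write a contact table
#' @param contacts data frame of contacts.
#' @param path file path.
#' @export
write_electrodes <- function(contacts, path) {
  write.table(contacts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a recording from delimited text plus a JSON sidecar
#'
#' The signal is a contacts x samples numeric table (no header); the JSON
#' sidecar carries `fs` and optionally `trial_bounds` (list of half-open
#' `[start, end)` pairs, 1-based).
#'
#' @param signal_path delimited text file (tab or comma separated).
#' @param sidecar_path JSON file with at least `fs`.
#' @param contacts optional contact table supplying ids/labels/hemispheres.
#' @return A [raw_recording()].
#' @export
read_recording <- function(signal_path, sidecar_path, contacts = NULL) {
  sig <- as.matrix(read.table(signal_path, header = FALSE,
                              sep = "", colClasses = "numeric"))
  dimnames(sig) <- NULL
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  tb <- NULL
  if (!is.null(meta$trial_bounds)) {
    m <- matrix(unlist(meta$trial_bounds), ncol = 2L, byrow = TRUE)
    tb <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  }
  raw_recording(sig, fs = meta$fs, trial_bounds = tb,
                contact_ids = contacts$id, labels = contacts$label,
                hemisphere = contacts$hemisphere)
}

#' Write a recording to delimited text plus a JSON sidecar
#' @param recording a [raw_recording()].
#' @param signal_path,sidecar_path output paths.
#' @export
write_recording <- function(recording, signal_path, sidecar_path) {
  write.table(recording$signal, signal_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(fs = recording$fs,
         trial_bounds = lapply(recording$trial_bounds, as.numeric)),
    sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(signal_path)
}

#' Read a Wavefront OBJ surface mesh
#'
#' Minimal OBJ reader for `v` and `f` records (triangular faces).  The
#' hemisphere of each vertex must be supplied either by reading one file
#' per hemisphere ([read_mesh_pair()]) or through `hemisphere`.
#'
#' @param path OBJ file.
#' @param hemisphere per-vertex labels (recycled if length 1).
#' @return A [cortical_mesh()].
#' @export
read_mesh_obj <- function(path, hemisphere = "left") {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
    as.numeric(p[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
    as.integer(sub("/.*", "", p[2:4]))))
  hemisphere <- rep(hemisphere, length.out = nrow(verts))
  cortical_mesh(verts, faces, hemisphere)
}

#' Read left and right hemisphere OBJ meshes into one object
#' @param left_path,right_path OBJ files.
#' @return A [cortical_mesh()].
#' @export
read_mesh_pair <- function(left_path, right_path) {
  l <- read_mesh_obj(left_path, "left")
  r <- read_mesh_obj(right_path, "right")
  cortical_mesh(rbind(l$vertices, r$vertices),
                rbind(l$faces, r$faces + nrow(l$vertices)),
                c(l$hemisphere, r$hemisphere))
}

#' Write a cortical mesh as Wavefront OBJ
#' @param mesh a [cortical_mesh()].
#' @param path output file (single file; hemisphere labels are written as
#'   a comment block of `# hemi` lines).
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hemi %s", paste(rle(mesh$hemisphere)$values,
                                        rle(mesh$hemisphere)$lengths,
                                        collapse = " ")), con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Write a spectrum as a tab-separated table with a JSON header
#'
#' One `#`-prefixed JSON header line (temporal frequency, rank, variant,
#' range, DC-removal flag, plus any `extra` metadata such as seed and
#' configuration), then columns `bin_low`, `bin_high`, `power`.
#'
#' @param spectrum an `sf_spectrum`.
#' @param path output file.
#' @param extra named list of additional header metadata.
#' @export
write_spectrum <- function(spectrum, path, extra = NULL) {
  hdr <- c(list(f = spectrum$f, rank = spectrum$rank,
                variant = spectrum$variant, sf_range = spectrum$sf_range,
                dc_removal = spectrum$dc_removal), extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(hdr, auto_unbox = TRUE,
                                           digits = NA)), con)
  e <- spectrum$bin_edges
  tab <- data.frame(bin_low = e[-length(e)], bin_high = e[-1],
                    power = spectrum$power)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#' @param path file path.
#' @return An `sf_spectrum` (header metadata restored; the
#'   `max_triangle_size` field is restored when present in the header).
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  tab <- read.table(text = lines[-1], header = TRUE, sep = "\t")
  structure(list(bin_edges = c(tab$bin_low, tab$bin_high[nrow(tab)]),
                 power = tab$power, f = hdr$f, rank = hdr$rank,
                 variant = hdr$variant, sf_range = hdr$sf_range,
                 dc_removal = hdr$dc_removal,
                 total_weight = sum(tab$power), excluded_weight = NA_real_,
                 n_standing_components = NA_integer_,
                 max_triangle_size = if (!is.null(hdr$max_triangle_size))
                   hdr$max_triangle_size else NA_real_),
            class = "sf_spectrum")
}

#' Export a triangle set as a tab-separated table
#' @param set a binned `triangle_set`.
#' @param path output file.
#' @export
write_triangles <- function(set, path) {
  write.table(set$triangles, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
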