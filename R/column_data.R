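#' Expected landmark counts per vertebral region
#'
#' Default numbers of homologous 3D landmarks digitised per vertebra in each
#' region of the presacral column: 34 cervical, 32 thoracic, 36 lumbar.
#' A dataset may override these, but the count must be uniform within a
#' region.
#'
#' @export
default_landmark_counts <- c(cervical = 34L, thoracic = 32L, lumbar = 36L)

.regions <- c("cervical", "thoracic", "lumbar")
.region_prefix <- c(cervical = "C", thoracic = "T", lumbar = "L")

#' Serial label for a vertebra
#'
#' Builds labels such as `"C03"`, `"T14"`, `"L07"` from region and 1-based
#' position within region.
#'
#' @param region character vector of regions.
#' @param position integer vector of within-region positions.
#' @return character vector of labels.
#' @export
serial_label <- function(region, position) {
  stopifnot(all(region %in% .regions))
  sprintf("%s%02d", .region_prefix[region], as.integer(position))
}

#' Construct a vertebra dataset
#'
#' A vertebra dataset couples one landmark configuration per vertebra per
#' specimen with its identifying metadata. Coordinates are K x 3 matrices
#' (columns x, y, z); K must be uniform within a region.
#'
#' @param coords list of K x 3 numeric matrices, one per vertebra record.
#' @param info data.frame with columns `specimen_id`, `species`, `region`,
#'   `position` aligned with `coords`.
#' @param landmark_counts named integer vector giving the expected K per
#'   region; defaults to [default_landmark_counts].
#' @return an object of class `vertebra_dataset`.
#' @export
vertebra_dataset <- function(coords, info,
                             landmark_counts = default_landmark_counts) {
  stopifnot(is.list(coords), is.data.frame(info),
            nrow(info) == length(coords))
  need <- c("specimen_id", "species", "region", "position")
  if (!all(need %in% names(info)))
    stop("info must contain columns: ", paste(need, collapse = ", "))
  info$region <- as.character(info$region)
  info$position <- as.integer(info$position)
  if (!all(info$region %in% .regions))
    stop("unknown region(s): ",
         paste(setdiff(info$region, .regions), collapse = ", "))
  if (any(info$position < 1L)) stop("positions must be >= 1")
  for (i in seq_along(coords)) {
    x <- coords[[i]]
    if (!is.matrix(x) || ncol(x) != 3L)
      stop("record ", i, ": coordinates must be a K x 3 matrix")
    if (any(!is.finite(x)))
      stop("record ", i, ": non-finite coordinates are not supported")
    k_exp <- landmark_counts[[info$region[i]]]
    if (nrow(x) != k_exp)
      stop(sprintf("record %d (%s %s): expected %d landmarks, observed %d",
                   i, info$species[i],
                   serial_label(info$region[i], info$position[i]),
                   k_exp, nrow(x)))
  }
  info$label <- serial_label(info$region, info$position)
  structure(list(coords = coords, info = info,
                 landmark_counts = landmark_counts),
            class = "vertebra_dataset")
}

#' @export
print.vertebra_dataset <- function(x, ...) {
  cat("Vertebra dataset:", nrow(x$info), "configurations,",
      length(unique(x$info$species)), "species\n")
  tab <- table(x$info$region)
  for (r in names(tab))
    cat(sprintf("  %-9s %4d records, K = %d\n", r, tab[[r]],
                x$landmark_counts[[r]]))
  invisible(x)
}

#' Read one landmark file
#'
#' Reads a single per-vertebra landmark file in either the plain `xyz_text`
#' dialect (one landmark per line, three whitespace- or comma-separated
#' numbers) or the TPS dialect (an `LM3=K` header followed by K coordinate
#' lines).
#'
#' @param path file path.
#' @param dialect `"xyz_text"` or `"tps"`.
#' @param expected_k optional integer; if given, a landmark-count mismatch is
#'   an error naming the expected and observed K.
#' @return a K x 3 numeric matrix.
#' @export
read_landmark_file <- function(path, dialect = c("xyz_text", "tps"),
                               expected_k = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "tps") {
    hdr <- grep("^LM3\\s*=", lines)
    if (length(hdr) != 1L)
      stop("TPS parse error in ", path, ": expected a single LM3= header")
    k <- as.integer(sub("^LM3\\s*=\\s*", "", lines[hdr]))
    lines <- lines[seq(hdr + 1L, hdr + k)]
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parse_row <- function(i) {
    parts <- strsplit(lines[i], "[,[:space:]]+")[[1]]
    parts <- parts[nzchar(parts)]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 3L || any(is.na(vals)))
      stop(sprintf("parse error in %s at line %d: %s", path, i, lines[i]))
    vals
  }
  m <- t(vapply(seq_along(lines), parse_row, numeric(3)))
  colnames(m) <- c("x", "y", "z")
  if (!is.null(expected_k) && nrow(m) != expected_k)
    stop(sprintf("landmark-count mismatch in %s: expected %d, observed %d",
                 path, expected_k, nrow(m)))
  m
}

#' Write one landmark file
#'
#' Writes a K x 3 configuration in the plain xyz text dialect. Full
#' precision (`format(..., digits = 17)`) is used so that a write/read
#' round trip reproduces coordinates exactly.
#'
#' @param coords K x 3 matrix.
#' @param path destination path.
#' @export
write_landmark_file <- function(coords, path) {
  txt <- apply(coords, 1, function(r)
    paste(format(r, digits = 17, scientific = TRUE, trim = TRUE),
          collapse = " "))
  writeLines(txt, path)
  invisible(path)
}

#' Read a directory of landmark files into a dataset
#'
#' File names must follow `<species>__<specimen>__<label>.txt`, with label a
#' serial label such as `C03` or `T12`. Landmark counts are validated per
#' region.
#'
#' @param dir directory containing the files.
#' @param dialect file dialect, see [read_landmark_file()].
#' @param landmark_counts expected K per region.
#' @return a [vertebra_dataset()].
#' @export
read_landmark_dir <- function(dir, dialect = "xyz_text",
                              landmark_counts = default_landmark_counts) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0L) stop("no .txt landmark files in ", dir)
  base <- sub("\\.txt$", "", basename(files))
  parts <- strsplit(base, "__", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("file name(s) not of the form <species>__<specimen>__<label>.txt: ",
         paste(basename(files)[bad], collapse = ", "))
  mat <- do.call(rbind, parts)
  lab <- mat[, 3]
  region <- .regions[match(substr(lab, 1, 1), .region_prefix)]
  if (any(is.na(region)))
    stop("unrecognised region prefix in label(s): ",
         paste(lab[is.na(region)], collapse = ", "))
  position <- as.integer(substr(lab, 2, nchar(lab)))
  coords <- vector("list", length(files))
  for (i in seq_along(files))
    coords[[i]] <- read_landmark_file(files[i], dialect,
                                      expected_k = landmark_counts[[region[i]]])
  info <- data.frame(specimen_id = mat[, 2], species = mat[, 1],
                     region = region, position = position,
                     stringsAsFactors = FALSE)
  vertebra_dataset(coords, info, landmark_counts)
}

#' Species metadata table
#'
#' Validates a per-species table of regional vertebral counts and the
#' diaphragmatic thoracic position. The thoracolumbar count is expected to be
#' fixed at 20 (homeotic, not meristic, variation); species that depart from
#' this must be declared via `allow_exceptions`, otherwise validation fails.
#'
#' @param meta data.frame with columns `species`, `n_cervical`, `n_thoracic`,
#'   `n_lumbar`, and optionally `diaphragmatic_position` and
#'   `ecology_source_category`.
#' @param allow_exceptions character vector of species allowed to deviate
#'   from the 20-vertebra thoracolumbar count (flagged, never silent).
#' @return the validated data.frame, class `species_meta`.
#' @export
species_meta <- function(meta, allow_exceptions = character()) {
  need <- c("species", "n_cervical", "n_thoracic", "n_lumbar")
  if (!all(need %in% names(meta)))
    stop("meta must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$species))
    stop("duplicated species in metadata")
  tl <- meta$n_thoracic + meta$n_lumbar
  off <- meta$species[tl != 20L]
  bad <- setdiff(off, allow_exceptions)
  if (length(bad))
    stop("thoracolumbar count != 20 for undeclared species: ",
         paste(bad, collapse = ", "))
  if (length(off))
    message("thoracolumbar count exception(s) accepted: ",
            paste(off, collapse = ", "))
  if (any(meta$n_thoracic < 13L | meta$n_thoracic > 16L))
    stop("n_thoracic outside the supported 13..16 range")
  if (any(meta$n_lumbar < 4L | meta$n_lumbar > 7L))
    stop("n_lumbar outside the supported 4..7 range")
  class(meta) <- c("species_meta", "data.frame")
  meta
}

.check_meta_cover <- function(dataset, meta) {
  miss <- setdiff(unique(dataset$info$species), meta$species)
  if (length(miss))
    stop("species missing from metadata: ", paste(miss, collapse = ", "))
}

#' Seriation scheme: group vertebrae by number
#'
#' Groups serially homologous vertebrae across species by their numeric
#' position within region (all C03 together, all T14 together, ...). Groups
#' at positions not present in every species (e.g. T14, T15, L05-L07) are
#' restricted to the species that possess them. A completeness warning lists
#' any vertebra a species should have (per its metadata counts) but that is
#' absent from the dataset.
#'
#' @param dataset a [vertebra_dataset()].
#' @param meta a [species_meta()] table covering all species in the dataset.
#' @return an object of class `seriation_scheme` with one member data.frame
#'   (species, region, position) per group key.
#' @export
build_by_number_groups <- function(dataset, meta) {
  .check_meta_cover(dataset, meta)
  info <- unique(dataset$info[, c("species", "region", "position", "label")])
  counts <- list(cervical = function(m) 3:7,  # C01/C02 (atlas, axis) excluded
                 thoracic = function(m) seq_len(m$n_thoracic),
                 lumbar = function(m) seq_len(m$n_lumbar))
  expected <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    do.call(rbind, lapply(.regions, function(r) {
      pos <- counts[[r]](m)
      pos <- intersect(pos, info$position[info$region == r])  # digitised range
      if (!length(pos)) return(NULL)
      data.frame(species = m$species, region = r, position = pos)
    }))
  }))
  expected$label <- serial_label(expected$region, expected$position)
  have <- paste(info$species, info$label)
  gaps <- expected[!(paste(expected$species, expected$label) %in% have), ]
  if (nrow(gaps))
    warning("completeness: missing vertebrae: ",
            paste(paste0(gaps$species, ":", gaps$label), collapse = ", "))
  present <- expected[paste(expected$species, expected$label) %in% have, ]
  groups <- split(present[, c("species", "region", "position")],
                  present$label)
  ord <- order(match(substr(names(groups), 1, 1), .region_prefix),
               as.integer(substr(names(groups), 2, 3)))
  structure(list(name = "by_number", groups = groups[ord]),
            class = "seriation_scheme")
}

#' Seriation scheme: select vertebrae by position
#'
#' Selects one vertebra per species per anatomically defined key,
#' irrespective of count: Tfirst (T01), Tmid (T06 for 13-14 thoracics, T07
#' for 15-16), Tdiaph (the per-species diaphragmatic vertebra, supplied as
#' metadata), Tlast, Lfirst (L01), Lmid (L03 for 4-5 lumbars, L04 for 6-7),
#' Llast. Cervicals (fixed count) pass through unchanged as C03-C07.
#'
#' @inheritParams build_by_number_groups
#' @return a `seriation_scheme`.
#' @export
build_by_position_groups <- function(dataset, meta) {
  .check_meta_cover(dataset, meta)
  if (is.null(meta$diaphragmatic_position) ||
      any(is.na(meta$diaphragmatic_position)))
    stop("diaphragmatic_position must be supplied for every species ",
         "(no heuristic guessing)")
  key_pos <- function(m) {
    tmid <- if (m$n_thoracic %in% c(13L, 14L)) 6L else 7L
    lmid <- if (m$n_lumbar %in% c(4L, 5L)) 3L else 4L
    data.frame(
      key = c(serial_label("cervical", 3:7),
              "Tfirst", "Tmid", "Tdiaph", "Tlast",
              "Lfirst", "Lmid", "Llast"),
      region = c(rep("cervical", 5), rep("thoracic", 4), rep("lumbar", 3)),
      position = c(3:7, 1L, tmid, as.integer(m$diaphragmatic_position),
                   m$n_thoracic, 1L, lmid, m$n_lumbar))
  }
  sel <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    k <- key_pos(meta[i, ])
    k$species <- meta$species[i]
    k
  }))
  have <- paste(dataset$info$species,
                dataset$info$region, dataset$info$position)
  sel <- sel[paste(sel$species, sel$region, sel$position) %in% have, ]
  groups <- split(sel[, c("species", "region", "position")], sel$key)
  order_keys <- c(serial_label("cervical", 3:7), "Tfirst", "Tmid", "Tdiaph",
                  "Tlast", "Lfirst", "Lmid", "Llast")
  groups <- groups[intersect(order_keys, names(groups))]
  structure(list(name = "by_position", groups = groups),
            class = "seriation_scheme")
}

#' @export
print.seriation_scheme <- function(x, ...) {
  cat("Seriation scheme:", x$name, "-", length(x$groups), "groups\n")
  n <- vapply(x$groups, nrow, integer(1))
  cat(paste(sprintf("%s(n=%d)", names(n), n), collapse = " "), "\n")
  invisible(x)
}

#' Landmark left/right pairing
#'
#' Describes the object symmetry of a configuration: `paired` holds
#' (left, right) landmark index pairs, `midline` the sagittal-plane indices.
#' Together they must partition 1..K.
#'
#' @param paired two-column integer matrix of (left, right) index pairs.
#' @param midline integer vector of midline landmark indices.
#' @param k total number of landmarks.
#' @return object of class `landmark_pairing`.
#' @export
landmark_pairing <- function(paired, midline, k) {
  paired <- matrix(as.integer(paired), ncol = 2)
  midline <- as.integer(midline)
  all_idx <- sort(c(paired, midline))
  if (!identical(all_idx, seq_len(k)))
    stop("pairing indices must partition 1..", k)
  structure(list(paired = paired, midline = midline, k = as.integer(k)),
            class = "landmark_pairing")
}

# permutation that swaps each left/right pair and fixes the midline
.pair_permutation <- function(pairing) {
  perm <- seq_len(pairing$k)
  perm[pairing$paired[, 1]] <- pairing$paired[, 2]
  perm[pairing$paired[, 2]] <- pairing$paired[, 1]
  perm
}

#' Write a dataset manifest
#'
#' Exports the validated record index (species, specimen, region, position,
#' landmark count) as CSV.
#'
#' @param dataset a [vertebra_dataset()].
#' @param path destination CSV path.
#' @export
write_dataset_manifest <- function(dataset, path) {
  out <- dataset$info
  out$k <- dataset$landmark_counts[out$region]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
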