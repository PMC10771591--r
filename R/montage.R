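#' Electrode montage
#'
#' A montage holds electrode labels and their 3-D positions in a head-centered
#' right-anterior-superior (RAS) frame, in meters. All spatial operations in the
#' package (adjacency, spatial component templates, spherical-spline
#' interpolation, the spherical head model) work off this container.
#'
#' @param labels character vector of unique electrode names (10-5 system or
#'   user-defined).
#' @param positions numeric matrix, one row per electrode, columns x (right),
#'   y (anterior), z (superior), meters.
#' @return An object of class `eeg_montage` with elements `labels` and
#'   `positions` (rownames set to labels).
#' @export
eeg_montage <- function(labels, positions) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (anyDuplicated(labels))
    stop("duplicate electrode label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (nrow(positions) != length(labels) || ncol(positions) != 3L)
    stop("positions must be a ", length(labels), " x 3 matrix")
  if (!all(is.finite(positions)))
    stop("electrode positions must be finite")
  rownames(positions) <- labels
  colnames(positions) <- c("x", "y", "z")
  structure(list(labels = labels, positions = positions),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$labels), " electrodes\n", sep = "")
  cat("  radius range [",
      paste(signif(range(sqrt(rowSums(x$positions^2))), 3), collapse = ", "),
      "] m\n", sep = "")
  invisible(x)
}

#' Read an electrode-position file
#'
#' Parses an SFP-style whitespace-delimited text file with one row per
#' electrode: `label x y z`, coordinates in meters, RAS frame. Blank lines and
#' lines starting with `#` are ignored. Row order is preserved.
#'
#' @param path path to the position file.
#' @return An [eeg_montage()].
#' @export
load_montage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no electrode rows in ", path)
  parts <- strsplit(lines, "[[:space:]]+")
  labels <- character(length(parts))
  pos <- matrix(NA_real_, length(parts), 3L)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 4L)
      stop("row ", i, ": expected 'label x y z', got ", length(p), " fields")
    labels[i] <- p[1L]
    xyz <- suppressWarnings(as.numeric(p[2:4]))
    if (anyNA(xyz))
      stop("row ", i, " ('", p[1L], "'): non-numeric coordinate")
    pos[i, ] <- xyz
  }
  eeg_montage(labels, pos)
}

#' Write a montage to an SFP-style text file
#'
#' @param montage an [eeg_montage()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "eeg_montage"))
  txt <- sprintf("%s\t%.6f\t%.6f\t%.6f", montage$labels,
                 montage$positions[, 1], montage$positions[, 2],
                 montage$positions[, 3])
  writeLines(txt, path)
  invisible(path)
}

#' Packaged 63-channel fixture montage
#'
#' A synthetic 63-electrode montage with 10-5-system labels laid out on a
#' sphere of radius 0.095 m in concentric rings around Cz (ring spacing 18
#' degrees of inclination). It is a geometric stand-in for a measured standard
#' montage: label-to-ring assignment is approximate, but inter-electrode
#' distances are representative of a 64-channel cap, which is all the spatial
#' machinery relies on. The same montage ships as
#' `inst/extdata/standard63_synthetic.sfp`.
#'
#' @param radius scalp sphere radius in meters.
#' @return An [eeg_montage()] with 63 electrodes.
#' @export
montage_63 <- function(radius = 0.095) {
  rings <- list(
    list(theta = 0, labels = "Cz"),
    list(theta = 18, labels = c("FCz", "C2", "CPz", "C1")),
    list(theta = 36, labels = c("Fz", "FC2", "C4", "CP2", "Pz", "CP1", "C3",
                                "FC1")),
    list(theta = 54, labels = c("AFz", "F2", "F4", "FC4", "C6", "CP4", "P4",
                                "P2", "POz", "P1", "P3", "CP3", "C5", "FC3",
                                "F3", "F1")),
    list(theta = 72, labels = c("Fpz", "AF4", "F6", "FT8", "T8", "TP8", "P6",
                                "PO4", "Oz", "PO3", "P5", "TP7", "T7", "FT7",
                                "F5", "AF3")),
    list(theta = 90, labels = c("Fp1", "Fp2", "AF7", "AF8", "F7", "F8", "FT9",
                                "FT10", "T9", "T10", "TP9", "TP10", "P7", "P8",
                                "PO7", "PO8", "O1", "O2"))
  )
  labels <- character(0)
  pos <- NULL
  for (ring in rings) {
    n <- length(ring$labels)
    th <- ring$theta * pi / 180
    # azimuth measured from the anterior (+y) axis, clockwise toward +x
    phi <- if (n == 1L) 0 else seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
    labels <- c(labels, ring$labels)
    pos <- rbind(pos, cbind(radius * sin(th) * sin(phi),
                            radius * sin(th) * cos(phi),
                            radius * cos(th)))
  }
  eeg_montage(labels, pos)
}

#' Spatial adjacency between electrodes
#'
#' Electrodes are neighbors iff their Euclidean distance is at most
#' `max_dist`. The relation is symmetric and irreflexive; it provides the
#' spatial part of the spatiotemporal connectivity used by the cluster-based
#' permutation test.
#'
#' @param montage an [eeg_montage()] with at least 2 electrodes.
#' @param max_dist neighbor distance threshold in meters (default 0.05).
#' @return An object of class `eeg_adjacency`: a list with `matrix` (logical
#'   K x K), `neighbors` (named list of neighbor label vectors) and `max_dist`.
#' @export
build_adjacency <- function(montage, max_dist = 0.05) {
  stopifnot(inherits(montage, "eeg_montage"))
  if (max_dist <= 0) stop("max_dist must be > 0")
  if (length(montage$labels) < 2L)
    stop("adjacency needs at least 2 electrodes")
  d <- as.matrix(stats::dist(montage$positions))
  adj <- d <= max_dist
  diag(adj) <- FALSE
  neighbors <- lapply(seq_along(montage$labels),
                      function(i) montage$labels[adj[i, ]])
  names(neighbors) <- montage$labels
  structure(list(matrix = adj, neighbors = neighbors, max_dist = max_dist,
                 labels = montage$labels),
            class = "eeg_adjacency")
}

#' @export
print.eeg_adjacency <- function(x, ...) {
  deg <- rowSums(x$matrix)
  cat("<eeg_adjacency> ", length(x$labels), " electrodes, max_dist ",
      x$max_dist, " m, degree range [", min(deg), ", ", max(deg), "]\n",
      sep = "")
  invisible(x)
}

#' Select electrodes near a scalp target
#'
#' Returns all electrode labels within `radius` of `target_pos`; the single
#' nearest electrode is always included even if it lies outside the radius, so
#' the returned set is never empty. Used to form the target-proximal electrode
#' average from which early evoked peaks are read when they are not visible in
#' the global field amplitude.
#'
#' @param montage an [eeg_montage()].
#' @param target_pos numeric length-3 position (meters, RAS).
#' @param radius inclusion radius in meters (default 0.04).
#' @return Character vector of electrode labels, ordered by distance.
#' @export
select_channels_near <- function(montage, target_pos, radius = 0.04) {
  stopifnot(inherits(montage, "eeg_montage"), length(target_pos) == 3L)
  if (radius <= 0) stop("radius must be > 0")
  d <- sqrt(colSums((t(montage$positions) - as.numeric(target_pos))^2))
  sel <- d <= radius
  sel[which.min(d)] <- TRUE
  montage$labels[sel][order(d[sel])]
}
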