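#' Construct a vertex-wise morphometry dataset
#'
#' A `surface_dataset` holds one morphometric measure (cortical thickness in
#' mm or vertex-wise surface area in mm\eqn{^2}) as a participants x vertices
#' matrix, together with per-vertex functional-network labels in 0..7
#' (1 = visual, 2 = somatomotor, 3 = dorsal attention, 4 = salience,
#' 5 = limbic, 6 = control, 7 = default mode; 0 = unlabeled / medial wall).
#'
#' @param values numeric matrix, participants x vertices, no missing values.
#' @param labels integer vector of network codes, length `ncol(values)`.
#' @param measure `"thickness"` or `"area"`.
#' @param participant_ids unique row identifiers (default `p001`, ...).
#' @param vertex_ids column identifiers (default `v00001`, ...).
#' @return An object of class `surface_dataset`.
#' @export
surface_dataset <- function(values, labels,
                            measure = c("thickness", "area"),
                            participant_ids = NULL, vertex_ids = NULL) {
  measure <- match.arg(measure)
  values <- as.matrix(values)
  if (anyNA(values) || !is.numeric(values))
    stop("surface values must be numeric with no missing entries", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != ncol(values))
    stop(sprintf("labels length (%d) must equal vertex count (%d)",
                 length(labels), ncol(values)), call. = FALSE)
  if (any(is.na(labels)) || any(labels < 0L | labels > 7L))
    stop("network labels must be integers in 0..7", call. = FALSE)
  participant_ids <- participant_ids %||% sprintf("p%03d", seq_len(nrow(values)))
  vertex_ids <- vertex_ids %||% sprintf("v%05d", seq_len(ncol(values)))
  if (anyDuplicated(participant_ids))
    stop("participant ids must be unique", call. = FALSE)
  if (length(participant_ids) != nrow(values) ||
      length(vertex_ids) != ncol(values))
    stop("id lengths must match the values matrix", call. = FALSE)
  dimnames(values) <- NULL
  structure(list(values = values, labels = labels, measure = measure,
                 participant_ids = as.character(participant_ids),
                 vertex_ids = as.character(vertex_ids)),
            class = "surface_dataset")
}

#' @export
print.surface_dataset <- function(x, ...) {
  nets <- tabulate(x$labels + 1L, nbins = 8L)
  cat(sprintf("surface_dataset: %s, %d participants x %d vertices\n",
              x$measure, nrow(x$values), ncol(x$values)))
  cat(sprintf("  network sizes (1..7): %s; unlabeled: %d\n",
              paste(nets[2:8], collapse = " "), nets[1]))
  invisible(x)
}

#' @export
dim.surface_dataset <- function(x) dim(x$values)

#' Read a morphometry matrix and its network labels from CSV
#'
#' The values file has one row per participant with an `id` first column and
#' one numeric column per vertex. The labels file has two columns
#' (`vertex_id`, `network_id` with codes 0--7) aligned with the value columns.
#'
#' @param values_path path to the matrix CSV.
#' @param labels_path path to the labels CSV.
#' @param measure `"thickness"` or `"area"`.
#' @return A [surface_dataset].
#' @export
read_surface_dataset <- function(values_path, labels_path,
                                 measure = c("thickness", "area")) {
  measure <- match.arg(measure)
  for (p in c(values_path, labels_path))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  dt <- data.table::fread(values_path, header = TRUE)
  if (!identical(names(dt)[1], "id"))
    stop(sprintf("format error in %s: first column must be 'id'", values_path),
         call. = FALSE)
  ids <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1])
  if (!is.numeric(vals))
    stop(sprintf("format error in %s: non-numeric cells in the value matrix",
                 values_path), call. = FALSE)
  lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  if (ncol(lab) < 2)
    stop(sprintf("format error in %s: expected columns vertex_id, network_id",
                 labels_path), call. = FALSE)
  if (nrow(lab) != ncol(vals))
    stop(sprintf("shape mismatch: %s has %d vertices but %s has %d labels",
                 values_path, ncol(vals), labels_path, nrow(lab)), call. = FALSE)
  if (any(is.na(lab[[2]])) || any(lab[[2]] < 0 | lab[[2]] > 7))
    stop(sprintf("format error in %s: network codes must be in 0..7",
                 labels_path), call. = FALSE)
  surface_dataset(vals, lab[[2]], measure = measure,
                  participant_ids = ids, vertex_ids = as.character(lab[[1]]))
}

#' Write a surface dataset to CSV
#'
#' Values are formatted with 17 significant digits so that reading the file
#' back reproduces the doubles bit-exactly.
#'
#' @param ds a [surface_dataset].
#' @param values_path output path for the matrix CSV.
#' @param labels_path output path for the labels CSV, or `NULL` to skip.
#' @return Invisibly, `values_path`.
#' @export
write_surface_dataset <- function(ds, values_path, labels_path = NULL) {
  stopifnot(inherits(ds, "surface_dataset"))
  chr <- formatC(ds$values, format = "g", digits = 17)
  dim(chr) <- dim(ds$values)
  out <- cbind(id = ds$participant_ids, chr)
  colnames(out) <- c("id", ds$vertex_ids)
  utils::write.table(out, values_path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  if (!is.null(labels_path))
    utils::write.csv(data.frame(vertex_id = ds$vertex_ids,
                                network_id = ds$labels),
                     labels_path, row.names = FALSE, quote = FALSE)
  invisible(values_path)
}

#' Restrict a surface dataset to one functional network
#'
#' @param ds a [surface_dataset].
#' @param network a network code 1..7, or `"whole"` to keep all labeled
#'   vertices (codes 1--7, dropping code 0).
#' @return A [surface_dataset] with the selected columns.
#' @export
subset_network <- function(ds, network) {
  stopifnot(inherits(ds, "surface_dataset"))
  if (identical(network, "whole")) {
    keep <- ds$labels >= 1L
  } else {
    network <- as.integer(network)
    if (is.na(network) || network < 1L || network > 7L)
      stop("network must be a code in 1..7 or \"whole\"", call. = FALSE)
    keep <- ds$labels == network
  }
  if (!any(keep))
    stop(sprintf("no vertices carry network code %s",
                 paste(network, collapse = "")), call. = FALSE)
  surface_dataset(ds$values[, keep, drop = FALSE], ds$labels[keep],
                  measure = ds$measure, participant_ids = ds$participant_ids,
                  vertex_ids = ds$vertex_ids[keep])
}

#' Robust per-vertex scaling (median / IQR)
#'
#' Centers every vertex on its median and scales by the interquartile range
#' (25th to 75th percentile, linear-interpolation quantiles). Vertices with
#' zero IQR are centered but left unscaled (divisor 1), so near-constant
#' vertices survive without producing infinities.
#'
#' `robust_scale()` fits on a training matrix and returns both the parameters
#' and the scaled matrix; `apply_scale()` applies previously fitted parameters
#' to new data (e.g. a held-out test fold), which is what keeps the
#' cross-validation free of train/test leakage.
#'
#' @param x numeric matrix (participants x vertices) or [surface_dataset].
#' @return For `robust_scale()`: a list with `params` (class `scale_params`:
#'   `center`, `scale`) and `scaled`. For `apply_scale()`: the scaled matrix.
#' @export
robust_scale <- function(x) {
  m <- if (inherits(x, "surface_dataset")) x$values else as.matrix(x)
  if (nrow(m) < 4)
    stop("robust scaling needs at least 4 rows", call. = FALSE)
  qs <- apply(m, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE, type = 7)
  center <- qs[2, ]
  iqr <- qs[3, ] - qs[1, ]
  scale <- ifelse(iqr > 0, iqr, 1)
  params <- structure(list(center = center, scale = scale),
                      class = "scale_params")
  list(params = params, scaled = apply_scale(params, m))
}

#' @rdname robust_scale
#' @param params a `scale_params` object from `robust_scale()`.
#' @export
apply_scale <- function(params, x) {
  stopifnot(inherits(params, "scale_params"))
  m <- if (inherits(x, "surface_dataset")) x$values else as.matrix(x)
  if (ncol(m) != length(params$center))
    stop(sprintf("scale params were fit on %d vertices but data has %d columns",
                 length(params$center), ncol(m)), call. = FALSE)
  sweep(sweep(m, 2, params$center, "-"), 2, params$scale, "/")
}
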