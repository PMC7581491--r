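as_prob_array <- function(probmap_or_labels, n_classes = 3L) {
  x <- probmap_or_labels
  if (is.matrix(x) && (is.integer(x) || all(x == floor(x)))) {
    # hard label map -> one-hot probabilities
    oh <- one_hot_regions(x, n_classes)
    return(array(oh, dim(oh)[1:3]))
  }
  if (is.array(x) && length(dim(x)) == 4) x <- array(x, dim(x)[1:3])
  if (!(is.array(x) && length(dim(x)) == 3))
    stop("expected an (H, W, C) probability array or an integer label matrix")
  x
}

#' Boundary probability map by columnwise edge detection
#'
#' The ILM is the exit from the vitreous, so its boundary probability at a
#' pixel is the positive part of the row-wise increase (downward) of
#' `1 - p(vitreous)` -- equal to the rise of the retina-class probability on
#' well-formed maps, but still defined where the retina class is empty
#' (coincident boundaries).  The RPE base is the retina-to-choroid
#' transition, detected as the rise of the choroid-class probability.  On an
#' ideal one-hot map this puts probability 1 exactly on the first row of the
#' region below the boundary.  Values are clipped to `[0, 1]`.
#'
#' @param probmap_or_labels `(H, W, 3)` (or `(H, W, 3, 1)`) probability array,
#'   or an integer label matrix in `{0, 1, 2}` (e.g. a majority-voted map),
#'   which is one-hot encoded first.
#' @param boundary `"ILM"` or `"RPE"`.
#' @return an `H x W` matrix of boundary probabilities.
#' @export
boundary_edge_map <- function(probmap_or_labels, boundary = c("ILM", "RPE")) {
  boundary <- match.arg(boundary)
  p <- as_prob_array(probmap_or_labels)
  pc <- if (boundary == "ILM") 1 - p[, , 1] else p[, , 3]
  inc <- rbind(rep(0, ncol(pc)), diff(pc))   # row 0 has nothing above it
  pmin(pmax(inc, 0), 1)
}

#' Shortest-path boundary extraction (Dijkstra)
#'
#' Builds the directed boundary graph: one vertex per pixel plus a dummy
#' column on each side whose vertices act as probability-1 pixels and are
#' vertically connected, so the fixed corner-to-corner path can enter and
#' leave the map at any row.  Each vertex connects to its three rightmost
#' neighbours (horizontal, diagonal up, diagonal down) with weight
#' `w(s, d) = 2 - (p_s + p_d)`, which is non-negative and minimal along rows
#' of high boundary probability; Dijkstra's algorithm then returns the
#' minimum-cost left-to-right path, the predicted boundary.  Ties are broken
#' deterministically (queue ordered by cost, then column, then row; on equal
#' cost the horizontal move is preferred, then diagonal-up, then
#' diagonal-down), so an all-zero map yields the topmost, horizontal path.
#'
#' @param edge an `H x W` boundary-probability matrix in `[0, 1]`.
#' @param formula `"standard"` for `w = 2 - (p_s + p_d)`;  `"printed"` for
#'   the literal variant `w = 2 - p_s + p_d`, retained for auditability.
#' @return `list(rows, cost)`: 0-based boundary row per column and the total
#'   path cost (dummy columns included; they contribute zero along fully
#'   confident boundaries).
#' @export
shortest_boundary_path <- function(edge, formula = c("standard", "printed")) {
  formula <- match.arg(formula)
  if (!is.matrix(edge) || !all(is.finite(edge)))
    stop("`edge` must be a finite numeric matrix")
  res <- cpp_dijkstra_boundary(edge, if (formula == "standard") 0L else 1L)
  list(rows = as.numeric(res$rows), cost = res$cost)
}

#' Extract both retinal boundaries from a probability or voted label map
#'
#' Runs [boundary_edge_map()] + [shortest_boundary_path()] independently for
#' the ILM and the RPE base, removes the top padding offset, and returns a
#' full-width [boundary_set()] (the method always predicts every column).
#'
#' @param probmap_or_labels as in [boundary_edge_map()]; computed on the
#'   padded image grid.
#' @param pad_rows rows of top padding to subtract from the extracted rows
#'   (default 16, matching [pad_top()]).
#' @param formula edge-weight variant, see [shortest_boundary_path()].
#' @return a [boundary_set()] (not validated: a poor map may order the
#'   boundaries arbitrarily).
#' @export
extract_boundaries <- function(probmap_or_labels, pad_rows = 16L,
                               formula = "standard") {
  ilm <- shortest_boundary_path(
    boundary_edge_map(probmap_or_labels, "ILM"), formula)
  rpe <- shortest_boundary_path(
    boundary_edge_map(probmap_or_labels, "RPE"), formula)
  boundary_set(pmax(ilm$rows - pad_rows, 0), pmax(rpe$rows - pad_rows, 0),
               validate = FALSE)
}
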