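# Structural connectomes: reading, writing, validation and synthesis.

new_connectome <- function(weights, labels) {
  dimnames(weights) <- list(labels, labels)
  structure(
    list(weights = weights, labels = labels, n_regions = nrow(weights)),
    class = "connectome"
  )
}

#' Validate a structural connectivity matrix
#'
#' Checks that `weights` is a square, finite, nonnegative, symmetric matrix
#' with a zero diagonal, and that `labels` (if supplied) matches its
#' dimension. Each violation raises a distinct condition class so callers can
#' react programmatically.
#'
#' @param weights Numeric matrix of coupling weights.
#' @param labels Optional character vector of region names.
#' @param tol Absolute tolerance for symmetry and zero-diagonal checks.
#'   Asymmetries beyond `tol` are an error rather than being silently
#'   symmetrized, because inter-mass coupling is defined as reciprocal.
#' @return `weights`, invisibly, if all checks pass.
#' @export
validate_connectome <- function(weights, labels = NULL, tol = 1e-9) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    abort("`weights` must be a numeric matrix.", class = "eidyn_error_nonsquare")
  }
  if (nrow(weights) != ncol(weights)) {
    abort(
      sprintf("connectivity matrix must be square, got %d x %d",
              nrow(weights), ncol(weights)),
      class = "eidyn_error_nonsquare"
    )
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    abort("connectivity matrix contains NA/NaN/Inf entries",
          class = "eidyn_error_nonfinite")
  }
  if (any(weights < 0)) {
    abort("connectivity weights must be nonnegative",
          class = "eidyn_error_negative")
  }
  if (any(abs(diag(weights)) > tol)) {
    abort("connectivity matrix must have a zero diagonal (no self-coupling)",
          class = "eidyn_error_diagonal")
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > tol) {
    abort(
      sprintf("connectivity matrix is asymmetric (max |w - t(w)| = %.3g > tol = %.3g)",
              asym, tol),
      class = "eidyn_error_asymmetric"
    )
  }
  if (!is.null(labels) && length(labels) != nrow(weights)) {
    abort(
      sprintf("%d labels supplied for a %d-region matrix",
              length(labels), nrow(weights)),
      class = "eidyn_error_labels"
    )
  }
  invisible(weights)
}

#' Read a structural connectome from delimited text
#'
#' Reads a whitespace- or tab-delimited square weight matrix (optional header
#' row) and an optional sidecar label file (one region name per line). The
#' matrix is validated: it must be square, finite, nonnegative, symmetric
#' within `tol` and zero on the diagonal.
#'
#' @param path Path to the delimited matrix file.
#' @param labels_path Optional path to a label file, one region per line.
#' @param normalize If `TRUE`, divide all weights by the mean nodal strength
#'   (mean row sum) so the network has unit average strength.
#' @param tol Symmetry/diagonal tolerance passed to [validate_connectome()].
#' @return A `connectome` object: list with `weights`, `labels`, `n_regions`.
#' @seealso [synthetic_connectome()], [write_connectome()]
#' @export
read_connectome <- function(path, labels_path = NULL, normalize = FALSE,
                            tol = 1e-9) {
  first <- strsplit(trimws(readLines(path, n = 1L)), "[\t ]+")[[1]]
  numeric_like <- !is.na(suppressWarnings(as.numeric(first))) |
    toupper(first) %in% c("NAN", "NA", "INF", "-INF")
  has_header <- !all(numeric_like)
  df <- read.table(path, header = has_header, check.names = FALSE)
  weights <- as.matrix(df)
  if (!is.numeric(weights)) {
    abort("connectivity matrix contains non-numeric entries",
          class = "eidyn_error_nonfinite")
  }
  labels <- if (!is.null(labels_path)) {
    trimws(readLines(labels_path))
  } else if (has_header) {
    colnames(weights)
  } else {
    sprintf("R%03d", seq_len(nrow(weights)))
  }
  validate_connectome(weights, labels, tol = tol)
  if (normalize) {
    weights <- weights / mean(rowSums(weights))
  }
  new_connectome(weights, labels)
}

#' Write a connectome as delimited text
#'
#' Writes the weight matrix as a tab-separated file at full double precision
#' (so that write-then-read round-trips exactly) and, optionally, the region
#' labels to a sidecar file.
#'
#' @param x A `connectome` object.
#' @param path Output path for the matrix.
#' @param labels_path Optional output path for the labels.
#' @return `x`, invisibly.
#' @export
write_connectome <- function(x, path, labels_path = NULL) {
  stopifnot(inherits(x, "connectome"))
  lines <- apply(x$weights, 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = "\t")
  })
  writeLines(lines, path)
  if (!is.null(labels_path)) writeLines(x$labels, labels_path)
  invisible(x)
}

#' Cortical region labels of the 78-region AAL parcellation
#'
#' Returns the region names of the 78 cortical areas of the Automated
#' Anatomical Labeling atlas (the 90-region atlas without the 12 subcortical
#' structures), the parcellation on which the whole-brain model is defined.
#'
#' @return Character vector of length 78.
#' @export
aal78_labels <- function() {
  path <- system.file("extdata", "aal78_labels.txt", package = "eidyn",
                      mustWork = TRUE)
  trimws(readLines(path))
}

#' Generate a synthetic hub-heterogeneous structural connectome
#'
#' Builds a symmetric, zero-diagonal, connected, weighted random graph with a
#' heterogeneous degree distribution: edges are drawn with probability
#' proportional to the product of per-node attractiveness values
#' \eqn{a_i = i^{-\gamma/2}}, so low-index nodes become hubs. Edge weights are
#' uniform on (0.5, 1.5) and the whole matrix is rescaled so that the mean
#' nodal strength (mean row sum) equals `mean_strength`. The default strength
#' places the coupled neural-mass network just below its synchronization
#' transition at unit global coupling, which is where the study's balanced
#' model is meant to live.
#'
#' @param n_regions Number of regions (default 78, the cortical AAL count;
#'   78-region graphs get the AAL labels, other sizes generic `R###` labels).
#' @param edge_density Fraction of possible edges present, in (0, 1].
#' @param hub_exponent Nonnegative heterogeneity exponent \eqn{\gamma}; 0
#'   gives an Erdos-Renyi-like graph, larger values stronger hubs (default 2).
#' @param mean_strength Target mean nodal strength after rescaling.
#' @param seed Integer seed; identical seeds give bitwise-identical matrices.
#' @return A validated `connectome` object.
#' @examples
#' conn <- synthetic_connectome(n_regions = 20, seed = 1)
#' range(rowSums(conn$weights))
#' @export
synthetic_connectome <- function(n_regions = 78, edge_density = 0.15,
                                 hub_exponent = 2, mean_strength = 8,
                                 seed = 1) {
  if (n_regions < 2) abort("`n_regions` must be at least 2")
  if (edge_density <= 0 || edge_density > 1) {
    abort("`edge_density` must lie in (0, 1]")
  }
  n_pairs <- n_regions * (n_regions - 1) / 2
  m <- round(edge_density * n_pairs)
  if (m < n_regions - 1) {
    abort(sprintf(
      "edge density %.3g gives %d edges; at least %d are needed to connect %d regions",
      edge_density, m, n_regions - 1, n_regions
    ), class = "eidyn_error_density")
  }
  weights <- with_seed(as.integer(seed), {
    attract <- seq_len(n_regions)^(-hub_exponent / 2)
    pr <- outer(attract, attract)
    W <- matrix(0, n_regions, n_regions)
    iu <- which(upper.tri(W))
    sel <- sample(iu, m, prob = pr[iu])
    W[sel] <- runif(m, 0.5, 1.5)
    W <- W + t(W)
    # deterministically attach any disconnected component to the strongest hub
    repeat {
      comp <- igraph::components(
        igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
      )
      if (comp$no == 1L) break
      hub_comp <- comp$membership[1L]
      orphan <- which(comp$membership != hub_comp)[1L]
      W[1L, orphan] <- W[orphan, 1L] <- 1
    }
    W * (mean_strength / mean(rowSums(W)))
  })
  labels <- if (n_regions == 78) aal78_labels() else
    sprintf("R%03d", seq_len(n_regions))
  validate_connectome(weights, labels)
  new_connectome(weights, labels)
}

#' @export
print.connectome <- function(x, ...) {
  s <- rowSums(x$weights)
  cat(sprintf(
    "<connectome> %d regions, %d edges, nodal strength %.2f-%.2f (mean %.2f)\n",
    x$n_regions, sum(x$weights[upper.tri(x$weights)] > 0),
    min(s), max(s), mean(s)
  ))
  invisible(x)
}

#' Tidy a connectome into an edge table
#'
#' @param x A `connectome` object.
#' @param ... Unused.
#' @return A tibble with one row per (unordered) connected region pair:
#'   `region_a`, `region_b`, `weight`.
#' @method tidy connectome
#' @export
tidy.connectome <- function(x, ...) {
  idx <- which(upper.tri(x$weights) & x$weights > 0, arr.ind = TRUE)
  tibble(
    region_a = x$labels[idx[, 1L]],
    region_b = x$labels[idx[, 2L]],
    weight = x$weights[idx]
  ) |> arrange(.data$region_a, .data$region_b)
}
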