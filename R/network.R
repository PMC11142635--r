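#' Weighted brain network
#'
#' A `brain_network` holds a symmetric weighted adjacency matrix over labelled
#' ROIs, with weights in `[0, 1]`, a zero diagonal, and (optionally) the link
#' density at which it was thresholded. Weights play the role of per-step
#' transmission probabilities in the SIR seizure model, so the `[0, 1]` range
#' is enforced at construction.
#'
#' @param weights symmetric numeric matrix, values in `[0, 1]`, zero diagonal.
#'   Asymmetries up to `1e-9` are tolerated; larger ones are symmetrized by
#'   averaging with a warning.
#' @param labels character vector of ROI identifiers (defaults to the matrix
#'   dimnames, else `roi1..roiN`).
#' @param density fraction of retained off-diagonal link slots, if known.
#' @return an object of class `brain_network` with elements `weights`,
#'   `labels`, `density`.
#' @export
brain_network <- function(weights, labels = NULL, density = NA_real_) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("adjacency matrix must be square")
  if (anyNA(weights)) stop("adjacency matrix contains missing values")
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-9) {
    warning(sprintf("adjacency asymmetric (max |w_ij - w_ji| = %.3g); symmetrizing by averaging", asym))
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (min(weights) < 0 || max(weights) > 1)
    stop("weights must lie in [0, 1]")
  if (is.null(labels)) labels <- rownames(weights)
  if (is.null(labels)) labels <- paste0("roi", seq_len(nrow(weights)))
  if (length(labels) != nrow(weights)) stop("labels length must equal matrix dimension")
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = as.character(labels),
                 density = density),
            class = "brain_network")
}

#' @export
print.brain_network <- function(x, ...) {
  n <- n_roi(x)
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("brain_network: %d ROIs, %d links (density %.4f%s)\n",
              n, m, m / (n * (n - 1) / 2),
              if (is.na(x$density)) "" else sprintf(", thresholded at %.4f", x$density)))
  invisible(x)
}

#' Number of ROIs in a network
#' @param net a `brain_network`
#' @export
n_roi <- function(net) length(net$labels)

as_igraph <- function(net, convention = c("inverse_weight", "hop")) {
  convention <- match.arg(convention)
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$length <- if (convention == "hop") 1 else 1 / igraph::E(g)$weight
  }
  g
}

#' Threshold a network at a target link density
#'
#' Keeps the `round(rho * N(N-1)/2)` strongest links at their original
#' (non-binarized) weights and zeroes the rest. Ties at the cutoff are broken
#' by a stable ordering (weight descending, then row then column index), which
#' makes the retained link sets nested across densities.
#'
#' @param net a `brain_network`
#' @param rho target density in `(0, 1]`
#' @return a new thresholded `brain_network`; the input is not modified.
#' @export
threshold_density <- function(net, rho) {
  if (!is.numeric(rho) || length(rho) != 1 || is.na(rho) || rho <= 0 || rho > 1)
    stop("rho must be a single value in (0, 1]")
  n <- n_roi(net)
  ut <- which(upper.tri(net$weights), arr.ind = TRUE)
  w <- net$weights[ut]
  keep_n <- round(rho * n * (n - 1) / 2)
  nz <- sum(w > 0)
  if (nz < keep_n) {
    warning(sprintf("only %d nonzero links available but %d requested; keeping all", nz, keep_n))
    keep_n <- nz
  }
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(keep_n)]
  out <- matrix(0, n, n)
  out[ut[keep, , drop = FALSE]] <- w[keep]
  out <- out + t(out)
  brain_network(out, labels = net$labels, density = rho)
}

#' Density preserving the mean degree of a reference operating point
#'
#' Maps a reference sparsity (`ref_links` links among `ref_n` ROIs, default the
#' 904 links retained at density 0.03 on a 246-ROI atlas) onto a network of
#' `n` ROIs by preserving the mean degree, so that smaller surrogate networks
#' stay connected and dynamically comparable.
#'
#' @param n number of ROIs of the target network
#' @param ref_links,ref_n links and ROI count of the reference network
#' @return equivalent density in `(0, 1]`
#' @export
equivalent_density <- function(n, ref_links = 904, ref_n = 246) {
  rho <- 2 * ref_links / (ref_n * (n - 1))
  min(1, rho)
}

#' Log-spaced density (or recovery-rate) grid
#'
#' @param n number of grid points
#' @param range two-element numeric range, both endpoints positive
#' @return strictly increasing numeric vector, log-spaced inclusive of both ends
#' @export
log_grid <- function(n = 12, range = c(0.01, 0.35)) {
  if (n < 2 || any(range <= 0)) stop("need n >= 2 and a positive range")
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' All-pairs shortest-path distances
#'
#' @param net a `brain_network`
#' @param convention `"inverse_weight"` (edge length `1/w_ij`, the standard
#'   weighted-efficiency convention, default) or `"hop"` (unit lengths)
#' @return symmetric matrix of distances; `Inf` for disconnected pairs, zero
#'   diagonal. Carries the convention in `attr(, "convention")`.
#' @export
shortest_path_distances <- function(net, convention = c("inverse_weight", "hop")) {
  convention <- match.arg(convention)
  g <- as_igraph(net, convention)
  d <- if (igraph::ecount(g) == 0) {
    m <- matrix(Inf, n_roi(net), n_roi(net)); diag(m) <- 0; m
  } else {
    igraph::distances(g, weights = igraph::E(g)$length)
  }
  dimnames(d) <- list(net$labels, net$labels)
  attr(d, "convention") <- convention
  d
}

#' Giant (largest) connected component
#'
#' Ties between equally sized components are broken toward the component
#' containing the smallest ROI index.
#'
#' @param net a `brain_network`
#' @return integer vector of ROI indices in the giant component
#' @export
giant_component <- function(net) {
  sort(cpp_giant_component(net$weights))
}

#' Generate an exponential-distance-rule surrogate connectome
#'
#' Structural connection weights in the brain decay roughly exponentially with
#' inter-regional distance; this generator builds `w_ij = exp(-alpha * d_ij)`
#' from 3-D ROI coordinates and affinely rescales the off-diagonal weights
#' into `rescale_range`. The default range `[0.5, 1]` mimics the amplitude
#' envelope correlation convention in which 0.5 denotes no coupling, so that
#' surrogate networks inhabit the same weight range as patient networks.
#'
#' @param n_roi number of ROIs (>= 2); ignored if `coordinates` given
#' @param alpha exponential decay rate per unit distance (>= 0)
#' @param coordinates optional `n x 3` matrix of ROI positions; when `NULL`,
#'   two-cluster ("two hemisphere") random coordinates are drawn
#' @param rescale_range target weight interval, or `NULL` to keep the raw
#'   `exp(-alpha d)` weights
#' @param seed RNG seed used when coordinates are generated
#' @return a `brain_network` with the coordinates attached as
#'   `attr(, "coordinates")`
#' @export
generate_edr_network <- function(n_roi, alpha, coordinates = NULL,
                                 rescale_range = c(0.5, 1), seed = NULL) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (is.null(coordinates)) {
    if (n_roi < 2) stop("need n_roi >= 2")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    coordinates <- two_cluster_coordinates(n_roi)
  }
  coordinates <- as.matrix(coordinates)
  n <- nrow(coordinates)
  d <- as.matrix(stats::dist(coordinates))
  if (max(d) <= 0) stop("degenerate coordinates: all ROIs coincide")
  w <- exp(-alpha * d)
  diag(w) <- 0
  if (!is.null(rescale_range)) {
    off <- w[upper.tri(w)]
    lo <- min(off); hi <- max(off)
    if (hi - lo < 1e-12) {
      w[] <- rescale_range[2]
    } else {
      w <- rescale_range[1] + (w - lo) / (hi - lo) * diff(rescale_range)
    }
    diag(w) <- 0
  }
  net <- brain_network(w)
  attr(net, "coordinates") <- coordinates
  net
}

#' Random two-cluster ROI coordinates
#'
#' Draws `n` 3-D positions split between two Gaussian clusters ("hemispheres")
#' centred at `(-separation/2, 0, 0)` and `(+separation/2, 0, 0)`.
#'
#' @param n number of ROIs
#' @param separation distance between cluster centres
#' @param sd within-cluster standard deviation per axis
#' @return `n x 3` numeric matrix
#' @export
two_cluster_coordinates <- function(n, separation = 2, sd = 1) {
  half <- c(rep(-separation / 2, ceiling(n / 2)), rep(separation / 2, floor(n / 2)))
  cbind(half + stats::rnorm(n, sd = sd),
        stats::rnorm(n, sd = sd),
        stats::rnorm(n, sd = sd))
}

#' Read / write adjacency matrices
#'
#' TSV/CSV with ROI labels in the first row and column. The reader checks
#' symmetry to `1e-9` and symmetrizes by averaging with a warning otherwise.
#'
#' @param path file path; delimiter inferred from the extension (`.csv` comma,
#'   otherwise tab)
#' @return `read_adjacency`: a `brain_network`
#' @export
read_adjacency <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE)
  brain_network(as.matrix(df), labels = rownames(df))
}

#' @param net a `brain_network` to write
#' @rdname read_adjacency
#' @export
write_adjacency <- function(net, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- as.data.frame(net$weights)
  utils::write.table(cbind(roi = net$labels, df), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ROI coordinates
#'
#' CSV with columns `roi,x,y,z`.
#' @param path file path
#' @return matrix with rownames = ROI labels
#' @export
read_coordinates <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("roi", "x", "y", "z") %in% names(df)))
  m <- as.matrix(df[, c("x", "y", "z")])
  rownames(m) <- df$roi
  m
}
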