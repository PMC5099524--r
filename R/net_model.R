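#' Weighted network objects
#'
#' A `hs_network` wraps a symmetric, signed, zero-diagonal weight matrix over
#' labelled nodes — the natural container for a region-by-region functional
#' connectivity matrix of Fisher-z-transformed correlations, but any symmetric
#' weighted graph fits. Node order is fixed at construction and every
#' downstream matrix and metric vector uses it.
#'
#' @param W square numeric matrix of edge weights. Small asymmetries (below
#'   `tol`) are symmetrised by averaging; larger asymmetry is an error. A
#'   nonzero diagonal is forced to zero with a warning.
#' @param labels character vector of unique node labels; defaults to the
#'   matrix dimnames or `V1..Vn`.
#' @param tol asymmetry tolerance (default `1e-9`).
#' @return An object of class `hs_network` with fields `n_nodes`, `labels`
#'   and `W`.
#' @examples
#' net <- weighted_network(matrix(c(0, 1, 1, 0), 2), labels = c("a", "b"))
#' net$W
#' @export
weighted_network <- function(W, labels = NULL, tol = 1e-9) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) {
    stop("weight matrix must be square, got ", nrow(W), " x ", ncol(W))
  }
  if (anyNA(W)) stop("weight matrix contains NA/NaN entries")
  storage.mode(W) <- "double"
  asym <- max(abs(W - t(W)))
  if (asym > tol) {
    stop("matrix is asymmetric beyond tolerance (max |W - t(W)| = ",
         format(asym), ")")
  }
  if (asym > 0) W <- (W + t(W)) / 2
  if (any(diag(W) != 0)) {
    warning("nonzero diagonal entries set to zero (self-loops are not allowed)")
    diag(W) <- 0
  }
  n <- nrow(W)
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(W))) rownames(W) else paste0("V", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) stop("need ", n, " labels, got ", length(labels))
  if (anyDuplicated(labels)) stop("node labels must be unique")
  dimnames(W) <- list(labels, labels)
  structure(list(n_nodes = n, labels = labels, W = W), class = "hs_network")
}

#' @export
print.hs_network <- function(x, ...) {
  nz <- sum(x$W[upper.tri(x$W)] != 0)
  cat("<hs_network> ", x$n_nodes, " nodes, ", nz, " nonzero edges\n", sep = "")
  invisible(x)
}

#' Read a weighted network from delimited text
#'
#' Two dialects are supported. `"matrix"`: a square numeric table, comma- or
#' tab-delimited, with an optional first header row of node labels.
#' `"edge-list"`: three columns `nodeA,nodeB,weight`; nodes appear in file
#' order and unlisted pairs get weight zero. `"auto"` sniffs the dialect from
#' the first line.
#'
#' @param path file to read.
#' @param format one of `"auto"`, `"matrix"`, `"edge-list"`.
#' @return A [weighted_network()] object.
#' @seealso [write_network()] for the mirror-image writers.
#' @export
read_network <- function(path, format = c("auto", "matrix", "edge-list")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    ncol1 <- length(strsplit(first, "[,\t]")[[1]])
    format <- if (ncol1 == 3L) "edge-list" else "matrix"
  }
  if (format == "matrix") {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    fields <- strsplit(first, sep, fixed = TRUE)[[1]]
    has_header <- anyNA(suppressWarnings(as.numeric(fields)))
    tab <- read.table(path, header = has_header, sep = sep,
                      check.names = FALSE, stringsAsFactors = FALSE)
    M <- as.matrix(tab)
    if (!is.numeric(M)) stop("matrix file contains non-numeric entries")
    labels <- if (has_header) colnames(tab) else NULL
    weighted_network(M, labels = labels)
  } else {
    sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
    el <- read.table(path, header = FALSE, sep = sep,
                     stringsAsFactors = FALSE,
                     col.names = c("from", "to", "weight"))
    if (anyNA(el$weight)) stop("edge list contains non-numeric weights")
    labels <- unique(c(rbind(as.character(el$from), as.character(el$to))))
    n <- length(labels)
    W <- matrix(0, n, n, dimnames = list(labels, labels))
    key <- paste(pmin(el$from, el$to), pmax(el$from, el$to))
    dup <- duplicated(key)
    if (any(dup)) {
      w_first <- el$weight[match(key[dup], key)]
      if (any(w_first != el$weight[dup])) {
        stop("duplicate edge-list rows with conflicting weights")
      }
      el <- el[!dup, , drop = FALSE]
    }
    for (r in seq_len(nrow(el))) {
      i <- el$from[r]; j <- el$to[r]
      W[i, j] <- el$weight[r]
      W[j, i] <- el$weight[r]
    }
    weighted_network(W, labels = labels)
  }
}

#' Write a weighted network as delimited text
#'
#' Writers mirror [read_network()] bit-exactly: `load(save(net))` returns the
#' same weights. The matrix dialect writes a label header row; the edge-list
#' dialect writes only nonzero edges `i < j`, ordered by `(max index, min
#' index)` so the reader's first-appearance node order reconstructs the label
#' order whenever every node beyond the first has a lower-indexed neighbour;
#' isolated nodes cannot be represented in the three-column dialect.
#'
#' @param net a [weighted_network()] object.
#' @param path destination file.
#' @param format `"matrix"` or `"edge-list"`.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("matrix", "edge-list"),
                          sep = ",") {
  stopifnot(inherits(net, "hs_network"))
  format <- match.arg(format)
  if (format == "matrix") {
    lines <- c(paste(net$labels, collapse = sep),
               apply(net$W, 1L, function(r) {
                 paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
                       collapse = sep)
               }))
    writeLines(lines, path)
  } else {
    idx <- which(upper.tri(net$W) & net$W != 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
    lines <- sprintf("%s%s%s%s%s", net$labels[idx[, 1]], sep,
                     net$labels[idx[, 2]], sep,
                     format(net$W[idx], digits = 17, trim = TRUE,
                            scientific = FALSE))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Functional connectivity matrix from regional time series
#'
#' Computes all pairwise Pearson correlations between the rows of `X` and
#' maps them through the Fisher z-transform `atanh(r)`; the diagonal is set
#' to zero. Correlations are clipped to `1 - 1e-12` in magnitude before the
#' transform so perfectly correlated regions yield a large finite weight
#' rather than infinity.
#'
#' @param X numeric matrix, regions in rows and timepoints in columns
#'   (at least 3).
#' @param labels optional region labels (default rownames or `R1..Rn`).
#' @return A [weighted_network()] of Fisher-z connectivity weights.
#' @export
fc_matrix <- function(X, labels = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 3L) stop("need at least 3 timepoints, got ", ncol(X))
  v <- apply(X, 1L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    nm <- if (!is.null(rownames(X))) rownames(X)[bad] else bad
    stop("zero-variance region(s): ", paste(nm, collapse = ", "))
  }
  R <- stats::cor(t(X))
  R <- pmin(pmax(R, -(1 - 1e-12)), 1 - 1e-12)
  Z <- atanh(R)
  diag(Z) <- 0
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(X))) rownames(X) else
      paste0("R", seq_len(nrow(X)))
  }
  weighted_network(Z, labels = labels)
}

#' Group-average connectivity matrix
#'
#' Element-wise arithmetic mean of per-subject connectivity matrices; all
#' inputs must share shape and label order.
#'
#' @param nets list of [weighted_network()] objects.
#' @return A [weighted_network()] holding the mean weight matrix.
#' @export
fc_group_average <- function(nets) {
  stopifnot(length(nets) >= 1L, all(vapply(nets, inherits, TRUE, "hs_network")))
  ref <- nets[[1L]]
  for (net in nets[-1L]) {
    if (net$n_nodes != ref$n_nodes || !identical(net$labels, ref$labels)) {
      stop("all matrices must share shape and label order")
    }
  }
  M <- Reduce(`+`, lapply(nets, `[[`, "W")) / length(nets)
  weighted_network(M, labels = ref$labels)
}

#' Edge table of a weighted network
#'
#' @param net a [weighted_network()] object.
#' @param keep_zero keep zero-weight pairs? Default drops them.
#' @return A tibble with columns `from`, `to`, `weight` (`from < to` in node
#'   order).
#' @export
network_edges <- function(net, keep_zero = FALSE) {
  stopifnot(inherits(net, "hs_network"))
  idx <- which(upper.tri(net$W), arr.ind = TRUE)
  out <- tibble::tibble(
    from = net$labels[idx[, 1]],
    to = net$labels[idx[, 2]],
    weight = net$W[idx]
  )
  out <- out[order(idx[, 1], idx[, 2]), ]
  if (!keep_zero) out <- out[out$weight != 0, ]
  out
}
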