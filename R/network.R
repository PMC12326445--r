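#' Construct a weighted network from an adjacency matrix
#'
#' A `weighted_network` wraps a symmetric, non-negative adjacency matrix with
#' node labels and a tag identifying the edge-weighting scheme (for diffusion
#' connectomes typically one of FA, MD, SC, OD, ISOVF, ICVF). The matrix is
#' validated on construction: the diagonal is zeroed (self-loops removed),
#' asymmetries beyond `tol` are an error, and small numerical asymmetries are
#' symmetrised by averaging. A weight of zero means "no edge".
#'
#' @param weights Square numeric matrix of non-negative edge weights.
#' @param node_labels Character vector of region identifiers; defaults to the
#'   matrix dimnames or `R1..Rn`.
#' @param weight_kind Tag naming the weighting scheme (free-form; conventional
#'   values are `"FA"`, `"MD"`, `"SC"`, `"OD"`, `"ISOVF"`, `"ICVF"`,
#'   `"other"`).
#' @param tol Absolute tolerance for symmetry; larger asymmetries raise an
#'   error rather than being silently averaged.
#' @return An object of class `weighted_network`.
#' @examples
#' w <- matrix(c(0, 1, 2, 1, 0, 0, 2, 0, 0), 3, 3)
#' net <- weighted_network(w)
#' node_strengths(net)
#' @export
weighted_network <- function(weights, node_labels = NULL,
                             weight_kind = "other", tol = 1e-10) {
  weights <- as.matrix(weights)
  if (!is.numeric(weights) || nrow(weights) != ncol(weights)) {
    stop("`weights` must be a square numeric matrix", call. = FALSE)
  }
  n <- nrow(weights)
  if (anyNA(weights)) stop("`weights` contains missing values", call. = FALSE)
  if (any(weights < 0)) {
    stop("negative edge weights are not allowed", call. = FALSE)
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > tol) {
    stop(sprintf("adjacency matrix asymmetric beyond tolerance (max |W - t(W)| = %.3g)",
                 asym), call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(node_labels)) {
    node_labels <- rownames(weights) %||% paste0("R", seq_len(n))
  }
  if (length(node_labels) != n) {
    stop("`node_labels` length must match matrix dimension", call. = FALSE)
  }
  dimnames(weights) <- list(node_labels, node_labels)
  structure(
    list(weights = weights, node_labels = as.character(node_labels),
         weight_kind = weight_kind),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  m <- sum(x$weights > 0) / 2
  cat(sprintf("<weighted_network> %d nodes, %d edges, weight kind: %s\n",
              length(x$node_labels), m, x$weight_kind))
  invisible(x)
}

n_nodes <- function(net) length(net$node_labels)

#' Read a weighted network from a text file
#'
#' Dense format is an n-by-n numeric grid (CSV or TSV), optionally carrying
#' node labels in a header row and first column. Edge-list format is a
#' three-column table `(label_i, label_j, weight)`; duplicate and reciprocal
#' rows must agree in weight and are stored once.
#'
#' @param path Path to the file.
#' @param format `"dense"` or `"edgelist"`.
#' @param weight_kind Weighting-scheme tag stored on the network.
#' @param tol Symmetry tolerance passed to [weighted_network()].
#' @return A `weighted_network`.
#' @export
read_network <- function(path, format = c("dense", "edgelist"),
                         weight_kind = "other", tol = 1e-10) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "dense") {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
    # header detection: a labelled file has non-numeric tokens past column 1
    tokens <- strsplit(first, delim, fixed = TRUE)[[1]]
    has_header <- suppressWarnings(any(is.na(as.numeric(tokens[-1]))))
    tab <- utils::read.table(path, sep = delim, header = has_header,
                             row.names = if (has_header) 1 else NULL,
                             check.names = FALSE)
    m <- as.matrix(tab)
    if (nrow(m) != ncol(m)) {
      stop("dense adjacency file is not square: ", nrow(m), " x ", ncol(m),
           call. = FALSE)
    }
    suppressWarnings(storage.mode(m) <- "double")
    if (anyNA(m)) {
      stop("dense adjacency file contains non-numeric entries", call. = FALSE)
    }
    labels <- if (has_header) colnames(m) else NULL
    weighted_network(m, node_labels = labels, weight_kind = weight_kind,
                     tol = tol)
  } else {
    tab <- utils::read.table(path, sep = ",", header = FALSE,
                             col.names = c("from", "to", "weight"),
                             colClasses = c("character", "character", "numeric"))
    labels <- sort(unique(c(tab$from, tab$to)))
    n <- length(labels)
    m <- matrix(0, n, n, dimnames = list(labels, labels))
    for (k in seq_len(nrow(tab))) {
      i <- tab$from[k]; j <- tab$to[k]; w <- tab$weight[k]
      if (w < 0) stop("negative edge weight in edge list", call. = FALSE)
      if (m[i, j] != 0 && abs(m[i, j] - w) > 1e-12) {
        stop(sprintf("conflicting duplicate edge (%s, %s)", i, j),
             call. = FALSE)
      }
      m[i, j] <- w
      m[j, i] <- w
    }
    weighted_network(m, node_labels = labels, weight_kind = weight_kind,
                     tol = tol)
  }
}

#' Bundle aligned subject networks into a cohort
#'
#' All member networks must share node count and node label order. Metadata is
#' an optional per-subject table (age, sex, site, global volumes, ...) aligned
#' with `subject_ids`.
#'
#' @param networks List of `weighted_network` objects, one per subject.
#' @param subject_ids Unique subject identifiers; default `S1..Sk`.
#' @param metadata Optional data frame with one row per subject.
#' @return An object of class `cohort`.
#' @export
cohort <- function(networks, subject_ids = NULL, metadata = NULL) {
  if (length(networks) == 0) stop("cohort must contain at least one network",
                                  call. = FALSE)
  if (!all(vapply(networks, inherits, logical(1), "weighted_network"))) {
    stop("all cohort members must be weighted_network objects", call. = FALSE)
  }
  labs <- networks[[1]]$node_labels
  same <- vapply(networks, function(x) identical(x$node_labels, labs),
                 logical(1))
  if (!all(same)) stop("all networks must share node labels and order",
                       call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_along(networks))
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique",
                                       call. = FALSE)
  if (length(subject_ids) != length(networks)) {
    stop("subject_ids must align with networks", call. = FALSE)
  }
  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)
    if (nrow(metadata) != length(networks)) {
      stop("metadata rows must align with networks", call. = FALSE)
    }
  }
  structure(list(networks = networks, subject_ids = subject_ids,
                 metadata = metadata, node_labels = labs),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d nodes\n",
              length(x$subject_ids), length(x$node_labels)))
  invisible(x)
}

#' Cohort-level proportional thresholding
#'
#' Retains only the edges present (weight > 0) in at least
#' `prevalence_threshold` of the cohort's subjects; "at least" is inclusive,
#' so with four subjects and threshold 0.5 an edge seen in two of them is
#' kept. Returns both the boolean edge mask and a new cohort with masked-out
#' entries set to zero. For multi-weighting studies the mask should be derived
#' once from the reference weighting (streamline count, if present) and
#' applied to every other weighting of the same subjects via `apply_mask()`.
#'
#' @param x A `cohort`.
#' @param prevalence_threshold Fraction in (0, 1]; default 0.5.
#' @return A list with elements `mask` (an `edge_mask`: symmetric logical
#'   matrix plus the threshold used) and `cohort` (the masked cohort).
#' @examples
#' nets <- replicate(3, weighted_network(matrix(c(0, 1, 1, 0), 2)),
#'                   simplify = FALSE)
#' group_threshold(cohort(nets), 0.5)$mask$keep
#' @export
group_threshold <- function(x, prevalence_threshold = 0.5) {
  stopifnot(inherits(x, "cohort"))
  if (prevalence_threshold <= 0 || prevalence_threshold > 1) {
    stop("prevalence_threshold must lie in (0, 1]", call. = FALSE)
  }
  n <- length(x$node_labels)
  presence <- Reduce(`+`, lapply(x$networks, function(w) (w$weights > 0) * 1))
  keep <- presence / length(x$networks) >= prevalence_threshold
  diag(keep) <- FALSE
  mask <- structure(list(keep = keep,
                         prevalence_threshold = prevalence_threshold),
                    class = "edge_mask")
  list(mask = mask, cohort = apply_mask(x, mask))
}

#' Apply an edge mask to a cohort
#'
#' Zeroes every edge not retained by the mask, for every subject. Used to
#' propagate a mask derived from one weighting (e.g. streamline count) to the
#' other weightings of the same subjects.
#'
#' @param x A `cohort`.
#' @param mask An `edge_mask` from [group_threshold()].
#' @return The masked `cohort`.
#' @export
apply_mask <- function(x, mask) {
  stopifnot(inherits(x, "cohort"), inherits(mask, "edge_mask"))
  if (!identical(dim(mask$keep), dim(x$networks[[1]]$weights))) {
    stop("mask dimension does not match cohort networks", call. = FALSE)
  }
  nets <- lapply(x$networks, function(net) {
    net$weights[!mask$keep] <- 0
    net
  })
  cohort(nets, x$subject_ids, x$metadata)
}

#' Write a subjects-by-measures table to CSV
#'
#' Values are serialised as decimal text with 12 significant digits so a
#' round-trip read reproduces them to that precision. Column names encode the
#' measure, weighting and parameters (e.g. `hrsv_w4_FA`).
#'
#' @param table Tibble with a `subject_id` column and numeric measure columns.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_measure_table <- function(table, path) {
  if (nrow(table) == 0 || ncol(table) == 0) {
    stop("measure table is empty", call. = FALSE)
  }
  if (!"subject_id" %in% names(table)) {
    stop("measure table must carry a subject_id column", call. = FALSE)
  }
  out <- dplyr::mutate(table, dplyr::across(
    dplyr::where(is.numeric), ~ formatC(.x, digits = 12, format = "g")))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measure table written by [write_measure_table()]
#'
#' @param path Path to the CSV.
#' @return A tibble with `subject_id` as character and measures numeric.
#' @export
read_measure_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(subject_id = "character"))
  tibble::as_tibble(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
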