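#' Correlations between AWM row profiles
#'
#' Pearson correlation of every pair of AWM rows across the trait columns.
#' Two genes are co-associated when their multi-trait effect profiles move
#' together; these correlations are the input of [pcit_filter()].
#'
#' @param awm an `"awm"` object or a numeric rows-by-traits matrix with at
#'   least 3 columns.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
row_correlations <- function(awm) {
  M <- if (inherits(awm, "awm")) awm$M else as.matrix(awm)
  if (ncol(M) < 3) stop("row_correlations: need at least 3 trait columns")
  rs <- apply(M, 1, stats::sd)
  if (any(rs == 0))
    stop("row_correlations: constant row(s): ",
         paste(rownames(M)[rs == 0], collapse = ", "))
  C <- stats::cor(t(M))
  diag(C) <- 1
  C
}

#' First-order partial correlation
#'
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`: the
#' correlation between x and y once their shared dependence on z is removed.
#'
#' @param rxy,rxz,ryz pairwise Pearson correlations in \[-1,1\];
#'   vectorised.
#' @return partial correlation(s).
#' @export
partial_correlation <- function(rxy, rxz, ryz) {
  if (any(abs(c(rxy, rxz, ryz)) > 1 + 1e-12))
    stop("partial_correlation: correlations must lie in [-1,1]")
  if (any(abs(rxz) >= 1) || any(abs(ryz) >= 1))
    stop("partial_correlation: undefined when |rxz| = 1 or |ryz| = 1")
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' PCIT co-association network
#'
#' Partial correlation and information theory filtering: for every node trio
#' the three first-order partial correlations define a local tolerance
#' (the mean of the absolute partial-to-direct ratios), and an association
#' x-y is flagged non-significant by a trio z when `|r_xy|` does not exceed
#' the tolerance times either `|r_xz|` or `|r_yz|`. An edge enters the
#' network iff no trio flags it. Surviving edges with `|r|` below a 1e-12
#' noise floor are dropped.
#'
#' @param C correlation matrix (symmetric, unit diagonal, n >= 3).
#' @return object of class `"coassoc_network"`: list with `nodes`
#'   (character) and `edges` (data.frame `a`, `b`, `weight`), each
#'   undirected pair recorded once with `a < b` in node order.
#' @export
pcit_filter <- function(C) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (n < 3) stop("pcit_filter: need at least 3 nodes")
  if (n != ncol(C) || max(abs(C - t(C))) > 1e-8)
    stop("pcit_filter: correlation matrix must be square and symmetric")
  nodes <- rownames(C)
  if (is.null(nodes)) nodes <- sprintf("N%04d", seq_len(n))
  keep <- pcit_keep_cpp(C)
  idx <- which(upper.tri(C) & keep & abs(C) >= 1e-12, arr.ind = TRUE)
  edges <- data.frame(
    a = nodes[idx[, 1]],
    b = nodes[idx[, 2]],
    weight = C[idx],
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges), class = "coassoc_network")
}

#' @export
print.coassoc_network <- function(x, ...) {
  cat("Co-association network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Summarise a co-association network
#'
#' Node and edge counts, density `2E / (N (N - 1))`, per-node degree, and
#' the best-connected nodes (a plain degree-based stand-in for clique-
#' density colouring).
#'
#' @param net a `"coassoc_network"`.
#' @param n_top how many top-degree nodes to list.
#' @return list `n_nodes`, `n_edges`, `density`, `degree` (named), `top`
#'   (data.frame `node`, `degree`).
#' @export
network_summary <- function(net, n_top = 10) {
  stopifnot(inherits(net, "coassoc_network"))
  deg <- setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    t1 <- table(factor(net$edges$a, levels = net$nodes))
    t2 <- table(factor(net$edges$b, levels = net$nodes))
    deg <- setNames(as.integer(t1 + t2), net$nodes)
  }
  n <- length(net$nodes)
  dens <- if (n > 1) 2 * nrow(net$edges) / (n * (n - 1)) else 0
  ord <- order(-deg, names(deg))
  list(
    n_nodes = n,
    n_edges = nrow(net$edges),
    density = dens,
    degree = deg,
    top = data.frame(node = names(deg)[ord], degree = deg[ord],
                     row.names = NULL)[seq_len(min(n_top, n)), ]
  )
}
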