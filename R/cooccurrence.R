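#' Taxon-taxon co-occurrence network
#'
#' Correlates all taxon pairs (both kingdoms in one family), keeps an edge
#' when |rho| >= `rho_min` and BH-adjusted q < `alpha` (BH over all taxon
#' pairs), and records each node's strength = sum of |rho| over incident
#' edges. Positive and negative edges are both kept, with the sign recorded.
#'
#' @param abund an [abundance_table()], typically prefiltered to the Major
#'   group.
#' @param method correlation method.
#' @param rho_min absolute correlation threshold for an edge.
#' @param alpha FDR threshold.
#' @return a `cooccurrence_network`: list(nodes, kingdom, edges =
#'   data.frame(taxon_a, taxon_b, rho, p, q, sign), strengths).
#' @export
build_network <- function(abund, method = c("spearman", "pearson"),
                          rho_min = 0.6, alpha = 0.05) {
  method <- match.arg(method)
  A <- abund$values
  if (nrow(A) < 2) stop("need at least 2 taxa after filtering")
  if (ncol(A) < 4) stop("need at least 4 samples")
  pairs <- t(combn(rownames(A), 2))
  res <- apply(pairs, 1, function(pr) {
    x <- A[pr[1], ]; y <- A[pr[2], ]
    if (sd(x) == 0 || sd(y) == 0) return(c(0, 1))
    ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  })
  edges <- data.frame(taxon_a = pairs[, 1], taxon_b = pairs[, 2],
                      rho = res[1, ], p = res[2, ], stringsAsFactors = FALSE)
  edges$q <- p.adjust(edges$p, method = "BH")
  keep <- abs(edges$rho) >= rho_min & edges$q < alpha
  edges <- edges[keep, , drop = FALSE]
  edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  rownames(edges) <- NULL
  strengths <- setNames(numeric(nrow(A)), rownames(A))
  for (i in seq_len(nrow(edges))) {
    w <- abs(edges$rho[i])
    strengths[edges$taxon_a[i]] <- strengths[edges$taxon_a[i]] + w
    strengths[edges$taxon_b[i]] <- strengths[edges$taxon_b[i]] + w
  }
  structure(list(nodes = rownames(A), kingdom = abund$kingdom,
                 edges = edges, strengths = strengths,
                 method = method, rho_min = rho_min, alpha = alpha),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("cooccurrence_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (", sum(x$edges$sign == "positive"), "positive )\n")
  invisible(x)
}

#' Strong-node (hub) taxa of a co-occurrence network
#'
#' Hubs are taxa whose strength (weighted degree) is at or above the given
#' quantile of the positive-strength distribution. Isolated nodes
#' (strength 0) never qualify; ties at the cutoff are all included.
#'
#' @param net a `cooccurrence_network`.
#' @param quantile quantile of the positive strengths (default 0.8, i.e.
#'   the top 20% of connected nodes).
#' @return character vector of hub taxa (empty, with a warning, if every
#'   node is isolated).
#' @export
hub_taxa <- function(net, quantile = 0.8) {
  pos <- net$strengths[net$strengths > 0]
  if (!length(pos)) {
    warning("all nodes isolated; no hubs")
    return(character(0))
  }
  cut <- stats::quantile(pos, quantile, names = FALSE, type = 7)
  sort(names(pos)[pos >= cut])
}

#' Write the network edge list as TSV and, optionally, GraphML
#'
#' @param net a `cooccurrence_network`.
#' @param path output TSV path.
#' @param graphml optional GraphML path for external viewers.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, graphml = NULL) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("taxon_a", "taxon_b", "rho", "q", "sign")],
      directed = FALSE,
      vertices = data.frame(name = net$nodes,
                            kingdom = unname(net$kingdom[net$nodes]),
                            strength = unname(net$strengths[net$nodes])))
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}
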