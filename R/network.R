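ham <- function(a, b) sum(a != b)

seq_matrix <- function(seqs) {
  do.call(rbind, strsplit(seqs, ""))
}

#' Pairwise Hamming distance matrix between haplotypes
#'
#' @param table A `haplotype_table` (distances are computed on its retained
#'   columns), or a character vector of equal-length sequences.
#' @return A symmetric integer matrix with zero diagonal.
#' @export
distance_matrix <- function(table) {
  seqs <- if (inherits(table, "haplotype_table")) {
    stats::setNames(table$haplotypes$sequence, table$haplotypes$label)
  } else table
  if (length(seqs) == 0L) stop("no haplotypes")
  m <- seq_matrix(seqs)
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1)
    for (i in seq_len(n - 1))
      for (j in seq.int(i + 1, n))
        d[i, j] <- d[j, i] <- ham(m[i, ], m[j, ])
  d
}

## minimax connection weights: delta[i,j] = min over paths of the maximum
## edge weight (Floyd-Warshall on the complete distance graph)
minimax_matrix <- function(d) {
  n <- nrow(d)
  g <- d
  for (k in seq_len(n)) {
    gk <- pmax(matrix(g[, k], n, n), matrix(g[k, ], n, n, byrow = TRUE))
    g <- pmin(g, gk)
  }
  g
}

## epsilon-relaxed minimum spanning network: edge (i,j) kept iff
## d(i,j) <= minimax(i,j) + eps.  For eps = 0 this is the union of all
## minimum spanning trees.
msn_edges <- function(d, eps = 0L) {
  n <- nrow(d)
  if (n < 2) return(cbind(i = integer(0), j = integer(0), w = integer(0)))
  mm <- minimax_matrix(d)
  out <- NULL
  for (i in seq_len(n - 1))
    for (j in seq.int(i + 1, n))
      if (d[i, j] <= mm[i, j] + eps)
        out <- rbind(out, c(i, j, d[i, j]))
  colnames(out) <- c("i", "j", "w")
  out
}

## majority-consensus median of three rows of a symbol matrix.  Only
## defined when every column has a majority symbol (>= 2 of 3 agree): the
## consensus is then a true Steiner point lying on the geodesic between
## each pair, so inserting it never stretches network distances.  Returns
## NULL for triples with an all-distinct column.
median_vector <- function(m3) {
  out <- character(ncol(m3))
  for (j in seq_len(ncol(m3))) {
    col <- m3[, j]
    t <- sort(table(col), decreasing = TRUE)
    if (t[1] < 2) return(NULL)
    out[j] <- names(t)[1]
  }
  out
}

#' Build a median-joining haplotype network
#'
#' Implements the median-joining construction for multistate sequence data:
#' starting from the epsilon-relaxed minimum spanning network over the
#' observed haplotypes, consensus (median) vectors of connected triplets
#' are proposed and added greedily whenever they reduce the total network
#' connection cost; after convergence, median nodes of degree <= 2 are
#' pruned (they offer no shortcut).  `epsilon = 0` is the most conservative
#' setting: no relaxation beyond the minimum spanning criterion.
#'
#' The procedure is deterministic: haplotypes enter in canonical order
#' (descending count, then lexicographic sequence) and ties in median
#' proposal and insertion follow that order.
#'
#' At `epsilon = 0` the spanning stage (before median insertion) is exactly
#' the union of all minimum spanning trees of the observed haplotypes;
#' after median insertion the same guarantee holds relative to the
#' network's full node set.  [min_spanning_network()] exposes the spanning
#' stage directly.
#'
#' @param table A `haplotype_table`.
#' @param epsilon Non-negative integer relaxation of the connection cost.
#' @param prune Remove obsolete median vectors (default TRUE).
#' @param medians Propose and insert median vectors (default TRUE); with
#'   `FALSE` the epsilon-relaxed minimum spanning network is returned.
#' @return An object of class `haplotype_network`: `nodes` (data.frame of
#'   `name`, `sequence`, `type`, `count`), `edges` (data.frame of `from`,
#'   `to`, `weight`, `positions`), `members`, `columns`.
#' @export
build_mjn <- function(table, epsilon = 0L, prune = TRUE, medians = TRUE) {
  stopifnot(inherits(table, "haplotype_table"), epsilon >= 0)
  seqs <- table$haplotypes$sequence
  names(seqs) <- table$haplotypes$label
  if (length(unique(nchar(seqs))) > 1L) stop("haplotype sequences differ in length")
  mat <- seq_matrix(seqs)
  rownames(mat) <- names(seqs)
  type <- rep("observed", nrow(mat))
  n_med <- 0L

  net_cost <- function(mat) {
    d <- dist_from_mat(mat)
    e <- msn_edges(d, epsilon)
    sum(e[, "w"])
  }
  dist_from_mat <- function(mat) {
    n <- nrow(mat)
    d <- matrix(0L, n, n)
    if (n > 1)
      for (i in seq_len(n - 1))
        for (j in seq.int(i + 1, n))
          d[i, j] <- d[j, i] <- ham(mat[i, ], mat[j, ])
    d
  }

  if (medians && nrow(mat) >= 3) {
    repeat {
      d <- dist_from_mat(mat)
      edges <- msn_edges(d, epsilon)
      cost <- sum(edges[, "w"])
      ## adjacency for triple enumeration
      n <- nrow(mat)
      adj <- matrix(FALSE, n, n)
      adj[edges[, 1:2, drop = FALSE]] <- TRUE
      adj <- adj | t(adj)
      ## candidate medians: triples with at least two of three links
      cand <- character(0)
      existing <- apply(mat, 1, paste0, collapse = "")
      for (u in seq_len(n - 1)) for (v in seq.int(u + 1, n)) {
        if (v < n) for (w in seq.int(v + 1, n)) {
          if (sum(adj[u, v], adj[u, w], adj[v, w]) >= 2) {
            mv <- median_vector(mat[c(u, v, w), , drop = FALSE])
            if (is.null(mv)) next
            med <- paste0(mv, collapse = "")
            if (!(med %in% existing)) cand <- c(cand, med)
          }
        }
      }
      cand <- unique(cand)
      if (!length(cand)) break
      ## greedy: add the median giving the largest cost reduction
      new_costs <- vapply(cand, function(s)
        net_cost(rbind(mat, strsplit(s, "")[[1]])), 0)
      best <- order(new_costs, cand)[1]
      if (new_costs[best] >= cost) break
      n_med <- n_med + 1L
      mat <- rbind(mat, strsplit(cand[best], "")[[1]])
      rownames(mat)[nrow(mat)] <- sprintf("mv%02d", n_med)
      type <- c(type, "median")
    }
  }

  ## prune obsolete medians: degree <= 2 in the final network
  repeat {
    d <- dist_from_mat(mat)
    edges <- msn_edges(d, epsilon)
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(mat))
    drop <- which(type == "median" & deg <= 2)
    if (!prune || !length(drop)) break
    mat <- mat[-drop, , drop = FALSE]
    type <- type[-drop]
  }

  d <- dist_from_mat(mat)
  edges <- msn_edges(d, epsilon)
  labels <- rownames(mat)
  counts <- stats::setNames(rep(0L, length(labels)), labels)
  obs <- table$haplotypes$label
  counts[obs] <- table$haplotypes$count
  pos_str <- apply(edges, 1, function(e) {
    cols <- which(mat[e[1], ] != mat[e[2], ])
    paste(table$columns[cols], collapse = ",")
  })
  nodes <- data.frame(name = labels,
                      sequence = apply(mat, 1, paste0, collapse = ""),
                      type = type, count = unname(counts[labels]),
                      stringsAsFactors = FALSE)
  edf <- data.frame(from = labels[edges[, 1]], to = labels[edges[, 2]],
                    weight = as.integer(edges[, 3]),
                    positions = if (length(pos_str)) pos_str else character(0),
                    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edf, members = table$members,
                 columns = table$columns, epsilon = epsilon),
            class = "haplotype_network")
}

#' @rdname build_mjn
#' @export
min_spanning_network <- function(table, epsilon = 0L) {
  build_mjn(table, epsilon = epsilon, medians = FALSE)
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("Median-joining network (epsilon = %d): %d observed + %d median nodes, %d edges, total cost %d\n",
              x$epsilon, sum(x$nodes$type == "observed"),
              sum(x$nodes$type == "median"), nrow(x$edges),
              sum(x$edges$weight)))
  invisible(x)
}

#' Annotate network nodes with sample counts and period composition
#'
#' @param net A `haplotype_network`.
#' @param samples Metadata data.frame with `id` and `period` columns.
#' @return The network with a `periods` element: per-node named count
#'   vectors; unknown ids are counted under `"unknown"` with a warning.
#' @export
annotate_nodes <- function(net, samples) {
  stopifnot(inherits(net, "haplotype_network"))
  lookup <- stats::setNames(samples$period, samples$id)
  periods <- lapply(net$nodes$name, function(nm) {
    mem <- net$members[[nm]]
    if (is.null(mem)) return(integer(0))
    per <- lookup[mem]
    if (anyNA(per)) {
      warning("unknown sample id(s) for haplotype ", nm)
      per[is.na(per)] <- "unknown"
    }
    table(per)
  })
  names(periods) <- net$nodes$name
  net$periods <- periods
  net
}

#' Convert a haplotype network to an igraph object
#' @param net A `haplotype_network`.
#' @return An igraph graph with node/edge attributes.
#' @export
network_to_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  if (!is.null(net$periods)) {
    pstr <- vapply(net$periods[igraph::V(g)$name], function(p)
      paste(names(p), unname(p), sep = ":", collapse = ","), "")
    g <- igraph::set_vertex_attr(g, "periods", value = pstr)
  }
  g
}

#' Export a haplotype network to GraphML and a TSV edge list
#'
#' @param net A `haplotype_network`.
#' @param path Output GraphML path; the edge list is written next to it
#'   with suffix `_edges.tsv`.
#' @return Invisibly, the two paths.
#' @export
export_network <- function(net, path) {
  g <- network_to_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  tsv <- paste0(sub("\\.graphml$", "", path), "_edges.tsv")
  utils::write.table(net$edges, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(graphml = path, edges = tsv))
}

#' Plot a haplotype network
#'
#' Node area proportional to haplotype count; median vectors drawn as small
#' black squares, in the conventional style of haplotype-network figures.
#'
#' @param x A `haplotype_network`.
#' @param ... Passed to `plot.igraph`.
#' @export
plot.haplotype_network <- function(x, ...) {
  g <- network_to_igraph(x)
  size <- ifelse(igraph::V(g)$type == "median", 2,
                 4 + 3 * sqrt(igraph::V(g)$count))
  shape <- ifelse(igraph::V(g)$type == "median", "square", "circle")
  color <- ifelse(igraph::V(g)$type == "median", "black", "grey80")
  set.seed(1)
  plot(g, vertex.size = size, vertex.shape = shape, vertex.color = color,
       edge.label = igraph::E(g)$weight, ...)
  invisible(x)
}
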