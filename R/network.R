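#' Assemble significant links into domain networks
#'
#' Builds the graph whose edges are the significant variant pairs and
#' returns its connected components as domain networks; each component is
#' interpreted as (part of) one biosynthetic gene cluster. Components
#' smaller than \code{min_size} nodes are discarded. Component ids are
#' deterministic: each network is named after its lexicographically smallest
#' member variant.
#'
#' @param links A \code{link_set} from [detect_links()].
#' @param matrix The \code{occurrence_matrix} the links were computed from
#'   (source of centroids, domain types and subpool sets for node
#'   annotation); optional, \code{NULL} leaves those fields empty.
#' @param min_size Minimum nodes per reported network (default 3).
#' @return A list of \code{"domain_network"} objects, each a list with
#'   \code{network_id}, \code{nodes} (data.frame \code{variant_id},
#'   \code{centroid}, \code{domain_type}, \code{subpools} (list column),
#'   \code{reads}), \code{edges} (data.frame \code{a}, \code{b},
#'   \code{p_adj}) and \code{merged_from}.
#' @export
build_networks <- function(links, matrix = NULL, min_size = 3L) {
  stopifnot(inherits(links, "link_set"))
  sig <- as.data.frame(links)[links$significant, , drop = FALSE]
  if (nrow(sig) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    sig[, c("variant_a", "variant_b", "p_adj")], directed = FALSE)
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == ci]
    if (length(members) < min_size) next
    members <- sort(members)
    edges <- sig[sig$variant_a %in% members & sig$variant_b %in% members,
                 c("variant_a", "variant_b", "p_adj")]
    names(edges) <- c("a", "b", "p_adj")
    rownames(edges) <- NULL
    out[[length(out) + 1L]] <- .domain_network(members[1L], members, edges,
                                               matrix)
  }
  # deterministic ordering by network id
  out[order(vapply(out, `[[`, "", "network_id"))]
}

.domain_network <- function(net_id, members, edges, matrix,
                            merged_from = NULL) {
  nodes <- data.frame(variant_id = members, centroid = NA_character_,
                      domain_type = NA_character_,
                      reads = NA_integer_, stringsAsFactors = FALSE)
  nodes$subpools <- vector("list", nrow(nodes))
  if (!is.null(matrix)) {
    idx <- match(members, matrix$variants$variant_id)
    nodes$centroid <- matrix$variants$centroid[idx]
    nodes$domain_type <- matrix$variants$domain_type[idx]
    nodes$reads <- as.integer(Matrix::rowSums(matrix$counts)[idx])
    P <- presence(matrix)
    nodes$subpools <- lapply(idx, function(i)
      matrix$subpools[as.logical(P[i, ])])
  }
  if (is.null(merged_from)) {
    merged_from <- as.list(members)
    names(merged_from) <- members
  }
  structure(list(network_id = paste0("net_", net_id), nodes = nodes,
                 edges = edges, merged_from = merged_from),
            class = "domain_network")
}

#' @export
print.domain_network <- function(x, ...) {
  cat(sprintf("domain_network %s: %d nodes, %d edges (%s)\n",
              x$network_id, nrow(x$nodes), nrow(x$edges),
              paste(unique(x$nodes$domain_type), collapse = "+")))
  invisible(x)
}

#' Merge near-identical nodes within a domain network
#'
#' Sequencing errors and fine-scale genetic diversity can split one domain
#' into several highly similar variants inside a network. Nodes of the same
#' domain type whose centroids exceed \code{id_threshold} global identity
#' are merged transitively (single linkage within the network). The merged
#' node keeps the centroid of the highest-total-read constituent, its
#' subpool set is the union, parallel edges collapse keeping the smallest
#' adjusted p-value, and self-edges are dropped.
#'
#' @param net A \code{domain_network}.
#' @param id_threshold Identity above which nodes merge (default 0.90,
#'   strict inequality).
#' @return A \code{domain_network} with \code{merged_from} recording the
#'   constituent variant ids of every surviving node.
#' @export
merge_similar_nodes <- function(net, id_threshold = 0.90) {
  stopifnot(inherits(net, "domain_network"))
  nodes <- net$nodes
  n <- nrow(nodes)
  if (n <= 1L || all(is.na(nodes$centroid))) return(net)
  # single-linkage groups: union-find over >threshold same-type pairs
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    ids <- .identities_to(nodes$centroid[i],
                          nodes$centroid[(i + 1L):n])
    for (off in which(ids > id_threshold &
                      nodes$domain_type[(i + 1L):n] ==
                        nodes$domain_type[i])) {
      j <- i + off
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  group <- vapply(seq_len(n), find, integer(1))
  keep_of_group <- vapply(unique(group), function(g) {
    idx <- which(group == g)
    idx[order(-nodes$reads[idx], nodes$variant_id[idx])][1L]
  }, integer(1))
  names(keep_of_group) <- as.character(unique(group))
  rep_of <- nodes$variant_id[keep_of_group[as.character(group)]]
  new_nodes <- nodes[sort(unique(keep_of_group)), , drop = FALSE]
  merged_from <- lapply(new_nodes$variant_id, function(v) {
    idx <- which(rep_of == v)
    sort(unlist(net$merged_from[nodes$variant_id[idx]], use.names = FALSE))
  })
  names(merged_from) <- new_nodes$variant_id
  for (k in seq_len(nrow(new_nodes))) {
    idx <- which(rep_of == new_nodes$variant_id[k])
    new_nodes$subpools[[k]] <- sort(unique(unlist(nodes$subpools[idx])))
    new_nodes$reads[k] <- sum(nodes$reads[idx])
  }
  rownames(new_nodes) <- NULL
  # remap edges, drop self-edges, collapse parallels keeping min p_adj
  e <- net$edges
  e$a <- rep_of[match(e$a, nodes$variant_id)]
  e$b <- rep_of[match(e$b, nodes$variant_id)]
  swap <- e$a > e$b
  tmp <- e$a[swap]; e$a[swap] <- e$b[swap]; e$b[swap] <- tmp
  e <- e[e$a != e$b, , drop = FALSE]
  if (nrow(e) > 0L) {
    key <- paste(e$a, e$b, sep = "\r")
    e <- do.call(rbind, lapply(split(e, key), function(d)
      d[which.min(d$p_adj), , drop = FALSE]))
    e <- e[order(e$a, e$b), , drop = FALSE]
    rownames(e) <- NULL
  }
  structure(list(network_id = net$network_id, nodes = new_nodes,
                 edges = e, merged_from = merged_from),
            class = "domain_network")
}

#' Export domain networks to graph or table files
#'
#' @param nets List of \code{domain_network} objects.
#' @param path Output file path (GraphML) or path prefix (TSV formats write
#'   \code{<path>_nodes.tsv} / \code{<path>_edges.tsv}).
#' @param format One of \code{"graphml"}, \code{"edgelist"},
#'   \code{"nodetable"} (the TSV formats always write both tables).
#' @return Invisibly, the paths written.
#' @export
export_graph <- function(nets, path, format = c("graphml", "edgelist",
                                                "nodetable")) {
  format <- match.arg(format)
  nodes <- do.call(rbind, c(list(
    data.frame(variant_id = character(), network_id = character(),
               domain_type = character(), centroid = character(),
               subpools = character(), reads = integer())),
    lapply(nets, function(nt)
      data.frame(variant_id = nt$nodes$variant_id,
                 network_id = nt$network_id,
                 domain_type = nt$nodes$domain_type,
                 centroid = nt$nodes$centroid,
                 subpools = vapply(nt$nodes$subpools, paste,
                                   "", collapse = ","),
                 reads = nt$nodes$reads, stringsAsFactors = FALSE))))
  edges <- do.call(rbind, c(list(
    data.frame(a = character(), b = character(), p_adj = numeric(),
               network_id = character())),
    lapply(nets, function(nt)
      if (nrow(nt$edges) == 0L) NULL else
        cbind(nt$edges, network_id = nt$network_id))))
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      edges[, c("a", "b", "p_adj", "network_id")],
      directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  paths <- c(paste0(path, "_nodes.tsv"), paste0(path, "_edges.tsv"))
  utils::write.table(nodes, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Import domain networks from a GraphML export
#'
#' Round-trip companion to [export_graph()].
#'
#' @param path GraphML file written by [export_graph()].
#' @return A list of \code{domain_network} objects.
#' @export
import_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) == 0L) return(list())
  vat <- igraph::as_data_frame(g, what = "vertices")
  eat <- igraph::as_data_frame(g, what = "edges")
  out <- list()
  for (nid in sort(unique(vat$network_id))) {
    vv <- vat[vat$network_id == nid, , drop = FALSE]
    nodes <- data.frame(variant_id = vv$name, centroid = vv$centroid,
                        domain_type = vv$domain_type,
                        reads = as.integer(vv$reads),
                        stringsAsFactors = FALSE)
    nodes$subpools <- lapply(strsplit(vv$subpools, ","), identity)
    nodes <- nodes[order(nodes$variant_id), , drop = FALSE]
    rownames(nodes) <- NULL
    ee <- eat[eat$network_id == nid, c("from", "to", "p_adj"), drop = FALSE]
    names(ee) <- c("a", "b", "p_adj")
    swap <- ee$a > ee$b
    tmp <- ee$a[swap]; ee$a[swap] <- ee$b[swap]; ee$b[swap] <- tmp
    ee <- ee[order(ee$a, ee$b), , drop = FALSE]
    rownames(ee) <- NULL
    mf <- as.list(nodes$variant_id)
    names(mf) <- nodes$variant_id
    out[[length(out) + 1L]] <- structure(
      list(network_id = nid, nodes = nodes, edges = ee, merged_from = mf),
      class = "domain_network")
  }
  out
}
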