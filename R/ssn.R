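# Sequence similarity networks from all-by-all pairwise identities.

#' Percent identity from a global pairwise alignment
#'
#' Aligns two protein sequences with standard affine-gap global
#' (Needleman-Wunsch) dynamic programming and returns
#' `100 * matches / alignment length`, the alignment length counting gap
#' columns. Set `denominator = "shorter"` to divide by the shorter
#' ungapped sequence length instead.
#'
#' @param a,b protein sequences (non-empty strings).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param match_matrix either the name of a built-in substitution matrix
#'   (default `"BLOSUM62"`) or a list `list(match =, mismatch =)` for a
#'   simple scoring scheme.
#' @param denominator `"alignment"` (default) or `"shorter"`.
#' @return percent identity in `[0, 100]`.
#' @examples
#' pairwise_identity("ACDEFG", "ACDFG")  # one gap, 5/6 columns match
#' @export
pairwise_identity <- function(a, b, gap_open = 10, gap_extend = 0.5,
                              match_matrix = "BLOSUM62",
                              denominator = c("alignment", "shorter")) {
  stopifnot(is_string(a), is_string(b))
  if (nchar(a) == 0 || nchar(b) == 0)
    stop("sequences must be non-empty")
  denominator <- match.arg(denominator)
  if (is.list(match_matrix)) {
    letters_used <- unique(strsplit(paste0(a, b), "", fixed = TRUE)[[1L]])
    m <- matrix(match_matrix$mismatch,
                nrow = length(letters_used), ncol = length(letters_used),
                dimnames = list(letters_used, letters_used))
    diag(m) <- match_matrix$match
    submat <- m
  } else {
    submat <- match_matrix
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  matches <- sum(p == s & p != "-")
  denom <- switch(denominator,
                  alignment = length(p),
                  shorter = min(nchar(a), nchar(b)))
  100 * matches / denom
}

#' All-by-all percent-identity matrix
#'
#' @param proteins named character vector of sequences, or a data.frame
#'   with `id` and `sequence` columns.
#' @param ... passed on to [pairwise_identity()].
#' @return a symmetric matrix of percent identities with 100 on the
#'   diagonal.
#' @export
identity_matrix <- function(proteins, ...) {
  if (is.data.frame(proteins))
    proteins <- stats::setNames(proteins$sequence, proteins$id)
  stopifnot(is.character(proteins), length(proteins) >= 1,
            !is.null(names(proteins)), !anyDuplicated(names(proteins)))
  n <- length(proteins)
  m <- matrix(100, n, n, dimnames = list(names(proteins), names(proteins)))
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        m[i, j] <- m[j, i] <- pairwise_identity(proteins[[i]],
                                                proteins[[j]], ...)
      }
    }
  }
  m
}

#' Build a sequence similarity network from an identity matrix
#'
#' Nodes are the proteins; an undirected edge connects two proteins
#' exactly when their pairwise identity is at or above the threshold
#' (e.g. the 30/35/40 percent thresholds conventionally used for
#' FKP/GFPP/FUK datasets). No self-edges.
#'
#' @param scores symmetric percent-identity matrix (values in 0-100,
#'   diagonal 100).
#' @param identity_threshold edge threshold in `[0, 100]`.
#' @return an `igraph` undirected graph with edge attribute `identity`
#'   and graph attribute `threshold`.
#' @export
build_ssn <- function(scores, identity_threshold) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores),
            !is.null(rownames(scores)))
  if (!isTRUE(all.equal(scores, t(scores), tolerance = 1e-8)))
    stop("identity matrix must be symmetric")
  if (!is_number(identity_threshold) || identity_threshold < 0 ||
        identity_threshold > 100)
    stop("identity_threshold must lie in [0, 100]")
  ids <- rownames(scores)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(ids) > 1) {
    idx <- which(upper.tri(scores) & scores >= identity_threshold,
                 arr.ind = TRUE)
    if (nrow(idx) > 0) {
      edges <- rbind(ids[idx[, 1]], ids[idx[, 2]])
      g <- igraph::add_edges(g, as.vector(edges),
                             identity = scores[idx])
    }
  }
  igraph::graph_attr(g, "threshold") <- identity_threshold
  g
}

#' Cluster a sequence similarity network
#'
#' Connected components, numbered by decreasing size and then by the
#' lexicographically smallest member; components below `min_size` are
#' left unclustered (`NA` cluster).
#'
#' @param graph an `igraph` graph from [build_ssn()].
#' @param min_size smallest component size that counts as a cluster.
#' @return a data.frame (`id`, `cluster`, `cluster_size`) with `cluster`
#'   `NA` for unclustered proteins.
#' @export
ssn_clusters <- function(graph, min_size = 1L) {
  stopifnot(igraph::is_igraph(graph), is_count(min_size, positive = TRUE))
  comp <- igraph::components(graph)
  ids <- igraph::V(graph)$name
  members <- split(ids, comp$membership)
  sizes <- vapply(members, length, 0L)
  minmember <- vapply(members, function(x) sort(x)[1L], "")
  ord <- order(-sizes, minmember, method = "radix")
  rank <- integer(length(members))
  rank[ord] <- seq_along(ord)
  cluster <- rank[comp$membership]
  size <- sizes[comp$membership]
  cluster[size < min_size] <- NA_integer_
  data.frame(id = ids, cluster = cluster, cluster_size = unname(size),
             stringsAsFactors = FALSE)
}

#' Congruence between SSN clusters and phylogenetic clades
#'
#' Cross-tabulates cluster membership against clade labels and reports
#' per-cluster purity (largest clade fraction) and the size-weighted
#' overall purity, quantifying how well network clusters mirror the
#' tree's clades.
#'
#' @param clusters data.frame from [ssn_clusters()] (unclustered rows are
#'   ignored).
#' @param clade_map named character vector mapping protein/tip ids to
#'   clade labels; must cover every clustered protein.
#' @return a list with `table` (cluster x clade contingency counts),
#'   `purity` (named per-cluster purity) and `overall_purity`.
#' @export
cluster_clade_congruence <- function(clusters, clade_map) {
  stopifnot(is.data.frame(clusters),
            all(c("id", "cluster") %in% names(clusters)))
  cl <- clusters[!is.na(clusters$cluster), , drop = FALSE]
  missing <- cl$id[!cl$id %in% names(clade_map)]
  if (length(missing))
    stop("no clade label for: ", paste(missing, collapse = ", "))
  if (nrow(cl) == 0)
    return(list(table = table(character(0), character(0)),
                purity = numeric(0), overall_purity = NA_real_))
  tab <- table(cluster = cl$cluster, clade = clade_map[cl$id])
  purity <- apply(tab, 1, function(r) max(r) / sum(r))
  overall <- sum(apply(tab, 1, max)) / sum(tab)
  list(table = tab, purity = purity, overall_purity = overall)
}

#' Write SSN node and edge tables
#'
#' @param graph an `igraph` graph from [build_ssn()].
#' @param node_path,edge_path output TSV paths.
#' @return invisibly, a list with the two paths.
#' @export
write_ssn_tables <- function(graph, node_path, edge_path) {
  nodes <- data.frame(id = igraph::V(graph)$name,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(graph)
  edges <- data.frame(source = el[, 1], target = el[, 2],
                      identity = igraph::E(graph)$identity %||%
                        rep(NA_real_, nrow(el)),
                      stringsAsFactors = FALSE)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(nodes = node_path, edges = edge_path))
}

#' Read an SSN back from node and edge tables
#'
#' @param node_path,edge_path TSV paths written by [write_ssn_tables()].
#' @return an `igraph` graph isomorphic to the one written.
#' @export
read_ssn_tables <- function(node_path, edge_path) {
  nodes <- utils::read.delim(node_path, stringsAsFactors = FALSE)
  edges <- utils::read.delim(edge_path, stringsAsFactors = FALSE)
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes$id)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, as.vector(rbind(edges$source, edges$target)),
                           identity = edges$identity)
  g
}
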