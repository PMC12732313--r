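# Tree I/O and fusion-hypothesis calculations: midpoint rooting,
# monophyly testing, enumeration of monophyly-compatible root edges,
# minimal clade cover, and fusion-event parsimony (unordered Fitch and
# single-gain Dollo counts).

#' Read a Newick tree
#'
#' Wraps `ape::read.tree()` with an upfront bracket-balance check so
#' malformed files fail with the byte offset of the first unbalanced
#' parenthesis, and rejects duplicate tip labels.
#'
#' @param path Newick file path, or a literal Newick string via `text`.
#' @param text optional Newick string (overrides `path`).
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(is_string(path))
    if (!file.exists(path)) stop("no such file: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("newick parse error: unbalanced ')' at offset ", i)
  }
  if (depth != 0L)
    stop("newick parse error: ", depth,
         " unclosed '(' at end of input (offset ", length(chars), ")")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("newick parse error: unparseable input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Write a tree in Newick format
#'
#' @param tree an `ape::phylo` tree.
#' @param path output path; if `NULL` the Newick string is returned.
#' @return the path (invisibly) or the Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}

# tip labels -> tip indices, with an informative error for unknown tips
tip_indices <- function(tree, tipset) {
  idx <- match(tipset, tree$tip.label)
  if (anyNA(idx))
    stop("unknown tip(s): ", paste(tipset[is.na(idx)], collapse = ", "))
  idx
}

# descendant tip indices for every node (tips included), robust to
# polytomies; uses a postorder sweep so children accumulate first
node_tipsets <- function(tree) {
  n <- ape::Ntip(tree)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  po <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Midpoint-root an unrooted tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path, which
#' equivalently minimizes the maximum root-to-tip distance. The root is
#' a point on an edge (the edge is bisected), not an existing node. When
#' several tip pairs tie for the diameter, the pair whose sorted label
#' pair is lexicographically smallest is used.
#'
#' @param tree an `ape::phylo` tree with branch lengths (rooted input is
#'   unrooted first).
#' @return a rooted `ape::phylo` tree.
#' @examples
#' tr <- read_newick(text = "(A:1,B:3);")
#' midpoint_root(tr)  # root 2 units from each tip
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("branch lengths are required")
  if (ape::Ntip(tree) < 2) stop("need at least 2 tips")
  tr <- if (ape::is.rooted(tree) && ape::Ntip(tree) > 2)
    ape::unroot(tree) else tree
  D <- ape::cophenetic.phylo(tr)
  dmax <- max(D)
  idx <- which(D >= dmax - 1e-12 & upper.tri(D), arr.ind = TRUE)
  labs <- rownames(D)
  keys <- apply(idx, 1L, function(r)
    paste(sort(c(labs[r[1]], labs[r[2]])), collapse = "\001"))
  pick <- idx[order(keys, method = "radix")[1L], ]
  a <- match(labs[pick[1]], tr$tip.label)
  b <- match(labs[pick[2]], tr$tip.label)
  if (tr$tip.label[a] > tr$tip.label[b]) { tmp <- a; a <- b; b <- tmp }
  np <- ape::nodepath(tr, a, b)
  target <- dmax / 2
  cum <- 0
  for (i in seq_len(length(np) - 1L)) {
    u <- np[i]; v <- np[i + 1L]
    ei <- which((tr$edge[, 1] == u & tr$edge[, 2] == v) |
                  (tr$edge[, 1] == v & tr$edge[, 2] == u))
    len <- tr$edge.length[ei]
    if (cum + len >= target - 1e-12) {
      child <- tr$edge[ei, 2]
      d_from_u <- target - cum
      # distance of the root point from the rootward (parent) end
      pos <- if (u == tr$edge[ei, 1]) d_from_u else len - d_from_u
      pos <- min(max(pos, 0), len)
      rooted <- phytools::reroot(tr, node.number = child, position = pos)
      return(rooted)
    }
    cum <- cum + len
  }
  stop("internal error: midpoint not found on diameter path")
}

#' Test whether a tip set is monophyletic
#'
#' TRUE exactly when the tip descendants of the most recent common
#' ancestor of `tipset` equal `tipset`.
#'
#' @param tree a rooted `ape::phylo` tree.
#' @param tipset non-empty character vector of tip labels.
#' @return logical.
#' @export
is_monophyletic <- function(tree, tipset) {
  stopifnot(inherits(tree, "phylo"), length(tipset) >= 1)
  idx <- tip_indices(tree, unique(tipset))
  if (length(idx) == 1L || length(idx) == ape::Ntip(tree)) return(TRUE)
  mrca <- ape::getMRCA(tree, idx)
  desc <- node_tipsets(tree)[[mrca]]
  setequal(desc, idx)
}

#' Enumerate root edges compatible with monophyly of a tip set
#'
#' Returns every edge of the unrooted tree that, used as the root
#' position, makes `tipset` monophyletic. If `tipset` does not form a
#' split of the tree the result is empty; a singleton tip set is
#' monophyletic under any rooting, so all edges are returned; if
#' `tipset` is all tips, all edges are returned with a warning.
#'
#' @param tree an `ape::phylo` tree (rooted input is unrooted first).
#' @param tipset non-empty character vector of tip labels.
#' @return an integer vector of row indices into the *unrooted* tree's
#'   `edge` matrix, with that tree attached as attribute `"tree"`.
#' @export
monophyly_roots <- function(tree, tipset) {
  stopifnot(inherits(tree, "phylo"), length(tipset) >= 1)
  tr <- if (ape::is.rooted(tree) && ape::Ntip(tree) > 2)
    ape::unroot(tree) else tree
  idx <- sort(tip_indices(tr, unique(tipset)))
  n_edge <- nrow(tr$edge)
  all_edges <- structure(seq_len(n_edge), tree = tr)
  if (length(idx) == ape::Ntip(tr)) {
    warning("tipset covers all tips; any rooting is compatible")
    return(all_edges)
  }
  if (length(idx) == 1L) return(all_edges)
  desc <- node_tipsets(tr)
  child_sets <- lapply(tr$edge[, 2], function(v) sort(desc[[v]]))
  comp <- sort(setdiff(seq_len(ape::Ntip(tr)), idx))
  star <- which(vapply(child_sets, identical, NA, y = idx))
  if (length(star) == 1L) {
    # stored root on the complement side: edges strictly inside the
    # tipset clade are incompatible
    bad <- which(vapply(child_sets, function(s)
      length(s) < length(idx) && all(s %in% idx), NA))
    good <- setdiff(seq_len(n_edge), bad)
    return(structure(good, tree = tr))
  }
  star_c <- which(vapply(child_sets, identical, NA, y = comp))
  if (length(star_c) == 1L) {
    # stored root inside the tipset side: only the defining edge and the
    # edges strictly inside the complement clade are compatible
    good <- which(vapply(child_sets, function(s)
      length(s) < length(comp) && all(s %in% comp), NA))
    return(structure(sort(c(star_c, good)), tree = tr))
  }
  structure(integer(0), tree = tr)
}

#' Minimal clade cover of a tip set
#'
#' Counts the maximal clades of a rooted tree whose tip sets are subsets
#' of `tipset` and whose union is `tipset`. The count is 1 exactly when
#' `tipset` is monophyletic; on a rooting that breaks up a fused group,
#' it is the number of separate clades the group is distributed across.
#'
#' @param tree a rooted `ape::phylo` tree.
#' @param tipset non-empty character vector of tip labels.
#' @return integer clade count.
#' @export
min_clade_cover <- function(tree, tipset) {
  stopifnot(inherits(tree, "phylo"), length(tipset) >= 1)
  idx <- tip_indices(tree, unique(tipset))
  n <- ape::Ntip(tree)
  n_node <- n + tree$Nnode
  pure <- rep(TRUE, n_node)
  pure[seq_len(n)] <- seq_len(n) %in% idx
  po <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    pure[p] <- pure[p] && pure[ch]
  }
  parent <- rep(NA_integer_, n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  sum(vapply(seq_len(n_node), function(v) {
    pure[v] && (is.na(parent[v]) || !pure[parent[v]])
  }, NA))
}

#' Count fusion events on a tree by parsimony
#'
#' For a binary fused/monofunctional tip character, `"unordered"` mode
#' returns the small-parsimony minimum number of state changes (Fitch
#' count, computed by Sankoff dynamic programming so polytomies are
#' handled exactly). `"dollo"` mode constrains the history to at most a
#' single 0 to 1 gain, placed at the most recent common ancestor of the
#' fused tips, and counts `1 gain + minimal losses`, the losses being
#' the maximal all-monofunctional clades inside the gained subtree; a
#' character with no fused tip costs 0 events.
#'
#' @param tree a rooted `ape::phylo` tree (an unrooted tree stored with a
#'   basal multifurcation gives the unrooted parsimony score in
#'   `"unordered"` mode).
#' @param states named 0/1 vector covering every tip.
#' @param mode `"unordered"` or `"dollo"`.
#' @return integer event count.
#' @examples
#' tr <- read_newick(text = "((A,B),(C,D));")
#' fitch_fusion_events(tr, c(A = 1, B = 0, C = 1, D = 0))  # 2
#' @export
fitch_fusion_events <- function(tree, states,
                                mode = c("unordered", "dollo")) {
  stopifnot(inherits(tree, "phylo"))
  mode <- match.arg(mode)
  if (is.null(names(states)))
    stop("states must be a named vector over the tips")
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing))
    stop("states missing for tip(s): ", paste(missing, collapse = ", "))
  st <- states[tree$tip.label]
  if (!all(st %in% c(0, 1)))
    stop("states must be binary (0 = monofunctional, 1 = fused)")
  n <- ape::Ntip(tree)
  if (mode == "unordered") {
    # Sankoff DP with unit change cost
    n_node <- n + tree$Nnode
    cost <- matrix(0, n_node, 2L)
    cost[seq_len(n), 1L] <- ifelse(st == 0, 0, Inf)
    cost[seq_len(n), 2L] <- ifelse(st == 1, 0, Inf)
    po <- stats::reorder(tree, "postorder")
    for (k in seq_len(nrow(po$edge))) {
      p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
      cost[p, 1L] <- cost[p, 1L] + min(cost[ch, 1L], cost[ch, 2L] + 1)
      cost[p, 2L] <- cost[p, 2L] + min(cost[ch, 2L], cost[ch, 1L] + 1)
    }
    root <- po$edge[nrow(po$edge), 1L]
    return(as.integer(min(cost[root, ])))
  }
  ones <- tree$tip.label[st == 1]
  if (length(ones) == 0L) return(0L)
  if (length(ones) == 1L) return(1L)
  gain <- ape::getMRCA(tree, ones)
  sub <- ape::extract.clade(tree, gain)
  zeros <- intersect(sub$tip.label, tree$tip.label[st == 0])
  losses <- if (length(zeros)) min_clade_cover(sub, zeros) else 0L
  as.integer(1L + losses)
}

#' Write a tip-annotation table
#'
#' @param tree an `ape::phylo` tree.
#' @param states optional named 0/1 fusion states over tips.
#' @param clades optional named clade labels over tips.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_tip_annotations <- function(tree, states = NULL, clades = NULL,
                                  path) {
  d <- data.frame(tip = tree$tip.label, stringsAsFactors = FALSE)
  if (!is.null(states)) d$state <- unname(states[tree$tip.label])
  if (!is.null(clades)) d$clade <- unname(clades[tree$tip.label])
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
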