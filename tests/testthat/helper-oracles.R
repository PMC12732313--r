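# Brute-force oracles, independent of the implementation paths they
# check, plus small shared fixtures.

# desk-scale family configuration (short domains keep alignments fast)
small_family_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_fuk = 4, n_gfpp = 4, n_fkp = 4,
             domain_len_fuk = 60, domain_len_gfpp = 80, linker_len = 8,
             ...)
}

no_length_filter <- function() {
  arch_thresholds(min_fuk = 0, min_gfpp = 0, min_fkp = 0)
}

# per-query model ranking by explicit sort on (score desc, model asc)
oracle_rank <- function(hits) {
  out <- list()
  for (q in unique(hits$query_id)) {
    d <- hits[hits$query_id == q, ]
    ids <- toupper(sub("\\.\\d+$", "", d$model_id))
    out[[q]] <- ids[order(-d$score, ids)]
  }
  out
}

# edge list by a double loop
oracle_edges <- function(scores, thr) {
  ids <- rownames(scores)
  out <- character(0)
  n <- nrow(scores)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (scores[i, j] >= thr)
        out <- c(out, paste(sort(c(ids[i], ids[j])), collapse = "|"))
    }
  }
  sort(out)
}

# connected components by union-find over the thresholded matrix
oracle_components <- function(scores, thr) {
  n <- nrow(scores)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (scores[i, j] >= thr) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  stats::setNames(match(roots, unique(roots)), rownames(scores))
}

# two cluster assignments describe the same partition (identical
# co-membership relation)
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# minimal max root-to-tip height over all points of all edges, by
# numerical optimization per edge
oracle_min_height <- function(tr) {
  D <- ape::dist.nodes(tr)
  n <- ape::Ntip(tr)
  best <- Inf
  for (i in seq_len(nrow(tr$edge))) {
    u <- tr$edge[i, 1]; v <- tr$edge[i, 2]; L <- tr$edge.length[i]
    du <- D[u, seq_len(n)]; dv <- D[v, seq_len(n)]
    f <- function(x) max(pmin(x + du, (L - x) + dv))
    opt <- stats::optimize(f, c(0, L), tol = 1e-9)
    best <- min(best, opt$objective, f(0), f(L))
  }
  best
}

# root-edge enumeration by literally rerooting on every edge midpoint
# and testing monophyly with ape
oracle_monophyly_roots <- function(tr, tipset) {
  which(vapply(seq_len(nrow(tr$edge)), function(i) {
    child <- tr$edge[i, 2]
    rooted <- phytools::reroot(tr, node.number = child,
                               position = tr$edge.length[i] / 2)
    ape::is.monophyletic(rooted, tipset)
  }, NA))
}

# maximal pure clades via ape::prop.part (independent clade inventory)
oracle_clade_cover <- function(tree, tips) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  idx <- match(tips, labs)
  clades <- c(lapply(seq_along(labs), function(i) i),
              lapply(pp, as.integer))
  pure <- Filter(function(s) all(s %in% idx), clades)
  maximal <- Filter(function(s) {
    !any(vapply(pure, function(t)
      length(t) > length(s) && all(s %in% t), NA))
  }, pure)
  length(maximal)
}

# minimum state changes by exhaustive enumeration of ancestral labelings
oracle_fitch <- function(tree, states) {
  n <- ape::Ntip(tree)
  st <- states[tree$tip.label]
  n_int <- tree$Nnode
  best <- Inf
  for (mask in 0:(2^n_int - 1)) {
    lab <- c(st, as.integer(intToBits(mask))[seq_len(n_int)])
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# a random symmetric percent-identity matrix
random_identity_matrix <- function(n, seed) {
  with_seed <- function(s, code) { set.seed(s); code }
  with_seed(seed, {
    m <- matrix(stats::runif(n * n, 0, 100), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 100
    dimnames(m) <- list(sprintf("p%02d", 1:n), sprintf("p%02d", 1:n))
    m
  })
}
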