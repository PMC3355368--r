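# Quantitative tree comparison: leaf-to-leaf traveling distances through the
# lowest common ancestor, the N x N traveling-distance matrix, and the tree
# similarity correlation coefficient computed between two such matrices.

# Depth of every node (edges below the root) of a rooted phylo tree.
node_depths <- function(t) {
  t <- stats::reorder(t, "cladewise")
  n_nodes <- ape::Ntip(t) + t$Nnode
  dep <- integer(n_nodes)
  root <- ape::Ntip(t) + 1L
  dep[root] <- 0L
  # cladewise order guarantees a parent is seen before its children
  for (r in seq_len(nrow(t$edge))) {
    dep[t$edge[r, 2]] <- dep[t$edge[r, 1]] + 1L
  }
  dep
}

tip_index <- function(t, label) {
  i <- match(label, t$tip.label)
  if (is.na(i)) stop("leaf not in tree: ", label, call. = FALSE)
  i
}

#' Traveling distance between two leaves of a rooted tree
#'
#' The traveling distance between leaves X and Y is `m + n`, where `m` and
#' `n` are the numbers of ancestor nodes each leaf passes through on the path
#' toward their lowest common ancestor (LCA), before reaching it.  By default
#' the LCA itself is not counted, so two sibling leaves are at distance 0;
#' with `include_lca = TRUE` each side also counts the LCA, adding exactly 2
#' to every between-leaf distance (the tree similarity correlation is
#' unchanged by this choice).
#'
#' @param t Rooted tree of class `phylo` (multifurcations allowed).
#' @param x,y Leaf labels.
#' @param include_lca Count the LCA node on both paths (default `FALSE`).
#' @return Non-negative integer; 0 when `x == y`.
#' @examples
#' t <- read_newick("((A,B),C);")
#' traveling_distance(t, "A", "B")  # 0: siblings meet at their parent
#' traveling_distance(t, "A", "C")  # 1: A passes one node below the root
#' @export
traveling_distance <- function(t, x, y, include_lca = FALSE) {
  stopifnot(inherits(t, "phylo"))
  i <- tip_index(t, x)
  j <- tip_index(t, y)
  if (i == j) return(0L)
  dep <- node_depths(t)
  lca <- ape::getMRCA(t, c(i, j))
  d <- dep[i] + dep[j] - 2L * dep[lca] - 2L
  if (include_lca) d <- d + 2L
  as.integer(d)
}

#' Leaf-to-leaf traveling-distance matrix of a tree
#'
#' All pairwise [traveling_distance()] values of a rooted tree with N leaves,
#' as a symmetric integer N x N matrix with zero diagonal, computed from
#' per-node depths and all-pairs LCAs.
#'
#' @inheritParams traveling_distance
#' @return Symmetric integer matrix with leaf-label dimnames.
#' @export
travel_distance_matrix <- function(t, include_lca = FALSE) {
  stopifnot(inherits(t, "phylo"), ape::Ntip(t) >= 2)
  dep <- node_depths(t)
  ntip <- ape::Ntip(t)
  lca <- ape::mrca(t)                      # tip x tip matrix of node ids
  tipdep <- dep[seq_len(ntip)]
  d <- outer(tipdep, tipdep, "+") - 2L * matrix(dep[lca], ntip, ntip) - 2L
  if (include_lca) d <- d + 2L
  diag(d) <- 0L
  storage.mode(d) <- "integer"
  dimnames(d) <- list(t$tip.label, t$tip.label)
  d
}

#' Tree similarity correlation coefficient (tree CC)
#'
#' Pearson correlation between the traveling-distance matrices of two rooted
#' trees over an identical leaf set, using the upper-triangle entries only,
#' with pairs aligned by leaf label.  Identical topologies give exactly 1;
#' independently generated random trees give values centered on 0.
#'
#' @param t1,t2 Rooted `phylo` trees with exactly the same leaf labels (>= 3
#'   leaves).
#' @param include_lca Passed to [travel_distance_matrix()]; the CC does not
#'   depend on it.
#' @return Real in \[-1, 1\].
#' @export
tree_cc <- function(t1, t2, include_lca = FALSE) {
  check_same_leaves(t1, t2)
  if (ape::Ntip(t1) < 3) {
    stop("tree CC needs at least 3 leaves", call. = FALSE)
  }
  m1 <- travel_distance_matrix(t1, include_lca)
  m2 <- travel_distance_matrix(t2, include_lca)
  labs <- rownames(m1)
  m2 <- m2[labs, labs]
  u1 <- m1[upper.tri(m1)]
  u2 <- m2[upper.tri(m2)]
  if (length(unique(u1)) == 1 || length(unique(u2)) == 1) {
    stop("correlation undefined: constant traveling-distance matrix",
         call. = FALSE)
  }
  if (identical(u1, u2)) return(1)   # self-correlation is exact
  stats::cor(u1, u2)
}

check_same_leaves <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  d1 <- setdiff(t1$tip.label, t2$tip.label)
  d2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(d1) || length(d2)) {
    stop("trees must have the same leaf set; only in first: {",
         paste(d1, collapse = ", "), "}; only in second: {",
         paste(d2, collapse = ", "), "}", call. = FALSE)
  }
  invisible(TRUE)
}

# Canonical form of a rooted topology: children of every node sorted by their
# smallest descendant leaf label; branch lengths ignored.
canonical_topology <- function(t) {
  t <- stats::reorder(t, "cladewise")
  ntip <- ape::Ntip(t)
  children <- split(t$edge[, 2], t$edge[, 1])
  canon <- function(node) {
    if (node <= ntip) {
      return(list(min = t$tip.label[node], str = t$tip.label[node]))
    }
    subs <- lapply(children[[as.character(node)]], canon)
    mins <- vapply(subs, `[[`, character(1), "min")
    ord <- order(mins)
    list(min = mins[ord[1]],
         str = paste0("(", paste(vapply(subs[ord], `[[`, character(1), "str"),
                                 collapse = ","), ")"))
  }
  canon(ntip + 1L)$str
}

#' Test whether two rooted trees have exactly the same topology
#'
#' Compares canonical forms in which each node's children are sorted by their
#' smallest descendant leaf label; child order and branch lengths are
#' immaterial.
#'
#' @param t1,t2 Rooted `phylo` trees over the same leaf set.
#' @return Logical.
#' @export
same_topology <- function(t1, t2) {
  check_same_leaves(t1, t2)
  canonical_topology(t1) == canonical_topology(t2)
}

#' Generate a random rooted binary tree
#'
#' Builds a rooted binary tree by uniform random sequential pair-joining:
#' starting from the leaf set, two subtrees chosen uniformly at random are
#' joined until one tree remains.  Used for the null distribution of the tree
#' similarity correlation.
#'
#' @param leaves Character vector of leaf labels, or a single integer n (the
#'   labels become `t1 ... tn`).
#' @param seed Optional integer seed; the tree is deterministic given it.
#' @return A rooted binary `phylo` tree (unit branch lengths omitted).
#' @export
random_tree <- function(leaves, seed = NULL) {
  if (is.numeric(leaves) && length(leaves) == 1) {
    leaves <- paste0("t", seq_len(leaves))
  }
  stopifnot(length(leaves) >= 2, !anyDuplicated(leaves))
  with_seed(seed, {
    subtrees <- as.list(leaves)
    while (length(subtrees) > 1) {
      idx <- sample.int(length(subtrees), 2)
      joined <- paste0("(", subtrees[[idx[1]]], ",", subtrees[[idx[2]]], ")")
      subtrees <- c(subtrees[-idx], joined)
    }
    read_newick(paste0(subtrees[[1]], ";"))
  })
}

# Evaluate code under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  A NULL seed uses (and advances) the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}
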