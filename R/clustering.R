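# Classification trees: Spearman-rank-correlation distance, agglomerative
# average-linkage clustering with a deterministic tie-break, and Newick I/O.
# Trees are rooted ape "phylo" objects; merge heights are recorded so that a
# child edge's length is the parent height minus the child height.

#' Spearman rank-correlation distance between two frequency patterns
#'
#' `1 - rho`, where `rho` is the Spearman rank correlation (average ranks for
#' ties).  Range \[0, 2\]; 0 for any monotone transform of the same pattern.
#'
#' @param a,b Numeric vectors of equal length (>= 2), not all-tied.
#' @return Non-negative real.
#' @export
spearman_distance <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (length(unique(a)) == 1 || length(unique(b)) == 1) {
    stop("rank correlation undefined: all-tied frequency pattern",
         call. = FALSE)
  }
  1 - stats::cor(a, b, method = "spearman")
}

#' Pairwise Spearman-distance matrix of a frequency matrix
#'
#' @param m Frequency matrix (organisms x probes).
#' @return Symmetric matrix of [spearman_distance()] values with organism
#'   dimnames.
#' @export
spearman_distance_matrix <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  ids <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- tryCatch(spearman_distance(m[i, ], m[j, ]), error = function(e) {
        stop(sprintf("distance between %s and %s failed: %s",
                     ids[i], ids[j], conditionMessage(e)), call. = FALSE)
      })
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

# Agglomerative average linkage over a dissimilarity matrix.  Returns merges
# in hclust convention (negative = original row, positive = earlier merge)
# plus merge heights.  When several cluster pairs share the minimal distance
# the pair whose sorted smallest original-row indices are lexicographically
# least is merged, so the tree is deterministic.
average_linkage <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 2)
  members <- lapply(seq_len(n), identity)   # original row indices per cluster
  cl_id <- -seq_len(n)                      # hclust-style ids
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  work <- d
  diag(work) <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    act <- which(active)
    sub <- work[act, act, drop = FALSE]
    dmin <- min(sub)
    cand <- which(sub == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(rc) {
      sort(c(min(members[[act[rc[1]]]]), min(members[[act[rc[2]]]])))
    })
    pick <- order(keys[1, ], keys[2, ])[1]
    i <- act[cand[pick, 1]]
    j <- act[cand[pick, 2]]
    merge[step, ] <- sort(c(cl_id[i], cl_id[j]))
    height[step] <- dmin
    # average linkage update: weighted mean of the two cluster distances
    others <- setdiff(act, c(i, j))
    if (length(others)) {
      new_d <- (sizes[i] * work[i, others] + sizes[j] * work[j, others]) /
        (sizes[i] + sizes[j])
      work[i, others] <- new_d
      work[others, i] <- new_d
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    cl_id[i] <- step
    active[j] <- FALSE
  }
  list(merge = merge, height = height)
}

# Convert an hclust-style merge table into a rooted binary "phylo".  Internal
# node k of ape's numbering is assigned so the root is n+1; the edge length
# of a child is parent merge height minus child merge height (leaves sit at
# height 0).
merges_to_phylo <- function(merge, height, labels) {
  n <- length(labels)
  node_of <- function(id) if (id < 0) -id else n + (n - id)
  height_of <- function(id) if (id < 0) 0 else height[id]
  edge <- matrix(0L, 2 * (n - 1), 2)
  elen <- numeric(2 * (n - 1))
  r <- 0
  for (k in seq_len(n - 1)) {
    parent <- n + (n - k)
    for (child_id in merge[k, ]) {
      r <- r + 1
      edge[r, ] <- c(parent, node_of(child_id))
      elen[r] <- height[k] - height_of(child_id)
    }
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = labels, Nnode = n - 1L),
                   class = "phylo")
  stats::reorder(phy, "cladewise")
}

#' Build a classification tree from a frequency matrix
#'
#' Agglomerative average-linkage (UPGMA-style) hierarchical clustering of the
#' organisms under Spearman rank-correlation distance (`1 - rho`), the
#' procedure used to classify proteomes from their probe-set frequency
#' patterns.  Tie-breaking is deterministic: among cluster pairs at the
#' minimal distance, the pair whose smallest original-row indices are
#' lexicographically least is merged first.
#'
#' @param m Frequency matrix, organisms in rows (>= 2), probes in columns.
#' @return A rooted binary tree of class `phylo` whose tips carry the
#'   organism ids; branch lengths encode cophenetic merge heights (a child
#'   edge is parent height minus child height).
#' @examples
#' m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 4, 3), c = c(4, 3, 2, 1))
#' t <- build_tree(m)
#' write_newick(t)
#' @export
build_tree <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 organisms", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("organism_", seq_len(nrow(m)))
  d <- spearman_distance_matrix(m)
  al <- average_linkage(d)
  merges_to_phylo(al$merge, al$height, rownames(m))
}

#' Write a classification tree as a Newick string
#'
#' @param t A `phylo` tree.
#' @param path Optional file path; when given the string is also written to
#'   it (with trailing newline).
#' @return Newick string (branch lengths included when present).
#' @export
write_newick <- function(t, path = NULL) {
  stopifnot(inherits(t, "phylo"))
  s <- ape::write.tree(t)
  if (!is.null(path)) writeLines(s, path)
  s
}

#' Read a rooted classification tree from Newick
#'
#' Accepts trees with or without branch lengths and with multifurcations.
#'
#' @param s Newick string, or a path to a file containing one.
#' @return A `phylo` tree.
#' @export
read_newick <- function(s) {
  text <- if (length(s) == 1 && file.exists(s)) {
    paste(readLines(s, warn = FALSE), collapse = "")
  } else {
    s
  }
  check_newick_balance(text)
  t <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                error = function(e) NULL)
  if (is.null(t) || !inherits(t, "phylo")) {
    stop("malformed Newick string", call. = FALSE)
  }
  if (is.null(t$tip.label) || anyDuplicated(t$tip.label)) {
    stop("Newick tree must have unique leaf labels", call. = FALSE)
  }
  t
}

check_newick_balance <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") {
      depth <- depth - 1
      if (depth < 0) {
        stop(sprintf("malformed Newick: unbalanced \")\" at character %d", i),
             call. = FALSE)
      }
    }
  }
  if (depth != 0) {
    stop(sprintf("malformed Newick: %d unclosed \"(\"", depth), call. = FALSE)
  }
  invisible(TRUE)
}
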