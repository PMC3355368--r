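# Independent oracles and shared fixtures.  The oracles deliberately share no
# code with the implementation: the matcher enumerates every start position
# and repeat-length combination, and the traveling-distance oracle intersects
# ascend-to-root ancestor paths.

# ---- brute-force pattern matcher ------------------------------------------

bf_element_match <- function(el, ch, wildcard_nonstandard = TRUE) {
  switch(el$kind,
         exact = ch %in% el$residues,
         one_of = ch %in% el$residues,
         none_of = (ch %in% AA_STANDARD) && !(ch %in% el$residues),
         any = if (wildcard_nonstandard) TRUE else ch %in% AA_STANDARD)
}

# Count of start positions with >= 1 way to match, honoring anchors.
bf_count <- function(probe, sequence, wildcard_nonstandard = TRUE) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  ends_from <- function(pos, idx) {
    if (idx > length(probe$elements)) return(pos - 1L)
    el <- probe$elements[[idx]]
    out <- integer()
    for (r in el$min_repeat:el$max_repeat) {
      if (pos + r - 1L > n) break
      ok <- all(vapply(seq_len(r), function(k) {
        bf_element_match(el, chars[pos + k - 1L], wildcard_nonstandard)
      }, logical(1)))
      if (!ok) break  # a longer repeat fails on the same prefix
      out <- c(out, ends_from(pos + r, idx + 1L))
    }
    unique(out)
  }
  starts <- if (probe$anchored_start) 1L else seq_len(n)
  hits <- 0L
  for (s in starts) {
    ends <- ends_from(s, 1L)
    matched <- if (probe$anchored_end) any(ends == n) else length(ends) > 0
    if (matched) hits <- hits + 1L
  }
  hits
}

# Random descriptor text over a small alphabet so matches actually occur.
rand_descriptor <- function() {
  alpha <- c("A", "C", "D", "G")
  k <- sample(1:8, 1)
  toks <- vapply(seq_len(k), function(i) {
    kind <- sample(c("exact", "any", "one_of", "none_of"), 1,
                   prob = c(0.4, 0.2, 0.2, 0.2))
    core <- switch(kind,
                   exact = sample(alpha, 1),
                   any = "x",
                   one_of = paste0("[", paste(sample(alpha, sample(1:2, 1)),
                                              collapse = ""), "]"),
                   none_of = paste0("{", paste(sample(AA_STANDARD,
                                                      sample(1:2, 1)),
                                               collapse = ""), "}"))
    lo <- sample(1:2, 1)
    hi <- lo + sample(0:2, 1, prob = c(0.6, 0.25, 0.15))
    if (lo == 1 && hi == 1) core
    else if (lo == hi) sprintf("%s(%d)", core, lo)
    else sprintf("%s(%d,%d)", core, lo, hi)
  }, character(1))
  text <- paste(toks, collapse = "-")
  if (stats::runif(1) < 0.15) text <- paste0("<", text)
  if (stats::runif(1) < 0.15) text <- paste0(text, ">")
  text
}

rand_sequence <- function(max_len = 30) {
  n <- sample(0:max_len, 1)
  pool <- c(rep(c("A", "C", "D", "G"), 5), AA_STANDARD, "B", "X", "U")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# ---- brute-force traveling distance ---------------------------------------

bf_ancestors <- function(t, node) {
  path <- integer()
  cur <- node
  repeat {
    e <- which(t$edge[, 2] == cur)
    if (!length(e)) break
    cur <- t$edge[e, 1]
    path <- c(path, cur)
  }
  path
}

bf_traveling_distance <- function(t, x, y, include_lca = FALSE) {
  i <- match(x, t$tip.label)
  j <- match(y, t$tip.label)
  if (i == j) return(0L)
  ai <- bf_ancestors(t, i)
  aj <- bf_ancestors(t, j)
  lca <- ai[ai %in% aj][1]
  d <- (match(lca, ai) - 1L) + (match(lca, aj) - 1L)
  if (include_lca) d + 2L else d
}

# Leaf sets under each child of the root (the root bipartition, as a set of
# sets of labels).
root_partition <- function(t) {
  ntip <- ape::Ntip(t)
  root <- ntip + 1L
  kids <- t$edge[t$edge[, 1] == root, 2]
  parts <- lapply(kids, function(k) {
    if (k <= ntip) return(t$tip.label[k])
    sub <- ape::extract.clade(t, k)
    sub$tip.label
  })
  lapply(parts, function(p) sort(p))
}

# ---- shared fixtures -------------------------------------------------------

.fixtures <- new.env()

# 12 organisms in 4 groups of 3, 16 probes (4 high-rate per group).
twelve_org_fixture <- function() {
  if (is.null(.fixtures$twelve)) {
    probes <- random_probes(16, seed = 101)
    profiles <- lapply(1:4, function(g) {
      rates <- rep(0.02, 16)
      rates[(g - 1) * 4 + 1:4] <- 0.5
      group_profile(paste0("g", g), rates, 3, 60)
    })
    prots <- make_group_proteomes(profiles, probes, seed = 202)
    .fixtures$twelve <- list(probes = probes, proteomes = prots,
                             groups = lapply(1:4, function(g) {
                               sort(paste0("g", g, "_", 1:3))
                             }))
  }
  .fixtures$twelve
}

prosite_fixture_file <- function() {
  path <- tempfile(fileext = ".dat")
  writeLines(c(
    "ID   CAT_EXAMPLE; PATTERN.",
    "AC   PS00100;",
    "PA   Q-[LIV]-H-H-[SA]-x(2)-D-G-",
    "PA   [FY]-H.",
    "//",
    "ID   VERY_FREQUENT; PATTERN.",
    "AC   PS90001;",
    "CC   /SKIP-FLAG=TRUE;",
    "PA   A-x-A.",
    "//",
    "ID   PROFILE_ONLY; MATRIX.",
    "AC   PS90002;",
    "//",
    "ID   ANCHORED; PATTERN.",
    "AC   PS90003;",
    "PA   <M-x(2,4)-{P}-D.",
    "//"), path)
  path
}

write_fasta_fixture <- function(seqs, path = tempfile(fileext = ".faa")) {
  lines <- unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  }))
  writeLines(as.character(lines), path)
  path
}
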