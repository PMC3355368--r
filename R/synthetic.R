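# Seeded synthetic data: random probe descriptors, group-structured proteomes
# with planted probe motifs at group-specific Poisson rates, random proteome
# truncation, and the truncation robustness experiments.

#' Generate random probe descriptors
#'
#' Emits syntactically valid probes mixing exact residues, `[..]` ambiguity
#' sets and bounded `x` wildcards.  Probe length (element count weighted by
#' minimum repeats) is drawn uniformly from `length_range`, matching the
#' 10-20 residue scale typical of conserved functional-site patterns.
#'
#' @param k Number of probes (>= 1).
#' @param length_range Integer length 2 within \[4, 30\].
#' @param seed Optional integer seed; output is deterministic given it.
#' @return List of `probe` objects with ids `RP00001 ...`.
#' @export
random_probes <- function(k, length_range = c(10, 20), seed = NULL) {
  stopifnot(k >= 1, length(length_range) == 2,
            length_range[1] >= 4, length_range[2] <= 30,
            length_range[1] <= length_range[2])
  with_seed(seed, {
    lapply(seq_len(k), function(i) {
      target <- sample(seq(length_range[1], length_range[2]), 1)
      elements <- list()
      len <- 0
      while (len < target) {
        remaining <- target - len
        kind <- sample(c("exact", "one_of", "any"), 1,
                       prob = c(0.6, 0.25, 0.15))
        if (kind == "exact") {
          el <- pattern_element("exact", sample(AA_STANDARD, 1))
        } else if (kind == "one_of") {
          el <- pattern_element("one_of",
                                sort(sample(AA_STANDARD,
                                            sample(2:3, 1))))
        } else {
          lo <- sample(seq_len(min(3, remaining)), 1)
          hi <- lo + sample(0:1, 1)
          el <- pattern_element("any", character(), lo, hi)
        }
        if (el$min_repeat > remaining) next
        elements[[length(elements) + 1]] <- el
        len <- len + el$min_repeat
      }
      structure(list(id = sprintf("RP%05d", i),
                     raw_pattern = "", elements = elements,
                     anchored_start = FALSE, anchored_end = FALSE,
                     skip_flagged = FALSE),
                class = "probe") -> p
      p$raw_pattern <- format(p)
      p
    })
  })
}

#' Group profile for synthetic proteomes
#'
#' Describes one group of organisms by the expected number of occurrences per
#' protein-coding gene (`lambda_i >= 0`) of each probe, the group size, and
#' the proteome size.
#'
#' @param group_id Group label.
#' @param probe_rates Numeric vector of per-gene occurrence rates, one per
#'   probe, all `>= 0`.
#' @param n_organisms Positive integer.
#' @param genes_per_organism Positive integer.
#' @return Object of class `group_profile`.
#' @export
group_profile <- function(group_id, probe_rates, n_organisms,
                          genes_per_organism) {
  stopifnot(all(probe_rates >= 0), n_organisms >= 1, genes_per_organism >= 1)
  structure(list(group_id = as.character(group_id),
                 probe_rates = as.numeric(probe_rates),
                 n_organisms = as.integer(n_organisms),
                 genes_per_organism = as.integer(genes_per_organism)),
            class = "group_profile")
}

# Draw one concrete string matching a probe (each element at a uniformly
# chosen repeat count, residues sampled from the allowed set).
sample_match <- function(probe) {
  paste(vapply(probe$elements, function(el) {
    reps <- if (el$min_repeat == el$max_repeat) el$min_repeat else
      sample(seq(el$min_repeat, el$max_repeat), 1)
    pool <- switch(el$kind,
                   exact = el$residues,
                   one_of = el$residues,
                   none_of = setdiff(AA_STANDARD, el$residues),
                   any = AA_STANDARD)
    paste(sample(pool, reps, replace = TRUE), collapse = "")
  }, character(1)), collapse = "")
}

#' Generate a synthetic proteome with planted probe motifs
#'
#' Builds `genes_per_organism` random-background proteins and embeds, for
#' each probe `i`, a Poisson(`lambda_i x genes`) number of concrete match
#' instances at random non-overlapping positions.  Stands in for a real
#' proteome whose functional-site content follows the group's rate profile.
#'
#' @param profile A [group_profile()].
#' @param organism_index Index of the organism within its group (used for the
#'   organism id `<group>_<index>`).
#' @param probes List of `probe` objects aligned with `profile$probe_rates`.
#' @param seed Optional integer seed.
#' @param protein_length Background protein length in residues.
#' @param background_freqs Optional named residue sampling weights (defaults
#'   to uniform over the 20 standard letters).
#' @return A `proteome`.
#' @export
synthetic_proteome <- function(profile, organism_index, probes, seed = NULL,
                               protein_length = 150L,
                               background_freqs = NULL) {
  stopifnot(inherits(profile, "group_profile"),
            length(probes) == length(profile$probe_rates))
  with_seed(seed, {
    n_genes <- profile$genes_per_organism
    prob <- if (is.null(background_freqs)) NULL else
      background_freqs[AA_STANDARD]
    proteins <- vapply(seq_len(n_genes), function(i) {
      paste(sample(AA_STANDARD, protein_length, replace = TRUE, prob = prob),
            collapse = "")
    }, character(1))
    names(proteins) <- sprintf("%s_%d_p%04d", profile$group_id,
                               organism_index, seq_len(n_genes))
    occupied <- vector("list", n_genes)   # planted intervals per protein
    for (i in seq_along(probes)) {
      n_inst <- stats::rpois(1, profile$probe_rates[i] * n_genes)
      for (inst in seq_len(n_inst)) {
        motif <- sample_match(probes[[i]])
        len <- nchar(motif)
        if (len > protein_length) {
          stop("probe ", probes[[i]]$id, " is longer than protein_length; ",
               "use longer proteins", call. = FALSE)
        }
        placed <- FALSE
        for (try in seq_len(200L)) {
          g <- sample.int(n_genes, 1)
          start <- sample.int(protein_length - len + 1L, 1)
          end <- start + len - 1L
          iv <- occupied[[g]]
          clash <- !is.null(iv) && any(start <= iv[, 2] & end >= iv[, 1])
          if (!clash) {
            substr(proteins[g], start, end) <- motif
            occupied[[g]] <- rbind(iv, c(start, end))
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place motif instances without overlap; rates too ",
               "high for protein_length - use longer proteins", call. = FALSE)
        }
      }
    }
    proteome(paste0(profile$group_id, "_", organism_index), proteins,
             gene_count = n_genes)
  })
}

#' Generate all organisms of several group profiles
#'
#' @param profiles List of [group_profile()] objects.
#' @param probes Probe list shared by all profiles.
#' @param seed Optional integer seed (per-organism sub-seeds are derived from
#'   it).
#' @param ... Passed to [synthetic_proteome()].
#' @return List of `proteome` objects, grouped profile by profile.
#' @export
make_group_proteomes <- function(profiles, probes, seed = NULL, ...) {
  n_total <- sum(vapply(profiles, function(p) p$n_organisms, integer(1)))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_total))
  out <- list()
  k <- 0
  for (pr in profiles) {
    for (i in seq_len(pr$n_organisms)) {
      k <- k + 1
      out[[k]] <- synthetic_proteome(pr, i, probes, seed = seeds[k], ...)
    }
  }
  out
}

#' Randomly truncate a proteome
#'
#' Uniformly samples `ceiling(retain_fraction x n)` proteins without
#' replacement (in original order) and scales the gene count by the same
#' fraction (rounded up), emulating an incompletely sequenced genome.
#'
#' @param p A `proteome`.
#' @param retain_fraction Real in (0, 1].
#' @param seed Optional integer seed.
#' @return A `proteome`.
#' @export
truncate_proteome <- function(p, retain_fraction, seed = NULL) {
  stopifnot(inherits(p, "proteome"))
  if (retain_fraction <= 0 || retain_fraction > 1) {
    stop("retain_fraction must be in (0, 1]", call. = FALSE)
  }
  n <- length(p$proteins)
  keep <- ceiling(retain_fraction * n)
  idx <- with_seed(seed, sort(sample.int(n, keep)))
  proteome(p$organism_id, p$proteins[idx],
           gene_count = ceiling(retain_fraction * p$gene_count))
}

# Frequency row of a truncated proteome from its precomputed per-protein
# count table (same sampling scheme as truncate_proteome).
truncated_row <- function(counts, gene_count, retain_fraction) {
  n <- nrow(counts)
  keep <- ceiling(retain_fraction * n)
  idx <- sample.int(n, keep)
  colSums(counts[idx, , drop = FALSE]) / ceiling(retain_fraction * gene_count)
}

#' Random-truncation robustness experiment
#'
#' Runs both truncation experiments against the reference tree built from the
#' full proteomes.  Experiment (a): in each replicate every organism is
#' truncated one at a time, the tree is rebuilt, and a precise classification
#' is recorded when the rebuilt topology equals the reference topology;
#' accuracy is the number of precise classifications divided by the number of
#' organisms.  Experiment (b): in each replicate all organisms are truncated
#' simultaneously, the tree is rebuilt, and its tree CC against the reference
#' tree is recorded.  Means and standard deviations are taken over
#' `replicates` repeats (sample sd; 0 for a single replicate).
#'
#' @param proteomes List of >= 3 `proteome` objects.
#' @param probes Probe list.
#' @param retain_fraction Real in (0, 1].
#' @param replicates Positive integer (default 10, the repeat count used to
#'   attach standard deviations to each truncation rate).
#' @param seed Optional integer seed.
#' @param wildcard_nonstandard Passed to the probe counter.
#' @return Object of class `truncation_result`: a list with
#'   `retain_fraction`, `replicates`, `accuracy_mean`, `accuracy_sd`,
#'   `cc_mean`, `cc_sd`, `seed`.
#' @export
truncation_experiment <- function(proteomes, probes, retain_fraction,
                                  replicates = 10L, seed = NULL,
                                  wildcard_nonstandard = TRUE) {
  stopifnot(length(proteomes) >= 3, replicates >= 1)
  if (retain_fraction <= 0 || retain_fraction > 1) {
    stop("retain_fraction must be in (0, 1]", call. = FALSE)
  }
  tables <- lapply(proteomes, probe_count_table, probes = probes,
                   wildcard_nonstandard = wildcard_nonstandard)
  gene_counts <- vapply(proteomes, function(p) p$gene_count, integer(1))
  ids <- vapply(proteomes, function(p) p$organism_id, character(1))
  full <- do.call(rbind, lapply(seq_along(tables), function(i) {
    colSums(tables[[i]]) / gene_counts[i]
  }))
  rownames(full) <- ids
  ref_tree <- build_tree(full)
  n_org <- length(proteomes)

  with_seed(seed, {
    acc <- numeric(replicates)
    cc <- numeric(replicates)
    for (r in seq_len(replicates)) {
      # (a) one organism truncated at a time
      hits <- 0L
      for (o in seq_len(n_org)) {
        m <- full
        m[o, ] <- truncated_row(tables[[o]], gene_counts[o], retain_fraction)
        if (same_topology(build_tree(m), ref_tree)) hits <- hits + 1L
      }
      acc[r] <- hits / n_org
      # (b) all organisms truncated simultaneously
      m <- full
      for (o in seq_len(n_org)) {
        m[o, ] <- truncated_row(tables[[o]], gene_counts[o], retain_fraction)
      }
      cc[r] <- tree_cc(build_tree(m), ref_tree)
    }
    structure(list(retain_fraction = retain_fraction,
                   replicates = as.integer(replicates),
                   accuracy_mean = mean(acc),
                   accuracy_sd = if (replicates > 1) stats::sd(acc) else 0,
                   cc_mean = mean(cc),
                   cc_sd = if (replicates > 1) stats::sd(cc) else 0,
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
              class = "truncation_result")
  })
}

#' @export
print.truncation_result <- function(x, ...) {
  cat(sprintf(paste0("truncation experiment: retain %.2f, %d replicates\n",
                     "  reclassification accuracy: %.4f (sd %.4f)\n",
                     "  tree CC vs reference:      %.4f (sd %.4f)\n"),
              x$retain_fraction, x$replicates,
              x$accuracy_mean, x$accuracy_sd, x$cc_mean, x$cc_sd))
  invisible(x)
}

#' Truncation experiments over a grid of retain fractions
#'
#' @inheritParams truncation_experiment
#' @param retain_fractions Numeric vector of retain fractions.
#' @return `data.frame` with one row per retain fraction (columns as in
#'   [truncation_experiment()]).
#' @export
truncation_grid <- function(proteomes, probes, retain_fractions,
                            replicates = 10L, seed = NULL, ...) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                      length(retain_fractions)))
  rows <- lapply(seq_along(retain_fractions), function(i) {
    res <- truncation_experiment(proteomes, probes, retain_fractions[i],
                                 replicates = replicates, seed = seeds[i], ...)
    data.frame(retain_fraction = res$retain_fraction,
               replicates = res$replicates,
               accuracy_mean = res$accuracy_mean,
               accuracy_sd = res$accuracy_sd,
               cc_mean = res$cc_mean, cc_sd = res$cc_sd,
               seed = res$seed)
  })
  do.call(rbind, rows)
}
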