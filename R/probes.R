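# Conserved-sequence probes: PROSITE-style pattern descriptors, their parser,
# serializer, and the occurrence counter used to profile proteomes.

#' The 20 standard amino-acid one-letter codes
#'
#' Uppercase one-letter codes of the 20 standard proteinogenic amino acids.
#' Ambiguity and non-standard codes (B, J, O, U, X, Z, and the stop symbol
#' `*`) are deliberately excluded: probe residue sets may only contain
#' standard letters, and non-standard letters in scanned sequences never
#' satisfy an exact residue, a `[..]` set or a `{..}` exclusion.
#'
#' @format A character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

pattern_element <- function(kind, residues = character(), min_repeat = 1L,
                            max_repeat = min_repeat) {
  stopifnot(kind %in% c("exact", "any", "one_of", "none_of"))
  structure(list(kind = kind,
                 residues = residues,
                 min_repeat = as.integer(min_repeat),
                 max_repeat = as.integer(max_repeat)),
            class = "pattern_element")
}

parse_error <- function(token, position, reason) {
  stop(sprintf("malformed pattern: %s at element %d (token \"%s\")",
               reason, position, token), call. = FALSE)
}

# Parse the optional (n) / (n,m) repeat suffix of one dash-separated token.
# Returns list(core, min_repeat, max_repeat).
split_repeat <- function(token, position) {
  m <- regmatches(token, regexec("^(.*?)\\((\\d+)(?:,(\\d+))?\\)$", token))[[1]]
  if (length(m) == 0) {
    return(list(core = token, min_repeat = 1L, max_repeat = 1L))
  }
  lo <- as.integer(m[3])
  hi <- if (m[4] == "") lo else as.integer(m[4])
  if (lo < 1) parse_error(token, position, "repeat count of 0")
  if (hi < lo) parse_error(token, position, "repeat range with n > m")
  list(core = m[2], min_repeat = lo, max_repeat = hi)
}

parse_element <- function(token, position) {
  if (!nzchar(token)) parse_error(token, position, "empty element")
  parts <- split_repeat(token, position)
  core <- parts$core
  if (core == "x") {
    kind <- "any"; residues <- character()
  } else if (grepl("^\\[", core) || grepl("^\\{", core)) {
    open <- substr(core, 1, 1)
    close <- if (open == "[") "]" else "}"
    if (substr(core, nchar(core), nchar(core)) != close) {
      parse_error(token, position, sprintf("unbalanced bracket \"%s\"", open))
    }
    inner <- substr(core, 2, nchar(core) - 1)
    if (!nzchar(inner)) parse_error(token, position, "empty residue set")
    residues <- strsplit(inner, "")[[1]]
    bad <- setdiff(residues, AA_STANDARD)
    if (length(bad)) {
      parse_error(token, position,
                  sprintf("non-standard residue letter \"%s\"", bad[1]))
    }
    residues <- unique(residues)
    kind <- if (open == "[") "one_of" else "none_of"
  } else if (nchar(core) == 1 && core %in% AA_STANDARD) {
    kind <- "exact"; residues <- core
  } else {
    parse_error(token, position, "unrecognized element")
  }
  pattern_element(kind, residues, parts$min_repeat, parts$max_repeat)
}

#' Parse a PROSITE-style pattern descriptor
#'
#' Parses a dash-separated conserved-sequence descriptor into a `probe`
#' object.  The grammar covers single residue letters, the `x` wildcard,
#' `[..]` ambiguity sets, `{..}` exclusion sets, `(n)` / `(n,m)` repeat
#' counts, an optional leading `<` (match must start at the first residue),
#' an optional trailing `>` (match must end at the last residue), and an
#' optional trailing period.  Whitespace is tolerated and stripped.
#'
#' @param text Pattern descriptor, e.g. `"Q-[LIV]-H-H-[SA]-x(2)-D-G-[FY]-H"`
#'   (the active-site pattern of chloramphenicol acetyltransferase, PROSITE
#'   accession PS00100).
#' @param id Accession string to attach to the probe (default `""`).
#' @param skip_flagged Logical; whether the source annotated the pattern as
#'   highly frequent (carried through by [read_probe_file()]).
#' @return An object of class `probe`: a list with fields `id`,
#'   `raw_pattern`, `elements` (ordered `pattern_element` list),
#'   `anchored_start`, `anchored_end`, `skip_flagged`.
#' @examples
#' p <- parse_pattern("Q-[LIV]-H-H-[SA]-x(2)-D-G-[FY]-H", id = "PS00100")
#' length(p$elements)  # 10
#' count_occurrences(p, "QLHHSGGDGFH")
#' @seealso [count_occurrences()], [read_probe_file()], [format.probe()]
#' @export
parse_pattern <- function(text, id = "", skip_flagged = FALSE) {
  raw <- text
  s <- gsub("[[:space:]]", "", text)
  s <- sub("\\.$", "", s)
  anchored_start <- startsWith(s, "<")
  if (anchored_start) s <- substring(s, 2)
  anchored_end <- endsWith(s, ">")
  if (anchored_end) s <- substring(s, 1, nchar(s) - 1)
  if (!nzchar(s)) stop("malformed pattern: empty descriptor", call. = FALSE)
  # Dashes inside [..] or {..} are not separators (they do not occur in the
  # grammar, but guard against splitting a malformed set silently).
  tokens <- strsplit(s, "-", fixed = TRUE)[[1]]
  elements <- lapply(seq_along(tokens),
                     function(i) parse_element(tokens[i], i))
  structure(list(id = id,
                 raw_pattern = raw,
                 elements = elements,
                 anchored_start = anchored_start,
                 anchored_end = anchored_end,
                 skip_flagged = isTRUE(skip_flagged)),
            class = "probe")
}

element_to_text <- function(el) {
  core <- switch(el$kind,
                 exact = el$residues,
                 any = "x",
                 one_of = paste0("[", paste(el$residues, collapse = ""), "]"),
                 none_of = paste0("{", paste(el$residues, collapse = ""), "}"))
  if (el$min_repeat == 1L && el$max_repeat == 1L) return(core)
  if (el$min_repeat == el$max_repeat) {
    return(sprintf("%s(%d)", core, el$min_repeat))
  }
  sprintf("%s(%d,%d)", core, el$min_repeat, el$max_repeat)
}

#' Serialize a probe back to canonical descriptor text
#'
#' The canonical text re-parses to an element-wise identical probe
#' (round-trip property).
#'
#' @param x A `probe`.
#' @param ... Ignored.
#' @return A descriptor string.
#' @export
format.probe <- function(x, ...) {
  body <- paste(vapply(x$elements, element_to_text, character(1)),
                collapse = "-")
  paste0(if (x$anchored_start) "<" else "", body,
         if (x$anchored_end) ">" else "", ".")
}

#' @export
as.character.probe <- function(x, ...) format(x)

#' @export
print.probe <- function(x, ...) {
  cat(sprintf("<probe %s> %s%s\n",
              if (nzchar(x$id)) x$id else "(unnamed)", format(x),
              if (x$skip_flagged) "  [skip-flagged]" else ""))
  invisible(x)
}

# Translate one element into a PCRE fragment.  Non-standard sequence letters
# (B, J, O, U, X, Z, *) never satisfy exact/one-of/none-of elements; whether
# the `x` wildcard accepts them is governed by wildcard_nonstandard.
element_to_regex <- function(el, wildcard_nonstandard = TRUE) {
  core <- switch(el$kind,
    exact = el$residues,
    any = if (wildcard_nonstandard) "." else
      paste0("[", paste(AA_STANDARD, collapse = ""), "]"),
    one_of = paste0("[", paste(el$residues, collapse = ""), "]"),
    none_of = paste0("[", paste(setdiff(AA_STANDARD, el$residues),
                                collapse = ""), "]"))
  if (el$min_repeat == 1L && el$max_repeat == 1L) return(core)
  if (el$min_repeat == el$max_repeat) {
    return(sprintf("%s{%d}", core, el$min_repeat))
  }
  sprintf("%s{%d,%d}", core, el$min_repeat, el$max_repeat)
}

probe_regex <- function(probe, wildcard_nonstandard = TRUE) {
  paste0(vapply(probe$elements, element_to_regex, character(1),
                wildcard_nonstandard = wildcard_nonstandard),
         collapse = "")
}

#' Count pattern occurrences in a protein sequence
#'
#' Counts the number of distinct start positions at which the probe matches.
#' Overlapping matches are all counted; a variable-repeat pattern that
#' matches a given start position in several ways counts that position once.
#' Matching is performed with a zero-width lookahead regular expression so
#' every start position is examined.
#'
#' @param probe A `probe` from [parse_pattern()].
#' @param sequence Amino-acid string (uppercased internally).  Non-standard
#'   letters fail exact residues, `[..]` sets and `{..}` exclusions; by
#'   default the `x` wildcard accepts them (set `wildcard_nonstandard =
#'   FALSE` to restrict `x` to the 20 standard letters).
#' @param wildcard_nonstandard Logical, see above.
#' @return Non-negative integer count; `0` for an empty sequence.
#' @examples
#' p <- parse_pattern("A-A")
#' count_occurrences(p, "AAAA")  # 3 overlapping start positions
#' @export
count_occurrences <- function(probe, sequence, wildcard_nonstandard = TRUE) {
  stopifnot(inherits(probe, "probe"))
  sequence <- toupper(as.character(sequence))
  if (is.na(sequence) || !nzchar(sequence)) return(0L)
  rx <- probe_regex(probe, wildcard_nonstandard)
  if (probe$anchored_end) rx <- paste0(rx, "$")
  if (probe$anchored_start) {
    return(if (grepl(paste0("^", rx), sequence, perl = TRUE)) 1L else 0L)
  }
  hits <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

#' Read a probe collection from a file
#'
#' Supports two formats.  `"prosite"`: a PROSITE flat file of records ending
#' in `//`, with `ID`, `AC`, `PA` and `CC` lines; `PA` lines may continue
#' across several lines and are concatenated before parsing; records whose
#' `CC` lines carry the `/SKIP-FLAG=TRUE` annotation (the database's mark for
#' highly frequent patterns) are flagged, and dropped when
#' `drop_frequent = TRUE`.  Records without any `PA` line (matrix profiles)
#' are skipped with a warning.  `"tsv"`: one `<id><TAB><pattern>` per line.
#'
#' @param path File path.
#' @param format `"prosite"` or `"tsv"`.
#' @param drop_frequent Drop skip-flagged (highly frequent) probes.
#' @param strict If `TRUE`, a record whose pattern fails to parse raises an
#'   error; otherwise it is skipped with a warning.
#' @return List of `probe` objects in file order.
#' @export
read_probe_file <- function(path, format = c("prosite", "tsv"),
                            drop_frequent = FALSE, strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read probe file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  probes <- if (format == "tsv") {
    read_probes_tsv(lines, strict)
  } else {
    read_probes_prosite(lines, strict)
  }
  if (drop_frequent) {
    probes <- Filter(function(p) !p$skip_flagged, probes)
  }
  probes
}

read_probes_tsv <- function(lines, strict) {
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      msg <- sprintf("probe line without a TAB-separated pattern: \"%s\"", ln)
      if (strict) stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      next
    }
    p <- try_parse(parts[2], parts[1], skip_flagged = FALSE, strict = strict)
    if (!is.null(p)) out[[length(out) + 1]] <- p
  }
  out
}

try_parse <- function(text, id, skip_flagged, strict) {
  tryCatch(parse_pattern(text, id = id, skip_flagged = skip_flagged),
           error = function(e) {
             if (strict) stop(e)
             warning(sprintf("skipping probe %s: %s", id, conditionMessage(e)),
                     call. = FALSE)
             NULL
           })
}

read_probes_prosite <- function(lines, strict) {
  out <- list()
  acc <- ""
  pa <- character()
  skip <- FALSE
  flush <- function() {
    if (!length(pa)) {
      if (nzchar(acc)) {
        warning(sprintf("record %s has no PA line (matrix profile?); skipped",
                        acc), call. = FALSE)
      }
      return(NULL)
    }
    try_parse(paste(pa, collapse = ""), acc, skip, strict)
  }
  for (ln in lines) {
    tag <- substr(ln, 1, 2)
    body <- trimws(substring(ln, 6))
    if (tag == "//") {
      p <- flush()
      if (!is.null(p)) out[[length(out) + 1]] <- p
      acc <- ""; pa <- character(); skip <- FALSE
    } else if (tag == "AC") {
      acc <- sub(";.*$", "", body)
    } else if (tag == "PA") {
      pa <- c(pa, body)
    } else if (tag == "CC") {
      if (grepl("/SKIP-FLAG\\s*=\\s*TRUE", body, ignore.case = TRUE)) {
        skip <- TRUE
      }
    }
  }
  out
}
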