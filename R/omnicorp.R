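#' Read a term lexicon
#'
#' TSV with header `term	curie`. Terms are lowercased; a term mapped to two
#' different CURIEs is an error (silent last-wins would hide curation bugs).
#'
#' @param path TSV path.
#' @return a named character vector (class `lexicon`): lowercased surface
#'   term to CURIE.
#' @export
read_lexicon <- function(path) {
  df <- read_tsv_raw(path, c("term", "curie"))
  lexicon(stats::setNames(df$curie, df$term))
}

#' Construct a term lexicon
#'
#' @param entries named character vector mapping surface terms to CURIEs.
#' @return a `lexicon` object.
#' @export
lexicon <- function(entries) {
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop("lexicon entries must be a named character vector (term -> CURIE)", call. = FALSE)
  }
  terms <- tolower(names(entries))
  dup <- duplicated(terms)
  if (any(dup)) {
    conflicting <- unique(terms[dup])
    for (tm in conflicting) {
      if (length(unique(entries[terms == tm])) > 1L) {
        stop(sprintf("lexicon term '%s' maps to multiple CURIEs", tm), call. = FALSE)
      }
    }
    entries <- entries[!dup]
    terms <- terms[!dup]
  }
  structure(stats::setNames(curie(unname(entries)), terms), class = "lexicon")
}

# lowercase, strip punctuation, split into tokens
tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1L]]
  toks[nzchar(toks)]
}

#' Annotate text against a lexicon
#'
#' Dictionary-based named-entity recognition: the text is lowercased, split
#' on token boundaries, and scanned left to right with greedy longest match
#' against the lexicon's (tokenized) surface terms. A shorter term contained
#' in a consumed longer match is suppressed — "carbon monoxide" consumes
#' "carbon". Multi-word terms match only on token boundaries, so "ada" does
#' not fire inside "adaptation".
#'
#' @param text a character string (may be empty).
#' @param lex a [lexicon()].
#' @return character vector of distinct matched CURIEs (sorted).
#' @export
annotate_text <- function(text, lex) {
  stopifnot(inherits(lex, "lexicon"))
  if (length(lex) == 0L) stop("lexicon is empty", call. = FALSE)
  toks <- tokenize(paste(text, collapse = " "))
  if (length(toks) == 0L) return(character(0))

  term_tokens <- lapply(names(lex), tokenize)
  term_joined <- vapply(term_tokens, paste, character(1), collapse = " ")
  term_len <- lengths(term_tokens)
  lookup <- as.list(stats::setNames(unname(lex), term_joined))
  max_len <- max(term_len)

  hits <- character(0)
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    matched <- FALSE
    for (L in seq(min(max_len, n - i + 1L), 1L)) {
      key <- paste(toks[i:(i + L - 1L)], collapse = " ")
      cur <- lookup[[key]]
      if (!is.null(cur)) {
        hits <- c(hits, cur)
        i <- i + L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  sort(unique(hits))
}

#' Build a PMID-concept co-occurrence index from an abstract corpus
#'
#' Each abstract record (PMID, title, abstract) is annotated with
#' [annotate_text()] over the concatenated title and abstract; the index
#' stores at most one link per (PMID, concept) pair.
#'
#' @param corpus data.frame with columns `pmid`, `title`, `abstract`, or a
#'   list of such records.
#' @param lex a [lexicon()].
#' @return a `cooc_index` object with elements `links` (data.frame `pmid`,
#'   `curie`) and `postings` (named list: CURIE to character vector of PMIDs).
#' @export
build_index <- function(corpus, lex) {
  if (!is.data.frame(corpus)) {
    corpus <- do.call(rbind, lapply(corpus, function(r) {
      data.frame(
        pmid = as.character(r$pmid), title = as.character(r$title %||% ""),
        abstract = as.character(r$abstract %||% ""), stringsAsFactors = FALSE
      )
    }))
  }
  for (col in c("pmid", "title", "abstract")) {
    if (!col %in% names(corpus)) stop(sprintf("corpus is missing column '%s'", col), call. = FALSE)
  }
  if (anyDuplicated(corpus$pmid)) {
    dup <- unique(corpus$pmid[duplicated(corpus$pmid)])
    stop(sprintf("duplicate PMID(s) in corpus: %s", paste(dup, collapse = ", ")), call. = FALSE)
  }
  pmids <- character(0)
  curies <- character(0)
  for (i in seq_len(nrow(corpus))) {
    concepts <- annotate_text(paste(corpus$title[i], corpus$abstract[i]), lex)
    if (length(concepts) > 0L) {
      pmids <- c(pmids, rep(corpus$pmid[i], length(concepts)))
      curies <- c(curies, concepts)
    }
  }
  cooc_index(data.frame(pmid = pmids, curie = curies, stringsAsFactors = FALSE))
}

#' Construct a co-occurrence index from explicit PMID-concept links
#'
#' @param links data.frame with columns `pmid` and `curie`.
#' @return a `cooc_index`.
#' @export
cooc_index <- function(links) {
  stopifnot(is.data.frame(links), all(c("pmid", "curie") %in% names(links)))
  links <- data.frame(
    pmid = as.character(links$pmid), curie = as.character(links$curie),
    stringsAsFactors = FALSE
  )
  if (nrow(links) > 0L) links$curie <- curie(links$curie)
  links <- unique(links)
  links <- links[order(links$pmid, links$curie), , drop = FALSE]
  rownames(links) <- NULL
  postings <- lapply(split(links$pmid, links$curie), unique)
  structure(list(links = links, postings = postings), class = "cooc_index")
}

#' Count abstracts mentioning both concepts
#'
#' The number of PMIDs whose abstracts mention both `a` and `b`; symmetric,
#' and zero for concepts absent from the index. `cooccurrence_count(x, a, a)`
#' is the number of abstracts mentioning `a` at all.
#'
#' @param index a `cooc_index`.
#' @param a,b CURIEs.
#' @return non-negative integer.
#' @export
cooccurrence_count <- function(index, a, b) {
  stopifnot(inherits(index, "cooc_index"))
  pa <- index$postings[[curie(a)]]
  pb <- index$postings[[curie(b)]]
  if (is.null(pa) || is.null(pb)) return(0L)
  length(intersect(pa, pb))
}

#' Write a co-occurrence index as a sorted TSV dump
#'
#' @param index a `cooc_index`.
#' @param path output path; TSV with header `pmid	curie`.
#' @return invisibly, `path`.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "cooc_index"))
  write_tsv_raw(index$links, path)
  invisible(path)
}

#' Read an abstract corpus from line-delimited JSON
#'
#' One JSON object per line with fields `pmid`, `title`, `abstract`.
#'
#' @param path file path.
#' @return data.frame with columns `pmid`, `title`, `abstract`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  do.call(rbind, lapply(recs, function(r) {
    data.frame(
      pmid = as.character(r$pmid), title = as.character(r$title %||% ""),
      abstract = as.character(r$abstract %||% ""), stringsAsFactors = FALSE
    )
  }))
}

#' Write an abstract corpus as line-delimited JSON
#'
#' @param corpus data.frame with columns `pmid`, `title`, `abstract`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(
      pmid = corpus$pmid[i], title = corpus$title[i], abstract = corpus$abstract[i]
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.cooc_index <- function(x, ...) {
  cat(sprintf(
    "<cooc_index> %d links, %d concepts, %d abstracts\n",
    nrow(x$links), length(x$postings), length(unique(x$links$pmid))
  ))
  invisible(x)
}
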