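#' Parse and normalize a CURIE
#'
#' A CURIE (Compact Uniform Resource Identifier) names an entity as
#' `"PREFIX:LOCALID"`. The prefix is uppercased on normalization; the local
#' identifier is kept verbatim so joins across files are stable.
#'
#' @param x character vector of CURIE strings.
#' @return character vector of normalized CURIEs.
#' @examples
#' curie("mesh:D002248")
#' @export
curie <- function(x) {
  if (!is.character(x)) stop("CURIEs must be character strings", call. = FALSE)
  out <- vapply(x, function(s) {
    if (is.na(s)) stop("CURIE must not be NA", call. = FALSE)
    parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !nzchar(parts[1L]) || !nzchar(parts[2L])) {
      stop(sprintf(
        "malformed CURIE '%s': expected exactly one ':' separating a non-empty prefix and local id",
        s
      ), call. = FALSE)
    }
    paste0(toupper(parts[1L]), ":", parts[2L])
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Construct a category ontology
#'
#' A miniature upper-level category forest standing in for a full biomedical
#' entity-type model: a set of category tokens with a parent map rooted at a
#' single universal category that subsumes everything.
#'
#' @param parent named character vector mapping each non-root category to its
#'   parent; the single category that does not appear as a name is the root.
#' @return an object of class `type_ontology` with elements `categories`,
#'   `parent` (named character) and `root`.
#' @seealso [default_ontology()], [is_subtype()]
#' @export
type_ontology <- function(parent) {
  if (is.null(names(parent)) || any(!nzchar(names(parent)))) {
    stop("'parent' must be a named character vector (child -> parent)", call. = FALSE)
  }
  categories <- sort(unique(c(names(parent), unname(parent))))
  roots <- setdiff(categories, names(parent))
  if (length(roots) != 1L) {
    stop(sprintf(
      "ontology must have exactly one root category; found: %s",
      paste(roots, collapse = ", ")
    ), call. = FALSE)
  }
  # every category must reach the root without cycles
  for (cat in categories) {
    seen <- character(0)
    cur <- cat
    while (cur != roots) {
      if (cur %in% seen) stop(sprintf("ontology has a cycle through '%s'", cur), call. = FALSE)
      seen <- c(seen, cur)
      cur <- unname(parent[[cur]])
    }
  }
  structure(
    list(categories = categories, parent = parent, root = roots),
    class = "type_ontology"
  )
}

#' The default miniature category ontology
#'
#' Four leaf categories under a universal `named_thing` root:
#' `chemical_substance`, `gene`, `disease`, and `phenotypic_feature`.
#'
#' @return a `type_ontology`.
#' @export
default_ontology <- function() {
  type_ontology(c(
    chemical_substance = "named_thing",
    gene = "named_thing",
    disease = "named_thing",
    phenotypic_feature = "named_thing"
  ))
}

#' Test category subsumption
#'
#' `TRUE` iff `ancestor` lies on `child`'s parent chain, inclusively: every
#' category is its own subtype, and the root subsumes all categories.
#'
#' @param ontology a [type_ontology()].
#' @param child,ancestor category tokens present in the ontology.
#' @return logical scalar.
#' @export
is_subtype <- function(ontology, child, ancestor) {
  stopifnot(inherits(ontology, "type_ontology"))
  for (cat in c(child, ancestor)) {
    if (!cat %in% ontology$categories) {
      stop(sprintf("unknown category '%s'", cat), call. = FALSE)
    }
  }
  cur <- child
  repeat {
    if (cur == ancestor) return(TRUE)
    if (cur == ontology$root) return(FALSE)
    cur <- unname(ontology$parent[[cur]])
  }
}

#' @export
print.type_ontology <- function(x, ...) {
  cat(sprintf(
    "<type_ontology> %d categories, root '%s'\n",
    length(x$categories), x$root
  ))
  invisible(x)
}
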