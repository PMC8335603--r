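#' Construct a cohort of subjects with exposures and outcomes
#'
#' @param subjects data.frame with a `subject_id` column plus one column per
#'   chemical exposure and per outcome condition, coded 1 (yes), 0 (no), or
#'   NA (missing).
#' @param chemicals character vector naming the exposure columns.
#' @param outcomes character vector naming the outcome columns.
#' @param classes named list mapping chemical-class names to character
#'   vectors of member chemicals (each a chemical column); may be empty.
#' @return an object of class `cohort`.
#' @export
cohort <- function(subjects, chemicals, outcomes, classes = list()) {
  stopifnot(is.data.frame(subjects), "subject_id" %in% names(subjects))
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject ids", call. = FALSE)
  missing_cols <- setdiff(c(chemicals, outcomes), names(subjects))
  if (length(missing_cols) > 0L) {
    stop(sprintf("subject table is missing column(s): %s", paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (length(intersect(chemicals, outcomes)) > 0L) {
    stop("a column cannot be both a chemical and an outcome", call. = FALSE)
  }
  for (cl in names(classes)) {
    stray <- setdiff(classes[[cl]], chemicals)
    if (length(stray) > 0L) {
      stop(sprintf("class '%s' member(s) not among the chemicals: %s", cl, paste(stray, collapse = ", ")), call. = FALSE)
    }
  }
  for (col in c(chemicals, outcomes)) {
    v <- subjects[[col]]
    if (!all(v %in% c(0L, 1L, NA))) {
      stop(sprintf("column '%s' must be coded 1/0/NA", col), call. = FALSE)
    }
  }
  structure(
    list(
      subjects = subjects, chemicals = chemicals, outcomes = outcomes,
      classes = classes
    ),
    class = "cohort"
  )
}

#' Read a cohort from TSV tables
#'
#' The subject table has one row per subject: `subject_id` plus one column
#' per chemical and per condition with values in \{1, 0, NA\}. Class
#' definitions come as a TSV with header `class	chemical`.
#'
#' @param subjects_path subject table path.
#' @param outcomes character vector naming the outcome columns; the
#'   remaining non-id columns are taken as chemicals.
#' @param classes_path optional class-definition TSV path.
#' @return a [cohort()].
#' @export
read_cohort <- function(subjects_path, outcomes, classes_path = NULL) {
  df <- utils::read.delim(subjects_path,
    sep = "\t", quote = "", stringsAsFactors = FALSE, check.names = FALSE
  )
  if (!"subject_id" %in% names(df)) stop("subject table needs a 'subject_id' column", call. = FALSE)
  chem <- setdiff(names(df), c("subject_id", outcomes))
  classes <- list()
  if (!is.null(classes_path)) {
    ct <- read_tsv_raw(classes_path, c("class", "chemical"))
    classes <- split(ct$chemical, ct$class)
  }
  cohort(df, chem, outcomes, classes)
}

#' Write a cohort to TSV tables
#'
#' @param ch a [cohort()].
#' @param subjects_path output path for the subject table.
#' @param classes_path optional output path for the class definitions.
#' @return invisibly, the subject table path.
#' @export
write_cohort <- function(ch, subjects_path, classes_path = NULL) {
  stopifnot(inherits(ch, "cohort"))
  write_tsv_raw(ch$subjects, subjects_path)
  if (!is.null(classes_path) && length(ch$classes) > 0L) {
    ct <- data.frame(
      class = rep(names(ch$classes), lengths(ch$classes)),
      chemical = unlist(ch$classes, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    write_tsv_raw(ct, classes_path)
  }
  invisible(subjects_path)
}

# exposure vector for a chemical or class: 1/0/NA per subject.
# class rule: exposed if any member is yes; missing only if no member is yes
# and at least one is missing; else unexposed.
exposure_vector <- function(ch, exposure) {
  if (exposure %in% ch$chemicals) {
    return(ch$subjects[[exposure]])
  }
  if (exposure %in% names(ch$classes)) {
    members <- ch$subjects[ch$classes[[exposure]]]
    any_yes <- apply(members, 1L, function(r) any(r == 1L, na.rm = TRUE))
    any_na <- apply(members, 1L, anyNA)
    out <- ifelse(any_yes, 1L, ifelse(any_na, NA_integer_, 0L))
    return(out)
  }
  stop(sprintf("unknown exposure label '%s'", exposure), call. = FALSE)
}

#' Build a 2x2 exposure-outcome contingency table
#'
#' Subjects missing either variable are excluded (pairwise deletion). For a
#' class-level exposure a subject is exposed if any member chemical is yes,
#' missing only if no member is yes and at least one is missing, and
#' unexposed otherwise.
#'
#' @param ch a [cohort()].
#' @param exposure a chemical or class label.
#' @param outcome an outcome label.
#' @return an object of class `contingency`: integer vector
#'   `c(a, b, c, d)` = (exposed case, exposed control, unexposed case,
#'   unexposed control).
#' @export
build_contingency <- function(ch, exposure, outcome) {
  stopifnot(inherits(ch, "cohort"))
  if (!outcome %in% ch$outcomes) stop(sprintf("unknown outcome label '%s'", outcome), call. = FALSE)
  e <- exposure_vector(ch, exposure)
  o <- ch$subjects[[outcome]]
  keep <- !is.na(e) & !is.na(o)
  e <- e[keep]
  o <- o[keep]
  contingency(
    a = sum(e == 1L & o == 1L), b = sum(e == 1L & o == 0L),
    c = sum(e == 0L & o == 1L), d = sum(e == 0L & o == 0L)
  )
}

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d non-negative integer counts: exposed case, exposed
#'   control, unexposed case, unexposed control.
#' @return class `contingency`, a named integer vector.
#' @export
contingency <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be non-negative integers", call. = FALSE)
  }
  structure(as.integer(cells), names = names(cells), class = "contingency")
}

as_matrix_2x2 <- function(tab) {
  matrix(as.integer(tab), nrow = 2L, byrow = TRUE,
    dimnames = list(exposure = c("yes", "no"), outcome = c("case", "control"))
  )
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson statistic `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`
#' on 1 degree of freedom; no continuity correction. All four margins must
#' be positive (use [fisher_exact_two_sided()] otherwise).
#'
#' @param tab a [contingency()].
#' @return list with `statistic` and `p_value`.
#' @export
pearson_chi2 <- function(tab) {
  stopifnot(inherits(tab, "contingency"))
  m <- as_matrix_2x2(tab)
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) {
    stop("chi-square requires all margins > 0; use the Fisher exact test", call. = FALSE)
  }
  ht <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Sums the hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table.
#'
#' @param tab a [contingency()].
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(tab) {
  stopifnot(inherits(tab, "contingency"))
  if (sum(tab) < 1L) stop("table must have at least one observation", call. = FALSE)
  unname(stats::fisher.test(as_matrix_2x2(tab))$p.value)
}

#' Choose the association test for a 2x2 table
#'
#' Cochran's rule: the Fisher exact test when any expected cell count
#' (row total x column total / n) is below 5 or any margin is zero;
#' otherwise the chi-square test.
#'
#' @param tab a [contingency()].
#' @return `"fisher"` or `"chi_square"`.
#' @export
select_test <- function(tab) {
  stopifnot(inherits(tab, "contingency"))
  m <- as_matrix_2x2(tab)
  rs <- rowSums(m)
  cs <- colSums(m)
  n <- sum(m)
  if (n == 0L || any(rs == 0L) || any(cs == 0L)) return("fisher")
  expected <- outer(rs, cs) / n
  if (any(expected < 5)) "fisher" else "chi_square"
}

#' Wald odds ratio with 95% confidence interval
#'
#' `OR = ad / bc`, `CI = exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Not adjusted for small samples: any zero cell makes the estimate
#' undefined, which is flagged (not thrown).
#'
#' @param tab a [contingency()].
#' @return list with `odds_ratio`, `ci_low`, `ci_high` (all `NA` when
#'   undefined) and `defined` (logical, with a `reason` when `FALSE`).
#' @export
wald_odds_ratio <- function(tab) {
  stopifnot(inherits(tab, "contingency"))
  if (any(tab == 0L)) {
    return(list(
      odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      defined = FALSE, reason = "zero cell"
    ))
  }
  a <- tab[["a"]]; b <- tab[["b"]]; cc <- tab[["c"]]; d <- tab[["d"]]
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  list(
    odds_ratio = or,
    ci_low = exp(log(or) - 1.96 * se),
    ci_high = exp(log(or) + 1.96 * se),
    defined = TRUE
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, clamped to 1 and monotone-enforced, returned
#' in input order.
#'
#' @param p numeric vector of p-values in \[0,1\] (NAs passed through).
#' @return numeric vector of adjusted p-values.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0,1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Screen all exposure-outcome pairs for association
#'
#' One test per (chemical, outcome) pair and, when classes are defined, per
#' (class, outcome) pair. Each 2x2 table uses pairwise deletion of missing
#' values; the test is chosen by [select_test()]; all non-degenerate tests
#' form a single Benjamini-Hochberg family; significance is flagged at
#' adjusted p < .05 and < .10. Degenerate tables (no usable subjects, or an
#' all-zero margin pair) are flagged and excluded from the FDR family. No
#' covariate adjustment is performed.
#'
#' @param ch a [cohort()].
#' @param outcomes outcome labels to screen (default: all in the cohort).
#' @return data.frame of class `assoc_results` with columns exposure,
#'   outcome, level, a, b, c, d, test, p, p_fdr, or, ci_low, ci_high,
#'   sig05, sig10, degenerate.
#' @export
screen_associations <- function(ch, outcomes = ch$outcomes) {
  stopifnot(inherits(ch, "cohort"), length(ch$chemicals) >= 1L, length(outcomes) >= 1L)
  exposures <- data.frame(
    label = c(ch$chemicals, names(ch$classes)),
    level = c(rep("chemical", length(ch$chemicals)), rep("class", length(ch$classes))),
    stringsAsFactors = FALSE
  )
  rows <- vector("list", nrow(exposures) * length(outcomes))
  k <- 0L
  for (i in seq_len(nrow(exposures))) {
    for (oc in outcomes) {
      tab <- build_contingency(ch, exposures$label[i], oc)
      n <- sum(tab)
      degenerate <- n == 0L
      if (degenerate) {
        test <- NA_character_
        p <- NA_real_
      } else {
        test <- select_test(tab)
        p <- if (test == "chi_square") pearson_chi2(tab)$p_value else fisher_exact_two_sided(tab)
      }
      orci <- wald_odds_ratio(tab)
      k <- k + 1L
      rows[[k]] <- data.frame(
        exposure = exposures$label[i], outcome = oc, level = exposures$level[i],
        a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
        test = test, p = p,
        or = orci$odds_ratio, ci_low = orci$ci_low, ci_high = orci$ci_high,
        degenerate = degenerate, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  res$p_fdr <- bh_adjust(res$p)
  res$sig05 <- !is.na(res$p_fdr) & res$p_fdr < 0.05
  res$sig10 <- !is.na(res$p_fdr) & res$p_fdr < 0.10
  res <- res[, c(
    "exposure", "outcome", "level", "a", "b", "c", "d", "test",
    "p", "p_fdr", "or", "ci_low", "ci_high", "sig05", "sig10", "degenerate"
  )]
  class(res) <- c("assoc_results", "data.frame")
  res
}

#' Write association-screen results as CSV
#'
#' @param results an `assoc_results` data.frame from [screen_associations()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_assoc_results <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a label-to-CURIE map
#'
#' TSV with header `label	curie`.
#'
#' @param path TSV path.
#' @return named character vector, label to CURIE.
#' @export
read_curie_map <- function(path) {
  df <- read_tsv_raw(path, c("label", "curie"))
  stats::setNames(curie(df$curie), df$label)
}

#' Turn significant screen hits into mediating-gene question graphs
#'
#' For each result with FDR-adjusted p below `alpha`, builds the three-node
#' question "pinned chemical - typed gene - pinned disease" asking what
#' genes might mediate the observed exposure-outcome association. Hits
#' whose exposure or outcome label has no CURIE mapping are skipped and
#' reported via the `skipped` attribute (and a message), not an error.
#'
#' @param results an `assoc_results` data.frame.
#' @param curie_map named character vector, label to CURIE (see
#'   [read_curie_map()]).
#' @param alpha significance threshold on `p_fdr` (default 0.05).
#' @return list of [question_graph()] objects, named
#'   `"<exposure>|<outcome>"`, with attribute `skipped` listing unmapped
#'   labels.
#' @export
questions_from_hits <- function(results, curie_map, alpha = 0.05) {
  stopifnot(is.data.frame(results), alpha > 0, alpha < 1)
  hits <- results[!is.na(results$p_fdr) & results$p_fdr < alpha, , drop = FALSE]
  out <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(hits))) {
    exp_label <- hits$exposure[i]
    out_label <- hits$outcome[i]
    unmapped <- c(exp_label, out_label)[!c(exp_label, out_label) %in% names(curie_map)]
    if (length(unmapped) > 0L) {
      skipped <- unique(c(skipped, unmapped))
      next
    }
    qg <- question_graph(
      qnodes = data.frame(
        qid = c("n0", "n1", "n2"),
        curie = c(curie_map[[exp_label]], NA, curie_map[[out_label]]),
        category = c("chemical_substance", "gene", "disease"),
        stringsAsFactors = FALSE
      ),
      qedges = data.frame(
        qeid = c("e0", "e1"), source = c("n0", "n1"), target = c("n1", "n2"),
        predicate = NA_character_, stringsAsFactors = FALSE
      )
    )
    out[[paste(exp_label, out_label, sep = "|")]] <- qg
  }
  if (length(skipped) > 0L) {
    message(sprintf("skipped hit label(s) without a CURIE mapping: %s", paste(skipped, collapse = ", ")))
  }
  attr(out, "skipped") <- skipped
  out
}
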