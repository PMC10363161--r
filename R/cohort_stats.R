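#' Carrier incidence in a cohort
#'
#' Counts samples whose CNV class matches `classes` (default: any
#' non-reference class, i.e. structural-variant carriers). Note the printed
#' duplication incidence of the study design counts `duplication` only — a
#' sample with both a duplication and a deletion is its own class; pass
#' `classes = c("duplication", "both")` for the inclusive definition.
#'
#' @param calls list of `CopyNumberProfile`s, or a character vector of CNV
#'   classes.
#' @param classes classes counted as positive.
#' @return `list(count =, total =, fraction =)`.
#' @export
incidence <- function(calls, classes = c("duplication", "deletion", "both")) {
  cls <- if (is.character(calls)) calls
         else vapply(calls, function(p) p$cnv_class, character(1))
  if (length(cls) == 0) stop("empty cohort")
  n <- sum(cls %in% classes)
  list(count = n, total = length(cls), fraction = n / length(cls))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that of
#' the observed table (the `<=` comparison uses a 1e-7 relative tolerance,
#' since exact equality of floating-point hypergeometric masses is fragile).
#' Degenerate tables with an empty row or column give p = 1.
#'
#' @param a,b,c,d cell counts: rows are carrier/non-carrier, columns the two
#'   cohorts (`a` carriers in cohort 1, `b` carriers in cohort 2, `c`, `d`
#'   the corresponding non-carriers). A 2x2 matrix may be passed as `a`.
#' @param rel_tol relative tolerance for the as-or-more-extreme comparison.
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL,
                                   rel_tol = 1e-7) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("all-zero table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + rel_tol)])
  min(p, 1)
}

#' Per-group carrier frequency table
#'
#' Joins per-sample carrier status with metadata and tabulates counts and
#' fractions per level of a grouping field, in deterministic (sorted) group
#' order. Errors listing the offenders if any sample lacks metadata.
#'
#' @param calls list of `CopyNumberProfile`s, or a named logical vector
#'   (sample id -> carrier status, e.g. from Y-STR screening).
#' @param metadata data.frame with a `sample_id` column plus grouping fields
#'   (haplogroup, ethnic_group, clan, ...).
#' @param group_by name of the metadata column to group by.
#' @param classes when `calls` is a profile list, the CNV classes counted as
#'   carrier (default any non-reference).
#' @return data.frame `group, count, total, fraction`, one row per group.
#' @export
group_frequency <- function(calls, metadata, group_by,
                            classes = c("duplication", "deletion", "both")) {
  if (is.logical(calls)) {
    status <- calls
  } else {
    status <- vapply(calls, function(p) p$cnv_class %in% classes, logical(1))
    names(status) <- vapply(calls, function(p) p$sample_id, character(1))
  }
  if (is.null(names(status))) stop("carrier vector must be named by sample id")
  if (!group_by %in% names(metadata)) {
    stop("metadata lacks grouping column '", group_by, "'")
  }
  miss <- setdiff(names(status), metadata$sample_id)
  if (length(miss)) {
    stop("samples without metadata: ", paste(miss, collapse = ", "))
  }
  grp <- metadata[[group_by]][match(names(status), metadata$sample_id)]
  levels <- sort(unique(grp))
  rows <- lapply(levels, function(g) {
    in_g <- grp == g
    data.frame(group = g, count = sum(status[in_g]), total = sum(in_g),
               fraction = sum(status[in_g]) / sum(in_g))
  })
  do.call(rbind, rows)
}

#' Distinct non-reference copy-number patterns in a cohort
#'
#' Groups samples by their exact per-family copy-number vector, drops the
#' samples identical to the reference, and returns the number of distinct
#' non-reference patterns with their memberships (patterns ordered by first
#' occurrence in sample-id order).
#'
#' @param calls list of `CopyNumberProfile`s or an integer matrix
#'   (samples x families) of called copy numbers.
#' @param ref_cn named reference copy-number vector; taken from the profiles
#'   when omitted.
#' @return `list(n_patterns =, patterns = named list pattern-key -> sample
#'   ids)`.
#' @export
distinct_patterns <- function(calls, ref_cn = NULL) {
  if (is.matrix(calls)) {
    m <- calls
    if (is.null(ref_cn)) stop("ref_cn required with a matrix input")
  } else {
    m <- calls_matrix(calls)
    if (is.null(ref_cn)) {
      ref_cn <- calls[[1]]$calls$ref_cn
      names(ref_cn) <- calls[[1]]$calls$family
    }
  }
  ref_cn <- ref_cn[colnames(m)]
  m <- m[order(rownames(m)), , drop = FALSE]
  keys <- apply(m, 1, function(v) paste(colnames(m), v, sep = "=",
                                        collapse = ","))
  ref_key <- paste(colnames(m), ref_cn, sep = "=", collapse = ",")
  keys <- keys[keys != ref_key]
  patterns <- split(names(keys), factor(keys, levels = unique(keys)))
  list(n_patterns = length(patterns), patterns = patterns)
}

#' Load the external comparison cohort counts
#'
#' Reads a YAML file with carrier counts of an external cohort (the packaged
#' default reconstructs the 1,216-male 1000 Genomes counts from the published
#' percentages; those counts are an editable input, not a measurement).
#'
#' @param path YAML path; default the packaged reconstruction.
#' @return `list(total, any_cnv, duplication_only, deletion_only)`.
#' @export
load_external_counts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "thousand_genomes_counts.yaml",
                        package = "azfcnv")
  }
  yaml::read_yaml(path)
}

#' Compare cohort incidences against an external cohort
#'
#' Builds the 2x2 carrier tables (any CNV, duplication-only, deletion-only)
#' against external counts and computes two-sided Fisher exact p-values.
#'
#' @param profiles list of `CopyNumberProfile`s.
#' @param external counts list as from [load_external_counts()].
#' @return data.frame `comparison, count, total, external_count,
#'   external_total, p_value`.
#' @export
compare_cohorts <- function(profiles, external = load_external_counts()) {
  comparisons <- list(
    any_cnv = c("duplication", "deletion", "both"),
    duplication_only = "duplication",
    deletion_only = "deletion")
  rows <- lapply(names(comparisons), function(nm) {
    inc <- incidence(profiles, comparisons[[nm]])
    ext_n <- external[[nm]]
    p <- fisher_exact_two_sided(inc$count, ext_n,
                                inc$total - inc$count, external$total - ext_n)
    data.frame(comparison = nm, count = inc$count, total = inc$total,
               external_count = ext_n, external_total = external$total,
               p_value = p)
  })
  do.call(rbind, rows)
}
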