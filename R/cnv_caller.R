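#' Normalise a family mean depth by the single-copy mean
#'
#' A family carrying the reference number of copies has a normalised depth of
#' about 1; the value is proportional to the true/reference copy ratio.
#' Errors when the single-copy mean is not positive (e.g. a female or
#' off-target sample, where normalisation is unusable).
#'
#' @param family_mean,single_copy_mean mean depths.
#' @return `family_mean / single_copy_mean`.
#' @export
normalize_depth <- function(family_mean, single_copy_mean) {
  if (!is.finite(single_copy_mean) || single_copy_mean <= 0) {
    stop("single-copy mean depth must be positive (got ", single_copy_mean,
         "); normalisation unusable")
  }
  family_mean / single_copy_mean
}

#' Call an integer copy number by midpoint thresholds
#'
#' A family with reference copy number R and true copy number k has expected
#' normalised depth k/R; the thresholds between consecutive calls sit at the
#' midpoints (k + 0.5)/R. Equivalently the call is the integer k minimising
#' |d - k/R|, i.e. the nearest integer to d*R, with exact midpoints rounding
#' up (toward more copies; ties have probability ~0 on real data and a fixed
#' rule keeps results deterministic). Values below 0.5/R call 0. Calls above
#' `cap_factor * R` are capped with a warning — values that wild usually mean
#' normalisation failed.
#'
#' @param normalized_depth non-negative normalised depth (vectorised).
#' @param ref_cn reference copy number (>= 1).
#' @param cap_factor cap calls at `cap_factor * ref_cn` (default 4).
#' @return integer copy number call(s).
#' @export
call_copy_number <- function(normalized_depth, ref_cn, cap_factor = 4) {
  if (any(normalized_depth < 0)) stop("normalised depth must be >= 0")
  if (ref_cn < 1) stop("ref_cn must be >= 1")
  k <- floor(normalized_depth * ref_cn + 0.5)  # half-up, not banker's
  cap <- cap_factor * ref_cn
  if (any(k > cap)) {
    warning("copy-number call above ", cap, " capped; check normalisation")
    k <- pmin(k, cap)
  }
  as.integer(k)
}

#' Classify a sample's CNV status from its per-family calls
#'
#' `reference` if every called copy number equals its reference; otherwise
#' `duplication` (some family above, none below), `deletion` (some below,
#' none above), or `both`. Families with no call (insufficient unmasked
#' length) are ignored.
#'
#' @param profile a `CopyNumberProfile` (see [call_sample()]) or a data.frame
#'   with `called_cn` and `ref_cn` columns.
#' @return one of `"reference"`, `"duplication"`, `"deletion"`, `"both"`.
#' @export
classify_sample <- function(profile) {
  calls <- if (inherits(profile, "CopyNumberProfile")) profile$calls else profile
  ok <- !is.na(calls$called_cn)
  up <- any(calls$called_cn[ok] > calls$ref_cn[ok])
  dn <- any(calls$called_cn[ok] < calls$ref_cn[ok])
  if (up && dn) "both" else if (up) "duplication" else if (dn) "deletion"
  else "reference"
}

#' Call amplicon copy numbers for one sample
#'
#' For each amplicon family: mean depth over the family's unmasked positions,
#' normalised by the single-copy masked mean, then converted to an integer
#' call by midpoint thresholds. Families with fewer than `min_unmasked_bp`
#' analysable positions are reported as no-call (NA) rather than guessed. A
#' per-family z-score (distance of the observed family mean from the called
#' expectation, in units of the Poisson standard error of the mean) is
#' emitted as a diagnostic only.
#'
#' @param track a [DepthTrack].
#' @param model a [region_model()].
#' @param min_unmasked_bp no-call threshold on analysable family length
#'   (default 1000).
#' @param cap_factor passed to [call_copy_number()].
#' @return a `CopyNumberProfile`: `list(sample_id, single_copy_mean, calls,
#'   cnv_class)` where `calls` has one row per family (`family, n_unmasked,
#'   mean_depth, normalized_depth, called_cn, ref_cn, z`).
#' @export
call_sample <- function(track, model, min_unmasked_bp = 1000, cap_factor = 4) {
  an <- model$analysis
  sc_idx <- an$single_copy_index
  sc_depth <- track_depth_at_index(track, an, sc_idx)
  sc_mean <- if (length(sc_depth)) sum(sc_depth) / length(sc_depth) else 0
  if (sc_mean <= 0) {
    stop("single-copy region has zero mean depth for sample ",
         track$sample_id, "; cannot normalise")
  }
  fams <- names(model$families)
  rows <- lapply(fams, function(f) {
    idx <- an$family_index[[f]]
    n <- length(idx)
    ref_cn <- model$families[[f]]$ref_cn
    if (n < min_unmasked_bp) {
      return(data.frame(family = f, n_unmasked = n, mean_depth = NA_real_,
                        normalized_depth = NA_real_, called_cn = NA_integer_,
                        ref_cn = ref_cn, z = NA_real_))
    }
    d <- track_depth_at_index(track, an, idx)
    m <- sum(d) / n
    nd <- normalize_depth(m, sc_mean)
    cn <- call_copy_number(nd, ref_cn, cap_factor = cap_factor)
    expected <- sc_mean * cn / ref_cn
    se <- sqrt(max(expected, .Machine$double.eps) / n)
    data.frame(family = f, n_unmasked = n, mean_depth = m,
               normalized_depth = nd, called_cn = cn, ref_cn = ref_cn,
               z = (m - expected) / se)
  })
  calls <- do.call(rbind, rows)
  out <- list(sample_id = track$sample_id, single_copy_mean = sc_mean,
              calls = calls)
  out$cnv_class <- classify_sample(calls)
  class(out) <- "CopyNumberProfile"
  out
}

#' @export
print.CopyNumberProfile <- function(x, ...) {
  cat("CopyNumberProfile", x$sample_id, "- class:", x$cnv_class,
      "(single-copy mean", round(x$single_copy_mean, 2), ")\n")
  print(x$calls, row.names = FALSE)
  invisible(x)
}

#' Call a whole cohort of depth tracks
#'
#' @param tracks list of [DepthTrack]s.
#' @param model a [region_model()].
#' @param ... passed to [call_sample()].
#' @return list of `CopyNumberProfile`s, named by sample id.
#' @export
call_cohort <- function(tracks, model, ...) {
  out <- lapply(tracks, call_sample, model = model, ...)
  names(out) <- vapply(out, function(p) p$sample_id, character(1))
  out
}

#' Called copy-number matrix of a cohort
#'
#' @param profiles list of `CopyNumberProfile`s.
#' @return integer matrix, samples x families.
#' @export
calls_matrix <- function(profiles) {
  fams <- profiles[[1]]$calls$family
  m <- t(vapply(profiles, function(p) p$calls$called_cn,
                integer(length(fams))))
  dimnames(m) <- list(vapply(profiles, function(p) p$sample_id, character(1)),
                      fams)
  m
}

#' Write per-sample calls as TSV
#'
#' Long format: one row per sample x family with normalised depth, call,
#' reference copy number and CNV class.
#'
#' @param profiles list of `CopyNumberProfile`s.
#' @param path output TSV path.
#' @return the written data.frame, invisibly.
#' @export
write_calls_tsv <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    cbind(sample_id = p$sample_id, p$calls, cnv_class = p$cnv_class)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
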