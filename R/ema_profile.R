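#' Normalised exponential-moving-average depth profile
#'
#' Computes a per-position EMA of depth over the unmasked positions of the
#' given intervals, in genomic order, then divides by the single-copy mean so
#' the profile reads as a copy-number ratio to the reference. The smoothing
#' uses the span convention: `alpha = 2 / (window_bp + 1)` with
#' `EMA(x_1) = depth(x_1)` and
#' `EMA(x_i) = alpha * depth(x_i) + (1 - alpha) * EMA(x_{i-1})`, evaluated at
#' every retained base (1 bp step). Masked positions neither update nor emit —
#' they appear as gaps in the profile, matching how excluded repeats and DAZ
#' intervals are shown as empty spaces in browser views.
#'
#' @param track a [DepthTrack].
#' @param intervals `GRanges` to profile (e.g. the AZFc family copies).
#' @param masks `GRanges` excluded from the profile.
#' @param window_bp smoothing window (span) in bp, default 10000.
#' @param single_copy_mean positive normaliser (masked mean depth of the
#'   single-copy region for the same sample).
#' @return an `EmaProfile`: `list(sample_id, chrom, pos, normalized_ema,
#'   window_bp)`.
#' @export
ema_track <- function(track, intervals, masks = GenomicRanges::GRanges(),
                      window_bp = 10000, single_copy_mean) {
  if (window_bp < 2) stop("window_bp must be >= 2")
  if (!is.finite(single_copy_mean) || single_copy_mean <= 0) {
    stop("single-copy mean must be positive")
  }
  unmasked <- masked_positions(intervals, masks)
  pos <- gr_positions(unmasked)
  if (length(pos) == 0) stop("no unmasked positions to profile")
  d <- depth_at_positions(track, pos)
  alpha <- 2 / (window_bp + 1)
  ema <- as.numeric(stats::filter(alpha * d, 1 - alpha,
                                  method = "recursive", init = d[1]))
  out <- list(sample_id = track$sample_id, chrom = track$chrom, pos = pos,
              normalized_ema = ema / single_copy_mean,
              window_bp = as.integer(window_bp))
  class(out) <- "EmaProfile"
  out
}

#' @export
print.EmaProfile <- function(x, ...) {
  cat("EmaProfile", x$sample_id, "-", length(x$pos), "positions, window",
      x$window_bp, "bp, normalised EMA range [",
      round(min(x$normalized_ema), 3), ",",
      round(max(x$normalized_ema), 3), "]\n")
  invisible(x)
}

#' Export an EMA profile as bedGraph
#'
#' Downsampled (every `every`-th retained position) for genome-browser
#' viewing; full resolution stays in memory for [confirm_calls()]. Output is
#' 0-based half-open, one 1 bp record per emitted position.
#'
#' @param profile an `EmaProfile`.
#' @param path output path.
#' @param every downsampling stride (default 100).
#' @export
write_ema_bedgraph <- function(profile, path, every = 100) {
  keep <- seq(1, length(profile$pos), by = every)
  df <- data.frame(chrom = profile$chrom,
                   start = profile$pos[keep] - 1L,
                   end = profile$pos[keep],
                   value = signif(profile$normalized_ema[keep], 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(df)
}

#' Check copy-number calls against the EMA profile
#'
#' For each family, the median normalised EMA over the family's profiled
#' positions is compared with the called ratio `called_cn / ref_cn`;
#' agreement means the absolute difference is below `tol_factor / ref_cn`
#' (default a quarter of the inter-call spacing). Families with no profiled
#' positions are flagged (`agree = NA`), not failed.
#'
#' @param profile an `EmaProfile`.
#' @param calls a `CopyNumberProfile` for the same sample.
#' @param model a [region_model()].
#' @param tol_factor tolerance numerator (default 0.25).
#' @return data.frame `family, median_ema, expected_ratio, agree`.
#' @export
confirm_calls <- function(profile, calls, model, tol_factor = 0.25) {
  if (!identical(profile$sample_id, calls$sample_id)) {
    stop("profile and calls come from different samples")
  }
  fams <- names(model$families)
  rows <- lapply(fams, function(f) {
    inside <- positions_in_ranges(profile$pos,
                                  model$analysis$family_unmasked[[f]])
    ref_cn <- model$families[[f]]$ref_cn
    called <- calls$calls$called_cn[calls$calls$family == f]
    expected <- called / ref_cn
    if (!any(inside) || is.na(called)) {
      return(data.frame(family = f, median_ema = NA_real_,
                        expected_ratio = expected, agree = NA))
    }
    med <- stats::median(profile$normalized_ema[inside])
    data.frame(family = f, median_ema = med, expected_ratio = expected,
               agree = abs(med - expected) < tol_factor / ref_cn)
  })
  do.call(rbind, rows)
}
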