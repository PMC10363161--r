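#' Per-base depth track for one sample
#'
#' A `DepthTrack` holds non-negative integer depth at every analysed position
#' of a region model (the unmasked positions of all family copies plus the
#' single-copy control set), in genomic order. Positions absent from the
#' source file are depth 0 — `samtools depth` omits zero-coverage positions
#' by default, so absence means zero, not missing data.
#'
#' @name DepthTrack
NULL

new_depth_track <- function(sample_id, chrom, pos, depth, fingerprint = NULL) {
  stopifnot(length(pos) == length(depth))
  if (any(depth < 0)) stop("negative depth")
  out <- list(sample_id = sample_id, chrom = chrom,
              pos = as.integer(pos), depth = as.integer(depth),
              fingerprint = fingerprint)
  class(out) <- "DepthTrack"
  out
}

#' @export
print.DepthTrack <- function(x, ...) {
  cat("DepthTrack", x$sample_id, "on", x$chrom, "-",
      length(x$pos), "positions, mean depth",
      round(mean(x$depth), 2), "\n")
  invisible(x)
}

#' Read a samtools-depth style TSV into a DepthTrack
#'
#' Expects three tab- or space-separated columns: chromosome, 1-based
#' position, integer depth (optionally gzip-compressed). Positions are
#' restricted to the model's analysed regions; analysed positions absent from
#' the file get depth 0. Lines on chromosomes other than the model's are
#' skipped with a warning; malformed lines raise an error naming the line
#' number.
#'
#' @param path TSV(.gz) path.
#' @param model a [region_model()].
#' @param sample_id sample label for the track.
#' @return a [DepthTrack].
#' @export
read_depth_tsv <- function(path, model, sample_id) {
  if (!file.exists(path)) stop("depth file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  raw <- tryCatch(
    scan(con, what = list(chrom = character(), pos = integer(),
                          depth = integer()),
         sep = "", quiet = TRUE, fill = FALSE),
    error = function(e) NULL)
  if (is.null(raw)) {
    # locate the offending line for a useful error
    lines <- readLines(path)
    for (i in seq_along(lines)) {
      f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      bad <- length(f) < 3 ||
        is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3])))
      if (bad) stop("malformed depth line ", i, " in ", basename(path),
                    ": '", lines[i], "'")
    }
    stop("failed to parse depth file ", path)
  }
  keep <- raw$chrom == model$chrom
  if (any(!keep)) {
    warning("skipping ", sum(!keep), " positions on unknown chromosome(s): ",
            paste(unique(raw$chrom[!keep]), collapse = ", "))
  }
  universe <- model$analysis$universe
  depth <- integer(length(universe))
  idx <- match(raw$pos[keep], universe)
  ok <- !is.na(idx)
  depth[idx[ok]] <- raw$depth[keep][ok]
  new_depth_track(sample_id, model$chrom, universe, depth,
                  fingerprint = model$analysis$fingerprint)
}

#' Extract a DepthTrack from an indexed BAM
#'
#' Per-position depth over the model's analysed regions via
#' [Rsamtools::pileup()], with optional mapping- and base-quality filters.
#' Defaults apply no filtering, matching plain `samtools depth`.
#'
#' @param bam_path coordinate-sorted, indexed BAM aligned to the model's
#'   build.
#' @param model a [region_model()].
#' @param sample_id sample label.
#' @param min_mapq,min_baseq minimum mapping / base quality (default 0).
#' @return a [DepthTrack].
#' @export
extract_depth_bam <- function(bam_path, model, sample_id,
                              min_mapq = 0, min_baseq = 0) {
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  bf <- Rsamtools::BamFile(bam_path)
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  if (!model$chrom %in% names(hdr)) {
    stop("contig ", model$chrom, " absent from BAM header")
  }
  regions <- GenomicRanges::reduce(c(
    GenomicRanges::reduce(do.call(c, unname(lapply(model$families,
                                                   function(f) f$copies)))),
    GenomicRanges::reduce(model$single_copy)))
  sp <- Rsamtools::ScanBamParam(which = regions)
  pp <- Rsamtools::PileupParam(max_depth = 100000L,
                               min_mapq = as.integer(min_mapq),
                               min_base_quality = as.integer(min_baseq),
                               min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = FALSE,
                               include_deletions = FALSE)
  pu <- Rsamtools::pileup(bf, scanBamParam = sp, pileupParam = pp)
  universe <- model$analysis$universe
  depth <- integer(length(universe))
  if (nrow(pu) > 0) {
    agg <- tapply(pu$count, pu$pos, sum)
    idx <- match(as.integer(names(agg)), universe)
    ok <- !is.na(idx)
    depth[idx[ok]] <- as.integer(agg[ok])
  }
  new_depth_track(sample_id, model$chrom, universe, depth,
                  fingerprint = model$analysis$fingerprint)
}

#' Masked mean depth over a set of intervals
#'
#' Arithmetic mean of depth over the unmasked positions of `intervals`;
#' positions absent from the track count as depth 0. Errors if masking leaves
#' no positions (a degenerate region).
#'
#' @param track a [DepthTrack].
#' @param intervals,masks `GRanges`.
#' @return `list(mean_depth =, n_positions =)`.
#' @export
masked_mean_depth <- function(track, intervals, masks = GenomicRanges::GRanges()) {
  unmasked <- masked_positions(intervals, masks)
  n <- gr_width_total(unmasked)
  if (n == 0) stop("no unmasked positions in region")
  pos <- gr_positions(unmasked)
  d <- depth_at_positions(track, pos)
  list(mean_depth = sum(d) / n, n_positions = as.integer(n))
}

#' Write a per-region depth summary
#'
#' One row per amplicon family plus the single-copy region:
#' `sample_id, region_id, n_positions, mean_depth`.
#'
#' @param track a [DepthTrack].
#' @param model a [region_model()].
#' @param path output TSV path (optional).
#' @return the summary data.frame, invisibly if written.
#' @export
depth_summary <- function(track, model, path = NULL) {
  an <- model$analysis
  fams <- names(model$families)
  rows <- lapply(fams, function(f) {
    idx <- an$family_index[[f]]
    data.frame(sample_id = track$sample_id, region_id = f,
               n_positions = length(idx),
               mean_depth = mean(track_depth_at_index(track, an, idx)))
  })
  sc <- an$single_copy_index
  rows[[length(rows) + 1L]] <- data.frame(
    sample_id = track$sample_id, region_id = "single_copy",
    n_positions = length(sc),
    mean_depth = mean(track_depth_at_index(track, an, sc)))
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

# Fast depth lookup: if the track is aligned to the model universe, index
# directly; otherwise fall back to position matching.
track_depth_at_index <- function(track, analysis, idx) {
  if (identical(track$fingerprint, analysis$fingerprint)) {
    track$depth[idx]
  } else {
    depth_at_positions(track, analysis$universe[idx])
  }
}
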