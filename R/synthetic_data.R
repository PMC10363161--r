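#' Coverage simulation settings
#'
#' The simulator emulates the statistical structure the calling pipeline
#' assumes: at haploid coverage c, a family with true copy number C and
#' reference copy number R receives per-position depth with mean c * C / R
#' (reads from every physical copy pile onto the reference copies), and the
#' single-copy region has mean c. Depth is drawn independently per position,
#' Poisson by default or negative-binomial with dispersion `size` for
#' overdispersed data. The default coverage of 30 matches the >30x
#' whole-genome depth of the study design.
#'
#' @param haploid_coverage mean haploid coverage (default 30).
#' @param noise `"poisson"` or `"negative_binomial"`.
#' @param dispersion negative-binomial size parameter (default 1000,
#'   near-Poisson).
#' @param seed integer seed; per-sample seeds are derived deterministically
#'   from it and the sample id.
#' @param masked_behavior `"omit"` (masked positions absent from the track,
#'   the samtools-depth convention) or `"zero"` (present with depth 0).
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(haploid_coverage = 30,
                              noise = c("poisson", "negative_binomial"),
                              dispersion = 1000, seed = 1,
                              masked_behavior = c("omit", "zero")) {
  noise <- match.arg(noise)
  masked_behavior <- match.arg(masked_behavior)
  if (haploid_coverage <= 0) stop("haploid_coverage must be positive")
  if (noise == "negative_binomial" && dispersion <= 0) {
    stop("dispersion must be positive")
  }
  out <- list(haploid_coverage = haploid_coverage, noise = noise,
              dispersion = dispersion, seed = as.integer(seed),
              masked_behavior = masked_behavior)
  class(out) <- "SimulationConfig"
  out
}

draw_depth <- function(n, lambda, config) {
  switch(config$noise,
         poisson = stats::rpois(n, lambda),
         negative_binomial = stats::rnbinom(n, mu = lambda,
                                            size = config$dispersion))
}

#' Simulate a per-base depth track from a copy-number truth vector
#'
#' Every unmasked position of family f gets depth with mean
#' `haploid_coverage * truth[f] / ref_cn[f]`; single-copy positions get mean
#' `haploid_coverage`. The draw is reproducible given `config$seed`.
#'
#' @param truth named vector, one true copy number per model family.
#' @param model a [region_model()].
#' @param config a [simulation_config()].
#' @param sample_id label for the track.
#' @return a [DepthTrack].
#' @export
simulate_depth <- function(truth, model, config = simulation_config(),
                           sample_id = "sim") {
  fams <- names(model$families)
  unknown <- setdiff(names(truth), fams)
  if (length(unknown)) {
    stop("truth names unknown families: ", paste(unknown, collapse = ", "))
  }
  if (!all(fams %in% names(truth))) {
    stop("truth missing families: ",
         paste(setdiff(fams, names(truth)), collapse = ", "))
  }
  an <- model$analysis
  lambda <- numeric(length(an$universe))
  lambda[an$single_copy_index] <- config$haploid_coverage
  for (f in fams) {
    ratio <- truth[[f]] / model$families[[f]]$ref_cn
    lambda[an$family_index[[f]]] <- config$haploid_coverage * ratio
  }
  set.seed(config$seed)
  depth <- draw_depth(length(lambda), lambda, config)
  if (config$masked_behavior == "zero") {
    all_copies <- do.call(c, unname(lapply(model$families,
                                           function(f) f$copies)))
    masked <- GenomicRanges::intersect(GenomicRanges::reduce(all_copies),
                                       model$masks)
    mpos <- gr_positions(masked)
    pos <- c(an$universe, mpos)
    depth <- c(depth, integer(length(mpos)))
    o <- order(pos)
    return(new_depth_track(sample_id, model$chrom, pos[o], depth[o]))
  }
  new_depth_track(sample_id, model$chrom, an$universe, depth,
                  fingerprint = an$fingerprint)
}

#' Load the packaged cohort truth fixture
#'
#' The 87-sample truth cohort: 66 reference-structure samples plus 21
#' carriers whose copy-number vectors were reconstructed by applying the
#' described NAHR event sequences to the reference structure (the fixture is
#' a synthetic reconstruction; see the packaged TSV header and the methods
#' vignette). Columns: sample metadata, one column per family, and the event
#' annotation.
#'
#' @param path TSV path; default the packaged fixture.
#' @return `list(truth = integer matrix samples x families, metadata =
#'   data.frame(sample_id, haplogroup, ethnic_group, events))`.
#' @export
load_cohort_truth <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_truth_synthetic.tsv",
                        package = "azfcnv")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("sample_id", "haplogroup", "ethnic_group", "events")
  fam_cols <- setdiff(names(df), meta_cols)
  truth <- as.matrix(df[, fam_cols])
  storage.mode(truth) <- "integer"
  rownames(truth) <- df$sample_id
  list(truth = truth, metadata = df[, intersect(meta_cols, names(df))])
}

#' Simulate depth files for a whole cohort
#'
#' One samtools-depth style TSV (gzipped) per sample, plus a truth table.
#' Per-sample seeds derive deterministically from `(config$seed, sample_id)`,
#' so any subset of the cohort reproduces identically. Zero-depth positions
#' are omitted from the files, as `samtools depth` does.
#'
#' @param truth integer matrix samples x families (e.g.
#'   `load_cohort_truth()$truth`).
#' @param model a [region_model()].
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @return manifest data.frame `sample_id, depth_file` plus the truth path as
#'   attribute `truth_file`.
#' @export
simulate_cohort <- function(truth, model, config = simulation_config(),
                            outdir) {
  ids <- rownames(truth)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("truth matrix needs unique sample ids as rownames")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(ids))
  for (i in seq_along(ids)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, ids[i])
    tr <- simulate_depth(truth[ids[i], ], model, cfg_i, sample_id = ids[i])
    f <- file.path(outdir, paste0(ids[i], ".depth.tsv.gz"))
    nz <- tr$depth > 0L
    con <- gzfile(f, "wt")
    utils::write.table(data.frame(tr$chrom, tr$pos[nz], tr$depth[nz]),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
    files[i] <- f
  }
  truth_file <- file.path(outdir, "truth.tsv")
  utils::write.table(data.frame(sample_id = ids, truth,
                                check.names = FALSE),
                     truth_file, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- data.frame(sample_id = ids, depth_file = files)
  attr(out, "truth_file") <- truth_file
  out
}

#' Simulate, call, and score a truth cohort
#'
#' The end-to-end harness: simulates each sample's depth in memory, runs
#' [call_sample()], and reports per-family and per-sample recovery of the
#' truth together with the recovered CNV classes, carrier incidence and
#' distinct non-reference patterns.
#'
#' @param truth integer matrix samples x families.
#' @param model a [region_model()].
#' @param config a [simulation_config()].
#' @return list with `called` (matrix), `truth`, `classes` (data.frame with
#'   true and called class per sample), `per_family_accuracy`,
#'   `per_sample_exact`, `carrier_incidence`, `class_counts`, `n_patterns`.
#' @export
recovery_experiment <- function(truth, model, config = simulation_config()) {
  ids <- rownames(truth)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("truth matrix needs unique sample ids as rownames")
  }
  fams <- names(model$families)
  truth <- truth[, fams, drop = FALSE]
  profiles <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, ids[i])
    tr <- simulate_depth(truth[ids[i], ], model, cfg_i, sample_id = ids[i])
    profiles[[i]] <- call_sample(tr, model)
  }
  names(profiles) <- ids
  called <- calls_matrix(profiles)[ids, fams, drop = FALSE]

  ref_cn <- vapply(model$families, function(f) f$ref_cn, integer(1))
  true_class <- apply(truth, 1, function(v) {
    up <- any(v > ref_cn); dn <- any(v < ref_cn)
    if (up && dn) "both" else if (up) "duplication" else if (dn) "deletion"
    else "reference"
  })
  called_class <- vapply(profiles, function(p) p$cnv_class, character(1))

  list(
    called = called,
    truth = truth,
    profiles = profiles,
    classes = data.frame(sample_id = ids, true_class = true_class,
                         called_class = called_class),
    per_family_accuracy = colMeans(called == truth),
    per_sample_exact = mean(rowSums(called != truth) == 0),
    carrier_incidence = incidence(called_class),
    class_counts = table(factor(called_class,
                                levels = c("reference", "duplication",
                                           "deletion", "both"))),
    n_patterns = distinct_patterns(called, ref_cn = ref_cn)$n_patterns)
}
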