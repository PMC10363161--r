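#' Coordinate model of the Y ampliconic region
#'
#' A `RegionModel` bundles everything the depth pipeline needs to know about
#' the chromosome: the amplicon families (colour-coded groups of near-identical
#' copies with a reference copy number), the mask track (interspersed and
#' simple repeats, plus genes excluded from depth calling such as DAZ), the
#' single-copy control region used for normalisation, the gene map, the
#' ordered oriented reference amplicon structure, and the named NAHR event
#' catalog.
#'
#' @param families named list; each element has `ref_cn` (positive integer)
#'   and `copies` (a [GenomicRanges::GRanges] with one range per reference
#'   copy).
#' @param single_copy `GRanges` of single-copy control intervals.
#' @param structure an [amplicon_structure()] giving the ordered oriented
#'   reference units; every unit's family must be declared in `families` and
#'   per-family unit counts must equal `ref_cn`.
#' @param masks `GRanges` of positions excluded from depth calling (merged on
#'   construction; overlapping RepeatMasker-style entries are fine).
#' @param genes named list; each element has `intervals` (`GRanges`) and
#'   `ref_copies`.
#' @param unit_genes named list mapping unit id to a named integer vector of
#'   gene copies carried by that unit.
#' @param unit_intervals `GRanges` named by unit id (reference coordinates of
#'   each structure unit), used for span bookkeeping; optional.
#' @param events named list of catalog entries
#'   (`list(kind =, a =, b =, aliases =)`) mapping conventional event labels
#'   (e.g. "gr/gr duplication") to anchor unit ids.
#'
#' @return an object of class `RegionModel`.
#' @export
region_model <- function(families, single_copy, structure,
                         masks = GenomicRanges::GRanges(),
                         genes = list(), unit_genes = list(),
                         unit_intervals = NULL, events = list()) {
  stopifnot(is.list(families), length(families) > 0)
  fam_ids <- names(families)
  if (is.null(fam_ids) || any(fam_ids == "")) {
    stop("families must be a named list")
  }
  for (id in fam_ids) {
    f <- families[[id]]
    if (is.null(f$ref_cn) || f$ref_cn < 1) {
      stop("family '", id, "' needs a positive ref_cn")
    }
    if (length(f$copies) != f$ref_cn) {
      stop("family '", id, "' declares ref_cn = ", f$ref_cn,
           " but lists ", length(f$copies), " copy intervals")
    }
    if (length(GenomicRanges::reduce(f$copies)) != length(f$copies)) {
      stop("family '", id, "' has overlapping copy intervals")
    }
    families[[id]]$family_id <- id
  }

  all_copies <- do.call(c, unname(lapply(families, function(f) f$copies)))
  chroms <- unique(as.character(GenomicRanges::seqnames(c(all_copies, single_copy))))
  if (length(chroms) != 1) {
    stop("all model intervals must sit on a single chromosome, got: ",
         paste(chroms, collapse = ", "))
  }
  if (gr_width_total(single_copy) <= 0) {
    stop("single-copy region must have positive total length")
  }
  if (length(GenomicRanges::intersect(
        GenomicRanges::reduce(single_copy),
        GenomicRanges::reduce(all_copies))) > 0) {
    stop("single-copy region intersects an amplicon family copy")
  }

  masks <- GenomicRanges::reduce(masks)

  structure <- as_amplicon_structure(structure)
  if (!all(structure$family_id %in% fam_ids)) {
    bad <- setdiff(unique(structure$family_id), fam_ids)
    stop("structure uses undeclared families: ", paste(bad, collapse = ", "))
  }
  cn <- copy_number_vector(structure, families = fam_ids)
  declared <- vapply(families, function(f) as.integer(f$ref_cn), integer(1))
  if (!identical(unname(cn[fam_ids]), unname(declared))) {
    stop("reference structure unit counts disagree with declared ref_cn for: ",
         paste(fam_ids[cn[fam_ids] != declared], collapse = ", "))
  }

  # every gene interval must lie inside exactly one family copy
  for (g in names(genes)) {
    gi <- genes[[g]]$intervals
    n_host <- GenomicRanges::countOverlaps(gi, all_copies, type = "within")
    if (any(n_host != 1)) {
      stop("gene '", g, "' has an interval not contained in exactly one ",
           "family copy")
    }
  }

  model <- list(families = families, masks = masks, single_copy = single_copy,
                genes = genes, structure = structure, unit_genes = unit_genes,
                unit_intervals = unit_intervals, events = events,
                chrom = chroms)
  class(model) <- "RegionModel"

  # declared gene dosage must be reproduced by the reference structure
  for (g in names(genes)) {
    got <- gene_copy_count(model$structure, model, g)
    if (got != genes[[g]]$ref_copies) {
      stop("gene '", g, "': structure carries ", got,
           " copies but ref_copies = ", genes[[g]]$ref_copies)
    }
  }

  model$analysis <- build_analysis_cache(model)
  model
}

# Precomputed position universe: sorted unmasked positions of every family
# union and of the single-copy set, plus index slices into the universe.
build_analysis_cache <- function(model) {
  fam_unmasked <- lapply(model$families, function(f) {
    masked_positions(f$copies, model$masks)
  })
  sc_unmasked <- masked_positions(model$single_copy, model$masks)
  fam_pos <- lapply(fam_unmasked, gr_positions)
  sc_pos <- gr_positions(sc_unmasked)
  universe <- sort(c(unlist(fam_pos, use.names = FALSE), sc_pos))
  if (anyDuplicated(universe)) {
    stop("internal error: overlapping analysis regions")
  }
  fam_index <- lapply(fam_pos, function(p) match(p, universe))
  list(
    family_unmasked = fam_unmasked,
    single_copy_unmasked = sc_unmasked,
    universe = universe,
    family_index = fam_index,
    single_copy_index = match(sc_pos, universe),
    fingerprint = paste0(length(universe), ":",
                         if (length(universe)) universe[1] else 0, ":",
                         if (length(universe)) universe[length(universe)] else 0)
  )
}

#' Subtract mask intervals from analysis intervals
#'
#' Computes the set difference `intervals \ masks` as disjoint sorted ranges.
#' Overlapping masks are merged first, so RepeatMasker-style tracks with
#' nested or duplicated entries behave correctly. Masking is idempotent and
#' conserves length: `width(result) + width(intervals ∩ masks) =
#' width(intervals)`.
#'
#' @param intervals,masks `GRanges` on the same chromosome.
#' @return a disjoint sorted `GRanges` (possibly empty).
#' @export
masked_positions <- function(intervals, masks) {
  intervals <- GenomicRanges::reduce(intervals)
  if (length(masks) == 0) return(sort(intervals))
  out <- GenomicRanges::setdiff(intervals, GenomicRanges::reduce(masks))
  sort(out)
}

#' Gene dosage carried by an amplicon structure
#'
#' Sums, over the units of `structure`, the gene copies each unit carries
#' according to the model's per-unit gene content. Because rearranged
#' structures reuse reference unit ids, dosage after any sequence of NAHR
#' events is obtained by counting units: e.g. two successive b2/b4
#' duplications quadruple DAZ, BPY2 and CDY1.
#'
#' @param structure an [amplicon_structure()].
#' @param model a [region_model()].
#' @param gene gene name present in the model's gene map.
#' @return integer copy count.
#' @export
gene_copy_count <- function(structure, model, gene) {
  known <- union(names(model$genes),
                 unique(unlist(lapply(model$unit_genes, names))))
  if (!gene %in% known) stop("unknown gene: ", gene)
  structure <- as_amplicon_structure(structure)
  total <- 0L
  for (u in structure$unit_id) {
    gc <- model$unit_genes[[u]]
    if (!is.null(gc) && gene %in% names(gc)) total <- total + gc[[gene]]
  }
  as.integer(total)
}

read_bed_granges <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (any(GenomicRanges::width(gr) < 1)) {
    stop("BED file ", basename(path), " contains an interval with start >= end")
  }
  gr
}

#' Load a region model from a YAML config
#'
#' The config names the BED files (amplicon copies with unit ids, masks,
#' single-copy region, genes), declares the families and their reference copy
#' numbers, the ordered oriented reference structure with per-unit gene
#' content, genes to exclude from depth calling (DAZ by default fixture), and
#' the named NAHR event catalog. Paths are resolved relative to the config
#' file. BED input is 0-based half-open and converted to 1-based closed
#' `GRanges` on read.
#'
#' @param config_path path to the YAML model config.
#' @return a validated [region_model()].
#' @export
load_region_model <- function(config_path) {
  if (!file.exists(config_path)) stop("model config not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  dir <- dirname(normalizePath(config_path))
  p <- function(f) file.path(dir, f)

  amplicons <- read_bed_granges(p(cfg$amplicons_bed))
  masks <- if (!is.null(cfg$masks_bed)) read_bed_granges(p(cfg$masks_bed))
           else GenomicRanges::GRanges()
  single_copy <- read_bed_granges(p(cfg$single_copy_bed))
  genes_gr <- if (!is.null(cfg$genes_bed)) read_bed_granges(p(cfg$genes_bed))
              else GenomicRanges::GRanges()

  units <- vapply(cfg$structure, function(u) u$unit, character(1))
  fams <- vapply(cfg$structure, function(u) u$family, character(1))
  oris <- vapply(cfg$structure, function(u) u$orientation, character(1))
  if (anyDuplicated(units)) stop("duplicate unit ids in reference structure")

  amp_names <- S4Vectors::mcols(amplicons)$name
  if (is.null(amp_names)) stop("amplicon BED needs unit names in column 4")
  missing_units <- setdiff(units, amp_names)
  if (length(missing_units)) {
    stop("structure units without BED intervals: ",
         paste(missing_units, collapse = ", "))
  }
  unit_intervals <- amplicons[match(units, amp_names)]
  names(unit_intervals) <- units

  families <- list()
  for (id in names(cfg$families)) {
    fam_units <- units[fams == id]
    families[[id]] <- list(
      ref_cn = as.integer(cfg$families[[id]]$ref_cn),
      copies = unname(unit_intervals[fam_units]),
      color = cfg$families[[id]]$color %||% id)
  }

  unit_genes <- list()
  for (u in cfg$structure) {
    if (!is.null(u$genes)) {
      unit_genes[[u$unit]] <- vapply(u$genes, as.integer, integer(1))
    }
  }

  genes <- list()
  if (length(genes_gr)) {
    gnames <- S4Vectors::mcols(genes_gr)$name
    for (g in names(cfg$genes)) {
      gi <- genes_gr[gnames == g]
      if (length(gi) == 0) stop("gene '", g, "' declared but absent from BED")
      genes[[g]] <- list(intervals = gi,
                         ref_copies = as.integer(cfg$genes[[g]]$ref_copies))
    }
  }

  # depth-excluded genes join the mask track (the DAZ exclusion)
  excl <- cfg$exclude_genes_from_depth %||% character(0)
  for (g in excl) {
    if (is.null(genes[[g]])) stop("exclude_genes_from_depth names unknown gene: ", g)
    masks <- c(masks, genes[[g]]$intervals)
  }

  events <- lapply(cfg$events %||% list(), function(e) {
    list(kind = e$kind, a = e$a, b = e$b %||% NA_character_,
         aliases = unlist(e$aliases) %||% character(0))
  })

  region_model(
    families = families, single_copy = single_copy,
    structure = amplicon_structure(units, fams, oris),
    masks = masks, genes = genes, unit_genes = unit_genes,
    unit_intervals = unit_intervals, events = events)
}

#' Packaged default AZFb/c model
#'
#' Loads (and memoises) the model shipped with the package: the six AZFc
#' amplicon families (blue, teal, green, red, grey, yellow), the P4-P8
#' palindrome-arm families, a ~900 kb single-copy control set, repeat masks,
#' the DAZ/BPY2/CDY1/HSFY gene map and the named NAHR event catalog. The
#' coordinates are a compact synthetic stand-in (see the packaged YAML for
#' details); family counts, unit order, orientations and gene content follow
#' the published AZFc architecture.
#'
#' @return a [region_model()].
#' @export
azf_model <- function() {
  if (is.null(.azfcnv_cache$default_model)) {
    cfg <- system.file("extdata", "azf_model.yaml", package = "azfcnv")
    .azfcnv_cache$default_model <- load_region_model(cfg)
  }
  .azfcnv_cache$default_model
}

#' @export
print.RegionModel <- function(x, ...) {
  cat("RegionModel on", x$chrom, "\n")
  cat("  families:",
      paste(sprintf("%s(x%d)", names(x$families),
                    vapply(x$families, function(f) f$ref_cn, integer(1))),
            collapse = " "), "\n")
  cat("  single-copy:", gr_width_total(x$single_copy), "bp in",
      length(x$single_copy), "intervals\n")
  cat("  masks:", gr_width_total(x$masks), "bp;",
      "structure:", nrow(x$structure), "units;",
      "genes:", paste(names(x$genes), collapse = ", "), "\n")
  invisible(x)
}
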