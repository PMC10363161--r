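# In-code fixtures shared across test files.

.helper_cache <- new.env(parent = emptyenv())

gr <- function(start, end, chrom = "chrY") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

make_track <- function(pos, depth, sample_id = "t", chrom = "chrY") {
  azfcnv:::new_depth_track(sample_id, chrom, pos, depth)
}

# Minimal two-family model for IO / caller unit tests.
tiny_model <- function() {
  if (!is.null(.helper_cache$tiny)) return(.helper_cache$tiny)
  m <- region_model(
    families = list(
      A = list(ref_cn = 1L, copies = gr(1001, 1100)),
      B = list(ref_cn = 2L, copies = gr(c(1201, 1401), c(1300, 1500)))),
    single_copy = gr(2001, 2400),
    structure = amplicon_structure(c("A1", "B1", "B2"), c("A", "B", "B"),
                                   c("+", "+", "+")),
    masks = gr(1051, 1100))
  .helper_cache$tiny <- m
  m
}

# Reduced-scale AZFc model for simulation-heavy property tests: the same
# reference structure, orientations and event catalog as the packaged model,
# but compact intervals (>= 50 kb unmasked per family) and an 80 kb
# single-copy set.
sim_model <- function() {
  if (!is.null(.helper_cache$sim)) return(.helper_cache$sim)
  full <- azf_model()
  azfc <- full$structure[full$structure$family_id %in%
                           c("b", "t", "g", "r", "Gr", "y"), ]
  fam_cn <- c(b = 4L, t = 2L, g = 3L, r = 4L, Gr = 1L, y = 2L)
  width <- c(b = 13000L, t = 26000L, g = 17400L, r = 13000L,
             Gr = 52000L, y = 26000L)
  starts <- integer(nrow(azfc))
  pos <- 1000000L
  for (i in seq_len(nrow(azfc))) {
    starts[i] <- pos
    pos <- pos + width[[azfc$family_id[i]]] + 1000L
  }
  unit_iv <- gr(starts, starts + width[azfc$family_id] - 1L)
  names(unit_iv) <- azfc$unit_id
  fams <- lapply(names(fam_cn), function(f) {
    list(ref_cn = fam_cn[[f]],
         copies = unname(unit_iv[azfc$unit_id[azfc$family_id == f]]))
  })
  names(fams) <- names(fam_cn)
  m <- region_model(
    families = fams,
    single_copy = gr(2000000, 2079999),
    structure = amplicon_structure(azfc$unit_id, azfc$family_id,
                                   azfc$orientation),
    unit_genes = full$unit_genes[intersect(names(full$unit_genes),
                                           azfc$unit_id)],
    unit_intervals = unit_iv,
    events = full$events[!vapply(full$events,
                                 function(e) identical(e$a, "P4a"),
                                 logical(1))])
  .helper_cache$sim <- m
  m
}

# 8-unit toy structure for search-oracle tests: three families with mixed
# orientations plus a singleton.
toy_model <- function() {
  if (!is.null(.helper_cache$toy)) return(.helper_cache$toy)
  units <- c("a1", "c1", "a2", "d1", "d2", "c2", "e1", "a3")
  fams  <- c("a",  "c",  "a",  "d",  "d",  "c",  "e",  "a")
  oris  <- c("+",  "+",  "+",  "+",  "-",  "+",  "+",  "-")
  starts <- seq(1000L, by = 2000L, length.out = 8L)
  unit_iv <- gr(starts, starts + 999L)
  names(unit_iv) <- units
  fams_list <- lapply(unique(fams), function(f) {
    list(ref_cn = sum(fams == f),
         copies = unname(unit_iv[units[fams == f]]))
  })
  names(fams_list) <- unique(fams)
  m <- region_model(
    families = fams_list,
    single_copy = gr(50000, 59999),
    structure = amplicon_structure(units, fams, oris),
    unit_intervals = unit_iv)
  .helper_cache$toy <- m
  m
}

ref_vector <- function(model) {
  vapply(model$families, function(f) f$ref_cn, integer(1))
}
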