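# Internal helpers shared across modules.

.azfcnv_cache <- new.env(parent = emptyenv())

#' @importFrom GenomicRanges GRanges start end reduce
#' @importFrom IRanges IRanges
NULL

# All 1-based positions covered by a GRanges, sorted, assuming a single
# chromosome (validated at model load).
gr_positions <- function(gr) {
  if (length(gr) == 0L) return(integer(0))
  s <- GenomicRanges::start(gr)
  e <- GenomicRanges::end(gr)
  sort(unlist(lapply(seq_along(s), function(i) seq.int(s[i], e[i])),
              use.names = FALSE))
}

gr_width_total <- function(gr) sum(GenomicRanges::width(gr))

# Deterministic 31-bit seed derived from a base seed and a sample label, so
# per-sample simulations are reproducible and independent of cohort order.
derive_seed <- function(seed, sample_id) {
  h <- as.double(seed %% 1000000007L)
  for (ch in utf8ToInt(as.character(sample_id))) {
    h <- (h * 131 + ch) %% 2147483629
  }
  as.integer(h)
}

# Membership of sorted integer positions in a set of disjoint sorted ranges.
positions_in_ranges <- function(pos, gr) {
  if (length(gr) == 0L || length(pos) == 0L) return(logical(length(pos)))
  gr <- GenomicRanges::reduce(gr)
  s <- GenomicRanges::start(gr)
  e <- GenomicRanges::end(gr)
  idx <- findInterval(pos, s)
  idx > 0L & pos <= e[pmax(idx, 1L)]
}

# Depth lookup in a track at arbitrary sorted positions; absent positions
# count as zero coverage (the samtools-depth convention).
depth_at_positions <- function(track, pos) {
  idx <- findInterval(pos, track$pos)
  hit <- idx > 0L
  hit[hit] <- track$pos[idx[hit]] == pos[hit]
  out <- numeric(length(pos))
  out[hit] <- track$depth[idx[hit]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
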