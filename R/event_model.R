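#' Ordered oriented amplicon structure
#'
#' The substrate of the NAHR algebra: an ordered (proximal to distal) list of
#' amplicon units, each belonging to a family and carrying an orientation.
#' Rearranged structures reuse the reference unit ids, so family copy numbers
#' and gene dosage are obtained by counting units.
#'
#' @param unit_id character vector of unit labels (e.g. `b2`, `g1`, `P4a`).
#' @param family_id character vector of family labels, same length.
#' @param orientation character vector of `"+"`/`"-"`, same length.
#' @return a data.frame of class `AmpliconStructure`.
#' @export
amplicon_structure <- function(unit_id, family_id, orientation) {
  stopifnot(length(unit_id) == length(family_id),
            length(unit_id) == length(orientation))
  if (!all(orientation %in% c("+", "-"))) {
    stop("orientation must be '+' or '-'")
  }
  out <- data.frame(unit_id = as.character(unit_id),
                    family_id = as.character(family_id),
                    orientation = as.character(orientation),
                    stringsAsFactors = FALSE)
  class(out) <- c("AmpliconStructure", "data.frame")
  out
}

as_amplicon_structure <- function(x) {
  if (inherits(x, "AmpliconStructure")) return(x)
  if (is.data.frame(x) &&
      all(c("unit_id", "family_id", "orientation") %in% names(x))) {
    return(amplicon_structure(x$unit_id, x$family_id, x$orientation))
  }
  stop("cannot interpret object as an AmpliconStructure")
}

#' Construct an NAHR event
#'
#' `duplication` and `deletion` act on the segment `[anchor_a, anchor_b)`
#' (unit indices, anchor_a < anchor_b) and require both anchors to be units of
#' the same family in the same orientation — the geometry of recombination
#' between direct repeats. `inversion` requires anchors of the same family in
#' opposite orientation and reverses (and flips) the units strictly between
#' them. `micro_duplication` is a single-unit tandem duplication (anchor_b is
#' ignored); it models the one- or two-amplicon micro-duplications that are
#' not explicable as repeat-pair NAHR.
#'
#' @param kind one of `"duplication"`, `"deletion"`, `"inversion"`,
#'   `"micro_duplication"`.
#' @param anchor_a,anchor_b unit indices into the structure the event will be
#'   applied to.
#' @param name optional conventional label.
#' @return an object of class `NAHREvent`.
#' @export
nahr_event <- function(kind, anchor_a, anchor_b = NA_integer_, name = NULL) {
  kind <- match.arg(kind, c("duplication", "deletion", "inversion",
                            "micro_duplication"))
  ev <- list(kind = kind, anchor_a = as.integer(anchor_a),
             anchor_b = as.integer(anchor_b), name = name)
  class(ev) <- "NAHREvent"
  ev
}

validate_event <- function(structure, event) {
  n <- nrow(structure)
  a <- event$anchor_a
  b <- event$anchor_b
  if (is.na(a) || a < 1L || a > n) stop("anchor_a out of range")
  if (event$kind == "micro_duplication") return(invisible(TRUE))
  if (is.na(b) || b < 1L || b > n) stop("anchor_b out of range")
  if (a >= b) stop("anchors must satisfy anchor_a < anchor_b")
  if (structure$family_id[a] != structure$family_id[b]) {
    stop("NAHR anchors must belong to the same amplicon family (got ",
         structure$family_id[a], " and ", structure$family_id[b], ")")
  }
  same <- structure$orientation[a] == structure$orientation[b]
  if (event$kind %in% c("duplication", "deletion") && !same) {
    stop(event$kind, " requires anchors in the same orientation")
  }
  if (event$kind == "inversion" && same) {
    stop("inversion requires anchors in opposite orientation")
  }
  invisible(TRUE)
}

#' Apply an NAHR event to a structure
#'
#' Duplication inserts a copy of the segment `[anchor_a, anchor_b)`
#' immediately after it (the tandem outcome of inter-sister-chromatid NAHR),
#' preserving unit orientations; deletion removes the segment; inversion
#' reverses the units strictly between the anchors and flips each of their
#' orientations, leaving the anchors themselves in place. A micro-duplication
#' tandem-duplicates the single unit at `anchor_a`.
#'
#' @param structure an [amplicon_structure()].
#' @param event an [nahr_event()].
#' @return the rearranged `AmpliconStructure`.
#' @export
apply_event <- function(structure, event) {
  structure <- as_amplicon_structure(structure)
  validate_event(structure, event)
  n <- nrow(structure)
  a <- event$anchor_a
  b <- event$anchor_b
  out <- switch(
    event$kind,
    duplication = {
      seg <- structure[a:(b - 1L), , drop = FALSE]
      rbind(structure[seq_len(b - 1L), , drop = FALSE], seg,
            structure[b:n, , drop = FALSE])
    },
    deletion = {
      keep <- setdiff(seq_len(n), a:(b - 1L))
      if (length(keep) == 0L) stop("deletion would empty the structure")
      structure[keep, , drop = FALSE]
    },
    inversion = {
      if (b - a > 1L) {
        mid <- structure[(b - 1L):(a + 1L), , drop = FALSE]
        mid$orientation <- ifelse(mid$orientation == "+", "-", "+")
        rbind(structure[seq_len(a), , drop = FALSE], mid,
              structure[b:n, , drop = FALSE])
      } else {
        structure
      }
    },
    micro_duplication = {
      rbind(structure[seq_len(a), , drop = FALSE],
            structure[a, , drop = FALSE],
            if (a < n) structure[(a + 1L):n, , drop = FALSE])
    })
  rownames(out) <- NULL
  class(out) <- c("AmpliconStructure", "data.frame")
  out
}

#' Apply a named event from the model catalog
#'
#' Resolves the catalog entry's anchor unit ids against the current structure
#' (first occurrence of each unit id) and applies the event. Because inserted
#' copies reuse unit ids, re-applying e.g. "b2/b4 duplication" to an already
#' duplicated structure anchors on the original b2 and the (unique) b4, so the
#' second application doubles the whole expanded segment — the mechanism
#' behind the fourfold AZFc gene dosage pattern.
#'
#' @param structure an [amplicon_structure()].
#' @param name catalog label (see `model$events`), e.g. "gr/gr duplication".
#' @param model a [region_model()].
#' @return the rearranged `AmpliconStructure`.
#' @export
apply_named_event <- function(structure, name, model) {
  entry <- model$events[[name]]
  if (is.null(entry)) {
    # allow lookup through aliases
    for (nm in names(model$events)) {
      if (name %in% model$events[[nm]]$aliases) entry <- model$events[[nm]]
    }
  }
  if (is.null(entry)) stop("unknown event name: ", name)
  structure <- as_amplicon_structure(structure)
  a <- match(entry$a, structure$unit_id)
  if (is.na(a)) stop("anchor unit ", entry$a, " absent from structure")
  if (entry$kind == "micro_duplication") {
    return(apply_event(structure, nahr_event("micro_duplication", a, name = name)))
  }
  b <- match(entry$b, structure$unit_id)
  if (is.na(b)) stop("anchor unit ", entry$b, " absent from structure")
  if (a >= b) stop("resolved anchors are not ordered for event: ", name)
  apply_event(structure, nahr_event(entry$kind, a, b, name = name))
}

#' Family copy-number vector of a structure
#'
#' @param structure an [amplicon_structure()] (may be empty).
#' @param families optional character vector fixing the families (and order)
#'   of the output; families absent from the structure count 0.
#' @return named integer vector family -> copy count.
#' @export
copy_number_vector <- function(structure, families = NULL) {
  structure <- as_amplicon_structure(structure)
  if (is.null(families)) families <- unique(structure$family_id)
  counts <- table(factor(structure$family_id, levels = families))
  out <- as.integer(counts)
  names(out) <- families
  out
}

#' Enumerate all valid NAHR events on a structure
#'
#' All same-family unit pairs in the same orientation yield a duplication and
#' a deletion; same-family pairs in opposite orientation yield an inversion.
#' With `allow_micro`, a single-unit tandem micro-duplication is emitted for
#' every unit. Order is deterministic: pairs scan `(i, j)` with `i < j`,
#' duplication before deletion, micro-duplications last.
#'
#' @param structure an [amplicon_structure()].
#' @param allow_micro include single-unit micro-duplications.
#' @return list of [nahr_event()]s.
#' @export
enumerate_events <- function(structure, allow_micro = FALSE) {
  structure <- as_amplicon_structure(structure)
  n <- nrow(structure)
  out <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (structure$family_id[i] != structure$family_id[j]) next
        if (structure$orientation[i] == structure$orientation[j]) {
          out[[length(out) + 1L]] <- nahr_event("duplication", i, j)
          out[[length(out) + 1L]] <- nahr_event("deletion", i, j)
        } else {
          out[[length(out) + 1L]] <- nahr_event("inversion", i, j)
        }
      }
    }
  }
  if (allow_micro) {
    for (i in seq_len(n)) {
      out[[length(out) + 1L]] <- nahr_event("micro_duplication", i)
    }
  }
  out
}

structure_key <- function(structure) {
  paste(structure$unit_id, structure$orientation, sep = "", collapse = ";")
}

# conventional label(s) for an event applied to a given structure
name_event <- function(structure, event, catalog) {
  ua <- structure$unit_id[event$anchor_a]
  ub <- if (event$kind == "micro_duplication") NA_character_
        else structure$unit_id[event$anchor_b]
  hits <- character(0)
  for (nm in names(catalog)) {
    e <- catalog[[nm]]
    if (!identical(e$kind, event$kind)) next
    ok <- if (event$kind == "micro_duplication") identical(e$a, ua)
          else identical(e$a, ua) && identical(e$b, ub)
    if (ok) hits <- c(hits, nm, e$aliases)
  }
  if (length(hits) == 0) {
    hits <- if (event$kind == "micro_duplication") {
      sprintf("%s micro-duplication", ua)
    } else {
      sprintf("%s/%s %s", ua, ub, event$kind)
    }
  }
  hits
}

#' Search for minimal NAHR event sequences explaining a copy-number vector
#'
#' Breadth-first search from the model's reference structure over
#' [enumerate_events()], deduplicating reached structures by their canonical
#' form (the ordered tuple of unit id + orientation). Returns all explanations
#' of minimal length whose [copy_number_vector()] equals `observed` (one
#' representative event path per distinct resulting structure). An empty
#' result means the vector is not reachable by at most `max_events` simple
#' NAHR events — the package's rendering of "complex non-NAHR" patterns.
#'
#' @param observed named integer vector, one entry per model family.
#' @param model a [region_model()].
#' @param max_events search depth (default 3).
#' @param allow_micro include single-unit micro-duplications as events.
#' @param size_cap structures growing beyond this many units are pruned with a
#'   warning.
#' @return list of explanations, each `list(events =, structure =)` where
#'   `events` is a list of applied [nahr_event()]s annotated with `names`
#'   (conventional labels). Length-0 event list means `observed` is the
#'   reference vector.
#' @export
infer_events <- function(observed, model, max_events = 3, allow_micro = FALSE,
                         size_cap = 64L) {
  if (max_events < 0) stop("max_events must be >= 0")
  fams <- names(model$families)
  if (!all(fams %in% names(observed))) {
    stop("observed vector missing families: ",
         paste(setdiff(fams, names(observed)), collapse = ", "))
  }
  observed <- as.integer(observed[fams])

  ref <- model$structure
  matches <- function(s) {
    identical(unname(copy_number_vector(s, families = fams)), observed)
  }

  frontier <- list(list(structure = ref, events = list()))
  visited <- new.env(parent = emptyenv())
  assign(structure_key(ref), TRUE, envir = visited)
  pruned <- FALSE

  for (depth in 0:max_events) {
    hits <- Filter(function(st) matches(st$structure), frontier)
    if (length(hits) > 0) {
      return(lapply(hits, function(st) {
        list(events = st$events, structure = st$structure)
      }))
    }
    if (depth == max_events) break
    nxt <- list()
    for (st in frontier) {
      for (ev in enumerate_events(st$structure, allow_micro = allow_micro)) {
        s2 <- apply_event(st$structure, ev)
        if (nrow(s2) > size_cap) { pruned <- TRUE; next }
        key <- structure_key(s2)
        if (exists(key, envir = visited, inherits = FALSE)) next
        assign(key, TRUE, envir = visited)
        ev$names <- name_event(st$structure, ev, model$events)
        nxt[[length(nxt) + 1L]] <- list(structure = s2,
                                        events = c(st$events, list(ev)))
      }
    }
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  if (pruned) {
    warning("search pruned structures exceeding ", size_cap, " units")
  }
  list()
}

#' Reference-length bookkeeping for structures and events
#'
#' `structure_span_bp()` sums the reference interval widths of a structure's
#' units (each inserted copy counted at its reference length);
#' `event_inserted_bp()` gives the sequence length a duplication inserts.
#' These are reporting utilities: with a full-scale coordinate annotation they
#' recover physical rearrangement sizes, with the compact packaged fixture
#' they are proportional stand-ins.
#'
#' @param structure an [amplicon_structure()].
#' @param model a [region_model()] with `unit_intervals`.
#' @return total width in bp.
#' @export
structure_span_bp <- function(structure, model) {
  structure <- as_amplicon_structure(structure)
  if (is.null(model$unit_intervals)) stop("model lacks unit intervals")
  w <- GenomicRanges::width(model$unit_intervals)
  names(w) <- names(model$unit_intervals)
  sum(w[structure$unit_id])
}

#' @rdname structure_span_bp
#' @param event an [nahr_event()] valid on `structure`.
#' @export
event_inserted_bp <- function(structure, event, model) {
  structure <- as_amplicon_structure(structure)
  validate_event(structure, event)
  if (!event$kind %in% c("duplication", "micro_duplication")) return(0L)
  idx <- if (event$kind == "micro_duplication") event$anchor_a
         else event$anchor_a:(event$anchor_b - 1L)
  structure_span_bp(structure[idx, , drop = FALSE], model)
}
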