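test_that("named events reproduce the published dosage arithmetic", {
  m <- azf_model()
  fam <- names(m$families)
  ref <- copy_number_vector(m$structure, fam)

  # gr/gr duplication: +1 blue, +1 green, +2 red, +1 grey, +1 yellow
  s_gr <- apply_named_event(m$structure, "gr/gr duplication", m)
  delta <- copy_number_vector(s_gr, fam) - ref
  expect_equal(delta[c("b", "g", "r", "Gr", "y")],
               c(b = 1L, g = 1L, r = 2L, Gr = 1L, y = 1L))
  expect_true(all(delta[c("t", "P4", "P5", "P6", "P7", "P8")] == 0L))

  # two successive b2/b4 duplications quadruple the AZFc gene content
  s_bb <- apply_named_event(
    apply_named_event(m$structure, "b2/b4 duplication", m),
    "b2/b4 duplication", m)
  expect_equal(gene_copy_count(s_bb, m, "DAZ"), 16L)
  expect_equal(gene_copy_count(s_bb, m, "BPY2"), 12L)
  expect_equal(gene_copy_count(s_bb, m, "CDY1"), 8L)

  # r2/r3 inversion conserves the copy-number vector
  s_inv <- apply_named_event(m$structure, "r2/r3 inversion", m)
  expect_equal(copy_number_vector(s_inv, fam), ref)
  expect_false(identical(s_inv, m$structure))

  # the inversion unlocks the b2/b3 deletion; it is invalid on the reference
  expect_error(apply_named_event(m$structure, "b2/b3 deletion", m),
               "same orientation")
  s_del <- apply_named_event(s_inv, "b2/b3 deletion", m)
  expect_equal(copy_number_vector(s_del, fam)[c("b", "t", "g", "r", "Gr", "y")],
               c(b = 3L, t = 2L, g = 1L, r = 2L, Gr = 1L, y = 1L))
  # rescue partially restores dosage: grey overshoots, green stays short
  s_res <- apply_named_event(s_del, "b2/b3 rescue", m)
  expect_equal(copy_number_vector(s_res, fam)[c("b", "g", "Gr")],
               c(b = 4L, g = 2L, Gr = 2L))
})

test_that("event application enforces NAHR geometry", {
  m <- azf_model()
  s <- m$structure
  i <- function(u) match(u, s$unit_id)
  # duplication between inverted units is not NAHR-competent
  expect_error(apply_event(s, nahr_event("duplication", i("b1"), i("b2"))),
               "same orientation")
  expect_error(apply_event(s, nahr_event("inversion", i("b1"), i("b3"))),
               "opposite orientation")
  expect_error(apply_event(s, nahr_event("deletion", i("b1"), i("t1"))),
               "same amplicon family")
  expect_error(apply_event(s, nahr_event("deletion", i("b3"), i("b1"))),
               "anchor_a < anchor_b")
  expect_error(apply_event(s, nahr_event("duplication", 99, 100)),
               "out of range")
})

test_that("duplication then deletion of the inserted segment is the identity", {
  for (m in list(azf_model(), toy_model())) {
    s <- m$structure
    for (ev in enumerate_events(s)) {
      if (ev$kind != "duplication") next
      dup <- apply_event(s, ev)
      len <- ev$anchor_b - ev$anchor_a
      undo <- nahr_event("deletion", ev$anchor_b, ev$anchor_b + len)
      expect_identical(apply_event(dup, undo), s)
    }
    # inversions are involutions
    for (ev in enumerate_events(s)) {
      if (ev$kind != "inversion") next
      expect_identical(apply_event(apply_event(s, ev), ev), s)
    }
  }
})

test_that("duplications grow, deletions shrink, inversions conserve counts", {
  m <- toy_model()
  s <- m$structure
  fam <- names(m$families)
  for (ev in enumerate_events(s, allow_micro = TRUE)) {
    s2 <- apply_event(s, ev)
    d <- sum(copy_number_vector(s2, fam)) - sum(copy_number_vector(s, fam))
    expected <- switch(ev$kind,
                       duplication = ev$anchor_b - ev$anchor_a,
                       micro_duplication = 1L,
                       deletion = -(ev$anchor_b - ev$anchor_a),
                       inversion = 0L)
    expect_equal(d, expected)
  }
})

test_that("event enumeration matches a brute-force pair scan", {
  two <- amplicon_structure(c("x1", "x2"), c("x", "x"), c("+", "+"))
  evs <- enumerate_events(two)
  expect_equal(sort(vapply(evs, function(e) e$kind, character(1))),
               c("deletion", "duplication"))
  flipped <- amplicon_structure(c("t1", "t2"), c("t", "t"), c("+", "-"))
  evs2 <- enumerate_events(flipped)
  expect_length(evs2, 1)
  expect_equal(evs2[[1]]$kind, "inversion")

  s <- azf_model()$structure
  got <- t(vapply(enumerate_events(s),
                  function(e) c(e$kind, e$anchor_a, e$anchor_b), character(3)))
  want <- NULL
  for (i in seq_len(nrow(s) - 1)) {
    for (j in (i + 1):nrow(s)) {
      if (s$family_id[i] != s$family_id[j]) next
      if (s$orientation[i] == s$orientation[j]) {
        want <- rbind(want, c("duplication", i, j), c("deletion", i, j))
      } else {
        want <- rbind(want, c("inversion", i, j))
      }
    }
  }
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("copy-number vectors count units, including edge cases", {
  m <- azf_model()
  fam <- names(m$families)
  expect_equal(copy_number_vector(m$structure, fam), ref_vector(m))
  # after b2/b4 deletion, deltas equal the deleted segment's family content
  s <- m$structure
  a <- match("b2", s$unit_id); b <- match("b4", s$unit_id)
  seg_content <- table(factor(s$family_id[a:(b - 1)], levels = fam))
  s_del <- apply_named_event(s, "b2/b4 deletion", m)
  expect_equal(copy_number_vector(s, fam) - copy_number_vector(s_del, fam),
               as.integer(seg_content), ignore_attr = TRUE)
  # empty structure
  empty <- amplicon_structure(character(0), character(0), character(0))
  expect_equal(copy_number_vector(empty, fam),
               setNames(integer(length(fam)), fam))
})

test_that("minimal event inference explains the published patterns", {
  m <- azf_model()
  fam <- names(m$families)
  ref <- copy_number_vector(m$structure, fam)

  # reference vector: one explanation of length zero
  ex0 <- infer_events(ref, m)
  expect_length(ex0, 1)
  expect_length(ex0[[1]]$events, 0)

  # gr/gr pattern: a minimal single-event explanation carrying the name
  obs_gr <- ref + c(b = 1L, t = 0L, g = 1L, r = 2L, Gr = 1L, y = 1L,
                    P4 = 0L, P5 = 0L, P6 = 0L, P7 = 0L, P8 = 0L)[fam]
  ex1 <- infer_events(obs_gr, m, max_events = 2)
  expect_gte(length(ex1), 1)
  expect_true(all(vapply(ex1, function(e) length(e$events), integer(1)) == 1))
  all_names <- unlist(lapply(ex1, function(e) e$events[[1]]$names))
  expect_true("gr/gr duplication" %in% all_names)

  # the g1/g2-duplication + b1/b3-deletion pattern needs two events
  s008 <- apply_named_event(
    apply_named_event(m$structure, "g1/g2 duplication", m),
    "b1/b3 deletion", m)
  ex2 <- infer_events(copy_number_vector(s008, fam), m, max_events = 2)
  expect_gte(length(ex2), 1)
  expect_true(all(vapply(ex2, function(e) length(e$events), integer(1)) == 2))
  has_pair <- vapply(ex2, function(e) {
    n1 <- unlist(lapply(e$events, function(v) v$names))
    ("g1/g2 duplication" %in% n1 || "gr/gr duplication" %in% n1) &&
      "b1/b3 deletion" %in% n1
  }, logical(1))
  expect_true(any(has_pair))

  # a vector unreachable by simple NAHR comes back unexplained
  impossible <- ref; impossible["t"] <- 5L
  expect_length(infer_events(impossible, m, max_events = 1), 0)
  expect_error(infer_events(ref, m, max_events = -1), ">= 0")
  expect_error(infer_events(ref[-1], m), "missing families")
})

test_that("search agrees with an exhaustive depth-2 oracle on the toy model", {
  m <- toy_model()
  fam <- names(m$families)
  key <- function(s) paste(copy_number_vector(s, fam), collapse = ",")

  # independent naive enumeration: all structures reachable in <= 2 events,
  # no deduplication, no canonical hashing
  reach <- new.env(parent = emptyenv())
  note <- function(s, d) {
    k <- key(s)
    old <- get0(k, envir = reach, ifnotfound = Inf)
    if (d < old) assign(k, d, envir = reach)
  }
  note(m$structure, 0L)
  for (e1 in enumerate_events(m$structure)) {
    s1 <- apply_event(m$structure, e1)
    note(s1, 1L)
    for (e2 in enumerate_events(s1)) note(apply_event(s1, e2), 2L)
  }
  vec_depth <- mget(ls(reach), envir = reach)

  for (k in names(vec_depth)) {
    obs <- setNames(as.integer(strsplit(k, ",")[[1]]), fam)
    ex <- infer_events(obs, m, max_events = 2)
    expect_gte(length(ex), 1)
    lens <- vapply(ex, function(e) length(e$events), integer(1))
    expect_true(all(lens == vec_depth[[k]]),
                info = paste("vector", k, "expected depth", vec_depth[[k]]))
    for (e in ex) {
      expect_equal(copy_number_vector(e$structure, fam), obs)
    }
  }
  # vectors outside the reachable set stay unexplained at depth 2
  set.seed(9)
  for (i in 1:10) {
    obs <- ref_vector(m) + sample(-2:3, length(fam), TRUE)
    obs <- setNames(pmax(obs, 0L), fam)
    if (!paste(obs, collapse = ",") %in% names(vec_depth)) {
      expect_length(infer_events(obs, m, max_events = 2), 0)
    }
  }
  # determinism of the search
  obs <- copy_number_vector(apply_event(m$structure, nahr_event("duplication", 1, 3)), fam)
  expect_identical(infer_events(obs, m, max_events = 2),
                   infer_events(obs, m, max_events = 2))
})

test_that("span bookkeeping sums reference unit widths", {
  m <- azf_model()
  s <- m$structure
  w <- GenomicRanges::width(m$unit_intervals)
  names(w) <- names(m$unit_intervals)
  expect_equal(structure_span_bp(s, m), sum(w[s$unit_id]))
  a <- match("g1", s$unit_id); b <- match("g2", s$unit_id)
  ev <- nahr_event("duplication", a, b)
  expect_equal(event_inserted_bp(s, ev, m), sum(w[s$unit_id[a:(b - 1)]]))
  expect_equal(event_inserted_bp(s, nahr_event("inversion",
                                               match("r2", s$unit_id),
                                               match("r3", s$unit_id)), m), 0L)
})
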