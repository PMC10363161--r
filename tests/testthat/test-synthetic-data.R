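test_that("simulated depth hits its target means within 3 SE", {
  m <- sim_model()
  truth <- ref_vector(m); truth["r"] <- 8L; truth["g"] <- 2L
  cfg <- simulation_config(haploid_coverage = 30, seed = 77)
  tr <- simulate_depth(truth, m, cfg, "s")
  an <- m$analysis
  # single-copy region
  sc <- tr$depth[an$single_copy_index]
  expect_lt(abs(mean(sc) - 30), 3 * sqrt(30 / length(sc)))
  for (f in names(m$families)) {
    d <- tr$depth[an$family_index[[f]]]
    lambda <- 30 * truth[[f]] / m$families[[f]]$ref_cn
    expect_lt(abs(mean(d) - lambda), 3 * sqrt(lambda / length(d)))
  }
  # red at twice the reference dosage: normalised depth in [1.9, 2.1]
  norm_r <- mean(tr$depth[an$family_index[["r"]]]) / mean(sc)
  expect_gt(norm_r, 1.9); expect_lt(norm_r, 2.1)
})

test_that("simulation is deterministic in the seed and validates truth", {
  m <- sim_model()
  cfg <- simulation_config(seed = 5)
  t1 <- simulate_depth(ref_vector(m), m, cfg, "a")
  t2 <- simulate_depth(ref_vector(m), m, cfg, "a")
  expect_identical(t1$depth, t2$depth)
  t3 <- simulate_depth(ref_vector(m), m, simulation_config(seed = 6), "a")
  expect_false(identical(t1$depth, t3$depth))
  expect_error(simulate_depth(c(ref_vector(m), zz = 2), m, cfg), "unknown")
  expect_error(simulate_depth(ref_vector(m)[-1], m, cfg), "missing families")
  # negative-binomial noise with huge dispersion stays near-Poisson
  cfg_nb <- simulation_config(noise = "negative_binomial", dispersion = 1e5,
                              seed = 5)
  t_nb <- simulate_depth(ref_vector(m), m, cfg_nb, "a")
  expect_lt(abs(mean(t_nb$depth[m$analysis$single_copy_index]) - 30), 0.5)
})

test_that("masked positions can be emitted as zeros or omitted", {
  m <- tiny_model()   # mask covers 1051..1100 inside family A
  cfg0 <- simulation_config(seed = 3, masked_behavior = "omit")
  tr0 <- simulate_depth(c(A = 1, B = 2), m, cfg0, "s")
  expect_false(any(tr0$pos %in% 1051:1100))
  cfgz <- simulation_config(seed = 3, masked_behavior = "zero")
  trz <- simulate_depth(c(A = 1, B = 2), m, cfgz, "s")
  expect_true(all(1051:1100 %in% trz$pos))
  expect_true(all(azfcnv:::depth_at_positions(trz, 1051:1100) == 0))
})

test_that("cohort simulation writes samtools-style files that round-trip", {
  m <- tiny_model()
  truth <- rbind(s1 = c(A = 1L, B = 2L), s2 = c(A = 2L, B = 2L))
  out <- simulate_cohort(truth, m, simulation_config(seed = 9),
                         outdir = tempfile())
  expect_equal(nrow(out), 2)
  expect_true(all(file.exists(out$depth_file)))
  expect_true(file.exists(attr(out, "truth_file")))
  # reading a written file reproduces the in-memory track (zeros omitted)
  cfg1 <- simulation_config(seed = azfcnv:::derive_seed(9, "s1"))
  mem <- simulate_depth(truth["s1", ], m, cfg1, "s1")
  disk <- read_depth_tsv(out$depth_file[1], m, "s1")
  expect_identical(disk$depth, mem$depth)
  # duplicate ids are refused
  bad <- truth; rownames(bad) <- c("s1", "s1")
  expect_error(simulate_cohort(bad, m, simulation_config(), tempfile()),
               "unique sample ids")
})

test_that("low coverage degrades gracefully and masking never helps", {
  # micro-model: one 2-copy family of 1 kb copies, 10 kb control region
  build <- function(masked) {
    region_model(
      families = list(F = list(ref_cn = 2L,
                               copies = gr(c(1001, 3001), c(2000, 4000)))),
      single_copy = gr(20001, 30000),
      structure = amplicon_structure(c("F1", "F2"), c("F", "F"), c("+", "+")),
      masks = if (masked) gr(c(1501, 3501), c(2000, 4000))
              else GenomicRanges::GRanges())
  }
  m_open <- build(FALSE); m_half <- build(TRUE)
  acc <- function(model, seed_off) {
    hits <- 0L
    for (i in 1:100) {
      truth <- c(F = sample(1:4, 1))
      cfg <- simulation_config(haploid_coverage = 0.05,
                               seed = 50000 + seed_off + i)
      tr <- simulate_depth(truth, model, cfg, "s")
      p <- call_sample(tr, model, min_unmasked_bp = 100)
      hits <- hits + (p$calls$called_cn[1] == truth[["F"]])
    }
    hits / 100
  }
  set.seed(1234)
  a_open <- acc(m_open, 0)
  set.seed(1234)
  a_half <- acc(m_half, 0)
  expect_lt(a_open, 1)               # coverage this thin must make mistakes
  expect_lte(a_half, a_open + 0.02)  # halving the data cannot help
})

test_that("a reference cohort is called reference essentially always", {
  m <- sim_model()
  ref <- ref_vector(m)
  ok <- 0L
  for (i in 1:1000) {
    cfg <- simulation_config(seed = 600000 + i)
    tr <- simulate_depth(ref, m, cfg, "s")
    ok <- ok + (call_sample(tr, m)$cnv_class == "reference")
  }
  expect_gte(ok / 1000, 0.999)
})

test_that("the recovery harness reports a coherent summary", {
  m <- sim_model()
  ref <- ref_vector(m)
  truth <- rbind(ref, ref, ref)
  truth[2, "r"] <- 8L
  truth[3, "b"] <- 3L
  rownames(truth) <- c("w1", "w2", "w3")
  rec <- recovery_experiment(truth, m, simulation_config(seed = 17))
  expect_equal(rec$classes$called_class,
               c("reference", "duplication", "deletion"))
  expect_equal(rec$per_sample_exact, 1)
  expect_equal(unname(rec$carrier_incidence$count), 2)
  expect_equal(rec$n_patterns, 2)
  # very low coverage: the report stays well-formed even when calls err
  rec_lo <- recovery_experiment(truth, m,
                                simulation_config(haploid_coverage = 0.5,
                                                  seed = 17))
  expect_true(all(rec_lo$per_family_accuracy >= 0 &
                    rec_lo$per_family_accuracy <= 1))
  expect_equal(dim(rec_lo$called), dim(truth))
})
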