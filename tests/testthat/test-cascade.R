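make_trio_gm <- function(p, f, m) {
  n <- length(p)
  sites <- data.frame(chrom = "chr16", pos = seq_len(n) * 1000,
                      ref = "A", alt = "G")
  genotype_matrix(sites, cbind(kid = p, dad = f, mum = m))
}

test_that("trio IBD filter keeps hom-proband / het-parents exactly", {
  gm <- make_trio_gm(p = c(2L, 2L, 1L, 2L, 2L),
                     f = c(1L, 2L, 1L, NA, 1L),
                     m = c(1L, 1L, 1L, 1L, 2L))
  out <- trio_ibd_filter(gm, "kid", "dad", "mum")
  expect_identical(out$pos, 1000)  # only (2,1,1); missing/hom parents drop
  expect_error(trio_ibd_filter(gm, "kid", "dad", "granny"), "granny")
})

test_that("proband-only filter keeps homozygous-alt calls", {
  gm <- make_trio_gm(p = c(2L, 1L, 0L, NA), f = rep(1L, 4), m = rep(1L, 4))
  out <- proband_homozygous_filter(gm, "kid")
  expect_identical(out$pos, 1000)
  expect_error(proband_homozygous_filter(gm, "nobody"), "nobody")
})

test_that("region and effect filters apply the functional classes", {
  df <- data.frame(
    chrom = "chr16", pos = 1:7, ref = "A", alt = "G",
    region_class = c("exonic", "intronic", "splice", "exonic", "exonic",
                     "exonic", NA),
    effect_class = c("nonsynonymous_SNV", "nonsynonymous_SNV", "synonymous",
                     "synonymous", "stopgain", "nonframeshift_indel", NA)
  )
  cands <- candidate_set(df)
  reg <- region_filter(cands)
  expect_identical(reg$pos, c(1L, 3L, 4L, 5L, 6L))
  eff <- effect_filter(reg)
  # splice kept regardless of effect; synonymous and non-frameshift dropped
  expect_identical(eff$pos, c(1L, 3L, 5L))
})

test_that("frequency and control filters subtract key sets", {
  cands <- random_candidates(50, seed = 1)
  db <- random_keyset(cands, 0.3, 2, "exclusion_db")
  panel <- random_keyset(cands, 0.3, 3, "control_panel")
  ff <- frequency_filter(cands, db)
  expect_false(any(ff$key %in% db$keys))
  cf <- control_filter(cands, panel)
  expect_false(any(cf$key %in% panel$keys))
  expect_identical(nrow(frequency_filter(cands,
                                         structure(list(keys = character()),
                                                   class = "exclusion_db"))),
                   nrow(cands))
})

test_that("cross-family intersection matches on full variant identity", {
  a <- candidate_set(data.frame(chrom = "chr16", pos = c(1, 2, 3),
                                ref = "A", alt = c("G", "G", "T")))
  b <- candidate_set(data.frame(chrom = "chr16", pos = c(2, 3, 4),
                                ref = "A", alt = c("G", "G", "T")))
  inter <- cross_family_intersection(a, b)
  expect_identical(inter$key, "chr16:2:A:G")  # pos 3 differs in alt
  expect_identical(nrow(cross_family_intersection(a, a)), nrow(a))
  empty <- candidate_set(data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character()))
  expect_identical(nrow(cross_family_intersection(a, empty)), 0L)
})

test_that("predictor consensus scores, ranks and flags unanimity", {
  df <- data.frame(
    chrom = "chr16", pos = 1:3, ref = "A", alt = "G",
    sift = c(0.006, 0.05, NA),
    polyphen2 = c(0.728, 0.4, NA),
    provean = c(-4.021, -1, NA),
    mutation_taster = c("disease_causing", "polymorphism", NA)
  )
  out <- predictor_consensus(candidate_set(df))
  # the reported mutation's scores are damaging under all four tools
  expect_identical(out$n_damaging[out$pos == 1], 4L)
  expect_true(out$prioritized[out$pos == 1])
  # exactly at the SIFT threshold is not damaging (strict <)
  expect_identical(out$n_damaging[out$pos == 2], 0L)
  # absent scores never count
  expect_identical(out$n_damaging[out$pos == 3], 0L)
  expect_false(any(out$prioritized[out$pos != 1]))
  expect_identical(out$pos[1], 1L)  # ranked first

  expect_error(predictor_consensus(candidate_set(df),
                                   thresholds = list(oracle9000 =
                                     list(cmp = "lt", cutoff = 1))),
               "unknown tool")
})

test_that("filters are contractive and idempotent, and commute", {
  for (seed in 1:10) {
    cands <- random_candidates(80, seed)
    db <- random_keyset(cands, 0.4, seed + 100, "exclusion_db")
    panel <- random_keyset(cands, 0.4, seed + 200, "control_panel")
    filters <- list(
      region = region_filter,
      effect = function(x) effect_filter(x),
      freq = function(x) frequency_filter(x, db),
      ctrl = function(x) control_filter(x, panel)
    )
    for (f in filters) {
      once <- f(cands)
      expect_true(all(once$key %in% cands$key))      # contractive
      expect_identical(as.data.frame(f(once))$key, once$key)  # idempotent
    }
    # frequency and effect commute; region-then-effect = joint predicate
    ab <- effect_filter(frequency_filter(cands, db))
    ba <- frequency_filter(effect_filter(cands), db)
    expect_identical(ab$key, ba$key)
    joint <- effect_filter(region_filter(cands))
    direct <- candidate_set(as.data.frame(cands)[
      with(cands, !is.na(region_class) & region_class %in% c("exonic", "splice") &
             ((!is.na(effect_class) & effect_class %in%
                 c("nonsynonymous_SNV", "stopgain", "stoploss",
                   "frameshift_indel")) | region_class == "splice")), ])
    expect_identical(joint$key, direct$key)
  }
})

test_that("the full cascade recovers the planted variant with a consistent report", {
  b <- simulate_dataset(small_config(seed = 55))
  res <- prioritize_bundle(b)
  expect_true(b$causal$key %in% res$candidates$key)
  expect_identical(res$report$n_out, res$report$n_in - res$report$n_removed)
  # per-family candidate sets contain the final intersection
  for (fc in res$family_candidates) {
    expect_true(all(res$candidates$key %in% fc$key))
  }
})

test_that("an empty genotype matrix yields an empty cascade", {
  sites <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character())
  gm <- genotype_matrix(sites, matrix(integer(), 0, 3,
                                      dimnames = list(NULL,
                                                      c("kid", "dad", "mum"))))
  ann <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), gene = character(),
                    region_class = character(), effect_class = character(),
                    sift = numeric(), polyphen2 = numeric(),
                    provean = numeric(), mutation_taster = character(),
                    key = character())
  trio <- list(proband = "kid", father = "dad", mother = "mum",
               mode = "trio")
  db <- structure(list(keys = character()), class = "exclusion_db")
  panel <- structure(list(keys = character()), class = "control_panel")
  res <- run_cascade(list(A = gm, B = gm), list(A = trio, B = trio),
                     ann, db, panel)
  expect_identical(nrow(res$candidates), 0L)
  expect_true(all(res$report$n_in == 0) && all(res$report$n_out == 0))
})
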