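test_that("ROH scanner applies count and span thresholds", {
  # 12 consecutive hom calls spanning 150 kb -> one region, n_variants 12
  pos <- seq(1e6, 1e6 + 150e3, length.out = 12)
  r <- roh_scan(pos, rep(2L, 12))
  expect_identical(nrow(r), 1L)
  expect_identical(r$n_variants, 12L)
  expect_identical(c(r$start, r$end), c(pos[1], pos[12]))

  # same calls over 50 kb fail the length rule
  expect_identical(nrow(roh_scan(seq(1e6, 1e6 + 50e3, length.out = 12),
                                 rep(0L, 12))), 0L)

  # missing calls are skipped without breaking a run
  states <- rep(0L, 13); states[7] <- NA
  r2 <- roh_scan(seq(1e6, 1e6 + 150e3, length.out = 13), states)
  expect_identical(r2$n_variants, 12L)

  # a heterozygous call breaks the run under max_het = 0
  states3 <- rep(0L, 24); states3[12] <- 1L
  pos3 <- seq(1e6, 1e6 + 400e3, length.out = 24)
  r3 <- roh_scan(pos3, states3, min_variants = 10)
  expect_identical(nrow(r3), 2L)

  expect_error(roh_scan(c(3, 1, 2), rep(0L, 3)), "sorted")
})

test_that("ROH scanner matches the exhaustive-window oracle", {
  set.seed(99)
  for (case in 1:120) {
    n <- sample(1:30, 1)
    pos <- sort(sample.int(3e6, n))
    states <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                     prob = c(0.4, 0.25, 0.25, 0.1))
    min_v <- sample(2:6, 1)
    min_l <- sample(c(1e4, 1e5, 5e5), 1)
    max_h <- sample(0:2, 1)
    got <- roh_scan(pos, states, min_v, min_l, max_h)
    want <- roh_oracle(pos, states, min_v, min_l, max_h)
    expect_equal(got, want, info = paste("case", case))
  }
})

test_that("shared regions are interval intersections over 100 kb", {
  regs <- rbind(
    data.frame(chrom = "chr16", start = 100e3, end = 500e3,
               n_variants = 10L, sample = "P1"),
    data.frame(chrom = "chr16", start = 300e3, end = 900e3,
               n_variants = 10L, sample = "P2")
  )
  sh <- shared_regions(regs)
  expect_identical(nrow(sh), 1L)
  expect_equal(c(sh$start, sh$end), c(3e5, 5e5))
  expect_equal(sh$length_bp, 2e5)

  # 40 kb overlap dropped at the default threshold
  regs2 <- regs
  regs2$start <- c(100e3, 150e3); regs2$end <- c(190e3, 260e3)
  expect_identical(nrow(shared_regions(regs2)), 0L)

  # disjoint regions give nothing
  regs3 <- regs
  regs3$start <- c(100e3, 700e3); regs3$end <- c(200e3, 900e3)
  expect_identical(nrow(shared_regions(regs3)), 0L)
})

test_that("every shared region lies inside each contributor's own ROH", {
  b <- simulate_dataset(small_config(seed = 61))
  hm <- hommap_bundle(b)
  for (i in seq_len(nrow(hm$shared))) {
    for (s in strsplit(hm$shared$samples[i], ",")[[1]]) {
      own <- hm$roh[hm$roh$sample == s & hm$roh$chrom == hm$shared$chrom[i], ]
      expect_true(any(own$start <= hm$shared$start[i] &
                        own$end >= hm$shared$end[i]))
    }
  }
})

test_that("raising thresholds never adds regions", {
  set.seed(7)
  n <- 200
  pos <- sort(sample.int(5e7, n))
  states <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(0.5, 0.1, 0.4))
  lens <- c(5e4, 1e5, 5e5, 1e6)
  counts <- vapply(lens, function(L) {
    nrow(roh_scan(pos, states, min_variants = 3, min_length_bp = L))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("region lengths reproduce the printed coordinate arithmetic", {
  shared <- region_length(4057603, 7657432)
  expect_identical(shared$bp, 3599829)
  expect_identical(shared$mb, 3.6)
  expect_identical(shared$label, "3.6 Mb")

  first <- region_length(4015729, 7102036)
  expect_identical(first$bp, 3086307)
  expect_identical(first$mb, 3.1)
  expect_identical(region_length(4015729, 7102036, digits = 0)$mb, 3)

  expect_identical(region_length(5, 5)$bp, 0)
})

test_that("BED converters are exact inverses", {
  regs <- data.frame(chrom = "chr16", start = c(1L, 4057603L),
                     end = c(10L, 7657432L))
  expect_identical(bed_to_regions(regions_to_bed(regs)), regs)
  expect_identical(regions_to_bed(regs)$start, regs$start - 1L)
})

str_row <- function(marker, pos, sample, a) {
  data.frame(marker = marker, chrom = "chr16", position = pos,
             sample = sample, allele1 = min(a), allele2 = max(a),
             stringsAsFactors = FALSE)
}

test_that("STR trio phasing resolves origins where forced", {
  df <- rbind(
    str_row("M1", 1e6, "kid", c(150, 154)),
    str_row("M1", 1e6, "dad", c(150, 150)),
    str_row("M1", 1e6, "mum", c(154, 158)),
    str_row("M2", 2e6, "kid", c(150, 150)),
    str_row("M2", 2e6, "dad", c(150, 152)),
    str_row("M2", 2e6, "mum", c(150, 152)),
    str_row("M3", 3e6, "kid", c(150, 154)),
    str_row("M3", 3e6, "dad", c(150, 154)),
    str_row("M3", 3e6, "mum", c(150, 154)),
    str_row("M4", 4e6, "kid", c(150, 150)),
    str_row("M4", 4e6, "dad", c(152, 154)),
    str_row("M4", 4e6, "mum", c(150, 152))
  )
  ph <- phase_str_trio(df, "kid", "dad", "mum")
  expect_identical(ph$paternal[ph$marker == "M1"], 150)
  expect_identical(ph$maternal[ph$marker == "M1"], 154)
  expect_true(ph$resolved[ph$marker == "M2"])
  expect_identical(ph$paternal[ph$marker == "M2"], 150)
  expect_false(ph$resolved[ph$marker == "M3"])  # both-compatible
  expect_false(ph$mendelian_ok[ph$marker == "M4"])
})

test_that("minimal shared haplotype is the longest common homozygous run", {
  mkrow <- function(m, pos, sample, a1, a2 = a1) {
    str_row(m, pos, sample, c(a1, a2))
  }
  markers <- sprintf("M%02d", 1:10)
  pos <- (1:10) * 1e6
  df <- list()
  for (i in 1:10) {
    # patients share homozygous alleles at markers 3..7, discordant at 2, 8
    a_p1 <- if (i %in% 3:7) 100 else if (i == 2) 100 else 90
    a_p2 <- if (i %in% 3:7) 100 else if (i == 2) 102 else 92
    df[[length(df) + 1]] <- mkrow(markers[i], pos[i], "P1", a_p1)
    df[[length(df) + 1]] <- mkrow(markers[i], pos[i], "P2", a_p2)
  }
  df <- do.call(rbind, df)
  msh <- minimal_shared_haplotype(df, c("P1", "P2"))
  expect_identical(msh$core_markers, markers[3:7])
  expect_identical(msh$boundary_markers, c("M02", "M08"))
  expect_identical(msh$region$start, pos[2])
  expect_identical(msh$region$end, pos[8])
  expect_identical(msh$region$span_bp, pos[8] - pos[2])

  # a patient heterozygous everywhere yields an empty result
  df_het <- df
  df_het$allele2[df_het$sample == "P2"] <-
    df_het$allele1[df_het$sample == "P2"] + 2
  out <- minimal_shared_haplotype(df_het, c("P1", "P2"))
  expect_null(out$region)
  expect_match(out$message, "no marker")
})

test_that("adding patients never widens the minimal shared haplotype", {
  b <- simulate_dataset(small_config(seed = 71))
  p1 <- attr(b$peds$F1, "proband"); p2 <- attr(b$peds$F2, "proband")
  two <- minimal_shared_haplotype(b$str_genotypes, c(p1, p2),
                                  b$strs$markers)
  three <- minimal_shared_haplotype(
    b$str_genotypes, c(p1, p2, "F2-III.1"), b$strs$markers)
  if (!is.null(three$region)) {
    expect_true(all(three$core_markers %in% two$core_markers))
  } else {
    succeed()
  }
})

test_that("the simulated founder haplotype contains the causal position", {
  b <- simulate_dataset(small_config(seed = 72))
  probands <- vapply(b$peds, attr, character(1), "proband")
  msh <- minimal_shared_haplotype(b$str_genotypes, unname(probands),
                                  b$strs$markers)
  expect_false(is.null(msh$region))
  expect_true(msh$region$start <= b$causal$pos &&
                msh$region$end >= b$causal$pos)
})
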