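test_that("founder haplotype alleles follow the site frequency spectrum", {
  cfg <- small_config()
  ped <- trio_ped()
  # degenerate spectra pin the sampler
  sites0 <- data.frame(chrom = "chr16", pos = seq(1e6, 2e6, by = 1e4),
                       ref = "A", alt = "G", freq = 0)
  set.seed(1)
  pool0 <- sample_founder_haplotypes(cfg, ped, sites0)
  expect_true(all(pool0$alleles$chr16 == 0))
  sites1 <- sites0; sites1$freq <- 1
  set.seed(1)
  pool1 <- sample_founder_haplotypes(cfg, ped, sites1)
  expect_true(all(pool1$alleles$chr16 == 1))

  # uniform(0.01, 0.5): empirical mean alt frequency within 3 SE of 0.255
  cfgU <- sim_config(freq_range = c(0.01, 0.5), rare_fraction = 0)
  set.seed(11)
  f <- homsift:::sample_site_freqs(cfgU, 10000)
  sitesU <- data.frame(chrom = "chr16",
                       pos = sort(sample.int(9e7, 10000)),
                       ref = "A", alt = "G", freq = f)
  poolU <- sample_founder_haplotypes(cfgU, ped, sitesU)
  draws <- as.vector(poolU$alleles$chr16)
  se <- sqrt(0.255 * 0.745 / length(draws))
  expect_lt(abs(mean(draws) - 0.255), 3 * se)
})

test_that("gene drop without recombination transmits intact haplotypes", {
  cfg <- small_config(recombination_rate = 0)
  ped <- family_pedigree("F2")
  sites <- simulate_sites(cfg)
  set.seed(3)
  pool <- sample_founder_haplotypes(cfg, ped, sites)
  drop <- gene_drop(ped, pool, cfg)
  for (id in ped$id) {
    labs <- drop$labels[[id]]$chr16
    expect_length(unique(labs[1, ]), 1)
    expect_length(unique(labs[2, ]), 1)
  }
})

test_that("gene drop is Mendelian-consistent at every locus", {
  cfg <- small_config()
  ped <- family_pedigree("F2")
  sites <- simulate_sites(cfg)
  set.seed(5)
  pool <- sample_founder_haplotypes(cfg, ped, sites)
  for (rep in 1:3) {
    drop <- gene_drop(ped, pool, cfg)
    for (i in which(!is.na(ped$father))) {
      id <- ped$id[i]
      labs <- drop$labels[[id]]$chr16
      flabs <- drop$labels[[ped$father[i]]]$chr16
      mlabs <- drop$labels[[ped$mother[i]]]$chr16
      expect_true(all(labs[1, ] == flabs[1, ] | labs[1, ] == flabs[2, ]))
      expect_true(all(labs[2, ] == mlabs[1, ] | labs[2, ] == mlabs[2, ]))
    }
  }
})

test_that("expected autozygous fraction of a first-cousin child matches F", {
  cfg <- small_config(seed = 9)
  ped <- family_pedigree("F2")
  sites <- simulate_sites(cfg)
  set.seed(9)
  pool <- sample_founder_haplotypes(cfg, ped, sites)
  fr <- replicate(50, autozygous_fraction(gene_drop(ped, pool, cfg),
                                          "F2-IV.3"))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - inbreeding(ped, "F2-IV.3")), 3 * se)
})

test_that("planting forces recessive segregation on the shared haplotype", {
  b <- simulate_dataset(small_config(seed = 21))
  ci <- which(b$sites$is_causal)
  g2 <- b$genotypes$F2
  expect_identical(unname(g2$geno[ci, "F2-IV.3"]), 2L)
  expect_identical(unname(g2$geno[ci, "F2-III.1"]), 1L)
  expect_identical(unname(g2$geno[ci, "F2-III.2"]), 1L)
  expect_identical(unname(b$genotypes$F1$geno[ci, "F1-IV.3"]), 2L)

  # the causal site sits inside an autozygous tract of each proband
  for (f in c("F1", "F2")) {
    proband <- attr(b$peds[[f]], "proband")
    loci <- b$drops[[f]]$loci$chr16
    cidx <- which(loci$type == "var" & loci$pos == b$causal$pos)
    labs <- b$drops[[f]]$labels[[proband]]$chr16[, cidx]
    expect_identical(labs[1], labs[2])
  }
  expect_true(all(b$rejections >= 0))
})

test_that("the causal variant is absent from the frequency table and controls", {
  b <- simulate_dataset(small_config(seed = 22))
  ft <- b$freq_table
  expect_false(b$causal$key %in% variant_key(ft$chrom, ft$pos, ft$ref,
                                             ft$alt))
  expect_false(b$causal$key %in% b$control_panel$keys)
  expect_identical(b$control_chrom_alt, 0L)
  expect_identical(b$config$n_control_chromosomes, 550L)
})

test_that("emitted bundles are byte-identical across equal seeds", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- emit_dataset(simulate_dataset(small_config(seed = 33)), d1)
  p2 <- emit_dataset(simulate_dataset(small_config(seed = 33)), d2)
  for (f in setdiff(names(p1), "manifest")) {
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])), label = f)
  }
  # and a different seed changes the genotype data
  d3 <- withr::local_tempdir()
  p3 <- emit_dataset(simulate_dataset(small_config(seed = 34)), d3)
  expect_false(identical(unname(tools::md5sum(p1[["vcf_f2"]])),
                         unname(tools::md5sum(p3[["vcf_f2"]]))))
})

test_that("VCF record count equals variants observed in the family", {
  b <- simulate_dataset(small_config(seed = 35))
  d <- withr::local_tempdir()
  paths <- emit_dataset(b, d)
  for (f in c("F1", "F2")) {
    gm <- b$genotypes[[f]]
    expected <- sum(rowSums(gm$geno, na.rm = TRUE) > 0)
    got <- read_vcf(paths[[paste0("vcf_", tolower(f))]])
    expect_identical(nrow(got$sites), expected)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(region_class_probs = c(exonic = 0.5)),
               "sum to 1")
  expect_error(sim_config(causal_pos = 1e12), "outside")
  expect_error(sim_config(causal_chrom = "chrZ"), "causal_chrom")
})
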