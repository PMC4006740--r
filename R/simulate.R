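#' Simulation configuration
#'
#' Parameters of the synthetic consanguineous-exome generator. The defaults
#' describe the emulated study: two unrelated first-cousin-union families
#' carrying the same founder mutation on a shared ancestral haplotype, a
#' desk-scale three-chromosome "exome" (~1 variant per 3 kb of exonic
#' space), a 14-individual control panel and 550 control chromosomes, and
#' an STR marker panel spanning 8.7 Mb around the causal locus.
#'
#' @param seed Integer master seed; all randomness derives from it through
#'   fixed labelled substreams, so identical seeds give byte-identical
#'   output bundles.
#' @param n_variants_per_chrom Variant sites simulated per chromosome.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param freq_range Range of the common part of the allele-frequency
#'   spectrum (uniform draw per site).
#' @param rare_fraction Fraction of sites drawn instead from `rare_range`
#'   (the rare tail).
#' @param rare_range Frequency range of the rare tail.
#' @param recombination_rate Recombination rate in cM/Mb (Haldane model,
#'   no interference; crossover counts Poisson with mean equal to the
#'   genetic length in Morgans).
#' @param region_class_probs Named probabilities of variant region classes
#'   (must sum to 1).
#' @param effect_class_probs Named probabilities of coding effect classes
#'   for exonic variants (must sum to 1).
#' @param causal_chrom,causal_pos Location of the planted causal variant.
#' @param causal_gene Gene symbol assigned to the causal variant.
#' @param causal_cds_pos Coding-sequence position of the causal change.
#' @param shared_segment_bp Length of the ancestral haplotype segment,
#'   centred on the causal site, copied identically into one founder
#'   haplotype of each family.
#' @param damaging_prob_causal,damaging_prob_neutral Per-tool probability
#'   that a simulated predictor score is in its damaging range, for the
#'   causal variant and for neutral variants respectively.
#' @param pathogenic_flag_rate Fraction of frequency-table records flagged
#'   as reported pathogenic.
#' @param db_missing_rate Fraction of sites absent from the frequency
#'   table (no frequency information).
#' @param n_controls Number of unrelated control individuals.
#' @param n_control_chromosomes Number of control chromosomes screened for
#'   the causal allele.
#' @param n_str_markers Number of STR markers around the causal locus.
#' @param str_span_bp Span of the STR marker panel in bp.
#' @param rejection_cap Maximum gene-drop attempts per family when forcing
#'   the proband homozygous for the ancestral haplotype.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_variants_per_chrom = 900L,
                       chrom_lengths = c(chr1 = 110e6, chr2 = 90e6, chr16 = 90e6),
                       freq_range = c(0.01, 0.5),
                       rare_fraction = 0.15,
                       rare_range = c(0.001, 0.01),
                       recombination_rate = 1.0,
                       region_class_probs = c(exonic = 0.85, splice = 0.03,
                                              intronic = 0.08, UTR = 0.03,
                                              intergenic = 0.01),
                       effect_class_probs = c(nonsynonymous_SNV = 0.40,
                                              synonymous = 0.45,
                                              stopgain = 0.02,
                                              stoploss = 0.01,
                                              frameshift_indel = 0.05,
                                              nonframeshift_indel = 0.07),
                       causal_chrom = "chr16",
                       causal_pos = 4600000L,
                       causal_gene = "PAM16",
                       causal_cds_pos = 226L,
                       shared_segment_bp = 4e6,
                       damaging_prob_causal = 0.9,
                       damaging_prob_neutral = 0.1,
                       pathogenic_flag_rate = 0.01,
                       db_missing_rate = 0.03,
                       n_controls = 14L,
                       n_control_chromosomes = 550L,
                       n_str_markers = 12L,
                       str_span_bp = 8.7e6,
                       rejection_cap = 10000L) {
  cfg <- as.list(environment())
  if (abs(sum(region_class_probs) - 1) > 1e-8) {
    stop("region_class_probs must sum to 1")
  }
  if (abs(sum(effect_class_probs) - 1) > 1e-8) {
    stop("effect_class_probs must sum to 1")
  }
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (!(causal_chrom %in% names(chrom_lengths))) {
    stop("causal_chrom not among chrom_lengths")
  }
  if (causal_pos < 1 || causal_pos > chrom_lengths[[causal_chrom]]) {
    stop("causal_pos outside its chromosome")
  }
  if (any(freq_range < 0) || any(freq_range > 1) ||
      freq_range[1] > freq_range[2]) {
    stop("invalid freq_range")
  }
  if (rare_fraction < 0 || rare_fraction > 1) stop("invalid rare_fraction")
  structure(cfg, class = "sim_config")
}

# Fixed labelled substreams off the master seed: adding a stage never
# perturbs earlier draws, and distinct labels never collide across seeds
# (offsets differ by < 7919).
substream_seed <- function(seed, label) {
  offsets <- c(sites = 101L, annotations = 211L, strs = 223L,
               founders_F1 = 307L, founders_F2 = 311L,
               ancestral = 401L, drop_F1 = 409L, drop_F2 = 419L,
               controls = 431L, control_chroms = 433L)
  if (!(label %in% names(offsets))) stop("unknown substream label: ", label)
  as.integer((as.double(seed) * 7919 + offsets[[label]]) %% 2147483629)
}

#' Built-in consanguineous family pedigree
#'
#' A four-generation pedigree in which the proband's parents are first
#' cousins (sharing one outbred grandparental couple), so the proband's
#' inbreeding coefficient is F = 1/16. The shared great-grandfather
#' (`<fam>-I.1`) is the loop founder on whose haplotype the causal variant
#' is planted.
#'
#' @param fam Family label prefix (e.g. `"F1"`).
#' @return A `pedigree` with attributes `proband` and `loop_founder`.
#' @export
family_pedigree <- function(fam = "F2") {
  p <- function(x) paste0(fam, "-", x)
  ped <- pedigree(
    id = p(c("I.1", "I.2", "II.1", "II.2", "II.3", "II.4",
             "III.1", "III.2", "IV.2", "IV.3")),
    father = c(NA, NA, NA, p("I.1"), p("I.1"), NA,
               p("II.2"), p("II.4"), p("III.1"), p("III.1")),
    mother = c(NA, NA, NA, p("I.2"), p("I.2"), NA,
               p("II.1"), p("II.3"), p("III.2"), p("III.2")),
    sex = c("male", "female", "female", "male", "female", "male",
            "male", "female", "male", "female"),
    affected = c(rep("unaffected", 8), "unaffected", "affected"),
    family_id = fam
  )
  attr(ped, "proband") <- p("IV.3")
  attr(ped, "loop_founder") <- p("I.1")
  ped
}

# Draw a per-site alternate allele frequency from the configured spectrum.
sample_site_freqs <- function(config, n) {
  rare <- stats::runif(n) < config$rare_fraction
  f <- stats::runif(n, config$freq_range[1], config$freq_range[2])
  f[rare] <- stats::runif(sum(rare), config$rare_range[1],
                          config$rare_range[2])
  f
}

#' Simulate the shared variant-site table
#'
#' Positions, ref/alt alleles and population frequencies are drawn once
#' and shared by both families and the control panel (one population).
#' The causal site is injected at its configured position with population
#' frequency 0 (it exists only on the planted founder haplotype).
#'
#' @param config A `sim_config`.
#' @return Data frame: chrom, pos, ref, alt, freq, in_db, pathogenic,
#'   is_causal, key.
#' @export
simulate_sites <- function(config) {
  set.seed(substream_seed(config$seed, "sites"))
  bases <- c("A", "C", "G", "T")
  chroms <- names(config$chrom_lengths)
  out <- lapply(chroms, function(ch) {
    pos <- sort(sample.int(as.integer(config$chrom_lengths[[ch]]),
                           config$n_variants_per_chrom))
    if (ch == config$causal_chrom) {
      pos <- sort(unique(c(pos, as.integer(config$causal_pos))))
    }
    n <- length(pos)
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, out)
  sites$freq <- sample_site_freqs(config, nrow(sites))
  sites$in_db <- stats::runif(nrow(sites)) >= config$db_missing_rate
  sites$pathogenic <- stats::runif(nrow(sites)) < config$pathogenic_flag_rate
  causal <- sites$chrom == config$causal_chrom &
    sites$pos == config$causal_pos
  sites$ref[causal] <- "A"
  sites$alt[causal] <- "G"
  sites$freq[causal] <- 0
  sites$in_db[causal] <- FALSE
  sites$pathogenic[causal] <- FALSE
  sites$is_causal <- causal
  rownames(sites) <- NULL
  sites$key <- variant_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  sites
}

#' Simulate the variant annotation table
#'
#' Region and effect classes follow the configured probabilities;
#' predictor scores (SIFT-like, PolyPhen-like, PROVEAN-like and a
#' categorical caller) fall in their damaging ranges with probability
#' `damaging_prob_causal` for the causal variant and
#' `damaging_prob_neutral` otherwise, independently per tool.
#'
#' @param config A `sim_config`.
#' @param sites Site table from [simulate_sites()].
#' @return Annotation data frame keyed like `sites`.
#' @export
simulate_annotations <- function(config, sites) {
  set.seed(substream_seed(config$seed, "annotations"))
  n <- nrow(sites)
  region <- sample(names(config$region_class_probs), n, replace = TRUE,
                   prob = config$region_class_probs)
  effect <- rep("other", n)
  coding <- region %in% c("exonic", "splice")
  effect[coding] <- sample(names(config$effect_class_probs), sum(coding),
                           replace = TRUE, prob = config$effect_class_probs)
  cds_pos <- rep(NA_integer_, n)
  cds_pos[region == "exonic"] <- sample.int(1500L, sum(region == "exonic"),
                                            replace = TRUE)
  gene <- paste0(sites$chrom, "_g",
                 stats::ave(seq_len(n), sites$chrom,
                            FUN = function(i) (seq_along(i) - 1) %/% 4 + 1))
  p_dmg <- ifelse(sites$is_causal, config$damaging_prob_causal,
                  config$damaging_prob_neutral)
  dmg <- function() stats::runif(n) < p_dmg
  sift <- ifelse(dmg(), stats::runif(n, 0, 0.0499),
                 stats::runif(n, 0.05, 1))
  polyphen2 <- ifelse(dmg(), stats::runif(n, 0.501, 1),
                      stats::runif(n, 0, 0.5))
  provean <- ifelse(dmg(), stats::runif(n, -8, -2.5),
                    stats::runif(n, -2.49, 3))
  mutation_taster <- ifelse(dmg(), "disease_causing", "polymorphism")
  ann <- data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    gene = gene, region_class = region, effect_class = effect,
    cds_pos = cds_pos, sift = sift, polyphen2 = polyphen2,
    provean = provean, mutation_taster = mutation_taster,
    stringsAsFactors = FALSE
  )
  ci <- which(sites$is_causal)
  if (length(ci) == 1) {
    ann$gene[ci] <- config$causal_gene
    ann$region_class[ci] <- "exonic"
    ann$effect_class[ci] <- "nonsynonymous_SNV"
    ann$cds_pos[ci] <- as.integer(config$causal_cds_pos)
  }
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann
}

#' Simulate the STR marker panel
#'
#' Markers are evenly spaced over `str_span_bp` centred on the causal
#' locus, each with its own allele ladder (integer repeat labels) and
#' population allele frequencies.
#'
#' @param config A `sim_config`.
#' @return List with `markers` (marker, chrom, position) and `ladders`
#'   (per-marker data frame of allele, freq).
#' @export
simulate_str_markers <- function(config) {
  set.seed(substream_seed(config$seed, "strs"))
  m <- config$n_str_markers
  half <- config$str_span_bp / 2
  pos <- round(seq(config$causal_pos - half, config$causal_pos + half,
                   length.out = m))
  pos <- pmax(1, pmin(pos, config$chrom_lengths[[config$causal_chrom]]))
  markers <- data.frame(
    marker = sprintf("STR%02d", seq_len(m)),
    chrom = config$causal_chrom,
    position = as.integer(pos),
    stringsAsFactors = FALSE
  )
  ladders <- lapply(seq_len(m), function(i) {
    k <- sample(6:10, 1)
    base <- sample(100:260, 1)
    alleles <- base + 2L * (0:(k - 1))
    w <- stats::runif(k)
    data.frame(allele = alleles, freq = w / sum(w))
  })
  names(ladders) <- markers$marker
  list(markers = markers, ladders = ladders)
}

# Combined locus grid per chromosome: variant sites plus STR marker
# positions, sorted, so one meiosis realization governs both.
build_loci <- function(sites, strs = NULL) {
  var_df <- data.frame(chrom = sites$chrom, pos = sites$pos, type = "var",
                       row = seq_len(nrow(sites)), stringsAsFactors = FALSE)
  if (!is.null(strs)) {
    str_df <- data.frame(chrom = strs$markers$chrom,
                         pos = strs$markers$position, type = "str",
                         row = seq_len(nrow(strs$markers)),
                         stringsAsFactors = FALSE)
    var_df <- rbind(var_df, str_df)
  }
  split_df <- split(var_df, var_df$chrom)
  lapply(split_df, function(d) d[order(d$pos, d$type), , drop = FALSE])
}

#' Sample founder haplotypes
#'
#' Each founder receives two haplotypes per chromosome; the allele at each
#' variant site is drawn independently per haplotype with the site's
#' population frequency, and STR alleles are drawn from each marker's
#' ladder. Every founder chromosome copy carries a globally unique integer
#' origin label, the substrate for identity-by-descent bookkeeping.
#'
#' @param config A `sim_config`.
#' @param ped A `pedigree`.
#' @param sites Site table from [simulate_sites()].
#' @param strs Optional STR panel from [simulate_str_markers()].
#' @return An object of class `founder_pool`.
#' @export
sample_founder_haplotypes <- function(config, ped, sites, strs = NULL) {
  fnd <- sort(founders(ped))
  labels <- data.frame(
    label = seq_len(2L * length(fnd)),
    id = rep(fnd, each = 2),
    copy = rep(1:2, length(fnd)),
    stringsAsFactors = FALSE
  )
  loci <- build_loci(sites, strs)
  alleles <- lapply(loci, function(d) {
    mat <- matrix(NA_real_, nrow = nrow(labels), ncol = nrow(d))
    vsel <- d$type == "var"
    freqs <- sites$freq[d$row[vsel]]
    for (l in labels$label) {
      mat[l, vsel] <- stats::rbinom(sum(vsel), 1L, freqs)
    }
    ssel <- which(d$type == "str")
    for (j in ssel) {
      ladder <- strs$ladders[[d$row[j]]]
      mat[, j] <- sample(ladder$allele, nrow(labels), replace = TRUE,
                         prob = ladder$freq)
    }
    mat
  })
  structure(list(labels = labels, loci = loci, alleles = alleles,
                 family = family_id(ped)),
            class = "founder_pool")
}

# One meiosis on a chromosome: Haldane model, crossover count Poisson with
# mean the genetic length in Morgans, breakpoints uniform, random start
# phase. hapmat is the parent's 2 x n label matrix at the locus grid.
meiosis <- function(hapmat, pos, chrom_len, rate_cM_per_Mb) {
  genetic_length <- chrom_len / 1e6 * rate_cM_per_Mb / 100
  k <- stats::rpois(1L, genetic_length)
  start <- sample.int(2L, 1L)
  if (k == 0L) return(hapmat[start, ])
  breaks <- sort(stats::runif(k, 0, chrom_len))
  src <- (start - 1L + findInterval(pos, breaks)) %% 2L + 1L
  out <- hapmat[1L, ]
  sel <- src == 2L
  out[sel] <- hapmat[2L, sel]
  out
}

#' Gene-drop founder haplotypes through a pedigree
#'
#' Transmits founder origin labels down the pedigree: each non-founder
#' inherits one recombinant haplotype per parent. Autozygosity is directly
#' readable wherever an individual's two labels coincide.
#'
#' @param ped A validated `pedigree`.
#' @param pool A `founder_pool` for this pedigree.
#' @param config A `sim_config` (recombination rate and chromosome
#'   lengths).
#' @return An object of class `gene_drop`: per individual, per chromosome,
#'   a 2 x n integer matrix of origin labels over the locus grid (row 1
#'   paternal, row 2 maternal).
#' @export
gene_drop <- function(ped, pool, config) {
  ord <- ped_topo_order(ped, strict = TRUE)
  father <- stats::setNames(ped$father, ped$id)
  mother <- stats::setNames(ped$mother, ped$id)
  chroms <- names(pool$loci)
  lab <- vector("list", length(ord))
  names(lab) <- ord
  founder_label <- function(id, copy) {
    pool$labels$label[pool$labels$id == id & pool$labels$copy == copy]
  }
  for (id in ord) {
    f <- father[[id]]; m <- mother[[id]]
    lab[[id]] <- lapply(chroms, function(ch) {
      n <- nrow(pool$loci[[ch]])
      if (is.na(f)) {
        rbind(rep(founder_label(id, 1L), n), rep(founder_label(id, 2L), n))
      } else {
        pos <- pool$loci[[ch]]$pos
        len <- config$chrom_lengths[[ch]]
        rbind(
          meiosis(lab[[f]][[ch]], pos, len, config$recombination_rate),
          meiosis(lab[[m]][[ch]], pos, len, config$recombination_rate)
        )
      }
    })
    names(lab[[id]]) <- chroms
  }
  structure(list(labels = lab, loci = pool$loci, family = pool$family),
            class = "gene_drop")
}

#' Autozygous genome fraction of an individual
#'
#' Fraction of locus-grid positions at which the individual's two origin
#' labels coincide (both alleles identical by descent). Its expectation
#' equals the pedigree inbreeding coefficient.
#'
#' @param drop A `gene_drop`.
#' @param id Individual id.
#' @return Proportion in \\[0, 1\\].
#' @export
autozygous_fraction <- function(drop, id) {
  labs <- drop$labels[[id]]
  if (is.null(labs)) stop("unknown individual id: ", id)
  eq <- unlist(lapply(labs, function(m) m[1, ] == m[2, ]))
  mean(eq)
}

# Resolve alleles for one individual on one chromosome from origin labels.
alleles_at <- function(drop, pool, id, chrom) {
  labs <- drop$labels[[id]][[chrom]]
  n <- ncol(labs)
  a1 <- pool$alleles[[chrom]][cbind(labs[1, ], seq_len(n))]
  a2 <- pool$alleles[[chrom]][cbind(labs[2, ], seq_len(n))]
  rbind(a1, a2)
}

#' Genotype matrix realized by a gene drop
#'
#' @param drop A `gene_drop`.
#' @param pool The `founder_pool` the drop was made from.
#' @param sites Site table from [simulate_sites()].
#' @param ids Individuals to include (default: all in the drop).
#' @return A `genotype_matrix` over the variant sites.
#' @export
drop_genotypes <- function(drop, pool, sites, ids = names(drop$labels)) {
  geno <- matrix(NA_integer_, nrow = nrow(sites), ncol = length(ids),
                 dimnames = list(NULL, ids))
  for (ch in names(pool$loci)) {
    d <- pool$loci[[ch]]
    vsel <- d$type == "var"
    rows <- d$row[vsel]
    for (id in ids) {
      al <- alleles_at(drop, pool, id, ch)
      geno[rows, id] <- as.integer(al[1, vsel] + al[2, vsel])
    }
  }
  genotype_matrix(sites[, c("chrom", "pos", "ref", "alt")], geno)
}

#' STR genotypes realized by a gene drop
#'
#' @param drop A `gene_drop`.
#' @param pool The `founder_pool` the drop was made from.
#' @param strs STR panel from [simulate_str_markers()].
#' @param ids Individuals to include.
#' @return Long data frame: marker, chrom, position, sample, allele1,
#'   allele2 (allele1 <= allele2; the pair is unordered).
#' @export
drop_str_genotypes <- function(drop, pool, strs, ids = names(drop$labels)) {
  ch <- strs$markers$chrom[1]
  d <- pool$loci[[ch]]
  ssel <- which(d$type == "str")
  out <- lapply(ids, function(id) {
    al <- alleles_at(drop, pool, id, ch)
    a1 <- al[1, ssel]; a2 <- al[2, ssel]
    data.frame(
      marker = strs$markers$marker[d$row[ssel]],
      chrom = ch,
      position = strs$markers$position[d$row[ssel]],
      sample = id,
      allele1 = as.integer(pmin(a1, a2)),
      allele2 = as.integer(pmax(a1, a2)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Plant the causal founder mutation and force recessive segregation
#'
#' Writes an identical ancestral haplotype segment (alternate allele at
#' the causal site plus flanking variant and STR alleles) onto one founder
#' haplotype of each family -- the loop founder's first copy -- then
#' gene-drops each family with rejection until its proband carries two
#' copies of that ancestral segment (homozygous by descent) while both
#' parents are heterozygous carriers. Rejection sampling preserves the
#' correct identity-by-descent tract structure around the causal site.
#'
#' @param config A `sim_config`.
#' @param peds Named list of two pedigrees (from [family_pedigree()]).
#' @param pools Named list of matching `founder_pool`s.
#' @param sites Site table.
#' @param strs STR panel.
#' @return List with modified `pools`, accepted `drops`, per-family
#'   `rejections`, the ancestral `window` (start, end) and `anc_labels`.
#' @export
plant_causal_variant <- function(config, peds, pools, sites, strs) {
  ch <- config$causal_chrom
  window <- c(max(1, config$causal_pos - config$shared_segment_bp / 2),
              min(config$chrom_lengths[[ch]],
                  config$causal_pos + config$shared_segment_bp / 2))

  set.seed(substream_seed(config$seed, "ancestral"))
  d <- pools[[1]]$loci[[ch]]
  in_win <- d$pos >= window[1] & d$pos <= window[2]
  anc <- rep(NA_real_, nrow(d))
  vsel <- in_win & d$type == "var"
  anc[vsel] <- stats::rbinom(sum(vsel), 1L, sites$freq[d$row[vsel]])
  anc[vsel & d$pos == config$causal_pos] <- 1
  ssel <- which(in_win & d$type == "str")
  for (j in ssel) {
    ladder <- strs$ladders[[d$row[j]]]
    anc[j] <- sample(ladder$allele, 1, prob = ladder$freq)
  }
  causal_idx <- which(d$type == "var" & d$pos == config$causal_pos)

  drops <- list(); rejections <- integer(); anc_labels <- integer()
  for (famname in names(peds)) {
    ped <- peds[[famname]]
    pool <- pools[[famname]]
    anc_id <- attr(ped, "loop_founder")
    lbl <- pool$labels$label[pool$labels$id == anc_id & pool$labels$copy == 1]
    pool$alleles[[ch]][lbl, in_win] <- anc[in_win]
    pools[[famname]] <- pool

    proband <- attr(ped, "proband")
    trio <- extract_trio(ped, proband)
    set.seed(substream_seed(config$seed, paste0("drop_", family_id(ped))))
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > config$rejection_cap) {
        stop("rejection cap exceeded while planting the causal variant in ",
             famname, "; consider a larger autozygous target segment")
      }
      dr <- gene_drop(ped, pool, config)
      pl <- dr$labels[[proband]][[ch]][, causal_idx]
      if (!all(pl == lbl)) next
      fl <- dr$labels[[trio$father]][[ch]][, causal_idx]
      ml <- dr$labels[[trio$mother]][[ch]][, causal_idx]
      if (sum(fl == lbl) == 1L && sum(ml == lbl) == 1L) break
    }
    drops[[famname]] <- dr
    rejections[famname] <- tries - 1L
    anc_labels[famname] <- lbl
  }
  list(pools = pools, drops = drops, rejections = rejections,
       window = window, anc_labels = anc_labels)
}

#' Simulate a complete two-family study bundle
#'
#' Runs the whole generator: shared site/annotation/STR panels, founder
#' haplotypes for two first-cousin-union families, causal-variant planting
#' with rejection gene-dropping, an unrelated control panel, and the
#' frequency table (causal variant absent). Family F2 is "sequenced" as a
#' trio (proband plus parents); family F1 proband-only, mirroring the
#' emulated study design.
#'
#' @param config A `sim_config`.
#' @return An object of class `sim_bundle`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  peds <- list(F1 = family_pedigree("F1"), F2 = family_pedigree("F2"))
  sites <- simulate_sites(config)
  annotations <- simulate_annotations(config, sites)
  strs <- simulate_str_markers(config)

  pools <- lapply(peds, function(ped) {
    set.seed(substream_seed(config$seed, paste0("founders_", family_id(ped))))
    sample_founder_haplotypes(config, ped, sites, strs)
  })
  planted <- plant_causal_variant(config, peds, pools, sites, strs)

  vcf_samples <- list(F1 = attr(peds$F1, "proband"),
                      F2 = c(attr(peds$F2, "proband"),
                             extract_trio(peds$F2, attr(peds$F2, "proband"))$father,
                             extract_trio(peds$F2, attr(peds$F2, "proband"))$mother))
  genotypes_full <- lapply(names(peds), function(f) {
    drop_genotypes(planted$drops[[f]], planted$pools[[f]], sites)
  })
  names(genotypes_full) <- names(peds)
  genotypes <- lapply(names(peds), function(f) {
    subset_samples(genotypes_full[[f]], vcf_samples[[f]])
  })
  names(genotypes) <- names(peds)
  str_genotypes <- do.call(rbind, lapply(names(peds), function(f) {
    drop_str_genotypes(planted$drops[[f]], planted$pools[[f]], strs)
  }))

  set.seed(substream_seed(config$seed, "controls"))
  ctrl_ids <- sprintf("CTRL%02d", seq_len(config$n_controls))
  ctrl_geno <- vapply(ctrl_ids, function(id) {
    as.integer(stats::rbinom(nrow(sites), 2L, sites$freq))
  }, integer(nrow(sites)))
  control_genotypes <- genotype_matrix(
    sites[, c("chrom", "pos", "ref", "alt")], ctrl_geno)
  control_panel <- build_control_panel(control_genotypes)

  set.seed(substream_seed(config$seed, "control_chroms"))
  causal_freq <- sites$freq[sites$is_causal]
  control_chrom_alt <- stats::rbinom(1L, config$n_control_chromosomes,
                                     causal_freq)

  freq_table <- sites[!sites$is_causal,
                      c("chrom", "pos", "ref", "alt", "freq", "pathogenic")]
  freq_table$freq[!sites$in_db[!sites$is_causal]] <- NA_real_
  rownames(freq_table) <- NULL

  structure(list(
    config = config, peds = peds, sites = sites, annotations = annotations,
    strs = strs, genotypes = genotypes, genotypes_full = genotypes_full,
    str_genotypes = str_genotypes, freq_table = freq_table,
    control_genotypes = control_genotypes, control_panel = control_panel,
    drops = planted$drops, vcf_samples = vcf_samples,
    causal = list(chrom = config$causal_chrom, pos = config$causal_pos,
                  key = sites$key[sites$is_causal],
                  gene = config$causal_gene),
    rejections = planted$rejections, window = planted$window,
    control_chrom_alt = control_chrom_alt
  ), class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("Simulated consanguineous-exome bundle (seed", x$config$seed, ")\n")
  cat(" ", nrow(x$sites), "variant sites on",
      length(x$config$chrom_lengths), "chromosomes\n")
  cat("  causal:", x$causal$key, "in", x$causal$gene, "\n")
  cat("  rejection gene-drops:",
      paste(names(x$rejections), x$rejections, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Emits every input file the analysis pipeline consumes: per-family VCF
#' (sequenced samples only), annotation TSV, frequency table TSV (causal
#' variant absent), control-panel TSV, PED files, STR marker and genotype
#' TSVs, and a YAML manifest. Output is byte-identical across runs with
#' equal seed.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
emit_dataset <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  paths <- c(
    vcf_f1 = fp("f1.vcf"), vcf_f2 = fp("f2.vcf"),
    ped_f1 = fp("f1.ped"), ped_f2 = fp("f2.ped"),
    annotations = fp("annotations.tsv"),
    frequencies = fp("frequencies.tsv"),
    control_panel = fp("control_panel.tsv"),
    str_markers = fp("str_markers.tsv"),
    str_genotypes = fp("str_genotypes.tsv"),
    manifest = fp("manifest.yaml")
  )
  observed <- function(gm) {
    alt_count <- rowSums(gm$geno, na.rm = TRUE)
    gm_keep <- gm
    gm_keep$sites <- gm$sites[alt_count > 0, , drop = FALSE]
    gm_keep$geno <- gm$geno[alt_count > 0, , drop = FALSE]
    gm_keep
  }
  write_vcf(observed(bundle$genotypes$F1), paths[["vcf_f1"]])
  write_vcf(observed(bundle$genotypes$F2), paths[["vcf_f2"]])
  write_ped(bundle$peds$F1, paths[["ped_f1"]])
  write_ped(bundle$peds$F2, paths[["ped_f2"]])

  ann <- bundle$annotations
  ann_out <- ann[, c("chrom", "pos", "ref", "alt", "gene", "region_class",
                     "effect_class", "cds_pos", "sift", "polyphen2",
                     "provean", "mutation_taster")]
  for (col in c("sift", "polyphen2", "provean")) {
    ann_out[[col]] <- sprintf("%.6g", ann_out[[col]])
  }
  write_tsv(ann_out, paths[["annotations"]])

  ft <- bundle$freq_table
  ft$freq <- ifelse(is.na(ft$freq), "NA", sprintf("%.6g", ft$freq))
  ft$pathogenic <- ifelse(ft$pathogenic, "TRUE", "FALSE")
  write_tsv(ft, paths[["frequencies"]])

  panel_df <- key_to_fields(bundle$control_panel$keys)
  write_tsv(panel_df, paths[["control_panel"]])

  write_tsv(bundle$strs$markers, paths[["str_markers"]])
  write_tsv(bundle$str_genotypes, paths[["str_genotypes"]])

  manifest <- list(
    seed = bundle$config$seed,
    files = as.list(basename(paths[setdiff(names(paths), "manifest")])),
    truth = list(causal_key = bundle$causal$key,
                 causal_gene = bundle$causal$gene,
                 rejections = as.list(bundle$rejections),
                 control_chromosomes = bundle$config$n_control_chromosomes,
                 causal_alt_in_control_chromosomes = bundle$control_chrom_alt)
  )
  writeLines(yaml::as.yaml(manifest), paths[["manifest"]])
  invisible(paths)
}

# Deterministic TSV writer (no quoting, no scientific notation for ints).
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, scientific = FALSE,
                                                trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
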