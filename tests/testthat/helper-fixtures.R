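# Shared fixtures and independent oracles, all built in code.

trio_ped <- function() {
  pedigree(
    id = c("dad", "mum", "kid"),
    father = c(NA, NA, "dad"),
    mother = c(NA, NA, "mum"),
    sex = c("male", "female", "female"),
    affected = c("unaffected", "unaffected", "affected"),
    family_id = "TRIO"
  )
}

sib_ped <- function() {
  pedigree(
    id = c("dad", "mum", "s1", "s2", "kid"),
    father = c(NA, NA, "dad", "dad", "s1"),
    mother = c(NA, NA, "mum", "mum", "s2"),
    sex = c("male", "female", "male", "female", "female"),
    family_id = "SIB"
  )
}

# Fast simulation conditions for structural tests (not the study defaults).
small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             n_variants_per_chrom = 150L,
             chrom_lengths = c(chr16 = 60e6),
             causal_pos = 30e6,
             ...)
}

write_vcf_text <- function(lines, samples = "S1") {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, lines), path)
  path
}

# Random annotated candidate set for filter property tests.
random_candidates <- function(n, seed) {
  set.seed(seed)
  regions <- c("exonic", "splice", "intronic", "intergenic", "UTR", "other",
               NA)
  effects <- c("nonsynonymous_SNV", "stopgain", "stoploss",
               "frameshift_indel", "nonframeshift_indel", "synonymous",
               "other", NA)
  df <- data.frame(
    chrom = sample(c("chr1", "chr2", "chr16"), n, replace = TRUE),
    pos = sample.int(1e6, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  df <- df[df$ref != df$alt, , drop = FALSE]
  m <- nrow(df)
  df$region_class <- sample(regions, m, replace = TRUE)
  df$effect_class <- sample(effects, m, replace = TRUE)
  df$sift <- ifelse(runif(m) < 0.2, NA, runif(m))
  df$polyphen2 <- ifelse(runif(m) < 0.2, NA, runif(m))
  df$provean <- ifelse(runif(m) < 0.2, NA, runif(m, -8, 3))
  df$mutation_taster <- sample(c("disease_causing", "polymorphism", NA), m,
                               replace = TRUE)
  candidate_set(df, "random")
}

random_keyset <- function(cands, frac, seed, class) {
  set.seed(seed)
  keys <- sample(cands$key, ceiling(frac * nrow(cands)))
  structure(list(keys = sort(unique(keys))),
            class = c(class, "homsift_keyset"))
}

# Independent single-locus allele-dropping oracle for kinship: founders get
# globally unique allele labels, children sample one allele per parent.
# Returns per-replicate IBD sharing (mean over the four allele pairings).
kinship_mc <- function(ped, a, b, nrep = 1e5) {
  ids <- ped$id
  father <- setNames(ped$father, ids)
  mother <- setNames(ped$mother, ids)
  al1 <- list(); al2 <- list()
  done <- character()
  fidx <- 0L
  while (length(done) < length(ids)) {
    for (id in setdiff(ids, done)) {
      f <- father[[id]]; m <- mother[[id]]
      if (is.na(f)) {
        fidx <- fidx + 1L
        al1[[id]] <- rep.int(2L * fidx - 1L, nrep)
        al2[[id]] <- rep.int(2L * fidx, nrep)
        done <- c(done, id)
      } else if (f %in% done && m %in% done) {
        pick_f <- runif(nrep) < 0.5
        pick_m <- runif(nrep) < 0.5
        al1[[id]] <- ifelse(pick_f, al1[[f]], al2[[f]])
        al2[[id]] <- ifelse(pick_m, al1[[m]], al2[[m]])
        done <- c(done, id)
      }
    }
  }
  ((al1[[a]] == al1[[b]]) + (al1[[a]] == al2[[b]]) +
     (al2[[a]] == al1[[b]]) + (al2[[a]] == al2[[b]])) / 4
}

# Exhaustive-window ROH oracle: enumerate every feasible window (hom
# endpoints, het count within budget), keep containment-maximal ones, then
# apply the count/span thresholds.
roh_oracle <- function(pos, states, min_variants = 10L,
                       min_length_bp = 1e5, max_het = 0L) {
  keep <- !is.na(states)
  pos <- pos[keep]; states <- states[keep]
  n <- length(pos)
  het <- states == 1L
  wins <- list()
  for (i in seq_len(n)) {
    for (j in seq(i, length.out = n - i + 1L)) {
      if (het[i] || het[j]) next
      if (sum(het[i:j]) > max_het) next
      wins[[length(wins) + 1L]] <- c(i, j)
    }
  }
  if (length(wins) == 0) {
    return(data.frame(start = pos[0], end = pos[0],
                      n_variants = integer()))
  }
  maximal <- vapply(seq_along(wins), function(a) {
    !any(vapply(seq_along(wins), function(b) {
      b != a && wins[[b]][1] <= wins[[a]][1] && wins[[b]][2] >= wins[[a]][2]
    }, logical(1)))
  }, logical(1))
  wins <- wins[maximal]
  rows <- lapply(wins, function(w) {
    data.frame(start = pos[w[1]], end = pos[w[2]],
               n_variants = as.integer(w[2] - w[1] + 1L))
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_variants >= min_variants &
               (out$end - out$start) >= min_length_bp, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Whole-sequence translation-and-diff oracle for coding substitutions.
consequence_oracle <- function(cds, pos, alt) {
  mut <- cds
  substr(mut, pos, pos) <- alt
  tr <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X"))
  }
  p_ref <- tr(substr(cds, 1, 3 * (nchar(cds) %/% 3)))
  p_alt <- tr(substr(mut, 1, 3 * (nchar(mut) %/% 3)))
  diff <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  list(residue = if (length(diff)) diff[1] else NA_integer_,
       ref_aa = if (length(diff)) substr(p_ref, diff[1], diff[1]) else NA,
       alt_aa = if (length(diff)) substr(p_alt, diff[1], diff[1]) else NA)
}
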