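#' Candidate sets and the prioritization cascade
#'
#' A candidate set is a data frame of variant keys (plus any attached
#' annotation columns) in deterministic (chrom, pos, ref, alt) order, with
#' a stage label attribute. Every filter is contractive and idempotent.
#'
#' @param df Data frame with chrom, pos, ref, alt (and optionally key).
#' @param stage Stage label.
#' @return A `candidate_set` data frame.
#' @export
candidate_set <- function(df, stage = "input") {
  if (!("key" %in% names(df))) {
    df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  }
  df <- df[!duplicated(df$key), , drop = FALSE]
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("candidate_set", "data.frame"), stage = stage)
}

#' Stage label of a candidate set
#' @param cands A `candidate_set`.
#' @return The stage label.
#' @export
stage_label <- function(cands) attr(cands, "stage")

restage <- function(cands, keep, stage) {
  candidate_set(as.data.frame(cands)[keep, , drop = FALSE], stage)
}

#' Identity-by-descent trio filter
#'
#' Keeps exactly the variants homozygous for the alternate allele in the
#' proband and heterozygous in both parents -- the genotype configuration
#' implied by a recessive variant inherited identical-by-descent through
#' a consanguineous pedigree. A missing genotype in any trio member
#' disqualifies the variant (no inheritance is fabricated).
#'
#' @param gm A `genotype_matrix` containing all three samples.
#' @param proband,father,mother Sample ids.
#' @return A `candidate_set`.
#' @export
trio_ibd_filter <- function(gm, proband, father, mother) {
  for (s in c(proband, father, mother)) {
    if (!(s %in% gm$samples)) {
      stop("trio sample absent from genotype matrix: ", s)
    }
  }
  p <- gm$geno[, proband]; f <- gm$geno[, father]; m <- gm$geno[, mother]
  keep <- !is.na(p) & !is.na(f) & !is.na(m) & p == 2L & f == 1L & m == 1L
  candidate_set(gm$sites[keep, , drop = FALSE], "trio_ibd")
}

#' Proband-only homozygosity filter
#'
#' Family mode for a proband whose parents were not sequenced: keeps the
#' variants homozygous for the alternate allele in the proband. All
#' downstream filters are identical to trio mode.
#'
#' @param gm A `genotype_matrix`.
#' @param proband Sample id.
#' @return A `candidate_set`.
#' @export
proband_homozygous_filter <- function(gm, proband) {
  if (!(proband %in% gm$samples)) {
    stop("sample absent from genotype matrix: ", proband)
  }
  p <- gm$geno[, proband]
  keep <- !is.na(p) & p == 2L
  candidate_set(gm$sites[keep, , drop = FALSE], "proband_homozygous")
}

#' Attach annotations to a candidate set
#'
#' Left-joins the annotation table by variant key; unannotated variants
#' get NA classes (and are then dropped by the region filter).
#'
#' @param cands A `candidate_set`.
#' @param annotations Annotation data frame with a `key` column.
#' @return A `candidate_set` with annotation columns.
#' @export
attach_annotations <- function(cands, annotations) {
  ann <- annotations[, setdiff(names(annotations),
                               c("chrom", "pos", "ref", "alt")),
                     drop = FALSE]
  df <- merge(as.data.frame(cands), ann, by = "key", all.x = TRUE,
              sort = FALSE)
  candidate_set(df, stage_label(cands))
}

#' Region-class filter: exonic and splice-site variants
#' @param cands Annotated `candidate_set`.
#' @return A `candidate_set`.
#' @export
region_filter <- function(cands) {
  keep <- !is.na(cands$region_class) &
    cands$region_class %in% c("exonic", "splice")
  restage(cands, keep, "region")
}

#' Effect-class filter: protein-altering variants
#'
#' Keeps non-synonymous and nonsense single-nucleotide variants, stop-loss
#' changes and frame-shifting indels; splice-site variants are kept
#' regardless of effect class.
#'
#' @param cands Annotated `candidate_set`.
#' @return A `candidate_set`.
#' @export
effect_filter <- function(cands) {
  damaging_classes <- c("nonsynonymous_SNV", "stopgain", "stoploss",
                        "frameshift_indel")
  keep <- (!is.na(cands$effect_class) &
             cands$effect_class %in% damaging_classes) |
    (!is.na(cands$region_class) & cands$region_class == "splice")
  restage(cands, keep, "effect")
}

#' Frequency filter against the exclusion database
#'
#' Removes variants that are members of the common, non-pathogenic
#' exclusion database (see [build_exclusion_db()]).
#'
#' @param cands A `candidate_set`.
#' @param db An `exclusion_db`.
#' @return A `candidate_set`.
#' @export
frequency_filter <- function(cands, db) {
  restage(cands, !set_contains(db, cands$key), "frequency")
}

#' Control-panel filter
#'
#' Removes variants homozygous in at least one in-house control exome.
#'
#' @param cands A `candidate_set`.
#' @param panel A `control_panel`.
#' @return A `candidate_set`.
#' @export
control_filter <- function(cands, panel) {
  restage(cands, !set_contains(panel, cands$key), "control")
}

#' Cross-family intersection of candidate sets
#'
#' Variants present in both families' post-cascade candidate sets, matched
#' on full variant-key identity. Annotation columns are carried from the
#' first argument.
#'
#' @param set_a,set_b `candidate_set`s.
#' @return A `candidate_set`.
#' @export
cross_family_intersection <- function(set_a, set_b) {
  restage(set_a, set_a$key %in% set_b$key, "intersection")
}

#' Default predictor damaging-call thresholds
#'
#' SIFT-like damaging strictly below 0.05; PolyPhen-like above 0.5;
#' PROVEAN-like at or below -2.5; categorical callers damaging when equal
#' to `"disease_causing"`.
#'
#' @return Named list of per-tool comparison specs.
#' @export
consensus_thresholds <- function() {
  list(
    sift = list(cmp = "lt", cutoff = 0.05),
    polyphen2 = list(cmp = "gt", cutoff = 0.5),
    provean = list(cmp = "le", cutoff = -2.5),
    mutation_taster = list(cmp = "eq", cutoff = "disease_causing")
  )
}

#' Predictor-consensus ranking
#'
#' Scores each variant by the number of prediction tools calling it
#' damaging under per-tool thresholds, ranks by damaging-call count
#' (descending; ties keep variant order) and flags variants with at least
#' `k` damaging calls as prioritized. The default `k` is the number of
#' configured tools (unanimity). Absent scores never count as damaging.
#'
#' @param cands Annotated `candidate_set` carrying score columns named
#'   after the tools in `thresholds`.
#' @param thresholds Named list as from [consensus_thresholds()]; a tool
#'   name without a matching score column is a configuration error.
#' @param k Minimum damaging calls for the prioritized flag.
#' @return A `candidate_set` with `n_damaging` and `prioritized` columns,
#'   ranked by `n_damaging`.
#' @export
predictor_consensus <- function(cands, thresholds = consensus_thresholds(),
                                k = NULL) {
  unknown <- setdiff(names(thresholds), names(cands))
  if (length(unknown) > 0) {
    stop("unknown tool name(s) in thresholds: ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(k)) k <- length(thresholds)
  df <- as.data.frame(cands)
  n_dmg <- rep(0L, nrow(df))
  for (tool in names(thresholds)) {
    spec <- thresholds[[tool]]
    x <- df[[tool]]
    hit <- switch(spec$cmp,
                  lt = x < spec$cutoff,
                  le = x <= spec$cutoff,
                  gt = x > spec$cutoff,
                  ge = x >= spec$cutoff,
                  eq = x == spec$cutoff,
                  stop("unknown comparison in thresholds: ", spec$cmp))
    hit[is.na(hit)] <- FALSE
    n_dmg <- n_dmg + as.integer(hit)
  }
  df$n_damaging <- n_dmg
  df$prioritized <- n_dmg >= k
  ranked <- candidate_set(df, "consensus")
  ranked <- ranked[order(-ranked$n_damaging), , drop = FALSE]
  rownames(ranked) <- NULL
  structure(ranked, class = c("candidate_set", "data.frame"),
            stage = "consensus")
}

report_row <- function(family, stage, n_in, n_out) {
  data.frame(family = family, stage = stage, n_in = n_in, n_out = n_out,
             n_removed = n_in - n_out, stringsAsFactors = FALSE)
}

# Per-family cascade: inheritance filter, then region / effect /
# frequency / control, with one report row per stage.
family_cascade <- function(gm, trio, annotations, db, panel, family) {
  if (trio$mode == "trio") {
    c0 <- trio_ibd_filter(gm, trio$proband, trio$father, trio$mother)
    first_stage <- "trio_ibd"
  } else {
    c0 <- proband_homozygous_filter(gm, trio$proband)
    first_stage <- "proband_homozygous"
  }
  rep <- report_row(family, first_stage, nrow(gm$sites), nrow(c0))
  c0 <- attach_annotations(c0, annotations)
  c1 <- region_filter(c0)
  rep <- rbind(rep, report_row(family, "region", nrow(c0), nrow(c1)))
  c2 <- effect_filter(c1)
  rep <- rbind(rep, report_row(family, "effect", nrow(c1), nrow(c2)))
  c3 <- frequency_filter(c2, db)
  rep <- rbind(rep, report_row(family, "frequency", nrow(c2), nrow(c3)))
  c4 <- control_filter(c3, panel)
  rep <- rbind(rep, report_row(family, "control", nrow(c3), nrow(c4)))
  list(candidates = c4, pre_filter = c0, report = rep)
}

#' Run the full two-family prioritization cascade
#'
#' Applies, per family, the inheritance filter (trio identity-by-descent
#' where parents are available, proband homozygosity otherwise), then the
#' region, effect, frequency-database and control-panel filters; then the
#' cross-family intersection; then predictor-consensus ranking. The report
#' carries every stage count, plus informational rows for the raw shared
#' homozygous set (before and after the region filter), covering both
#' readings of a pre-intersection shared-variant count.
#'
#' @param gms Named list of `genotype_matrix`, one per family.
#' @param trios Named list of trio descriptors from [extract_trio()]
#'   (same names as `gms`).
#' @param annotations Annotation data frame with a `key` column.
#' @param db An `exclusion_db`.
#' @param panel A `control_panel`.
#' @param thresholds Predictor thresholds ([consensus_thresholds()]).
#' @param k Consensus count for the prioritized flag (default unanimity).
#' @return An object of class `cascade_result`: `candidates` (final ranked
#'   set), `report`, and `family_candidates`.
#' @export
run_cascade <- function(gms, trios, annotations, db, panel,
                        thresholds = consensus_thresholds(), k = NULL) {
  stopifnot(length(gms) == 2, identical(sort(names(gms)), sort(names(trios))))
  fams <- names(gms)
  per_family <- lapply(fams, function(f) {
    family_cascade(gms[[f]], trios[[f]], annotations, db, panel, f)
  })
  names(per_family) <- fams
  report <- do.call(rbind, lapply(per_family, `[[`, "report"))

  shared_pre <- cross_family_intersection(per_family[[1]]$pre_filter,
                                          per_family[[2]]$pre_filter)
  shared_pre_exonic <- region_filter(shared_pre)
  report <- rbind(report,
                  report_row("shared", "shared_homozygous",
                             nrow(per_family[[1]]$pre_filter),
                             nrow(shared_pre)),
                  report_row("shared", "shared_homozygous_exonic",
                             nrow(shared_pre), nrow(shared_pre_exonic)))

  inter <- cross_family_intersection(per_family[[1]]$candidates,
                                     per_family[[2]]$candidates)
  report <- rbind(report,
                  report_row("shared", "intersection",
                             nrow(per_family[[1]]$candidates), nrow(inter)))
  final <- predictor_consensus(inter, thresholds, k)
  rownames(report) <- NULL
  structure(list(candidates = final,
                 family_candidates = lapply(per_family, `[[`, "candidates"),
                 report = report),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Variant prioritization cascade\n")
  print.data.frame(x$report, row.names = FALSE)
  cat("final candidates:", nrow(x$candidates),
      "| prioritized:", sum(x$candidates$prioritized), "\n")
  invisible(x)
}
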