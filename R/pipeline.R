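#' Trio descriptor constrained to sequenced samples
#'
#' Selects trio mode when the proband's parents are both present in the
#' genotype matrix, otherwise falls back to proband-only mode (only the
#' parental-heterozygosity condition is dropped; all downstream filters
#' are identical).
#'
#' @param ped A `pedigree` with a `proband` attribute (or pass `proband`).
#' @param gm The family's `genotype_matrix`.
#' @param proband Proband id (default: the pedigree attribute).
#' @return A trio descriptor as from [extract_trio()].
#' @export
sequenced_trio <- function(ped, gm, proband = attr(ped, "proband")) {
  t <- extract_trio(ped, proband)
  if (t$mode == "trio" &&
      !all(c(t$father, t$mother) %in% gm$samples)) {
    t <- list(proband = t$proband, father = NA_character_,
              mother = NA_character_, mode = "proband_only")
  }
  t
}

#' Run the prioritization cascade on a simulated bundle
#'
#' Builds the exclusion database from the bundle's frequency table, takes
#' the bundle's control panel, and runs [run_cascade()] on the two
#' families' sequenced genotypes.
#'
#' @param bundle A `sim_bundle`.
#' @param thresholds,k Passed to [run_cascade()].
#' @return A `cascade_result`.
#' @export
prioritize_bundle <- function(bundle, thresholds = consensus_thresholds(),
                              k = NULL) {
  db <- build_exclusion_db(bundle$freq_table)
  trios <- lapply(names(bundle$peds), function(f) {
    sequenced_trio(bundle$peds[[f]], bundle$genotypes[[f]])
  })
  names(trios) <- names(bundle$peds)
  run_cascade(bundle$genotypes, trios, bundle$annotations, db,
              bundle$control_panel, thresholds, k)
}

#' Homozygosity mapping on a simulated bundle
#'
#' Calls runs of homozygosity for both probands and intersects them into
#' shared regions.
#'
#' @param bundle A `sim_bundle`.
#' @param ... ROH parameters passed to [call_roh()].
#' @return List with `roh` (both probands, row-bound) and `shared`.
#' @export
hommap_bundle <- function(bundle, ...) {
  roh <- do.call(rbind, lapply(names(bundle$peds), function(f) {
    call_roh(bundle$genotypes[[f]], attr(bundle$peds[[f]], "proband"), ...)
  }))
  list(roh = roh, shared = shared_regions(roh))
}

#' End-to-end planted-variant recovery across seeds
#'
#' For each seed: simulate a bundle, run the full cascade and the
#' homozygosity mapping, and record whether the planted causal variant is
#' in the final candidate set, whether it carries the prioritized
#' consensus flag, how many other candidates survive (false positives),
#' and whether a shared run-of-homozygosity region contains the planted
#' site.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param config_args Named list of [sim_config()] overrides (the seed is
#'   supplied per replicate).
#' @return Data frame with one row per seed: seed, recovered, prioritized,
#'   n_candidates, false_positives, roh_contains_causal,
#'   minimal_str_span_mb.
#' @export
evaluate_recovery <- function(seeds, config_args = list()) {
  rows <- lapply(seeds, function(s) {
    cfg <- do.call(sim_config, c(list(seed = as.integer(s)), config_args))
    bundle <- simulate_dataset(cfg)
    res <- prioritize_bundle(bundle)
    recovered <- bundle$causal$key %in% res$candidates$key
    prio <- recovered &&
      res$candidates$prioritized[res$candidates$key == bundle$causal$key]
    hm <- hommap_bundle(bundle)
    contains <- any(hm$shared$chrom == bundle$causal$chrom &
                      hm$shared$start <= bundle$causal$pos &
                      hm$shared$end >= bundle$causal$pos)
    probands <- vapply(bundle$peds, attr, character(1), "proband")
    msh <- minimal_shared_haplotype(bundle$str_genotypes, unname(probands),
                                    bundle$strs$markers)
    data.frame(
      seed = as.integer(s),
      recovered = recovered,
      prioritized = prio,
      n_candidates = nrow(res$candidates),
      false_positives = nrow(res$candidates) - as.integer(recovered),
      roh_contains_causal = contains,
      minimal_str_span_mb = if (is.null(msh$region)) NA_real_
                            else msh$region$span_mb
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
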