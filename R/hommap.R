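#' Call runs of homozygosity on one sample
#'
#' Scans position-sorted genotype calls per chromosome for maximal runs of
#' homozygous calls (hom ref or hom alt) containing at most `max_het`
#' heterozygous calls. Missing calls are skipped without breaking a run
#' and are not counted. Region boundaries are the positions of the first
#' and last homozygous variant in the run; a run is reported when it holds
#' at least `min_variants` (non-missing) variants and spans at least
#' `min_length_bp` (difference convention, end - start).
#'
#' @param gm A `genotype_matrix`.
#' @param sample Sample id.
#' @param min_variants Minimum non-missing calls per run (default 10).
#' @param min_length_bp Minimum span in bp (default 100,000 -- the
#'   reporting rule for shared regions).
#' @param max_het Maximum heterozygous calls tolerated inside a run
#'   (default 0: at exome variant density a single het is strong evidence
#'   against autozygosity).
#' @return Data frame of regions: chrom, start, end, n_variants, sample.
#' @export
call_roh <- function(gm, sample, min_variants = 10L, min_length_bp = 1e5,
                     max_het = 0L) {
  if (!(sample %in% gm$samples)) {
    stop("sample absent from genotype matrix: ", sample)
  }
  out <- lapply(split(seq_len(nrow(gm$sites)), gm$sites$chrom), function(i) {
    pos <- gm$sites$pos[i]
    states <- gm$geno[i, sample]
    r <- roh_scan(pos, states, min_variants, min_length_bp, max_het)
    if (nrow(r) > 0) r$chrom <- gm$sites$chrom[i][1]
    r
  })
  out <- do.call(rbind, out[vapply(out, nrow, integer(1)) > 0])
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_variants = integer())
  }
  out <- out[, c("chrom", "start", "end", "n_variants")]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$sample <- rep(sample, nrow(out))
  rownames(out) <- NULL
  out
}

#' ROH scan on a single chromosome
#'
#' Core scanner behind [call_roh()]: positions must be sorted ascending.
#' A window over the non-missing calls is feasible when it starts and ends
#' at homozygous calls and contains at most `max_het` heterozygous calls;
#' reported runs are the feasible windows maximal under containment that
#' meet the variant-count and span thresholds.
#'
#' @param pos Sorted integer positions.
#' @param states Genotype states (0/1/2, NA missing), same length.
#' @param min_variants,min_length_bp,max_het As in [call_roh()].
#' @return Data frame: start, end, n_variants.
#' @export
roh_scan <- function(pos, states, min_variants = 10L, min_length_bp = 1e5,
                     max_het = 0L) {
  if (is.unsorted(pos)) stop("genotypes must be position-sorted")
  keep <- !is.na(states)
  pos <- pos[keep]; states <- states[keep]
  n <- length(pos)
  empty <- data.frame(start = pos[0], end = pos[0],
                      n_variants = integer())
  if (n == 0) return(empty)
  het <- states == 1L
  chet <- cumsum(het)
  het_count <- function(i, j) chet[j] - chet[i] + het[i]
  # two-pointer: maximal feasible right end for each left end; jmax is
  # non-decreasing, so window i is containment-maximal iff it reaches
  # further right than window i-1 did
  res <- list(); nres <- 0L
  j <- 0L; prev_jmax <- 0L
  for (i in seq_len(n)) {
    if (het[i]) next  # runs start at homozygous calls
    if (j < i) j <- i
    while (j < n && het_count(i, j + 1L) <= max_het) j <- j + 1L
    jj <- j
    while (het[jj]) jj <- jj - 1L  # runs end at homozygous calls
    if (jj <= prev_jmax) next  # contained in an earlier window
    prev_jmax <- jj
    nv <- jj - i + 1L
    if (nv >= min_variants && (pos[jj] - pos[i]) >= min_length_bp) {
      nres <- nres + 1L
      res[[nres]] <- c(i, jj)
    }
  }
  if (nres == 0L) return(empty)
  m <- do.call(rbind, res)
  data.frame(start = pos[m[, 1]], end = pos[m[, 2]],
             n_variants = m[, 2] - m[, 1] + 1L)
}

#' Shared homozygous regions across samples
#'
#' Intersects per-sample ROH calls k-wise across all contributing samples
#' and keeps intersections spanning at least `min_shared_length_bp`
#' (difference convention). Every shared region is contained in each
#' contributing sample's own ROH.
#'
#' @param regions Data frame of ROH regions with a `sample` column (as
#'   returned by [call_roh()], rbind-ed across samples), or a list of such
#'   data frames.
#' @param min_shared_length_bp Minimum shared span (default 100,000, the
#'   "over 100 kb" reporting rule).
#' @return Data frame: chrom, start, end, length_bp, samples (comma-joined
#'   contributing ids), sorted by (chrom, start).
#' @export
shared_regions <- function(regions, min_shared_length_bp = 1e5) {
  if (is.list(regions) && !is.data.frame(regions)) {
    regions <- do.call(rbind, regions)
  }
  samples <- sort(unique(regions$sample))
  if (length(samples) < 2) stop("shared regions need ROH from >= 2 samples")
  grl <- lapply(samples, function(s) {
    r <- regions[regions$sample == s, , drop = FALSE]
    GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start, r$end))
  })
  inter <- Reduce(GenomicRanges::intersect, grl)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(inter)),
    start = GenomicRanges::start(inter),
    end = GenomicRanges::end(inter),
    stringsAsFactors = FALSE
  )
  df$length_bp <- df$end - df$start
  df <- df[df$length_bp >= min_shared_length_bp, , drop = FALSE]
  df$samples <- rep(paste(samples, collapse = ","), nrow(df))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Genomic region length and Mb rendering
#'
#' Length uses the difference convention (end - start), matching how the
#' source coordinates were reported; Mb renderings round half-up.
#'
#' @param start,end 1-based coordinates.
#' @param digits Decimal places of the Mb rendering (0 gives the integer
#'   "~N Mb" style).
#' @return List with `bp`, `mb` (numeric, rounded half-up) and `label`.
#' @export
region_length <- function(start, end, digits = 1) {
  bp <- end - start
  mb <- round_half_up(bp / 1e6, digits)
  list(bp = bp, mb = mb,
       label = paste0(format(mb, nsmall = digits, trim = TRUE), " Mb"))
}

# round() is banker's; printed region sizes use arithmetic half-up.
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Convert regions to BED (0-based half-open) and back
#'
#' Internal coordinates are 1-based closed; BED output shifts start by -1.
#' The converters are exact inverses.
#'
#' @param regions Data frame with chrom, start, end.
#' @return Data frame in the other convention.
#' @export
regions_to_bed <- function(regions) {
  data.frame(chrom = regions$chrom, start = regions$start - 1L,
             end = regions$end, stringsAsFactors = FALSE)
}

#' @rdname regions_to_bed
#' @export
bed_to_regions <- function(regions) {
  data.frame(chrom = regions$chrom, start = regions$start + 1L,
             end = regions$end, stringsAsFactors = FALSE)
}

str_pair <- function(str_df, sample_id, marker) {
  r <- str_df[str_df$sample == sample_id & str_df$marker == marker, ]
  if (nrow(r) != 1 || is.na(r$allele1) || is.na(r$allele2)) return(NULL)
  c(r$allele1, r$allele2)
}

#' Phase STR genotypes of a child against its parents
#'
#' For each marker, a child allele is assigned paternal origin exactly
#' when it occurs in the father's pair and the assignment is unique given
#' the mother's pair; when both orderings of the child's alleles are
#' compatible with the parents, the origins are unresolved. Markers whose
#' child genotype is incompatible with the parents are flagged as
#' Mendelian-inconsistent, never raised as errors.
#'
#' @param str_df Long STR genotype data frame (marker, chrom, position,
#'   sample, allele1, allele2).
#' @param child,father,mother Sample ids sharing the marker set.
#' @return Data frame in chromosomal position order: marker, chrom,
#'   position, paternal, maternal (NA when unresolved), resolved,
#'   mendelian_ok.
#' @export
phase_str_trio <- function(str_df, child, father, mother) {
  markers <- unique(str_df[, c("marker", "chrom", "position")])
  markers <- markers[order(markers$chrom, markers$position), , drop = FALSE]
  out <- lapply(seq_len(nrow(markers)), function(i) {
    mk <- markers$marker[i]
    base <- data.frame(marker = mk, chrom = markers$chrom[i],
                       position = markers$position[i],
                       paternal = NA_integer_, maternal = NA_integer_,
                       resolved = FALSE, mendelian_ok = TRUE,
                       stringsAsFactors = FALSE)
    cp <- str_pair(str_df, child, mk)
    fp <- str_pair(str_df, father, mk)
    mp <- str_pair(str_df, mother, mk)
    if (is.null(cp) || is.null(fp) || is.null(mp)) return(base)
    orderings <- list(cp, rev(cp))
    valid <- vapply(orderings, function(o) {
      o[1] %in% fp && o[2] %in% mp
    }, logical(1))
    if (!any(valid)) {
      base$mendelian_ok <- FALSE
    } else if (all(valid) && cp[1] != cp[2]) {
      # both assignments compatible and distinguishable: unresolved
    } else {
      o <- orderings[[which(valid)[1]]]
      base$paternal <- o[1]; base$maternal <- o[2]; base$resolved <- TRUE
    }
    base
  })
  do.call(rbind, out)
}

#' Minimal shared ancestral homozygous haplotype over STR markers
#'
#' Finds the maximal run of consecutive markers (in chromosomal order) at
#' which every patient is homozygous for the same allele -- the signature
#' of a founder mutation. Boundaries are reported as the first discordant
#' or heterozygous flanking marker on each side (the run's edge marker
#' when it touches the panel end); the span is computed between boundary
#' marker positions by the difference convention.
#'
#' @param str_df Long STR genotype data frame.
#' @param patients Sample ids of the affected individuals (>= 2).
#' @param markers Marker map (marker, chrom, position); defaults to the
#'   markers present in `str_df`.
#' @return List with `region` (chrom, start, end, span_bp, span_mb),
#'   `core_markers`, `boundary_markers`, and `shared_allele` per core
#'   marker; or a `message` diagnostic when no marker is shared
#'   homozygous.
#' @export
minimal_shared_haplotype <- function(str_df, patients, markers = NULL) {
  stopifnot(length(patients) >= 2)
  if (is.null(markers)) {
    markers <- unique(str_df[, c("marker", "chrom", "position")])
  }
  markers <- markers[order(markers$chrom, markers$position), , drop = FALSE]
  shared <- vapply(seq_len(nrow(markers)), function(i) {
    alleles <- vapply(patients, function(p) {
      pr <- str_pair(str_df, p, markers$marker[i])
      if (is.null(pr) || pr[1] != pr[2]) NA_real_ else as.numeric(pr[1])
    }, numeric(1))
    if (anyNA(alleles) || length(unique(alleles)) != 1) NA_real_
    else alleles[1]
  }, numeric(1))
  ok <- !is.na(shared)
  if (!any(ok)) {
    return(list(region = NULL,
                message = "no marker with shared homozygosity"))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i <- starts[best]; j <- ends[best]
  lb <- max(1L, i - 1L)
  rb <- min(nrow(markers), j + 1L)
  list(
    region = data.frame(
      chrom = markers$chrom[i],
      start = markers$position[lb],
      end = markers$position[rb],
      span_bp = markers$position[rb] - markers$position[lb],
      span_mb = round_half_up(
        (markers$position[rb] - markers$position[lb]) / 1e6, 1),
      stringsAsFactors = FALSE
    ),
    core_markers = markers$marker[i:j],
    boundary_markers = c(markers$marker[lb], markers$marker[rb]),
    shared_allele = stats::setNames(shared[i:j], markers$marker[i:j])
  )
}
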