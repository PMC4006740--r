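#' Construct a pedigree
#'
#' A pedigree is a data frame with one row per individual and columns
#' `id`, `father`, `mother`, `sex` and `affected`. Founders have `NA` for
#' both parent ids. Consanguinity loops (marriages between relatives) are
#' permitted; the parent-child relation itself must be acyclic.
#'
#' @param id Character vector of unique individual labels.
#' @param father,mother Character vectors of parent ids; `NA` or `"0"` means
#'   unknown/absent. An individual must have either both parents or neither.
#' @param sex One of `"male"`, `"female"`, `"unknown"` (recycled).
#' @param affected One of `"affected"`, `"unaffected"`, `"unknown"` (recycled).
#' @param family_id Family label attached as an attribute.
#' @return An object of class `pedigree` (a data frame).
#' @examples
#' trio <- pedigree(
#'   id = c("dad", "mum", "kid"),
#'   father = c(NA, NA, "dad"),
#'   mother = c(NA, NA, "mum"),
#'   sex = c("male", "female", "female"),
#'   affected = c("unaffected", "unaffected", "affected")
#' )
#' kinship(trio, "dad", "kid")
#' @export
pedigree <- function(id, father = NA_character_, mother = NA_character_,
                     sex = "unknown", affected = "unknown",
                     family_id = "FAM") {
  id <- as.character(id)
  n <- length(id)
  norm_parent <- function(x) {
    x <- rep_len(as.character(x), n)
    x[!is.na(x) & x == "0"] <- NA_character_
    x
  }
  df <- data.frame(
    id = id,
    father = norm_parent(father),
    mother = norm_parent(mother),
    sex = rep_len(as.character(sex), n),
    affected = rep_len(as.character(affected), n),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("pedigree", "data.frame"), family_id = family_id)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree", attr(x, "family_id"), "-", nrow(x), "individuals,",
      sum(is.na(x$father) & is.na(x$mother)), "founders\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Family id of a pedigree
#' @param ped A `pedigree`.
#' @return The family label.
#' @export
family_id <- function(ped) attr(ped, "family_id")

#' Founder ids of a pedigree
#' @param ped A `pedigree`.
#' @return Character vector of ids with no recorded parents.
#' @export
founders <- function(ped) ped$id[is.na(ped$father) & is.na(ped$mother)]

#' Validate pedigree structure
#'
#' Checks the structural invariants: unique ids, both-or-neither parents,
#' parent references resolving within the pedigree, father male / mother
#' female where sexes are known, and acyclicity of the parent-child
#' relation (loops through shared ancestors are fine; an individual being
#' its own ancestor is not).
#'
#' @param ped A `pedigree`.
#' @return Character vector of issues, empty when the pedigree is valid.
#'   Issues are returned, never raised.
#' @export
validate_pedigree <- function(ped) {
  issues <- character()
  dup <- unique(ped$id[duplicated(ped$id)])
  for (d in dup) issues <- c(issues, paste0("duplicate id: ", d))

  one_parent <- xor(is.na(ped$father), is.na(ped$mother))
  for (i in which(one_parent)) {
    issues <- c(issues, paste0("single parent: ", ped$id[i],
                               " has exactly one recorded parent"))
  }
  for (i in seq_len(nrow(ped))) {
    for (role in c("father", "mother")) {
      p <- ped[[role]][i]
      if (!is.na(p) && !(p %in% ped$id)) {
        issues <- c(issues, paste0("unresolved parent: ", ped$id[i],
                                   " references ", role, " ", p,
                                   " not in pedigree"))
      }
    }
  }
  sex_of <- stats::setNames(ped$sex, ped$id)
  for (i in seq_len(nrow(ped))) {
    f <- ped$father[i]; m <- ped$mother[i]
    if (!is.na(f) && f %in% ped$id && sex_of[[f]] == "female") {
      issues <- c(issues, paste0("sex conflict: father ", f, " of ",
                                 ped$id[i], " is recorded female"))
    }
    if (!is.na(m) && m %in% ped$id && sex_of[[m]] == "male") {
      issues <- c(issues, paste0("sex conflict: mother ", m, " of ",
                                 ped$id[i], " is recorded male"))
    }
  }
  ord <- ped_topo_order(ped, strict = FALSE)
  cyc <- attr(ord, "cyclic")
  for (cid in cyc) {
    issues <- c(issues, paste0("cycle: ", cid, " is its own ancestor"))
  }
  issues
}

# Topological order of individuals: founders first (sorted by id), then
# Kahn's algorithm over the parent->child relation with lexicographic
# tie-breaks so the evaluation order is deterministic. With strict = FALSE,
# ids trapped in a parent-cycle are reported via the "cyclic" attribute
# instead of an error.
ped_topo_order <- function(ped, strict = TRUE) {
  ids <- ped$id
  father <- stats::setNames(ped$father, ids)
  mother <- stats::setNames(ped$mother, ids)
  resolved_parent <- function(p, done) is.na(p) || !(p %in% ids) || p %in% done
  done <- character()
  remaining <- sort(ids)
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      resolved_parent(father[[i]], done) && resolved_parent(mother[[i]], done)
    }, logical(1))]
    if (length(ready) == 0) break
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining) > 0 && strict) {
    stop("pedigree contains a parental cycle involving: ",
         paste(remaining, collapse = ", "))
  }
  structure(done, cyclic = remaining)
}

#' Kinship matrix of a pedigree
#'
#' Computes the kinship coefficient phi(a, b) -- the probability that two
#' alleles sampled at random, one from each individual, are identical by
#' descent -- for every pair, by the classical tabular recursion: founders
#' are unrelated and non-inbred, phi(a, a) = (1 + F_a) / 2, and for a
#' non-founder b with b not an ancestor of a, phi(a, b) =
#' (phi(a, father_b) + phi(a, mother_b)) / 2. Individuals are processed in
#' topological order (founders first, lexicographic tie-breaks).
#'
#' @param ped A `pedigree` (must validate cleanly for parental structure).
#' @return Symmetric numeric matrix with id dimnames.
#' @export
kinship_matrix <- function(ped) {
  ord <- ped_topo_order(ped, strict = TRUE)
  n <- length(ord)
  K <- matrix(0, n, n, dimnames = list(ord, ord))
  father <- stats::setNames(ped$father, ped$id)
  mother <- stats::setNames(ped$mother, ped$id)
  for (i in seq_len(n)) {
    a <- ord[i]
    f <- father[[a]]; m <- mother[[a]]
    if (is.na(f) || is.na(m)) {
      K[a, a] <- 0.5
      # founder: unrelated to everyone processed so far
    } else {
      if (i > 1) {
        prev <- ord[seq_len(i - 1)]
        K[a, prev] <- 0.5 * (K[f, prev] + K[m, prev])
        K[prev, a] <- K[a, prev]
      }
      K[a, a] <- 0.5 * (1 + K[f, m])
    }
  }
  K
}

#' Kinship coefficient between two individuals
#'
#' @param ped A `pedigree`.
#' @param a,b Individual ids.
#' @return phi(a, b) in \\[0, 1\\].
#' @export
kinship <- function(ped, a, b) {
  for (x in c(a, b)) {
    if (!(x %in% ped$id)) stop("unknown individual id: ", x)
  }
  K <- kinship_matrix(ped)
  unname(K[a, b])
}

#' Inbreeding coefficient of an individual
#'
#' F_a is the kinship between a's parents: the probability that a's two
#' alleles at a locus are identical by descent. Founders (and children of
#' unrelated parents) have F = 0; the offspring of first cousins has
#' F = 1/16.
#'
#' @param ped A `pedigree`.
#' @param a Individual id.
#' @return F_a in \\[0, 1\\].
#' @export
inbreeding <- function(ped, a) {
  if (!(a %in% ped$id)) stop("unknown individual id: ", a)
  f <- ped$father[ped$id == a]
  m <- ped$mother[ped$id == a]
  if (is.na(f) || is.na(m)) return(0)
  kinship(ped, f, m)
}

#' Extract the sequenced trio around a proband
#'
#' Returns the proband with both parents when present (trio mode), or a
#' proband-only marker when the proband is a founder, selecting the
#' corresponding filtering mode downstream. Exactly one recorded parent
#' violates the pedigree invariant and is an error.
#'
#' @param ped A `pedigree`.
#' @param proband Proband id.
#' @return List with `proband`, `father`, `mother` (NA in proband-only
#'   mode) and `mode` (`"trio"` or `"proband_only"`).
#' @export
extract_trio <- function(ped, proband) {
  if (!(proband %in% ped$id)) stop("unknown individual id: ", proband)
  f <- ped$father[ped$id == proband]
  m <- ped$mother[ped$id == proband]
  if (xor(is.na(f), is.na(m))) {
    stop("individual ", proband,
         " has exactly one recorded parent; pedigree invariant violated")
  }
  if (is.na(f)) {
    list(proband = proband, father = NA_character_, mother = NA_character_,
         mode = "proband_only")
  } else {
    list(proband = proband, father = f, mother = m, mode = "trio")
  }
}

#' Read pedigrees from a PED file
#'
#' Standard 6-column whitespace-delimited PED: family, individual, father,
#' mother, sex (1 = male, 2 = female, other = unknown), phenotype
#' (2 = affected, 1 = unaffected, other = unknown). `"0"` denotes a
#' missing parent.
#'
#' @param path Path to a PED file.
#' @return Named list of `pedigree` objects, one per family id.
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 6) stop("PED file must have 6 columns: ", path)
  names(df)[1:6] <- c("family", "id", "father", "mother", "sex", "phenotype")
  sex <- c("1" = "male", "2" = "female")[df$sex]
  sex[is.na(sex)] <- "unknown"
  aff <- c("2" = "affected", "1" = "unaffected")[df$phenotype]
  aff[is.na(aff)] <- "unknown"
  out <- lapply(split(seq_len(nrow(df)), df$family), function(i) {
    pedigree(df$id[i], df$father[i], df$mother[i], sex[i], aff[i],
             family_id = df$family[i][1])
  })
  out[unique(df$family)]
}

#' Write pedigrees to a PED file
#'
#' @param ped A `pedigree` or list of pedigrees.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  if (inherits(ped, "pedigree")) ped <- list(ped)
  rows <- lapply(ped, function(p) {
    data.frame(
      family = family_id(p),
      id = p$id,
      father = ifelse(is.na(p$father), "0", p$father),
      mother = ifelse(is.na(p$mother), "0", p$mother),
      sex = c(male = "1", female = "2", unknown = "0")[p$sex],
      phenotype = c(affected = "2", unaffected = "1", unknown = "0")[p$affected],
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
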