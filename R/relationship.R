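#' Numerator relationship matrix from a pedigree
#'
#' Builds the dense additive (numerator) relationship matrix `A` by the
#' tabular method over the topologically sorted pedigree:
#' `A[i,i] = 1 + 0.5 * A[sire_i, dam_i]` and
#' `A[i,j] = 0.5 * (A[j, sire_i] + A[j, dam_i])` for `j` preceding `i`,
#' with a missing parent contributing zero (i.e. treated as an unrelated,
#' non-inbred founder).  Diagonal entries equal `1 + F_i` where `F_i` is the
#' inbreeding coefficient.
#'
#' @param ped a [pedigree].
#' @return A symmetric numeric matrix with animal ids as dimnames.
#' @export
build_numerator_relationship <- function(ped) {
  n <- nrow(ped)
  id <- ped$animal_id
  idx <- seq_len(n); names(idx) <- id
  si <- unname(idx[ped$sire_id])
  di <- unname(idx[ped$dam_id])
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (is.na(s)) 0 else A[j, s]
      ad_ <- if (is.na(d)) 0 else A[j, d]
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  A
}

#' Breed ancestry fractions and purebred flags
#'
#' The breed fraction of a founder is a unit vector on its own label
#' (`"unknown"` for unlabelled founders); every other animal's fractions
#' are the average of its parents', with a missing parent counted as
#' entirely `"unknown"`.  An animal is flagged purebred for a breed when its
#' fraction reaches `purebred_threshold`, by default 15/16.
#'
#' @param ped a [pedigree].
#' @param purebred_threshold minimum ancestry fraction to call an animal
#'   purebred (default `15/16`).
#' @return data.frame with `animal_id`, one fraction column per breed, and
#'   `purebred` (the breed name, or `NA` when no breed reaches the
#'   threshold).
#' @export
breed_fractions <- function(ped, purebred_threshold = 15 / 16) {
  n <- nrow(ped)
  breeds <- sort(unique(stats::na.omit(ped$breed)))
  has_unknown <- any(ped$founder & is.na(ped$breed)) ||
    any(!ped$founder & (is.na(ped$sire_id) | is.na(ped$dam_id)))
  cols <- c(breeds, if (has_unknown) "unknown")
  frac <- matrix(0, n, length(cols), dimnames = list(ped$animal_id, cols))
  idx <- seq_len(n); names(idx) <- ped$animal_id
  unk <- numeric(length(cols)); names(unk) <- cols
  if (has_unknown) unk["unknown"] <- 1
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      b <- ped$breed[i]
      if (is.na(b)) frac[i, "unknown"] <- 1 else frac[i, b] <- 1
    } else {
      pv <- function(p) if (is.na(p)) unk else frac[idx[[p]], ]
      frac[i, ] <- 0.5 * (pv(ped$sire_id[i]) + pv(ped$dam_id[i]))
    }
  }
  best <- cols[max.col(frac, ties.method = "first")]
  top <- frac[cbind(seq_len(n), max.col(frac, ties.method = "first"))]
  purebred <- ifelse(top >= purebred_threshold & best != "unknown",
                     best, NA_character_)
  out <- data.frame(animal_id = ped$animal_id, frac, purebred = purebred,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Pedigree-genotype Mendelian concordance
#'
#' For every genotyped (offspring, recorded parent) pair, counts
#' opposite-homozygote conflicts -- parent dosage 0 with child dosage 2, or
#' parent 2 with child 0 -- over variants where both members are called.
#' Pairs whose conflict rate exceeds `max_conflict_rate` are flagged for
#' exclusion, mirroring the exclusion of animals whose genotypes are not
#' concordant with their sire or dam.
#'
#' @param ped a [pedigree].
#' @param g a [genotype_matrix].
#' @param max_conflict_rate conflict-rate threshold above which a pair is
#'   flagged (default 0.02).
#' @return data.frame with one row per tested pair: `animal_id`, `parent_id`,
#'   `relationship` ("sire"/"dam"), `n_tested`, `n_conflicts`,
#'   `conflict_rate`, `exclude`.
#' @export
mendel_concordance <- function(ped, g, max_conflict_rate = 0.02) {
  d <- g$dosages
  ids <- rownames(d)
  rows <- list()
  for (i in seq_len(nrow(ped))) {
    child <- ped$animal_id[i]
    if (!child %in% ids) next
    for (rel in c("sire", "dam")) {
      par <- ped[[paste0(rel, "_id")]][i]
      if (is.na(par) || !par %in% ids) next
      dc <- d[child, ]; dp <- d[par, ]
      both <- !is.na(dc) & !is.na(dp)
      conf <- both & ((dc == 0 & dp == 2) | (dc == 2 & dp == 0))
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = child, parent_id = par, relationship = rel,
        n_tested = sum(both), n_conflicts = sum(conf),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no genotyped parent-offspring pairs to test")
  out <- do.call(rbind, rows)
  if (all(out$n_tested == 0L)) stop("no overlapping called variants in any pair")
  out$conflict_rate <- ifelse(out$n_tested > 0L,
                              out$n_conflicts / out$n_tested, NA_real_)
  out$exclude <- !is.na(out$conflict_rate) &
    out$conflict_rate > max_conflict_rate
  out
}
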