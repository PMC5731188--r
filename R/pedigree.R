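#' Pedigree objects
#'
#' A `pedigree` is a topologically sorted table of animals with sire/dam
#' links and founder breed labels.  Founders have both parents missing;
#' the missing-parent token on disk is `"0"` or the empty string.
#'
#' @param animal_id character vector of unique animal ids.
#' @param sire_id,dam_id character vectors of parent ids; `NA` for missing.
#' @param breed character vector of breed labels; `NA` for non-founders or
#'   unlabelled founders.
#' @return An object of class `pedigree`: a `data.frame` with columns
#'   `animal_id`, `sire_id`, `dam_id`, `breed`, sorted so that every parent
#'   precedes its offspring.
#' @export
pedigree <- function(animal_id, sire_id = NA_character_, dam_id = NA_character_,
                     breed = NA_character_) {
  n <- length(animal_id)
  ped <- data.frame(
    animal_id = as.character(animal_id),
    sire_id   = rep_len(as.character(sire_id), n),
    dam_id    = rep_len(as.character(dam_id), n),
    breed     = rep_len(as.character(breed), n),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
}

#' @keywords internal
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$animal_id))
    stop("duplicate animal ids: ",
         paste(unique(ped$animal_id[duplicated(ped$animal_id)]), collapse = ", "))
  for (col in c("sire_id", "dam_id")) {
    x <- ped[[col]]
    x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
    ped[[col]] <- x
  }
  # parents referenced but never defined become implicit unlabelled founders
  parents <- setdiff(stats::na.omit(c(ped$sire_id, ped$dam_id)), ped$animal_id)
  if (length(parents)) {
    ped <- rbind(
      data.frame(animal_id = parents, sire_id = NA_character_,
                 dam_id = NA_character_, breed = NA_character_,
                 stringsAsFactors = FALSE),
      ped
    )
  }
  ped <- topo_sort_pedigree(ped)
  founder <- is.na(ped$sire_id) & is.na(ped$dam_id)
  if (any(!founder & (is.na(ped$sire_id) != is.na(ped$dam_id)))) {
    # one known parent is fine; nothing to do, kept as-is
  }
  ped$founder <- founder
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn's algorithm; errors naming a cycle member when no topological order
# exists.
#' @keywords internal
topo_sort_pedigree <- function(ped) {
  id <- ped$animal_id
  idx <- seq_along(id)
  names(idx) <- id
  si <- unname(idx[ped$sire_id]); di <- unname(idx[ped$dam_id])
  indeg <- integer(length(id))
  children <- vector("list", length(id))
  for (i in seq_along(id)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(id)) {
    left <- setdiff(seq_along(id), order)
    stop("pedigree contains a cycle involving animal '", id[left[1L]], "'")
  }
  ped[order, , drop = FALSE]
}

#' Read a pedigree from a delimited text file
#'
#' Expects a header with columns `id`, `sire`, `dam` and optionally `breed`
#' (TSV or CSV; the delimiter is sniffed).  `"0"` or an empty field denotes a
#' missing parent.  Parents that are referenced but have no row of their own
#' are added as implicit unlabelled founders.  The result is topologically
#' sorted (parents before offspring); a cyclic pedigree is an error.
#'
#' @param path path to the pedigree file.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path) {
  dt <- data.table::fread(path, colClasses = "character", na.strings = NULL)
  nm <- tolower(names(dt))
  need <- c("id", "sire", "dam")
  if (!all(need %in% nm))
    stop("pedigree file must have columns id, sire, dam (found: ",
         paste(names(dt), collapse = ", "), ")")
  names(dt) <- nm
  breed <- if ("breed" %in% nm) dt$breed else NA_character_
  breed[!is.na(breed) & breed == ""] <- NA_character_
  pedigree(dt$id, dt$sire, dt$dam, breed)
}

#' Write a pedigree to TSV
#'
#' Missing parents are written as `"0"`, missing breed labels as empty
#' strings.
#'
#' @param ped a [pedigree].
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    id    = ped$animal_id,
    sire  = ifelse(is.na(ped$sire_id), "0", ped$sire_id),
    dam   = ifelse(is.na(ped$dam_id), "0", ped$dam_id),
    breed = ifelse(is.na(ped$breed), "", ped$breed),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d animals (%d founders)\n",
              nrow(x), sum(x$founder)))
  NextMethod()
}
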