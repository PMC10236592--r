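#' Construct a validated, topologically sorted pedigree
#'
#' Builds a pedigree object from parallel vectors of animal, sire and dam
#' identifiers. Identifiers are opaque strings; `0`, `""` and `NA` denote an
#' unknown parent. Parents that are referenced but not listed as animals are
#' added as founder records (the usual base-population convention). Records
#' are re-ordered so that every parent precedes its offspring; a cycle (an
#' animal appearing among its own ancestors) is an error.
#'
#' @param animal character vector of animal ids (must be unique).
#' @param sire,dam character vectors of parent ids, same length as `animal`.
#' @param series optional vector of farrowing-series labels per animal.
#' @return An object of class `pedigree`: a data frame with columns
#'   `animal`, `sire`, `dam` (parent `NA` = unknown founder) and optionally
#'   `series`, in topological order, with attribute `depth` (longest
#'   ancestor chain; founders have depth 1).
#' @examples
#' ped <- pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
#' pedigree_depth(ped)
#' @export
pedigree <- function(animal, sire, dam, series = NULL) {
  animal <- as.character(animal)
  sire <- normalize_parent(sire)
  dam <- normalize_parent(dam)
  if (anyDuplicated(animal)) {
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  if (length(sire) != length(animal) || length(dam) != length(animal)) {
    stop("animal, sire and dam must have the same length")
  }
  if (!is.null(series) && length(series) != length(animal)) {
    stop("series must have one entry per animal")
  }

  # add referenced-but-unlisted parents as founders
  parents <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(parents)) {
    animal <- c(animal, parents)
    sire <- c(sire, rep(NA_character_, length(parents)))
    dam <- c(dam, rep(NA_character_, length(parents)))
    if (!is.null(series)) series <- c(series, rep(NA, length(parents)))
  }

  ord <- topo_order(animal, sire, dam)
  ped <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(series)) ped$series <- series[ord]

  depth <- integer(nrow(ped))
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  for (i in seq_len(nrow(ped))) {
    dp <- 0L
    if (!is.na(si[i])) dp <- depth[si[i]]
    if (!is.na(di[i])) dp <- max(dp, depth[di[i]])
    depth[i] <- dp + 1L
  }
  structure(ped, class = c("pedigree", "data.frame"),
            depth = max(depth), animal_depth = stats::setNames(depth, ped$animal))
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[x %in% c("0", "", "NA") | is.na(x)] <- NA_character_
  x
}

# Kahn's algorithm; reports an id on a cycle if one exists.
topo_order <- function(animal, sire, dam) {
  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stop("pedigree cycle detected involving animal '",
         animal[setdiff(seq_len(n), ord)[1L]], "'")
  }
  ord
}

#' Read a pedigree file
#'
#' Reads a delimited pedigree file with a header row `animal,sire,dam[,series]`
#' (comma- or tab-delimited, auto-detected). `0`, empty and `NA` parent fields
#' are treated as unknown.
#'
#' @param path path to the pedigree file.
#' @return A [pedigree] object (topologically sorted).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE)
  if (ncol(tab) < 3L) stop("pedigree file needs at least 3 columns (animal, sire, dam)")
  nm <- tolower(names(tab))
  pick <- function(what, k) if (what %in% nm) tab[[which(nm == what)[1L]]] else tab[[k]]
  pedigree(pick("animal", 1L), pick("sire", 2L), pick("dam", 3L),
           series = if ("series" %in% nm) tab[[which(nm == "series")[1L]]]
                    else if (ncol(tab) >= 4L) tab[[4L]] else NULL)
}

#' Pedigree depth
#'
#' Longest ancestor chain in the pedigree, counting founders as depth 1.
#'
#' @param ped a [pedigree] object.
#' @return integer depth.
#' @export
pedigree_depth <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  attr(ped, "depth")
}

#' Numerator (additive) relationship matrix
#'
#' Computes the full numerator relationship matrix A by the tabular method:
#' processing animals in topological order,
#' `a_ij = (a_{j,s(i)} + a_{j,d(i)}) / 2` for j before i, and
#' `a_ii = 1 + a_{s(i),d(i)} / 2`. Unknown parents are unrelated, non-inbred
#' base-population founders.
#'
#' @param ped a [pedigree] object (topologically sorted; enforced).
#' @return symmetric matrix with dimnames = animal ids; diagonal `1 + F`.
#' @export
additive_relationship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  check_sorted(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  zero <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    cs <- if (is.na(s)) zero else A[, s]
    cd <- if (is.na(d)) zero else A[, d]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- (cs[j] + cd[j]) / 2
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + (if (is.na(s) || is.na(d)) 0 else A[s, d] / 2)
  }
  A
}

check_sorted <- function(ped) {
  pos <- seq_len(nrow(ped))
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  bad <- which((!is.na(si) & si >= pos) | (!is.na(di) & di >= pos))
  if (length(bad)) {
    stop("pedigree is not topologically sorted at animal '",
         ped$animal[bad[1L]], "'")
  }
  invisible(TRUE)
}

#' Inbreeding coefficients
#'
#' Per-animal inbreeding coefficients `F_i = a_ii - 1` from the numerator
#' relationship matrix, plus their mean over all animals in the pedigree.
#'
#' @param ped a [pedigree] object.
#' @return list with `f` (named vector of per-animal F) and `mean_f`.
#' @export
inbreeding <- function(ped) {
  A <- additive_relationship(ped)
  f <- diag(A) - 1
  list(f = f, mean_f = mean(f))
}

#' Prune a pedigree to a set of animals and their ancestors
#'
#' Keeps the requested animals plus every ancestor, preserving all
#' relationships among the kept animals.
#'
#' @param ped a [pedigree] object.
#' @param keep_ids character vector of animal ids to retain.
#' @return a [pedigree] object restricted to `keep_ids` and their ancestors.
#' @export
prune_pedigree <- function(ped, keep_ids) {
  stopifnot(inherits(ped, "pedigree"))
  keep_ids <- as.character(keep_ids)
  missing <- setdiff(keep_ids, ped$animal)
  if (length(missing)) {
    stop("unknown animal id(s) in keep_ids: ", paste(missing, collapse = ", "))
  }
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  keep <- ped$animal %in% keep_ids
  # pedigree is sorted, so a reverse sweep closes over ancestors
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (!is.na(si[i])) keep[si[i]] <- TRUE
      if (!is.na(di[i])) keep[di[i]] <- TRUE
    }
  }
  pedigree(ped$animal[keep], ped$sire[keep], ped$dam[keep],
           series = if ("series" %in% names(ped)) ped$series[keep] else NULL)
}

#' Write a relationship matrix with id header row and column
#'
#' @param A matrix from [additive_relationship()].
#' @param path output path (tab-delimited).
#' @return invisibly, `path`.
#' @export
write_relationship_matrix <- function(A, path) {
  out <- data.frame(animal = rownames(A), A, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree: ", nrow(x), " animals, depth ", attr(x, "depth"),
      ", ", sum(is.na(x$sire) & is.na(x$dam)), " founders\n", sep = "")
  NextMethod()
}
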