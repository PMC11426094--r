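#' Construct and validate a pedigree
#'
#' A pedigree is a data frame with columns `id`, `sire`, `dam` and
#' `generation`, one row per individual, in topological order (parents
#' before offspring). Unknown parents are `NA`.
#'
#' @param id character vector of unique individual ids.
#' @param sire,dam character vectors of parent ids (`NA` = unknown).
#' @param generation integer generation number (founders = 0). Inferred
#'   as 1 + max(parent generation) when missing.
#' @return A `data.frame` of class `pedigree` with integer parent indices
#'   in attributes `sire_idx` / `dam_idx` (0 = unknown).
#' @export
pedigree <- function(id, sire = NA, dam = NA, generation = NULL) {
  id <- as.character(id)
  n <- length(id)
  sire <- rep_len(as.character(sire), n)
  dam <- rep_len(as.character(dam), n)
  if (anyDuplicated(id)) {
    stop("duplicated individual ids in pedigree: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  pos <- seq_len(n)
  names(pos) <- id
  sidx <- ifelse(is.na(sire), 0L, pos[sire])
  didx <- ifelse(is.na(dam), 0L, pos[dam])
  if (anyNA(sidx) || anyNA(didx)) {
    stop("pedigree refers to parent ids that are not in the pedigree")
  }
  sidx <- as.integer(sidx); didx <- as.integer(didx)
  if (any(sidx >= pos) || any(didx >= pos)) {
    stop("pedigree is not in topological order (a parent appears at or after its offspring)")
  }
  if (is.null(generation)) {
    generation <- integer(n)
    for (i in seq_len(n)) {
      g <- 0L
      if (sidx[i] > 0L) g <- max(g, generation[sidx[i]] + 1L)
      if (didx[i] > 0L) g <- max(g, generation[didx[i]] + 1L)
      generation[i] <- g
    }
  }
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    generation = as.integer(generation),
                    stringsAsFactors = FALSE)
  attr(ped, "sire_idx") <- sidx
  attr(ped, "dam_idx") <- didx
  class(ped) <- c("pedigree", "data.frame")
  ped
}

parent_indices <- function(ped) {
  s <- attr(ped, "sire_idx")
  if (is.null(s)) {
    ped2 <- pedigree(ped$id, ped$sire, ped$dam, ped$generation)
    return(list(sire = attr(ped2, "sire_idx"), dam = attr(ped2, "dam_idx")))
  }
  list(sire = s, dam = attr(ped, "dam_idx"))
}

#' Read a pedigree from CSV
#'
#' Expects columns `id,sire,dam` (header required; empty fields, `NA`, `0`
#' or `.` denote unknown parents). Offspring listed before a parent are
#' reordered into topological order unless `strict = TRUE`, in which case
#' the out-of-order file is an error. Cycles are always an error.
#'
#' @param path CSV file path.
#' @param strict logical; refuse to reorder rows.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path, strict = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree file must have columns id, sire, dam")
  }
  clean <- function(x) {
    x <- trimws(x)
    x[x %in% c("", "NA", "0", ".")] <- NA
    x
  }
  id <- clean(df$id); sire <- clean(df$sire); dam <- clean(df$dam)
  if (anyNA(id)) stop("missing individual id in pedigree file")
  pos <- seq_along(id); names(pos) <- id
  si <- ifelse(is.na(sire), 0L, pos[sire])
  di <- ifelse(is.na(dam), 0L, pos[dam])
  if (anyNA(si) || anyNA(di)) stop("pedigree refers to unknown parent ids")
  ok_order <- all(si < pos) && all(di < pos)
  if (!ok_order) {
    if (strict) stop("pedigree not in topological order (offspring before parent)")
    ord <- topo_order(as.integer(si), as.integer(di))
    id <- id[ord]; sire <- sire[ord]; dam <- dam[ord]
  }
  pedigree(id, sire, dam)
}

# Kahn topological sort over parent->offspring edges; errors on cycles.
topo_order <- function(sire_idx, dam_idx) {
  n <- length(sire_idx)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_idx[i], dam_idx[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) stop("pedigree contains a cycle (an individual is its own ancestor)")
  out
}

#' Inbreeding coefficients from a pedigree
#'
#' F_i is the kinship coefficient of the parents of i, computed by a
#' memoised recursion on the pedigree (founders and individuals with an
#' unknown parent have F = 0). Scales to pedigrees where the dense
#' tabular relationship matrix would not fit.
#'
#' @param ped a [pedigree()].
#' @return numeric vector of inbreeding coefficients, one per individual.
#' @export
inbreeding <- function(ped) {
  pi <- parent_indices(ped)
  s <- pi$sire; d <- pi$dam
  memo <- new.env(hash = TRUE, parent = emptyenv())
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    key <- paste0(i, ":", j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) {
      0.5 * (1 + phi(s[i], d[i]))
    } else {
      0.5 * (phi(s[i], j) + phi(d[i], j))
    }
    memo[[key]] <- v
    v
  }
  n <- nrow(ped)
  Fv <- numeric(n)
  for (i in seq_len(n)) {
    Fv[i] <- if (s[i] == 0L || d[i] == 0L) 0 else phi(s[i], d[i])
  }
  names(Fv) <- ped$id
  Fv
}
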