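#' Build a stand pedigree with known relationship categories
#'
#' Constructs a two-generation pedigree for a mixed stand: unrelated founders
#' of each species plus offspring families in the four relationship
#' categories observed among sibling pairs in such stands: parent-offspring
#' by selfing (expected additive relationship 1 with the parent),
#' parent-offspring (0.5), full sibs (0.5), and half sibs (0.25).
#'
#' Founders are allocated to families sequentially so families share no
#' parents except where the category requires it; requesting more families
#' than the founder pool supports is an error.
#'
#' @param n_founders_A,n_founders_B Number of unrelated founders per species.
#' @param offspring_spec Named list with elements `A` and/or `B`, each a
#'   named integer vector with any of the counts `parent_offspring`,
#'   `full_sib`, `half_sib`, `selfed` (number of families of that type).
#' @param seed Optional seed (ordering is deterministic; the seed only
#'   matters if downstream consumers draw from the RNG).
#' @return A `data.frame` of class `pedigree` with columns `id`, `sire`,
#'   `dam`, `species`, `generation`, and an attribute `"pairs"`: a
#'   `data.frame` (`id1`, `id2`, `category`, `expected`) listing the
#'   constructed known-relationship pairs and their expected additive
#'   relationship.
#' @examples
#' ped <- build_pedigree(4, 0, list(A = c(full_sib = 1, selfed = 1)))
#' attr(ped, "pairs")
#' @export
build_pedigree <- function(n_founders_A, n_founders_B,
                           offspring_spec = list(), seed = NULL) {
  stopifnot(n_founders_A >= 0, n_founders_B >= 0)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  pairs <- list()
  for (sp in c("A", "B")) {
    nf <- if (sp == "A") n_founders_A else n_founders_B
    if (nf > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_F%03d", sp, seq_len(nf)),
        sire = NA_character_, dam = NA_character_,
        species = sp, generation = 0L, stringsAsFactors = FALSE
      )
    }
  }
  founders_used <- c(A = 0L, B = 0L)
  take_founders <- function(sp, k) {
    nf <- if (sp == "A") n_founders_A else n_founders_B
    idx <- founders_used[[sp]] + seq_len(k)
    if (max(idx) > nf)
      stop(sprintf(
        "species %s: offspring spec needs %d founders but only %d available",
        sp, founders_used[[sp]] + k, nf
      ))
    founders_used[[sp]] <<- founders_used[[sp]] + k
    sprintf("%s_F%03d", sp, idx)
  }
  kid_n <- c(A = 0L, B = 0L)
  new_kid <- function(sp) {
    kid_n[[sp]] <<- kid_n[[sp]] + 1L
    sprintf("%s_O%03d", sp, kid_n[[sp]])
  }
  add <- function(id, sire, dam, sp) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, sire = sire, dam = dam, species = sp, generation = 1L,
      stringsAsFactors = FALSE
    )
  }
  add_pair <- function(id1, id2, category, expected) {
    pairs[[length(pairs) + 1L]] <<- data.frame(
      id1 = id1, id2 = id2, category = category, expected = expected,
      stringsAsFactors = FALSE
    )
  }
  for (sp in intersect(c("A", "B"), names(offspring_spec))) {
    spec <- offspring_spec[[sp]]
    bad <- setdiff(names(spec),
                   c("parent_offspring", "full_sib", "half_sib", "selfed"))
    if (length(bad)) stop("unknown offspring categories: ",
                          paste(bad, collapse = ", "))
    cnt <- function(nm) {
      v <- spec[nm]
      if (is.na(v)) 0L else as.integer(v)
    }
    for (i in seq_len(cnt("selfed"))) {
      p <- take_founders(sp, 1L)
      k <- new_kid(sp)
      add(k, p, p, sp)
      add_pair(p, k, "parent_offspring_selfed", 1)
    }
    for (i in seq_len(cnt("parent_offspring"))) {
      p <- take_founders(sp, 2L)
      k <- new_kid(sp)
      add(k, p[1], p[2], sp)
      add_pair(p[1], k, "parent_offspring", 0.5)
      add_pair(p[2], k, "parent_offspring", 0.5)
    }
    for (i in seq_len(cnt("full_sib"))) {
      p <- take_founders(sp, 2L)
      k1 <- new_kid(sp); k2 <- new_kid(sp)
      add(k1, p[1], p[2], sp)
      add(k2, p[1], p[2], sp)
      add_pair(k1, k2, "full_sib", 0.5)
    }
    for (i in seq_len(cnt("half_sib"))) {
      p <- take_founders(sp, 3L)  # shared dam, two sires
      k1 <- new_kid(sp); k2 <- new_kid(sp)
      add(k1, p[2], p[1], sp)
      add(k2, p[3], p[1], sp)
      add_pair(k1, k2, "half_sib", 0.25)
    }
  }
  ped <- do.call(rbind, rows)
  if (is.null(ped))
    ped <- data.frame(id = character(), sire = character(),
                      dam = character(), species = character(),
                      generation = integer(), stringsAsFactors = FALSE)
  rownames(ped) <- NULL
  validate_pedigree(ped)
  attr(ped, "pairs") <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(id1 = character(), id2 = character(),
               category = character(), expected = numeric())
  class(ped) <- c("pedigree", "data.frame")
  ped
}

validate_pedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam", "species", "generation") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  known <- c(ped$sire, ped$dam)
  known <- known[!is.na(known)]
  miss <- setdiff(known, ped$id)
  if (length(miss)) stop("unknown parents in pedigree: ",
                         paste(miss, collapse = ", "))
  # parents must precede offspring in generation order
  gen <- setNames(ped$generation, ped$id)
  for (k in seq_len(nrow(ped))) {
    for (par in c(ped$sire[k], ped$dam[k])) {
      if (!is.na(par) && gen[[par]] >= ped$generation[k])
        stop("parent ", par, " does not precede offspring ", ped$id[k])
    }
  }
  invisible(ped)
}

#' Known-relationship pairs of a pedigree
#'
#' @param pedigree A pedigree built by [build_pedigree()].
#' @return The `data.frame` of constructed pairs with expected additive
#'   relationship values.
#' @export
pedigree_pairs <- function(pedigree) {
  p <- attr(pedigree, "pairs")
  if (is.null(p)) stop("pedigree carries no recorded relationship pairs")
  p
}

#' Pedigree additive relationship matrix (tabular method)
#'
#' Computes the expected additive relationship matrix A by the recursive
#' tabular method: processing individuals so parents precede offspring,
#' `A[i,j] = (A[j,sire] + A[j,dam]) / 2` and
#' `A[i,i] = 1 + A[sire,dam] / 2`, with unknown parents contributing 0.
#' Off-diagonals are twice the kinship coefficient: 0.5 for parent-offspring
#' and full sibs, 0.25 for half sibs, 1 between a non-inbred parent and its
#' selfed offspring. The diagonal is `1 + F`, so pedigree inbreeding is
#' `diag(A) - 1`.
#'
#' @param pedigree A `data.frame` with columns `id`, `sire`, `dam`,
#'   `generation` (parents listed before or in an earlier generation than
#'   their offspring).
#' @return Symmetric matrix with individual ids as dimnames.
#' @examples
#' ped <- build_pedigree(3, 0, list(A = c(half_sib = 1)))
#' A <- pedigree_A(ped)
#' A["A_O001", "A_O002"]  # 0.25
#' @export
pedigree_A <- function(pedigree) {
  validate_pedigree(pedigree)
  ord <- order(pedigree$generation)
  ids <- pedigree$id[ord]
  sire <- pedigree$sire[ord]
  dam <- pedigree$dam[ord]
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  pos <- setNames(seq_len(n), ids)
  for (i in seq_len(n)) {
    si <- if (is.na(sire[i])) 0L else pos[[sire[i]]]
    di <- if (is.na(dam[i])) 0L else pos[[dam[i]]]
    if (i > 1L) {
      js <- seq_len(i - 1L)
      as <- if (si > 0L) A[js, si] else rep(0, i - 1L)
      ad <- if (di > 0L) A[js, di] else rep(0, i - 1L)
      A[js, i] <- A[i, js] <- (as + ad) / 2
    }
    A[i, i] <- 1 + if (si > 0L && di > 0L) A[si, di] / 2 else 0
  }
  A[pedigree$id, pedigree$id, drop = FALSE]
}
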