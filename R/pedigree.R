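# Numerator relationship matrix machinery for the animal model.
#
# Pedigrees are plain data frames with integer columns `animal`, `sire`,
# `dam`; 0 marks an unknown parent. Animals are re-indexed internally to
# consecutive integers in a parents-before-offspring order; the original ids
# are kept as dimnames on every matrix returned.

#' Validate and topologically sort a pedigree
#'
#' Checks the `animal`/`sire`/`dam` columns, verifies that no animal is its
#' own ancestor, and reorders rows so that parents always precede their
#' offspring.
#'
#' @param pedigree data frame with integer columns `animal`, `sire`, `dam`
#'   (0 = unknown parent). Extra columns are carried through.
#' @return the pedigree, sorted parents-before-offspring, with an integer
#'   attribute `index` mapping each row to its position.
#' @export
pedigree_sort <- function(pedigree) {
  stopifnot(is.data.frame(pedigree),
            all(c("animal", "sire", "dam") %in% names(pedigree)))
  ids <- pedigree$animal
  if (anyDuplicated(ids)) stop("duplicated animal ids in pedigree")
  if (any(ids == 0)) stop("animal id 0 is reserved for unknown parents")
  n <- nrow(pedigree)
  pos <- match(pedigree$sire, ids, nomatch = 0L)
  pod <- match(pedigree$dam, ids, nomatch = 0L)
  if (any(pedigree$sire != 0 & pos == 0L))
    stop("sire ids not present in pedigree: ",
         paste(setdiff(pedigree$sire, c(0, ids)), collapse = ", "))
  if (any(pedigree$dam != 0 & pod == 0L))
    stop("dam ids not present in pedigree: ",
         paste(setdiff(pedigree$dam, c(0, ids)), collapse = ", "))
  # fast path: input already lists parents before offspring (kept stable)
  if (all(pos < seq_len(n)) && all(pod < seq_len(n))) {
    out <- pedigree
    rownames(out) <- NULL
    attr(out, "index") <- stats::setNames(seq_len(n), out$animal)
    return(out)
  }
  # Kahn's algorithm; a leftover set means a cycle, which we name explicitly.
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(pos[i], pod[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  order <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    order <- c(order, ready)
    nxt <- integer(0)
    for (p in ready) {
      for (ch in kids[[p]]) {
        indeg[ch] <- indeg[ch] - 1L
        if (indeg[ch] == 0L) nxt <- c(nxt, ch)
      }
    }
    ready <- nxt
  }
  if (length(order) < n) {
    bad <- setdiff(seq_len(n), order)
    stop("pedigree contains a cycle involving animals: ",
         paste(ids[utils::head(bad, 10)], collapse = " -> "))
  }
  out <- pedigree[order, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "index") <- stats::setNames(seq_len(n), out$animal)
  out
}

# 1-based parent position vectors for a sorted pedigree (0 = unknown)
.parent_positions <- function(ped) {
  list(s = match(ped$sire, ped$animal, nomatch = 0L),
       d = match(ped$dam, ped$animal, nomatch = 0L))
}

#' Inbreeding coefficients
#'
#' Computes per-animal inbreeding coefficients by the Meuwissen--Luo
#' recursion over the pedigree's Cholesky representation.
#'
#' @inheritParams pedigree_sort
#' @return named numeric vector of inbreeding coefficients F.
#' @export
inbreeding <- function(pedigree) {
  ped <- pedigree_sort(pedigree)
  pp <- .parent_positions(ped)
  stats::setNames(inbreeding_cpp(pp$s, pp$d), ped$animal)
}

#' Numerator relationship matrix A
#'
#' Builds the additive genetic relationship matrix by the tabular method:
#' `a_ij = (a_{j,s(i)} + a_{j,d(i)})/2` for `j < i` and
#' `a_ii = 1 + a_{s(i),d(i)}/2`.
#'
#' @inheritParams pedigree_sort
#' @return dense symmetric matrix with animal ids as dimnames and the
#'   inbreeding coefficients attached as attribute `"F"`.
#' @export
build_A <- function(pedigree) {
  ped <- pedigree_sort(pedigree)
  pp <- .parent_positions(ped)
  A <- build_A_cpp(pp$s, pp$d)
  dimnames(A) <- list(ped$animal, ped$animal)
  attr(A, "F") <- diag(A) - 1
  A
}

#' Sparse inverse of the relationship matrix
#'
#' Assembles `A^{-1}` directly from the pedigree by Henderson's rules with
#' inbreeding-adjusted Mendelian-sampling variances, without ever forming A.
#' Non-zero entries occur only among `{animal, sire, dam}` triples, so the
#' result is sparse even for large pedigrees.
#'
#' @inheritParams pedigree_sort
#' @return sparse symmetric [Matrix::Matrix] with animal ids as dimnames.
#' @export
build_A_inverse <- function(pedigree) {
  ped <- pedigree_sort(pedigree)
  pp <- .parent_positions(ped)
  n <- nrow(ped)
  F <- inbreeding_cpp(pp$s, pp$d)
  Fs <- ifelse(pp$s > 0, F[pmax(pp$s, 1)], 0)
  Fd <- ifelse(pp$d > 0, F[pmax(pp$d, 1)], 0)
  both <- pp$s > 0 & pp$d > 0
  one  <- xor(pp$s > 0, pp$d > 0)
  dvec <- ifelse(both, 0.5 - 0.25 * (Fs + Fd),
          ifelse(one, 0.75 - 0.25 * (Fs + Fd), 1))
  alpha <- 1 / dvec
  ii <- seq_len(n)
  hs <- pp$s > 0; hd <- pp$d > 0
  tri_i <- c(ii,
             ii[hs], pp$s[hs], ii[hd], pp$d[hd],
             pp$s[hs], pp$d[hd],
             pp$s[both], pp$d[both])
  tri_j <- c(ii,
             pp$s[hs], ii[hs], pp$d[hd], ii[hd],
             pp$s[hs], pp$d[hd],
             pp$d[both], pp$s[both])
  tri_x <- c(alpha,
             -alpha[hs] / 2, -alpha[hs] / 2, -alpha[hd] / 2, -alpha[hd] / 2,
             alpha[hs] / 4, alpha[hd] / 4,
             alpha[both] / 4, alpha[both] / 4)
  # sparseMatrix sums duplicated (i, j) pairs, which is exactly
  # Henderson's accumulation rule
  Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x,
                       dims = c(n, n),
                       dimnames = list(ped$animal, ped$animal))
}

#' Coefficient of coancestry (kinship)
#'
#' Recursive coancestry between two animals; `a_ij = 2 * kinship(i, j)` for
#' distinct animals. Serves as an independent oracle for [build_A()].
#'
#' @inheritParams pedigree_sort
#' @param i,j animal ids.
#' @return kinship coefficient in `[0, 1]`.
#' @export
kinship <- function(pedigree, i, j) {
  ped <- pedigree_sort(pedigree)
  pp <- .parent_positions(ped)
  pi <- match(i, ped$animal)
  pj <- match(j, ped$animal)
  if (is.na(pi) || is.na(pj))
    stop("unknown animal id: ", paste(c(i, j)[is.na(c(pi, pj))], collapse = ", "))
  memo <- new.env(parent = emptyenv())
  f <- function(x, y) {
    if (x == 0L || y == 0L) return(0)
    if (x > y) { tmp <- x; x <- y; y <- tmp }
    key <- paste(x, y)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (x == y) {
      0.5 * (1 + f(pp$s[x], pp$d[x]))
    } else {
      # y is the later-born animal; recurse through its parents
      0.5 * (f(x, pp$s[y]) + f(x, pp$d[y]))
    }
    memo[[key]] <- val
    val
  }
  f(pi, pj)
}
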