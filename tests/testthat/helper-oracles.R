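# Independent brute-force oracles used to validate the network and pedigree
# machinery. These deliberately use naive algorithms (Floyd-Warshall distance
# matrices, path-count dynamic programming, power iteration, subset
# enumeration, top-down kinship recursion) rather than the package's code
# paths.

random_graph <- function(n, p = 0.4) {
  adj <- matrix(FALSE, n, n)
  adj[upper.tri(adj)] <- stats::runif(n * (n - 1) / 2) < p
  adj <- adj | t(adj)
  dimnames(adj) <- list(seq_len(n), seq_len(n))
  adj
}

net_from_adj <- function(adj) {
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  recs <- data.frame(initiator_id = rownames(adj)[idx[, 1]],
                     receiver_id = colnames(adj)[idx[, 2]],
                     kind = rep("fight", nrow(idx)))
  build_pen_network(recs, rownames(adj))
}

# all-pairs shortest-path distances (Floyd-Warshall)
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj] <- 1
  for (m in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, m] + d[m, j] < d[i, j]) d[i, j] <- d[i, m] + d[m, j]
  d
}

# shortest-path counts via DP on the distance matrix
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (len in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (d[s, t] == len) {
        pre <- which(adj[, t] & d[s, ] == len - 1)
        sigma[s, t] <- sum(sigma[s, pre])
      }
    }
  }
  sigma
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  sigma <- oracle_path_counts(adj, d)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(d[s, t]) || sigma[s, t] == 0) next
      if (d[s, v] + d[v, t] == d[s, t])
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    bc[v] <- acc / ((n - 1) * (n - 2) / 2)
  }
  bc
}

oracle_closeness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (!length(dv)) return(0)
    (length(dv) / sum(dv)) * (length(dv) / (n - 1))
  }, numeric(1))
}

oracle_eigenvector <- function(adj, iters = 10000) {
  n <- nrow(adj)
  # largest connected component via distance matrix
  d <- oracle_distances(adj)
  comp_of <- integer(n)
  cid <- 0
  for (v in seq_len(n)) if (comp_of[v] == 0) {
    cid <- cid + 1
    comp_of[is.finite(d[v, ])] <- cid
  }
  sizes <- tabulate(comp_of)
  keep <- which(comp_of == which.max(sizes))
  sub <- adj[keep, keep, drop = FALSE] * 1
  # shifted power iteration (A + I keeps the Perron vector but makes the
  # dominant eigenvalue strictly largest in modulus, so bipartite
  # components cannot oscillate)
  v <- rep(1, length(keep))
  for (i in seq_len(iters)) {
    v2 <- as.numeric(sub %*% v) + v
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < 1e-15) { v <- v2; break }
    v <- v2
  }
  out <- numeric(n)
  out[keep] <- v / max(v)
  out
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ])
    if (length(nb) < 2) return(0)
    tri <- sum(adj[nb, nb, drop = FALSE]) / 2
    2 * tri / (length(nb) * (length(nb) - 1))
  }, numeric(1))
}

oracle_max_cliques <- function(adj) {
  n <- nrow(adj)
  best <- 1
  members <- rep(FALSE, n)
  for (size in n:1) {
    combs <- utils::combn(n, size)
    found <- FALSE
    for (ci in seq_len(ncol(combs))) {
      s <- combs[, ci]
      sub <- adj[s, s, drop = FALSE]
      if (all(sub[upper.tri(sub)])) {
        if (!found) { best <- size; found <- TRUE }
        members[s] <- TRUE
      }
    }
    if (found) break
  }
  list(size = best, members = as.integer(members))
}

# Random pedigree over a few overlapping generations, some unknown parents.
random_pedigree <- function(n_founders = 10, n_later = 40, p_unknown = 0.1) {
  n <- n_founders + n_later
  sire <- dam <- integer(n)
  for (i in (n_founders + 1):n) {
    pool <- seq_len(i - 1)
    sire[i] <- if (stats::runif(1) < p_unknown) 0L else sample(pool, 1)
    dam[i] <- if (stats::runif(1) < p_unknown) 0L else sample(pool, 1)
    if (sire[i] != 0 && sire[i] == dam[i]) dam[i] <- 0L
  }
  data.frame(animal = seq_len(n), sire = sire, dam = dam,
             generation = c(rep(0L, n_founders), rep(1L, n_later)))
}

# Full kinship matrix by top-down coancestry recursion with a shared memo;
# an independent construction of A/2 (the package builds A bottom-up).
oracle_kinship_matrix <- function(ped) {
  n <- nrow(ped)
  s <- match(ped$sire, ped$animal, nomatch = 0L)
  d <- match(ped$dam, ped$animal, nomatch = 0L)
  phi <- matrix(NA_real_, n, n)
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    if (!is.na(phi[i, j])) return(phi[i, j])
    val <- if (i == j) 0.5 * (1 + f(s[i], d[i]))
           else 0.5 * (f(i, s[j]) + f(i, d[j]))
    phi[i, j] <<- val
    val
  }
  for (i in seq_len(n)) for (j in i:n) phi[j, i] <- phi[i, j] <- f(i, j)
  phi
}

# Reference single-trait Gibbs sampler for unrelated animals (A = I):
# y = mu + a_i + c_pen + e, all full conditionals conjugate, vectorised.
# Independent of the compiled sampler.
reference_gibbs_iid <- function(y, pen, n_iter, burn_in, thin) {
  n <- length(y)
  npen <- length(unique(pen))
  pen <- as.integer(factor(pen))
  nj <- tabulate(pen, npen)
  mu <- 0; a <- numeric(n); cc <- numeric(npen)
  va <- vc <- ve <- stats::var(y) / 3
  keep <- NULL
  for (it in seq_len(n_iter)) {
    res <- y - a - cc[pen]
    mu <- mean(res) + stats::rnorm(1, 0, sqrt(ve / n))
    # animal effects (A = I): independent conditionals
    prec <- 1 / ve + 1 / va
    a <- stats::rnorm(n, (y - mu - cc[pen]) / ve / prec, sqrt(1 / prec))
    # pen effects
    resp <- y - mu - a
    sums <- tapply(resp, pen, sum)[as.character(seq_len(npen))]
    sums[is.na(sums)] <- 0
    precc <- nj / ve + 1 / vc
    cc <- stats::rnorm(npen, (sums / ve) / precc, sqrt(1 / precc))
    va <- sum(a^2) / stats::rchisq(1, n - 2)
    vc <- sum(cc^2) / stats::rchisq(1, npen - 2)
    e <- y - mu - a - cc[pen]
    ve <- sum(e^2) / stats::rchisq(1, n - 2)
    if (it > burn_in && (it - burn_in) %% thin == 0)
      keep <- rbind(keep, c(va = va, vc = vc, ve = ve))
  }
  keep
}

# Generalised-least-squares / BLUP solutions at known variance components,
# via the mixed-model equations assembled with Matrix. Returns the fixed
# effects (with a sum-to-zero style pseudoinverse handling for the
# intercept-confounded system) and the BLUP of a.
oracle_mme_blup <- function(y, X, zid, wid, Ainv, q, npen, va, vc, ve) {
  n <- nrow(X)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = zid, x = 1, dims = c(n, q))
  W <- Matrix::sparseMatrix(i = seq_len(n), j = wid, x = 1, dims = c(n, npen))
  T <- cbind(Matrix::Matrix(X, sparse = TRUE), Z, W)
  C <- Matrix::crossprod(T) / ve
  p <- ncol(X)
  ia <- p + seq_len(q)
  ic <- p + q + seq_len(npen)
  C[ia, ia] <- C[ia, ia] + Ainv / va
  C[ic, ic] <- C[ic, ic] + Matrix::Diagonal(npen) / vc
  rhs <- Matrix::crossprod(T, y) / ve
  sol <- as.numeric(Matrix::solve(C, rhs))
  list(b = sol[seq_len(p)], a = sol[ia], c = sol[ic])
}

make_recovery_data <- function(seed, h2 = 0.30, c2 = 0.10, n_sires = 80,
                               n_dams = 200, offspring_per_dam = 10,
                               n_pens = 78) {
  ped <- simulate_pedigree(n_sires, n_dams, offspring_per_dam, seed = seed)
  asg <- random_pen_assignment(ped, n_pens = n_pens, seed = seed + 1)
  pars <- make_parameters(h2 = c(tr = h2), c2 = c(tr = c2), Vp = c(tr = 1))
  bv <- simulate_breeding_values(ped, pars$G0, seed = seed + 2)
  tab <- simulate_phenotypes(asg, bv, pars, seed = seed + 3)
  list(ped = ped, asg = asg, tab = tab, bv = bv, pars = pars)
}
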