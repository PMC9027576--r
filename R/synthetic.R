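# Synthetic-data generator emulating the structure of a post-mixing
# aggression study: a two-generation pedigree (sires x dams -> litters),
# same-sex same-line pens drawn 3-per-litter from 5 litters, latent
# aggressiveness driving per-pen interaction networks, and multivariate
# phenotypes (network + skin-lesion traits) on the modelled scale with
# pedigree-structured genetic effects, common pen effects and residuals.

#' Simulate a two-generation pedigree
#'
#' Founder sires and dams are unrelated and non-inbred; each dam is mated to
#' one randomly chosen sire, and her offspring are split into litters of at
#' most `litter_size`.
#'
#' @param n_sires,n_dams founder counts.
#' @param offspring_per_dam expected offspring per dam (may be fractional;
#'   the fractional part is realised as a Bernoulli extra).
#' @param litter_size maximum animals per litter.
#' @param seed optional RNG seed for reproducibility.
#' @return data frame with columns `animal`, `sire`, `dam`, `generation`,
#'   `litter` (NA for founders); parents precede offspring.
#' @export
simulate_pedigree <- function(n_sires = 82, n_dams = 217,
                              offspring_per_dam = 10, litter_size = 10,
                              seed = NULL) {
  if (n_sires < 1 || n_dams < 1 || offspring_per_dam <= 0 || litter_size < 1)
    stop("counts must be positive")
  if (!is.null(seed)) set.seed(seed)
  sires <- seq_len(n_sires)
  dams <- n_sires + seq_len(n_dams)
  n_off <- floor(offspring_per_dam) +
    stats::rbinom(n_dams, 1, offspring_per_dam - floor(offspring_per_dam))
  mate <- sample(sires, n_dams, replace = TRUE)
  off_dam <- rep(dams, n_off)
  off_sire <- rep(mate, n_off)
  litter_no <- unlist(lapply(n_off, function(k) {
    if (k == 0) integer(0) else rep(seq_len(ceiling(k / litter_size)),
                                    each = litter_size, length.out = k)
  }))
  n_total <- n_sires + n_dams + length(off_dam)
  data.frame(
    animal = c(sires, dams, n_sires + n_dams + seq_along(off_dam)),
    sire = c(rep(0L, n_sires + n_dams), off_sire),
    dam = c(rep(0L, n_sires + n_dams), off_dam),
    generation = c(rep(0L, n_sires + n_dams), rep(1L, length(off_dam))),
    litter = c(rep(NA_character_, n_sires + n_dams),
               paste0("D", off_dam, "_L", litter_no))
  )
}

#' Distribute offspring into same-sex, same-line pens
#'
#' Offspring are given a sex (female / male / castrated) and inherit their
#' dam's genetic line; pens are then filled greedily with exactly
#' `per_litter` animals from each of `litters_per_pen` litters, all of one
#' sex and line, cycling over the line-by-sex cells. Pens mixed on the same
#' day share a batch (round-robin over `n_batches`). A body-weight-at-mixing
#' covariate is drawn from a normal distribution.
#'
#' @param pedigree output of [simulate_pedigree()].
#' @param pen_size animals per pen (`per_litter * litters_per_pen`).
#' @param per_litter animals drawn per litter.
#' @param litters_per_pen litters contributing to each pen.
#' @param n_pens number of pens to form.
#' @param n_batches number of mixing batches.
#' @param sex_probs probabilities for female, male, castrated.
#' @param weight_mean,weight_sd weight-at-mixing distribution (kg).
#' @param seed optional RNG seed.
#' @return data frame with columns `animal_id`, `pen_id`, `litter_id`,
#'   `sex`, `line`, `batch`, `weight_at_mixing`; offspring that could not be
#'   penned are listed in the attribute `"unpenned"`.
#' @export
assign_pens <- function(pedigree, pen_size = 15, per_litter = 3,
                        litters_per_pen = 5, n_pens = 78, n_batches = 14,
                        sex_probs = c(female = 0.5, male = 0.25,
                                      castrated = 0.25),
                        weight_mean = 30, weight_sd = 2.5, seed = NULL) {
  if (pen_size != per_litter * litters_per_pen)
    stop("pen_size must equal per_litter * litters_per_pen")
  if (!is.null(seed)) set.seed(seed)
  off <- pedigree[pedigree$generation == 1L, , drop = FALSE]
  if (!nrow(off)) stop("pedigree has no offspring generation to pen")
  off$sex <- sample(names(sex_probs), nrow(off), replace = TRUE,
                    prob = sex_probs)
  dams <- sort(unique(off$dam))
  dam_line <- stats::setNames(
    rep(c("Y", "YxL"), length.out = length(dams))[sample(length(dams))], dams)
  off$line <- dam_line[as.character(off$dam)]

  used <- rep(FALSE, nrow(off))
  cells <- expand.grid(line = c("Y", "YxL"),
                       sex = names(sex_probs), stringsAsFactors = FALSE)
  rows <- list()
  pen <- 0L
  exhausted <- rep(FALSE, nrow(cells))
  while (pen < n_pens && !all(exhausted)) {
    progressed <- FALSE
    for (ci in seq_len(nrow(cells))) {
      if (pen >= n_pens || exhausted[ci]) next
      sel <- !used & off$sex == cells$sex[ci] & off$line == cells$line[ci]
      avail <- table(off$litter[sel])
      avail <- avail[avail >= per_litter]
      if (length(avail) < litters_per_pen) { exhausted[ci] <- TRUE; next }
      # take the litters with most unused animals to keep the pool balanced
      pick <- names(sort(avail, decreasing = TRUE))[seq_len(litters_per_pen)]
      pen <- pen + 1L
      progressed <- TRUE
      for (lt in pick) {
        idx <- which(sel & off$litter == lt)[seq_len(per_litter)]
        used[idx] <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = off$animal[idx], pen_id = pen, litter_id = lt,
          sex = cells$sex[ci], line = cells$line[ci])
      }
    }
    if (!progressed) break
  }
  if (pen < n_pens)
    stop("infeasible pen composition: only ", pen, " of ", n_pens,
         " pens could be formed with ", per_litter, " animals from each of ",
         litters_per_pen, " litters")
  out <- do.call(rbind, rows)
  out <- out[order(out$pen_id, out$animal_id), ]
  rownames(out) <- NULL
  out$batch <- ((out$pen_id - 1L) %% n_batches) + 1L
  out$weight_at_mixing <- stats::rnorm(nrow(out), weight_mean, weight_sd)
  attr(out, "unpenned") <- off$animal[!used]
  out
}

#' Loosely structured pen assignment
#'
#' Spreads all offspring evenly over `n_pens` pens without the
#' litter-composition constraint, assigning one sex and line per pen and
#' batches round-robin. Intended for parameter-recovery experiments where
#' the record count and pen count are fixed independently of litter
#' structure.
#'
#' @inheritParams assign_pens
#' @return pen assignment data frame as in [assign_pens()].
#' @export
random_pen_assignment <- function(pedigree, n_pens = 78, n_batches = 14,
                                  weight_mean = 30, weight_sd = 2.5,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  off <- pedigree[pedigree$generation == 1L, , drop = FALSE]
  ord <- sample(nrow(off))
  pen_of <- rep(seq_len(n_pens), length.out = nrow(off))[order(ord)]
  pen_sex <- sample(c("female", "male", "castrated"), n_pens, replace = TRUE)
  pen_line <- sample(c("Y", "YxL"), n_pens, replace = TRUE)
  out <- data.frame(animal_id = off$animal, pen_id = pen_of,
                    litter_id = ifelse(is.na(off$litter), "none", off$litter),
                    sex = pen_sex[pen_of], line = pen_line[pen_of],
                    batch = ((pen_of - 1L) %% n_batches) + 1L,
                    weight_at_mixing = stats::rnorm(nrow(off), weight_mean,
                                                    weight_sd))
  out[order(out$pen_id, out$animal_id), ]
}

#' Simulate pedigree-structured breeding values
#'
#' Founders are drawn iid from `N(0, G0)`; each non-founder gets the parent
#' average plus a Mendelian-sampling deviation with covariance
#' `(1/2 - (F_s + F_d)/4) G0` (inbreeding is tracked; unknown parents
#' contribute as fresh founders). Over replicates the covariance of the
#' stacked values converges to `A (x) G0`.
#'
#' @param pedigree a pedigree data frame (see [simulate_pedigree()]).
#' @param G0 genetic covariance matrix (k x k, SPD; a scalar is accepted for
#'   one trait). A zero matrix yields all-zero values.
#' @param seed optional RNG seed.
#' @return numeric matrix (animals x traits) with animal ids as rownames.
#' @export
simulate_breeding_values <- function(pedigree, G0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G0 <- as.matrix(G0)
  k <- ncol(G0)
  if (!isSymmetric(unname(G0), tol = 1e-8)) stop("G0 must be symmetric")
  ev <- eigen(G0, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1))) stop("G0 must be positive semi-definite")
  ped <- pedigree_sort(pedigree)
  pp <- .parent_positions(ped)
  F <- inbreeding_cpp(pp$s, pp$d)
  n <- nrow(ped)
  Lg <- if (all(G0 == 0)) matrix(0, k, k) else t(chol(G0 + 1e-12 * diag(k)))
  a <- matrix(0, n, k, dimnames = list(ped$animal, colnames(G0)))
  z <- matrix(stats::rnorm(n * k), n, k)
  for (i in seq_len(n)) {
    s <- pp$s[i]; d <- pp$d[i]
    pa <- numeric(k)
    if (s > 0) pa <- pa + 0.5 * a[s, ]
    if (d > 0) pa <- pa + 0.5 * a[d, ]
    msv <- if (s > 0 && d > 0) 0.5 - 0.25 * (F[s] + F[d])
           else if (s > 0) 0.75 - 0.25 * F[s]
           else if (d > 0) 0.75 - 0.25 * F[d]
           else 1
    a[i, ] <- pa + sqrt(msv) * as.numeric(Lg %*% z[i, ])
  }
  a
}

#' True simulation parameters
#'
#' Bundles the generator's genetic (`G0`), pen (`C0`) and residual (`R0`)
#' covariance matrices, fixed-effect values and the latent-aggressiveness
#' edge model into one validated object.
#'
#' @param G0,C0,R0 symmetric positive semi-definite covariance matrices with
#'   matching trait names.
#' @param fixed_effects optional list with elements `intercept` (vector per
#'   trait), `line`, `sex`, `batch` (matrices levels x traits) and
#'   `weight_slope` (vector per trait); missing pieces default to zero.
#' @param edge_model list with `fight = c(intercept, slope)` and
#'   `bully = c(intercept, slope)` on the logit scale.
#' @return object of class `true_parameters`.
#' @export
true_parameters <- function(G0, C0, R0, fixed_effects = NULL,
                            edge_model = list(fight = c(intercept = -1.0,
                                                        slope = 0.8),
                                              bully = c(intercept = -2.0,
                                                        slope = 0.5))) {
  G0 <- as.matrix(G0); C0 <- as.matrix(C0); R0 <- as.matrix(R0)
  k <- ncol(G0)
  stopifnot(ncol(C0) == k, ncol(R0) == k)
  for (M in list(G0, C0, R0))
    if (!isSymmetric(unname(M), tol = 1e-8)) stop("covariance matrices must be symmetric")
  h2 <- diag(G0) / (diag(G0) + diag(C0) + diag(R0))
  if (any(!is.finite(h2)) || any(h2 < 0) || any(h2 > 1))
    stop("implied heritabilities must lie in [0, 1]")
  structure(list(G0 = G0, C0 = C0, R0 = R0, fixed_effects = fixed_effects,
                 edge_model = edge_model, h2 = h2,
                 traits = colnames(G0)),
            class = "true_parameters")
}

#' Build covariance matrices from heritabilities and correlations
#'
#' Convenience constructor: given per-trait heritability `h2`, pen-effect
#' fraction `c2`, phenotypic variance `Vp` and a genetic correlation matrix,
#' returns `G0`, `C0`, `R0` with uncorrelated pen and residual effects.
#'
#' @param h2,c2,Vp named numeric vectors (same trait order).
#' @param rg genetic correlation matrix; non-PSD inputs are projected to the
#'   nearest positive semi-definite correlation matrix with a message.
#' @param ... passed on to [true_parameters()].
#' @return a `true_parameters` object.
#' @export
make_parameters <- function(h2, c2, Vp, rg = diag(length(h2)), ...) {
  k <- length(h2)
  stopifnot(length(c2) == k, length(Vp) == k)
  rg <- as.matrix(rg)
  ev <- eigen(rg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    message("genetic correlation matrix is not PSD (min eigenvalue ",
            signif(min(ev), 3), "); projecting to the nearest correlation matrix")
    rg <- as.matrix(Matrix::nearPD(rg, corr = TRUE)$mat)
  }
  sg <- sqrt(h2 * Vp)
  G0 <- diag(sg, k) %*% rg %*% diag(sg, k)
  dimnames(G0) <- list(names(h2), names(h2))
  C0 <- diag(c2 * Vp, k); dimnames(C0) <- dimnames(G0)
  R0 <- diag((1 - h2 - c2) * Vp, k); dimnames(R0) <- dimnames(G0)
  true_parameters(G0, C0, R0, ...)
}

#' Study-calibrated simulation preset
#'
#' True parameters for eigenvector centrality, clustering coefficient and
#' the six skin-lesion traits (three body regions x 24 h / 3 weeks), with
#' heritabilities, pen-effect fractions, phenotypic variances and genetic
#' correlations set to posterior-mean estimates reported for a Swedish
#' post-mixing aggression study; quantities that study did not report
#' (lesion h2/c2/Vp and lesion-lesion correlations) use plausible values
#' from the related literature. The assembled correlation matrix is
#' projected to the nearest PSD correlation matrix.
#'
#' @return a `true_parameters` object for 8 traits.
#' @export
paperlike_parameters <- function() {
  tr <- c("sna_eigenvector", "sna_clustering",
          "sl_anterior_24h", "sl_central_24h", "sl_posterior_24h",
          "sl_anterior_3wk", "sl_central_3wk", "sl_posterior_3wk")
  h2 <- stats::setNames(c(0.22, 0.18, 0.25, 0.20, 0.20, 0.20, 0.20, 0.15), tr)
  c2 <- stats::setNames(c(0.01, 0.23, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10), tr)
  Vp <- stats::setNames(c(0.006, 0.008, 1.166, 1.210, 1.040,
                          0.325, 0.360, 0.504), tr)
  rg <- diag(8); dimnames(rg) <- list(tr, tr)
  set <- function(a, b, v) { rg[a, b] <<- v; rg[b, a] <<- v }
  set(tr[1], tr[2], -0.95)
  # eigenvector centrality vs lesions
  set(tr[1], tr[3], 0.54); set(tr[1], tr[4], -0.19); set(tr[1], tr[5], -0.13)
  set(tr[1], tr[6], -0.47); set(tr[1], tr[7], -0.23); set(tr[1], tr[8], -0.17)
  # clustering coefficient vs lesions
  set(tr[2], tr[3], -0.14); set(tr[2], tr[4], 0.63); set(tr[2], tr[5], 0.73)
  set(tr[2], tr[6], 0.68); set(tr[2], tr[7], 0.62); set(tr[2], tr[8], 0.40)
  # lesion-lesion correlations: moderate within time point, weak across
  les <- tr[3:8]
  for (i in 1:5) for (j in (i + 1):6) {
    same_tp <- substring(les[i], nchar(les[i]) - 2) ==
      substring(les[j], nchar(les[j]) - 2)
    set(les[i], les[j], if (same_tp) 0.3 else 0.1)
  }
  suppressMessages(make_parameters(h2, c2, Vp, rg))
}

#' Simulate phenotypes on the modelled scale
#'
#' `y = fixed effects + breeding value + pen effect + residual`, with one
#' pen effect per pen drawn from `N(0, C0)` and iid residuals from
#' `N(0, R0)`; phenotypes are emitted directly on the (transformed) analysis
#' scale.
#'
#' @param assignment pen assignment data frame.
#' @param breeding_values matrix from [simulate_breeding_values()].
#' @param params a [true_parameters()] object.
#' @param seed optional RNG seed.
#' @return a `trait_table` data frame with fixed-effect columns and one
#'   column per trait.
#' @export
simulate_phenotypes <- function(assignment, breeding_values, params,
                                seed = NULL) {
  stopifnot(inherits(params, "true_parameters"))
  if (!is.null(seed)) set.seed(seed)
  k <- ncol(params$G0)
  miss <- setdiff(assignment$animal_id, rownames(breeding_values))
  if (length(miss))
    stop("breeding values missing for animals: ",
         paste(utils::head(miss, 10), collapse = ", "))
  n <- nrow(assignment)
  a <- breeding_values[as.character(assignment$animal_id), , drop = FALSE]
  chol_or_zero <- function(M) {
    if (all(M == 0)) matrix(0, ncol(M), ncol(M))
    else t(chol(M + 1e-12 * diag(ncol(M))))
  }
  Lc <- chol_or_zero(params$C0)
  Lr <- chol_or_zero(params$R0)
  pens <- sort(unique(assignment$pen_id))
  cpen <- t(Lc %*% matrix(stats::rnorm(length(pens) * k), k))
  rownames(cpen) <- pens
  e <- t(Lr %*% matrix(stats::rnorm(n * k), k))
  y <- a + cpen[as.character(assignment$pen_id), , drop = FALSE] + e
  fe <- params$fixed_effects
  if (!is.null(fe)) {
    if (!is.null(fe$intercept)) y <- sweep(y, 2, fe$intercept, `+`)
    for (term in c("line", "sex", "batch")) {
      if (!is.null(fe[[term]]))
        y <- y + fe[[term]][as.character(assignment[[term]]), , drop = FALSE]
    }
    if (!is.null(fe$weight_slope)) {
      w <- assignment$weight_at_mixing - mean(assignment$weight_at_mixing)
      y <- y + outer(w, fe$weight_slope)
    }
  }
  out <- cbind(assignment, as.data.frame(y))
  rownames(out) <- NULL
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Simulate per-pen aggressive interactions
#'
#' For every within-pen dyad `(i, j)` an undirected fight edge occurs with
#' probability `plogis(intercept + slope * (l_i + l_j))`, where `l` is each
#' animal's latent aggressiveness; bullying edges are generated analogously
#' with their own intercept and slope. The initiator is chosen at random and
#' a nominal duration is attached (unused downstream: networks are
#' unweighted and undirected).
#'
#' @param assignment pen assignment data frame.
#' @param latent named numeric vector of latent aggressiveness, one value
#'   per penned animal.
#' @param edge_model list with numeric `fight` and `bully` elements, each
#'   `c(intercept, slope)` on the logit scale.
#' @param seed optional RNG seed.
#' @return data frame of interaction records (`pen_id`, `initiator_id`,
#'   `receiver_id`, `kind`, `duration`).
#' @export
simulate_interactions <- function(assignment, latent,
                                  edge_model = list(fight = c(-1.0, 0.8),
                                                    bully = c(-2.0, 0.5)),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  miss <- setdiff(as.character(assignment$animal_id), names(latent))
  if (length(miss))
    stop("latent aggressiveness missing for animals: ",
         paste(utils::head(miss, 10), collapse = ", "))
  res <- lapply(split(assignment$animal_id, assignment$pen_id), function(ids) {
    if (length(ids) < 2) return(NULL)
    pairs <- utils::combn(ids, 2)
    lsum <- latent[as.character(pairs[1, ])] + latent[as.character(pairs[2, ])]
    out <- NULL
    for (kind in names(edge_model)) {
      par <- edge_model[[kind]]
      p <- stats::plogis(par[[1]] + par[[2]] * lsum)
      hit <- stats::runif(length(p)) < p
      if (!any(hit)) next
      flip <- stats::runif(sum(hit)) < 0.5
      out <- rbind(out, data.frame(
        initiator_id = ifelse(flip, pairs[1, hit], pairs[2, hit]),
        receiver_id = ifelse(flip, pairs[2, hit], pairs[1, hit]),
        kind = kind,
        duration = round(stats::rexp(sum(hit), 1 / 20), 1)))
    }
    out
  })
  pens <- rep(names(res), vapply(res, function(x) if (is.null(x)) 0L else nrow(x),
                                 integer(1)))
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(pen_id = integer(0), initiator_id = integer(0),
                      receiver_id = integer(0), kind = character(0),
                      duration = numeric(0)))
  out <- cbind(pen_id = as.integer(pens), out)
  rownames(out) <- NULL
  out
}

#' Threshold a liability into a binary trait
#'
#' @param liability_values numeric vector of liabilities.
#' @param threshold cut point; observations strictly above it score 1.
#' @return integer vector of 0/1.
#' @export
simulate_binary_trait <- function(liability_values, threshold = 0) {
  as.integer(liability_values > threshold)
}

#' Simulate a complete synthetic study
#'
#' Chains the generator end to end: pedigree, pen assignment, breeding
#' values, and multivariate phenotypes for the preset traits; optionally
#' also a latent-aggressiveness trait with per-pen interaction records so
#' that the network-trait module can be exercised on raw records.
#'
#' @param params a `true_parameters` object; default [paperlike_parameters()].
#' @param n_sires,n_dams,n_pens,n_batches population structure.
#' @param seed RNG seed covering every stage.
#' @param interactions if `TRUE`, additionally simulate latent
#'   aggressiveness (`h2` 0.3, unit phenotypic variance) and per-pen fight /
#'   bullying records.
#' @return list with `pedigree`, `assignment`, `breeding_values`, `traits`
#'   (a `trait_table`), `truth`, and optionally `latent` and `interactions`.
#' @export
simulate_dataset <- function(params = paperlike_parameters(),
                             n_sires = 82, n_dams = 217, n_pens = 78,
                             n_batches = 14, seed = 1,
                             interactions = FALSE) {
  set.seed(seed)
  ped <- simulate_pedigree(n_sires, n_dams)
  assignment <- assign_pens(ped, n_pens = n_pens, n_batches = n_batches)
  bv <- simulate_breeding_values(ped, params$G0)
  traits <- simulate_phenotypes(assignment, bv, params)
  out <- list(pedigree = ped, assignment = assignment, breeding_values = bv,
              traits = traits, truth = params)
  if (interactions) {
    lat_par <- make_parameters(h2 = c(latent = 0.3), c2 = c(latent = 0.1),
                               Vp = c(latent = 1))
    lat_bv <- simulate_breeding_values(ped, lat_par$G0)
    lat <- simulate_phenotypes(assignment, lat_bv, lat_par)
    out$latent <- stats::setNames(lat$latent, lat$animal_id)
    out$interactions <- simulate_interactions(assignment, out$latent,
                                              params$edge_model)
  }
  out
}
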