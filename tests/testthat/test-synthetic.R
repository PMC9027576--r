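test_that("simulated pedigrees have the declared structure", {
  ped <- simulate_pedigree(seed = 1)
  founders <- ped[ped$generation == 0, ]
  off <- ped[ped$generation == 1, ]
  expect_equal(nrow(founders), 82 + 217)
  expect_gt(nrow(ped), 2200)           # ~2427-scale two-generation pedigree
  expect_lt(nrow(ped), 2700)
  sires <- founders$animal[1:82]
  dams <- founders$animal[83:299]
  expect_true(all(off$sire %in% sires))
  expect_true(all(off$dam %in% dams))
  # one sire per dam
  expect_true(all(tapply(off$sire, off$dam, function(x) length(unique(x))) == 1))

  tiny <- simulate_pedigree(1, 1, 2, seed = 2)
  expect_equal(sum(tiny$generation == 0), 2)
  expect_equal(sum(tiny$generation == 1), 2)
  expect_equal(tiny$sire[3:4], c(1L, 1L))
  expect_equal(tiny$dam[3:4], c(2L, 2L))

  expect_error(simulate_pedigree(0, 10), "positive")
  expect_identical(simulate_pedigree(seed = 9), simulate_pedigree(seed = 9))
})

test_that("pens hold 15 same-sex same-line animals, 3 from each of 5 litters", {
  ped <- simulate_pedigree(seed = 21)
  asg <- assign_pens(ped, seed = 22)
  expect_equal(length(unique(asg$pen_id)), 78)
  per_pen <- split(asg, asg$pen_id)
  expect_true(all(vapply(per_pen, nrow, integer(1)) == 15))
  expect_true(all(vapply(per_pen, function(p)
    length(unique(p$litter_id)), integer(1)) == 5))
  expect_true(all(vapply(per_pen, function(p)
    all(table(p$litter_id) == 3), logical(1))))
  expect_true(all(vapply(per_pen, function(p)
    length(unique(p$sex)) == 1 && length(unique(p$line)) == 1, logical(1))))
  expect_false(anyDuplicated(asg$animal_id) > 0)
  expect_lte(length(unique(asg$batch)), 14)

  # singleton pens are a degenerate but legal configuration
  single <- assign_pens(ped, pen_size = 1, per_litter = 1, litters_per_pen = 1,
                        n_pens = 10, seed = 23)
  expect_true(all(table(single$pen_id) == 1))

  expect_error(assign_pens(simulate_pedigree(2, 4, 4, seed = 1), n_pens = 78),
               "infeasible pen composition")
})

test_that("breeding values have pedigree-structured covariance", {
  # 10,000 independent trios simulated in one pedigree call
  nfam <- 10000
  ped <- data.frame(
    animal = seq_len(3 * nfam),
    sire = c(rep(0L, 2 * nfam), seq_len(nfam)),
    dam = c(rep(0L, 2 * nfam), nfam + seq_len(nfam)),
    generation = c(rep(0L, 2 * nfam), rep(1L, nfam)))
  G0 <- matrix(2, 1, 1, dimnames = list("t", "t"))
  a <- simulate_breeding_values(ped, G0, seed = 31)
  sire_bv <- a[seq_len(nfam), 1]
  off_bv <- a[2 * nfam + seq_len(nfam), 1]
  # cov(parent, offspring) = 0.5 G0; MC tolerance ~ 3 SE
  se <- sqrt(2) * G0[1, 1] / sqrt(nfam)
  expect_lt(abs(cov(sire_bv, off_bv) - 0.5 * G0[1, 1]), 3 * se)
  expect_lt(abs(var(off_bv) - G0[1, 1]), 3 * se)

  # full sibs
  ped2 <- data.frame(
    animal = seq_len(4 * nfam),
    sire = c(rep(0L, 2 * nfam), rep(seq_len(nfam), 2)),
    dam = c(rep(0L, 2 * nfam), rep(nfam + seq_len(nfam), 2)),
    generation = c(rep(0L, 2 * nfam), rep(1L, 2 * nfam)))
  a2 <- simulate_breeding_values(ped2, G0, seed = 32)
  sib1 <- a2[2 * nfam + seq_len(nfam), 1]
  sib2 <- a2[3 * nfam + seq_len(nfam), 1]
  expect_lt(abs(cov(sib1, sib2) - 0.5 * G0[1, 1]), 3 * se)

  expect_equal(unname(simulate_breeding_values(ped[1:100, ],
                                               matrix(0, 1, 1), seed = 1)),
               matrix(0, 100, 1))
  expect_error(simulate_breeding_values(ped[1:10, ],
                                        matrix(c(1, 2, 2, 1), 2), seed = 1),
               "positive semi-definite")
})

test_that("phenotype variance decomposes into G0 + C0 + R0", {
  n_dams <- 2500
  ped <- simulate_pedigree(250, n_dams, 20, litter_size = 20, seed = 41)
  asg <- random_pen_assignment(ped, n_pens = 3400, seed = 42)  # ~50k animals
  pars <- make_parameters(h2 = c(x = 0.4), c2 = c(x = 0.2), Vp = c(x = 2.5))
  bv <- simulate_breeding_values(ped, pars$G0, seed = 43)
  tab <- simulate_phenotypes(asg, bv, pars, seed = 44)
  expect_gt(nrow(tab), 45000)
  expect_lt(abs(var(tab$x) - 2.5), 0.1)

  # noiseless limit: phenotype equals breeding value
  p0 <- true_parameters(pars$G0, matrix(0, 1, 1, dimnames = dimnames(pars$G0)),
                        matrix(0, 1, 1, dimnames = dimnames(pars$G0)))
  tab0 <- simulate_phenotypes(asg, bv, p0, seed = 45)
  expect_equal(tab0$x, unname(bv[as.character(asg$animal_id), 1]))

  # two traits with genetic correlation 0.9
  pars2 <- make_parameters(h2 = c(u = 0.3, v = 0.3), c2 = c(u = .1, v = .1),
                           Vp = c(u = 1, v = 1),
                           rg = matrix(c(1, 0.9, 0.9, 1), 2))
  bv2 <- simulate_breeding_values(ped, pars2$G0, seed = 46)
  expect_lt(abs(cor(bv2[, 1], bv2[, 2]) - 0.9), 0.01)
})

test_that("pen effects create the implied intraclass correlation when G0 = 0", {
  ped <- simulate_pedigree(20, 100, 15, seed = 51)
  asg <- random_pen_assignment(ped, n_pens = 100, seed = 52)
  G0 <- matrix(1e-12, 1, 1, dimnames = list("x", "x"))
  C0 <- matrix(0.3, 1, 1, dimnames = list("x", "x"))
  R0 <- matrix(0.7, 1, 1, dimnames = list("x", "x"))
  pars <- true_parameters(G0, C0, R0)
  bv <- simulate_breeding_values(ped, G0, seed = 53)
  tab <- simulate_phenotypes(asg, bv, pars, seed = 54)
  fit <- stats::aov(x ~ factor(pen_id), data = tab)
  ms <- summary(fit)[[1]]$`Mean Sq`
  nbar <- nrow(tab) / 100
  icc <- (ms[1] - ms[2]) / (ms[1] + (nbar - 1) * ms[2])
  expect_lt(abs(icc - 0.3), 0.08)
})

test_that("interaction networks follow the logistic edge model", {
  ped <- simulate_pedigree(20, 60, 10, seed = 61)
  asg <- assign_pens(ped, n_pens = 20, seed = 62)
  lat <- setNames(rnorm(nrow(asg)), asg$animal_id)

  none <- simulate_interactions(asg, lat,
                                edge_model = list(fight = c(-Inf, 0)),
                                seed = 63)
  expect_equal(nrow(none), 0)

  half <- simulate_interactions(asg, lat,
                                edge_model = list(fight = c(0, 0)), seed = 64)
  net_sizes <- nrow(half)
  # Bernoulli(0.5) per dyad: mean per-animal degree ~ (pen_size - 1) / 2
  deg <- table(factor(c(half$initiator_id, half$receiver_id),
                      levels = asg$animal_id))
  expect_lt(abs(mean(deg) - 7), 0.5)

  pos <- simulate_interactions(asg, lat,
                               edge_model = list(fight = c(-1, 0.8)),
                               seed = 65)
  deg2 <- table(factor(c(pos$initiator_id, pos$receiver_id),
                       levels = asg$animal_id))
  rho <- cor(lat[names(deg2)], as.numeric(deg2), method = "spearman")
  expect_gt(rho, 0.2)

  expect_identical(simulate_interactions(asg, lat, seed = 66),
                   simulate_interactions(asg, lat, seed = 66))
})

test_that("liability thresholding behaves monotonically", {
  set.seed(71)
  liab <- rnorm(10000)
  expect_true(all(simulate_binary_trait(liab, -Inf) == 1))
  expect_lt(abs(mean(simulate_binary_trait(liab, 0)) - 0.5), 0.02)
  p1 <- mean(simulate_binary_trait(liab, 0.5))
  p2 <- mean(simulate_binary_trait(liab, 1.5))
  expect_lt(p2, p1)
})

test_that("the study preset is a valid parameter set with the reported signs", {
  pars <- paperlike_parameters()
  expect_s3_class(pars, "true_parameters")
  expect_equal(unname(pars$h2["sna_eigenvector"]), 0.22, tolerance = 1e-10)
  ev <- eigen(pars$G0, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  rg <- cov2cor(pars$G0)
  # sign pattern that drives the selection-response analysis
  expect_lt(rg["sna_eigenvector", "sna_clustering"], -0.5)
  expect_gt(rg["sna_eigenvector", "sl_anterior_24h"], 0.3)
  expect_gt(rg["sna_clustering", "sl_posterior_3wk"], 0.2)
  expect_lt(rg["sna_clustering", "sl_anterior_24h"], 0)
})

test_that("the end-to-end generator is deterministic given a seed", {
  s1 <- simulate_dataset(seed = 81, n_sires = 10, n_dams = 30, n_pens = 8)
  s2 <- simulate_dataset(seed = 81, n_sires = 10, n_dams = 30, n_pens = 8)
  expect_identical(s1$traits, s2$traits)
  expect_identical(s1$pedigree, s2$pedigree)
})
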