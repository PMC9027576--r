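small_fit_data <- function(seed = 1, h2 = 0.3, c2 = 0.1) {
  ped <- simulate_pedigree(20, 60, 8, seed = seed)
  asg <- random_pen_assignment(ped, n_pens = 30, seed = seed + 1)
  pars <- make_parameters(h2 = c(tr = h2), c2 = c(tr = c2), Vp = c(tr = 1))
  bv <- simulate_breeding_values(ped, pars$G0, seed = seed + 2)
  tab <- simulate_phenotypes(asg, bv, pars, seed = seed + 3)
  list(ped = ped, asg = asg, tab = tab)
}

test_that("the design system encodes fixed effects as in the study model", {
  d <- make_recovery_data(301)
  des <- build_design(d$tab, model_spec("tr"), d$ped)
  # intercept + line (2 lev) + sex (3 lev) + batch (14 lev) + weight
  expect_equal(ncol(des$X), 1 + 1 + 2 + 13 + 1)
  expect_equal(unname(des$X[, 1]), rep(1, nrow(des$X)))
  # covariate is centred
  expect_lt(abs(mean(des$X[, "weight_at_mixing"])), 1e-10)
  # every record maps to exactly one pen and one pedigree animal
  expect_true(all(des$wid >= 1 & des$wid <= des$npen))
  expect_true(all(des$zid >= 1 & des$zid <= des$q))

  tab2 <- d$tab
  tab2$tr[1:7] <- NA
  expect_message(des2 <- build_design(tab2, model_spec("tr"), d$ped),
                 "dropping 7")
  expect_equal(nrow(des2$y), nrow(d$tab) - 7)

  tab3 <- d$tab
  tab3$line <- "Y"
  expect_warning(build_design(tab3, model_spec("tr"), d$ped),
                 "single observed level")

  tab4 <- d$tab
  tab4$tr <- NA_real_
  expect_error(suppressMessages(build_design(tab4, model_spec("tr"), d$ped)),
               "no complete records")

  tab5 <- d$tab
  tab5$bin <- 0
  expect_error(build_design(tab5, model_spec("bin", "threshold"), d$ped),
               "separation")
})

test_that("HPD intervals are the shortest windows over sorted draws", {
  expect_equal(hpd_interval(1:100), c(lower = 1, upper = 95))
  expect_equal(unname(diff(hpd_interval(rep(3.5, 50)))), 0)
  expect_error(hpd_interval(1:10), "at least 20")

  # brute-force window oracle
  set.seed(12)
  for (rep in 1:20) {
    x <- rgamma(200, shape = 2)
    m <- ceiling(0.9 * 200)
    xs <- sort(x)
    widths <- xs[m:200] - xs[1:(200 - m + 1)]
    i <- which.min(widths)
    expect_equal(hpd_interval(x, 0.9),
                 c(lower = xs[i], upper = xs[i + m - 1]))
  }

  # symmetric unimodal: HPD approximately the equal-tail interval
  set.seed(13)
  z <- rnorm(1e6)
  hpd <- hpd_interval(z)
  expect_equal(unname(hpd), c(-1.96, 1.96), tolerance = 0.02)
})

test_that("posterior summaries derive h2, c2, Vp, rg correctly", {
  chains <- cbind(G_1_1 = rep(1, 200), C_1_1 = rep(1, 200),
                  R_1_1 = rep(2, 200))
  fake <- structure(list(chains = chains, n_stored = 200, traits = "x",
                         kinds = "linear",
                         ebv = matrix(0, 1, 1, dimnames = list("1", "x"))),
                    class = "posterior_samples")
  s <- summarize_posterior(fake)
  p <- s$parameters
  expect_equal(p$mean[p$parameter == "h2_x"], 0.25)
  expect_equal(p$mean[p$parameter == "c2_x"], 0.25)
  expect_equal(p$mean[p$parameter == "Vp_x"], 4)
  expect_equal(unname(diff(unlist(
    p[p$parameter == "h2_x", c("hpd_lower", "hpd_upper")]))), 0)

  # perfectly correlated bivariate draws imply rg = 1
  g <- rgamma(200, 3)
  chains2 <- cbind(G_1_1 = g, G_1_2 = g, G_2_2 = g,
                   C_1_1 = 1, C_1_2 = 0, C_2_2 = 1,
                   R_1_1 = 1, R_1_2 = 0, R_2_2 = 1)
  fake2 <- structure(list(chains = chains2, n_stored = 200,
                          traits = c("x", "y"), kinds = c("linear", "linear"),
                          ebv = matrix(0, 1, 2,
                                       dimnames = list("1", c("x", "y")))),
                     class = "posterior_samples")
  s2 <- summarize_posterior(fake2)
  expect_equal(s2$parameters$mean[s2$parameters$parameter == "rg"], 1)

  fake$n_stored <- 50
  expect_error(summarize_posterior(fake), "at least 100")
})

test_that("the truncated-normal sampler has the closed-form tail mean", {
  set.seed(14)
  draws <- pensna:::rtnorm_cpp(1e6, 0, 1, TRUE)
  expect_true(all(draws > 0))
  expect_equal(mean(draws), sqrt(2 / pi), tolerance = 0.005)
  neg <- pensna:::rtnorm_cpp(1e5, 0.3, 1.5, FALSE)
  expect_true(all(neg < 0))
})

test_that("chains are bit-identical given the same seed and settings", {
  d <- small_fit_data(401)
  des <- build_design(d$tab, model_spec("tr"), d$ped)
  Ainv <- build_A_inverse(d$ped)
  st <- mcmc_settings(4000, 500, 5, seed = 402)
  f1 <- gibbs_linear(des, Ainv, st)
  f2 <- gibbs_linear(des, Ainv, st)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$ebv, f2$ebv)
  # every stored covariance draw is a valid variance
  expect_true(all(f1$chains[, "G_1_1"] > 0))
  expect_true(all(f1$chains[, "C_1_1"] > 0))
  expect_true(all(f1$chains[, "R_1_1"] > 0))
})

test_that("the sampler agrees with an independent conjugate sampler when A = I", {
  set.seed(411)
  n <- 400
  npen <- 40
  pen <- rep(seq_len(npen), each = n / npen)
  a_true <- rnorm(n, 0, sqrt(0.4))
  c_true <- rnorm(npen, 0, sqrt(0.2))
  y <- 1 + a_true + c_true[pen] + rnorm(n, 0, sqrt(0.6))
  ped <- data.frame(animal = 1:n, sire = 0, dam = 0, generation = 1L)
  tab <- data.frame(animal_id = 1:n, pen_id = pen, tr = y)
  spec <- model_spec("tr", fixed = character(0), covariate = NULL)
  des <- build_design(tab, spec, ped)
  Ainv <- build_A_inverse(ped)
  fit <- gibbs_linear(des, Ainv, mcmc_settings(12000, 2000, 5, seed = 412))
  ref <- reference_gibbs_iid(y, pen, 12000, 2000, 5)
  # without relatives, sigma_a and sigma_e are separated only weakly, so the
  # total variance is compared tightly and the components loosely
  tot_fit <- mean(fit$chains[, "G_1_1"] + fit$chains[, "C_1_1"] +
                    fit$chains[, "R_1_1"])
  tot_ref <- mean(rowSums(ref))
  expect_equal(tot_fit, tot_ref, tolerance = 0.03)
  expect_equal(mean(fit$chains[, "G_1_1"]), mean(ref[, "va"]), tolerance = 0.3)
  expect_equal(mean(fit$chains[, "C_1_1"]), mean(ref[, "vc"]), tolerance = 0.3)
  expect_equal(mean(fit$chains[, "R_1_1"]), mean(ref[, "ve"]), tolerance = 0.3)
})

test_that("posterior fixed effects match the GLS/BLUP solution at scale", {
  d <- make_recovery_data(421)
  des <- build_design(d$tab, model_spec("tr"), d$ped)
  Ainv <- build_A_inverse(d$ped)
  fit <- gibbs_linear(des, Ainv, mcmc_settings(8000, 1000, 5, seed = 422))
  sol <- oracle_mme_blup(des$y[, 1], des$X, des$zid, des$wid,
                         Ainv, des$q, des$npen, va = 0.3, vc = 0.1, ve = 0.6)
  bpost <- colMeans(fit$chains[, grep("^b_", colnames(fit$chains))])
  # contrast-coded effects and the covariate slope agree to a few hundredths
  # (the chain also averages over variance-component uncertainty)
  expect_lt(max(abs(unname(bpost[-1]) - sol$b[-1])), 0.06)
  # EBVs from the chain correlate strongly with the known-variance BLUP
  expect_gt(cor(fit$ebv[, 1], sol$a), 0.97)
})

test_that("a duplicated trait drives the genetic correlation towards one", {
  d <- small_fit_data(431)
  tab <- d$tab
  tab$tr2 <- tab$tr
  des <- build_design(tab, model_spec(c("tr", "tr2")), d$ped)
  Ainv <- build_A_inverse(d$ped)
  fit <- gibbs_bivariate(des, Ainv, mcmc_settings(4000, 1000, 5, seed = 432))
  s <- summarize_posterior(fit)
  expect_gt(s$parameters$mean[s$parameters$parameter == "rg"], 0.95)
})

test_that("convergence diagnostics separate iid from sticky chains", {
  set.seed(441)
  iid <- rnorm(1e5)
  rep_iid <- convergence_diagnostic(iid)
  expect_lt(rep_iid$dependence_factor, 1.5)
  expect_gt(rep_iid$effective_size, 5e4)

  ar <- as.numeric(stats::arima.sim(list(ar = 0.95), 1e5))
  rep_ar <- convergence_diagnostic(ar)
  expect_gt(rep_ar$dependence_factor, 5)

  expect_error(convergence_diagnostic(rnorm(10)), "too short")
})

test_that("mcmc settings are validated", {
  expect_error(mcmc_settings(1000, 1000), "burn_in")
  expect_error(mcmc_settings(1000, 10, 0), "thin")
  expect_error(gibbs_threshold(
    structure(list(y = matrix(0, 2, 2),
                   spec = list(kinds = c("linear", "linear"))),
              class = "design_system"), NULL), "single threshold")
})
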