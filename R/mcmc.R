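# Bayesian animal models by Gibbs sampling.
#
# The model is y = Xb + Za + Wc + e with flat priors on b and on the
# covariance components, a ~ N(0, A (x) G0), c ~ N(0, I (x) C0),
# e ~ N(0, I (x) R0). Univariate and bivariate responses are supported;
# each trait is either linear or threshold-binary (liability scale,
# threshold fixed at 0 and residual variance fixed at 1).

#' Specify an animal model
#'
#' @param traits character vector of 1 or 2 response column names.
#' @param kinds `"linear"` or `"threshold"` per trait (recycled).
#' @param fixed factor fixed-effect columns; default line, sex and batch.
#' @param covariate numeric covariate column (centred internally); `NULL`
#'   to omit.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(traits, kinds = "linear",
                       fixed = c("line", "sex", "batch"),
                       covariate = "weight_at_mixing") {
  if (length(traits) < 1 || length(traits) > 2)
    stop("1 or 2 response traits are supported")
  kinds <- rep(match.arg(kinds, c("linear", "threshold"), several.ok = TRUE),
               length.out = length(traits))
  if (sum(kinds == "threshold") == 2)
    warning("threshold-threshold bivariate models are experimental")
  structure(list(traits = traits, kinds = kinds, fixed = fixed,
                 covariate = covariate),
            class = "model_spec")
}

#' Build the mixed-model design system
#'
#' Assembles the stacked response, the fixed-effect matrix X (intercept,
#' treatment-coded factors, centred covariate), and the record-to-animal and
#' record-to-pen maps. Records with a missing value in any used column are
#' dropped with a message. Z implicitly includes every pedigree animal, so
#' non-phenotyped ancestors contribute through the relationship structure
#' only.
#'
#' @param trait_table a `trait_table` data frame.
#' @param spec a [model_spec()].
#' @param pedigree pedigree data frame covering every phenotyped animal.
#' @return object of class `design_system`.
#' @export
build_design <- function(trait_table, spec, pedigree) {
  stopifnot(inherits(spec, "model_spec"))
  cols <- c(spec$traits, spec$fixed, spec$covariate, "animal_id", "pen_id")
  missing_cols <- setdiff(cols, names(trait_table))
  if (length(missing_cols))
    stop("columns missing from trait table: ",
         paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(trait_table[, cols, drop = FALSE])
  if (!all(keep))
    message("dropping ", sum(!keep), " record(s) with missing values")
  tab <- trait_table[keep, , drop = FALSE]
  if (!nrow(tab)) stop("no complete records for the requested model")

  y <- as.matrix(tab[, spec$traits, drop = FALSE])
  for (t in seq_along(spec$traits)) {
    if (spec$kinds[t] == "threshold") {
      vals <- unique(y[, t])
      if (!all(vals %in% c(0, 1)))
        stop("threshold trait '", spec$traits[t], "' must be binary 0/1")
      if (length(vals) < 2)
        stop("threshold trait '", spec$traits[t],
             "' has a single observed category (complete separation)")
    }
  }

  terms <- character(0)
  for (f in spec$fixed) {
    tab[[f]] <- droplevels(factor(tab[[f]]))
    if (nlevels(tab[[f]]) < 2) {
      warning("fixed effect '", f, "' has a single observed level; dropped ",
              "(rank deficiency)")
    } else terms <- c(terms, f)
  }
  if (!is.null(spec$covariate)) {
    tab$.cov <- tab[[spec$covariate]] - mean(tab[[spec$covariate]])
    terms <- c(terms, ".cov")
  }
  form <- stats::as.formula(paste("~", paste(c("1", terms), collapse = " + ")))
  X <- stats::model.matrix(form, data = tab)
  colnames(X)[colnames(X) == ".cov"] <- spec$covariate

  ped <- pedigree_sort(pedigree)
  zid <- match(tab$animal_id, ped$animal)
  if (anyNA(zid))
    stop("phenotyped animals missing from the pedigree: ",
         paste(utils::head(tab$animal_id[is.na(zid)], 10), collapse = ", "))
  pen_ids <- sort(unique(tab$pen_id))
  wid <- match(tab$pen_id, pen_ids)
  structure(list(y = y, X = X, zid = zid, wid = wid,
                 q = nrow(ped), npen = length(pen_ids),
                 animal_ids = ped$animal, pen_ids = pen_ids,
                 record_ids = tab$animal_id,
                 spec = spec, pedigree = ped),
            class = "design_system")
}

#' MCMC settings
#'
#' Desk-scale default protocol: 50,000 iterations, 5,000 burn-in, thinning
#' 10. The full-scale protocol used for production analyses of this model
#' family is 1,000,000 / 100,000 / 20.
#'
#' @param n_iter,burn_in,thin chain length, burn-in, thinning lag.
#' @param seed RNG seed (mandatory for reproducible chains).
#' @param prior `"auto"` (default: flat for all-linear models, weak for any
#'   model with a threshold trait), `"flat"` (improper inverse-Wishart) or
#'   `"weak"` (proper, df `k + 1`, scale `0.1 I`) for the genetic and pen
#'   covariance components. Binary data constrain the liability-scale
#'   variances only weakly, and under a fully flat prior the genetic
#'   variance chain can drift towards an improper mode, so threshold models
#'   get the proper prior unless explicitly overridden.
#' @return object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 50000, burn_in = 5000, thin = 10,
                          seed = NULL, prior = c("auto", "flat", "weak")) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed,
                 prior = match.arg(prior)),
            class = "mcmc_settings")
}

.run_gibbs <- function(design, A_inverse, settings) {
  stopifnot(inherits(design, "design_system"),
            inherits(settings, "mcmc_settings"))
  k <- ncol(design$y)
  q <- design$q
  Ainv <- methods::as(methods::as(A_inverse, "CsparseMatrix"), "generalMatrix")
  if (nrow(Ainv) != q)
    stop("A_inverse dimension does not match the pedigree")
  if (!is.null(settings$seed)) set.seed(settings$seed)
  thr <- design$spec$kinds == "threshold"
  prior <- settings$prior
  if (prior == "auto") prior <- if (any(thr)) "weak" else "flat"
  if (prior == "flat") {
    nu0 <- -(k + 1); S0 <- matrix(0, k, k)
  } else {
    nu0 <- k + 1; S0 <- diag(0.1, k)
  }
  # starting values: an even split of the phenotypic variance
  vy <- apply(design$y, 2, stats::var)
  vy[thr] <- 1 / 0.6  # liability scale
  Gs <- diag(0.3 * vy, k); Cs <- diag(0.1 * vy, k); Rs <- diag(0.6 * vy, k)
  fit <- gibbs_animal_cpp(design$y, design$X,
                          as.integer(design$zid - 1L),
                          as.integer(design$wid - 1L),
                          q, design$npen,
                          Ainv@p, Ainv@i, Ainv@x,
                          thr,
                          settings$n_iter, settings$burn_in, settings$thin,
                          nu0, S0, nu0, S0, nu0, S0,
                          Gs, Cs, Rs)
  covnames <- function(prefix) {
    idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
    idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
    paste0(prefix, "_", idx[, "row"], "_", idx[, "col"])
  }
  colnames(fit$chains) <- c(covnames("G"), covnames("C"), covnames("R"),
                            paste0("b_", rep(colnames(design$X), k), "_t",
                                   rep(seq_len(k), each = ncol(design$X))))
  rownames(fit$a_mean) <- rownames(fit$a_sd) <- design$animal_ids
  colnames(fit$a_mean) <- colnames(fit$a_sd) <- design$spec$traits
  structure(list(chains = fit$chains, ebv = fit$a_mean, ebv_sd = fit$a_sd,
                 n_stored = fit$n_stored, traits = design$spec$traits,
                 kinds = design$spec$kinds, settings = settings,
                 n_records = nrow(design$y)),
            class = "posterior_samples")
}

#' Gibbs sampler for the linear animal model
#'
#' @param design a [build_design()] object with linear trait(s).
#' @param A_inverse sparse inverse relationship matrix from
#'   [build_A_inverse()], in pedigree order.
#' @param settings an [mcmc_settings()] object.
#' @return object of class `posterior_samples`: thinned post-burn-in chains
#'   of the covariance components and fixed effects, plus per-animal
#'   posterior means and SDs of the additive genetic effects (EBVs).
#' @export
gibbs_linear <- function(design, A_inverse, settings = mcmc_settings()) {
  if (any(design$spec$kinds != "linear"))
    stop("gibbs_linear expects linear traits; use gibbs_threshold")
  .run_gibbs(design, A_inverse, settings)
}

#' Gibbs sampler for the threshold liability animal model
#'
#' Binary observations are augmented with a latent normal liability;
#' identifiability is fixed by a zero threshold and unit residual variance,
#' so the reported genetic and pen variances are on the liability scale.
#'
#' @inheritParams gibbs_linear
#' @export
gibbs_threshold <- function(design, A_inverse, settings = mcmc_settings()) {
  if (ncol(design$y) != 1 || design$spec$kinds[1] != "threshold")
    stop("gibbs_threshold expects a single threshold trait")
  .run_gibbs(design, A_inverse, settings)
}

#' Gibbs sampler for bivariate animal models
#'
#' Linear-linear, linear-threshold or (experimental) threshold-threshold
#' trait pairs; 2x2 covariance matrices are drawn from inverse-Wishart full
#' conditionals, and each threshold trait's scale is fixed to unit residual
#' variance.
#'
#' @inheritParams gibbs_linear
#' @export
gibbs_bivariate <- function(design, A_inverse, settings = mcmc_settings()) {
  if (ncol(design$y) != 2)
    stop("gibbs_bivariate expects exactly two traits")
  .run_gibbs(design, A_inverse, settings)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval over the sorted draws containing
#' `ceiling(mass * n)` draws; ties resolved towards the smallest lower
#' bound.
#'
#' @param chain numeric vector of posterior draws (length >= 20).
#' @param mass posterior mass to cover.
#' @return named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(chain, mass = 0.95) {
  n <- length(chain)
  if (n < 20) stop("need at least 20 draws for an HPD interval")
  m <- ceiling(mass * n)
  xs <- sort(chain)
  if (m >= n) return(c(lower = xs[1], upper = xs[n]))
  lo <- seq_len(n - m + 1)
  width <- xs[lo + m - 1] - xs[lo]
  i <- which.min(width)  # which.min takes the first minimum: smallest lower bound
  c(lower = xs[i], upper = xs[i + m - 1])
}

#' Summarise posterior samples
#'
#' Computes, per stored draw, the derived genetic parameters -- heritability
#' `h2 = s2_a / (s2_a + s2_c + s2_e)`, pen-effect fraction `c2`, phenotypic
#' variance `Vp`, and for trait pairs the genetic correlation
#' `rg = G_12 / sqrt(G_11 G_22)` -- and reports posterior mean, SD and HPD95%
#' of each, together with posterior-mean EBVs. For threshold traits the
#' residual variance in the denominator is the fixed liability-scale 1.
#'
#' @param samples a `posterior_samples` object.
#' @param mass HPD mass (default 0.95).
#' @return object of class `posterior_summary` with elements `parameters`
#'   (data frame) and `ebv` (data frame of posterior-mean breeding values).
#' @export
summarize_posterior <- function(samples, mass = 0.95) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (samples$n_stored < 100)
    stop("need at least 100 stored draws to summarise")
  ch <- samples$chains
  k <- length(samples$traits)
  derived <- list()
  for (t in seq_len(k)) {
    g <- ch[, sprintf("G_%d_%d", t, t)]
    cc <- ch[, sprintf("C_%d_%d", t, t)]
    e <- ch[, sprintf("R_%d_%d", t, t)]
    vp <- g + cc + e
    derived[[paste0("h2_", samples$traits[t])]] <- g / vp
    derived[[paste0("c2_", samples$traits[t])]] <- cc / vp
    derived[[paste0("Vp_", samples$traits[t])]] <- vp
  }
  if (k == 2) {
    den <- sqrt(ch[, "G_1_1"] * ch[, "G_2_2"])
    derived[["rg"]] <- ifelse(den > 0, ch[, "G_1_2"] / den, NA_real_)
  }
  for (nm in colnames(ch)) derived[[nm]] <- ch[, nm]
  params <- do.call(rbind, lapply(names(derived), function(nm) {
    x <- derived[[nm]]
    hpd <- hpd_interval(x[is.finite(x)], mass)
    data.frame(parameter = nm, mean = mean(x, na.rm = TRUE),
               sd = stats::sd(x, na.rm = TRUE),
               hpd_lower = hpd[["lower"]], hpd_upper = hpd[["upper"]])
  }))
  ebv <- data.frame(animal_id = rownames(samples$ebv), samples$ebv,
                    row.names = NULL, check.names = FALSE)
  structure(list(parameters = params, ebv = ebv, traits = samples$traits,
                 n_stored = samples$n_stored),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary (", x$n_stored, " stored draws)\n", sep = "")
  show <- x$parameters[grepl("^(h2|c2|Vp|rg)", x$parameters$parameter), ]
  print(format(show, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Chain convergence diagnostics
#'
#' Raftery--Lewis run-length control for estimating the 2.5% posterior
#' quantile to within +/- 0.005 with 95% confidence, plus the effective
#' sample size of the chain.
#'
#' @param chain numeric vector of (ideally unthinned) MCMC draws.
#' @param q,r,s quantile, precision and confidence of the Raftery--Lewis
#'   criterion.
#' @return object of class `convergence_report` with the required burn-in,
#'   required chain length, minimum (independence) length, dependence
#'   factor and effective sample size.
#' @export
convergence_diagnostic <- function(chain, q = 0.025, r = 0.005, s = 0.95) {
  nmin <- ceiling(stats::qnorm((1 + s) / 2)^2 * q * (1 - q) / r^2)
  if (length(chain) < nmin)
    stop("chain too short for the Raftery-Lewis pilot estimate: need >= ",
         nmin, " draws, have ", length(chain))
  rl <- coda::raftery.diag(coda::mcmc(chain), q = q, r = r, s = s)
  res <- rl$resmatrix
  structure(list(burn_in = unname(res[1, "M"]),
                 n_required = unname(res[1, "N"]),
                 n_min = unname(res[1, "Nmin"]),
                 dependence_factor = unname(res[1, "I"]),
                 effective_size = unname(coda::effectiveSize(coda::mcmc(chain)))),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Raftery-Lewis: burn-in", x$burn_in, "| required N", x$n_required,
      "| dependence factor", round(x$dependence_factor, 2),
      "| ESS", round(x$effective_size), "\n")
  invisible(x)
}
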