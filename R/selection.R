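# Truncation selection on standardized EBVs and the correlated response on
# skin-lesion traits, at the individual and at the pen level.

#' Standardise EBV columns into z-scores
#'
#' Each trait column is centred and scaled to unit standard deviation
#' (sample SD, divisor `n - 1`, by default) over the whole population.
#'
#' @param ebv_table data frame with `animal_id` (optionally `pen_id`) and
#'   numeric EBV columns.
#' @param sd_type `"sample"` (divisor n-1, default) or `"population"`
#'   (divisor n).
#' @return the table with every numeric EBV column standardised.
#' @export
standardize_ebv <- function(ebv_table, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  num <- setdiff(names(ebv_table)[vapply(ebv_table, is.numeric, logical(1))],
                 c("animal_id", "pen_id"))
  if (nrow(ebv_table) < 2) stop("need at least 2 animals to standardise")
  for (col in num) {
    x <- ebv_table[[col]]
    s <- stats::sd(x)
    if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
    if (!is.finite(s) || s == 0)
      stop("EBV column '", col, "' has zero standard deviation")
    ebv_table[[col]] <- (x - mean(x)) / s
  }
  ebv_table
}

#' Equal-weight selection index from two standardised EBV vectors
#'
#' The eigenvector-clustering index: a weighted sum of the standardised
#' EBVs of both traits, with equal weights by default.
#'
#' @param z_eigen,z_clustering named numeric vectors of standardised EBVs
#'   over the same animals.
#' @param weights length-2 numeric weights.
#' @return named numeric index vector.
#' @export
build_index <- function(z_eigen, z_clustering, weights = c(1, 1)) {
  if (is.null(names(z_eigen)) || is.null(names(z_clustering)))
    stop("index inputs must be named by animal id")
  if (!setequal(names(z_eigen), names(z_clustering)))
    stop("index inputs cover different animal sets")
  z_clustering <- z_clustering[names(z_eigen)]
  weights[1] * z_eigen + weights[2] * z_clustering
}

#' Truncation-select the lowest fraction
#'
#' Picks the `floor(fraction * n)` animals with the smallest criterion
#' values; ties at the cut are broken by stable input order.
#'
#' @param values named numeric criterion vector (e.g. standardised EBVs).
#' @param fraction selected proportion, in (0, 1).
#' @return character vector of selected ids.
#' @export
select_lowest <- function(values, fraction = 0.10) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (is.null(names(values))) stop("values must be named by animal id")
  m <- floor(fraction * length(values))
  if (m < 1) stop("selected fraction is empty at this population size")
  names(values)[order(values)[seq_len(m)]]
}

#' Correlated response of target traits in a selected group
#'
#' Mean and standard error (`SD / sqrt(n)`) of every target column within
#' the selected animals, next to the population mean.
#'
#' @param selected_ids ids returned by [select_lowest()].
#' @param target_table data frame with `animal_id` and numeric target
#'   columns (standardised EBVs or phenotypes).
#' @return data frame of class `selection_report`.
#' @export
correlated_response <- function(selected_ids, target_table) {
  if (!length(selected_ids)) stop("empty selection")
  sel <- target_table[target_table$animal_id %in% selected_ids, , drop = FALSE]
  if (!nrow(sel)) stop("no selected animals found in the target table")
  num <- setdiff(names(target_table)[vapply(target_table, is.numeric,
                                            logical(1))],
                 c("animal_id", "pen_id"))
  out <- do.call(rbind, lapply(num, function(col) {
    x <- sel[[col]]
    data.frame(target = col,
               group_mean = mean(x, na.rm = TRUE),
               group_se = stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))),
               population_mean = mean(target_table[[col]], na.rm = TRUE),
               n_selected = sum(!is.na(x)))
  }))
  class(out) <- c("selection_report", "data.frame")
  out
}

#' Pen-level truncation selection
#'
#' Ranks pens by the per-pen mean or standard deviation (a diversity
#' measure) of a criterion column, selects the lowest `fraction` of pens,
#' and reports the correlated response of the target columns over all
#' animals in the selected pens.
#'
#' @param ebv_table data frame with `animal_id`, `pen_id` and numeric
#'   columns.
#' @param criterion criterion column name.
#' @param stat `"mean"` or `"sd"` of the criterion within pen.
#' @param fraction fraction of pens selected (floor rounding).
#' @param targets target column names; default all numeric columns.
#' @return data frame of class `selection_report` with the selected pen ids
#'   as attribute `"selected_pens"`.
#' @export
pen_rank_select <- function(ebv_table, criterion, stat = c("mean", "sd"),
                            fraction = 0.20, targets = NULL) {
  stat <- match.arg(stat)
  stopifnot(criterion %in% names(ebv_table),
            all(c("animal_id", "pen_id") %in% names(ebv_table)))
  tab <- ebv_table
  if (stat == "sd") {
    sizes <- table(tab$pen_id)
    singles <- names(sizes)[sizes < 2]
    if (length(singles)) {
      warning("excluding ", length(singles),
              " singleton pen(s) from SD ranking")
      tab <- tab[!tab$pen_id %in% singles, , drop = FALSE]
    }
  }
  f <- if (stat == "mean") mean else stats::sd
  per_pen <- stats::aggregate(tab[[criterion]], list(pen_id = tab$pen_id),
                              f)
  m <- floor(fraction * nrow(per_pen))
  if (m < 1) stop("selected fraction is empty at this number of pens")
  sel_pens <- per_pen$pen_id[order(per_pen$x)[seq_len(m)]]
  if (is.null(targets))
    targets <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                       c("animal_id", "pen_id"))
  sel_ids <- tab$animal_id[tab$pen_id %in% sel_pens]
  out <- correlated_response(sel_ids,
                             tab[, c("animal_id", targets), drop = FALSE])
  attr(out, "selected_pens") <- sel_pens
  attr(out, "stat") <- stat
  out
}

#' Spearman rank correlations between trait columns
#'
#' Pairwise Spearman correlations with average-rank ties and pairwise
#' complete observations; pairs with fewer than 3 complete rows or a
#' constant column yield `NA` with a warning.
#'
#' @param trait_table a data frame.
#' @param columns column names to correlate.
#' @return symmetric correlation matrix.
#' @export
spearman_matrix <- function(trait_table, columns) {
  stopifnot(all(columns %in% names(trait_table)))
  x <- as.matrix(trait_table[, columns, drop = FALSE])
  const <- apply(x, 2, function(v) length(unique(v[!is.na(v)])) < 2)
  if (any(const))
    warning("constant column(s): ", paste(columns[const], collapse = ", "),
            "; correlations set to NA")
  suppressWarnings(rho <- stats::cor(x, method = "spearman",
                                     use = "pairwise.complete.obs"))
  for (i in seq_along(columns)) for (j in seq_along(columns)) {
    ok <- sum(stats::complete.cases(x[, c(i, j)]))
    if (i != j && ok < 3) rho[i, j] <- NA_real_
  }
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho) <- 1
  rho
}
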