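# Variable transformations linking raw records to the modelled traits:
# pre-mixing lesion adjustment, log(x + 1) for lesion counts and square root
# for the skewed continuous network traits.

#' Net skin-lesion count 24 h post-mixing
#'
#' Subtracts each animal's pre-mixing lesion count from its 24 h count so
#' that only fresh, mixing-induced lesions remain. Negative differences
#' (more lesions before mixing than after, e.g. healed or miscounted ones)
#' are clamped to zero with a warning.
#'
#' @param count_24h,count_premix non-negative integer vectors.
#' @return integer vector of adjusted counts; the number of clamped records
#'   is attached as attribute `"clamped"`.
#' @export
net_lesions <- function(count_24h, count_premix) {
  if (any(count_24h < 0, na.rm = TRUE) || any(count_premix < 0, na.rm = TRUE))
    stop("lesion counts must be non-negative")
  d <- count_24h - count_premix
  clamped <- sum(d < 0, na.rm = TRUE)
  if (clamped > 0)
    warning(clamped, " net lesion count(s) were negative and clamped to 0")
  structure(as.integer(pmax(d, 0)), clamped = clamped)
}

#' log(x + 1) transform for lesion counts
#'
#' @param count non-negative numeric vector.
#' @return `log(count + 1)` (natural log).
#' @export
log1_transform <- function(count) {
  if (any(count < 0, na.rm = TRUE)) stop("counts must be non-negative")
  log(count + 1)
}

#' Square-root transform for skewed network traits
#'
#' @param value non-negative numeric vector.
#' @return `sqrt(value)`.
#' @export
sqrt_transform <- function(value) {
  if (any(value < 0, na.rm = TRUE)) stop("values must be non-negative")
  sqrt(value)
}

#' Assemble the modelling trait table
#'
#' Joins per-animal network traits (square-root transformed; categorical as
#' 0/1), skin-lesion records (pre-mixing-adjusted and log(x+1)-transformed at
#' 24 h; raw fresh counts log-transformed at 3 weeks) and the fixed-effect
#' columns into one table on the modelled scale, one row per animal.
#'
#' Column conventions: network traits `sna_degree`, `sna_betweenness`,
#' `sna_closeness`, `sna_eigenvector`, `sna_clustering`,
#' `sna_betweenness_cat`, `sna_clique`; lesions
#' `sl_{anterior|central|posterior}_{24h|3wk}`.
#'
#' @param sna_records output of [pen_sna_traits()].
#' @param lesion_records long data frame with columns `animal_id`, `region`
#'   (anterior/central/posterior), `timepoint` (premix/24h/3wk), `count`.
#' @param assignment pen assignment table with `animal_id`, `pen_id`,
#'   `litter_id`, `sex`, `line`, `batch`, `weight_at_mixing`.
#' @return data frame of class `trait_table`.
#' @export
assemble_trait_table <- function(sna_records, lesion_records, assignment) {
  ids <- assignment$animal_id
  miss <- setdiff(union(sna_records$animal_id, lesion_records$animal_id), ids)
  if (length(miss))
    stop("animal ids not present in the pen assignment: ",
         paste(sort(miss), collapse = ", "))
  out <- assignment[, c("animal_id", "pen_id", "litter_id", "sex", "line",
                        "batch", "weight_at_mixing")]
  m <- match(out$animal_id, sna_records$animal_id)
  out$sna_degree <- sqrt_transform(sna_records$degree[m])
  out$sna_betweenness <- sqrt_transform(sna_records$betweenness[m])
  out$sna_closeness <- sqrt_transform(sna_records$closeness[m])
  out$sna_eigenvector <- sqrt_transform(sna_records$eigenvector[m])
  out$sna_clustering <- sqrt_transform(sna_records$clustering[m])
  out$sna_betweenness_cat <-
    as.integer(sna_records$betweenness_cat[m] == "high")
  out$sna_clique <- sna_records$clique_member[m]

  wide <- function(region, timepoint) {
    sel <- lesion_records$region == region & lesion_records$timepoint == timepoint
    stats::setNames(lesion_records$count[sel],
                    lesion_records$animal_id[sel])[as.character(out$animal_id)]
  }
  for (region in c("anterior", "central", "posterior")) {
    premix <- wide(region, "premix")
    c24 <- wide(region, "24h")
    ok <- !is.na(c24)
    net <- rep(NA_integer_, nrow(out))
    if (any(ok)) {
      premix[is.na(premix)] <- 0L
      net[ok] <- net_lesions(c24[ok], premix[ok])
    }
    out[[paste0("sl_", region, "_24h")]] <- log1_transform(pmax(net, 0L))
    c3w <- wide(region, "3wk")
    out[[paste0("sl_", region, "_3wk")]] <-
      ifelse(is.na(c3w), NA_real_, log1_transform(pmax(c3w, 0L)))
  }
  class(out) <- c("trait_table", "data.frame")
  out
}
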