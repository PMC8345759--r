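#' Majority classification over member foods
#'
#' Returns the most frequent label among a category's member foods. Ties
#' are broken conservatively toward the more-processed label for NOVA
#' (unprocessed < culinary < processed < ultra_processed); for logical
#' discretionary flags a tie resolves to discretionary (`TRUE`).
#'
#' @param codes Character vector of NOVA labels, or logical vector of
#'   discretionary flags.
#' @return A single label (or logical).
#' @export
#' @examples
#' majority_code(c("processed", "ultra_processed")) # tie -> ultra_processed
majority_code <- function(codes) {
  if (!length(codes)) stop("majority_code: empty input", call. = FALSE)
  if (is.logical(codes)) {
    return(sum(codes) >= sum(!codes))
  }
  bad <- setdiff(codes, NOVA_LEVELS)
  if (length(bad)) {
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(codes, levels = NOVA_LEVELS))
  winners <- names(counts)[counts == max(counts)]
  # NOVA_LEVELS is ordered least- to most-processed
  winners[which.max(match(winners, NOVA_LEVELS))]
}

#' Distribution of NOVA processing levels in a weighted set of categories
#'
#' Computes the percentage share of each processing level, weighting each
#' category by `weight`: counts for the quartile-membership tables,
#' servings for diet-level distributions.
#'
#' @param nova Character vector of NOVA levels, one per category.
#' @param weights Non-negative weights, same length (default all 1 =
#'   count weighting).
#' @return Tibble `nova`, `percentage` (sums to 100), in NOVA order.
#' @export
#' @examples
#' processing_distribution(c("unprocessed", "ultra_processed"), c(1, 3))
processing_distribution <- function(nova, weights = rep(1, length(nova))) {
  if (!length(nova)) stop("empty category set", call. = FALSE)
  if (length(weights) != length(nova)) {
    stop("weights must match categories", call. = FALSE)
  }
  if (any(weights < 0)) stop("negative weight", call. = FALSE)
  if (sum(weights) == 0) stop("all weights zero", call. = FALSE)
  bad <- setdiff(nova, NOVA_LEVELS)
  if (length(bad)) {
    stop("unknown NOVA level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  share <- tapply(weights, factor(nova, levels = NOVA_LEVELS), sum,
                  default = 0)
  tibble::tibble(nova = NOVA_LEVELS,
                 percentage = as.numeric(share) / sum(weights) * 100)
}
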