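# Replicate peak concordance: nearest-neighbour distances between two
# replicate peak lists, the distance ECDF, and the mutual-nearest-neighbour
# cutoff filter that produces the merged high-confidence peak set.

# For each x, index of the nearest value in sorted vector y; exact distance
# ties resolve toward the lower coordinate.
nearest_index <- function(x, y) {
  stopifnot(!is.unsorted(y))
  i <- findInterval(x, y)          # last y <= x (0 if none)
  left <- pmax(i, 1L)
  right <- pmin(i + 1L, length(y))
  d_left <- ifelse(i >= 1L, x - y[left], Inf)
  d_right <- ifelse(i < length(y), y[right] - x, Inf)
  ifelse(d_left <= d_right, left, right)
}

#' Nearest-replicate peak distances
#'
#' For every peak in each replicate, the absolute distance to the nearest peak
#' in the other replicate.
#'
#' @param peaks_a,peaks_b peak tibbles (see [peak_table()]).
#' @return tibble with columns replicate ("A"/"B"), coordinate,
#'   nearest_coordinate, distance.
#' @export
nearest_replicate_distances <- function(peaks_a, peaks_b) {
  assert_that(nrow(peaks_a) > 0 && nrow(peaks_b) > 0,
              "both peak collections must be nonempty")
  a <- sort(peaks_a$coordinate)
  b <- sort(peaks_b$coordinate)
  ia <- nearest_index(a, b)
  ib <- nearest_index(b, a)
  bind_rows(
    tibble(replicate = "A", coordinate = a, nearest_coordinate = b[ia],
           distance = abs(a - b[ia])),
    tibble(replicate = "B", coordinate = b, nearest_coordinate = a[ib],
           distance = abs(b - a[ib]))
  )
}

#' Empirical cumulative distribution of distances
#'
#' @param distances nonnegative distances.
#' @return a right-continuous nondecreasing step function `F(d)` with
#'   `F(max(distances)) = 1` (a [stats::ecdf] object).
#' @export
distance_ecdf <- function(distances) {
  assert_that(length(distances) > 0, "no distances supplied")
  ecdf(distances)
}

#' Filter replicate peaks to a concordant merged set
#'
#' Pairs are mutual nearest neighbours (each peak's nearest neighbour in the
#' other replicate must nominate it back) whose maxima lie within `cutoff` bp;
#' distance ties resolve toward the lower coordinate, so the pairing is
#' deterministic and each source peak joins at most one merged peak. The
#' merged coordinate is the arithmetic mean of the two maxima rounded half
#' away from zero; `overall_rank` orders merged peaks by descending mean
#' replicate enrichment (ties toward the lower coordinate).
#'
#' @param peaks_a,peaks_b peak tibbles.
#' @param cutoff maximum replicate-maxima distance in bp (>= 0).
#' @return tibble of merged peaks with columns overall_rank, coordinate,
#'   coordinate_rep1, coordinate_rep2, rank_rep1, rank_rep2, enrichment_rep1,
#'   enrichment_rep2, mean_enrichment, replicate_distance.
#' @export
filter_concordant <- function(peaks_a, peaks_b, cutoff = 65) {
  assert_that(is.numeric(cutoff) && length(cutoff) == 1 && cutoff >= 0,
              "cutoff must be a nonnegative scalar")
  a <- arrange(peaks_a, .data$coordinate)
  b <- arrange(peaks_b, .data$coordinate)
  ia <- nearest_index(a$coordinate, b$coordinate)   # A -> nearest B
  ib <- nearest_index(b$coordinate, a$coordinate)   # B -> nearest A
  mutual <- which(ib[ia] == seq_len(nrow(a)))
  j <- ia[mutual]
  dist <- abs(a$coordinate[mutual] - b$coordinate[j])
  keep <- dist <= cutoff
  mutual <- mutual[keep]; j <- j[keep]; dist <- dist[keep]
  merged <- tibble(
    coordinate = round_half_away(
      (a$coordinate[mutual] + b$coordinate[j]) / 2),
    coordinate_rep1 = a$coordinate[mutual],
    coordinate_rep2 = b$coordinate[j],
    rank_rep1 = a$rank_in_replicate[mutual],
    rank_rep2 = b$rank_in_replicate[j],
    enrichment_rep1 = a$enrichment[mutual],
    enrichment_rep2 = b$enrichment[j],
    replicate_distance = dist
  )
  merged$mean_enrichment <-
    (merged$enrichment_rep1 + merged$enrichment_rep2) / 2
  ord <- order(-merged$mean_enrichment, merged$coordinate)
  merged$overall_rank <- integer(nrow(merged))
  merged$overall_rank[ord] <- seq_len(nrow(merged))
  merged <- arrange(merged, .data$overall_rank)
  stopifnot(all(merged$replicate_distance <= cutoff))
  select(merged, "overall_rank", dplyr::everything())
}

#' Summarise replicate peak concordance
#'
#' @param peaks_a,peaks_b peak tibbles.
#' @param cutoff concordance cutoff in bp.
#' @return one-row tibble: per-replicate counts, merged count, the retained
#'   fraction `2 * merged / (nA + nB)`, the median replicate distance over
#'   merged pairs, and the fraction of all nearest-neighbour distances within
#'   30 bp (`f30`).
#' @export
concordance_report <- function(peaks_a, peaks_b, cutoff = 65) {
  nn <- nearest_replicate_distances(peaks_a, peaks_b)
  merged <- filter_concordant(peaks_a, peaks_b, cutoff)
  f <- distance_ecdf(nn$distance)
  tibble(
    n_rep1 = nrow(peaks_a),
    n_rep2 = nrow(peaks_b),
    n_merged = nrow(merged),
    cutoff = cutoff,
    retained_fraction = 2 * nrow(merged) / (nrow(peaks_a) + nrow(peaks_b)),
    median_distance = if (nrow(merged)) median(merged$replicate_distance)
                      else NA_real_,
    f30 = f(30)
  )
}
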