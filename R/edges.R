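#' Enumerate the upper-triangle region-pair index of a connectivity matrix
#'
#' Maps edge ids 1..n(n-1)/2 bijectively onto unordered region pairs (i < j),
#' regions 1-based, row-major over the upper triangle: (1,2), (1,3), ...,
#' (1,n), (2,3), ... With the 200-region functional atlas used for
#' resting-state connectivity this yields 19,900 links.
#'
#' @param n_regions number of atlas regions (>= 2).
#' @return data.frame with columns `edge_id`, `region_i`, `region_j`.
#' @examples
#' edge_index(3)
#' @export
edge_index <- function(n_regions) {
  if (length(n_regions) != 1 || !is.finite(n_regions) || n_regions < 2) {
    stop("n_regions must be a single integer >= 2", call. = FALSE)
  }
  n <- as.integer(n_regions)
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = seq_len(n - 1L) + 1L)
  data.frame(edge_id = seq_along(i), region_i = i, region_j = j)
}
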