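#' Open-field path length
#'
#' Total distance travelled in the arena: the sum of Euclidean distances
#' between consecutive trajectory samples, accumulated per time bin and in
#' total. Samples outside the arena bounds are rejected.
#'
#' @param traj Trajectory tibble with columns `t` (s, strictly increasing),
#'   `x`, `y` (cm).
#' @param bin Bin width in seconds for the per-bin breakdown.
#' @param arena Arena side in cm (samples must lie in `[0, arena]`).
#' @return A list of class `open_field_result` with `total_distance` (cm) and
#'   `distance_per_bin` (tibble `bin_start`, `distance`); the bin distances
#'   sum to the total.
#' @export
#' @examples
#' tr <- simulate_open_field(5, duration = 60, seed = 1)
#' path_length(tr)$total_distance
path_length <- function(traj, bin = 60, arena = 50) {
  traj <- tibble::as_tibble(traj)
  if (nrow(traj) < 2L) {
    stop("path_length: need at least 2 trajectory samples", call. = FALSE)
  }
  if (any(diff(traj$t) <= 0)) {
    stop("path_length: timestamps must be strictly increasing", call. = FALSE)
  }
  out_of_bounds <- traj$x < 0 | traj$x > arena | traj$y < 0 | traj$y > arena
  if (any(out_of_bounds)) {
    stop(sprintf("path_length: %d sample(s) outside the %g x %g cm arena",
                 sum(out_of_bounds), arena, arena), call. = FALSE)
  }
  seg <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  # attribute each segment to the bin of its starting sample
  bins <- floor(traj$t[-nrow(traj)] / bin) * bin
  per_bin <- tapply(seg, bins, sum)
  structure(list(
    total_distance = sum(seg),
    distance_per_bin = tibble::tibble(
      bin_start = as.numeric(names(per_bin)),
      distance = as.numeric(per_bin))
  ), class = "open_field_result")
}

#' @export
print.open_field_result <- function(x, ...) {
  cat(sprintf("<open_field_result> total distance %.1f cm over %d bin(s)\n",
              x$total_distance, nrow(x$distance_per_bin)))
  invisible(x)
}
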