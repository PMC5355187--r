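#' Simulate interaction rewiring during population expansion
#'
#' Runs the release-and-expansion experiment: for each replicate a fresh
#' arena is populated from the pool, the population is released at a fixed
#' cell and expanded one von Neumann ring per step until the whole arena is
#' occupied, and the cumulative number of distinct partner species "rewired"
#' (first encountered in an occupied cell) is recorded at every step. A
#' partner counts as rewired at the first step at which any occupied cell
#' contains it; rewiring is permanent. Stochasticity lives entirely in arena
#' composition; the expansion geometry is deterministic, so under radial
#' growth the cells occupied at step t are exactly those within Manhattan
#' distance t of the release cell (after any initial lag).
#'
#' An optional `lag_steps` holds the population at the release cell for the
#' first `lag_steps` steps, mimicking the slow early phase of reintroductions
#' (acclimation, supplementary feeding, Allee effects) without modelling its
#' mechanism.
#'
#' @param pool a [build_pool()] species pool.
#' @param partner_set a [sample_partner_set()] partner set drawn from `pool`.
#' @param width,height arena dimensions in cells.
#' @param release_cell `"center"` (default) or a 0-based `(x, y)` pair.
#' @param n_replicates number of independent arena replicates.
#' @param seed master seed; replicate `r` uses a seed derived from
#'   `(seed, r)`, so replicates are reproducible independently.
#' @param lag_steps integer >= 0; steps spent confined to the release cell.
#' @return a `rewiring_trajectory`: list with `steps` (0..T), a
#'   `n_replicates` x `length(steps)` integer matrix `richness` of cumulative
#'   rewired partner counts, the partner `degree`, and the run configuration.
#' @seealso [summarize_trajectory()], [ledger_from_trajectory()],
#'   [rewiring_time()]
#' @examples
#' pool <- build_pool(50, seed = 1)
#' ps <- sample_partner_set(pool, 10, seed = 2)
#' traj <- simulate_rewiring(pool, ps, 9, 9, n_replicates = 5, seed = 3)
#' summarize_trajectory(traj)
#' @export
simulate_rewiring <- function(pool, partner_set, width = 50, height = 50,
                              release_cell = "center", n_replicates = 100,
                              seed = 1L, lag_steps = 0L) {
  stopifnot(inherits(pool, "species_pool"), inherits(partner_set, "partner_set"))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (lag_steps < 0) stop("lag_steps must be >= 0")
  if (!all(partner_set$partner_ids %in% pool$species_id)) {
    stop("partner set contains species not in the pool")
  }
  n_replicates <- as.integer(n_replicates)
  lag_steps <- as.integer(lag_steps)

  geom <- arena_geometry(width, height, release_cell)
  t_max <- geom$max_dist + lag_steps
  partner_rows <- match(partner_set$partner_ids, pool$species_id)

  richness <- matrix(NA_integer_, nrow = n_replicates, ncol = t_max + 1L)
  for (r in seq_len(n_replicates)) {
    arena <- populate_arena(pool, width, height, seed = derive_seed(seed, r))
    richness[r, ] <- rewire_on_arena(arena, partner_set$partner_ids,
                                     release_cell, lag_steps)
  }

  structure(
    list(steps = 0:t_max, richness = richness,
         degree = partner_set$degree, animal_id = partner_set$animal_id,
         n_replicates = n_replicates, seed = as.integer(seed),
         width = as.integer(width), height = as.integer(height),
         release_cell = geom$release, lag_steps = lag_steps),
    class = "rewiring_trajectory"
  )
}

#' Cumulative rewiring trajectory on one explicit arena
#'
#' The deterministic inner step of [simulate_rewiring()]: given a realized
#' arena, returns the cumulative count of distinct partner species reached by
#' radial expansion from the release cell, one value per step from release
#' (step 0) to full arena coverage.
#'
#' @param arena a [populate_arena()] arena.
#' @param partner_ids character vector of partner species identifiers.
#' @param release_cell `"center"` or a 0-based `(x, y)` pair.
#' @param lag_steps steps spent confined to the release cell.
#' @return integer vector of cumulative richness, steps `0..T`.
#' @export
rewire_on_arena <- function(arena, partner_ids, release_cell = "center",
                            lag_steps = 0L) {
  stopifnot(inherits(arena, "arena"))
  partner_ids <- canonicalize_species(partner_ids)
  if (!all(partner_ids %in% arena$species_ids)) {
    stop("partner set contains species not in the arena")
  }
  geom <- arena_geometry(arena$width, arena$height, release_cell)
  t_max <- geom$max_dist + as.integer(lag_steps)
  rows <- match(partner_ids, arena$species_ids)
  first <- partner_first_steps(arena, rows, geom$dist, as.integer(lag_steps))
  cumsum(tabulate(first + 1L, nbins = t_max + 1L))
}

# Manhattan distance of every cell from the release cell, plus the step at
# which the expansion covers the whole arena.
arena_geometry <- function(width, height, release_cell) {
  width <- as.integer(width); height <- as.integer(height)
  dummy <- structure(list(width = width, height = height), class = "arena")
  rc <- resolve_release_cell(dummy, release_cell)
  xs <- rep(0:(width - 1L), times = height)
  ys <- rep(0:(height - 1L), each = width)
  d <- abs(xs - rc[1]) + abs(ys - rc[2])
  list(release = rc, dist = d, max_dist = max(d))
}

# First expansion step at which each partner species is reached: the minimum
# release-cell distance over the cells containing it (guaranteed non-empty by
# force-seeding), shifted by the lag unless the species sits at the release
# cell itself.
partner_first_steps <- function(arena, partner_rows, dist, lag_steps) {
  vapply(partner_rows, function(row) {
    d <- min(dist[arena$presence[row, ]])
    if (d == 0L) 0L else d + lag_steps
  }, integer(1))
}

#' @export
print.rewiring_trajectory <- function(x, ...) {
  final <- x$richness[, ncol(x$richness)]
  cat("Rewiring trajectory for '", x$animal_id, "': degree ", x$degree, ", ",
      x$n_replicates, " replicate(s), steps 0..", max(x$steps), "\n",
      "  final cumulative richness: ", paste(range(final), collapse = ".."),
      "\n", sep = "")
  invisible(x)
}

#' Per-step summary of a rewiring trajectory
#'
#' Collapses the replicate matrix to a per-step mean and the min--max range
#' across replicates. The band between the minimum and the maximum is the
#' trajectory's 100% envelope: every simulated replicate lies within it.
#'
#' @param traj a [simulate_rewiring()] trajectory.
#' @return data frame with columns `step`, `mean`, `min`, `max`.
#' @export
summarize_trajectory <- function(traj) {
  stopifnot(inherits(traj, "rewiring_trajectory"))
  if (nrow(traj$richness) < 1L) stop("trajectory has no replicates")
  data.frame(
    step = traj$steps,
    mean = colMeans(traj$richness),
    min = apply(traj$richness, 2, min),
    max = apply(traj$richness, 2, max)
  )
}

#' @export
plot.rewiring_trajectory <- function(x, col = "black", add = FALSE, ...) {
  s <- summarize_trajectory(x)
  if (!add) {
    plot(s$step, s$mean, type = "n", ylim = c(0, max(s$max)),
         xlab = "population expansions",
         ylab = "cumulative rewired interactions", ...)
  }
  graphics::polygon(c(s$step, rev(s$step)), c(s$min, rev(s$max)),
                    col = grDevices::adjustcolor(col, alpha.f = 0.2),
                    border = NA)
  graphics::lines(s$step, s$mean, col = col, lwd = 2)
  invisible(s)
}
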