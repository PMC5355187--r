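#' Populate an arena with plant species
#'
#' Fills a `width` x `height` grid with the pool's species: each species is
#' independently present in each cell with probability equal to its occupancy
#' weight. Any species that ends up absent from every cell is then
#' force-seeded into one uniformly chosen cell, so the realized arena always
#' contains the full pool. Force-seeding makes the full-credit endpoint
#' deterministic: once the population occupies the whole arena, every partner
#' species has been encountered.
#'
#' @param pool a [build_pool()] species pool.
#' @param width,height arena dimensions in cells. Cells hold species sets, so
#'   a pool larger than the cell count is fine: absent species simply pile up
#'   in their force-seeded cells.
#' @param seed integer seed; composition is deterministic given the seed.
#' @return an `arena`: list with `width`, `height`, `species_ids` and a
#'   species-by-cell logical `presence` matrix. Cell coordinates are 0-based
#'   `(x, y)` pairs with `x` in `[0, width)` and `y` in `[0, height)`.
#' @examples
#' pool <- build_pool(5, "uniform", p = 1)
#' ar <- populate_arena(pool, 3, 3, seed = 1)
#' cell_species(ar, 0, 0)  # all five species: occupancy 1 everywhere
#' @export
populate_arena <- function(pool, width, height, seed = 1L) {
  stopifnot(inherits(pool, "species_pool"))
  if (width < 1 || height < 1) stop("arena dimensions must be positive")
  width <- as.integer(width); height <- as.integer(height)
  n_cells <- width * height
  n_sp <- nrow(pool)
  presence <- with_seed(seed, {
    m <- matrix(stats::runif(n_sp * n_cells) < pool$occupancy_weight,
                nrow = n_sp, ncol = n_cells)
    absent <- which(rowSums(m) == 0L)
    for (s in absent) m[s, sample.int(n_cells, 1L)] <- TRUE
    m
  })
  structure(
    list(width = width, height = height,
         species_ids = pool$species_id, presence = presence),
    class = "arena"
  )
}

# Column index of cell (x, y), 0-based coordinates.
cell_index <- function(arena, x, y) {
  if (any(x < 0 | x >= arena$width | y < 0 | y >= arena$height)) {
    stop("cell (", x, ", ", y, ") is outside the ", arena$width, "x",
         arena$height, " arena")
  }
  x + y * arena$width + 1L
}

#' Species present in one arena cell
#'
#' @param arena an [populate_arena()] arena.
#' @param x,y 0-based cell coordinates.
#' @return character vector of species identifiers present in the cell.
#' @export
cell_species <- function(arena, x, y) {
  stopifnot(inherits(arena, "arena"))
  arena$species_ids[arena$presence[, cell_index(arena, x, y)]]
}

#' @export
print.arena <- function(x, ...) {
  cat("Arena ", x$width, "x", x$height, " cells, ",
      length(x$species_ids), " species; mean per-cell richness ",
      format(mean(colSums(x$presence)), digits = 4), "\n", sep = "")
  invisible(x)
}

resolve_release_cell <- function(arena, release_cell) {
  if (identical(release_cell, "center")) {
    c((arena$width - 1L) %/% 2L, (arena$height - 1L) %/% 2L)
  } else {
    rc <- as.integer(release_cell)
    if (length(rc) != 2L) stop("release_cell must be 'center' or an (x, y) pair")
    cell_index(arena, rc[1], rc[2])  # bounds check
    rc
  }
}

#' Release a population into an arena
#'
#' Creates the step-0 population state: a single occupied cell from which the
#' population expands. Occupancy of cells is the package's proxy for
#' population increase through time.
#'
#' @param arena an arena.
#' @param release_cell `"center"` (default) or a 0-based `(x, y)` pair.
#' @return a `population_state`: list with a `width` x `height` logical
#'   `occupied` matrix and the expansion `step` index (0 at release).
#' @export
release <- function(arena, release_cell = "center") {
  stopifnot(inherits(arena, "arena"))
  rc <- resolve_release_cell(arena, release_cell)
  occupied <- matrix(FALSE, nrow = arena$width, ncol = arena$height)
  occupied[rc[1] + 1L, rc[2] + 1L] <- TRUE
  structure(list(occupied = occupied, step = 0L), class = "population_state")
}

#' Expand an occupied range by one step
#'
#' Deterministic radial growth: the next state occupies the current cells plus
#' every cell 4-adjacent (von Neumann neighbourhood) to an occupied cell,
#' clipped to the arena bounds. Once the whole arena is occupied the
#' operation is idempotent.
#'
#' @param state a [release()] population state.
#' @param arena the arena the population lives in.
#' @return the population state at `step + 1`.
#' @export
expand <- function(state, arena) {
  stopifnot(inherits(state, "population_state"), inherits(arena, "arena"))
  occ <- state$occupied
  if (!any(occ)) stop("cannot expand an empty occupied set")
  if (nrow(occ) != arena$width || ncol(occ) != arena$height) {
    stop("population state does not match arena dimensions")
  }
  grown <- occ
  n <- nrow(occ); m <- ncol(occ)
  if (n > 1L) {
    grown[-1L, ] <- grown[-1L, ] | occ[-n, ]
    grown[-n, ] <- grown[-n, ] | occ[-1L, ]
  }
  if (m > 1L) {
    grown[, -1L] <- grown[, -1L] | occ[, -m]
    grown[, -m] <- grown[, -m] | occ[, -1L]
  }
  structure(list(occupied = grown, step = state$step + 1L),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat("Population state: step ", x$step, ", ", sum(x$occupied), "/",
      length(x$occupied), " cells occupied\n", sep = "")
  invisible(x)
}
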