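# Independent oracles for the simulator tests. These recompute trajectories
# by explicit set unions over cells, without touching the package's
# distance-based implementation.

# Build an arena object from hand-specified cell contents.
# `cells` is a named list: "x,y" -> character vector of species in that cell.
make_arena <- function(width, height, cells, species_ids) {
  presence <- matrix(FALSE, nrow = length(species_ids), ncol = width * height)
  rownames(presence) <- species_ids
  for (key in names(cells)) {
    xy <- as.integer(strsplit(key, ",")[[1]])
    j <- xy[1] + xy[2] * width + 1L
    presence[cells[[key]], j] <- TRUE
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 species_ids = species_ids, presence = presence),
            class = "arena")
}

# Brute-force union-intersect trajectory: at each step, union the contents of
# every cell within the radially grown occupied set and intersect with the
# partner set. Radius grows by one per step after an initial lag.
oracle_trajectory <- function(arena, partner_ids, release = "center",
                              lag_steps = 0) {
  w <- arena$width; h <- arena$height
  if (identical(release, "center")) {
    release <- c((w - 1) %/% 2, (h - 1) %/% 2)
  }
  t_max <- max(abs(0:(w - 1) - release[1])) + max(abs(0:(h - 1) - release[2])) +
    lag_steps
  sapply(0:t_max, function(t) {
    radius <- max(0, t - lag_steps)
    seen <- character(0)
    for (x in 0:(w - 1)) for (y in 0:(h - 1)) {
      if (abs(x - release[1]) + abs(y - release[2]) <= radius) {
        seen <- union(seen, arena$species_ids[arena$presence[, x + y * w + 1]])
      }
    }
    length(intersect(seen, partner_ids))
  })
}

# Breadth-first-search coverage oracle: the step at which radial expansion
# from the release cell covers the whole arena equals the maximum Manhattan
# distance from the release cell to any cell.
oracle_full_coverage_step <- function(width, height, release) {
  max(abs(0:(width - 1) - release[1])) + max(abs(0:(height - 1) - release[2]))
}

# Occupied set expected at a given step under von Neumann radial growth.
oracle_manhattan_ball <- function(width, height, release, radius) {
  outer(0:(width - 1), 0:(height - 1),
        function(x, y) abs(x - release[1]) + abs(y - release[2]) <= radius)
}
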