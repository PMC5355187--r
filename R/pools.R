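#' Build a plant species pool with occupancy structure
#'
#' A species pool represents the plant community of a focal area. Each species
#' carries an occupancy weight: the probability that any given arena cell
#' contains it. Occupancy is the package's representation of commonness versus
#' rarity — the abundance structure that, together with the reintroduced
#' animal's traits, drives how fast the credit of ecological interactions is
#' cashed.
#'
#' Two occupancy models are available:
#' \describe{
#'   \item{`lognormal_rank`}{weights drawn from a lognormal distribution with
#'     median `base` and log-scale standard deviation `sigma`, clipped to
#'     `[min_occupancy, 1]` and sorted in decreasing order, so rank 1 is the
#'     most common species. This emulates the steep common-to-rare abundance
#'     gradients typical of tropical tree communities.}
#'   \item{`uniform`}{every species receives the same weight `p`; with
#'     `p = 1` every species occurs in every cell (useful for deterministic
#'     geometry checks).}
#' }
#'
#' @param n_species number of species in the pool (>= 1).
#' @param occupancy_model `"lognormal_rank"` (default) or `"uniform"`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param p occupancy shared by all species under the uniform model, in (0, 1].
#' @param sigma log-scale standard deviation of the lognormal model (> 0).
#' @param base median occupancy of the lognormal model, in (0, 1].
#' @param min_occupancy floor applied to lognormal weights, in (0, 1].
#' @param prefix stem used to generate species identifiers.
#' @return a `species_pool`: a data frame with columns `species_id` and
#'   `occupancy_weight`.
#' @seealso [sample_partner_set()], [populate_arena()]
#' @examples
#' pool <- build_pool(100, "lognormal_rank", seed = 1)
#' head(pool)
#' @export
build_pool <- function(n_species,
                       occupancy_model = c("lognormal_rank", "uniform"),
                       seed = 1L,
                       p = 1,
                       sigma = 1.5,
                       base = 0.3,
                       min_occupancy = 0.005,
                       prefix = "species") {
  occupancy_model <- match.arg(occupancy_model)
  if (!is.numeric(n_species) || length(n_species) != 1L || is.na(n_species) ||
      n_species < 1) {
    stop("n_species must be a positive integer, got ",
         deparse(substitute(n_species)))
  }
  n_species <- as.integer(n_species)
  ids <- sprintf("%s_%0*d", prefix, max(4L, nchar(as.character(n_species))),
                 seq_len(n_species))
  if (occupancy_model == "uniform") {
    if (p <= 0 || p > 1) stop("parameter p must lie in (0, 1], got ", p)
    w <- rep(p, n_species)
  } else {
    if (sigma <= 0) stop("parameter sigma must be > 0, got ", sigma)
    if (base <= 0 || base > 1) stop("parameter base must lie in (0, 1], got ", base)
    if (min_occupancy <= 0 || min_occupancy > 1) {
      stop("parameter min_occupancy must lie in (0, 1], got ", min_occupancy)
    }
    w <- with_seed(seed, rank_lognormal_weights(n_species, sigma, base, min_occupancy))
  }
  new_species_pool(ids, w)
}

# Clipped-lognormal occupancy weights, sorted so rank 1 = most common.
# Shared by build_pool() and the synthetic generator (single source of truth
# for "common vs. rare"). sigma = 0 degenerates to equal weights.
rank_lognormal_weights <- function(n, sigma, base, min_occupancy) {
  w <- if (sigma == 0) rep(base, n) else stats::rlnorm(n, meanlog = log(base), sdlog = sigma)
  sort(pmin(1, pmax(min_occupancy, w)), decreasing = TRUE)
}

new_species_pool <- function(species_id, occupancy_weight) {
  species_id <- canonicalize_species(species_id)
  if (anyDuplicated(species_id)) {
    stop("species identifiers must be unique after canonicalization")
  }
  if (any(occupancy_weight <= 0 | occupancy_weight > 1)) {
    stop("every occupancy_weight must lie in (0, 1]")
  }
  structure(
    data.frame(species_id = species_id, occupancy_weight = occupancy_weight,
               stringsAsFactors = FALSE),
    class = c("species_pool", "data.frame")
  )
}

#' @export
print.species_pool <- function(x, ...) {
  cat("Species pool:", nrow(x), "species; occupancy in [",
      format(min(x$occupancy_weight), digits = 3), ",",
      format(max(x$occupancy_weight), digits = 3), "]\n")
  print.data.frame(utils::head(x, 6), ...)
  if (nrow(x) > 6) cat("... and", nrow(x) - 6L, "more species\n")
  invisible(x)
}

#' Sample a partner set for a reintroduced animal
#'
#' The partner set is the subset of the pool the animal can interact with; its
#' size (degree) encodes the generalist/specialist trait axis and equals the
#' maximal credit of ecological interactions the animal can cash from this
#' pool. Strategy `"uniform"` draws species uniformly without replacement from
#' the whole pool. Strategy `"nested_within"` draws them from an existing
#' (larger) partner set, guaranteeing that a specialist's partners are a
#' subset of the generalist's — the paired design used to compare cashing
#' speed between the two traits on identical arenas.
#'
#' @param pool a [build_pool()] species pool.
#' @param degree number of partner species (1 <= degree <= pool size).
#' @param strategy `"uniform"` or `"nested_within"`.
#' @param seed integer seed.
#' @param superset a `partner_set` to nest within (required for
#'   `"nested_within"`; its degree must be >= `degree`).
#' @param animal_id identifier for the animal the set belongs to.
#' @return a `partner_set`: list with `animal_id`, `partner_ids`, `degree`.
#' @examples
#' pool <- build_pool(200, seed = 1)
#' gen <- sample_partner_set(pool, 100, seed = 2, animal_id = "generalist")
#' spec <- sample_partner_set(pool, 25, "nested_within", seed = 3,
#'                            superset = gen, animal_id = "specialist")
#' all(spec$partner_ids %in% gen$partner_ids)
#' @export
sample_partner_set <- function(pool, degree,
                               strategy = c("uniform", "nested_within"),
                               seed = 1L, superset = NULL,
                               animal_id = "animal_1") {
  strategy <- match.arg(strategy)
  stopifnot(inherits(pool, "species_pool"))
  if (!is.numeric(degree) || length(degree) != 1L || degree < 1) {
    stop("degree must be a positive integer")
  }
  degree <- as.integer(degree)
  if (degree > nrow(pool)) {
    stop("degree (", degree, ") exceeds pool size (", nrow(pool), ")")
  }
  candidates <- if (strategy == "nested_within") {
    if (is.null(superset) || !inherits(superset, "partner_set")) {
      stop("strategy 'nested_within' requires a partner_set superset")
    }
    if (superset$degree < degree) {
      stop("superset degree (", superset$degree,
           ") is smaller than the requested degree (", degree, ")")
    }
    superset$partner_ids
  } else {
    pool$species_id
  }
  ids <- with_seed(seed, sample(candidates, degree))
  new_partner_set(animal_id, sort(ids), pool)
}

new_partner_set <- function(animal_id, partner_ids, pool = NULL) {
  partner_ids <- unique(canonicalize_species(partner_ids))
  if (length(partner_ids) < 1L) stop("a partner set needs at least one species")
  if (!is.null(pool) && !all(partner_ids %in% pool$species_id)) {
    stop("partner_ids must be a subset of the pool's species")
  }
  structure(
    list(animal_id = as.character(animal_id), partner_ids = partner_ids,
         degree = length(partner_ids)),
    class = "partner_set"
  )
}

#' @export
print.partner_set <- function(x, ...) {
  cat("Partner set for '", x$animal_id, "': degree ", x$degree,
      " (maximal credit from this pool)\n", sep = "")
  invisible(x)
}
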