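# Internal helpers shared across modules.

# Canonical categorical vocabularies used by every table in the package.
SPECIES_LEVELS <- c("H_dipterurus", "N_entemedor", "R_steindachneri")
SEX_LEVELS <- c("female", "male")
STAGE_LEVELS <- c("adult", "juvenile")
SEASON_LEVELS <- c("cold", "warm")

# The ten broad prey categories used in the stomach-content stage.
PREY_CATEGORIES <- c(
  "amphipods", "crabs", "bivalves", "echinoderms", "other_crustaceans",
  "shrimps", "polychaetes", "sipunculids", "stomatopods", "fishes"
)

#' Prey category names
#'
#' The ten broad taxonomic prey categories into which stomach-content items
#' are aggregated: amphipods, brachyuran/anomuran crabs, bivalves,
#' echinoderms, other crustaceans, penaeid shrimps, polychaetes, sipunculids,
#' stomatopods and teleost fishes.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' prey_categories()
prey_categories <- function() PREY_CATEGORIES

# Normalize a string for tolerant matching: lower-case, strip accents and
# every non-alphanumeric character.
.norm_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- iconv(x, to = "ASCII//TRANSLIT")
  gsub("[^a-z0-9]", "", x)
}

# Map raw labels onto a controlled vocabulary; synonyms is a named list
# canonical -> character vector of extra accepted spellings.
.match_levels <- function(x, levels, synonyms = NULL, what = "value") {
  lut <- stats::setNames(levels, .norm_label(levels))
  for (canon in names(synonyms)) {
    lut[.norm_label(synonyms[[canon]])] <- canon
  }
  key <- .norm_label(x)
  out <- unname(lut[key])
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf(
      "unmappable %s '%s' at row %d (expected one of: %s)",
      what, x[bad[1]], bad[1], paste(levels, collapse = ", ")
    ), call. = FALSE)
  }
  out
}

# Symmetric positive-definite check for small matrices.
.is_spd <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) < 1e-8 * max(1, max(abs(m))) &&
    min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) > tol
}

# Deterministic per-stage seed derived from one root seed; stays < 2^31.
.stage_seed <- function(root, idx) {
  as.integer((as.double(root) * 97 + 13 * idx) %% 2147483587L) + 1L
}

# Run an expression with a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483587L))
  }
  force(expr)
}

# Draws from a bivariate Student-t with given location, SCATTER matrix and
# df. The covariance of the draws is nu/(nu-2) * scatter.
.rmvt_scatter <- function(n, mu, scatter, nu) {
  L <- chol(scatter)
  z <- matrix(stats::rnorm(2L * n), n, 2L) %*% L
  w <- stats::rgamma(n, nu / 2, nu / 2)
  sweep(z / sqrt(w), 2L, mu, "+")
}

# Draws from a bivariate normal.
.rmvn2 <- function(n, mu, Sigma) {
  L <- chol(Sigma)
  sweep(matrix(stats::rnorm(2L * n), n, 2L) %*% L, 2L, mu, "+")
}
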