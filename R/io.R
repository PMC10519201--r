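# Reading, validating and writing the two tabular inputs. CSV only (UTF-8,
# header row). Matching of column names and categorical levels is
# case-insensitive and accent-stripping, with user-supplied mappings for
# arbitrary source spellings; unknown extra columns are preserved untouched.

# Accepted alternative spellings for the canonical column names.
.ISO_COL_SYNONYMS <- list(
  id = c("individual", "individual_id", "sample", "sample_id", "code"),
  species = c("sp", "especie", "taxon"),
  sex = c("sexo", "gender"),
  stage = c("maturity", "maturity_stage", "madurez", "estadio"),
  season = c("temporada", "estacion"),
  month = c("mes", "sampling_month"),
  d13C = c("delta13c", "delta_13c", "c13", "carbon", "x13c", "d13cvpdb"),
  d15N = c("delta15n", "delta_15n", "n15", "nitrogen", "x15n", "d15nair")
)

.LEVEL_SYNONYMS <- list(
  species = list(
    H_dipterurus = c("hypanus dipterurus", "h. dipterurus", "hdipterurus",
                     "dipterurus", "diamond stingray"),
    N_entemedor = c("narcine entemedor", "n. entemedor", "nentemedor",
                    "entemedor", "giant electric ray"),
    R_steindachneri = c("rhinoptera steindachneri", "r. steindachneri",
                        "rsteindachneri", "steindachneri", "golden cownose ray")
  ),
  sex = list(female = c("f", "hembra"), male = c("m", "macho")),
  stage = list(adult = c("a", "mature", "adulto"),
               juvenile = c("j", "immature", "juvenil")),
  season = list(cold = c("fria", "cool", "winter"), warm = c("calida", "summer"))
)

# Find canonical columns in a header, honouring a user column_map
# (canonical -> source name). Returns named character of source names.
.resolve_columns <- function(header, required, optional = character(),
                             column_map = NULL) {
  all_names <- c(required, optional)
  found <- stats::setNames(rep(NA_character_, length(all_names)), all_names)
  norm_head <- .norm_label(header)
  for (nm in all_names) {
    if (!is.null(column_map) && nm %in% names(column_map)) {
      src <- column_map[[nm]]
      if (!src %in% header) {
        stop(sprintf("column_map: source column '%s' (for '%s') not in file",
                     src, nm), call. = FALSE)
      }
      found[nm] <- src
      next
    }
    cand <- .norm_label(c(nm, .ISO_COL_SYNONYMS[[nm]], gsub("_", " ", nm)))
    hit <- which(norm_head %in% cand)
    if (length(hit)) found[nm] <- header[hit[1L]]
  }
  missing <- required[is.na(found[required])]
  if (length(missing)) {
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  found
}

# Map calendar months to the two hydrographic seasons of the study region:
# cold October-April, warm May-September.
.season_from_month <- function(month) {
  if (is.character(month) || is.factor(month)) {
    m <- match(.norm_label(substr(as.character(month), 1L, 3L)),
               .norm_label(substr(month.name, 1L, 3L)))
  } else {
    m <- as.integer(month)
  }
  if (any(is.na(m) | m < 1L | m > 12L)) {
    bad <- which(is.na(m) | m < 1L | m > 12L)[1L]
    stop(sprintf("unmappable month '%s' at row %d", month[bad], bad), call. = FALSE)
  }
  ifelse(m >= 5L & m <= 9L, "warm", "cold")
}

#' Validate an isotope table
#'
#' Checks and canonicalizes an individual-level isotope table: categorical
#' columns are mapped onto the controlled vocabularies (species, sex
#' female/male, stage adult/juvenile, season cold/warm), isotope values must
#' be present and inside configurable sanity bounds. Validation is
#' idempotent.
#'
#' @param d Data frame with columns `id` (created if absent), `species`,
#'   `sex`, `stage`, `season`, `d13C`, `d15N`.
#' @param d13C_range,d15N_range Sanity bounds (open intervals, per-mil).
#' @param species_levels Accepted species labels.
#' @return The validated data frame.
#' @export
validate_isotope_table <- function(d, d13C_range = c(-40, 0),
                                   d15N_range = c(0, 30),
                                   species_levels = SPECIES_LEVELS) {
  d <- as.data.frame(d)
  need <- c("species", "sex", "stage", "season", "d13C", "d15N")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!"id" %in% names(d)) d$id <- sprintf("row_%04d", seq_len(nrow(d)))
  d$id <- as.character(d$id)
  d$species <- .match_levels(d$species, species_levels,
                             .LEVEL_SYNONYMS$species, "species level")
  d$sex <- .match_levels(d$sex, SEX_LEVELS, .LEVEL_SYNONYMS$sex, "sex level")
  d$stage <- .match_levels(d$stage, STAGE_LEVELS, .LEVEL_SYNONYMS$stage,
                           "stage level")
  d$season <- .match_levels(d$season, SEASON_LEVELS, .LEVEL_SYNONYMS$season,
                            "season level")
  for (col in c("d13C", "d15N")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v)) {
      stop(sprintf("validation error: missing or non-numeric %s at row %d",
                   col, which(is.na(v))[1L]), call. = FALSE)
    }
    rng <- if (col == "d13C") d13C_range else d15N_range
    if (any(v <= rng[1L] | v >= rng[2L])) {
      bad <- which(v <= rng[1L] | v >= rng[2L])[1L]
      stop(sprintf("validation error: %s = %.3f at row %d outside sanity bounds (%g, %g)",
                   col, v[bad], bad, rng[1L], rng[2L]), call. = FALSE)
    }
    d[[col]] <- v
  }
  d[, c("id", need, setdiff(names(d), c("id", need))), drop = FALSE]
}

#' Read an isotope table from CSV
#'
#' Reads a comma-separated file with one row per individual, maps columns
#' and categorical levels onto the package's controlled vocabularies
#' (case-insensitive, accent-stripping; a `column_map` absorbs arbitrary
#' source headers), and validates with [validate_isotope_table()]. If the
#' file has a `month` column but no `season`, seasons are derived from the
#' month (cold = October-April, warm = May-September).
#'
#' @param path CSV file path.
#' @param column_map Optional named character/list mapping canonical names
#'   (`species`, `sex`, `stage`, `season`, `month`, `d13C`, `d15N`, `id`) to
#'   the file's column names.
#' @param ... Passed to [validate_isotope_table()].
#' @return Validated isotope data frame.
#' @export
read_isotope_table <- function(path, column_map = NULL, ...) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  cols <- .resolve_columns(names(raw),
                           required = c("species", "sex", "stage", "d13C", "d15N"),
                           optional = c("id", "season", "month"),
                           column_map = column_map)
  if (is.na(cols["season"]) && is.na(cols["month"])) {
    stop("schema error: missing required column(s): season (or month)",
         call. = FALSE)
  }
  d <- raw
  keep <- !is.na(cols)
  names(d)[match(cols[keep], names(d))] <- names(cols)[keep]
  if (!"season" %in% names(d)) {
    d$season <- .season_from_month(d$month)
  }
  validate_isotope_table(d, ...)
}

#' Validate a stomach-content table
#'
#' Checks and canonicalizes an individual-level prey-weight table: exactly
#' the ten prey-weight columns of [prey_categories()] (grams, >= 0, no
#' missing values); rows whose ten weights are all zero (empty stomachs) are
#' dropped with a message.
#'
#' @param d Data frame with `species`, `sex`, `stage`, `season` (and
#'   optionally `id`) plus the ten prey columns.
#' @param species_levels Accepted species labels.
#' @return The validated data frame.
#' @export
validate_diet_table <- function(d, species_levels = SPECIES_LEVELS) {
  d <- as.data.frame(d)
  need <- c("species", "sex", "stage", "season")
  missing <- setdiff(c(need, PREY_CATEGORIES), names(d))
  if (length(missing)) {
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!"id" %in% names(d)) d$id <- sprintf("row_%04d", seq_len(nrow(d)))
  d$id <- as.character(d$id)
  d$species <- .match_levels(d$species, species_levels,
                             .LEVEL_SYNONYMS$species, "species level")
  d$sex <- .match_levels(d$sex, SEX_LEVELS, .LEVEL_SYNONYMS$sex, "sex level")
  d$stage <- .match_levels(d$stage, STAGE_LEVELS, .LEVEL_SYNONYMS$stage,
                           "stage level")
  d$season <- .match_levels(d$season, SEASON_LEVELS, .LEVEL_SYNONYMS$season,
                            "season level")
  for (col in PREY_CATEGORIES) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v)) {
      stop(sprintf("validation error: missing or non-numeric %s weight at row %d",
                   col, which(is.na(v))[1L]), call. = FALSE)
    }
    if (any(v < 0)) {
      stop(sprintf("validation error: negative %s weight at row %d",
                   col, which(v < 0)[1L]), call. = FALSE)
    }
    d[[col]] <- v
  }
  w <- as.matrix(d[, PREY_CATEGORIES])
  empty <- rowSums(w) == 0
  if (any(empty)) {
    message(sprintf("dropping %d row(s) with all-zero prey weights", sum(empty)))
    d <- d[!empty, , drop = FALSE]
    rownames(d) <- NULL
  }
  d[, c("id", need, PREY_CATEGORIES,
        setdiff(names(d), c("id", need, PREY_CATEGORIES))), drop = FALSE]
}

#' Read a stomach-content table from CSV
#'
#' As [read_isotope_table()] but against the diet schema: grouping factors
#' plus the ten prey-weight columns, validated by [validate_diet_table()].
#'
#' @inheritParams read_isotope_table
#' @param ... Passed to [validate_diet_table()].
#' @return Validated diet data frame.
#' @export
read_diet_table <- function(path, column_map = NULL, ...) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  cols <- .resolve_columns(names(raw),
                           required = c("species", "sex", "stage", "season"),
                           optional = c("id", "month"), column_map = column_map)
  prey_found <- stats::setNames(rep(NA_character_, 10L), PREY_CATEGORIES)
  norm_head <- .norm_label(names(raw))
  for (pc in PREY_CATEGORIES) {
    if (!is.null(column_map) && pc %in% names(column_map)) {
      prey_found[pc] <- column_map[[pc]]
      next
    }
    cand <- .norm_label(c(pc, sub("s$", "", pc), gsub("_", " ", pc)))
    hit <- which(norm_head %in% cand)
    if (length(hit)) prey_found[pc] <- names(raw)[hit[1L]]
  }
  if (anyNA(prey_found)) {
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(names(prey_found)[is.na(prey_found)], collapse = ", ")),
         call. = FALSE)
  }
  d <- raw
  keep <- !is.na(cols)
  names(d)[match(cols[keep], names(d))] <- names(cols)[keep]
  names(d)[match(prey_found, names(d))] <- names(prey_found)
  validate_diet_table(d, ...)
}

#' Write an isotope or diet table to CSV
#'
#' Plain UTF-8 comma-separated output with a header row, the exact inverse
#' of the corresponding reader: writing then reading reproduces the table.
#'
#' @param d A validated table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_isotope_table <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_isotope_table
#' @export
write_diet_table <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
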