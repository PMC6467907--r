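#' Parse a trait quantity cell
#'
#' Trait tables compiled from heterogeneous sources routinely report ranges
#' ("2-6") or several source values ("100|200|300") for a single species.
#' Following the compilation convention that mean quantity and quality are
#' used when sources differ or ranges are given, this parser returns:
#'
#' * a plain number unchanged (`"120"` -> 120); thousands separators are
#'   accepted (`"1,000,000"` -> 1e6);
#' * the midpoint of a range written with a hyphen or en-dash
#'   (`"2-6"` -> 4);
#' * the arithmetic mean of `|`-separated values (`"100|200|300"` -> 200).
#'   Each component may itself be a range.
#'
#' @param cell Character (or numeric) vector of raw cells.
#' @return Numeric vector; errors name the offending value.
#' @examples
#' parse_quantity(c("2-6", "120", "100|200|300"))
#' @export
parse_quantity <- function(cell) {
  if (is.numeric(cell)) {
    if (any(cell < 0, na.rm = TRUE)) {
      stop("negative trait value: ", min(cell), call. = FALSE)
    }
    return(as.numeric(cell))
  }
  vapply(as.character(cell), parse_quantity_one, numeric(1), USE.NAMES = FALSE)
}

parse_quantity_one <- function(txt) {
  if (is.na(txt)) return(NA_real_)
  raw <- txt
  txt <- trimws(txt)
  if (txt == "") return(NA_real_)
  parts <- trimws(strsplit(txt, "|", fixed = TRUE)[[1]])
  vals <- vapply(parts, function(p) {
    p <- gsub(",", "", p)                # thousands separators
    p <- gsub("–", "-", p)          # en-dash ranges
    direct <- suppressWarnings(as.numeric(p))
    if (!is.na(direct)) {                # plain number (incl. 1e-05 etc.)
      if (direct < 0) stop("negative trait value: '", raw, "'", call. = FALSE)
      return(direct)
    }
    if (grepl("^[^-]+-[^-]+$", p)) {     # range a-b (no sign support needed)
      ends <- suppressWarnings(as.numeric(trimws(strsplit(p, "-")[[1]])))
      if (length(ends) != 2 || any(is.na(ends))) {
        stop("cannot parse trait value: '", raw, "'", call. = FALSE)
      }
      if (any(ends < 0) || ends[1] > ends[2]) {
        stop("invalid range (need 0 <= a <= b): '", raw, "'", call. = FALSE)
      }
      mean(ends)
    } else {
      v <- suppressWarnings(as.numeric(p))
      if (is.na(v)) stop("cannot parse trait value: '", raw, "'",
                         call. = FALSE)
      if (v < 0) stop("negative trait value: '", raw, "'", call. = FALSE)
      v
    }
  }, numeric(1))
  mean(vals)
}

# Semicolon-separated per-offspring masses -> numeric vector (NULL if blank).
parse_brood_masses <- function(txt) {
  if (is.null(txt) || is.na(txt) || trimws(txt) == "") return(NULL)
  vals <- suppressWarnings(as.numeric(trimws(strsplit(txt, ";")[[1]])))
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("cannot parse brood_masses: '", txt,
         "' (need semicolon-separated non-negative numbers)", call. = FALSE)
  }
  vals
}

required_species_cols <- c("species", "taxon_group", "n_offspring",
                           "offspring_mass", "breeder_mass")

#' Read and validate a species-trait table
#'
#' Reads a delimited species table (comma by default, tab via `delimiter`)
#' with header columns `species`, `taxon_group`, `n_offspring`,
#' `offspring_mass`, `breeder_mass`, and optionally `brood_masses`
#' (semicolon-separated per-offspring masses) and `source`. Quantity and mass
#' cells may contain ranges or `|`-separated multi-source values; they are
#' reduced to means by [parse_quantity()].
#'
#' Rows that fail validation (non-positive breeder mass or offspring
#' quantity, negative offspring mass, unparseable cells, fewer than two
#' brood masses) are skipped, not fatal: each skipped row is itemised in the
#' issue report attached as the `issues` attribute (a tibble with `row`,
#' `species`, `problem`), and a summary of read/kept/skipped counts is
#' emitted as a message. A missing file or missing required columns is fatal.
#'
#' @param path Path to the delimited file (UTF-8).
#' @param delimiter Field delimiter, `","` (default) or `"\t"`.
#' @return A tibble of validated species records, with `brood_masses` as a
#'   list-column of numeric vectors (`NULL` where absent); the issue report
#'   is in `attr(x, "issues")` (see [read_issues()]).
#' @examples
#' path <- system.file("extdata", "example_species.csv", package = "matrisk")
#' spp <- read_species_table(path)
#' read_issues(spp)
#' @export
read_species_table <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("species table not found: ", path,
                               call. = FALSE)
  raw <- readr::read_delim(path, delim = delimiter, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  missing_cols <- setdiff(required_species_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("species table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  issues <- list()
  records <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    rec <- tryCatch(validate_species_row(row), error = function(e) e)
    if (inherits(rec, "error")) {
      sp_name <- if (is.na(row$species)) "<unnamed>" else row$species
      issues[[length(issues) + 1]] <- tibble::tibble(
        row = i,
        species = sp_name,
        problem = conditionMessage(rec)
      )
    } else {
      records[[i]] <- rec
    }
  }
  kept <- dplyr::bind_rows(records)
  issues <- if (length(issues) > 0) dplyr::bind_rows(issues) else
    tibble::tibble(row = integer(), species = character(),
                   problem = character())
  message(sprintf("read %d row(s): kept %d, skipped %d",
                  nrow(raw), nrow(kept), nrow(issues)))
  for (j in seq_len(nrow(issues))) {
    message(sprintf("  row %d (%s): %s", issues$row[j], issues$species[j],
                    issues$problem[j]))
  }
  attr(kept, "issues") <- issues
  kept
}

validate_species_row <- function(row) {
  n <- parse_quantity(row$n_offspring)
  m <- parse_quantity(row$offspring_mass)
  big_m <- parse_quantity(row$breeder_mass)
  if (is.na(n) || n <= 0) stop("non-positive or missing offspring quantity",
                               call. = FALSE)
  if (is.na(m) || m < 0) stop("negative or missing offspring mass",
                              call. = FALSE)
  if (is.na(big_m) || big_m <= 0) stop("non-positive breeder mass",
                                       call. = FALSE)
  bm <- if ("brood_masses" %in% names(row)) {
    parse_brood_masses(row$brood_masses)
  } else NULL
  if (!is.null(bm) && length(bm) < 2) {
    stop("brood_masses needs at least 2 entries", call. = FALSE)
  }
  tibble::tibble(
    species = row$species,
    taxon_group = row$taxon_group,
    n_offspring = n,
    offspring_mass = m,
    breeder_mass = big_m,
    brood_masses = list(bm),
    source = if ("source" %in% names(row)) row$source else NA_character_
  )
}

#' Issue report from a species-table read
#'
#' @param x A tibble returned by [read_species_table()].
#' @return The issue tibble (`row`, `species`, `problem`), zero rows if all
#'   input rows validated.
#' @export
read_issues <- function(x) {
  issues <- attr(x, "issues")
  if (is.null(issues)) {
    tibble::tibble(row = integer(), species = character(),
                   problem = character())
  } else {
    issues
  }
}

#' Write classification results to a delimited file
#'
#' Writes the output schema: the input columns plus `S`, `P`, `C`, `G`,
#' `category`, `effective_n`, `singleton_rule_applied`. `brood_masses`
#' list-columns are rendered back to semicolon-separated text; an absent `G`
#' is an empty cell, never `0`. Numbers are written at full precision so the
#' table round-trips through [read_species_table()] without changing any
#' category assignment.
#'
#' @param results A data frame, typically from [classify_species()].
#' @param path Output file path.
#' @param delimiter Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, delimiter = ",") {
  if (!is.data.frame(results)) stop("`results` must be a data frame",
                                    call. = FALSE)
  out <- tibble::as_tibble(results)
  if ("brood_masses" %in% names(out) && is.list(out$brood_masses)) {
    out$brood_masses <- purrr::map_chr(out$brood_masses, function(m) {
      if (is.null(m)) NA_character_ else
        paste(format(m, digits = 17, trim = TRUE, scientific = FALSE),
              collapse = ";")
    })
  }
  if ("category" %in% names(out)) out$category <- as.character(out$category)
  ok <- tryCatch({
    readr::write_delim(out, path, delim = delimiter, na = "")
    TRUE
  }, error = function(e) e)
  if (inherits(ok, "error")) {
    stop("cannot write results to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}
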