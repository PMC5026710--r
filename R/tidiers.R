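#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a residue propensity table
#'
#' @param x A `propensity_table` from [residue_propensities()].
#' @param ... Unused.
#' @return The table as a plain tibble (one row per residue).
#' @method tidy propensity_table
#' @export
tidy.propensity_table <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "propensity_table")
  out
}

#' @rdname tidy.propensity_table
#' @method glance propensity_table
#' @export
glance.propensity_table <- function(x, ...) {
  tibble(
    group = attr(x, "group") %||% NA_character_,
    n_residues = attr(x, "n_residues") %||% NA_integer_,
    n_enriched = sum(x$shade != "none", na.rm = TRUE),
    max_propensity = max(x$propensity, na.rm = TRUE),
    top_residue = x$residue[which.max(x$propensity)])
}

#' Tidy a dyad propensity matrix into long form
#'
#' @param x A `dyad_propensity` from [dyad_propensities()].
#' @param ... Unused.
#' @return A tibble with one row per cell: `n_side`, `c_side`, `count`,
#'   `observed`, `expected`, `propensity`, `shade`.
#' @method tidy dyad_propensity
#' @export
tidy.dyad_propensity <- function(x, ...) {
  grid <- expand.grid(n_side = aa_standard(), c_side = aa_standard(),
                      stringsAsFactors = FALSE)
  tibble(
    n_side = grid$n_side, c_side = grid$c_side,
    count = as.integer(x$counts[cbind(grid$n_side, grid$c_side)]),
    observed = x$observed[cbind(grid$n_side, grid$c_side)],
    expected = x$expected[cbind(grid$n_side, grid$c_side)],
    propensity = x$propensity[cbind(grid$n_side, grid$c_side)],
    shade = x$shade[cbind(grid$n_side, grid$c_side)])
}

#' @rdname tidy.dyad_propensity
#' @method glance dyad_propensity
#' @export
glance.dyad_propensity <- function(x, ...) {
  tibble(
    model = x$model, n_dyads = x$n_total,
    n_verylight = sum(x$shade == "verylight", na.rm = TRUE),
    n_light = sum(x$shade == "light", na.rm = TRUE),
    n_dark = sum(x$shade == "dark", na.rm = TRUE),
    max_propensity = suppressWarnings(max(x$propensity, na.rm = TRUE)))
}

#' Tidy a scale profile
#'
#' @param x A `scale_profile` from [profile_groups()].
#' @param ... Unused.
#' @return The per-member AI values as a tibble.
#' @method tidy scale_profile
#' @export
tidy.scale_profile <- function(x, ...) as_tibble(x$values)

#' @rdname tidy.scale_profile
#' @method glance scale_profile
#' @export
glance.scale_profile <- function(x, ...) as_tibble(x$summaries)
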