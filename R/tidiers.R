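# broom-style tidiers for the package's fitted objects.

#' Tidy a Guinier fit
#'
#' @param x A `guinier_fit`.
#' @param ... Unused.
#' @return One-row tibble with `I0`, `Rg`, `q_max_used`, `n_points`,
#'   `r_squared`.
#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble::tibble(I0 = x$I0, Rg = x$Rg, q_max_used = x$q_max_used,
                 n_points = x$n_points, r_squared = x$r_squared)
}

#' @rdname tidy.guinier_fit
#' @export
glance.guinier_fit <- function(x, ...) tidy.guinier_fit(x, ...)

#' Tidy a chi fit: per-point residuals
#'
#' @param x A `saxs_fit` from [chi_fit()].
#' @param ... Unused.
#' @return Tibble of `q`, `residual` with the model label attached.
#' @export
tidy.saxs_fit <- function(x, ...) {
  out <- x$residuals
  out$model_label <- x$model_label
  out
}

#' One-row summary of a chi fit
#'
#' @param x A `saxs_fit`.
#' @param ... Unused.
#' @return Tibble with `model_label`, `scale`, `chi`, `n`.
#' @export
glance.saxs_fit <- function(x, ...) {
  tibble::tibble(model_label = x$model_label, scale = x$scale, chi = x$chi,
                 n = x$n)
}

#' Tidy an oligomeric-state call: one row per candidate
#'
#' @param x An `oligomer_call` from [classify_oligomer()].
#' @param ... Unused.
#' @return Tibble with `model_label`, `chi`, `scale`, `best`.
#' @export
tidy.oligomer_call <- function(x, ...) {
  tibble::tibble(
    model_label = names(x$chis),
    chi = unname(x$chis),
    scale = vapply(x$fits, `[[`, numeric(1), "scale"),
    best = names(x$chis) == x$best_model
  )
}

#' One-row summary of an oligomeric-state call
#'
#' @param x An `oligomer_call`.
#' @param ... Unused.
#' @return Tibble with `best_model`, `best_chi`, `subunit_count`,
#'   `mass_consistent`.
#' @export
glance.oligomer_call <- function(x, ...) {
  tibble::tibble(best_model = x$best_model,
                 best_chi = unname(min(x$chis)),
                 subunit_count = x$subunit_count,
                 mass_consistent = x$mass_consistent)
}

#' Tidy a design screen: the candidate table
#'
#' @param x A `design_screen` from [run_screen()].
#' @param ... Unused.
#' @return The candidates tibble.
#' @export
tidy.design_screen <- function(x, ...) x$candidates

#' One-row summary of a design screen
#'
#' @param x A `design_screen`.
#' @param ... Unused.
#' @return Tibble with `n_candidates`, `n_sites`, `selected_id`,
#'   `selected_mutations`, `selected_hbonds`, `seed`.
#' @export
glance.design_screen <- function(x, ...) {
  sel <- x$candidates[x$candidates$id == x$selected, ]
  tibble::tibble(n_candidates = nrow(x$candidates), n_sites = nrow(x$sites),
                 selected_id = x$selected,
                 selected_mutations = x$selected_mutations,
                 selected_hbonds = sel$hbonds, seed = x$seed)
}
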