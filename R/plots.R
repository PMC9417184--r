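# ggplot2 autoplot methods for the package's result types.

#' Plot a SAXS profile
#'
#' Log-intensity versus q, the conventional presentation of a scattering
#' curve.
#'
#' @param object A [saxs_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saxs_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(q, intensity)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q) (log scale)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot a chi fit's residuals
#'
#' @param object A `saxs_fit` from [chi_fit()].
#' @param ... Unused.
#' @return A ggplot of `(I_exp - c I_model)/sigma` versus q.
#' @export
autoplot.saxs_fit <- function(object, ...) {
  ggplot2::ggplot(object$residuals, ggplot2::aes(q, residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)),
                  y = "scaled residual",
                  title = sprintf("%s: chi = %.3g", object$model_label,
                                  object$chi)) +
    ggplot2::theme_minimal()
}

#' Plot the chi values of an oligomeric-state call
#'
#' @param object An `oligomer_call` from [classify_oligomer()].
#' @param ... Unused.
#' @return A ggplot bar chart of chi per candidate model.
#' @export
autoplot.oligomer_call <- function(object, ...) {
  tb <- tidy.oligomer_call(object)
  ggplot2::ggplot(tb, ggplot2::aes(model_label, chi, fill = best)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70")) +
    ggplot2::labs(x = "candidate model", y = expression(chi)) +
    ggplot2::theme_minimal()
}

#' Plot a design screen: score versus mutation count
#'
#' Finalists are highlighted; the selected candidate is labelled.
#'
#' @param object A `design_screen` from [run_screen()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.design_screen <- function(object, ...) {
  tb <- object$candidates
  sel <- tb[tb$id == object$selected, ]
  ggplot2::ggplot(tb, ggplot2::aes(n_mutations, best_score)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 0.8,
                         colour = "grey60") +
    ggplot2::geom_point(data = tb[tb$is_finalist, ],
                        ggplot2::aes(colour = hbonds), size = 2) +
    ggplot2::geom_point(data = sel, shape = 1, size = 4, stroke = 1.1) +
    ggplot2::labs(x = "mutations in candidate", y = "best surrogate score",
                  colour = "interface\nH-bonds") +
    ggplot2::theme_minimal()
}
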