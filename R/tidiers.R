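# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a confusion matrix into one row per cell
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Tibble: `solution` (row index, for ambiguous solver output),
#'   `cell`, `count`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  as_tibble(x) %>%
    mutate(solution = row_number(), .before = 1) %>%
    tidyr::pivot_longer(c("tp", "fn", "fp", "tn"),
                        names_to = "cell", values_to = "count") %>%
    select("solution", "cell", "count")
}

#' One-row concordance summary of a confusion matrix
#'
#' @param x A `confusion_matrix` (single solution).
#' @param ... Unused.
#' @return The [concordance_metrics()] row.
#' @export
glance.confusion_matrix <- function(x, ...) {
  if (nrow(x) > 1L) {
    abort_invalid("glance() needs a single confusion matrix; got several solutions.")
  }
  concordance_metrics(x)
}

#' Tidy a clinical table's tests
#'
#' @param x A `clinical_table`.
#' @param ... Unused.
#' @return The per-characteristic test tibble.
#' @export
tidy.clinical_table <- function(x, ...) x$tests

#' Group-level age summary of a clinical table
#'
#' @param x A `clinical_table`.
#' @param ... Unused.
#' @return Per-group median age and range.
#' @export
glance.clinical_table <- function(x, ...) x$age
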