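# Activity bookkeeping: potency conversion, censoring, classification
# bands, the screening rule and the pharmacological distribution diagram.

#' Convert IC50 to pIC50
#'
#' `pIC50 = -log10(IC50)` with IC50 expressed in molar units. The assay
#' values in this series are reported in units of M/1e5, so an IC50 of 1
#' maps to pIC50 = 5. A right-censored IC50 (`"> x"`) yields a pIC50 that
#' is an upper bound (`"< -log10(x)"`); the companion
#' `censored` flag is simply carried through.
#'
#' @param ic50 Positive numeric IC50 values in M/1e5 units.
#' @return Numeric pIC50 values (upper bounds where the input was a lower
#'   bound).
#' @export
#' @examples
#' pic50_from_ic50(c(1, 0.3))  # 5.000, 5.523
pic50_from_ic50 <- function(ic50) {
  if (any(!is.finite(ic50) | ic50 <= 0)) {
    stop("IC50 values must be positive", call. = FALSE)
  }
  -log10(ic50 * 1e-5)
}

#' Parse possibly right-censored IC50 strings
#'
#' Turns strings such as `"0.3"` or `">20"` into a value/censoring pair.
#'
#' @param x Character vector.
#' @return A tibble with columns `ic50` (numeric) and `ic50_censored`
#'   (`TRUE` when the measurement is a lower bound, i.e. "greater than").
#' @export
parse_ic50 <- function(x) {
  x <- trimws(as.character(x))
  censored <- startsWith(x, ">")
  value <- suppressWarnings(as.numeric(sub("^>", "", x)))
  if (anyNA(value)) {
    stop("unparseable IC50 value(s): ",
         paste(x[is.na(value)], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(ic50 = value, ic50_censored = censored)
}

#' Classify a discriminant-function value
#'
#' The activity bands of the discriminant model: scores of 0 or below are
#' inactive (`I`), scores of 1 or above active (`A`), and the open
#' interval between them is non-classified (`NC`).
#'
#' @param df Numeric discriminant scores.
#' @return A character vector over `{"A", "I", "NC"}`.
#' @export
#' @examples
#' classify_df(c(-2.4, 0.02, 3.7))
classify_df <- function(df) {
  dplyr::case_when(
    df <= 0 ~ "I",
    df < 1 ~ "NC",
    .default = "A"
  )
}

#' Activity and inactivity expectancy
#'
#' The expectancies of a pharmacological distribution diagram bin:
#' `Ea = a / (i + 1)` and `Ei = i / (a + 1)`, where `a` and `i` are the
#' fractions of all active and inactive compounds that fall in the bin.
#'
#' @param a,i Fractions in `[0, 1]`.
#' @return A tibble with columns `Ea` and `Ei`.
#' @export
#' @examples
#' expectancy(0.5, 0.25)
expectancy <- function(a, i) {
  stopifnot(all(a >= 0 & a <= 1), all(i >= 0 & i <= 1))
  tibble::tibble(Ea = a / (i + 1), Ei = i / (a + 1))
}

#' Pharmacological distribution diagram
#'
#' Histogram of activity expectancy along the discriminant-function axis:
#' half-open bins `[lo, lo + width)` covering the score range, and per bin
#' the fractions `a` and `i` of all active/inactive compounds it holds and
#' the expectancies `Ea`, `Ei` (see [expectancy()]). The diagram shows
#' where actives concentrate with little inactive overlap, which is how
#' the screening window on the discriminant score is chosen.
#'
#' @param data A data frame of scored compounds.
#' @param df Column with discriminant scores (tidy-eval; default `df`).
#' @param class Column with experimental classes, `"A"`/`"I"` (default
#'   `class_exp`).
#' @param bin_width Bin width on the score axis (default 1).
#' @return A tibble of class `topoqsar_pdd` with columns `bin_lo`,
#'   `bin_hi`, `n_active`, `n_inactive`, `a`, `i`, `Ea`, `Ei`. Has an
#'   [ggplot2::autoplot()] method.
#' @export
build_pdd <- function(data, df = df, class = class_exp, bin_width = 1) {
  stopifnot(bin_width > 0)
  scores <- dplyr::pull(data, {{ df }})
  cls <- as.character(dplyr::pull(data, {{ class }}))
  if (!length(scores)) stop("no compounds to bin", call. = FALSE)
  if (!any(cls == "A") || !any(cls == "I")) {
    stop("need at least one active and one inactive compound",
         call. = FALSE)
  }
  lo <- floor(min(scores) / bin_width) * bin_width
  edges <- seq(lo, max(scores) + bin_width, by = bin_width)
  idx <- findInterval(scores, edges)  # half-open [edge, edge + width)
  n_a_tot <- sum(cls == "A")
  n_i_tot <- sum(cls == "I")
  out <- tibble::tibble(
    bin_lo = edges[seq_len(length(edges) - 1)],
    bin_hi = edges[seq_len(length(edges) - 1)] + bin_width
  )
  out$n_active <- vapply(seq_len(nrow(out)),
                         function(b) sum(idx == b & cls == "A"), integer(1))
  out$n_inactive <- vapply(seq_len(nrow(out)),
                           function(b) sum(idx == b & cls == "I"),
                           integer(1))
  out$a <- out$n_active / n_a_tot
  out$i <- out$n_inactive / n_i_tot
  e <- expectancy(out$a, out$i)
  out$Ea <- e$Ea
  out$Ei <- e$Ei
  structure(out, class = c("topoqsar_pdd", base::class(out)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pharmacological distribution diagram
#'
#' Expectancy of activity (filled bars) and of inactivity (open bars)
#' against the discriminant score.
#'
#' @param object A [build_pdd()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.topoqsar_pdd <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("bin_lo", "bin_hi", "Ea", "Ei")],
    cols = c("Ea", "Ei"), names_to = "which", values_to = "expectancy"
  )
  long$mid <- (long$bin_lo + long$bin_hi) / 2
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$mid, y = .data$expectancy,
                               fill = .data$which)) +
    ggplot2::geom_col(position = "dodge", colour = "black", width = 0.9 *
                        (object$bin_hi[1] - object$bin_lo[1])) +
    ggplot2::scale_fill_manual(values = c(Ea = "black", Ei = "white"),
                               labels = c(Ea = "active", Ei = "inactive"),
                               name = NULL) +
    ggplot2::labs(x = "discriminant function",
                  y = "expectancy") +
    ggplot2::theme_minimal()
}

#' Apply the antileukemic screening rule
#'
#' A compound is a screening candidate when its discriminant score lies in
#' the open window (1, 5) and its regression-predicted pIC50 exceeds 9.
#' Both conditions are strict inequalities; every candidate is therefore
#' also classified active by [classify_df()].
#'
#' @param df Numeric discriminant scores.
#' @param pic50_pred Numeric predicted pIC50 values.
#' @return A tibble with columns `df`, `pred_class`, `pic50_pred`,
#'   `candidate`.
#' @export
#' @examples
#' screen(c(2, 3.9, 6), c(9.5, 8.6, 9.5))
screen <- function(df, pic50_pred) {
  stopifnot(length(df) == length(pic50_pred))
  tibble::tibble(
    df = df,
    pred_class = classify_df(df),
    pic50_pred = pic50_pred,
    candidate = df > 1 & df < 5 & pic50_pred > 9
  )
}
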