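#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a group factor analysis fit
#'
#' One row per variable per factor with the posterior-mean loading, block
#' membership, and the factor's variance-explained share.
#'
#' @param x a `pub_gfa` fit.
#' @param retained_only keep only retained factors (default `TRUE`).
#' @param ... unused.
#' @return tibble: block, variable, factor, loading, ve, retained.
#' @exportS3Method generics::tidy
tidy.pub_gfa <- function(x, retained_only = TRUE, ...) {
  out <- purrr::map_dfr(seq_along(x$W), function(m) {
    W <- x$W[[m]]
    vn <- x$var_names[[m]] %||% paste0("v", seq_len(nrow(W)))
    purrr::map_dfr(seq_len(x$K), function(k) {
      tibble::tibble(block = x$block_names[m], variable = vn,
                     factor = k, loading = W[, k], ve = x$ve[k],
                     retained = k %in% x$retained)
    })
  })
  if (retained_only) out <- dplyr::filter(out, .data$retained)
  out
}

#' Glance at a group factor analysis fit
#'
#' @param x a `pub_gfa` fit.
#' @param ... unused.
#' @return one-row tibble: n, n_blocks, k_init, n_retained, total_ve
#'   (retained factors), ll_mean.
#' @exportS3Method generics::glance
glance.pub_gfa <- function(x, ...) {
  tibble::tibble(
    n = x$N, n_blocks = length(x$W), k_init = x$K,
    n_retained = length(x$retained),
    total_ve = sum(x$ve[x$retained]),
    ll_mean = mean(x$ll_trace)
  )
}

#' Plot retained factor loadings of a fit
#'
#' Bar panels of posterior-mean loadings per retained factor, coloured by
#' block, in the style of published latent-factor loading figures.
#'
#' @param object a `pub_gfa` fit.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pub_gfa <- function(object, ...) {
  td <- tidy(object)
  td$variable <- factor(td$variable, levels = unique(td$variable))
  lab <- paste0("LF", seq_along(object$retained), " (",
                sprintf("%.1f%%", 100 * object$ve[object$retained]), ")")
  td$panel <- factor(lab[match(td$factor, object$retained)], levels = lab)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$variable, y = .data$loading,
                                   fill = .data$block)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "posterior-mean loading") +
    ggplot2::theme_minimal()
}

#' Plot latent synchrony profiles
#'
#' Scatter of LF1 (hormone-led) against LF2 (physical-led) scores coloured
#' by synchrony quadrant.
#'
#' @param object a `pub_profiles` table.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pub_profiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lf1, y = .data$lf2,
                                       colour = .data$synchrony)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "LF1 score (hormone-led)",
                  y = "LF2 score (physical-led)") +
    ggplot2::theme_minimal()
}

#' Plot a caregiver-youth agreement report
#'
#' Dot-and-interval display of weighted kappa (with CI) and polychoric rho
#' per measure and sex.
#'
#' @param report output of [agreement_report()].
#' @return a ggplot object.
#' @export
plot_agreement <- function(report) {
  long <- dplyr::bind_rows(
    dplyr::transmute(report, .data$sex, .data$measure, stat = "kappa",
                     est = .data$kappa, lo = .data$kappa_low,
                     hi = .data$kappa_high),
    dplyr::transmute(report, .data$sex, .data$measure, stat = "rho",
                     est = .data$rho, lo = .data$rho - 1.96 * .data$rho_se,
                     hi = .data$rho + 1.96 * .data$rho_se)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$est, y = .data$measure,
                                     colour = .data$stat)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2,
                            position = ggplot2::position_dodge(0.5)) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "agreement", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
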